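test_that("median locus depth treats uncovered positions as zero", {
  cov <- tibble::tibble(contig = "c1", pos = c(2L, 3L), depth = c(40, 40))
  expect_equal(locus_median_depth(cov, "c1", 0, 4), 20) # depths 0,0,40,40
  expect_equal(locus_median_depth(cov[0, ], "c1", 0, 4), 0)
})

test_that("intergenic hits cluster by gap and genic hits group per gene", {
  w <- cached_world()
  blocks1 <- list(tibble::tibble(start = 100, end = 127))
  blocks2 <- list(tibble::tibble(start = 227, end = 254)) # 100 nt gap
  blocks3 <- list(tibble::tibble(start = 10254, end = 10281)) # 10 kb away
  hits <- tibble::tibble(
    peptide = c("AAAAAAAAK", "CCCCCCCCK", "DDDDDDDDK"),
    contig = "contig_1", strand = "+", frame = 0L,
    blocks = c(blocks1, blocks2, blocks3),
    gene_id = NA_character_, n_loci = 1L, is_unique = TRUE,
    novelty = "novel_intergenic")
  cov <- tibble::tibble(contig = character(), pos = integer(), depth = numeric())
  # use an annotation-free world region: empty annotation keeps them intergenic
  bundles <- bundle_evidence(hits, w$annotation[0, ], cov, max_gap = 500)
  expect_equal(nrow(bundles), 2)
  expect_equal(sort(bundles$n_novel), c(1L, 2L))
})

test_that("the novel-gene rules reproduce an exhaustive truth table", {
  # brute-force evaluation of the published rules over all combinations
  grid <- expand.grid(n = 0:3, cov = c(TRUE, FALSE), hom = c(TRUE, FALSE))
  for (i in seq_len(nrow(grid))) {
    n <- grid$n[i]; cov <- grid$cov[i]; hom <- grid$hom[i]
    bundle <- tibble::tibble(
      locus_id = "x", contig = "c", start = 0L, end = 100L,
      is_intergenic = TRUE, gene_id = NA_character_,
      novel_peptides = list(character(n)),
      n_novel = n, n_novel_good = n, n_novel_classI = n, n_known = 0L,
      rnaseq_sufficient = cov, homology_support = hom,
      spans_junction = FALSE, upstream_of_tis = FALSE,
      downstream_of_stop = FALSE, out_of_frame_in_cds = FALSE,
      spans_two_genes = FALSE, splits_gene = FALSE, has_two_variants = FALSE)
    call <- decide_refinement(bundle)
    expected <- if (n >= 2 && cov) "classI"
      else if (n == 1 && cov) "classII"
      else if (n >= 2 && !cov && hom) "classII"
      else "rejected"
    expect_equal(call$confidence, expected,
                 info = sprintf("n=%d cov=%s hom=%s", n, cov, hom))
    expect_equal(call$accepted, expected != "rejected")
    expect_equal(call$type, "novel")
  }
})

test_that("the class-I gate requires long unmodified peptides", {
  base <- tibble::tibble(
    locus_id = "x", contig = "c", start = 0L, end = 100L,
    is_intergenic = TRUE, gene_id = NA_character_,
    novel_peptides = list(c("SHORTK", "ALSOSHORT")),
    n_novel = 2L, n_novel_good = 2L, n_novel_classI = 0L, n_known = 0L,
    rnaseq_sufficient = TRUE, homology_support = FALSE,
    spans_junction = FALSE, upstream_of_tis = FALSE, downstream_of_stop = FALSE,
    out_of_frame_in_cds = FALSE, spans_two_genes = FALSE, splits_gene = FALSE,
    has_two_variants = FALSE)
  # two peptides but none >8 aa: cannot be class I
  expect_false(decide_refinement(base)$confidence == "classI")
})

test_that("gene-linked refinements follow the two-route evidence rule", {
  mk <- function(n_novel, n_known, junction = TRUE, frameshift = FALSE) {
    tibble::tibble(
      locus_id = "g1", contig = "c", start = 0L, end = 100L,
      is_intergenic = FALSE, gene_id = "g1",
      novel_peptides = list(character(n_novel)),
      n_novel = n_novel, n_novel_good = n_novel, n_novel_classI = n_novel,
      n_known = n_known, rnaseq_sufficient = TRUE, homology_support = FALSE,
      spans_junction = junction, upstream_of_tis = FALSE,
      downstream_of_stop = FALSE, out_of_frame_in_cds = frameshift,
      spans_two_genes = FALSE, splits_gene = FALSE, has_two_variants = FALSE)
  }
  # one novel junction peptide + known peptides: splice-site call via route B
  c1 <- decide_refinement(mk(1, 2))
  expect_true(c1$accepted)
  expect_equal(c1$type, "splice_site")
  # one novel peptide alone is not enough
  expect_false(decide_refinement(mk(1, 0))$accepted)
  # two novel peptides suffice regardless of known support (route A)
  expect_true(decide_refinement(mk(2, 0))$accepted)
  # route B does not apply to frameshifts
  expect_false(decide_refinement(mk(1, 1, junction = FALSE, frameshift = TRUE))$accepted)
  # geometry precedence: junction beats frameshift
  expect_equal(decide_refinement(mk(2, 0, junction = TRUE, frameshift = TRUE))$type,
               "splice_site")
})

test_that("the rule engine is a pure function of the bundle", {
  sc <- synth_refinement_scenarios()
  expect_identical(decide_refinement(sc$bundles), decide_refinement(sc$bundles))
})

test_that("planted refinement scenarios reproduce their category counts exactly", {
  sc <- synth_refinement_scenarios()
  calls <- decide_refinement(sc$bundles)
  got <- table(calls$type[calls$accepted])
  exp_named <- sc$expected
  for (type in c("splice_site", "TIS", "extension", "frameshift", "fusion")) {
    expect_equal(unname(got[[type]]), exp_named$n[exp_named$type == type])
  }
  novel <- calls[calls$type == "novel", ]
  expect_equal(sum(novel$confidence == "classI"),
               exp_named$n[exp_named$type == "novel_classI"])
  expect_equal(sum(novel$confidence == "classII"),
               exp_named$n[exp_named$type == "novel_classII"])
  expect_equal(sum(novel$confidence == "rejected"),
               exp_named$n[exp_named$type == "novel_rejected"])
  smry <- summarize_refinements(calls)
  expect_equal(smry$n[smry$type == "splice_site"],
               exp_named$n[exp_named$type == "splice_site"])
  expect_equal(sum(summarize_refinements(calls[0, ])$n), 0)
})

test_that("applied refinements keep gene models valid and log changes", {
  w <- cached_world()
  # TIS shift 60 nt upstream on a plus-strand gene with room
  plus <- w$annotation[w$annotation$strand == "+", ]
  ok <- which(vapply(seq_len(nrow(plus)), function(i) {
    ex <- plus$exons[[i]]
    s <- min(ex$start)
    s > 70 && substring(w$genome[[plus$contig[i]]], s - 59, s - 59 + 2) != "TAA"
  }, logical(1)))
  g <- NULL
  for (i in ok) {
    ex <- plus$exons[[i]]
    s <- min(ex$start)
    up <- substring(w$genome[[plus$contig[i]]], s - 59, s)
    cand <- plus[i, ]
    cand$exons[[1]]$start[1] <- s - 60
    valid <- tryCatch({
      validate_annotation(cand, w$genome); TRUE
    }, error = function(e) FALSE)
    if (valid) { g <- plus[i, ]; break }
  }
  skip_if(is.null(g), "no gene admits a clean 60 nt TIS shift in this world")
  call <- tibble::tibble(
    locus_id = g$gene_id, gene_id = g$gene_id, contig = g$contig,
    start = 0L, end = 0L, type = "TIS", confidence = NA_character_,
    accepted = TRUE, reason = NA_character_, peptides = list("X"),
    has_two_variants = FALSE, shift_nt = 60L)
  res <- apply_refinements(w$annotation, call, w$genome)
  new_ex <- res$annotation$exons[[match(g$gene_id, res$annotation$gene_id)]]
  expect_equal(min(new_ex$start), min(g$exons[[1]]$start) - 60)
  expect_equal(sum(new_ex$end - new_ex$start) %% 3, 0)
  expect_true(res$log$applied[1])
  # conflicting TIS calls: none applied, conflict reported
  call2 <- dplyr::bind_rows(call, dplyr::mutate(call, shift_nt = -30L))
  res2 <- apply_refinements(w$annotation, call2, w$genome)
  expect_equal(nrow(res2$conflicts), 2)
  expect_identical(res2$annotation$exons[[match(g$gene_id, res2$annotation$gene_id)]],
                   g$exons[[1]])
})

test_that("novel calls add genes that re-validate; bad coordinates are refused", {
  w <- cached_world()
  hidden <- w$truth$genes[!w$truth$genes$annotated, ][1, ]
  call <- tibble::tibble(
    locus_id = hidden$gene_id, gene_id = NA_character_, contig = hidden$contig,
    start = 0L, end = 0L, type = "novel", confidence = "classI",
    accepted = TRUE, reason = NA_character_, peptides = list("X"),
    has_two_variants = FALSE, new_exons = hidden$exons, new_strand = hidden$strand)
  res <- apply_refinements(w$annotation, call, w$genome)
  expect_equal(nrow(res$annotation), nrow(w$annotation) + 1)
  expect_true(res$log$applied[1])
  # invalid coordinates (not ending at a stop) are refused but logged
  bad <- call
  bad$new_exons[[1]] <- tibble::tibble(start = hidden$exons[[1]]$start[1] + 1L,
                                       end = hidden$exons[[1]]$start[1] + 10L)
  res_bad <- apply_refinements(w$annotation, bad, w$genome)
  expect_equal(nrow(res_bad$annotation), nrow(w$annotation))
  expect_false(res_bad$log$applied[1])
})
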