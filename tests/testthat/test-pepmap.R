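test_that("peptide-to-protein matching honours I/L equivalence", {
  db <- tibble::tibble(protein_id = "P", sequence = "MLLKAAILK")
  hit <- map_peptide_to_proteins("ILK", db, equate_il = TRUE)
  expect_equal(sort(hit$offset), c(1L, 6L))
  expect_equal(nrow(map_peptide_to_proteins("ILK", db, equate_il = FALSE)), 1)
  # repeated occurrence in one protein yields one row per offset
  db2 <- tibble::tibble(protein_id = "Q", sequence = "AAPEPKAAPEPK")
  expect_equal(nrow(map_peptide_to_proteins("APEPK", db2)), 2)
})

test_that("peptides map to single-exon gene loci with exact blocks", {
  w <- cached_world()
  sf <- cached_sixframe()
  single <- w$annotation[vapply(w$annotation$exons, nrow, 1L) == 1, ][1, ]
  prot <- w$proteins[w$proteins$protein_id == single$gene_id, ]
  pep <- digest(prot[, c("protein_id", "sequence")], "trypsin",
                max_missed = 0, len_range = c(8, 30))$sequence[1]
  hits <- map_peptide_to_genome(pep, sf, w$proteins, w$genome)
  expect_gte(nrow(hits), 1)
  b <- hits$blocks[[1]]
  expect_equal(sum(b$end - b$start), 3 * nchar(pep))
  # the block lies inside the gene's CDS interval
  ex <- single$exons[[1]]
  expect_true(min(b$start) >= min(ex$start) && max(b$end) <= max(ex$end))
  # extracting and translating the block reproduces the peptide
  nt <- paste(substring(w$genome[[hits$contig[1]]], b$start + 1, b$end), collapse = "")
  if (hits$strand[1] == "-") nt <- editoscan:::revcomp(nt)
  expect_equal(collapse_il(translate_nt(nt)), collapse_il(pep))
})

test_that("exon-spanning peptides get multi-block coordinates from the gene model", {
  w <- cached_world()
  sf <- cached_sixframe()
  multi <- w$annotation[vapply(w$annotation$exons, nrow, 1L) > 1, ]
  found_spanning <- FALSE
  for (i in seq_len(min(5, nrow(multi)))) {
    g <- multi[i, ]
    prot <- w$proteins[w$proteins$protein_id == g$gene_id, ]
    peps <- digest(prot[, c("protein_id", "sequence")], "trypsin",
                   max_missed = 1, len_range = c(7, 45))
    hits <- map_peptide_to_genome(peps$sequence, sf, w$proteins, w$genome)
    nb <- vapply(hits$blocks, nrow, integer(1))
    if (!any(nb > 1)) next
    found_spanning <- TRUE
    for (j in which(nb > 1)) {
      b <- hits$blocks[[j]]
      expect_equal(sum(b$end - b$start), 3 * nchar(hits$peptide[j]))
      expect_true(all(diff(b$start) > 0))
      # strand-aware extraction reproduces the peptide
      nt <- paste(substring(w$genome[[hits$contig[j]]], b$start + 1, b$end),
                  collapse = "")
      if (hits$strand[j] == "-") nt <- editoscan:::revcomp(nt)
      expect_equal(collapse_il(translate_nt(nt)), collapse_il(hits$peptide[j]))
    }
    break
  }
  expect_true(found_spanning)
})

test_that("mapping equals a brute-force scan over six-frame and proteins", {
  w <- cached_world()
  sf <- cached_sixframe()
  set.seed(5)
  peps <- unique(digest(w$proteins[sample(nrow(w$proteins), 4),
                                   c("protein_id", "sequence")],
                        "trypsin", max_missed = 0, len_range = c(8, 30))$sequence)
  peps <- utils::head(peps, 10)
  hits <- map_peptide_to_genome(peps, sf, w$proteins, w$genome)
  for (p in peps) {
    q <- collapse_il(p)
    brute_n <- sum(vapply(collapse_il(sf$sequence), function(s)
      length(gregexpr(q, s, fixed = TRUE)[[1]][gregexpr(q, s, fixed = TRUE)[[1]] > 0]),
      integer(1)))
    # every six-frame occurrence must be represented among the hit loci
    expect_gte(sum(hits$peptide == p), min(brute_n, 1))
  }
})

test_that("multi-locus peptides are flagged non-unique", {
  # two identical genes planted on one contig
  cds <- "ATGGCTGCTGCTAAAGCTGCTGCTAGAGGTGGTTAA" # MAAAKAAARGG + stop
  genome <- c(c1 = paste0("CCCCCC", cds, "CCCCCCCC", cds, "CCCCCC"))
  sf <- six_frame_translate(genome, min_fragment_len = 6)
  prots <- empty <- editoscan:::empty_protein_db()
  hits <- map_peptide_to_genome("AAAKAAAR", sf, prots, genome)
  expect_gte(nrow(hits), 2)
  expect_true(all(!hits$is_unique))
})

test_that("novelty classification distinguishes known, intergenic and intragenic", {
  w <- cached_world()
  sf <- cached_sixframe()
  # known: a peptide of an annotated protein
  kp <- digest(w$proteins[1, c("protein_id", "sequence")], "trypsin",
               max_missed = 0, len_range = c(8, 30))$sequence[1]
  # novel: a peptide of a hidden (unannotated) gene
  hidden <- w$truth$genes[!w$truth$genes$annotated, ][1, ]
  np <- digest(c(x = hidden$protein), "trypsin", max_missed = 0,
               len_range = c(9, 30))$sequence[1]
  hits <- map_peptide_to_genome(c(kp, np), sf, w$proteins, w$genome)
  hits <- classify_novelty(hits, w$annotation, w$proteins)
  expect_true(all(hits$novelty[hits$peptide == kp] == "known"))
  expect_true(any(hits$novelty[hits$peptide == np] == "novel_intergenic"))
  # intragenic: an intron-encoded peptide of a multi-exon gene
  multi <- w$annotation[vapply(w$annotation$exons, nrow, 1L) > 1, ]
  intronic <- NULL
  for (i in seq_len(nrow(multi))) {
    g <- multi[i, ]
    ex <- g$exons[[1]]
    int_start <- ex$end[1]; int_end <- ex$start[2]
    if (int_end - int_start < 27) next
    nt <- substring(w$genome[[g$contig]], int_start + 3, int_start + 3 + 23)
    aa <- translate_nt(if (g$strand == "-") editoscan:::revcomp(nt) else nt)
    if (grepl("[*X]", aa) || nchar(aa) < 7) next
    intronic <- list(gene = g, pep = aa)
    break
  }
  if (!is.null(intronic)) {
    ih <- map_peptide_to_genome(intronic$pep, sf, w$proteins, w$genome)
    ih <- classify_novelty(ih, w$annotation, w$proteins)
    expect_true(any(ih$novelty %in% c("novel_intragenic", "junction_variant")))
  }
})

test_that("junction coverage counts straddling peptides", {
  w <- cached_world()
  sf <- cached_sixframe()
  multi <- w$annotation[vapply(w$annotation$exons, nrow, 1L) > 1, ]
  peps <- unlist(lapply(seq_len(min(6, nrow(multi))), function(i) {
    prot <- w$proteins[w$proteins$protein_id == multi$gene_id[i], ]
    digest(prot[, c("protein_id", "sequence")], "trypsin",
           max_missed = 1, len_range = c(7, 45))$sequence
  }))
  hits <- map_peptide_to_genome(peps, sf, w$proteins, w$genome)
  jc <- count_junction_coverage(hits, w$annotation)
  # intronless genes report (0, 0)
  n_ex <- vapply(w$annotation$exons, nrow, integer(1))
  expect_true(all(jc$total[match(w$annotation$gene_id[n_ex == 1], jc$gene_id)] == 0))
  # with dense peptide coverage some junctions of the sampled genes are hit
  expect_gt(sum(jc$covered), 0)
  expect_true(all(jc$covered <= jc$total))
  expect_true(attr(jc, "ratio") >= 0 && attr(jc, "ratio") <= 1)
})

test_that("N-terminal acetylation validates TIS only at protein starts", {
  prots <- tibble::tibble(protein_id = c("P1", "P2"),
                          sequence = c("MSTARTPEPTIDEK", "MAAAAKInternalK"))
  mk <- function(pep, pos) tibble::tibble(position = pos, name = "acetyl", delta = 42.010565)
  psms <- tibble::tibble(
    peptide = c("MSTARTPEP", "STARTPEP", "AAAAK", "TERNAL"),
    mods = list(mk("a", "N-term"), mk("b", "N-term"), mk("c", "N-term"), mk("d", "N-term")))
  tis <- detect_nterm_acetyl_tis(psms, prots)
  # offset 0 validates; offset 1 after initiator Met validates; internal does not
  expect_true("P1" %in% tis$protein_id) # MSTARTPEP at offset 0
  expect_true(any(tis$peptide == "STARTPEP")) # Met-excised start
  expect_false(any(tis$peptide == "TERNAL"))
})

test_that("BED12 and proBAM exports round-trip through the genome", {
  w <- cached_world()
  sf <- cached_sixframe()
  multi <- w$annotation[vapply(w$annotation$exons, nrow, 1L) > 1, ][1, ]
  prot <- w$proteins[w$proteins$protein_id == multi$gene_id, ]
  peps <- digest(prot[, c("protein_id", "sequence")], "trypsin",
                 max_missed = 1, len_range = c(7, 45))$sequence
  hits <- map_peptide_to_genome(peps, sf, w$proteins, w$genome)
  hits <- classify_novelty(hits, w$annotation, w$proteins)

  bed <- tempfile(fileext = ".bed")
  export_bed(hits, bed)
  blines <- strsplit(readLines(bed), "\t")
  expect_true(all(lengths(blines) == 12))
  for (bl in blines) {
    sizes <- as.integer(strsplit(bl[[11]], ",")[[1]])
    starts <- as.integer(strsplit(bl[[12]], ",")[[1]])
    cs <- as.integer(bl[[2]])
    nt <- paste(substring(w$genome[[bl[[1]]]], cs + starts + 1,
                          cs + starts + sizes), collapse = "")
    if (bl[[6]] == "-") nt <- editoscan:::revcomp(nt)
    pep <- sub("\\|.*$", "", bl[[4]])
    expect_equal(collapse_il(translate_nt(nt)), collapse_il(pep))
  }

  sam <- tempfile(fileext = ".sam")
  export_probam(hits, w$genome, sam)
  lines <- readLines(sam)
  expect_true(any(grepl("^@SQ", lines)))
  recs <- strsplit(lines[!grepl("^@", lines)], "\t")
  expect_gt(length(recs), 0)
  for (r in recs) {
    cig <- r[[6]]
    ops <- regmatches(cig, gregexpr("[0-9]+[MN]", cig))[[1]]
    lens <- as.integer(sub("[MN]", "", ops))
    types <- sub("[0-9]+", "", ops)
    pos <- as.integer(r[[4]]) - 1L
    nt <- ""
    at <- pos
    for (k in seq_along(ops)) {
      if (types[k] == "M") nt <- paste0(nt, substring(w$genome[[r[[3]]]], at + 1, at + lens[k]))
      at <- at + lens[k]
    }
    expect_equal(nt, r[[10]]) # SEQ equals reference blocks
    flag <- as.integer(r[[2]])
    if (bitwAnd(flag, 16L) > 0) nt <- editoscan:::revcomp(nt)
    pep <- sub("^XP:Z:", "", r[[12]])
    expect_equal(collapse_il(translate_nt(nt)), collapse_il(pep))
  }
})
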