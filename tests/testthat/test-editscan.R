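test_that("one-mismatch alignment reports the substituted residue pair", {
  prots <- tibble::tibble(protein_id = "P", sequence = "AAAPEPTIDEKAAA")
  ali <- align_one_mismatch("PEPTKDEK", prots)
  one <- ali[ali$n_mismatch == 1, ]
  expect_equal(nrow(one), 1)
  expect_equal(one$mismatch_pos, 4L)
  expect_equal(one$ref_aa, "I")
  expect_equal(one$alt_aa, "K")
  # exact placement is distance 0, not a variant
  exact <- align_one_mismatch("PEPTIDEK", prots)
  expect_true(all(exact$n_mismatch == 0))
  # a peptide matching two proteins at distance 1 yields two rows
  prots2 <- tibble::tibble(protein_id = c("P1", "P2"),
                           sequence = c("AAPEPTIDEKAA", "GGPEPTIDEKGG"))
  two <- align_one_mismatch("PEPTWDEK", prots2)
  expect_equal(nrow(two[two$n_mismatch == 1, ]), 2)
  expect_true(all(two$n_placements == 2))
})

test_that("ambiguity prefilters discard acetyl- and deamidation-mimics", {
  cands <- tibble::tibble(
    ref_aa = c("S", "N", "K", "S"),
    alt_aa = c("E", "D", "E", "E"),
    mismatch_pos = c(0L, 3L, 3L, 3L))
  out <- prefilter_saav(cands)
  expect_equal(out$discard_reason[1], "nterm_acetyl_ambiguity") # S->E at N-term
  expect_equal(out$discard_reason[2], "deamidation_ambiguity") # N->D anywhere
  expect_true(out$keep[3]) # K->E is a reported class
  expect_true(out$keep[4]) # S->E away from the N-terminus survives
  # Q->E is also a deamidation mimic
  qe <- prefilter_saav(tibble::tibble(ref_aa = "Q", alt_aa = "E", mismatch_pos = 5L))
  expect_equal(qe$discard_reason, "deamidation_ambiguity")
})

test_that("codon-level feasibility agrees with exhaustive enumeration", {
  expect_true(a2i_feasible("AAA", "E")$feasible) # GAA = Glu
  expect_equal(a2i_feasible("AAA", "E")$offsets[[1]], 0L)
  expect_true(a2i_feasible("TAG", "W")$feasible) # amber readthrough
  expect_equal(a2i_feasible("TAG", "W")$offsets[[1]], 1L)
  expect_false(a2i_feasible("TTT", "L")$feasible) # no A to edit
  expect_true(is.na(a2i_feasible("ANA", "E")$feasible)) # indeterminate
  # full oracle: every codon x residue, single and multi edits
  code <- Biostrings::getGeneticCode("1")
  nts <- c("A", "C", "G", "T")
  codons <- apply(expand.grid(nts, nts, nts), 1, paste, collapse = "")
  for (allow_multi in c(FALSE, TRUE)) {
    targets <- unique(unname(code))
    for (codon in codons) {
      a_pos <- which(strsplit(codon, "")[[1]] == "A")
      reach <- character(0)
      if (length(a_pos)) {
        # independent enumeration: iterate bitmask subsets of A positions
        subsets <- lapply(seq_len(2^length(a_pos) - 1), function(mask) {
          a_pos[bitwAnd(mask, 2^(seq_along(a_pos) - 1)) > 0]
        })
        if (!allow_multi) subsets <- subsets[lengths(subsets) == 1]
        for (s in subsets) {
          ed <- strsplit(codon, "")[[1]]; ed[s] <- "G"
          reach <- c(reach, unname(code[paste(ed, collapse = "")]))
        }
      }
      got <- a2i_feasible(codon, targets, allow_multi = allow_multi)
      expect_equal(got$feasible, targets %in% reach,
                   info = paste(codon, allow_multi))
    }
  }
})

test_that("single-edit enumeration contains exactly the expected classes", {
  subs <- enumerate_a2i_substitutions(allow_multi = FALSE)
  observed_classes <- tibble::tribble(
    ~from, ~to,
    "K", "E", "I", "V", "S", "G", "R", "G", "K", "R", "T", "A",
    "Q", "R", "Y", "C", "M", "V", "E", "G", "N", "S", "I", "M")
  for (i in seq_len(nrow(observed_classes))) {
    expect_true(any(subs$from == observed_classes$from[i] &
                      subs$to == observed_classes$to[i]))
  }
  # the excluded-by-ambiguity and stop-involving classes are reachable too
  expect_true(any(subs$from == "N" & subs$to == "D"))
  expect_true(any(subs$from == "*" & subs$to == "W"))
  # never a substitution needing a non-A->G change
  expect_false(any(subs$from == "F" & subs$to == "L"))
  # every pair is validated by direct codon arithmetic
  code <- Biostrings::getGeneticCode("1")
  for (i in seq_len(nrow(subs))) {
    found <- FALSE
    for (codon in names(code)[code == subs$from[i]]) {
      a_pos <- which(strsplit(codon, "")[[1]] == "A")
      for (p in a_pos) {
        ed <- strsplit(codon, "")[[1]]; ed[p] <- "G"
        if (code[paste(ed, collapse = "")] == subs$to[i]) found <- TRUE
      }
    }
    expect_true(found, info = paste(subs$from[i], subs$to[i]))
  }
})

test_that("planted edits are recovered with correct codon provenance", {
  w <- cached_world()
  saavs <- call_saavs(w$truth$edited_peptides, w$proteins, w$genome, w$annotation)
  truth <- w$truth$saav[w$truth$saav$detectable, ]
  key_t <- paste(truth$gene_id, truth$protein_pos0, truth$class)
  key_c <- paste(saavs$protein_id, saavs$protein_pos, saavs$class)
  expect_gte(mean(key_t %in% key_c), 0.95)
  # candidate invariants: codon translates to ref, edited codon to alt
  code <- Biostrings::getGeneticCode("1")
  for (i in seq_len(nrow(saavs))) {
    s <- saavs[i, ]
    expect_equal(unname(code[s$ref_codon]), s$ref_aa)
    ed <- strsplit(s$ref_codon, "")[[1]]
    ed[s$edited_offsets[[1]] + 1] <- "G"
    expect_equal(unname(code[paste(ed, collapse = "")]), s$alt_aa)
    expect_equal(s$mass_shift, substitution_mass_shift(s$ref_aa, s$alt_aa))
    # every edited genomic position holds the expected base: A on the
    # coding strand, so A (+) or T (-) on the forward strand
    base <- substring(w$genome[[s$contig]], s$codon_positions[[1]] + 1,
                      s$codon_positions[[1]] + 1)
    codon_fwd <- paste(base, collapse = "")
    if (s$strand == "-") codon_fwd <- editoscan:::revcomp(codon_fwd)
    expect_equal(codon_fwd, s$ref_codon)
  }
  # no call ever sits at a codon without an A on the coding strand
  expect_true(all(grepl("A", saavs$ref_codon, fixed = TRUE)))
})

test_that("SAAV calls are invariant under reverse-complementing the world", {
  w <- cached_world()
  saavs <- call_saavs(w$truth$edited_peptides, w$proteins, w$genome, w$annotation)
  fl <- flip_world(w$genome, w$annotation)
  prot_fl <- translate_genes(fl$annotation, fl$genome)
  expect_equal(sort(prot_fl$sequence), sort(w$proteins$sequence))
  saavs_fl <- call_saavs(w$truth$edited_peptides, prot_fl, fl$genome, fl$annotation)
  key <- function(s) sort(paste(s$protein_id, s$protein_pos, s$class, s$ref_codon))
  expect_equal(key(saavs_fl), key(saavs))
})

test_that("non-editable mismatches are filtered at the codon stage", {
  w <- cached_world()
  # construct a K->Q mismatch peptide (AAA->CAA needs A->C, not A->G)
  prot <- w$proteins[1, ]
  kpos <- which(strsplit(prot$sequence, "")[[1]] == "K")
  kpos <- kpos[kpos > 8 & kpos < nchar(prot$sequence) - 8][1]
  skip_if(is.na(kpos))
  pep <- substring(prot$sequence, kpos - 4, kpos + 4)
  pep_q <- paste0(substring(pep, 1, 4), "Q", substring(pep, 6))
  saavs <- call_saavs(pep_q, w$proteins, w$genome, w$annotation)
  expect_false(any(saavs$protein_id == prot$protein_id &
                     saavs$protein_pos == kpos - 1 & saavs$alt_aa == "Q"))
})

test_that("stop-loss events require an amber stop and matching junction", {
  w <- cached_world()
  res <- detect_stop_loss(w$truth$edited_peptides, w$proteins, w$genome, w$annotation)
  truth <- w$truth$stoploss
  expect_true(all(truth$gene_id %in% res$events$gene_id))
  ev <- res$events[match(truth$gene_id, res$events$gene_id), ]
  expect_true(all(ev$stop_codon == "TAG"))
  expect_equal(ev$extension_length, truth$extension_length)
  expect_equal(ev$extension, truth$extension)
  # extension starts with the recoded Trp and ends before the next stop
  expect_true(all(substring(ev$extension, 1, 1) == "W"))
  # a TAA gene with a Trp junction peptide is rejected, not called
  taa <- w$truth$genes[w$truth$genes$annotated & w$truth$genes$stop_codon == "TAA", ][1, ]
  if (!is.na(taa$gene_id)) {
    gene <- w$annotation[match(taa$gene_id, w$annotation$gene_id), ]
    ext <- editoscan:::readthrough_extension(gene, w$genome)
    fake <- paste0(substring(taa$protein, nchar(taa$protein) - 5), "W",
                   substring(ext$extension, 2, 4))
    res2 <- detect_stop_loss(fake, w$proteins, w$genome, w$annotation)
    expect_false(taa$gene_id %in% res2$events$gene_id)
    expect_true(any(res2$rejected$reason == "non-UAG stop"))
  }
})

test_that("manual-review export flags isobaric alternatives without dropping rows", {
  w <- cached_world()
  saavs <- call_saavs(w$truth$edited_peptides, w$proteins, w$genome, w$annotation)
  out <- manual_review_export(saavs)
  expect_equal(nrow(out), nrow(saavs))
  # T->A candidates with an adjacent Ser are flagged as Ser-mod mimics
  ta <- out[out$class == "T->A", ]
  for (i in seq_len(nrow(ta))) {
    nb <- substring(ta$peptide[i], max(1, ta$peptide_pos[i]), ta$peptide_pos[i] + 2)
    if (grepl("S", nb, fixed = TRUE)) expect_match(ta$isobaric_flags[i], "formaldehyde_loss")
  }
  # candidates with no isobaric alternative carry an empty flag
  ke <- out[out$class == "K->E" & !grepl("S|T", substring(out$peptide, 1, 3)), ]
  expect_true(all(ke$isobaric_flags == "" | nchar(ke$isobaric_flags) > 0))
})
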