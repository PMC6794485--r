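test_that("genome loading normalises and validates FASTA input", {
  fa <- tempfile(fileext = ".fa")
  writeLines(c(">c1", "acgt"), fa)
  g <- load_genome(fa)
  expect_equal(g, c(c1 = "ACGT"))
  writeLines(c(">c1", "ACGT", ">c1", "GGGG"), fa)
  expect_error(load_genome(fa), "duplicate")
  writeLines(character(0), fa)
  expect_error(load_genome(fa))
  writeLines(c(">c1", "ACXT"), fa)
  expect_error(load_genome(fa), "non-ACGTN")
})

test_that("single-exon CDS loads and translates", {
  toy <- write_toy_genome(
    list(c1 = "ATGGCCTAAGTTTTT"),
    c("c1\ttoy\tgene\t1\t9\t.\t+\t.\tID=gA",
      "c1\ttoy\tmRNA\t1\t9\t.\t+\t.\tID=gA.t1;Parent=gA",
      "c1\ttoy\tCDS\t1\t9\t.\t+\t0\tID=cA;Parent=gA.t1"))
  genome <- load_genome(toy$fasta)
  ann <- load_annotation(toy$gff, genome)
  expect_equal(ann$exons[[1]], tibble::tibble(start = 0L, end = 9L))
  prot <- translate_genes(ann, genome)
  expect_equal(prot$sequence, "MA")
})

test_that("two-exon CDS across a GT..AG intron splices in transcript order", {
  # exon1 ATGGC + intron GTAAAG + exon2 CTAA -> spliced ATGGCCTAA -> "MA"
  toy <- write_toy_genome(
    list(c1 = "ATGGCGTAAAGCTAAGGG"),
    c("c1\ttoy\tgene\t1\t15\t.\t+\t.\tID=gB",
      "c1\ttoy\tmRNA\t1\t15\t.\t+\t.\tID=gB.t1;Parent=gB",
      "c1\ttoy\tCDS\t1\t5\t.\t+\t0\tID=cB1;Parent=gB.t1",
      "c1\ttoy\tCDS\t12\t15\t.\t+\t1\tID=cB2;Parent=gB.t1"))
  genome <- load_genome(toy$fasta)
  ann <- load_annotation(toy$gff, genome)
  expect_equal(nrow(ann$exons[[1]]), 2)
  expect_equal(translate_genes(ann, genome)$sequence, "MA")
})

test_that("invalid gene models are rejected", {
  toy <- write_toy_genome(
    list(c1 = "ATGGCCTAAGTT"),
    c("c1\ttoy\tgene\t1\t8\t.\t+\t.\tID=gC",
      "c1\ttoy\tmRNA\t1\t8\t.\t+\t.\tID=gC.t1;Parent=gC",
      "c1\ttoy\tCDS\t1\t8\t.\t+\t0\tID=cC;Parent=gC.t1"))
  genome <- load_genome(toy$fasta)
  expect_error(load_annotation(toy$gff, genome), "multiple of 3")
  # missing parent linkage names the offending feature
  toy2 <- write_toy_genome(
    list(c1 = "ATGGCCTAAGTT"),
    c("c1\ttoy\tgene\t1\t9\t.\t+\t.\tID=gD",
      "c1\ttoy\tmRNA\t1\t9\t.\t+\t.\tID=gD.t1;Parent=gD",
      "c1\ttoy\tCDS\t1\t9\t.\t+\t0\tID=cD;Parent=nosuch.t1"))
  expect_error(load_annotation(toy2$gff, load_genome(toy2$fasta)), "nosuch")
})

test_that("reverse-strand genes translate via the reverse complement", {
  # revcomp("TTCTTTCAT") = ATGAAAGAA -> MKE (no stop; mark partial 3p)
  toy <- write_toy_genome(
    list(c1 = "TTCTTTCAT"),
    c("c1\ttoy\tgene\t1\t9\t.\t-\t.\tID=gE;partial=3p",
      "c1\ttoy\tmRNA\t1\t9\t.\t-\t.\tID=gE.t1;Parent=gE;partial=3p",
      "c1\ttoy\tCDS\t1\t9\t.\t-\t0\tID=cE;Parent=gE.t1"))
  genome <- load_genome(toy$fasta)
  ann <- load_annotation(toy$gff, genome)
  expect_true(ann$is_partial_3p)
  expect_equal(translate_genes(ann, genome)$sequence, "MKE")
})

test_that("internal stop codons error unless readthrough is requested", {
  toy <- write_toy_genome(
    list(c1 = "ATGTAGAAATAA"),
    c("c1\ttoy\tgene\t1\t12\t.\t+\t.\tID=gF",
      "c1\ttoy\tmRNA\t1\t12\t.\t+\t.\tID=gF.t1;Parent=gF",
      "c1\ttoy\tCDS\t1\t12\t.\t+\t0\tID=cF;Parent=gF.t1"))
  genome <- load_genome(toy$fasta)
  ann <- load_annotation(toy$gff, genome)
  expect_error(translate_genes(ann, genome), "codon 2")
  expect_equal(translate_genes(ann, genome, readthrough_tag = TRUE)$sequence, "MWK")
})

test_that("six-frame translation covers a toy contig with exact provenance", {
  g <- c(c1 = "ATGAAATAGCCCCCC")
  frags <- six_frame_translate(g, min_fragment_len = 2)
  f0 <- frags[frags$strand == "+" & frags$frame == 0 & frags$start == 0, ]
  expect_equal(f0$sequence[1], "MK")
  expect_equal(f0$end[1], 6)
  # genome shorter than one codon yields nothing
  expect_equal(nrow(six_frame_translate(c(c1 = "AT"), 1)), 0)
})

test_that("six-frame fragments contain every single-exon gene peptide", {
  w <- cached_world()
  frags <- cached_sixframe()
  single <- w$annotation[vapply(w$annotation$exons, nrow, 1L) == 1, ]
  prots <- w$proteins[w$proteins$protein_id %in% single$gene_id, ]
  for (i in utils::head(seq_len(nrow(prots)), 5)) {
    peps <- digest(prots[i, c("protein_id", "sequence")], "trypsin",
                   max_missed = 0, len_range = c(7, 50))
    pool <- frags$sequence[frags$contig == prots$contig[i] &
                             frags$strand == prots$strand[i]]
    found <- vapply(peps$sequence, function(p) any(grepl(p, pool, fixed = TRUE)),
                    logical(1))
    expect_true(all(found))
  }
})

test_that("six-frame provenance round-trips through the genome", {
  w <- cached_world()
  frags <- cached_sixframe()
  set.seed(1)
  for (i in sample(nrow(frags), 40)) {
    f <- frags[i, ]
    nt <- substring(w$genome[[f$contig]], f$start + 1, f$end)
    if (f$strand == "-") nt <- editoscan:::revcomp(nt)
    expect_identical(translate_nt(nt), f$sequence)
  }
})

test_that("chunked six-frame translation deduplicates to the whole-contig set", {
  w <- cached_world()
  contig1 <- w$genome[1]
  whole <- six_frame_translate(contig1, min_fragment_len = 7)
  chunked <- six_frame_translate(contig1, min_fragment_len = 7,
                                 chunk_len = 5000, chunk_overlap = 600)
  expect_gt(nrow(chunked), nrow(dedup_fragments(chunked)) - 1)
  # a fragment is guaranteed to reappear when it fits, with its flanking
  # stop codons, inside a single chunk (length <= overlap - 6)
  dedup <- dedup_fragments(chunked)
  key <- function(d) paste(d$contig, d$strand, d$frame, d$start, d$end)
  L <- nchar(w$genome[[1]])
  fits <- whole[whole$end - whole$start <= 600 - 6 &
                  whole$start >= 3 & whole$end <= L - 3, ]
  expect_gt(nrow(fits), 10)
  expect_true(all(key(fits) %in% key(dedup)))
  expect_error(six_frame_translate(contig1, 7, chunk_len = 100, chunk_overlap = 100),
               "chunk_overlap")
})

test_that("decoys conserve count and composition and flag palindromes", {
  db <- tibble::tibble(protein_id = c("a", "b"), sequence = c("MKE", "MKM"),
                       source = "annotated", contig = NA, strand = NA,
                       frame = NA, start = NA, end = NA, gene_id = NA,
                       segments = list(NULL, NULL))
  dec <- build_decoys(db)
  expect_equal(nrow(dec), nrow(db))
  expect_equal(dec$sequence, c("EKM", "MKM"))
  expect_equal(dec$is_collision, c(FALSE, TRUE))
  expect_true(all(dec$source == "decoy"))
  comp <- function(x) sort(table(strsplit(paste(x, collapse = ""), "")[[1]]))
  expect_equal(comp(dec$sequence), comp(db$sequence))
  expect_error(build_decoys(db[0, ]), "empty")
})

test_that("hybrid databases add deduplicated peptide entries", {
  db <- tibble::tibble(protein_id = c("P1", "P2"), sequence = c("MKELLK", "MAAAAR"),
                       source = "annotated", contig = NA, strand = NA, frame = NA,
                       start = NA, end = NA, gene_id = NA, segments = list(NULL, NULL))
  hyb <- build_hybrid_db(db, c("PEPTIDEK"))
  expect_equal(nrow(hyb), 3)
  expect_equal(hyb$source[3], "hybrid_peptide")
  # I/L-equivalent peptides collapse to one entry
  hyb2 <- build_hybrid_db(db, c("ILKAAA", "LLKAAA"))
  expect_equal(sum(hyb2$source == "hybrid_peptide"), 1)
  expect_identical(build_hybrid_db(db, character(0)), db)
})

test_that("GFF3 writing round-trips losslessly", {
  w <- cached_world()
  path <- tempfile(fileext = ".gff3")
  write_gff3(w$annotation, path)
  back <- load_annotation(path, w$genome)
  a <- w$annotation[order(w$annotation$gene_id), ]
  b <- back[order(back$gene_id), ]
  expect_equal(b$gene_id, a$gene_id)
  expect_equal(b$strand, a$strand)
  expect_equal(b$cds_phase, a$cds_phase)
  expect_equal(b$exons, a$exons)
})
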