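# shared fixtures, built once per test run

.synth_cache <- new.env(parent = emptyenv())

cached_world <- function(key = "small") {
  if (!exists(key, envir = .synth_cache)) {
    w <- switch(key,
      small = plant_edits(
        synth_genome(n_contigs = 2, n_genes = 30, n_novel_genes = 3, seed = 11),
        n_saav = 10, n_stoploss = 2, seed = 11),
      stop("unknown world key: ", key))
    assign(key, w, envir = .synth_cache)
  }
  get(key, envir = .synth_cache)
}

cached_sixframe <- function() {
  if (!exists("sixframe_small", envir = .synth_cache)) {
    assign("sixframe_small", six_frame_translate(cached_world()$genome),
           envir = .synth_cache)
  }
  get("sixframe_small", envir = .synth_cache)
}

# independent brute-force q-value oracle: for each PSM, the minimum FDR
# over every threshold at or below its own score
brute_qvalues <- function(scores, is_decoy) {
  thresholds <- sort(unique(scores))
  fdr_at <- vapply(thresholds, function(t) {
    nt <- sum(scores >= t & !is_decoy)
    nd <- sum(scores >= t & is_decoy)
    if (nt == 0) 1 else min(1, nd / nt)
  }, numeric(1))
  vapply(scores, function(s) min(fdr_at[thresholds <= s]), numeric(1))
}

# write a tiny GFF3/FASTA pair to tempfiles; returns the two paths
write_toy_genome <- function(contigs, gff_body) {
  fa <- tempfile(fileext = ".fa")
  writeLines(unlist(purrr::imap(contigs, function(s, n) c(paste0(">", n), s))), fa)
  gff <- tempfile(fileext = ".gff3")
  writeLines(c("##gff-version 3", gff_body), gff)
  list(fasta = fa, gff = gff)
}
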