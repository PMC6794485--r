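#' @importFrom rlang .data
#' @importFrom dplyr %>%
NULL

#' Collapse Ile to Leu
#'
#' Ile and Leu are isobaric and indistinguishable by conventional MS/MS, so
#' peptide/protein comparisons are done after mapping every I to L.
#'
#' @param x Character vector of amino-acid sequences.
#' @return Character vector with all `I` replaced by `L`.
#' @export
collapse_il <- function(x) chartr("I", "L", x)

# reverse-complement of DNA strings (vectorised)
revcomp <- function(x) {
  as.character(Biostrings::reverseComplement(Biostrings::DNAStringSet(x)))
}

# reverse a character string
str_rev <- function(x) {
  vapply(x, function(s) paste(rev(strsplit(s, "", fixed = TRUE)[[1]]), collapse = ""),
         character(1), USE.NAMES = FALSE)
}

#' Translate a nucleotide sequence
#'
#' Codon-wise translation with the standard genetic code (or any NCBI table
#' available to [Biostrings::getGeneticCode()]). Stop codons translate to
#' `*`; codons containing `N` translate to `X`; a trailing incomplete codon
#' is dropped. With `readthrough_tag = TRUE` the amber stop `TAG` is read as
#' Trp (`W`), the readthrough used to translate stop-loss extensions
#' (UAG-to-UGG editing).
#'
#' @param nt Character vector of DNA sequences (coding strand).
#' @param readthrough_tag Read TAG as W instead of stop.
#' @param code_id NCBI genetic-code table id (default "1", standard code).
#' @return Character vector of amino-acid sequences (may contain `*`/`X`).
#' @export
translate_nt <- function(nt, readthrough_tag = FALSE, code_id = "1") {
  code <- Biostrings::getGeneticCode(code_id)
  if (readthrough_tag) code[["TAG"]] <- "W"
  vapply(nt, function(s) {
    n <- nchar(s) %/% 3L
    if (n == 0L) return("")
    codons <- substring(s, 3L * seq_len(n) - 2L, 3L * seq_len(n))
    aa <- unname(code[codons])
    aa[is.na(aa)] <- "X"
    paste(aa, collapse = "")
  }, character(1), USE.NAMES = FALSE)
}

# split a translated frame at stop codons into fragments;
# returns tibble(aa_start, aa_end) of 1-based inclusive aa positions
stop_free_runs <- function(aa) {
  if (!nzchar(aa)) return(tibble::tibble(aa_start = integer(), aa_end = integer()))
  chars <- strsplit(aa, "", fixed = TRUE)[[1]]
  keep <- chars != "*"
  r <- rle(keep)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  tibble::tibble(aa_start = starts[r$values], aa_end = ends[r$values])
}

# stable short id from content (used to stamp outputs with their config)
config_hash <- function(x) rlang::hash(x)
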