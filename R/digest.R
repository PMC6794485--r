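#' In-silico proteolytic digestion
#'
#' Cleaves protein sequences with trypsin or Glu-C and returns all peptides
#' with up to `max_missed` missed cleavages, filtered by length. Trypsin
#' cleaves C-terminal to Lys/Arg but not before Pro (the classic KP/RP
#' rule, switchable); Glu-C in ammonium-bicarbonate buffer cleaves
#' C-terminal to Glu only, with Asp cleavage available behind `cleave_d`.
#'
#' @param proteins A data frame with columns `protein_id` and `sequence`,
#'   or a (optionally named) character vector of sequences.
#' @param enzyme `"trypsin"` or `"gluc"`.
#' @param max_missed Maximum number of missed cleavages (default 2).
#' @param len_range Length bounds `c(min, max)` applied last (default 6-50).
#' @param kp_rule Suppress tryptic cleavage before proline (default TRUE).
#' @param cleave_d Let Glu-C cleave after Asp as well (default FALSE).
#' @return Tibble with columns `protein_id`, `sequence`, `start` (0-based
#'   offset in the protein), `missed`, `length`, `enzyme`.
#' @export
#' @examples
#' digest(c(P1 = "MKAAAR"), "trypsin", max_missed = 0, len_range = c(1, 50))
digest <- function(proteins, enzyme = c("trypsin", "gluc"), max_missed = 2,
                   len_range = c(6, 50), kp_rule = TRUE, cleave_d = FALSE) {
  enzyme <- match.arg(enzyme)
  if (is.character(proteins)) {
    ids <- names(proteins)
    if (is.null(ids)) ids <- paste0("protein_", seq_along(proteins))
    proteins <- tibble::tibble(protein_id = ids, sequence = unname(proteins))
  }
  stopifnot(all(c("protein_id", "sequence") %in% names(proteins)))
  if (any(!nzchar(proteins$sequence))) stop("digest(): empty protein sequence")

  res <- purrr::map2(proteins$protein_id, proteins$sequence, function(id, seq) {
    frag <- cleave_sequence(seq, enzyme, kp_rule = kp_rule, cleave_d = cleave_d)
    n <- length(frag$start)
    out <- vector("list", max_missed + 1L)
    for (m in 0:max_missed) {
      idx <- seq_len(max(0L, n - m))
      if (!length(idx)) next
      starts <- frag$start[idx]
      ends <- frag$end[idx + m]
      out[[m + 1L]] <- tibble::tibble(
        protein_id = id,
        sequence = substring(seq, starts + 1L, ends),
        start = starts,
        missed = m
      )
    }
    dplyr::bind_rows(out)
  })
  res <- dplyr::bind_rows(res)
  res$length <- nchar(res$sequence)
  res$enzyme <- enzyme
  dplyr::filter(res, .data$length >= len_range[1], .data$length <= len_range[2])
}

# 0-missed fragment coordinates (0-based start, 1-based end inclusive as
# substring end) for one sequence
cleave_sequence <- function(seq, enzyme, kp_rule = TRUE, cleave_d = FALSE) {
  aa <- strsplit(seq, "", fixed = TRUE)[[1]]
  n <- length(aa)
  if (enzyme == "trypsin") {
    cut_after <- which(aa %in% c("K", "R"))
    if (kp_rule) cut_after <- cut_after[cut_after == n | aa[pmin(cut_after + 1L, n)] != "P"]
  } else {
    targets <- if (cleave_d) c("E", "D") else "E"
    cut_after <- which(aa %in% targets)
  }
  cut_after <- cut_after[cut_after < n]
  bounds <- c(0L, cut_after, n) # cut points in 0-based coordinates
  list(start = bounds[-length(bounds)], end = bounds[-1])
}
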