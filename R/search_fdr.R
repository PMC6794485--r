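#' Theoretical singly-charged b/y fragment m/z values
#'
#' @param sequence One peptide sequence.
#' @return Tibble with columns `ion` (e.g. `"b2"`, `"y5"`) and `mz`.
#' @export
fragment_ions <- function(sequence) {
  aa <- strsplit(sequence, "", fixed = TRUE)[[1]]
  n <- length(aa)
  if (n < 2) stop("fragment_ions(): peptide must have at least 2 residues")
  m <- unname(residue_masses()[aa])
  b <- cumsum(m)[-n] + MASS_PROTON
  y <- rev(cumsum(rev(m))[-n]) + MASS_WATER + MASS_PROTON
  tibble::tibble(
    ion = c(paste0("b", seq_len(n - 1)), paste0("y", rev(seq_len(n - 1)))),
    mz = c(b, y)
  )
}

#' Synthesise a spectrum from a peptide
#'
#' Builds an idealised peak list containing all singly-charged b/y ions of
#' the peptide (unit intensities), the spectrum model understood by
#' [naive_score()].
#'
#' @param sequence One peptide sequence.
#' @return Tibble with columns `mz`, `intensity`.
#' @export
synth_spectrum <- function(sequence) {
  fi <- fragment_ions(sequence)
  tibble::tibble(mz = sort(fi$mz), intensity = 1)
}

#' Naive fragment-matching score
#'
#' Deterministic stand-in scorer: the fraction of the peptide's theoretical
#' singly-charged b/y ions found in the spectrum within `frag_tol_da`.
#' A spectrum containing every b/y ion of the peptide scores 1.
#'
#' @param spectrum Tibble/data frame with an `mz` column (one peak per row).
#' @param peptide Peptide sequence (character scalar).
#' @param frag_tol_da Fragment match tolerance in Da (default 0.02).
#' @return Score in `[0, 1]`.
#' @export
naive_score <- function(spectrum, peptide, frag_tol_da = 0.02) {
  if (is.null(spectrum) || nrow(spectrum) < 1) stop("naive_score(): empty spectrum")
  if (!nzchar(peptide)) stop("naive_score(): empty peptide")
  theo <- fragment_ions(peptide)$mz
  peaks <- sort(spectrum$mz)
  hit <- vapply(theo, function(mz) {
    i <- findInterval(mz, peaks)
    (i >= 1 && abs(peaks[i] - mz) <= frag_tol_da) ||
      (i < length(peaks) && abs(peaks[i + 1] - mz) <= frag_tol_da)
  }, logical(1))
  sum(hit) / length(theo)
}

#' Target-decoy q-values
#'
#' For a score threshold s, FDR(s) = (#decoys >= s) / (#targets >= s); the
#' q-value of a PSM is the minimum FDR over all thresholds at or below its
#' own score (monotone in score). Tied scores share one threshold, and
#' decoys at a tie are counted before targets (conservative). With no
#' targets, all q-values are 1. By default no +1 pseudocount is added to
#' the decoy count; set `plus_one = TRUE` for the more conservative
#' estimator.
#'
#' @param psms Tibble with at least `score` and `is_decoy` columns.
#' @param plus_one Add 1 to the decoy count (default FALSE).
#' @return `psms` with a `q_value` column appended (input order preserved).
#' @export
compute_qvalues <- function(psms, plus_one = FALSE) {
  stopifnot(all(c("score", "is_decoy") %in% names(psms)))
  if (!nrow(psms)) return(dplyr::mutate(psms, q_value = numeric(0)))
  if (any(!is.finite(psms$score))) stop("compute_qvalues(): non-finite score")
  ord <- order(psms$score, decreasing = TRUE)
  sc <- psms$score[ord]
  dec <- psms$is_decoy[ord]
  n_target_total <- sum(!dec)
  if (n_target_total == 0) {
    psms$q_value <- 1
    return(psms)
  }
  # cumulative counts at each threshold = distinct score, ties pooled
  cum_dec <- cumsum(dec)
  cum_tar <- cumsum(!dec)
  last_of_tie <- c(sc[-1] != sc[-length(sc)], TRUE)
  fdr <- (cum_dec + as.integer(plus_one)) / pmax(cum_tar, 1L)
  # propagate the tie-pooled counts to every member of the tie: each PSM
  # uses the counts at the last (lowest-ranked) member of its tie group
  idx <- rev(cummin(rev(ifelse(last_of_tie, seq_along(sc), .Machine$integer.max))))
  fdr <- fdr[idx]
  q <- rev(cummin(rev(pmin(fdr, 1))))
  psms$q_value <- q[order(ord)]
  psms
}

#' Class-specific FDR filtering
#'
#' Runs [compute_qvalues()] independently within each peptide class
#' (`known`, `novel`, `saav`, `stoploss`, ...) so that the abundant known
#' class cannot mask errors in the rare classes, then accepts PSMs with
#' q-value at or below `threshold` per class. A class with no decoys gets
#' q = 0 for all members plus a warning record (attribute `"warnings"`).
#'
#' @param psms Tibble with `score`, `is_decoy`, `peptide_class` columns.
#' @param threshold q-value acceptance threshold (default 0.01).
#' @param plus_one Passed to [compute_qvalues()].
#' @return `psms` with `q_value` and `accepted` columns; attribute
#'   `"warnings"` holds a tibble of per-class warnings (possibly empty).
#' @export
class_specific_fdr <- function(psms, threshold = 0.01, plus_one = FALSE) {
  stopifnot("peptide_class" %in% names(psms))
  warn <- tibble::tibble(peptide_class = character(), warning = character())
  out <- psms %>%
    dplyr::group_by(.data$peptide_class) %>%
    dplyr::group_modify(function(d, key) {
      if (!any(d$is_decoy)) {
        warn <<- dplyr::bind_rows(warn, tibble::tibble(
          peptide_class = key$peptide_class[[1]],
          warning = "no decoys in class; q-values set to 0"
        ))
        d$q_value <- 0
        d
      } else {
        compute_qvalues(d, plus_one = plus_one)
      }
    }) %>%
    dplyr::ungroup()
  out$accepted <- !out$is_decoy & out$q_value <= threshold
  attr(out, "warnings") <- warn
  out
}

#' Search spectra against one protein database
#'
#' Minimal deterministic search engine used for synthetic end-to-end runs:
#' the database (targets plus decoys) is digested, candidates are selected
#' by precursor mass, scored with [naive_score()], and the best match per
#' spectrum is reported.
#'
#' @param spectra Tibble with columns `spectrum_id`, `precursor_mz`,
#'   `charge`, `retention_time` (optional) and list-column `peaks`
#'   (tibbles with `mz`).
#' @param db Protein database tibble including decoy entries.
#' @param peptide_class Class label stamped on the resulting PSMs.
#' @param enzyme,max_missed,len_range Digestion settings.
#' @param precursor_tol_ppm Precursor selection window (default 10 ppm).
#' @param frag_tol_da Fragment tolerance for the scorer.
#' @return PSM tibble: `spectrum_id`, `peptide`, `protein_id`, `charge`,
#'   `score`, `precursor_mz`, `is_decoy`, `peptide_class`,
#'   `retention_time`, `q_value` (NA until computed).
#' @export
search_spectra <- function(spectra, db, peptide_class = "known",
                           enzyme = "trypsin", max_missed = 2,
                           len_range = c(6, 50), precursor_tol_ppm = 10,
                           frag_tol_da = 0.02) {
  peps <- digest(db[, c("protein_id", "sequence")], enzyme = enzyme,
                 max_missed = max_missed, len_range = len_range)
  peps$is_decoy <- db$source[match(peps$protein_id, db$protein_id)] == "decoy"
  peps <- dplyr::distinct(peps, .data$sequence, .data$is_decoy, .keep_all = TRUE)
  peps$mass <- peptide_mass(peps$sequence)
  peps <- peps[order(peps$mass), ]
  rt <- if ("retention_time" %in% names(spectra)) spectra$retention_time else NA_real_
  rows <- purrr::map(seq_len(nrow(spectra)), function(i) {
    sp <- spectra[i, ]
    neutral <- sp$precursor_mz * sp$charge - sp$charge * MASS_PROTON
    tol <- neutral * precursor_tol_ppm * 1e-6
    lo <- findInterval(neutral - tol, peps$mass) + 1L
    hi <- findInterval(neutral + tol, peps$mass)
    if (hi < lo) return(NULL)
    cand <- peps[lo:hi, ]
    scores <- vapply(cand$sequence, naive_score, numeric(1),
                     spectrum = sp$peaks[[1]], frag_tol_da = frag_tol_da)
    # deterministic tie-break: best score, then decoy before target, then sequence
    ord <- order(-scores, -cand$is_decoy, cand$sequence)
    j <- ord[1]
    tibble::tibble(
      spectrum_id = sp$spectrum_id, peptide = cand$sequence[j],
      protein_id = cand$protein_id[j], charge = sp$charge,
      score = scores[j], precursor_mz = sp$precursor_mz,
      is_decoy = cand$is_decoy[j], peptide_class = peptide_class,
      retention_time = rt[min(i, length(rt))], q_value = NA_real_
    )
  })
  dplyr::bind_rows(rows)
}

#' Stepped database search
#'
#' Searches the spectra against an ordered list of databases; after every
#' step, spectra accepted at the per-step FDR threshold are excluded from
#' the subsequent search, so abundant matches to the first (known) database
#' cannot distort the error estimate of later, larger databases. FDR is
#' computed per step on that step's PSMs only (PSM-level).
#'
#' @param spectra Spectra tibble (see [search_spectra()]).
#' @param databases Named list of protein database tibbles (each already
#'   containing its decoys), searched in order.
#' @param threshold Per-step q-value threshold (default 0.01).
#' @param classes Optional character vector of per-step peptide classes
#'   (default: database names).
#' @param ... Passed to [search_spectra()].
#' @return Object of class `editoscan_search`: list with `psms` (all steps,
#'   with `q_value`, `accepted`, `step`), `steps` (per-step summary),
#'   `unmatched` (spectrum ids left at the end).
#' @export
stepped_search <- function(spectra, databases, threshold = 0.01,
                           classes = NULL, ...) {
  stopifnot(length(databases) >= 1)
  if (is.null(names(databases))) names(databases) <- paste0("db", seq_along(databases))
  if (is.null(classes)) classes <- names(databases)
  remaining <- spectra
  all_psms <- list()
  steps <- list()
  for (k in seq_along(databases)) {
    psms <- search_spectra(remaining, databases[[k]], peptide_class = classes[[k]], ...)
    if (nrow(psms)) {
      psms <- compute_qvalues(psms)
      psms$accepted <- !psms$is_decoy & psms$q_value <= threshold
    } else {
      psms <- tibble::tibble(
        spectrum_id = character(), peptide = character(),
        protein_id = character(), charge = integer(), score = numeric(),
        precursor_mz = numeric(), is_decoy = logical(),
        peptide_class = character(), retention_time = numeric(),
        q_value = numeric(), accepted = logical())
    }
    psms$step <- k
    psms$database <- names(databases)[k]
    accepted_ids <- unique(psms$spectrum_id[psms$accepted])
    steps[[k]] <- tibble::tibble(
      step = k, database = names(databases)[k],
      n_searched = nrow(remaining), n_accepted = length(accepted_ids),
      n_remaining = nrow(remaining) - length(accepted_ids)
    )
    all_psms[[k]] <- psms
    remaining <- remaining[!remaining$spectrum_id %in% accepted_ids, , drop = FALSE]
  }
  structure(list(
    psms = dplyr::bind_rows(all_psms),
    steps = dplyr::bind_rows(steps),
    unmatched = remaining$spectrum_id
  ), class = "editoscan_search")
}

#' @export
print.editoscan_search <- function(x, ...) {
  cat("Stepped search:", nrow(x$steps), "step(s),",
      sum(x$steps$n_accepted), "spectra accepted,",
      length(x$unmatched), "unmatched\n")
  print(x$steps)
  invisible(x)
}

#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' Tidy PSM table of a stepped search
#' @param x An `editoscan_search` object.
#' @param ... Unused.
#' @return The PSM tibble with q-values and per-step provenance.
#' @export
tidy.editoscan_search <- function(x, ...) x$psms

#' One-row summary of a stepped search
#' @param x An `editoscan_search` object.
#' @param ... Unused.
#' @return Tibble with totals over all steps.
#' @export
glance.editoscan_search <- function(x, ...) {
  tibble::tibble(
    n_steps = nrow(x$steps),
    n_spectra = x$steps$n_searched[1],
    n_accepted = sum(x$steps$n_accepted),
    n_unmatched = length(x$unmatched)
  )
}

#' Theoretical de novo FDR
#'
#' The fraction (in percent, one decimal) of initially reported de novo
#' candidates that failed the downstream database-search criteria.
#'
#' @param n_initial Number of initially reported candidates (> 0).
#' @param n_failed Number failing the criteria (0..n_initial).
#' @return Percentage rounded to one decimal.
#' @export
#' @examples
#' theoretical_denovo_fdr(118, 5) # 4.2
theoretical_denovo_fdr <- function(n_initial, n_failed) {
  if (n_initial <= 0) stop("theoretical_denovo_fdr(): n_initial must be > 0")
  if (n_failed < 0 || n_failed > n_initial) {
    stop("theoretical_denovo_fdr(): n_failed out of range")
  }
  round(100 * n_failed / n_initial, 1)
}

#' Write spectra as MGF
#'
#' @param spectra Spectra tibble (see [search_spectra()]).
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_mgf <- function(spectra, path) {
  con <- file(path, "w")
  on.exit(close(con))
  for (i in seq_len(nrow(spectra))) {
    sp <- spectra[i, ]
    rt <- if ("retention_time" %in% names(spectra)) sp$retention_time else NA
    lines <- c(
      "BEGIN IONS",
      paste0("TITLE=", sp$spectrum_id),
      sprintf("PEPMASS=%.6f", sp$precursor_mz),
      sprintf("CHARGE=%d+", sp$charge),
      if (!is.na(rt)) sprintf("RTINSECONDS=%.3f", rt * 60),
      sprintf("%.6f %.1f", sp$peaks[[1]]$mz, sp$peaks[[1]]$intensity),
      "END IONS"
    )
    writeLines(lines, con)
  }
  invisible(path)
}

#' Read an MGF peak-list file
#'
#' @param path Path to an MGF file (BEGIN IONS/END IONS blocks with TITLE,
#'   PEPMASS, CHARGE, optional RTINSECONDS).
#' @return Spectra tibble with `spectrum_id`, `precursor_mz`, `charge`,
#'   `retention_time` (min) and list-column `peaks`.
#' @export
read_mgf <- function(path) {
  lines <- readLines(path)
  begins <- which(lines == "BEGIN IONS")
  ends <- which(lines == "END IONS")
  if (length(begins) != length(ends)) stop("read_mgf(): malformed MGF: ", path)
  rows <- purrr::map2(begins, ends, function(b, e) {
    block <- lines[(b + 1):(e - 1)]
    kv <- grepl("=", block, fixed = TRUE)
    keys <- sub("=.*$", "", block[kv])
    vals <- sub("^[^=]*=", "", block[kv])
    peaks <- do.call(rbind, strsplit(block[!kv], "\\s+"))
    tibble::tibble(
      spectrum_id = vals[match("TITLE", keys)],
      precursor_mz = as.numeric(vals[match("PEPMASS", keys)]),
      charge = as.integer(sub("\\+$", "", vals[match("CHARGE", keys)])),
      retention_time = if ("RTINSECONDS" %in% keys)
        as.numeric(vals[match("RTINSECONDS", keys)]) / 60 else NA_real_,
      peaks = list(tibble::tibble(
        mz = as.numeric(peaks[, 1]),
        intensity = as.numeric(peaks[, 2])
      ))
    )
  })
  dplyr::bind_rows(rows)
}
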