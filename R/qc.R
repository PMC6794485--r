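#' Precursor mass deviation in ppm
#'
#' Deviation of the observed neutral precursor mass from the theoretical
#' monoisotopic peptide mass, in parts per million. Vectorised.
#'
#' @param observed_mz Observed precursor m/z (Th).
#' @param charge Precursor charge (>= 1).
#' @param sequence Peptide sequence(s).
#' @param mods Summed modification deltas in Da (recycled; default 0).
#' @param fixed_cam Treat Cys as carbamidomethylated.
#' @return Numeric vector of ppm deviations.
#' @export
mass_deviation_ppm <- function(observed_mz, charge, sequence, mods = 0,
                               fixed_cam = FALSE) {
  if (any(charge < 1)) stop("mass_deviation_ppm(): charge must be >= 1")
  if (any(observed_mz <= 0)) stop("mass_deviation_ppm(): non-positive m/z")
  theo <- peptide_mass(sequence, mods = mods, fixed_cam = fixed_cam)
  obs_neutral <- observed_mz * charge - charge * MASS_PROTON
  1e6 * (obs_neutral - theo) / theo
}

#' Simple additive hydrophobicity-index predictor
#'
#' Sum of per-residue retention coefficients, a deliberately simple linear
#' stand-in for dedicated retention predictors: the QC logic only needs a
#' peptide-level hydrophobicity score whose correlation with observed
#' retention time separates genuine identifications from decoys. External
#' HI values can be supplied instead wherever a predictor is accepted.
#'
#' @param sequence Character vector of peptide sequences.
#' @return Numeric vector of predicted HI (dimensionless).
#' @export
predict_hi <- function(sequence) {
  coefs <- c(W = 11.0, F = 10.5, L = 8.1, I = 7.4, M = 5.5, V = 5.0,
             Y = 4.0, A = 1.0, T = 0.4, P = 2.0, E = 1.0, D = 0.15,
             C = 0.8, S = 0.1, Q = 0.0, N = 0.0, G = 0.0, R = 0.2,
             H = 0.1, K = 0.0)
  vapply(sequence, function(s) {
    aa <- strsplit(s, "", fixed = TRUE)[[1]]
    sum(coefs[aa], na.rm = TRUE)
  }, numeric(1), USE.NAMES = FALSE)
}

#' Retention-time vs hydrophobicity correlation per peptide class
#'
#' Pearson correlation between observed retention time and predicted
#' hydrophobicity within each peptide class. Genuine identifications
#' (known and novel alike) correlate tightly; decoy matches scatter.
#'
#' @param records Tibble with `peptide_class`, `retention_time` and either
#'   `predicted_hi` or a `peptide` column (HI then computed with
#'   `hi_predictor`).
#' @param hi_predictor Function peptide -> HI (default [predict_hi()]).
#' @return Tibble `peptide_class`, `n`, `r`, `flag` (NA r with reason when
#'   fewer than 3 records or zero variance).
#' @export
rt_hi_correlation <- function(records, hi_predictor = predict_hi) {
  if (!"predicted_hi" %in% names(records)) {
    records$predicted_hi <- hi_predictor(records$peptide)
  }
  records %>%
    dplyr::group_by(.data$peptide_class) %>%
    dplyr::summarise(
      n = dplyr::n(),
      r = if (dplyr::n() < 3 ||
              stats::sd(.data$retention_time) == 0 ||
              stats::sd(.data$predicted_hi) == 0) NA_real_
          else stats::cor(.data$retention_time, .data$predicted_hi),
      flag = dplyr::case_when(
        dplyr::n() < 3 ~ "fewer than 3 records",
        stats::sd(.data$retention_time) == 0 | stats::sd(.data$predicted_hi) == 0 ~
          "zero variance",
        TRUE ~ NA_character_),
      .groups = "drop")
}

#' Normalised spectral dot product
#'
#' Cosine similarity of square-root-transformed intensity vectors (the
#' spectral-contrast-angle family); 1 iff the vectors are proportional.
#'
#' @param x,y Non-negative intensity vectors of equal length.
#' @return Dot product in `[0, 1]`.
#' @export
spectral_dot_product <- function(x, y) {
  stopifnot(length(x) == length(y), all(x >= 0), all(y >= 0))
  sx <- sqrt(x); sy <- sqrt(y)
  nx <- sqrt(sum(sx^2)); ny <- sqrt(sum(sy^2))
  if (nx == 0 || ny == 0) return(0)
  sum(sx * sy) / (nx * ny)
}

#' Filter PRM transition sets
#'
#' A monitored peptide passes when the dot product of its transition
#' intensities against the library spectrum reaches `dot_min`, no
#' transition deviates by more than `ppm_max`, at least `min_transitions`
#' transitions were monitored, and (for edited peptides) at least one
#' SAAV-diagnostic transition is included.
#'
#' @param transitions Tibble with one row per transition: `peptide`,
#'   `fragment`, `observed_intensity`, `library_intensity`, `ppm`,
#'   `is_diagnostic` (logical), `is_edited` (logical, per peptide).
#' @param dot_min Dot-product cutoff (default 0.85).
#' @param ppm_max Per-transition mass-deviation cutoff (default 1.3 ppm).
#' @param min_transitions Minimum transitions per peptide (default 2).
#' @return Tibble per peptide: `peptide`, `n_transitions`, `dot_product`,
#'   `max_ppm`, `pass`, `reasons` (semicolon-joined; empty when passing).
#' @export
prm_filter <- function(transitions, dot_min = 0.85, ppm_max = 1.3,
                       min_transitions = 2) {
  transitions %>%
    dplyr::group_by(.data$peptide) %>%
    dplyr::group_modify(function(d, key) {
      reasons <- character(0)
      dot <- NA_real_
      if (nrow(d) < min_transitions) {
        reasons <- c(reasons, sprintf("fewer than %d transitions", min_transitions))
      } else {
        dot <- spectral_dot_product(d$observed_intensity, d$library_intensity)
        if (dot < dot_min) reasons <- c(reasons, "dot_product")
      }
      mp <- max(abs(d$ppm))
      if (mp > ppm_max) reasons <- c(reasons, "ppm")
      if (any(d$is_edited) && !any(d$is_diagnostic)) {
        reasons <- c(reasons, "no diagnostic transition")
      }
      tibble::tibble(n_transitions = nrow(d), dot_product = dot, max_ppm = mp,
                     pass = length(reasons) == 0,
                     reasons = paste(reasons, collapse = ";"))
    }) %>%
    dplyr::ungroup()
}
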