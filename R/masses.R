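#' Monoisotopic residue masses
#'
#' Returns the monoisotopic masses (Da) of the 20 proteinogenic amino acid
#' residues (i.e. the mass each residue contributes inside a peptide chain,
#' water excluded).
#'
#' @return Named numeric vector of length 20 (one-letter residue codes).
#' @export
#' @examples
#' residue_masses()[["G"]]
residue_masses <- function() {
  c(
    G = 57.02146373, A = 71.03711379, S = 87.03202841, P = 97.05276385,
    V = 99.06841392, T = 101.04767847, C = 103.00918448, L = 113.08406398,
    I = 113.08406398, N = 114.04292744, D = 115.02694302, Q = 128.05857751,
    K = 128.09496302, E = 129.04259309, M = 131.04048509, H = 137.05891186,
    F = 147.06841392, R = 156.10111102, Y = 163.06332853, W = 186.07931295
  )
}

# physical constants (Da)
MASS_WATER <- 18.0105646863
MASS_PROTON <- 1.00727646688

#' Named modification mass deltas
#'
#' Monoisotopic deltas (Da) for the modifications handled by the pipeline:
#' carbamidomethylation of Cys (fixed alkylation), N-terminal acetylation,
#' and deamidation (Asn/Gln).
#'
#' @return Named numeric vector.
#' @export
mod_deltas <- function() {
  c(
    carbamidomethyl = 57.021464,
    acetyl = 42.010565,
    deamidation = 0.984016,
    water = MASS_WATER
  )
}

#' Monoisotopic peptide mass
#'
#' Sum of residue masses plus one water, plus any modification deltas.
#' Vectorised over `sequence`.
#'
#' @param sequence Character vector of peptide sequences (20-letter alphabet).
#' @param mods Numeric vector (recycled) of summed modification deltas in Da,
#'   e.g. `mod_deltas()[["acetyl"]]` for an N-terminally acetylated peptide.
#' @param fixed_cam Add carbamidomethyl (+57.021464 Da) to every Cys, the
#'   usual fixed alkylation.
#' @return Numeric vector of monoisotopic masses (Da).
#' @export
#' @examples
#' peptide_mass("G")               # 75.03203
#' peptide_mass("PEPTIDE", mods = mod_deltas()[["acetyl"]])
peptide_mass <- function(sequence, mods = 0, fixed_cam = FALSE) {
  stopifnot(is.character(sequence))
  if (any(!nzchar(sequence)) || any(is.na(sequence))) {
    stop("peptide_mass(): empty or missing peptide sequence")
  }
  tab <- residue_masses()
  if (fixed_cam) tab[["C"]] <- tab[["C"]] + mod_deltas()[["carbamidomethyl"]]
  vapply(sequence, function(s) {
    aa <- strsplit(s, "", fixed = TRUE)[[1]]
    bad <- setdiff(aa, names(tab))
    if (length(bad)) stop("peptide_mass(): unknown residue(s): ", paste(bad, collapse = ","))
    sum(tab[aa]) + MASS_WATER
  }, numeric(1), USE.NAMES = FALSE) + mods
}

#' Mass shift of an amino-acid substitution
#'
#' The theoretical monoisotopic mass difference caused by replacing one
#' residue by another: `mass(to) - mass(from)`. Antisymmetric by
#' construction.
#'
#' @param from_aa,to_aa Character vectors of one-letter residue codes
#'   (recycled against each other).
#' @return Numeric vector of mass shifts (Da).
#' @export
#' @examples
#' substitution_mass_shift("K", "E")  #  0.94763
#' substitution_mass_shift("R", "G")  # -99.07965
substitution_mass_shift <- function(from_aa, to_aa) {
  tab <- residue_masses()
  bad <- setdiff(c(from_aa, to_aa), names(tab))
  if (length(bad)) stop("substitution_mass_shift(): unknown residue(s): ", paste(bad, collapse = ","))
  unname(tab[to_aa] - tab[from_aa])
}
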