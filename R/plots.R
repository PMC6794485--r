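#' Density plot of precursor mass deviations by peptide class
#'
#' @param records Tibble with `ppm` and `peptide_class` columns.
#' @return A ggplot object.
#' @export
plot_mass_deviation <- function(records) {
  ggplot2::ggplot(records, ggplot2::aes(x = .data$ppm, colour = .data$peptide_class)) +
    ggplot2::geom_density() +
    ggplot2::labs(x = "precursor mass deviation (ppm)", y = "density",
                  colour = "class") +
    ggplot2::theme_minimal()
}

#' Peptide length distribution by class
#'
#' @param records Tibble with `length` and `peptide_class` columns.
#' @return A ggplot object.
#' @export
plot_peptide_length <- function(records) {
  ggplot2::ggplot(records, ggplot2::aes(x = .data$peptide_class, y = .data$length,
                                        fill = .data$peptide_class)) +
    ggplot2::geom_boxplot(show.legend = FALSE) +
    ggplot2::labs(x = NULL, y = "peptide length (aa)") +
    ggplot2::theme_minimal()
}

#' Observed retention time vs predicted hydrophobicity
#'
#' @param records Tibble with `retention_time`, `predicted_hi` (or
#'   `peptide`) and `peptide_class` columns.
#' @return A ggplot object (facetted per class).
#' @export
plot_rt_hi <- function(records) {
  if (!"predicted_hi" %in% names(records)) {
    records$predicted_hi <- predict_hi(records$peptide)
  }
  ggplot2::ggplot(records, ggplot2::aes(x = .data$predicted_hi,
                                        y = .data$retention_time)) +
    ggplot2::geom_point(alpha = 0.4, size = 0.8) +
    ggplot2::facet_wrap(ggplot2::vars(.data$peptide_class)) +
    ggplot2::labs(x = "predicted hydrophobicity index",
                  y = "retention time (min)") +
    ggplot2::theme_minimal()
}

#' Relative phylostratum occurrence plot
#'
#' @param distribution Output of [ps_distribution()].
#' @return A ggplot object.
#' @export
plot_ps_distribution <- function(distribution) {
  ggplot2::ggplot(distribution,
                  ggplot2::aes(x = factor(.data$ps_index), y = .data$fraction,
                               fill = .data$class)) +
    ggplot2::geom_col(position = "dodge") +
    ggplot2::labs(x = "phylostratum (1 = oldest)", y = "relative occurrence",
                  fill = "class") +
    ggplot2::theme_minimal()
}

#' Score distributions of a stepped search
#'
#' @param object An `editoscan_search` object.
#' @param ... Unused.
#' @return A ggplot object: per-step target vs decoy score densities.
#' @export
autoplot.editoscan_search <- function(object, ...) {
  d <- object$psms
  d$kind <- ifelse(d$is_decoy, "decoy", "target")
  ggplot2::ggplot(d, ggplot2::aes(x = .data$score, colour = .data$kind)) +
    ggplot2::geom_density() +
    ggplot2::facet_wrap(ggplot2::vars(.data$database)) +
    ggplot2::labs(x = "search score", y = "density", colour = NULL) +
    ggplot2::theme_minimal()
}

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot
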