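#' Default 15-phylostratum map
#'
#' Ordered taxonomy levels from all cellular organisms (PS1, oldest) to
#' *Sordaria macrospora* (PS15, youngest). PS1 and PS15 follow the study
#' design directly; the intermediate ranks are a reconstruction from the
#' standard NCBI lineage of *S. macrospora* and are meant to be edited for
#' other focal species (the map ships as a plain TSV, see
#' `system.file("extdata", "ps15_map.tsv", package = "editoscan")`).
#'
#' @return Tibble `ps_index`, `ps_name`, `lineage_token`.
#' @export
default_ps_map <- function() {
  path <- system.file("extdata", "ps15_map.tsv", package = "editoscan")
  dplyr::mutate(readr::read_tsv(path, show_col_types = FALSE, progress = FALSE),
                ps_index = as.integer(.data$ps_index))
}

# deepest (youngest) PS whose lineage token equals one of the subject's
# semicolon-delimited lineage fields; NA when none matches. Field equality
# (not substring) keeps nested rank names (e.g. a genus name contained in
# an order name) from cross-matching.
subject_ps <- function(lineage, ps_map) {
  fields <- trimws(strsplit(lineage, ";", fixed = TRUE)[[1]])
  hits <- ps_map$lineage_token %in% fields
  if (!any(hits)) return(NA_integer_)
  as.integer(max(ps_map$ps_index[hits]))
}

#' Assign phylostrata from homology hit tables
#'
#' Each protein is assigned to the oldest phylostratum producing at least
#' one hit with E-value below `cutoff`; proteins with no qualifying hit are
#' assigned to the youngest phylostratum. A hit's phylostratum is the
#' deepest map level whose taxon token occurs in the subject's
#' semicolon-delimited lineage; hits with unresolvable lineages are skipped
#' with a warning.
#'
#' @param hits Tibble with columns `query` (protein id), `lineage`
#'   (semicolon-delimited subject lineage) and `evalue`.
#' @param ps_map Phylostratum map (default [default_ps_map()]).
#' @param cutoff E-value cutoff (default 1e-5); hits must be strictly
#'   below it to qualify.
#' @param all_queries Optional character vector of protein ids to report
#'   even when absent from `hits` (they get the youngest PS).
#' @return Tibble `protein_id`, `ps_index`.
#' @export
assign_phylostratum <- function(hits, ps_map = default_ps_map(), cutoff = 1e-5,
                                all_queries = NULL) {
  youngest <- max(ps_map$ps_index)
  hits$hit_ps <- vapply(hits$lineage, subject_ps, integer(1), ps_map = ps_map,
                        USE.NAMES = FALSE)
  if (any(is.na(hits$hit_ps))) {
    warning("assign_phylostratum(): skipping ", sum(is.na(hits$hit_ps)),
            " hit(s) with unresolvable lineage")
    hits <- hits[!is.na(hits$hit_ps), , drop = FALSE]
  }
  qual <- hits[hits$evalue < cutoff, , drop = FALSE]
  assigned <- if (nrow(qual)) {
    qual %>%
      dplyr::group_by(protein_id = .data$query) %>%
      dplyr::summarise(ps_index = min(.data$hit_ps), .groups = "drop")
  } else {
    tibble::tibble(protein_id = character(), ps_index = integer())
  }
  queries <- unique(c(hits$query, all_queries))
  missing <- setdiff(queries, assigned$protein_id)
  dplyr::bind_rows(
    assigned,
    tibble::tibble(protein_id = missing, ps_index = youngest)
  ) %>% dplyr::arrange(.data$protein_id)
}

#' Relative phylostratum occurrence per protein class
#'
#' @param assignments Tibble `protein_id`, `ps_index` and (optionally) a
#'   `class` column (e.g. known_detected / novel / known_undetected).
#' @param ps_map Phylostratum map (defines the row range).
#' @return Tibble with one row per (class, ps_index) and the fraction of
#'   the class assigned there; fractions sum to 1 within each non-empty
#'   class.
#' @export
ps_distribution <- function(assignments, ps_map = default_ps_map()) {
  if (!nrow(assignments)) stop("ps_distribution(): no assignments")
  if (!"class" %in% names(assignments)) assignments$class <- "all"
  grid <- tidyr::expand_grid(class = unique(assignments$class),
                             ps_index = ps_map$ps_index)
  counts <- assignments %>%
    dplyr::count(.data$class, .data$ps_index, name = "n")
  grid %>%
    dplyr::left_join(counts, by = c("class", "ps_index")) %>%
    dplyr::mutate(n = dplyr::coalesce(.data$n, 0L)) %>%
    dplyr::group_by(.data$class) %>%
    dplyr::mutate(fraction = .data$n / sum(.data$n)) %>%
    dplyr::ungroup()
}

#' Per-protein best-E-value heat table across phylostrata
#'
#' For every protein and phylostratum, the mean log10 E-value of the up to
#' `top_k` best qualifying hits; cells with no hit get `sentinel`. Rows are
#' ordered by hierarchical clustering (Ward linkage on Euclidean distance)
#' so related age profiles are adjacent.
#'
#' @param hits Homology hit tibble (`query`, `lineage`, `evalue`).
#' @param ps_map Phylostratum map.
#' @param top_k Number of best hits averaged per cell (default 5).
#' @param sentinel Value for empty cells (default 0, i.e. log10 of a
#'   cutoff-failing E-value of 1).
#' @return Numeric matrix (proteins x PS) in clustered row order.
#' @export
ps_heat_table <- function(hits, ps_map = default_ps_map(), top_k = 5, sentinel = 0) {
  hits$hit_ps <- vapply(hits$lineage, subject_ps, integer(1), ps_map = ps_map,
                        USE.NAMES = FALSE)
  hits <- hits[!is.na(hits$hit_ps), , drop = FALSE]
  cells <- hits %>%
    dplyr::group_by(.data$query, .data$hit_ps) %>%
    dplyr::summarise(
      value = mean(log10(sort(.data$evalue)[seq_len(min(top_k, dplyr::n()))])),
      .groups = "drop")
  proteins <- sort(unique(hits$query))
  m <- matrix(sentinel, nrow = length(proteins), ncol = max(ps_map$ps_index),
              dimnames = list(proteins, paste0("PS", ps_map$ps_index)))
  m[cbind(match(cells$query, proteins), cells$hit_ps)] <- cells$value
  if (nrow(m) > 2) {
    ord <- stats::hclust(stats::dist(m), method = "ward.D2")$order
    m <- m[ord, , drop = FALSE]
  }
  m
}
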