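#' Median RNA-Seq depth over a locus
#'
#' @param coverage Tibble with `contig`, `pos` (0-based) and `depth`
#'   columns (per-base rows; positions absent from the table count as 0).
#' @param contig,start,end Locus (0-based half-open).
#' @return Median depth over the locus.
#' @export
locus_median_depth <- function(coverage, contig, start, end) {
  n <- end - start
  if (n <= 0) return(0)
  cc <- coverage[coverage$contig == contig &
                   coverage$pos >= start & coverage$pos < end, , drop = FALSE]
  depths <- c(cc$depth, rep(0, n - nrow(cc)))
  stats::median(depths)
}

#' Collect refinement evidence bundles
#'
#' Groups classified peptide hits into per-locus evidence bundles:
#' gene-linked bundles (one per annotated gene with overlapping novel
#' evidence) and intergenic bundles (clusters of intergenic hits merged
#' while gaps stay below `max_gap`). Each bundle carries the distinct novel
#' peptides (I/L-deduplicated, with length/uniqueness/modification flags),
#' the count of known peptides at the locus, whether median RNA-Seq depth
#' reaches `depth_threshold`, the external homology-support flag, and
#' geometry flags consumed by [decide_refinement()].
#'
#' @param hits Genomic peptide hits with a `novelty` column.
#' @param annotation Gene-model tibble.
#' @param coverage Per-base coverage tibble (`contig`, `pos`, `depth`).
#' @param depth_threshold Median depth needed for "sufficient" RNA-Seq
#'   support (default 10).
#' @param max_gap Maximum gap (nt) when clustering intergenic hits
#'   (default 500).
#' @param modified_peptides Character vector of peptide sequences carrying
#'   modifications (such peptides cannot support novel-gene calls).
#' @param homology_loci Character vector of gene ids / cluster keys with
#'   external homology support (pass-through flag).
#' @return Tibble of evidence bundles.
#' @export
bundle_evidence <- function(hits, annotation, coverage, depth_threshold = 10,
                            max_gap = 500, modified_peptides = character(0),
                            homology_loci = character(0)) {
  stopifnot("novelty" %in% names(hits))
  hits$hit_start <- vapply(hits$blocks, function(b) min(b$start), numeric(1))
  hits$hit_end <- vapply(hits$blocks, function(b) max(b$end), numeric(1))

  bundles <- list()

  # gene-linked bundles: novel evidence overlapping an annotated gene
  genic <- hits[hits$novelty %in% c("novel_intragenic", "junction_variant"), , drop = FALSE]
  if (nrow(genic)) {
    genic$near_gene <- vapply(seq_len(nrow(genic)), function(i) {
      g <- gene_span_overlap(genic$contig[i], genic$hit_start[i], genic$hit_end[i], annotation)
      if (length(g)) g[1] else NA_character_
    }, character(1))
    genic <- genic[!is.na(genic$near_gene), , drop = FALSE]
    for (gid in unique(genic$near_gene)) {
      gh <- genic[genic$near_gene == gid, , drop = FALSE]
      g <- annotation[match(gid, annotation$gene_id), ]
      span <- c(min(gh$hit_start), max(gh$hit_end))
      known_here <- hits[hits$novelty == "known" & hits$contig == g$contig &
                           !is.na(hits$gene_id) & hits$gene_id == gid, , drop = FALSE]
      bundles[[length(bundles) + 1L]] <- make_bundle(
        locus_id = gid, contig = g$contig, start = span[1], end = span[2],
        is_intergenic = FALSE, gene_id = gid, novel = gh, n_known = nrow(known_here),
        coverage = coverage, depth_threshold = depth_threshold,
        modified_peptides = modified_peptides,
        homology = gid %in% homology_loci, annotation = annotation, gene = g)
    }
  }

  # intergenic clusters
  inter <- hits[hits$novelty == "novel_intergenic", , drop = FALSE]
  if (nrow(inter)) {
    inter <- inter[order(inter$contig, inter$hit_start), , drop = FALSE]
    cluster <- integer(nrow(inter))
    cid <- 0L
    last_contig <- ""
    last_end <- -Inf
    for (i in seq_len(nrow(inter))) {
      if (i == 1L || inter$contig[i] != last_contig ||
          inter$hit_start[i] - last_end >= max_gap) {
        cid <- cid + 1L
        last_end <- inter$hit_end[i]
      } else {
        last_end <- max(last_end, inter$hit_end[i])
      }
      cluster[i] <- cid
      last_contig <- inter$contig[i]
    }
    inter$cluster <- cluster
    for (cl in unique(cluster)) {
      ch <- inter[inter$cluster == cl, , drop = FALSE]
      key <- sprintf("%s:%d-%d", ch$contig[1], min(ch$hit_start), max(ch$hit_end))
      bundles[[length(bundles) + 1L]] <- make_bundle(
        locus_id = key, contig = ch$contig[1],
        start = min(ch$hit_start), end = max(ch$hit_end),
        is_intergenic = TRUE, gene_id = NA_character_, novel = ch, n_known = 0L,
        coverage = coverage, depth_threshold = depth_threshold,
        modified_peptides = modified_peptides,
        homology = key %in% homology_loci, annotation = annotation, gene = NULL)
    }
  }
  dplyr::bind_rows(bundles)
}

make_bundle <- function(locus_id, contig, start, end, is_intergenic, gene_id,
                        novel, n_known, coverage, depth_threshold,
                        modified_peptides, homology, annotation, gene) {
  novel <- novel[!duplicated(collapse_il(novel$peptide)), , drop = FALSE]
  unmod <- !novel$peptide %in% modified_peptides
  uniq <- if ("is_unique" %in% names(novel)) novel$is_unique else TRUE
  lens <- nchar(novel$peptide)
  geom <- bundle_geometry(novel, gene, annotation)
  tibble::tibble(
    locus_id = locus_id, contig = contig, start = start, end = end,
    is_intergenic = is_intergenic, gene_id = gene_id,
    novel_peptides = list(novel$peptide),
    n_novel = nrow(novel),
    n_novel_good = sum(unmod & uniq),
    n_novel_classI = sum(unmod & uniq & lens > 8),
    n_known = n_known,
    rnaseq_sufficient = locus_median_depth(coverage, contig, start, end) >= depth_threshold,
    homology_support = homology,
    spans_junction = geom["spans_junction"],
    upstream_of_tis = geom["upstream_of_tis"],
    downstream_of_stop = geom["downstream_of_stop"],
    out_of_frame_in_cds = geom["out_of_frame_in_cds"],
    spans_two_genes = geom["spans_two_genes"],
    splits_gene = geom["splits_gene"],
    has_two_variants = FALSE
  )
}

# geometry flags of a gene-linked bundle (all FALSE for intergenic ones)
bundle_geometry <- function(novel, gene, annotation) {
  out <- c(spans_junction = FALSE, upstream_of_tis = FALSE,
           downstream_of_stop = FALSE, out_of_frame_in_cds = FALSE,
           spans_two_genes = FALSE, splits_gene = FALSE)
  if (is.null(gene) || !nrow(novel)) return(out)
  ex <- gene$exons[[1]]
  g_start <- min(ex$start); g_end <- max(ex$end)
  for (i in seq_len(nrow(novel))) {
    b <- novel$blocks[[i]]
    multiblock <- nrow(b) > 1
    if (multiblock || novel$novelty[i] == "junction_variant") out["spans_junction"] <- TRUE
    if (gene$strand == "+") {
      if (min(b$start) < g_start) out["upstream_of_tis"] <- TRUE
      if (max(b$end) > g_end) out["downstream_of_stop"] <- TRUE
    } else {
      if (max(b$end) > g_end) out["upstream_of_tis"] <- TRUE
      if (min(b$start) < g_start) out["downstream_of_stop"] <- TRUE
    }
    if (novel$novelty[i] == "novel_intragenic" &&
        min(b$start) >= g_start && max(b$end) <= g_end) {
      out["out_of_frame_in_cds"] <- TRUE
    }
    others <- gene_span_overlap(novel$contig[i], min(b$start), max(b$end), annotation)
    if (length(setdiff(others, gene$gene_id)) > 0) out["spans_two_genes"] <- TRUE
  }
  out
}

#' Decide refinement calls from evidence bundles
#'
#' Pure rule engine. For gene-linked bundles (refinements of existing
#' annotation) a call is emitted when (A) at least two distinct novel
#' peptides support it, or (B) one novel peptide plus at least one known
#' peptide when the geometry indicates a splice-site or TIS change. For
#' intergenic bundles (novel genes): class I (high confidence) requires at
#' least two distinct unmodified unique peptides longer than 8 residues
#' and sufficient RNA-Seq depth; class II (medium confidence) one such
#' peptide with sufficient depth, or two or more peptides with insufficient
#' depth but external homology support; anything else is rejected. The
#' refinement type is inferred from geometry with precedence splice_site >
#' TIS > extension > frameshift (fission/fusion from their dedicated flags).
#'
#' @param bundles Evidence-bundle tibble from [bundle_evidence()].
#' @return Tibble of refinement calls: `locus_id`, `gene_id`, `type`,
#'   `confidence` (`classI`/`classII`/`rejected`, novel calls only),
#'   `accepted`, `reason`, supporting-peptide list, `has_two_variants`.
#' @export
decide_refinement <- function(bundles) {
  rows <- purrr::map(seq_len(nrow(bundles)), function(i) {
    b <- bundles[i, ]
    if (b$is_intergenic) {
      classI <- b$n_novel_classI >= 2 && b$rnaseq_sufficient
      classII <- (!classI) &&
        ((b$n_novel_good == 1 && b$rnaseq_sufficient) ||
           (b$n_novel_good >= 2 && !b$rnaseq_sufficient && b$homology_support))
      conf <- if (classI) "classI" else if (classII) "classII" else "rejected"
      tibble::tibble(
        locus_id = b$locus_id, gene_id = NA_character_, contig = b$contig,
        start = b$start, end = b$end, type = "novel", confidence = conf,
        accepted = conf != "rejected",
        reason = if (conf == "rejected") "insufficient evidence (rule ii)" else NA_character_,
        peptides = b$novel_peptides, has_two_variants = b$has_two_variants
      )
    } else {
      type <- if (b$spans_two_genes) "fusion"
        else if (b$splits_gene) "fission"
        else if (b$spans_junction) "splice_site"
        else if (b$upstream_of_tis) "TIS"
        else if (b$downstream_of_stop) "extension"
        else if (b$out_of_frame_in_cds) "frameshift"
        else NA_character_
      ok_a <- b$n_novel >= 2
      ok_b <- b$n_novel >= 1 && b$n_known >= 1 && isTRUE(type %in% c("splice_site", "TIS"))
      accepted <- !is.na(type) && (ok_a || ok_b)
      tibble::tibble(
        locus_id = b$locus_id, gene_id = b$gene_id, contig = b$contig,
        start = b$start, end = b$end, type = type, confidence = NA_character_,
        accepted = accepted,
        reason = dplyr::case_when(
          is.na(type) ~ "no geometric signal",
          !accepted ~ "insufficient evidence (rule i)",
          TRUE ~ NA_character_),
        peptides = b$novel_peptides, has_two_variants = b$has_two_variants
      )
    }
  })
  dplyr::bind_rows(rows)
}

#' Apply refinement calls to an annotation
#'
#' Applies accepted calls and logs every change with before/after
#' coordinates. Novel calls need explicit new-gene coordinates (`new_exons`
#' list-column plus `strand`); TIS/extension calls shift the CDS start/end
#' by `shift_nt` (positive = move the coding start upstream / the coding
#' end downstream on the coding strand); splice-site calls replace the
#' donor/acceptor coordinates of exon `exon_index` via `new_end` /
#' `new_start2`. Conflicting calls on one gene (two accepted calls of the
#' same type) are both logged and neither applied. The output annotation
#' is re-validated; calls whose result violates gene-model invariants are
#' logged as failed and skipped.
#'
#' @param annotation Gene-model tibble.
#' @param calls Refinement-call tibble (accepted rows are applied). Novel
#'   calls may carry `new_exons` (list of exon tibbles), `new_strand`,
#'   `new_phase`; TIS/extension calls carry `shift_nt`.
#' @param genome Genome for re-validation (optional but recommended).
#' @return List with `annotation` (updated), `log` (change log tibble) and
#'   `conflicts` (conflict report tibble).
#' @export
apply_refinements <- function(annotation, calls, genome = NULL) {
  log <- list()
  conflicts <- list()
  ann <- annotation
  applied <- calls[calls$accepted, , drop = FALSE]

  # conflict detection: >1 accepted call of the same type on one gene
  if (nrow(applied)) {
    key <- paste(applied$gene_id, applied$type)
    dup <- key %in% key[duplicated(key)] & !is.na(applied$gene_id)
    if (any(dup)) {
      conflicts <- list(tibble::tibble(
        gene_id = applied$gene_id[dup], type = applied$type[dup],
        locus_id = applied$locus_id[dup], note = "conflicting calls; none applied"))
      applied <- applied[!dup, , drop = FALSE]
    }
  }

  for (i in seq_len(nrow(applied))) {
    cl <- applied[i, ]
    before <- NA_character_
    ok <- TRUE
    note <- NA_character_
    if (cl$type == "novel") {
      new_ex <- if ("new_exons" %in% names(cl)) cl$new_exons[[1]] else NULL
      if (is.null(new_ex)) {
        ok <- FALSE; note <- "novel call without explicit coordinates"
      } else {
        gid <- paste0("novel_", gsub("[^A-Za-z0-9]", "_", cl$locus_id))
        cand <- tibble::tibble(
          gene_id = gid, locus_tag = gid, contig = cl$contig,
          strand = if ("new_strand" %in% names(cl)) cl$new_strand else "+",
          exons = list(new_ex), cds_phase = 0L,
          is_partial_5p = FALSE, is_partial_3p = FALSE)
        ok <- validate_or_fail(cand, genome)
        if (ok) ann <- dplyr::bind_rows(ann, cand) else note <- "new gene fails validation"
      }
    } else if (cl$type %in% c("TIS", "extension")) {
      j <- match(cl$gene_id, ann$gene_id)
      shift <- if ("shift_nt" %in% names(cl)) cl$shift_nt else NA_integer_
      if (is.na(j) || is.na(shift)) {
        ok <- FALSE; note <- "missing gene or shift_nt"
      } else {
        g <- ann[j, ]
        ex <- g$exons[[1]]
        before <- exons_str(ex)
        if (cl$type == "TIS") {
          if (g$strand == "+") ex$start[1] <- ex$start[1] - shift
          else ex$end[nrow(ex)] <- ex$end[nrow(ex)] + shift
        } else {
          if (g$strand == "+") ex$end[nrow(ex)] <- ex$end[nrow(ex)] + shift
          else ex$start[1] <- ex$start[1] - shift
        }
        g$exons <- list(ex)
        ok <- validate_or_fail(g, genome)
        if (ok) ann$exons[[j]] <- ex else note <- "refined model fails validation"
      }
    } else if (cl$type == "splice_site") {
      j <- match(cl$gene_id, ann$gene_id)
      if (is.na(j) || !"exon_index" %in% names(cl) || is.na(cl$exon_index)) {
        ok <- FALSE; note <- "missing gene or exon_index"
      } else {
        g <- ann[j, ]
        ex <- g$exons[[1]]
        before <- exons_str(ex)
        k <- cl$exon_index
        if ("new_end" %in% names(cl) && !is.na(cl$new_end)) ex$end[k] <- cl$new_end
        if ("new_start2" %in% names(cl) && !is.na(cl$new_start2)) ex$start[k + 1] <- cl$new_start2
        g$exons <- list(ex)
        ok <- validate_or_fail(g, genome)
        if (ok) ann$exons[[j]] <- ex else note <- "refined model fails validation"
      }
    } else {
      # frameshift / fission / fusion restructure models in ways that need
      # manual coordinates; log only unless coordinates were provided
      ok <- FALSE
      note <- paste0(cl$type, " call logged; manual coordinates required")
    }
    j2 <- match(cl$gene_id, ann$gene_id)
    log[[length(log) + 1L]] <- tibble::tibble(
      locus_id = cl$locus_id, gene_id = cl$gene_id, type = cl$type,
      applied = ok, before = before,
      after = if (ok && !is.na(cl$gene_id) && !is.na(j2)) exons_str(ann$exons[[j2]]) else NA_character_,
      note = note)
  }
  list(annotation = ann,
       log = dplyr::bind_rows(log),
       conflicts = dplyr::bind_rows(conflicts))
}

exons_str <- function(ex) paste(ex$start, ex$end, sep = "-", collapse = ";")

validate_or_fail <- function(gene_row, genome) {
  if (is.null(genome)) return(TRUE)
  ok <- TRUE
  tryCatch(validate_annotation(gene_row, genome), error = function(e) ok <<- FALSE)
  ok
}

#' Summarise refinement calls by category
#'
#' @param calls Refinement-call tibble.
#' @param accepted_only Count only accepted calls (default TRUE).
#' @return Tibble `type`, `n`, `n_two_variants`.
#' @export
summarize_refinements <- function(calls, accepted_only = TRUE) {
  types <- c("splice_site", "TIS", "extension", "frameshift",
             "fission", "fusion", "novel")
  if (accepted_only) calls <- calls[calls$accepted, , drop = FALSE]
  counts <- table(factor(calls$type, levels = types))
  tv <- table(factor(calls$type[calls$has_two_variants], levels = types))
  tibble::tibble(type = types, n = as.integer(counts), n_two_variants = as.integer(tv))
}
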