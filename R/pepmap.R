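#' Map peptides to protein sequences
#'
#' Exact substring search of each peptide against a protein database, by
#' default after collapsing I to L on both sides (Ile/Leu are isobaric).
#' All occurrences are reported.
#'
#' @param peptides Character vector of peptide sequences, or a data frame
#'   with a `sequence` column.
#' @param db Protein database tibble (`protein_id`, `sequence`).
#' @param equate_il Collapse I to L before matching (default TRUE).
#' @return Tibble with `peptide`, `protein_id`, `offset` (0-based).
#' @export
map_peptide_to_proteins <- function(peptides, db, equate_il = TRUE) {
  if (is.data.frame(peptides)) peptides <- peptides$sequence
  peptides <- unique(peptides[!is.na(peptides) & nzchar(peptides)])
  if (!length(peptides) || !nrow(db)) {
    return(tibble::tibble(peptide = character(), protein_id = character(),
                          offset = integer()))
  }
  subj <- Biostrings::AAStringSet(stats::setNames(
    if (equate_il) collapse_il(db$sequence) else db$sequence, db$protein_id))
  rows <- purrr::map(peptides, function(p) {
    q <- if (equate_il) collapse_il(p) else p
    m <- Biostrings::vmatchPattern(q, subj)
    st <- Biostrings::startIndex(m)
    hits <- purrr::imap(st, function(s, i) {
      if (is.null(s) || !length(s)) return(NULL)
      tibble::tibble(peptide = p, protein_id = db$protein_id[i], offset = s - 1L)
    })
    dplyr::bind_rows(hits)
  })
  dplyr::bind_rows(rows)
}

# transcript-coordinate nt interval [nt_start, nt_end) -> genomic blocks
# through the gene's coding segments (ascending forward-strand tibble)
transcript_to_blocks <- function(segments, strand, nt_start, nt_end) {
  lens <- segments$end - segments$start
  # order segments in transcript (coding) order
  ord <- if (strand == "+") seq_len(nrow(segments)) else rev(seq_len(nrow(segments)))
  lens <- lens[ord]
  offs <- cumsum(c(0, lens))[seq_along(lens)]
  blocks <- list()
  for (k in seq_along(ord)) {
    s0 <- max(nt_start, offs[k])
    e0 <- min(nt_end, offs[k] + lens[k])
    if (e0 <= s0) next
    seg <- segments[ord[k], ]
    if (strand == "+") {
      blocks[[length(blocks) + 1L]] <- c(seg$start + (s0 - offs[k]), seg$start + (e0 - offs[k]))
    } else {
      blocks[[length(blocks) + 1L]] <- c(seg$end - (e0 - offs[k]), seg$end - (s0 - offs[k]))
    }
  }
  b <- do.call(rbind, blocks)
  tibble::tibble(start = b[, 1], end = b[, 2]) %>% dplyr::arrange(.data$start)
}

#' Map peptides to genome coordinates
#'
#' Combines exact matches against deduplicated six-frame fragments (via
#' their stored provenance) with matches against annotated spliced proteins
#' (which yield multi-block, exon-spanning coordinates through the gene
#' model). Hits identical in genomic location are deduplicated;
#' `is_unique` marks peptides hitting exactly one genomic locus after I/L
#' collapsing.
#'
#' @param peptides Character vector (or data frame with `sequence`).
#' @param sixframe Six-frame protein database tibble (with provenance).
#' @param proteins Annotated protein tibble from [translate_genes()].
#' @param genome Genome named character vector (used to verify provenance).
#' @param equate_il Collapse I/L before matching (default TRUE).
#' @return Tibble of genomic peptide hits: `peptide`, `contig`, `strand`,
#'   `frame`, `blocks` (list of 0-based half-open intervals ascending on
#'   the forward strand), `gene_id`, `n_loci`, `is_unique`.
#' @export
map_peptide_to_genome <- function(peptides, sixframe, proteins, genome,
                                  equate_il = TRUE) {
  if (is.data.frame(peptides)) peptides <- peptides$sequence
  peptides <- unique(peptides)
  sixframe <- dedup_fragments(sixframe)

  # verify six-frame provenance against the genome (corrupt-database guard)
  if (nrow(sixframe)) {
    chk <- sample(seq_len(nrow(sixframe)), min(25L, nrow(sixframe)))
    for (i in chk) {
      f <- sixframe[i, ]
      nt <- substring(genome[[f$contig]], f$start + 1L, f$end)
      if (f$strand == "-") nt <- revcomp(nt)
      if (!identical(translate_nt(nt), f$sequence)) {
        stop("map_peptide_to_genome(): six-frame provenance does not reproduce ",
             "fragment ", f$protein_id, " (corrupt database)")
      }
    }
  }

  hits6 <- map_peptide_to_proteins(peptides, sixframe, equate_il = equate_il)
  rows6 <- purrr::map(seq_len(nrow(hits6)), function(i) {
    h <- hits6[i, ]
    f <- sixframe[match(h$protein_id, sixframe$protein_id), ]
    plen <- nchar(h$peptide)
    if (f$strand == "+") {
      bs <- f$start + 3L * h$offset
      be <- bs + 3L * plen
    } else {
      be <- f$end - 3L * h$offset
      bs <- be - 3L * plen
    }
    tibble::tibble(peptide = h$peptide, contig = f$contig, strand = f$strand,
                   frame = f$frame, blocks = list(tibble::tibble(start = bs, end = be)),
                   gene_id = NA_character_)
  })

  ann <- proteins[proteins$source == "annotated", , drop = FALSE]
  hitsA <- map_peptide_to_proteins(peptides, ann, equate_il = equate_il)
  rowsA <- purrr::map(seq_len(nrow(hitsA)), function(i) {
    h <- hitsA[i, ]
    p <- ann[match(h$protein_id, ann$protein_id), ]
    blocks <- transcript_to_blocks(p$segments[[1]], p$strand,
                                   3L * h$offset, 3L * (h$offset + nchar(h$peptide)))
    tibble::tibble(peptide = h$peptide, contig = p$contig, strand = p$strand,
                   frame = NA_integer_, blocks = list(blocks), gene_id = p$gene_id)
  })

  hits <- dplyr::bind_rows(c(rows6, rowsA))
  if (!nrow(hits)) {
    return(tibble::tibble(peptide = character(), contig = character(),
                          strand = character(), frame = integer(), blocks = list(),
                          gene_id = character(), n_loci = integer(), is_unique = logical()))
  }
  hits$locus_key <- paste(
    hits$contig, hits$strand,
    vapply(hits$blocks, function(b) paste(b$start, b$end, sep = "-", collapse = ";"),
           character(1)),
    sep = "|")
  hits <- hits %>%
    dplyr::arrange(.data$peptide, .data$locus_key, !is.na(.data$gene_id)) %>%
    dplyr::group_by(.data$peptide, .data$locus_key) %>%
    dplyr::slice_tail(n = 1) %>% # prefer the gene-linked record at a shared locus
    dplyr::ungroup()
  hits <- hits %>%
    dplyr::group_by(.data$peptide) %>%
    dplyr::mutate(n_loci = dplyr::n_distinct(.data$locus_key)) %>%
    dplyr::ungroup() %>%
    dplyr::mutate(is_unique = .data$n_loci == 1L) %>%
    dplyr::select(-"locus_key")
  hits
}

# does a hit overlap a gene's span on the same strand?
gene_span_overlap <- function(hit_contig, hit_start, hit_end, annotation) {
  spans <- annotation %>%
    dplyr::mutate(
      g_start = vapply(.data$exons, function(e) min(e$start), numeric(1)),
      g_end = vapply(.data$exons, function(e) max(e$end), numeric(1))
    )
  spans$gene_id[spans$contig == hit_contig &
                  spans$g_start < hit_end & spans$g_end > hit_start]
}

#' Classify mapped peptides as known or novel
#'
#' A peptide is `known` if it is an (I/L-collapsed) substring of an
#' annotated protein; `novel_intergenic` if its locus overlaps no annotated
#' gene span; `novel_intragenic` if it overlaps a gene but is absent from
#' its protein and not in frame with an annotated coding exon;
#' `junction_variant` if it overlaps annotated coding sequence in frame but
#' disagrees with the annotation across an exon boundary.
#'
#' @param hits Genomic peptide hits from [map_peptide_to_genome()].
#' @param annotation Gene-model tibble.
#' @param proteins Annotated protein tibble.
#' @param equate_il Collapse I/L for the known check (default TRUE).
#' @return `hits` with a `novelty` column.
#' @export
classify_novelty <- function(hits, annotation, proteins, equate_il = TRUE) {
  ann <- proteins[proteins$source == "annotated", , drop = FALSE]
  prot_seq <- if (equate_il) collapse_il(ann$sequence) else ann$sequence
  hay <- paste(prot_seq, collapse = "#")
  known_pep <- vapply(unique(hits$peptide), function(p) {
    grepl(if (equate_il) collapse_il(p) else p, hay, fixed = TRUE)
  }, logical(1))

  hits$novelty <- NA_character_
  for (i in seq_len(nrow(hits))) {
    h <- hits[i, ]
    if (known_pep[[h$peptide]]) {
      hits$novelty[i] <- "known"
      next
    }
    b <- h$blocks[[1]]
    genes <- gene_span_overlap(h$contig, min(b$start), max(b$end), annotation)
    if (!length(genes)) {
      hits$novelty[i] <- "novel_intergenic"
      next
    }
    # in-frame with an annotated coding exon of an overlapping same-strand gene?
    inframe <- FALSE
    for (gid in genes) {
      g <- annotation[match(gid, annotation$gene_id), ]
      if (g$strand != h$strand) next
      segs <- coding_segments(g, drop_stop = FALSE)
      for (j in seq_len(nrow(b))) {
        for (k in seq_len(nrow(segs))) {
          ov_s <- max(b$start[j], segs$start[k])
          ov_e <- min(b$end[j], segs$end[k])
          if (ov_e <= ov_s) next
          ph <- if (g$strand == "+") {
            (b$start[j] - segs$start[k]) %% 3L
          } else {
            (segs$end[k] - b$end[j]) %% 3L
          }
          if (ph == 0L) inframe <- TRUE
        }
      }
    }
    hits$novelty[i] <- if (inframe) "junction_variant" else "novel_intragenic"
  }
  hits
}

#' Splice-junction coverage from exon-spanning peptides
#'
#' A junction is covered when at least one mapped peptide has two adjacent
#' blocks abutting the intron with at least `min_flank_aa` residues' worth
#' of coding sequence on each side.
#'
#' @param hits Genomic peptide hits.
#' @param annotation Gene-model tibble.
#' @param min_flank_aa Minimum residues on each side (default 1).
#' @return Tibble `gene_id`, `covered`, `total`; intronless genes report
#'   `(0, 0)` and drop out of the global ratio, which is stored in the
#'   `"ratio"` attribute.
#' @export
count_junction_coverage <- function(hits, annotation, min_flank_aa = 1) {
  res <- purrr::map(seq_len(nrow(annotation)), function(i) {
    g <- annotation[i, ]
    segs <- coding_segments(g, drop_stop = FALSE)
    n_j <- max(0L, nrow(segs) - 1L)
    covered <- 0L
    if (n_j > 0) {
      gh <- hits[hits$contig == g$contig & hits$strand == g$strand, , drop = FALSE]
      for (j in seq_len(n_j)) {
        int_start <- segs$end[j]
        int_end <- segs$start[j + 1]
        hit_ok <- FALSE
        for (r in seq_len(nrow(gh))) {
          b <- gh$blocks[[r]]
          if (nrow(b) < 2) next
          for (k in seq_len(nrow(b) - 1)) {
            flank_nt <- 3 * (min_flank_aa - 1) + 1 # partially encoded residues count
            if (b$end[k] == int_start && b$start[k + 1] == int_end &&
                (b$end[k] - b$start[k]) >= flank_nt &&
                (b$end[k + 1] - b$start[k + 1]) >= flank_nt) {
              hit_ok <- TRUE
            }
          }
        }
        covered <- covered + as.integer(hit_ok)
      }
    }
    tibble::tibble(gene_id = g$gene_id, covered = covered, total = n_j)
  })
  out <- dplyr::bind_rows(res)
  denom <- sum(out$total)
  attr(out, "ratio") <- if (denom > 0) sum(out$covered) / denom else NA_real_
  out
}

#' Validate translation initiation sites from N-terminal acetylation
#'
#' A TIS is validated when an accepted PSM carries an N-terminal acetyl
#' modification and its peptide starts at protein position 1, or at
#' position 2 when residue 1 is Met (initiator-Met excision).
#'
#' @param psms PSM tibble with `peptide` and a `mods` list-column (tibbles
#'   with `position` -- 0-based or "N-term" -- and `name`).
#' @param proteins Annotated protein tibble.
#' @param equate_il Collapse I/L when locating peptides (default TRUE).
#' @return Tibble `protein_id`, `peptide` of validated TIS.
#' @export
detect_nterm_acetyl_tis <- function(psms, proteins, equate_il = TRUE) {
  has_nterm_acetyl <- vapply(seq_len(nrow(psms)), function(i) {
    m <- psms$mods[[i]]
    if (is.null(m) || !nrow(m)) return(FALSE)
    any(m$name == "acetyl" & (m$position %in% c("N-term", "0")))
  }, logical(1))
  cand <- psms[has_nterm_acetyl, , drop = FALSE]
  if (!nrow(cand)) return(tibble::tibble(protein_id = character(), peptide = character()))
  locs <- map_peptide_to_proteins(unique(cand$peptide), proteins, equate_il = equate_il)
  met1 <- substring(proteins$sequence[match(locs$protein_id, proteins$protein_id)], 1, 1) == "M"
  ok <- locs$offset == 0L | (locs$offset == 1L & met1)
  dplyr::distinct(locs[ok, c("protein_id", "peptide")])
}

#' Export genomic peptide hits as BED12
#'
#' Blocks encode the coding segments of each hit (exon-spanning peptides
#' get one block per exon).
#'
#' @param hits Genomic peptide hits (optionally with `novelty`).
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
export_bed <- function(hits, path) {
  lines <- character(0)
  hits <- hits[order(hits$contig, vapply(hits$blocks, function(b) min(b$start), numeric(1))), ]
  for (i in seq_len(nrow(hits))) {
    h <- hits[i, ]
    b <- h$blocks[[1]]
    cs <- min(b$start); ce <- max(b$end)
    name <- if ("novelty" %in% names(hits) && !is.na(h$novelty)) {
      paste0(h$peptide, "|", h$novelty)
    } else h$peptide
    lines <- c(lines, paste(
      h$contig, cs, ce, name, 0, h$strand, cs, ce, "0,0,0",
      nrow(b), paste0(paste(b$end - b$start, collapse = ","), ","),
      paste0(paste(b$start - cs, collapse = ","), ","),
      sep = "\t"))
  }
  writeLines(lines, path)
  invisible(path)
}

#' Export genomic peptide hits as proBAM-style SAM
#'
#' Plain-text SAM with nucleotide-space alignments: `M` operations for
#' coding blocks and `N` operations across introns; reverse-strand hits set
#' FLAG 16 and SEQ is the forward-strand (reference) nucleotide sequence.
#' Optional tags: `XP:Z` peptide sequence, `XN:Z` novelty class.
#'
#' @param hits Genomic peptide hits (with `novelty` column if available).
#' @param genome Genome named character vector.
#' @param path Output path.
#' @return `path`, invisibly. Unmapped inputs are skipped with a message.
#' @export
export_probam <- function(hits, genome, path) {
  hdr <- c("@HD\tVN:1.6\tSO:coordinate",
           sprintf("@SQ\tSN:%s\tLN:%d", names(genome), nchar(genome)))
  hits <- hits[order(hits$contig, vapply(hits$blocks, function(b) min(b$start), numeric(1))), ]
  recs <- character(0)
  for (i in seq_len(nrow(hits))) {
    h <- hits[i, ]
    b <- h$blocks[[1]]
    if (!nrow(b) || !h$contig %in% names(genome)) {
      message("export_probam(): skipping unmapped record for peptide ", h$peptide)
      next
    }
    cig <- character(0)
    for (k in seq_len(nrow(b))) {
      cig <- c(cig, paste0(b$end[k] - b$start[k], "M"))
      if (k < nrow(b)) cig <- c(cig, paste0(b$start[k + 1] - b$end[k], "N"))
    }
    seq_nt <- paste(substring(genome[[h$contig]], b$start + 1L, b$end), collapse = "")
    flag <- if (h$strand == "-") 16L else 0L
    novelty <- if ("novelty" %in% names(hits) && !is.na(h$novelty)) h$novelty else "unclassified"
    recs <- c(recs, paste(
      paste0(h$peptide, "_", i), flag, h$contig, min(b$start) + 1L, 255,
      paste(cig, collapse = ""), "*", 0, 0, seq_nt, "*",
      paste0("XP:Z:", h$peptide), paste0("XN:Z:", novelty),
      sep = "\t"))
  }
  writeLines(c(hdr, recs), path)
  invisible(path)
}
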