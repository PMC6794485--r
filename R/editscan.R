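#' Align de novo peptides to proteins allowing one mismatch
#'
#' Finds every placement of each peptide in the protein database with
#' Hamming distance at most 1 after I/L collapsing. Distance-0 placements
#' flag the peptide as known (no variant); distance-1 placements record the
#' mismatch position and the reference/observed residue pair. I/L
#' exchanges are invisible by construction (mass-identical).
#'
#' @param denovo_peps Character vector of de novo peptide sequences, or a
#'   data frame with a `sequence` column.
#' @param proteins Protein database tibble.
#' @param equate_il Collapse I/L (default TRUE).
#' @param min_len Minimum peptide length considered (default 6).
#' @return Tibble with `peptide`, `protein_id`, `offset` (0-based),
#'   `n_mismatch` (0 or 1), `mismatch_pos` (0-based in the peptide, NA for
#'   exact), `ref_aa`, `alt_aa`, `n_placements` (distance-1 placements of
#'   this peptide, for uniqueness flags).
#' @export
align_one_mismatch <- function(denovo_peps, proteins, equate_il = TRUE, min_len = 6) {
  if (is.data.frame(denovo_peps)) denovo_peps <- denovo_peps$sequence
  denovo_peps <- denovo_peps[!is.na(denovo_peps)]
  denovo_peps <- unique(denovo_peps[nchar(denovo_peps) >= min_len])
  empty <- tibble::tibble(
    peptide = character(), protein_id = character(), offset = integer(),
    n_mismatch = integer(), mismatch_pos = integer(),
    ref_aa = character(), alt_aa = character(), n_placements = integer())
  if (!length(denovo_peps) || !nrow(proteins)) return(empty)
  subj <- Biostrings::AAStringSet(stats::setNames(
    if (equate_il) collapse_il(proteins$sequence) else proteins$sequence,
    proteins$protein_id))
  rows <- purrr::map(denovo_peps, function(p) {
    q <- if (equate_il) collapse_il(p) else p
    m <- Biostrings::vmatchPattern(q, subj, max.mismatch = 1)
    st <- Biostrings::startIndex(m)
    hits <- purrr::imap(st, function(s, i) {
      if (is.null(s) || !length(s)) return(NULL)
      prot <- proteins$sequence[i]
      prot_cmp <- as.character(subj[[i]])
      purrr::map(s, function(start) {
        if (start < 1 || start + nchar(q) - 1 > nchar(prot)) return(NULL)
        win <- substring(prot_cmp, start, start + nchar(q) - 1)
        diff <- which(strsplit(win, "")[[1]] != strsplit(q, "")[[1]])
        if (length(diff) > 1) return(NULL)
        if (length(diff) == 0) {
          tibble::tibble(peptide = p, protein_id = proteins$protein_id[i],
                         offset = start - 1L, n_mismatch = 0L,
                         mismatch_pos = NA_integer_, ref_aa = NA_character_,
                         alt_aa = NA_character_)
        } else {
          tibble::tibble(peptide = p, protein_id = proteins$protein_id[i],
                         offset = start - 1L, n_mismatch = 1L,
                         mismatch_pos = diff - 1L,
                         ref_aa = substring(prot, start + diff - 1L, start + diff - 1L),
                         alt_aa = substring(p, diff, diff))
        }
      }) %>% dplyr::bind_rows()
    })
    dplyr::bind_rows(hits)
  })
  out <- dplyr::bind_rows(rows)
  if (!nrow(out)) return(empty)
  out <- dplyr::distinct(out)
  out %>%
    dplyr::group_by(.data$peptide) %>%
    dplyr::mutate(n_placements = sum(.data$n_mismatch == 1L)) %>%
    dplyr::ungroup()
}

#' Ambiguity prefilter for SAAV candidates
#'
#' Discards single-mismatch hits whose theoretical mass difference is
#' indistinguishable from a common modification: +42.01056 Da at the
#' peptide N-terminal position (e.g. Ser-to-Glu, masked by N-terminal
#' acetylation) and +0.98402 Da at any position (Gln-to-Glu / Asn-to-Asp,
#' masked by deamidation).
#'
#' @param cands Tibble with `ref_aa`, `alt_aa`, `mismatch_pos` columns.
#' @param tol Absolute mass tolerance in Da (default 5e-4).
#' @return `cands` with `mass_shift`, `keep`, `discard_reason` columns.
#' @export
prefilter_saav <- function(cands, tol = 5e-4) {
  if (!nrow(cands)) {
    return(dplyr::mutate(cands, mass_shift = numeric(0), keep = logical(0),
                         discard_reason = character(0)))
  }
  cands$mass_shift <- substitution_mass_shift(cands$ref_aa, cands$alt_aa)
  acetyl <- mod_deltas()[["acetyl"]]
  deam <- mod_deltas()[["deamidation"]]
  nterm_amb <- abs(cands$mass_shift - acetyl) <= tol & cands$mismatch_pos == 0L
  deam_amb <- abs(cands$mass_shift - deam) <= tol
  cands$discard_reason <- dplyr::case_when(
    deam_amb ~ "deamidation_ambiguity",
    nterm_amb ~ "nterm_acetyl_ambiguity",
    TRUE ~ NA_character_
  )
  cands$keep <- is.na(cands$discard_reason)
  cands
}

# non-empty subsets of the A positions of a codon (singletons only unless
# multi); guards the combn() scalar pitfall for a single A position
a_subsets <- function(a_pos, multi) {
  if (!length(a_pos)) return(list())
  if (!multi || length(a_pos) == 1L) return(as.list(a_pos))
  unlist(lapply(seq_along(a_pos),
                function(k) utils::combn(a_pos, k, simplify = FALSE)),
         recursive = FALSE)
}

#' Can A-to-I editing produce this substitution at this codon?
#'
#' Inosine is read as guanosine, so at the codon level A-to-I editing is an
#' A-to-G substitution. Returns whether replacing a single A (or, with
#' `allow_multi`, any non-empty subset of the A positions) of the reference
#' codon by G yields a codon translating to `alt_aa`, together with the
#' minimal set of edited codon offsets. The codon is always given on the
#' coding strand; for stop-loss, `alt_aa = "W"` with codon `TAG` is the
#' amber-to-Trp readthrough case.
#'
#' @param ref_codon Character vector of 3-nt codons (coding strand, ACGT/N).
#' @param alt_aa Character vector of target residues (recycled).
#' @param allow_multi Allow several A positions to be edited at once.
#' @return Tibble with `ref_codon`, `alt_aa`, `feasible`, `offsets`
#'   (list of 0-based edited positions), `indeterminate` (codon contained N).
#' @export
a2i_feasible <- function(ref_codon, alt_aa, allow_multi = FALSE) {
  n <- max(length(ref_codon), length(alt_aa))
  ref_codon <- rep_len(toupper(ref_codon), n)
  alt_aa <- rep_len(alt_aa, n)
  code <- Biostrings::getGeneticCode("1")
  rows <- purrr::map2(ref_codon, alt_aa, function(codon, aa) {
    if (grepl("N", codon, fixed = TRUE)) {
      return(tibble::tibble(ref_codon = codon, alt_aa = aa, feasible = NA,
                            offsets = list(integer(0)), indeterminate = TRUE))
    }
    if (grepl("[^ACGT]", codon)) stop("a2i_feasible(): invalid codon ", codon)
    a_pos <- which(strsplit(codon, "")[[1]] == "A")
    # minimal edit set: smaller subsets tried first
    subsets <- a_subsets(a_pos, allow_multi)
    if (length(subsets)) subsets <- subsets[order(lengths(subsets))]
    for (s in subsets) {
      edited <- strsplit(codon, "")[[1]]
      edited[s] <- "G"
      trans <- unname(code[paste(edited, collapse = "")])
      if (identical(trans, aa)) {
        return(tibble::tibble(ref_codon = codon, alt_aa = aa, feasible = TRUE,
                              offsets = list(s - 1L), indeterminate = FALSE))
      }
    }
    tibble::tibble(ref_codon = codon, alt_aa = aa, feasible = FALSE,
                   offsets = list(integer(0)), indeterminate = FALSE)
  })
  dplyr::bind_rows(rows)
}

#' Enumerate all substitutions reachable by A-to-I editing
#'
#' Brute force over the 64 codons of the standard genetic code and every
#' single (or, with `allow_multi`, multiple) A-to-G edit; returns the
#' distinct nonsynonymous residue exchanges, with stop codons written `*`.
#'
#' @param allow_multi Allow multiple A positions per codon.
#' @return Tibble `from`, `to` of distinct amino-acid (or stop) exchanges.
#' @export
enumerate_a2i_substitutions <- function(allow_multi = FALSE) {
  code <- Biostrings::getGeneticCode("1")
  nts <- c("A", "C", "G", "T")
  rows <- list()
  for (n1 in nts) for (n2 in nts) for (n3 in nts) {
    codon <- c(n1, n2, n3)
    a_pos <- which(codon == "A")
    if (!length(a_pos)) next
    subsets <- a_subsets(a_pos, allow_multi)
    from <- unname(code[paste(codon, collapse = "")])
    for (s in subsets) {
      ed <- codon
      ed[s] <- "G"
      to <- unname(code[paste(ed, collapse = "")])
      if (!identical(from, to)) {
        rows[[length(rows) + 1L]] <- tibble::tibble(from = from, to = to)
      }
    }
  }
  dplyr::distinct(dplyr::bind_rows(rows))
}

# genomic coordinates (forward strand, ascending) of protein codon `pos`
# (0-based) of a gene; also returns the coding-strand codon sequence
codon_at <- function(gene, genome, pos) {
  segs <- coding_segments(gene, drop_stop = TRUE)
  blocks <- transcript_to_blocks(segs, gene$strand, 3L * pos, 3L * pos + 3L)
  nt <- paste(substring(genome[[gene$contig]], blocks$start + 1L, blocks$end),
              collapse = "")
  if (gene$strand == "-") nt <- revcomp(nt)
  positions <- unlist(purrr::map2(blocks$start, blocks$end, function(s, e) seq(s, e - 1L)))
  list(codon = nt, positions = sort(positions))
}

#' Call A-to-I editing-derived SAAV candidates from de novo peptides
#'
#' Full candidate pipeline: one-mismatch alignment against annotated
#' proteins, ambiguity prefilters, strand-aware codon lookup in the genome,
#' and the codon-level A-to-G feasibility check. Candidates carry the
#' substitution class, theoretical mass shift, edited codon offsets, and a
#' flag for whether the non-edited counterpart peptide was also observed.
#'
#' @param denovo_peps Character vector of de novo peptides (repeats count
#'   as PSM-level support), or a data frame with a `sequence` column.
#' @param proteins Annotated protein tibble (with genomic provenance).
#' @param genome Genome named character vector.
#' @param annotation Gene-model tibble.
#' @param equate_il Collapse I/L during alignment (default TRUE).
#' @param allow_multi Allow multi-site codon edits (default FALSE).
#' @param known_peptides Optional extra peptide set used for the
#'   `both_variants_detected` flag (e.g. database-search identifications).
#' @return Tibble of SAAV candidates (one row per peptide placement):
#'   sequence, protein, position, ref/alt residues, reference codon and
#'   genomic codon coordinates, edited offsets, mass shift, class label,
#'   `both_variants_detected`, `psm_support`, and a `provean_score` column
#'   reserved for external pathogenicity scores (never computed here).
#' @export
call_saavs <- function(denovo_peps, proteins, genome, annotation,
                       equate_il = TRUE, allow_multi = FALSE,
                       known_peptides = character(0)) {
  if (is.data.frame(denovo_peps)) denovo_peps <- denovo_peps$sequence
  support <- table(denovo_peps)
  ali <- align_one_mismatch(denovo_peps, proteins, equate_il = equate_il)
  exact <- unique(ali$peptide[ali$n_mismatch == 0L])
  observed0 <- collapse_il(unique(c(denovo_peps, known_peptides)))
  cand <- ali[ali$n_mismatch == 1L & !ali$peptide %in% exact, , drop = FALSE]
  # I<->L exchanges are mass-identical and never called
  cand <- cand[collapse_il(cand$ref_aa) != collapse_il(cand$alt_aa), , drop = FALSE]
  cand <- prefilter_saav(cand)
  cand <- cand[cand$keep, , drop = FALSE]
  if (!nrow(cand)) return(empty_saav())
  rows <- purrr::map(seq_len(nrow(cand)), function(i) {
    cc <- cand[i, ]
    prot <- proteins[match(cc$protein_id, proteins$protein_id), ]
    if (is.na(prot$gene_id[1])) return(NULL) # no genomic provenance
    gene <- annotation[match(prot$gene_id, annotation$gene_id), ]
    prot_pos <- cc$offset + cc$mismatch_pos
    cd <- codon_at(gene, genome, prot_pos)
    if (!identical(unname(Biostrings::getGeneticCode("1")[cd$codon]), cc$ref_aa)) {
      return(NULL) # provenance/translation mismatch; drop with log reason
    }
    feas <- a2i_feasible(cd$codon, cc$alt_aa, allow_multi = allow_multi)
    if (!isTRUE(feas$feasible[1])) return(NULL)
    counterpart <- paste0(
      substring(cc$peptide, 1, cc$mismatch_pos),
      cc$ref_aa,
      substring(cc$peptide, cc$mismatch_pos + 2L))
    tibble::tibble(
      peptide = cc$peptide, protein_id = cc$protein_id,
      protein_pos = prot_pos, peptide_pos = cc$mismatch_pos,
      ref_aa = cc$ref_aa, alt_aa = cc$alt_aa,
      ref_codon = cd$codon, contig = gene$contig, strand = gene$strand,
      codon_positions = list(cd$positions),
      edited_offsets = list(feas$offsets[[1]]),
      mass_shift = cc$mass_shift,
      class = paste0(cc$ref_aa, "->", cc$alt_aa),
      both_variants_detected = collapse_il(counterpart) %in% observed0,
      psm_support = as.integer(support[[cc$peptide]]),
      provean_score = NA_real_,
      is_unique = cc$n_placements == 1L
    )
  })
  out <- dplyr::bind_rows(rows)
  if (!nrow(out)) return(empty_saav())
  out
}

empty_saav <- function() {
  tibble::tibble(
    peptide = character(), protein_id = character(), protein_pos = integer(),
    peptide_pos = integer(),
    ref_aa = character(), alt_aa = character(), ref_codon = character(),
    contig = character(), strand = character(), codon_positions = list(),
    edited_offsets = list(), mass_shift = numeric(), class = character(),
    both_variants_detected = logical(), psm_support = integer(),
    provean_score = numeric(), is_unique = logical()
  )
}

#' Detect stop-loss (UAG-to-UGG) readthrough events
#'
#' An event is called when a query peptide's prefix matches an annotated
#' protein's C-terminal suffix, the residue aligned to the stop position is
#' Trp, and the genomic stop codon is TAG on the coding strand (amber;
#' editing UAG to UGG recodes it as Trp). The C-terminal extension is
#' translated by readthrough to the next in-frame stop, and peptides lying
#' entirely inside the extension attach as additional evidence.
#'
#' @param peptides Character vector of candidate peptides (de novo and/or
#'   six-frame novel peptides).
#' @param proteins Annotated protein tibble.
#' @param genome Genome named character vector.
#' @param annotation Gene-model tibble.
#' @param equate_il Collapse I/L when matching (default TRUE).
#' @param min_flank Minimum residues on each side of the junction (default 1).
#' @return List with `events` (one row per extended protein: stop codon
#'   coordinates/sequence, junction peptides, extension sequence and length,
#'   supporting extension peptides, detection source) and `rejected`
#'   (junction-like matches at non-TAG stops, with reason).
#' @export
detect_stop_loss <- function(peptides, proteins, genome, annotation,
                             equate_il = TRUE, min_flank = 1) {
  peptides <- unique(peptides[grepl("W", peptides, fixed = TRUE)])
  events <- list()
  rejected <- list()
  ann <- proteins[proteins$source == "annotated", , drop = FALSE]
  for (i in seq_len(nrow(ann))) {
    prot <- ann[i, ]
    gene <- annotation[match(prot$gene_id, annotation$gene_id), ]
    if (is.na(gene$gene_id[1])) next
    ext <- readthrough_extension(gene, genome)
    if (is.null(ext)) next
    pseq <- if (equate_il) collapse_il(prot$sequence) else prot$sequence
    ext_seq_cmp <- if (equate_il) collapse_il(ext$extension) else ext$extension
    n <- nchar(pseq)
    junction_peps <- character(0)
    ext_peps <- character(0)
    for (p in peptides) {
      q <- if (equate_il) collapse_il(p) else p
      lp <- nchar(q)
      # junction: prefix of length k matches protein C-terminal suffix,
      # residue k+1 sits on the stop codon and must be W
      for (k in seq(min_flank, lp - min_flank)) {
        if (substring(q, 1, k) != substring(pseq, n - k + 1, n)) next
        tail_part <- substring(q, k + 1)
        if (substring(tail_part, 1, 1) != "W") next
        if (nchar(tail_part) > nchar(ext_seq_cmp)) next
        if (substring(ext_seq_cmp, 1, nchar(tail_part)) == tail_part) {
          if (ext$stop_codon == "TAG") {
            junction_peps <- c(junction_peps, p)
          } else {
            rejected[[length(rejected) + 1L]] <- tibble::tibble(
              protein_id = prot$protein_id, peptide = p, reason = "non-UAG stop")
          }
        }
      }
      # fully inside the extension (past the recoded stop)
      if (ext$stop_codon == "TAG" && nchar(ext_seq_cmp) > 1 &&
          grepl(q, substring(ext_seq_cmp, 2), fixed = TRUE)) {
        ext_peps <- c(ext_peps, p)
      }
    }
    if (length(junction_peps)) {
      events[[length(events) + 1L]] <- tibble::tibble(
        protein_id = prot$protein_id, gene_id = gene$gene_id,
        contig = gene$contig, strand = gene$strand,
        stop_codon = ext$stop_codon,
        stop_positions = list(ext$stop_positions),
        junction_peptides = list(unique(junction_peps)),
        extension_peptides = list(unique(ext_peps)),
        extension = ext$extension,
        extension_length = nchar(ext$extension),
        detection_source = "denovo"
      )
    }
  }
  empty_events <- tibble::tibble(
    protein_id = character(), gene_id = character(), contig = character(),
    strand = character(), stop_codon = character(), stop_positions = list(),
    junction_peptides = list(), extension_peptides = list(),
    extension = character(), extension_length = integer(),
    detection_source = character())
  empty_rej <- tibble::tibble(protein_id = character(), peptide = character(),
                              reason = character())
  list(
    events = if (length(events)) dplyr::bind_rows(events) else empty_events,
    rejected = if (length(rejected)) dplyr::bind_rows(rejected) else empty_rej
  )
}

# stop codon and readthrough extension (W + residues to the next in-frame
# stop) of a gene; extension is translated on the coding strand continuing
# downstream of the CDS in the genome (no introns assumed past the stop)
readthrough_extension <- function(gene, genome) {
  ex <- gene$exons[[1]]
  contig_seq <- genome[[gene$contig]]
  cds <- spliced_cds(gene, genome)
  stop_codon <- substring(cds, nchar(cds) - 2L, nchar(cds))
  if (!stop_codon %in% c("TAA", "TAG", "TGA")) return(NULL)
  if (gene$strand == "+") {
    stop_start <- max(ex$end) - 3L
    down <- substring(contig_seq, max(ex$end) + 1L, nchar(contig_seq))
  } else {
    stop_start <- min(ex$start)
    down <- revcomp(substring(contig_seq, 1L, min(ex$start)))
  }
  aa <- translate_nt(down)
  stop_at <- regexpr("*", aa, fixed = TRUE)
  ext_aa <- if (stop_at > 0) substring(aa, 1, stop_at - 1L) else aa
  # the recoded stop reads W; events are only *accepted* for TAG stops,
  # but the W-form is needed to recognise (and reject) non-amber evidence
  list(
    stop_codon = stop_codon,
    stop_positions = seq(stop_start, stop_start + 2L),
    extension = paste0("W", ext_aa)
  )
}

#' Default isobaric-PTM delta table
#'
#' Mass deltas of modifications (and modification-equivalent losses) that
#' can mimic an amino-acid substitution when placed on the relevant or a
#' neighbouring residue, used by [manual_review_export()].
#'
#' @return Tibble `name`, `delta` (Da), `residues` (string of residues the
#'   modification can sit on; `"^"` marks the peptide N-terminus).
#' @export
default_ptm_deltas <- function() {
  tibble::tibble(
    name = c("acetyl", "trimethyl", "deamidation", "methyl",
             "dehydration", "formaldehyde_loss", "dioxidation", "oxidation"),
    delta = c(42.010565, 42.046950, 0.984016, 14.015650,
              -18.010565, -30.010565, 31.989829, 15.994915),
    residues = c("^K", "KR", "NQ", "KRED", "ST", "ST", "MWC", "MWC")
  )
}

#' Export SAAV candidates for manual spectrum review
#'
#' Lists, for every candidate, all isobaric PTM explanations within
#' tolerance whose target residue is the mismatched residue itself or an
#' immediate neighbour, so a reviewer can exclude identifications equally
#' well explained by a modification. Nothing is auto-discarded here.
#'
#' @param candidates SAAV candidate tibble from [call_saavs()].
#' @param ptm_deltas PTM delta table (default [default_ptm_deltas()]).
#' @param tol Mass tolerance in Da (default 0.005).
#' @param path Optional output TSV path.
#' @return `candidates` with an `isobaric_flags` column (semicolon-joined;
#'   empty when no alternative exists).
#' @export
manual_review_export <- function(candidates, ptm_deltas = default_ptm_deltas(),
                                 tol = 0.005, path = NULL) {
  flags <- vapply(seq_len(nrow(candidates)), function(i) {
    cc <- candidates[i, ]
    mm_pos <- cc$peptide_pos + 1L # 1-based position of the mismatch
    hits <- character(0)
    for (j in seq_len(nrow(ptm_deltas))) {
      d <- ptm_deltas[j, ]
      if (abs(cc$mass_shift - d$delta) > tol) next
      res <- strsplit(gsub("^\\^", "", d$residues), "")[[1]]
      nterm_ok <- grepl("^\\^", d$residues)
      aa <- strsplit(cc$peptide, "")[[1]]
      for (p0 in mm_pos) {
        nbh <- seq(max(1, p0 - 1), min(length(aa), p0 + 1))
        if (any(aa[nbh] %in% res) || (nterm_ok && 1 %in% nbh)) {
          hits <- c(hits, sprintf("equally explained by %s at/near position %d", d$name, p0))
          break
        }
      }
    }
    paste(unique(hits), collapse = ";")
  }, character(1))
  out <- dplyr::mutate(candidates, isobaric_flags = flags)
  if (!is.null(path)) {
    flat <- out
    flat$codon_positions <- vapply(flat$codon_positions, paste, character(1), collapse = ",")
    flat$edited_offsets <- vapply(flat$edited_offsets, paste, character(1), collapse = ",")
    readr::write_tsv(flat, path)
  }
  out
}
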