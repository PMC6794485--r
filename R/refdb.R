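#' Load a genome FASTA
#'
#' Reads a nucleotide FASTA into a named character vector (one element per
#' contig). Sequences are uppercased and U is mapped to T; only A,C,G,T,N
#' are accepted.
#'
#' @param path Path to a FASTA file.
#' @return Named character vector of contig sequences.
#' @export
load_genome <- function(path) {
  if (!file.exists(path)) stop("load_genome(): file not found: ", path)
  ss <- Biostrings::readBStringSet(path)
  if (length(ss) == 0) stop("load_genome(): empty FASTA: ", path)
  ids <- sub("\\s.*$", "", names(ss))
  if (any(!nzchar(ids))) stop("load_genome(): empty contig id")
  if (anyDuplicated(ids)) {
    stop("load_genome(): duplicate contig id(s): ",
         paste(unique(ids[duplicated(ids)]), collapse = ","))
  }
  seqs <- chartr("u", "t", toupper(as.character(ss)))
  seqs <- chartr("U", "T", seqs)
  if (any(!nzchar(seqs))) stop("load_genome(): empty sequence for contig")
  bad <- grepl("[^ACGTN]", seqs)
  if (any(bad)) {
    stop("load_genome(): non-ACGTN characters in contig(s): ",
         paste(ids[bad], collapse = ","))
  }
  stats::setNames(seqs, ids)
}

#' Write a genome FASTA
#'
#' @param genome Named character vector of contig sequences.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_genome <- function(genome, path) {
  ss <- Biostrings::DNAStringSet(genome)
  Biostrings::writeXStringSet(ss, path, width = 60)
  invisible(path)
}

#' Load gene models from GFF3
#'
#' Parses gene/mRNA/CDS features (1-based closed coordinates per the GFF3
#' standard) into a gene-model table with 0-based half-open internal
#' coordinates on the forward strand. CDS features are grouped per mRNA and
#' stored in ascending genomic order regardless of strand.
#'
#' @param path Path to a GFF3 file.
#' @param genome Optional genome (from [load_genome()]); when supplied,
#'   coordinates are bounds-checked and gene-model invariants (CDS length
#'   multiple of 3 ending at a stop codon, unless flagged partial) are
#'   enforced.
#' @return Tibble with columns `gene_id`, `locus_tag`, `contig`, `strand`,
#'   `exons` (list of tibbles with 0-based half-open `start`,`end`),
#'   `cds_phase`, `is_partial_5p`, `is_partial_3p`.
#' @export
load_annotation <- function(path, genome = NULL) {
  gr <- rtracklayer::import(path)
  df <- as.data.frame(gr, stringsAsFactors = FALSE)
  df$Parent <- vapply(df$Parent, function(p) if (length(p)) p[[1]] else NA_character_, character(1))
  genes <- df[df$type == "gene", , drop = FALSE]
  mrnas <- df[df$type == "mRNA", , drop = FALSE]
  cds <- df[df$type == "CDS", , drop = FALSE]
  if (nrow(cds) && any(is.na(cds$Parent))) {
    stop("load_annotation(): CDS feature without Parent at ",
         paste(cds$seqnames[is.na(cds$Parent)], cds$start[is.na(cds$Parent)],
               sep = ":", collapse = ","))
  }
  if (nrow(mrnas) && any(!mrnas$Parent %in% genes$ID)) {
    bad <- mrnas$ID[!mrnas$Parent %in% genes$ID]
    stop("load_annotation(): mRNA with unknown Parent gene: ", paste(bad, collapse = ","))
  }
  if (any(!cds$Parent %in% mrnas$ID)) {
    bad <- unique(cds$Parent[!cds$Parent %in% mrnas$ID])
    stop("load_annotation(): CDS with unknown Parent mRNA: ", paste(bad, collapse = ","))
  }
  mrnas$gene_id <- genes$ID[match(mrnas$Parent, genes$ID)]
  out <- purrr::map(seq_len(nrow(mrnas)), function(i) {
    m <- mrnas[i, ]
    g <- genes[match(m$gene_id, genes$ID), ]
    cc <- cds[cds$Parent == m$ID, , drop = FALSE]
    cc <- cc[order(cc$start), , drop = FALSE]
    partial <- if ("partial" %in% names(m)) m$partial else NA_character_
    first_cds <- if (as.character(m$strand) == "+") 1L else nrow(cc)
    phase <- suppressWarnings(as.integer(as.character(cc$phase[first_cds])))
    tibble::tibble(
      gene_id = m$gene_id,
      locus_tag = if ("locus_tag" %in% names(g) && !is.na(g$locus_tag)) g$locus_tag else m$gene_id,
      contig = as.character(m$seqnames),
      strand = as.character(m$strand),
      exons = list(tibble::tibble(start = cc$start - 1L, end = cc$end)),
      cds_phase = if (is.na(phase)) 0L else phase,
      is_partial_5p = !is.na(partial) && grepl("5p", partial),
      is_partial_3p = !is.na(partial) && grepl("3p", partial)
    )
  })
  ann <- dplyr::bind_rows(out)
  if (!is.null(genome)) validate_annotation(ann, genome)
  ann
}

#' Check gene-model invariants
#'
#' Errors if exons are unsorted/overlapping, extend past contig bounds, the
#' spliced CDS is shorter than one codon, or (for non-partial models) its
#' length is not a multiple of 3 ending at a stop codon.
#'
#' @param annotation Gene-model tibble (see [load_annotation()]).
#' @param genome Genome named character vector.
#' @return `annotation`, invisibly.
#' @export
validate_annotation <- function(annotation, genome) {
  for (i in seq_len(nrow(annotation))) {
    g <- annotation[i, ]
    ex <- g$exons[[1]]
    id <- g$gene_id
    if (!g$contig %in% names(genome)) stop("validate_annotation(): unknown contig for ", id)
    clen <- nchar(genome[[g$contig]])
    if (any(ex$start < 0) || any(ex$end > clen)) {
      stop("validate_annotation(): CDS outside contig bounds for ", id)
    }
    if (nrow(ex) > 1 && any(diff(ex$start) <= 0 | ex$start[-1] < ex$end[-nrow(ex)])) {
      stop("validate_annotation(): exons unsorted or overlapping for ", id)
    }
    len <- sum(ex$end - ex$start)
    if (len < 3) stop("validate_annotation(): spliced CDS shorter than one codon for ", id)
    if (!g$is_partial_5p && !g$is_partial_3p) {
      if (len %% 3 != 0) {
        stop("validate_annotation(): CDS length ", len,
             " not a multiple of 3 and not flagged partial for ", id)
      }
      cds_nt <- spliced_cds(g, genome)
      last <- substring(cds_nt, nchar(cds_nt) - 2L, nchar(cds_nt))
      if (!last %in% c("TAA", "TAG", "TGA")) {
        stop("validate_annotation(): CDS does not end at a stop codon for ", id)
      }
    }
  }
  invisible(annotation)
}

# coding-strand spliced CDS sequence of one gene-model row (phase applied)
spliced_cds <- function(gene, genome) {
  ex <- gene$exons[[1]]
  seqs <- substring(genome[[gene$contig]], ex$start + 1L, ex$end)
  nt <- paste(seqs, collapse = "")
  if (gene$strand == "-") nt <- revcomp(nt)
  if (gene$cds_phase > 0) nt <- substring(nt, gene$cds_phase + 1L)
  nt
}

#' Write gene models as GFF3
#'
#' Inverse of [load_annotation()]: emits gene/mRNA/CDS features with 1-based
#' closed coordinates, per-CDS phases, and `locus_tag`/`partial` attributes,
#' so that loading the written file reproduces the input table.
#'
#' @param annotation Gene-model tibble.
#' @param path Output path.
#' @param header_extra Optional character vector of extra `#` header lines.
#' @return `path`, invisibly.
#' @export
write_gff3 <- function(annotation, path, header_extra = NULL) {
  lines <- c("##gff-version 3", header_extra)
  ann <- annotation[order(annotation$contig,
                          vapply(annotation$exons, function(e) min(e$start), numeric(1))), ]
  for (i in seq_len(nrow(ann))) {
    g <- ann[i, ]
    ex <- g$exons[[1]]
    gs <- min(ex$start) + 1L
    ge <- max(ex$end)
    partial <- c(if (g$is_partial_5p) "5p", if (g$is_partial_3p) "3p")
    pattr <- if (length(partial)) paste0(";partial=", paste(partial, collapse = ",")) else ""
    lines <- c(lines,
      sprintf("%s\teditoscan\tgene\t%d\t%d\t.\t%s\t.\tID=%s;locus_tag=%s%s",
              g$contig, gs, ge, g$strand, g$gene_id, g$locus_tag, pattr),
      sprintf("%s\teditoscan\tmRNA\t%d\t%d\t.\t%s\t.\tID=%s.t1;Parent=%s%s",
              g$contig, gs, ge, g$strand, g$gene_id, g$gene_id, pattr))
    # per-CDS phase in translation order
    ord <- if (g$strand == "+") seq_len(nrow(ex)) else rev(seq_len(nrow(ex)))
    lens <- (ex$end - ex$start)[ord]
    phases <- integer(length(ord))
    carried <- g$cds_phase
    for (k in seq_along(ord)) {
      phases[k] <- carried
      carried <- (3L - ((lens[k] - carried) %% 3L)) %% 3L
    }
    phase_by_row <- integer(nrow(ex))
    phase_by_row[ord] <- phases
    for (j in seq_len(nrow(ex))) {
      lines <- c(lines,
        sprintf("%s\teditoscan\tCDS\t%d\t%d\t.\t%s\t%d\tID=%s.t1.cds%d;Parent=%s.t1",
                g$contig, ex$start[j] + 1L, ex$end[j], g$strand, phase_by_row[j],
                g$gene_id, j, g$gene_id))
    }
  }
  writeLines(lines, path)
  invisible(path)
}

#' Translate annotated gene models to proteins
#'
#' Reverse-strand genes are reverse-complemented before translation; the
#' trailing stop codon is removed. An internal stop codon is an error
#' unless `readthrough_tag = TRUE`, in which case amber (TAG) codons are
#' read as Trp (used when translating stop-loss readthrough extensions).
#'
#' @param annotation Gene-model tibble.
#' @param genome Genome named character vector.
#' @param readthrough_tag Read internal TAG codons as Trp.
#' @return Protein database tibble with columns `protein_id`, `sequence`,
#'   `source` (`"annotated"`), `contig`, `strand`, `frame`, `start`, `end`,
#'   `gene_id`, and `segments` (list of coding segments on the forward
#'   strand, stop codon excluded).
#' @export
translate_genes <- function(annotation, genome, readthrough_tag = FALSE) {
  rows <- purrr::map(seq_len(nrow(annotation)), function(i) {
    g <- annotation[i, ]
    nt <- spliced_cds(g, genome)
    aa <- translate_nt(nt, readthrough_tag = readthrough_tag)
    has_stop <- substring(aa, nchar(aa)) == "*"
    if (has_stop) aa <- substring(aa, 1L, nchar(aa) - 1L)
    internal <- regexpr("*", aa, fixed = TRUE)
    if (internal > 0) {
      stop("translate_genes(): internal stop codon at codon ", internal,
           " in gene ", g$gene_id)
    }
    segs <- coding_segments(g, drop_stop = has_stop)
    tibble::tibble(
      protein_id = g$gene_id, sequence = aa, source = "annotated",
      contig = g$contig, strand = g$strand, frame = NA_integer_,
      start = min(segs$start), end = max(segs$end),
      gene_id = g$gene_id, segments = list(segs)
    )
  })
  dplyr::bind_rows(rows)
}

# exon intervals trimmed by the 5' phase and (optionally) the 3 nt of the
# stop codon, strand-aware; returned ascending on the forward strand
coding_segments <- function(gene, drop_stop = TRUE) {
  ex <- gene$exons[[1]]
  trim_front <- gene$cds_phase # coding 5' end
  trim_back <- if (drop_stop) 3L else 0L # coding 3' end
  if (gene$strand == "-") {
    tmp <- trim_front; trim_front <- trim_back; trim_back <- tmp
  }
  # trim_front now applies at the lowest forward coordinate
  i <- 1L
  while (trim_front > 0 && i <= nrow(ex)) {
    take <- min(trim_front, ex$end[i] - ex$start[i])
    ex$start[i] <- ex$start[i] + take
    trim_front <- trim_front - take
    i <- i + 1L
  }
  j <- nrow(ex)
  while (trim_back > 0 && j >= 1L) {
    take <- min(trim_back, ex$end[j] - ex$start[j])
    ex$end[j] <- ex$end[j] - take
    trim_back <- trim_back - take
    j <- j - 1L
  }
  ex[ex$end > ex$start, , drop = FALSE]
}

#' Six-frame translation of a genome
#'
#' Translates every contig in all three frames on both strands, splits the
#' translations at stop codons, and returns every stop-free fragment of at
#' least `min_fragment_len` residues with exact genomic provenance. Frames
#' are numbered 0-2 on each strand from position 0 of that strand's
#' reading; fragment coordinates are always on the forward strand. Long
#' contigs can optionally be processed as overlapping chunks (duplicate
#' fragments from the overlaps are removed at mapping time, see
#' [dedup_fragments()]).
#'
#' @param genome Genome named character vector.
#' @param min_fragment_len Minimum fragment length in residues (default 7).
#' @param chunk_len,chunk_overlap Optional chunking of long contigs
#'   (`chunk_len = NULL` translates each contig whole).
#' @return Protein database tibble (`source = "sixframe"`) with provenance
#'   columns `contig`, `strand`, `frame`, `start`, `end`.
#' @export
six_frame_translate <- function(genome, min_fragment_len = 7,
                                chunk_len = NULL, chunk_overlap = 0) {
  stopifnot(min_fragment_len >= 1)
  if (!is.null(chunk_len) && chunk_overlap >= chunk_len) {
    stop("six_frame_translate(): chunk_overlap must be smaller than chunk_len")
  }
  out <- purrr::imap(genome, function(seq, contig) {
    L <- nchar(seq)
    if (is.null(chunk_len) || L <= chunk_len) {
      six_frame_one(seq, contig, 0L, min_fragment_len, L)
    } else {
      starts <- seq(0L, L - 1L, by = chunk_len - chunk_overlap)
      starts <- starts[starts < L]
      dplyr::bind_rows(purrr::map(starts, function(cs) {
        chunk <- substring(seq, cs + 1L, min(cs + chunk_len, L))
        six_frame_one(chunk, contig, cs, min_fragment_len, L)
      }))
    }
  })
  dplyr::bind_rows(out)
}

# frames are numbered globally per contig: on "+" from contig position 0,
# on "-" from the last contig position of the reverse reading, so chunked
# and whole-contig runs agree on provenance
six_frame_one <- function(seq, contig, offset, min_fragment_len, contig_len) {
  L <- nchar(seq)
  if (L < 3) return(empty_protein_db())
  res <- list()
  for (strand in c("+", "-")) {
    s <- if (strand == "+") seq else revcomp(seq)
    for (frame in 0:2) {
      aa <- translate_nt(substring(s, frame + 1L, L))
      runs <- stop_free_runs(aa)
      runs <- runs[runs$aa_end - runs$aa_start + 1L >= min_fragment_len, , drop = FALSE]
      if (!nrow(runs)) next
      nt_start <- frame + 3L * (runs$aa_start - 1L) # on reading strand, 0-based
      nt_end <- frame + 3L * runs$aa_end
      if (strand == "+") {
        fs <- nt_start; fe <- nt_end
      } else {
        fs <- L - nt_end; fe <- L - nt_start
      }
      gs <- fs + offset
      ge <- fe + offset
      gframe <- if (strand == "+") gs %% 3L else (contig_len - ge) %% 3L
      frag <- substring(aa, runs$aa_start, runs$aa_end)
      res[[length(res) + 1L]] <- tibble::tibble(
        protein_id = sprintf("%s|%s|f%d|%d", contig, strand, gframe, gs),
        sequence = frag, source = "sixframe", contig = contig, strand = strand,
        frame = gframe, start = gs, end = ge,
        gene_id = NA_character_,
        segments = purrr::map2(gs, ge, ~tibble::tibble(start = .x, end = .y))
      )
    }
  }
  if (!length(res)) return(empty_protein_db())
  dplyr::bind_rows(res)
}

empty_protein_db <- function() {
  tibble::tibble(
    protein_id = character(), sequence = character(), source = character(),
    contig = character(), strand = character(), frame = integer(),
    start = integer(), end = integer(), gene_id = character(), segments = list()
  )
}

#' Remove duplicate six-frame fragments
#'
#' Overlapping chunks emit the same fragment more than once; this keeps one
#' record per distinct (contig, strand, frame, start, end) locus.
#'
#' @param fragments Six-frame protein database tibble.
#' @return Deduplicated tibble.
#' @export
dedup_fragments <- function(fragments) {
  dplyr::distinct(fragments, .data$contig, .data$strand, .data$frame,
                  .data$start, .data$end, .keep_all = TRUE)
}

#' Build reversed decoy entries
#'
#' One decoy per target with the full sequence reversed and the id prefixed
#' with `tag`. Palindromic sequences whose decoy equals the target are
#' flagged in the `is_collision` column.
#'
#' @param db Protein database tibble.
#' @param method Decoy generation method; only `"reverse"` is implemented.
#' @param tag Id prefix for decoy entries (default `"DECOY_"`).
#' @return Tibble of decoy records (`source = "decoy"`).
#' @export
build_decoys <- function(db, method = c("reverse"), tag = "DECOY_") {
  method <- match.arg(method)
  if (!nrow(db)) stop("build_decoys(): empty database")
  dec <- db
  dec$sequence <- str_rev(db$sequence)
  dec$protein_id <- paste0(tag, db$protein_id)
  dec$source <- "decoy"
  dec$is_collision <- dec$sequence == db$sequence
  if ("segments" %in% names(dec)) dec$segments <- vector("list", nrow(dec))
  dec$gene_id <- NA_character_
  dec
}

#' Build a hybrid search database
#'
#' Adds de novo-derived candidate peptides as standalone entries alongside
#' refined protein sequences, the database used for the class-specific FDR
#' round on editing candidates. Peptides identical after I/L collapsing are
#' deduplicated; peptides shorter than 6 residues are dropped with a
#' warning.
#'
#' @param refined_proteins Protein database tibble (passed through).
#' @param novel_peptides Character vector of candidate peptide sequences.
#' @return Combined tibble; peptide entries have `source = "hybrid_peptide"`.
#' @export
build_hybrid_db <- function(refined_proteins, novel_peptides) {
  novel_peptides <- unique(novel_peptides)
  short <- nchar(novel_peptides) < 6
  if (any(short)) {
    warning("build_hybrid_db(): dropping ", sum(short), " peptide(s) shorter than 6 aa")
    novel_peptides <- novel_peptides[!short]
  }
  novel_peptides <- novel_peptides[!duplicated(collapse_il(novel_peptides))]
  if (!length(novel_peptides)) return(refined_proteins)
  hyb <- tibble::tibble(
    protein_id = paste0("HYB_", seq_along(novel_peptides)),
    sequence = novel_peptides, source = "hybrid_peptide",
    contig = NA_character_, strand = NA_character_, frame = NA_integer_,
    start = NA_integer_, end = NA_integer_, gene_id = NA_character_,
    segments = vector("list", length(novel_peptides))
  )
  dplyr::bind_rows(refined_proteins, hyb)
}

#' Write a protein database as FASTA plus manifest
#'
#' @param db Protein database tibble.
#' @param fasta_path Output FASTA path.
#' @param manifest_path Optional TSV manifest (id, source, provenance).
#' @return `fasta_path`, invisibly.
#' @export
write_protein_db <- function(db, fasta_path, manifest_path = NULL) {
  ss <- Biostrings::AAStringSet(stats::setNames(db$sequence, db$protein_id))
  Biostrings::writeXStringSet(ss, fasta_path, width = 60)
  if (!is.null(manifest_path)) {
    man <- dplyr::select(db, "protein_id", "source", "contig", "strand",
                         "frame", "start", "end", "gene_id")
    readr::write_tsv(man, manifest_path)
  }
  invisible(fasta_path)
}
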