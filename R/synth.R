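#' Generate a synthetic genome with gene models and ground truth
#'
#' Builds a deterministic (seeded) fungal-style test world: multi-exon
#' protein-coding genes with GT..AG introns on both strands, separated by
#' random intergenic spacers, plus optionally a set of "hidden" genes that
#' are present in the genome but left out of the annotation (novel-gene
#' ground truth for annotation refinement). Every gene model satisfies the
#' package's gene-model invariants by construction.
#'
#' @param n_contigs Number of contigs (default 2).
#' @param n_genes Number of annotated genes (default 150).
#' @param intron_rate Fraction of genes carrying at least one intron
#'   (genes get 0-3 introns; default 0.6).
#' @param strand_mix Fraction of genes on the minus strand (default 0.5).
#' @param n_novel_genes Hidden genes left out of the annotation (default 10).
#' @param len_range Protein length range in residues (default 80-250).
#' @param seed Random seed; the output is a pure function of the arguments.
#' @return List of class `editoscan_synth`: `genome` (named character),
#'   `annotation` (annotated gene models), `proteins` (their translations),
#'   `truth` (tibbles `genes` -- including hidden ones -- with coding
#'   sequences and protein sequences, and the `seed`).
#' @export
synth_genome <- function(n_contigs = 2, n_genes = 150, intron_rate = 0.6,
                         strand_mix = 0.5, n_novel_genes = 10,
                         len_range = c(80, 250), seed = 42) {
  stopifnot(n_genes >= 1)
  set.seed(seed)
  code <- Biostrings::getGeneticCode("1")
  sense_codons <- names(code)[code != "*"]
  codons_by_aa <- split(sense_codons, code[sense_codons])
  aa_pool <- setdiff(names(codons_by_aa), character(0))
  # residue frequencies: keep K/R/E common so digestion yields peptides
  aa_freq <- stats::setNames(rep(1, length(aa_pool)), aa_pool)
  aa_freq[c("K", "R", "E")] <- 2.2
  aa_freq[c("A", "S", "T", "G", "L", "V")] <- 1.6
  aa_freq["W"] <- 0.4

  n_total <- n_genes + n_novel_genes
  gene_rows <- list()
  contig_parts <- stats::setNames(rep(list(character(0)), n_contigs),
                                  paste0("contig_", seq_len(n_contigs)))
  contig_len <- stats::setNames(rep(0L, n_contigs), names(contig_parts))

  for (i in seq_len(n_total)) {
    n_aa <- sample(seq(len_range[1], len_range[2]), 1)
    aa <- c("M", sample(aa_pool, n_aa - 1, replace = TRUE, prob = aa_freq))
    cds_codons <- vapply(aa, function(a) sample(codons_by_aa[[a]], 1), character(1))
    stop_codon <- sample(c("TAG", "TAA", "TGA"), 1, prob = c(0.6, 0.2, 0.2))
    cds <- paste(c(cds_codons, stop_codon), collapse = "")
    n_int <- if (stats::runif(1) < intron_rate) sample(1:3, 1, prob = c(0.5, 0.3, 0.2)) else 0L
    cds_len <- nchar(cds)
    int_pos <- sort(sample(seq(10L, cds_len - 10L), n_int))
    int_seqs <- vapply(seq_len(n_int), function(k) {
      paste0("GT", paste(sample(c("A", "C", "T"), sample(40:140, 1), replace = TRUE),
                         collapse = ""), "AG")
    }, character(1))
    # assemble locus on the coding strand; record exon intervals in local coords
    pieces <- character(0)
    exon_local <- list()
    prev <- 0L
    offset_local <- 0L
    bounds <- c(int_pos, cds_len)
    for (k in seq_along(bounds)) {
      seg_len <- bounds[k] - prev
      pieces <- c(pieces, substring(cds, prev + 1L, bounds[k]))
      exon_local[[k]] <- c(offset_local, offset_local + seg_len)
      offset_local <- offset_local + seg_len
      if (k <= n_int) {
        pieces <- c(pieces, int_seqs[k])
        offset_local <- offset_local + nchar(int_seqs[k])
      }
      prev <- bounds[k]
    }
    locus <- paste(pieces, collapse = "")
    L <- nchar(locus)
    strand <- if (stats::runif(1) < strand_mix) "-" else "+"
    placed <- if (strand == "+") locus else revcomp(locus)
    contig <- names(contig_parts)[(i - 1L) %% n_contigs + 1L]
    spacer <- paste(sample(c("A", "C", "G", "T"), sample(300:600, 1), replace = TRUE),
                    collapse = "")
    gene_offset <- contig_len[contig] + nchar(spacer)
    contig_parts[[contig]] <- c(contig_parts[[contig]], spacer, placed)
    contig_len[contig] <- gene_offset + L
    exons_fwd <- purrr::map(exon_local, function(e) {
      if (strand == "+") c(gene_offset + e[1], gene_offset + e[2])
      else c(gene_offset + L - e[2], gene_offset + L - e[1])
    })
    em <- do.call(rbind, exons_fwd)
    exons <- tibble::tibble(start = as.integer(em[, 1]), end = as.integer(em[, 2]))
    exons <- exons[order(exons$start), ]
    gene_rows[[i]] <- tibble::tibble(
      gene_id = sprintf("g%04d", i), locus_tag = sprintf("SYN_%04d", i),
      contig = contig, strand = strand, exons = list(exons),
      cds_phase = 0L, is_partial_5p = FALSE, is_partial_3p = FALSE,
      cds = cds, protein = paste(aa, collapse = ""),
      stop_codon = stop_codon, n_introns = n_int,
      annotated = i <= n_genes
    )
  }
  # terminal spacers so no gene touches a contig end
  genome <- vapply(names(contig_parts), function(cn) {
    tail_spacer <- paste(sample(c("A", "C", "G", "T"), 400, replace = TRUE), collapse = "")
    paste(c(contig_parts[[cn]], tail_spacer), collapse = "")
  }, character(1))

  genes <- dplyr::bind_rows(gene_rows)
  model_cols <- c("gene_id", "locus_tag", "contig", "strand", "exons",
                  "cds_phase", "is_partial_5p", "is_partial_3p")
  annotation <- genes[genes$annotated, model_cols]
  validate_annotation(annotation, genome)
  proteins <- translate_genes(annotation, genome)
  structure(list(
    genome = genome, annotation = annotation, proteins = proteins,
    truth = list(genes = genes, seed = seed)
  ), class = "editoscan_synth")
}

#' Default SAAV class mix for the edit planter
#'
#' The twelve single-A-to-G editable substitution classes with weights
#' proportional to their observed frequencies (K-to-E dominates; I-to-M is
#' rare), the default composition used by [plant_edits()].
#'
#' @return Tibble `from`, `to`, `weight`.
#' @export
default_saav_class_mix <- function() {
  tibble::tibble(
    from = c("K", "I", "S", "R", "K", "T", "Q", "Y", "M", "E", "N", "I"),
    to = c("E", "V", "G", "G", "R", "A", "R", "C", "V", "G", "S", "M"),
    weight = c(32, 19, 14, 11, 10, 7, 6, 5, 5, 2, 1, 1)
  )
}

#' Plant A-to-I editing events into a synthetic world
#'
#' Selects codons where a single A-to-G edit produces the requested
#' substitution class, edits the transcript (not the genome), and records
#' the full ground truth: edited proteins, the edited codon offsets, and
#' the tryptic peptide that would reveal each event (with a flag for
#' whether that peptide survives the digestion length filters).
#' Stop-loss events are planted on genes ending in TAG whose downstream
#' in-frame readthrough extension is 10-150 residues and yields a
#' digestible junction peptide.
#'
#' @param world An `editoscan_synth` object from [synth_genome()].
#' @param n_saav Number of SAAV events (default 40).
#' @param n_stoploss Number of stop-loss events (default 4).
#' @param class_mix Tibble `from`, `to`, `weight` (default: observed-class
#'   frequencies, see `default_saav_class_mix()`).
#' @param seed Random seed.
#' @return The world with `truth$saav`, `truth$stoploss`,
#'   `edited_proteins`, and `truth$edited_peptides` added.
#' @export
plant_edits <- function(world, n_saav = 40, n_stoploss = 4,
                        class_mix = default_saav_class_mix(), seed = 42) {
  set.seed(seed + 1L)
  genes <- world$truth$genes
  ann_genes <- genes[genes$annotated, , drop = FALSE]
  code <- Biostrings::getGeneticCode("1")

  # per-class quotas proportional to weights
  quota <- round(n_saav * class_mix$weight / sum(class_mix$weight))
  while (sum(quota) < n_saav) quota[which.max(class_mix$weight - quota)] <-
    quota[which.max(class_mix$weight - quota)] + 1L
  while (sum(quota) > n_saav) quota[which.max(quota)] <- quota[which.max(quota)] - 1L

  saav_rows <- list()
  used <- character(0) # gene:pos keys already edited
  for (ci in seq_len(nrow(class_mix))) {
    if (quota[ci] == 0) next
    from <- class_mix$from[ci]; to <- class_mix$to[ci]
    # all eligible sites for this class across annotated genes
    sites <- purrr::map(seq_len(nrow(ann_genes)), function(gi) {
      g <- ann_genes[gi, ]
      prot <- g$protein
      pos <- which(strsplit(prot, "")[[1]] == from)
      pos <- pos[pos > 1] # spare the initiator Met position convention
      if (!length(pos)) return(NULL)
      codons <- substring(g$cds, 3L * pos - 2L, 3L * pos)
      feas <- a2i_feasible(codons, rep(to, length(pos)))
      keep <- which(feas$feasible %in% TRUE)
      if (!length(keep)) return(NULL)
      tibble::tibble(gene_id = g$gene_id, protein_pos0 = pos[keep] - 1L,
                     ref_codon = codons[keep],
                     edited_offsets = feas$offsets[keep])
    })
    sites <- dplyr::bind_rows(sites)
    if (!is.null(sites) && nrow(sites)) {
      sites$key <- paste(sites$gene_id, sites$protein_pos0)
      sites <- sites[!sites$key %in% used, , drop = FALSE]
    }
    if (is.null(sites) || nrow(sites) < quota[ci]) {
      stop("plant_edits(): only ", if (is.null(sites)) 0 else nrow(sites),
           " eligible site(s) for class ", from, "->", to,
           " but ", quota[ci], " requested")
    }
    pick <- sites[sample(nrow(sites), quota[ci]), , drop = FALSE]
    used <- c(used, pick$key)
    pick$from <- from; pick$to <- to
    saav_rows[[length(saav_rows) + 1L]] <- pick
  }
  saav <- dplyr::bind_rows(saav_rows)

  # edited proteins + revealing tryptic peptides
  gene_idx <- match(saav$gene_id, genes$gene_id)
  saav$edited_protein <- vapply(seq_len(nrow(saav)), function(i) {
    p <- genes$protein[gene_idx[i]]
    paste0(substring(p, 1, saav$protein_pos0[i]), saav$to[i],
           substring(p, saav$protein_pos0[i] + 2L))
  }, character(1))
  pep_info <- purrr::map(seq_len(nrow(saav)), function(i) {
    peps <- digest(c(x = saav$edited_protein[i]), "trypsin", max_missed = 1,
                   len_range = c(6, 50))
    cover <- peps[peps$start <= saav$protein_pos0[i] &
                    peps$start + peps$length > saav$protein_pos0[i], , drop = FALSE]
    if (!nrow(cover)) {
      return(tibble::tibble(edited_peptide = NA_character_, detectable = FALSE))
    }
    cover <- cover[order(cover$missed, -cover$length), , drop = FALSE]
    tibble::tibble(edited_peptide = cover$sequence[1], detectable = TRUE)
  })
  saav <- dplyr::bind_cols(saav, dplyr::bind_rows(pep_info))
  saav$class <- paste0(saav$from, "->", saav$to)

  # stop-loss events
  cand <- genes[genes$annotated & genes$stop_codon == "TAG", , drop = FALSE]
  cand <- cand[sample(nrow(cand)), , drop = FALSE]
  sl_rows <- list()
  for (i in seq_len(nrow(cand))) {
    if (length(sl_rows) >= n_stoploss) break
    g <- cand[i, ]
    gene <- world$annotation[match(g$gene_id, world$annotation$gene_id), ]
    ext <- readthrough_extension(gene, world$genome)
    if (is.null(ext)) next
    if (nchar(ext$extension) < 10 || nchar(ext$extension) > 150) next
    if (grepl("X", ext$extension, fixed = TRUE)) next
    rt_protein <- paste0(g$protein, ext$extension)
    n <- nchar(g$protein)
    peps <- digest(c(x = rt_protein), "trypsin", max_missed = 1, len_range = c(6, 50))
    junction <- peps[peps$start < n & peps$start + peps$length > n + 1L, , drop = FALSE]
    if (!nrow(junction)) next
    junction <- junction[order(junction$missed, -junction$length), , drop = FALSE]
    ext_peps <- peps[peps$start > n, , drop = FALSE]
    sl_rows[[length(sl_rows) + 1L]] <- tibble::tibble(
      gene_id = g$gene_id, stop_codon = g$stop_codon,
      extension = ext$extension, extension_length = nchar(ext$extension),
      readthrough_protein = rt_protein,
      junction_peptide = junction$sequence[1],
      extension_peptide = if (nrow(ext_peps)) ext_peps$sequence[1] else NA_character_
    )
  }
  if (length(sl_rows) < n_stoploss) {
    stop("plant_edits(): only ", length(sl_rows), " eligible stop-loss gene(s), ",
         n_stoploss, " requested")
  }
  stoploss <- dplyr::bind_rows(sl_rows)

  world$truth$saav <- saav
  world$truth$stoploss <- stoploss
  world$truth$edited_peptides <- c(
    stats::na.omit(saav$edited_peptide),
    stoploss$junction_peptide,
    stats::na.omit(stoploss$extension_peptide)
  )
  world$edited_proteins <- tibble::tibble(
    protein_id = paste0(saav$gene_id, "_", saav$class, "_", saav$protein_pos0),
    sequence = saav$edited_protein
  )
  world
}

#' Simulated peptide observations: PSM tables, de novo lists, spectra
#'
#' Digests the canonical (and, when edits were planted, edited) proteomes
#' with trypsin, samples observed peptides, and emits (i) a PSM table with
#' target scores drawn from a signal distribution and decoy scores from a
#' null, precursor m/z with ppm-scale Gaussian error, and retention times
#' linear in predicted hydrophobicity for targets but shuffled for decoys;
#' (ii) a de novo peptide list containing every detectable planted edited
#' peptide plus a controlled fraction of corrupted sequences; and (iii)
#' idealised b/y-ion spectra for the naive scorer.
#'
#' @param world An `editoscan_synth` object (edits optional).
#' @param detection_prob Probability a canonical peptide is observed
#'   (default 0.7).
#' @param denovo_error_rate Fraction of corrupted entries in the de novo
#'   list (default 0.05, matching a 5%-FDR de novo input).
#' @param ppm_sd Precursor mass error s.d. in ppm (default 1).
#' @param score_delta Mean score separation between true and false PSMs
#'   (default 3.5).
#' @param seed Random seed.
#' @return List: `psms` (with `true_label`), `denovo` (tibble `sequence`,
#'   `corrupted`), `spectra` (tibble for [search_spectra()]).
#' @export
synth_observations <- function(world, detection_prob = 0.7,
                               denovo_error_rate = 0.05, ppm_sd = 1,
                               score_delta = 3.5, seed = 42) {
  stopifnot(detection_prob >= 0, detection_prob <= 1)
  set.seed(seed + 2L)
  peps <- digest(world$proteins[, c("protein_id", "sequence")], "trypsin",
                 max_missed = 0, len_range = c(6, 50))
  peps <- peps[!duplicated(peps$sequence), , drop = FALSE]
  obs <- peps[stats::runif(nrow(peps)) < detection_prob, , drop = FALSE]

  mass <- peptide_mass(obs$sequence)
  charge <- 2L
  theo_mz <- (mass + charge * MASS_PROTON) / charge
  hi <- predict_hi(obs$sequence)
  rt <- 10 + 0.9 * hi + stats::rnorm(nrow(obs), 0, 1.5)
  psms <- tibble::tibble(
    spectrum_id = sprintf("S%05d", seq_len(nrow(obs))),
    peptide = obs$sequence, protein_id = obs$protein_id, charge = charge,
    precursor_mz = theo_mz * (1 + stats::rnorm(nrow(obs), 0, ppm_sd * 1e-6)),
    retention_time = rt,
    score = stats::rnorm(nrow(obs), score_delta, 1),
    is_decoy = FALSE, peptide_class = "known", true_label = TRUE
  )
  n_dec <- nrow(obs)
  dec_pep <- str_rev(obs$sequence)
  decoys <- tibble::tibble(
    spectrum_id = sprintf("D%05d", seq_len(n_dec)),
    peptide = dec_pep, protein_id = paste0("DECOY_", obs$protein_id),
    charge = charge,
    precursor_mz = theo_mz * (1 + stats::rnorm(n_dec, 0, ppm_sd * 1e-6)),
    retention_time = sample(rt),
    score = stats::rnorm(n_dec, 0, 1),
    is_decoy = TRUE, peptide_class = "known", true_label = FALSE
  )
  psms <- dplyr::bind_rows(psms, decoys)

  # de novo list: all detectable edited peptides + corrupted canonical ones
  edited <- unique(world$truth$edited_peptides)
  n_corrupt <- ceiling(denovo_error_rate / max(1e-9, 1 - denovo_error_rate) *
                         length(edited))
  corrupt_src <- sample(peps$sequence, min(n_corrupt, nrow(peps)))
  corrupted <- vapply(corrupt_src, function(p) {
    i <- sample(nchar(p), 1)
    aa <- sample(setdiff(strsplit("ACDEFGHKLMNPQRSTVWY", "")[[1]],
                         substring(p, i, i)), 1)
    paste0(substring(p, 1, i - 1), aa, substring(p, i + 1))
  }, character(1), USE.NAMES = FALSE)
  denovo <- tibble::tibble(
    sequence = c(edited, corrupted),
    corrupted = c(rep(FALSE, length(edited)), rep(TRUE, length(corrupted)))
  )

  spectra <- tibble::tibble(
    spectrum_id = psms$spectrum_id[!psms$is_decoy],
    precursor_mz = psms$precursor_mz[!psms$is_decoy],
    charge = charge,
    retention_time = psms$retention_time[!psms$is_decoy],
    peaks = purrr::map(psms$peptide[!psms$is_decoy], synth_spectrum)
  )
  list(psms = psms, denovo = denovo, spectra = spectra)
}

#' Simple labelled PSM score mixture
#'
#' Score-only PSM tables for FDR-calibration experiments: `n_true` target
#' PSMs from a shifted signal distribution, `n_false` target PSMs and
#' `n_decoy` decoy PSMs from the same null, all labelled.
#'
#' @param n_true,n_false,n_decoy Component sizes.
#' @param delta Signal mean shift (default 3.5; null is N(0,1)).
#' @param seed Random seed.
#' @return PSM tibble with `score`, `is_decoy`, `true_label`,
#'   `peptide_class`.
#' @export
synth_psm_mixture <- function(n_true = 2000, n_false = 1500, n_decoy = 1500,
                              delta = 3.5, seed = 1) {
  set.seed(seed)
  tibble::tibble(
    score = c(stats::rnorm(n_true, delta, 1), stats::rnorm(n_false), stats::rnorm(n_decoy)),
    is_decoy = rep(c(FALSE, FALSE, TRUE), c(n_true, n_false, n_decoy)),
    true_label = rep(c(TRUE, FALSE, FALSE), c(n_true, n_false, n_decoy)),
    peptide_class = "known"
  )
}

#' Per-base RNA-Seq coverage for chosen loci
#'
#' @param loci Tibble `contig`, `start`, `end`, `depth` (target median).
#' @param seed Random seed (small integer jitter around the target).
#' @return Per-base coverage tibble `contig`, `pos`, `depth`.
#' @export
synth_coverage <- function(loci, seed = 42) {
  set.seed(seed + 3L)
  rows <- purrr::map(seq_len(nrow(loci)), function(i) {
    l <- loci[i, ]
    pos <- seq(l$start, l$end - 1L)
    tibble::tibble(contig = l$contig, pos = pos,
                   depth = pmax(0, l$depth + sample(-1:1, length(pos), replace = TRUE)))
  })
  dplyr::bind_rows(rows)
}

#' Phylostratigraphy hit tables with planted age labels
#'
#' For each protein a planted phylostratum is drawn; the hit table then
#' contains one qualifying hit whose subject lineage reaches exactly that
#' level, a few younger qualifying hits, and possibly an older
#' non-qualifying hit (E-value above the cutoff) -- so the oldest-PS rule
#' must recover the planted label exactly. A fraction of proteins get no
#' hits at all (planted youngest PS).
#'
#' @param n_proteins Number of proteins (default 100).
#' @param ps_map Phylostratum map (default [default_ps_map()]).
#' @param cutoff E-value cutoff the consumer will use (default 1e-5).
#' @param frac_no_hit Fraction of proteins without any hit (default 0.1).
#' @param seed Random seed.
#' @return List: `hits` tibble (`query`, `lineage`, `evalue`), `truth`
#'   tibble (`protein_id`, `ps_index`).
#' @export
synth_phylo_hits <- function(n_proteins = 100, ps_map = default_ps_map(),
                             cutoff = 1e-5, frac_no_hit = 0.1, seed = 42) {
  set.seed(seed + 4L)
  youngest <- max(ps_map$ps_index)
  lineage_to <- function(k) paste(ps_map$lineage_token[seq_len(k)], collapse = "; ")
  rows <- list()
  truth <- list()
  for (i in seq_len(n_proteins)) {
    id <- sprintf("prot_%04d", i)
    if (stats::runif(1) < frac_no_hit) {
      truth[[i]] <- tibble::tibble(protein_id = id, ps_index = youngest)
      next
    }
    planted <- sample(seq_len(youngest), 1)
    qual_e <- 10^(-stats::runif(1, 6, 60))
    hit_rows <- tibble::tibble(query = id, lineage = lineage_to(planted), evalue = qual_e)
    n_young <- sample(0:3, 1)
    if (n_young > 0 && planted < youngest) {
      yk <- sample(seq(planted, youngest), n_young, replace = TRUE)
      hit_rows <- dplyr::bind_rows(hit_rows, tibble::tibble(
        query = id, lineage = vapply(yk, lineage_to, character(1)),
        evalue = 10^(-stats::runif(n_young, 6, 60))))
    }
    if (planted > 1 && stats::runif(1) < 0.3) {
      ok <- sample(seq_len(planted - 1), 1)
      hit_rows <- dplyr::bind_rows(hit_rows, tibble::tibble(
        query = id, lineage = lineage_to(ok),
        evalue = 10^(-stats::runif(1, 0.5, log10(1 / cutoff)))))
    }
    rows[[i]] <- hit_rows
    truth[[i]] <- tibble::tibble(protein_id = id, ps_index = planted)
  }
  list(hits = dplyr::bind_rows(rows), truth = dplyr::bind_rows(truth))
}

#' Planted refinement scenarios for the rule engine
#'
#' Constructs evidence bundles whose expected refinement category is known
#' by construction, covering every category and both novel-gene
#' confidence classes plus rejections.
#'
#' @param n_per_type Named integer vector of scenario counts.
#' @param seed Random seed (ordering only).
#' @return List: `bundles` tibble, `expected` tibble (`type`, `n`).
#' @export
synth_refinement_scenarios <- function(
    n_per_type = c(splice_site = 6, TIS = 4, extension = 3, frameshift = 2,
                   fusion = 1, novel_classI = 4, novel_classII = 3,
                   novel_rejected = 2),
    seed = 42) {
  set.seed(seed + 5L)
  mk <- function(type, i) {
    base <- tibble::tibble(
      locus_id = paste0(type, "_", i), contig = "contig_1",
      start = 1000L * i, end = 1000L * i + 300L,
      is_intergenic = grepl("^novel", type),
      gene_id = if (grepl("^novel", type)) NA_character_ else paste0("g_", type, i),
      novel_peptides = list(paste0("PEPTIDEK", seq_len(3))),
      n_novel = 2L, n_novel_good = 2L, n_novel_classI = 2L, n_known = 1L,
      rnaseq_sufficient = TRUE, homology_support = FALSE,
      spans_junction = FALSE, upstream_of_tis = FALSE,
      downstream_of_stop = FALSE, out_of_frame_in_cds = FALSE,
      spans_two_genes = FALSE, splits_gene = FALSE, has_two_variants = FALSE)
    switch(type,
      splice_site = dplyr::mutate(base, spans_junction = TRUE),
      TIS = dplyr::mutate(base, upstream_of_tis = TRUE),
      extension = dplyr::mutate(base, downstream_of_stop = TRUE),
      frameshift = dplyr::mutate(base, out_of_frame_in_cds = TRUE),
      fusion = dplyr::mutate(base, spans_two_genes = TRUE),
      fission = dplyr::mutate(base, splits_gene = TRUE),
      novel_classI = base,
      novel_classII = dplyr::mutate(base, n_novel = 1L, n_novel_good = 1L,
                                    n_novel_classI = 1L),
      novel_rejected = dplyr::mutate(base, n_novel = 1L, n_novel_good = 1L,
                                     n_novel_classI = 0L, rnaseq_sufficient = FALSE))
  }
  bundles <- dplyr::bind_rows(purrr::imap(
    as.list(n_per_type),
    function(n, type) dplyr::bind_rows(lapply(seq_len(n), function(i) mk(type, i)))))
  expected <- tibble::tibble(type = names(n_per_type), n = as.integer(n_per_type))
  list(bundles = bundles, expected = expected)
}

#' Reverse-complement an entire synthetic world
#'
#' Flips every contig and rewrites all annotation coordinates and strands
#' accordingly; gene content is unchanged, so coordinate-independent
#' results (e.g. SAAV call sets) must be identical on the flipped world.
#'
#' @param genome Named character vector of contigs.
#' @param annotation Gene-model tibble.
#' @return List `genome`, `annotation`.
#' @export
flip_world <- function(genome, annotation) {
  lens <- nchar(genome)
  flipped <- stats::setNames(revcomp(genome), names(genome))
  ann <- annotation
  for (i in seq_len(nrow(ann))) {
    L <- lens[[ann$contig[i]]]
    ex <- ann$exons[[i]]
    new <- tibble::tibble(start = L - ex$end, end = L - ex$start)
    ann$exons[[i]] <- new[order(new$start), ]
    ann$strand[i] <- if (ann$strand[i] == "+") "-" else "+"
  }
  list(genome = flipped, annotation = ann)
}
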