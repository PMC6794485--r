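#' Default pipeline configuration
#'
#' Thresholds and switches for the whole pipeline, each with its
#' study-level default: 1% PSM-level FDR per search step and per class,
#' minimum peptide length 6, de novo ambiguity prefilter tolerance 5e-4 Da,
#' RNA-Seq median-depth threshold 10, intergenic clustering gap 500 nt,
#' single-site A-to-G edits, PRM dot product 0.85 and 1.3 ppm, and a
#' phylostratigraphy E-value cutoff of 1e-5.
#'
#' @return Named list of configuration values.
#' @export
default_config <- function() {
  list(
    fdr = 0.01,
    min_fragment_len = 7,
    enzyme = "trypsin",
    max_missed = 2,
    len_min = 6, len_max = 50,
    prefilter_tol = 5e-4,
    allow_multi_edit = FALSE,
    depth_min = 10,
    max_gap = 500,
    prm_dot_min = 0.85,
    prm_ppm_max = 1.3,
    phylo_cutoff = 1e-5,
    seed = 42
  )
}

validate_config <- function(config) {
  cfg <- utils::modifyList(default_config(), config)
  if (cfg$fdr <= 0 || cfg$fdr > 1) stop("config: fdr must be in (0, 1]")
  if (cfg$depth_min < 0) stop("config: depth_min must be >= 0")
  if (cfg$len_min < 1 || cfg$len_max < cfg$len_min) stop("config: bad peptide length range")
  if (cfg$phylo_cutoff <= 0) stop("config: phylo_cutoff must be positive")
  if (cfg$prm_dot_min < 0 || cfg$prm_dot_min > 1) stop("config: prm_dot_min must be in [0, 1]")
  cfg
}

#' Run the whole proteogenomic editing pipeline
#'
#' Wires the modules into one deterministic run over a directory of
#' inputs: builds annotated/six-frame/decoy databases, performs the
#' stepped search (when spectra are given), maps and classifies peptides,
#' calls SAAV and stop-loss candidates from the de novo list, bundles
#' refinement evidence against RNA-Seq coverage, assigns phylostrata, and
#' writes every result as TSV (plus BED/SAM/GFF3) into `out_dir`. Every
#' output carries the configuration hash in a header comment. Inputs are
#' never modified.
#'
#' @param genome_path Genome FASTA.
#' @param gff_path Gene models (GFF3).
#' @param denovo_path Optional de novo peptide TSV (column `sequence`).
#' @param spectra_path Optional MGF file for the stepped search.
#' @param coverage_path Optional per-base coverage TSV
#'   (`contig`, `pos`, `depth`).
#' @param phylo_hits_path Optional homology hit TSV
#'   (`query`, `lineage`, `evalue`).
#' @param out_dir Output directory (created if missing).
#' @param config Configuration list (see [default_config()]); partial
#'   lists are completed with the defaults and validated.
#' @return Invisibly, a list of the main result objects.
#' @export
run_all <- function(genome_path, gff_path, denovo_path = NULL,
                    spectra_path = NULL, coverage_path = NULL,
                    phylo_hits_path = NULL, out_dir = "editoscan_out",
                    config = list()) {
  cfg <- validate_config(config)
  for (p in c(genome_path, gff_path, denovo_path, spectra_path,
              coverage_path, phylo_hits_path)) {
    if (!is.null(p) && !file.exists(p)) stop("run_all(): missing input file: ", p)
  }
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  hash <- config_hash(cfg)
  stamp <- function(path, df) {
    con <- file(path, "w")
    writeLines(paste0("# editoscan config_hash=", hash, " seed=", cfg$seed), con)
    close(con)
    readr::write_tsv(df, path, append = TRUE, col_names = TRUE)
  }
  set.seed(cfg$seed)

  genome <- load_genome(genome_path)
  annotation <- load_annotation(gff_path, genome)
  proteins <- translate_genes(annotation, genome)
  sixframe <- six_frame_translate(genome, min_fragment_len = cfg$min_fragment_len)
  db_known <- dplyr::bind_rows(proteins, build_decoys(proteins))
  db_six <- dplyr::bind_rows(sixframe, build_decoys(sixframe))
  write_protein_db(db_known, file.path(out_dir, "db_known.fasta"),
                   file.path(out_dir, "db_known_manifest.tsv"))

  results <- list(config = cfg, proteins = proteins, sixframe = sixframe)

  search <- NULL
  if (!is.null(spectra_path)) {
    spectra <- read_mgf(spectra_path)
    search <- stepped_search(spectra, list(known = db_known, sixframe = db_six),
                             threshold = cfg$fdr,
                             classes = c("known", "novel"),
                             enzyme = cfg$enzyme, max_missed = cfg$max_missed,
                             len_range = c(cfg$len_min, cfg$len_max))
    stamp(file.path(out_dir, "psms.tsv"), tidy(search))
    results$search <- search
  }

  if (!is.null(denovo_path)) {
    denovo <- readr::read_tsv(denovo_path, show_col_types = FALSE, progress = FALSE)
    saavs <- call_saavs(denovo$sequence, proteins, genome, annotation,
                        allow_multi = cfg$allow_multi_edit)
    sl <- detect_stop_loss(denovo$sequence, proteins, genome, annotation)
    review <- manual_review_export(saavs)
    review$codon_positions <- vapply(review$codon_positions, paste,
                                     character(1), collapse = ",")
    review$edited_offsets <- vapply(review$edited_offsets, paste,
                                    character(1), collapse = ",")
    stamp(file.path(out_dir, "saav_candidates.tsv"), review)
    if (nrow(sl$events)) {
      ev <- sl$events
      ev$junction_peptides <- vapply(ev$junction_peptides, paste, character(1), collapse = ",")
      ev$extension_peptides <- vapply(ev$extension_peptides, paste, character(1), collapse = ",")
      ev$stop_positions <- vapply(ev$stop_positions, paste, character(1), collapse = ",")
      stamp(file.path(out_dir, "stoploss_events.tsv"), ev)
    }
    hits <- map_peptide_to_genome(denovo$sequence, sixframe, proteins, genome)
    hits <- classify_novelty(hits, annotation, proteins)
    export_bed(hits, file.path(out_dir, "peptides.bed"))
    export_probam(hits, genome, file.path(out_dir, "peptides.sam"))
    results$saavs <- saavs
    results$stoploss <- sl$events
    results$hits <- hits

    if (!is.null(coverage_path)) {
      coverage <- readr::read_tsv(coverage_path, show_col_types = FALSE, progress = FALSE)
      bundles <- bundle_evidence(hits, annotation, coverage,
                                 depth_threshold = cfg$depth_min,
                                 max_gap = cfg$max_gap)
      calls <- decide_refinement(bundles)
      flat <- calls
      flat$peptides <- vapply(flat$peptides, paste, character(1), collapse = ",")
      stamp(file.path(out_dir, "refinement_calls.tsv"), flat)
      stamp(file.path(out_dir, "refinement_summary.tsv"), summarize_refinements(calls))
      results$refinement <- calls
    }
  }

  if (!is.null(phylo_hits_path)) {
    phits <- readr::read_tsv(phylo_hits_path, show_col_types = FALSE, progress = FALSE)
    assign <- assign_phylostratum(phits, cutoff = cfg$phylo_cutoff,
                                  all_queries = proteins$protein_id)
    stamp(file.path(out_dir, "phylostrata.tsv"), assign)
    results$phylo <- assign
  }

  write_gff3(annotation, file.path(out_dir, "annotation.gff3"),
             header_extra = paste0("# editoscan config_hash=", hash))
  invisible(results)
}
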