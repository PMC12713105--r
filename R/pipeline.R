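#' Pipeline configuration
#'
#' All analysis constants in one validated list. Defaults are the analysis
#' constants used throughout the package: 5 kb DSB bins, 10 kb loop
#' anchors, 100 kb compartments, 50 kb TADs, 0.95/0.8 differential-loop
#' probability thresholds, a 20 kb enhancer-proximity window, 500
#' ratio-distance bins, 100 expression bins, ten ratio classes, busy-anchor
#' frequency 2, and BH q < 0.05 with fold >= 2 for enrichment regions.
#'
#' @param ... Overrides for any default field (unknown fields warn and are
#'   kept, for forward compatibility).
#' @return A `pipeline_config` list.
#' @export
pipeline_config <- function(...) {
  defaults <- list(
    bin_width = 5000,
    loop_resolution = 10000,
    compartment_resolution = 100000,
    tad_resolution = 50000,
    p_high = 0.95,
    p_low = 0.8,
    enhancer_window = 20000,
    n_ratio_bins = 500,
    n_expr_bins = 100,
    n_classes = 10,
    busy_min_frequency = 2,
    q_threshold = 0.05,
    fold_threshold = 2,
    pseudocount = 0.5,
    apa_window = 10,
    seed = 1L,
    simulate = TRUE,
    sim = list()
  )
  overrides <- list(...)
  unknown <- setdiff(names(overrides), names(defaults))
  if (length(unknown) > 0) {
    warning("unknown config field(s) kept as-is: ", paste(unknown, collapse = ", "))
  }
  cfg <- utils::modifyList(defaults, overrides)
  structure(cfg, class = "pipeline_config")
}

#' Validate and normalize a pipeline configuration
#'
#' Fills missing fields with the defaults and returns the complete list of
#' problems rather than stopping at the first.
#'
#' @param config A list or `pipeline_config`.
#' @return The normalized config; attribute `errors` holds a character
#'   vector of problems (empty when valid). Use [stopifnot_valid_config()]
#'   to turn problems into an error.
#' @export
validate_config <- function(config = list()) {
  cfg <- do.call(pipeline_config, as.list(config))
  errors <- character(0)
  for (nm in c("bin_width", "loop_resolution", "compartment_resolution",
               "tad_resolution", "enhancer_window", "n_ratio_bins",
               "n_expr_bins", "n_classes", "busy_min_frequency")) {
    if (!is.numeric(cfg[[nm]]) || cfg[[nm]] <= 0) {
      errors <- c(errors, paste0("`", nm, "` must be positive"))
    }
  }
  if (cfg$p_low >= cfg$p_high) errors <- c(errors, "`p_low` must be below `p_high`")
  for (nm in c("p_high", "p_low", "q_threshold")) {
    if (!is.numeric(cfg[[nm]]) || cfg[[nm]] < 0 || cfg[[nm]] > 1) {
      errors <- c(errors, paste0("`", nm, "` must be in [0, 1]"))
    }
  }
  if (cfg$fold_threshold < 0) errors <- c(errors, "`fold_threshold` must be >= 0")
  attr(cfg, "errors") <- errors
  cfg
}

#' @rdname validate_config
#' @export
stopifnot_valid_config <- function(config) {
  cfg <- validate_config(config)
  errs <- attr(cfg, "errors", exact = TRUE)
  if (length(errs) > 0) {
    stop("invalid configuration:\n  - ", paste(errs, collapse = "\n  - "), call. = FALSE)
  }
  cfg
}

#' Run the full simulated analysis pipeline
#'
#' Generates a synthetic dataset, writes every intermediate in its standard
#' text format, runs DSB quantification, differential-loop calling, APA,
#' busy-anchor and colocalization statistics, compartment/TAD/expression
#' integration and the multi-evidence gene intersection, and writes a
#' machine-readable JSON run report. Identical config and seed reproduce
#' byte-identical outputs (no timestamps enter any file).
#'
#' @param config A [pipeline_config()]; `config$seed` seeds the generator
#'   and `config$sim` holds [sim_params()] overrides.
#' @param outdir Output directory (created if absent).
#' @param quiet Suppress stage messages.
#' @return The run report, invisibly (also written to `report.json`).
#' @export
run_pipeline <- function(config = pipeline_config(), outdir = tempfile("dsbloop_run_"),
                         quiet = FALSE) {
  cfg <- stopifnot_valid_config(config)
  if (!dir.exists(outdir)) dir.create(outdir, recursive = TRUE)
  say <- function(...) if (!quiet) message("[dsbloop] ", sprintf(...))
  path <- function(f) file.path(outdir, f)

  say("simulate: generating synthetic dataset (seed %d)", cfg$seed)
  sim_args <- utils::modifyList(
    list(seed = cfg$seed, bin_width = cfg$bin_width,
         loop_resolution = cfg$loop_resolution),
    cfg$sim
  )
  params <- do.call(sim_params, sim_args)
  ds <- simulate_dataset(params, contacts = "treated")
  ann <- ds$annotation

  # write inputs in their interchange formats
  write_chrom_sizes(ann$chrom_sizes, path("genome.chrom.sizes"))
  write_bed(dplyr::rename(ann$states, name = state), path("chromatin_states.bed"))
  write_bed(dplyr::rename(ann$repeats, name = subtype), path("repeats.bed"))
  write_gene_table(ds$genes, path("genes.tsv"))
  write_loops(ds$loops$control, path("loops_control.bedpe"))
  write_loops(ds$loops$treated, path("loops_treated.bedpe"))
  write_contacts(ds$contacts$treated, path("contacts_treated.txt"))
  input_files <- c("genome.chrom.sizes", "chromatin_states.bed", "repeats.bed",
                   "genes.tsv", "loops_control.bedpe", "loops_treated.bedpe",
                   "contacts_treated.txt")
  hashes <- as.list(tools::md5sum(vapply(input_files, path, character(1))))
  names(hashes) <- input_files

  say("dsb: ratio, enrichment regions, classes, correlations")
  ratio <- dsb_ratio(ds$dsb$treated, ds$dsb$control, pseudocount = cfg$pseudocount)
  ratio <- bin_enrichment_test(ratio)
  regions <- call_enrichment_regions(ratio, cfg$q_threshold, cfg$fold_threshold)
  write_bedgraph(ratio, path("dsb_ratio.bedgraph"), value = "ratio")
  write_bed(regions, path("dsb_regions.bed"))
  classes <- split_ratio_classes(ratio, cfg$n_classes)
  class_prof <- element_fraction_by_class(classes, ann$states)
  readr::write_tsv(tibble::as_tibble(class_prof), path("ratio_classes.tsv"))
  tssdist <- tss_distance_profile(ratio, ann$genes, cfg$n_ratio_bins)
  readr::write_tsv(tibble::as_tibble(tssdist), path("tss_distance_profile.tsv"))
  states_prox <- classify_enhancer_proximity(ann$states, cfg$enhancer_window)
  enh_cmp <- compare_ratio_by_enhancer(ratio, states_prox)
  rep_cor <- repeat_subtype_correlation(ratio, ann$repeats)
  readr::write_tsv(rep_cor, path("repeat_correlations.tsv"))

  say("loops: differential call, anchors, APA, associations")
  diff <- call_differential_loops(ds$loops$treated, ds$loops$control,
                                  cfg$p_high, cfg$p_low)
  as_loopset <- function(d) {
    new_loopset(tibble::tibble(chrom = d$chrom, start1 = d$start1, start2 = d$start2,
                               probability = pmax(d$p_treated, d$p_control)),
                cfg$loop_resolution)
  }
  write_loops(as_loopset(differential_subset(diff, "gained")), path("loops_gained.bedpe"))
  write_loops(as_loopset(differential_subset(diff, "lost")), path("loops_lost.bedpe"))
  anchors <- build_anchor_table(diff, diff = diff,
                                busy_min_frequency = cfg$busy_min_frequency)
  readr::write_tsv(anchors, path("anchor_table.tsv"))
  assoc <- busy_anchor_association(anchors)
  coloc <- dsb_anchor_enrichment(regions, diff, ann$binning)
  treated_present <- ds$loops$treated[ds$loops$treated$probability > cfg$p_high, ]
  apa_res <- apa(ds$contacts$treated, treated_present, window = cfg$apa_window)
  utils::write.table(apa_res$matrix, path("apa_matrix.tsv"), sep = "\t",
                     row.names = FALSE, col.names = FALSE)

  say("integrate: anchor genes, expression coupling, evidence overlap")
  anchor_genes <- genes_in_anchors(ds$genes, diff)
  readr::write_tsv(anchor_genes, path("anchor_genes.tsv"))
  expr_prof <- expression_dsb_correlation(ds$genes, ratio, regions, cfg$n_expr_bins)
  readr::write_tsv(tibble::as_tibble(expr_prof), path("expression_dsb_profile.tsv"))

  deg_ids <- ds$genes$gene_id[ds$genes$is_deg]
  dsb_gene_ids <- {
    pts <- tibble::tibble(chrom = ds$genes$chrom, start = ds$genes$tss,
                          end = ds$genes$tss + 1)
    hits <- overlap_pairs(pts, regions)
    unique(ds$genes$gene_id[hits$qi])
  }
  evidence <- multi_evidence_overlap(
    list(dsb = dsb_gene_ids, loop = unique(anchor_genes$gene_id), deg = deg_ids),
    candidate_sets = c("dsb", "loop", "deg")
  )
  readr::write_tsv(
    dplyr::select(evidence$combinations, -genes), path("evidence_overlap.tsv")
  )
  writeLines(evidence$candidates, path("candidate_genes.txt"))

  report <- list(
    schema_version = "1.0",
    config = cfg[setdiff(names(cfg), "sim")],
    sim_params = unclass(params),
    input_hashes = hashes,
    summary = list(
      n_bins = nrow(ratio),
      mean_bin_ratio = attr(ratio, "mean_bin_ratio", exact = TRUE),
      totals_ratio = attr(ratio, "totals_ratio", exact = TRUE),
      n_enrichment_regions = nrow(regions),
      n_loops = nrow(ds$loops$treated),
      n_gained = sum(diff$status == "gained"),
      n_lost = sum(diff$status == "lost"),
      n_busy_anchors = sum(anchors$busy),
      busy_assoc_chisq = assoc$statistic,
      busy_assoc_p = assoc$p_value,
      dsb_anchor_overlap_bins = unname(coloc$overlap),
      dsb_anchor_chisq = coloc$statistic,
      dsb_anchor_p = coloc$p_value,
      apa_score = apa_res$apa_score,
      apa_loops_used = apa_res$n_loops_used,
      tss_distance_spearman = attr(tssdist, "spearman_rho", exact = TRUE),
      tss_distance_pearson = attr(tssdist, "pearson_r", exact = TRUE),
      class_tssa_rho = attr(class_prof, "tssa_rho", exact = TRUE),
      class_enha_rho = attr(class_prof, "enha_rho", exact = TRUE),
      enhancer_tests = enh_cmp$tests,
      expression_dsb_pearson_r = attr(expr_prof, "pearson_r", exact = TRUE),
      n_anchor_genes = length(unique(anchor_genes$gene_id)),
      n_deg = length(deg_ids),
      n_candidate_genes = length(evidence$candidates)
    ),
    warnings = character(0)
  )
  jsonlite::write_json(report, path("report.json"), auto_unbox = TRUE,
                       digits = NA, pretty = TRUE)
  say("done: report written to %s", path("report.json"))
  invisible(report)
}
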