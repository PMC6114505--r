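## End-to-end pipeline: layer-1 metadata summaries, the analysis-set
## filter, cumulative DEG categorization, stratified counts and the
## activity-change report, with a machine-readable run manifest.

#' Pipeline configuration
#'
#' Collects every parameter of [run_pipeline()]. Exactly one input mode is
#' active: file mode (`metadata_path` + `matrix_path`) or simulate mode
#' (`simulate` = a [sim_config()]).
#'
#' @param metadata_path,matrix_path Input files (TSV metadata, GCT/GCTX
#'   matrix); both or neither.
#' @param simulate A [sim_config()] for simulate mode, or `NULL`.
#' @param cells Explicit cell-line selection, or `NULL` to select cells
#'   with more than `min_profiles` profiles.
#' @param min_profiles Strict profile-count threshold for automatic cell
#'   selection.
#' @param z_hi,z_lo Strict DEG z-score thresholds.
#' @param thresholds Cumulative category thresholds.
#' @param dose_cutoff_um Low/high dose boundary (uM).
#' @param times Treatment durations kept in the analysis set (hours).
#' @param convention Change-fraction denominator convention.
#' @param seed Integer seed recorded in the manifest (the generator uses
#'   the seed inside `simulate`).
#' @return A `pipeline_config` list.
#' @export
pipeline_config <- function(metadata_path = NULL, matrix_path = NULL,
                            simulate = NULL, cells = NULL,
                            min_profiles = 20000L,
                            z_hi = 2.0, z_lo = -2.0,
                            thresholds = c(1L, 50L, 100L),
                            dose_cutoff_um = 5.0,
                            times = c(6, 24, 48),
                            convention = c("stratum", "as_printed"),
                            seed = 1L) {
  convention <- match.arg(convention)
  file_mode <- !is.null(metadata_path) || !is.null(matrix_path)
  sim_mode <- !is.null(simulate)
  if (file_mode && sim_mode) {
    stop("exactly one of file inputs or simulate must be given",
         call. = FALSE)
  }
  if (file_mode && (is.null(metadata_path) || is.null(matrix_path))) {
    stop("file mode needs both metadata_path and matrix_path",
         call. = FALSE)
  }
  if (!file_mode && !sim_mode) {
    stop("either file inputs or a simulate config is required",
         call. = FALSE)
  }
  if (sim_mode) stopifnot(inherits(simulate, "sim_config"))
  stopifnot(z_lo < z_hi, min_profiles >= 0, dose_cutoff_um > 0,
            all(thresholds >= 1L))
  structure(list(metadata_path = metadata_path, matrix_path = matrix_path,
                 simulate = simulate, cells = cells,
                 min_profiles = as.integer(min_profiles),
                 z_hi = z_hi, z_lo = z_lo,
                 thresholds = as.integer(thresholds),
                 dose_cutoff_um = dose_cutoff_um, times = times,
                 convention = convention, seed = as.integer(seed)),
            class = "pipeline_config")
}

.write_tsv <- function(x, dir, name) {
  path <- file.path(dir, name)
  write.table(as.data.frame(x), path, sep = "\t", quote = FALSE,
              row.names = FALSE)
  path
}

## serializable echo of the configuration for the manifest
.config_manifest <- function(config) {
  sim <- config$simulate
  list(
    mode = if (is.null(sim)) "file" else "simulate",
    metadata_path = config$metadata_path,
    matrix_path = config$matrix_path,
    simulate = if (!is.null(sim)) {
      list(n_genes = sim$n_genes, seed = sim$seed, noise_sd = sim$noise_sd,
           cells = lapply(sim$cell_specs, function(s) {
             list(cell_id = s$cell_id, n_signatures = s$n_signatures,
                  category_mix = as.list(s$category_mix),
                  dose_levels = s$dose_levels, time_levels = s$time_levels,
                  replicate_probs = as.list(s$replicate_probs),
                  hit_probs = as.list(s$hit_probs),
                  base_effect = s$base_effect,
                  dose_response = s$dose_response,
                  time_response = s$time_response)
           }))
    },
    cells = config$cells, min_profiles = config$min_profiles,
    z_hi = config$z_hi, z_lo = config$z_lo,
    thresholds = config$thresholds,
    dose_cutoff_um = config$dose_cutoff_um, times = config$times,
    convention = config$convention, seed = config$seed
  )
}

#' Run the full two-layer analysis pipeline
#'
#' Executes, in order: input acquisition (simulation or file reading),
#' layer-1 metadata summaries (per-cell profile counts, category
#' distribution, replicate/dose/time multiplicity histograms), cell-line
#' selection, the analysis-set filter, per-signature DEG counting,
#' cumulative categorization overall and stratified by cell, dose group
#' and time point, and the activity-change report with segment
#' classifications. All tables are written as TSV under `out_dir`
#' together with a JSON manifest that records every parameter and seed, so
#' a run can be reproduced bit-identically from the manifest alone.
#'
#' @param config A [pipeline_config()].
#' @param out_dir Output directory (created if needed).
#' @param quiet Suppress progress messages.
#' @return Invisibly, a list with every computed table plus the manifest.
#' @export
run_pipeline <- function(config, out_dir, quiet = FALSE) {
  stopifnot(inherits(config, "pipeline_config"))
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  say <- if (quiet) function(...) invisible() else function(...) {
    message("[run_pipeline] ", ...)
  }

  ## stage 1: inputs
  if (!is.null(config$simulate)) {
    say("simulating metadata and signatures (seed ", config$simulate$seed,
        ")")
    meta <- simulate_metadata(config$simulate)
    sim <- simulate_signatures(config$simulate, meta)
    mat <- sim$matrix
  } else {
    say("reading ", config$metadata_path, " and ", config$matrix_path)
    meta <- read_metadata(config$metadata_path)
    mat <- read_zscore_matrix(config$matrix_path)
  }

  ## stage 2: layer-1 summaries
  counts <- profile_counts_by_cell(meta)
  cells <- config$cells %||% select_highly_profiled(counts,
                                                    config$min_profiles)
  if (!length(cells)) {
    stop("no cell lines selected: none exceeds ", config$min_profiles,
         " profiles and no explicit list was given", call. = FALSE)
  }
  say("selected ", length(cells), " cell line(s): ",
      paste(cells, collapse = ", "))
  cat_dist <- category_distribution(meta, cells)
  rep_hist <- replicate_histogram(meta, cells)
  dose_hist <- dose_multiplicity_histogram(meta, cells)
  time_hist <- time_multiplicity_histogram(
    dplyr::filter(meta, .data$cell_id %in% cells))

  ## stage 3: analysis set + DEG counting
  analysis_meta <- filter_analysis_set(meta, cells = cells,
                                       times = config$times)
  deg <- count_deg(mat, z_hi = config$z_hi, z_lo = config$z_lo)
  deg <- deg[deg$sig_id %in% analysis_meta$sig_id, ]
  say("analysis set: ", nrow(analysis_meta), " profiles, ",
      length(unique(analysis_meta$pert_id)), " distinct molecules")

  categories <- categorize_counts(deg, analysis_meta, config$thresholds)
  strat_cell <- stratified_category_counts(deg, analysis_meta, "cell",
                                           config$thresholds)
  strat_dose <- stratified_category_counts(deg, analysis_meta, "cell_dose",
                                           config$thresholds,
                                           config$dose_cutoff_um)
  strat_time <- stratified_category_counts(deg, analysis_meta, "cell_time",
                                           config$thresholds)

  ## stage 4: activity change
  fractions <- dplyr::bind_rows(lapply(cells, function(cl) {
    out <- list()
    for (ctr in c("dose", "time")) {
      strat <- if (ctr == "dose") strat_dose else strat_time
      f <- tryCatch(
        compute_change_fractions(strat, cl, ctr,
                                 convention = config$convention),
        error = function(e) NULL)
      if (!is.null(f)) out[[ctr]] <- f
    }
    dplyr::bind_rows(out)
  }))
  report <- if (nrow(fractions)) activity_change_report(fractions) else
    tibble::tibble()

  ## stage 5: artifacts + manifest
  files <- c(
    .write_tsv(counts, out_dir, "profile_counts.tsv"),
    .write_tsv(cat_dist, out_dir, "category_distribution.tsv"),
    .write_tsv(histogram_table(rep_hist$per_cell), out_dir,
               "replicate_histogram.tsv"),
    .write_tsv(histogram_table(dose_hist$per_cell), out_dir,
               "dose_multiplicity.tsv"),
    .write_tsv(histogram_table(list(all = time_hist$histogram)), out_dir,
               "time_multiplicity.tsv"),
    .write_tsv(categories, out_dir, "deg_categories.tsv"),
    .write_tsv(strat_cell, out_dir, "strat_by_cell.tsv"),
    .write_tsv(strat_dose, out_dir, "strat_by_cell_dose.tsv"),
    .write_tsv(strat_time, out_dir, "strat_by_cell_time.tsv"),
    .write_tsv(fractions, out_dir, "change_fractions.tsv"),
    .write_tsv(report, out_dir, "activity_report.tsv")
  )
  manifest <- list(
    package = "lincsprofiler",
    version = as.character(utils::packageVersion("lincsprofiler")),
    config = .config_manifest(config),
    selected_cells = cells,
    n_profiles_total = nrow(meta),
    n_profiles_analysis = nrow(analysis_meta),
    replicate_fraction_within = rep_hist$fraction_within,
    outputs = basename(files)
  )
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA)
  say("wrote ", length(files) + 1L, " file(s) to ", out_dir)

  invisible(list(meta = meta, matrix = mat, counts = counts, cells = cells,
                 category_distribution = cat_dist,
                 replicate_histogram = rep_hist,
                 dose_multiplicity = dose_hist,
                 time_multiplicity = time_hist,
                 analysis_meta = analysis_meta, deg = deg,
                 categories = categories, strat_cell = strat_cell,
                 strat_dose = strat_dose, strat_time = strat_time,
                 fractions = fractions, report = report,
                 manifest = manifest))
}
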