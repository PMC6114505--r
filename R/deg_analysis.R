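## Layer-2 analysis: per-signature DEG counting by z-score thresholding,
## cumulative "at least k significant genes" categorization, the analysis-set
## filter, and stratification by cell line, dose group and time point.

#' Count differentially expressed genes per signature
#'
#' Applies the strict z-score thresholds to every signature column: a gene
#' is up-regulated when `z > z_hi` and down-regulated when `z < z_lo`
#' (defaults +2 / -2; values exactly at a threshold are not significant).
#' Missing z-scores are excluded from both counts.
#'
#' @param matrix A [signature_matrix()] or bare numeric matrix (genes in
#'   rows, signatures in columns).
#' @param z_hi Upper threshold (strict).
#' @param z_lo Lower threshold (strict); must satisfy `z_lo < z_hi`.
#' @return A tibble (`sig_id`, `n_up`, `n_down`, `n_total`) with one row
#'   per signature.
#' @export
#' @examples
#' z <- matrix(c(2.5, -3, 1.9, -2), ncol = 1,
#'             dimnames = list(paste0("G", 1:4), "s1"))
#' count_deg(z)
count_deg <- function(matrix, z_hi = 2.0, z_lo = -2.0) {
  if (!(z_lo < z_hi)) stop("z_lo must be < z_hi", call. = FALSE)
  m <- .as_signature_matrix(matrix)
  n_up <- as.integer(colSums(m$z > z_hi, na.rm = TRUE))
  n_down <- as.integer(colSums(m$z < z_lo, na.rm = TRUE))
  tibble::tibble(sig_id = m$sig_ids, n_up = n_up, n_down = n_down,
                 n_total = n_up + n_down)
}

#' Restrict metadata to the analysis set
#'
#' Subsets a metadata table to the requested cell lines, perturbation
#' categories and treatment durations — by default the compound signatures
#' of the selected cells at 6, 24 and 48 hours. The number of removed rows
#' is reported via `message()`; an empty result is legal but warns.
#'
#' @param meta Canonical metadata tibble.
#' @param cells Cell ids to keep (`NULL` = all).
#' @param categories Perturbation categories to keep.
#' @param times Treatment durations (hours) to keep (`NULL` = all).
#' @return The filtered metadata tibble.
#' @export
filter_analysis_set <- function(meta, cells = NULL,
                                categories = "compound",
                                times = c(6, 24, 48)) {
  out <- meta
  if (!is.null(cells)) out <- dplyr::filter(out, .data$cell_id %in% cells)
  if (!is.null(categories)) {
    out <- dplyr::filter(out, .data$pert_category %in% categories)
  }
  if (!is.null(times)) out <- dplyr::filter(out, .data$time_h %in% times)
  message("filter_analysis_set: removed ", nrow(meta) - nrow(out),
          " of ", nrow(meta), " profiles")
  if (nrow(out) == 0L) {
    warning("analysis set is empty after filtering", call. = FALSE)
  }
  out
}

## join DEG counts with metadata; orphan sig_ids are a hard error
.join_deg_meta <- function(deg, meta) {
  orphans <- setdiff(deg$sig_id, meta$sig_id)
  if (length(orphans)) {
    stop("DEG records with no matching metadata (", length(orphans),
         " orphan sig_id): ",
         paste(utils::head(orphans, 5), collapse = ", "), call. = FALSE)
  }
  dplyr::inner_join(deg, meta, by = "sig_id")
}

#' Cumulative significance categories for profiles and molecules
#'
#' Tabulates, over an analysis set, how many signature profiles and how
#' many distinct small molecules reach each cumulative category "at least
#' k significant genes" (default k in 1, 50, 100), plus the "no
#' significant gene" category. Profile categories are cumulative in the
#' per-signature DEG total; a distinct molecule (`pert_id`) is counted in
#' category >= k when at least one of its signatures reaches k
#' (equivalently, when its maximum per-signature DEG total does), and in
#' the "none" category when all of its signatures have zero.
#'
#' @param deg DEG-count tibble from [count_deg()].
#' @param meta Canonical metadata tibble covering every `sig_id` in `deg`.
#' @param thresholds Increasing positive integers defining the cumulative
#'   categories.
#' @return A tibble (`category`, `n_profiles`, `n_molecules`) with rows
#'   `"none"` and `"at_least_<k>"`, carrying attributes `total_profiles`
#'   and `total_molecules`.
#' @export
categorize_counts <- function(deg, meta, thresholds = c(1L, 50L, 100L)) {
  thresholds <- as.integer(thresholds)
  stopifnot(length(thresholds) >= 1L, all(thresholds >= 1L),
            !is.unsorted(thresholds, strictly = TRUE))
  joined <- .join_deg_meta(deg, meta)
  per_mol <- joined |>
    dplyr::group_by(.data$pert_id) |>
    dplyr::summarise(max_total = max(.data$n_total), .groups = "drop")

  n_profiles <- c(sum(joined$n_total == 0L),
                  vapply(thresholds, function(k) sum(joined$n_total >= k),
                         integer(1)))
  n_molecules <- c(sum(per_mol$max_total == 0L),
                   vapply(thresholds, function(k) sum(per_mol$max_total >= k),
                          integer(1)))
  out <- tibble::tibble(
    category = c("none", paste0("at_least_", thresholds)),
    n_profiles = as.integer(n_profiles),
    n_molecules = as.integer(n_molecules)
  )
  attr(out, "thresholds") <- thresholds
  attr(out, "total_profiles") <- nrow(joined)
  attr(out, "total_molecules") <- nrow(per_mol)
  out
}

#' Assign doses to low/high concentration groups
#'
#' Two-way split of canonical micromolar doses at a cutoff (default 5 uM):
#' doses less than or equal to the cutoff — which includes every nanomolar
#' dose — are "low", doses above it are "high". Missing doses stay `NA`
#' (genetic perturbations and controls carry no concentration).
#'
#' @param dose_um Numeric doses in micromolar.
#' @param cutoff_um Boundary, inclusive on the low side.
#' @return Factor with levels `"low"`, `"high"`.
#' @export
#' @examples
#' assign_dose_group(c(0.5, 5, 10, NA))
assign_dose_group <- function(dose_um, cutoff_um = 5.0) {
  factor(ifelse(is.na(dose_um), NA_character_,
                ifelse(dose_um <= cutoff_um, "low", "high")),
         levels = c("low", "high"))
}

#' Stratified cumulative category counts
#'
#' Computes, within each stratum, the same cumulative "at least k" profile
#' counts as [categorize_counts()]. Strata are cell lines (`by = "cell"`),
#' cell lines crossed with the low/high dose group (`"cell_dose"`), or cell
#' lines crossed with the treatment duration (`"cell_time"`). Dose
#' stratification excludes records with a missing dose and reports the
#' excluded count via `message()`. Strata with zero profiles are omitted.
#'
#' @param deg DEG-count tibble from [count_deg()].
#' @param meta Canonical metadata tibble covering every `sig_id` in `deg`.
#' @param by Stratifier: `"cell"`, `"cell_dose"` or `"cell_time"`.
#' @param thresholds Increasing positive integers, as in
#'   [categorize_counts()].
#' @param dose_cutoff_um Dose-group boundary for `"cell_dose"`.
#' @return A tibble with the stratum columns (`cell_id` and, as
#'   applicable, `dose_group` or `time_h`) followed by `n_profiles`,
#'   `n_none` and one `n_ge<k>` column per threshold.
#' @export
stratified_category_counts <- function(deg, meta,
                                       by = c("cell", "cell_dose",
                                              "cell_time"),
                                       thresholds = c(1L, 50L, 100L),
                                       dose_cutoff_um = 5.0) {
  by <- match.arg(by)
  thresholds <- as.integer(thresholds)
  joined <- .join_deg_meta(deg, meta)
  if (by == "cell_dose") {
    n_missing <- sum(is.na(joined$dose_um))
    if (n_missing > 0L) {
      message("stratified_category_counts: excluded ", n_missing,
              " profile(s) with missing dose")
      joined <- dplyr::filter(joined, !is.na(.data$dose_um))
    }
    joined$dose_group <- assign_dose_group(joined$dose_um, dose_cutoff_um)
  }
  group_cols <- switch(by,
                       cell = "cell_id",
                       cell_dose = c("cell_id", "dose_group"),
                       cell_time = c("cell_id", "time_h"))
  out <- joined |>
    dplyr::group_by(dplyr::across(dplyr::all_of(group_cols))) |>
    dplyr::summarise(
      n_profiles = dplyr::n(),
      n_none = sum(.data$n_total == 0L),
      !!!setNames(
        lapply(thresholds, function(k) {
          rlang::expr(sum(.data$n_total >= !!k))
        }),
        paste0("n_ge", thresholds)
      ),
      .groups = "drop"
    )
  if (by == "cell_dose") out$dose_group <- as.character(out$dose_group)
  out
}

#' Direction of a count change between two condition levels
#'
#' Compares a cumulative category count for one cell line across two
#' ordered condition levels (e.g. low vs high dose, or 6 h vs 24 h) and
#' reports whether activity increases, decreases or is unchanged up to a
#' tolerance.
#'
#' @param strat Stratified counts from [stratified_category_counts()] with
#'   `by = "cell_dose"` or `"cell_time"`.
#' @param cell Cell id to evaluate.
#' @param levels Length-2 vector giving the ordered condition levels
#'   (A, B), matched against `dose_group` or `time_h`.
#' @param category Name of the count column to compare (default
#'   `"n_ge100"`).
#' @param tol Non-negative tolerance: differences of at most `tol` count
#'   as `"unchanged"`.
#' @return `"increasing"`, `"decreasing"` or `"unchanged"`; `NA` with a
#'   warning when a level is missing for the cell.
#' @export
behavior_direction <- function(strat, cell, levels,
                               category = "n_ge100", tol = 0) {
  stopifnot(length(levels) == 2L)
  level_col <- intersect(c("dose_group", "time_h"), names(strat))
  if (length(level_col) != 1L) {
    stop("strat must carry exactly one of 'dose_group' or 'time_h'",
         call. = FALSE)
  }
  if (!category %in% names(strat)) {
    stop("unknown category column: ", category, call. = FALSE)
  }
  rows <- strat[strat$cell_id == cell, ]
  a <- rows[[category]][rows[[level_col]] == levels[[1L]]]
  b <- rows[[category]][rows[[level_col]] == levels[[2L]]]
  if (length(a) != 1L || length(b) != 1L) {
    warning("behavior_direction not evaluable for cell ", cell,
            ": missing level", call. = FALSE)
    return(NA_character_)
  }
  if (b > a + tol) "increasing"
  else if (b < a - tol) "decreasing"
  else "unchanged"
}
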