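## Layer-1 summaries: profile counts per cell line, highly profiled cell
## selection, category distributions, and capped multiplicity histograms
## for replicates, dosages and time points.

#' Capped integer histogram
#'
#' Tallies positive integer values into bins `1 .. cap-1` plus a single
#' overflow bucket labelled `"<cap>+"` that pools all values `>= cap` —
#' the "9 or more" convention used for replicate and dose-multiplicity
#' distributions.
#'
#' @param values Positive integer values.
#' @param cap Overflow boundary (default 9): values `>= cap` pool into the
#'   `"<cap>+"` bucket.
#' @return An object of class `capped_histogram`: a list with
#'   `bin_counts` (named integer vector over `1..cap-1` and `"<cap>+"`),
#'   `cap` and `total`.
#' @export
#' @examples
#' capped_histogram(c(3, 3, 5, 9, 27))
capped_histogram <- function(values, cap = 9L) {
  cap <- as.integer(cap)
  stopifnot(cap >= 2L)
  values <- values[!is.na(values)]
  values <- as.integer(values)
  if (any(values < 1L)) stop("values must be positive integers", call. = FALSE)
  labels <- c(as.character(seq_len(cap - 1L)), paste0(cap, "+"))
  binned <- ifelse(values >= cap, paste0(cap, "+"), as.character(values))
  counts <- table(factor(binned, levels = labels))
  structure(list(bin_counts = setNames(as.integer(counts), labels),
                 cap = cap, total = length(values)),
            class = "capped_histogram")
}

#' @export
print.capped_histogram <- function(x, ...) {
  cat("capped_histogram (cap ", x$cap, ", total ", x$total, "):\n", sep = "")
  print(x$bin_counts)
  invisible(x)
}

#' Tidy a set of capped histograms into one table
#'
#' @param histograms Named list of [capped_histogram()] objects.
#' @return A tibble with columns `group`, `bin`, `n`.
#' @export
histogram_table <- function(histograms) {
  dplyr::bind_rows(lapply(names(histograms), function(g) {
    h <- histograms[[g]]
    tibble::tibble(group = g, bin = names(h$bin_counts),
                   n = unname(h$bin_counts))
  }))
}

#' Signature profile counts per cell line
#'
#' Counts available signature profiles per cell line, optionally restricted
#' to a set of perturbation categories (the unrestricted count and the
#' category-filtered count are both one call away, since whether control
#' profiles belong in a per-cell census is an analysis choice).
#'
#' @param meta Canonical metadata tibble.
#' @param categories Optional character vector of categories to keep
#'   (`NULL` = all).
#' @return A tibble (`cell_id`, `n_profiles`) sorted by descending count,
#'   ties broken by cell id.
#' @export
profile_counts_by_cell <- function(meta, categories = NULL) {
  if (!is.null(categories)) {
    meta <- dplyr::filter(meta, .data$pert_category %in% categories)
  }
  meta |>
    dplyr::count(.data$cell_id, name = "n_profiles") |>
    dplyr::arrange(dplyr::desc(.data$n_profiles), .data$cell_id)
}

#' Total profile count with category exclusions
#'
#' Sums profiles over a metadata table, leaving out records from excluded
#' perturbation categories (e.g. knockdown and overexpression when counting
#' the treatment-side compendium).
#'
#' @param meta Canonical metadata tibble carrying `pert_category`.
#' @param excluded_categories Character vector of categories to exclude.
#' @return Integer total.
#' @export
#' @examples
#' meta <- tibble::tibble(pert_category = c("compound", "compound",
#'                                          "compound", "shRNA", "shRNA",
#'                                          "overexpression"))
#' total_profiles(meta, c("shRNA", "overexpression"))
total_profiles <- function(meta, excluded_categories = character()) {
  sum(!meta$pert_category %in% excluded_categories)
}

#' Select highly profiled cell lines
#'
#' Returns cell lines whose profile count strictly exceeds `min_profiles`,
#' ordered by descending count (ties broken by cell id). With the default
#' threshold of 20,000 this is the "more than 20,000 profiles" rule that
#' singles out the small set of deeply profiled lines from a compendium.
#'
#' @param counts Tibble from [profile_counts_by_cell()].
#' @param min_profiles Strict lower bound on the profile count.
#' @return Character vector of cell ids.
#' @export
select_highly_profiled <- function(counts, min_profiles = 20000L) {
  counts |>
    dplyr::filter(.data$n_profiles > min_profiles) |>
    dplyr::arrange(dplyr::desc(.data$n_profiles), .data$cell_id) |>
    dplyr::pull(.data$cell_id)
}

#' Perturbation-category distribution per cell line
#'
#' Tallies, for each requested cell line, the profiles in each of the six
#' perturbation categories. Cells absent from the metadata yield all-zero
#' rows, and zero-count categories are kept, so row sums always equal the
#' per-cell profile counts.
#'
#' @param meta Canonical metadata tibble.
#' @param cells Character vector of cell ids to tabulate.
#' @return A tibble (`cell_id`, `pert_category`, `n`) with
#'   `length(cells) * 6` rows.
#' @export
category_distribution <- function(meta, cells) {
  sub <- dplyr::filter(meta, .data$cell_id %in% cells)
  tab <- table(factor(sub$cell_id, levels = cells),
               factor(sub$pert_category, levels = lincs_categories()))
  out <- tibble::as_tibble(as.data.frame(tab, stringsAsFactors = FALSE))
  names(out) <- c("cell_id", "pert_category", "n")
  out$n <- as.integer(out$n)
  dplyr::arrange(out, match(.data$cell_id, cells),
                 match(.data$pert_category, lincs_categories()))
}

#' Replicate-count distribution per cell line
#'
#' Builds a capped histogram of collapsed replicate counts for each cell
#' line, plus the pooled fraction of profiles whose replicate count lies in
#' `1 .. cap-1` (the complement is the rare "cap or more" tail).
#'
#' @param meta Canonical metadata tibble with `n_replicates`.
#' @param cells Cell ids to stratify by (`NULL` = all cells present).
#' @param cap Overflow boundary, see [capped_histogram()].
#' @return A list with `per_cell` (named list of [capped_histogram()]),
#'   `pooled` (one histogram over all selected profiles) and
#'   `fraction_within` (pooled fraction with `1 <= r <= cap-1`).
#' @export
replicate_histogram <- function(meta, cells = NULL, cap = 9L) {
  if (is.null(cells)) cells <- sort(unique(meta$cell_id))
  sub <- dplyr::filter(meta, .data$cell_id %in% cells,
                       !is.na(.data$n_replicates))
  per_cell <- lapply(setNames(cells, cells), function(cl) {
    capped_histogram(sub$n_replicates[sub$cell_id == cl], cap = cap)
  })
  pooled <- capped_histogram(sub$n_replicates, cap = cap)
  frac <- if (pooled$total > 0L) {
    sum(pooled$bin_counts[seq_len(cap - 1L)]) / pooled$total
  } else {
    NA_real_
  }
  list(per_cell = per_cell, pooled = pooled, fraction_within = frac)
}

## distinct-value multiplicity per (cell, pert) pair
.multiplicity <- function(meta, value_col, by_cell = TRUE) {
  groups <- if (by_cell) c("cell_id", "pert_id") else "pert_id"
  meta |>
    dplyr::group_by(dplyr::across(dplyr::all_of(groups))) |>
    dplyr::summarise(multiplicity = dplyr::n_distinct(.data[[value_col]]),
                     .groups = "drop")
}

#' Dose-multiplicity distribution per cell line
#'
#' For each (cell line, compound) pair, counts the number of distinct
#' canonical micromolar doses at which the compound was profiled, then
#' histograms that multiplicity per cell line with a `"cap+"` overflow.
#' Distinctness is on the canonical micromolar value, so 500 nM and 0.5 uM
#' are one dose. Only compound records with a non-missing dose contribute.
#'
#' @param meta Canonical metadata tibble.
#' @param cells Cell ids to stratify by (`NULL` = all).
#' @param cap Overflow boundary.
#' @return A list with `per_cell` (named list of [capped_histogram()]) and
#'   `pairs` (tibble of per-(cell, pert) multiplicities).
#' @export
dose_multiplicity_histogram <- function(meta, cells = NULL, cap = 9L) {
  sub <- dplyr::filter(meta, .data$pert_category == "compound",
                       !is.na(.data$dose_um))
  if (is.null(cells)) cells <- sort(unique(sub$cell_id))
  sub <- dplyr::filter(sub, .data$cell_id %in% cells)
  pairs <- .multiplicity(sub, "dose_um", by_cell = TRUE)
  per_cell <- lapply(setNames(cells, cells), function(cl) {
    capped_histogram(pairs$multiplicity[pairs$cell_id == cl], cap = cap)
  })
  list(per_cell = per_cell, pairs = pairs)
}

#' Time-point multiplicity distribution
#'
#' For each perturbagen, counts the number of distinct treatment durations
#' at which it was profiled and histograms the multiplicities with a
#' `"cap+"` overflow.
#'
#' @param meta Canonical metadata tibble with `time_h`.
#' @param cap Overflow boundary.
#' @return A list with `histogram` (a [capped_histogram()]) and `perts`
#'   (tibble of per-pert multiplicities).
#' @export
time_multiplicity_histogram <- function(meta, cap = 9L) {
  sub <- dplyr::filter(meta, !is.na(.data$time_h))
  perts <- .multiplicity(sub, "time_h", by_cell = FALSE)
  list(histogram = capped_histogram(perts$multiplicity, cap = cap),
       perts = perts)
}
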