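## Change fractions between condition pairs (low->high dose, 6h->24h) and
## the geometric classification of dose-contrast vs time-contrast segments
## as parallel or intersecting.

#' Change fractions for one cell line and one contrast
#'
#' For a two-level contrast A -> B (dose: low -> high; time: 6 h -> 24 h),
#' computes the fraction of profiles in the "at least 1 significant gene"
#' category that also reach "at least 50" and "at least 100":
#' `f_X_k = count(>=k | X) / denominator`. Under the default `"stratum"`
#' convention each level is normalized by its own `>=1` count, so all four
#' fractions lie in `[0, 1]`; under `"as_printed"` all four share the
#' level-A denominator (the literal conditional form), so the B fractions
#' may exceed 1.
#'
#' @param strat Stratified counts from [stratified_category_counts()]
#'   (`by = "cell_dose"` for the dose contrast, `"cell_time"` for the time
#'   contrast) with `n_ge1`, `n_ge50`, `n_ge100` columns.
#' @param cell Cell id.
#' @param contrast `"dose"` (A = low, B = high) or `"time"` (A = 6, B =
#'   24).
#' @param convention Denominator convention, `"stratum"` or
#'   `"as_printed"`.
#' @param levels Optional length-2 override of the contrast levels.
#' @return A one-row tibble (`cell_id`, `contrast`, `convention`,
#'   `level_A`, `level_B`, `f_A50`, `f_A100`, `f_B50`, `f_B100`).
#' @export
compute_change_fractions <- function(strat, cell,
                                     contrast = c("dose", "time"),
                                     convention = c("stratum", "as_printed"),
                                     levels = NULL) {
  contrast <- match.arg(contrast)
  convention <- match.arg(convention)
  level_col <- if (contrast == "dose") "dose_group" else "time_h"
  if (!level_col %in% names(strat)) {
    stop("strat lacks the '", level_col, "' column needed for the ",
         contrast, " contrast", call. = FALSE)
  }
  if (is.null(levels)) {
    levels <- if (contrast == "dose") c("low", "high") else c(6, 24)
  }
  stopifnot(length(levels) == 2L)
  needed <- c("n_ge1", "n_ge50", "n_ge100")
  if (!all(needed %in% names(strat))) {
    stop("strat must carry columns ", paste(needed, collapse = ", "),
         call. = FALSE)
  }
  rows <- strat[strat$cell_id == cell, ]
  pick <- function(level) {
    r <- rows[rows[[level_col]] == level, ]
    if (nrow(r) != 1L) {
      stop("level '", level, "' of the ", contrast,
           " contrast is missing for cell ", cell, call. = FALSE)
    }
    r
  }
  a <- pick(levels[[1L]])
  b <- pick(levels[[2L]])
  if (a$n_ge1 == 0L) {
    stop("zero '>=1' denominator in stratum (", cell, ", ", levels[[1L]],
         ")", call. = FALSE)
  }
  den_b <- if (convention == "stratum") b$n_ge1 else a$n_ge1
  if (den_b == 0L) {
    stop("zero '>=1' denominator in stratum (", cell, ", ", levels[[2L]],
         ")", call. = FALSE)
  }
  tibble::tibble(
    cell_id = cell, contrast = contrast, convention = convention,
    level_A = as.character(levels[[1L]]), level_B = as.character(levels[[2L]]),
    f_A50 = a$n_ge50 / a$n_ge1,
    f_A100 = a$n_ge100 / a$n_ge1,
    f_B50 = b$n_ge50 / den_b,
    f_B100 = b$n_ge100 / den_b
  )
}

#' Classify two A->B segments as parallel, intersecting or neither
#'
#' Each segment is a pair of ordinates over the shared abscissa A -> B
#' (coded 0 -> 1, so the slope is simply `f_B - f_A`). The pair is
#' `"intersecting"` when the endpoint differences change sign
#' (`(p_A - q_A) * (p_B - q_B) < 0`), `"parallel"` when the slopes agree
#' within `slope_tol` and no sign change occurs, and `"neither"`
#' otherwise. The classification is symmetric in its two arguments.
#'
#' @param p,q Numeric length-2 vectors `(f_A, f_B)`.
#' @param slope_tol Absolute slope tolerance for parallelism.
#' @return `"parallel"`, `"intersecting"` or `"neither"`.
#' @export
#' @examples
#' classify_segment_pair(c(0.4, 0.6), c(0.2, 0.4))  # parallel
#' classify_segment_pair(c(0.4, 0.3), c(0.2, 0.5))  # intersecting
classify_segment_pair <- function(p, q, slope_tol = 0.02) {
  stopifnot(length(p) == 2L, length(q) == 2L,
            all(is.finite(p)), all(is.finite(q)))
  d_a <- p[[1L]] - q[[1L]]
  d_b <- p[[2L]] - q[[2L]]
  if (d_a * d_b < 0) return("intersecting")
  slope_p <- p[[2L]] - p[[1L]]
  slope_q <- q[[2L]] - q[[1L]]
  if (abs(slope_p - slope_q) <= slope_tol) "parallel" else "neither"
}

#' Per-cell activity-change report
#'
#' Combines the dose-contrast and time-contrast fraction sets of each cell
#' line into one row: the eight fractions as percentages, the four segment
#' slopes, the parallel/intersecting classification of the dose vs time
#' segments at each category level, and the maximum percentage. Cells
#' missing one contrast are reported with `evaluable = FALSE` and `NA`
#' markers rather than dropped.
#'
#' @param fractions Tibble of rows from [compute_change_fractions()],
#'   covering (ideally) both contrasts per cell.
#' @param slope_tol Tolerance passed to [classify_segment_pair()].
#' @return A tibble with one row per cell line.
#' @export
activity_change_report <- function(fractions, slope_tol = 0.02) {
  cells <- unique(fractions$cell_id)
  rows <- lapply(cells, function(cl) {
    d <- fractions[fractions$cell_id == cl & fractions$contrast == "dose", ]
    t <- fractions[fractions$cell_id == cl & fractions$contrast == "time", ]
    base <- tibble::tibble(cell_id = cl, evaluable = nrow(d) == 1L &&
                             nrow(t) == 1L)
    if (!base$evaluable) {
      return(dplyr::bind_cols(base, tibble::tibble(
        pct_dose_A50 = NA_real_, pct_dose_A100 = NA_real_,
        pct_dose_B50 = NA_real_, pct_dose_B100 = NA_real_,
        pct_time_A50 = NA_real_, pct_time_A100 = NA_real_,
        pct_time_B50 = NA_real_, pct_time_B100 = NA_real_,
        slope_dose_50 = NA_real_, slope_dose_100 = NA_real_,
        slope_time_50 = NA_real_, slope_time_100 = NA_real_,
        class_50 = NA_character_, class_100 = NA_character_,
        max_pct = NA_real_
      )))
    }
    seg_d50 <- c(d$f_A50, d$f_B50)
    seg_d100 <- c(d$f_A100, d$f_B100)
    seg_t50 <- c(t$f_A50, t$f_B50)
    seg_t100 <- c(t$f_A100, t$f_B100)
    pcts <- 100 * c(seg_d50[1], seg_d100[1], seg_d50[2], seg_d100[2],
                    seg_t50[1], seg_t100[1], seg_t50[2], seg_t100[2])
    dplyr::bind_cols(base, tibble::tibble(
      pct_dose_A50 = pcts[1], pct_dose_A100 = pcts[2],
      pct_dose_B50 = pcts[3], pct_dose_B100 = pcts[4],
      pct_time_A50 = pcts[5], pct_time_A100 = pcts[6],
      pct_time_B50 = pcts[7], pct_time_B100 = pcts[8],
      slope_dose_50 = seg_d50[2] - seg_d50[1],
      slope_dose_100 = seg_d100[2] - seg_d100[1],
      slope_time_50 = seg_t50[2] - seg_t50[1],
      slope_time_100 = seg_t100[2] - seg_t100[1],
      class_50 = classify_segment_pair(seg_d50, seg_t50, slope_tol),
      class_100 = classify_segment_pair(seg_d100, seg_t100, slope_tol),
      max_pct = max(pcts)
    ))
  })
  dplyr::bind_rows(rows)
}
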