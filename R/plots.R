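## Optional figures mirroring the standard compendium summaries: per-cell
## profile counts, stacked category distributions, and the four-segment
## activity-change panels.

#' Bar chart of profile counts per cell line
#'
#' @param counts Tibble from [profile_counts_by_cell()].
#' @return A ggplot object.
#' @export
plot_profile_counts <- function(counts) {
  ggplot2::ggplot(counts,
                  ggplot2::aes(x = stats::reorder(.data$cell_id,
                                                  -.data$n_profiles),
                               y = .data$n_profiles)) +
    ggplot2::geom_col() +
    ggplot2::labs(x = "cell line", y = "signature profiles") +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 60,
                                                       hjust = 1))
}

#' Stacked bar chart of perturbation categories per cell line
#'
#' @param cat_dist Tibble from [category_distribution()].
#' @return A ggplot object.
#' @export
plot_category_distribution <- function(cat_dist) {
  ggplot2::ggplot(cat_dist,
                  ggplot2::aes(x = .data$cell_id, y = .data$n,
                               fill = .data$pert_category)) +
    ggplot2::geom_col(position = "stack") +
    ggplot2::labs(x = "cell line", y = "profiles", fill = "category") +
    ggplot2::theme_minimal()
}

#' Four-segment activity-change panels
#'
#' One panel per cell line showing the dose-contrast and time-contrast
#' segments at the two category levels over the shared A -> B abscissa —
#' the visual counterpart of the parallel/intersecting classification in
#' [activity_change_report()].
#'
#' @param fractions Tibble of rows from [compute_change_fractions()].
#' @return A ggplot object.
#' @export
plot_activity_segments <- function(fractions) {
  long <- dplyr::bind_rows(lapply(c("50", "100"), function(k) {
    tibble::tibble(
      cell_id = rep(fractions$cell_id, 2L),
      segment = paste0(rep(fractions$contrast, 2L), k),
      x = rep(c(0, 1), each = nrow(fractions)),
      pct = 100 * c(fractions[[paste0("f_A", k)]],
                    fractions[[paste0("f_B", k)]])
    )
  }))
  ggplot2::ggplot(long, ggplot2::aes(x = .data$x, y = .data$pct,
                                     colour = .data$segment)) +
    ggplot2::geom_line() +
    ggplot2::geom_point() +
    ggplot2::facet_wrap(~cell_id) +
    ggplot2::scale_x_continuous(breaks = c(0, 1), labels = c("A", "B")) +
    ggplot2::labs(x = NULL, y = "% of active profiles") +
    ggplot2::theme_minimal()
}
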