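# Fixtures are built in code: toy metadata tables, small simulation
# configurations, and an independent element-by-element DEG counter used as
# the oracle against the vectorized implementation.

toy_meta <- function(cell_id, pert_category, dose_um = NA_real_,
                     time_h = 24, pert_id = NULL, n_replicates = 3L,
                     sig_id = NULL) {
  n <- max(length(cell_id), length(pert_category), length(dose_um),
           length(time_h), length(n_replicates))
  if (is.null(pert_id)) pert_id <- sprintf("P%03d", seq_len(n))
  if (is.null(sig_id)) sig_id <- sprintf("SIG%04d", seq_len(n))
  tibble::tibble(
    sig_id = sig_id,
    cell_id = rep_len(cell_id, n),
    pert_id = rep_len(pert_id, n),
    pert_iname = rep_len(pert_id, n),
    pert_category = rep_len(pert_category, n),
    dose_um = rep_len(as.numeric(dose_um), n),
    time_h = rep_len(as.numeric(time_h), n),
    n_replicates = rep_len(as.integer(n_replicates), n)
  )
}

## independent oracle: per-element loop, no vectorized shortcuts
brute_force_deg <- function(z, z_hi = 2.0, z_lo = -2.0) {
  n_up <- integer(ncol(z))
  n_down <- integer(ncol(z))
  for (j in seq_len(ncol(z))) {
    for (i in seq_len(nrow(z))) {
      v <- z[i, j]
      if (is.na(v)) next
      if (v > z_hi) n_up[j] <- n_up[j] + 1L
      if (v < z_lo) n_down[j] <- n_down[j] + 1L
    }
  }
  tibble::tibble(sig_id = colnames(z), n_up = n_up, n_down = n_down,
                 n_total = n_up + n_down)
}

## one-cell compound-only configuration used across DEG/activity tests
compound_config <- function(cell_id = "X", n = 240L, seed = 11L,
                            dose_levels = c(1, 10), time_levels = c(6, 24),
                            hit_count = 100L, base_effect = 3,
                            dose_response = "increasing",
                            time_response = "flat", n_genes = 978L) {
  sim_config(list(cell_spec(
    cell_id, n, category_mix = c(compound = 1),
    dose_levels = dose_levels, time_levels = time_levels,
    hit_count = hit_count, base_effect = base_effect,
    dose_response = dose_response, time_response = time_response
  )), n_genes = n_genes, seed = seed)
}

## per-gene null significance rate under the strict |z| > 2 rule
P0_NULL <- 2 * stats::pnorm(-2)

write_lincs_tsv <- function(path, rows) {
  header <- paste(c("sig_id", "cell_id", "pert_id", "pert_iname",
                    "pert_type", "pert_dose", "pert_dose_unit",
                    "pert_time", "pert_time_unit", "distil_nsample"),
                  collapse = "\t")
  writeLines(c(header, rows), path)
}
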