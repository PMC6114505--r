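## LINCS-shaped synthetic data: metadata tables and z-score matrices with
## planted differential-expression effects, plus exact analytic oracles for
## the downstream category fractions.

#' Per-cell-line simulation specification
#'
#' Describes one cell line of a synthetic compendium: how many signatures
#' to generate, the mixture over the six perturbation categories, the
#' compound dose and time designs, the replicate-count distribution, the
#' number of planted hit genes per active signature, and the direction of
#' the dose and time responses.
#'
#' Compound signatures enumerate the full dose x time grid per distinct
#' compound, so each compound is profiled at every configured dose and
#' time (extra signatures beyond a whole number of grids are assigned as
#' repeats of grid cells, preserving the per-compound dose multiplicity).
#' The planted per-hit effect mean is `mu0 * g(dose) * h(time)`, with `g`
#' and `h` equal to 1 for a `"flat"` response, `x / max(levels)` for
#' `"increasing"` and `min(levels) / x` for `"decreasing"` — simple
#' monotone forms.
#'
#' @param cell_id Cell line name.
#' @param n_signatures Number of signatures to generate for this cell.
#' @param category_mix Named probabilities over [lincs_categories()]
#'   (must sum to 1; omitted categories get 0).
#' @param dose_levels Compound dose design, micromolar.
#' @param time_levels Treatment durations, hours.
#' @param replicate_probs Named probabilities over replicate counts.
#' @param hit_count Either a single integer (every active signature gets
#'   that many hit genes) or a named probability vector over hit counts.
#' @param base_effect `mu0 > 0`, the per-hit absolute z-shift at the
#'   reference dose/time.
#' @param dose_response,time_response `"flat"`, `"increasing"` or
#'   `"decreasing"`.
#' @return A `cell_spec` list.
#' @export
cell_spec <- function(cell_id,
                      n_signatures,
                      category_mix = c(control = 0.30, ligand = 0.02,
                                       poscon = 0.03, compound = 0.45,
                                       overexpression = 0.12, shRNA = 0.08),
                      dose_levels = c(0.1, 1, 5, 10),
                      time_levels = c(6, 24, 48),
                      replicate_probs = c(`1` = 0.10, `2` = 0.22, `3` = 0.34,
                                          `4` = 0.18, `5` = 0.07, `6` = 0.04,
                                          `7` = 0.02, `8` = 0.02, `9` = 0.005,
                                          `13` = 0.003, `27` = 0.002),
                      hit_count = 100L,
                      base_effect = 3,
                      dose_response = c("flat", "increasing", "decreasing"),
                      time_response = c("flat", "increasing", "decreasing")) {
  dose_response <- match.arg(dose_response)
  time_response <- match.arg(time_response)
  mix <- setNames(rep(0, 6L), lincs_categories())
  if (!all(names(category_mix) %in% lincs_categories())) {
    stop("category_mix names must be in lincs_categories()", call. = FALSE)
  }
  mix[names(category_mix)] <- category_mix
  if (abs(sum(mix) - 1) > 1e-8) {
    stop("category_mix must sum to 1", call. = FALSE)
  }
  if (abs(sum(replicate_probs) - 1) > 1e-8) {
    stop("replicate_probs must sum to 1", call. = FALSE)
  }
  if (is.null(names(replicate_probs))) {
    stop("replicate_probs must be named by replicate count", call. = FALSE)
  }
  hit_probs <- if (length(hit_count) == 1L && is.null(names(hit_count))) {
    setNames(1, as.character(as.integer(hit_count)))
  } else {
    if (abs(sum(hit_count) - 1) > 1e-8 || is.null(names(hit_count))) {
      stop("hit_count must be a single count or a named probability vector",
           call. = FALSE)
    }
    hit_count
  }
  stopifnot(n_signatures >= 1L, base_effect > 0, all(dose_levels > 0),
            all(time_levels > 0))
  structure(list(cell_id = cell_id,
                 n_signatures = as.integer(n_signatures),
                 category_mix = mix,
                 dose_levels = sort(unique(dose_levels)),
                 time_levels = sort(unique(time_levels)),
                 replicate_probs = replicate_probs,
                 hit_probs = hit_probs,
                 base_effect = base_effect,
                 dose_response = dose_response,
                 time_response = time_response),
            class = "cell_spec")
}

#' Simulation configuration
#'
#' @param cell_specs List of [cell_spec()] objects (unique cell ids).
#' @param n_genes Number of landmark genes (default 978).
#' @param seed Integer seed; all generator randomness derives from it.
#' @param noise_sd Null z-score standard deviation (1 for proper
#'   z-scores).
#' @return A `sim_config` list.
#' @export
sim_config <- function(cell_specs, n_genes = 978L, seed = 1L,
                       noise_sd = 1.0) {
  if (inherits(cell_specs, "cell_spec")) cell_specs <- list(cell_specs)
  if (!length(cell_specs) ||
      !all(vapply(cell_specs, inherits, logical(1), "cell_spec"))) {
    stop("cell_specs must be a non-empty list of cell_spec objects",
         call. = FALSE)
  }
  ids <- vapply(cell_specs, function(s) s$cell_id, character(1))
  if (anyDuplicated(ids)) stop("duplicate cell ids", call. = FALSE)
  stopifnot(n_genes >= 1L, noise_sd > 0)
  structure(list(cell_specs = setNames(cell_specs, ids),
                 n_genes = as.integer(n_genes),
                 seed = as.integer(seed),
                 noise_sd = noise_sd),
            class = "sim_config")
}

#' Default LINCS-shaped fixture configuration
#'
#' Nine deeply profiled cell lines (A375, A549, HCC515, HA1E, HEPG2, HT29,
#' MCF7, PC3, VCAP), 200 signatures each, compound doses 0.1/1/5/10 uM and
#' durations 6/24/48 h. The planted response directions mirror the two
#' qualitative behaviors seen in large compendia: activity rising with
#' dose everywhere except VCAP (falling), and rising with time except
#' HA1E and HCC515 (falling).
#'
#' @param seed Integer seed.
#' @param n_per_cell Signatures per cell line (default 200).
#' @return A [sim_config()].
#' @export
default_sim_config <- function(seed = 1L, n_per_cell = 200L) {
  cells <- c("A375", "A549", "HCC515", "HA1E", "HEPG2", "HT29", "MCF7",
             "PC3", "VCAP")
  dose_dec <- "VCAP"
  time_dec <- c("HA1E", "HCC515")
  specs <- lapply(cells, function(cl) {
    cell_spec(cl, n_signatures = n_per_cell,
              dose_response = if (cl %in% dose_dec) "decreasing"
                              else "increasing",
              time_response = if (cl %in% time_dec) "decreasing"
                              else "increasing")
  })
  sim_config(specs, seed = seed)
}

## response multiplier g(x) for the configured direction over design levels
.response_multiplier <- function(x, levels, direction) {
  switch(direction,
         flat = rep(1, length(x)),
         increasing = x / max(levels),
         decreasing = min(levels) / x)
}

## draw from a named probability vector over integer values
.draw_named <- function(probs, n) {
  vals <- as.integer(names(probs))
  if (length(vals) == 1L) rep(vals, n)
  else sample(vals, n, replace = TRUE, prob = probs)
}

#' Simulate a LINCS-shaped metadata table
#'
#' Generates one metadata record per signature: categories drawn from the
#' configured mixture, compound signatures laid out on the full dose x
#' time grid per distinct compound, genetic/control/ligand records without
#' a dose, and replicate counts drawn from the configured distribution.
#' Deterministic given the configuration seed.
#'
#' @param config A [sim_config()].
#' @return A canonical metadata tibble (same columns as
#'   [read_metadata()]).
#' @export
simulate_metadata <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  set.seed(config$seed)
  per_cell <- lapply(config$cell_specs, function(spec) {
    n <- spec$n_signatures
    category <- sample(names(spec$category_mix), n, replace = TRUE,
                       prob = spec$category_mix)
    pert_id <- character(n)
    pert_iname <- character(n)
    dose_um <- rep(NA_real_, n)
    time_h <- sample(spec$time_levels, n, replace = TRUE)

    ## compounds: full dose x time grid per distinct compound
    idx_cp <- which(category == "compound")
    if (length(idx_cp)) {
      grid <- expand.grid(dose = spec$dose_levels, time = spec$time_levels,
                          KEEP.OUT.ATTRS = FALSE)
      g <- nrow(grid)
      n_cp <- length(idx_cp)
      n_perts <- max(1L, n_cp %/% g)
      assign_pert <- integer(n_cp)
      assign_cell <- integer(n_cp)
      full <- min(n_cp, n_perts * g)
      assign_pert[seq_len(full)] <- rep(seq_len(n_perts), each = g)[seq_len(full)]
      assign_cell[seq_len(full)] <- rep(seq_len(g), times = n_perts)[seq_len(full)]
      if (full < n_cp) {        # leftover rows repeat grid cells of pert 1..
        extra <- n_cp - full
        assign_pert[full + seq_len(extra)] <-
          rep_len(seq_len(n_perts), extra)
        assign_cell[full + seq_len(extra)] <-
          sample(g, extra, replace = TRUE)
      }
      pert_id[idx_cp] <- sprintf("%s-CP%04d", spec$cell_id, assign_pert)
      pert_iname[idx_cp] <- sprintf("cmpd-%04d", assign_pert)
      dose_um[idx_cp] <- grid$dose[assign_cell]
      time_h[idx_cp] <- grid$time[assign_cell]
    }

    ## other categories: small per-category perturbagen pools
    for (cat in setdiff(lincs_categories(), "compound")) {
      idx <- which(category == cat)
      if (!length(idx)) next
      if (cat == "control") {
        pert_id[idx] <- "DMSO"
        pert_iname[idx] <- "DMSO"
      } else {
        pool <- max(1L, ceiling(length(idx) / 6))
        pick <- sample(pool, length(idx), replace = TRUE)
        pert_id[idx] <- sprintf("%s-%s%03d", spec$cell_id, toupper(cat), pick)
        pert_iname[idx] <- sprintf("%s-%03d", cat, pick)
      }
      if (cat == "poscon") {
        dose_um[idx] <- sample(spec$dose_levels, length(idx), replace = TRUE)
      }
    }

    tibble::tibble(
      sig_id = sprintf("%s_SIG%05d", spec$cell_id,
                       seq_len(n)),
      cell_id = spec$cell_id,
      pert_id = pert_id,
      pert_iname = pert_iname,
      pert_category = category,
      dose_um = dose_um,
      time_h = as.numeric(time_h),
      n_replicates = .draw_named(spec$replicate_probs, n)
    )
  })
  dplyr::bind_rows(per_cell)
}

## planted per-hit effect mean for each metadata row (0 = null signature)
.planted_mu <- function(config, meta) {
  mu <- numeric(nrow(meta))
  for (spec in config$cell_specs) {
    idx <- which(meta$cell_id == spec$cell_id &
                   meta$pert_category %in% c("compound", "poscon"))
    if (!length(idx)) next
    is_cp <- meta$pert_category[idx] == "compound"
    g <- rep(1, length(idx))
    h <- rep(1, length(idx))
    g[is_cp] <- .response_multiplier(meta$dose_um[idx][is_cp],
                                     spec$dose_levels, spec$dose_response)
    h[is_cp] <- .response_multiplier(meta$time_h[idx][is_cp],
                                     spec$time_levels, spec$time_response)
    mu[idx] <- spec$base_effect * g * h
  }
  mu
}

#' Probability that one gene is called significant
#'
#' For a z-score drawn from `N(+/-mu, sd)`, the probability of exceeding
#' the strict thresholds `z > z_hi` or `z < z_lo`. By the symmetry of the
#' default thresholds the sign of the shift does not matter. `mu = 0`
#' gives the per-gene null rate `2 * pnorm(-2) ~ 0.0455`.
#'
#' @param mu Absolute effect mean(s).
#' @param z_hi,z_lo Strict thresholds.
#' @param sd Z-score standard deviation.
#' @return Numeric vector of probabilities.
#' @export
hit_probability <- function(mu, z_hi = 2.0, z_lo = -2.0, sd = 1.0) {
  pnorm(z_hi, mean = mu, sd = sd, lower.tail = FALSE) +
    pnorm(z_lo, mean = mu, sd = sd)
}

#' Simulate z-score signatures with planted effects
#'
#' Draws, for every metadata record, a 978-gene (configurable) vector of
#' z-scores: non-hit genes are `N(0, noise_sd)` null noise, while compound
#' and poscon signatures carry `n_hits` planted hit genes at
#' `N(+/-mu, noise_sd)` with `mu = mu0 * g(dose) * h(time)` and signs
#' split 50/50 up/down. Control, ligand and genetic signatures are pure
#' null. Deterministic given the configuration seed.
#'
#' @param config A [sim_config()].
#' @param meta Metadata from [simulate_metadata()] with the same config
#'   (a subset of its rows is allowed).
#' @return A list with `matrix` (a [signature_matrix()]) and `truth`, a
#'   tibble (`sig_id`, `mu`, `n_hits`, `hit_genes` list-column,
#'   `expected_deg` with the analytic expectation
#'   `n_hits * P(|N(mu,1)| > 2) + (n_genes - n_hits) * 2 * pnorm(-2)`).
#' @export
simulate_signatures <- function(config, meta) {
  stopifnot(inherits(config, "sim_config"))
  required <- c("sig_id", "cell_id", "pert_category", "dose_um", "time_h")
  if (!all(required %in% names(meta))) {
    stop("meta lacks required columns: ",
         paste(setdiff(required, names(meta)), collapse = ", "),
         call. = FALSE)
  }
  unknown <- setdiff(unique(meta$cell_id), names(config$cell_specs))
  if (length(unknown)) {
    stop("meta/config mismatch: cell(s) not in config: ",
         paste(unknown, collapse = ", "), call. = FALSE)
  }
  set.seed(config$seed + 7919L)   # separate stream from simulate_metadata
  ng <- config$n_genes
  ns <- nrow(meta)
  gene_ids <- sprintf("G%04d", seq_len(ng))
  z <- matrix(rnorm(ng * as.double(ns), mean = 0, sd = config$noise_sd),
              nrow = ng, ncol = ns)

  mu <- .planted_mu(config, meta)
  n_hits <- integer(ns)
  hit_genes <- vector("list", ns)
  active <- which(mu > 0)
  if (length(active)) {
    hit_draw <- lapply(config$cell_specs, function(spec) spec$hit_probs)
    for (j in active) {
      probs <- hit_draw[[meta$cell_id[[j]]]]
      nh <- .draw_named(probs, 1L)
      if (nh > ng) stop("hit count exceeds n_genes", call. = FALSE)
      n_hits[[j]] <- nh
      if (nh > 0L) {
        rows <- sample.int(ng, nh)
        signs <- sample(c(-1, 1), nh, replace = TRUE)
        z[rows, j] <- rnorm(nh, mean = signs * mu[[j]], sd = config$noise_sd)
        hit_genes[[j]] <- gene_ids[rows]
      } else {
        hit_genes[[j]] <- character(0)
      }
    }
  }
  p0 <- hit_probability(0, sd = 1)
  truth <- tibble::tibble(
    sig_id = meta$sig_id,
    mu = mu,
    n_hits = n_hits,
    hit_genes = hit_genes,
    expected_deg = n_hits * hit_probability(mu) + (ng - n_hits) * p0
  )
  list(matrix = signature_matrix(z, gene_ids, meta$sig_id), truth = truth)
}

#' Exact tail probability of the per-signature DEG count
#'
#' The DEG count of a signature with `n_hits` planted hit genes at effect
#' mean `mu` is the sum of two independent binomials:
#' `Bin(n_hits, p_hit(mu)) + Bin(n_genes - n_hits, p0)`. This computes
#' `P(DEG >= k)` exactly by convolving the two probability mass functions.
#'
#' @param k Category threshold(s).
#' @param n_genes Total number of genes.
#' @param n_hits Number of planted hit genes.
#' @param mu Absolute effect mean of the hits.
#' @param z_hi,z_lo Strict significance thresholds.
#' @return Numeric vector `P(DEG >= k)`, one per element of `k`.
#' @export
deg_tail_prob <- function(k, n_genes, n_hits = 0L, mu = 0,
                          z_hi = 2.0, z_lo = -2.0) {
  n_genes <- as.integer(n_genes)
  n_hits <- as.integer(n_hits)
  stopifnot(n_hits >= 0L, n_hits <= n_genes)
  p0 <- hit_probability(0, z_hi, z_lo)
  ph <- hit_probability(mu, z_hi, z_lo)
  pmf <- if (n_hits == 0L) {
    dbinom(0:n_genes, n_genes, p0)
  } else if (n_hits == n_genes) {
    dbinom(0:n_genes, n_genes, ph)
  } else {
    a <- dbinom(0:n_hits, n_hits, ph)
    b <- dbinom(0:(n_genes - n_hits), n_genes - n_hits, p0)
    convolve(a, rev(b), type = "open")
  }
  pmf[pmf < 0] <- 0    # guard tiny negative FFT round-off
  cum <- cumsum(pmf)
  vapply(as.integer(k), function(kk) {
    if (kk <= 0L) 1 else if (kk > n_genes) 0
    else max(0, min(1, 1 - cum[[kk]]))
  }, numeric(1))
}

## P(DEG >= k) for one metadata row under a spec's hit-count distribution
.row_tail_prob <- function(k, n_genes, hit_probs, mu) {
  if (mu <= 0) return(deg_tail_prob(k, n_genes))
  vals <- as.integer(names(hit_probs))
  sum(vapply(seq_along(vals), function(i) {
    hit_probs[[i]] * deg_tail_prob(k, n_genes, vals[[i]], mu)
  }, numeric(1)))
}

#' Analytic category fractions for a simulated design
#'
#' For every cell line and every compound dose x time design cell, the
#' exact probability that a signature reaches each cumulative category,
#' computed from the binomial-convolution law of the planted generator
#' (see [deg_tail_prob()]). This is the independent oracle the pipeline's
#' empirical stratified fractions are checked against.
#'
#' @param config A [sim_config()].
#' @param thresholds Cumulative category thresholds.
#' @return A tibble (`cell_id`, `dose_um`, `time_h`, `mu`, one
#'   `p_ge<k>` column per threshold).
#' @export
expected_category_fractions <- function(config,
                                        thresholds = c(1L, 50L, 100L)) {
  stopifnot(inherits(config, "sim_config"))
  thresholds <- as.integer(thresholds)
  rows <- lapply(config$cell_specs, function(spec) {
    grid <- expand.grid(dose_um = spec$dose_levels,
                        time_h = spec$time_levels,
                        KEEP.OUT.ATTRS = FALSE)
    g <- .response_multiplier(grid$dose_um, spec$dose_levels,
                              spec$dose_response)
    h <- .response_multiplier(grid$time_h, spec$time_levels,
                              spec$time_response)
    grid$mu <- spec$base_effect * g * h
    probs <- vapply(seq_len(nrow(grid)), function(i) {
      vapply(thresholds, function(k) {
        .row_tail_prob(k, config$n_genes, spec$hit_probs, grid$mu[[i]])
      }, numeric(1))
    }, numeric(length(thresholds)))
    probs <- matrix(probs, nrow = length(thresholds))
    out <- tibble::as_tibble(grid)
    out$cell_id <- spec$cell_id
    for (i in seq_along(thresholds)) {
      out[[paste0("p_ge", thresholds[[i]])]] <- probs[i, ]
    }
    dplyr::relocate(out, "cell_id")
  })
  dplyr::bind_rows(rows)
}

#' Analytic change fractions for one cell line of a simulated design
#'
#' Marginalizes the exact design-cell probabilities of
#' [expected_category_fractions()] over the strata of a contrast (equal
#' design weights, matching the generator's balanced grid) to produce the
#' expected fraction set — the planted truth against which empirical
#' change fractions and segment classifications are checked.
#'
#' @param config A [sim_config()].
#' @param cell Cell id.
#' @param contrast `"dose"` (low = doses <= `dose_cutoff_um`) or `"time"`
#'   (levels `time_levels[1:2]` of the design, by default 6 vs 24 h).
#' @param dose_cutoff_um Low/high dose boundary.
#' @return A one-row tibble like [compute_change_fractions()] (stratum
#'   convention).
#' @export
expected_fraction_set <- function(config, cell,
                                  contrast = c("dose", "time"),
                                  dose_cutoff_um = 5.0) {
  contrast <- match.arg(contrast)
  ecf <- expected_category_fractions(config, c(1L, 50L, 100L))
  ecf <- ecf[ecf$cell_id == cell, ]
  if (!nrow(ecf)) stop("cell not in config: ", cell, call. = FALSE)
  if (contrast == "dose") {
    in_a <- ecf$dose_um <= dose_cutoff_um
    lev <- c("low", "high")
  } else {
    times <- sort(unique(ecf$time_h))[1:2]
    ecf <- ecf[ecf$time_h %in% times, ]
    in_a <- ecf$time_h == times[[1L]]
    lev <- as.character(times)
  }
  frac <- function(sel, k) {
    mean(ecf[[paste0("p_ge", k)]][sel]) / mean(ecf$p_ge1[sel])
  }
  tibble::tibble(
    cell_id = cell, contrast = contrast, convention = "stratum",
    level_A = lev[[1L]], level_B = lev[[2L]],
    f_A50 = frac(in_a, 50), f_A100 = frac(in_a, 100),
    f_B50 = frac(!in_a, 50), f_B100 = frac(!in_a, 100)
  )
}
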