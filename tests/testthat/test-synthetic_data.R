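test_that("configuration validation rejects improper specifications", {
  expect_error(cell_spec("A", 10, category_mix = c(compound = 0.5)),
               "sum to 1")
  expect_error(cell_spec("A", 10, category_mix = c(banana = 1)),
               "lincs_categories")
  expect_error(cell_spec("A", 10, replicate_probs = c(`1` = 0.5)),
               "sum to 1")
  expect_error(sim_config(list()), "non-empty")
  expect_error(sim_config(list(cell_spec("A", 5), cell_spec("A", 5))),
               "duplicate")
})

test_that("simulated metadata has unique ids and the configured shape", {
  cfg <- sim_config(list(cell_spec("A", 100L), cell_spec("B", 100L)),
                    seed = 2L)
  meta <- simulate_metadata(cfg)
  expect_equal(nrow(meta), 200L)
  expect_equal(anyDuplicated(meta$sig_id), 0L)
  expect_setequal(unique(meta$cell_id), c("A", "B"))
  expect_true(all(meta$pert_category %in% lincs_categories()))
  expect_true(all(meta$n_replicates >= 1L))
  expect_true(all(is.na(meta$dose_um) | meta$dose_um > 0))
  expect_true(all(meta$time_h > 0))
  # genetic and control records carry no dose; compounds always do
  expect_true(all(is.na(meta$dose_um[meta$pert_category %in%
                                       c("control", "shRNA",
                                         "overexpression", "ligand")])))
  expect_true(all(!is.na(meta$dose_um[meta$pert_category == "compound"])))
})

test_that("the generator is deterministic under a fixed seed", {
  cfg <- default_sim_config(seed = 123, n_per_cell = 40)
  m1 <- simulate_metadata(cfg)
  m2 <- simulate_metadata(cfg)
  expect_identical(m1, m2)
  s1 <- simulate_signatures(cfg, m1)
  s2 <- simulate_signatures(cfg, m2)
  expect_identical(s1$matrix$z, s2$matrix$z)
  expect_identical(s1$truth$n_hits, s2$truth$n_hits)
  # different seed, different draws
  m3 <- simulate_metadata(default_sim_config(seed = 124, n_per_cell = 40))
  expect_false(identical(m1$pert_category, m3$pert_category))
})

test_that("null signatures follow the analytic DEG-count law", {
  cfg <- sim_config(list(cell_spec("N", 2000L,
                                   category_mix = c(control = 1))),
                    seed = 6L)
  meta <- simulate_metadata(cfg)
  sim <- simulate_signatures(cfg, meta)
  expect_true(all(sim$truth$n_hits == 0L))
  deg <- count_deg(sim$matrix)
  expected <- 978 * P0_NULL
  se <- sd(deg$n_total) / sqrt(nrow(deg))
  expect_lt(abs(mean(deg$n_total) - expected), 3 * se)
})

test_that("planted hits shift the DEG count by the analytic expectation", {
  cfg <- sim_config(list(cell_spec("H", 400L,
                                   category_mix = c(compound = 1),
                                   hit_count = 100L, base_effect = 6,
                                   dose_response = "flat",
                                   time_response = "flat")), seed = 8L)
  meta <- simulate_metadata(cfg)
  sim <- simulate_signatures(cfg, meta)
  expected <- 100 * hit_probability(6) + 878 * P0_NULL
  expect_equal(expected, 139.9, tolerance = 1e-3)
  expect_true(all(abs(sim$truth$expected_deg - expected) < 1e-9))
  deg <- count_deg(sim$matrix)
  se <- sd(deg$n_total) / sqrt(nrow(deg))
  expect_lt(abs(mean(deg$n_total) - expected), 3 * se)
  expect_true(all(lengths(sim$truth$hit_genes) == 100L))
})

test_that("signature simulation rejects metadata from another design", {
  cfg <- compound_config(n = 24L)
  meta <- simulate_metadata(cfg)
  meta$cell_id[1] <- "IMPOSTOR"
  expect_error(simulate_signatures(cfg, meta), "IMPOSTOR")
})

test_that("deg_tail_prob matches closed forms on the null design", {
  # >=1 tail: 1 - (1 - p0)^978, indistinguishable from 1
  expect_equal(deg_tail_prob(1, 978), 1 - (1 - P0_NULL)^978,
               tolerance = 1e-12)
  expect_gt(deg_tail_prob(1, 978), 1 - 1e-15)
  # >=50 tail: exact binomial
  expect_equal(deg_tail_prob(50, 978), 1 - pbinom(49, 978, P0_NULL),
               tolerance = 1e-12)
  expect_equal(deg_tail_prob(c(0, 979), 978), c(1, 0))
})

test_that("the convolution tail matches an independent mixture sum", {
  # P(X + Y >= k) = sum_x P(X = x) P(Y >= k - x), X over hit genes
  ph <- hit_probability(6)
  k <- 100L
  direct <- sum(dbinom(0:100, 100, ph) *
                  (1 - pbinom(k - 1 - (0:100), 878, P0_NULL)))
  expect_equal(deg_tail_prob(k, 978, 100, 6), direct, tolerance = 1e-10)
})

test_that("expected category fractions enumerate the dose-time design", {
  cfg <- compound_config(n = 48L, dose_levels = c(1, 10),
                         time_levels = c(6, 24),
                         dose_response = "increasing")
  ecf <- expected_category_fractions(cfg)
  expect_equal(nrow(ecf), 4L)
  expect_true(all(ecf$p_ge1 >= ecf$p_ge50))
  expect_true(all(ecf$p_ge50 >= ecf$p_ge100))
  # increasing dose response: larger dose, larger effect, fatter tail
  by_dose <- dplyr::arrange(ecf[ecf$time_h == 24, ], dose_um)
  expect_lt(by_dose$p_ge100[1], by_dose$p_ge100[2])
})

test_that("empirical stratified fractions converge to the exact oracle", {
  cfg <- compound_config(n = 4000L, seed = 19L, dose_levels = c(1, 10),
                         time_levels = c(6, 24),
                         dose_response = "increasing",
                         time_response = "flat")
  meta <- simulate_metadata(cfg)
  deg <- count_deg(simulate_signatures(cfg, meta)$matrix)
  strat <- suppressMessages(stratified_category_counts(deg, meta,
                                                       "cell_dose"))
  emp <- compute_change_fractions(strat, "X", "dose")
  exp_ <- expected_fraction_set(cfg, "X", "dose")
  for (col in c("f_A50", "f_A100", "f_B50", "f_B100")) {
    p <- exp_[[col]]
    se <- sqrt(max(p * (1 - p), 1e-6) / 2000)
    expect_lt(abs(emp[[col]] - p), 4 * se)
  }
})
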