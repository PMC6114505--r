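test_that("count_deg applies strict thresholds and splits directions", {
  z <- matrix(c(2.5, -3.0, 1.9, -2.0), ncol = 1,
              dimnames = list(paste0("G", 1:4), "s1"))
  deg <- count_deg(z)
  expect_equal(deg$n_up, 1L)       # 2.5 only; 1.9 below threshold
  expect_equal(deg$n_down, 1L)     # -3.0 only; boundary -2.0 not counted
  expect_equal(deg$n_total, 2L)

  zero <- matrix(0, 5, 1, dimnames = list(paste0("G", 1:5), "s"))
  expect_equal(count_deg(zero)$n_total, 0L)
  expect_error(count_deg(z, z_hi = -2, z_lo = 2), "z_lo")
})

test_that("count_deg ignores missing z-scores per gene", {
  z <- matrix(c(3, NA, -3, NA), ncol = 1,
              dimnames = list(paste0("G", 1:4), "s1"))
  deg <- count_deg(z)
  expect_equal(c(deg$n_up, deg$n_down), c(1L, 1L))
})

test_that("count_deg matches the element-wise oracle on random matrices", {
  set.seed(2024)
  for (i in 1:25) {
    z <- matrix(rnorm(12 * 8, sd = 1.5), 12, 8,
                dimnames = list(sprintf("G%02d", 1:12),
                                sprintf("s%02d", 1:8)))
    z[sample(length(z), 6)] <- c(2, -2, 2, -2, NA, NA)  # boundary + missing
    expect_equal(count_deg(z), brute_force_deg(z))
  }
})

test_that("filter_analysis_set subsets by cell, category and time", {
  meta <- toy_meta(c("A", "A", "A", "B"),
                   c("compound", "compound", "control", "compound"),
                   time_h = c(6, 96, 24, 24))
  out <- suppressMessages(filter_analysis_set(meta, cells = "A"))
  expect_equal(out$sig_id, meta$sig_id[1])  # 96 h, control and cell B gone
  all_cat <- suppressMessages(
    filter_analysis_set(meta, categories = lincs_categories(), times = NULL))
  expect_equal(nrow(all_cat), 4L)
  expect_warning(suppressMessages(
    filter_analysis_set(meta, cells = "ZZ")), "empty")
})

test_that("categorize_counts builds cumulative profile and molecule tallies", {
  meta <- toy_meta("A", "compound", pert_id = c("P1", "P2", "P3"))
  deg <- tibble::tibble(sig_id = meta$sig_id, n_up = c(0L, 10L, 120L),
                        n_down = 0L, n_total = c(0L, 10L, 120L))
  cats <- categorize_counts(deg, meta)
  expect_equal(cats$n_profiles, c(1L, 2L, 1L, 1L))
  expect_equal(cats$category,
               c("none", "at_least_1", "at_least_50", "at_least_100"))
  # partition: none + >=1 = total
  expect_equal(cats$n_profiles[1] + cats$n_profiles[2],
               attr(cats, "total_profiles"))
})

test_that("a molecule is categorized by its best signature", {
  meta <- toy_meta("A", "compound", pert_id = c("P1", "P1"))
  deg <- tibble::tibble(sig_id = meta$sig_id, n_up = c(5L, 60L), n_down = 0L,
                        n_total = c(5L, 60L))
  cats <- categorize_counts(deg, meta)
  expect_equal(cats$n_molecules, c(0L, 1L, 1L, 0L))
})

test_that("orphan sig_ids abort the categorization with names", {
  meta <- toy_meta("A", "compound")
  deg <- tibble::tibble(sig_id = c(meta$sig_id, "GHOST"), n_up = 0L,
                        n_down = 0L, n_total = 0L)
  expect_error(categorize_counts(deg, meta), "GHOST")
})

test_that("dose groups split at 5 uM, boundary inclusive to low", {
  expect_equal(as.character(assign_dose_group(c(0.5, 5, 10, NA))),
               c("low", "low", "high", NA))
})

test_that("stratified counts partition profiles and stay monotone", {
  cfg <- compound_config(n = 400L, seed = 13L)
  meta <- simulate_metadata(cfg)
  deg <- count_deg(simulate_signatures(cfg, meta)$matrix)
  for (by in c("cell", "cell_dose", "cell_time")) {
    strat <- suppressMessages(stratified_category_counts(deg, meta, by))
    expect_true(all(strat$n_ge1 >= strat$n_ge50))
    expect_true(all(strat$n_ge50 >= strat$n_ge100))
    expect_true(all(strat$n_none + strat$n_ge1 == strat$n_profiles))
  }
  strat_dose <- suppressMessages(
    stratified_category_counts(deg, meta, "cell_dose"))
  expect_equal(sum(strat_dose$n_profiles), sum(!is.na(meta$dose_um)))
})

test_that("dose-missing records are excluded from dose strata with a note", {
  meta <- toy_meta("A", c("compound", "compound", "shRNA"),
                   dose_um = c(1, 10, NA))
  deg <- tibble::tibble(sig_id = meta$sig_id, n_up = c(2L, 60L, 5L),
                        n_down = 0L, n_total = c(2L, 60L, 5L))
  expect_message(strat <- stratified_category_counts(deg, meta, "cell_dose"),
                 "excluded 1")
  expect_equal(sum(strat$n_profiles), 2L)
})

test_that("planted strong/weak cells separate across the >=100 boundary", {
  meta <- toy_meta(c("X", "X", "Y", "Y"), "compound", dose_um = 10)
  deg <- tibble::tibble(sig_id = meta$sig_id, n_up = c(150L, 120L, 10L, 40L),
                        n_down = 0L, n_total = c(150L, 120L, 10L, 40L))
  strat <- stratified_category_counts(deg, meta, "cell")
  x <- strat[strat$cell_id == "X", ]
  y <- strat[strat$cell_id == "Y", ]
  expect_equal(c(x$n_ge1, x$n_ge50, x$n_ge100), c(2L, 2L, 2L))
  expect_equal(c(y$n_ge1, y$n_ge50, y$n_ge100), c(2L, 0L, 0L))
})

test_that("behavior_direction compares ordered levels with a tie rule", {
  strat <- tibble::tibble(cell_id = "A", dose_group = c("low", "high"),
                          n_profiles = c(200L, 200L), n_none = 0L,
                          n_ge1 = c(200L, 200L), n_ge50 = c(150L, 180L),
                          n_ge100 = c(100L, 150L))
  expect_equal(behavior_direction(strat, "A", c("low", "high")), "increasing")
  expect_equal(behavior_direction(strat, "A", c("high", "low")), "decreasing")
  strat$n_ge100 <- c(100L, 100L)
  expect_equal(behavior_direction(strat, "A", c("low", "high")), "unchanged")
  expect_warning(out <- behavior_direction(strat, "B", c("low", "high")),
                 "not evaluable")
  expect_true(is.na(out))
})
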