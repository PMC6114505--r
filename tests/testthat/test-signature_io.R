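test_that("parse_dose canonicalizes recognized units to micromolar", {
  expect_equal(parse_dose("10", "um"), 10.0)
  expect_equal(parse_dose("500", "nM"), 0.5)
  expect_equal(parse_dose("2", "mM"), 2000)
  expect_equal(parse_dose(c("10", "0.5"), c("µM", "μM")),
               c(10, 0.5))
})

test_that("parse_dose maps sentinels and bad input to missing", {
  expect_true(is.na(parse_dose("-666", "")))
  expect_true(is.na(parse_dose("", "um")))
  expect_true(is.na(parse_dose("abc", "um")))
  expect_true(is.na(parse_dose("-1", "um")))   # doses must be positive
  expect_warning(out <- parse_dose("10", "parsec"), "unrecognized dose unit")
  expect_true(is.na(out))
})

test_that("parse_dose is idempotent on canonical micromolar values", {
  x <- c(0.5, 5, 10)
  once <- parse_dose(x, "um")
  expect_equal(parse_dose(once), once)
  expect_equal(parse_dose(once, "uM"), once)
})

test_that("parse_time_h strips hour suffixes and rejects non-positive", {
  expect_equal(parse_time_h(c("6", "24 h", "48h", "3hr")), c(6, 24, 48, 3))
  expect_true(all(is.na(parse_time_h(c("-666", "0", "soon")))))
})

test_that("map_pert_category covers the published code table", {
  expect_equal(
    map_pert_category(c("trt_cp", "trt_lig", "trt_sh", "trt_oe",
                        "ctl_vehicle", "ctl_vector", "ctl_trt_poscon",
                        "trt_poscon")),
    c("compound", "ligand", "shRNA", "overexpression", "control",
      "control", "poscon", "poscon"))
  # idempotent on canonical names
  expect_equal(map_pert_category(lincs_categories()), lincs_categories())
})

test_that("map_pert_category reports unknown codes instead of binning", {
  expect_warning(out <- map_pert_category(c("trt_cp", "banana")), "banana")
  expect_equal(out, c("compound", NA))
})

test_that("read_metadata canonicalizes a LINCS-dialect TSV", {
  path <- withr::local_tempfile(fileext = ".tsv")
  write_lincs_tsv(path, c(
    "S1\tA375\tBRD-1\tdrugA\ttrt_cp\t10\tum\t24\th\t3",
    "S2\tA375\tDMSO\tDMSO\tctl_vehicle\t-666\t-666\t6\th\t2",
    "S3\tMCF7\tBRD-2\tdrugB\ttrt_cp\t500\tnM\t48\th\t4"))
  meta <- read_metadata(path)
  expect_equal(nrow(meta), 3L)
  expect_equal(meta$pert_category, c("compound", "control", "compound"))
  expect_equal(meta$dose_um, c(10, NA, 0.5))
  expect_equal(meta$time_h, c(24, 6, 48))
  expect_equal(meta$n_replicates, c(3L, 2L, 4L))
  expect_true(all(meta$pert_category %in% lincs_categories()))
})

test_that("read_metadata handles degenerate and malformed inputs", {
  path <- withr::local_tempfile(fileext = ".tsv")
  write_lincs_tsv(path, character(0))         # header only
  meta <- read_metadata(path)
  expect_equal(nrow(meta), 0L)

  # unknown category and unparseable time are dropped, with a message
  write_lincs_tsv(path, c(
    "S1\tA375\tP1\tP1\ttrt_cp\t10\tum\t24\th\t3",
    "S2\tA375\tP2\tP2\tmystery\t10\tum\t24\th\t3",
    "S3\tA375\tP3\tP3\ttrt_cp\t10\tum\tnever\th\t3"))
  expect_message(meta <- read_metadata(path), "dropped 2")
  expect_equal(meta$sig_id, "S1")

  # missing mandatory column is a hard error naming it
  writeLines(c("sig_id\tcell_id", "S1\tA375"), path)
  expect_error(read_metadata(path), "pert_type")
  expect_error(read_metadata(withr::local_tempfile()), "does not exist")
})

test_that("metadata round-trips through the TSV dialect", {
  meta <- simulate_metadata(default_sim_config(seed = 5, n_per_cell = 30))
  path <- withr::local_tempfile(fileext = ".tsv")
  write_metadata(meta, path)
  back <- read_metadata(path)
  expect_equal(back$sig_id, meta$sig_id)
  expect_equal(back$pert_category, meta$pert_category)
  expect_equal(back$dose_um, meta$dose_um, tolerance = 1e-9)
  expect_equal(back$time_h, meta$time_h)
  expect_equal(back$n_replicates, meta$n_replicates)
})

test_that("signature_matrix validates aligned identifiers", {
  z <- matrix(rnorm(6), 3, 2)
  expect_error(signature_matrix(z), "gene_ids")
  m <- signature_matrix(z, paste0("G", 1:3), c("s1", "s2"))
  expect_equal(dim(m), c(3L, 2L))
  expect_error(signature_matrix(z, paste0("G", 1:2), c("s1", "s2")),
               "gene_ids length")
  expect_error(signature_matrix(z, paste0("G", 1:3), c("s1", "s1")),
               "unique")
})

test_that("GCT files carry the #1.3 version and dimension header", {
  m <- signature_matrix(matrix(c(1.5, -2.25, 0, 3), 2, 2),
                        c("G1", "G2"), c("s1", "s2"))
  path <- withr::local_tempfile(fileext = ".gct")
  write_zscore_matrix(m, path)
  lines <- readLines(path)
  expect_equal(lines[1], "#1.3")
  expect_equal(lines[2], "2\t2\t0\t0")
})

test_that("GCT and GCTX round-trip identifiers exactly and values closely", {
  set.seed(404)
  for (dims in list(c(5L, 3L), c(20L, 1L), c(7L, 9L))) {
    m <- signature_matrix(
      matrix(rnorm(prod(dims)), dims[1], dims[2]),
      sprintf("G%03d", seq_len(dims[1])), sprintf("sig_%02d", seq_len(dims[2])))
    for (fmt in c("gct", "gctx")) {
      path <- withr::local_tempfile(fileext = paste0(".", fmt))
      write_zscore_matrix(m, path)
      back <- read_zscore_matrix(path)
      expect_identical(back$gene_ids, m$gene_ids)
      expect_identical(back$sig_ids, m$sig_ids)
      expect_lt(max(abs(back$z - m$z)), 1e-6)
    }
  }
})

test_that("a landmark-sized GCTX fixture keeps its shape", {
  m <- signature_matrix(matrix(rnorm(978 * 5), 978, 5),
                        sprintf("G%04d", 1:978), sprintf("s%d", 1:5))
  path <- withr::local_tempfile(fileext = ".gctx")
  write_zscore_matrix(m, path)
  back <- read_zscore_matrix(path)
  expect_equal(dim(back), c(978L, 5L))
})

test_that("an empty matrix writes a valid zero-column GCT", {
  m <- signature_matrix(matrix(numeric(0), 3, 0), paste0("G", 1:3),
                        character(0))
  path <- withr::local_tempfile(fileext = ".gct")
  write_zscore_matrix(m, path)
  back <- read_zscore_matrix(path)
  expect_equal(dim(back), c(3L, 0L))
  expect_identical(back$gene_ids, m$gene_ids)
})

test_that("GCT dimension disagreements are hard errors naming the position", {
  path <- withr::local_tempfile(fileext = ".gct")
  writeLines(c("#1.3", "3\t2\t0\t0", "id\ts1\ts2",
               "G1\t0.1\t0.2", "G2\t0.3\t0.4"), path)
  expect_error(read_zscore_matrix(path), "expected 3")
  writeLines(c("#1.2", "2\t2", "id\ts1\ts2",
               "G1\t0.1\t0.2", "G2\t0.3\t0.4"), path)
  expect_error(read_zscore_matrix(path), "unsupported GCT version")
  writeLines(c("#1.3", "2\t2\t0\t0", "id\ts1\ts2",
               "G1\t0.1\t0.2", "G2\t0.3"), path)
  expect_error(read_zscore_matrix(path), "row 2")
})
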