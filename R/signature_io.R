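## Reading/writing signature metadata (TSV) and z-score matrices (GCT/GCTX),
## plus canonicalization of doses, times and perturbation categories.

## LINCS pert_type codes -> canonical category
.pert_code_map <- c(
  trt_cp         = "compound",
  trt_lig        = "ligand",
  trt_sh         = "shRNA",
  trt_oe         = "overexpression",
  ctl_vehicle    = "control",
  ctl_vector     = "control",
  ctl_trt_poscon = "poscon",
  trt_poscon     = "poscon"
)

## canonical category -> representative LINCS code (used when writing TSV)
.category_code_map <- c(
  compound       = "trt_cp",
  ligand         = "trt_lig",
  shRNA          = "trt_sh",
  overexpression = "trt_oe",
  control        = "ctl_vehicle",
  poscon         = "ctl_trt_poscon"
)

.DOSE_SENTINELS <- c("", "-666", "-666.0", "NA", "na", "nan")

#' Map raw perturbation type codes to the six canonical categories
#'
#' Translates LINCS `pert_type` codes (`trt_cp`, `trt_lig`, `trt_sh`,
#' `trt_oe`, `ctl_vehicle`, `ctl_vector`, `ctl_trt_poscon`, `trt_poscon`)
#' to the closed category set of [lincs_categories()]. Already-canonical
#' category names pass through unchanged, so the mapping is idempotent.
#' Unknown codes become `NA` with a warning naming them; they are never
#' silently binned into a category.
#'
#' @param raw_code Character vector of raw perturbation type codes.
#' @return Character vector of the same length with values in
#'   `lincs_categories()`, or `NA` for unrecognized codes.
#' @export
#' @examples
#' map_pert_category(c("trt_cp", "ctl_vehicle", "trt_oe"))
map_pert_category <- function(raw_code) {
  raw_code <- as.character(raw_code)
  out <- unname(.pert_code_map[raw_code])
  pass <- is.na(out) & raw_code %in% lincs_categories()
  out[pass] <- raw_code[pass]
  unknown <- !is.na(raw_code) & is.na(out)
  if (any(unknown)) {
    warning("unrecognized perturbation code(s): ",
            paste(unique(raw_code[unknown]), collapse = ", "),
            call. = FALSE)
  }
  out
}

#' Canonicalize a dose to micromolar
#'
#' Converts dose value/unit pairs to a single micromolar scale. Recognized
#' units are nanomolar (`"nM"`), micromolar (`"uM"`, `"um"`, `"µM"`,
#' `"μM"`) and millimolar (`"mM"`); an empty or missing unit is taken
#' as already-micromolar, which makes the function idempotent on canonical
#' input. The LINCS not-applicable sentinel `"-666"`, empty strings and
#' non-numeric values all yield `NA`; an unrecognized unit yields `NA` with
#' a warning. Non-positive doses are invalid and also become `NA`.
#'
#' @param value Dose values (character or numeric).
#' @param unit Dose units, recycled against `value`. `NULL` means
#'   micromolar.
#' @return Numeric vector of doses in micromolar, `NA` where missing.
#' @export
#' @examples
#' parse_dose(c("10", "500", "-666"), c("um", "nM", ""))
parse_dose <- function(value, unit = NULL) {
  value <- as.character(value)
  if (is.null(unit) || length(unit) == 0L) unit <- ""
  unit <- as.character(unit)
  n <- max(length(value), length(unit))
  value <- rep_len(value, n)
  unit <- rep_len(unit, n)

  v <- trimws(value)
  v[is.na(v) | v %in% .DOSE_SENTINELS] <- NA
  num <- suppressWarnings(as.numeric(v))

  u <- tolower(trimws(unit))
  u[is.na(u) | u %in% .DOSE_SENTINELS] <- "um"
  scale <- rep(NA_real_, n)
  scale[u == "nm"] <- 1e-3
  scale[u %in% c("um", "µm", "μm")] <- 1
  scale[u == "mm"] <- 1e3

  unrec <- !is.na(num) & is.na(scale)
  if (any(unrec)) {
    warning("unrecognized dose unit(s): ",
            paste(unique(unit[unrec]), collapse = ", "),
            "; treating dose as missing", call. = FALSE)
  }
  out <- num * scale
  out[!is.na(out) & out <= 0] <- NA_real_
  out
}

#' Canonicalize a treatment time to hours
#'
#' Strips an `"h"`/`"hr"`/`"hrs"`/`"hours"` suffix, converts to numeric
#' hours and maps sentinels and non-positive values to `NA`.
#'
#' @param value Time values (character or numeric), e.g. `"24 h"`.
#' @return Numeric vector of durations in hours, `NA` where unparseable.
#' @export
#' @examples
#' parse_time_h(c("6", "24 h", "48h"))
parse_time_h <- function(value) {
  v <- trimws(as.character(value))
  v[is.na(v) | v %in% .DOSE_SENTINELS] <- NA
  v <- sub("\\s*(h|hr|hrs|hours)\\s*$", "", v, ignore.case = TRUE)
  num <- suppressWarnings(as.numeric(v))
  num[!is.na(num) & num <= 0] <- NA_real_
  num
}

#' Field-name dialect for metadata tables
#'
#' Maps the canonical record fields onto the column names of an input TSV.
#' The default is the GSE92742 `sig_info` dialect, so real signature
#' metadata and the files written by [write_metadata()] share one reader.
#' Set an entry to `NA` to declare the column absent.
#'
#' @param sig_id,cell_id,pert_id,pert_iname,pert_type,dose,dose_unit,time,time_unit,n_replicates
#'   Column names in the input file for each canonical field.
#' @return A named list of column names.
#' @export
lincs_dialect <- function(sig_id = "sig_id",
                          cell_id = "cell_id",
                          pert_id = "pert_id",
                          pert_iname = "pert_iname",
                          pert_type = "pert_type",
                          dose = "pert_dose",
                          dose_unit = "pert_dose_unit",
                          time = "pert_time",
                          time_unit = "pert_time_unit",
                          n_replicates = "distil_nsample") {
  list(sig_id = sig_id, cell_id = cell_id, pert_id = pert_id,
       pert_iname = pert_iname, pert_type = pert_type,
       dose = dose, dose_unit = dose_unit,
       time = time, time_unit = time_unit,
       n_replicates = n_replicates)
}

## pull a dialect column from a raw data.frame, or NULL if absent
.dialect_col <- function(raw, dialect, field) {
  nm <- dialect[[field]]
  if (is.null(nm) || is.na(nm) || !nm %in% names(raw)) return(NULL)
  raw[[nm]]
}

#' Read a signature metadata table
#'
#' Reads a tab-separated metadata table (GSE92742 `sig_info`-style by
#' default), canonicalizes doses to micromolar via [parse_dose()], times to
#' hours via [parse_time_h()] and perturbation types via
#' [map_pert_category()], and returns one record per usable row. Rows whose
#' mandatory fields cannot be canonicalized (unknown perturbation code,
#' unparseable time) are dropped and the dropped count is reported via
#' `message()`.
#'
#' Mandatory columns (after dialect mapping): `sig_id`, `cell_id`,
#' `pert_type` and `time`. `pert_id` falls back to `pert_iname` (and vice
#' versa) when absent; a missing dose column yields `NA` doses; a missing
#' replicate column yields `n_replicates = 1`.
#'
#' @param path Path to a TSV file with a header row.
#' @param dialect Field-name mapping, see [lincs_dialect()].
#' @return A tibble with columns `sig_id`, `cell_id`, `pert_id`,
#'   `pert_iname`, `pert_category`, `dose_um`, `time_h`, `n_replicates`.
#' @export
read_metadata <- function(path, dialect = lincs_dialect()) {
  if (!file.exists(path)) {
    stop("metadata file does not exist: ", path, call. = FALSE)
  }
  raw <- read.delim(path, sep = "\t", header = TRUE,
                    colClasses = "character", check.names = FALSE,
                    quote = "", comment.char = "")
  for (field in c("sig_id", "cell_id", "pert_type", "time")) {
    nm <- dialect[[field]]
    if (is.null(nm) || is.na(nm) || !nm %in% names(raw)) {
      stop("mandatory metadata column missing: '", nm %||% field,
           "' (field ", field, ")", call. = FALSE)
    }
  }

  sig_id <- .dialect_col(raw, dialect, "sig_id")
  n <- length(sig_id)
  if (n == 0L) {
    return(tibble::tibble(sig_id = character(), cell_id = character(),
                          pert_id = character(), pert_iname = character(),
                          pert_category = character(), dose_um = numeric(),
                          time_h = numeric(), n_replicates = integer()))
  }

  pert_id <- .dialect_col(raw, dialect, "pert_id")
  pert_iname <- .dialect_col(raw, dialect, "pert_iname")
  if (is.null(pert_id)) pert_id <- pert_iname %||% sig_id
  if (is.null(pert_iname)) pert_iname <- pert_id

  category <- suppressWarnings(
    map_pert_category(.dialect_col(raw, dialect, "pert_type"))
  )
  dose_um <- parse_dose(.dialect_col(raw, dialect, "dose") %||%
                          rep(NA_character_, n),
                        .dialect_col(raw, dialect, "dose_unit"))
  time_h <- parse_time_h(.dialect_col(raw, dialect, "time"))
  reps_raw <- .dialect_col(raw, dialect, "n_replicates")
  n_replicates <- if (is.null(reps_raw)) {
    rep(1L, n)
  } else {
    as.integer(round(suppressWarnings(as.numeric(reps_raw))))
  }
  n_replicates[!is.na(n_replicates) & n_replicates < 1L] <- NA_integer_

  meta <- tibble::tibble(
    sig_id = as.character(sig_id),
    cell_id = as.character(.dialect_col(raw, dialect, "cell_id")),
    pert_id = as.character(pert_id),
    pert_iname = as.character(pert_iname),
    pert_category = category,
    dose_um = dose_um,
    time_h = time_h,
    n_replicates = n_replicates
  )

  keep <- !is.na(meta$pert_category) & !is.na(meta$time_h) &
    !is.na(meta$sig_id) & !is.na(meta$n_replicates)
  if (any(!keep)) {
    message("read_metadata: dropped ", sum(!keep),
            " row(s) with unmappable mandatory fields")
    meta <- meta[keep, ]
  }
  if (anyDuplicated(meta$sig_id)) {
    stop("duplicate sig_id values in metadata: ",
         paste(utils::head(unique(meta$sig_id[duplicated(meta$sig_id)]), 5),
               collapse = ", "), call. = FALSE)
  }
  meta
}

#' Write a canonical metadata table in the LINCS TSV dialect
#'
#' Inverse of [read_metadata()]: emits a tab-separated file using the
#' dialect's column names, doses in micromolar with unit `"um"`, times in
#' hours with unit `"h"`, missing doses as the `-666` sentinel, and
#' categories as representative LINCS codes.
#'
#' @param meta Canonical metadata tibble (as returned by [read_metadata()]
#'   or [simulate_metadata()]).
#' @param path Output file path.
#' @param dialect Field-name mapping, see [lincs_dialect()].
#' @return `path`, invisibly.
#' @export
write_metadata <- function(meta, path, dialect = lincs_dialect()) {
  out <- data.frame(
    sig_id = meta$sig_id,
    cell_id = meta$cell_id,
    pert_id = meta$pert_id,
    pert_iname = meta$pert_iname,
    pert_type = unname(.category_code_map[meta$pert_category]),
    dose = ifelse(is.na(meta$dose_um), "-666", format(meta$dose_um, trim = TRUE,
                                                      scientific = FALSE)),
    dose_unit = ifelse(is.na(meta$dose_um), "-666", "um"),
    time = format(meta$time_h, trim = TRUE, scientific = FALSE),
    time_unit = "h",
    n_replicates = meta$n_replicates,
    check.names = FALSE, stringsAsFactors = FALSE
  )
  names(out) <- vapply(
    c("sig_id", "cell_id", "pert_id", "pert_iname", "pert_type",
      "dose", "dose_unit", "time", "time_unit", "n_replicates"),
    function(f) dialect[[f]], character(1)
  )
  write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# ---------------------------------------------------------------------------
# SignatureMatrix container

#' Construct a signature matrix
#'
#' A light container for a landmark-gene-by-signature matrix of
#' differential-expression z-scores with aligned row (gene) and column
#' (signature) identifiers — the in-memory analogue of a Level-5 GCT/GCTX
#' slice.
#'
#' @param z Numeric matrix, one row per gene, one column per signature.
#' @param gene_ids Character vector of gene identifiers (defaults to
#'   `rownames(z)`).
#' @param sig_ids Character vector of signature identifiers (defaults to
#'   `colnames(z)`).
#' @return An object of class `signature_matrix` with elements `z`,
#'   `gene_ids`, `sig_ids`.
#' @export
#' @examples
#' m <- signature_matrix(matrix(rnorm(6), 3, 2,
#'                              dimnames = list(paste0("G", 1:3), c("s1", "s2"))))
#' dim(m)
signature_matrix <- function(z, gene_ids = rownames(z), sig_ids = colnames(z)) {
  z <- as.matrix(z)
  storage.mode(z) <- "double"
  if (is.null(gene_ids)) stop("gene_ids are required", call. = FALSE)
  if (is.null(sig_ids)) {
    if (ncol(z) == 0L) sig_ids <- character(0)
    else stop("sig_ids are required", call. = FALSE)
  }
  gene_ids <- as.character(gene_ids)
  sig_ids <- as.character(sig_ids)
  if (length(gene_ids) != nrow(z)) {
    stop("gene_ids length (", length(gene_ids), ") != number of rows (",
         nrow(z), ")", call. = FALSE)
  }
  if (length(sig_ids) != ncol(z)) {
    stop("sig_ids length (", length(sig_ids), ") != number of columns (",
         ncol(z), ")", call. = FALSE)
  }
  if (anyDuplicated(sig_ids)) stop("sig_ids must be unique", call. = FALSE)
  dimnames(z) <- list(gene_ids, sig_ids)
  structure(list(z = z, gene_ids = gene_ids, sig_ids = sig_ids),
            class = "signature_matrix")
}

#' @export
dim.signature_matrix <- function(x) dim(x$z)

#' @export
print.signature_matrix <- function(x, ...) {
  cat("signature_matrix: ", nrow(x$z), " genes x ", ncol(x$z),
      " signatures\n", sep = "")
  invisible(x)
}

## accept either a signature_matrix or a bare numeric matrix
.as_signature_matrix <- function(x) {
  if (inherits(x, "signature_matrix")) return(x)
  if (is.matrix(x)) {
    if (is.null(rownames(x))) rownames(x) <- sprintf("G%04d", seq_len(nrow(x)))
    if (is.null(colnames(x))) colnames(x) <- sprintf("S%04d", seq_len(ncol(x)))
    return(signature_matrix(x))
  }
  stop("expected a signature_matrix or a numeric matrix", call. = FALSE)
}

# ---------------------------------------------------------------------------
# GCT 1.3 text format

.read_gct <- function(path) {
  lines <- readLines(path)
  if (length(lines) < 3L) {
    stop("malformed GCT file (fewer than 3 lines): ", path, call. = FALSE)
  }
  if (!identical(lines[[1L]], "#1.3")) {
    stop("unsupported GCT version line '", lines[[1L]],
         "' (only #1.3 is supported)", call. = FALSE)
  }
  dims <- suppressWarnings(as.integer(strsplit(lines[[2L]], "\t",
                                               fixed = TRUE)[[1L]]))
  if (length(dims) < 2L || anyNA(dims[1:2])) {
    stop("malformed GCT dimension line (line 2): '", lines[[2L]], "'",
         call. = FALSE)
  }
  nr <- dims[[1L]]
  nc <- dims[[2L]]
  nrhd <- if (length(dims) >= 3L && !is.na(dims[[3L]])) dims[[3L]] else 0L
  nchd <- if (length(dims) >= 4L && !is.na(dims[[4L]])) dims[[4L]] else 0L

  header <- strsplit(lines[[3L]], "\t", fixed = TRUE)[[1L]]
  want_fields <- 1L + nrhd + nc
  if (length(header) != want_fields) {
    stop("GCT header (line 3): expected ", want_fields,
         " fields, found ", length(header), call. = FALSE)
  }
  body <- lines[-(1:3)]
  ## trailing blank line tolerated
  if (length(body) && body[[length(body)]] == "") body <- body[-length(body)]
  if (length(body) != nchd + nr) {
    stop("GCT body: expected ", nchd + nr, " rows (", nchd,
         " column-metadata + ", nr, " data), found ", length(body),
         call. = FALSE)
  }
  data_lines <- body[nchd + seq_len(nr)]
  parts <- strsplit(data_lines, "\t", fixed = TRUE)
  nfield <- lengths(parts)
  if (nr > 0L && any(nfield != want_fields)) {
    bad <- which(nfield != want_fields)[[1L]]
    stop("GCT data row ", bad, " (file line ", 3L + nchd + bad,
         "): expected ", want_fields, " fields, found ", nfield[[bad]],
         call. = FALSE)
  }
  gene_ids <- vapply(parts, function(p) p[[1L]], character(1))
  sig_ids <- if (nc > 0L) header[(1L + nrhd) + seq_len(nc)] else character(0)
  z <- matrix(NA_real_, nrow = nr, ncol = nc)
  if (nr > 0L && nc > 0L) {
    z <- t(vapply(parts, function(p) {
      as.numeric(p[(1L + nrhd) + seq_len(nc)])
    }, numeric(nc)))
    if (nc == 1L) z <- matrix(z, ncol = 1L)
  }
  signature_matrix(z, gene_ids, sig_ids)
}

.write_gct <- function(m, path) {
  con <- file(path, open = "w")
  on.exit(close(con))
  writeLines("#1.3", con)
  writeLines(paste(nrow(m$z), ncol(m$z), 0L, 0L, sep = "\t"), con)
  writeLines(paste(c("id", m$sig_ids), collapse = "\t"), con)
  if (nrow(m$z) > 0L) {
    if (ncol(m$z) > 0L) {
      vals <- apply(m$z, 1L, function(r) {
        paste(sprintf("%.10g", r), collapse = "\t")
      })
      writeLines(paste(m$gene_ids, vals, sep = "\t"), con)
    } else {
      writeLines(m$gene_ids, con)
    }
  }
  invisible(path)
}

# ---------------------------------------------------------------------------
# GCTX (HDF5) format, /0/DATA/0/matrix + /0/META/{ROW,COL}/id layout

.require_rhdf5 <- function() {
  if (!requireNamespace("rhdf5", quietly = TRUE)) {
    stop("GCTX (HDF5) support requires the 'rhdf5' package", call. = FALSE)
  }
}

.read_gctx <- function(path) {
  .require_rhdf5()
  on.exit(rhdf5::h5closeAll(), add = TRUE)
  z <- rhdf5::h5read(path, "0/DATA/0/matrix")
  gene_ids <- as.character(rhdf5::h5read(path, "0/META/ROW/id"))
  sig_ids <- as.character(rhdf5::h5read(path, "0/META/COL/id"))
  z <- as.matrix(z)
  ## files written column-major by other tool chains come back transposed
  if (nrow(z) != length(gene_ids) && ncol(z) == length(gene_ids)) {
    z <- t(z)
  }
  if (nrow(z) != length(gene_ids) || ncol(z) != length(sig_ids)) {
    stop("GCTX dimension mismatch in ", path, ": matrix is ", nrow(z), "x",
         ncol(z), " but found ", length(gene_ids), " row ids and ",
         length(sig_ids), " column ids", call. = FALSE)
  }
  signature_matrix(z, trimws(gene_ids), trimws(sig_ids))
}

.write_gctx <- function(m, path) {
  .require_rhdf5()
  if (file.exists(path)) unlink(path)
  on.exit(rhdf5::h5closeAll(), add = TRUE)
  rhdf5::h5createFile(path)
  for (g in c("0", "0/DATA", "0/DATA/0", "0/META", "0/META/ROW",
              "0/META/COL")) {
    rhdf5::h5createGroup(path, g)
  }
  rhdf5::h5write(m$z, path, "0/DATA/0/matrix")
  rhdf5::h5write(m$gene_ids, path, "0/META/ROW/id")
  rhdf5::h5write(m$sig_ids, path, "0/META/COL/id")
  fid <- rhdf5::H5Fopen(path)
  rhdf5::h5writeAttribute("GCTX1.0", fid, "version")
  rhdf5::H5Fclose(fid)
  invisible(path)
}

.guess_matrix_format <- function(path, format) {
  format <- match.arg(format, c("auto", "gct", "gctx"))
  if (format != "auto") return(format)
  if (grepl("\\.gctx$", path, ignore.case = TRUE)) "gctx" else "gct"
}

#' Read a z-score signature matrix from GCT or GCTX
#'
#' Reads a gene-by-signature matrix from either the GCT 1.3 tab-separated
#' text layout or the GCTX HDF5 layout (`/0/DATA/0/matrix` with row and
#' column identifiers under `/0/META`). Values are read without rescaling.
#' Malformed headers or declared dimensions that disagree with the body are
#' hard errors naming the offending position.
#'
#' @param path Path to a `.gct` or `.gctx` file.
#' @param format `"auto"` (by extension), `"gct"` or `"gctx"`.
#' @return A [signature_matrix()].
#' @export
read_zscore_matrix <- function(path, format = "auto") {
  if (!file.exists(path)) {
    stop("matrix file does not exist: ", path, call. = FALSE)
  }
  switch(.guess_matrix_format(path, format),
         gct = .read_gct(path),
         gctx = .read_gctx(path))
}

#' Write a z-score signature matrix to GCT or GCTX
#'
#' Writes a [signature_matrix()] so that [read_zscore_matrix()] recovers
#' identifiers exactly and values to within representation precision
#' (text GCT values are printed with 10 significant digits).
#'
#' @param matrix A [signature_matrix()] or bare numeric matrix with
#'   dimnames.
#' @param path Output path.
#' @param format `"auto"` (by extension), `"gct"` or `"gctx"`.
#' @return `path`, invisibly.
#' @export
write_zscore_matrix <- function(matrix, path, format = "auto") {
  m <- .as_signature_matrix(matrix)
  switch(.guess_matrix_format(path, format),
         gct = .write_gct(m, path),
         gctx = .write_gctx(m, path))
  invisible(path)
}
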