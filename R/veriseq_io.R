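# Canonical per-run result CSV dialect.
#
# Vendor NIPT analysis software emits one CSV per sequencing run (up to 16
# samples). The vendor schema is proprietary, so this package defines its own
# documented dialect carrying the same metrics:
#
#   SampleID, Barcode, SampleType,
#   NCV_13, NCV_18, NCV_21, NCV_X, NCV_Y,        # Z-score-like chromosome values
#   FF,                                          # fetal fraction, PERCENT in files
#   NCD_*,                                       # >=1 denominator-group columns
#   Cov_chr1 .. Cov_chr22, Cov_chrX, Cov_chrY,   # normalized coverage (euploid ~ 1)
#   [Q30_pct, ClusterDensity_K_mm2, LibraryConc_nM]  # optional run-level QC
#   ... any other column is preserved per sample in vendor_qc.
#
# The filename must begin with the run date as YYMMDD. FF is stored internally
# as a fraction in [0,1]; the percent/fraction conversion happens only here.

NCV_CHROMS <- c("13", "18", "21", "X", "Y")
COV_CHROMS <- c(as.character(1:22), "X", "Y")
RUN_QC_COLUMNS <- c("Q30_pct", "ClusterDensity_K_mm2", "LibraryConc_nM")
MAX_SAMPLES_PER_RUN <- 16L
SAMPLE_TYPES <- c("singleton", "control", "unknown")

ncv_columns <- function() paste0("NCV_", NCV_CHROMS)
cov_columns <- function() paste0("Cov_chr", COV_CHROMS)

required_columns <- function() {
  c("SampleID", "Barcode", "SampleType", ncv_columns(), "FF", cov_columns())
}

#' Construct a single-sample record
#'
#' A `sample_record` holds one sample's normalized chromosome values (NCV,
#' Z-score-like), normalized chromosomal denominator (NCD) values, fetal
#' fraction (FF, as a fraction of cfDNA), normalized per-chromosome coverage,
#' and any pass-through vendor QC fields.
#'
#' @param sample_id Non-empty sample identifier, unique within its run.
#' @param barcode Library barcode string.
#' @param sample_type One of `"singleton"`, `"control"`, `"unknown"`.
#' @param ncv Named numeric vector with entries for exactly
#'   chromosomes `13, 18, 21, X, Y`.
#' @param ncd Non-empty named numeric vector of denominator-group values
#'   (names are the group labels, e.g. `"A"`, `"B"`).
#' @param ff Fetal fraction as a fraction in `[0, 1]` (serialized as percent
#'   in run CSV files).
#' @param coverage Named numeric vector of normalized coverage, one entry per
#'   chromosome `1..22, X, Y` (24 entries), all `>= 0`; autosome-mean scaled
#'   so the euploid expectation is 1.
#' @param vendor_qc Named character vector of pass-through fields (may be
#'   empty).
#' @return An object of class `sample_record`.
#' @export
sample_record <- function(sample_id, barcode = "", sample_type = "singleton",
                          ncv, ncd, ff, coverage,
                          vendor_qc = character()) {
  rec <- structure(
    list(sample_id = as.character(sample_id),
         barcode = as.character(barcode),
         sample_type = as.character(sample_type),
         ncv = ncv, ncd = ncd, ff = as.numeric(ff),
         coverage = coverage,
         vendor_qc = vendor_qc),
    class = "sample_record")
  validate_sample_record(rec)
  rec
}

#' Validate a sample record's invariants
#'
#' @param rec A [sample_record()].
#' @return `rec`, invisibly; raises a `nipt_validation_error` otherwise.
#' @export
validate_sample_record <- function(rec) {
  if (!inherits(rec, "sample_record")) stop_validation("not a sample_record")
  if (is.na(rec$sample_id) || !nzchar(rec$sample_id))
    stop_validation("sample_id must be non-empty")
  if (!setequal(names(rec$ncv), NCV_CHROMS) || length(rec$ncv) != 5L)
    stop_validation(sprintf("sample '%s': ncv must have entries for exactly {13,18,21,X,Y}",
                            rec$sample_id))
  if (length(rec$ncd) < 1L || is.null(names(rec$ncd)) || any(!nzchar(names(rec$ncd))))
    stop_validation(sprintf("sample '%s': ncd must be a non-empty named vector", rec$sample_id))
  if (is.na(rec$ff) || rec$ff < 0 || rec$ff > 1)
    stop_validation(sprintf("sample '%s': ff=%s outside [0,1]", rec$sample_id, rec$ff))
  if (!setequal(names(rec$coverage), COV_CHROMS) || length(rec$coverage) != 24L)
    stop_validation(sprintf("sample '%s': coverage must have exactly 24 chromosome entries",
                            rec$sample_id))
  if (any(is.na(rec$coverage)) || any(rec$coverage < 0))
    stop_validation(sprintf("sample '%s': coverage values must be >= 0", rec$sample_id))
  if (!rec$sample_type %in% SAMPLE_TYPES)
    stop_validation(sprintf("sample '%s': sample_type '%s' not in {%s}",
                            rec$sample_id, rec$sample_type,
                            paste(SAMPLE_TYPES, collapse = ", ")))
  invisible(rec)
}

#' Construct a run batch
#'
#' One sequencing run: a dated, ordered collection of 1-16 sample records plus
#' optional run-level QC metrics.
#'
#' @param run_id Run identifier (by convention the source filename stem).
#' @param run_date A `Date`; must agree with the `YYMMDD` prefix of
#'   `source_filename`.
#' @param samples List of [sample_record()] objects (1-16, distinct ids).
#' @param run_qc List with optional entries `q30_pct` (scalar),
#'   `cluster_density_k_mm2` (scalar) and `library_conc_nM` (numeric vector).
#' @param source_filename Basename of the originating CSV; must begin with the
#'   run date as `YYMMDD`.
#' @return An object of class `run_batch`.
#' @export
run_batch <- function(run_id, run_date, samples, run_qc = list(),
                      source_filename) {
  b <- structure(
    list(run_id = as.character(run_id),
         run_date = as.Date(run_date),
         samples = samples,
         run_qc = run_qc,
         source_filename = as.character(source_filename)),
    class = "run_batch")
  validate_run_batch(b)
  b
}

#' Validate a run batch's invariants
#'
#' @param batch A [run_batch()].
#' @return `batch`, invisibly; raises a typed error otherwise.
#' @export
validate_run_batch <- function(batch) {
  if (!inherits(batch, "run_batch")) stop_validation("not a run_batch")
  n <- length(batch$samples)
  if (n < 1L || n > MAX_SAMPLES_PER_RUN)
    stop_validation(sprintf("run '%s': %d samples outside 1..%d",
                            batch$run_id, n, MAX_SAMPLES_PER_RUN))
  for (s in batch$samples) validate_sample_record(s)
  ids <- vapply(batch$samples, function(s) s$sample_id, character(1))
  if (anyDuplicated(ids)) stop_duplicate_sample(ids[duplicated(ids)])
  d <- parse_run_date(batch$source_filename)
  if (d != batch$run_date)
    stop_validation(sprintf("run '%s': run_date %s does not match filename prefix of '%s'",
                            batch$run_id, format(batch$run_date), batch$source_filename))
  invisible(batch)
}

#' Parse a run date from a YYMMDD-prefixed filename
#'
#' Run files are named `YYMMDD_<runid>.csv`. Two-digit years pivot at 80:
#' `00-79` map to `2000-2079`, `80-99` to `1980 - 100 = 19YY` (the assay era is
#' post-2020, so the low pivot keeps modern dates unambiguous).
#'
#' @param filename A file name or path; only the basename is inspected.
#' @return A `Date`.
#' @export
parse_run_date <- function(filename) {
  stem <- basename(filename)
  prefix <- substr(stem, 1L, 6L)
  if (!grepl("^[0-9]{6}", stem))
    stop_malformed_filename(stem, "first 6 characters are not digits")
  yy <- as.integer(substr(prefix, 1, 2))
  mm <- as.integer(substr(prefix, 3, 4))
  dd <- as.integer(substr(prefix, 5, 6))
  year <- if (yy <= 79L) 2000L + yy else 1900L + yy
  d <- as.Date(strptime(sprintf("%04d-%02d-%02d", year, mm, dd),
                        format = "%Y-%m-%d", tz = "UTC"))
  if (is.na(d))
    stop_malformed_filename(stem, sprintf("'%s' is not a valid calendar date", prefix))
  d
}

#' Read a per-run result CSV
#'
#' Parses one canonical run CSV into a validated [run_batch()]. FF percent
#' values are converted to fractions; columns may appear in any order; columns
#' outside the canonical dialect are preserved per-sample in `vendor_qc`.
#' Malformed inputs always raise a typed condition
#' (`nipt_malformed_filename`, `nipt_schema_error`, `nipt_value_error`,
#' `nipt_duplicate_sample`, `nipt_empty_run`), never a partial batch.
#'
#' @param path Path to a run CSV whose basename begins with `YYMMDD`.
#' @return A [run_batch()].
#' @export
parse_run_csv <- function(path) {
  if (!file.exists(path)) stop_io(sprintf("file '%s' does not exist", path))
  stem <- basename(path)
  run_date <- parse_run_date(stem)

  df <- tryCatch(
    utils::read.csv(path, colClasses = "character", check.names = FALSE,
                    stringsAsFactors = FALSE),
    error = function(e) stop_schema(sprintf("cannot read '%s' as CSV: %s",
                                            stem, conditionMessage(e))))
  if (nrow(df) == 0L) stop_empty_run(stem)
  if (nrow(df) > MAX_SAMPLES_PER_RUN)
    stop_schema(sprintf("run capacity exceeded: %d sample rows, format allows at most %d",
                        nrow(df), MAX_SAMPLES_PER_RUN))

  missing <- setdiff(required_columns(), names(df))
  if (length(missing))
    stop_schema(sprintf("missing required column '%s'", missing[[1]]),
                column = missing[[1]])
  ncd_cols <- grep("^NCD_", names(df), value = TRUE)
  if (!length(ncd_cols))
    stop_schema("no NCD_* column present; at least one denominator group is required",
                column = "NCD_*")

  known <- c(required_columns(), ncd_cols, RUN_QC_COLUMNS)
  vendor_cols <- setdiff(names(df), known)

  num_cell <- function(row, col) {
    v <- df[[col]][row]
    x <- suppressWarnings(as.numeric(v))
    if (is.na(x) && !identical(toupper(trimws(v)), "NAN")) stop_value(v, row, col)
    if (is.na(x)) x <- NaN
    x
  }

  samples <- vector("list", nrow(df))
  for (i in seq_len(nrow(df))) {
    ncv <- vapply(ncv_columns(), function(cl) num_cell(i, cl), numeric(1))
    names(ncv) <- NCV_CHROMS
    ncd <- vapply(ncd_cols, function(cl) num_cell(i, cl), numeric(1))
    names(ncd) <- sub("^NCD_", "", ncd_cols)
    cov <- vapply(cov_columns(), function(cl) num_cell(i, cl), numeric(1))
    names(cov) <- COV_CHROMS
    ff_pct <- num_cell(i, "FF")
    if (is.na(ff_pct) || is.nan(ff_pct) || ff_pct < 0 || ff_pct > 100)
      stop_value(df[["FF"]][i], i, "FF")
    st <- df[["SampleType"]][i]
    if (!nzchar(trimws(st))) st <- "unknown"
    vq <- character(0)
    if (length(vendor_cols)) {
      vq <- vapply(vendor_cols, function(cl) df[[cl]][i], character(1))
      names(vq) <- vendor_cols
    }
    samples[[i]] <- tryCatch(
      sample_record(sample_id = df[["SampleID"]][i],
                    barcode = df[["Barcode"]][i],
                    sample_type = st,
                    ncv = ncv, ncd = ncd, ff = ff_pct / 100,
                    coverage = cov, vendor_qc = vq),
      nipt_validation_error = function(e)
        stop_value(conditionMessage(e), i, "<record>"))
  }

  ids <- vapply(samples, function(s) s$sample_id, character(1))
  if (anyDuplicated(ids)) stop_duplicate_sample(ids[duplicated(ids)])

  run_qc <- list()
  first_num <- function(col) {
    if (!col %in% names(df)) return(NULL)
    v <- df[[col]]
    v <- v[nzchar(trimws(v))]
    if (!length(v)) return(NULL)
    x <- suppressWarnings(as.numeric(v[[1]]))
    if (is.na(x)) stop_value(v[[1]], 1L, col)
    x
  }
  run_qc$q30_pct <- first_num("Q30_pct")
  run_qc$cluster_density_k_mm2 <- first_num("ClusterDensity_K_mm2")
  if ("LibraryConc_nM" %in% names(df)) {
    v <- df[["LibraryConc_nM"]]
    keep <- nzchar(trimws(v))
    if (any(keep)) {
      x <- suppressWarnings(as.numeric(v[keep]))
      if (any(is.na(x))) stop_value(v[keep][which(is.na(x))[1]], which(keep)[which(is.na(x))[1]],
                                    "LibraryConc_nM")
      run_qc$library_conc_nM <- x
    }
  }
  run_qc <- run_qc[!vapply(run_qc, is.null, logical(1))]

  run_batch(run_id = tools::file_path_sans_ext(stem),
            run_date = run_date, samples = samples,
            run_qc = run_qc, source_filename = stem)
}

fmt_num <- function(x) {
  # deterministic, full-precision-enough formatting for round trips (<=1e-12 rel)
  vapply(x, function(v) {
    if (is.nan(v)) "NaN" else sprintf("%.12g", v)
  }, character(1))
}

#' Write a run batch to the canonical CSV dialect
#'
#' The written file re-parses to a batch equal to the input (FF within 1e-9;
#' FF is written as percent). The basename of `path` must begin with the
#' batch's run date as `YYMMDD` so that the file is self-describing.
#'
#' @param batch A valid [run_batch()].
#' @param path Output path; its basename must carry the batch's `YYMMDD` date.
#' @return `path`, invisibly.
#' @export
write_run_csv <- function(batch, path) {
  validate_run_batch(batch)
  stem <- basename(path)
  if (!grepl("^[0-9]{6}", stem) || parse_run_date(stem) != batch$run_date)
    stop_validation(sprintf("output filename '%s' must begin with the run date %s as YYMMDD",
                            stem, format(batch$run_date, "%y%m%d")))

  ncd_names <- names(batch$samples[[1]]$ncd)
  vendor_names <- unique(unlist(lapply(batch$samples, function(s) names(s$vendor_qc))))
  n <- length(batch$samples)

  df <- data.frame(
    SampleID = vapply(batch$samples, `[[`, character(1), "sample_id"),
    Barcode = vapply(batch$samples, `[[`, character(1), "barcode"),
    SampleType = vapply(batch$samples, `[[`, character(1), "sample_type"),
    check.names = FALSE, stringsAsFactors = FALSE)
  for (ch in NCV_CHROMS)
    df[[paste0("NCV_", ch)]] <- fmt_num(vapply(batch$samples, function(s) s$ncv[[ch]], numeric(1)))
  df[["FF"]] <- fmt_num(vapply(batch$samples, function(s) s$ff * 100, numeric(1)))
  for (nm in ncd_names)
    df[[paste0("NCD_", nm)]] <- fmt_num(vapply(batch$samples, function(s) s$ncd[[nm]], numeric(1)))
  for (ch in COV_CHROMS)
    df[[paste0("Cov_chr", ch)]] <- fmt_num(vapply(batch$samples, function(s) s$coverage[[ch]], numeric(1)))

  qc <- batch$run_qc
  if (!is.null(qc$q30_pct)) df[["Q30_pct"]] <- fmt_num(rep(qc$q30_pct, n))
  if (!is.null(qc$cluster_density_k_mm2))
    df[["ClusterDensity_K_mm2"]] <- fmt_num(rep(qc$cluster_density_k_mm2, n))
  if (!is.null(qc$library_conc_nM)) {
    lc <- rep("", n)
    lc[seq_along(qc$library_conc_nM)] <- fmt_num(qc$library_conc_nM)
    df[["LibraryConc_nM"]] <- lc
  }
  for (nm in vendor_names)
    df[[nm]] <- vapply(batch$samples, function(s) {
      v <- s$vendor_qc[nm]
      if (is.na(v)) "" else unname(v)
    }, character(1))

  ok <- tryCatch({
    utils::write.csv(df, path, row.names = FALSE, quote = TRUE)
    TRUE
  }, error = function(e) FALSE, warning = function(w) FALSE)
  if (!ok) stop_io(sprintf("cannot write run CSV to '%s'", path))
  invisible(path)
}

#' Compare two run batches field by field
#'
#' @param a,b [run_batch()] objects.
#' @param tol Numeric tolerance (absolute) for NCV/FF/NCD/coverage values.
#' @return `TRUE` if equal within `tol`, else `FALSE`.
#' @export
run_batch_equal <- function(a, b, tol = 1e-9) {
  num_eq <- function(x, y) {
    if (length(x) != length(y)) return(FALSE)
    both_nan <- is.nan(x) & is.nan(y)
    all(both_nan | (!is.na(x) & !is.na(y) & abs(x - y) <= tol))
  }
  if (a$run_id != b$run_id || a$run_date != b$run_date ||
      a$source_filename != b$source_filename) return(FALSE)
  if (length(a$samples) != length(b$samples)) return(FALSE)
  for (i in seq_along(a$samples)) {
    x <- a$samples[[i]]; y <- b$samples[[i]]
    if (x$sample_id != y$sample_id || x$barcode != y$barcode ||
        x$sample_type != y$sample_type) return(FALSE)
    if (!num_eq(x$ncv[NCV_CHROMS], y$ncv[NCV_CHROMS])) return(FALSE)
    if (!setequal(names(x$ncd), names(y$ncd))) return(FALSE)
    if (!num_eq(x$ncd[names(x$ncd)], y$ncd[names(x$ncd)])) return(FALSE)
    if (abs(x$ff - y$ff) > tol) return(FALSE)
    if (!num_eq(x$coverage[COV_CHROMS], y$coverage[COV_CHROMS])) return(FALSE)
    xv <- x$vendor_qc[nzchar(x$vendor_qc)]
    yv <- y$vendor_qc[nzchar(y$vendor_qc)]
    if (!setequal(names(xv), names(yv))) return(FALSE)
    if (length(xv) && !identical(unname(xv[names(xv)]), unname(yv[names(xv)]))) return(FALSE)
  }
  qa <- a$run_qc; qb <- b$run_qc
  for (k in union(names(qa), names(qb))) {
    va <- qa[[k]]; vb <- qb[[k]]
    if (is.null(va) != is.null(vb)) return(FALSE)
    if (!is.null(va) && !num_eq(va, vb)) return(FALSE)
  }
  TRUE
}

#' @export
print.run_batch <- function(x, ...) {
  cat(sprintf("<run_batch> %s (%s): %d sample(s), source '%s'\n",
              x$run_id, format(x$run_date), length(x$samples), x$source_filename))
  invisible(x)
}

#' Flatten run batch samples to a data frame
#'
#' One row per sample with columns `sample_id`, `ff`, `ncv_13` .. `ncv_Y`
#' (plus `run_id`/`run_date` when given); convenient for plotting and fitting.
#'
#' @param samples List of [sample_record()]s.
#' @param run_id,run_date Optional provenance added as constant columns.
#' @return A `data.frame`.
#' @export
samples_to_df <- function(samples, run_id = NA_character_, run_date = as.Date(NA)) {
  if (!length(samples)) {
    return(data.frame(sample_id = character(0), ff = numeric(0),
                      ncv_13 = numeric(0), ncv_18 = numeric(0), ncv_21 = numeric(0),
                      ncv_X = numeric(0), ncv_Y = numeric(0),
                      run_id = character(0), stringsAsFactors = FALSE))
  }
  df <- data.frame(
    sample_id = vapply(samples, `[[`, character(1), "sample_id"),
    ff = vapply(samples, `[[`, numeric(1), "ff"),
    stringsAsFactors = FALSE)
  for (ch in NCV_CHROMS)
    df[[paste0("ncv_", ch)]] <- vapply(samples, function(s) s$ncv[[ch]], numeric(1))
  df$run_id <- run_id
  df$run_date <- run_date
  df
}
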