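# Per-sample classification and QC flagging.
#
# The engine emits flags that guide human review; it never diagnoses. The
# autosomal rule is the verified one-sided decision rule: flag at NCV > 4
# with FF >= 2%, inconclusive over the CLOSED span [3, 4] (NCV exactly 3 or
# exactly 4 is inconclusive), normal below 3, and no call at all when FF is
# below the minimum. Large negative autosomal NCVs (possible monosomy or a
# processing problem) are not auto-called; they are surfaced through a
# symmetric |NCV| >= ncv_gray_low highlight while the call follows the
# one-sided rule.

AUTOSOMES <- c("13", "18", "21")
AUTOSOME_CALLS <- c("normal", "inconclusive", "aneuploidy_flag", "no_call_low_ff")
SEX_ASSESSMENTS <- c("xx_consistent", "xy_consistent", "sca_flag", "no_call_low_ff")

empty_highlights <- function() {
  data.frame(field = character(0), value = numeric(0), rule = character(0),
             stringsAsFactors = FALSE)
}

highlight_row <- function(field, value, rule) {
  data.frame(field = field, value = value, rule = rule, stringsAsFactors = FALSE)
}

new_interpretation <- function(sample_id, autosome_calls, sex_assessment,
                               qc_status, highlights, run_qc_findings = character(0)) {
  structure(list(sample_id = sample_id,
                 autosome_calls = autosome_calls,
                 sex_assessment = sex_assessment,
                 qc_status = qc_status,
                 highlights = highlights,
                 run_qc_findings = run_qc_findings),
            class = "interpretation")
}

#' Classify one autosomal NCV value
#'
#' Decision rule (given a fetal fraction `ff` and config `cfg`):
#' `ff < ff_min` yields `no_call_low_ff` regardless of NCV; otherwise
#' `ncv > ncv_call` yields `aneuploidy_flag`, `ncv` in the closed interval
#' `[ncv_gray_low, ncv_call]` yields `inconclusive`, and `ncv < ncv_gray_low`
#' yields `normal`. A non-finite NCV is `inconclusive`.
#'
#' @param ncv Numeric NCV value(s) for one of chromosomes 13/18/21.
#' @param ff Fetal fraction(s), as fraction.
#' @param cfg A [threshold_config()].
#' @return Character vector of calls in
#'   `{normal, inconclusive, aneuploidy_flag, no_call_low_ff}`.
#' @export
classify_autosome <- function(ncv, ff, cfg = threshold_config()) {
  n <- max(length(ncv), length(ff))
  ncv <- rep_len(ncv, n); ff <- rep_len(ff, n)
  out <- character(n)
  for (i in seq_len(n)) {
    out[i] <- if (ff[i] < cfg$ff_min) "no_call_low_ff"
    else if (!is.finite(ncv[i])) "inconclusive"
    else if (ncv[i] > cfg$ncv_call) "aneuploidy_flag"
    else if (ncv[i] >= cfg$ncv_gray_low) "inconclusive"
    else "normal"
  }
  out
}

#' Assess sex-chromosome consistency for one sample
#'
#' With adequate fetal fraction, a presumed-male sample
#' (`ncv_y >= male_ncvY_min`) is checked against the calibrated NCV(X)/NCV(Y)
#' line: inside the +/- `band_sd_mult * resid_sd` band it is
#' `xy_consistent`, outside it is flagged (`sca_flag`). A presumed-female
#' sample is checked against the female NCV_X cluster:
#' `|ncv_x - female_x_mean| <= band_sd_mult * female_x_sd` is
#' `xx_consistent`, otherwise `sca_flag`. Low FF yields `no_call_low_ff`.
#'
#' @param ncv_x,ncv_y Sex-chromosome NCVs.
#' @param ff Fetal fraction (fraction).
#' @param calib A `sex_calibration` from [fit_sex_regression()].
#' @param cfg A [threshold_config()].
#' @return One of `xx_consistent`, `xy_consistent`, `sca_flag`,
#'   `no_call_low_ff`.
#' @export
assess_sex <- function(ncv_x, ncv_y, ff, calib, cfg = threshold_config()) {
  validate_sex_calibration(calib)
  if (ff < cfg$ff_min) return("no_call_low_ff")
  if (!is.finite(ncv_x) || !is.finite(ncv_y)) return("sca_flag")
  if (ncv_y >= cfg$male_ncvY_min) {
    b <- band_bounds(calib, cfg, ncv_x)
    if (ncv_y >= b$low && ncv_y <= b$high) "xy_consistent" else "sca_flag"
  } else {
    if (abs(ncv_x - calib$female_x_mean) <= cfg$band_sd_mult * calib$female_x_sd)
      "xx_consistent" else "sca_flag"
  }
}

#' Per-chromosome coverage statistics of a historical set
#'
#' @param history A `historical_set`.
#' @param min_n Minimum number of historical samples needed (default 2).
#' @return A list with numeric vectors `mean` and `sd` named by chromosome,
#'   or `NULL` when the history is too small.
#' @export
history_coverage_stats <- function(history, min_n = 2L) {
  recs <- history_records(history)
  if (length(recs) < min_n) return(NULL)
  m <- vapply(recs, function(r) r$coverage[COV_CHROMS], numeric(24))
  list(mean = apply(m, 1, mean), sd = apply(m, 1, stats::sd))
}

#' Sample-level quality control
#'
#' Highlights every denominator value with `|NCD| > ncd_limit`, every
#' chromosome whose coverage z-score against the historical per-chromosome
#' mean/SD exceeds `coverage_z_limit` in absolute value, and a fetal fraction
#' below `ff_min`. `qc_status` is `fail` iff FF is below the minimum, `warn`
#' iff any other highlight exists, `pass` otherwise. With too little history
#' the coverage check is skipped and noted in the findings.
#'
#' @param rec A [sample_record()].
#' @param history A `historical_set` used as the coverage reference.
#' @param cfg A [threshold_config()].
#' @return A list with `qc_status`, `highlights` (data frame with columns
#'   `field`, `value`, `rule`) and `findings` (character).
#' @export
qc_sample <- function(rec, history, cfg = threshold_config()) {
  highlights <- empty_highlights()
  findings <- character(0)

  for (nm in names(rec$ncd)) {
    v <- rec$ncd[[nm]]
    if (is.finite(v) && abs(v) > cfg$ncd_limit)
      highlights <- rbind(highlights, highlight_row(paste0("NCD_", nm), v, "ncd_limit"))
  }

  stats <- history_coverage_stats(history)
  if (is.null(stats)) {
    findings <- c(findings, "coverage checks skipped: insufficient historical data")
  } else {
    for (ch in COV_CHROMS) {
      s <- stats$sd[[ch]]
      if (!is.finite(s) || s < 1e-12) next
      z <- (rec$coverage[[ch]] - stats$mean[[ch]]) / s
      if (abs(z) > cfg$coverage_z_limit)
        highlights <- rbind(highlights,
                            highlight_row(paste0("Cov_chr", ch), rec$coverage[[ch]],
                                          "coverage_z_limit"))
    }
  }

  low_ff <- rec$ff < cfg$ff_min
  if (low_ff)
    highlights <- rbind(highlights, highlight_row("FF", rec$ff, "ff_min"))

  status <- if (low_ff) "fail" else if (nrow(highlights) > 0) "warn" else "pass"
  list(qc_status = status, highlights = highlights, findings = findings)
}

#' Run-level quality control
#'
#' Emits one finding per run metric outside its configured range (Q30
#' minimum, cluster density range, library concentration range); metrics
#' absent from the run yield a "not assessed" finding.
#'
#' @param batch A [run_batch()].
#' @param cfg A [threshold_config()].
#' @return Character vector of findings (empty when all present metrics are
#'   in range and none are missing).
#' @export
qc_run <- function(batch, cfg = threshold_config()) {
  findings <- character(0)
  qc <- batch$run_qc

  if (is.null(qc$q30_pct)) {
    findings <- c(findings, "q30_pct: not assessed (missing from run)")
  } else if (qc$q30_pct <= cfg$q30_min_pct) {
    findings <- c(findings,
                  sprintf("q30_pct %.2f outside range: must exceed %.2f (q30_min_pct)",
                          qc$q30_pct, cfg$q30_min_pct))
  }

  dr <- cfg$cluster_density_range_k_mm2
  if (is.null(qc$cluster_density_k_mm2)) {
    findings <- c(findings, "cluster_density_k_mm2: not assessed (missing from run)")
  } else if (qc$cluster_density_k_mm2 < dr[1] || qc$cluster_density_k_mm2 > dr[2]) {
    findings <- c(findings,
                  sprintf("cluster_density_k_mm2 %.1f outside range %g-%g (cluster_density_range_k_mm2)",
                          qc$cluster_density_k_mm2, dr[1], dr[2]))
  }

  lr <- cfg$library_conc_range_nM
  if (is.null(qc$library_conc_nM) || !length(qc$library_conc_nM)) {
    findings <- c(findings, "library_conc_nM: not assessed (missing from run)")
  } else {
    bad <- qc$library_conc_nM < lr[1] | qc$library_conc_nM > lr[2]
    if (any(bad))
      findings <- c(findings,
                    sprintf("library_conc_nM: %d value(s) outside range %g-%g (library_conc_range_nM)",
                            sum(bad), lr[1], lr[2]))
  }
  findings
}

#' Interpret every sample of a run
#'
#' Composes [classify_autosome()], [assess_sex()], [qc_sample()] and
#' [qc_run()] into one interpretation per sample. Deterministic given its
#' inputs. In addition to the QC highlights, any autosomal NCV with
#' `|NCV| >= ncv_gray_low` is highlighted (rule `ncv_gray_low`) so that both
#' flagged trisomies and unusually negative values are marked for review.
#'
#' @param batch A [run_batch()].
#' @param history A `historical_set` (the run's own samples must be excluded
#'   by the caller, e.g. via `get_history(store, exclude_run = ...)`).
#' @param calib A `sex_calibration`; required.
#' @param cfg A [threshold_config()].
#' @return A list of `interpretation` objects (one per sample, in run order),
#'   each with fields `sample_id`, `autosome_calls` (named by chromosome),
#'   `sex_assessment`, `qc_status`, `highlights`, `run_qc_findings`.
#' @export
interpret_run <- function(batch, history, calib, cfg = threshold_config()) {
  validate_run_batch(batch)
  validate_sex_calibration(calib)
  run_findings <- qc_run(batch, cfg)

  lapply(batch$samples, function(rec) {
    calls <- vapply(AUTOSOMES, function(ch)
      classify_autosome(rec$ncv[[ch]], rec$ff, cfg), character(1))
    names(calls) <- AUTOSOMES
    sex <- assess_sex(rec$ncv[["X"]], rec$ncv[["Y"]], rec$ff, calib, cfg)
    qc <- qc_sample(rec, history, cfg)
    highlights <- qc$highlights
    for (ch in AUTOSOMES) {
      v <- rec$ncv[[ch]]
      if (!is.finite(v) || abs(v) >= cfg$ncv_gray_low)
        highlights <- rbind(highlights,
                            highlight_row(paste0("NCV_", ch),
                                          if (is.finite(v)) v else NaN,
                                          "ncv_gray_low"))
    }
    status <- if (rec$ff < cfg$ff_min) "fail"
    else if (nrow(highlights) > 0) "warn" else "pass"
    new_interpretation(sample_id = rec$sample_id,
                       autosome_calls = calls,
                       sex_assessment = sex,
                       qc_status = status,
                       highlights = highlights,
                       run_qc_findings = run_findings)
  })
}

#' @export
print.interpretation <- function(x, ...) {
  cat(sprintf("<interpretation> %s: 13=%s 18=%s 21=%s sex=%s qc=%s (%d highlight(s))\n",
              x$sample_id, x$autosome_calls[["13"]], x$autosome_calls[["18"]],
              x$autosome_calls[["21"]], x$sex_assessment, x$qc_status,
              nrow(x$highlights)))
  invisible(x)
}

#' Serialize interpretations to a results CSV
#'
#' One row per sample and assessed chromosome (13, 18, 21, sex), plus the
#' sample's QC status and highlight count.
#'
#' @param interpretations List of interpretations from [interpret_run()].
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
interpretations_to_csv <- function(interpretations, path) {
  rows <- do.call(rbind, lapply(interpretations, function(it) {
    data.frame(sample_id = it$sample_id,
               chromosome = c(AUTOSOMES, "XY"),
               call = c(unname(it$autosome_calls[AUTOSOMES]), it$sex_assessment),
               qc_status = it$qc_status,
               n_highlights = nrow(it$highlights),
               stringsAsFactors = FALSE)
  }))
  utils::write.csv(rows, path, row.names = FALSE)
  invisible(path)
}

#' Does an interpretation recover a known truth label?
#'
#' Used to validate the pipeline against synthetic cohorts: a trisomy label
#' requires `aneuploidy_flag` on its chromosome, `normal` on the other two
#' and a consistent (unflagged) sex assessment; a sex-chromosome aneuploidy
#' label requires `sca_flag` with all autosomes `normal`; a euploid label
#' requires all autosomes `normal` and a consistent sex assessment.
#'
#' @param interp An `interpretation`.
#' @param karyotype_class One of `euploid_xx`, `euploid_xy`, `T13`, `T18`,
#'   `T21`, `X0`, `XXX`, `XXY`, `XYY`.
#' @return Logical scalar.
#' @export
interpretation_matches_truth <- function(interp, karyotype_class) {
  calls <- interp$autosome_calls
  sex_ok <- interp$sex_assessment %in% c("xx_consistent", "xy_consistent")
  all_normal <- all(calls[AUTOSOMES] == "normal")
  switch(karyotype_class,
    euploid_xx = ,
    euploid_xy = all_normal && sex_ok,
    T13 = calls[["13"]] == "aneuploidy_flag" &&
      all(calls[c("18", "21")] == "normal") && sex_ok,
    T18 = calls[["18"]] == "aneuploidy_flag" &&
      all(calls[c("13", "21")] == "normal") && sex_ok,
    T21 = calls[["21"]] == "aneuploidy_flag" &&
      all(calls[c("13", "18")] == "normal") && sex_ok,
    X0 = ,
    XXX = ,
    XXY = ,
    XYY = all_normal && interp$sex_assessment == "sca_flag",
    stop_validation(sprintf("unknown karyotype class '%s'", karyotype_class)))
}
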