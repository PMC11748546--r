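# Decision constants and the NCV(X)/NCV(Y) sex-chromosome calibration.
#
# All decision constants live in one `threshold_config` object so a laboratory
# can recalibrate without touching code. The sex-chromosome calibration fits
# an ordinary least-squares line of NCV_Y on NCV_X over the presumed-male
# subset (only XY pregnancies trace a line: fetal Y signal rises and fetal X
# signal falls together with fetal fraction) and summarizes presumed females
# as an NCV_X cluster. The decision band around the line has constant width
# +/- band_sd_mult * resid_sd (3 residual SDs by default, a ~99% band under
# normality).

#' Decision threshold configuration
#'
#' Holds every decision constant used by classification, QC and charting.
#' Defaults are the clinically verified values: trisomy flag at NCV > 4 with
#' FF >= 2%, inconclusive span at NCV in \[3, 4\], a 3-SD sex-chromosome band,
#' Q30 > 95%, cluster density 140-250 K/mm2 and library concentration
#' 10-250 nM.
#'
#' @param ncv_call NCV above which an autosome is flagged (default 4).
#' @param ncv_gray_low Lower edge of the inconclusive NCV span (default 3).
#' @param ff_min Minimum fetal fraction (fraction, default 0.02) below which
#'   no call is issued.
#' @param band_sd_mult Half-width of the sex-chromosome band in residual SDs
#'   (default 3).
#' @param ncd_limit Absolute NCD value above which a denominator group is
#'   highlighted (default 4).
#' @param coverage_z_limit Absolute z-score (vs historical per-chromosome
#'   coverage) above which coverage is highlighted (default 3).
#' @param q30_min_pct Minimum run Q30 percent (default 95).
#' @param cluster_density_range_k_mm2 Acceptable cluster density range in
#'   K/mm2 (default `c(140, 250)`).
#' @param library_conc_range_nM Acceptable library concentration range in nM
#'   (default `c(10, 250)`).
#' @param male_ncvY_min NCV_Y at or above which a sample is treated as
#'   presumed male (default 4).
#' @return An object of class `threshold_config`.
#' @export
threshold_config <- function(ncv_call = 4.0, ncv_gray_low = 3.0, ff_min = 0.02,
                             band_sd_mult = 3.0, ncd_limit = 4.0,
                             coverage_z_limit = 3.0, q30_min_pct = 95,
                             cluster_density_range_k_mm2 = c(140, 250),
                             library_conc_range_nM = c(10, 250),
                             male_ncvY_min = 4.0) {
  cfg <- structure(
    list(ncv_call = as.numeric(ncv_call), ncv_gray_low = as.numeric(ncv_gray_low),
         ff_min = as.numeric(ff_min), band_sd_mult = as.numeric(band_sd_mult),
         ncd_limit = as.numeric(ncd_limit),
         coverage_z_limit = as.numeric(coverage_z_limit),
         q30_min_pct = as.numeric(q30_min_pct),
         cluster_density_range_k_mm2 = as.numeric(cluster_density_range_k_mm2),
         library_conc_range_nM = as.numeric(library_conc_range_nM),
         male_ncvY_min = as.numeric(male_ncvY_min)),
    class = "threshold_config")
  validate_threshold_config(cfg)
  cfg
}

#' Validate a threshold configuration
#' @param cfg A [threshold_config()].
#' @return `cfg`, invisibly; raises `nipt_validation_error` otherwise.
#' @export
validate_threshold_config <- function(cfg) {
  if (!inherits(cfg, "threshold_config")) stop_validation("not a threshold_config")
  if (!(cfg$ncv_gray_low < cfg$ncv_call))
    stop_validation("ncv_gray_low must be < ncv_call")
  if (!(cfg$ff_min > 0 && cfg$ff_min < 1))
    stop_validation("ff_min must lie in (0, 1)")
  if (!(cfg$band_sd_mult >= 0)) stop_validation("band_sd_mult must be >= 0")
  for (nm in c("cluster_density_range_k_mm2", "library_conc_range_nM")) {
    r <- cfg[[nm]]
    if (length(r) != 2L || !(r[1] < r[2]))
      stop_validation(sprintf("%s must be (low, high) with low < high", nm))
  }
  invisible(cfg)
}

#' Save a threshold configuration to JSON
#' @param cfg A [threshold_config()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
config_save <- function(cfg, path) {
  validate_threshold_config(cfg)
  jsonlite::write_json(unclass(cfg), path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Load a threshold configuration from JSON
#' @param path Path written by [config_save()].
#' @return A [threshold_config()].
#' @export
config_load <- function(path) {
  x <- jsonlite::fromJSON(path)
  do.call(threshold_config, x)
}

# -- sex-chromosome calibration ----------------------------------------------

new_sex_calibration <- function(slope, intercept, resid_sd, n_fit,
                                female_x_mean, female_x_sd, n_female,
                                fitted_on = character(0)) {
  calib <- structure(
    list(slope = slope, intercept = intercept, resid_sd = resid_sd,
         n_fit = as.integer(n_fit), female_x_mean = female_x_mean,
         female_x_sd = female_x_sd, n_female = as.integer(n_female),
         fitted_on = fitted_on),
    class = "sex_calibration")
  validate_sex_calibration(calib)
  calib
}

#' Validate a sex-chromosome calibration
#' @param calib A `sex_calibration`.
#' @return `calib`, invisibly.
#' @export
validate_sex_calibration <- function(calib) {
  if (!inherits(calib, "sex_calibration")) stop_validation("not a sex_calibration")
  if (calib$n_fit < 3L) stop_validation("n_fit must be >= 3")
  if (!is.finite(calib$resid_sd) || calib$resid_sd <= 0)
    stop_validation("resid_sd must be finite and > 0")
  if (!is.finite(calib$female_x_sd) || calib$female_x_sd <= 0)
    stop_validation("female_x_sd must be finite and > 0")
  invisible(calib)
}

calibration_to_list <- function(calib) unclass(calib)

calibration_from_list <- function(x) {
  new_sex_calibration(slope = x$slope, intercept = x$intercept,
                      resid_sd = x$resid_sd, n_fit = x$n_fit,
                      female_x_mean = x$female_x_mean, female_x_sd = x$female_x_sd,
                      n_female = x$n_female %||% 3L,
                      fitted_on = as.character(unlist(x$fitted_on)))
}

trimmed_indices <- function(resid, trim_sd, keep_min) {
  s <- stats::sd(resid)
  if (!is.finite(s) || s < 1e-12) return(seq_along(resid))
  keep <- abs(resid) <= trim_sd * s
  if (sum(keep) < keep_min) return(seq_along(resid))
  which(keep)
}

#' Fit the NCV(X) vs NCV(Y) sex-chromosome calibration
#'
#' Splits `samples` into presumed males (`ncv_Y >= cfg$male_ncvY_min`) and
#' presumed females, fits an OLS line of NCV_Y on NCV_X over the males and
#' summarizes the females' NCV_X as mean/SD. Both fits drop gross outliers
#' (residual beyond `trim_sd` SDs, iterated) so that a calibration set
#' contaminated by the occasional sex-chromosome aneuploidy still yields a
#' tight band; on clean data trimming is a no-op to within Monte-Carlo noise.
#'
#' An exact-line fit (zero residual spread) is degenerate: a
#' `nipt_degenerate_fit` warning is raised and `resid_sd` is floored at 1e-6.
#'
#' @param samples List of [sample_record()]s or a `historical_set`.
#' @param cfg A [threshold_config()] (supplies `male_ncvY_min`).
#' @param trim_sd Outlier trimming threshold in residual SDs (default 3).
#' @param max_iter Maximum trimming iterations (default 5).
#' @return An object of class `sex_calibration` with fields `slope`,
#'   `intercept`, `resid_sd`, `n_fit`, `female_x_mean`, `female_x_sd`,
#'   `fitted_on`.
#' @export
fit_sex_regression <- function(samples, cfg = threshold_config(),
                               trim_sd = 3, max_iter = 5) {
  fitted_on <- character(0)
  if (inherits(samples, "historical_set")) {
    fitted_on <- unique(vapply(samples$samples, `[[`, character(1), "run_id"))
    samples <- history_records(samples)
  }
  x <- vapply(samples, function(s) s$ncv[["X"]], numeric(1))
  y <- vapply(samples, function(s) s$ncv[["Y"]], numeric(1))
  male <- !is.na(y) & y >= cfg$male_ncvY_min
  n_male <- sum(male); n_female <- sum(!male)
  if (n_male < 3L) stop_insufficient_calibration("male", n_male, 3L)
  if (n_female < 3L) stop_insufficient_calibration("female", n_female, 3L)

  # male line: OLS of NCV_Y on NCV_X with iterative residual trimming
  mx <- x[male]; my <- y[male]
  keep <- seq_along(mx)
  for (i in seq_len(max_iter)) {
    fit <- stats::lm(my[keep] ~ mx[keep])
    r <- stats::residuals(fit)
    kk <- trimmed_indices(r, trim_sd, keep_min = 3L)
    if (length(kk) == length(keep)) break
    keep <- keep[kk]
  }
  fit <- stats::lm(my[keep] ~ mx[keep])
  coefs <- stats::coef(fit)
  resid_sd <- stats::sd(stats::residuals(fit))
  if (!is.finite(resid_sd) || resid_sd < 1e-12) {
    nipt_warn("nipt_degenerate_fit",
              "exact-line sex calibration: residual SD is 0; flooring at 1e-6")
    resid_sd <- 1e-6
  }

  # female cluster: trimmed NCV_X mean/SD
  fx <- x[!male]
  fkeep <- seq_along(fx)
  for (i in seq_len(max_iter)) {
    r <- fx[fkeep] - mean(fx[fkeep])
    kk <- trimmed_indices(r, trim_sd, keep_min = 3L)
    if (length(kk) == length(fkeep)) break
    fkeep <- fkeep[kk]
  }
  female_x_mean <- mean(fx[fkeep])
  female_x_sd <- stats::sd(fx[fkeep])
  if (!is.finite(female_x_sd) || female_x_sd < 1e-12) female_x_sd <- 1e-6

  new_sex_calibration(slope = unname(coefs[2]), intercept = unname(coefs[1]),
                      resid_sd = resid_sd, n_fit = length(keep),
                      female_x_mean = female_x_mean, female_x_sd = female_x_sd,
                      n_female = length(fkeep), fitted_on = fitted_on)
}

#' Confidence band around the fitted sex-chromosome line
#'
#' The band has constant width: center `slope * ncv_x + intercept`, bounds
#' `center -/+ band_sd_mult * resid_sd`.
#'
#' @param calib A `sex_calibration`.
#' @param cfg A [threshold_config()] (supplies `band_sd_mult`).
#' @param ncv_x NCV_X value(s) at which to evaluate the band.
#' @return A list with numeric vectors `low` and `high` (and `center`).
#' @export
band_bounds <- function(calib, cfg, ncv_x) {
  validate_sex_calibration(calib)
  center <- calib$slope * ncv_x + calib$intercept
  half <- cfg$band_sd_mult * calib$resid_sd
  list(low = center - half, high = center + half, center = center)
}

#' @export
print.sex_calibration <- function(x, ...) {
  cat(sprintf("<sex_calibration> NCV_Y = %.4f * NCV_X + %.4f (resid SD %.4f, n=%d males)\n",
              x$slope, x$intercept, x$resid_sd, x$n_fit))
  cat(sprintf("  female NCV_X cluster: mean %.4f, SD %.4f (n=%d)\n",
              x$female_x_mean, x$female_x_sd, x$n_female))
  invisible(x)
}

#' @export
print.threshold_config <- function(x, ...) {
  cat("<threshold_config>\n")
  for (nm in names(unclass(x)))
    cat(sprintf("  %s: %s\n", nm, paste(x[[nm]], collapse = " - ")))
  invisible(x)
}
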