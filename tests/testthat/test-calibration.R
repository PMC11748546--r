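# Stated generator for parameter-recovery checks: male points on the line
# y = slope * x + intercept with residual noise SD 1, NCV_X spanning the
# fetal-fraction range; females at the standard-normal NCV_X baseline.
simulate_calibration_samples <- function(n_male = 200, n_female = 50,
                                         slope = -1.5, intercept = 0,
                                         resid_sd = 1.0) {
  x <- stats::runif(n_male, -29, -4)
  y <- slope * x + intercept + stats::rnorm(n_male, 0, resid_sd)
  males <- lapply(seq_len(n_male), function(i)
    make_sample(id = sprintf("M%03d", i),
                ncv = c("13" = 0, "18" = 0, "21" = 0, "X" = x[i], "Y" = y[i])))
  females <- lapply(seq_len(n_female), function(i)
    make_sample(id = sprintf("F%03d", i),
                ncv = c("13" = 0, "18" = 0, "21" = 0,
                        "X" = stats::rnorm(1), "Y" = stats::rnorm(1))))
  c(males, females)
}

test_that("threshold config defaults carry the verified decision constants", {
  cfg <- threshold_config()
  expect_equal(cfg$ncv_call, 4.0)
  expect_equal(cfg$ncv_gray_low, 3.0)
  expect_equal(cfg$ff_min, 0.02)
  expect_equal(cfg$band_sd_mult, 3.0)
  expect_equal(cfg$q30_min_pct, 95)
  expect_equal(cfg$cluster_density_range_k_mm2, c(140, 250))
  expect_equal(cfg$library_conc_range_nM, c(10, 250))
  expect_error(threshold_config(ncv_gray_low = 5), class = "nipt_validation_error")
  expect_error(threshold_config(ff_min = 0), class = "nipt_validation_error")
  expect_error(threshold_config(library_conc_range_nM = c(250, 10)),
               class = "nipt_validation_error")
})

test_that("config serialization round-trips exactly", {
  dir <- withr::local_tempdir()
  cfg <- threshold_config(ncv_call = 4.25, ff_min = 0.0213,
                          cluster_density_range_k_mm2 = c(141.5, 249.25))
  path <- file.path(dir, "thresholds.json")
  config_save(cfg, path)
  cfg2 <- config_load(path)
  expect_identical(unclass(cfg2), unclass(cfg))
})

test_that("regression recovers simulated slope and residual SD", {
  set.seed(101)
  samples <- simulate_calibration_samples(n_male = 200, slope = -1.5,
                                          resid_sd = 1.0)
  calib <- fit_sex_regression(samples, threshold_config())
  expect_gt(calib$slope, -1.65); expect_lt(calib$slope, -1.35)
  expect_gt(calib$resid_sd, 0.85); expect_lt(calib$resid_sd, 1.15)
  expect_gte(calib$n_fit, 3L)
  # female cluster summarized at its baseline
  expect_lt(abs(calib$female_x_mean), 0.5)
  expect_gt(calib$female_x_sd, 0.7); expect_lt(calib$female_x_sd, 1.3)
})

test_that("an exact-line fit is degenerate: warned and floored", {
  x <- c(-5, -10, -15, -20)
  samples <- c(
    lapply(seq_along(x), function(i)
      make_sample(id = sprintf("M%d", i),
                  ncv = c("13" = 0, "18" = 0, "21" = 0,
                          "X" = x[i], "Y" = -2 * x[i] + 1))),
    lapply(1:3, function(i) make_sample(id = sprintf("F%d", i))))
  expect_warning(calib <- fit_sex_regression(samples, threshold_config()),
                 class = "nipt_degenerate_fit")
  expect_equal(calib$slope, -2, tolerance = 1e-9)
  expect_equal(calib$intercept, 1, tolerance = 1e-9)
  expect_equal(calib$resid_sd, 1e-6)
  # the band collapses onto the line
  b <- band_bounds(calib, threshold_config(), -10)
  expect_equal(b$high - b$low, 6e-6)
})

test_that("too few samples on either side is a typed error naming the subset", {
  males <- lapply(1:2, function(i)
    make_sample(id = sprintf("M%d", i),
                ncv = c("13" = 0, "18" = 0, "21" = 0, "X" = -5, "Y" = 8)))
  females <- lapply(1:5, function(i) make_sample(id = sprintf("F%d", i)))
  err <- expect_error(fit_sex_regression(c(males, females), threshold_config()),
                      class = "nipt_insufficient_calibration")
  expect_match(conditionMessage(err), "male")
  err <- expect_error(fit_sex_regression(c(males, males, males[1]),
                                         threshold_config()),
                      class = "nipt_insufficient_calibration")
  expect_match(conditionMessage(err), "female")
})

test_that("band arithmetic and constant width", {
  calib <- toy_calibration(slope = -1.5, intercept = 0, resid_sd = 2)
  cfg <- threshold_config(band_sd_mult = 3)
  b <- band_bounds(calib, cfg, -4)          # center 6, half-width 6
  expect_equal(b$low, 0); expect_equal(b$high, 12)
  # constant width 2 * mult * resid_sd at every NCV_X
  xs <- seq(-30, 5, by = 2.5)
  bb <- band_bounds(calib, cfg, xs)
  expect_equal(bb$high - bb$low, rep(2 * 3 * 2, length(xs)))
  # zero multiplier collapses the band to the center line
  b0 <- band_bounds(calib, threshold_config(band_sd_mult = 0), -4)
  expect_equal(b0$low, b0$high)
  expect_equal(b0$low, b0$center)
})

test_that("estimates are unbiased over replicates (property)", {
  set.seed(202)
  n_rep <- 30
  slopes <- sds <- numeric(n_rep)
  for (i in seq_len(n_rep)) {
    samples <- simulate_calibration_samples(n_male = 200)
    calib <- fit_sex_regression(samples, threshold_config())
    slopes[i] <- calib$slope; sds[i] <- calib$resid_sd
  }
  expect_lt(abs(mean(slopes) - (-1.5)), 0.02)
  expect_lt(abs(mean(sds) - 1.0), 0.1)  # resid_sd within 10% of truth at n=200
})

test_that("gross sex-aneuploid outliers do not blow up the calibration", {
  set.seed(303)
  samples <- simulate_calibration_samples(n_male = 40, n_female = 40)
  # contaminate: an XXY-like point (x ~ 0, male-level y) and an X0-like female
  contam <- list(
    make_sample(id = "XXY", ncv = c("13" = 0, "18" = 0, "21" = 0, "X" = 0, "Y" = 15)),
    make_sample(id = "X0", ncv = c("13" = 0, "18" = 0, "21" = 0, "X" = -10, "Y" = 0)))
  calib <- fit_sex_regression(c(samples, contam), threshold_config())
  expect_lt(calib$resid_sd, 1.5)       # outlier trimmed from the male fit
  expect_lt(calib$female_x_sd, 1.5)    # X0 trimmed from the female cluster
})
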