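cfg <- threshold_config()

test_that("autosomal decision rule matches the printed thresholds", {
  expect_equal(classify_autosome(5.0, 0.03, cfg), "aneuploidy_flag")
  expect_equal(classify_autosome(3.5, 0.05, cfg), "inconclusive")
  expect_equal(classify_autosome(10.0, 0.015, cfg), "no_call_low_ff")
  expect_equal(classify_autosome(0.0, 0.10, cfg), "normal")
  # closed gray interval: both edges are inconclusive
  expect_equal(classify_autosome(3.0, 0.10, cfg), "inconclusive")
  expect_equal(classify_autosome(4.0, 0.10, cfg), "inconclusive")
  expect_equal(classify_autosome(4.0 + 1e-9, 0.10, cfg), "aneuploidy_flag")
  expect_equal(classify_autosome(3.0 - 1e-9, 0.10, cfg), "normal")
  # FF boundary: exactly the minimum is callable
  expect_equal(classify_autosome(5.0, 0.02, cfg), "aneuploidy_flag")
  expect_equal(classify_autosome(5.0, 0.02 - 1e-9, cfg), "no_call_low_ff")
  # NaN is inconclusive, and deeply negative values are NOT auto-called
  expect_equal(classify_autosome(NaN, 0.10, cfg), "inconclusive")
  expect_equal(classify_autosome(-12, 0.10, cfg), "normal")
})

test_that("severity is monotone in NCV at fixed adequate FF (property)", {
  severity <- c(normal = 1, inconclusive = 2, aneuploidy_flag = 3)
  ncvs <- sort(c(seq(-6, 8, by = 0.25), 3, 4))
  calls <- classify_autosome(ncvs, 0.05, cfg)
  expect_true(all(diff(severity[calls]) >= 0))
  # low FF always wins, whatever the NCV
  expect_true(all(classify_autosome(ncvs, 0.01, cfg) == "no_call_low_ff"))
})

test_that("sex assessment separates band members from SCA geometries", {
  calib <- toy_calibration(slope = -1.5, intercept = 0, resid_sd = 1,
                           female_x_mean = 0, female_x_sd = 1)
  # male-line point inside the +/-3 SD band
  expect_equal(assess_sex(-6, 9.5, 0.1, calib, cfg), "xy_consistent")
  expect_equal(assess_sex(-6, 9 + 3 - 1e-9, 0.1, calib, cfg), "xy_consistent")
  # off the male line (XXY-like: NCV_X ~ 0, elevated NCV_Y)
  expect_equal(assess_sex(0, 9, 0.1, calib, cfg), "sca_flag")
  # X-depleted with no Y signal (45,X-like)
  expect_equal(assess_sex(-8, 0, 0.1, calib, cfg), "sca_flag")
  # X-enriched female (47,XXX-like)
  expect_equal(assess_sex(8, 0, 0.1, calib, cfg), "sca_flag")
  # ordinary female at the baseline
  expect_equal(assess_sex(0.5, -0.3, 0.1, calib, cfg), "xx_consistent")
  # low FF gives no call regardless of geometry
  expect_equal(assess_sex(-8, 0, 0.01, calib, cfg), "no_call_low_ff")
})

test_that("sample QC highlights NCD, coverage and FF breaches", {
  hist <- nominal_history(n = 30)

  # all nominal -> pass with no highlights
  qc <- qc_sample(make_sample(), hist, cfg)
  expect_equal(qc$qc_status, "pass")
  expect_equal(nrow(qc$highlights), 0L)

  # |NCD| over the limit -> warn with exactly one highlight naming the rule
  qc <- qc_sample(make_sample(ncd = c(A = 5.2, B = 0)), hist, cfg)
  expect_equal(qc$qc_status, "warn")
  expect_equal(nrow(qc$highlights), 1L)
  expect_equal(qc$highlights$field, "NCD_A")
  expect_equal(qc$highlights$rule, "ncd_limit")

  # coverage far from the historical cloud -> warn
  cov <- stats::setNames(rep(1, 24), c(as.character(1:22), "X", "Y"))
  cov[["21"]] <- 1.08  # ~8 SDs above the N(1, 0.01) history
  qc <- qc_sample(make_sample(coverage = cov), hist, cfg)
  expect_equal(qc$qc_status, "warn")
  expect_true("Cov_chr21" %in% qc$highlights$field)
  expect_true(all(qc$highlights$rule %in% c("coverage_z_limit")))

  # low FF -> fail, highlighted under ff_min
  qc <- qc_sample(make_sample(ff = 0.01), hist, cfg)
  expect_equal(qc$qc_status, "fail")
  expect_true("FF" %in% qc$highlights$field)
  expect_true("ff_min" %in% qc$highlights$rule)

  # empty history: coverage checks are skipped and noted
  qc <- qc_sample(make_sample(), empty_history(), cfg)
  expect_equal(qc$qc_status, "pass")
  expect_match(qc$findings, "insufficient historical data", all = FALSE)
})

test_that("run QC emits one finding per out-of-range or missing metric", {
  # all metrics present and in range
  b <- make_batch(run_qc = list(q30_pct = 96.2, cluster_density_k_mm2 = 180,
                                library_conc_nM = c(50, 100)))
  expect_length(qc_run(b, cfg), 0L)

  # density out of range -> exactly one finding
  b <- make_batch(run_qc = list(q30_pct = 96.2, cluster_density_k_mm2 = 300,
                                library_conc_nM = c(50)))
  f <- qc_run(b, cfg)
  expect_length(f, 1L)
  expect_match(f, "cluster_density")

  # Q30 at/below the minimum fails the "must exceed" rule
  b <- make_batch(run_qc = list(q30_pct = 95, cluster_density_k_mm2 = 180,
                                library_conc_nM = c(50)))
  expect_match(qc_run(b, cfg), "q30_pct", all = FALSE)

  # nothing measured -> every metric reported as not assessed
  f <- qc_run(make_batch(run_qc = list()), cfg)
  expect_length(f, 3L)
  expect_true(all(grepl("not assessed", f)))
})

test_that("interpret_run composes calls, sex, QC and highlights per sample", {
  calib <- toy_calibration()
  hist <- nominal_history(n = 30)
  samples <- list(
    make_sample(id = "NORM", ff = 0.10),
    make_sample(id = "T21", ff = 0.10,
                ncv = c("13" = 0.2, "18" = -0.5, "21" = 9, "X" = 0, "Y" = 0)),
    make_sample(id = "LOWFF", ff = 0.01,
                ncv = c("13" = 6, "18" = 0, "21" = 0, "X" = 0, "Y" = 0)),
    make_sample(id = "SCA", ff = 0.10,
                ncv = c("13" = 0, "18" = 0, "21" = 0, "X" = -9, "Y" = 0)))
  b <- make_batch(samples = samples,
                  run_qc = list(q30_pct = 97, cluster_density_k_mm2 = 200,
                                library_conc_nM = rep(100, 4)))
  interps <- interpret_run(b, hist, calib, cfg)
  expect_length(interps, 4L)
  byid <- stats::setNames(interps, vapply(interps, `[[`, character(1), "sample_id"))

  expect_true(all(byid$NORM$autosome_calls == "normal"))
  expect_equal(byid$NORM$qc_status, "pass")
  expect_equal(nrow(byid$NORM$highlights), 0L)

  expect_equal(unname(byid$T21$autosome_calls[["21"]]), "aneuploidy_flag")
  expect_true("NCV_21" %in% byid$T21$highlights$field)

  # low FF dominates: every chromosome no-call, QC fail
  expect_true(all(byid$LOWFF$autosome_calls == "no_call_low_ff"))
  expect_equal(byid$LOWFF$sex_assessment, "no_call_low_ff")
  expect_equal(byid$LOWFF$qc_status, "fail")
  # and its big NCV_13 is still highlighted for the reviewer
  expect_true("NCV_13" %in% byid$LOWFF$highlights$field)

  expect_equal(byid$SCA$sex_assessment, "sca_flag")
  expect_true(all(byid$SCA$autosome_calls == "normal"))

  # every highlight rule names a threshold_config field (invariant)
  rules <- unlist(lapply(interps, function(it) it$highlights$rule))
  expect_true(all(rules %in% names(unclass(cfg))))

  # determinism
  interps2 <- interpret_run(b, hist, calib, cfg)
  expect_identical(lapply(interps2, unclass), lapply(interps, unclass))

  # serializes one row per sample-chromosome call
  dir <- withr::local_tempdir()
  path <- file.path(dir, "results.csv")
  interpretations_to_csv(interps, path)
  df <- read.csv(path)
  expect_equal(nrow(df), 16L)  # 4 samples x (13, 18, 21, sex)
})

test_that("truth matching follows the recovery rules", {
  calib <- toy_calibration()
  b <- make_batch(samples = list(
    make_sample(id = "A", ncv = c("13" = 9, "18" = 0, "21" = 0, "X" = 0, "Y" = 0),
                ff = 0.1)))
  it <- interpret_run(b, empty_history(), calib, cfg)[[1]]
  expect_true(interpretation_matches_truth(it, "T13"))
  expect_false(interpretation_matches_truth(it, "T21"))
  expect_false(interpretation_matches_truth(it, "euploid_xx"))
  expect_error(interpretation_matches_truth(it, "T99"),
               class = "nipt_validation_error")
})
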