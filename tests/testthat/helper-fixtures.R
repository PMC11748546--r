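# Fixtures are built in code; no data files.

make_sample <- function(id = "S1", ncv = c("13" = 0, "18" = 0, "21" = 0,
                                           "X" = 0, "Y" = 0),
                        ff = 0.10, ncd = c(A = 0, B = 0),
                        coverage = NULL, barcode = "BC01",
                        sample_type = "singleton", vendor_qc = character()) {
  if (is.null(coverage))
    coverage <- stats::setNames(rep(1, 24), c(as.character(1:22), "X", "Y"))
  sample_record(sample_id = id, barcode = barcode, sample_type = sample_type,
                ncv = ncv, ncd = ncd, ff = ff, coverage = coverage,
                vendor_qc = vendor_qc)
}

make_batch <- function(n = 3, date = as.Date("2021-01-15"), runid = "runA",
                       run_qc = list(), ids = sprintf("S%02d", seq_len(n)),
                       samples = NULL) {
  if (is.null(samples))
    samples <- lapply(ids, function(i) make_sample(id = i))
  fname <- sprintf("%s_%s.csv", format(date, "%y%m%d"), runid)
  run_batch(run_id = tools::file_path_sans_ext(fname), run_date = date,
            samples = samples, run_qc = run_qc, source_filename = fname)
}

# randomized but valid batch for fuzz/round-trip testing (uses current RNG)
random_batch <- function(n = NULL, runid = "fuzz", date = as.Date("2021-03-01")) {
  if (is.null(n)) n <- sample(1:16, 1)
  samples <- lapply(seq_len(n), function(i) {
    make_sample(
      id = sprintf("FZ%03d", i),
      ncv = stats::setNames(round(stats::rnorm(5, 0, 5), 6),
                            c("13", "18", "21", "X", "Y")),
      ff = round(stats::runif(1, 0, 0.25), 6),
      ncd = stats::setNames(round(stats::rnorm(2), 6), c("A", "B")),
      coverage = stats::setNames(round(stats::runif(24, 0.5, 1.5), 6),
                                 c(as.character(1:22), "X", "Y")),
      barcode = sprintf("BC%02d", i),
      sample_type = sample(c("singleton", "control", "unknown"), 1),
      vendor_qc = c(FlowcellID = sprintf("FC%04d", sample.int(9999, 1))))
  })
  qc <- list(q30_pct = round(stats::runif(1, 90, 99), 3),
             cluster_density_k_mm2 = round(stats::runif(1, 120, 260), 2),
             library_conc_nM = round(stats::runif(n, 5, 260), 3))
  fname <- sprintf("%s_%s.csv", format(date, "%y%m%d"), runid)
  run_batch(run_id = tools::file_path_sans_ext(fname), run_date = date,
            samples = samples, run_qc = qc, source_filename = fname)
}

# calibration with simple round numbers for geometric oracle tests
toy_calibration <- function(slope = -1.5, intercept = 0, resid_sd = 1,
                            female_x_mean = 0, female_x_sd = 1) {
  samples_m <- lapply(1:5, function(i)
    make_sample(id = sprintf("M%d", i),
                ncv = c("13" = 0, "18" = 0, "21" = 0,
                        "X" = -i - 2, "Y" = slope * (-i - 2) + intercept)))
  calib <- suppressWarnings(fit_sex_regression(
    c(samples_m, lapply(1:5, function(i) make_sample(id = sprintf("F%d", i)))),
    threshold_config()))
  calib$slope <- slope; calib$intercept <- intercept; calib$resid_sd <- resid_sd
  calib$female_x_mean <- female_x_mean; calib$female_x_sd <- female_x_sd
  validate_sex_calibration(calib)
  calib
}

empty_history <- function() {
  structure(list(samples = list(), filter_spec = "empty"), class = "historical_set")
}

# history of n nominal samples (coverage ~ N(1, 0.01)) for coverage QC tests
nominal_history <- function(n = 30, seed = 99) {
  set.seed(seed)
  samples <- lapply(seq_len(n), function(i)
    list(record = make_sample(
           id = sprintf("H%03d", i),
           coverage = stats::setNames(stats::rnorm(24, 1, 0.01),
                                      c(as.character(1:22), "X", "Y"))),
         run_id = "hist", run_date = as.Date("2020-12-01")))
  structure(list(samples = samples, filter_spec = "synthetic history"),
            class = "historical_set")
}
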