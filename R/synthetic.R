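# Synthetic VeriSeq-style cohort generator with known truth labels.
#
# Generative model (NCVs are Z-score-like, so the euploid reference is
# standard normal):
#   euploid autosome:       NCV_c ~ N(0, 1)
#   trisomy of autosome c:  NCV_c ~ N((ff/2) / cv[c], 1)
#     -- a fetal trisomy adds half an extra chromosome dose weighted by the
#        fetal fraction; dividing by the assay's relative SD (cv) of the
#        chromosomal representation converts the shift to Z units.
#   XY fetus:   NCV_X ~ N(-(ff/2)/cv_X, 1),  NCV_Y ~ N(muY, 1)
#               with muY = (ff/2)/cv_X * |slope_true| (default slope -1.5),
#               so male samples trace the NCV_Y = slope_true * NCV_X line.
#   XX fetus:   NCV_X ~ N(0, 1), NCV_Y ~ N(0, 1) (female-referenced Y scale)
#   45,X (X0):  NCV_X as XY (depleted), NCV_Y at the female baseline
#   47,XXX:     NCV_X ~ N(+(ff/2)/cv_X, 1), NCV_Y female
#   47,XXY:     NCV_X ~ N(0, 1), NCV_Y at the male level muY
#   47,XYY:     NCV_Y ~ N(2 * muY, 1), NCV_X as XY
# Coverage: the affected autosome scaled by (1 + ff/2); X scaled by
# (1 -/+ ff/2) for X0/XXX; all other chromosomes ~ N(1, 0.01).
# NCDs ~ N(0, 1). Fully reproducible from the seed.

KARYOTYPE_CLASSES <- c("euploid_xx", "euploid_xy", "T13", "T18", "T21",
                       "X0", "XXX", "XXY", "XYY")
SCA_SUBTYPES <- c("X0", "XXX", "XXY", "XYY")

#' Specification of a synthetic cohort
#'
#' Defaults reproduce the clinical-verification design: 47 normal, 5 trisomy
#' 13, 13 trisomy 18, 16 trisomy 21 and 3 sex-chromosome-aneuploid samples
#' over six 14-sample runs, with at most three samples of the same trisomy
#' per run, and fetal fractions spanning 2-23%.
#'
#' @param n_normal,n_t13,n_t18,n_t21,n_sca Class counts (non-negative).
#' @param sca_mix SCA subtypes cycled over the `n_sca` samples.
#' @param n_runs Number of sequencing runs to spread the cohort over.
#' @param max_same_trisomy_per_run At most this many samples of one trisomy
#'   per run (default 3).
#' @param ff_range_euploid Fetal-fraction range for euploid samples
#'   (fractions; default `c(0.02, 0.23)`).
#' @param ff_range_aneuploid Fetal-fraction range for aneuploid samples;
#'   default `c(0.08, 0.23)`, a margin-safe range emulating confirmed
#'   aneuploidies with adequate fetal signal.
#' @param cv Relative SD of chromosomal representation per chromosome
#'   (controls how many Z units one chromosome dose is worth).
#' @param slope_true True male-line slope in the NCV(X)/NCV(Y) plane.
#' @param prob_male Probability a euploid or trisomic fetus is male.
#' @param seed RNG seed; the whole cohort is a pure function of the spec.
#' @param start_date First synthetic run date; runs fall on consecutive days.
#' @return An object of class `cohort_spec`.
#' @export
cohort_spec <- function(n_normal = 47L, n_t13 = 5L, n_t18 = 13L, n_t21 = 16L,
                        n_sca = 3L, sca_mix = SCA_SUBTYPES, n_runs = 6L,
                        max_same_trisomy_per_run = 3L,
                        ff_range_euploid = c(0.02, 0.23),
                        ff_range_aneuploid = c(0.08, 0.23),
                        cv = c("13" = 0.006, "18" = 0.005, "21" = 0.004, "X" = 0.004),
                        slope_true = -1.5, prob_male = 0.5,
                        seed = 20201101L,
                        start_date = as.Date("2020-11-02")) {
  spec <- structure(
    list(n_normal = as.integer(n_normal), n_t13 = as.integer(n_t13),
         n_t18 = as.integer(n_t18), n_t21 = as.integer(n_t21),
         n_sca = as.integer(n_sca), sca_mix = sca_mix,
         n_runs = as.integer(n_runs),
         max_same_trisomy_per_run = as.integer(max_same_trisomy_per_run),
         ff_range_euploid = as.numeric(ff_range_euploid),
         ff_range_aneuploid = as.numeric(ff_range_aneuploid),
         cv = cv, slope_true = slope_true, prob_male = prob_male,
         seed = as.integer(seed), start_date = as.Date(start_date)),
    class = "cohort_spec")
  counts <- c(spec$n_normal, spec$n_t13, spec$n_t18, spec$n_t21, spec$n_sca)
  if (any(counts < 0)) stop_validation("class counts must be >= 0")
  if (any(spec$ff_range_euploid < 0) || any(spec$ff_range_euploid > 1) ||
      any(spec$ff_range_aneuploid < 0) || any(spec$ff_range_aneuploid > 1))
    stop_validation("ff ranges must lie within [0, 1]")
  if (spec$max_same_trisomy_per_run < 1L)
    stop_validation("max_same_trisomy_per_run must be >= 1")
  if (!all(spec$sca_mix %in% SCA_SUBTYPES))
    stop_validation(sprintf("sca_mix must be drawn from {%s}",
                            paste(SCA_SUBTYPES, collapse = ", ")))
  spec
}

round_robin_assign <- function(n, n_runs, offset = 0L) {
  if (n == 0L) return(integer(0))
  ((seq_len(n) - 1L + offset) %% n_runs) + 1L
}

#' Simulate a cohort of runs with known truth labels
#'
#' Samples are assigned to runs round-robin per class (which bounds the
#' per-run count of each trisomy by `ceiling(n_class / n_runs)`), then
#' generated under the documented NCV/coverage model. Reproducible: the
#' same spec (including its seed) yields an identical cohort.
#'
#' @param spec A [cohort_spec()].
#' @return A list with `batches` (list of [run_batch()]) and `truth`
#'   (data frame with `sample_id`, `karyotype_class`, `ff_true`, `run_id`).
#' @export
simulate_cohort <- function(spec = cohort_spec()) {
  total <- spec$n_normal + spec$n_t13 + spec$n_t18 + spec$n_t21 + spec$n_sca
  if (total == 0L) {
    return(list(batches = list(),
                truth = data.frame(sample_id = character(0),
                                   karyotype_class = character(0),
                                   ff_true = numeric(0), run_id = character(0),
                                   stringsAsFactors = FALSE)))
  }
  if (total > MAX_SAMPLES_PER_RUN * spec$n_runs)
    stop_infeasible_design(sprintf("%d samples exceed capacity of %d runs x %d",
                                   total, spec$n_runs, MAX_SAMPLES_PER_RUN))
  for (cls in c("n_t13", "n_t18", "n_t21")) {
    need <- ceiling(spec[[cls]] / spec$n_runs)
    if (need > spec$max_same_trisomy_per_run)
      stop_infeasible_design(sprintf(
        "%s=%d cannot be spread over %d runs with at most %d of one trisomy per run",
        cls, spec[[cls]], spec$n_runs, spec$max_same_trisomy_per_run))
  }

  # class sequence and per-class round-robin run assignment
  classes <- c(rep("T13", spec$n_t13), rep("T18", spec$n_t18),
               rep("T21", spec$n_t21),
               rep_len(spec$sca_mix, spec$n_sca),
               rep("euploid", spec$n_normal))
  runs <- c(round_robin_assign(spec$n_t13, spec$n_runs),
            round_robin_assign(spec$n_t18, spec$n_runs),
            round_robin_assign(spec$n_t21, spec$n_runs),
            round_robin_assign(spec$n_sca, spec$n_runs),
            round_robin_assign(spec$n_normal, spec$n_runs))
  per_run <- tabulate(runs, nbins = spec$n_runs)
  if (any(per_run > MAX_SAMPLES_PER_RUN))
    stop_infeasible_design(sprintf("round-robin assignment overfills a run (max %d samples)",
                                   max(per_run)))

  set.seed(spec$seed)
  cv_x <- spec$cv[["X"]]
  runif_range <- function(r) stats::runif(1, r[1], r[2])

  gen_sample <- function(cls, sample_idx, pos_in_run) {
    is_tri <- cls %in% c("T13", "T18", "T21")
    ff <- if (cls == "euploid") runif_range(spec$ff_range_euploid)
          else runif_range(spec$ff_range_aneuploid)
    shift_x <- (ff / 2) / cv_x
    mu_y <- shift_x * abs(spec$slope_true)

    sex <- if (cls %in% c("X0", "XXX")) "female"
           else if (cls %in% c("XXY", "XYY")) "male"
           else if (stats::runif(1) < spec$prob_male) "male" else "female"

    ncv <- stats::setNames(stats::rnorm(5), NCV_CHROMS)
    if (is_tri) {
      ch <- sub("^T", "", cls)
      ncv[[ch]] <- stats::rnorm(1, (ff / 2) / spec$cv[[ch]], 1)
    }
    ncv[["X"]] <- switch(cls,
      X0 = stats::rnorm(1, -shift_x, 1),
      XXX = stats::rnorm(1, +shift_x, 1),
      XXY = stats::rnorm(1, 0, 1),
      XYY = stats::rnorm(1, -shift_x, 1),
      if (sex == "male") stats::rnorm(1, -shift_x, 1) else stats::rnorm(1, 0, 1))
    ncv[["Y"]] <- switch(cls,
      X0 = stats::rnorm(1, 0, 1),
      XXX = stats::rnorm(1, 0, 1),
      XXY = stats::rnorm(1, mu_y, 1),
      XYY = stats::rnorm(1, 2 * mu_y, 1),
      if (sex == "male") stats::rnorm(1, mu_y, 1) else stats::rnorm(1, 0, 1))

    coverage <- stats::setNames(stats::rnorm(24, 1, 0.01), COV_CHROMS)
    if (is_tri) {
      ch <- sub("^T", "", cls)
      coverage[[ch]] <- coverage[[ch]] * (1 + ff / 2)
    } else if (cls == "X0") {
      coverage[["X"]] <- coverage[["X"]] * (1 - ff / 2)
    } else if (cls == "XXX") {
      coverage[["X"]] <- coverage[["X"]] * (1 + ff / 2)
    }
    coverage[coverage < 0] <- 0

    karyo <- if (cls == "euploid") paste0("euploid_", if (sex == "male") "xy" else "xx")
             else cls
    rec <- sample_record(
      sample_id = sprintf("S%04d", sample_idx),
      barcode = sprintf("BC%02d", pos_in_run),
      sample_type = "singleton",
      ncv = ncv,
      ncd = stats::setNames(stats::rnorm(2), c("A", "B")),
      ff = ff,
      coverage = coverage)
    list(rec = rec, karyo = karyo, ff = ff)
  }

  batches <- list()
  truth <- list()
  sample_idx <- 0L
  for (r in seq_len(spec$n_runs)) {
    members <- which(runs == r)
    if (!length(members)) next  # small cohorts may not fill every run
    date <- spec$start_date + (r - 1L)
    fname <- sprintf("%s_sim_run%02d.csv", format(date, "%y%m%d"), r)
    run_id <- tools::file_path_sans_ext(fname)
    samples <- vector("list", length(members))
    for (j in seq_along(members)) {
      sample_idx <- sample_idx + 1L
      g <- gen_sample(classes[members[j]], sample_idx, j)
      samples[[j]] <- g$rec
      truth[[length(truth) + 1L]] <-
        data.frame(sample_id = g$rec$sample_id, karyotype_class = g$karyo,
                   ff_true = g$ff, run_id = run_id, stringsAsFactors = FALSE)
    }
    run_qc <- list(q30_pct = stats::runif(1, 95.5, 98.5),
                   cluster_density_k_mm2 = stats::runif(1, 150, 240),
                   library_conc_nM = stats::runif(length(members), 20, 200))
    batches[[length(batches) + 1L]] <- run_batch(run_id = run_id, run_date = date,
                                                 samples = samples, run_qc = run_qc,
                                                 source_filename = fname)
  }
  list(batches = batches, truth = do.call(rbind, truth))
}

#' Write a simulated cohort as canonical run CSVs
#'
#' @param batches List of [run_batch()]s (e.g. from [simulate_cohort()]).
#' @param dir Output directory (created if needed).
#' @return Character vector of written file paths, in run order.
#' @export
write_cohort <- function(batches, dir) {
  if (!dir.exists(dir) && !dir.create(dir, recursive = TRUE))
    stop_io(sprintf("cannot create directory '%s'", dir))
  vapply(batches, function(b) {
    path <- file.path(dir, b$source_filename)
    write_run_csv(b, path)
    path
  }, character(1))
}

#' Write truth labels as CSV
#' @param truth Truth data frame from [simulate_cohort()].
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_truth_csv <- function(truth, path) {
  utils::write.csv(truth, path, row.names = FALSE)
  invisible(path)
}
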