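# End-to-end verification replay: simulate -> write CSVs -> parse -> import
# -> calibrate -> interpret, then score interpretations against the
# generator's truth labels. This is the harness used by the acceptance tests
# and the acceptance report; it exercises every module through the same code
# paths a user would.

#' Replay the clinical-verification design end to end
#'
#' Simulates the verification cohort (by default 47 normal, 5 T13, 13 T18,
#' 16 T21, 3 SCA over six runs with margin-safe aneuploid fetal fractions),
#' writes the run CSVs, parses and imports them into a fresh store,
#' calibrates the sex-chromosome regression on all imported samples
#' (outlier-trimmed, see [fit_sex_regression()]), interprets each run against
#' the history formed by the other runs, and scores every interpretation
#' against its truth label.
#'
#' @param seed RNG seed for the cohort.
#' @param dir Working directory for CSVs and the store (default: fresh temp
#'   directory).
#' @param spec A [cohort_spec()]; defaults to the verification design with
#'   the given `seed`.
#' @param cfg A [threshold_config()].
#' @param user Audit user name.
#' @return A list: `n_total`, `n_match` (interpretations recovering their
#'   truth label), `n_consistent_normal` (samples normal on 13/18/21 with an
#'   unflagged sex assessment), `per_sample` (data frame joining truth and
#'   calls), `store`, `calib`, `cfg`.
#' @export
replay_verification <- function(seed = 20201101L,
                                dir = tempfile("nipt_replay_"),
                                spec = cohort_spec(seed = seed),
                                cfg = threshold_config(),
                                user = "verification") {
  sim <- simulate_cohort(spec)
  paths <- write_cohort(sim$batches, dir)
  store <- nipt_store_open(file.path(dir, "store.json"))
  for (p in paths) import_run(store, parse_run_csv(p), user)

  calib <- fit_sex_regression(get_history(store), cfg)
  store_calibration(store, calib, user)

  rows <- list()
  for (rid in list_runs(store)) {
    batch <- get_run(store, rid)
    history <- get_history(store, exclude_run = rid)
    interps <- interpret_run(batch, history, calib, cfg)
    store_interpretations(store, rid, interps, user)
    for (it in interps) {
      truth <- sim$truth[sim$truth$sample_id == it$sample_id, ]
      rows[[length(rows) + 1L]] <- data.frame(
        sample_id = it$sample_id,
        run_id = rid,
        karyotype_class = truth$karyotype_class,
        ff_true = truth$ff_true,
        call_13 = it$autosome_calls[["13"]],
        call_18 = it$autosome_calls[["18"]],
        call_21 = it$autosome_calls[["21"]],
        sex_assessment = it$sex_assessment,
        qc_status = it$qc_status,
        match = interpretation_matches_truth(it, truth$karyotype_class),
        stringsAsFactors = FALSE)
    }
  }
  per_sample <- do.call(rbind, rows)
  consistent_normal <-
    per_sample$call_13 == "normal" & per_sample$call_18 == "normal" &
    per_sample$call_21 == "normal" &
    per_sample$sex_assessment %in% c("xx_consistent", "xy_consistent")

  list(n_total = nrow(per_sample),
       n_match = sum(per_sample$match),
       n_consistent_normal = sum(consistent_normal),
       per_sample = per_sample,
       store = store, calib = calib, cfg = cfg)
}
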