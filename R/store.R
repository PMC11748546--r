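# Persistent run store with an append-only audit trail.
#
# The backing store is a single JSON file written atomically (temp file +
# rename) on every state-changing operation. JSON keeps the store inspectable
# and diffable; the access functions below form the storage contract, so a
# relational backend could be swapped in without touching callers. Every
# state-changing operation emits exactly one audit entry tagged with the
# acting user, in non-decreasing timestamp order.

AUDIT_ACTIONS <- c("import", "calibrate", "interpret", "report_export")

#' Open (or create) a run store
#'
#' @param path Path to the store file; created on first mutation if absent.
#' @return An object of class `nipt_store` (environment-backed handle).
#' @export
nipt_store_open <- function(path) {
  st <- new.env(parent = emptyenv())
  st$path <- path
  if (file.exists(path)) {
    raw <- jsonlite::fromJSON(path, simplifyVector = FALSE)
    st$runs <- raw$runs %||% list()
    st$audit <- raw$audit %||% list()
    st$calibration <- if (!is.null(raw$calibration)) calibration_from_list(raw$calibration)
  } else {
    st$runs <- list()
    st$audit <- list()
    st$calibration <- NULL
  }
  class(st) <- "nipt_store"
  st
}

`%||%` <- function(a, b) if (is.null(a)) b else a

store_save <- function(store) {
  state <- list(runs = store$runs, audit = store$audit,
                calibration = if (!is.null(store$calibration))
                  calibration_to_list(store$calibration))
  tmp <- paste0(store$path, ".tmp")
  jsonlite::write_json(state, tmp, auto_unbox = TRUE, digits = NA, null = "null")
  if (!file.rename(tmp, store$path))
    stop_io(sprintf("cannot write store file '%s'", store$path))
  invisible(store)
}

audit_append <- function(store, user, action, run_id = "") {
  stopifnot(action %in% AUDIT_ACTIONS)
  if (is.null(user) || is.na(user) || !nzchar(user))
    stop_validation("user must be non-empty for state-changing operations")
  now <- as.numeric(Sys.time())
  if (length(store$audit)) {
    last <- store$audit[[length(store$audit)]]$timestamp
    now <- max(now, last)  # monotone non-decreasing per store
  }
  store$audit[[length(store$audit) + 1L]] <-
    list(user = user, timestamp = now, action = action, run_id = run_id)
  invisible(store)
}

# -- run (de)serialization ----------------------------------------------------

batch_to_list <- function(batch) {
  list(run_id = batch$run_id,
       run_date = format(batch$run_date, "%Y-%m-%d"),
       source_filename = batch$source_filename,
       run_qc = batch$run_qc,
       samples = lapply(batch$samples, function(s)
         list(sample_id = s$sample_id, barcode = s$barcode,
              sample_type = s$sample_type,
              ncv = as.list(s$ncv), ncd = as.list(s$ncd), ff = s$ff,
              coverage = as.list(s$coverage),
              vendor_qc = as.list(s$vendor_qc))))
}

batch_from_list <- function(x) {
  samples <- lapply(x$samples, function(s) {
    vq <- unlist(s$vendor_qc) %||% character(0)
    if (is.null(vq)) vq <- character(0)
    sample_record(sample_id = s$sample_id, barcode = s$barcode,
                  sample_type = s$sample_type,
                  ncv = unlist(s$ncv)[NCV_CHROMS],
                  ncd = unlist(s$ncd),
                  ff = s$ff,
                  coverage = unlist(s$coverage)[COV_CHROMS],
                  vendor_qc = as.character(vq) |> stats::setNames(names(vq)))
  })
  qc <- x$run_qc %||% list()
  qc <- lapply(qc, function(v) as.numeric(unlist(v)))
  run_batch(run_id = x$run_id, run_date = as.Date(x$run_date),
            samples = samples, run_qc = qc,
            source_filename = x$source_filename)
}

interp_to_list <- function(it) {
  list(sample_id = it$sample_id,
       autosome_calls = as.list(it$autosome_calls),
       sex_assessment = it$sex_assessment,
       qc_status = it$qc_status,
       highlights = lapply(seq_len(nrow(it$highlights)), function(i)
         list(field = it$highlights$field[i], value = it$highlights$value[i],
              rule = it$highlights$rule[i])),
       run_qc_findings = as.list(it$run_qc_findings))
}

interp_from_list <- function(x) {
  hl <- x$highlights %||% list()
  highlights <- if (length(hl)) {
    data.frame(field = vapply(hl, `[[`, character(1), "field"),
               value = vapply(hl, function(h) as.numeric(h$value %||% NA_real_), numeric(1)),
               rule = vapply(hl, `[[`, character(1), "rule"),
               stringsAsFactors = FALSE)
  } else empty_highlights()
  new_interpretation(sample_id = x$sample_id,
                     autosome_calls = unlist(x$autosome_calls)[AUTOSOMES],
                     sex_assessment = x$sex_assessment,
                     qc_status = x$qc_status,
                     highlights = highlights,
                     run_qc_findings = as.character(unlist(x$run_qc_findings %||% list())))
}

# -- operations ---------------------------------------------------------------

#' Import a run into the store
#'
#' Persists the batch atomically and records one `import` audit entry tagged
#' with `user`. Importing a file whose `source_filename` is already stored
#' raises `nipt_duplicate_run` (no silent overwrite).
#'
#' @param store A [nipt_store_open()] handle.
#' @param batch A valid [run_batch()].
#' @param user Non-empty user name performing the import.
#' @return The stored `run_id`, invisibly.
#' @export
import_run <- function(store, batch, user) {
  validate_run_batch(batch)
  existing <- vapply(store$runs, function(r) r$batch$source_filename, character(1))
  if (batch$source_filename %in% existing) stop_duplicate_run(batch$source_filename)
  if (batch$run_id %in% names(store$runs)) stop_duplicate_run(batch$source_filename)
  store$runs[[batch$run_id]] <- list(batch = batch_to_list(batch),
                                     interpretations = NULL)
  audit_append(store, user, "import", batch$run_id)
  store_save(store)
  invisible(batch$run_id)
}

#' List stored run ids in import order
#' @param store A store handle.
#' @return Character vector of run ids.
#' @export
list_runs <- function(store) names(store$runs)

#' Fetch one stored run
#' @param store A store handle.
#' @param run_id A stored run id.
#' @return The [run_batch()].
#' @export
get_run <- function(store, run_id) {
  if (!run_id %in% names(store$runs))
    stop_validation(sprintf("run '%s' not in store", run_id))
  batch_from_list(store$runs[[run_id]]$batch)
}

#' Retrieve historical samples for plotting and calibration
#'
#' Returns all stored samples except those of `exclude_run` (the run under
#' review must never sit in its own reference cloud). With
#' `euploid_only = TRUE`, only samples whose stored interpretation is
#' `normal` on all of chromosomes 13/18/21 are returned; samples without a
#' stored interpretation are excluded.
#'
#' @param store A store handle.
#' @param exclude_run Run id to exclude, or `NULL`.
#' @param euploid_only Restrict to previously-interpreted euploid samples.
#' @return An object of class `historical_set`: `$samples` is a list of
#'   `list(record, run_id, run_date)`, `$filter_spec` describes the filter.
#' @export
get_history <- function(store, exclude_run = NULL, euploid_only = FALSE) {
  out <- list()
  for (rid in names(store$runs)) {
    if (!is.null(exclude_run) && rid == exclude_run) next
    entry <- store$runs[[rid]]
    batch <- batch_from_list(entry$batch)
    interps <- entry$interpretations
    for (i in seq_along(batch$samples)) {
      rec <- batch$samples[[i]]
      if (euploid_only) {
        if (is.null(interps)) next
        it <- interps[[rec$sample_id]]
        if (is.null(it)) next
        calls <- unlist(it$autosome_calls)
        if (!all(calls[AUTOSOMES] == "normal")) next
      }
      out[[length(out) + 1L]] <- list(record = rec, run_id = rid,
                                      run_date = batch$run_date)
    }
  }
  structure(list(samples = out,
                 filter_spec = sprintf("exclude_run=%s; euploid_only=%s",
                                       exclude_run %||% "<none>", euploid_only)),
            class = "historical_set")
}

#' @export
print.historical_set <- function(x, ...) {
  cat(sprintf("<historical_set> %d sample(s) [%s]\n", length(x$samples), x$filter_spec))
  invisible(x)
}

history_records <- function(history) lapply(history$samples, `[[`, "record")

#' Store per-sample interpretations for a run
#'
#' @param store A store handle.
#' @param run_id Stored run id the interpretations belong to.
#' @param interpretations List of interpretation objects (see
#'   [interpret_run()]).
#' @param user Acting user (audited, action `interpret`).
#' @return `store`, invisibly.
#' @export
store_interpretations <- function(store, run_id, interpretations, user) {
  if (!run_id %in% names(store$runs))
    stop_validation(sprintf("run '%s' not in store", run_id))
  keyed <- lapply(interpretations, interp_to_list)
  names(keyed) <- vapply(interpretations, `[[`, character(1), "sample_id")
  store$runs[[run_id]]$interpretations <- keyed
  audit_append(store, user, "interpret", run_id)
  store_save(store)
  invisible(store)
}

#' Fetch stored interpretations for a run (or NULL)
#' @param store A store handle.
#' @param run_id Stored run id.
#' @return Named list of interpretation objects, or `NULL`.
#' @export
get_interpretations <- function(store, run_id) {
  entry <- store$runs[[run_id]]
  if (is.null(entry) || is.null(entry$interpretations)) return(NULL)
  lapply(entry$interpretations, interp_from_list)
}

#' Store the active sex-chromosome calibration
#' @param store A store handle.
#' @param calib A `sex_calibration` (see [fit_sex_regression()]).
#' @param user Acting user (audited, action `calibrate`).
#' @return `store`, invisibly.
#' @export
store_calibration <- function(store, calib, user) {
  store$calibration <- calib
  audit_append(store, user, "calibrate", "")
  store_save(store)
  invisible(store)
}

#' Fetch the active calibration (or NULL)
#' @param store A store handle.
#' @return A `sex_calibration` or `NULL`.
#' @export
get_calibration <- function(store) store$calibration

#' Record a report export in the audit trail
#' @param store A store handle.
#' @param run_id Run the report covers.
#' @param user Acting user.
#' @return `store`, invisibly.
#' @export
record_report_export <- function(store, run_id, user) {
  audit_append(store, user, "report_export", run_id)
  store_save(store)
  invisible(store)
}

#' Read the complete audit trail
#'
#' The trail is append-only and chronologically ordered. The returned data
#' frame is a copy: mutating it cannot alter the store.
#'
#' @param store A store handle.
#' @return A `data.frame` with columns `user`, `timestamp` (POSIXct, UTC),
#'   `action`, `run_id`.
#' @export
audit_log <- function(store) {
  if (!length(store$audit)) {
    return(data.frame(user = character(0),
                      timestamp = as.POSIXct(numeric(0), origin = "1970-01-01", tz = "UTC"),
                      action = character(0), run_id = character(0),
                      stringsAsFactors = FALSE))
  }
  data.frame(
    user = vapply(store$audit, `[[`, character(1), "user"),
    timestamp = as.POSIXct(vapply(store$audit, function(e) as.numeric(e$timestamp), numeric(1)),
                           origin = "1970-01-01", tz = "UTC"),
    action = vapply(store$audit, `[[`, character(1), "action"),
    run_id = vapply(store$audit, function(e) as.character(e$run_id %||% ""), character(1)),
    stringsAsFactors = FALSE)
}

#' Export the audit trail as CSV
#' @param store A store handle.
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
export_audit_csv <- function(store, path) {
  log <- audit_log(store)
  log$timestamp <- format(log$timestamp, "%Y-%m-%dT%H:%M:%OS3Z")
  utils::write.csv(log, path, row.names = FALSE)
  invisible(path)
}

#' @export
print.nipt_store <- function(x, ...) {
  cat(sprintf("<nipt_store> %s: %d run(s), %d audit entr%s, calibration %s\n",
              x$path, length(x$runs), length(x$audit),
              if (length(x$audit) == 1) "y" else "ies",
              if (is.null(x$calibration)) "absent" else "present"))
  invisible(x)
}
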