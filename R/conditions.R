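# Typed condition constructors. Every domain failure raises a condition whose
# class identifies the violated contract, so callers (and the CLI) can map
# failures to exit codes without string matching.

nipt_stop <- function(class, message, ...) {
  stop(errorCondition(message, ..., class = c(class, "nipt_error")))
}

nipt_warn <- function(class, message, ...) {
  warning(warningCondition(message, ..., class = c(class, "nipt_warning")))
}

#' @noRd
stop_malformed_filename <- function(filename, why) {
  nipt_stop("nipt_malformed_filename",
            sprintf("filename '%s' does not carry a valid YYMMDD date prefix: %s",
                    filename, why),
            filename = filename)
}

stop_schema <- function(message, column = NULL) {
  nipt_stop("nipt_schema_error", message, column = column)
}

stop_value <- function(value, row, column) {
  nipt_stop("nipt_value_error",
            sprintf("non-numeric or invalid value '%s' at row %d, column '%s'",
                    value, row, column),
            row = row, column = column)
}

stop_duplicate_sample <- function(ids) {
  nipt_stop("nipt_duplicate_sample",
            sprintf("duplicate sample_id within run: %s",
                    paste(unique(ids), collapse = ", ")))
}

stop_empty_run <- function(path) {
  nipt_stop("nipt_empty_run", sprintf("run file '%s' contains 0 sample rows", path))
}

stop_duplicate_run <- function(source_filename) {
  nipt_stop("nipt_duplicate_run",
            sprintf("a run with source filename '%s' is already stored; refusing to overwrite",
                    source_filename))
}

stop_insufficient_calibration <- function(subset, n, need) {
  nipt_stop("nipt_insufficient_calibration",
            sprintf("insufficient calibration data: %s subset has %d samples, need >= %d",
                    subset, n, need),
            subset = subset)
}

stop_infeasible_design <- function(message) {
  nipt_stop("nipt_infeasible_design", message)
}

stop_missing_interpretation <- function(ids) {
  nipt_stop("nipt_missing_interpretation",
            sprintf("no interpretation supplied for sample(s): %s",
                    paste(ids, collapse = ", ")))
}

stop_io <- function(message) {
  nipt_stop("nipt_io_error", message)
}

stop_validation <- function(message) {
  nipt_stop("nipt_validation_error", message)
}
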