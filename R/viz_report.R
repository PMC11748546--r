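# Chart construction and report rendering.
#
# Charts are renderer-agnostic `chart_spec` data structures: current-run
# points drawn over the historical reference cloud, plus overlays carrying
# the active decision constants (threshold separator lines, the calibrated
# sex-chromosome regression line and its band). Reports are rendered from an
# HTML template (the testable surface) with a PDF sibling drawn through the
# standard graphics device; PDF bytes are toolchain-dependent and are never
# bit-compared.

new_chart_spec <- function(kind, title, current_points, history_points, overlays) {
  structure(list(kind = kind, title = title,
                 current_points = current_points,
                 history_points = history_points,
                 overlays = overlays),
            class = "chart_spec")
}

points_df <- function(x = numeric(0), y = numeric(0), sample_id = NULL) {
  df <- data.frame(x = x, y = y, stringsAsFactors = FALSE)
  if (!is.null(sample_id)) df$sample_id <- sample_id
  df
}

hline_overlay <- function(value, rule) {
  list(type = "hline", value = value, rule = rule)
}

line_overlay <- function(slope, intercept, rule) {
  list(type = "line", slope = slope, intercept = intercept, rule = rule)
}

#' Build chart data for a run over its history
#'
#' Produces, deterministically (points ordered by run sample order, history
#' by run then sample order):
#' * five `ncv_vs_ff` charts (chromosomes 13, 18, 21, X, Y) with FF percent
#'   on the x axis; the autosomal charts carry threshold lines at
#'   `ncv_gray_low` and `ncv_call`, the Y chart the `male_ncvY_min` line;
#' * one `ncvx_vs_ncvy` chart with the calibrated regression line and its
#'   +/- `band_sd_mult * resid_sd` band as overlays;
#' * one `coverage_profile` chart per sample (chromosome index 1..24 on x).
#'
#' @param batch A [run_batch()].
#' @param history A `historical_set` (may be empty).
#' @param calib A `sex_calibration`, or `NULL` to omit regression overlays.
#' @param cfg A [threshold_config()].
#' @return List of `chart_spec` objects.
#' @export
build_charts <- function(batch, history, calib = NULL, cfg = threshold_config()) {
  validate_run_batch(batch)
  recs <- batch$samples
  ids <- vapply(recs, `[[`, character(1), "sample_id")
  ff_pct <- vapply(recs, `[[`, numeric(1), "ff") * 100
  hrecs <- history_records(history)
  h_ff_pct <- vapply(hrecs, `[[`, numeric(1), "ff") * 100

  charts <- list()
  for (ch in NCV_CHROMS) {
    cur <- points_df(ff_pct, vapply(recs, function(s) s$ncv[[ch]], numeric(1)), ids)
    hist_pts <- points_df(h_ff_pct,
                          vapply(hrecs, function(s) s$ncv[[ch]], numeric(1)))
    overlays <- if (ch %in% AUTOSOMES) {
      list(hline_overlay(cfg$ncv_gray_low, "ncv_gray_low"),
           hline_overlay(cfg$ncv_call, "ncv_call"))
    } else if (ch == "Y") {
      list(hline_overlay(cfg$male_ncvY_min, "male_ncvY_min"))
    } else list()
    charts[[length(charts) + 1L]] <-
      new_chart_spec("ncv_vs_ff", sprintf("NCV chr%s vs fetal fraction", ch),
                     cur, hist_pts, overlays)
  }

  xy_overlays <- list()
  if (!is.null(calib)) {
    validate_sex_calibration(calib)
    half <- cfg$band_sd_mult * calib$resid_sd
    xy_overlays <- list(
      line_overlay(calib$slope, calib$intercept, "regression"),
      line_overlay(calib$slope, calib$intercept - half, "band_low"),
      line_overlay(calib$slope, calib$intercept + half, "band_high"))
  }
  charts[[length(charts) + 1L]] <- new_chart_spec(
    "ncvx_vs_ncvy", "NCV X vs NCV Y",
    points_df(vapply(recs, function(s) s$ncv[["X"]], numeric(1)),
              vapply(recs, function(s) s$ncv[["Y"]], numeric(1)), ids),
    points_df(vapply(hrecs, function(s) s$ncv[["X"]], numeric(1)),
              vapply(hrecs, function(s) s$ncv[["Y"]], numeric(1))),
    xy_overlays)

  hist_cov <- if (length(hrecs)) {
    points_df(rep(seq_along(COV_CHROMS), times = length(hrecs)),
              as.vector(vapply(hrecs, function(s) s$coverage[COV_CHROMS], numeric(24))))
  } else points_df()
  for (i in seq_along(recs)) {
    s <- recs[[i]]
    charts[[length(charts) + 1L]] <- new_chart_spec(
      "coverage_profile", sprintf("Coverage profile: %s", s$sample_id),
      points_df(seq_along(COV_CHROMS), unname(s$coverage[COV_CHROMS]),
                rep(s$sample_id, 24)),
      hist_cov, list())
  }
  charts
}

#' Export chart specs as JSON
#' @param charts List of `chart_spec`s from [build_charts()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
charts_to_json <- function(charts, path) {
  jsonlite::write_json(lapply(charts, unclass), path, auto_unbox = TRUE,
                       digits = NA, dataframe = "rows")
  invisible(path)
}

#' @export
print.chart_spec <- function(x, ...) {
  cat(sprintf("<chart_spec> %s '%s': %d current, %d history point(s), %d overlay(s)\n",
              x$kind, x$title, nrow(x$current_points), nrow(x$history_points),
              length(x$overlays)))
  invisible(x)
}

html_escape <- function(x) {
  x <- gsub("&", "&amp;", x, fixed = TRUE)
  x <- gsub("<", "&lt;", x, fixed = TRUE)
  gsub(">", "&gt;", x, fixed = TRUE)
}

report_html <- function(batch, interpretations, charts, kind, user, cfg, calib) {
  it_by_id <- stats::setNames(interpretations,
                              vapply(interpretations, `[[`, character(1), "sample_id"))
  out <- c(
    "<!DOCTYPE html>",
    "<html><head><meta charset='utf-8'>",
    sprintf("<title>%s %s</title>", html_escape(batch$run_id),
            if (kind == "qc_report") "QC report" else "NIPT report"),
    "<style>td.highlight{background:#c62828;color:#fff;} table{border-collapse:collapse;} td,th{border:1px solid #888;padding:2px 6px;}</style>",
    "</head><body>",
    sprintf("<h1>%s</h1>", if (kind == "qc_report") "NIPT QC report" else "NIPT report"),
    "<div class='meta'>",
    sprintf("<p>Run: <b>%s</b> (date %s, source file %s)</p>",
            html_escape(batch$run_id), format(batch$run_date),
            html_escape(batch$source_filename)),
    sprintf("<p>Exported by: %s</p>", html_escape(user)),
    sprintf("<p>Thresholds: flag NCV &gt; %g, inconclusive [%g, %g], FF minimum %g%%, band %g SD</p>",
            cfg$ncv_call, cfg$ncv_gray_low, cfg$ncv_call, cfg$ff_min * 100,
            cfg$band_sd_mult),
    if (!is.null(calib))
      sprintf("<p>Sex calibration: NCV_Y = %.4f * NCV_X + %.4f, residual SD %.4f (n=%d)</p>",
              calib$slope, calib$intercept, calib$resid_sd, calib$n_fit)
    else "<p>Sex calibration: none</p>",
    "<p>Machine flags guide review; interpretation remains with the laboratory.</p>",
    "</div>")

  out <- c(out, "<h2>Sample calls</h2>",
           "<table class='calls'><tr><th>Sample</th><th>FF %</th><th>chr13</th><th>chr18</th><th>chr21</th><th>Sex</th><th>QC</th></tr>")
  for (s in batch$samples) {
    it <- it_by_id[[s$sample_id]]
    out <- c(out, sprintf(
      "<tr class='sample-row'><td>%s</td><td>%.2f</td><td>%s</td><td>%s</td><td>%s</td><td>%s</td><td>%s</td></tr>",
      html_escape(s$sample_id), s$ff * 100,
      it$autosome_calls[["13"]], it$autosome_calls[["18"]],
      it$autosome_calls[["21"]], it$sex_assessment, it$qc_status))
  }
  out <- c(out, "</table>")

  out <- c(out, "<h2>Highlighted values</h2>",
           "<table class='highlights'><tr><th>Sample</th><th>Field</th><th>Value</th><th>Rule</th></tr>")
  for (it in interpretations) {
    hl <- it$highlights
    for (i in seq_len(nrow(hl))) {
      out <- c(out, sprintf(
        "<tr><td>%s</td><td>%s</td><td class='highlight'>%s</td><td>%s</td></tr>",
        html_escape(it$sample_id), html_escape(hl$field[i]),
        fmt_num(hl$value[i]), html_escape(hl$rule[i])))
    }
  }
  out <- c(out, "</table>")

  if (kind == "qc_report") {
    findings <- if (length(interpretations)) interpretations[[1]]$run_qc_findings
                else character(0)
    out <- c(out, "<h2>Run QC findings</h2>", "<ul class='run-qc'>")
    if (length(findings)) {
      out <- c(out, sprintf("<li>%s</li>", html_escape(findings)))
    } else {
      out <- c(out, "<li>all run metrics within range</li>")
    }
    out <- c(out, "</ul>")
  }

  out <- c(out, "<h2>Charts</h2>")
  for (chs in charts) {
    out <- c(out, sprintf(
      "<div class='chart' data-kind='%s' data-current='%d' data-history='%d' data-overlays='%d'>%s</div>",
      chs$kind, nrow(chs$current_points), nrow(chs$history_points),
      length(chs$overlays), html_escape(chs$title)))
  }
  c(out, "</body></html>")
}

plot_chart <- function(chs) {
  cur <- chs$current_points; hist_pts <- chs$history_points
  xs <- c(cur$x, hist_pts$x); ys <- c(cur$y, hist_pts$y)
  for (ov in chs$overlays) {
    if (ov$type == "hline") ys <- c(ys, ov$value)
  }
  if (!length(xs)) xs <- 0
  if (!length(ys)) ys <- 0
  graphics::plot(range(xs), range(ys), type = "n", main = chs$title,
                 xlab = switch(chs$kind, ncv_vs_ff = "FF (%)",
                               ncvx_vs_ncvy = "NCV X", "chromosome index"),
                 ylab = switch(chs$kind, coverage_profile = "normalized coverage", "NCV"))
  if (nrow(hist_pts))
    graphics::points(hist_pts$x, hist_pts$y, pch = 16, col = "grey70", cex = 0.6)
  if (nrow(cur))
    graphics::points(cur$x, cur$y, pch = 17, col = "firebrick", cex = 0.9)
  for (ov in chs$overlays) {
    if (ov$type == "hline") graphics::abline(h = ov$value, lty = 2, col = "steelblue")
    else if (ov$type == "line")
      graphics::abline(a = ov$intercept, b = ov$slope,
                       lty = if (ov$rule == "regression") 1 else 3, col = "steelblue")
  }
}

#' Render a clinical report (PDF plus HTML twin)
#'
#' Writes a PDF to `out` and an HTML twin next to it (same stem, `.html`).
#' The report contains the run metadata and date, a per-sample call table,
#' every highlighted value styled for review (exactly one styled cell per
#' highlight), all charts, the active thresholds and calibration, and the
#' exporting user; `qc_report` additionally carries the run QC findings.
#' When a store is supplied the export is recorded in the audit trail.
#'
#' @param batch A [run_batch()].
#' @param interpretations List of interpretations covering all samples of
#'   `batch` (else `nipt_missing_interpretation`).
#' @param charts List of `chart_spec`s from [build_charts()].
#' @param kind `"nipt_report"` or `"qc_report"`.
#' @param out Output PDF path.
#' @param user Exporting user (appears in the report and the audit trail).
#' @param cfg A [threshold_config()].
#' @param calib Optional `sex_calibration` echoed in the report header.
#' @param store Optional [nipt_store_open()] handle for audit recording.
#' @return Named list with paths `pdf` and `html`, invisibly.
#' @export
render_report <- function(batch, interpretations, charts,
                          kind = c("nipt_report", "qc_report"), out,
                          user = "unknown", cfg = threshold_config(),
                          calib = NULL, store = NULL) {
  kind <- match.arg(kind)
  validate_run_batch(batch)
  have <- vapply(interpretations, `[[`, character(1), "sample_id")
  need <- vapply(batch$samples, `[[`, character(1), "sample_id")
  if (length(setdiff(need, have))) stop_missing_interpretation(setdiff(need, have))

  html_path <- sub("\\.pdf$", ".html", out)
  if (identical(html_path, out)) html_path <- paste0(out, ".html")
  html <- report_html(batch, interpretations, charts, kind, user, cfg, calib)
  ok <- tryCatch({
    writeLines(html, html_path)
    TRUE
  }, error = function(e) FALSE, warning = function(w) FALSE)
  if (!ok) stop_io(sprintf("cannot write report to '%s'", html_path))

  grDevices::pdf(out, width = 8, height = 6, onefile = TRUE)
  on.exit(grDevices::dev.off(), add = TRUE)
  graphics::par(mar = c(4, 4, 3, 1))
  # title/table page
  graphics::plot.new()
  lines <- c(sprintf("%s - run %s (%s)",
                     if (kind == "qc_report") "NIPT QC report" else "NIPT report",
                     batch$run_id, format(batch$run_date)),
             sprintf("exported by %s", user), "",
             sprintf("%-12s %6s %-16s %-16s %-16s %-14s %s",
                     "sample", "FF%", "chr13", "chr18", "chr21", "sex", "QC"))
  for (s in batch$samples) {
    it <- interpretations[[match(s$sample_id, have)]]
    lines <- c(lines, sprintf("%-12s %6.2f %-16s %-16s %-16s %-14s %s",
                              s$sample_id, s$ff * 100,
                              it$autosome_calls[["13"]], it$autosome_calls[["18"]],
                              it$autosome_calls[["21"]], it$sex_assessment,
                              it$qc_status))
  }
  if (kind == "qc_report" && length(interpretations))
    lines <- c(lines, "", "Run QC findings:",
               if (length(interpretations[[1]]$run_qc_findings))
                 paste(" -", interpretations[[1]]$run_qc_findings)
               else " - all run metrics within range")
  graphics::text(0, seq(1, by = -0.04, length.out = length(lines)),
                 lines, adj = c(0, 1), cex = 0.55, family = "mono")
  for (chs in charts) plot_chart(chs)

  if (!is.null(store)) record_report_export(store, batch$run_id, user)
  invisible(list(pdf = out, html = html_path))
}
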