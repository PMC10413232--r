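#' @title Signal-confidence quality control
#' @description Quality report for one stream/window: input, retained and
#'   confidence-dropped sample counts, gap count, and the fraction of a
#'   target window covered by valid seconds.
#' @param n_input,n_valid,n_dropped_conf,n_gaps counts.
#' @param coverage fraction in `[0, 1]`, `NA` when no window was assessed.
#' @param window the assessed half-open window `c(a, b)`, or `NULL`.
#' @param usable logical flag (coverage at or above the required minimum).
#' @return object of class `qc_report`.
#' @export
qc_report <- function(n_input, n_valid, n_dropped_conf, n_gaps = 0L,
                      coverage = NA_real_, window = NULL, usable = NA) {
  stopifnot(n_valid + n_dropped_conf <= n_input,
            is.na(coverage) || (coverage >= 0 && coverage <= 1))
  structure(list(n_input = as.integer(n_input),
                 n_valid = as.integer(n_valid),
                 n_dropped_conf = as.integer(n_dropped_conf),
                 n_gaps = as.integer(n_gaps),
                 coverage = coverage, window = window, usable = usable),
            class = "qc_report")
}

#' @export
print.qc_report <- function(x, ...) {
  cat(sprintf("n_input: %d\n", x$n_input))
  cat(sprintf("n_valid: %d\n", x$n_valid))
  cat(sprintf("n_dropped_conf: %d\n", x$n_dropped_conf))
  cat(sprintf("n_gaps: %d\n", x$n_gaps))
  if (!is.na(x$coverage)) {
    cat(sprintf("window: [%g, %g)\n", x$window[1], x$window[2]))
    cat(sprintf("coverage: %.4f\n", x$coverage))
    cat("usable:", x$usable, "\n")
  }
  invisible(x)
}

#' Serialize a QC report to JSON
#' @param report a [qc_report()].
#' @return a JSON string.
#' @export
qc_report_json <- function(report) {
  stopifnot(inherits(report, "qc_report"))
  jsonlite::toJSON(unclass(report), auto_unbox = TRUE, digits = NA,
                   null = "null")
}

#' Apply the signal-confidence exclusion rule
#'
#' Drops every second whose HR confidence or system confidence is strictly
#' below the threshold (default 20%, the device vendor's reliability floor):
#' such readings are unstable and are removed rather than interpolated, so
#' downstream window means are taken over valid seconds only. Samples at
#' exactly the threshold are kept. Sample order is preserved, and the report
#' reconciles: every input sample is either retained or counted as dropped.
#'
#' @param stream a [sensor_stream()].
#' @param threshold confidence threshold in percent (0-100).
#' @return list with elements `stream` (the filtered [sensor_stream()]) and
#'   `report` (a [qc_report()]; `n_gaps` counts missing-second gaps in the
#'   filtered stream).
#' @examples
#' s <- sensor_stream(data.frame(t = 0:4, hr = 80, activity = 0.02,
#'                               hr_conf = c(100, 15, 100, 100, 19.9),
#'                               sys_conf = 100))
#' quality_filter(s)$report
#' @export
quality_filter <- function(stream, threshold = 20) {
  stopifnot(inherits(stream, "sensor_stream"))
  if (!is.numeric(threshold) || length(threshold) != 1 ||
      is.na(threshold) || threshold < 0 || threshold > 100)
    stop("confidence threshold must be a single value in [0, 100]")
  s <- stream$samples
  ok <- !is.na(s$hr) & s$hr_conf >= threshold & s$sys_conf >= threshold
  out <- sensor_stream(s[ok, , drop = FALSE], stream$participant_id)
  gaps <- if (n_samples(out) > 1) sum(diff(out$samples$t) > 1) else 0L
  list(stream = out,
       report = qc_report(n_input = nrow(s), n_valid = sum(ok),
                          n_dropped_conf = sum(!ok), n_gaps = gaps))
}

#' Window coverage check
#'
#' Fraction of a half-open analysis window `[a, b)` covered by valid seconds
#' of a (quality-filtered) stream. Seconds missing from the stream --
#' including any part of the window beyond the end of the recording -- count
#' as invalid, so the denominator is always `b - a`. Participants whose
#' required analysis windows fall below `min_coverage` are flagged unusable;
#' this is the participant-level exclusion rule applied by [run_process()].
#'
#' @param stream a [sensor_stream()] (apply [quality_filter()] first).
#' @param window numeric `c(a, b)`, half-open `[a, b)` in elapsed seconds.
#' @param min_coverage minimum acceptable coverage fraction.
#' @return a [qc_report()] with `coverage` and `usable` populated.
#' @export
coverage_check <- function(stream, window, min_coverage = 0.8) {
  stopifnot(inherits(stream, "sensor_stream"))
  if (length(window) != 2 || anyNA(window) || window[2] <= window[1])
    stop("window must be a non-empty half-open interval c(a, b) with b > a")
  s <- stream$samples
  inside <- s$t >= window[1] & s$t < window[2]
  cov <- sum(inside) / (window[2] - window[1])
  gaps <- if (sum(inside) > 1) sum(diff(s$t[inside]) > 1) else 0L
  qc_report(n_input = nrow(s), n_valid = sum(inside),
            n_dropped_conf = 0L, n_gaps = gaps,
            coverage = cov, window = window,
            usable = cov >= min_coverage)
}
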