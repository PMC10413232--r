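#' Activity from triaxial acceleration
#'
#' The activity channel is the vector magnitude of the accelerometer's
#' three axes, `sqrt(ax^2 + ay^2 + az^2)`, in g-units (the device's VMU
#' convention). Vectorized over its arguments.
#'
#' @param ax,ay,az per-axis acceleration, g.
#' @return activity in g-units.
#' @examples
#' accel_to_activity(0.6, 0.8, 0)  # 1
#' @export
accel_to_activity <- function(ax, ay, az) {
  stopifnot(is.finite(ax), is.finite(ay), is.finite(az))
  sqrt(ax^2 + ay^2 + az^2)
}

#' Per-second cardiac force index
#'
#' `CFI = weight x activity / HR`, in kg x G/bpm: the instantaneous
#' mechanical load the heart is moving per beat. Vectorized.
#'
#' @param weight body weight, kg (> 0).
#' @param activity activity level, g-units (>= 0).
#' @param hr heart rate, bpm (> 0; invalid seconds must be filtered
#'   upstream, see [quality_filter()]).
#' @return CFI in kg x G/bpm.
#' @examples
#' cfi_per_second(70, 0.2, 100)  # 0.14
#' @export
cfi_per_second <- function(weight, activity, hr) {
  if (any(!is.finite(weight) | weight <= 0))
    stop("weight must be positive")
  if (any(!is.finite(hr) | hr <= 0))
    stop("heart rate must be positive; filter invalid samples first")
  if (any(!is.finite(activity) | activity < 0))
    stop("activity must be non-negative")
  weight * activity / hr
}

#' Per-second CFI series for a stream
#'
#' Computes the cardiac force index for every valid second of a stream.
#' Seconds without a usable heart rate are omitted (the series is defined
#' only where HR > 0).
#'
#' @param stream a (quality-filtered) [sensor_stream()].
#' @param weight body weight, kg.
#' @return data frame with columns `t` (s) and `cfi` (kg x G/bpm).
#' @export
cfi_series <- function(stream, weight) {
  stopifnot(inherits(stream, "sensor_stream"), weight > 0)
  s <- stream$samples
  ok <- !is.na(s$hr) & s$hr > 0
  data.frame(t = s$t[ok],
             cfi = cfi_per_second(weight, s$activity[ok], s$hr[ok]))
}

#' Windowed mean CFI
#'
#' Arithmetic mean of the per-second CFI over the valid seconds inside a
#' half-open window `[a, b)`. The denominator is the number of valid
#' seconds actually present, not the nominal window length, which keeps the
#' mean unbiased under dropped samples.
#'
#' @param series a [cfi_series()] data frame.
#' @param window numeric `c(a, b)`.
#' @return the window mean (kg x G/bpm) with attribute `n_valid`, the
#'   number of seconds averaged.
#' @export
window_mean_cfi <- function(series, window) {
  stopifnot(is.data.frame(series), all(c("t", "cfi") %in% names(series)))
  if (length(window) != 2 || window[2] <= window[1])
    stop("window must be a half-open interval c(a, b) with b > a")
  inside <- series$t >= window[1] & series$t < window[2]
  if (!any(inside))
    stop("empty window: no valid seconds in [", window[1], ", ",
         window[2], ")")
  structure(mean(series$cfi[inside]), n_valid = sum(inside))
}

#' Per-participant CFI summary
#'
#' Reduces one ground-phase session to the three cardiac force statistics:
#' RCFI (mean CFI over the 2-minute rest window), WCFI (mean CFI over the
#' 2-minute walk window) and their ratio CFR = WCFI / RCFI.
#'
#' @param stream a quality-filtered [sensor_stream()].
#' @param annotation a [segment_phases()] result.
#' @param weight body weight, kg.
#' @param id participant label; defaults to the stream's.
#' @return one-row data frame: `id`, `rcfi`, `wcfi`, `cfr`, `n_rest_s`,
#'   `n_walk_s`.
#' @export
summarize_participant <- function(stream, annotation, weight, id = NULL) {
  stopifnot(inherits(stream, "sensor_stream"),
            inherits(annotation, "phase_annotation"))
  if (is.null(id)) id <- stream$participant_id
  series <- cfi_series(stream, weight)
  rcfi <- tryCatch(window_mean_cfi(series, annotation$rest),
                   error = function(e) stop("rest phase: ",
                                            conditionMessage(e)))
  wcfi <- tryCatch(window_mean_cfi(series, annotation$walk),
                   error = function(e) stop("walk phase: ",
                                            conditionMessage(e)))
  data.frame(id = as.character(id),
             rcfi = as.numeric(rcfi), wcfi = as.numeric(wcfi),
             cfr = as.numeric(wcfi) / as.numeric(rcfi),
             n_rest_s = attr(rcfi, "n_valid"),
             n_walk_s = attr(wcfi, "n_valid"),
             stringsAsFactors = FALSE)
}

#' Write per-participant CFI summaries
#'
#' CSV with header `id,rcfi,wcfi,cfr,n_rest_s,n_walk_s`. Indices are
#' written with full precision; round for display instead
#' (3 significant figures is the reporting convention).
#'
#' @param summaries data frame of [summarize_participant()] rows.
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_cfi_summaries <- function(summaries, path) {
  utils::write.csv(summaries[c("id", "rcfi", "wcfi", "cfr",
                               "n_rest_s", "n_walk_s")],
                   path, row.names = FALSE, quote = FALSE)
  invisible(path)
}
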