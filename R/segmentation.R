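#' Protocol clock for the ground phase
#'
#' Nominal timing of the ground protocol: 5 minutes seated rest, a squat
#' bout, 3 minutes relaxed walking, a second squat bout. Used as the
#' fallback when squat markers cannot be detected in the activity channel.
#'
#' @param rest_end end of the nominal rest span (s).
#' @param walk_start start of the nominal walk span (s).
#' @param walk_duration nominal walk duration (s).
#' @return object of class `protocol_clock`.
#' @export
protocol_clock <- function(rest_end = 300, walk_start = 310,
                           walk_duration = 180) {
  stopifnot(rest_end >= 120, walk_start >= rest_end, walk_duration >= 120)
  structure(list(rest_end = rest_end, walk_start = walk_start,
                 walk_duration = walk_duration), class = "protocol_clock")
}

#' Detect squat markers in the activity channel
#'
#' The protocol brackets the walk with squat bouts, which show up as large
#' activity spikes against both the resting and the walking baseline. A
#' marker is a maximal run of at least `min_spike_s` consecutive seconds
#' whose activity exceeds `spike_factor` times the rolling-median activity
#' (window `median_window` s, robust to the rest-to-walk baseline shift and
#' to between-person activity scale). Runs are tolerant of up to 2 s of
#' missing/dropped samples, and runs closer together than `merge_gap` s are
#' merged into one marker (a squat bout briefly interrupted by signal
#' dropout is one bout, not two). Marker times are run midpoints.
#'
#' @param stream a quality-filtered [sensor_stream()].
#' @param spike_factor multiple of the rolling median that counts as a spike.
#' @param min_spike_s minimum spike run length in seconds.
#' @param median_window rolling median window length (odd, seconds).
#' @param merge_gap runs with midpoints closer than this merge (seconds).
#' @return numeric vector of marker times (possibly empty), with attribute
#'   `runs`: data frame of `start`/`end` (inclusive seconds) per merged run.
#' @export
detect_squat_markers <- function(stream, spike_factor = 3.0, min_spike_s = 3,
                                 median_window = 61, merge_gap = 60) {
  stopifnot(inherits(stream, "sensor_stream"), spike_factor > 0,
            min_spike_s >= 1)
  s <- stream$samples
  empty <- structure(numeric(0),
                     runs = data.frame(start = numeric(0), end = numeric(0)))
  if (nrow(s) < min_spike_s) {
    warning("stream shorter than min_spike_s; no markers detectable",
            call. = FALSE)
    return(empty)
  }
  k <- min(median_window, nrow(s))
  if (k %% 2 == 0) k <- k - 1
  base <- if (k >= 3) stats::runmed(s$activity, k, endrule = "median")
          else s$activity
  above <- s$activity > spike_factor * base

  # maximal runs of above-threshold samples, tolerating <= 2 s gaps
  runs <- list()
  i <- 1L
  n <- nrow(s)
  while (i <= n) {
    if (above[i]) {
      j <- i
      while (j < n && above[j + 1L] && (s$t[j + 1L] - s$t[j]) <= 3) j <- j + 1L
      if (s$t[j] - s$t[i] + 1 >= min_spike_s)
        runs[[length(runs) + 1L]] <- c(s$t[i], s$t[j])
      i <- j + 1L
    } else i <- i + 1L
  }
  if (!length(runs)) return(empty)
  runs <- do.call(rbind, runs)

  # merge runs belonging to one squat bout
  merged <- list(runs[1, ])
  if (nrow(runs) > 1) {
    for (r in 2:nrow(runs)) {
      last <- merged[[length(merged)]]
      if (runs[r, 1] - last[2] < merge_gap)
        merged[[length(merged)]] <- c(last[1], runs[r, 2])
      else merged[[length(merged) + 1L]] <- runs[r, ]
    }
  }
  merged <- do.call(rbind, merged)
  markers <- (merged[, 1] + merged[, 2]) / 2
  structure(markers,
            runs = data.frame(start = merged[, 1], end = merged[, 2]))
}

#' Locate the rest and walk analysis windows
#'
#' Places the two 2-minute averaging windows the cardiac force indices are
#' computed over. With two or more squat markers, the rest span is
#' everything before the first marker bout and the walk span lies between
#' the first and last bout: the rest window is the final 120 s of the rest
#' span (heart rate is most settled just before the first squat) and the
#' walk window is the central 120 s of the walk span (excludes gait
#' transients at either end), with the start second floored to keep windows
#' integer-aligned. With fewer than two markers the protocol clock is the
#' fallback: rest `[rest_end - 120, rest_end)` and the central 120 s of the
#' nominal walk. When marker run extents are available (the `runs`
#' attribute of [detect_squat_markers()]), spans are bounded by run edges so
#' no window can overlap a squat bout.
#'
#' @param stream a quality-filtered [sensor_stream()].
#' @param markers marker times from [detect_squat_markers()] (or numeric).
#' @param protocol a [protocol_clock()] fallback.
#' @param runs optional data frame of marker run `start`/`end` seconds;
#'   defaults to the `runs` attribute of `markers`.
#' @param onset_guard seconds subtracted before the first detected spike
#'   run when ending the rest window, absorbing a late-detected squat
#'   onset (thresholding can miss the first second or two of a bout, and a
#'   single leaked squat second would dominate a resting CFI mean).
#' @return object of class `phase_annotation`: list with `rest` and `walk`
#'   half-open windows `c(a, b)`, `markers`, and `mode`
#'   (`"markers"` or `"clock"`).
#' @examples
#' ann <- segment_phases(NULL, markers = c(310, 505))
#' ann$walk  # central 120 s of the 195 s inter-marker span
#' @export
segment_phases <- function(stream = NULL, markers = numeric(0),
                           protocol = protocol_clock(),
                           runs = attr(markers, "runs"),
                           onset_guard = 3) {
  stopifnot(inherits(protocol, "protocol_clock"))
  force(runs)  # default reads attr(markers, ...): resolve before stripping
  markers <- as.numeric(markers)

  if (length(markers) >= 2) {
    m1 <- markers[1]
    m2 <- markers[length(markers)]
    have_runs <- is.data.frame(runs) && nrow(runs) >= 2
    rest_end <- (if (have_runs) runs$start[1] else m1) - onset_guard
    walk_span <- if (have_runs) c(runs$end[1] + 1, runs$start[nrow(runs)])
                 else c(m1, m2)
    if (rest_end < 120)
      stop("segmentation error: rest span before the first squat marker ",
           "is shorter than 120 s")
    if (diff(walk_span) < 120)
      stop("segmentation error: inter-marker span (", diff(walk_span),
           " s) is too short to place a 120 s walk window")
    rest <- c(rest_end - 120, rest_end)
    wstart <- floor(walk_span[1] + (diff(walk_span) - 120) / 2)
    walk <- c(wstart, wstart + 120)
    mode <- "markers"
  } else {
    rest <- c(protocol$rest_end - 120, protocol$rest_end)
    wstart <- floor(protocol$walk_start + (protocol$walk_duration - 120) / 2)
    walk <- c(wstart, wstart + 120)
    mode <- "clock"
  }
  stopifnot(diff(rest) == 120, diff(walk) == 120, rest[2] <= walk[1])
  structure(list(rest = rest, walk = walk, markers = markers, mode = mode),
            class = "phase_annotation")
}

#' @export
print.phase_annotation <- function(x, ...) {
  cat(sprintf("<phase_annotation> rest [%g, %g)  walk [%g, %g)  mode: %s\n",
              x$rest[1], x$rest[2], x$walk[1], x$walk[2], x$mode))
  if (length(x$markers))
    cat("squat markers at:", paste(x$markers, collapse = ", "), "s\n")
  invisible(x)
}

#' Serialize a phase annotation to JSON
#' @param annotation a [segment_phases()] result.
#' @return a JSON string `{"rest":[a,b],"walk":[c,d],"markers":[...]}`.
#' @export
annotation_json <- function(annotation) {
  stopifnot(inherits(annotation, "phase_annotation"))
  jsonlite::toJSON(list(rest = annotation$rest, walk = annotation$walk,
                        markers = annotation$markers),
                   digits = NA)
}
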