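#' Sensor stream CSV dialect
#'
#' Describes the per-second "Summary" export dialect of the chest-strap
#' device: comma-separated, dot decimal, one row per second. Required columns
#' are matched case-insensitively by name; any extra columns the device adds
#' are ignored. Reading is permissive, writing is strict (fixed column order
#' and decimal places, see [write_stream()]).
#'
#' @param t,hr,activity,hr_conf,sys_conf column names for elapsed seconds,
#'   heart rate (bpm), activity (g, accelerometer vector magnitude), HR
#'   confidence (percent) and system confidence (percent).
#' @param timestamp name of an optional wall-clock column. When `t` is absent
#'   but `timestamp` present, elapsed seconds are derived from it (first
#'   sample is second 0).
#' @return An object of class `stream_dialect`.
#' @export
stream_dialect <- function(t = "t_s", hr = "hr_bpm", activity = "activity_g",
                           hr_conf = "hr_conf_pct", sys_conf = "sys_conf_pct",
                           timestamp = "timestamp") {
  structure(list(t = t, hr = hr, activity = activity, hr_conf = hr_conf,
                 sys_conf = sys_conf, timestamp = timestamp),
            class = "stream_dialect")
}

#' Construct a sensor stream
#'
#' A sensor stream is one participant's ordered 1 Hz session: per-second
#' heart rate (bpm), activity (g-units, triaxial-accelerometer vector
#' magnitude), and the device's HR/system confidence channels (percent).
#' Timestamps are elapsed whole seconds from session start; gaps (missing
#' seconds) are permitted. A device row with HR 0 at HR confidence 0 is the
#' vendor's "no reading" convention and is normalized to an invalid sample
#' (HR `NA`, confidence 0) so no downstream division by zero can occur.
#'
#' @param samples data frame with columns `t`, `hr`, `activity`, `hr_conf`,
#'   `sys_conf`.
#' @param participant_id opaque participant label.
#' @return An object of class `sensor_stream`: a list with `participant_id`
#'   and the validated `samples` data frame.
#' @examples
#' s <- sensor_stream(data.frame(t = 0:2, hr = 80, activity = 0.02,
#'                               hr_conf = 100, sys_conf = 100))
#' n_samples(s)
#' @export
sensor_stream <- function(samples, participant_id = "unknown") {
  stopifnot(is.data.frame(samples))
  need <- c("t", "hr", "activity", "hr_conf", "sys_conf")
  miss <- setdiff(need, names(samples))
  if (length(miss))
    stop("sensor stream is missing column(s): ", paste(miss, collapse = ", "))
  samples <- samples[need]
  for (nm in need) samples[[nm]] <- as.numeric(samples[[nm]])

  # vendor "no reading" rows -> invalid sample
  dead <- !is.na(samples$hr) & samples$hr <= 0
  samples$hr[dead] <- NA_real_
  samples$hr_conf[dead] <- 0

  if (nrow(samples)) {
    if (anyNA(samples$t) || any(samples$t < 0))
      stop("timestamps must be non-negative elapsed seconds")
    if (is.unsorted(samples$t, strictly = TRUE)) {
      bad <- which(diff(samples$t) <= 0)[1] + 1L
      stop("timestamps not strictly increasing at row ", bad)
    }
    with_hr <- !is.na(samples$hr)
    if (any(samples$hr[with_hr] <= 0 & samples$hr_conf[with_hr] > 0))
      stop("non-positive heart rate with positive confidence")
    if (any(samples$activity < 0, na.rm = TRUE))
      stop("activity must be non-negative")
    for (cc in c("hr_conf", "sys_conf"))
      if (any(samples[[cc]] < 0 | samples[[cc]] > 100, na.rm = TRUE))
        stop(cc, " outside [0, 100]")
  }
  rownames(samples) <- NULL
  structure(list(participant_id = as.character(participant_id),
                 samples = samples),
            class = "sensor_stream")
}

#' @export
print.sensor_stream <- function(x, ...) {
  s <- x$samples
  cat("<sensor_stream> participant", x$participant_id, "-",
      nrow(s), "samples")
  if (nrow(s)) {
    cat(sprintf(" spanning [%d, %d] s", as.integer(min(s$t)),
                as.integer(max(s$t))))
    gaps <- sum(diff(s$t) > 1)
    if (gaps) cat(",", gaps, "gap(s)")
  }
  cat("\n")
  invisible(x)
}

#' Number of samples in a stream
#' @param stream a [sensor_stream()].
#' @return integer sample count.
#' @export
n_samples <- function(stream) nrow(stream$samples)

.match_col <- function(header, name) {
  hit <- which(tolower(header) == tolower(name))
  if (length(hit)) hit[1] else NA_integer_
}

#' Read a 1 Hz sensor stream CSV
#'
#' Reads the per-second "Summary" dialect (see [stream_dialect()]).
#' Column matching is case-insensitive and extra columns are ignored.
#' Malformed rows (non-numeric fields, negative activity, confidence outside
#' 0-100) are rejected with row-indexed diagnostics rather than silently
#' dropped: `attr(result, "diagnostics")` is a data frame of `row`/`reason`
#' pairs and `rows read = samples returned + diagnostics emitted` always
#' holds. Non-monotone or duplicated timestamps are an ordering error (the
#' session clock is broken, not a single row).
#'
#' @param path CSV file path.
#' @param dialect a [stream_dialect()].
#' @param participant_id label for the stream; defaults to the file stem.
#' @return A [sensor_stream()] with a `diagnostics` attribute.
#' @export
read_stream <- function(path, dialect = stream_dialect(),
                        participant_id = NULL) {
  if (!file.exists(path)) stop("no such file: ", path)
  if (is.null(participant_id))
    participant_id <- sub("\\.[^.]*$", "", basename(path))
  raw <- utils::read.csv(path, check.names = FALSE,
                         colClasses = "character", strip.white = TRUE)
  header <- names(raw)

  cols <- c(t = .match_col(header, dialect$t),
            hr = .match_col(header, dialect$hr),
            activity = .match_col(header, dialect$activity),
            hr_conf = .match_col(header, dialect$hr_conf),
            sys_conf = .match_col(header, dialect$sys_conf))
  ts_col <- .match_col(header, dialect$timestamp)
  if (is.na(cols["t"]) && !is.na(ts_col)) {
    # wall-clock export: convert to elapsed seconds on read
    wall <- as.POSIXct(raw[[ts_col]], tz = "UTC")
    raw[[dialect$t]] <- as.numeric(wall) - as.numeric(wall[1])
    header <- names(raw)
    cols["t"] <- .match_col(header, dialect$t)
  }
  miss <- names(cols)[is.na(cols)]
  if (length(miss)) {
    want <- unlist(dialect[miss], use.names = FALSE)
    stop("stream file lacks required column(s): ",
         paste(want, collapse = ", "))
  }

  df <- data.frame(t = suppressWarnings(as.numeric(raw[[cols["t"]]])),
                   hr = suppressWarnings(as.numeric(raw[[cols["hr"]]])),
                   activity = suppressWarnings(as.numeric(raw[[cols["activity"]]])),
                   hr_conf = suppressWarnings(as.numeric(raw[[cols["hr_conf"]]])),
                   sys_conf = suppressWarnings(as.numeric(raw[[cols["sys_conf"]]])))

  reason <- rep(NA_character_, nrow(df))
  flag <- function(bad, why) reason[bad & is.na(reason)] <<- why
  flag(is.na(df$t) | df$t < 0, "missing or negative timestamp")
  flag(is.na(df$activity) | df$activity < 0, "missing or negative activity")
  flag(is.na(df$hr_conf) | df$hr_conf < 0 | df$hr_conf > 100,
       "HR confidence outside [0, 100]")
  flag(is.na(df$sys_conf) | df$sys_conf < 0 | df$sys_conf > 100,
       "system confidence outside [0, 100]")
  flag(is.na(df$hr), "non-numeric heart rate")
  flag(df$hr < 0, "negative heart rate")
  flag(!is.na(df$hr) & df$hr <= 0 & df$hr_conf > 0,
       "zero heart rate with positive confidence")

  keep <- is.na(reason)
  diagnostics <- data.frame(row = which(!keep),
                            reason = reason[!keep],
                            stringsAsFactors = FALSE)
  df <- df[keep, , drop = FALSE]

  if (nrow(df) && anyDuplicated(df$t)) {
    dup <- which(duplicated(df$t))[1]
    stop("duplicate timestamp ", df$t[dup], " s at row ",
         which(keep)[dup], ": ordering is ambiguous")
  }
  if (nrow(df) && is.unsorted(df$t, strictly = TRUE)) {
    bad <- which(diff(df$t) <= 0)[1] + 1L
    stop("timestamps not increasing at row ", which(keep)[bad])
  }

  stream <- sensor_stream(df, participant_id)
  attr(stream, "diagnostics") <- diagnostics
  if (nrow(diagnostics))
    warning(nrow(diagnostics), " malformed row(s) rejected while reading ",
            basename(path), call. = FALSE)
  stream
}

#' Write a sensor stream CSV
#'
#' Strict writer for the dialect read by [read_stream()]: header
#' `t_s,hr_bpm,activity_g,hr_conf_pct,sys_conf_pct`, timestamps as integers,
#' heart rate and confidences with 2 decimals, activity with 6 decimals.
#' Writing then reading a stream already at these precisions is the
#' identity; writing is idempotent (a re-written re-read file is bit-equal).
#'
#' @param stream a [sensor_stream()].
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_stream <- function(stream, path) {
  stopifnot(inherits(stream, "sensor_stream"))
  con <- tryCatch(file(path, "w"),
                  error = function(e) stop("cannot write to ", path))
  on.exit(close(con))
  writeLines("t_s,hr_bpm,activity_g,hr_conf_pct,sys_conf_pct", con)
  s <- stream$samples
  if (nrow(s)) {
    hr <- ifelse(is.na(s$hr), "0.00", sprintf("%.2f", s$hr))
    writeLines(paste(sprintf("%d", as.integer(round(s$t))), hr,
                     sprintf("%.6f", s$activity),
                     sprintf("%.2f", s$hr_conf),
                     sprintf("%.2f", s$sys_conf), sep = ","), con)
  }
  invisible(path)
}

.cohort_required <- c("id", "age_y", "gender", "height_cm", "weight_kg",
                      "smoker", "drinker", "exerciser", "sbp_mmhg",
                      "dbp_mmhg", "hr_rest_bpm")

.as_flag <- function(x) {
  if (is.logical(x)) return(x)
  if (is.numeric(x)) return(x != 0)
  tolower(trimws(as.character(x))) %in% c("1", "true", "yes", "y")
}

#' Read a participant covariate table
#'
#' Reads the cohort CSV (header `id,age_y,gender,height_cm,weight_kg,smoker,
#' drinker,exerciser,sbp_mmhg,dbp_mmhg,hr_rest_bpm,rgt_g,sgt_g`; the two
#' centrifuge outcome columns are optional for pre-training cohorts, and an
#' optional `bmi_kgm2` column is cross-checked). Row-level validation:
#' straining G tolerance above the 9 G training ceiling, or a relaxed
#' tolerance exceeding the straining tolerance, rejects the row (listed in
#' the `rejected` attribute with a warning, or an error under
#' `strict = TRUE`); a supplied BMI disagreeing with weight/(height/100)^2 by
#' more than 0.5 kg/m^2 only warns. BMI is (re)computed for every record.
#'
#' @param path CSV file path.
#' @param strict if `TRUE`, any invalid row is an error instead of a
#'   rejection.
#' @return data frame of validated participant records (one row each), with
#'   attribute `rejected` (data frame of `row`/`reason`).
#' @export
read_cohort <- function(path, strict = FALSE) {
  if (!file.exists(path)) stop("no such file: ", path)
  first <- readLines(path, n = 1L)
  if (!length(first) || !nzchar(first)) {
    warning("empty cohort file: ", basename(path), call. = FALSE)
    return(structure(data.frame(), rejected = data.frame(
      row = integer(), reason = character())))
  }
  raw <- utils::read.csv(path, check.names = FALSE, strip.white = TRUE)
  names(raw) <- tolower(names(raw))
  miss <- setdiff(.cohort_required, names(raw))
  if (length(miss))
    stop("cohort file lacks required column(s): ",
         paste(miss, collapse = ", "))
  if (!nrow(raw)) {
    warning("cohort file has a header but no records", call. = FALSE)
    return(structure(data.frame(), rejected = data.frame(
      row = integer(), reason = character())))
  }

  gender <- tolower(trimws(as.character(raw$gender)))
  gender[gender %in% c("w", "f", "female")] <- "woman"
  gender[gender %in% c("m", "male")] <- "man"

  df <- data.frame(
    id = as.character(raw$id),
    age = as.numeric(raw$age_y),
    gender = gender,
    height = as.numeric(raw$height_cm),
    weight = as.numeric(raw$weight_kg),
    smoker = .as_flag(raw$smoker),
    drinker = .as_flag(raw$drinker),
    exerciser = .as_flag(raw$exerciser),
    sbp = as.numeric(raw$sbp_mmhg),
    dbp = as.numeric(raw$dbp_mmhg),
    hr_rest = as.numeric(raw$hr_rest_bpm),
    stringsAsFactors = FALSE
  )
  df$rgt <- if ("rgt_g" %in% names(raw)) as.numeric(raw$rgt_g) else NA_real_
  df$sgt <- if ("sgt_g" %in% names(raw)) as.numeric(raw$sgt_g) else NA_real_
  df$bmi <- df$weight / (df$height / 100)^2

  reason <- rep(NA_character_, nrow(df))
  flag <- function(bad, why) {
    bad[is.na(bad)] <- FALSE
    reason[bad & is.na(reason)] <<- why
  }
  flag(!df$gender %in% c("woman", "man"), "unrecognized gender")
  flag(df$age <= 0 | df$height <= 0 | df$weight <= 0,
       "non-positive anthropometry")
  flag(df$sbp <= 0 | df$dbp <= 0 | df$hr_rest <= 0, "non-positive vitals")
  flag(df$dbp >= df$sbp, "diastolic not below systolic")
  flag(df$sgt > 9.0, "SGT exceeds the 9 G training ceiling")
  flag(df$rgt > df$sgt, "RGT exceeds SGT")

  if ("bmi_kgm2" %in% names(raw)) {
    given <- as.numeric(raw$bmi_kgm2)
    off <- which(!is.na(given) & abs(given - df$bmi) > 0.5)
    if (length(off))
      warning("BMI column disagrees with height/weight by > 0.5 kg/m^2 ",
              "in row(s) ", paste(off, collapse = ", "), call. = FALSE)
  }

  bad <- !is.na(reason)
  rejected <- data.frame(row = which(bad), reason = reason[bad],
                         stringsAsFactors = FALSE)
  if (nrow(rejected)) {
    msg <- paste0("row ", rejected$row, ": ", rejected$reason,
                  collapse = "; ")
    if (strict) stop("invalid cohort record(s) - ", msg)
    warning("rejected ", nrow(rejected), " cohort record(s) - ", msg,
            call. = FALSE)
  }
  out <- df[!bad, , drop = FALSE]
  rownames(out) <- NULL
  structure(out, rejected = rejected)
}

#' Write a participant covariate table
#'
#' Inverse of [read_cohort()]; columns are written in the documented cohort
#' schema order with full precision where quantities are continuous.
#'
#' @param cohort data frame as returned by [read_cohort()] or
#'   [simulate_cohort()] (`$cohort`).
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_cohort <- function(cohort, path) {
  out <- data.frame(
    id = cohort$id,
    age_y = sprintf("%.2f", cohort$age),
    gender = cohort$gender,
    height_cm = sprintf("%.2f", cohort$height),
    weight_kg = sprintf("%.2f", cohort$weight),
    smoker = as.integer(cohort$smoker),
    drinker = as.integer(cohort$drinker),
    exerciser = as.integer(cohort$exerciser),
    sbp_mmhg = sprintf("%.2f", cohort$sbp),
    dbp_mmhg = sprintf("%.2f", cohort$dbp),
    hr_rest_bpm = sprintf("%.2f", cohort$hr_rest)
  )
  if (!is.null(cohort$rgt)) out$rgt_g <- sprintf("%.2f", cohort$rgt)
  if (!is.null(cohort$sgt)) out$sgt_g <- sprintf("%.2f", cohort$sgt)
  utils::write.csv(out, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}
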