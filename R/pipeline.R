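.manifest_hash <- function(obj) {
  tmp <- tempfile(fileext = ".json")
  on.exit(unlink(tmp))
  jsonlite::write_json(obj, tmp, auto_unbox = TRUE, digits = 12,
                       force = TRUE)
  unname(tools::md5sum(tmp))
}

#' Process a directory (or list) of sensor streams into CFI summaries
#'
#' The per-participant measurement pipeline: confidence quality filter,
#' squat-marker detection with protocol-clock fallback, phase segmentation,
#' coverage check of both 2-minute windows, and CFI summarisation
#' (RCFI, WCFI, CFR). Participants whose rest or walk window coverage falls
#' below `min_coverage` -- or whose session cannot be segmented -- are
#' excluded and listed with a reason, mirroring the study practice of
#' dropping sessions with poor data quality.
#'
#' @param streams a directory of stream CSVs (`<id>.csv`), or a named list
#'   of [sensor_stream()] objects.
#' @param cohort cohort CSV path, or a data frame as from [read_cohort()] /
#'   [simulate_cohort()] (`$cohort`); must contain `id` and `weight`.
#' @param conf_threshold confidence threshold, percent.
#' @param min_coverage minimum window coverage fraction.
#' @param protocol a [protocol_clock()] fallback.
#' @param spike_factor squat-spike threshold for [detect_squat_markers()].
#' @return object of class `gtol_process`: list with `summaries` (data
#'   frame of [summarize_participant()] rows), `exclusions` (data frame
#'   `id`/`reason`), `qc` (named list of [qc_report()]s), and `manifest`
#'   (parameters, per-stage counts, and a reproducibility hash over inputs
#'   and outputs).
#' @export
run_process <- function(streams, cohort, conf_threshold = 20,
                        min_coverage = 0.8, protocol = protocol_clock(),
                        spike_factor = 3.0) {
  if (is.character(streams)) {
    if (!dir.exists(streams)) stop("no such stream directory: ", streams)
    paths <- list.files(streams, pattern = "\\.csv$", full.names = TRUE)
    streams <- lapply(paths, read_stream)
    names(streams) <- vapply(streams, function(s) s$participant_id,
                             character(1))
  }
  stopifnot(is.list(streams), length(streams) > 0)
  if (is.character(cohort)) cohort <- read_cohort(cohort)
  stopifnot(is.data.frame(cohort), all(c("id", "weight") %in% names(cohort)))

  summaries <- list()
  exclusions <- list()
  qc <- list()
  for (id in names(streams)) {
    wt <- cohort$weight[match(id, cohort$id)]
    if (is.na(wt)) {
      exclusions[[id]] <- "no cohort record (weight unknown)"
      next
    }
    filt <- quality_filter(streams[[id]], threshold = conf_threshold)
    qc[[id]] <- filt$report
    res <- tryCatch({
      markers <- suppressWarnings(
        detect_squat_markers(filt$stream, spike_factor = spike_factor))
      ann <- segment_phases(filt$stream, markers, protocol = protocol)
      cov_rest <- coverage_check(filt$stream, ann$rest, min_coverage)
      cov_walk <- coverage_check(filt$stream, ann$walk, min_coverage)
      if (!cov_rest$usable)
        stop(sprintf("rest window coverage %.2f below %.2f",
                     cov_rest$coverage, min_coverage))
      if (!cov_walk$usable)
        stop(sprintf("walk window coverage %.2f below %.2f",
                     cov_walk$coverage, min_coverage))
      summarize_participant(filt$stream, ann, weight = wt, id = id)
    }, error = function(e) conditionMessage(e))
    if (is.character(res)) exclusions[[id]] <- res
    else summaries[[id]] <- res
  }
  if (!length(summaries))
    stop("pipeline error: no usable participants")

  summaries <- do.call(rbind, c(summaries, make.row.names = FALSE))
  exclusions <- data.frame(id = names(exclusions),
                           reason = unlist(exclusions, use.names = FALSE),
                           stringsAsFactors = FALSE)
  params <- list(conf_threshold = conf_threshold,
                 min_coverage = min_coverage,
                 spike_factor = spike_factor,
                 protocol = unclass(protocol))
  manifest <- list(
    params = params,
    n_streams = length(streams),
    n_summarised = nrow(summaries),
    n_excluded = nrow(exclusions),
    hash = .manifest_hash(list(params = params, summaries = summaries,
                               exclusions = exclusions)),
    created = format(Sys.time(), tz = "UTC")
  )
  structure(list(summaries = summaries, exclusions = exclusions, qc = qc,
                 manifest = manifest),
            class = "gtol_process")
}

#' @export
print.gtol_process <- function(x, ...) {
  cat("<gtol_process>", x$manifest$n_streams, "stream(s):",
      x$manifest$n_summarised, "summarised,",
      x$manifest$n_excluded, "excluded\n")
  if (nrow(x$exclusions)) print(x$exclusions, row.names = FALSE)
  cat("manifest hash:", x$manifest$hash, "\n")
  invisible(x)
}

.default_candidates <- c("age", "gender_woman", "height", "weight", "bmi",
                         "smoker", "drinker", "exerciser", "sbp", "dbp",
                         "hr_rest", "wcfi100")

#' Analyze a merged cohort: correlations, models, histograms
#'
#' The study's statistical stage on a merged table of covariates, CFI
#' summaries and centrifuge outcomes: the 8-variable Pearson correlation
#' matrix (RGT, SGT, SBP, DBP, HR, RCFI, WCFI, CFR; two-tailed p-values,
#' alpha .05), stepwise linear models for RGT and SGT over the candidate
#' covariates (WCFI entering on the x100 scale), observed-vs-estimated
#' paired comparisons using in-sample predictions, and 0.5 G histograms of
#' both outcomes.
#'
#' @param summaries data frame of per-participant CFI summaries
#'   (`id`, `rcfi`, `wcfi`, `cfr`), e.g. `run_process(...)$summaries`;
#'   may be `NULL` when `cohort` already carries `rcfi`/`wcfi`/`cfr`
#'   columns (as a [simulate_cohort()] cohort does).
#' @param cohort cohort data frame or CSV path; must contain the outcomes
#'   `rgt` and `sgt`.
#' @param candidates candidate covariate columns offered to stepwise
#'   selection.
#' @param p_enter,p_remove stepwise thresholds.
#' @return object of class `gtol_analysis`: list with `data` (the merged
#'   analysis table), `correlations`, `rgt_fit`, `sgt_fit`, `rgt_check`,
#'   `sgt_check`, `rgt_hist`, `sgt_hist`.
#' @export
run_analyze <- function(summaries, cohort,
                        candidates = .default_candidates,
                        p_enter = 0.05, p_remove = 0.10) {
  if (is.character(cohort)) cohort <- read_cohort(cohort)
  stopifnot(is.data.frame(cohort))
  if (!is.null(summaries)) {
    keep <- setdiff(names(cohort), c("rcfi", "wcfi", "cfr"))
    d <- merge(cohort[keep], summaries[c("id", "rcfi", "wcfi", "cfr")],
               by = "id")
  } else d <- cohort
  for (col in c("rgt", "sgt"))
    if (!col %in% names(d))
      stop("analysis error: cohort lacks outcome column '", col, "'")
  for (col in c("rcfi", "wcfi", "cfr"))
    if (!col %in% names(d))
      stop("analysis error: merged table lacks CFI column '", col, "'")

  d$wcfi100 <- 100 * d$wcfi
  if ("gender" %in% names(d)) d$gender_woman <- d$gender == "woman"
  candidates <- intersect(candidates, names(d))

  corr <- correlation_matrix(
    d, c("rgt", "sgt", "sbp", "dbp", "hr_rest", "rcfi", "wcfi", "cfr"))

  design <- d[candidates]
  rgt_fit <- fit_stepwise(design, d$rgt, p_enter = p_enter,
                          p_remove = p_remove, response_name = "rgt")
  sgt_fit <- fit_stepwise(design, d$sgt, p_enter = p_enter,
                          p_remove = p_remove, response_name = "sgt")

  rgt_check <- compare_observed_estimated(d$rgt, fitted(rgt_fit))
  sgt_check <- compare_observed_estimated(d$sgt, fitted(sgt_fit))

  hist_origin <- function(v) min(3.0, floor(min(v) * 2) / 2)
  hist_ceiling <- function(v) max(9.0, ceiling(max(v) * 2) / 2)
  rgt_hist <- bin_gtolerance(d$rgt, origin = hist_origin(d$rgt),
                             ceiling = hist_ceiling(d$rgt))
  sgt_hist <- bin_gtolerance(d$sgt, origin = hist_origin(d$sgt),
                             ceiling = hist_ceiling(d$sgt))

  structure(list(data = d, correlations = corr,
                 rgt_fit = rgt_fit, sgt_fit = sgt_fit,
                 rgt_check = rgt_check, sgt_check = sgt_check,
                 rgt_hist = rgt_hist, sgt_hist = sgt_hist),
            class = "gtol_analysis")
}

#' @export
print.gtol_analysis <- function(x, ...) {
  cat("<gtol_analysis> n =", nrow(x$data), "\n\n")
  cat("RGT model: selected",
      if (length(x$rgt_fit$selected))
        paste(x$rgt_fit$selected, collapse = ", ") else "(none)", "\n")
  cat("SGT model: selected",
      if (length(x$sgt_fit$selected))
        paste(x$sgt_fit$selected, collapse = ", ") else "(none)", "\n\n")
  cat("Observed vs estimated:\n")
  print(x$rgt_check)
  print(x$sgt_check)
  invisible(x)
}
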