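.warn_range <- function(value, name, lo, hi) {
  out <- which(!is.na(value) & (value < lo | value > hi))
  if (length(out))
    warning(name, " outside the development-cohort range [", lo, ", ", hi,
            "] for ", length(out), " value(s); prediction extrapolates",
            call. = FALSE)
}

#' Predict relaxed G tolerance (RGT)
#'
#' The published linear equation
#' `RGT = 0.066 age + 0.043 (WCFI x 100) - 0.037 height + 0.015 SBP
#'  - 0.010 HR + 7.724` (G). WCFI is supplied on its natural scale
#' (kg x G/bpm) and rescaled to the x100 scale internally, exactly as the
#' model was estimated. Inputs outside the development-cohort ranges warn
#' (the model extrapolates) but are not rejected. Vectorized.
#'
#' @param age years.
#' @param wcfi walking cardiac force index, kg x G/bpm (natural scale).
#' @param height cm.
#' @param sbp systolic blood pressure, mm Hg.
#' @param hr resting heart rate, bpm.
#' @return predicted RGT in G.
#' @examples
#' predict_rgt(25.61, 0.141, 173.18, 140.40, 88.56)  # ~4.83 G
#' @export
predict_rgt <- function(age, wcfi, height, sbp, hr) {
  ref <- gtol_reference()
  cv <- ref$covariates
  .warn_range(age, "age", 16, 60)
  .warn_range(wcfi, "wcfi", cv["wcfi", "min"], cv["wcfi", "max"])
  .warn_range(height, "height", cv["height", "min"], cv["height", "max"])
  .warn_range(sbp, "sbp", cv["sbp", "min"], cv["sbp", "max"])
  .warn_range(hr, "hr", cv["hr_rest", "min"], cv["hr_rest", "max"])
  b <- stats::setNames(ref$rgt_model$beta, ref$rgt_model$term)
  b[["age"]] * age + b[["wcfi100"]] * (wcfi * 100) +
    b[["height"]] * height + b[["sbp"]] * sbp + b[["hr_rest"]] * hr +
    b[["(Intercept)"]]
}

#' Predict straining G tolerance (SGT)
#'
#' The published linear equation
#' `SGT = 0.103 (WCFI x 100) - 0.069 height + 0.018 SBP + 15.899` (G).
#' WCFI is supplied on its natural scale and rescaled internally.
#'
#' @inheritParams predict_rgt
#' @return predicted SGT in G.
#' @examples
#' predict_sgt(0.141, 173.18, 140.40)  # ~7.93 G
#' @export
predict_sgt <- function(wcfi, height, sbp) {
  ref <- gtol_reference()
  cv <- ref$covariates
  .warn_range(wcfi, "wcfi", cv["wcfi", "min"], cv["wcfi", "max"])
  .warn_range(height, "height", cv["height", "min"], cv["height", "max"])
  .warn_range(sbp, "sbp", cv["sbp", "min"], cv["sbp", "max"])
  b <- stats::setNames(ref$sgt_model$beta, ref$sgt_model$term)
  b[["wcfi100"]] * (wcfi * 100) + b[["height"]] * height +
    b[["sbp"]] * sbp + b[["(Intercept)"]]
}

#' Published G-tolerance model as a model object
#'
#' Wraps the published coefficient tables as a lightweight model object so
#' the usual verbs (`coef`, `predict`, `print`) apply. `predict` takes a
#' data frame with columns on the natural scale (`age`, `wcfi`, `height`,
#' `sbp`, `hr_rest` as required by the response).
#'
#' @param response `"rgt"` or `"sgt"`.
#' @return object of class `gtol_published`.
#' @examples
#' m <- published_model("sgt")
#' predict(m, data.frame(wcfi = 0.141, height = 173.18, sbp = 140.40))
#' @export
published_model <- function(response = c("rgt", "sgt")) {
  response <- match.arg(response)
  ref <- gtol_reference()
  tab <- if (response == "rgt") ref$rgt_model else ref$sgt_model
  structure(list(response = toupper(response), table = tab),
            class = "gtol_published")
}

#' @export
coef.gtol_published <- function(object, ...)
  stats::setNames(object$table$beta, object$table$term)

#' @export
print.gtol_published <- function(x, ...) {
  cat("Published", x$response, "prediction model (WCFI enters as WCFI x 100)\n")
  print(x$table, row.names = FALSE)
  invisible(x)
}

#' @export
predict.gtol_published <- function(object, newdata, ...) {
  if (object$response == "RGT")
    predict_rgt(newdata$age, newdata$wcfi, newdata$height, newdata$sbp,
                newdata$hr_rest)
  else
    predict_sgt(newdata$wcfi, newdata$height, newdata$sbp)
}

#' Pairwise Pearson correlation matrix with p-values
#'
#' Pearson correlations among the cardiovascular and G-tolerance variables
#' with two-tailed p-values from the t transform
#' `t = r sqrt((n - 2) / (1 - r^2))`. Zero-variance columns have no defined
#' correlation; their entries are `NA` and they are listed in
#' `$degenerate`.
#'
#' @param data data frame of numeric columns (rows with any `NA` are
#'   dropped listwise, matching the usual complete-case convention).
#' @param variables columns to use; defaults to all numeric columns.
#' @return object of class `gtol_cormat`: list with matrices `r` and `p`,
#'   `n`, `variables`, `degenerate`.
#' @export
correlation_matrix <- function(data, variables = NULL) {
  data <- as.data.frame(data)
  if (is.null(variables))
    variables <- names(data)[vapply(data, is.numeric, logical(1))]
  miss <- setdiff(variables, names(data))
  if (length(miss))
    stop("missing column(s): ", paste(miss, collapse = ", "))
  m <- as.matrix(data[variables])
  m <- m[stats::complete.cases(m), , drop = FALSE]
  n <- nrow(m)
  if (n < 3) stop("need at least 3 complete observations")
  sds <- apply(m, 2, stats::sd)
  degenerate <- variables[sds == 0]
  r <- suppressWarnings(stats::cor(m))
  r[degenerate, ] <- NA_real_
  r[, degenerate] <- NA_real_
  diag(r) <- ifelse(variables %in% degenerate, NA_real_, 1)
  tstat <- r * sqrt((n - 2) / pmax(1 - r^2, 0))
  p <- 2 * stats::pt(-abs(tstat), n - 2)
  p[which(!is.na(r) & abs(r) >= 1)] <- 0  # perfect correlation
  diag(p) <- NA_real_
  p[degenerate, ] <- NA_real_
  p[, degenerate] <- NA_real_
  structure(list(r = r, p = p, n = n, variables = variables,
                 degenerate = degenerate),
            class = "gtol_cormat")
}

#' @export
print.gtol_cormat <- function(x, digits = 3, ...) {
  cat("Pearson correlations (n =", x$n, "), two-tailed p-values below\n")
  print(round(x$r, digits))
  cat("\np-values:\n")
  print(round(x$p, digits))
  if (length(x$degenerate))
    cat("zero-variance (undefined):", paste(x$degenerate, collapse = ", "),
        "\n")
  invisible(x)
}

#' Observed-vs-estimated paired comparison
#'
#' Paired t-test of observed against model-estimated G tolerance, with the
#' means and SDs of both vectors. When the differences have zero variance
#' the t-test is undefined; the comparison then reports the (common)
#' difference with `p = 1` by convention and is flagged degenerate.
#'
#' Note that for in-sample OLS predictions the mean difference is exactly
#' zero by construction (residuals sum to zero), so this check is only
#' informative out of sample or for an externally specified equation.
#'
#' @param observed,estimated numeric vectors of equal length (n >= 2).
#' @return object of class `gtol_comparison`: list with `n`, `mean_obs`,
#'   `sd_obs`, `mean_est`, `sd_est`, `mean_diff`, `t`, `df`, `p`,
#'   `degenerate`.
#' @export
compare_observed_estimated <- function(observed, estimated) {
  observed <- as.numeric(observed)
  estimated <- as.numeric(estimated)
  if (length(observed) != length(estimated))
    stop("observed and estimated must have equal length")
  keep <- stats::complete.cases(observed, estimated)
  observed <- observed[keep]
  estimated <- estimated[keep]
  n <- length(observed)
  if (n < 2) stop("need at least 2 pairs")
  d <- observed - estimated
  degenerate <- isTRUE(all.equal(stats::sd(d), 0)) || stats::sd(d) == 0
  if (degenerate) {
    tt <- list(statistic = 0, parameter = n - 1, p.value = 1)
  } else {
    ht <- stats::t.test(observed, estimated, paired = TRUE)
    tt <- list(statistic = unname(ht$statistic),
               parameter = unname(ht$parameter), p.value = ht$p.value)
  }
  structure(list(n = n,
                 mean_obs = mean(observed), sd_obs = stats::sd(observed),
                 mean_est = mean(estimated), sd_est = stats::sd(estimated),
                 mean_diff = mean(d),
                 t = tt$statistic, df = tt$parameter, p = tt$p.value,
                 degenerate = degenerate),
            class = "gtol_comparison")
}

#' @export
print.gtol_comparison <- function(x, ...) {
  cat(sprintf("observed  mean %.3f (SD %.3f)\n", x$mean_obs, x$sd_obs))
  cat(sprintf("estimated mean %.3f (SD %.3f)\n", x$mean_est, x$sd_est))
  cat(sprintf("paired difference %.4f, t(%d) = %.3f, p = %.3g%s\n",
              x$mean_diff, x$df, x$t, x$p,
              if (x$degenerate) " [degenerate: zero-variance differences]"
              else ""))
  invisible(x)
}

#' Bin G-tolerance values into the reporting histogram
#'
#' Half-open 0.5 G bins from the 3.0 G origin, labelled `"3.0-3.4"`,
#' `"3.5-3.9"`, ... The training ceiling (9.0 G by default) is its own
#' terminal single-value bin labelled `"9.0"`, matching how capped
#' straining G tolerances are reported. Values below the origin or above
#' the ceiling are a binning error.
#'
#' @param values numeric G-tolerance values.
#' @param bin_width bin width in G.
#' @param origin lower edge of the first bin, G.
#' @param ceiling terminal single-value bin, G.
#' @return named integer vector of counts (all bins from origin to ceiling,
#'   including empty ones); counts sum to `length(values)`.
#' @examples
#' bin_gtolerance(c(3.2, 3.4999, 3.5, 9.0))
#' @export
bin_gtolerance <- function(values, bin_width = 0.5, origin = 3.0,
                           ceiling = 9.0) {
  values <- as.numeric(values)
  stopifnot(bin_width > 0, ceiling > origin)
  if (anyNA(values)) stop("values contain NA")
  if (any(values < origin))
    stop("binning error: value(s) below the ", origin, " G origin")
  if (any(values > ceiling))
    stop("binning error: value(s) above the ", ceiling, " G ceiling")
  lowers <- seq(origin, ceiling - bin_width, by = bin_width)
  labels <- c(sprintf("%.1f-%.1f", lowers, lowers + bin_width - 0.1),
              sprintf("%.1f", ceiling))
  idx <- ifelse(values == ceiling, length(labels),
                floor((values - origin) / bin_width) + 1)
  counts <- tabulate(idx, nbins = length(labels))
  stats::setNames(as.integer(counts), labels)
}
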