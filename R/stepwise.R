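#' Stepwise multiple linear regression by coefficient p-values
#'
#' The classical p-value-driven stepwise procedure: starting from the
#' intercept-only model, repeatedly (1) add, among the excluded candidates,
#' the one whose coefficient would have the smallest p-value, provided that
#' p-value is below `p_enter`; then (2) remove, among the included
#' covariates, the one with the largest p-value above `p_remove`; until a
#' full pass changes nothing. Thresholds default to the conventional
#' entry/removal probabilities .05/.10. Ties (identical p-values) break
#' deterministically by candidate order, then name. `p_remove >= p_enter`
#' is required, which excludes add/remove cycling; a 100-iteration guard
#' backstops the loop regardless.
#'
#' With `p_enter = p_remove = 1` every candidate is admitted and the result
#' equals the full-model [fit_ols()]; with `p_enter = 0` nothing is ever
#' selected.
#'
#' @param design data frame (or matrix) of candidate covariates, one column
#'   per candidate; logicals are coerced to 0/1.
#' @param response numeric response vector.
#' @param p_enter entry threshold on the coefficient p-value.
#' @param p_remove removal threshold (must be `>= p_enter`).
#' @param max_iter iteration guard.
#' @param response_name label for printing.
#' @return A `gtol_fit` (see [fit_ols()]) for the selected model, with
#'   additional class `gtol_step` and elements `selected` (covariate names
#'   in entry order) and `steps` (data frame trace of the add/remove
#'   history).
#' @examples
#' set.seed(1)
#' d <- data.frame(a = rnorm(200), b = rnorm(200), c = rnorm(200))
#' y <- 2 * d$a + rnorm(200)
#' fit_stepwise(d, y)$selected  # "a"
#' @export
fit_stepwise <- function(design, response, p_enter = 0.05, p_remove = 0.10,
                         max_iter = 100, response_name = "y") {
  design <- as.data.frame(design)
  stopifnot(ncol(design) >= 1)
  if (p_enter < 0 || p_enter > 1 || p_remove < 0 || p_remove > 1)
    stop("p_enter and p_remove must lie in [0, 1]")
  if (p_remove < p_enter)
    stop("p_remove must be >= p_enter (otherwise the procedure can cycle)")
  candidates <- names(design)

  coef_p <- function(vars) {
    fit <- fit_ols(design[vars], y = response,
                   response_name = response_name)
    fit$pvalue[setdiff(names(fit$pvalue), "(Intercept)")]
  }

  included <- character(0)
  steps <- list()
  for (iter in seq_len(max_iter)) {
    changed <- FALSE

    excluded <- setdiff(candidates, included)
    if (length(excluded) && p_enter > 0) {
      entry_p <- vapply(excluded, function(v) {
        p <- tryCatch(coef_p(c(included, v)),
                      error = function(e) NULL)  # collinear with included
        if (is.null(p)) NA_real_ else unname(p[v])
      }, numeric(1))
      ok <- !is.na(entry_p) & entry_p < p_enter
      if (any(ok)) {
        # smallest p; ties by candidate order (vapply preserves it), then name
        best <- excluded[ok][order(entry_p[ok],
                                   match(excluded[ok], candidates),
                                   excluded[ok])][1]
        included <- c(included, best)
        steps[[length(steps) + 1L]] <-
          data.frame(iter = iter, action = "add", term = best,
                     p = unname(entry_p[best]))
        changed <- TRUE
      }
    }

    while (length(included)) {
      p_in <- coef_p(included)
      worst <- which(p_in > p_remove)
      if (!length(worst)) break
      drop_ix <- worst[order(-p_in[worst],
                             match(included[worst], candidates),
                             included[worst])][1]
      term <- included[drop_ix]
      steps[[length(steps) + 1L]] <-
        data.frame(iter = iter, action = "remove", term = term,
                   p = unname(p_in[drop_ix]))
      included <- setdiff(included, term)
      changed <- TRUE
    }

    if (!changed) break
    if (iter == max_iter)
      stop("stepwise selection did not stabilize within ", max_iter,
           " iterations")
  }

  fit <- fit_ols(design[included], y = response,
                 response_name = response_name)
  fit$selected <- included
  fit$steps <- if (length(steps)) do.call(rbind, steps) else
    data.frame(iter = integer(), action = character(), term = character(),
               p = numeric())
  class(fit) <- c("gtol_step", class(fit))
  fit
}

#' @export
print.gtol_step <- function(x, digits = 4, ...) {
  cat("Stepwise-selected ")
  NextMethod()
  if (!length(x$selected)) cat("(no covariate met the entry criterion)\n")
  invisible(x)
}
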