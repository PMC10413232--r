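#' Ordinary least squares with t-based inference
#'
#' Fits a linear model by QR decomposition and derives standard errors,
#' two-sided t-test p-values and 95% confidence intervals from the residual
#' variance and the inverse cross-product of the design. The fitter is
#' self-contained (it is also the engine under [fit_stepwise()]); its
#' agreement with an independent closed-form oracle is part of the test
#' suite. An intercept is always included.
#'
#' Accepts either a formula with a data frame, or a design (data frame or
#' matrix of numeric/logical covariates, no intercept column) with a
#' response vector.
#'
#' @param x a formula, or a design data frame/matrix.
#' @param data data frame (formula interface).
#' @param y response vector (design interface).
#' @param conf_level confidence level for the reported intervals.
#' @param response_name label for the response (design interface).
#' @return An object of class `gtol_fit`: list with `coefficients`, `se`,
#'   `tvalue`, `pvalue`, `ci` (matrix `lo`/`hi`), `sigma`, `df_residual`,
#'   `n`, `r_squared`, `adj_r_squared`, `fitted`, `residuals`,
#'   `terms` (covariate names), `response`. Supports `print()`,
#'   `summary()`, `coef()`, `confint()`, `vcov()`, `predict()`,
#'   `residuals()` and `fitted()`.
#' @examples
#' d <- data.frame(x = 1:5, y = c(2, 4, 5, 4, 5))
#' fit <- fit_ols(y ~ x, d)
#' coef(fit)  # intercept 2.2, slope 0.6
#' @export
fit_ols <- function(x, data = NULL, y = NULL, conf_level = 0.95,
                    response_name = "y") {
  if (inherits(x, "formula")) {
    mf <- stats::model.frame(x, data = data, na.action = stats::na.omit)
    yv <- stats::model.response(mf)
    X <- stats::model.matrix(attr(mf, "terms"), mf)
    response_name <- deparse(x[[2]])
  } else {
    if (is.null(y)) stop("design interface requires a response vector y")
    xd <- as.data.frame(x)
    yv <- as.numeric(y)
    if (ncol(xd)) {
      X <- as.matrix(as.data.frame(lapply(xd, as.numeric)))
      if (is.null(colnames(X)))
        colnames(X) <- paste0("x", seq_len(ncol(X)))
    } else {
      X <- matrix(numeric(0), nrow = length(yv), ncol = 0)
    }
    if (length(yv) != nrow(X))
      stop("length(y) must equal nrow(design)")
    keep <- stats::complete.cases(X, yv)
    X <- X[keep, , drop = FALSE]
    yv <- yv[keep]
    X <- cbind(`(Intercept)` = 1, X)
  }
  n <- nrow(X)
  p <- ncol(X)
  if (n <= p)
    stop("need more observations (", n, ") than parameters (", p, ")")

  qx <- qr(X)
  if (qx$rank < p) {
    bad <- colnames(X)[qx$pivot[(qx$rank + 1):p]]
    stop("design is rank deficient; collinear column(s): ",
         paste(bad, collapse = ", "))
  }
  beta <- qr.coef(qx, yv)
  fitted <- drop(X %*% beta)
  resid <- yv - fitted
  df_res <- n - p
  rss <- sum(resid^2)
  sigma2 <- rss / df_res

  # (X'X)^-1 from the R factor, undoing any pivoting
  R <- qr.R(qx)
  xtx_inv <- chol2inv(R)
  piv <- qx$pivot
  xtx_inv[piv, piv] <- xtx_inv
  vc <- sigma2 * xtx_inv
  dimnames(vc) <- list(colnames(X), colnames(X))

  se <- sqrt(diag(vc))
  tval <- beta / se
  pval <- 2 * stats::pt(-abs(tval), df_res)
  tq <- stats::qt(1 - (1 - conf_level) / 2, df_res)
  ci <- cbind(lo = beta - tq * se, hi = beta + tq * se)

  tss <- sum((yv - mean(yv))^2)
  r2 <- if (tss > 0) 1 - rss / tss else NA_real_

  structure(list(coefficients = beta, se = se, tvalue = tval, pvalue = pval,
                 ci = ci, vcov = vc, sigma = sqrt(sigma2),
                 df_residual = df_res, n = n, r_squared = r2,
                 adj_r_squared = if (is.na(r2)) NA_real_ else
                   1 - (1 - r2) * (n - 1) / df_res,
                 fitted = fitted, residuals = resid,
                 terms = setdiff(colnames(X), "(Intercept)"),
                 response = response_name, conf_level = conf_level),
            class = "gtol_fit")
}

#' @export
print.gtol_fit <- function(x, digits = 4, ...) {
  cat("Linear model:", x$response, "~",
      if (length(x$terms)) paste(x$terms, collapse = " + ") else "1", "\n")
  cat("n =", x$n, " residual SD =", signif(x$sigma, digits),
      " R^2 =", signif(x$r_squared, digits), "\n")
  print(signif(x$coefficients, digits))
  invisible(x)
}

#' @export
summary.gtol_fit <- function(object, ...) {
  tab <- cbind(beta = object$coefficients, se = object$se,
               ci_lo = object$ci[, "lo"], ci_hi = object$ci[, "hi"],
               t = object$tvalue, p = object$pvalue)
  structure(list(fit = object, coef_table = tab),
            class = "summary.gtol_fit")
}

#' @export
print.summary.gtol_fit <- function(x, digits = 4, ...) {
  f <- x$fit
  cat("Linear model:", f$response, "~",
      if (length(f$terms)) paste(f$terms, collapse = " + ") else "1", "\n")
  cat("n =", f$n, ", residual df =", f$df_residual, "\n\n")
  printCoefmat(x$coef_table[, c("beta", "se", "t", "p"), drop = FALSE],
               digits = digits, P.values = TRUE, has.Pvalue = TRUE)
  cat(sprintf("\nResidual SD %.4g, R^2 %.4f, adjusted R^2 %.4f\n",
              f$sigma, f$r_squared, f$adj_r_squared))
  invisible(x)
}

#' @export
coef.gtol_fit <- function(object, ...) object$coefficients

#' @export
vcov.gtol_fit <- function(object, ...) object$vcov

#' @export
residuals.gtol_fit <- function(object, ...) object$residuals

#' @export
fitted.gtol_fit <- function(object, ...) object$fitted

#' @export
confint.gtol_fit <- function(object, parm, level = 0.95, ...) {
  tq <- stats::qt(1 - (1 - level) / 2, object$df_residual)
  ci <- cbind(object$coefficients - tq * object$se,
              object$coefficients + tq * object$se)
  colnames(ci) <- paste0(100 * c((1 - level) / 2, 1 - (1 - level) / 2), " %")
  if (!missing(parm)) ci <- ci[parm, , drop = FALSE]
  ci
}

#' @describeIn fit_ols predict from a fitted model; `newdata` must contain
#'   the model's covariate columns (extra columns are ignored).
#' @param object a `gtol_fit`.
#' @param newdata data frame of covariates.
#' @param ... unused.
#' @export
predict.gtol_fit <- function(object, newdata, ...) {
  if (missing(newdata)) return(object$fitted)
  miss <- setdiff(object$terms, names(newdata))
  if (length(miss))
    stop("newdata lacks column(s): ", paste(miss, collapse = ", "))
  X <- cbind(1, as.matrix(as.data.frame(
    lapply(newdata[object$terms], as.numeric))))
  drop(X %*% object$coefficients[c("(Intercept)", object$terms)])
}
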