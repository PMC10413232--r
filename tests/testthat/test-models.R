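test_that("published RGT equation reproduces its printed arithmetic", {
  # cohort means -> 4.833 by direct evaluation of the printed coefficients
  expect_equal(predict_rgt(25.61, 0.141, 173.18, 140.40, 88.56),
               0.066 * 25.61 + 0.043 * 14.1 - 0.037 * 173.18 +
                 0.015 * 140.40 - 0.010 * 88.56 + 7.724)
  expect_equal(round(predict_rgt(25.61, 0.141, 173.18, 140.40, 88.56), 3),
               4.833)
  # intercept at the origin; out-of-range inputs warn but evaluate
  w <- capture_warnings(v0 <- predict_rgt(0, 0, 0, 0, 0))
  expect_true(all(grepl("outside", w)) && length(w) >= 1)
  expect_equal(v0, 7.724)
  # +0.01 natural-scale WCFI (= +1 on the x100 scale) adds exactly 0.043
  expect_equal(predict_rgt(25, 0.151, 173, 140, 88) -
                 predict_rgt(25, 0.141, 173, 140, 88), 0.043)
})

test_that("published SGT equation reproduces its printed arithmetic", {
  expect_equal(predict_sgt(0.141, 173.18, 140.40),
               0.103 * 14.1 - 0.069 * 173.18 + 0.018 * 140.40 + 15.899)
  expect_equal(round(predict_sgt(0.141, 173.18, 140.40), 1), 7.9)
  w <- capture_warnings(v0 <- predict_sgt(0, 0, 0))
  expect_true(all(grepl("outside", w)) && length(w) >= 1)
  expect_equal(v0, 15.899)
  expect_equal(predict_sgt(0.141, 174.18, 140.40) -
                 predict_sgt(0.141, 173.18, 140.40), -0.069)
})

test_that("published equations are exactly linear (superposition)", {
  set.seed(5)
  base <- c(age = 26, wcfi = 0.14, height = 172, sbp = 138, hr = 90)
  d1 <- c(age = 2, wcfi = 0.01, height = -3, sbp = 5, hr = -4)
  d2 <- c(age = -1, wcfi = 0.02, height = 4, sbp = -6, hr = 2)
  f <- function(v) predict_rgt(v["age"], v["wcfi"], v["height"], v["sbp"],
                               v["hr"])
  expect_equal(f(base + d1 + d2) - f(base),
               (f(base + d1) - f(base)) + (f(base + d2) - f(base)))
  g <- function(v) predict_sgt(v["wcfi"], v["height"], v["sbp"])
  expect_equal(g(base + d1 + d2) - g(base),
               (g(base + d1) - g(base)) + (g(base + d2) - g(base)))
})

test_that("published models wrap as predictable model objects", {
  m <- published_model("sgt")
  expect_equal(unname(coef(m)["wcfi100"]), 0.103)
  nd <- data.frame(wcfi = 0.141, height = 173.18, sbp = 140.40)
  expect_equal(predict(m, nd), predict_sgt(0.141, 173.18, 140.40))
})

test_that("fit_ols reproduces an exact linear relationship to machine precision", {
  x <- 1:20
  y <- 2 * x + 1
  fit <- fit_ols(data.frame(x = x), y = y)
  expect_equal(unname(coef(fit)), c(1, 2), tolerance = 1e-12)
  expect_equal(max(abs(residuals(fit))), 0, tolerance = 1e-10)
})

test_that("fit_ols matches the closed-form simple-regression oracle", {
  x <- 1:5
  y <- c(2, 4, 5, 4, 5)
  or <- simple_lm_oracle(x, y)
  expect_equal(or$slope, 0.6)          # oracle sanity (hand arithmetic)
  expect_equal(or$intercept, 2.2)
  fit <- fit_ols(data.frame(x = x), y = y)
  expect_equal(unname(coef(fit)), c(or$intercept, or$slope),
               tolerance = 1e-12)
  expect_equal(unname(fit$se["x"]), or$se_slope, tolerance = 1e-12)
  expect_equal(unname(fit$pvalue["x"]), or$p_slope, tolerance = 1e-12)
})

test_that("fit_ols agrees with stats::lm as an independent cross-check", {
  set.seed(11)
  d <- data.frame(a = rnorm(40), b = runif(40), c = rnorm(40))
  y <- 1 + 0.5 * d$a - 2 * d$b + rnorm(40)
  fit <- fit_ols(d, y = y)
  ref <- lm(y ~ a + b + c, data = d)
  expect_equal(unname(coef(fit)), unname(coef(ref)), tolerance = 1e-10)
  sref <- summary(ref)$coefficients
  expect_equal(unname(fit$se), unname(sref[, "Std. Error"]),
               tolerance = 1e-10)
  expect_equal(unname(fit$pvalue), unname(sref[, "Pr(>|t|)"]),
               tolerance = 1e-10)
  expect_equal(unname(confint(fit)), unname(confint(ref)),
               tolerance = 1e-10)
})

test_that("rank-deficient designs are refused, naming the collinear column", {
  d <- data.frame(a = 1:10, b = rnorm(10))
  d$dup <- d$a
  expect_error(fit_ols(d, y = rnorm(10)), "collinear.*dup")
  expect_error(fit_ols(data.frame(x = 1:3), y = c(1, 2, 3) * 0 + rnorm(3),
                       conf_level = 0.95), NA)
  expect_error(fit_ols(data.frame(x = 1:2), y = 1:2), "more observations")
})

test_that("predict on new data applies the fitted coefficients", {
  d <- data.frame(x = 1:10)
  fit <- fit_ols(d, y = 3 * d$x + 2)
  expect_equal(predict(fit, data.frame(x = c(0, 100))), c(2, 302),
               tolerance = 1e-9)
  expect_error(predict(fit, data.frame(z = 1)), "lacks column")
})

test_that("stepwise selects exactly the informative covariate among noise", {
  set.seed(42)
  n <- 500
  d <- data.frame(v1 = rnorm(n), v2 = rnorm(n), v3 = rnorm(n),
                  v4 = rnorm(n), v5 = rnorm(n))
  y <- 3 * d$v3 + rnorm(n)
  fit <- fit_stepwise(d, y)
  expect_identical(fit$selected, "v3")
  expect_equal(unname(coef(fit)["v3"]), 3, tolerance = 0.2)
})

test_that("stepwise degenerates correctly at extreme thresholds", {
  set.seed(8)
  d <- data.frame(a = rnorm(60), b = rnorm(60), c = rnorm(60))
  y <- 1 + d$a + 0.5 * d$b + rnorm(60)
  full <- fit_ols(d, y = y)
  all_in <- fit_stepwise(d, y, p_enter = 1, p_remove = 1)
  expect_setequal(all_in$selected, names(d))
  expect_equal(coef(all_in)[names(coef(full))], coef(full),
               tolerance = 1e-12)
  none <- fit_stepwise(d, y, p_enter = 0)
  expect_length(none$selected, 0)
  expect_error(fit_stepwise(d, y, p_enter = 0.5, p_remove = 0.1),
               "p_remove")
})

test_that("stepwise never beats exhaustive best-subset on small instances", {
  set.seed(13)
  for (rep in 1:8) {
    n <- 40
    k <- 4
    d <- as.data.frame(matrix(rnorm(n * k), n,
                              dimnames = list(NULL, paste0("x", 1:k))))
    beta <- c(2, 0, 0.5, 0) * sample(c(1, -1), k, replace = TRUE)
    y <- as.matrix(d) %*% beta + rnorm(n, sd = 0.5)
    fit <- fit_stepwise(d, y)
    rss <- function(vars) {
      f <- fit_ols(d[vars], y = y)
      sum(residuals(f)^2)
    }
    subsets <- unlist(lapply(0:k, function(m)
      combn(names(d), m, simplify = FALSE)), recursive = FALSE)
    same_size <- Filter(function(s) length(s) == length(fit$selected),
                        subsets)
    best_rss <- min(vapply(same_size, rss, numeric(1)))
    expect_gte(sum(residuals(fit)^2) + 1e-10, best_rss)
    # strong, well-separated signals: stepwise finds the best subset
    expect_true(all(c("x1", "x3") %in% fit$selected))
  }
})

test_that("correlation matrix matches the covariance-formula oracle", {
  expect_equal(correlation_matrix(data.frame(x = 1:10, y = 2 * (1:10)))$r[1, 2],
               1)
  hand <- correlation_matrix(data.frame(a = c(1, 2, 3, 4),
                                        b = c(2, 1, 4, 3)))
  expect_equal(hand$r["a", "b"], 0.6)
  set.seed(9)
  d <- as.data.frame(matrix(rnorm(200), 50))
  cm <- correlation_matrix(d)
  for (i in 1:3) for (j in (i + 1):4) {
    expect_equal(cm$r[i, j], pearson_oracle(d[[i]], d[[j]]),
                 tolerance = 1e-12)
    r <- cm$r[i, j]
    tt <- r * sqrt((50 - 2) / (1 - r^2))
    expect_equal(cm$p[i, j], 2 * pt(-abs(tt), 48), tolerance = 1e-12)
  }
  expect_true(isSymmetric(cm$r))
})

test_that("zero-variance columns are reported as undefined, not fabricated", {
  cm <- correlation_matrix(data.frame(x = rnorm(10), const = 5))
  expect_identical(cm$degenerate, "const")
  expect_true(all(is.na(cm$r["const", ])))
  expect_false(is.na(cm$r["x", "x"]))
})

test_that("observed-vs-estimated comparison follows the paired t oracle", {
  # identical vectors: degenerate, difference 0, p = 1
  same <- compare_observed_estimated(c(5, 6, 7), c(5, 6, 7))
  expect_equal(same$mean_diff, 0)
  expect_equal(same$p, 1)
  expect_true(same$degenerate)

  # in-sample OLS predictions: mean residual is exactly zero
  set.seed(14)
  d <- data.frame(x = rnorm(30))
  y <- 2 + d$x + rnorm(30)
  fit <- fit_ols(d, y = y)
  chk <- compare_observed_estimated(y, fitted(fit))
  expect_equal(chk$mean_diff, 0, tolerance = 1e-12)

  # hand-computed paired t
  obs <- c(5, 4, 6)
  est <- c(5, 5, 6)
  cmp <- compare_observed_estimated(obs, est)
  dd <- obs - est
  t_hand <- mean(dd) / (sd(dd) / sqrt(3))
  expect_equal(cmp$t, t_hand, tolerance = 1e-12)
  expect_equal(cmp$p, 2 * pt(-abs(t_hand), 2), tolerance = 1e-12)
  expect_equal(cmp$sd_obs, sd(obs))
})

test_that("G-tolerance binning follows the half-open 0.5 G convention", {
  counts <- bin_gtolerance(c(3.2, 3.4999, 3.5, 9.0))
  expect_equal(unname(counts["3.0-3.4"]), 2)
  expect_equal(unname(counts["3.5-3.9"]), 1)
  expect_equal(unname(counts["9.0"]), 1)
  expect_error(bin_gtolerance(2.9), "below")
  expect_error(bin_gtolerance(9.1), "above")
})

test_that("binning reproduces the reference distributions and conserves counts", {
  ref <- gtol_reference()
  # reconstruct representative values from the published RGT histogram
  vals <- rep(ref$rgt_distribution$lower + 0.2, ref$rgt_distribution$count)
  counts <- bin_gtolerance(vals)
  expect_equal(sum(counts), 213)
  expect_equal(unname(counts[ref$rgt_distribution$bin]),
               ref$rgt_distribution$count)
  # high-tolerance subgroup: bins with lower edge >= 6 G
  lowers <- as.numeric(sub("-.*", "", names(counts)))
  expect_equal(sum(counts[lowers >= 6]), 23)

  svals <- c(rep(head(ref$sgt_distribution$lower, -1) + 0.2,
                 head(ref$sgt_distribution$count, -1)),
             rep(9.0, 60))
  scounts <- bin_gtolerance(svals)
  expect_equal(sum(scounts), 213)
  expect_equal(unname(scounts["9.0"]), 60)
})
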