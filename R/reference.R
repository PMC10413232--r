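#' Development-cohort reference statistics
#'
#' Summary statistics of the development cohort on which the cardiac force
#' index (CFI) G-tolerance models were estimated: 213 military aircrew
#' trainees who completed a ground rest/walk protocol wearing a chest-strap
#' sensor followed by slow-onset (0.1 G/s) centrifuge G-tolerance runs.
#' These numbers parameterize the published prediction equations
#' ([predict_rgt()], [predict_sgt()]) and the defaults of the synthetic
#' cohort generator ([sim_config()]).
#'
#' @return A list with components:
#' \describe{
#'   \item{n}{cohort size (213).}
#'   \item{covariates}{data frame of mean, SD, min, max for age (years),
#'     height (cm), weight (kg), BMI (kg/m^2), SBP and DBP (mm Hg), resting
#'     HR (bpm), RCFI and WCFI (kg x G/bpm), CFR (dimensionless), RGT and
#'     SGT (G).}
#'   \item{proportions}{named vector: women, smoker, drinker, exerciser.}
#'   \item{correlations}{8 x 8 Pearson correlation matrix among RGT, SGT,
#'     SBP, DBP, HR, RCFI, WCFI, CFR as reported for the cohort.}
#'   \item{rgt_model, sgt_model}{data frames of the published regression
#'     coefficients (term, beta, se, ci_lo, ci_hi) for relaxed and straining
#'     G tolerance. WCFI enters on the x100 scale.}
#'   \item{rgt_distribution, sgt_distribution}{data frames (bin label, lower
#'     edge, count) of the cohort G-tolerance histograms in 0.5 G bins from
#'     3.0 G; the terminal SGT bin is the single value 9.0 G (training
#'     ceiling).}
#'   \item{estimated}{data frame of observed and model-estimated outcome
#'     means/SDs used for the observed-vs-estimated check.}
#' }
#' @examples
#' ref <- gtol_reference()
#' ref$covariates["wcfi", ]
#' @export
gtol_reference <- function() {
  covariates <- data.frame(
    mean = c(age = 25.61, height = 173.18, weight = 70.39, bmi = 23.38,
             sbp = 140.40, dbp = 81.42, hr_rest = 88.56,
             rcfi = 0.016, wcfi = 0.141, cfr = 10.76, rgt = 4.9, sgt = 7.9),
    sd   = c(3.66, 6.75, 11.44, 2.91, 14.47, 8.33, 15.33,
             0.001, 0.037, 4.38, 0.9, 1.06),
    min  = c(22, 156, 48, 17.31, 102, 50, 56, 0.006, 0.020, 1.52, 3.0, 4.5),
    max  = c(27, 188, 99, 32.70, 177, 107, 145, 0.088, 0.266, 23.02, 8.4, 9.0)
  )

  vars <- c("rgt", "sgt", "sbp", "dbp", "hr_rest", "rcfi", "wcfi", "cfr")
  r <- diag(8)
  dimnames(r) <- list(vars, vars)
  fill <- function(a, b, x) {
    r[a, b] <<- x
    r[b, a] <<- x
  }
  fill("rgt", "sgt", .535); fill("rgt", "sbp", .149); fill("rgt", "dbp", .127)
  fill("rgt", "hr_rest", -.187); fill("rgt", "rcfi", .087)
  fill("rgt", "wcfi", .234); fill("rgt", "cfr", -.025)
  fill("sgt", "sbp", .167); fill("sgt", "dbp", .199); fill("sgt", "hr_rest", -.111)
  fill("sgt", "rcfi", .124); fill("sgt", "wcfi", .256); fill("sgt", "cfr", -.048)
  fill("sbp", "dbp", .519); fill("sbp", "hr_rest", .181); fill("sbp", "rcfi", -.034)
  fill("sbp", "wcfi", .245); fill("sbp", "cfr", .068)
  fill("dbp", "hr_rest", .372); fill("dbp", "rcfi", -.020); fill("dbp", "wcfi", .091)
  fill("dbp", "cfr", .060)
  fill("hr_rest", "rcfi", -.310); fill("hr_rest", "wcfi", -.337)
  fill("hr_rest", "cfr", .203)
  fill("rcfi", "wcfi", .329); fill("rcfi", "cfr", -.724)
  fill("wcfi", "cfr", .177)

  rgt_model <- data.frame(
    term  = c("age", "wcfi100", "height", "sbp", "hr_rest", "(Intercept)"),
    beta  = c(0.066, 0.043, -0.037, 0.015, -0.010, 7.724),
    se    = c(0.015, 0.017, 0.009, 0.004, 0.004, 1.516),
    ci_lo = c(0.037, 0.009, -0.055, 0.007, -0.017, 4.736),
    ci_hi = c(0.095, 0.078, -0.020, 0.023, -0.001, 10.712)
  )
  sgt_model <- data.frame(
    term  = c("wcfi100", "height", "sbp", "(Intercept)"),
    beta  = c(0.103, -0.069, 0.018, 15.899),
    se    = c(0.019, 0.011, 0.005, 1.700),
    ci_lo = c(0.065, -0.091, 0.008, 12.549),
    ci_hi = c(0.141, -0.048, 0.028, 19.250)
  )

  rgt_distribution <- data.frame(
    bin   = c("3.0-3.4", "3.5-3.9", "4.0-4.4", "4.5-4.9", "5.0-5.4",
              "5.5-5.9", "6.0-6.4", "6.5-6.9", "7.0-7.4", "7.5-7.9",
              "8.0-8.4"),
    lower = seq(3.0, 8.0, by = 0.5),
    count = c(8L, 17L, 40L, 53L, 45L, 27L, 10L, 8L, 3L, 1L, 1L)
  )
  sgt_distribution <- data.frame(
    bin   = c("4.5-4.9", "5.0-5.4", "5.5-5.9", "6.0-6.4", "6.5-6.9",
              "7.0-7.4", "7.5-7.9", "8.0-8.4", "8.5-8.9", "9.0"),
    lower = c(seq(4.5, 8.5, by = 0.5), 9.0),
    count = c(1L, 4L, 9L, 13L, 18L, 19L, 36L, 35L, 18L, 60L)
  )

  estimated <- data.frame(
    response = c("rgt", "sgt"),
    mean_est = c(4.9, 7.9), sd_est = c(0.4, 0.5),
    mean_obs = c(4.9, 7.9), sd_obs = c(0.9, 1.06)
  )

  list(
    n = 213L,
    covariates = covariates,
    proportions = c(women = 0.131, smoker = 0.235, drinker = 0.178,
                    exerciser = 0.535),
    correlations = r,
    rgt_model = rgt_model,
    sgt_model = sgt_model,
    rgt_distribution = rgt_distribution,
    sgt_distribution = sgt_distribution,
    estimated = estimated
  )
}
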