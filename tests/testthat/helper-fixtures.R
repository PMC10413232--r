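# In-code fixtures shared across test files.

# constant-rate stream: n seconds of given hr/activity/confidences
make_stream <- function(n = 120, hr = 80, activity = 0.02, hr_conf = 100,
                        sys_conf = 100, t0 = 0, id = "T1") {
  sensor_stream(data.frame(t = t0 + seq_len(n) - 1, hr = hr,
                           activity = activity, hr_conf = hr_conf,
                           sys_conf = sys_conf),
                participant_id = id)
}

# write a stream CSV with explicit text (for reader contract tests)
write_stream_text <- function(lines, path = tempfile(fileext = ".csv")) {
  writeLines(lines, path)
  path
}

# minimal valid cohort CSV text for one or more rows
cohort_csv <- function(rows, path = tempfile(fileext = ".csv")) {
  writeLines(c(paste0("id,age_y,gender,height_cm,weight_kg,smoker,drinker,",
                      "exerciser,sbp_mmhg,dbp_mmhg,hr_rest_bpm,rgt_g,sgt_g"),
               rows), path)
  path
}

# closed-form simple linear regression (independent oracle for fit_ols)
simple_lm_oracle <- function(x, y) {
  sxx <- sum((x - mean(x))^2)
  slope <- sum((x - mean(x)) * (y - mean(y))) / sxx
  intercept <- mean(y) - slope * mean(x)
  n <- length(x)
  resid <- y - intercept - slope * x
  s2 <- sum(resid^2) / (n - 2)
  se_slope <- sqrt(s2 / sxx)
  list(intercept = intercept, slope = slope, se_slope = se_slope,
       t_slope = slope / se_slope,
       p_slope = 2 * pt(-abs(slope / se_slope), n - 2))
}

# covariance-formula Pearson correlation (independent oracle)
pearson_oracle <- function(x, y) {
  sum((x - mean(x)) * (y - mean(y))) /
    sqrt(sum((x - mean(x))^2) * sum((y - mean(y))^2))
}

jaccard <- function(a, b) {
  inter <- max(0, min(a[2], b[2]) - max(a[1], b[1]))
  union <- (a[2] - a[1]) + (b[2] - b[1]) - inter
  inter / union
}
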