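test_that("stream write/read round-trips exactly at the writer's precision", {
  s <- make_stream(n = 3, hr = c(80.25, 81.5, 79), activity = 0.123456)
  p <- tempfile(fileext = ".csv")
  write_stream(s, p)
  r <- read_stream(p, participant_id = "T1")
  expect_identical(r$samples, s$samples)
  # idempotence: a re-written re-read file is bit-equal
  p2 <- tempfile(fileext = ".csv")
  write_stream(r, p2)
  expect_identical(readLines(p), readLines(p2))
})

test_that("empty stream writes a header-only file that reads back empty", {
  s <- sensor_stream(data.frame(t = numeric(0), hr = numeric(0),
                                activity = numeric(0), hr_conf = numeric(0),
                                sys_conf = numeric(0)))
  p <- tempfile(fileext = ".csv")
  write_stream(s, p)
  expect_identical(readLines(p),
                   "t_s,hr_bpm,activity_g,hr_conf_pct,sys_conf_pct")
  expect_equal(n_samples(read_stream(p)), 0)
})

test_that("reader requires the five dialect columns and names the missing one", {
  p <- write_stream_text(c("t_s,hr_bpm,activity_g,sys_conf_pct",
                           "0,80,0.02,100"))
  expect_error(read_stream(p), "hr_conf_pct")
})

test_that("reader matches columns case-insensitively and ignores extras", {
  p <- write_stream_text(c("T_S,HR_BPM,Activity_G,hr_conf_pct,SYS_CONF_PCT,battery_pct",
                           "0,80,0.02,100,100,55",
                           "1,81,0.03,100,100,54"))
  s <- read_stream(p)
  expect_equal(n_samples(s), 2)
  expect_equal(s$samples$hr, c(80, 81))
})

test_that("a wall-clock column is converted to elapsed seconds on read", {
  p <- write_stream_text(c("timestamp,hr_bpm,activity_g,hr_conf_pct,sys_conf_pct",
                           "2022-03-01 10:00:05,80,0.02,100,100",
                           "2022-03-01 10:00:06,81,0.02,100,100",
                           "2022-03-01 10:00:08,82,0.02,100,100"))
  s <- read_stream(p)
  expect_equal(s$samples$t, c(0, 1, 3))
})

test_that("duplicate timestamps are an ordering error naming the row", {
  p <- write_stream_text(c("t_s,hr_bpm,activity_g,hr_conf_pct,sys_conf_pct",
                           "41,80,0.02,100,100",
                           "42,81,0.02,100,100",
                           "42,82,0.02,100,100"))
  expect_error(read_stream(p), "duplicate timestamp 42.*row 3")
})

test_that("malformed rows are rejected with diagnostics, never silently dropped", {
  p <- write_stream_text(c("t_s,hr_bpm,activity_g,hr_conf_pct,sys_conf_pct",
                           "0,80,0.02,100,100",
                           "1,eighty,0.02,100,100",   # non-numeric hr
                           "2,80,-0.1,100,100",       # negative activity
                           "3,80,0.02,140,100",       # conf out of range
                           "4,80,0.02,100,100"))
  expect_warning(s <- read_stream(p), "3 malformed")
  d <- attr(s, "diagnostics")
  expect_equal(d$row, c(2, 3, 4))
  expect_equal(n_samples(s) + nrow(d), 5)  # reader conservation
})

test_that("device 'HR 0 at confidence 0' rows become invalid samples, not errors", {
  p <- write_stream_text(c("t_s,hr_bpm,activity_g,hr_conf_pct,sys_conf_pct",
                           "0,80,0.02,100,100",
                           "1,0,0.02,0,100",
                           "2,80,0.02,100,100"))
  s <- read_stream(p)
  expect_equal(n_samples(s), 3)
  expect_true(is.na(s$samples$hr[2]))
  expect_equal(quality_filter(s)$report$n_valid, 2)
})

test_that("cohort reader computes BMI and validates rows individually", {
  p <- cohort_csv(c("A1,26,man,173.18,70.39,0,0,1,140,80,88,4.5,8.0",
                    "A2,24,woman,165,60,0,0,0,130,75,90,9.1,9.5",  # SGT > 9
                    "A3,30,man,180,80,1,0,0,150,85,80,6.5,6.0"))   # RGT > SGT
  expect_warning(co <- read_cohort(p), "rejected 2")
  expect_equal(co$id, "A1")
  expect_equal(co$bmi, 70.39 / 1.7318^2, tolerance = 1e-12)
  rej <- attr(co, "rejected")
  expect_setequal(rej$row, c(2, 3))
  expect_match(rej$reason[rej$row == 2], "ceiling")
  expect_match(rej$reason[rej$row == 3], "RGT exceeds SGT")
  expect_error(read_cohort(p, strict = TRUE), "invalid cohort record")
})

test_that("a supplied BMI column inconsistent beyond 0.5 kg/m^2 warns but keeps the row", {
  p <- tempfile(fileext = ".csv")
  writeLines(c(paste0("id,age_y,gender,height_cm,weight_kg,smoker,drinker,",
                      "exerciser,sbp_mmhg,dbp_mmhg,hr_rest_bpm,bmi_kgm2"),
               "A1,26,man,173.18,70.39,0,0,1,140,80,88,23.38",  # within 0.5
               "A2,26,man,173.18,70.39,0,0,1,140,80,88,25.00"), p)
  expect_warning(co <- read_cohort(p), "row\\(s\\) 2")
  expect_equal(nrow(co), 2)
})

test_that("empty cohort files yield an empty cohort with a warning", {
  p <- tempfile(fileext = ".csv")
  file.create(p)
  expect_warning(co <- read_cohort(p), "empty")
  expect_equal(nrow(co), 0)
})

test_that("cohort write/read round-trips the validated records", {
  sim <- simulate_cohort(sim_config(n = 8), seed = 4)
  p <- tempfile(fileext = ".csv")
  write_cohort(sim$cohort, p)
  back <- read_cohort(p)
  expect_equal(nrow(back), 8)
  expect_equal(back$weight, round(sim$cohort$weight, 2))
  expect_equal(back$gender, sim$cohort$gender)
  expect_equal(back$sgt, round(sim$cohort$sgt, 2))
})
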