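test_that("percent change follows the control-to-treatment formula", {
  expect_equal(percent_change(100, 100), 0)
  expect_equal(percent_change(50, 75), 50)
  expect_equal(percent_change(80, 60), -25)
  expect_error(percent_change(0, 10), "zero")
  expect_error(percent_change(NA_real_, 10), "finite")
})

test_that("identical arms score the baseline utility on every indicator", {
  cfg <- mini_config()
  tr <- mini_trial(list(
    yield = list(control = c(8, 8, 8), treatment = c(8, 8, 8)),
    enzyme = list(control = 60, treatment = 60),
    compaction = list(control = c(2.5, 2.5), treatment = c(2.5, 2.5))))
  s <- score_trial(cfg, tr)
  expect_equal(s$utility_impact, rep(0.7, 3))
  expect_equal(s$index_impact, rep(0, 3))
})

test_that("beneficial changes move utilities the right way by direction", {
  cfg <- mini_config()
  tr <- mini_trial(list(
    yield = list(control = 8, treatment = 10),       # +25 % on positive-good
    compaction = list(control = 3, treatment = 2.4)))  # -20 % on negative-good
  s <- score_trial(cfg, tr)
  expect_gt(s$utility_impact[s$indicator_id == "yield"], 0.7)
  expect_gt(s$utility_impact[s$indicator_id == "compaction"], 0.7)
  # clamped top: treatment at the upper threshold takes the top-knot utility
  ind <- mini_config()$indicators$enzyme
  r <- score_indicator(ind, control = 100, treatment = 200)
  expect_equal(r$utility_performance, 1.0)
})

test_that("impact index is invariant to rescaling both arms", {
  ind <- mini_config()$indicators$yield
  a <- score_indicator(ind, c(5, 6, 7), c(7, 8, 9))
  b <- score_indicator(ind, 10 * c(5, 6, 7), 10 * c(7, 8, 9))
  expect_equal(a$index_impact, b$index_impact, tolerance = 1e-12)
})

test_that("replicate summary uses the mean by default and median on request", {
  ind <- mini_config()$indicators$yield
  r_mean <- score_indicator(ind, c(6, 8, 13), c(9, 9, 9))
  expect_equal(r_mean$index_impact, percent_change(9, 9))
  r_med <- score_indicator(ind, c(6, 8, 13), c(9, 9, 9), summarize = "median")
  expect_equal(r_med$index_impact, percent_change(8, 9))
})

test_that("missing control arm skips impact but keeps performance", {
  ind <- mini_config()$indicators$enzyme
  r <- score_indicator(ind, control = NULL, treatment = c(60, 60))
  expect_true(is.na(r$utility_impact))
  expect_equal(r$utility_performance, 0.7)
  expect_match(r$flags, "no control arm")

  r0 <- score_indicator(ind, control = c(0, 0), treatment = 60)
  expect_true(is.na(r0$utility_impact))
  expect_match(r0$flags, "control level zero")
})

test_that("unit declarations are enforced by string equality", {
  ind <- mini_config()$indicators$yield
  expect_error(score_indicator(ind, 8, 9, unit = "kg/ha"), "unit mismatch")
  expect_silent(score_indicator(ind, 8, 9, unit = "t/ha"))
})

test_that("partially covered systems yield results plus no-data flags", {
  cfg <- default_config()
  spec <- synthetic_trial_spec(seed = 5, n_farms = 1, cv = 0,
                               mask_themes = "plant_health")
  tr <- generate_trials(spec, cfg)[[1]]
  s <- score_trial(cfg, tr)
  expect_equal(nrow(s), 29L)
  expect_length(attr(s, "missing_indicators"), 10L)
  expect_true(all(grepl("^plant_health", attr(s, "missing_indicators"))))

  bad <- tr
  bad$measurements$indicator_id[1] <- "not_an_indicator"
  expect_error(score_trial(cfg, bad), "not_an_indicator")

  empty <- trial_dataset("f0", data.frame(indicator_id = character(),
                                          arm = character(),
                                          value = numeric()))
  expect_warning(s0 <- score_trial(cfg, empty), "no measurements")
  expect_equal(nrow(s0), 0L)
})

test_that("field data survive the CSV dialect round trip", {
  cfg <- mini_config()
  trials <- generate_trials(
    synthetic_trial_spec(seed = 9, n_farms = 2, replicates = 2, cv = 0.1),
    cfg)
  path <- withr::local_tempfile(fileext = ".csv")
  write_trial_csv(trials, path)
  back <- read_trial_csv(path)
  expect_length(back, 2L)
  for (i in 1:2) {
    a <- trials[[i]]$measurements
    b <- back[[trials[[i]]$farm_id]]$measurements
    expect_equal(b$value, a$value, tolerance = 1e-12)
    expect_identical(b$indicator_id, a$indicator_id)
    expect_identical(b$arm, a$arm)
  }
  writeLines("farm,indicator,values", path)
  expect_error(read_trial_csv(path), "bad header")
})
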