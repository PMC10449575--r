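# Build an apoia_scores frame directly, bypassing curve evaluation, so
# aggregation arithmetic can be checked against hand-computed values.
scores_frame <- function(theme_id, u_imp, u_perf = u_imp,
                         farm = "f1", cfg = NULL) {
  d <- data.frame(indicator_id = paste0("i", seq_along(u_imp)),
                  theme_id = theme_id,
                  index_impact = 0, index_performance = 0,
                  utility_impact = u_imp, utility_performance = u_perf,
                  flags = "", stringsAsFactors = FALSE)
  attr(d, "farm_id") <- farm
  attr(d, "missing_indicators") <- character()
  class(d) <- c("apoia_scores", class(d))
  d
}

two_theme_config <- function(sizes = c(2L, 6L)) {
  ids <- paste0("i", seq_len(sum(sizes)))
  themes <- list(
    theme_definition("A", "theme A", ids[seq_len(sizes[1])]),
    theme_definition("B", "theme B", ids[sizes[1] + seq_len(sizes[2])]))
  inds <- lapply(seq_along(ids), function(i)
    indicator_definition(ids[i], ids[i],
                         if (i <= sizes[1]) "A" else "B", "u", "positive",
                         c(0, 10), 5,
                         impact_table = correspondence_table(
                           c(-50, 0, 50), c(0.3, 0.7, 1.0)),
                         performance_table = correspondence_table(
                           c(0, 5, 10), c(0.1, 0.7, 1.0))))
  system_config(themes, inds)
}

test_that("constant utilities aggregate to the same constant", {
  cfg <- two_theme_config()
  s <- scores_frame(rep(c("A", "B"), c(2, 6)), rep(0.7, 8))
  a <- aggregate_scores(s, cfg)
  expect_equal(a$themes$impact_index, c(0.7, 0.7))
  expect_equal(a$overall_impact, 0.7)
  # equal member utilities average to the theme value
  s2 <- scores_frame(rep(c("A", "B"), c(2, 6)), c(0.84, 0.84, rep(0.7, 6)))
  a2 <- aggregate_scores(s2, cfg)
  expect_equal(a2$themes$impact_index[a2$themes$theme_id == "A"], 0.84)
})

test_that("overall index is the pooled mean, not the mean of theme means", {
  cfg <- two_theme_config(c(2L, 6L))
  u <- c(0.9, 0.8, rep(0.6, 6))
  s <- scores_frame(rep(c("A", "B"), c(2, 6)), u)
  a <- aggregate_scores(s, cfg)
  pooled <- mean(u)                       # 0.675
  theme_means <- mean(c(mean(u[1:2]), mean(u[3:8])))  # 0.725
  expect_equal(a$overall_impact, pooled)
  expect_equal(a$overall_impact_theme_mean, theme_means)
  expect_false(isTRUE(all.equal(pooled, theme_means)))
})

test_that("theme indices respect mean bounds and permutation invariance", {
  set.seed(21)
  cfg <- two_theme_config()
  for (rep in 1:10) {
    u <- runif(8)
    s <- aggregate_scores(scores_frame(rep(c("A", "B"), c(2, 6)), u), cfg)
    for (i in seq_len(nrow(s$themes))) {
      members <- u[rep(c("A", "B"), c(2, 6)) == s$themes$theme_id[i]]
      expect_gte(s$themes$impact_index[i], min(members))
      expect_lte(s$themes$impact_index[i], max(members))
    }
    perm <- sample(8)
    sf <- scores_frame(rep(c("A", "B"), c(2, 6))[perm], u[perm])
    sf$indicator_id <- paste0("i", perm)
    sp <- aggregate_scores(sf, cfg)
    expect_equal(sp$themes[order(sp$themes$theme_id), -1],
                 s$themes[order(s$themes$theme_id), -1])
    expect_equal(sp$overall_impact, s$overall_impact)
  }
})

test_that("adding an indicator at the theme mean leaves the index unchanged", {
  cfg <- two_theme_config(c(2L, 3L))
  u <- c(0.8, 0.6, 0.5, 0.7, 0.9)
  s <- aggregate_scores(scores_frame(rep(c("A", "B"), c(2, 3)), u), cfg)
  b_mean <- s$themes$impact_index[s$themes$theme_id == "B"]
  cfg4 <- two_theme_config(c(2L, 4L))
  u4 <- c(u, b_mean)
  s4 <- aggregate_scores(scores_frame(rep(c("A", "B"), c(2, 4)), u4), cfg4)
  expect_equal(s4$themes$impact_index[s4$themes$theme_id == "B"], b_mean)
})

test_that("unscored themes are absent and excluded from the overall index", {
  cfg <- default_config()
  tr <- generate_trials(synthetic_trial_spec(seed = 2, n_farms = 1, cv = 0,
                                             mask_themes = "plant_health"),
                        cfg)[[1]]
  a <- apoia(cfg, tr)
  expect_equal(nrow(a$themes), 4L)
  expect_false("plant_health" %in% a$themes$theme_id)
  expect_equal(nrow(a$indicators), 29L)
})

test_that("assessments survive the JSON round trip", {
  cfg <- default_config()
  tr <- generate_trials(demo_spec(31), cfg)[[1]]
  a <- apoia(cfg, tr)
  b <- assessment_from_json(assessment_to_json(a))
  expect_equal(b$overall_impact, a$overall_impact, tolerance = 1e-12)
  expect_equal(b$themes, a$themes, tolerance = 1e-12)
  expect_equal(as.data.frame(b), as.data.frame(a), tolerance = 1e-12)
  expect_identical(b$missing_indicators, a$missing_indicators)
  expect_identical(b$farm_id, a$farm_id)
})

test_that("the report bundle contains summary, theme charts, table and JSON", {
  cfg <- default_config()
  tr <- generate_trials(demo_spec(32), cfg)[[1]]
  a <- apoia(cfg, tr)
  dir <- withr::local_tempdir()
  files <- render_report(a, dir)
  expect_true(all(file.exists(unlist(files))))
  expect_length(files, 3 + nrow(a$themes))  # summary + per-theme + csv + json
  tab <- read.csv(files$table)
  expect_equal(nrow(tab), nrow(a$indicators))
})
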