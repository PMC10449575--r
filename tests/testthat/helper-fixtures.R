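# Small fixtures built in code.

# Two-theme, three-indicator system for fast scoring tests.
mini_config <- function() {
  up <- correspondence_table(c(-50, 0, 50), c(0.3, 0.7, 1.0))
  down <- correspondence_table(c(-50, 0, 50), c(1.0, 0.7, 0.3))
  inds <- list(
    indicator_definition("yield", "Yield", "prod", "t/ha", "positive",
                         c(0, 20), 8,
                         impact_table = up,
                         performance_table = correspondence_table(
                           c(0, 8, 20), c(0.1, 0.7, 1.0))),
    indicator_definition("enzyme", "Enzyme", "soil", "mg/kg/h", "positive",
                         c(0, 200), 60,
                         impact_table = up,
                         performance_table = correspondence_table(
                           c(0, 60, 200), c(0.1, 0.7, 1.0))),
    indicator_definition("compaction", "Compaction", "soil", "MPa", "negative",
                         c(0, 6), 2.5,
                         impact_table = down,
                         performance_table = correspondence_table(
                           c(0, 2.5, 6), c(1.0, 0.7, 0.1))))
  system_config(
    list(theme_definition("prod", "production", "yield"),
         theme_definition("soil", "soil quality", c("enzyme", "compaction"))),
    inds)
}

# A paired trial over mini_config with given per-indicator arm levels.
mini_trial <- function(levels, farm_id = "f1") {
  rows <- do.call(rbind, lapply(names(levels), function(id)
    data.frame(indicator_id = id,
               arm = rep(c("control", "biostimulant"),
                         times = c(length(levels[[id]]$control),
                                   length(levels[[id]]$treatment))),
               value = c(levels[[id]]$control, levels[[id]]$treatment))))
  trial_dataset(farm_id, rows)
}

# Random calibrated indicator: monotone utilities passing through the
# anchor (0, 0.7); direction positive by construction.
random_indicator <- function(id = "rnd") {
  n_lo <- sample(1:3, 1); n_hi <- sample(1:3, 1)
  x <- c(sort(-runif(n_lo, 1, 80)), 0, sort(runif(n_hi, 1, 80)))
  u <- c(sort(runif(n_lo, 0, 0.7)), 0.7, sort(runif(n_hi, 0.7, 1)))
  lo <- min(x) - runif(1, 0, 10); hi <- max(x) + runif(1, 0, 10)
  indicator_definition(id, id, "t", "u", "positive", c(lo, hi),
                       baseline_level = 0,
                       impact_table = correspondence_table(x, u),
                       performance_table = correspondence_table(x, u))
}
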