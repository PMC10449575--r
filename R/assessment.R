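#' Aggregate indicator utilities into theme and overall indices
#'
#' Theme indices are unweighted arithmetic means of the member
#' indicators' utilities, computed only over indicators with data; themes
#' with no scored indicator are reported as absent and excluded from the
#' overall index.  The overall impact and performance indices are pooled
#' means over all scored indicators — not means of theme means, which
#' differ when theme sizes are unequal; the theme-mean average is also
#' reported for comparison.
#'
#' @param scores an `"apoia_scores"` data.frame from [score_trial()].
#' @param config the `"apoia_config"` the scores were computed against.
#' @return an object of class `"apoia_assessment"`: `farm_id`,
#'   `indicators` (the scores), `themes` (per-theme indices),
#'   `overall_impact`, `overall_performance`,
#'   `overall_impact_theme_mean`, `overall_performance_theme_mean`,
#'   `baseline`, `missing_indicators`.
#' @export
aggregate_scores <- function(scores, config) {
  stopifnot(inherits(scores, "apoia_scores"), inherits(config, "apoia_config"))
  theme_rows <- lapply(config$themes, function(th) {
    s <- scores[scores$theme_id == th$theme_id, , drop = FALSE]
    if (!nrow(s)) return(NULL)
    data.frame(theme_id = th$theme_id, name = th$name,
               impact_index = mean(s$utility_impact, na.rm = TRUE),
               performance_index = mean(s$utility_performance, na.rm = TRUE),
               n_indicators_scored = nrow(s), stringsAsFactors = FALSE)
  })
  themes <- do.call(rbind, c(theme_rows, make.row.names = FALSE))
  baselines <- vapply(config$indicators, `[[`, 0, "baseline_utility")
  structure(list(
    farm_id = attr(scores, "farm_id"),
    indicators = scores,
    themes = themes,
    overall_impact = mean(scores$utility_impact, na.rm = TRUE),
    overall_performance = mean(scores$utility_performance, na.rm = TRUE),
    overall_impact_theme_mean = mean(themes$impact_index),
    overall_performance_theme_mean = mean(themes$performance_index),
    baseline = unname(baselines[1L]),
    missing_indicators = attr(scores, "missing_indicators")),
    class = "apoia_assessment")
}

#' Score and aggregate a trial in one call
#'
#' Convenience wrapper running [score_trial()] then [aggregate_scores()].
#'
#' @inheritParams score_trial
#' @return an `"apoia_assessment"`.
#' @examples
#' cfg <- default_config()
#' tr <- generate_trials(synthetic_trial_spec(seed = 1, n_farms = 1), cfg)[[1]]
#' a <- apoia(cfg, tr)
#' a$overall_impact
#' @export
apoia <- function(config, trial, summarize = c("mean", "median")) {
  aggregate_scores(score_trial(config, trial, summarize), config)
}

#' @export
print.apoia_assessment <- function(x, ...) {
  cat(sprintf("Assessment of farm '%s' (baseline %.2f)\n", x$farm_id,
              x$baseline))
  if (!is.null(x$themes)) {
    t <- x$themes
    for (i in seq_len(nrow(t)))
      cat(sprintf("  %-16s impact %.3f  performance %.3f  (n = %d)\n",
                  t$name[i], t$impact_index[i], t$performance_index[i],
                  t$n_indicators_scored[i]))
  }
  cat(sprintf("  overall (pooled)  impact %.3f  performance %.3f  over %d indicators\n",
              x$overall_impact, x$overall_performance, nrow(x$indicators)))
  if (length(x$missing_indicators))
    cat("  no data for:", paste(x$missing_indicators, collapse = ", "), "\n")
  invisible(x)
}

#' @export
summary.apoia_assessment <- function(object, ...) {
  print(object)
  cat("\nPer-indicator utilities:\n")
  print(as.data.frame(object$indicators), row.names = FALSE, digits = 3)
  invisible(object)
}

#' @export
as.data.frame.apoia_assessment <- function(x, ...) {
  d <- x$indicators
  class(d) <- "data.frame"
  d
}

#' Summary chart of theme and overall indices
#'
#' Grouped bars of per-theme impact (blue) and technical-performance
#' (magenta) indices, two pooled overall bars, and the baseline drawn as
#' a red horizontal line.
#'
#' @param x an `"apoia_assessment"`.
#' @param ... passed to [graphics::barplot()].
#' @export
plot.apoia_assessment <- function(x, ...) {
  t <- x$themes
  vals <- rbind(impact = c(t$impact_index, overall = x$overall_impact),
                performance = c(t$performance_index, x$overall_performance))
  colnames(vals) <- c(t$theme_id, "overall")
  graphics::barplot(vals, beside = TRUE, ylim = c(0, 1),
                    col = c("steelblue", "magenta"),
                    legend.text = c("impact", "technical performance"),
                    args.legend = list(x = "topright", bty = "n"),
                    ylab = "utility index", las = 2, ...)
  graphics::abline(h = x$baseline, col = "red", lwd = 2)
  invisible(x)
}

# ---- report bundle ----------------------------------------------------------

#' Render an assessment as a report bundle
#'
#' Emits (i) the summary chart (per-theme and overall indices with the
#' baseline), (ii) one per-theme indicator chart, (iii) a delimited
#' results table, and (iv) a JSON document round-trippable via
#' [assessment_from_json()].
#'
#' @param a an `"apoia_assessment"`.
#' @param dir output directory (created if needed).
#' @param format figure device, `"png"` or `"pdf"`.
#' @return invisibly, a named list of written file paths.
#' @export
render_report <- function(a, dir, format = c("png", "pdf")) {
  stopifnot(inherits(a, "apoia_assessment"))
  format <- match.arg(format)
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  dev <- if (format == "png") function(f) grDevices::png(f, 900, 600)
         else function(f) grDevices::pdf(f, 9, 6)
  files <- list()
  f <- file.path(dir, paste0("summary.", format))
  dev(f); plot(a, main = paste("Assessment summary:", a$farm_id))
  grDevices::dev.off()
  files$summary <- f
  for (tid in a$themes$theme_id) {
    s <- a$indicators[a$indicators$theme_id == tid, , drop = FALSE]
    f <- file.path(dir, paste0("theme_", tid, ".", format))
    dev(f)
    vals <- rbind(impact = s$utility_impact,
                  performance = s$utility_performance)
    colnames(vals) <- s$indicator_id
    graphics::barplot(vals, beside = TRUE, ylim = c(0, 1),
                      col = c("steelblue", "magenta"), las = 2,
                      ylab = "utility index", main = tid)
    graphics::abline(h = a$baseline, col = "red", lwd = 2)
    grDevices::dev.off()
    files[[paste0("theme_", tid)]] <- f
  }
  f <- file.path(dir, "results.csv")
  utils::write.csv(as.data.frame(a), f, row.names = FALSE)
  files$table <- f
  f <- file.path(dir, "assessment.json")
  writeLines(assessment_to_json(a), f)
  files$json <- f
  invisible(files)
}

#' Serialize an assessment to JSON
#'
#' @param a an `"apoia_assessment"`.
#' @return a JSON string; [assessment_from_json()] restores an identical
#'   assessment.
#' @export
assessment_to_json <- function(a) {
  stopifnot(inherits(a, "apoia_assessment"))
  ind <- as.data.frame(a)
  jsonlite::toJSON(list(
    farm_id = a$farm_id, baseline = a$baseline,
    overall_impact = a$overall_impact,
    overall_performance = a$overall_performance,
    overall_impact_theme_mean = a$overall_impact_theme_mean,
    overall_performance_theme_mean = a$overall_performance_theme_mean,
    themes = a$themes, indicators = ind,
    missing_indicators = a$missing_indicators),
    auto_unbox = TRUE, digits = NA, na = "null")
}

#' Restore an assessment from its JSON form
#'
#' @param json a JSON string or file path as accepted by
#'   [jsonlite::fromJSON()].
#' @return an `"apoia_assessment"`.
#' @export
assessment_from_json <- function(json) {
  d <- jsonlite::fromJSON(json)
  ind <- as.data.frame(d$indicators, stringsAsFactors = FALSE)
  ind$index_impact <- as.numeric(ind$index_impact)
  ind$utility_impact <- as.numeric(ind$utility_impact)
  attr(ind, "farm_id") <- d$farm_id
  attr(ind, "missing_indicators") <- as.character(unlist(d$missing_indicators))
  class(ind) <- c("apoia_scores", class(ind))
  structure(list(
    farm_id = d$farm_id, indicators = ind,
    themes = as.data.frame(d$themes, stringsAsFactors = FALSE),
    overall_impact = d$overall_impact,
    overall_performance = d$overall_performance,
    overall_impact_theme_mean = d$overall_impact_theme_mean,
    overall_performance_theme_mean = d$overall_performance_theme_mean,
    baseline = d$baseline,
    missing_indicators = as.character(unlist(d$missing_indicators))),
    class = "apoia_assessment")
}
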