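#' Percent change between control and treatment levels
#'
#' The impact calculated index: `100 * (treatment - control) / control`.
#' A zero control level makes the ratio undefined; rather than fabricate
#' a denominator the function refuses and the caller records a flag.
#'
#' @param control summarized control-arm level (nonzero).
#' @param treatment summarized treatment-arm level.
#' @return percent change (e.g. `+50` for a 50 % lift).
#' @examples
#' percent_change(50, 75)   # +50
#' percent_change(80, 60)   # -25
#' @export
percent_change <- function(control, treatment) {
  if (!is.numeric(control) || !is.numeric(treatment) ||
      any(!is.finite(control)) || any(!is.finite(treatment)))
    stop("control and treatment levels must be finite numeric")
  if (any(control == 0))
    stop("control level is zero: percent change is undefined")
  100 * (treatment - control) / control
}

#' Assemble a paired trial dataset
#'
#' @param farm_id identifier of the assessed farm.
#' @param measurements data.frame with columns `indicator_id`, `arm`
#'   (`"control"` or `"biostimulant"`), `value` (one row per replicate)
#'   and optionally `unit`.
#' @param metadata named list (crop, location, dates, ...).
#' @return a list of class `"apoia_trial"`.
#' @export
trial_dataset <- function(farm_id, measurements, metadata = list()) {
  stopifnot(is.data.frame(measurements))
  req <- c("indicator_id", "arm", "value")
  missing_cols <- setdiff(req, names(measurements))
  if (length(missing_cols))
    stop("measurements lack column(s): ", paste(missing_cols, collapse = ", "))
  bad_arm <- setdiff(unique(measurements$arm), c("control", "biostimulant"))
  if (length(bad_arm))
    stop("unknown arm(s): ", paste(bad_arm, collapse = ", "),
         " (expected 'control' or 'biostimulant')")
  if (anyNA(measurements$value) || any(!is.finite(measurements$value)))
    stop("replicate values must be finite")
  structure(list(farm_id = farm_id, metadata = metadata,
                 measurements = measurements),
            class = "apoia_trial")
}

#' @export
print.apoia_trial <- function(x, ...) {
  m <- x$measurements
  cat(sprintf("Trial '%s': %d indicators, %d measurement rows\n",
              x$farm_id, length(unique(m$indicator_id)), nrow(m)))
  invisible(x)
}

.summarize_arm <- function(values, summarize) {
  if (summarize == "median") stats::median(values) else mean(values)
}

#' Score one indicator from paired measurements
#'
#' Summarizes the replicate values per arm (arithmetic mean by default;
#' median offered for outlier-prone profiles such as penetrometer
#' readings), computes the impact index (percent change control to
#' treatment) and the performance index (treatment-arm level), and maps
#' both through the indicator's utility curves.
#'
#' A missing control arm skips the impact index with a flag while the
#' performance index is still computed; a zero control mean likewise.
#'
#' @param ind an `"apoia_indicator"`.
#' @param control numeric replicate values for the control arm, or `NULL`.
#' @param treatment numeric replicate values for the treatment arm.
#' @param summarize `"mean"` or `"median"`.
#' @param unit measurement unit of the supplied data; when non-`NULL` it
#'   must equal the indicator's declared unit (string equality; no
#'   conversion engine).
#' @return one-row data.frame: `indicator_id`, `theme_id`,
#'   `index_impact` (% change), `index_performance` (treatment level),
#'   `utility_impact`, `utility_performance`, `flags`.
#' @export
score_indicator <- function(ind, control, treatment,
                            summarize = c("mean", "median"), unit = NULL) {
  stopifnot(inherits(ind, "apoia_indicator"))
  summarize <- match.arg(summarize)
  if (!is.null(unit) && !identical(unit, ind$units))
    stop("indicator '", ind$indicator_id, "': unit mismatch ('", unit,
         "' vs declared '", ind$units, "')")
  if (is.null(treatment) || !length(treatment))
    stop("indicator '", ind$indicator_id, "': treatment arm is empty")
  flags <- character()
  t_lvl <- .summarize_arm(treatment, summarize)
  idx1 <- u1 <- NA_real_
  if (is.null(control) || !length(control)) {
    flags <- c(flags, "no control arm: impact skipped")
  } else {
    c_lvl <- .summarize_arm(control, summarize)
    if (c_lvl == 0) {
      flags <- c(flags, "control level zero: impact undefined")
    } else {
      idx1 <- percent_change(c_lvl, t_lvl)
      u1 <- predict(utility_curve(ind, "impact"), idx1)
    }
  }
  u2 <- predict(utility_curve(ind, "performance"), t_lvl)
  data.frame(indicator_id = ind$indicator_id, theme_id = ind$theme_id,
             index_impact = idx1, index_performance = t_lvl,
             utility_impact = u1, utility_performance = u2,
             flags = paste(flags, collapse = "; "),
             stringsAsFactors = FALSE)
}

#' Score a whole trial against a system configuration
#'
#' Produces one scored row per indicator with data; indicators in the
#' configuration lacking data are omitted and listed in the
#' `"missing_indicators"` attribute.  Measurements referencing an
#' indicator unknown to the configuration raise an error naming the
#' offenders.
#'
#' @param config an `"apoia_config"`.
#' @param trial an `"apoia_trial"`.
#' @param summarize replicate summary, `"mean"` (default) or `"median"`.
#' @return a data.frame of class `"apoia_scores"` (see
#'   [score_indicator()] for columns) with attributes `farm_id` and
#'   `missing_indicators`.
#' @export
score_trial <- function(config, trial, summarize = c("mean", "median")) {
  stopifnot(inherits(config, "apoia_config"), inherits(trial, "apoia_trial"))
  summarize <- match.arg(summarize)
  m <- trial$measurements
  unknown <- setdiff(unique(m$indicator_id), names(config$indicators))
  if (length(unknown))
    stop("measurements reference indicator(s) unknown to the configuration: ",
         paste(unknown, collapse = ", "))
  if (!nrow(m))
    warning("trial '", trial$farm_id, "' has no measurements")
  rows <- list()
  missing_ind <- character()
  for (ind in config$indicators) {
    mi <- m[m$indicator_id == ind$indicator_id, , drop = FALSE]
    if (!nrow(mi)) {
      missing_ind <- c(missing_ind, ind$indicator_id)
      next
    }
    unit <- if ("unit" %in% names(mi)) unique(mi$unit) else NULL
    if (length(unit) > 1L)
      stop("indicator '", ind$indicator_id, "': inconsistent units in data")
    ctrl <- mi$value[mi$arm == "control"]
    trt <- mi$value[mi$arm == "biostimulant"]
    if (!length(trt)) {
      missing_ind <- c(missing_ind, ind$indicator_id)
      next
    }
    rows[[ind$indicator_id]] <-
      score_indicator(ind, if (length(ctrl)) ctrl else NULL, trt,
                      summarize = summarize, unit = unit)
  }
  out <- if (length(rows)) do.call(rbind, c(rows, make.row.names = FALSE))
         else data.frame(indicator_id = character(), theme_id = character(),
                         index_impact = numeric(),
                         index_performance = numeric(),
                         utility_impact = numeric(),
                         utility_performance = numeric(),
                         flags = character(), stringsAsFactors = FALSE)
  attr(out, "farm_id") <- trial$farm_id
  attr(out, "missing_indicators") <- missing_ind
  class(out) <- c("apoia_scores", class(out))
  out
}

# ---- CSV dialect ------------------------------------------------------------

.TRIAL_HEADER <- c("farm_id", "indicator_id", "arm", "replicate", "value",
                   "unit")

#' Read field data in the package CSV dialect
#'
#' Strict-header UTF-8 CSV with one row per replicate and columns
#' `farm_id, indicator_id, arm, replicate, value, unit`.
#'
#' @param path CSV file path.
#' @return a named list of `"apoia_trial"` objects, one per farm.
#' @export
read_trial_csv <- function(path) {
  d <- utils::read.csv(path, stringsAsFactors = FALSE, encoding = "UTF-8")
  if (!identical(names(d), .TRIAL_HEADER))
    stop("bad header: expected exactly '",
         paste(.TRIAL_HEADER, collapse = ","), "'")
  lapply(split(d, d$farm_id), function(df)
    trial_dataset(df$farm_id[1L],
                  df[, c("indicator_id", "arm", "value", "unit")]))
}

#' Write trials in the package CSV dialect
#'
#' @param trials a list of `"apoia_trial"` objects (or a single one).
#' @param path output CSV path.
#' @export
write_trial_csv <- function(trials, path) {
  if (inherits(trials, "apoia_trial")) trials <- list(trials)
  rows <- lapply(trials, function(tr) {
    m <- tr$measurements
    rep_id <- stats::ave(seq_len(nrow(m)),
                         m$indicator_id, m$arm, FUN = seq_along)
    data.frame(farm_id = tr$farm_id, indicator_id = m$indicator_id,
               arm = m$arm, replicate = rep_id, value = m$value,
               unit = if ("unit" %in% names(m)) m$unit else NA_character_,
               stringsAsFactors = FALSE)
  })
  utils::write.csv(do.call(rbind, rows), path, row.names = FALSE,
                   fileEncoding = "UTF-8")
  invisible(path)
}
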