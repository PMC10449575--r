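#' @title Indicator system configuration
#' @name indicator-schema
#' @description
#' An assessment system is a set of *analytical themes*, each grouping
#' measurable *indicators*.  Every indicator carries two correspondence
#' tables mapping a calculated index to the 0-1 utility scale: the
#' *impact* table over percent change (control vs. treatment) and the
#' *performance* table over the measured level in the treatment arm.
#' Both are anchored at a compliance baseline utility of 0.7.
NULL

.VALID_DIRECTIONS <- c("positive", "negative")
.SCHEMA_VERSION <- "1.0"

#' Define one analytical theme
#'
#' @param theme_id short identifier, e.g. `"soil_biology"`.
#' @param name human-readable label.
#' @param indicator_ids ordered character vector of member indicator ids.
#' @return a list of class `"apoia_theme"`.
#' @export
theme_definition <- function(theme_id, name, indicator_ids) {
  stopifnot(is.character(theme_id), length(theme_id) == 1L,
            is.character(name), length(name) == 1L,
            is.character(indicator_ids), length(indicator_ids) >= 1L)
  structure(list(theme_id = theme_id, name = name,
                 indicator_ids = indicator_ids),
            class = "apoia_theme")
}

#' Build a correspondence table
#'
#' A correspondence table is the set of (calculated index, utility) knots
#' defining an indicator's utility curve.  Knots must be strictly
#' increasing in the calculated index and utilities must lie in [0, 1].
#'
#' @param x numeric vector of calculated-index values (percent change for
#'   impact tables, measured level for performance tables).
#' @param utility numeric vector of utilities in [0, 1], same length.
#' @return a data.frame with columns `x` and `utility`.
#' @export
correspondence_table <- function(x, utility) {
  stopifnot(is.numeric(x), is.numeric(utility), length(x) == length(utility))
  if (anyNA(x) || anyNA(utility) || any(!is.finite(x)))
    stop("correspondence table values must be finite")
  if (any(utility < 0 | utility > 1))
    stop("utility values must lie in [0, 1]; found ",
         paste(utility[utility < 0 | utility > 1], collapse = ", "))
  if (length(x) >= 2L && any(diff(x) <= 0))
    stop("calculated-index values must be strictly increasing")
  data.frame(x = as.numeric(x), utility = as.numeric(utility))
}

#' Define one indicator
#'
#' @param indicator_id short identifier.
#' @param name label, e.g. `"beta-Glycosidase"`.
#' @param theme_id id of the owning theme.
#' @param units free-text measurement units, checked by string equality
#'   against supplied field data.
#' @param direction `"positive"` when larger raw values are agronomically
#'   favourable, `"negative"` when smaller values are (e.g. soil
#'   compaction, potential acidity).
#' @param explanatory_range numeric `c(lower, upper)` bounds of the
#'   performance explanatory variable, in indicator units.
#' @param baseline_level the technical-suitability level of the
#'   explanatory variable: the performance curve is anchored at
#'   `(baseline_level, baseline_utility)`.
#' @param impact_table correspondence table over percent change; must
#'   contain (or receive by anchoring) the knot `(0, baseline_utility)`.
#' @param performance_table correspondence table over measured levels.
#' @param baseline_utility compliance baseline, 0.7 by convention.
#' @param anchor logical; inject the baseline knot when absent (default
#'   `TRUE`).  With `anchor = FALSE` a table lacking the baseline knot is
#'   reported by [validate_calibration()].
#' @return a list of class `"apoia_indicator"`.
#' @export
indicator_definition <- function(indicator_id, name, theme_id, units,
                                 direction = c("positive", "negative"),
                                 explanatory_range,
                                 baseline_level,
                                 impact_table,
                                 performance_table,
                                 baseline_utility = 0.7,
                                 anchor = TRUE) {
  direction <- match.arg(direction)
  stopifnot(is.character(indicator_id), length(indicator_id) == 1L,
            is.numeric(explanatory_range), length(explanatory_range) == 2L,
            is.numeric(baseline_level), length(baseline_level) == 1L,
            is.numeric(baseline_utility), length(baseline_utility) == 1L)
  if (explanatory_range[1L] >= explanatory_range[2L])
    stop("indicator '", indicator_id,
         "': explanatory_range lower bound must be < upper bound")
  if (baseline_utility < 0 || baseline_utility > 1)
    stop("baseline_utility must lie in [0, 1]")
  if (!is.data.frame(impact_table))
    impact_table <- do.call(correspondence_table, as.list(impact_table))
  if (!is.data.frame(performance_table))
    performance_table <- do.call(correspondence_table, as.list(performance_table))
  structure(list(indicator_id = indicator_id, name = name,
                 theme_id = theme_id, units = units, direction = direction,
                 explanatory_range = as.numeric(explanatory_range),
                 baseline_level = baseline_level,
                 impact_table = impact_table,
                 performance_table = performance_table,
                 baseline_utility = baseline_utility,
                 anchor = isTRUE(anchor)),
            class = "apoia_indicator")
}

#' Assemble a system configuration
#'
#' @param themes list of [theme_definition()] objects.
#' @param indicators list of [indicator_definition()] objects.
#' @param metadata named list identifying the assessment context (farm,
#'   crop, cultivar, location, climate zone, area, years of biostimulant
#'   application, growth stage, planting and sampling dates).
#' @return a list of class `"apoia_config"`.
#' @export
system_config <- function(themes, indicators, metadata = list()) {
  ids <- vapply(indicators, `[[`, "", "indicator_id")
  if (anyDuplicated(ids))
    stop("duplicate indicator_id: ",
         paste(unique(ids[duplicated(ids)]), collapse = ", "))
  names(indicators) <- ids
  theme_ids <- vapply(themes, `[[`, "", "theme_id")
  if (anyDuplicated(theme_ids))
    stop("duplicate theme_id: ",
         paste(unique(theme_ids[duplicated(theme_ids)]), collapse = ", "))
  names(themes) <- theme_ids
  referenced <- unlist(lapply(themes, `[[`, "indicator_ids"), use.names = FALSE)
  if (anyDuplicated(referenced))
    stop("indicator assigned to more than one theme: ",
         paste(unique(referenced[duplicated(referenced)]), collapse = ", "))
  missing_def <- setdiff(referenced, ids)
  if (length(missing_def))
    stop("theme references undefined indicator(s): ",
         paste(missing_def, collapse = ", "))
  for (ind in indicators) {
    if (!ind$theme_id %in% theme_ids)
      stop("indicator '", ind$indicator_id, "' references unknown theme '",
           ind$theme_id, "'")
    if (!ind$indicator_id %in% themes[[ind$theme_id]]$indicator_ids)
      stop("indicator '", ind$indicator_id,
           "' is not listed by its theme '", ind$theme_id, "'")
  }
  structure(list(schema_version = .SCHEMA_VERSION, metadata = metadata,
                 themes = themes, indicators = indicators),
            class = "apoia_config")
}

#' @export
print.apoia_config <- function(x, ...) {
  cat("Indicator system configuration (schema", x$schema_version, ")\n")
  for (th in x$themes)
    cat(sprintf("  %-16s %-16s %2d indicators\n", th$theme_id, th$name,
                length(th$indicator_ids)))
  cat("  total:", length(x$indicators), "indicators\n")
  invisible(x)
}

# ---- default system ---------------------------------------------------------

# Default correspondence tables.  Impact tables span -50 % .. +50 % change
# with the mandatory (0, 0.7) anchor; performance tables span the
# explanatory range with the (baseline_level, 0.7) anchor.  For
# negative-direction indicators the utilities decrease in the raw
# variable.  These knots are calibration defaults, intended to be
# overridden per deployment; only the anchoring and shapes are fixed.
.default_impact_table <- function(direction) {
  x <- c(-50, -25, 0, 25, 50)
  u <- c(0.20, 0.45, 0.70, 0.85, 1.00)
  if (direction == "negative") u <- rev(u)
  correspondence_table(x, u)
}

.default_performance_table <- function(range, baseline_level, direction) {
  lo <- range[1L]; hi <- range[2L]; b <- baseline_level
  stopifnot(lo < b, b < hi)
  x <- c(lo, (lo + b) / 2, b, (b + hi) / 2, hi)
  u <- c(0.10, 0.40, 0.70, 0.85, 1.00)
  if (direction == "negative") u <- rev(u)
  correspondence_table(x, u)
}

.default_indicator <- function(id, name, theme, units, range, baseline_level,
                               direction = "positive") {
  indicator_definition(
    indicator_id = id, name = name, theme_id = theme, units = units,
    direction = direction, explanatory_range = range,
    baseline_level = baseline_level,
    impact_table = .default_impact_table(direction),
    performance_table = .default_performance_table(range, baseline_level,
                                                   direction))
}

#' The built-in biostimulant assessment system
#'
#' Returns the default five-theme, 39-indicator system: crop development
#' and production (9 indicators), soil chemistry (9), soil physics (5),
#' soil biology (6) and plant health (10).  Named indicators follow the
#' published system structure; the ten plant-health indicators are shipped
#' as configurable placeholders (`plant_health_01` ... `plant_health_10`)
#' so the theme is structurally complete but inert until calibrated.
#' Correspondence tables other than the anchoring convention are
#' deployment calibration defaults (see the package vignette).
#'
#' @param metadata optional identification metadata (see [system_config()]).
#' @return an `"apoia_config"` object.
#' @examples
#' cfg <- default_config()
#' length(cfg$indicators)                       # 39
#' cfg$indicators$beta_glycosidase$explanatory_range  # 0 200
#' @export
default_config <- function(metadata = list()) {
  d <- .default_indicator
  crop <- list(
    d("stand_quality",   "Stand quality",        "crop_production", "plants per transect",   c(0, 100),  60),
    d("plant_vigor_1",   "Plant vigor 1 (leaves per plant)",     "crop_production", "leaves per plant",      c(0, 30),   15),
    d("plant_vigor_2",   "Plant vigor 2 (pods or grains per plant)", "crop_production", "pods or grains per plant", c(0, 120), 50),
    d("plant_vigor_3",   "Plant vigor 3 (stem length)",          "crop_production", "cm",                    c(0, 250),  120),
    d("plant_vigor_4",   "Plant vigor 4 (average plant height)", "crop_production", "cm",                    c(0, 300),  150),
    d("rooting",         "Rooting",              "crop_production", "root development score", c(0, 10),   6),
    d("product_quality", "Product quality",      "crop_production", "crop quality units",    c(0, 100),  60),
    d("crop_productivity", "Crop productivity",  "crop_production", "bags or t per ha",      c(0, 200),  80),
    d("net_revenue",     "Net revenue",          "crop_production", "$ per ha",              c(0, 5000), 1500))
  chem <- list(
    d("ph",              "pH",                   "soil_chemistry", "pH (CaCl2)",             c(3, 9),    5.5),
    d("p",               "Phosphorus (P)",       "soil_chemistry", "mg dm-3",                c(0, 100),  15),
    d("k",               "Potassium (K)",        "soil_chemistry", "mmolc dm-3",             c(0, 15),   3),
    d("ca_mg",           "Calcium + Magnesium (Ca+Mg)", "soil_chemistry", "mmolc dm-3",      c(0, 120),  40),
    d("cec",             "Cation exchange capacity (CEC)", "soil_chemistry", "mmolc dm-3",   c(0, 200),  80),
    d("total_bases",     "Total bases",          "soil_chemistry", "mmolc dm-3",             c(0, 150),  50),
    d("base_saturation", "Base saturation",      "soil_chemistry", "%",                      c(0, 100),  50),
    d("potential_acidity", "Potential acidity (H+Al)", "soil_chemistry", "mmolc dm-3",       c(0, 120),  40, "negative"),
    d("organic_matter",  "Organic matter",       "soil_chemistry", "g dm-3",                 c(0, 80),   25))
  phys <- list(
    d("soil_compaction", "Soil compaction",      "soil_physics", "MPa (penetrometer resistance)", c(0, 6), 2.5, "negative"),
    d("bulk_density",    "Bulk density",         "soil_physics", "g cm-3",                 c(0.8, 2),  1.4, "negative"),
    d("water_infiltration", "Water infiltration", "soil_physics", "mm h-1",                c(0, 300),  60),
    d("aggregate_stability", "Aggregate stability", "soil_physics", "% stable aggregates", c(0, 100),  60),
    d("water_holding",   "Water holding capacity", "soil_physics", "% field capacity",     c(0, 60),   25))
  biol <- list(
    d("arylsulfatase",   "Arylsulfatase",        "soil_biology", "mg p-nitrophenol kg soil-1 h-1", c(0, 120), 40),
    d("beta_glycosidase", "beta-Glycosidase",    "soil_biology", "mg p-nitrophenol kg soil-1 h-1", c(0, 200), 60),
    d("acid_phosphatase", "Acid phosphatase",    "soil_biology", "mg p-nitrophenol kg soil-1 h-1", c(0, 800), 300),
    d("urease",          "Urease",               "soil_biology", "ug NH4-N g soil-1 2h-1", c(0, 120),  40),
    d("microbial_biomass_c", "Microbial biomass carbon", "soil_biology", "mg C kg soil-1", c(0, 800),  250),
    d("basal_respiration", "Basal respiration",  "soil_biology", "mg CO2-C kg soil-1 d-1", c(0, 60),   15))
  health <- lapply(1:10, function(i)
    d(sprintf("plant_health_%02d", i), sprintf("Plant health %02d (placeholder)", i),
      "plant_health", "score", c(0, 10), 7))
  inds <- c(crop, chem, phys, biol, health)
  ids_of <- function(lst) vapply(lst, `[[`, "", "indicator_id")
  themes <- list(
    theme_definition("crop_production", "crop production", ids_of(crop)),
    theme_definition("soil_chemistry",  "soil chemistry",  ids_of(chem)),
    theme_definition("soil_physics",    "soil physics",    ids_of(phys)),
    theme_definition("soil_biology",    "soil biology",    ids_of(biol)),
    theme_definition("plant_health",    "plant health",    ids_of(health)))
  system_config(themes, inds, metadata)
}

# ---- calibration checks -----------------------------------------------------

#' Calibration checks for an indicator definition
#'
#' Runs the probability test (the explanatory-variable thresholds bracket
#' the performance table's domain and the declared direction is consistent
#' with the utility monotonicity of both tables) and the sensitivity test
#' (the baseline anchor is available and the utility response over the
#' table has nonzero amplitude).  Findings are returned, not raised; an
#' empty character vector means the indicator is calibrated.
#'
#' @param ind an `"apoia_indicator"`.
#' @return character vector of findings (empty when calibrated).
#' @export
validate_calibration <- function(ind) {
  stopifnot(inherits(ind, "apoia_indicator"))
  findings <- character()
  say <- function(...) findings <<- c(findings, paste0(...))
  rng <- ind$explanatory_range
  if (rng[1L] >= rng[2L]) say("invalid explanatory range")
  for (which in c("impact", "performance")) {
    tab <- ind[[paste0(which, "_table")]]
    if (nrow(tab) < 2L) {
      say(which, " table degenerate (fewer than 2 points)")
      next
    }
    du <- diff(tab$utility)
    mono_up   <- all(du >= -1e-9)
    mono_down <- all(du <=  1e-9)
    want_up <- ind$direction == "positive"
    if (!(mono_up || mono_down))
      say(which, " table utilities not monotone")
    else if ((want_up && !mono_up) || (!want_up && !mono_down))
      say(which, " table: direction/monotonicity conflict")
    if (max(tab$utility) - min(tab$utility) <= 1e-9)
      say(which, " table has zero utility amplitude (insensitive)")
  }
  # probability test: performance knots must lie inside the thresholds
  ptab <- ind$performance_table
  if (nrow(ptab) && (min(ptab$x) < rng[1L] - 1e-9 ||
                     max(ptab$x) > rng[2L] + 1e-9))
    say("performance table extends outside the explanatory thresholds")
  if (ind$baseline_level < rng[1L] || ind$baseline_level > rng[2L])
    say("baseline level outside the explanatory thresholds")
  # sensitivity test: the anchor must be present or injectable
  has0 <- any(abs(ind$impact_table$x) <= 1e-9)
  if (has0) {
    u0 <- ind$impact_table$utility[which.min(abs(ind$impact_table$x))]
    if (abs(u0 - ind$baseline_utility) > 1e-9)
      say("impact table knot at 0 % conflicts with the baseline utility")
  } else if (!ind$anchor) {
    say("missing baseline anchor")
  }
  findings
}

# ---- serialization ----------------------------------------------------------

.indicator_to_list <- function(ind) {
  list(indicator_id = ind$indicator_id, name = ind$name,
       theme_id = ind$theme_id, units = ind$units,
       direction = ind$direction,
       explanatory_range = ind$explanatory_range,
       baseline_level = ind$baseline_level,
       baseline_utility = ind$baseline_utility,
       anchor = ind$anchor,
       impact_table = list(x = ind$impact_table$x,
                           utility = ind$impact_table$utility),
       performance_table = list(x = ind$performance_table$x,
                                utility = ind$performance_table$utility))
}

#' Write a system configuration to YAML
#'
#' @param config an `"apoia_config"`.
#' @param path file path; when `NULL` the YAML text is returned.
#' @return `path` invisibly, or the YAML string when `path = NULL`.
#' @seealso [load_config()]
#' @export
write_config <- function(config, path = NULL) {
  stopifnot(inherits(config, "apoia_config"))
  doc <- list(
    schema_version = config$schema_version,
    metadata = config$metadata,
    themes = lapply(unname(config$themes), function(th)
      list(theme_id = th$theme_id, name = th$name,
           indicator_ids = th$indicator_ids)),
    indicators = lapply(unname(config$indicators), .indicator_to_list))
  txt <- yaml::as.yaml(doc, precision = 15L)
  if (is.null(path)) return(txt)
  writeLines(txt, path)
  invisible(path)
}

#' Load and validate a system configuration
#'
#' Reads a YAML document with `schema_version`, `metadata`, `themes` and
#' `indicators` keys and enforces every structural invariant (utilities in
#' [0, 1], strictly increasing knots, unique ids, complete theme
#' membership).  Violations raise errors naming the offending indicator
#' and field.
#'
#' @param source path to a YAML file, or a YAML string.
#' @return an `"apoia_config"`.
#' @export
load_config <- function(source) {
  doc <- if (length(source) == 1L && !grepl("\n", source) &&
             file.exists(source)) yaml::read_yaml(source)
         else yaml::yaml.load(paste(source, collapse = "\n"))
  for (key in c("themes", "indicators"))
    if (is.null(doc[[key]])) stop("config is missing required key '", key, "'")
  themes <- lapply(doc$themes, function(th) {
    for (f in c("theme_id", "name", "indicator_ids"))
      if (is.null(th[[f]])) stop("theme is missing field '", f, "'")
    theme_definition(th$theme_id, th$name, unlist(th$indicator_ids))
  })
  indicators <- lapply(doc$indicators, function(it) {
    for (f in c("indicator_id", "name", "theme_id", "units", "direction",
                "explanatory_range", "baseline_level", "impact_table",
                "performance_table"))
      if (is.null(it[[f]]))
        stop("indicator '", if (is.null(it$indicator_id)) "<unnamed>"
             else it$indicator_id, "' is missing field '", f, "'")
    tab <- function(t, lbl) tryCatch(
      correspondence_table(unlist(t$x), unlist(t$utility)),
      error = function(e) stop("indicator '", it$indicator_id, "', ", lbl,
                               ": ", conditionMessage(e), call. = FALSE))
    indicator_definition(
      indicator_id = it$indicator_id, name = it$name, theme_id = it$theme_id,
      units = it$units, direction = it$direction,
      explanatory_range = unlist(it$explanatory_range),
      baseline_level = it$baseline_level,
      impact_table = tab(it$impact_table, "impact_table"),
      performance_table = tab(it$performance_table, "performance_table"),
      baseline_utility = if (is.null(it$baseline_utility)) 0.7
                         else it$baseline_utility,
      anchor = if (is.null(it$anchor)) TRUE else it$anchor)
  })
  system_config(themes, indicators,
                metadata = if (is.null(doc$metadata)) list() else doc$metadata)
}
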