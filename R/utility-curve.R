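#' Build a utility curve from an indicator's correspondence table
#'
#' Converts a correspondence table into an evaluable curve on the 0-1
#' utility scale.  The baseline anchor is enforced by knot injection:
#' impact curves always pass exactly through `(0, baseline_utility)` and
#' performance curves through `(baseline_level, baseline_utility)`.
#'
#' Two fitting modes are available.  The default,
#' `fit = "interpolate"`, is monotone piecewise-linear interpolation
#' through the knots — the unique assumption-free monotone curve through
#' the correspondence structure, reproducing every knot exactly.
#' `fit = "least-squares"` fits a polynomial minimizing squared knot
#' error subject to the exact baseline-anchor constraint (the anchor is
#' absorbed into the basis so it holds by construction); it is intended
#' for parity experiments with externally fitted "best fit equations"
#' and does not guarantee monotonicity between knots.
#'
#' Evaluation clamps the input to the curve domain (values beyond the
#' thresholds take the endpoint utility) and the output to [0, 1].
#'
#' @param ind an `"apoia_indicator"` (see [indicator_definition()]).
#' @param which `"impact"` (curve over percent change) or
#'   `"performance"` (curve over measured level).
#' @param fit `"interpolate"` (default) or `"least-squares"`.
#' @param degree polynomial degree for the least-squares mode.
#' @return an object of class `"utility_curve"` with elements `knots`,
#'   `fit_kind`, `coefficients`, `domain`, `anchor_x`, `baseline_utility`,
#'   `direction`, `indicator_id`, `which`.
#' @examples
#' ind <- default_config()$indicators$beta_glycosidase
#' cv <- utility_curve(ind, "impact")
#' predict(cv, 0)     # 0.7, the baseline axiom
#' predict(cv, 1e6)   # clamped to the top-knot utility
#' @export
utility_curve <- function(ind, which = c("impact", "performance"),
                          fit = c("interpolate", "least-squares"),
                          degree = 3L) {
  stopifnot(inherits(ind, "apoia_indicator"))
  which <- match.arg(which)
  fit <- match.arg(fit)
  tab <- ind[[paste0(which, "_table")]]
  if (nrow(tab) < 2L)
    stop("indicator '", ind$indicator_id, "': ", which,
         " table is degenerate (fewer than 2 points)")
  findings <- validate_calibration(ind)
  conflict <- grepl("monotone|conflict", findings) &
    grepl(which, findings, fixed = TRUE)
  if (any(conflict))
    stop("indicator '", ind$indicator_id, "' fails calibration: ",
         paste(findings[conflict], collapse = "; "))
  anchor_x <- if (which == "impact") 0 else ind$baseline_level
  u0 <- ind$baseline_utility
  if (ind$anchor) {
    at <- which(abs(tab$x - anchor_x) <= 1e-9)
    if (length(at)) {
      if (abs(tab$utility[at] - u0) > 1e-9)
        stop("indicator '", ind$indicator_id, "': knot at the anchor (",
             anchor_x, ") conflicts with baseline utility ", u0)
      tab$utility[at] <- u0
    } else {
      tab <- rbind(tab, data.frame(x = anchor_x, utility = u0))
      tab <- tab[order(tab$x), , drop = FALSE]
      row.names(tab) <- NULL
    }
  }
  coefficients <- NULL
  if (fit == "least-squares") {
    # basis (x - anchor)^k without intercept: curve(anchor) = u0 exactly
    dg <- min(as.integer(degree), nrow(tab) - 1L)
    B <- outer(tab$x - anchor_x, seq_len(dg), "^")
    coefficients <- stats::coef(stats::lm.fit(B, tab$utility - u0))
    coefficients[is.na(coefficients)] <- 0
  }
  structure(list(knots = tab, fit_kind = fit, coefficients = coefficients,
                 domain = range(tab$x), anchor_x = anchor_x,
                 baseline_utility = u0, direction = ind$direction,
                 indicator_id = ind$indicator_id, which = which,
                 flags = findings),
            class = "utility_curve")
}

#' Evaluate a utility curve
#'
#' @param object a `"utility_curve"`.
#' @param x numeric vector of calculated indices; must be finite.
#' @param ... unused.
#' @return utilities in [0, 1], same length as `x`.  Inputs below the
#'   lower threshold return the utility at the lower threshold, inputs
#'   above the upper threshold the utility at the upper threshold.
#' @export
predict.utility_curve <- function(object, x, ...) {
  if (!is.numeric(x) || anyNA(x) || any(!is.finite(x)))
    stop("calculated index must be finite numeric")
  xc <- pmin(pmax(x, object$domain[1L]), object$domain[2L])
  u <- if (object$fit_kind == "interpolate") {
    stats::approx(object$knots$x, object$knots$utility, xout = xc,
                  method = "linear", rule = 2, ties = "ordered")$y
  } else {
    dg <- length(object$coefficients)
    drop(outer(xc - object$anchor_x, seq_len(dg), "^") %*%
           object$coefficients) + object$baseline_utility
  }
  pmin(pmax(u, 0), 1)
}

#' @export
print.utility_curve <- function(x, ...) {
  cat(sprintf("Utility curve: %s (%s index), %s fit\n", x$indicator_id,
              x$which, x$fit_kind))
  cat(sprintf("  domain [%g, %g], anchor (%g, %g), direction %s\n",
              x$domain[1L], x$domain[2L], x$anchor_x, x$baseline_utility,
              x$direction))
  cat("  knots:\n")
  print(x$knots, row.names = FALSE)
  invisible(x)
}

#' Plot a utility curve with its knots and baseline
#'
#' Draws the calculated-index vs. utility correspondence with knot
#' markers and the baseline level.
#'
#' @param x a `"utility_curve"`.
#' @param n grid resolution.
#' @param ... passed to [graphics::plot()].
#' @export
plot.utility_curve <- function(x, n = 200L, ...) {
  xs <- seq(x$domain[1L], x$domain[2L], length.out = n)
  graphics::plot(xs, predict(x, xs), type = "l", ylim = c(0, 1),
                 xlab = if (x$which == "impact") "% change (control vs treatment)"
                        else "measured level",
                 ylab = "utility", main = x$indicator_id, ...)
  graphics::points(x$knots$x, x$knots$utility, pch = 19)
  graphics::abline(h = x$baseline_utility, col = "red", lty = 2)
  graphics::abline(v = x$anchor_x, col = "grey", lty = 3)
  invisible(x)
}

#' Tabulate a curve's knots as delimited text
#'
#' @param curve a `"utility_curve"`.
#' @param path output file; when `NULL` the data.frame is returned.
#' @export
export_knots <- function(curve, path = NULL) {
  stopifnot(inherits(curve, "utility_curve"))
  tab <- curve$knots
  if (is.null(path)) return(tab)
  utils::write.csv(tab, path, row.names = FALSE)
  invisible(path)
}
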