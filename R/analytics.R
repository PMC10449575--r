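#' Build a cross-case index matrix from assessments
#'
#' Rows are case studies (farms), columns are indicators, values are the
#' chosen utility indices.  Indicators never scored in any case are
#' dropped.
#'
#' @param assessments list of `"apoia_assessment"` objects.
#' @param which `"impact"` or `"performance"`.
#' @return a numeric matrix with farm ids as row names and indicator ids
#'   as column names; missing entries are `NA`.
#' @export
index_matrix <- function(assessments, which = c("impact", "performance")) {
  which <- match.arg(which)
  col <- paste0("utility_", which)
  ids <- unique(unlist(lapply(assessments, function(a) a$indicators$indicator_id)))
  m <- t(vapply(assessments, function(a) {
    v <- stats::setNames(rep(NA_real_, length(ids)), ids)
    v[a$indicators$indicator_id] <- a$indicators[[col]]
    v
  }, stats::setNames(numeric(length(ids)), ids)))
  rownames(m) <- vapply(assessments, `[[`, "", "farm_id")
  if (anyDuplicated(colnames(m))) stop("duplicate indicator columns")
  m
}

#' Pearson correlation matrix with significance flags
#'
#' Pairwise-complete Pearson correlations between indicator index
#' columns, with two-sided p-values from the t statistic
#' `t = r * sqrt((n - 2) / (1 - r^2))` on `n - 2` degrees of freedom and
#' a significance flag at level `alpha`.  Squared correlations are
#' reported alongside.  No multiple-testing correction is applied across
#' the matrix; this is recorded in the result's `note`.
#'
#' Pairs with fewer than 3 complete observations or a constant column
#' are reported as `NA` and listed in `flags`.  For numerically perfect
#' correlations the p-value underflows; it is floored at the smallest
#' positive double so that reported p-values stay in (0, 1].
#'
#' @param m a numeric matrix (cases x indicators), e.g. from
#'   [index_matrix()].
#' @param alpha significance level (default 0.05).
#' @return an object of class `"apoia_cor"`: matrices `r`, `r2`, `p`,
#'   `n`, logical `significant`, plus `alpha`, `flags`, `note`.
#' @export
pearson_matrix <- function(m, alpha = 0.05) {
  stopifnot(is.matrix(m), is.numeric(m), ncol(m) >= 2L)
  k <- ncol(m)
  nm <- colnames(m)
  r <- p <- matrix(NA_real_, k, k, dimnames = list(nm, nm))
  nobs <- matrix(0L, k, k, dimnames = list(nm, nm))
  flags <- character()
  for (i in seq_len(k)) for (j in i:k) {
    ok <- stats::complete.cases(m[, i], m[, j])
    n <- sum(ok)
    nobs[i, j] <- nobs[j, i] <- n
    if (n < 3L) {
      flags <- c(flags, sprintf("%s~%s: fewer than 3 complete pairs",
                                nm[i], nm[j]))
      next
    }
    x <- m[ok, i]; y <- m[ok, j]
    sxx <- sum((x - mean(x))^2); syy <- sum((y - mean(y))^2)
    if (sxx == 0 || syy == 0) {
      flags <- c(flags, sprintf("%s~%s: constant column, r undefined",
                                nm[i], nm[j]))
      next
    }
    rij <- sum((x - mean(x)) * (y - mean(y))) / sqrt(sxx * syy)
    rij <- min(max(rij, -1), 1)
    pij <- if (abs(rij) >= 1) 0 else {
      tt <- rij * sqrt((n - 2) / (1 - rij^2))
      2 * stats::pt(-abs(tt), df = n - 2)
    }
    r[i, j] <- r[j, i] <- rij
    p[i, j] <- p[j, i] <- max(pij, .Machine$double.xmin)
  }
  diag(p)[!is.na(diag(r))] <- NA_real_  # self-correlation untested
  structure(list(r = r, r2 = r^2, p = p, n = nobs,
                 significant = !is.na(p) & p < alpha, alpha = alpha,
                 flags = flags,
                 note = "no multiple-testing correction applied"),
            class = "apoia_cor")
}

#' @export
print.apoia_cor <- function(x, ...) {
  cat(sprintf("Pearson correlation matrix (%d columns, alpha = %g)\n",
              ncol(x$r), x$alpha))
  cat("significant pairs:", sum(x$significant[upper.tri(x$significant)]),
      "\n")
  if (length(x$flags)) cat("flags:", length(x$flags), "\n")
  cat(x$note, "\n")
  invisible(x)
}

#' Principal component analysis with Kaiser-criterion retention
#'
#' PCA on the correlation matrix: columns are standardized and the
#' decomposition is obtained from the singular values of the
#' standardized data matrix (eigenvalues are squared singular values
#' divided by `n - 1`).  Components with eigenvalue strictly greater
#' than 1 are retained (Kaiser criterion; ties at exactly 1.0 are
#' excluded).  Per-component variance fraction is eigenvalue divided by
#' the number of columns.
#'
#' @param m numeric matrix (cases x indicators).  Missing values are
#'   handled listwise (complete rows) or by column-mean imputation, with
#'   a flag.
#' @param missing `"listwise"` or `"mean"`.
#' @return an object of class `"apoia_pca"`: `eigenvalues`, `loadings`
#'   (columns = components), `scores`, `variance_fraction`, `retained`
#'   (indices of retained components), `n`, `flags`.
#' @export
pca_kaiser <- function(m, missing = c("listwise", "mean")) {
  stopifnot(is.matrix(m), is.numeric(m), ncol(m) >= 2L)
  missing <- match.arg(missing)
  flags <- character()
  if (anyNA(m)) {
    if (missing == "listwise") {
      m <- m[stats::complete.cases(m), , drop = FALSE]
      flags <- c(flags, "incomplete rows dropped (listwise)")
    } else {
      for (j in seq_len(ncol(m)))
        m[is.na(m[, j]), j] <- mean(m[, j], na.rm = TRUE)
      flags <- c(flags, "missing values mean-imputed")
    }
  }
  if (nrow(m) < 2L) stop("need at least 2 complete rows for PCA")
  sds <- apply(m, 2L, stats::sd)
  if (any(sds == 0))
    stop("constant column(s): ",
         paste(colnames(m)[sds == 0], collapse = ", "))
  z <- scale(m)
  sv <- svd(z)
  k <- ncol(m)
  ev <- sv$d^2 / (nrow(m) - 1)
  if (length(ev) < k) ev <- c(ev, rep(0, k - length(ev)))
  loadings <- sv$v
  dimnames(loadings) <- list(colnames(m), paste0("PC", seq_len(ncol(loadings))))
  scores <- sv$u %*% diag(sv$d, nrow = length(sv$d))
  dimnames(scores) <- list(rownames(m), paste0("PC", seq_len(ncol(scores))))
  structure(list(eigenvalues = ev, loadings = loadings, scores = scores,
                 variance_fraction = ev / k,
                 retained = which(ev > 1), n = nrow(m), flags = flags),
            class = "apoia_pca")
}

#' @export
print.apoia_pca <- function(x, ...) {
  cat(sprintf("PCA on the correlation matrix: %d cases, %d components\n",
              x$n, length(x$eigenvalues)))
  d <- data.frame(eigenvalue = round(x$eigenvalues, 4),
                  variance_fraction = round(x$variance_fraction, 4),
                  retained = seq_along(x$eigenvalues) %in% x$retained)
  rownames(d) <- paste0("PC", seq_along(x$eigenvalues))
  print(d)
  if (length(x$flags)) cat("flags:", paste(x$flags, collapse = "; "), "\n")
  invisible(x)
}

#' Export PCA biplot data as delimited text
#'
#' Writes component scores and loadings of the retained components.
#'
#' @param pca an `"apoia_pca"`.
#' @param dir output directory.
#' @return invisibly, the written file paths.
#' @export
export_biplot_data <- function(pca, dir) {
  stopifnot(inherits(pca, "apoia_pca"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  keep <- if (length(pca$retained)) pca$retained else 1L
  fs <- file.path(dir, c("pca_scores.csv", "pca_loadings.csv"))
  utils::write.csv(pca$scores[, keep, drop = FALSE], fs[1L])
  utils::write.csv(pca$loadings[, keep, drop = FALSE], fs[2L])
  invisible(fs)
}
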