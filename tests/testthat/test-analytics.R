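# Independent textbook-formula oracle for one correlation pair.
pearson_oracle <- function(x, y) {
  n <- length(x)
  r <- sum((x - mean(x)) * (y - mean(y))) /
    sqrt(sum((x - mean(x))^2) * sum((y - mean(y))^2))
  t <- r * sqrt((n - 2) / (1 - r^2))
  list(r = r, p = 2 * pt(-abs(t), n - 2))
}

test_that("correlation matrix reproduces exact and degenerate cases", {
  set.seed(31)
  x <- rnorm(10)
  m <- cbind(a = x, b = -x, c = rnorm(10))
  pm <- pearson_matrix(m)
  expect_equal(unname(diag(pm$r)), rep(1, 3))
  expect_equal(pm$r["a", "b"], -1)
  expect_true(all(pm$p[!is.na(pm$p)] > 0 & pm$p[!is.na(pm$p)] <= 1))
  expect_true(all(abs(pm$r[!is.na(pm$r)]) <= 1))
  expect_true(pm$significant["a", "b"])
  expect_equal(pm$r2["a", "b"], 1)

  const <- cbind(a = x, k = rep(0.7, 10))
  pmc <- pearson_matrix(const)
  expect_true(is.na(pmc$r["a", "k"]))
  expect_match(pmc$flags, "constant column", all = FALSE)
})

test_that("r and p match the textbook formula and cor.test to 1e-10", {
  x <- c(0.61, 0.72, 0.55, 0.80, 0.69, 0.74)
  y <- c(0.58, 0.75, 0.52, 0.84, 0.66, 0.70)
  pm <- pearson_matrix(cbind(x = x, y = y))
  o <- pearson_oracle(x, y)
  expect_equal(pm$r["x", "y"], o$r, tolerance = 1e-10)
  expect_equal(pm$p["x", "y"], o$p, tolerance = 1e-10)
  ct <- cor.test(x, y)
  expect_equal(pm$r["x", "y"], unname(ct$estimate), tolerance = 1e-10)
  expect_equal(pm$p["x", "y"], ct$p.value, tolerance = 1e-10)

  set.seed(32)
  for (rep in 1:5) {
    a <- runif(8); b <- 0.5 * a + rnorm(8, sd = 0.2)
    pm <- pearson_matrix(cbind(a = a, b = b))
    o <- pearson_oracle(a, b)
    expect_equal(pm$r["a", "b"], o$r, tolerance = 1e-10)
    expect_equal(pm$p["a", "b"], o$p, tolerance = 1e-10)
  }
})

test_that("pairwise-complete correlations use the available pairs", {
  set.seed(33)
  m <- cbind(a = rnorm(8), b = rnorm(8), c = rnorm(8))
  m[1:2, 2] <- NA
  pm <- pearson_matrix(m)
  expect_equal(pm$n["a", "b"], 6L)
  expect_equal(pm$n["a", "c"], 8L)
  ok <- complete.cases(m[, "a"], m[, "b"])
  expect_equal(pm$r["a", "b"], cor(m[ok, "a"], m[ok, "b"]),
               tolerance = 1e-12)
  m[, 2] <- NA
  m[3:4, 2] <- c(1, 2)
  expect_match(pearson_matrix(m)$flags, "fewer than 3", all = FALSE)
})

test_that("PCA eigenvalues match an explicit eigendecomposition oracle", {
  set.seed(34)
  m <- matrix(rnorm(40 * 5), 40, 5,
              dimnames = list(NULL, paste0("v", 1:5)))
  m[, 2] <- m[, 1] * 0.8 + m[, 2] * 0.2
  pc <- pca_kaiser(m)
  oracle <- eigen(cor(m), symmetric = TRUE)$values
  expect_equal(pc$eigenvalues, oracle, tolerance = 1e-10)
  expect_equal(sum(pc$eigenvalues), ncol(m), tolerance = 1e-9)
  expect_equal(pc$variance_fraction, pc$eigenvalues / 5, tolerance = 1e-12)
  expect_identical(pc$retained, which(pc$eigenvalues > 1))
  # prcomp cross-check on the same standardized problem
  expect_equal(pc$eigenvalues, unname(prcomp(m, scale. = TRUE)$sdev^2),
               tolerance = 1e-10)
})

test_that("rank-one and independent-column cases behave as expected", {
  set.seed(35)
  x <- rnorm(30)
  m2 <- cbind(a = x, b = 2 * x + 3)        # perfectly correlated pair
  pc2 <- pca_kaiser(m2)
  expect_equal(pc2$eigenvalues, c(2, 0), tolerance = 1e-9)
  expect_equal(pc2$variance_fraction[1], 1, tolerance = 1e-9)
  expect_identical(pc2$retained, 1L)

  big <- matrix(rnorm(10000 * 4), ncol = 4,
                dimnames = list(NULL, paste0("v", 1:4)))
  pcb <- pca_kaiser(big)
  expect_equal(pcb$eigenvalues, rep(1, 4), tolerance = 0.1)
  expect_equal(pcb$variance_fraction, rep(0.25, 4), tolerance = 0.05)
})

test_that("missing-value policies and degenerate input are handled", {
  set.seed(36)
  m <- matrix(rnorm(20 * 3), 20, 3, dimnames = list(NULL, c("a", "b", "c")))
  m[3, 2] <- NA
  pl <- pca_kaiser(m, missing = "listwise")
  expect_equal(pl$n, 19L)
  expect_match(pl$flags, "listwise", all = FALSE)
  pi_ <- pca_kaiser(m, missing = "mean")
  expect_equal(pi_$n, 20L)
  expect_match(pi_$flags, "imputed", all = FALSE)
  expect_error(pca_kaiser(m[1, , drop = FALSE]), "at least 2")
  mc <- m; mc[, 1] <- 1
  expect_error(pca_kaiser(mc), "constant")
})

test_that("the cross-farm index matrix aligns farms and indicators", {
  cfg <- default_config()
  trials <- generate_trials(demo_spec(37), cfg)
  as <- lapply(trials, function(t) apoia(cfg, t))
  m <- index_matrix(as, "impact")
  expect_equal(dim(m), c(8L, 29L))
  expect_identical(rownames(m), vapply(as, `[[`, "", "farm_id"))
  expect_true(all(m >= 0 & m <= 1))
  expect_equal(m["farm_03", "cec"],
               as[[3]]$indicators$utility_impact[
                 as[[3]]$indicators$indicator_id == "cec"])
})
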