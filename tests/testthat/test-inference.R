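# builds an n x p data matrix whose sample correlation matrix is exactly R
data_with_exact_cor <- function(n, R, seed = 1) {
  p <- ncol(R)
  set.seed(seed)
  Z <- matrix(rnorm(n * p), n, p)
  Zc <- scale(Z, center = TRUE, scale = FALSE)
  Q <- qr.Q(qr(Zc))          # orthonormal, centred columns
  X <- Q %*% chol(R)
  colnames(X) <- colnames(R)
  as.data.frame(X * sqrt(n - 1))
}

test_that("pearson_matrix handles exact collinearity and degenerate columns", {
  x <- data.frame(a = 1:10, b = 2 * (1:10) + 3, c = -(1:10))
  cm <- pearson_matrix(x)
  expect_equal(cm$r["a", "b"], 1)
  expect_equal(cm$r["a", "c"], -1)
  expect_equal(diag(cm$r), c(a = 1, b = 1, c = 1))
  expect_error(pearson_matrix(data.frame(a = 1:5, z = rep(2, 5))), "z")
  expect_error(pearson_matrix(data.frame(a = 1:2, b = 2:3)), "3 complete rows")
})

test_that("corr_to_cov scales correlations by the SD outer product", {
  r <- matrix(c(1, 0.30, 0.30, 1), 2,
              dimnames = list(c("dvc_sudden", "dsp_p2"),
                              c("dvc_sudden", "dsp_p2")))
  s <- corr_to_cov(r, c(dvc_sudden = 5.4, dsp_p2 = 1.0))
  expect_equal(s["dvc_sudden", "dsp_p2"], 1.62)
  expect_equal(diag(s), c(dvc_sudden = 5.4^2, dsp_p2 = 1))
  expect_identical(corr_to_cov(r, c(dvc_sudden = 1, dsp_p2 = 1)), r)
  expect_error(corr_to_cov(r, c(foo = 1, dsp_p2 = 1)), "missing")
})

test_that("standardized regression reduces to closed forms in simple designs", {
  v <- c("y", "x1", "x2")
  r <- diag(3); dimnames(r) <- list(v, v)
  r["y", "x1"] <- r["x1", "y"] <- 0.6
  r["y", "x2"] <- r["x2", "y"] <- -0.3
  # orthogonal predictors: beta_i = r_yi
  m <- standardized_regression(r, "y", c("x1", "x2"), n = 50)
  expect_equal(unname(m$beta), c(0.6, -0.3), tolerance = 1e-12)
  expect_equal(m$R2, 0.6^2 + 0.3^2, tolerance = 1e-12)
  m1 <- standardized_regression(r, "y", "x1", n = 50)
  expect_equal(unname(m1$beta), 0.6)
  expect_equal(m1$df1, 1); expect_equal(m1$df2, 48)
  # collinear predictors are refused with the offending combination
  r["x1", "x2"] <- r["x2", "x1"] <- 1
  expect_error(standardized_regression(r, "y", c("x1", "x2"), n = 50),
               "collinear")
})

test_that("correlation-matrix regression equals least squares on matching data", {
  v <- c("y", "x1", "x2", "x3")
  R <- diag(4); dimnames(R) <- list(v, v)
  R["y", "x1"] <- R["x1", "y"] <- 0.5
  R["y", "x2"] <- R["x2", "y"] <- -0.3
  R["y", "x3"] <- R["x3", "y"] <- 0.2
  R["x1", "x2"] <- R["x2", "x1"] <- 0.4
  R["x1", "x3"] <- R["x3", "x1"] <- -0.1
  R["x2", "x3"] <- R["x3", "x2"] <- 0.25
  n <- 60
  dat <- data_with_exact_cor(n, R, seed = 3)
  expect_equal(unname(cor(dat)), unname(R), tolerance = 1e-12)
  z <- as.data.frame(scale(dat))
  fit <- lm(y ~ x1 + x2 + x3, data = z)
  m <- standardized_regression(pearson_matrix(dat), "y", c("x1", "x2", "x3"))
  expect_equal(unname(m$beta), unname(coef(fit)[-1]), tolerance = 1e-8)
  expect_equal(m$R2, summary(fit)$r.squared, tolerance = 1e-8)
  expect_equal(m$adjR2, summary(fit)$adj.r.squared, tolerance = 1e-8)
  expect_equal(unname(m$F), unname(summary(fit)$fstatistic["value"]),
               tolerance = 1e-6)
})

test_that("correlation stars reproduce the published two-sided thresholds at n = 101", {
  rs <- c(0.30, -0.20, -0.25, 0.35, 0.50, 0.19, 0.10)
  stars <- p_stars(r_pvalue(rs, 101))
  expect_identical(stars, c("**", "*", "*", "***", "***", "", ""))
})

test_that("a saturated path model fits the covariance exactly", {
  v <- c("a", "b", "c")
  S <- matrix(c(4, 1, 0.5, 1, 2, 0.3, 0.5, 0.3, 1), 3,
              dimnames = list(v, v))
  # no regressions: every variable exogenous, all covariances free, df = 0
  spec <- path_model_spec(list(), variables = v)
  fit <- fit_path_model(S, n = 50, spec = spec)
  expect_equal(fit$fit$df, 0)
  expect_equal(fit$fit$chi2, 0, tolerance = 1e-9)
  expect_equal(fit$fit$GFI, 1, tolerance = 1e-9)
  expect_equal(fit$fit$RMSEA, 0)
  expect_true(is.na(fit$fit$AGFI))
  expect_equal(fit$Sigma, S, tolerance = 1e-8)
})

test_that("ML path estimates equal least squares fitted to matching data", {
  spec <- path_model_spec(list(y1 ~ a + b + c, y2 ~ y1))
  v <- c("a", "b", "c", "y1", "y2")
  R <- diag(5); dimnames(R) <- list(v, v)
  R["a", "b"] <- R["b", "a"] <- 0.3
  R["a", "c"] <- R["c", "a"] <- -0.2
  R["b", "c"] <- R["c", "b"] <- 0.1
  R["y1", "a"] <- R["a", "y1"] <- 0.4
  R["y1", "b"] <- R["b", "y1"] <- -0.25
  R["y1", "c"] <- R["c", "y1"] <- 0.15
  R["y2", "y1"] <- R["y1", "y2"] <- 0.35
  R["y2", "a"] <- R["a", "y2"] <- 0.2
  R["y2", "b"] <- R["b", "y2"] <- -0.1
  R["y2", "c"] <- R["c", "y2"] <- 0.05
  n <- 80
  dat <- data_with_exact_cor(n, R, seed = 8)
  dat <- as.data.frame(mapply(function(col, s) col * s, dat,
                              c(2, 0.5, 10, 3, 1.5)))
  S <- cov(dat)
  fit <- fit_path_model(S, n = n, spec = spec)
  ols1 <- coef(lm(y1 ~ a + b + c, data = dat))[-1]
  ols2 <- coef(lm(y2 ~ y1, data = dat))[-1]
  est <- fit$estimates
  get <- function(lhs, rhs) est$est[est$lhs == lhs & est$op == "~" & est$rhs == rhs]
  expect_equal(get("y1", "a"), unname(ols1["a"]), tolerance = 1e-6)
  expect_equal(get("y1", "b"), unname(ols1["b"]), tolerance = 1e-6)
  expect_equal(get("y1", "c"), unname(ols1["c"]), tolerance = 1e-6)
  expect_equal(get("y2", "y1"), unname(ols2["y1"]), tolerance = 1e-6)
  # exogenous moments reproduce the sample moments
  expect_equal(est$est[est$lhs == "a" & est$rhs == "a"], S["a", "a"],
               tolerance = 1e-6)
  # chi-squared conventions differ by n / (n - 1)
  fit_n <- fit_path_model(S, n = n, spec = spec, chi2_convention = "normal")
  expect_equal(fit_n$fit$chi2, fit$fit$chi2 * n / (n - 1), tolerance = 1e-8)
})

test_that("fit indices match a hand-derived two-variable case", {
  # S = [[1, r], [r, 1]], Sigma = I:  W = S,
  # tr[(W - I)^2] = 2 r^2, tr[W^2] = 2 (1 + r^2)  =>  GFI = 1 / (1 + r^2)
  r <- 0.5
  S <- matrix(c(1, r, r, 1), 2)
  fi <- fit_indices(S, diag(2), n = 40, df = 1, n_free = 2)
  expect_equal(fi$GFI, 1 / (1 + r^2), tolerance = 1e-12)
  expect_equal(fi$AGFI, 1 - (2 * 3 / 2) * (1 - fi$GFI), tolerance = 1e-12)
  expect_lte(fi$AGFI, fi$GFI)
  # F_ML has the closed form -log(1 - r^2) here
  expect_equal(fi$F_ML, -log(1 - r^2), tolerance = 1e-12)
  expect_equal(fi$chi2, 39 * -log(1 - r^2), tolerance = 1e-12)
  # RMSEA is zero whenever chi2 <= df, monotone in chi2 beyond
  expect_equal(fit_indices(diag(2), diag(2), 40, df = 1)$RMSEA, 0)
  expect_gt(fi$RMSEA, 0)
})

test_that("path models reject cycles and negative degrees of freedom", {
  expect_error(path_model_spec(list(a ~ b, b ~ a)), "recursive")
  v <- c("a", "b")
  S <- diag(2); dimnames(S) <- list(v, v)
  spec <- path_model_spec(list(b ~ a))
  expect_silent(fit <- fit_path_model(S, n = 20, spec = spec))
  expect_equal(fit$fit$df, 0)
})

test_that("the full report runs on both input routes and they agree", {
  rep_printed <- run_paper_analyses()
  expect_identical(rep_printed$source, "printed_tables")
  expect_equal(rep_printed$path_fit$fit$df, 3)
  expect_length(rep_printed$dsp_regressions, 6)
  expect_length(rep_printed$dvc_regressions, 2)

  coh <- simulate_cohort(cohort_spec(n = 2e4, seed = 12))
  rep_sim <- run_paper_analyses(coh)
  b1 <- rep_printed$dsp_regressions$dsp_p2$beta
  b2 <- rep_sim$dsp_regressions$dsp_p2$beta
  # simulated route converges on the printed route (n = 2e4 sampling error)
  expect_lt(max(abs(b1 - b2)), 0.05)
  expect_error(run_paper_analyses(data.frame()), "empty")
  expect_error(run_paper_analyses(data.frame(age = 1:5)), "lacks column")
})
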