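#' Pearson correlation matrix of a cohort table
#'
#' Pairwise Pearson correlations over complete observations, with the
#' effective sample size attached for downstream inference.
#'
#' @param cohort `data.frame` of numeric variables.
#' @param variables Optional subset of columns.
#' @return Object of class `cor_mat`: list with `r` (symmetric matrix with
#'   unit diagonal), `n`, `variables`.
#' @export
pearson_matrix <- function(cohort, variables = NULL) {
  if (!is.null(variables)) cohort <- cohort[, variables, drop = FALSE]
  cohort <- cohort[stats::complete.cases(cohort), , drop = FALSE]
  if (nrow(cohort) < 3) stop("need at least 3 complete rows")
  vars <- apply(cohort, 2, stats::var)
  if (any(vars == 0))
    stop("zero-variance column(s): ",
         paste(names(vars)[vars == 0], collapse = ", "))
  r <- stats::cor(as.matrix(cohort))
  structure(list(r = r, n = nrow(cohort), variables = colnames(r)),
            class = "cor_mat")
}

as_cor_mat <- function(x, n = NULL) {
  if (inherits(x, "cor_mat")) return(x)
  if (is.matrix(x)) {
    n <- n %||% attr(x, "n")
    if (is.null(n)) stop("sample size n required with a plain matrix")
    return(structure(list(r = x, n = n, variables = colnames(x)),
                     class = "cor_mat"))
  }
  stop("expected a cor_mat or a correlation matrix")
}

#' Convert a correlation matrix to a covariance matrix
#'
#' @param corr Correlation matrix (or `cor_mat`) with variable names.
#' @param sds Named vector of standard deviations (> 0) covering the
#'   correlation variables.
#' @return Covariance matrix `cov_ij = r_ij * sd_i * sd_j`; any `n`
#'   attribute/field is carried over.
#' @export
corr_to_cov <- function(corr, sds) {
  n <- NULL
  if (inherits(corr, "cor_mat")) { n <- corr$n; corr <- corr$r }
  v <- colnames(corr)
  if (is.null(v)) stop("correlation matrix must have variable names")
  if (is.null(names(sds))) {
    if (length(sds) != length(v)) stop("sds misaligned with variables")
    names(sds) <- v
  }
  if (!all(v %in% names(sds)))
    stop("sds missing for: ", paste(setdiff(v, names(sds)), collapse = ", "))
  sds <- sds[v]
  if (any(sds <= 0)) stop("sds must be > 0")
  s <- corr * outer(sds, sds)
  if (!is.null(n)) attr(s, "n") <- n
  s
}

#' Two-sided p-value of a Pearson correlation
#'
#' @param r Correlation coefficient(s).
#' @param n Sample size.
#' @return p-value(s) from the t distribution with n - 2 df.
#' @export
r_pvalue <- function(r, n) {
  t <- r * sqrt((n - 2) / pmax(1 - r^2, .Machine$double.eps))
  2 * stats::pt(abs(t), df = n - 2, lower.tail = FALSE)
}

#' Significance stars at the 0.05 / 0.01 / 0.001 thresholds
#'
#' @param p p-value(s).
#' @return `""`, `"*"`, `"**"` or `"***"`.
#' @export
p_stars <- function(p) {
  as.character(cut(p, breaks = c(-Inf, 0.001, 0.01, 0.05, Inf),
                   labels = c("***", "**", "*", "")))
}

#' Standardized multiple regression from a correlation matrix
#'
#' Solves `beta = Rxx^-1 rxy` for the standardized partial regression
#' coefficients, with `R^2 = rxy' beta`,
#' `adjusted R^2 = 1 - (1 - R^2)(n - 1)/(n - k - 1)` and
#' `F = (R^2 / k) / ((1 - R^2)/(n - k - 1))` on (k, n - k - 1) df.
#' Identical to least squares on z-scored data with that exact sample
#' correlation matrix.
#'
#' @param corr A `cor_mat` (or correlation matrix with an `n` attribute /
#'   explicit `n`).
#' @param outcome Outcome variable name.
#' @param predictors Predictor variable names.
#' @param n Sample size override.
#' @return Object of class `std_regression`: `beta` (named), `se`, `t`,
#'   `p_coef`, `R2`, `adjR2`, `F`, `df1`, `df2`, `p_value`, `kappa`
#'   (condition number of the predictor correlation submatrix), `n`.
#' @export
standardized_regression <- function(corr, outcome, predictors, n = NULL) {
  cm <- as_cor_mat(corr, n)
  r <- cm$r; n <- n %||% cm$n
  miss <- setdiff(c(outcome, predictors), colnames(r))
  if (length(miss)) stop("variables not in matrix: ", paste(miss, collapse = ", "))
  rxx <- r[predictors, predictors, drop = FALSE]
  rxy <- r[predictors, outcome]
  eg <- eigen(rxx, symmetric = TRUE)
  if (min(eg$values) < 1e-12) {
    v <- eg$vectors[, which.min(eg$values)]
    stop("singular predictor correlation matrix; collinear combination: ",
         paste(sprintf("%+.3f*%s", v, predictors), collapse = " "))
  }
  beta <- drop(solve(rxx, rxy))
  names(beta) <- predictors
  k <- length(predictors)
  r2 <- drop(crossprod(rxy, beta))
  df2 <- n - k - 1
  fstat <- (r2 / k) / ((1 - r2) / df2)
  se <- sqrt((1 - r2) / df2 * diag(solve(rxx)))
  tval <- beta / se
  structure(list(outcome = outcome, predictors = predictors, beta = beta,
                 se = se, t = tval,
                 p_coef = 2 * stats::pt(abs(tval), df2, lower.tail = FALSE),
                 R2 = r2, adjR2 = 1 - (1 - r2) * (n - 1) / df2,
                 F = fstat, df1 = k, df2 = df2,
                 p_value = stats::pf(fstat, k, df2, lower.tail = FALSE),
                 kappa = max(eg$values) / min(eg$values), n = n),
            class = "std_regression")
}

#' @export
print.std_regression <- function(x, ...) {
  cat("standardized regression:", x$outcome, "~",
      paste(x$predictors, collapse = " + "), "\n")
  tab <- data.frame(beta = round(x$beta, 3), se = round(x$se, 3),
                    p = signif(x$p_coef, 3), sig = p_stars(x$p_coef))
  print(tab)
  cat(sprintf("R2 = %.3f, adj R2 = %.3f, F(%d, %d) = %.2f, p = %.4f\n",
              x$R2, x$adjR2, x$df1, x$df2, x$F, x$p_value))
  invisible(x)
}

#' Specify a recursive path model over observed variables
#'
#' A path model is a set of linear regressions among observed variables,
#' fitted jointly to a covariance matrix. Exogenous variables (those never
#' appearing on a left-hand side) covary freely; residuals of endogenous
#' variables are mutually uncorrelated. The model must be recursive
#' (acyclic).
#'
#' @param regressions List of formulas, e.g.
#'   `list(y ~ x1 + x2, z ~ y)`. An empty list with explicit `variables`
#'   gives the saturated model (all covariances free, df = 0).
#' @param variables Optional explicit variable set (required when
#'   `regressions` is empty).
#' @return Object of class `path_model_spec`: `outcomes`, `predictors`
#'   (named list), `variables`, `exogenous`.
#' @export
path_model_spec <- function(regressions, variables = NULL) {
  if (inherits(regressions, "formula")) regressions <- list(regressions)
  if (!length(regressions)) {
    if (is.null(variables)) stop("saturated model needs explicit variables")
    return(structure(list(outcomes = character(0),
                          predictors = stats::setNames(list(), character(0)),
                          variables = variables, exogenous = variables),
                     class = "path_model_spec"))
  }
  outcomes <- character(0); preds <- list()
  for (f in regressions) {
    stopifnot(inherits(f, "formula"), length(f) == 3L)
    y <- all.vars(f[[2]])
    x <- all.vars(f[[3]])
    if (length(y) != 1L || !length(x)) stop("each regression needs one outcome and >= 1 predictor")
    if (y %in% outcomes) stop("duplicate outcome: ", y)
    outcomes <- c(outcomes, y)
    preds[[y]] <- x
  }
  edges <- do.call(rbind, lapply(outcomes, function(y)
    cbind(preds[[y]], y)))
  g <- igraph::graph_from_edgelist(edges, directed = TRUE)
  if (!igraph::is_dag(g)) stop("path model must be recursive (acyclic)")
  vars <- unique(c(unlist(preds), outcomes))
  structure(list(outcomes = outcomes, predictors = preds, variables = vars,
                 exogenous = setdiff(vars, outcomes)),
            class = "path_model_spec")
}

#' The default published path model
#'
#' Age, brain atrophy and occipital leukoaraiosis volume predict the
#' sudden-motion visual-cognition score, which in turn predicts the
#' right-turn driving-safety score (P2); the three exogenous predictors
#' covary freely. With 5 observed variables this model has
#' 15 - 12 = 3 degrees of freedom.
#'
#' @return A [path_model_spec()].
#' @export
default_path_model <- function() {
  path_model_spec(list(
    dvc_sudden ~ age + brain_atrophy + la_occipital,
    dsp_p2 ~ dvc_sudden))
}

# number of free parameters of a spec over p variables
n_free_params <- function(spec) {
  n_exo <- length(spec$exogenous)
  n_exo * (n_exo + 1) / 2 +                    # exogenous (co)variances
    sum(lengths(spec$predictors)) +            # path coefficients
    length(spec$outcomes)                      # residual variances
}

# build B and Psi from a parameter vector; vars gives the ordering
theta_matrices <- function(theta, spec, vars) {
  p <- length(vars)
  exo <- match(spec$exogenous, vars)
  n_exo <- length(exo)
  n_phi <- n_exo * (n_exo + 1) / 2
  B <- matrix(0, p, p); Psi <- matrix(0, p, p)
  phi <- matrix(0, n_exo, n_exo)
  phi[lower.tri(phi, TRUE)] <- theta[seq_len(n_phi)]
  phi <- phi + t(phi) - diag(diag(phi), n_exo)
  Psi[exo, exo] <- phi
  k <- n_phi
  for (y in spec$outcomes) {
    xs <- match(spec$predictors[[y]], vars)
    B[match(y, vars), xs] <- theta[k + seq_along(xs)]
    k <- k + length(xs)
  }
  for (y in spec$outcomes) {
    k <- k + 1
    Psi[match(y, vars), match(y, vars)] <- theta[k]
  }
  list(B = B, Psi = Psi)
}

implied_sigma <- function(theta, spec, vars) {
  m <- theta_matrices(theta, spec, vars)
  G <- solve(diag(length(vars)) - m$B)
  G %*% m$Psi %*% t(G)
}

# per-equation least-squares solution on a covariance matrix: the exact ML
# optimum for recursive models with uncorrelated residuals, used both as
# initializer and as the independent oracle in tests
ols_theta <- function(S, spec, vars) {
  exo <- spec$exogenous
  phi <- S[exo, exo, drop = FALSE]
  th <- phi[lower.tri(phi, TRUE)]
  psis <- numeric(0)
  for (y in spec$outcomes) {
    xs <- spec$predictors[[y]]
    b <- drop(solve(S[xs, xs, drop = FALSE], S[xs, y]))
    th <- c(th, b)
    psis <- c(psis, S[y, y] - drop(crossprod(S[xs, y], b)))
  }
  c(th, psis)
}

fml_value <- function(S, Sigma) {
  p <- nrow(S)
  ev <- eigen(Sigma, symmetric = TRUE, only.values = TRUE)$values
  if (min(ev) <= 0) return(NA_real_)
  as.numeric(determinant(Sigma, logarithm = TRUE)$modulus) +
    sum(diag(S %*% solve(Sigma))) -
    as.numeric(determinant(S, logarithm = TRUE)$modulus) - p
}

# analytic gradient of F_ML wrt theta
fml_gradient <- function(theta, S, spec, vars) {
  p <- length(vars)
  m <- theta_matrices(theta, spec, vars)
  G <- solve(diag(p) - m$B)
  Sigma <- G %*% m$Psi %*% t(G)
  Sinv <- solve(Sigma)
  A <- Sinv - Sinv %*% S %*% Sinv          # dF = tr(A dSigma)
  M <- t(G) %*% A %*% G
  SAG <- Sigma %*% A %*% G
  exo <- match(spec$exogenous, vars)
  n_exo <- length(exo)
  g <- numeric(0)
  for (j in seq_len(n_exo)) for (i in j:n_exo) {
    gi <- exo[i]; gj <- exo[j]
    g <- c(g, if (gi == gj) M[gi, gi] else 2 * M[gi, gj])
  }
  for (y in spec$outcomes) {
    yi <- match(y, vars)
    for (x in spec$predictors[[y]])
      g <- c(g, 2 * SAG[match(x, vars), yi])
  }
  for (y in spec$outcomes) {
    yi <- match(y, vars)
    g <- c(g, M[yi, yi])
  }
  g
}

#' Fit a recursive path model to a covariance matrix by maximum likelihood
#'
#' Minimizes the normal-theory discrepancy
#' `F_ML = log|Sigma(theta)| + tr(S Sigma(theta)^-1) - log|S| - p`
#' over the free parameters (exogenous covariances, path coefficients,
#' residual variances), starting from the per-equation least-squares
#' solution. For numerical conditioning the fit runs on the
#' correlation-scaled covariance `D^-1 S D^-1` (D = sqrt(diag(S))), which
#' leaves `F_ML` and all fit indices invariant because every variance is a
#' free parameter; estimates are mapped back to the original scale.
#'
#' `chi2 = (n - 1) * F_ML` by default (Wishart convention, consistent with
#' the `n - 1` in the RMSEA denominator); `chi2_convention = "normal"`
#' uses `n * F_ML`.
#'
#' @param S Covariance matrix (positive definite) with variable names.
#' @param n Sample size (taken from `attr(S, "n")` if missing).
#' @param spec A [path_model_spec()]; defaults to [default_path_model()].
#' @param chi2_convention `"wishart"` (n - 1) or `"normal"` (n).
#' @param grad_tol Maximum allowed gradient norm at the optimum.
#' @return Object of class `path_fit`: `estimates` (data.frame with
#'   unstandardized and standardized coefficients), `Sigma` (implied
#'   covariance), `S`, `spec`, `theta`, `fit` (a `fit_indices` list),
#'   `convergence`.
#' @export
fit_path_model <- function(S, n = NULL, spec = default_path_model(),
                           chi2_convention = c("wishart", "normal"),
                           grad_tol = 1e-8) {
  chi2_convention <- match.arg(chi2_convention)
  n <- n %||% attr(S, "n")
  if (is.null(n)) stop("sample size n required")
  stopifnot(inherits(spec, "path_model_spec"))
  vars <- intersect(colnames(S), spec$variables)
  if (!setequal(vars, spec$variables))
    stop("covariance lacks model variables: ",
         paste(setdiff(spec$variables, colnames(S)), collapse = ", "))
  S <- S[vars, vars]
  ev <- eigen(S, symmetric = TRUE, only.values = TRUE)$values
  if (min(ev) <= 0) stop("covariance matrix is not positive definite")
  p <- length(vars)
  q <- n_free_params(spec)
  df <- p * (p + 1) / 2 - q
  if (df < 0) stop("model has negative degrees of freedom")

  d <- sqrt(diag(S))
  Ssc <- S / outer(d, d)
  th0 <- ols_theta(Ssc, spec, vars)
  fn <- function(th) {
    v <- fml_value(Ssc, implied_sigma(th, spec, vars))
    if (is.na(v)) 1e10 else v
  }
  gr <- function(th) fml_gradient(th, Ssc, spec, vars)
  opt <- stats::optim(th0, fn, gr, method = "BFGS",
                      control = list(maxit = 1000, reltol = 1e-14))
  # keep whichever of {optimized, initializer} has the lower discrepancy
  theta_sc <- if (opt$value <= fn(th0)) opt$par else th0
  gmax <- max(abs(gr(theta_sc)))
  if (gmax > grad_tol)
    stop(sprintf("path model failed to converge: |gradient| = %.2e > %.0e",
                 gmax, grad_tol))

  Sigma <- implied_sigma(theta_sc, spec, vars) * outer(d, d)
  dimnames(Sigma) <- dimnames(S)
  fit <- fit_indices(S, Sigma, n = n, df = df, n_free = q,
                     chi2_convention = chi2_convention)

  # estimates on the original scale, plus standardized coefficients
  est <- list()
  msc <- theta_matrices(theta_sc, spec, vars)
  for (y in spec$outcomes) {
    yi <- match(y, vars)
    for (x in spec$predictors[[y]]) {
      xi <- match(x, vars)
      std <- msc$B[yi, xi]
      est[[length(est) + 1L]] <- data.frame(
        lhs = y, op = "~", rhs = x,
        est = std * d[yi] / d[xi], std = std)
    }
  }
  for (y in spec$outcomes) {
    yi <- match(y, vars)
    est[[length(est) + 1L]] <- data.frame(
      lhs = y, op = "~~", rhs = y,
      est = msc$Psi[yi, yi] * d[yi]^2, std = msc$Psi[yi, yi])
  }
  exo <- spec$exogenous
  for (j in seq_along(exo)) for (i in j:length(exo)) {
    gi <- match(exo[i], vars); gj <- match(exo[j], vars)
    est[[length(est) + 1L]] <- data.frame(
      lhs = exo[j], op = "~~", rhs = exo[i],
      est = msc$Psi[gi, gj] * d[gi] * d[gj],
      std = msc$Psi[gi, gj] / sqrt(msc$Psi[gi, gi] * msc$Psi[gj, gj]))
  }
  structure(list(estimates = do.call(rbind, est), Sigma = Sigma, S = S,
                 spec = spec, theta = theta_sc, scale = d, fit = fit,
                 convergence = list(code = opt$convergence, max_grad = gmax)),
            class = "path_fit")
}

#' @export
print.path_fit <- function(x, ...) {
  cat("path model fit (ML)\n")
  est <- x$estimates
  est$est <- round(est$est, 4); est$std <- round(est$std, 4)
  print(est, row.names = FALSE)
  f <- x$fit
  cat(sprintf(
    "chi2(%d) = %.3f, p = %.3f, GFI = %.3f, AGFI = %s, RMSEA = %.3f, AIC = %.1f\n",
    f$df, f$chi2, f$p, f$GFI,
    if (is.na(f$AGFI)) "NA" else sprintf("%.3f", f$AGFI), f$RMSEA, f$AIC))
  invisible(x)
}

#' Goodness-of-fit indices of a covariance-structure model
#'
#' Computes the ML discrepancy between a sample covariance `S` and a model
#' implied covariance `Sigma`, and the derived indices:
#' `chi2 = (n - 1) * F_ML` (or `n * F_ML`),
#' `GFI = 1 - tr[(Sigma^-1 S - I)^2] / tr[(Sigma^-1 S)^2]`,
#' `AGFI = 1 - [p(p+1)/(2 df)] (1 - GFI)` (absent when df = 0),
#' `RMSEA = sqrt(max(chi2 - df, 0) / (df (n - 1)))`, and
#' `AIC = -2 logL + 2 q` with the multivariate-normal log-likelihood of S,
#' `logL = -(n/2) [p log(2 pi) + log|Sigma| + tr(S Sigma^-1)]`.
#'
#' @param S Sample covariance matrix.
#' @param Sigma Implied covariance matrix (same order).
#' @param n Sample size.
#' @param df Model degrees of freedom (>= 0).
#' @param n_free Number of free parameters (for AIC).
#' @param chi2_convention `"wishart"` (n - 1) or `"normal"` (n).
#' @return List of class `fit_indices`: `chi2`, `df`, `p`, `GFI`, `AGFI`,
#'   `RMSEA`, `AIC`, `F_ML`, `N`, `p_vars`.
#' @export
fit_indices <- function(S, Sigma, n, df, n_free = NULL,
                        chi2_convention = c("wishart", "normal")) {
  chi2_convention <- match.arg(chi2_convention)
  stopifnot(nrow(S) == nrow(Sigma), df >= 0)
  p <- nrow(S)
  f <- fml_value(S, Sigma)
  if (is.na(f)) stop("implied covariance is not positive definite")
  f <- max(f, 0)  # guard tiny negative rounding at the saturated optimum
  chi2 <- if (chi2_convention == "wishart") (n - 1) * f else n * f
  W <- solve(Sigma) %*% S
  gfi <- 1 - sum(diag((W - diag(p)) %*% (W - diag(p)))) / sum(diag(W %*% W))
  agfi <- if (df > 0) 1 - (p * (p + 1) / (2 * df)) * (1 - gfi) else NA_real_
  rmsea <- if (df > 0) sqrt(max(chi2 - df, 0) / (df * (n - 1))) else 0
  logl <- -(n / 2) * (p * log(2 * pi) +
                        as.numeric(determinant(Sigma)$modulus) +
                        sum(diag(S %*% solve(Sigma))))
  aic <- if (is.null(n_free)) NA_real_ else -2 * logl + 2 * n_free
  structure(list(chi2 = chi2, df = df,
                 p = if (df > 0) stats::pchisq(chi2, df, lower.tail = FALSE)
                     else NA_real_,
                 GFI = gfi, AGFI = agfi, RMSEA = rmsea, AIC = aic,
                 F_ML = f, N = n, p_vars = p, logLik = logl),
            class = "fit_indices")
}

#' Run the full published statistical stage
#'
#' Produces the correlation matrix of all 17 analysis variables, the six
#' per-location driving-score regressions (on age, the two
#' visual-cognition scores, brain atrophy and the five regional
#' leukoaraiosis volumes), the two visual-cognition regressions (on age,
#' brain atrophy and the five regional leukoaraiosis volumes), and the
#' path-model fit — either from a cohort table or from the packaged
#' printed correlation/SD tables.
#'
#' @param cohort Optional cohort `data.frame` carrying the
#'   [analysis_variables()] columns; when `NULL` the printed tables are
#'   used (n = 101).
#' @param model A [path_model_spec()].
#' @param chi2_convention Passed to [fit_path_model()].
#' @return Object of class `la_report`: `correlations` (`cor_mat`),
#'   `dsp_regressions` (list over P1..P6), `dvc_regressions` (list over
#'   tracking/sudden), `path_fit`, `source`.
#' @export
run_paper_analyses <- function(cohort = NULL, model = default_path_model(),
                               chi2_convention = c("wishart", "normal")) {
  chi2_convention <- match.arg(chi2_convention)
  vars <- analysis_variables()
  if (is.null(cohort)) {
    tabs <- printed_tables()
    cm <- structure(list(r = tabs$corr, n = tabs$n, variables = vars),
                    class = "cor_mat")
    sds <- tabs$sds
    src <- "printed_tables"
  } else {
    if (!nrow(cohort)) stop("empty cohort")
    miss <- setdiff(vars, names(cohort))
    if (length(miss))
      stop("cohort lacks column(s): ", paste(miss, collapse = ", "))
    cm <- pearson_matrix(cohort, vars)
    sds <- vapply(cohort[vars], stats::sd, numeric(1))
    src <- "cohort"
  }
  dsp_pred <- c("age", "dvc_tracking", "dvc_sudden", "brain_atrophy",
                "la_frontal", "la_temporal", "la_parietal", "la_occipital",
                "la_periventricular")
  dvc_pred <- c("age", "brain_atrophy", "la_frontal", "la_temporal",
                "la_parietal", "la_occipital", "la_periventricular")
  dsp_reg <- lapply(paste0("dsp_p", 1:6), function(y)
    standardized_regression(cm, y, dsp_pred))
  names(dsp_reg) <- paste0("dsp_p", 1:6)
  dvc_reg <- lapply(c("dvc_tracking", "dvc_sudden"), function(y)
    standardized_regression(cm, y, dvc_pred))
  names(dvc_reg) <- c("dvc_tracking", "dvc_sudden")
  S <- corr_to_cov(cm$r[model$variables, model$variables], sds[model$variables])
  pf <- fit_path_model(S, n = cm$n, spec = model,
                       chi2_convention = chi2_convention)
  structure(list(correlations = cm, dsp_regressions = dsp_reg,
                 dvc_regressions = dvc_reg, path_fit = pf, source = src),
            class = "la_report")
}

#' @export
print.la_report <- function(x, ...) {
  cat("== leukoaraiosis / driving-safety analysis report (source:",
      x$source, ", n =", x$correlations$n, ") ==\n\n")
  cat("-- correlations with significance stars --\n")
  r <- x$correlations$r
  stars <- matrix(p_stars(r_pvalue(r, x$correlations$n)), nrow(r))
  out <- matrix(paste0(sprintf("%5.2f", r), stars), nrow(r),
                dimnames = dimnames(r))
  diag(out) <- "    1"
  print(as.data.frame(out[, seq_len(min(8, ncol(out)))]), right = TRUE)
  cat("\n-- driving-score regressions (standardized beta) --\n")
  bet <- sapply(x$dsp_regressions, function(m) m$beta)
  print(round(rbind(bet,
                    R2 = sapply(x$dsp_regressions, `[[`, "R2"),
                    adjR2 = sapply(x$dsp_regressions, `[[`, "adjR2"),
                    F = sapply(x$dsp_regressions, `[[`, "F")), 3))
  cat("\n-- visual-cognition regressions (standardized beta) --\n")
  bet <- sapply(x$dvc_regressions, function(m) m$beta)
  print(round(rbind(bet,
                    R2 = sapply(x$dvc_regressions, `[[`, "R2"),
                    adjR2 = sapply(x$dvc_regressions, `[[`, "adjR2"),
                    F = sapply(x$dvc_regressions, `[[`, "F")), 3))
  cat("\n-- path model --\n")
  print(x$path_fit)
  invisible(x)
}
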