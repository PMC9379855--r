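# Maximum-likelihood covariance-structure fitting for recursive path models,
# with asymptotic standard errors, a standardized solution, the usual fit
# indices and direct/indirect/total effect decomposition.

#' Sample moments of an observation table
#'
#' @param data data frame of observations.
#' @param variables character vector of column names (fixes the order).
#' @param denominator `"n-1"` (default, unbiased) or `"n"` (ML) for the
#'   covariance matrix.
#' @return A `moment_summary`: list with `n`, `means`, `cov`, `denominator`.
#' @export
sample_moments <- function(data, variables, denominator = c("n-1", "n")) {
  denominator <- match.arg(denominator)
  if (!all(variables %in% names(data)))
    stop("missing column(s): ",
         paste(setdiff(variables, names(data)), collapse = ", "),
         call. = FALSE)
  X <- as.matrix(data[variables])
  if (nrow(X) < 2L) stop("need >= 2 records", call. = FALSE)
  for (v in variables)
    if (anyNA(X[, v]))
      stop(sprintf("missing value in field '%s' (record %d)",
                   v, which(is.na(X[, v]))[1]), call. = FALSE)
  S <- stats::cov(X)
  n <- nrow(X)
  if (denominator == "n") S <- S * (n - 1) / n
  structure(list(n = n, means = colMeans(X), cov = S,
                 denominator = denominator),
            class = "moment_summary")
}

#' Descriptive statistics with bias-corrected skewness and excess kurtosis
#'
#' Skewness and kurtosis follow the bias-corrected convention of the major
#' statistics packages: `skew = g1 * sqrt(n(n-1))/(n-2)` and
#' `kurt = ((n+1) g2 + 6)(n-1)/((n-2)(n-3))` with `g1`, `g2` the moment
#' coefficients (kurtosis is excess, i.e. 0 for the normal).
#'
#' @param data data frame.
#' @param variables columns to describe.
#' @return Data frame with columns `variable`, `mean`, `variance`,
#'   `skewness`, `kurtosis` (variance with n-1 denominator).
#' @export
describe <- function(data, variables = names(data)) {
  out <- lapply(variables, function(v) {
    x <- data[[v]]
    if (is.null(x)) stop("no column ", v, call. = FALSE)
    n <- length(x)
    if (n < 4L) stop("need n >= 4 for kurtosis", call. = FALSE)
    m <- mean(x)
    m2 <- mean((x - m)^2); m3 <- mean((x - m)^3); m4 <- mean((x - m)^4)
    g1 <- m3 / m2^1.5
    g2 <- m4 / m2^2 - 3
    data.frame(
      variable = v, mean = m, variance = stats::var(x),
      skewness = g1 * sqrt(n * (n - 1)) / (n - 2),
      kurtosis = ((n + 1) * g2 + 6) * (n - 1) / ((n - 2) * (n - 3)),
      stringsAsFactors = FALSE)
  })
  do.call(rbind, out)
}

#' Pearson correlation matrix with two-sided p-values
#'
#' @param data data frame.
#' @param variables columns to correlate.
#' @return List with `r` (correlation matrix) and `p` (two-sided p-values
#'   from the t-transform of r; `NA` on the diagonal). Constant columns give
#'   `NA` entries with a warning.
#' @export
pearson_matrix <- function(data, variables = names(data)) {
  X <- as.matrix(data[variables])
  n <- nrow(X)
  if (n < 3L) stop("need >= 3 records", call. = FALSE)
  const <- apply(X, 2, function(x) stats::var(x) == 0)
  if (any(const))
    warning("constant column(s): ",
            paste(variables[const], collapse = ", "),
            "; correlations undefined", call. = FALSE)
  r <- suppressWarnings(stats::cor(X))
  tstat <- r * sqrt((n - 2) / pmax(1 - r^2, .Machine$double.eps))
  p <- 2 * stats::pt(abs(tstat), df = n - 2, lower.tail = FALSE)
  diag(p) <- NA_real_
  list(r = r, p = p, n = n)
}

# ML discrepancy F(S, Sigma) = ln|Sigma| + tr(S Sigma^-1) - ln|S| - p.
.f_ml <- function(S, Sigma) {
  p <- nrow(S)
  ch <- tryCatch(chol(Sigma), error = function(e) NULL)
  if (is.null(ch)) return(1e10)
  logdet_sigma <- 2 * sum(log(diag(ch)))
  Sinv_S <- chol2inv(ch) %*% S
  logdet_s <- as.numeric(determinant(S, logarithm = TRUE)$modulus)
  val <- logdet_sigma + sum(diag(Sinv_S)) - logdet_s - p
  if (!is.finite(val)) 1e10 else val
}

# Closed-form per-equation estimates on a covariance matrix: for a recursive
# model with uncorrelated residuals the ML solution coincides with
# equation-wise least squares computed from S.
.ols_theta <- function(model, S) {
  theta <- stats::setNames(numeric(length(model$parameters)),
                           model$parameters)
  for (x in model$exogenous) theta[paste0("var:", x)] <- S[x, x]
  for (y in model$endogenous) {
    xs <- model$paths$source[model$paths$target == y]
    b <- solve(S[xs, xs, drop = FALSE], S[xs, y])
    theta[paste0(xs, "->", y)] <- b
    theta[paste0("psi:", y)] <- S[y, y] - sum(b * S[xs, y])
  }
  theta
}

# Diagonal scale map between raw and unit-variance parameterizations:
# theta_raw = scale * theta_std elementwise.
.theta_scale <- function(model, sds) {
  sc <- stats::setNames(numeric(length(model$parameters)), model$parameters)
  for (i in seq_len(nrow(model$paths))) {
    s <- model$paths$source[i]; t <- model$paths$target[i]
    sc[paste0(s, "->", t)] <- sds[t] / sds[s]
  }
  for (x in model$exogenous)  sc[paste0("var:", x)] <- sds[x]^2
  for (y in model$endogenous) sc[paste0("psi:", y)] <- sds[y]^2
  sc
}

# Analytic gradient of F_ML: dF/dtheta_j = tr(W dSigma_j) with
# W = Sigma^-1 - Sigma^-1 S Sigma^-1. With M = (I-A)^-1 and Sigma = M Psi M',
# a path s->t gives dSigma = u v' + v u' (u = M[,t], v = Sigma[,s]) so the
# trace is 2 v' W u; a variance of variable i gives dSigma = M[,i] M[,i]'.
.f_ml_grad <- function(model, theta, S) {
  v <- model$variables
  m <- .theta_matrices(model, theta)
  p <- length(v)
  M <- solve(diag(p) - m$A)
  Sigma <- M %*% m$Psi %*% t(M)
  ch <- tryCatch(chol((Sigma + t(Sigma)) / 2), error = function(e) NULL)
  if (is.null(ch)) return(rep(NA_real_, length(model$parameters)))
  Sinv <- chol2inv(ch)
  W <- Sinv - Sinv %*% S %*% Sinv
  dimnames(M) <- dimnames(Sigma) <- dimnames(W) <- list(v, v)
  g <- stats::setNames(numeric(length(model$parameters)), model$parameters)
  for (i in seq_len(nrow(model$paths))) {
    s <- model$paths$source[i]; t <- model$paths$target[i]
    g[paste0(s, "->", t)] <- 2 * drop(Sigma[, s] %*% W %*% M[, t])
  }
  for (x in model$exogenous)
    g[paste0("var:", x)] <- drop(M[, x] %*% W %*% M[, x])
  for (y in model$endogenous)
    g[paste0("psi:", y)] <- drop(M[, y] %*% W %*% M[, y])
  g
}

# Hessian as the symmetrized finite-difference Jacobian of the analytic
# gradient, with per-parameter relative steps.
.grad_jacobian_hessian <- function(gradfun, x) {
  k <- length(x)
  H <- matrix(0, k, k)
  for (i in seq_len(k)) {
    h <- 1e-6 * max(1, abs(x[i]))
    e <- x; e[i] <- x[i] + h; gp <- gradfun(e)
    e[i] <- x[i] - h; gm <- gradfun(e)
    H[i, ] <- (gp - gm) / (2 * h)
  }
  (H + t(H)) / 2
}

#' Fit a path model by maximum likelihood
#'
#' Minimizes the ML discrepancy
#' `F(theta) = ln|Sigma(theta)| + tr(S Sigma(theta)^-1) - ln|S| - p`
#' over the model's free parameters. Variables are internally rescaled to
#' unit sample variance for optimization (raw coefficient scales can span
#' several orders of magnitude) and estimates are back-transformed. The
#' optimizer is quasi-Newton ([stats::nlminb()]) started at the per-equation
#' least-squares solution, which for recursive models with uncorrelated
#' residuals is already the ML optimum.
#'
#' @param model a [path_model()].
#' @param moments a [sample_moments()] summary; `cov` must be positive
#'   definite and `n` must exceed the free-parameter count.
#' @param chisq_multiplier multiplier m in `chi2 = m * F_min`: `"n-1"`
#'   (default, the AMOS convention) or `"n"`.
#' @param gradtol gradient-norm threshold for the `converged` flag.
#' @param maxit iteration cap.
#' @param rescale internally standardize variables for optimization
#'   (default `TRUE`).
#' @return A `sem_fit`: list with `model`, `moments`, `theta` (named
#'   estimates), `implied` (model-implied covariance), `discrepancy`
#'   (minimized F), `chi2`, `df`, `converged`, `iterations`, `grad_norm`.
#' @export
fit_ml <- function(model, moments, chisq_multiplier = c("n-1", "n"),
                   gradtol = 1e-8, maxit = 500, rescale = TRUE) {
  stopifnot(inherits(model, "path_model"),
            inherits(moments, "moment_summary"))
  chisq_multiplier <- match.arg(chisq_multiplier)
  v <- model$variables
  if (!all(v %in% rownames(moments$cov)))
    stop("moments do not cover the model variables", call. = FALSE)
  S <- moments$cov[v, v]
  if (inherits(tryCatch(chol(S), error = function(e) e), "error"))
    stop("sample covariance matrix is not positive definite", call. = FALSE)
  npar <- length(model$parameters)
  if (moments$n <= npar)
    stop("n must exceed the number of free parameters", call. = FALSE)
  sds <- if (rescale) sqrt(diag(S)) else stats::setNames(rep(1, length(v)), v)
  Dinv <- diag(1 / sds); dimnames(Dinv) <- list(v, v)
  Sstd <- Dinv %*% S %*% Dinv; dimnames(Sstd) <- list(v, v)
  scale <- .theta_scale(model, sds)
  obj <- function(th) {
    names(th) <- model$parameters
    .f_ml(Sstd, implied_sigma(model, th))
  }
  grfun <- function(th) {
    names(th) <- model$parameters
    g <- .f_ml_grad(model, th, Sstd)
    if (anyNA(g)) rep(0, length(g)) else g   # outside the PD region
  }
  start <- .ols_theta(model, Sstd)
  lower <- ifelse(grepl("^(var|psi):", model$parameters), 1e-12, -Inf)
  opt <- stats::nlminb(start, obj, gradient = grfun, lower = lower,
                       control = list(iter.max = maxit, eval.max = 4 * maxit,
                                      rel.tol = 1e-12))
  # the least-squares start is the exact optimum for recursive models with
  # uncorrelated residuals; do not let the line search drift off it by a
  # rounding-level "improvement"
  theta_std <- if (obj(start) <= opt$objective + 1e-12) start else opt$par
  theta_std <- stats::setNames(theta_std, model$parameters)
  grad <- .f_ml_grad(model, theta_std, Sstd)
  theta <- theta_std * scale
  implied <- implied_sigma(model, theta)
  Fmin <- .f_ml(S, implied)
  mult <- if (chisq_multiplier == "n-1") moments$n - 1 else moments$n
  fit <- structure(list(
    model = model, moments = moments,
    theta = theta, theta_std_scale = scale, theta_internal = theta_std,
    internal_cov = Sstd, sds = sds,
    implied = implied, discrepancy = Fmin,
    chi2 = mult * Fmin, df = model_df(model),
    chisq_multiplier = mult,
    converged = sqrt(sum(grad^2)) < gradtol,
    grad_norm = sqrt(sum(grad^2)),
    iterations = opt$iterations
  ), class = "sem_fit")
  if (!fit$converged)
    warning(sprintf("fit did not reach gradient norm < %g (got %g)",
                    gradtol, fit$grad_norm), call. = FALSE)
  fit
}

#' @export
print.sem_fit <- function(x, ...) {
  cat(sprintf("<sem_fit> F = %.6g, chi2 = %.4f (df = %d), %s\n",
              x$discrepancy, x$chi2, x$df,
              if (x$converged) "converged" else "NOT converged"))
  print(round(x$theta, 6))
  invisible(x)
}

#' Asymptotic standard errors and critical ratios
#'
#' Standard errors from the inverse of the numerical Hessian of the ML
#' discrepancy at the solution, `acov = (2/m) H^-1` with `m` the chi-square
#' multiplier; the Hessian is computed on the internally standardized
#' parameterization and mapped back by the (diagonal) scale transform.
#' The critical ratio is `estimate / SE`; under the closed-form ML solution
#' every residual-variance critical ratio equals `sqrt(m/2)`.
#'
#' @param fit a [fit_ml()] result (must have converged).
#' @return Data frame with columns `parameter`, `estimate`, `se`,
#'   `critical_ratio`, `p_value` (two-sided normal).
#' @export
standard_errors <- function(fit) {
  stopifnot(inherits(fit, "sem_fit"))
  if (!fit$converged)
    stop("standard errors require a converged fit", call. = FALSE)
  model <- fit$model
  grfun <- function(th) {
    names(th) <- model$parameters
    .f_ml_grad(model, th, fit$internal_cov)
  }
  H <- .grad_jacobian_hessian(grfun, fit$theta_internal)
  Hinv <- tryCatch(solve(H), error = function(e) NULL)
  if (is.null(Hinv) || any(!is.finite(Hinv)) || any(diag(Hinv) <= 0)) {
    bad <- model$parameters[which.min(abs(diag(H)))]
    stop("information matrix is singular; parameter '", bad,
         "' appears underidentified", call. = FALSE)
  }
  se_std <- sqrt((2 / fit$chisq_multiplier) * diag(Hinv))
  se <- se_std * abs(fit$theta_std_scale)
  cr <- unname(fit$theta / se)
  data.frame(parameter = model$parameters,
             estimate = unname(fit$theta),
             se = unname(se),
             critical_ratio = cr,
             p_value = 2 * stats::pnorm(abs(cr), lower.tail = FALSE),
             stringsAsFactors = FALSE, row.names = NULL)
}

#' Standardized path coefficients
#'
#' `beta = b * SD(source) / SD(target)` using model-implied standard
#' deviations.
#'
#' @param fit a [fit_ml()] result.
#' @return Data frame with `source`, `target`, `b`, `beta`.
#' @export
standardize <- function(fit) {
  stopifnot(inherits(fit, "sem_fit"))
  sds <- sqrt(diag(fit$implied))
  if (any(sds == 0)) stop("zero implied variance", call. = FALSE)
  p <- fit$model$paths
  b <- vapply(seq_len(nrow(p)), function(i)
    fit$theta[[paste0(p$source[i], "->", p$target[i])]], numeric(1))
  data.frame(source = p$source, target = p$target, b = b,
             beta = b * sds[p$source] / sds[p$target],
             stringsAsFactors = FALSE, row.names = NULL)
}

#' Covariance-structure fit indices
#'
#' Computes the chi-square test and the absolute (RMR, SRMR, GFI, AGFI),
#' incremental (NFI, RFI, IFI, CFI), parsimony (PNFI, PCFI) and
#' error-of-approximation (RMSEA) indices. The baseline for incremental
#' indices is the independence model (zero covariances, free variances,
#' `df_b = p(p-1)/2`). SRMR is computed on correlation-metric residuals,
#' RMR on raw covariance residuals, both over the `p(p+1)/2` distinct
#' moments.
#'
#' @param fit a [fit_ml()] result.
#' @return One-row data frame with columns `chi2`, `df`, `p_value`, `rmr`,
#'   `srmr`, `gfi`, `agfi`, `nfi`, `rfi`, `ifi`, `cfi`, `pnfi`, `pcfi`,
#'   `rmsea`. With `df = 0`, `rmsea` and `rfi` are `NA`.
#' @export
fit_indices <- function(fit) {
  stopifnot(inherits(fit, "sem_fit"))
  v <- fit$model$variables
  p <- length(v)
  S <- fit$moments$cov[v, v]
  Sig <- fit$implied
  mult <- fit$chisq_multiplier
  chi2 <- fit$chi2; df <- fit$df
  # baseline: independence model; its ML solution is Sigma = diag(S)
  F_b <- .f_ml(S, diag(diag(S), p))
  chi2_b <- mult * F_b
  df_b <- p * (p - 1) / 2
  lower <- lower.tri(S, diag = TRUE)
  res <- S - Sig
  Ds <- diag(1 / sqrt(diag(S)), p); Dg <- diag(1 / sqrt(diag(Sig)), p)
  res_c <- Ds %*% S %*% Ds - Dg %*% Sig %*% Dg
  M <- solve(Sig, S)   # Sigma^-1 S, not symmetric: use plain matrix squares
  gfi <- 1 - sum(diag((M - diag(p)) %*% (M - diag(p)))) /
             sum(diag(M %*% M))
  agfi <- if (df > 0) 1 - (p * (p + 1) / (2 * df)) * (1 - gfi) else NA_real_
  nfi <- (chi2_b - chi2) / chi2_b
  rfi <- if (df > 0) 1 - (chi2 / df) / (chi2_b / df_b) else NA_real_
  ifi <- (chi2_b - chi2) / (chi2_b - df)
  cfi_den <- max(chi2_b - df_b, chi2 - df, 0)
  cfi <- if (cfi_den == 0) 1 else 1 - max(chi2 - df, 0) / cfi_den
  data.frame(
    chi2 = chi2, df = df,
    p_value = if (df > 0) stats::pchisq(chi2, df, lower.tail = FALSE)
              else NA_real_,
    rmr = sqrt(mean(res[lower]^2)),
    srmr = sqrt(mean(res_c[lower]^2)),
    gfi = gfi, agfi = agfi, nfi = nfi, rfi = rfi, ifi = ifi, cfi = cfi,
    pnfi = (df / df_b) * nfi, pcfi = (df / df_b) * cfi,
    rmsea = if (df > 0) sqrt(max(chi2 - df, 0) / (df * (fit$moments$n - 1)))
            else NA_real_,
    row.names = NULL)
}

#' Direct, indirect and total effects
#'
#' For the coefficient matrix A the total-effect matrix is
#' `(I - A)^-1 - I` (the sum of coefficient products over all directed
#' routes); indirect = total - direct, so additivity is exact by
#' construction. Computed on both the unstandardized (b) and standardized
#' (beta) scales.
#'
#' @param fit a [fit_ml()] result.
#' @return An `effect_table` data frame over all ordered (source, target)
#'   pairs with endogenous target: columns `source`, `target`, `direct_b`,
#'   `indirect_b`, `total_b`, `direct_beta`, `indirect_beta`, `total_beta`.
#'   The full effect matrices are in attributes `total_b` and `total_beta`.
#' @export
decompose_effects <- function(fit) {
  stopifnot(inherits(fit, "sem_fit"))
  model <- fit$model
  v <- model$variables
  m <- .theta_matrices(model, fit$theta)
  A <- m$A
  sds <- sqrt(diag(fit$implied))
  B <- A * outer(1 / sds, sds)          # B[t, s] = A[t, s] * sd(s) / sd(t)
  p <- length(v)
  Tb <- solve(diag(p) - A) - diag(p)
  TB <- solve(diag(p) - B) - diag(p)
  dimnames(Tb) <- dimnames(TB) <- list(v, v)
  pairs <- expand.grid(source = v, target = model$endogenous,
                       stringsAsFactors = FALSE)
  pairs <- pairs[pairs$source != pairs$target, ]
  out <- data.frame(
    source = pairs$source, target = pairs$target,
    direct_b = A[cbind(pairs$target, pairs$source)],
    total_b = Tb[cbind(pairs$target, pairs$source)],
    direct_beta = B[cbind(pairs$target, pairs$source)],
    total_beta = TB[cbind(pairs$target, pairs$source)],
    stringsAsFactors = FALSE, row.names = NULL)
  # report total as direct + indirect so additivity is exact in floating point
  out$indirect_b <- out$total_b - out$direct_b
  out$total_b <- out$direct_b + out$indirect_b
  out$indirect_beta <- out$total_beta - out$direct_beta
  out$total_beta <- out$direct_beta + out$indirect_beta
  out <- out[c("source", "target", "direct_b", "indirect_b", "total_b",
               "direct_beta", "indirect_beta", "total_beta")]
  attr(out, "total_b") <- Tb
  attr(out, "total_beta") <- TB
  class(out) <- c("effect_table", class(out))
  out
}
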