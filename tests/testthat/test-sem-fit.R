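tab1 <- load_table1()
vars <- gpre_path_model()$variables

test_that("sample moments honour the denominator convention", {
  mom <- sample_moments(tab1, vars)
  expect_equal(mom$n, 37L)
  expect_equal(unname(mom$means["cu"]), 5.43, tolerance = 1e-3)
  expect_equal(unname(mom$cov["cu", "cu"]), 12.785, tolerance = 1e-3)
  momn <- sample_moments(tab1, vars, denominator = "n")
  expect_equal(momn$cov, mom$cov * 36 / 37, tolerance = 1e-12)

  bad <- tab1; bad$gsh[5] <- NA
  expect_error(sample_moments(bad, vars), "gsh")
  expect_error(sample_moments(tab1, c("cu", "nope")), "nope")
})

test_that("describe uses the bias-corrected skewness/kurtosis convention", {
  d <- describe(tab1, "gpre")
  expect_equal(d$mean, 2.556, tolerance = 1e-3)
  expect_equal(d$variance, 2.752, tolerance = 1e-3)
  expect_equal(d$skewness, 0.932, tolerance = 1e-2)
  expect_equal(d$kurtosis, -0.122, tolerance = 1e-2)

  # a symmetric sample has zero skewness
  expect_equal(describe(data.frame(x = c(-1, 1, -1, 1)), "x")$skewness, 0)

  # agrees with the reference implementation (e1071 type 2)
  set.seed(7)
  x <- rexp(60)
  d2 <- describe(data.frame(x = x), "x")
  expect_equal(d2$skewness, e1071::skewness(x, type = 2), tolerance = 1e-12)
  expect_equal(d2$kurtosis, e1071::kurtosis(x, type = 2), tolerance = 1e-12)
  expect_error(describe(data.frame(x = 1:3), "x"), "n >= 4")
})

test_that("pearson_matrix reproduces published correlations and cor.test p-values", {
  pm <- pearson_matrix(tab1, vars)
  expect_equal(pm$r["cu", "gpre"], 0.807, tolerance = 5e-3)
  expect_equal(pm$r["cu", "chh_sv"], -0.386, tolerance = 5e-3)
  expect_equal(unname(diag(pm$r)), rep(1, 5))
  expect_equal(pm$r, t(pm$r))
  ct <- cor.test(tab1$cu, tab1$gpre)
  expect_equal(pm$p["cu", "gpre"], ct$p.value, tolerance = 1e-10)
  expect_warning(pearson_matrix(data.frame(a = rep(1, 5), b = 1:5)),
                 "constant")
})

test_that("ML estimates equal the per-equation least-squares oracle", {
  model <- gpre_path_model()
  fit <- fit_ml(model, sample_moments(tab1, vars))
  expect_true(fit$converged)
  # oracle: ordinary regressions on the raw data
  o1 <- lm(chh_dnmv ~ cu, tab1)
  o2 <- lm(chh_sv ~ chh_dnmv + cu, tab1)
  o4 <- lm(gpre ~ cu + chh_sv + chh_dnmv + gsh, tab1)
  expect_equal(unname(fit$theta["cu->chh_dnmv"]), unname(coef(o1)[2]),
               tolerance = 1e-6)
  expect_equal(unname(fit$theta["chh_dnmv->chh_sv"]), unname(coef(o2)[2]),
               tolerance = 1e-6)
  expect_equal(unname(fit$theta["gsh->gpre"]), unname(coef(o4)[5]),
               tolerance = 1e-6)
  # residual variance = RSS / (n-1), matching the covariance denominator
  expect_equal(unname(fit$theta["psi:gpre"]), sum(resid(o4)^2) / 36,
               tolerance = 1e-6)
  expect_gte(fit$discrepancy, 0)

  # single-path model: b = cov(x, y) / var(x)
  m1 <- path_model("cu -> gpre")
  f1 <- fit_ml(m1, sample_moments(tab1, c("cu", "gpre")))
  expect_equal(unname(f1$theta["cu->gpre"]),
               cov(tab1$cu, tab1$gpre) / var(tab1$cu), tolerance = 1e-8)
  expect_lt(f1$discrepancy, 1e-12)   # saturated
})

test_that("the OLS-oracle identity holds across random recursive models", {
  set.seed(101)
  for (rep in 1:25) {
    rm <- random_path_model_data(p = sample(3:5, 1), n = 200)
    mom <- sample_moments(rm$data, rm$model$variables)
    fit <- fit_ml(rm$model, mom)
    expect_true(fit$converged)
    for (y in rm$model$endogenous) {
      parents <- rm$model$paths$source[rm$model$paths$target == y]
      ols <- coef(lm(stats::reformulate(parents, y), rm$data))[parents]
      got <- fit$theta[paste0(parents, "->", y)]
      expect_equal(unname(got), unname(ols), tolerance = 1e-6)
    }
  }
})

test_that("fit_ml validates its inputs", {
  m <- gpre_path_model()
  mom <- sample_moments(tab1, vars)
  mombad <- mom
  mombad$cov <- matrix(1, 5, 5, dimnames = dimnames(mom$cov))  # singular
  expect_error(fit_ml(m, mombad), "positive definite")
  momsmall <- mom; momsmall$n <- 10L
  expect_error(fit_ml(m, momsmall), "free parameters")
})

test_that("standard errors follow the inverse-information closed forms", {
  model <- gpre_path_model()
  mom <- sample_moments(tab1, vars)
  fit <- fit_ml(model, mom)
  se <- standard_errors(fit)
  # every residual-variance critical ratio equals sqrt((n-1)/2)
  res_rows <- grepl("^(psi|var):", se$parameter)
  expect_equal(se$critical_ratio[res_rows], rep(sqrt(36 / 2), sum(res_rows)),
               tolerance = 1e-4)
  # path SEs match the ML regression closed form psi * Sxx^-1 / (n-1)
  S <- mom$cov
  xs <- c("cu", "chh_sv", "chh_dnmv", "gsh")
  Vb <- fit$theta[["psi:gpre"]] * solve(S[xs, xs]) / 36
  expect_equal(se$se[se$parameter == "cu->gpre"], sqrt(Vb["cu", "cu"]),
               tolerance = 1e-4)

  # quadrupling n - 1 on fixed S halves every SE
  mom2 <- mom; mom2$n <- 4L * 36L + 1L
  fit2 <- fit_ml(model, mom2)
  se2 <- standard_errors(fit2)
  expect_equal(se2$se, se$se / 2, tolerance = 1e-6)
})

test_that("standardized coefficients equal correlations in the bivariate case", {
  m1 <- path_model("cu -> gpre")
  f1 <- fit_ml(m1, sample_moments(tab1, c("cu", "gpre")))
  expect_equal(standardize(f1)$beta, cor(tab1$cu, tab1$gpre),
               tolerance = 1e-8)
})

test_that("the standardized solution is invariant to rescaling variables", {
  model <- gpre_path_model()
  fit <- fit_ml(model, sample_moments(tab1, vars))
  resc <- tab1
  resc$gsh <- resc$gsh * 1e4      # re-express the band integral
  resc$cu <- resc$cu / 10
  fit2 <- fit_ml(model, sample_moments(resc, vars))
  expect_equal(standardize(fit2)$beta, standardize(fit)$beta,
               tolerance = 1e-6)
  idx <- fit_indices(fit); idx2 <- fit_indices(fit2)
  expect_equal(idx2$chi2, idx$chi2, tolerance = 1e-6)
  expect_equal(idx2$srmr, idx$srmr, tolerance = 1e-6)
})

test_that("fit indices take their boundary values for a saturated model", {
  set.seed(5)
  d <- data.frame(x = rnorm(40)); d$y <- 0.5 * d$x + rnorm(40)
  f <- fit_ml(path_model("x -> y"), sample_moments(d, c("x", "y")))
  idx <- fit_indices(f)
  expect_lt(idx$chi2, 1e-8)
  expect_equal(idx$cfi, 1)
  expect_equal(idx$df, 0L)
  expect_true(is.na(idx$rmsea) && is.na(idx$rfi))   # undefined at df = 0
  expect_equal(idx$gfi, 1, tolerance = 1e-6)
})

test_that("effects decompose additively and match route enumeration", {
  # chain x -> m -> y: indirect(x, y) = b1 b2, direct 0
  set.seed(11)
  d <- data.frame(x = rnorm(100))
  d$m <- 0.5 * d$x + rnorm(100)
  d$y <- 0.7 * d$m + rnorm(100)
  fch <- fit_ml(path_model(c("x -> m", "m -> y")),
                sample_moments(d, c("x", "m", "y")))
  ech <- decompose_effects(fch)
  row <- ech[ech$source == "x" & ech$target == "y", ]
  expect_equal(row$direct_b, 0)
  expect_equal(row$indirect_b,
               fch$theta[["x->m"]] * fch$theta[["m->y"]], tolerance = 1e-10)

  # brute-force path-sum oracle on random DAGs, both scales, exact additivity
  set.seed(202)
  for (rep in 1:10) {
    rm <- random_path_model_data(p = 5, n = 150)
    fit <- fit_ml(rm$model, sample_moments(rm$data, rm$model$variables))
    eff <- decompose_effects(fit)
    expect_equal(eff$total_b, eff$direct_b + eff$indirect_b)
    expect_equal(eff$total_beta, eff$direct_beta + eff$indirect_beta)
    coefs <- as.list(fit$theta)
    for (i in seq_len(nrow(eff))) {
      brute <- enumerate_total_effect(rm$model$paths, coefs,
                                      eff$source[i], eff$target[i])
      expect_equal(eff$total_b[i], brute, tolerance = 1e-8)
    }
  }
})
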