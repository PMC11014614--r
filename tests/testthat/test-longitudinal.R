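test_that("partial Spearman is monotone-invariant and unmasks confounding", {
  x <- withr::with_seed(1, rnorm(80))
  out <- partialSpearman(x, x^3)
  expect_equal(out$rho, 1)
  # confounder z drives both; direct effect of x on y is negative
  withr::with_seed(2, {
    z <- rnorm(400)
    x2 <- 2 * z + rnorm(400, sd = 0.5)
    y2 <- 3 * z - 0.8 * x2 + rnorm(400, sd = 0.5)
  })
  naive <- cor(x2, y2, method = "spearman")
  partial <- partialSpearman(x2, y2, covariates = data.frame(z = z))
  expect_gt(naive, 0)
  expect_lt(partial$rho, 0)
  expect_lt(partial$p, 1e-6)
  expect_error(partialSpearman(rep(1, 50), rnorm(50)), "constant")
})

test_that("partial Spearman p-values are calibrated under the null", {
  ps <- vapply(1:150, function(s) {
    withr::with_seed(1000 + s, {
      z <- rnorm(60); x <- z + rnorm(60); y <- z + rnorm(60)
    })
    partialSpearman(x, y, covariates = data.frame(z = z))$p
  }, numeric(1))
  expect_gt(suppressWarnings(stats::ks.test(ps, "punif"))$p.value, 0.01)
})

test_that("BH step-up matches the literal all-subsets oracle", {
  expect_equal(fdrBH(c(0.001, 0.5))$reject, c(TRUE, FALSE))
  expect_true(all(fdrBH(rep(0.01, 10))$reject))
  withr::with_seed(4, {
    for (i in 1:25) {
      p <- runif(sample(1:10, 1))^sample(1:3, 1)
      out <- fdrBH(p, q = 0.05)
      expect_identical(out$reject, bhOracle(p, 0.05))
      expect_true(all(diff(out$adjusted[order(p)]) >= -1e-15))
    }
  })
  expect_error(fdrBH(numeric(0)), "empty")
  expect_error(fdrBH(c(0.5, 1.2)), "0, 1")
})

test_that("model specification counts parameters and degrees of freedom", {
  eq <- specifyBivariateLcs(TRUE)
  expect_equal(nrow(eq@parameters), 14)
  expect_equal(sum(grepl("gamma", eq@parameters$label)), 2)
  free <- specifyBivariateLcs(FALSE)
  expect_gt(nrow(free@parameters), nrow(eq@parameters))
  expect_equal(27 - nrow(eq@parameters), 13)   # >= 0: identified
  expect_gte(27 - nrow(free@parameters), 0)
  expect_error(specifyBivariateLcs(NA), "TRUE or FALSE")
})

test_that("implied moments handle static dynamics and stay PSD", {
  pv <- setNames(rep(0, 14), specifyBivariateLcs()@parameters$label)
  pv[c("v_x1", "v_y1")] <- c(2, 1)
  pv[c("alpha_x", "alpha_y")] <- c(0.5, -0.1)
  im <- impliedMoments(pv)
  xs <- c("x1", "x2", "x3")
  expect_true(all(im$Sigma[xs, xs] == 2))
  expect_equal(unname(im$mu[c("x1", "x2", "x3")]), c(0, 0.5, 1.0))
  withr::with_seed(5, {
    for (i in 1:20) {
      pv2 <- pv
      pv2[c("beta_x", "beta_y")] <- runif(2, -0.6, 0)
      pv2[c("gamma_x", "gamma_y")] <- runif(2, -0.3, 0.3)
      pv2[c("q_x", "q_y")] <- runif(2, 0.05, 0.5)
      pv2["c_xy1"] <- runif(1, -0.5, 0.5)
      ev <- eigen(impliedMoments(pv2)$Sigma, symmetric = TRUE,
                  only.values = TRUE)$values
      expect_gte(min(ev), -1e-10)
    }
  })
  pv["v_x1"] <- -1
  expect_error(impliedMoments(pv), "inadmissible")
})

test_that("the ML fit agrees with an independent scipy implementation", {
  # Frozen oracle: the same fixed synthetic dataset fitted with an
  # independently written scipy optimizer (Nelder-Mead + BFGS over the
  # same 14-parameter model).
  p <- lcsParams(mu0 = c(0.3, 0.1),
                 sigma0 = matrix(c(1, 0.25, 0.25, 0.9), 2),
                 alpha = c(0.15, -0.05), beta = c(-0.35, -0.2),
                 gammaX = 0.12, gammaY = 0.08,
                 residual = matrix(c(0.3, 0.04, 0.04, 0.22), 2))
  d <- genLcsCohort(p, 500, seed = 777)
  f <- fitBivariateLcs(d, seed = 2)
  expect_equal(f@chisq, 10.035205, tolerance = 1e-4)
  expect_equal(unname(f@fitIndices[["cfi"]]), 1.0, tolerance = 0.01)
  expect_equal(unname(f@fitIndices[["rmsea"]]), 0.0, tolerance = 0.01)
  expect_equal(unname(f@fitIndices[["srmr"]]), 0.009449, tolerance = 0.01)
  oracle <- c(mu_x1 = 0.318047, mu_y1 = 0.091614, v_x1 = 1.044607,
              v_y1 = 0.880613, c_xy1 = 0.312179, alpha_x = 0.148695,
              alpha_y = -0.074364, beta_x = -0.348588, beta_y = -0.182164,
              gamma_x = 0.096026, gamma_y = 0.084768, q_x = 0.282629,
              q_y = 0.212529, q_xy = 0.038397)
  expect_equal(f@estimates[names(oracle)], oracle, tolerance = 1e-3)
})

test_that("couplings are recovered within sampling error at n = 2000", {
  p <- lcsParams(gammaX = 0.12, gammaY = 0.1, beta = c(-0.3, -0.25))
  d <- genLcsCohort(p, 2000, seed = 91)
  f <- fitBivariateLcs(d, nStarts = 2, seed = 1)
  expect_lt(abs(f@estimates[["gamma_x"]] - 0.12), 3 * f@se[["gamma_x"]])
  expect_lt(abs(f@estimates[["gamma_y"]] - 0.10), 3 * f@se[["gamma_y"]])
  # standardized and raw couplings agree in sign
  expect_equal(sign(f@std[["gamma_x"]]), sign(f@estimates[["gamma_x"]]))
  expect_equal(sign(f@std[["gamma_y"]]), sign(f@estimates[["gamma_y"]]))
  # deterministic refit
  f2 <- fitBivariateLcs(d, nStarts = 2, seed = 1)
  expect_identical(f@estimates, f2@estimates)
})

test_that("data matching the implied moments exactly yield a perfect fit", {
  pv <- c(mu_x1 = 0.2, mu_y1 = 0, v_x1 = 1, v_y1 = 0.8, c_xy1 = 0.2,
          alpha_x = 0.1, alpha_y = 0, beta_x = -0.3, beta_y = -0.2,
          gamma_x = 0.1, gamma_y = 0.05, q_x = 0.25, q_y = 0.2, q_xy = 0.02)
  im <- impliedMoments(pv)
  panel <- exactMomentPanel(400, im$mu, im$Sigma, seed = 8)
  f <- fitBivariateLcs(panel, seed = 3)
  expect_lt(f@chisq, 1e-4)
  expect_equal(unname(f@fitIndices), c(1, 0, 0), tolerance = 1e-4)
  expect_equal(f@estimates[names(pv)], pv, tolerance = 1e-3)
  # likelihood at the optimum beats perturbed parameter sets
  obj <- function(v) attncpm:::.lcsDiscrepancy(
    v, names(pv), TRUE, cov(panel), colMeans(panel),
    determinant(cov(panel), logarithm = TRUE)$modulus)
  withr::with_seed(9, for (i in 1:10)
    expect_gt(obj(pv + rnorm(14, 0, 0.05)), f@chisq / (400 - 1) - 1e-12))
})

test_that("the fitter requires the panel schema and enough rows", {
  expect_error(fitBivariateLcs(data.frame(x1 = 1:100)), "missing column")
  p <- lcsParams()
  expect_error(fitBivariateLcs(genLcsCohort(p, 30, seed = 1)), "at least 50")
  expect_warning(fitBivariateLcs(genLcsCohort(p, 120, seed = 1), nStarts = 1),
                 "200")
})
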