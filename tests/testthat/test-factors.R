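# Items with an exactly diagonal sample correlation matrix (principal
# component scores are uncorrelated by construction).
uncorrelatedItems <- function(n = 300, p = 4, seed = 1) {
  X <- withr::with_seed(seed, matrix(rnorm(n * p), n, p))
  out <- stats::prcomp(X, center = TRUE, scale. = TRUE)$x
  colnames(out) <- paste0("item", seq_len(p))
  as.data.frame(out)
}

twoFactorItems <- function(n = 2000, seed = 11) {
  L <- cbind(c(.8, .75, .7, 0, 0, 0), c(0, 0, 0, .8, .75, .7))
  list(items = genSubstanceItems(n, L, seed = seed), loadings = L)
}

test_that("KMO equals one half for any two-item table", {
  it2 <- genSubstanceItems(400, cbind(c(0.7, 0.6)), seed = 5)
  expect_equal(kmoStatistic(it2)$overall, 0.5, tolerance = 1e-12)
  it2b <- genSubstanceItems(400, cbind(c(0.3, 0.9)), seed = 6)
  expect_equal(kmoStatistic(it2b)$overall, 0.5, tolerance = 1e-12)
})

test_that("KMO is undefined on an identity correlation and flags weak items", {
  expect_error(kmoStatistic(uncorrelatedItems()), "undefined")
  tf <- twoFactorItems()
  it <- tf$items
  # near-collinear item: raw correlations modest, partial correlations huge
  it$junk <- it$item1 - it$item4 +
    withr::with_seed(3, rnorm(nrow(it), sd = 0.3))
  k <- kmoStatistic(it)
  expect_true("junk" %in% k$flagged)
  # items untouched by the collinearity stay adequate
  expect_true(all(k$perItem[paste0("item", c(2, 3, 5, 6))] > 0.5))
})

test_that("Bartlett sphericity matches its closed form and edge cases", {
  it <- uncorrelatedItems(p = 6)
  b0 <- bartlettSphericity(it)
  expect_equal(b0$chisq, 0, tolerance = 1e-8)
  expect_equal(b0$p, 1, tolerance = 1e-6)
  expect_equal(b0$df, 15)                     # 6 items -> 15 df
  tf <- twoFactorItems()
  b <- bartlettSphericity(tf$items)
  X <- as.matrix(tf$items)
  nObs <- nrow(X)
  chisqOracle <- -(nObs - 1 - (2 * 6 + 5) / 6) *
    log(prod(eigen(cor(X), only.values = TRUE)$values))
  expect_equal(b$chisq, chisqOracle, tolerance = 1e-8)
  expect_lt(b$p, 1e-10)
})

test_that("full-rank principal extraction reproduces the correlation matrix", {
  tf <- twoFactorItems(n = 500)
  m <- efaPrincipal(tf$items, retention = "fixed", nFactors = 6)
  L <- factorLoadings(m)
  expect_equal(L %*% t(L), cor(tf$items), ignore_attr = TRUE,
               tolerance = 1e-10)
})

test_that("Kaiser retention recovers the planted two-factor structure", {
  tf <- twoFactorItems()
  m <- efaPrincipal(tf$items)
  expect_equal(ncol(factorLoadings(m)), 2)
  # loadings match an independent eigen oracle up to sign
  R <- cor(tf$items)
  e <- eigen(R, symmetric = TRUE)
  for (k in 1:2) {
    oracle <- e$vectors[, k] * sqrt(e$values[k])
    got <- factorLoadings(m)[, k]
    expect_equal(abs(got), abs(oracle), tolerance = 1e-10,
                 ignore_attr = TRUE)
  }
  r <- varimaxRotate(m)
  cg <- tuckerCongruence(factorLoadings(r), tf$loadings)
  expect_true(all(cg > 0.95))
})

test_that("varimax rotation is orthogonal and fit-preserving", {
  tf <- twoFactorItems(n = 800, seed = 21)
  m <- efaPrincipal(tf$items)
  r <- varimaxRotate(m)
  expect_lt(max(abs(crossprod(r@rotation) - diag(2))), 1e-10)
  expect_lt(max(abs(communalities(r) - communalities(m))), 1e-10)
  L <- factorLoadings(m); Lr <- factorLoadings(r)
  expect_lt(max(abs(L %*% t(L) - Lr %*% t(Lr))), 1e-10)
  # a perfect simple structure is left alone (up to sign/permutation)
  simple <- structure(rbind(diag(2) * c(0.9, 0.8), c(0.85, 0), c(0, 0.7)),
                      dimnames = list(paste0("item", 1:4), c("F1", "F2")))
  mSimple <- new("FactorModel", loadings = simple, rotation = diag(2),
                 eigenvalues = c(2, 1.5, 0.3, 0.2),
                 correlation = diag(4), center = rep(0, 4),
                 scaleSd = rep(1, 4), retention = "fixed")
  rSimple <- varimaxRotate(mSimple)
  expect_true(all(tuckerCongruence(factorLoadings(rSimple), simple) > 0.999))
  # single factor: identity rotation
  one <- efaPrincipal(tf$items, retention = "fixed", nFactors = 1)
  expect_identical(varimaxRotate(one), one)
})

test_that("regression factor scores match their algebraic definition", {
  tf <- twoFactorItems(n = 600, seed = 31)
  m <- varimaxRotate(efaPrincipal(tf$items))
  sc <- factorScores(tf$items, m)
  expect_lt(max(abs(colMeans(sc))), 1e-10)
  X <- as.matrix(tf$items)
  Z <- scale(X)
  oracle <- Z %*% solve(cor(X)) %*% factorLoadings(m)
  expect_equal(sc, oracle, ignore_attr = TRUE, tolerance = 1e-8)
  expect_error(factorScores(tf$items[, 1:3], m), "missing model column")
  # recovered scores track the generative factors
  truth <- attr(tf$items, "truth")$factors
  agreement <- abs(cor(sc, truth))
  expect_gt(max(agreement[1, ]), 0.8)
  expect_gt(max(agreement[2, ]), 0.8)
})
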