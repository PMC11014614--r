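test_that("residualization projects out the covariates", {
  withr::with_seed(3, {
    X <- cbind(a = rnorm(100), b = rnorm(100))
    y <- 2 + X %*% c(1, -2) + rnorm(100)
  })
  r <- residualize(y, X)
  expect_lt(max(abs(cor(r, X))), 1e-10)
  expect_equal(residualize(drop(y)), drop(y) - mean(y))
  Xdup <- cbind(X, a2 = X[, "a"])
  expect_warning(r2 <- residualize(y, Xdup), "collinear")
  expect_equal(drop(r2), drop(r))
  expect_error(residualize(y[1:2], cbind(X[1:2, ], X[1:2, ], X[1:2, ])),
               "fewer rows")
})

test_that("edge selection splits by sign at the exact threshold", {
  co <- smallPlantedCohort()
  sel <- selectEdges(co, pThreshold = 0.01)
  expect_true(all(sel$positive$p < 0.01 & sel$positive$r > 0))
  expect_true(all(sel$negative$p < 0.01 & sel$negative$r < 0))
  # threshold behaves as a strict cut on the reported p-values
  notSelected <- setdiff(which(sel$stats$p < 0.02), which(sel$stats$p < 0.01))
  selectedAt02 <- selectEdges(co, pThreshold = 0.02)
  expect_equal(nrow(selectedAt02$positive) + nrow(selectedAt02$negative),
               sum(sel$stats$p < 0.02))
  expect_gt(length(notSelected), 0)
  # planted edges found with matching signs
  tr <- cohortTruth(co)
  key <- function(d) paste(d$nodeA, d$nodeB)
  pos <- tr$plantedEdges[tr$plantedEdges$sign > 0, ]
  expect_gt(mean(key(pos) %in% key(sel$positive)), 0.8)
})

test_that("per-edge statistics agree with a direct partial-correlation oracle", {
  co <- genConnectomeCohort(60, 8, nPlanted = 4, edgeR = 0.4, seed = 12)
  sel <- selectEdges(co)
  cd <- as.data.frame(SummarizedExperiment::colData(co))
  Xc <- stats::model.matrix(~ age + sex + site + fd, cd)[, -1]
  E <- edgeValues(co)
  k <- qr(cbind(1, Xc))$rank - 1
  for (e in c(1, 7, 20)) {
    re <- residuals(lm(E[e, ] ~ Xc))
    rp <- residuals(lm(cd$phenotype ~ Xc))
    rOracle <- cor(re, rp)
    df <- ncol(E) - 2 - k
    tOracle <- rOracle * sqrt(df / (1 - rOracle^2))
    expect_equal(sel$stats$r[e], rOracle, tolerance = 1e-10)
    expect_equal(sel$stats$p[e], 2 * pt(-abs(tOracle), df),
                 tolerance = 1e-10)
  }
})

test_that("constant edges are skipped rather than propagating NaN", {
  co <- genConnectomeCohort(40, 6, seed = 2)
  E <- edgeValues(co)
  E[3, ] <- 5
  co2 <- connectomeCohort(E,
    as.data.frame(SummarizedExperiment::colData(co)), nNodes = 6)
  sel <- selectEdges(co2)
  expect_equal(sel$skipped, 3)
  expect_true(is.na(sel$stats$p[3]))
})

test_that("network strength sums each selected edge once", {
  m <- matrix(0, 4, 4)
  m[1, 2] <- m[2, 1] <- 2.0
  m[3, 4] <- m[4, 3] <- 0.5
  edges <- list(positive = data.frame(nodeA = 1, nodeB = 2),
                negative = data.frame(nodeA = 3, nodeB = 4))
  s <- networkStrength(m, edges)
  expect_equal(unname(s), c(2.0, 0.5, 1.5))
  empty <- list(positive = data.frame(), negative = data.frame())
  expect_equal(unname(networkStrength(m, empty)), c(0, 0, 0))
  bad <- list(positive = data.frame(nodeA = 1, nodeB = 9),
              negative = data.frame())
  expect_error(networkStrength(m, bad), "bounds")
})

test_that("a noiseless linear phenotype is fit almost perfectly", {
  co <- genConnectomeCohort(150, 12, nPlanted = 6, edgeR = 0.3, seed = 30)
  tr <- cohortTruth(co)
  E <- edgeValues(co)
  strength <- colSums(E[tr$plantedRows, ] * tr$plantedEdges$sign)
  cd <- as.data.frame(SummarizedExperiment::colData(co))
  cd$phenotype <- strength                      # exact linear rule
  co2 <- connectomeCohort(E, cd, nNodes = 12)
  model <- fitCpm(co2, pThreshold = 1e-8)   # only the exact edges survive
  pred <- predictCpm(model, co2)
  expect_gt(cor(pred[, "combined"], cd$phenotype), 0.999)
  # refitting is deterministic
  model2 <- fitCpm(co2, pThreshold = 1e-8)
  expect_identical(cpmCoefficients(model), cpmCoefficients(model2))
})

test_that("prediction on the training set reproduces fitted values", {
  co <- smallPlantedCohort(n = 100, nodes = 15, planted = 5, seed = 44)
  model <- fitCpm(co)
  pred <- predictCpm(model, co)
  cd <- as.data.frame(SummarizedExperiment::colData(co))
  Xc <- attncpm:::.covariateMatrix(cd, model@covariates)
  str <- networkStrength(co, cpmEdges(model))
  fitted <- lm(cd$phenotype ~ str$positive + Xc)$fitted.values
  expect_equal(unname(pred[, "positive"]), unname(fitted), tolerance = 1e-8)
})

test_that("degenerate models and unseen sites are refused", {
  co <- genConnectomeCohort(60, 8, nPlanted = 0, seed = 3)
  model <- fitCpm(co, pThreshold = 1e-9)       # selects nothing
  expect_true(all(model@degenerate))
  expect_error(predictCpm(model, co), "degenerate")
  co2 <- smallPlantedCohort(n = 80, nodes = 10, planted = 4, seed = 9)
  m2 <- fitCpm(co2)
  cd <- as.data.frame(SummarizedExperiment::colData(co2))
  levels(cd$site) <- c("siteX", "site2", "site3")
  co3 <- connectomeCohort(edgeValues(co2), cd, nNodes = 10)
  expect_error(predictCpm(m2, co3, networks = names(which(!m2@degenerate))),
               "unseen")
})

test_that("cross-validation predicts every subject exactly once per repeat", {
  co <- smallPlantedCohort(n = 90, nodes = 15, planted = 6, seed = 7)
  cv <- crossvalCpm(co, k = 5, nRepeats = 3, seed = 2)
  expect_false(anyNA(cv@predicted))
  expect_equal(dim(cv@repeatR), c(3, 3))
  expect_equal(meanR(cv), colMeans(cv@repeatR))
  expect_gt(meanR(cv)[["combined"]], 0.2)
})

test_that("leave-site-out folds are the scan sites", {
  co <- genConnectomeCohort(160, 10, nPlanted = 4, edgeR = 0.4,
                            nSites = 8, seed = 5)
  cv <- crossvalCpm(co, scheme = "leave_site_out", seed = 1)
  expect_equal(cv@k, 8)
  expect_equal(cv@nRepeats, 1L)
})

test_that("the 95% consensus rule over 50 repeats cuts at 48", {
  co <- smallPlantedCohort(n = 80, nodes = 10, planted = 4, seed = 13)
  cv <- crossvalCpm(co, k = 5, nRepeats = 50, seed = 3)
  expect_equal(cv@consensusCut, 48L)
})

test_that("consensus edges are stable across seeds on a planted cohort", {
  co <- genConnectomeCohort(300, 60, nPlanted = 40, edgeR = 0.3, seed = 21)
  key <- function(d) paste(d$nodeA, d$nodeB)
  cons <- lapply(c(101, 202), function(s) {
    cv <- crossvalCpm(co, k = 10, nRepeats = 20, seed = s)
    c(key(consensusEdges(cv)$positive), key(consensusEdges(cv)$negative))
  })
  jaccard <- length(intersect(cons[[1]], cons[[2]])) /
    length(union(cons[[1]], cons[[2]]))
  expect_gt(jaccard, 0.8)
})

test_that("permutation p-values behave like add-one estimates", {
  co <- smallPlantedCohort(n = 150, nodes = 15, planted = 6, seed = 6)
  pt1 <- permutationTestCpm(co, k = 5, nPerm = 199, seed = 4)
  expect_equal(unname(pt1$p[["combined"]]), 1 / 200, tolerance = 1e-12)
  pt2 <- permutationTestCpm(co, k = 5, nPerm = 199, seed = 4)
  expect_identical(pt1$nullR, pt2$nullR)
  expect_warning(permutationTestCpm(co, k = 5, nPerm = 50, seed = 1),
                 "nPerm")
})

test_that("model transfer generalizes across cohorts sharing planted truth", {
  edges <- data.frame(nodeA = c(1, 2, 3, 5), nodeB = c(4, 6, 7, 8),
                      sign = c(1, 1, -1, -1))
  coA <- genConnectomeCohort(250, 12, plantedEdges = edges, edgeR = 0.4,
                             seed = 31)
  coB <- genConnectomeCohort(250, 12, plantedEdges = edges, edgeR = 0.4,
                             seed = 32)
  model <- fitCpm(coA)
  perf <- transferModel(model, coB, mode = "coefficients", nShuffle = 200,
                        seed = 9)
  expect_gt(perf$r[perf$network == "combined"], 0)
  expect_lt(perf$p[perf$network == "combined"], 0.05)
  # identity transfer reproduces the in-sample fit
  same <- transferModel(model, coA, mode = "coefficients", nShuffle = 50,
                        seed = 1)
  predA <- predictCpm(model, coA)
  expect_equal(same$r[same$network == "positive"],
               cor(predA[, "positive"], phenotype(coA)), tolerance = 1e-12)
  resid <- transferModel(model, coB, mode = "residual_correlation",
                         nShuffle = 200, seed = 10)
  expect_gt(resid$r[resid$network == "combined"], 0)
  expect_lt(resid$p[resid$network == "combined"], 0.05)
})
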