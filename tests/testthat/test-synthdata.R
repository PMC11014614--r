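test_that("task event sequences respect trial counts and stop spacing", {
  for (s in 1:5) {
    ev <- genTaskEvents(sstProtocolAge14(), seed = s)
    expect_equal(sum(ev$trial_type == "go"), 400)
    expect_equal(sum(ev$trial_type == "stop"), 80)
    expect_true(all(diff(ev$onset) > 0))
    runs <- rle(ev$trial_type)
    gaps <- runs$lengths[runs$values == "go"]
    inner <- gaps[seq(2, length(gaps) - (utils::tail(runs$values, 1) == "go"))]
    expect_true(all(inner >= 3 & inner <= 7))
  }
  ev19 <- genTaskEvents(sstProtocolAge19(), seed = 1)
  expect_equal(sum(ev19$trial_type == "go"), 300)
  expect_equal(sum(ev19$trial_type == "stop"), 60)
  expect_true(all(!is.na(ev19$ssd_ms[ev19$trial_type == "stop"])))
})

test_that("infeasible stop spacing is rejected", {
  expect_error(genTaskEvents(taskProtocol(nGo = 20, nStop = 10), seed = 1),
               "infeasible gap")
})

test_that("simulated stop trials follow the SSD staircase grid", {
  proto <- taskProtocol(nGo = 1000, nStop = 200)
  tr <- genSstTrials(proto, raceModelParams(), seed = 3)
  st <- tr[tr$trial_type == "stop", ]
  expect_true(all(st$ssd_ms %in% seq(250, 900, by = 50)))
  expect_true(all(is.na(tr$ssd_ms[tr$trial_type == "go"])))
  steps <- diff(st$ssd_ms)
  expect_true(all(abs(steps) <= 50))         # one step per stop trial, clamped
  # staircase moves up after success, down after failure (away from clamps)
  mid <- st$ssd_ms[-nrow(st)] > 250 & st$ssd_ms[-nrow(st)] < 900
  up <- st$outcome[-nrow(st)] == "stop_success"
  expect_true(all(steps[mid & up] == 50))
  expect_true(all(steps[mid & !up] == -50))
})

test_that("trial simulation is a pure function of parameters and seed", {
  proto <- sstProtocolAge19()
  a <- genSstTrials(proto, raceModelParams(), seed = 17)
  b <- genSstTrials(proto, raceModelParams(), seed = 17)
  expect_identical(a, b)
  c <- genSstTrials(proto, raceModelParams(), seed = 18)
  expect_false(identical(a, c))
})

test_that("race-model parameter validation rejects impossible inputs", {
  expect_error(raceModelParams(goMeanMs = -10), "positive")
  expect_error(raceModelParams(omissionRate = 1.5), "rates")
})

test_that("connectome cohort plants edges at the requested correlation", {
  co <- genConnectomeCohort(4000, 20, nPlanted = 10, edgeR = 0.3, seed = 2)
  tr <- cohortTruth(co)
  E <- edgeValues(co)
  ph <- phenotype(co)
  rPlanted <- apply(E[tr$plantedRows, ], 1, cor, y = ph)
  expect_equal(mean(abs(rPlanted)), 0.3, tolerance = 0.1)
  expect_true(all(sign(rPlanted) == tr$plantedEdges$sign))
  nullRows <- setdiff(seq_len(nrow(E)), tr$plantedRows)[1:50]
  rNull <- apply(E[nullRows, ], 1, cor, y = ph)
  expect_lt(max(abs(rNull)), 0.1)
})

test_that("null cohorts carry no edge-phenotype association", {
  co <- genConnectomeCohort(500, 15, nPlanted = 0, seed = 9)
  sel <- selectEdges(co, pThreshold = 0.01)
  expect_lt(nrow(sel$positive) + nrow(sel$negative),
            0.05 * nrow(sel$stats))
  expect_null(cohortTruth(co)$plantedEdges)
})

test_that("duplicate planted edges are rejected", {
  bad <- data.frame(nodeA = c(1, 1), nodeB = c(2, 2), sign = c(1, -1))
  expect_error(genConnectomeCohort(50, 10, plantedEdges = bad, seed = 1),
               "duplicate")
})

test_that("latent change score generator matches its own implied moments", {
  pv <- c(mu_x1 = 0.2, mu_y1 = -0.1, v_x1 = 1, v_y1 = 0.8, c_xy1 = 0.3,
          alpha_x = 0.1, alpha_y = 0.05, beta_x = -0.3, beta_y = -0.25,
          gamma_x = 0.15, gamma_y = 0.12, q_x = 0.25, q_y = 0.2,
          q_xy = 0.05)
  p <- lcsParams(mu0 = c(0.2, -0.1),
                 sigma0 = matrix(c(1, 0.3, 0.3, 0.8), 2),
                 alpha = c(0.1, 0.05), beta = c(-0.3, -0.25),
                 gammaX = 0.15, gammaY = 0.12,
                 residual = matrix(c(0.25, 0.05, 0.05, 0.2), 2))
  d <- genLcsCohort(p, 100000, seed = 3)
  im <- impliedMoments(pv)
  expect_lt(max(abs(im$mu - colMeans(d))), 0.02)
  expect_lt(max(abs(im$Sigma - cov(d)) / (abs(im$Sigma) + 0.1)), 0.03)
})

test_that("zero-dynamics cohorts change only by their intercepts", {
  p <- lcsParams(alpha = c(0.5, -0.2), beta = c(0, 0),
                 residual = matrix(0, 2, 2))
  d <- genLcsCohort(p, 200, seed = 4)
  expect_equal(d$x2, d$x1 + 0.5)
  expect_equal(d$x3, d$x1 + 1.0)
  expect_equal(d$y2, d$y1 - 0.2)
})

test_that("non-positive-definite initial covariance is rejected", {
  p <- lcsParams(sigma0 = matrix(c(1, 2, 2, 1), 2))
  expect_error(genLcsCohort(p, 100, seed = 1), "positive definite")
})

test_that("substance item generator reproduces its loading structure", {
  L <- cbind(c(.8, .75, .7, 0, 0, 0), c(0, 0, 0, .8, .75, .7))
  it <- genSubstanceItems(3000, L, seed = 6)
  expect_identical(it, genSubstanceItems(3000, L, seed = 6))
  R <- cor(it)
  expect_equal(R[1, 2], 0.8 * 0.75, tolerance = 0.05)
  expect_equal(R[1, 4], 0, tolerance = 0.05)
  expect_error(genSubstanceItems(100, matrix(0.5, 2, 3), seed = 1),
               "more factors")
})

test_that("pure-noise items give a non-significant sphericity test", {
  it <- genSubstanceItems(3000, matrix(0, 6, 1), seed = 7)
  expect_gt(bartlettSphericity(it)$p, 0.01)
})
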