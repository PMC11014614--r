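# Independent oracles and fixture builders used across the suite.

# Tucker congruence between loading matrices, after matching each column of
# A to its best-matching column of B (sign-free).
tuckerCongruence <- function(A, B) {
  An <- sweep(A, 2, sqrt(colSums(A^2)), `/`)
  Bn <- sweep(B, 2, sqrt(colSums(B^2)), `/`)
  phi <- abs(crossprod(An, Bn))
  apply(phi, 2, max)
}

# Literal Benjamini-Hochberg step-up: reject the largest k with
# p_(k) <= k q / m, then everything at or below it.
bhOracle <- function(p, q) {
  m <- length(p)
  o <- order(p)
  ok <- which(p[o] <= seq_len(m) * q / m)
  reject <- logical(m)
  if (length(ok)) reject[o[seq_len(max(ok))]] <- TRUE
  reject
}

# Data matrix whose sample mean and covariance (n - 1 divisor) equal the
# given moments exactly.
exactMomentPanel <- function(n, mu, Sigma, seed = 1) {
  p <- length(mu)
  Z <- withr::with_seed(seed, matrix(rnorm(n * p), n, p))
  Z <- scale(Z, scale = FALSE)
  Z <- Z %*% solve(chol(cov(Z)))
  X <- Z %*% chol(Sigma)
  X <- sweep(X, 2, mu, `+`)
  colnames(X) <- names(mu)
  as.data.frame(X)
}

# Small deterministic planted cohort for CPM unit tests.
smallPlantedCohort <- function(n = 120, nodes = 20, planted = 8, seed = 5,
                               edgeR = 0.45) {
  genConnectomeCohort(n, nodes, nPlanted = planted, edgeR = edgeR,
                      edgeLoading = sqrt(0.5), nSites = 3, seed = seed)
}

# Short synthetic task run for gPPI tests.
smallPpiRun <- function(seed, coef = 1, nRois = 5, noiseSd = 0.2,
                        nVolumes = 160) {
  proto <- taskProtocol(nGo = 60, nStop = 12, soaSeconds = 4)
  trials <- genSstTrials(proto, raceModelParams(), seed)
  genRoiTimeSeries(trialsToEvents(trials), nRois = nRois,
                   nVolumes = nVolumes, trSeconds = 2.2,
                   ppiPairs = if (coef != 0)
                     data.frame(from = 1, to = 2, condition = "GO",
                                coef = coef) else NULL,
                   noiseSd = noiseSd, seed = seed + 1000)
}
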