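#' Simulate a cross-sectional connectome cohort with planted signal
#'
#' Matrix-level generator for exercising the CPM stage. Null edges are
#' independent standard normal across subjects. Planted edges share a
#' latent "network factor" per subject: a planted edge with sign `s` takes
#' the value `s * loading * f + sqrt(1 - loading^2) * u`, and the phenotype
#' loads on the same factor so that each planted edge has population
#' (partial) correlation `edgeR` with the phenotype — positive-signed edges
#' correlate positively, negative ones negatively. (A phenotype built as a
#' plain sum of 40 independent edges cannot give per-edge correlations of
#' 0.3 — the squared correlations would sum past 1 — so shared edge variance
#' is the realistic structure, mirroring the fact that edges of one
#' functional network co-vary.) Covariate and site effects can be added to
#' both edges and phenotype; they carry no information about the planted
#' factor, so they are removable by residualization.
#'
#' @param nSubjects,nNodes Cohort size and atlas size (>= 3 nodes).
#' @param nPlanted Number of planted edges (half negative by default);
#'   ignored when `plantedEdges` is given.
#' @param plantedEdges Optional data.frame `nodeA`, `nodeB`, `sign`
#'   (+1/-1), `nodeA < nodeB`, no duplicates.
#' @param edgeR Target population correlation magnitude between each
#'   planted edge and the phenotype (must not exceed `edgeLoading`).
#' @param edgeLoading Loading of planted edges on the latent factor.
#' @param nSites Number of acquisition sites.
#' @param siteEdgeSd SD of per-site, per-edge mean shifts.
#' @param phenoCovariateBeta Named vector of phenotype effects for
#'   `age`, `sex`, `fd`, plus `siteSd` for random site intercepts (all 0 by
#'   default, the calibration null).
#' @param seed Integer seed.
#' @return A [ConnectomeCohort-class]; planted truth (edges, factor,
#'   loadings, seed) in `metadata(x)$truth`.
#' @export
genConnectomeCohort <- function(nSubjects, nNodes, nPlanted = 0,
                                plantedEdges = NULL, edgeR = 0.3,
                                edgeLoading = sqrt(0.5), nSites = 8,
                                siteEdgeSd = 0,
                                phenoCovariateBeta = c(age = 0, sex = 0,
                                                       fd = 0, siteSd = 0),
                                seed = 1) {
  if (nNodes < 3) stop("nNodes must be at least 3")
  idx <- edgeIndex(nNodes)
  nEdges <- nrow(idx)
  seeds <- splitSeed(seed, 4L)
  if (is.null(plantedEdges) && nPlanted > 0) {
    plantedEdges <- withr::with_seed(seeds[1], {
      pick <- sample.int(nEdges, nPlanted)
      data.frame(nodeA = idx[pick, 1], nodeB = idx[pick, 2],
                 sign = rep(c(1, -1), length.out = nPlanted))
    })
  }
  plantedRows <- integer(0)
  if (!is.null(plantedEdges)) {
    if (anyDuplicated(paste(plantedEdges$nodeA, plantedEdges$nodeB)))
      stop("duplicate planted edges")
    if (any(plantedEdges$nodeA >= plantedEdges$nodeB) ||
        any(plantedEdges$nodeB > nNodes))
      stop("planted edges must satisfy nodeA < nodeB <= nNodes")
    plantedRows <- match(paste(plantedEdges$nodeA, plantedEdges$nodeB),
                         paste(idx[, 1], idx[, 2]))
    if (abs(edgeR) > edgeLoading)
      stop("edgeR cannot exceed edgeLoading")
  }
  withr::with_seed(seeds[2], {
    f <- rnorm(nSubjects)
    E <- matrix(rnorm(nEdges * nSubjects), nEdges, nSubjects)
    if (length(plantedRows)) {
      u <- E[plantedRows, , drop = FALSE]
      E[plantedRows, ] <- outer(plantedEdges$sign * edgeLoading, f) +
        sqrt(1 - edgeLoading^2) * u
    }
  })
  withr::with_seed(seeds[3], {
    cohort <- data.frame(
      subject = sprintf("sub%04d", seq_len(nSubjects)),
      age = rnorm(nSubjects, 19, 0.8),
      sex = factor(sample(c("F", "M"), nSubjects, replace = TRUE)),
      site = factor(sprintf("site%d", sample.int(nSites, nSubjects,
                                                 replace = TRUE)),
                    levels = sprintf("site%d", seq_len(nSites))),
      fd = rlnorm(nSubjects, log(0.15), 0.4))
  })
  withr::with_seed(seeds[4], {
    if (siteEdgeSd > 0) {
      shift <- matrix(rnorm(nEdges * nSites, 0, siteEdgeSd), nEdges, nSites)
      E <- E + shift[, as.integer(cohort$site)]
    }
    b <- if (length(plantedRows)) edgeR / edgeLoading else 0
    siteInt <- rnorm(nSites, 0, phenoCovariateBeta[["siteSd"]])
    pheno <- b * f + sqrt(1 - b^2) * rnorm(nSubjects) +
      phenoCovariateBeta[["age"]] * (cohort$age - mean(cohort$age)) +
      phenoCovariateBeta[["sex"]] * (as.integer(cohort$sex) - 1.5) +
      phenoCovariateBeta[["fd"]] * scale(log(cohort$fd))[, 1] +
      siteInt[as.integer(cohort$site)]
  })
  cohort$phenotype <- pheno
  connectomeCohort(E, cohort, nNodes = nNodes,
                   truth = list(plantedEdges = plantedEdges,
                                plantedRows = plantedRows, edgeR = edgeR,
                                edgeLoading = edgeLoading, factor = f,
                                phenoCovariateBeta = phenoCovariateBeta,
                                seed = seed))
}

#' Default generative parameters for the bivariate latent change score model
#'
#' @param mu0 Initial means of (x, y).
#' @param sigma0 Initial 2 x 2 covariance of (x1, y1).
#' @param alpha Change intercepts (x, y).
#' @param beta Self-feedback of each construct on its own change.
#' @param gammaX Coupling: previous-wave y on the change in x.
#' @param gammaY Coupling: previous-wave x on the change in y.
#' @param residual 2 x 2 covariance of the change residuals within a wave.
#' @return Named list of generative parameters.
#' @export
lcsParams <- function(mu0 = c(0, 0), sigma0 = diag(2), alpha = c(0, 0),
                      beta = c(-0.3, -0.3), gammaX = 0, gammaY = 0,
                      residual = 0.25 * diag(2)) {
  list(mu0 = mu0, sigma0 = sigma0, alpha = alpha, beta = beta,
       gammaX = gammaX, gammaY = gammaY, residual = residual)
}

#' Simulate a three-wave bivariate cohort from the latent change score model
#'
#' Follows the generative equations of the model: initial scores are
#' bivariate normal; the change over each interval is
#' `intercept + beta * same construct + gamma * other construct + residual`,
#' and the observed score is the latent score (single indicator, no
#' measurement error). Parameters are constant across the two intervals.
#'
#' @param params List from [lcsParams].
#' @param nSubjects Sample size.
#' @param seed Integer seed.
#' @return data.frame `x1`, `y1`, `x2`, `y2`, `x3`, `y3` with the generative
#'   parameters attached as `attr(, "truth")`.
#' @export
genLcsCohort <- function(params, nSubjects, seed) {
  p <- params
  ev0 <- eigen(p$sigma0, symmetric = TRUE, only.values = TRUE)$values
  if (any(ev0 <= 0)) stop("initial covariance must be positive definite")
  evQ <- eigen(p$residual, symmetric = TRUE, only.values = TRUE)$values
  if (any(evQ < 0)) stop("residual covariance must be positive semidefinite")
  rmvn <- function(n, mu, S) {
    L <- if (all(S == 0)) matrix(0, 2, 2) else
      tryCatch(chol(S), error = function(e) {   # PSD fallback
        e <- eigen(S, symmetric = TRUE)
        t(e$vectors %*% (sqrt(pmax(e$values, 0)) * t(e$vectors)))
      })
    sweep(matrix(rnorm(n * 2), n) %*% L, 2, mu, `+`)
  }
  withr::with_seed(as.integer(seed), {
    s1 <- rmvn(nSubjects, p$mu0, p$sigma0)
    step <- function(s) {
      delta <- cbind(p$alpha[1] + p$beta[1] * s[, 1] + p$gammaX * s[, 2],
                     p$alpha[2] + p$beta[2] * s[, 2] + p$gammaY * s[, 1]) +
        rmvn(nSubjects, c(0, 0), p$residual)
      s + delta
    }
    s2 <- step(s1)
    s3 <- step(s2)
  })
  out <- data.frame(x1 = s1[, 1], y1 = s1[, 2], x2 = s2[, 1], y2 = s2[, 2],
                    x3 = s3[, 1], y3 = s3[, 2])
  attr(out, "truth") <- c(p, list(seed = seed))
  out
}

#' Simulate substance-use item tables with a planted factor structure
#'
#' Items are linear combinations of latent factors plus unique noise:
#' `item = loadings %*% factors + uniqueness * e`. With unit-variance
#' factors and `uniqueness = sqrt(1 - communality)` the items have unit
#' variance and the population correlation matrix is
#' `loadings %*% t(loadings)` off the diagonal. Optional flooring at zero
#' mimics consumption counts.
#'
#' @param nSubjects Sample size.
#' @param loadings Items x factors loading matrix (rows' squared sums must
#'   not exceed 1); at least as many items as factors.
#' @param floorAtZero Truncate negative values to zero.
#' @param itemNames Optional item names.
#' @param seed Integer seed.
#' @return data.frame of items with `attr(, "truth")` recording loadings
#'   and factor scores.
#' @export
genSubstanceItems <- function(nSubjects, loadings, floorAtZero = FALSE,
                              itemNames = NULL, seed = 1) {
  loadings <- as.matrix(loadings)
  if (ncol(loadings) > nrow(loadings))
    stop("more factors than items")
  comm <- rowSums(loadings^2)
  if (any(comm > 1)) stop("row communalities exceed 1")
  withr::with_seed(as.integer(seed), {
    f <- matrix(rnorm(nSubjects * ncol(loadings)), nSubjects)
    e <- matrix(rnorm(nSubjects * nrow(loadings)), nSubjects)
    items <- f %*% t(loadings) + sweep(e, 2, sqrt(1 - comm), `*`)
  })
  if (floorAtZero) items <- pmax(items, 0)
  colnames(items) <- if (!is.null(itemNames)) itemNames else
    paste0("item", seq_len(nrow(loadings)))
  out <- as.data.frame(items)
  attr(out, "truth") <- list(loadings = loadings, factors = f, seed = seed)
  out
}
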