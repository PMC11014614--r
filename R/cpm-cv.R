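## Batched CPM cross-validation engine.
##
## Runs the full CPM pipeline (edge selection -> strength -> linear model ->
## held-out prediction) for every phenotype column of PH simultaneously,
## under one fold partition. Because edge residualization never involves the
## phenotype, running P phenotype columns at once is numerically identical
## to P naive reruns; the batching is what makes 1000-fold permutation
## reruns tractable. The per-network linear model is solved by
## Frisch-Waugh-Lovell: regress strength and phenotype on covariates, slope
## from the residual inner products, covariate coefficients from the
## strength-adjusted phenotype.
##
## E: edges x subjects; PH: subjects x P phenotypes; Xc: covariates or NULL.
## Returns r (P x 3) and, when collectSel (P == 1), per-fold selections.
.cpmCvEngine <- function(E, PH, Xc, foldId, pThreshold, collectSel = FALSE) {
  n <- ncol(E); P <- ncol(PH)
  nets <- c("positive", "negative", "combined")
  Xfull <- cbind(`(Intercept)` = rep(1, n), Xc)
  pred <- array(NA_real_, c(n, P, 3))
  selFolds <- list()
  for (f in sort(unique(foldId))) {
    te <- which(foldId == f); tr <- which(foldId != f)
    q0 <- qr(Xfull[tr, , drop = FALSE])
    keep <- sort(q0$pivot[seq_len(q0$rank)])
    kRank <- length(keep) - 1L
    if (length(tr) < kRank + 3L)
      stop("fold ", f, " leaves a training set smaller than the covariate ",
           "rank + 3")
    Xtr <- Xfull[tr, keep, drop = FALSE]
    Xte <- Xfull[te, keep, drop = FALSE]
    qrX <- qr(Xtr)
    A <- qr.resid(qrX, t(E[, tr, drop = FALSE]))    # n_tr x edges
    PHtr <- PH[tr, , drop = FALSE]
    PHres <- qr.resid(qrX, PHtr)
    a2 <- colSums(A^2)
    R <- crossprod(A, PHres) /
      sqrt(outer(pmax(a2, 1e-300), pmax(colSums(PHres^2), 1e-300)))
    df <- length(tr) - 2L - kRank
    pMat <- 2 * pt(-abs(R * sqrt(df / pmax(1 - R^2, 1e-300))), df)
    sel <- pMat < pThreshold & a2 > 1e-20
    Mpos <- sel & R > 0
    Mneg <- sel & R < 0
    if (collectSel)
      selFolds[[length(selFolds) + 1L]] <-
        list(positive = Mpos[, 1], negative = Mneg[, 1])
    strTr <- list(crossprod(E[, tr, drop = FALSE], Mpos),
                  crossprod(E[, tr, drop = FALSE], Mneg))
    strTe <- list(crossprod(E[, te, drop = FALSE], Mpos),
                  crossprod(E[, te, drop = FALSE], Mneg))
    strTr[[3]] <- strTr[[1]] - strTr[[2]]
    strTe[[3]] <- strTe[[1]] - strTe[[2]]
    for (net in 1:3) {
      Sres <- qr.resid(qrX, strTr[[net]])
      den <- colSums(Sres^2)
      bS <- ifelse(den > 1e-12, colSums(Sres * PHres) / den, 0)
      coefB <- qr.coef(qrX, PHtr - sweep(strTr[[net]], 2, bS, `*`))
      coefB[is.na(coefB)] <- 0
      pred[te, , net] <- Xte %*% coefB + sweep(strTe[[net]], 2, bS, `*`)
    }
  }
  r <- vapply(1:3, function(net) {
    cp <- scale(pred[, , net], scale = FALSE)
    cy <- scale(PH, scale = FALSE)
    num <- colSums(cp * cy)
    den <- sqrt(colSums(cp^2) * colSums(cy^2))
    ifelse(den > 1e-12, num / den, 0)
  }, numeric(P))
  r <- matrix(r, nrow = P, ncol = 3, dimnames = list(NULL, nets))
  list(r = r, pred = pred, selFolds = selFolds)
}

.foldAssignment <- function(n, k, site = NULL, scheme = "kfold",
                            siteStratified = FALSE) {
  if (scheme == "leave_site_out") {
    if (is.null(site)) stop("leave-site-out CV requires a site covariate")
    if (length(unique(site)) < 2) stop("leave-site-out CV needs >= 2 sites")
    return(as.integer(factor(site)))
  }
  if (k > n) stop("k cannot exceed the number of subjects")
  if (siteStratified && !is.null(site)) {
    foldId <- integer(n)
    for (s in unique(site)) {
      idx <- which(site == s)
      foldId[idx] <- sample(rep(seq_len(k), length.out = length(idx)))
    }
    foldId
  } else sample(rep(seq_len(k), length.out = n))
}

#' Cross-validated connectome-based predictive modelling
#'
#' Runs the full CPM pipeline under k-fold (default 10-fold, 50 random
#' repeats) or leave-site-out cross-validation: within each fold, edges are
#' selected and the per-network linear models fitted on the training folds
#' only, and the held-out subjects' phenotypes are predicted. Performance
#' per repeat is the correlation between concatenated predictions and
#' observed phenotype; the summary is its mean over repeats. Consensus edge
#' sets collect edges selected in every fold of a repeat, in at least
#' `ceiling(consensusProp * nRepeats)` repeats (48 of 50 at defaults).
#'
#' @inheritParams selectEdges
#' @param scheme `"kfold"` or `"leave_site_out"` (folds = scan sites,
#'   deterministic, 1 repeat).
#' @param k Number of folds for k-fold.
#' @param nRepeats Random re-partitions of the k-fold scheme.
#' @param siteStratified Balance site composition across folds.
#' @param consensusProp Consensus proportion over repeats.
#' @param seed Integer seed; all partitions derive from it.
#' @return A [CVResult-class].
#' @export
crossvalCpm <- function(cohort, scheme = c("kfold", "leave_site_out"),
                        k = 10, nRepeats = 50, pThreshold = 0.01,
                        phenotypeName = "phenotype",
                        covariates = c("age", "sex", "site", "fd"),
                        siteStratified = FALSE, consensusProp = 0.95,
                        seed = 1) {
  scheme <- match.arg(scheme)
  E <- edgeValues(cohort)
  cd <- SummarizedExperiment::colData(cohort)
  ph <- cd[[phenotypeName]]
  Xc <- .covariateMatrix(cd, covariates)
  site <- if ("site" %in% colnames(cd)) cd[["site"]] else NULL
  n <- ncol(E)
  if (scheme == "leave_site_out") nRepeats <- 1L
  seeds <- splitSeed(seed, nRepeats)
  PH <- matrix(ph, ncol = 1)
  nSel <- nrow(E)
  posCount <- negCount <- integer(nSel)
  repeatR <- matrix(NA_real_, nRepeats, 3,
                    dimnames = list(NULL, c("positive", "negative",
                                            "combined")))
  predSum <- matrix(0, n, 3)
  kUsed <- if (scheme == "leave_site_out") length(unique(site)) else
    as.integer(k)
  for (rep in seq_len(nRepeats)) {
    foldId <- withr::with_seed(seeds[rep],
      .foldAssignment(n, k, site, scheme, siteStratified))
    fit <- .cpmCvEngine(E, PH, Xc, foldId, pThreshold, collectSel = TRUE)
    repeatR[rep, ] <- fit$r[1, ]
    predSum <- predSum + fit$pred[, 1, ]
    inAll <- Reduce(`&`, lapply(fit$selFolds, `[[`, "positive"))
    posCount <- posCount + inAll
    inAll <- Reduce(`&`, lapply(fit$selFolds, `[[`, "negative"))
    negCount <- negCount + inAll
  }
  cut <- as.integer(ceiling(consensusProp * nRepeats))
  idx <- edgeIndex(nNodes(cohort))
  consensus <- list(
    positive = as.data.frame(idx[posCount >= cut, , drop = FALSE]),
    negative = as.data.frame(idx[negCount >= cut, , drop = FALSE]))
  new("CVResult", observed = as.numeric(ph), predicted = predSum / nRepeats,
      repeatR = repeatR, meanR = colMeans(repeatR), consensus = consensus,
      consensusCut = cut, scheme = scheme, k = kUsed,
      nRepeats = as.integer(nRepeats), seed = as.integer(seed))
}

#' Permutation significance of cross-validated CPM performance
#'
#' Reruns the entire CPM pipeline — selection included — with the
#' correspondence between phenotype and connectome shuffled, keeping the
#' covariates attached to the connectomes. The observed statistic and every
#' null reun use the same cross-validation scheme under the same fold
#' partition (drawn once per repeat from the seed), so observed and null
#' values are exchangeable under the null hypothesis. One CV split per
#' permutation is the default; `nRepeats` averages several partitions.
#' The p-value uses the add-one estimator
#' `p = (1 + #\{null >= observed\}) / (nPerm + 1)`.
#'
#' @inheritParams crossvalCpm
#' @param nPerm Number of phenotype shuffles (default 1000).
#' @param nRepeats CV partitions averaged per statistic (default 1).
#' @return List: `p` (per network), `observedR`, `nullR` (nPerm x 3),
#'   `nPerm`.
#' @export
permutationTestCpm <- function(cohort, scheme = c("kfold", "leave_site_out"),
                               k = 10, nPerm = 1000, nRepeats = 1,
                               pThreshold = 0.01,
                               phenotypeName = "phenotype",
                               covariates = c("age", "sex", "site", "fd"),
                               siteStratified = FALSE, seed = 1) {
  scheme <- match.arg(scheme)
  if (nPerm < 100)
    warning("nPerm < 100 gives a minimum attainable p of ",
            round(1 / (nPerm + 1), 3), "; interpret with care")
  E <- edgeValues(cohort)
  cd <- SummarizedExperiment::colData(cohort)
  ph <- cd[[phenotypeName]]
  Xc <- .covariateMatrix(cd, covariates)
  site <- if ("site" %in% colnames(cd)) cd[["site"]] else NULL
  n <- ncol(E)
  if (scheme == "leave_site_out") nRepeats <- 1L
  seeds <- splitSeed(seed, nRepeats + 1L)
  PH <- withr::with_seed(seeds[1],
    cbind(ph, vapply(seq_len(nPerm), function(i) ph[sample.int(n)],
                     numeric(n))))
  rSum <- matrix(0, nPerm + 1L, 3)
  for (rep in seq_len(nRepeats)) {
    foldId <- withr::with_seed(seeds[rep + 1L],
      .foldAssignment(n, k, site, scheme, siteStratified))
    rSum <- rSum + .cpmCvEngine(E, PH, Xc, foldId, pThreshold)$r
  }
  r <- rSum / nRepeats
  observedR <- r[1, ]
  nullR <- r[-1, , drop = FALSE]
  p <- vapply(1:3, function(net)
    (1 + sum(nullR[, net] >= observedR[net])) / (nPerm + 1), numeric(1))
  names(p) <- names(observedR) <- colnames(nullR) <-
    c("positive", "negative", "combined")
  list(p = p, observedR = observedR, nullR = nullR, nPerm = nPerm)
}

#' Transfer a fitted CPM model to another cohort
#'
#' Two transfer modes mirror the two published generalization analyses.
#' `"coefficients"`: network strengths are computed on the target cohort
#' with the source model's edge sets, the source linear model (slope and
#' intercept, plus covariate terms) produces predictions, and performance
#' is the correlation between predicted and observed phenotype.
#' `"residual_correlation"`: strengths and phenotype are residualized on
#' the target cohort's covariates and correlated directly. Significance in
#' both modes comes from shuffling the predicted (or residual strength)
#' values `nShuffle` times and correlating with the observed values.
#'
#' @param model A [CPMModel-class] trained on the source cohort.
#' @param cohort Target [ConnectomeCohort-class]; same atlas.
#' @param mode Transfer mode (see above).
#' @param phenotypeName Phenotype column in the target cohort.
#' @param covariates Covariates for `residual_correlation` mode.
#' @param nShuffle Number of shuffles for the null (default 1000).
#' @param seed Integer seed.
#' @return data.frame per network: `r`, `p`, `mode`, `n`.
#' @export
transferModel <- function(model, cohort,
                          mode = c("coefficients", "residual_correlation"),
                          phenotypeName = model@phenotype,
                          covariates = c("age", "sex", "fd"),
                          nShuffle = 1000, seed = 1) {
  mode <- match.arg(mode)
  cd <- SummarizedExperiment::colData(cohort)
  ph <- cd[[phenotypeName]]
  nets <- names(which(!model@degenerate))
  if (mode == "coefficients") {
    vals <- predictCpm(model, cohort, networks = nets)
  } else {
    str <- networkStrength(cohort, model@edges)
    Xc <- .covariateMatrix(cd, covariates)
    vals <- apply(as.matrix(str[nets]), 2, residualize, covariates = Xc)
    ph <- residualize(ph, Xc)
  }
  shufSeeds <- splitSeed(seed, length(nets))
  out <- lapply(seq_along(nets), function(i) {
    v <- vals[, i]
    rObs <- cor(v, ph)
    rNull <- withr::with_seed(shufSeeds[i],
      vapply(seq_len(nShuffle), function(s) cor(v[sample.int(length(v))], ph),
             numeric(1)))
    data.frame(network = nets[i], r = rObs,
               p = (1 + sum(rNull >= rObs)) / (nShuffle + 1),
               mode = mode, n = length(v))
  })
  do.call(rbind, out)
}
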