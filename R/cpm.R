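## ---- covariate handling -----------------------------------------------

## Numeric covariate matrix from a cohort's colData: factors/characters are
## dummy-coded against a first-level reference; `refLevels` pins the level
## sets of a training run so unseen test levels fail loudly.
.covariateMatrix <- function(df, covariates, refLevels = NULL) {
  if (length(covariates) == 0) return(NULL)
  df <- as.data.frame(df)
  blocks <- lapply(covariates, function(v) {
    x <- df[[v]]
    if (is.null(x)) stop("missing covariate column: ", v)
    if (is.factor(x) || is.character(x)) {
      lev <- if (!is.null(refLevels[[v]])) refLevels[[v]]
             else if (is.factor(x)) levels(x) else sort(unique(as.character(x)))
      unseen <- setdiff(unique(as.character(x)), lev)
      if (length(unseen))
        stop("covariate '", v, "' has level(s) unseen in training: ",
             paste(unseen, collapse = ", "),
             "; map them onto training levels or drop those subjects")
      m <- outer(as.character(x), lev[-1], `==`) * 1
      colnames(m) <- paste0(v, lev[-1])
      m
    } else {
      m <- matrix(as.numeric(x), ncol = 1, dimnames = list(NULL, v))
      m
    }
  })
  do.call(cbind, blocks)
}

.covariateLevels <- function(df, covariates) {
  df <- as.data.frame(df)
  out <- list()
  for (v in covariates) {
    x <- df[[v]]
    if (is.factor(x)) out[[v]] <- levels(x)
    else if (is.character(x)) out[[v]] <- sort(unique(x))
  }
  out
}

## least squares with rank-deficiency tolerance: NA coefficients become 0
.solveLS <- function(X, Y) {
  b <- qr.coef(qr(X), Y)
  b[is.na(b)] <- 0
  b
}

## ---- edge selection ----------------------------------------------------

#' Select phenotype-correlated edges by partial correlation
#'
#' For each edge (strict upper triangle, each pair once) the partial
#' Pearson correlation between edge value and phenotype is computed across
#' subjects, controlling the covariates: both sides are residualized on the
#' covariate design (with intercept) and the correlation of residuals is
#' tested with `df = n - 2 - k` (k = covariate rank). Edges with two-sided
#' `p < pThreshold` form the positive or negative network according to the
#' sign of the correlation. Edges constant across subjects are skipped and
#' reported.
#'
#' @param cohort A [ConnectomeCohort-class].
#' @param pThreshold Selection threshold (default 0.01).
#' @param phenotypeName Phenotype column in `colData`.
#' @param covariates Covariate columns in `colData`.
#' @param subset Optional subject indices (training set).
#' @return List: `positive`/`negative` edge data.frames (`nodeA`, `nodeB`,
#'   `r`, `p`), `stats` (all edges), `skipped` (row indices of constant
#'   edges), `df`.
#' @export
selectEdges <- function(cohort, pThreshold = 0.01,
                        phenotypeName = "phenotype",
                        covariates = c("age", "sex", "site", "fd"),
                        subset = NULL) {
  E <- edgeValues(cohort)
  cd <- SummarizedExperiment::colData(cohort)
  if (!is.null(subset)) { E <- E[, subset, drop = FALSE]
                          cd <- cd[subset, , drop = FALSE] }
  ph <- cd[[phenotypeName]]
  Xc <- .covariateMatrix(cd, covariates)
  n <- ncol(E)
  k <- if (is.null(Xc)) 0L else qr(cbind(1, Xc))$rank - 1L
  if (n < k + 3L) stop("need at least covariates + 3 subjects, got ", n)
  qrX <- .qrDesign(cbind(`(Intercept)` = rep(1, n), Xc), warnDrop = FALSE)
  A <- qr.resid(qrX, t(E))              # subjects x edges residuals
  phr <- qr.resid(qrX, ph)
  a2 <- colSums(A^2)
  skipped <- which(a2 < 1e-20)
  r <- as.numeric(crossprod(A, phr)) / sqrt(pmax(a2, 1e-300) * sum(phr^2))
  r[skipped] <- NA_real_
  df <- n - 2L - k
  tstat <- r * sqrt(df / pmax(1 - r^2, 1e-300))
  p <- 2 * pt(-abs(tstat), df)
  idx <- edgeIndex(nNodes(cohort))
  stats <- data.frame(nodeA = idx[, 1], nodeB = idx[, 2], r = r, p = p)
  sel <- !is.na(p) & p < pThreshold
  list(positive = stats[sel & r > 0, , drop = FALSE],
       negative = stats[sel & r < 0, , drop = FALSE],
       stats = stats, skipped = skipped, df = df)
}

## ---- network strength --------------------------------------------------

#' Network strength of selected edge sets
#'
#' Sums each subject's connectivity values over the selected edges (each
#' undirected edge counted once): `positive` over the positive set,
#' `negative` over the negative set, and `combined = positive - negative`.
#'
#' @param x A symmetric connectivity matrix (one subject) or a
#'   [ConnectomeCohort-class].
#' @param edges List with `positive` and `negative` data.frames carrying
#'   `nodeA`/`nodeB` (as produced by [selectEdges] or stored in a
#'   [CPMModel-class]).
#' @return One-subject: named vector; cohort: data.frame with one row per
#'   subject (`positive`, `negative`, `combined`).
#' @export
networkStrength <- function(x, edges) {
  sumSet <- function(vals, idx, set) {
    if (is.null(set) || nrow(set) == 0) return(numeric(ncol(vals)))
    rows <- match(paste(set$nodeA, set$nodeB), paste(idx[, 1], idx[, 2]))
    if (anyNA(rows)) stop("edge set outside matrix bounds")
    colSums(vals[rows, , drop = FALSE])
  }
  if (is(x, "ConnectomeCohort")) {
    vals <- edgeValues(x); idx <- edgeIndex(nNodes(x))
  } else {
    m <- as.matrix(x)
    if (nrow(m) != ncol(m)) stop("x must be square or a ConnectomeCohort")
    if (any(edges$positive$nodeB > nrow(m)) ||
        any(edges$negative$nodeB > nrow(m)))
      stop("edge set outside matrix bounds")
    vals <- matrix(upperTriVec(m), ncol = 1); idx <- edgeIndex(nrow(m))
  }
  pos <- sumSet(vals, idx, edges$positive)
  neg <- sumSet(vals, idx, edges$negative)
  out <- data.frame(positive = pos, negative = neg, combined = pos - neg)
  if (ncol(vals) == 1) unlist(out[1, ]) else out
}

## ---- model fit / predict ----------------------------------------------

#' Fit a connectome-based predictive model
#'
#' Selects edges on the (training) subjects, computes network strengths,
#' and fits, per network (positive, negative, combined), the linear model
#' `phenotype ~ intercept + strength + covariates` by least squares. A
#' network whose edge set is empty is flagged degenerate and refuses
#' prediction.
#'
#' @inheritParams selectEdges
#' @return A [CPMModel-class].
#' @export
fitCpm <- function(cohort, pThreshold = 0.01, phenotypeName = "phenotype",
                   covariates = c("age", "sex", "site", "fd"),
                   subset = NULL) {
  sel <- selectEdges(cohort, pThreshold, phenotypeName, covariates, subset)
  cd <- SummarizedExperiment::colData(cohort)
  if (!is.null(subset)) cd <- cd[subset, , drop = FALSE]
  ph <- cd[[phenotypeName]]
  Xc <- .covariateMatrix(cd, covariates)
  str <- if (is.null(subset)) networkStrength(cohort, sel) else {
    E <- edgeValues(cohort)[, subset, drop = FALSE]
    sub <- connectomeCohort(E, as.data.frame(cd), nNodes = nNodes(cohort))
    networkStrength(sub, sel)
  }
  degenerate <- c(positive = nrow(sel$positive) == 0,
                  negative = nrow(sel$negative) == 0)
  degenerate["combined"] <- degenerate[["positive"]] && degenerate[["negative"]]
  coefs <- lapply(c("positive", "negative", "combined"), function(net) {
    X <- cbind(`(Intercept)` = 1, strength = str[[net]], Xc)
    drop(.solveLS(X, ph))
  })
  names(coefs) <- c("positive", "negative", "combined")
  new("CPMModel",
      edges = sel[c("positive", "negative")], coefficients = coefs,
      threshold = pThreshold, covariates = covariates,
      covariateLevels = .covariateLevels(cd, covariates),
      phenotype = phenotypeName, nTrain = length(ph),
      degenerate = degenerate)
}

#' Apply a fitted CPM model to new subjects
#'
#' Network strengths are computed on the new connectomes with the
#' *training* edge sets, and the stored coefficients are applied to
#' strength plus covariates. Covariate factor levels must be reconcilable
#' with the training scheme; unseen levels raise an error.
#'
#' @param model A [CPMModel-class].
#' @param cohort Test [ConnectomeCohort-class] (same atlas).
#' @param networks Networks to predict.
#' @param subset Optional subject indices.
#' @return Subjects x networks matrix of predictions.
#' @export
predictCpm <- function(model, cohort,
                       networks = c("positive", "negative", "combined"),
                       subset = NULL) {
  bad <- networks[model@degenerate[networks]]
  if (length(bad))
    stop("model is degenerate (no selected edges) for network(s): ",
         paste(bad, collapse = ", "))
  cd <- SummarizedExperiment::colData(cohort)
  E <- edgeValues(cohort)
  if (!is.null(subset)) { cd <- cd[subset, , drop = FALSE]
                          E <- E[, subset, drop = FALSE] }
  maxNode <- max(c(model@edges$positive$nodeB, model@edges$negative$nodeB, 0))
  if (maxNode > nNodes(cohort))
    stop("atlas mismatch: model edges reference node ", maxNode,
         " but cohort has ", nNodes(cohort), " nodes")
  sub <- connectomeCohort(E, as.data.frame(cd), nNodes = nNodes(cohort))
  str <- networkStrength(sub, model@edges)
  Xc <- .covariateMatrix(cd, model@covariates,
                         refLevels = model@covariateLevels)
  out <- vapply(networks, function(net) {
    X <- cbind(`(Intercept)` = 1, strength = str[[net]], Xc)
    drop(X %*% model@coefficients[[net]][colnames(X)])
  }, numeric(nrow(cd)))
  rownames(out) <- rownames(cd)
  out
}
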