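#' Derive child seeds from a master seed
#'
#' All randomness in the package flows from a single integer seed. Where a
#' routine needs several independent random streams (one per stage, per
#' repeat, per replicate cohort, ...) it derives child seeds with this
#' splitting rule: seed the generator with the master seed and draw `n`
#' integers uniformly from `[1, 2^31 - 2]`. The rule is part of the package
#' contract, so any sub-computation can be reproduced in isolation from its
#' recorded child seed.
#'
#' @param seed Integer master seed.
#' @param n Number of child seeds to derive.
#' @return Integer vector of length `n`.
#' @export
splitSeed <- function(seed, n) {
  stopifnot(is.numeric(seed), length(seed) == 1L, is.finite(seed))
  withr::with_seed(as.integer(seed), sample.int(2147483646L, n, replace = FALSE))
}

#' Upper-triangle edge index for a square connectivity matrix
#'
#' Edges are enumerated in column-major order over the strict upper triangle
#' (`i < j`), the order used throughout the package to vectorize
#' connectivity matrices.
#'
#' @param nNodes Number of nodes.
#' @return Two-column integer matrix with columns `nodeA` (< `nodeB`).
#' @export
edgeIndex <- function(nNodes) {
  stopifnot(nNodes >= 2)
  idx <- which(upper.tri(matrix(0, nNodes, nNodes)), arr.ind = TRUE)
  colnames(idx) <- c("nodeA", "nodeB")
  idx[, c("nodeA", "nodeB"), drop = FALSE]
}

#' Vectorize the strict upper triangle of a symmetric matrix
#' @param m Square matrix.
#' @return Numeric vector in `edgeIndex()` order.
#' @export
upperTriVec <- function(m) {
  stopifnot(is.matrix(m), nrow(m) == ncol(m))
  m[upper.tri(m)]
}

#' Rebuild a symmetric matrix (zero diagonal) from its upper-triangle vector
#' @param v Edge vector in `edgeIndex()` order.
#' @param nNodes Number of nodes.
#' @return Symmetric `nNodes x nNodes` matrix with zero diagonal.
#' @export
vecToSymMatrix <- function(v, nNodes) {
  stopifnot(length(v) == nNodes * (nNodes - 1) / 2)
  m <- matrix(0, nNodes, nNodes)
  m[upper.tri(m)] <- v
  m + t(m)
}

## qr-based residualization used by several modules; drops collinear columns.
.qrDesign <- function(X, warnDrop = TRUE) {
  qrX <- qr(X)
  if (qrX$rank < ncol(X)) {
    keep <- qrX$pivot[seq_len(qrX$rank)]
    dropped <- colnames(X)[setdiff(seq_len(ncol(X)), keep)]
    if (warnDrop)
      warning("dropping collinear covariate column(s): ",
              paste(dropped, collapse = ", "))
    qrX <- qr(X[, sort(keep), drop = FALSE])
  }
  qrX
}

#' Residualize values on a covariate design
#'
#' Least-squares residuals of `values` (vector or matrix, one column per
#' variable) on the columns of `covariates`. An intercept is always
#' included; exactly collinear covariate columns are dropped with a warning.
#'
#' @param values Numeric vector or matrix (rows = observations).
#' @param covariates Numeric design matrix (may be `NULL` for intercept-only),
#'   same number of rows.
#' @return Residuals with the shape of `values`, orthogonal to the design.
#' @export
residualize <- function(values, covariates = NULL) {
  v <- as.matrix(values)
  n <- nrow(v)
  X <- cbind(`(Intercept)` = rep(1, n), covariates)
  if (nrow(X) != n) stop("covariates and values disagree in length")
  if (n < ncol(X)) stop("fewer rows than covariate columns")
  res <- qr.resid(.qrDesign(X), v)
  if (is.vector(values)) drop(res) else res
}

## md5 of an arbitrary R object, via its serialization (used in manifests)
.objectHash <- function(x) {
  f <- tempfile()
  on.exit(unlink(f))
  saveRDS(x, f, version = 2)
  unname(tools::md5sum(f))
}
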