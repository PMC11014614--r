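## correlation matrix of complete rows, with diagnostics
.itemCor <- function(items) {
  X <- as.matrix(items)
  if (!is.numeric(X)) stop("item table must be numeric")
  X <- X[complete.cases(X), , drop = FALSE]
  if (nrow(X) < 3) stop("need at least 3 complete rows")
  list(R = cor(X), n = nrow(X), X = X)
}

#' Kaiser-Meyer-Olkin measure of sampling adequacy
#'
#' Overall and per-item KMO from the squared zero-order correlations and
#' squared anti-image partial correlations:
#' `KMO = sum r^2 / (sum r^2 + sum q^2)` over off-diagonal elements, where
#' `q_ij = -Rinv_ij / sqrt(Rinv_ii Rinv_jj)`. Items whose individual KMO
#' falls below 0.5 — the conventional adequacy floor — are flagged for
#' exclusion before factoring. For two items the partial correlation equals
#' the correlation, so the overall KMO is exactly 0.5.
#'
#' @param items Numeric item table (data.frame or matrix).
#' @return List: `overall`, `perItem` (named), `flagged` (items with
#'   per-item KMO < 0.5).
#' @export
kmoStatistic <- function(items) {
  cc <- .itemCor(items)
  R <- cc$R
  if (rcond(R) < 1e-12) stop("singular item correlation matrix")
  Ri <- solve(R)
  d <- 1 / sqrt(diag(Ri))
  Q <- -Ri * outer(d, d)              # anti-image partial correlations
  off <- upper.tri(R)
  r2 <- R[off]^2; q2 <- Q[off]^2
  denom <- sum(r2) + sum(q2)
  if (denom < 1e-14)
    stop("all correlations are zero; KMO is undefined (0/0)")
  r2i <- rowSums(R^2) - 1
  q2i <- rowSums(Q^2) - diag(Q)^2
  perItem <- r2i / (r2i + q2i)
  names(perItem) <- colnames(R)
  list(overall = sum(r2) / denom, perItem = perItem,
       flagged = names(perItem)[perItem < 0.5])
}

#' Bartlett's test of sphericity
#'
#' Tests the null that the item correlation matrix is the identity:
#' `chisq = -(n - 1 - (2p + 5)/6) * log det(R)` on `p(p-1)/2` degrees of
#' freedom. A significant result licenses factoring.
#'
#' @param items Numeric item table.
#' @return List: `chisq`, `df`, `p`, `n`.
#' @export
bartlettSphericity <- function(items) {
  cc <- .itemCor(items)
  p <- ncol(cc$R)
  if (cc$n <= p) stop("need more rows than items")
  detR <- det(cc$R)
  if (detR <= 0) stop("non-positive correlation determinant")
  chisq <- -(cc$n - 1 - (2 * p + 5) / 6) * log(detR)
  df <- p * (p - 1) / 2
  list(chisq = chisq, df = df, p = pchisq(chisq, df, lower.tail = FALSE),
       n = cc$n)
}

#' Exploratory factor analysis by principal-component extraction
#'
#' Eigendecomposition of the item correlation matrix (items are
#' standardized implicitly); unrotated loadings are eigenvectors scaled by
#' the square roots of their eigenvalues. Factors are retained by the
#' Kaiser rule (eigenvalue > 1) or a fixed count. Column signs follow the
#' convention that each factor's largest-magnitude loading is positive.
#'
#' @param items Numeric item table.
#' @param retention `"kaiser"` or `"fixed"`.
#' @param nFactors Number of factors when `retention = "fixed"`.
#' @return An unrotated [FactorModel-class].
#' @export
efaPrincipal <- function(items, retention = c("kaiser", "fixed"),
                         nFactors = NULL) {
  retention <- match.arg(retention)
  cc <- .itemCor(items)
  eig <- eigen(cc$R, symmetric = TRUE)
  nf <- if (retention == "kaiser") sum(eig$values > 1) else {
    if (is.null(nFactors)) stop("nFactors required for fixed retention")
    as.integer(nFactors)
  }
  if (nf < 1) stop("retention rule keeps no factors")
  if (nf > ncol(cc$R)) stop("cannot retain more factors than items")
  L <- eig$vectors[, seq_len(nf), drop = FALSE] %*%
    diag(sqrt(eig$values[seq_len(nf)]), nf)
  flip <- apply(L, 2, function(col) sign(col[which.max(abs(col))]))
  L <- sweep(L, 2, flip, `*`)
  dimnames(L) <- list(colnames(cc$R), paste0("F", seq_len(nf)))
  new("FactorModel", loadings = L, rotation = diag(nf),
      eigenvalues = eig$values, correlation = cc$R,
      center = colMeans(cc$X), scaleSd = apply(cc$X, 2, sd),
      retention = retention)
}

#' Varimax rotation with Kaiser normalization
#'
#' Orthogonally rotates the retained loadings to maximize the varimax
#' simplicity criterion, with rows rescaled to unit communality during the
#' rotation (Kaiser normalization). The rotation leaves communalities and
#' the reproduced correlation matrix unchanged. A single factor is returned
#' unrotated.
#'
#' @param model A [FactorModel-class] from [efaPrincipal].
#' @param eps Convergence tolerance on the criterion.
#' @return The rotated [FactorModel-class].
#' @export
varimaxRotate <- function(model, eps = 1e-8) {
  L <- model@loadings
  if (ncol(L) < 2) return(model)
  v <- stats::varimax(L, normalize = TRUE, eps = eps)
  Lr <- L %*% v$rotmat
  flip <- apply(Lr, 2, function(col) sign(col[which.max(abs(col))]))
  Lr <- sweep(Lr, 2, flip, `*`)
  rot <- model@rotation %*% v$rotmat %*% diag(flip, length(flip))
  dimnames(Lr) <- dimnames(L)
  methods::initialize(model, loadings = Lr, rotation = rot)
}

#' Regression-method factor scores
#'
#' Scores new (or training) observations on a factor model:
#' `scores = Z %*% solve(R) %*% loadings`, where `Z` standardizes the items
#' with the model's training means and SDs. Training scores have mean zero
#' per factor.
#'
#' @param items Numeric item table whose columns match the model's items.
#' @param model A [FactorModel-class].
#' @return Matrix of factor scores (rows = complete observations).
#' @export
factorScores <- function(items, model) {
  X <- as.matrix(items)
  want <- rownames(model@loadings)
  if (!all(want %in% colnames(X)))
    stop("item table is missing model column(s): ",
         paste(setdiff(want, colnames(X)), collapse = ", "))
  X <- X[complete.cases(X[, want, drop = FALSE]), want, drop = FALSE]
  Z <- sweep(sweep(X, 2, model@center[want]), 2, model@scaleSd[want], `/`)
  Z %*% solve(model@correlation, model@loadings)
}
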