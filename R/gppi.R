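#' Canonical double-gamma haemodynamic response function
#'
#' The canonical HRF used throughout: a gamma density peaking near 5 s minus
#' a 1/6-weighted gamma undershoot peaking near 15 s, sampled on a regular
#' grid and scaled to unit peak. `hrfKernel(tr)` samples it at the scanner
#' TR for convolution on the volume grid.
#'
#' @param trSeconds Sampling interval (s); must be positive.
#' @param durationSeconds Kernel support (s).
#' @return Numeric vector `h(0), h(tr), ...`; `h(0) = 0`.
#' @export
hrfKernel <- function(trSeconds, durationSeconds = 32) {
  if (trSeconds <= 0) stop("trSeconds must be positive")
  t <- seq(0, durationSeconds, by = trSeconds)
  h <- dgamma(t, shape = 6, rate = 1) - dgamma(t, shape = 16, rate = 1) / 6
  h / max(h)
}

## causal discrete convolution on the volume grid, truncated to length(x)
.convolveTR <- function(x, h) {
  n <- length(x)
  y <- stats::convolve(x, rev(h), type = "open")
  y[seq_len(n)]
}

## lower-triangular Toeplitz operator y = C %*% neural for kernel h
.convMatrix <- function(nVolumes, h) {
  C <- matrix(0, nVolumes, nVolumes)
  for (k in seq_along(h)) {
    i <- seq(k, nVolumes)
    C[cbind(i, i - k + 1L)] <- h[k]
  }
  C
}

#' Discrete-cosine high-pass basis
#'
#' DCT columns implementing a high-pass cutoff when entered as regressors:
#' `K = floor(2 * T * tr / cutoff)` non-constant cosines.
#'
#' @param nVolumes,trSeconds Scan geometry.
#' @param cutoffSeconds High-pass cutoff (default 128 s).
#' @return `nVolumes x K` matrix (possibly 0 columns).
#' @export
highpassBasis <- function(nVolumes, trSeconds, cutoffSeconds = 128) {
  K <- floor(2 * nVolumes * trSeconds / cutoffSeconds)
  t <- seq_len(nVolumes) - 1L
  B <- vapply(seq_len(K), function(k)
    cos(pi * (2 * t + 1) * k / (2 * nVolumes)), numeric(nVolumes))
  matrix(B, nrow = nVolumes, ncol = K,
         dimnames = list(NULL, if (K) paste0("dct", seq_len(K))))
}

#' Expand motion and tissue channels into the 36-regressor nuisance set
#'
#' Takes the 6 rigid-body motion parameters (3 translations, 3 rotations)
#' and 3 mean tissue signals (white matter, CSF, grey matter) and expands
#' them into 36 columns: the 9 base channels, their backward-difference
#' derivatives (first row 0), and the squares of base and derivative
#' channels, in that fixed order.
#'
#' @param motion T x 6 matrix.
#' @param tissue T x 3 matrix.
#' @return T x 36 matrix with systematic column names.
#' @export
expandNuisance <- function(motion, tissue) {
  motion <- as.matrix(motion); tissue <- as.matrix(tissue)
  if (ncol(motion) != 6) stop("motion must have 6 channels, got ", ncol(motion))
  if (ncol(tissue) != 3) stop("tissue must have 3 channels, got ", ncol(tissue))
  if (nrow(motion) != nrow(tissue)) stop("channel lengths differ")
  base <- cbind(motion, tissue)
  colnames(base) <- c(paste0("mot", 1:6), "wm", "csf", "gm")
  deriv <- rbind(0, diff(base))
  colnames(deriv) <- paste0("d_", colnames(base))
  sq <- base^2; colnames(sq) <- paste0("sq_", colnames(base))
  dsq <- deriv^2; colnames(dsq) <- paste0("sq_d_", colnames(base))
  cbind(base, deriv, sq, dsq)
}

#' Build the task design for a stop-signal GLM
#'
#' Constructs HRF-convolved task regressors on the volume grid for one of
#' the two task GLMs: the go-trial model (`"GO_MODEL"`: GO, FS and SS
#' regressors) or the successful-stop model (`"SS_MODEL"`: FS and SS only,
#' go trials serving as implicit baseline). Boxcars are built on a microtime
#' grid (TR/16), convolved with the canonical HRF and sampled at volume
#' onsets. The bundle also carries the raw 0/1 condition indicators on the
#' volume grid (the neural-level psychological variables used for PPI
#' terms), the 128 s discrete-cosine high-pass basis, and optionally the
#' 36-column nuisance expansion.
#'
#' @param events Event table: `onset`, `duration` (s), `condition` in
#'   `GO`/`SS`/`FS`.
#' @param nVolumes,trSeconds Scan geometry.
#' @param model `"GO_MODEL"` or `"SS_MODEL"`.
#' @param motion,tissue Optional nuisance channels, passed to
#'   [expandNuisance].
#' @param cutoffSeconds High-pass cutoff.
#' @return List: `task` (T x conditions, convolved), `boxcars` (T x
#'   conditions indicators), `hpBasis`, `nuisance` (or NULL), `conditions`,
#'   `model`, `nVolumes`, `trSeconds`, `hrf`.
#' @export
buildDesign <- function(events, nVolumes, trSeconds,
                        model = c("GO_MODEL", "SS_MODEL"),
                        motion = NULL, tissue = NULL, cutoffSeconds = 128) {
  model <- match.arg(model)
  conditions <- if (model == "GO_MODEL") c("GO", "FS", "SS") else c("FS", "SS")
  bad <- setdiff(unique(events$condition), c("GO", "FS", "SS"))
  if (length(bad)) stop("unknown condition label(s): ",
                        paste(bad, collapse = ", "))
  scanEnd <- nVolumes * trSeconds
  if (any(events$onset < 0) || any(events$onset > scanEnd))
    stop("event onsets must lie within the scan")
  dt <- trSeconds / 16
  tMicro <- seq(0, scanEnd, by = dt)
  hMicro <- dgamma(tMicro[tMicro <= 32], shape = 6, rate = 1) -
    dgamma(tMicro[tMicro <= 32], shape = 16, rate = 1) / 6
  hMicro <- hMicro / max(hMicro)
  volT <- (seq_len(nVolumes) - 1L) * trSeconds
  volIdx <- round(volT / dt) + 1L
  mkCol <- function(cond, convolved) {
    ev <- events[events$condition == cond, , drop = FALSE]
    box <- numeric(length(tMicro))
    for (r in seq_len(nrow(ev))) {
      on <- ev$onset[r]; off <- on + max(ev$duration[r], dt)
      box[tMicro >= on & tMicro < off] <- 1
    }
    if (convolved) .convolveTR(box, hMicro)[volIdx] else box[volIdx]
  }
  task <- vapply(conditions, mkCol, numeric(nVolumes), convolved = TRUE)
  boxcars <- vapply(conditions, mkCol, numeric(nVolumes), convolved = FALSE)
  nuis <- if (!is.null(motion)) expandNuisance(motion, tissue) else NULL
  list(task = task, boxcars = boxcars,
       hpBasis = highpassBasis(nVolumes, trSeconds, cutoffSeconds),
       nuisance = nuis, conditions = conditions, model = model,
       nVolumes = nVolumes, trSeconds = trSeconds,
       hrf = hrfKernel(trSeconds))
}

#' Deconvolve BOLD series to neural-level series
#'
#' Inverts the HRF convolution operator by ridge-regularized least squares;
#' the penalty is chosen per series by generalized cross-validation over a
#' log-spaced grid, using one SVD of the convolution operator.
#' `"passthrough"` returns the input unchanged (sensitivity analyses);
#' `"direct"` attempts an unregularized solve and fails with advice when the
#' operator is singular (it always is for a kernel with `h(0) = 0`).
#' The final ~kernel-length samples of the recovered series are only weakly
#' constrained by the data (their haemodynamic response falls beyond the
#' scan) and are shrunk towards zero by the ridge penalty.
#'
#' @param bold Numeric vector or T x N matrix of BOLD series.
#' @param hrf Kernel sampled at the series' TR ([hrfKernel]).
#' @param mode `"ridge"`, `"passthrough"` or `"direct"`.
#' @param lambdaGrid Ridge penalties searched by GCV.
#' @return Neural-level series, same shape as `bold`.
#' @export
deconvolveNeural <- function(bold, hrf, mode = c("ridge", "passthrough",
                                                 "direct"),
                             lambdaGrid = 10^seq(-6, 1, length.out = 20)) {
  mode <- match.arg(mode)
  if (mode == "passthrough") return(bold)
  B <- as.matrix(bold)
  if (nrow(B) < length(hrf)) stop("series shorter than the kernel")
  C <- .convMatrix(nrow(B), hrf)
  if (mode == "direct") {
    if (rcond(C) < 1e-12)
      stop("convolution operator is numerically singular; ",
           "use mode = 'ridge'")
    out <- solve(C, B)
    return(if (is.matrix(bold)) out else drop(out))
  }
  sv <- svd(C)
  d <- sv$d
  Uy <- crossprod(sv$u, B)                      # T x N
  out <- matrix(0, nrow(B), ncol(B))
  for (j in seq_len(ncol(B))) {
    gcv <- vapply(lambdaGrid, function(lam) {
      f <- d^2 / (d^2 + lam)
      rss <- sum(((1 - f) * Uy[, j])^2)
      nrow(B) * rss / (nrow(B) - sum(f))^2
    }, numeric(1))
    lam <- lambdaGrid[which.min(gcv)]
    out[, j] <- sv$v %*% (d / (d^2 + lam) * Uy[, j])
  }
  dimnames(out) <- dimnames(B)
  if (is.matrix(bold)) out else drop(out)
}

#' Symmetrize a connectivity matrix
#'
#' `(M + t(M)) / 2` with the diagonal zeroed; idempotent.
#' @param m Square matrix.
#' @export
symmetrizeMatrix <- function(m) {
  out <- (m + t(m)) / 2
  diag(out) <- 0
  out
}

#' ROI-to-ROI generalized psychophysiological interaction matrix
#'
#' For every ordered ROI pair (seed, partner) a GLM regresses the seed BOLD
#' series on: an intercept, the partner BOLD series (the physiological
#' regressor), the HRF-convolved task regressors of the model, one PPI term
#' per model condition (the partner's deconvolved neural series multiplied
#' by the 0/1 condition indicator and re-convolved with the HRF), the
#' nuisance columns and the high-pass basis. The matrix entry is the
#' coefficient of the PPI term of the condition of interest — GO for the
#' go-trial model, SS for the successful-stop model (configurable). The raw
#' directed matrix is then averaged with its transpose and the diagonal
#' zeroed, yielding the symmetric per-subject connectome.
#'
#' @param ts T x N matrix of ROI time series.
#' @param design Bundle from [buildDesign] (same T).
#' @param ppiOf Condition whose PPI coefficient fills the matrix; defaults
#'   to GO under `GO_MODEL` and SS under `SS_MODEL`.
#' @param centerPsycho Center the condition indicator before forming the
#'   neural-level product (default uncentered 0/1).
#' @param deconvolveMode Passed to [deconvolveNeural].
#' @return N x N symmetric matrix, zero diagonal, with attributes
#'   `condition` and `model`.
#' @export
computeGppiMatrix <- function(ts, design, ppiOf = NULL, centerPsycho = FALSE,
                              deconvolveMode = "ridge") {
  ts <- as.matrix(ts)
  N <- ncol(ts); Tn <- nrow(ts)
  if (N < 2) stop("need at least 2 ROIs")
  if (Tn != design$nVolumes) stop("design rows do not match the series")
  if (is.null(ppiOf))
    ppiOf <- if (design$model == "GO_MODEL") "GO" else "SS"
  if (!ppiOf %in% design$conditions)
    stop("ppiOf must be one of: ", paste(design$conditions, collapse = ", "))
  neural <- deconvolveNeural(ts, design$hrf, mode = deconvolveMode)
  neural <- as.matrix(neural)
  psy <- design$boxcars
  if (centerPsycho) psy <- scale(psy, scale = FALSE)
  ## conditions with no events yield all-zero task and PPI columns; drop them
  present <- colSums(abs(design$boxcars)) > 0
  if (!present[ppiOf])
    stop("condition of interest '", ppiOf, "' has no events")
  shared <- cbind(design$task[, present, drop = FALSE], design$nuisance,
                  design$hpBasis)
  conditions <- design$conditions[present]
  ppiNames <- paste0("ppi_", conditions)
  M <- matrix(0, N, N)
  for (j in seq_len(N)) {
    ppiTerms <- vapply(which(present), function(c)
      .convolveTR(neural[, j] * psy[, c], design$hrf), numeric(Tn))
    colnames(ppiTerms) <- ppiNames
    X <- cbind(`(Intercept)` = 1, physio = ts[, j], shared, ppiTerms)
    qrX <- qr(X)
    if (qrX$rank < ncol(X)) {
      bad <- colnames(X)[qrX$pivot[(qrX$rank + 1):ncol(X)]]
      stop("rank-deficient PPI design for partner ROI ", j,
           "; offending column(s): ", paste(bad, collapse = ", "))
    }
    beta <- qr.coef(qrX, ts[, -j, drop = FALSE])
    M[seq_len(N)[-j], j] <- beta[paste0("ppi_", ppiOf), ]
  }
  out <- symmetrizeMatrix(M)   # M[i, j]: seed i, partner j
  attr(out, "condition") <- ppiOf
  attr(out, "model") <- design$model
  out
}
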