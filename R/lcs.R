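#' Partial Spearman correlation
#'
#' Residualizes both variables on the covariates (least squares, intercept
#' included), then computes the Spearman rank correlation of the residuals.
#' The two-sided p-value uses the t approximation with
#' `df = n - 2 - k` (k = covariate rank).
#'
#' @param x,y Numeric vectors.
#' @param covariates Optional design matrix/data.frame of confounders.
#' @return List: `rho`, `p`, `df`, `n`.
#' @export
partialSpearman <- function(x, y, covariates = NULL) {
  stopifnot(length(x) == length(y))
  Xc <- if (is.null(covariates)) NULL else
    .covariateMatrix(as.data.frame(covariates),
                     colnames(as.data.frame(covariates)))
  k <- if (is.null(Xc)) 0L else qr(cbind(1, Xc))$rank - 1L
  if (length(x) < k + 3L) stop("need at least covariate rank + 3 rows")
  rx <- residualize(x, Xc); ry <- residualize(y, Xc)
  if (sd(rx) < 1e-12 || sd(ry) < 1e-12)
    stop("constant residuals; partial Spearman undefined")
  rho <- cor(rx, ry, method = "spearman")
  df <- length(x) - 2L - k
  tstat <- rho * sqrt(df / max(1 - rho^2, 1e-300))
  list(rho = rho, p = 2 * pt(-abs(tstat), df), df = df, n = length(x))
}

#' Benjamini-Hochberg false discovery rate control
#'
#' Step-up procedure at level `q`; returns the monotone adjusted values and
#' the rejection mask (`adjusted <= q`).
#'
#' @param p Vector of p-values in `[0, 1]`.
#' @param q FDR level (default 0.05).
#' @return List: `reject` (logical), `adjusted`, `q`.
#' @export
fdrBH <- function(p, q = 0.05) {
  if (length(p) == 0) stop("empty p-value vector")
  if (any(p < 0 | p > 1, na.rm = TRUE)) stop("p-values must lie in [0, 1]")
  adjusted <- p.adjust(p, method = "BH")
  list(reject = !is.na(adjusted) & adjusted <= q, adjusted = adjusted, q = q)
}

## ---- bivariate latent change score model -------------------------------

.lcsLabels <- function(equal) {
  init <- c("mu_x1", "mu_y1", "v_x1", "v_y1", "c_xy1")
  dyn <- c("alpha_x", "alpha_y", "beta_x", "beta_y", "gamma_x", "gamma_y",
           "q_x", "q_y", "q_xy")
  if (equal) c(init, dyn)
  else c(init, paste0(dyn, "_12"), paste0(dyn, "_23"))
}

.lcsStarts <- function(equal) {
  s <- c(mu_x1 = 0, mu_y1 = 0, v_x1 = 1, v_y1 = 1, c_xy1 = 0,
         alpha_x = 0, alpha_y = 0, beta_x = -0.3, beta_y = -0.3,
         gamma_x = 0, gamma_y = 0, q_x = 0.3, q_y = 0.3, q_xy = 0)
  setNames(s[sub("_(12|23)$", "", .lcsLabels(equal))], .lcsLabels(equal))
}

#' Specify the three-wave bivariate latent change score model
#'
#' Two constructs x and y observed at three waves (single indicators, no
#' measurement error). The latent change over each interval is regressed on
#' the previous-wave level of the same construct (self-feedback `beta`) and
#' of the other construct (coupling `gamma`): `gamma_x` carries y's lagged
#' effect on the change in x, `gamma_y` carries x's lagged effect on the
#' change in y. With `equalAcrossWaves = TRUE` (default) the intercepts,
#' feedbacks, couplings and change residual (co)variances are constrained
#' equal across the two intervals, giving one coupling per direction (14
#' free parameters against 27 sample moments, 13 df).
#'
#' @param equalAcrossWaves Logical flag.
#' @return An [LCSSpec-class].
#' @export
specifyBivariateLcs <- function(equalAcrossWaves = TRUE) {
  if (!is.logical(equalAcrossWaves) || length(equalAcrossWaves) != 1 ||
      is.na(equalAcrossWaves))
    stop("equalAcrossWaves must be TRUE or FALSE")
  labels <- .lcsLabels(equalAcrossWaves)
  new("LCSSpec", equalAcrossWaves = equalAcrossWaves,
      parameters = data.frame(label = labels,
                              start = unname(.lcsStarts(equalAcrossWaves))))
}

## parameters -> per-interval structural matrices; NULL on inadmissibility
.lcsStructure <- function(par, equal) {
  g <- function(name, iv) {
    key <- if (equal) name else paste0(name, c("_12", "_23")[iv])
    par[[key]]
  }
  lapply(1:2, function(iv) {
    A <- matrix(c(1 + g("beta_x", iv), g("gamma_y", iv),
                  g("gamma_x", iv), 1 + g("beta_y", iv)), 2)
    Q <- matrix(c(g("q_x", iv), g("q_xy", iv),
                  g("q_xy", iv), g("q_y", iv)), 2)
    list(a = c(g("alpha_x", iv), g("alpha_y", iv)), A = A, Q = Q)
  })
}

.lcsImpliedInternal <- function(par, equal) {
  S0 <- matrix(c(par[["v_x1"]], par[["c_xy1"]],
                 par[["c_xy1"]], par[["v_y1"]]), 2)
  if (par[["v_x1"]] <= 0 || par[["v_y1"]] <= 0 || det(S0) <= 0) return(NULL)
  st <- .lcsStructure(par, equal)
  for (iv in 1:2)
    if (st[[iv]]$Q[1, 1] < 0 || st[[iv]]$Q[2, 2] < 0 ||
        det(st[[iv]]$Q) < 0) return(NULL)
  mu1 <- c(par[["mu_x1"]], par[["mu_y1"]])
  A1 <- st[[1]]$A; A2 <- st[[2]]$A
  mu2 <- st[[1]]$a + A1 %*% mu1
  mu3 <- st[[2]]$a + A2 %*% mu2
  S2 <- A1 %*% S0 %*% t(A1) + st[[1]]$Q
  Sigma <- matrix(0, 6, 6)
  Sigma[1:2, 1:2] <- S0
  Sigma[1:2, 3:4] <- S0 %*% t(A1)
  Sigma[3:4, 3:4] <- S2
  Sigma[1:2, 5:6] <- S0 %*% t(A1) %*% t(A2)
  Sigma[3:4, 5:6] <- S2 %*% t(A2)
  Sigma[5:6, 5:6] <- A2 %*% S2 %*% t(A2) + st[[2]]$Q
  Sigma[lower.tri(Sigma)] <- t(Sigma)[lower.tri(Sigma)]
  vars <- c("x1", "y1", "x2", "y2", "x3", "y3")
  dimnames(Sigma) <- list(vars, vars)
  list(mu = setNames(c(mu1, mu2, mu3), vars), Sigma = Sigma)
}

#' Model-implied moments of the bivariate latent change score model
#'
#' Propagates the structural equations in closed form: with state
#' `s_t = (x_t, y_t)`, `s_{t+1} = a + A s_t + z_t` where
#' `A = I + [beta, gamma; gamma, beta]` and `z` is the change residual, the
#' implied mean vector and covariance of the six observables
#' `(x1, y1, x2, y2, x3, y3)` follow from the initial moments.
#'
#' @param params Named numeric vector of parameters (see
#'   [specifyBivariateLcs] for labels).
#' @param spec An [LCSSpec-class] (controls the equality constraints).
#' @return List: `mu` (length 6), `Sigma` (6 x 6).
#' @export
impliedMoments <- function(params, spec = specifyBivariateLcs()) {
  par <- as.list(params)
  need <- setdiff(spec@parameters$label, names(par))
  if (length(need)) stop("missing parameter(s): ", paste(need, collapse = ", "))
  out <- .lcsImpliedInternal(par, spec@equalAcrossWaves)
  if (is.null(out))
    stop("inadmissible parameters: variances must be positive and ",
         "covariance blocks positive definite")
  out
}

## ML discrepancy F(theta) given sample moments; large value when inadmissible
.lcsDiscrepancy <- function(parVec, labels, equal, S, m, logDetS) {
  par <- as.list(setNames(parVec, labels))
  imp <- .lcsImpliedInternal(par, equal)
  if (is.null(imp)) return(1e10)
  ch <- tryCatch(chol(imp$Sigma), error = function(e) NULL)
  if (is.null(ch)) return(1e10)
  logDet <- 2 * sum(log(diag(ch)))
  Sinv <- chol2inv(ch)
  dm <- m - imp$mu
  val <- logDet + sum(Sinv * S) + drop(t(dm) %*% Sinv %*% dm) - logDetS - 6
  if (!is.finite(val)) 1e10 else val
}

#' Fit the bivariate latent change score model by maximum likelihood
#'
#' Minimizes the multivariate-normal discrepancy between sample and
#' model-implied moments of the six observables with a quasi-Newton
#' optimizer from several starts: one moment-based start (initial moments
#' from the data, dynamics from pooled OLS of the observed changes on the
#' previous-wave scores) plus seed-controlled jitters. Standard errors come
#' from the inverse observed information ((n-1)/2 times the Hessian of the
#' discrepancy), the chi-square against the saturated model is
#' `(n - 1) * F` at the optimum, and standardized structural coefficients
#' rescale by the implied SDs of the predictor and of the latent change.
#' Covariates, if any, are expected to have been residualized out of the
#' six observed columns beforehand (see [residualize]).
#'
#' @param panel data.frame with columns `x1`, `y1`, `x2`, `y2`, `x3`, `y3`
#'   (extra columns ignored); listwise deletion on the six.
#' @param spec An [LCSSpec-class].
#' @param nStarts Number of optimizer starts (first is moment-based).
#' @param seed Seed for the start jitter.
#' @return An [LCSFit-class].
#' @export
fitBivariateLcs <- function(panel, spec = specifyBivariateLcs(),
                            nStarts = 5, seed = 1) {
  vars <- c("x1", "y1", "x2", "y2", "x3", "y3")
  miss <- setdiff(vars, names(panel))
  if (length(miss)) stop("panel missing column(s): ",
                         paste(miss, collapse = ", "))
  X <- as.matrix(panel[vars])
  X <- X[complete.cases(X), , drop = FALSE]
  n <- nrow(X)
  if (n < 50) stop("need at least 50 complete rows, got ", n)
  if (n < 200) warning("fewer than 200 complete rows; estimates may be ",
                       "unstable")
  m <- colMeans(X)
  S <- stats::cov(X)
  logDetS <- determinant(S, logarithm = TRUE)$modulus
  if (!is.finite(logDetS)) stop("singular sample covariance")
  equal <- spec@equalAcrossWaves
  labels <- spec@parameters$label
  ## moment-based start
  start <- .lcsStarts(equal)
  start[c("mu_x1", "mu_y1")] <- m[c("x1", "y1")]
  start[c("v_x1", "v_y1")] <- diag(S)[c("x1", "y1")]
  start["c_xy1"] <- S["x1", "y1"]
  dX <- c(X[, "x2"] - X[, "x1"], X[, "x3"] - X[, "x2"])
  dY <- c(X[, "y2"] - X[, "y1"], X[, "y3"] - X[, "y2"])
  px <- c(X[, "x1"], X[, "x2"]); py <- c(X[, "y1"], X[, "y2"])
  cx <- coef(lm(dX ~ px + py)); cy <- coef(lm(dY ~ py + px))
  rx <- dX - cbind(1, px, py) %*% cx
  ry <- dY - cbind(1, py, px) %*% cy
  dynStart <- c(alpha_x = unname(cx[1]), alpha_y = unname(cy[1]),
                beta_x = unname(cx["px"]), beta_y = unname(cy["py"]),
                gamma_x = unname(cx["py"]), gamma_y = unname(cy["px"]),
                q_x = var(rx), q_y = var(ry), q_xy = cov(rx, ry))
  for (nm in names(dynStart)) {
    keys <- if (equal) nm else paste0(nm, c("_12", "_23"))
    start[keys] <- dynStart[[nm]]
  }
  obj <- function(v) .lcsDiscrepancy(v, labels, equal, S, m, logDetS)
  jitters <- withr::with_seed(as.integer(seed),
    replicate(max(nStarts - 1, 0),
              rnorm(length(start), 0, 0.05), simplify = FALSE))
  starts <- c(list(start),
              lapply(jitters, function(j) start * (1 + j) + 0.01 * j))
  fits <- lapply(starts, function(s0)
    tryCatch(optim(s0, obj, method = "BFGS",
                   control = list(maxit = 1000, reltol = 1e-12)),
             error = function(e) NULL))
  fits <- Filter(Negate(is.null), fits)
  if (!length(fits)) stop("optimizer failed from every start; consider ",
                          "rescaling the observed variables")
  best <- fits[[which.min(vapply(fits, `[[`, numeric(1), "value"))]]
  if (best$value >= 1e9)
    stop("no admissible solution found; consider rescaling the variables ",
         "or freeing the equality constraints")
  est <- setNames(best$par, labels)
  ## observed information
  H <- tryCatch(optimHess(best$par, obj), error = function(e) NULL)
  se <- rep(NA_real_, length(est))
  if (!is.null(H)) {
    I <- (n - 1) / 2 * H
    cv <- tryCatch(solve(I), error = function(e) NULL)
    if (!is.null(cv)) {
      dg <- diag(cv)
      se[dg > 0] <- sqrt(dg[dg > 0])
    }
  }
  names(se) <- labels
  imp <- .lcsImpliedInternal(as.list(est), equal)
  ## standardized structural coefficients: predictor SD / latent-change SD
  st <- .lcsStructure(as.list(est), equal)
  sdx1 <- sqrt(imp$Sigma["x1", "x1"]); sdy1 <- sqrt(imp$Sigma["y1", "y1"])
  S0 <- imp$Sigma[1:2, 1:2]
  B1 <- st[[1]]$A - diag(2)        # change loadings on previous wave
  varD <- diag(B1 %*% S0 %*% t(B1) + st[[1]]$Q)
  std <- setNames(rep(NA_real_, length(est)), labels)
  for (nm in intersect(c("beta_x", "beta_y", "gamma_x", "gamma_y"),
                       sub("_(12|23)$", "", labels))) {
    key <- if (equal) nm else paste0(nm, "_12")
    pred <- switch(nm, beta_x = sdx1, gamma_x = sdy1,
                   beta_y = sdy1, gamma_y = sdx1)
    which <- if (nm %in% c("beta_x", "gamma_x")) 1 else 2
    std[key] <- est[[key]] * pred / sqrt(varD[which])
  }
  z <- est / se
  pv <- 2 * pnorm(-abs(z))
  chisq <- (n - 1) * best$value
  df <- as.integer(27 - length(labels))
  Sml <- S * (n - 1) / n
  dm <- m - imp$mu
  ch <- chol(imp$Sigma)
  ll <- -(n / 2) * (6 * log(2 * pi) + 2 * sum(log(diag(ch))) +
                    sum(chol2inv(ch) * Sml) +
                    drop(t(dm) %*% chol2inv(ch) %*% dm))
  heywood <- any(est[grep("^(v_|q_[xy]$|q_[xy]_)", labels)] < 1e-6)
  fit <- new("LCSFit", estimates = est, se = se, std = std,
             zvalue = z, pvalue = pv, logLik = ll, chisq = chisq, df = df,
             fitIndices = c(cfi = NA_real_, rmsea = NA_real_,
                            srmr = NA_real_),
             n = as.integer(n), sampleMoments = list(mean = m, cov = S),
             spec = spec,
             convergence = list(code = best$convergence,
                                value = best$value, nStarts = length(fits),
                                heywood = heywood))
  fit@fitIndices <- lcsFitIndices(fit)
  fit
}

#' Fit indices for a latent change score fit
#'
#' CFI compares the model's noncentrality to that of the independence
#' baseline (all covariances zero, means and variances free);
#' `RMSEA = sqrt(max(chisq - df, 0) / (df (n - 1)))`; SRMR is the root
#' mean square of the standardized covariance residuals
#' `(s_ij - sigma_ij) / sqrt(s_ii s_jj)` over the unique elements.
#'
#' @param fit An [LCSFit-class].
#' @return Named vector `cfi`, `rmsea`, `srmr`.
#' @export
lcsFitIndices <- function(fit) {
  S <- fit@sampleMoments$cov
  m <- fit@sampleMoments$mean
  n <- fit@n
  R <- stats::cov2cor(S)
  detR <- det(R)
  if (detR <= 0) stop("baseline (independence) model cannot be evaluated: ",
                      "singular sample correlation matrix")
  chisqB <- -(n - 1) * log(detR)
  dfB <- 6 * 5 / 2
  lamM <- max(fit@chisq - fit@df, 0)
  lamB <- max(chisqB - dfB, lamM)
  cfi <- if (lamB <= 0) 1 else 1 - lamM / lamB
  rmsea <- sqrt(lamM / (fit@df * (n - 1)))
  imp <- impliedMoments(fit@estimates, fit@spec)
  d <- sqrt(diag(S))
  res <- (S - imp$Sigma) / outer(d, d)
  srmr <- sqrt(mean(res[upper.tri(res, diag = TRUE)]^2))
  c(cfi = cfi, rmsea = rmsea, srmr = srmr)
}
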