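#' Simulate ROI time series with planted PPI interaction effects
#'
#' Generates task fMRI data that the gPPI estimator should invert: each
#' ROI's neural series is a sum of condition boxcars scaled by per-ROI
#' amplitudes; for every planted pair `(from, to, condition, coef)` the
#' `to` ROI additionally receives `coef x (neural series of from x condition
#' indicator)` — a true psychophysiological interaction. Neural series are
#' convolved with the canonical HRF and AR(1) noise is added. A matched
#' nuisance table (6 slowly drifting motion-like channels, 3 tissue-like
#' channels) is emitted alongside; it is not mixed into the ROI series.
#'
#' @param events Event table (`onset`, `duration`, `condition`).
#' @param nRois Number of ROIs (>= 2).
#' @param nVolumes,trSeconds Scan geometry.
#' @param ppiPairs `NULL` or data.frame `from`, `to`, `condition`, `coef`.
#' @param amplitudes Optional nRois x 3 matrix of condition amplitudes
#'   (columns GO, FS, SS); drawn uniformly from [0.5, 1.5] when omitted.
#' @param neuralNoiseSd Marginal SD of each ROI's ongoing background neural
#'   fluctuation (AR(1), added before the interaction and the HRF). This is
#'   the signal that carries psychophysiological interactions in real data;
#'   setting it to 0 leaves the interaction term nearly collinear with the
#'   task regressors.
#' @param noiseSd Marginal SD of the AR(1) measurement noise added to the
#'   BOLD series.
#' @param arCoef AR(1) autocorrelation of both noise sources (default 0.3).
#' @param seed Integer seed.
#' @return List: `ts` (T x nRois), `motion` (T x 6), `tissue` (T x 3),
#'   `design` (the [buildDesign] bundle used), `truth` (planted pairs,
#'   amplitudes, noise parameters, seed).
#' @export
genRoiTimeSeries <- function(events, nRois, nVolumes, trSeconds = 2.2,
                             ppiPairs = NULL, amplitudes = NULL,
                             neuralNoiseSd = 1, noiseSd = 0.5,
                             arCoef = 0.3, seed = 1) {
  if (nRois < 2) stop("nRois must be at least 2")
  design <- buildDesign(events, nVolumes, trSeconds, model = "GO_MODEL")
  conds <- design$conditions
  if (!is.null(ppiPairs)) {
    if (any(ppiPairs$from > nRois | ppiPairs$to > nRois |
            ppiPairs$from < 1 | ppiPairs$to < 1))
      stop("planted pair index outside 1..nRois")
    if (!all(ppiPairs$condition %in% conds))
      stop("planted pair condition must be one of: ",
           paste(conds, collapse = ", "))
  }
  seeds <- splitSeed(seed, 4L)
  if (is.null(amplitudes))
    amplitudes <- withr::with_seed(seeds[1],
      matrix(runif(nRois * length(conds), 0.5, 1.5), nRois,
             dimnames = list(NULL, conds)))
  ar1pre <- function(n, rho, sdMarg, innov)
    as.numeric(stats::filter(innov, rho, method = "recursive")) *
      sdMarg * sqrt(1 - rho^2)
  background <- withr::with_seed(seeds[4], {
    if (neuralNoiseSd > 0)
      vapply(seq_len(nRois), function(j)
        ar1pre(nVolumes, arCoef, neuralNoiseSd, rnorm(nVolumes)),
        numeric(nVolumes))
    else matrix(0, nVolumes, nRois)
  })
  ## task-evoked BOLD comes straight from the convolved regressors;
  ## background and interaction signals live at the neural level on the
  ## volume grid and are convolved with the TR-sampled HRF
  base <- design$boxcars %*% t(amplitudes) + background     # neural, T x nRois
  extra <- background
  if (!is.null(ppiPairs)) {
    for (r in seq_len(nrow(ppiPairs)))
      extra[, ppiPairs$to[r]] <- extra[, ppiPairs$to[r]] +
        ppiPairs$coef[r] * base[, ppiPairs$from[r]] *
        design$boxcars[, ppiPairs$condition[r]]
  }
  bold <- design$task %*% t(amplitudes) +
    apply(extra, 2, .convolveTR, h = design$hrf)
  ar1 <- function(n, rho, sdMarg, innov) {
    x <- as.numeric(stats::filter(innov, rho, method = "recursive"))
    x * sdMarg * sqrt(1 - rho^2)
  }
  withr::with_seed(seeds[2], {
    noise <- vapply(seq_len(nRois), function(j)
      ar1(nVolumes, arCoef, noiseSd, rnorm(nVolumes)), numeric(nVolumes))
  })
  withr::with_seed(seeds[3], {
    motion <- vapply(1:6, function(j)
      ar1(nVolumes, 0.95, 0.2, rnorm(nVolumes)), numeric(nVolumes))
    tissue <- vapply(1:3, function(j)
      ar1(nVolumes, 0.8, 0.5, rnorm(nVolumes)), numeric(nVolumes))
  })
  list(ts = bold + if (noiseSd > 0) noise else 0,
       motion = motion, tissue = tissue, design = design,
       truth = list(ppiPairs = ppiPairs, amplitudes = amplitudes,
                    neuralNoiseSd = neuralNoiseSd, noiseSd = noiseSd,
                    arCoef = arCoef, seed = seed))
}
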