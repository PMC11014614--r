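#' @import methods
#' @importClassesFrom SummarizedExperiment SummarizedExperiment
#' @importFrom SummarizedExperiment SummarizedExperiment assay assayNames
#'   rowData colData
#' @importFrom S4Vectors DataFrame metadata
#' @importFrom stats coef cor lm median optim p.adjust pchisq pnorm pt qr.resid
#'   quantile rbinom rlnorm rnorm runif sd setNames var complete.cases
#'   model.matrix optimHess dgamma
NULL

setClassUnion("listOrNULL", c("list", "NULL"))

#' Stop-signal task protocol
#'
#' Describes one acquisition of the stop-signal task: trial counts, the
#' spacing of stop trials among go trials, the stop-signal-delay (SSD)
#' staircase grid, and timing used to lay trials out on a scanner clock.
#'
#' @slot nGo,nStop Trial counts.
#' @slot goGapRange Inclusive integer range of go trials between successive
#'   stop trials.
#' @slot ssdMinMs,ssdMaxMs,ssdStepMs SSD staircase grid (ms).
#' @slot ssdStartMs Staircase starting value (ms); defaults to the grid
#'   midpoint.
#' @slot goDisplayMs Go-signal display duration (ms).
#' @slot soaSeconds Mean stimulus-onset asynchrony between trials (s).
#' @slot trSeconds Scanner repetition time (s), used when events are turned
#'   into fMRI designs.
#' @exportClass TaskProtocol
setClass("TaskProtocol", representation(
  nGo = "integer", nStop = "integer", goGapRange = "integer",
  ssdMinMs = "numeric", ssdMaxMs = "numeric", ssdStepMs = "numeric",
  ssdStartMs = "numeric", goDisplayMs = "numeric",
  soaSeconds = "numeric", trSeconds = "numeric"))

setValidity("TaskProtocol", function(object) {
  msg <- character()
  if (object@nGo <= 0L || object@nStop <= 0L)
    msg <- c(msg, "nGo and nStop must be positive")
  if (object@ssdMinMs > object@ssdMaxMs)
    msg <- c(msg, "ssdMinMs must not exceed ssdMaxMs")
  if (object@ssdStepMs <= 0 ||
      (object@ssdMaxMs - object@ssdMinMs) %% object@ssdStepMs != 0)
    msg <- c(msg, "ssdStepMs must be positive and divide ssdMaxMs - ssdMinMs")
  if (length(object@goGapRange) != 2L ||
      object@goGapRange[1] > object@goGapRange[2] || object@goGapRange[1] < 0L)
    msg <- c(msg, "goGapRange must be a nonempty non-negative integer range")
  if (!(object@ssdStartMs %in% seq(object@ssdMinMs, object@ssdMaxMs,
                                   by = object@ssdStepMs)))
    msg <- c(msg, "ssdStartMs must lie on the SSD grid")
  if (length(msg)) msg else TRUE
})

#' Construct a stop-signal task protocol
#'
#' Defaults follow the adolescent acquisition of the task: 400 go trials and
#' 80 stop trials with 3-7 go trials between successive stops, SSD tracked
#' over 250-900 ms in 50 ms steps, go signal shown for 1000 ms, TR 2.2 s.
#' `sstProtocolAge14()` and `sstProtocolAge19()` return the two published
#' acquisitions (the age-19 protocol, 300 go / 60 stop trials, is also used
#' at age 23).
#'
#' @param nGo,nStop Trial counts.
#' @param goGapRange Integer range of go trials between successive stops.
#' @param ssdMinMs,ssdMaxMs,ssdStepMs SSD staircase grid in ms.
#' @param ssdStartMs Staircase start; default the grid value nearest the
#'   midpoint from below.
#' @param goDisplayMs Go-signal display duration (ms).
#' @param soaSeconds Mean inter-trial stimulus-onset asynchrony (s).
#' @param trSeconds Scanner TR (s).
#' @return A [TaskProtocol-class] object.
#' @export
taskProtocol <- function(nGo = 400, nStop = 80, goGapRange = c(3L, 7L),
                         ssdMinMs = 250, ssdMaxMs = 900, ssdStepMs = 50,
                         ssdStartMs = NULL, goDisplayMs = 1000,
                         soaSeconds = 2, trSeconds = 2.2) {
  if (is.null(ssdStartMs))
    ssdStartMs <- ssdMinMs +
      ssdStepMs * floor((ssdMaxMs - ssdMinMs) / (2 * ssdStepMs))
  new("TaskProtocol", nGo = as.integer(nGo), nStop = as.integer(nStop),
      goGapRange = as.integer(goGapRange), ssdMinMs = ssdMinMs,
      ssdMaxMs = ssdMaxMs, ssdStepMs = ssdStepMs, ssdStartMs = ssdStartMs,
      goDisplayMs = goDisplayMs, soaSeconds = soaSeconds,
      trSeconds = trSeconds)
}

#' @rdname taskProtocol
#' @export
sstProtocolAge14 <- function() taskProtocol(nGo = 400, nStop = 80)

#' @rdname taskProtocol
#' @export
sstProtocolAge19 <- function() taskProtocol(nGo = 300, nStop = 60)

#' Race-model parameters for stop-signal trial simulation
#'
#' Generative stand-in for the horse race between the go and stop processes:
#' go reaction times and stop-signal reaction times (SSRT) are drawn from
#' lognormal laws (positive, right-skewed, the conventional shape for
#' empirical RT distributions), parameterized here by their mean and SD on
#' the millisecond scale. A stop trial ends in successful inhibition iff the
#' go RT draw exceeds SSD + SSRT draw.
#'
#' @slot goMeanlog,goSdlog,ssrtMeanlog,ssrtSdlog Lognormal parameters (log-ms).
#' @slot omissionRate,choiceErrorRate Go-process failure probabilities.
#' @exportClass RaceModelParams
setClass("RaceModelParams", representation(
  goMeanlog = "numeric", goSdlog = "numeric",
  ssrtMeanlog = "numeric", ssrtSdlog = "numeric",
  omissionRate = "numeric", choiceErrorRate = "numeric"))

setValidity("RaceModelParams", function(object) {
  msg <- character()
  rates <- c(object@omissionRate, object@choiceErrorRate)
  if (any(rates < 0 | rates > 1)) msg <- c(msg, "rates must lie in [0, 1]")
  if (object@goSdlog <= 0 || object@ssrtSdlog <= 0)
    msg <- c(msg, "lognormal sdlog parameters must be positive")
  if (length(msg)) msg else TRUE
})

#' Construct race-model parameters from moments on the ms scale
#'
#' @param goMeanMs,goSdMs Mean and SD of the go RT distribution (ms).
#' @param ssrtMeanMs,ssrtSdMs Mean and SD of the SSRT distribution (ms).
#' @param omissionRate Probability that the go process produces no response.
#' @param choiceErrorRate Probability of a wrong-side response on go trials.
#' @return A [RaceModelParams-class] object.
#' @export
raceModelParams <- function(goMeanMs = 520, goSdMs = 130,
                            ssrtMeanMs = 200, ssrtSdMs = 50,
                            omissionRate = 0.02, choiceErrorRate = 0.02) {
  if (any(c(goMeanMs, goSdMs, ssrtMeanMs, ssrtSdMs) <= 0))
    stop("distribution moments must be positive")
  lnPar <- function(m, s) {
    s2 <- log(1 + (s / m)^2)
    c(meanlog = log(m) - s2 / 2, sdlog = sqrt(s2))
  }
  g <- lnPar(goMeanMs, goSdMs); r <- lnPar(ssrtMeanMs, ssrtSdMs)
  new("RaceModelParams", goMeanlog = g[["meanlog"]], goSdlog = g[["sdlog"]],
      ssrtMeanlog = r[["meanlog"]], ssrtSdlog = r[["sdlog"]],
      omissionRate = omissionRate, choiceErrorRate = choiceErrorRate)
}

#' Cohort of vectorized connectomes with phenotype and covariates
#'
#' A `ConnectomeCohort` stores one vectorized connectivity matrix per
#' subject as a SummarizedExperiment: the `"edges"` assay is edges x
#' subjects (strict upper triangle in `edgeIndex()` order, so each edge is
#' counted once), `rowData` holds the node pair of each edge, and `colData`
#' holds the phenotype and covariates. Planted ground truth from the
#' synthetic generator, when present, lives in `metadata(x)$truth` and is
#' never consulted by the analysis path.
#'
#' @exportClass ConnectomeCohort
setClass("ConnectomeCohort", contains = "SummarizedExperiment")

setValidity("ConnectomeCohort", function(object) {
  msg <- character()
  if (!"edges" %in% SummarizedExperiment::assayNames(object))
    msg <- c(msg, "assay 'edges' is required")
  rd <- SummarizedExperiment::rowData(object)
  if (!all(c("nodeA", "nodeB") %in% colnames(rd))) {
    msg <- c(msg, "rowData must carry nodeA and nodeB")
  } else {
    if (any(rd$nodeA >= rd$nodeB))
      msg <- c(msg, "edges must satisfy nodeA < nodeB")
    if (anyDuplicated(paste(rd$nodeA, rd$nodeB)))
      msg <- c(msg, "duplicate edges")
  }
  if (anyDuplicated(colnames(object)))
    msg <- c(msg, "duplicate subject ids")
  if (length(msg)) msg else TRUE
})

#' Assemble a ConnectomeCohort from per-subject matrices
#'
#' @param matrices List (one per subject) of symmetric connectivity
#'   matrices, or an edges x subjects numeric matrix already in
#'   `edgeIndex()` order.
#' @param cohort data.frame of per-subject phenotype/covariates, one row per
#'   subject (in the order of `matrices`). A `subject` column, if present,
#'   supplies subject ids.
#' @param nNodes Number of nodes; required when `matrices` is an edge
#'   matrix.
#' @param truth Optional list of planted generative truth, stored in
#'   metadata.
#' @return A [ConnectomeCohort-class].
#' @export
connectomeCohort <- function(matrices, cohort, nNodes = NULL, truth = NULL) {
  if (is.list(matrices)) {
    nNodes <- nrow(matrices[[1]])
    E <- vapply(matrices, upperTriVec, numeric(nNodes * (nNodes - 1) / 2))
  } else {
    if (is.null(nNodes)) stop("nNodes required for a pre-vectorized cohort")
    E <- as.matrix(matrices)
  }
  idx <- edgeIndex(nNodes)
  if (nrow(E) != nrow(idx)) stop("edge count does not match nNodes")
  cohort <- as.data.frame(cohort)
  if (nrow(cohort) != ncol(E)) stop("one cohort row per subject required")
  ids <- if ("subject" %in% names(cohort)) as.character(cohort$subject) else
    sprintf("sub%04d", seq_len(ncol(E)))
  colnames(E) <- ids
  se <- SummarizedExperiment::SummarizedExperiment(
    assays = list(edges = E),
    rowData = S4Vectors::DataFrame(idx),
    colData = S4Vectors::DataFrame(cohort, row.names = ids),
    metadata = list(nNodes = nNodes, truth = truth))
  new("ConnectomeCohort", se)
}

#' A fitted connectome-based predictive model
#'
#' Holds the positive and negative edge sets selected at the chosen
#' threshold, the per-network linear model coefficients (intercept, network
#' strength slope, covariate slopes), and the training covariate scheme
#' needed to apply the model to new subjects.
#'
#' @slot edges List with `positive` and `negative` edge data.frames
#'   (`nodeA`, `nodeB`, `r`, `p`).
#' @slot coefficients Named list (`positive`, `negative`, `combined`) of
#'   coefficient vectors.
#' @slot threshold Edge-selection p-value threshold.
#' @slot covariates Character vector of covariate column names.
#' @slot covariateLevels Named list of factor levels seen in training for
#'   each categorical covariate (e.g. scan site); applying the model to
#'   subjects with unseen levels is an error.
#' @slot phenotype Name of the phenotype column.
#' @slot nTrain Training sample size.
#' @slot degenerate Named logical: networks with an empty edge set.
#' @exportClass CPMModel
setClass("CPMModel", representation(
  edges = "list", coefficients = "list", threshold = "numeric",
  covariates = "character", covariateLevels = "list",
  phenotype = "character", nTrain = "integer", degenerate = "logical"))

#' Cross-validated CPM performance
#'
#' @slot observed Observed phenotype, one value per subject.
#' @slot predicted Subjects x networks matrix of cross-validated
#'   predictions, averaged over repeats.
#' @slot repeatR Repeats x networks matrix of prediction-performance
#'   correlations.
#' @slot meanR Mean of `repeatR` over repeats.
#' @slot consensus List of `positive`/`negative` edge index matrices for
#'   edges selected in at least `consensusCut` repeats (selection within a
#'   repeat = selected in every fold).
#' @slot consensusCut Integer cut (e.g. 48 of 50 at the 95% default).
#' @slot scheme,k,nRepeats CV scheme metadata.
#' @slot seed Master seed used.
#' @exportClass CVResult
setClass("CVResult", representation(
  observed = "numeric", predicted = "matrix", repeatR = "matrix",
  meanR = "numeric", consensus = "list", consensusCut = "integer",
  scheme = "character", k = "integer", nRepeats = "integer",
  seed = "integer"))

#' Principal-component factor model
#'
#' @slot loadings Items x factors loading matrix (rotated or unrotated).
#' @slot rotation Orthogonal rotation matrix applied to the initial
#'   loadings (identity when unrotated).
#' @slot eigenvalues Eigenvalues of the item correlation matrix.
#' @slot correlation Item correlation matrix used for extraction.
#' @slot center,scaleSd Item means and SDs used for standardization.
#' @slot retention Retention rule in force ("kaiser" or "fixed").
#' @exportClass FactorModel
setClass("FactorModel", representation(
  loadings = "matrix", rotation = "matrix", eigenvalues = "numeric",
  correlation = "matrix", center = "numeric", scaleSd = "numeric",
  retention = "character"))

#' Specification of the three-wave bivariate latent change score model
#'
#' @slot equalAcrossWaves Logical; constrain intercepts, self-feedbacks,
#'   couplings and change residual (co)variances to be equal across the two
#'   wave-to-wave intervals (the default, yielding one coupling per
#'   direction).
#' @slot parameters data.frame of free parameters: `label`, `start`.
#' @exportClass LCSSpec
setClass("LCSSpec", representation(
  equalAcrossWaves = "logical", parameters = "data.frame"))

#' Fitted bivariate latent change score model
#'
#' @slot estimates Named numeric vector of ML estimates.
#' @slot se Standard errors (inverse observed information).
#' @slot std Standardized structural coefficients.
#' @slot zvalue,pvalue Wald statistics for the structural parameters.
#' @slot logLik Maximized multivariate-normal log-likelihood.
#' @slot chisq,df Likelihood-ratio statistic against the saturated model.
#' @slot fitIndices CFI, RMSEA, SRMR.
#' @slot n Sample size (complete rows).
#' @slot sampleMoments List with the sample mean vector and covariance.
#' @slot spec The [LCSSpec-class] fitted.
#' @slot convergence optim convergence record over the multistart.
#' @exportClass LCSFit
setClass("LCSFit", representation(
  estimates = "numeric", se = "numeric", std = "numeric",
  zvalue = "numeric", pvalue = "numeric", logLik = "numeric",
  chisq = "numeric", df = "integer", fitIndices = "numeric",
  n = "integer", sampleMoments = "list", spec = "LCSSpec",
  convergence = "list"))
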