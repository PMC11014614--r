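#' @describeIn connectomeCohort Edge-by-subject value matrix.
#' @param x A `ConnectomeCohort`.
#' @export
edgeValues <- function(x) SummarizedExperiment::assay(x, "edges")

#' @describeIn connectomeCohort Number of atlas nodes.
#' @export
nNodes <- function(x) S4Vectors::metadata(x)$nNodes

#' @describeIn connectomeCohort Planted generative truth (or NULL).
#' @export
cohortTruth <- function(x) S4Vectors::metadata(x)$truth

#' @describeIn connectomeCohort Phenotype vector.
#' @param name Phenotype column name.
#' @export
phenotype <- function(x, name = "phenotype")
  SummarizedExperiment::colData(x)[[name]]

#' Selected edge sets of a CPM model
#' @param object A [CPMModel-class].
#' @return List with `positive` and `negative` edge data.frames.
#' @export
cpmEdges <- function(object) object@edges

#' Per-network linear coefficients of a CPM model
#' @param object A [CPMModel-class].
#' @export
cpmCoefficients <- function(object) object@coefficients

#' Mean cross-validated prediction performance per network
#' @param object A [CVResult-class].
#' @export
meanR <- function(object) object@meanR

#' Consensus edge sets across CV repeats
#' @param object A [CVResult-class].
#' @export
consensusEdges <- function(object) object@consensus

#' Loadings of a factor model
#' @param object A [FactorModel-class].
#' @export
factorLoadings <- function(object) object@loadings

#' Communalities (row sums of squared loadings)
#' @param object A [FactorModel-class].
#' @export
communalities <- function(object) rowSums(object@loadings^2)

#' Estimates / fit indices of a latent change score fit
#' @param object An [LCSFit-class].
#' @export
lcsEstimates <- function(object) object@estimates

#' @rdname lcsEstimates
#' @export
lcsFitIndicesOf <- function(object) object@fitIndices

setMethod("show", "TaskProtocol", function(object) {
  cat("TaskProtocol:", object@nGo, "go +", object@nStop, "stop trials;",
      "SSD", object@ssdMinMs, "-", object@ssdMaxMs, "ms by",
      object@ssdStepMs, "(start", object@ssdStartMs, "); gap",
      paste(object@goGapRange, collapse = "-"), "; TR",
      object@trSeconds, "s\n")
})

setMethod("show", "ConnectomeCohort", function(object) {
  cat("ConnectomeCohort:", ncol(object), "subjects,", nNodes(object),
      "nodes (", nrow(object), "edges )\n")
  cat("colData:", paste(colnames(SummarizedExperiment::colData(object)),
                        collapse = ", "), "\n")
  if (!is.null(cohortTruth(object))) cat("planted truth recorded\n")
})

setMethod("show", "CPMModel", function(object) {
  cat("CPMModel (threshold p <", object@threshold, ", n =",
      object@nTrain, ")\n")
  cat("  positive edges:", nrow(object@edges$positive),
      " negative edges:", nrow(object@edges$negative), "\n")
  if (any(object@degenerate))
    cat("  degenerate networks:",
        paste(names(object@degenerate)[object@degenerate], collapse = ", "),
        "\n")
})

setMethod("show", "CVResult", function(object) {
  cat("CVResult:", object@scheme,
      if (object@scheme == "kfold") paste0("(k=", object@k, ")") else "",
      "x", object@nRepeats, "repeats\n")
  print(round(object@meanR, 3))
})

setMethod("show", "FactorModel", function(object) {
  cat("FactorModel:", nrow(object@loadings), "items,",
      ncol(object@loadings), "factors (", object@retention, ")\n")
  print(round(object@loadings, 3))
})

setMethod("show", "LCSFit", function(object) {
  cat("Bivariate latent change score fit (n =", object@n, ")\n")
  cat("  chisq =", round(object@chisq, 3), "df =", object@df, "\n")
  cat("  CFI =", round(object@fitIndices[["cfi"]], 4),
      " RMSEA =", round(object@fitIndices[["rmsea"]], 4),
      " SRMR =", round(object@fitIndices[["srmr"]], 4), "\n")
  est <- object@estimates
  show <- intersect(c("gamma_x", "gamma_y", "beta_x", "beta_y"), names(est))
  tab <- data.frame(estimate = est[show], se = object@se[show],
                    std = object@std[show], p = object@pvalue[show])
  print(round(tab, 4))
})
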