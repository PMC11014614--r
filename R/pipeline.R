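## Known configuration keys; anything else is a typo and rejected.
.configDefaults <- function() list(
  seed = NULL, out_dir = NULL,
  stages = c("simulate", "behaviour", "gppi", "cpm", "factors", "lcs"),
  n_subjects = 100, n_nodes = 40, n_planted = 20, edge_r = 0.3,
  n_sites = 4,
  selection_p = 0.01, cv_k = 10, cv_repeats = 10, n_perm = 100,
  fdr_q = 0.05, fd_threshold_mm = 0.5, go_error_threshold = 0.2,
  n_gppi_subjects = 4, gppi_n_rois = 8, gppi_n_volumes = 160,
  tr_seconds = 2.2,
  n_items = 6, n_lcs_subjects = 500, lcs_gamma_x = 0.12, lcs_gamma_y = 0.1)

#' Load and validate a pipeline run configuration
#'
#' YAML configuration with a strict schema: unknown keys are errors, the
#' master seed is mandatory, and thresholds must lie in their legal ranges.
#'
#' @param config Path to a YAML file, or a named list.
#' @return Validated configuration list with defaults filled in.
#' @export
loadRunConfig <- function(config) {
  if (is.character(config)) config <- yaml::read_yaml(config)
  defaults <- .configDefaults()
  unknown <- setdiff(names(config), names(defaults))
  if (length(unknown))
    stop("unknown config key(s): ", paste(unknown, collapse = ", "))
  cfg <- utils::modifyList(defaults, config)
  if (is.null(cfg$seed)) stop("config must set a seed")
  if (is.null(cfg$out_dir)) stop("config must set out_dir")
  stopifnot(cfg$selection_p > 0, cfg$selection_p < 1,
            cfg$fdr_q > 0, cfg$fdr_q < 1,
            cfg$fd_threshold_mm > 0, cfg$go_error_threshold > 0)
  bad <- setdiff(cfg$stages, .configDefaults()$stages)
  if (length(bad)) stop("unknown stage(s): ", paste(bad, collapse = ", "))
  cfg
}

#' Run the full analysis pipeline on synthetic data
#'
#' Executes the requested stages in dependency order — simulate ->
#' behaviour -> gppi -> cpm -> factors -> lcs — writing each stage's
#' outputs as delimited text under `out_dir` and recording a manifest
#' (config hash, package version, per-file md5 checksums, wall-clock per
#' stage). All randomness derives from the master seed through
#' [splitSeed], so identical config + seed reproduces identical output
#' checksums.
#'
#' @param config Path to a YAML config or a named list ([loadRunConfig]).
#' @return The manifest (invisibly also written to `manifest.yaml`).
#' @export
runPipeline <- function(config) {
  cfg <- loadRunConfig(config)
  dir.create(cfg$out_dir, recursive = TRUE, showWarnings = FALSE)
  stageSeeds <- setNames(splitSeed(cfg$seed, 6),
                         c("simulate", "behaviour", "gppi", "cpm",
                           "factors", "lcs"))
  manifest <- list(config_hash = .objectHash(cfg[setdiff(names(cfg),
                                                         "out_dir")]),
                   package_version = as.character(
                     utils::packageVersion("attncpm")),
                   seed = cfg$seed, stages = list())
  outputs <- character()
  emit <- function(name, writer) {
    path <- file.path(cfg$out_dir, name)
    writer(path)
    outputs[[name]] <<- path
    path
  }
  state <- new.env(parent = emptyenv())
  runStage <- function(name, fun) {
    if (!name %in% cfg$stages) return()
    t0 <- proc.time()[["elapsed"]]
    before <- names(outputs)
    fun()
    manifest$stages[[name]] <<- list(
      seconds = round(proc.time()[["elapsed"]] - t0, 3),
      outputs = as.list(vapply(setdiff(names(outputs), before), function(f)
        unname(tools::md5sum(outputs[[f]])), character(1))))
  }

  runStage("simulate", function() {
    seeds <- splitSeed(stageSeeds[["simulate"]], 4)
    proto <- taskProtocol()
    race <- raceModelParams()
    subSeeds <- splitSeed(seeds[1], cfg$n_subjects)
    state$trials <- lapply(seq_len(cfg$n_subjects), function(i)
      genSstTrials(proto, race, subSeeds[i],
                   subject = sprintf("sub%04d", i)))
    emit("trials.tsv", function(p)
      writeTable(do.call(rbind, state$trials), p))
    state$cohort <- genConnectomeCohort(
      cfg$n_subjects, cfg$n_nodes, nPlanted = cfg$n_planted,
      edgeR = cfg$edge_r, nSites = cfg$n_sites, seed = seeds[2])
    emit("cohort.tsv", function(p)
      writeTable(as.data.frame(SummarizedExperiment::colData(state$cohort)),
                 p))
    emit("edges.tsv", function(p)
      writeTable(as.data.frame(edgeValues(state$cohort)), p))
    state$items <- genSubstanceItems(
      cfg$n_subjects,
      loadings = cbind(c(0.8, 0.75, 0.7, 0, 0, 0)[seq_len(cfg$n_items)],
                       c(0, 0, 0, 0.8, 0.75, 0.7)[seq_len(cfg$n_items)]),
      seed = seeds[3])
    emit("items.tsv", function(p) writeTable(
      cbind(subject = sprintf("sub%04d", seq_len(cfg$n_subjects)),
            state$items), p))
    state$panel <- genLcsCohort(
      lcsParams(gammaX = cfg$lcs_gamma_x, gammaY = cfg$lcs_gamma_y),
      cfg$n_lcs_subjects, seed = seeds[4])
    emit("wave_panel.tsv", function(p) writeTable(state$panel, p))
  })

  runStage("behaviour", function() {
    if (is.null(state$trials)) stop("behaviour stage requires the simulate ",
                                    "stage (missing trial tables)")
    icv <- do.call(rbind, lapply(state$trials, computeICV))
    qc <- do.call(rbind, lapply(state$trials, function(tr) {
      go <- tr[tr$trial_type == "go", ]
      data.frame(subject = tr$subject[1],
                 go_error_rate = mean(go$response == "none" |
                                      go$response != go$correct_response))
    }))
    qc$mean_fd_mm <- SummarizedExperiment::colData(state$cohort)$fd
    excl <- applyExclusions(qc, cfg$go_error_threshold, cfg$fd_threshold_mm)
    state$icv <- icv
    emit("icv.tsv", function(p) writeTable(icv, p))
    emit("exclusions.tsv", function(p) writeTable(excl$log, p))
  })

  runStage("gppi", function() {
    seeds <- splitSeed(stageSeeds[["gppi"]], cfg$n_gppi_subjects)
    # 72 trials with up-to-25% onset jitter must fit inside the scan
    proto <- taskProtocol(nGo = 60, nStop = 12,
                          soaSeconds = cfg$gppi_n_volumes *
                            cfg$tr_seconds / 100)
    race <- raceModelParams()
    mats <- lapply(seq_len(cfg$n_gppi_subjects), function(i) {
      s <- splitSeed(seeds[i], 2)
      trials <- genSstTrials(proto, race, s[1])
      run <- genRoiTimeSeries(trialsToEvents(trials), cfg$gppi_n_rois,
                              cfg$gppi_n_volumes, cfg$tr_seconds,
                              noiseSd = 0.5, seed = s[2])
      computeGppiMatrix(run$ts, run$design)
    })
    state$gppi <- mats
    for (i in seq_along(mats))
      emit(sprintf("gppi_GO_sub%04d.tsv", i), local({
        m <- mats[[i]]; function(p) writeTable(as.data.frame(m), p)
      }))
  })

  runStage("cpm", function() {
    if (is.null(state$cohort)) stop("cpm stage requires the simulate stage ",
                                    "(missing connectome cohort)")
    cv <- crossvalCpm(state$cohort, k = cfg$cv_k,
                      nRepeats = cfg$cv_repeats,
                      pThreshold = cfg$selection_p,
                      seed = stageSeeds[["cpm"]])
    perm <- permutationTestCpm(state$cohort, k = cfg$cv_k,
                               nPerm = cfg$n_perm,
                               pThreshold = cfg$selection_p,
                               seed = stageSeeds[["cpm"]])
    state$cv <- cv
    emit("cpm_performance.tsv", function(p) writeTable(
      data.frame(network = names(meanR(cv)), mean_r = meanR(cv),
                 perm_p = perm$p[names(meanR(cv))]), p))
    emit("cpm_consensus_positive.tsv", function(p)
      writeTable(consensusEdges(cv)$positive, p))
    emit("cpm_consensus_negative.tsv", function(p)
      writeTable(consensusEdges(cv)$negative, p))
  })

  runStage("factors", function() {
    if (is.null(state$items)) stop("factors stage requires the simulate ",
                                   "stage (missing item table)")
    kmo <- kmoStatistic(state$items)
    bart <- bartlettSphericity(state$items)
    model <- varimaxRotate(efaPrincipal(state$items))
    scores <- factorScores(state$items, model)
    state$scores <- scores
    emit("factor_diagnostics.tsv", function(p) writeTable(
      data.frame(kmo_overall = kmo$overall, bartlett_chisq = bart$chisq,
                 bartlett_df = bart$df, bartlett_p = bart$p), p))
    emit("factor_loadings.tsv", function(p)
      writeTable(data.frame(item = rownames(factorLoadings(model)),
                            factorLoadings(model)), p))
    emit("factor_scores.tsv", function(p)
      writeTable(as.data.frame(scores), p))
  })

  runStage("lcs", function() {
    if (is.null(state$panel)) stop("lcs stage requires the simulate stage ",
                                   "(missing wave panel)")
    fit <- fitBivariateLcs(state$panel, seed = stageSeeds[["lcs"]])
    keep <- c("gamma_x", "gamma_y", "beta_x", "beta_y")
    est <- data.frame(parameter = keep,
                      estimate = fit@estimates[keep],
                      se = fit@se[keep], std = fit@std[keep],
                      p = fit@pvalue[keep])
    est$fdr_significant <- fdrBH(est$p, cfg$fdr_q)$reject
    emit("lcs_estimates.tsv", function(p) writeTable(est, p))
    emit("lcs_fit_indices.tsv", function(p) writeTable(
      data.frame(t(fit@fitIndices), chisq = fit@chisq, df = fit@df,
                 n = fit@n), p))
  })

  manifest$outputs <- as.list(vapply(outputs, function(p)
    unname(tools::md5sum(p)), character(1)))
  yaml::write_yaml(manifest[c("config_hash", "package_version", "seed",
                              "outputs")],
                   file.path(cfg$out_dir, "manifest.yaml"))
  manifest
}
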