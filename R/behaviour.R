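#' Intra-individual coefficient of variation of go reaction times
#'
#' ICV — the sustained-attention phenotype — is the sample standard
#' deviation of a subject's valid go-trial RTs divided by their mean. Lower
#' ICV means steadier responding, i.e. better sustained attention. A valid
#' go RT is a responded go trial whose response matches the required side;
#' omissions and (by default) choice errors are excluded from the
#' computation.
#'
#' @param trials Trial table (see [genSstTrials] for the schema); columns
#'   `trial_type`, `rt_ms`, `response`, `correct_response` are used.
#' @param includeChoiceErrors Keep wrong-side responses in the RT pool.
#' @return data.frame with `subject`, `icv`, `go_rt_mean_ms`, `go_rt_sd_ms`,
#'   `n_valid_go`.
#' @export
computeICV <- function(trials, includeChoiceErrors = FALSE) {
  go <- trials[trials$trial_type == "go", , drop = FALSE]
  valid <- !is.na(go$rt_ms) & go$response != "none"
  if (!includeChoiceErrors)
    valid <- valid & go$response == go$correct_response
  rts <- go$rt_ms[valid]
  if (length(rts) < 2)
    stop("need at least 2 valid go RTs to compute ICV (got ",
         length(rts), ")")
  m <- mean(rts); s <- sd(rts)
  data.frame(subject = if ("subject" %in% names(trials))
               as.character(trials$subject[1]) else NA_character_,
             icv = s / m, go_rt_mean_ms = m, go_rt_sd_ms = s,
             n_valid_go = length(rts))
}

#' Stop-signal task summary statistics
#'
#' Go RT mean, failed-stop RT mean, mean SSD, and the three error
#' probabilities reported for the task, each as a percentage: go omissions
#' (no response) and choice errors over go trials, commissions (responses)
#' over stop trials. With no stop trials, the stop-dependent summaries are
#' `NA` and flagged.
#'
#' @param trials Trial table.
#' @return One-row data.frame: `go_rt_mean_ms`, `stop_fail_rt_mean_ms`,
#'   `mean_ssd_ms`, `p_omission_pct`, `p_choice_error_pct`,
#'   `p_commission_pct`, `stop_summaries_defined`.
#' @export
computeSstSummaries <- function(trials) {
  go <- trials[trials$trial_type == "go", , drop = FALSE]
  if (nrow(go) == 0) stop("trial table contains no go trials")
  st <- trials[trials$trial_type == "stop", , drop = FALSE]
  hasStop <- nrow(st) > 0
  responded <- go$response != "none"
  data.frame(
    go_rt_mean_ms = mean(go$rt_ms[responded]),
    stop_fail_rt_mean_ms = if (hasStop) mean(st$rt_ms, na.rm = TRUE)
                           else NA_real_,
    mean_ssd_ms = if (hasStop) mean(st$ssd_ms) else NA_real_,
    p_omission_pct = 100 * mean(!responded),
    p_choice_error_pct = 100 * mean(responded &
                                    go$response != go$correct_response),
    p_commission_pct = if (hasStop) 100 * mean(st$response != "none")
                       else NA_real_,
    stop_summaries_defined = hasStop)
}

#' Apply subject-level quality-control exclusions
#'
#' A subject is excluded from downstream analysis if their go-trial error
#' rate (wrong or missing responses) exceeds 20% or their mean framewise
#' displacement exceeds 0.5 mm. Both comparisons are strict — a subject
#' sitting exactly on a threshold is retained.
#'
#' @param qc data.frame with `subject`, `go_error_rate` (fraction) and
#'   `mean_fd_mm`.
#' @param goErrorThreshold,fdThresholdMm Exclusion cutoffs.
#' @return List with `retained` (subject ids) and `log` (data.frame
#'   `subject`, `retained`, `reason`; reason one of `""`, `"go_errors"`,
#'   `"motion"`, `"go_errors;motion"`).
#' @export
applyExclusions <- function(qc, goErrorThreshold = 0.20, fdThresholdMm = 0.5) {
  stopifnot(goErrorThreshold > 0, fdThresholdMm > 0)
  need <- c("subject", "go_error_rate", "mean_fd_mm")
  miss <- setdiff(need, names(qc))
  if (length(miss)) stop("qc table missing column(s): ",
                         paste(miss, collapse = ", "))
  bad <- !complete.cases(qc[need])
  if (any(bad))
    stop("missing QC fields for subject(s): ",
         paste(qc$subject[bad], collapse = ", "))
  goBad <- qc$go_error_rate > goErrorThreshold
  fdBad <- qc$mean_fd_mm > fdThresholdMm
  reason <- paste0(ifelse(goBad, "go_errors", ""),
                   ifelse(goBad & fdBad, ";", ""),
                   ifelse(fdBad, "motion", ""))
  log <- data.frame(subject = as.character(qc$subject),
                    retained = !(goBad | fdBad), reason = reason)
  list(retained = log$subject[log$retained], log = log)
}
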