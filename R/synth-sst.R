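#' Generate a stop-signal task event sequence
#'
#' Lays out `nGo` go trials and `nStop` stop trials so that the number of go
#' trials between successive stop trials always falls in the protocol's
#' inclusive gap range (default 3-7). Gap lengths are drawn uniformly on the
#' range and then repaired by unit increments/decrements (staying inside the
#' range) until the go-trial budget is met exactly; any surplus go trials
#' run out after the final stop trial. Onsets advance by the protocol SOA
#' with a small uniform jitter. Stop events carry the staircase starting SSD;
#' the trial simulator ([genSstTrials]) overwrites it with the tracked value.
#'
#' @param protocol A [TaskProtocol-class].
#' @param seed Integer seed.
#' @return data.frame with `trial`, `onset` (s), `duration` (s),
#'   `trial_type` (`"go"`/`"stop"`), `ssd_ms`.
#' @export
genTaskEvents <- function(protocol, seed) {
  validObject(protocol)
  p <- protocol
  gmin <- p@goGapRange[1]; gmax <- p@goGapRange[2]
  if (p@nGo < p@nStop * gmin)
    stop("infeasible gap constraint: need at least ", p@nStop * gmin,
         " go trials for ", p@nStop, " stop trials with minimum gap ", gmin)
  withr::with_seed(as.integer(seed), {
    gaps <- sample(gmin:gmax, p@nStop, replace = TRUE)
    budget <- min(p@nGo, p@nStop * gmax)  # surplus beyond gmax trails at the end
    pick <- function(idx) idx[sample.int(length(idx), 1L)]
    while (sum(gaps) > budget) {
      i <- pick(which(gaps > gmin))
      gaps[i] <- gaps[i] - 1L
    }
    while (sum(gaps) < budget) {
      i <- pick(which(gaps < gmax))
      gaps[i] <- gaps[i] + 1L
    }
    types <- unlist(lapply(seq_len(p@nStop), function(i)
      c(rep("go", gaps[i]), "stop")))
    types <- c(types, rep("go", p@nGo - sum(gaps)))
    n <- length(types)
    soa <- p@soaSeconds + runif(n, 0, 0.25 * p@soaSeconds)
    onset <- cumsum(c(0, soa[-n]))
  })
  data.frame(
    trial = seq_along(types), onset = onset,
    duration = ifelse(types == "go", p@goDisplayMs / 1000, 0.3),
    trial_type = types,
    ssd_ms = ifelse(types == "stop", p@ssdStartMs, NA_real_))
}

#' Simulate stop-signal trials under the adaptive SSD staircase
#'
#' Each go RT and stop-signal RT is drawn from the race-model laws; a stop
#' trial ends in successful inhibition iff the go RT draw exceeds
#' SSD + SSRT draw (or the go process omits). After a successful stop the
#' SSD increases by one step (harder), after a failed stop it decreases
#' (easier), clamped to the protocol grid — the tracking rule that drives
#' long-run stop success towards 50%.
#'
#' @param protocol A [TaskProtocol-class].
#' @param race A [RaceModelParams-class].
#' @param seed Integer seed.
#' @param events Optional pre-generated event sequence from [genTaskEvents];
#'   generated internally (from a child seed) when omitted.
#' @param subject Subject id recorded on every row.
#' @return Trial table: `subject`, `trial`, `onset`, `trial_type`
#'   (`"go"`/`"stop"`), `rt_ms` (NA when no response), `response`
#'   (`"left"`/`"right"`/`"none"`), `correct_response`, `ssd_ms` (stop trials
#'   only), `outcome` (`"go"`, `"stop_success"`, `"stop_fail"`).
#' @export
genSstTrials <- function(protocol, race, seed, events = NULL,
                         subject = "sub0001") {
  validObject(protocol); validObject(race)
  seeds <- splitSeed(seed, 2L)
  if (is.null(events)) events <- genTaskEvents(protocol, seeds[1])
  n <- nrow(events)
  withr::with_seed(seeds[2], {
    goRt <- rlnorm(n, race@goMeanlog, race@goSdlog)
    ssrt <- rlnorm(n, race@ssrtMeanlog, race@ssrtSdlog)
    side <- sample(c("left", "right"), n, replace = TRUE)
    omit <- runif(n) < race@omissionRate
    wrong <- runif(n) < race@choiceErrorRate
  })
  isStop <- events$trial_type == "stop"
  ssd <- rep(NA_real_, n)
  outcome <- rep("go", n)
  rt <- goRt
  cur <- protocol@ssdStartMs
  for (i in which(isStop)) {
    ssd[i] <- cur
    success <- omit[i] || goRt[i] > cur + ssrt[i]
    outcome[i] <- if (success) "stop_success" else "stop_fail"
    cur <- if (success) min(cur + protocol@ssdStepMs, protocol@ssdMaxMs)
           else max(cur - protocol@ssdStepMs, protocol@ssdMinMs)
  }
  responded <- !omit & !(outcome == "stop_success")
  response <- ifelse(!responded, "none", ifelse(wrong,
    ifelse(side == "left", "right", "left"), side))
  rt[!responded] <- NA_real_
  data.frame(
    subject = subject, trial = events$trial, onset = events$onset,
    trial_type = events$trial_type, rt_ms = rt, response = response,
    correct_response = side, ssd_ms = ssd, outcome = outcome)
}

#' Convert a simulated trial table to a BIDS-style event table
#'
#' Conditions are `GO` for go trials and `SS`/`FS` for successful/failed
#' stop trials, the three regressor families of the task GLMs.
#'
#' @param trials Output of [genSstTrials].
#' @param goDurationSeconds,stopDurationSeconds Event durations.
#' @return data.frame with `onset`, `duration`, `condition`.
#' @export
trialsToEvents <- function(trials, goDurationSeconds = 1,
                           stopDurationSeconds = 1) {
  condition <- c(go = "GO", stop_success = "SS", stop_fail = "FS")[trials$outcome]
  data.frame(onset = trials$onset,
             duration = ifelse(condition == "GO", goDurationSeconds,
                               stopDurationSeconds),
             condition = unname(condition))
}
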