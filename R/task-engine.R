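# Anticipated-response stop signal task: schedule generation, outcome
# classification, horse-race resolution, staircase SSD tracking, session
# simulation and behavioural summaries.

# Per-block stop-trial counts realizing a 2:1 go:stop ratio. 40 is not
# divisible by 3, so blocks alternate floor/ceil of trialsPerBlock/3
# (13,14,13,14 for the default 4 x 40 design; 54 stop / 106 go overall).
stopCounts <- function(nBlocks, trialsPerBlock) {
  base <- trialsPerBlock / 3
  if (base == floor(base)) return(rep.int(as.integer(base), nBlocks))
  ifelse(seq_len(nBlocks) %% 2L == 1L, floor(base), ceiling(base))
}

#' Generate the planned trial-type schedule
#'
#' Fixed per-block stop counts (closest integer realization of the 2:1
#' go:stop ratio), order randomized within block.
#'
#' @param cfg a \linkS4class{TaskConfig}.
#' @param seed integer seed; the schedule is deterministic given the seed.
#' @return list with one character vector (\code{"go"}/\code{"stop"}) per
#'   block; attribute \code{stopCounts} holds the per-block stop counts.
#' @examples
#' sched <- generateSchedule(taskConfig(), seed = 1)
#' sum(lengths(sched))  # 160 trials
#' @export
generateSchedule <- function(cfg, seed) {
  stopifnot(is(cfg, "TaskConfig"))
  validObject(cfg)
  ns <- stopCounts(cfg@nBlocks, cfg@trialsPerBlock)
  sched <- withSeed(seed, lapply(seq_len(cfg@nBlocks), function(b) {
    types <- c(rep("stop", ns[b]), rep("go", cfg@trialsPerBlock - ns[b]))
    sample(types)
  }))
  attr(sched, "stopCounts") <- as.integer(ns)
  sched
}

#' Classify a go-trial response
#'
#' Release before the go window is early, inside it (inclusive) a success,
#' after it -- or never (omission, \code{NA}) -- late.
#'
#' @param releaseLatency release latency in ms after motion onset, or
#'   \code{NA} if the button was never released.
#' @param cfg a \linkS4class{TaskConfig}.
#' @return list with \code{outcome} and \code{feedback}.
#' @export
classifyGoResponse <- function(releaseLatency, cfg) {
  stopifnot(is(cfg, "TaskConfig"))
  if (!is.na(releaseLatency) && releaseLatency < 0)
    stopf("input error: negative release latency")
  if (is.na(releaseLatency) || releaseLatency > cfg@goWindow[2])
    list(outcome = "go_late", feedback = "Too late!")
  else if (releaseLatency < cfg@goWindow[1])
    list(outcome = "go_early", feedback = "Too early!")
  else list(outcome = "go_success", feedback = "Great job!")
}

#' Resolve a stop trial by the horse race
#'
#' The stop process wins (successful stop) when \code{ssd + ssrt <=}
#' planned release; otherwise the planned release escapes.
#'
#' @param plannedRelease planned release latency draw (ms).
#' @param ssrt internal stop-process latency draw (ms).
#' @param ssd stop signal delay (ms), within the staircase bounds.
#' @param cfg a \linkS4class{TaskConfig}.
#' @return list with \code{outcome} (\code{"stop_success"} /
#'   \code{"stop_fail"}), \code{releaseLatency} (\code{NA} on success) and
#'   \code{feedback}.
#' @export
resolveStopTrial <- function(plannedRelease, ssrt, ssd, cfg) {
  stopifnot(is(cfg, "TaskConfig"))
  if (ssd < cfg@ssdMin || ssd > cfg@ssdMax)
    stopf("contract violation: ssd %g outside [%g, %g]", ssd, cfg@ssdMin, cfg@ssdMax)
  if (ssd + ssrt <= plannedRelease)
    list(outcome = "stop_success", releaseLatency = NA_real_,
         feedback = "Great job!")
  else
    list(outcome = "stop_fail", releaseLatency = plannedRelease,
         feedback = "Too early!")
}

#' Staircase update of the stop signal delay
#'
#' A successful stop makes the next stop trial harder (later cue, + step); a
#' failed stop makes it easier (- step). The result is clamped to
#' \code{[ssdMin, ssdMax]}.
#'
#' @param current current SSD (ms); must be within bounds.
#' @param stopSuccess logical, was the stop successful.
#' @param cfg a \linkS4class{TaskConfig}.
#' @return the next SSD (ms).
#' @export
updateSSD <- function(current, stopSuccess, cfg) {
  stopifnot(is(cfg, "TaskConfig"), is.logical(stopSuccess))
  if (current < cfg@ssdMin || current > cfg@ssdMax)
    stopf("contract violation: ssd %g outside [%g, %g]", current,
          cfg@ssdMin, cfg@ssdMax)
  nxt <- current + if (stopSuccess) cfg@ssdStep else -cfg@ssdStep
  min(max(nxt, cfg@ssdMin), cfg@ssdMax)
}

# Simulate one block of given trial types, staircase restarting at
# ssdInitial. Returns a data.frame of trial records.
simulateBlock <- function(types, cfg, subject, phase, block) {
  n <- length(types)
  ssd <- rep(NA_real_, n); rel <- rep(NA_real_, n)
  outcome <- character(n); feedback <- character(n)
  cur <- cfg@ssdInitial
  for (i in seq_len(n)) {
    planned <- rtnorm(1, subject@goMu, subject@goSigma)
    if (types[i] == "go") {
      omit <- subject@goOmissionRate > 0 &&
        stats::runif(1) < subject@goOmissionRate
      lat <- if (omit) NA_real_ else planned
      cls <- classifyGoResponse(lat, cfg)
      rel[i] <- lat; outcome[i] <- cls$outcome; feedback[i] <- cls$feedback
    } else {
      ssrtDraw <- rtnorm(1, subject@ssrtMu, subject@ssrtSigma)
      ssd[i] <- cur
      res <- resolveStopTrial(planned, ssrtDraw, cur, cfg)
      rel[i] <- res$releaseLatency
      outcome[i] <- res$outcome; feedback[i] <- res$feedback
      cur <- updateSSD(cur, outcome[i] == "stop_success", cfg)
    }
  }
  data.frame(phase = phase, block = block, trial = seq_len(n), type = types,
             ssd = ssd, release_latency = rel, outcome = outcome,
             feedback = feedback, stringsAsFactors = FALSE)
}

#' Simulate a full task session
#'
#' Runs the practice phase (10 go-only, 10 stop-only, 20 mixed trials;
#' flagged \code{phase = "practice"} and excluded from all summaries) and the
#' main phase (\code{nBlocks} mixed blocks with randomized schedules and a
#' staircase restarting at \code{ssdInitial} each block). Deterministic given
#' the seed.
#'
#' @param cfg a \linkS4class{TaskConfig}.
#' @param subject a \linkS4class{SubjectModel}.
#' @param seed integer seed.
#' @param includePractice simulate the practice phase (default \code{TRUE}).
#' @return data.frame of trial records with columns \code{phase},
#'   \code{block}, \code{trial}, \code{type}, \code{ssd},
#'   \code{release_latency}, \code{outcome}, \code{feedback}.
#' @examples
#' trials <- runSession(taskConfig(), subjectModel(), seed = 7)
#' sum(trials$phase == "main")  # 160
#' @export
runSession <- function(cfg, subject, seed, includePractice = TRUE) {
  stopifnot(is(cfg, "TaskConfig"), is(subject, "SubjectModel"))
  validObject(cfg); validObject(subject)
  sched <- generateSchedule(cfg, seed)
  withSeed(deriveSeed(seed, 1L), {
    out <- list()
    if (includePractice) {
      nMix <- 20L
      nStopMix <- as.integer(ceiling(nMix / 3))
      mixTypes <- sample(c(rep("stop", nStopMix), rep("go", nMix - nStopMix)))
      out <- list(
        simulateBlock(rep("go", 10L), cfg, subject, "practice", 1L),
        simulateBlock(rep("stop", 10L), cfg, subject, "practice", 2L),
        simulateBlock(mixTypes, cfg, subject, "practice", 3L))
    }
    main <- lapply(seq_along(sched), function(b)
      simulateBlock(sched[[b]], cfg, subject, "main", b))
    do.call(rbind, c(out, main))
  })
}

#' Means-method stop signal reaction time
#'
#' With a staircase holding stop success near 0.5, the SSRT estimate is the
#' mean go reaction time minus the mean stop signal delay.
#'
#' @param goRtMean mean go-trial release latency (ms).
#' @param ssdMean mean stop signal delay (ms).
#' @return SSRT (ms).
#' @examples
#' ssrtMeans(798.0, 548.4)  # 249.6
#' @export
ssrtMeans <- function(goRtMean, ssdMean) goRtMean - ssdMean

#' Summarize behaviour of a simulated session
#'
#' Per main block and pooled: probability of inhibiting (stop-success rate),
#' go success rate, mean go reaction time (over go trials with a realized
#' release; omissions are excluded), mean SSD, and the means-method SSRT.
#' Practice trials are excluded.
#'
#' @param trials trial records from [runSession()].
#' @return data.frame with one row per block plus \code{"block_mean"}
#'   (across-block mean) and \code{"overall"} (pooled trials); columns
#'   \code{unit}, \code{n_go}, \code{n_stop}, \code{p_inhibit},
#'   \code{go_success_rate}, \code{go_rt_mean}, \code{ssd_mean},
#'   \code{ssrt}.
#' @export
summarizeBehavior <- function(trials) {
  main <- trials[trials$phase == "main", , drop = FALSE]
  if (!nrow(main)) stopf("undefined-measure error: no main trials")
  oneUnit <- function(d, unit) {
    go <- d[d$type == "go", , drop = FALSE]
    st <- d[d$type == "stop", , drop = FALSE]
    if (!nrow(go) || !nrow(st))
      stopf("undefined-measure error: unit '%s' lacks go or stop trials", unit)
    rt <- go$release_latency[!is.na(go$release_latency)]
    if (!length(rt))
      stopf("undefined-measure error: unit '%s' has no realized go releases", unit)
    goRt <- mean(rt); ssdM <- mean(st$ssd)
    data.frame(unit = unit, n_go = nrow(go), n_stop = nrow(st),
               p_inhibit = mean(st$outcome == "stop_success"),
               go_success_rate = mean(go$outcome == "go_success"),
               go_rt_mean = goRt, ssd_mean = ssdM,
               ssrt = ssrtMeans(goRt, ssdM), stringsAsFactors = FALSE)
  }
  blocks <- sort(unique(main$block))
  perBlock <- do.call(rbind, lapply(blocks, function(b)
    oneUnit(main[main$block == b, , drop = FALSE], as.character(b))))
  blockMean <- perBlock[1, , drop = FALSE]
  blockMean$unit <- "block_mean"
  num <- c("p_inhibit", "go_success_rate", "go_rt_mean", "ssd_mean", "ssrt")
  blockMean[num] <- lapply(perBlock[num], mean)
  blockMean$n_go <- sum(perBlock$n_go); blockMean$n_stop <- sum(perBlock$n_stop)
  rbind(perBlock, blockMean, oneUnit(main, "overall"))
}

#' Write / read a behavioural trial log
#'
#' Tab-separated, one row per trial, with session metadata (seed, config
#' hash, ...) as commented header lines.
#'
#' @param trials trial records from [runSession()].
#' @param path file path.
#' @param meta named list of metadata written as \code{# key: value} lines.
#' @return \code{writeTrialLog}: the path, invisibly. \code{readTrialLog}:
#'   the trial data.frame with a \code{meta} attribute.
#' @export
writeTrialLog <- function(trials, path, meta = list()) {
  con <- file(path, "w")
  on.exit(close(con))
  for (k in names(meta)) writeLines(sprintf("# %s: %s", k, meta[[k]]), con)
  utils::write.table(trials, con, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' @rdname writeTrialLog
#' @export
readTrialLog <- function(path) {
  lines <- readLines(path)
  metaLines <- grep("^# ", lines, value = TRUE)
  meta <- list()
  for (l in metaLines) {
    kv <- sub("^# ", "", l)
    k <- sub(":.*$", "", kv)
    meta[[k]] <- sub("^[^:]*: ?", "", kv)
  }
  d <- utils::read.delim(text = lines[!startsWith(lines, "#")],
                         stringsAsFactors = FALSE)
  attr(d, "meta") <- meta
  d
}
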