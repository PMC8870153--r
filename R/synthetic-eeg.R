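# Synthetic per-ROI source EEG: 1/f background plus a bank of
# constant-envelope oscillators with per-trial frequency jitter, into which
# event-locked dB effects (ERD/ERS) are injected by amplitude scaling.

#' Default oscillator bank
#'
#' Ten sub-bands tiling 3.5-50 Hz. Each trial every oscillator contributes
#' one constant-envelope sinusoid with frequency drawn uniformly inside its
#' sub-band and a random phase, so trial-averaged spectra are band-limited
#' while single-trial band power stays near-deterministic (which is what
#' makes injected dB effects recoverable at fraction-of-a-dB precision).
#' Amplitudes fall off as sqrt(10/f) so band power decreases roughly as 1/f.
#'
#' @return data.frame with columns \code{low}, \code{high}, \code{amplitude}.
#' @export
defaultOscillators <- function() {
  # sub-band edges aligned to canonical band boundaries (theta 3.5-7.5,
  # alpha 7.5-12.5, beta 12.5-30, gamma 30-50) so a band-defined effect
  # scales whole sub-bands
  edges <- c(3.5, 5.5, 7.5, 10, 12.5, 16, 21, 25.5, 30, 36, 43, 50)
  lo <- edges[-length(edges)]; hi <- edges[-1]
  fc <- (lo + hi) / 2
  data.frame(low = lo, high = hi, amplitude = sqrt(10 / fc))
}

#' Define an event-locked spectral effect
#'
#' An effect multiplies, for matching trials, the amplitude of every
#' oscillator component whose frequency falls in \code{band} by
#' \code{10^(deltaDb/20)} inside \code{window} (so wavelet *power* changes
#' by \code{deltaDb}), with raised-cosine on/off ramps. Negative
#' \code{deltaDb} is event-related desynchronization (ERD), positive is
#' synchronization (ERS).
#'
#' @param roi ROI name the effect applies to.
#' @param band numeric length-2 frequency band (Hz), within [3, 50].
#' @param window numeric length-2 time window (ms) relative to the lock
#'   event.
#' @param deltaDb power change in dB.
#' @param lock \code{"motion_onset"} or \code{"stop_signal"}.
#' @param group \code{"A"}, \code{"B"} or \code{"both"}: which subject group
#'   receives the effect.
#' @return one-row data.frame; rows can be \code{rbind}-ed into the
#'   \code{effects} slot of an \linkS4class{EEGGenConfig}.
#' @examples
#' erspEffect("RSFG", band = c(30, 50), window = c(0, 300), deltaDb = -10)
#' @export
erspEffect <- function(roi, band, window, deltaDb,
                       lock = c("motion_onset", "stop_signal"),
                       group = c("both", "A", "B")) {
  lock <- match.arg(lock); group <- match.arg(group)
  stopifnot(length(band) == 2L, band[1] < band[2],
            length(window) == 2L, window[1] < window[2], is.finite(deltaDb))
  data.frame(roi = roi, fLow = band[1], fHigh = band[2],
             tStart = window[1], tEnd = window[2], lock = lock,
             deltaDb = deltaDb, group = group, stringsAsFactors = FALSE)
}

#' Construct a synthetic-EEG generator configuration
#'
#' @param fs sampling rate (Hz); must exceed twice the highest analysed
#'   frequency.
#' @param rois ROI names.
#' @param bgExponent,bgVariance 1/f^chi background exponent and total
#'   variance. The default variance (0.1) keeps the background one to two
#'   orders of magnitude below oscillator band power so injected dB effects
#'   are diluted by well under 0.5 dB.
#' @param oscillators oscillator bank (see [defaultOscillators()]).
#' @param effects data.frame of effects from [erspEffect()] (possibly
#'   zero rows for a null configuration).
#' @param spanMs generated continuous span, ms relative to motion onset.
#'   The default covers the 200 ms fixation baseline and both epochs of
#'   interest plus the edge pad needed by the slowest (3 Hz) wavelet.
#' @param selfPacedHold,preMotionDelay ms from "get set" to button press,
#'   and from press to motion onset.
#' @param rampMs effect envelope ramp (ms); keeps injected effects
#'   band-limited instead of splattering across frequencies.
#' @return an \linkS4class{EEGGenConfig}.
#' @export
eegGenConfig <- function(fs = 1000, rois = c("RSFG", "RMFG", "RIFG"),
                         bgExponent = 1, bgVariance = 0.1,
                         oscillators = defaultOscillators(),
                         effects = NULL, spanMs = c(-2900, 2200),
                         selfPacedHold = 600, preMotionDelay = 1400,
                         rampMs = 50) {
  if (is.null(effects))
    effects <- data.frame(roi = character(0), fLow = numeric(0),
                          fHigh = numeric(0), tStart = numeric(0),
                          tEnd = numeric(0), lock = character(0),
                          deltaDb = numeric(0), group = character(0),
                          stringsAsFactors = FALSE)
  new("EEGGenConfig", fs = fs, rois = rois, bgExponent = bgExponent,
      bgVariance = bgVariance, oscillators = oscillators, effects = effects,
      spanMs = spanMs, selfPacedHold = selfPacedHold,
      preMotionDelay = preMotionDelay, rampMs = rampMs)
}

# "Get set" cue time on the trial clock (motion onset = 0): the button is
# pressed selfPacedHold ms after the cue and motion starts preMotionDelay ms
# after the press. The baseline is the last 200 ms of fixation, ending at
# the cue.
getSetTime <- function(cfg) -(cfg@preMotionDelay + cfg@selfPacedHold)

# Gaussian noise shaped to a 1/f^chi amplitude spectrum (flat below 1 Hz),
# scaled to the requested total variance.
shapedNoise <- function(n, fs, chi, variance) {
  if (variance <= 0) return(numeric(n))
  w <- stats::rnorm(n)
  if (chi == 0) return(w * sqrt(variance) / stats::sd(w))
  f <- (seq_len(n) - 1) * fs / n
  fFold <- pmin(f, fs - f)
  gain <- 1 / pmax(fFold, 1)^(chi / 2)
  gain[1] <- 0
  x <- Re(stats::fft(stats::fft(w) * gain, inverse = TRUE)) / n
  x * sqrt(variance) / stats::sd(x)
}

# Brickwall FFT bandpass (adequate for synthetic series; no real-data use).
bandpassFFT <- function(x, fLow, fHigh, fs) {
  n <- length(x)
  f <- (seq_len(n) - 1) * fs / n
  fFold <- pmin(f, fs - f)
  X <- stats::fft(x)
  X[fFold < fLow | fFold > fHigh] <- 0
  Re(stats::fft(X, inverse = TRUE)) / n
}

# Multiplicative amplitude envelope for one effect on the trial time axis:
# 1 outside [t1, t2], g = 10^(deltaDb/20) inside, raised-cosine ramps of
# length rampMs at each end (shortened if the window is narrow).
effectEnvelope <- function(timeMs, t1, t2, deltaDb, rampMs) {
  g <- 10^(deltaDb / 20)
  r <- min(rampMs, (t2 - t1) / 2)
  env <- rep(1, length(timeMs))
  inside <- timeMs >= t1 & timeMs <= t2
  env[inside] <- g
  if (r > 0) {
    up <- timeMs >= t1 & timeMs < t1 + r
    env[up] <- 1 + (g - 1) * (1 - cos(pi * (timeMs[up] - t1) / r)) / 2
    dn <- timeMs > t2 - r & timeMs <= t2
    env[dn] <- 1 + (g - 1) * (1 - cos(pi * (t2 - timeMs[dn]) / r)) / 2
  }
  env
}

#' Synthesize one trial of multi-ROI source EEG
#'
#' Emits the continuous series for one trial spanning fixation through the
#' end of motion: shaped 1/f background plus the oscillator bank, with every
#' applicable effect of the configuration applied (matching ROI, matching
#' group, oscillator frequency inside the effect band, window placed on the
#' trial clock -- stop-locked windows are shifted by the trial's SSD and
#' skipped on go trials).
#'
#' @param cfg an \linkS4class{EEGGenConfig}.
#' @param trial a single trial record (one row of [runSession()] output, or
#'   a list with \code{type} and \code{ssd}).
#' @param group subject group label (\code{"A"} or \code{"B"}) used to match
#'   effects.
#' @param seed integer seed; the trial is deterministic given the seed.
#' @return list with \code{time} (ms, motion onset = 0), \code{series}
#'   (samples x ROI matrix), and \code{events} (\code{motion_onset},
#'   \code{stop_signal}, \code{get_set}).
#' @export
synthesizeTrial <- function(cfg, trial, group = "A", seed = NULL) {
  stopifnot(is(cfg, "EEGGenConfig"))
  validObject(cfg)
  timeMs <- seq(cfg@spanMs[1], cfg@spanMs[2], by = 1000 / cfg@fs)
  n <- length(timeMs)
  ssd <- if (!is.null(trial$ssd)) trial$ssd else NA_real_
  eff <- cfg@effects
  if (nrow(eff)) {
    absStart <- ifelse(eff$lock == "stop_signal", eff$tStart + ssd, eff$tStart)
    absEnd <- ifelse(eff$lock == "stop_signal", eff$tEnd + ssd, eff$tEnd)
    use <- !is.na(absStart)
    if (any(use & (absStart < cfg@spanMs[1] | absEnd > cfg@spanMs[2])))
      stopf("configuration error: effect window outside the generated span")
  }
  withSeed(seed, {
    series <- matrix(0, n, length(cfg@rois),
                     dimnames = list(NULL, cfg@rois))
    for (j in seq_along(cfg@rois)) {
      x <- shapedNoise(n, cfg@fs, cfg@bgExponent, cfg@bgVariance)
      # an effect suppresses/enhances ALL band-limited activity of the ROI,
      # background included, so the in-band background is scaled too
      if (nrow(eff)) for (e in seq_len(nrow(eff))) {
        if (eff$roi[e] != cfg@rois[j]) next
        if (!(eff$group[e] == "both" || eff$group[e] == group)) next
        if (eff$lock[e] == "stop_signal") {
          if (is.na(ssd)) next
          t1 <- eff$tStart[e] + ssd; t2 <- eff$tEnd[e] + ssd
        } else {
          t1 <- eff$tStart[e]; t2 <- eff$tEnd[e]
        }
        bgIn <- bandpassFFT(x, eff$fLow[e], eff$fHigh[e], cfg@fs)
        x <- x - bgIn + bgIn * effectEnvelope(timeMs, t1, t2,
                                              eff$deltaDb[e], cfg@rampMs)
      }
      osc <- cfg@oscillators
      for (k in seq_len(nrow(osc))) {
        f0 <- stats::runif(1, osc$low[k], osc$high[k])
        phi <- stats::runif(1, 0, 2 * pi)
        comp <- osc$amplitude[k] * cos(2 * pi * f0 * timeMs / 1000 + phi)
        if (nrow(eff)) for (e in seq_len(nrow(eff))) {
          if (eff$roi[e] != cfg@rois[j]) next
          if (!(eff$group[e] == "both" || eff$group[e] == group)) next
          if (f0 < eff$fLow[e] || f0 > eff$fHigh[e]) next
          if (eff$lock[e] == "stop_signal") {
            if (is.na(ssd)) next
            t1 <- eff$tStart[e] + ssd; t2 <- eff$tEnd[e] + ssd
          } else {
            t1 <- eff$tStart[e]; t2 <- eff$tEnd[e]
          }
          comp <- comp * effectEnvelope(timeMs, t1, t2, eff$deltaDb[e],
                                        cfg@rampMs)
        }
        x <- x + comp
      }
      series[, j] <- x
    }
    list(time = timeMs, series = series,
         events = list(motion_onset = 0, stop_signal = ssd,
                       get_set = getSetTime(cfg)))
  })
}

#' Cut event-locked epochs from continuous trials
#'
#' Epochs are cut to \code{span} around the lock event plus a symmetric pad
#' (kept so downstream wavelet convolution is edge-valid inside the span);
#' the matching per-trial baseline segment (last 200 ms of fixation, also
#' padded) is attached. Trials without the lock event (go trials under a
#' stop-signal lock) are skipped with a message.
#'
#' @param trialsEEG list of [synthesizeTrial()] results (one per trial).
#' @param roi ROI to extract.
#' @param lockEvent \code{"motion_onset"} or \code{"stop_signal"}.
#' @param span analysis window (ms relative to the lock event).
#' @param info data.frame of per-trial metadata aligned with
#'   \code{trialsEEG} (skipped trials are dropped from it too).
#' @param padMs edge pad on each side (ms); 650 ms covers a 3 Hz wavelet
#'   with 3 cycles.
#' @param baselineLenMs baseline length (ms), 200 by default.
#' @return an \linkS4class{EpochSet}.
#' @export
makeEpochs <- function(trialsEEG, roi, lockEvent = c("motion_onset", "stop_signal"),
                       span, info = NULL, padMs = 650, baselineLenMs = 200) {
  lockEvent <- match.arg(lockEvent)
  stopifnot(length(span) == 2L, span[1] < span[2], length(trialsEEG) >= 1L)
  if (is.null(info))
    info <- data.frame(trial = seq_along(trialsEEG))
  stopifnot(nrow(info) == length(trialsEEG))
  tGrid <- trialsEEG[[1]]$time
  fs <- 1000 / (tGrid[2] - tGrid[1])
  relTime <- seq(span[1] - padMs, span[2] + padMs, by = 1000 / fs)
  gs <- trialsEEG[[1]]$events$get_set
  blSpan <- c(gs - baselineLenMs, gs)
  blTime <- seq(blSpan[1] - padMs, blSpan[2] + padMs, by = 1000 / fs)
  idxOf <- function(t0) round((t0 - tGrid[1]) * fs / 1000) + 1
  blIdx <- idxOf(blTime[1]) + seq_along(blTime) - 1
  if (blIdx[1] < 1 || max(blIdx) > length(tGrid))
    stopf("span request beyond generated samples (baseline)")
  keep <- logical(length(trialsEEG))
  rows <- vector("list", length(trialsEEG))
  blRows <- vector("list", length(trialsEEG))
  for (i in seq_along(trialsEEG)) {
    ev <- trialsEEG[[i]]$events[[lockEvent]]
    if (is.null(ev) || is.na(ev)) next
    i0 <- idxOf(ev + relTime[1])
    idx <- i0 + seq_along(relTime) - 1
    if (idx[1] < 1 || max(idx) > length(tGrid))
      stopf("span request beyond generated samples (trial %d)", i)
    rows[[i]] <- trialsEEG[[i]]$series[idx, roi]
    blRows[[i]] <- trialsEEG[[i]]$series[blIdx, roi]
    keep[i] <- TRUE
  }
  skipped <- which(!keep)
  if (length(skipped))
    message(sprintf("makeEpochs: skipped %d trial(s) without event '%s'",
                    length(skipped), lockEvent))
  if (!any(keep)) stopf("no trials with event '%s'", lockEvent)
  new("EpochSet", roi = roi, data = do.call(rbind, rows[keep]),
      time = relTime, span = as.numeric(span), fs = fs,
      lockEvent = lockEvent, baseline = do.call(rbind, blRows[keep]),
      baselineTime = blTime, baselineSpan = blSpan,
      info = info[keep, , drop = FALSE], skipped = as.integer(skipped))
}

#' Generate a synthetic clinical table
#'
#' Per-subject age, sex and clinical scores with marginal distributions
#' matching the studied chronic-tic-disorder cohort (mean age 13.3 y, tic
#' severity 23 +/- 9.3, premonitory-urge total 22 +/- 5.9). An optional
#' linkage draws a per-subject EEG effect size (dB) jointly normal with the
#' latent tic-severity score at a requested correlation, enabling
#' correlation-recovery experiments.
#'
#' @param n number of subjects (>= 2).
#' @param seed integer seed.
#' @param group diagnosis label (\code{"CTD"} or \code{"HC"}; controls get
#'   zero tic/urge/compulsion scores).
#' @param linkage optional list with \code{r} (correlation between the dB
#'   effect and the tic-severity score, |r| <= 1), \code{deltaMean} and
#'   \code{deltaSd} (dB); adds a \code{trueDelta} column.
#' @return data.frame with columns \code{id}, \code{diagnosis}, \code{age},
#'   \code{sex}, \code{ygtss_total_tic}, \code{puts_total},
#'   \code{puts_item10}, \code{cybocs}, \code{dupaul_adhd} (and
#'   \code{trueDelta} under linkage).
#' @export
generateClinicalCohort <- function(n, seed = NULL, group = c("CTD", "HC"),
                                   linkage = NULL) {
  group <- match.arg(group)
  if (n < 2) stopf("cohort needs n >= 2 subjects")
  if (!is.null(linkage) && abs(linkage$r) > 1)
    stopf("degenerate correlation request: |r| > 1")
  withSeed(seed, {
    age <- round(rtnorm(n, 13.3, 1.9, 10, 17))
    sex <- sample(c("M", "F"), n, replace = TRUE, prob = c(11, 3) / 14)
    d <- data.frame(id = sprintf("%s%02d", group, seq_len(n)),
                    diagnosis = group, age = age, sex = sex,
                    stringsAsFactors = FALSE)
    if (group == "CTD") {
      zTic <- stats::rnorm(n)
      d$ygtss_total_tic <- pmin(50, pmax(0, round(23.4 + 9.3 * zTic)))
      d$puts_total <- pmin(36, pmax(9, round(rtnorm(n, 21.6, 5.9, 9, 36))))
      d$puts_item10 <- 1L + findInterval(stats::rnorm(n),
                                         stats::qnorm(c(0.25, 0.5, 0.75)))
      d$cybocs <- ifelse(stats::runif(n) < 0.43, round(stats::runif(n, 15, 22)), 0)
      d$dupaul_adhd <- pmax(0, round(rtnorm(n, 17, 11, 0, 54)))
      if (!is.null(linkage)) {
        zE <- linkage$r * zTic + sqrt(1 - linkage$r^2) * stats::rnorm(n)
        d$trueDelta <- linkage$deltaMean + linkage$deltaSd * zE
      }
    } else {
      d$ygtss_total_tic <- 0; d$puts_total <- 0
      d$puts_item10 <- NA_integer_; d$cybocs <- 0
      d$dupaul_adhd <- pmax(0, round(rtnorm(n, 8, 6, 0, 54)))
    }
    d
  })
}

#' Build a paired synthetic cohort: sessions, EEG epochs and clinical table
#'
#' Each subject gets a simulated task session, per-trial source EEG, and a
#' clinical row. Under \code{linkage}, the per-subject dB amplitude of the
#' chosen effect is drawn jointly with the latent tic-severity score at the
#' requested correlation (group A only), enabling recovery tests of the
#' power/severity correlation.
#'
#' @param nA,nB subjects per group (each >= 2). Group A maps to the CTD-like
#'   cohort, group B to controls.
#' @param taskCfg a \linkS4class{TaskConfig}.
#' @param eegCfg an \linkS4class{EEGGenConfig}; its effects with
#'   \code{group = "A"} are the group difference.
#' @param subjectA,subjectB \linkS4class{SubjectModel}s per group.
#' @param seed integer seed.
#' @param linkage optional list (\code{r}, \code{deltaMean}, \code{deltaSd},
#'   \code{effect} = row index of the linked effect, default 1); overrides
#'   that effect's \code{deltaDb} per subject in group A.
#' @param lockEvents which epoch sets to cut per ROI.
#' @param spans named list of analysis spans (ms) per lock event.
#' @param eeg set \code{FALSE} to skip EEG synthesis (sessions and clinical
#'   table only).
#' @return list with \code{clinical} (both groups, \code{trueDelta} attached
#'   under linkage), \code{sessions} (per-subject trial records), and --
#'   when \code{eeg} -- \code{epochs}: a list \code{[[roi]][[lockEvent]]} of
#'   \linkS4class{EpochSet}s pooling all subjects' trials.
#' @export
buildCohort <- function(nA, nB, taskCfg = taskConfig(),
                        eegCfg = eegGenConfig(),
                        subjectA = subjectModel(), subjectB = subjectModel(),
                        seed = 1, linkage = NULL,
                        lockEvents = c("motion_onset", "stop_signal"),
                        spans = list(motion_onset = c(-500, 1000),
                                     stop_signal = c(-500, 800)),
                        eeg = TRUE) {
  if (nA < 2 || nB < 2) stopf("cohort needs at least 2 subjects per group")
  clinA <- generateClinicalCohort(nA, deriveSeed(seed, 1L), "CTD",
                                  linkage = linkage)
  clinB <- generateClinicalCohort(nB, deriveSeed(seed, 2L), "HC")
  if (!is.null(linkage)) clinB$trueDelta <- NA_real_
  clinical <- rbind(clinA, clinB)
  rownames(clinical) <- NULL
  groups <- rep(c("A", "B"), c(nA, nB))
  ids <- c(clinA$id, clinB$id)
  models <- c(rep(list(subjectA), nA), rep(list(subjectB), nB))
  sessions <- list(); allEEG <- list(); infos <- list()
  for (s in seq_len(nA + nB)) {
    sSeed <- deriveSeed(seed, 100L + s)
    trials <- runSession(taskCfg, models[[s]], sSeed, includePractice = FALSE)
    sessions[[ids[s]]] <- trials
    if (!eeg) next
    cfgS <- eegCfg
    if (!is.null(linkage) && groups[s] == "A") {
      eIdx <- if (is.null(linkage$effect)) 1L else linkage$effect
      cfgS@effects$deltaDb[eIdx] <- clinA$trueDelta[s]
    }
    main <- trials[trials$phase == "main", , drop = FALSE]
    tEEG <- lapply(seq_len(nrow(main)), function(i)
      synthesizeTrial(cfgS, main[i, ], group = groups[s],
                      seed = deriveSeed(sSeed, i)))
    allEEG <- c(allEEG, tEEG)
    infos[[s]] <- data.frame(subject = ids[s], group = groups[s],
                             diagnosis = ifelse(groups[s] == "A", "CTD", "HC"),
                             type = main$type, block = main$block,
                             trial = main$trial, stringsAsFactors = FALSE)
  }
  out <- list(clinical = clinical, sessions = sessions)
  if (eeg) {
    info <- do.call(rbind, infos)
    out$epochs <- lapply(stats::setNames(eegCfg@rois, eegCfg@rois), function(r)
      lapply(stats::setNames(lockEvents, lockEvents), function(le)
        suppressMessages(makeEpochs(allEEG, r, le, spans[[le]], info = info))))
  }
  out
}
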