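# S4 classes for the task simulator, synthetic EEG, time-frequency arrays and
# cluster statistics.

#' Task configuration for the anticipated-response stop signal task
#'
#' Holds the timing and staircase parameters of the task: a fixation screen,
#' a self-paced button press, a pre-motion delay, a 1000 ms motion period
#' during which the go response (button release) must land inside the go
#' window, and for stop trials a stop cue whose delay (SSD) is tracked by a
#' one-up/one-down 50 ms staircase bounded to the printed stop-cue range.
#'
#' @slot nBlocks number of main mixed blocks.
#' @slot trialsPerBlock trials per main block.
#' @slot ssdInitial staircase starting stop signal delay (ms); each block
#'   restarts here.
#' @slot ssdStep staircase step (ms).
#' @slot ssdMin,ssdMax staircase clamp bounds (ms).
#' @slot goWindow two-element window (ms after motion onset) inside which a
#'   release counts as a successful go.
#' @slot motionDuration duration of target motion (ms).
#' @slot preMotionDelay delay between button press and motion onset (ms).
#' @slot fixationDuration fixation screen duration (ms).
#' @slot stopHoldSuccess required post-cue hold for a successful stop (ms).
#' @exportClass TaskConfig
setClass("TaskConfig", representation(
  nBlocks = "integer", trialsPerBlock = "integer",
  ssdInitial = "numeric", ssdStep = "numeric",
  ssdMin = "numeric", ssdMax = "numeric",
  goWindow = "numeric", motionDuration = "numeric",
  preMotionDelay = "numeric", fixationDuration = "numeric",
  stopHoldSuccess = "numeric"))

setValidity("TaskConfig", function(object) {
  msg <- character(0)
  if (!isCount(object@nBlocks)) msg <- c(msg, "nBlocks must be a positive count")
  if (!isCount(object@trialsPerBlock)) msg <- c(msg, "trialsPerBlock must be a positive count")
  durs <- c(object@ssdStep, object@motionDuration, object@preMotionDelay,
            object@fixationDuration, object@stopHoldSuccess)
  if (any(!is.finite(durs)) || any(durs <= 0)) msg <- c(msg, "all durations must be > 0")
  if (!(object@ssdMin <= object@ssdInitial && object@ssdInitial <= object@ssdMax))
    msg <- c(msg, "need ssdMin <= ssdInitial <= ssdMax")
  if (length(object@goWindow) != 2L || diff(object@goWindow) <= 0)
    msg <- c(msg, "goWindow must be an increasing interval")
  else if (object@goWindow[1] <= 0 || object@goWindow[2] > object@motionDuration)
    msg <- c(msg, "goWindow must lie within (0, motionDuration]")
  if (length(msg)) msg else TRUE
})

#' @describeIn TaskConfig-class Constructor with the study's task parameters
#'   as defaults (4 blocks of 40 trials, 2:1 go:stop ratio, SSD staircase
#'   500/50 ms clamped to 300-700 ms, go window 700-800 ms).
#' @param nBlocks,trialsPerBlock,ssdInitial,ssdStep,ssdMin,ssdMax,goWindow
#'   see slots.
#' @param motionDuration,preMotionDelay,fixationDuration,stopHoldSuccess
#'   see slots.
#' @export
taskConfig <- function(nBlocks = 4, trialsPerBlock = 40, ssdInitial = 500,
                       ssdStep = 50, ssdMin = 300, ssdMax = 700,
                       goWindow = c(700, 800), motionDuration = 1000,
                       preMotionDelay = 1400, fixationDuration = 2000,
                       stopHoldSuccess = 1000) {
  if (!isCount(nBlocks) || !isCount(trialsPerBlock))
    stopf("configuration error: block and trial counts must be positive integers")
  new("TaskConfig", nBlocks = as.integer(nBlocks),
      trialsPerBlock = as.integer(trialsPerBlock),
      ssdInitial = ssdInitial, ssdStep = ssdStep, ssdMin = ssdMin,
      ssdMax = ssdMax, goWindow = goWindow, motionDuration = motionDuration,
      preMotionDelay = preMotionDelay, fixationDuration = fixationDuration,
      stopHoldSuccess = stopHoldSuccess)
}

setMethod("show", "TaskConfig", function(object) {
  cat("TaskConfig:", object@nBlocks, "x", object@trialsPerBlock,
      "trials; SSD", object@ssdInitial, "ms start,", object@ssdStep,
      "ms step, clamp [", object@ssdMin, ",", object@ssdMax, "] ms; go window",
      object@goWindow[1], "-", object@goWindow[2], "ms\n")
})

#' Horse-race subject model
#'
#' Generative behavioural model: the planned button release latency
#' (motion-locked) and the covert stop-process latency are independent
#' truncated-normal (positive) draws; on stop trials the stop process wins
#' when it finishes before the planned release.
#'
#' @slot goMu,goSigma mean/SD of the planned release latency (ms).
#' @slot ssrtMu,ssrtSigma mean/SD of the internal stop latency (ms).
#' @slot goOmissionRate probability a go trial is omitted (button never
#'   released).
#' @exportClass SubjectModel
setClass("SubjectModel", representation(
  goMu = "numeric", goSigma = "numeric", ssrtMu = "numeric",
  ssrtSigma = "numeric", goOmissionRate = "numeric"))

setValidity("SubjectModel", function(object) {
  msg <- character(0)
  if (object@goSigma < 0 || object@ssrtSigma < 0) msg <- c(msg, "sigmas must be >= 0")
  if (object@goOmissionRate < 0 || object@goOmissionRate >= 1)
    msg <- c(msg, "goOmissionRate must be in [0, 1)")
  if (object@goMu <= 0 || object@ssrtMu < 0) msg <- c(msg, "latency means must be positive")
  if (length(msg)) msg else TRUE
})

#' @describeIn SubjectModel-class Constructor; defaults reproduce the
#'   equilibrium behaviour of the studied cohorts (go latency 798 +/- 25 ms,
#'   stop latency 250 +/- 35 ms).
#' @param goMu,goSigma,ssrtMu,ssrtSigma,goOmissionRate see slots.
#' @export
subjectModel <- function(goMu = 798, goSigma = 25, ssrtMu = 250,
                         ssrtSigma = 35, goOmissionRate = 0) {
  new("SubjectModel", goMu = goMu, goSigma = goSigma, ssrtMu = ssrtMu,
      ssrtSigma = ssrtSigma, goOmissionRate = goOmissionRate)
}

setMethod("show", "SubjectModel", function(object) {
  cat(sprintf("SubjectModel: go %g +/- %g ms, stop %g +/- %g ms, omission %g\n",
              object@goMu, object@goSigma, object@ssrtMu, object@ssrtSigma,
              object@goOmissionRate))
})

#' Synthetic source-EEG generator configuration
#'
#' Describes what the generator emits for each region of interest (ROI):
#' weak 1/f-shaped Gaussian background plus a bank of constant-envelope
#' oscillators (one sinusoid per trial per sub-band, frequency jittered
#' uniformly inside the sub-band) covering the analysed 3-50 Hz range.
#' Event-locked spectral effects multiply oscillator amplitudes by
#' 10^(deltaDb/20) inside their time window (raised-cosine on/off ramps), so
#' wavelet power changes by deltaDb.
#'
#' @slot fs sampling rate (Hz).
#' @slot rois ROI names.
#' @slot bgExponent 1/f^chi background exponent.
#' @slot bgVariance total background variance (source units squared).
#' @slot oscillators data.frame with columns \code{low}, \code{high},
#'   \code{amplitude} (one oscillator per row).
#' @slot effects data.frame of spectral effects (see [erspEffect()]).
#' @slot spanMs generated continuous span (ms, motion onset = 0).
#' @slot selfPacedHold ms between the "get set" cue and the button press
#'   (fixed in simulation; the task itself is self-paced).
#' @slot preMotionDelay ms between button press and motion onset (mirrors
#'   the task configuration; used to place the fixation/baseline window).
#' @slot rampMs effect envelope ramp length (ms).
#' @exportClass EEGGenConfig
setClass("EEGGenConfig", representation(
  fs = "numeric", rois = "character", bgExponent = "numeric",
  bgVariance = "numeric", oscillators = "data.frame", effects = "data.frame",
  spanMs = "numeric", selfPacedHold = "numeric", preMotionDelay = "numeric",
  rampMs = "numeric"))

setValidity("EEGGenConfig", function(object) {
  msg <- character(0)
  if (object@fs <= 100) msg <- c(msg, "fs implausibly low")
  if (nrow(object@oscillators) &&
      (object@fs <= 2 * max(object@oscillators$high)))
    msg <- c(msg, "fs must exceed twice the highest oscillator frequency")
  if (object@bgVariance < 0) msg <- c(msg, "bgVariance must be >= 0")
  if (length(object@spanMs) != 2L || diff(object@spanMs) <= 0)
    msg <- c(msg, "spanMs must be an increasing interval")
  if (nrow(object@effects)) {
    need <- c("roi", "fLow", "fHigh", "tStart", "tEnd", "lock", "deltaDb", "group")
    if (!all(need %in% names(object@effects)))
      msg <- c(msg, "effects is missing required columns")
    else {
      if (any(!is.finite(object@effects$deltaDb))) msg <- c(msg, "deltaDb must be finite")
      if (any(object@effects$fLow < 3 | object@effects$fHigh > 50))
        msg <- c(msg, "effect bands must lie within [3, 50] Hz")
    }
  }
  if (length(msg)) msg else TRUE
})

setMethod("show", "EEGGenConfig", function(object) {
  cat("EEGGenConfig:", length(object@rois), "ROI(s) @", object@fs, "Hz;",
      nrow(object@oscillators), "oscillators;", nrow(object@effects),
      "effect(s); span", object@spanMs[1], "..", object@spanMs[2], "ms\n")
})

#' Set of single-trial epochs for one ROI
#'
#' A trials x samples matrix cut around a lock event (motion onset or stop
#' signal), together with the matching per-trial baseline segment (last
#' 200 ms of fixation) and trial metadata. Rows of \code{data},
#' \code{baseline} and \code{info} align. The stored samples include a
#' symmetric pad beyond the analysis span so that wavelet convolution is
#' edge-valid inside the span.
#'
#' @slot roi ROI name.
#' @slot data trials x samples amplitude matrix (includes pad).
#' @slot time sample times (ms, relative to the lock event).
#' @slot span requested analysis window (ms).
#' @slot fs sampling rate (Hz).
#' @slot lockEvent \code{"motion_onset"} or \code{"stop_signal"}.
#' @slot baseline trials x samples baseline matrix (includes pad).
#' @slot baselineTime baseline sample times (ms, trial clock).
#' @slot baselineSpan the valid 200 ms baseline window (ms, trial clock).
#' @slot info per-trial metadata (subject, group, type, ...).
#' @slot skipped indices of input trials without the lock event.
#' @exportClass EpochSet
setClass("EpochSet", representation(
  roi = "character", data = "matrix", time = "numeric", span = "numeric",
  fs = "numeric", lockEvent = "character", baseline = "matrix",
  baselineTime = "numeric", baselineSpan = "numeric", info = "data.frame",
  skipped = "integer"))

setValidity("EpochSet", function(object) {
  msg <- character(0)
  if (nrow(object@data) != nrow(object@info)) msg <- c(msg, "data/info row mismatch")
  if (nrow(object@baseline) != nrow(object@data)) msg <- c(msg, "baseline/data row mismatch")
  if (ncol(object@data) != length(object@time)) msg <- c(msg, "time axis length mismatch")
  dt <- diff(object@time)
  if (length(dt) && (any(dt <= 0) || max(abs(dt - 1000 / object@fs)) > 1e-6))
    msg <- c(msg, "time axis must increase uniformly at 1/fs")
  nb <- sum(object@baselineTime >= object@baselineSpan[1] &
            object@baselineTime <= object@baselineSpan[2])
  if (nb < round(200 * object@fs / 1000))
    msg <- c(msg, "baseline window must cover 200 ms of samples")
  if (length(msg)) msg else TRUE
})

setMethod("show", "EpochSet", function(object) {
  cat(sprintf("EpochSet '%s': %d trials x %d samples @ %g Hz, lock = %s, span %g..%g ms (%d skipped)\n",
              object@roi, nrow(object@data), ncol(object@data), object@fs,
              object@lockEvent, object@span[1], object@span[2],
              length(object@skipped)))
})

#' Complex Morlet wavelet family
#'
#' Gaussian-windowed complex exponentials with unit energy, sigma_t =
#' cycles / (2 pi f). The default family spans 3-50 Hz in 0.5 Hz steps (95
#' wavelets) with cycles increasing linearly from 3 to 10.
#'
#' @slot frequencies centre frequencies (Hz), strictly increasing.
#' @slot cycles per-frequency cycle counts.
#' @slot fs sampling rate (Hz).
#' @slot kernels list of complex time-domain kernels (unit energy).
#' @slot halfWidthMs per-frequency kernel half support (ms); samples closer
#'   than this to a series edge are edge-contaminated.
#' @exportClass WaveletFamily
setClass("WaveletFamily", representation(
  frequencies = "numeric", cycles = "numeric", fs = "numeric",
  kernels = "list", halfWidthMs = "numeric"))

setValidity("WaveletFamily", function(object) {
  msg <- character(0)
  if (any(diff(object@frequencies) <= 0)) msg <- c(msg, "frequencies must strictly increase")
  if (max(object@frequencies) >= object@fs / 2) msg <- c(msg, "frequencies must be below Nyquist")
  if (length(object@kernels) != length(object@frequencies))
    msg <- c(msg, "one kernel per frequency required")
  if (length(msg)) msg else TRUE
})

setMethod("show", "WaveletFamily", function(object) {
  cat(sprintf("WaveletFamily: %d wavelets, %g-%g Hz, %g-%g cycles @ %g Hz\n",
              length(object@frequencies), min(object@frequencies),
              max(object@frequencies), min(object@cycles), max(object@cycles),
              object@fs))
})

#' Time-frequency power array
#'
#' A frequency x time x trials power array (raw wavelet power, or dB after
#' baseline normalization) with axis vectors, per-trial per-frequency
#' baseline power, and trial metadata.
#'
#' @slot power freq x time x trials array.
#' @slot freq frequency axis (Hz).
#' @slot time time axis (ms relative to lock event).
#' @slot lockEvent lock event identity.
#' @slot units \code{"raw"} or \code{"dB"}.
#' @slot baselinePower freq x trials matrix of mean baseline power.
#' @slot baselineMode \code{"trial"} or \code{"average"} (how dB was formed).
#' @slot info per-trial metadata.
#' @exportClass TFArray
setClass("TFArray", representation(
  power = "array", freq = "numeric", time = "numeric", lockEvent = "character",
  units = "character", baselinePower = "matrix", baselineMode = "character",
  info = "data.frame"))

setValidity("TFArray", function(object) {
  msg <- character(0)
  d <- dim(object@power)
  if (length(d) != 3L) msg <- c(msg, "power must be a 3-d array")
  else {
    if (d[1] != length(object@freq)) msg <- c(msg, "freq axis mismatch")
    if (d[2] != length(object@time)) msg <- c(msg, "time axis mismatch")
    if (d[3] != nrow(object@info)) msg <- c(msg, "metadata length must equal trial count")
    if (nrow(object@baselinePower) != d[1] || ncol(object@baselinePower) != d[3])
      msg <- c(msg, "baselinePower must be freq x trials")
  }
  if (!object@units %in% c("raw", "dB")) msg <- c(msg, "units must be 'raw' or 'dB'")
  if (object@units == "dB" && !all(is.finite(object@power)))
    msg <- c(msg, "dB values must be finite")
  if (length(msg)) msg else TRUE
})

setMethod("show", "TFArray", function(object) {
  d <- dim(object@power)
  cat(sprintf("TFArray [%s]: %d freq x %d time x %d trials, lock = %s, %g-%g Hz, %g..%g ms\n",
              object@units, d[1], d[2], d[3], object@lockEvent,
              min(object@freq), max(object@freq), min(object@time),
              max(object@time)))
})

#' Result of the permutation cluster-mass test
#'
#' Observed group-difference and t maps, the pixel threshold, connected
#' suprathreshold clusters with their masses (sum of |t|), the permutation
#' null distribution of maximum cluster masses, the multi-ROI corrected mass
#' threshold, and per-cluster corrected p values.
#'
#' @slot diffMap,observed tMap freq x time matrices (group A minus group B,
#'   dB; pooled-variance two-sample t).
#' @slot freq,time axes.
#' @slot pixelThreshold two-tailed critical |t| at the pixel alpha.
#' @slot labels integer matrix of cluster labels (0 = background).
#' @slot mass per-cluster sum of |t|.
#' @slot nullMasses permutation distribution of the maximum cluster mass.
#' @slot massThreshold corrected cluster-mass threshold.
#' @slot percentile the percentile used (98.3 for 3 ROIs at alpha 0.05).
#' @slot significant logical flag per cluster.
#' @slot mask logical freq x time mask of significant clusters.
#' @slot clusterP per-cluster corrected p (fraction of null >= mass).
#' @slot nPerm,alpha,nRois,seed test parameters.
#' @slot groups the two group labels (A, B order used for the difference).
#' @exportClass ClusterResult
setClass("ClusterResult", representation(
  diffMap = "matrix", tMap = "matrix", freq = "numeric", time = "numeric",
  pixelThreshold = "numeric", labels = "matrix", mass = "numeric",
  nullMasses = "numeric", massThreshold = "numeric", percentile = "numeric",
  significant = "logical", mask = "matrix", clusterP = "numeric",
  nPerm = "integer", alpha = "numeric", nRois = "integer", seed = "numeric",
  groups = "character"))

setValidity("ClusterResult", function(object) {
  msg <- character(0)
  if (length(object@nullMasses) != object@nPerm)
    msg <- c(msg, "null distribution length must equal nPerm")
  if (any(object@significant & object@mass < object@massThreshold))
    msg <- c(msg, "significant clusters must have mass >= massThreshold")
  supra <- abs(object@tMap) > object@pixelThreshold
  if (any(object@mask & !supra)) msg <- c(msg, "mask must be a subset of suprathreshold pixels")
  if (length(object@mass) != length(object@significant) ||
      length(object@mass) != length(object@clusterP))
    msg <- c(msg, "per-cluster vectors must align")
  if (length(msg)) msg else TRUE
})

setMethod("show", "ClusterResult", function(object) {
  cat(sprintf("ClusterResult: %d cluster(s), %d significant (mass threshold %.3f = %.1f%%ile of %d permutations)\n",
              length(object@mass), sum(object@significant),
              object@massThreshold, object@percentile, object@nPerm))
})
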