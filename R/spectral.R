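# Complex Morlet wavelet time-frequency decomposition and dB baseline
# normalization.

#' Build a complex Morlet wavelet family
#'
#' Gaussian-windowed complex exponentials w(t) = exp(i 2 pi f t)
#' exp(-t^2 / (2 sigma_t^2)) with sigma_t = cycles / (2 pi f), truncated at
#' 3.5 sigma_t and normalized to unit energy (so white noise of variance
#' sigma^2 yields expected power sigma^2 at every frequency). The default
#' grid is 3-50 Hz in 0.5 Hz steps: 95 wavelets.
#'
#' @param fmin,fmax,df frequency grid (Hz); \code{fmax} must be below
#'   Nyquist.
#' @param fs sampling rate (Hz).
#' @param cycles either a single cycle count used at every frequency, or a
#'   length-2 vector: cycles increase linearly from \code{cycles[1]} at
#'   \code{fmin} to \code{cycles[2]} at \code{fmax} (default 3 to 10, the
#'   usual time/frequency-resolution trade-off).
#' @return a \linkS4class{WaveletFamily}.
#' @examples
#' length(buildWavelets()@frequencies)  # 95
#' @export
buildWavelets <- function(fmin = 3, fmax = 50, df = 0.5, fs = 1000,
                          cycles = c(3, 10)) {
  if (fmax >= fs / 2) stopf("fmax must be below the Nyquist frequency fs/2")
  if (fmin <= 0 || df <= 0 || fmax < fmin) stopf("invalid frequency grid")
  freqs <- seq(fmin, fmax, by = df)
  cyc <- if (length(cycles) == 1L) rep(cycles, length(freqs))
         else seq(cycles[1], cycles[2], length.out = length(freqs))
  kernels <- vector("list", length(freqs))
  halfW <- numeric(length(freqs))
  for (i in seq_along(freqs)) {
    sigT <- cyc[i] / (2 * pi * freqs[i])            # seconds
    half <- ceiling(3.5 * sigT * fs)
    tt <- (-half:half) / fs
    w <- exp(2i * pi * freqs[i] * tt) * exp(-tt^2 / (2 * sigT^2))
    kernels[[i]] <- w / sqrt(sum(Mod(w)^2))
    halfW[i] <- half * 1000 / fs
  }
  new("WaveletFamily", frequencies = freqs, cycles = cyc, fs = fs,
      kernels = kernels, halfWidthMs = halfW)
}

# Frequency-domain bank of wrapped kernels: kernel centre placed at index 1
# so the circular convolution output is aligned with the input samples.
# Returns an nfft x nfreq complex matrix.
kernelBank <- function(wavelets, nfft) {
  K <- matrix(0 + 0i, nfft, length(wavelets@kernels))
  for (i in seq_along(wavelets@kernels)) {
    w <- wavelets@kernels[[i]]
    L <- length(w); c0 <- (L + 1) / 2
    kp <- complex(nfft)
    kp[1:(L - c0 + 1)] <- w[c0:L]
    kp[(nfft - c0 + 2):nfft] <- w[1:(c0 - 1)]
    K[, i] <- stats::fft(kp)
  }
  K
}

# Wavelet power of the rows of `dat` (trials x samples) at the sample
# indices `outIdx`. Returns freq x out x trials array.
waveletPower <- function(dat, K, nfft, outIdx) {
  nTrial <- nrow(dat); ns <- ncol(dat)
  out <- array(NA_real_, c(ncol(K), length(outIdx), nTrial))
  pad <- complex(nfft)
  for (tr in seq_len(nTrial)) {
    x <- pad; x[seq_len(ns)] <- dat[tr, ]
    X <- stats::fft(x)
    Y <- stats::mvfft(K * X, inverse = TRUE) / nfft
    out[, , tr] <- t(Mod(Y[outIdx, , drop = FALSE])^2)
  }
  out
}

#' Single-trial wavelet power of an epoch set
#'
#' Convolves every trial with every wavelet (frequency-domain
#' multiplication) and returns squared magnitudes over the epoch's analysis
#' span, together with each trial's mean baseline power per frequency
#' (computed from the attached fixation baseline segment). Frequencies whose
#' kernel half-width exceeds the epoch's edge pad would return
#' edge-contaminated samples inside the span; this is an error.
#'
#' @param epochs an \linkS4class{EpochSet}.
#' @param wavelets a \linkS4class{WaveletFamily}.
#' @param timeStep optional output time step (ms); \code{NULL} keeps every
#'   sample. Decimating the time axis (wavelet power is smooth at the
#'   sigma_t scale) keeps master arrays small.
#' @return a \linkS4class{TFArray} with raw power.
#' @export
tfPower <- function(epochs, wavelets, timeStep = NULL) {
  stopifnot(is(epochs, "EpochSet"), is(wavelets, "WaveletFamily"))
  fs <- epochs@fs
  if (abs(fs - wavelets@fs) > 1e-9)
    stopf("sampling-rate mismatch between epochs and wavelets")
  padLeft <- epochs@span[1] - epochs@time[1]
  padRight <- epochs@time[length(epochs@time)] - epochs@span[2]
  bad <- wavelets@halfWidthMs > min(padLeft, padRight) + 1e-9
  if (any(bad))
    stopf("analysis window overlaps edge-contaminated samples for %d wavelet(s) (lowest: %g Hz); increase the epoch pad",
          sum(bad), min(wavelets@frequencies[bad]))
  blPadLeft <- epochs@baselineSpan[1] - epochs@baselineTime[1]
  blPadRight <- epochs@baselineTime[length(epochs@baselineTime)] -
    epochs@baselineSpan[2]
  if (any(wavelets@halfWidthMs > min(blPadLeft, blPadRight) + 1e-9))
    stopf("baseline segment pad too small for the lowest-frequency wavelets")
  dt <- 1000 / fs
  step <- if (is.null(timeStep)) dt else timeStep
  tOut <- seq(epochs@span[1], epochs@span[2], by = step)
  outIdx <- round((tOut - epochs@time[1]) / dt) + 1
  maxLen <- max(lengths(wavelets@kernels))
  nfft <- stats::nextn(ncol(epochs@data) + maxLen, 2)
  K <- kernelBank(wavelets, nfft)
  pow <- waveletPower(epochs@data, K, nfft, outIdx)
  blT <- epochs@baselineTime
  blSel <- which(blT >= epochs@baselineSpan[1] & blT <= epochs@baselineSpan[2])
  nfftB <- stats::nextn(ncol(epochs@baseline) + maxLen, 2)
  KB <- if (nfftB == nfft) K else kernelBank(wavelets, nfftB)
  blPow <- waveletPower(epochs@baseline, KB, nfftB, blSel)
  blMean <- apply(blPow, c(1, 3), mean)
  new("TFArray", power = pow, freq = wavelets@frequencies, time = tOut,
      lockEvent = epochs@lockEvent, units = "raw",
      baselinePower = blMean, baselineMode = "none", info = epochs@info)
}

#' Decibel baseline normalization
#'
#' dB(f, t, trial) = 10 log10( P(f, t, trial) / B(f, trial) ), with B the
#' mean baseline power of the same trial at the same frequency
#' (\code{mode = "trial"}, the default) or the trial-averaged baseline
#' (\code{mode = "average"}).
#'
#' @param tf a raw-power \linkS4class{TFArray} (from [tfPower()]).
#' @param mode \code{"trial"} or \code{"average"}.
#' @return a dB-units \linkS4class{TFArray}.
#' @export
dbNormalize <- function(tf, mode = c("trial", "average")) {
  stopifnot(is(tf, "TFArray"))
  mode <- match.arg(mode)
  if (tf@units != "raw") stopf("tf is already normalized")
  B <- tf@baselinePower
  if (any(!is.finite(B)) || any(B <= 0))
    stopf("baseline power must be strictly positive")
  if (mode == "average") B <- matrix(rowMeans(B), nrow(B), ncol(B))
  d <- dim(tf@power)
  denom <- aperm(array(B, c(d[1], d[3], d[2])), c(1, 3, 2))
  out <- tf
  out@power <- 10 * log10(tf@power / denom)
  out@units <- "dB"
  out@baselineMode <- mode
  out
}

#' Invert dB normalization back to raw power
#'
#' @param tf a dB-units \linkS4class{TFArray} produced by [dbNormalize()].
#' @return the raw-power \linkS4class{TFArray}.
#' @export
dbDenormalize <- function(tf) {
  stopifnot(is(tf, "TFArray"))
  if (tf@units != "dB") stopf("tf is not in dB units")
  B <- tf@baselinePower
  if (tf@baselineMode == "average") B <- matrix(rowMeans(B), nrow(B), ncol(B))
  d <- dim(tf@power)
  denom <- aperm(array(B, c(d[1], d[3], d[2])), c(1, 3, 2))
  out <- tf
  out@power <- 10^(tf@power / 10) * denom
  out@units <- "raw"
  out@baselineMode <- "none"
  out
}

#' Event-related spectral perturbation map
#'
#' Arithmetic mean over (a subset of) trials of a dB-normalized
#' time-frequency array.
#'
#' @param tf a dB-units \linkS4class{TFArray}.
#' @param trials optional integer or logical trial subset (e.g. a group or
#'   condition mask over \code{trialInfo(tf)}); default all trials.
#' @return freq x time matrix of mean dB power change.
#' @export
erspMap <- function(tf, trials = NULL) {
  stopifnot(is(tf, "TFArray"))
  d <- dim(tf@power)
  sel <- if (is.null(trials)) seq_len(d[3]) else seq_len(d[3])[trials]
  if (!length(sel) || anyNA(sel)) stopf("empty or invalid trial subset")
  m <- rowMeans(matrix(tf@power[, , sel, drop = FALSE], d[1] * d[2],
                       length(sel)))
  matrix(m, d[1], d[2], dimnames = list(NULL, NULL))
}
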