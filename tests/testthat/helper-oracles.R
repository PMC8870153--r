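# Independent brute-force oracles used to validate the package's
# implementations, deliberately written with naive loops / direct formulas.

# Exhaustive BFS flood fill with 8-connectivity; labels assigned in
# row-major discovery order (matches the contract of findClusters).
bfFloodFill <- function(mask) {
  nr <- nrow(mask); nc <- ncol(mask)
  lab <- matrix(0L, nr, nc); cur <- 0L
  for (ii in seq_len(nr)) for (jj in seq_len(nc)) {
    if (!mask[ii, jj] || lab[ii, jj] != 0L) next
    cur <- cur + 1L
    queue <- list(c(ii, jj)); lab[ii, jj] <- cur
    while (length(queue)) {
      p <- queue[[1]]; queue <- queue[-1]
      for (dr in -1:1) for (dc in -1:1) {
        r <- p[1] + dr; cc <- p[2] + dc
        if (r >= 1 && r <= nr && cc >= 1 && cc <= nc &&
            mask[r, cc] && lab[r, cc] == 0L) {
          lab[r, cc] <- cur
          queue[[length(queue) + 1L]] <- c(r, cc)
        }
      }
    }
  }
  lab
}

# Naive per-pixel pooled-variance two-sample t.
bfTMap <- function(x, gA) {
  d <- dim(x)
  tm <- matrix(0, d[1], d[2])
  for (i in seq_len(d[1])) for (j in seq_len(d[2])) {
    a <- x[i, j, gA]; b <- x[i, j, !gA]
    na <- length(a); nb <- length(b)
    sp <- sqrt(((na - 1) * var(a) + (nb - 1) * var(b)) / (na + nb - 2))
    tm[i, j] <- (mean(a) - mean(b)) / (sp * sqrt(1 / na + 1 / nb))
  }
  tm
}

# Cluster masses (sum of |t|) from a label matrix, ordered by label id.
bfMasses <- function(tMap, lab) {
  k <- max(lab)
  vapply(seq_len(k), function(i) sum(abs(tMap)[lab == i]), numeric(1))
}

# Hann-tapered periodogram band-power change (dB) between two equal-length
# within-trial segments, averaged over trials; independent of the wavelet
# code path. The taper keeps out-of-band sidelobe leakage well below the
# smallest measured suppression.
welchBandChange <- function(trialsEEG, roi, band, window, controlStart,
                            fs = 1000) {
  len <- diff(window)
  control <- c(controlStart, controlStart + len)
  # shrink the measured band by the Hann main-lobe half-width (2 bins) so
  # cross-edge smearing does not contaminate the band estimate
  margin <- 2 * fs / (len * fs / 1000)
  bandPow <- function(x) {
    n <- length(x)
    h <- 0.5 - 0.5 * cos(2 * pi * seq_len(n) / (n + 1))
    P <- Mod(fft(x * h))^2 / sum(h^2)
    f <- (seq_len(n) - 1) * fs / n
    mean(P[f >= band[1] + margin & f <= band[2] - margin])
  }
  w <- vapply(trialsEEG, function(tr) {
    c(bandPow(tr$series[tr$time >= window[1] & tr$time < window[2], roi]),
      bandPow(tr$series[tr$time >= control[1] & tr$time < control[2], roi]))
  }, numeric(2))
  10 * log10(mean(w[1, ]) / mean(w[2, ]))
}

# Closed-form first-order partial correlation.
partialCorrClosed <- function(x, y, z) {
  rxy <- cor(x, y); rxz <- cor(x, z); ryz <- cor(y, z)
  (rxy - rxz * ryz) / sqrt((1 - rxz^2) * (1 - ryz^2))
}

# Build a minimal EpochSet from a trials x samples signal matrix (test
# fixture helper, not an oracle). The baseline reuses the leading samples.
toyEpochSet <- function(dat, fs = 1000, pad = 700, blLen = 200) {
  n <- ncol(dat)
  time <- seq_len(n) * 1000 / fs
  span <- c(time[1] + pad, time[n] - pad)
  nb <- round((blLen + 2 * pad) * fs / 1000) + 1L
  blTime <- time[seq_len(nb)]
  methods::new("EpochSet", roi = "TEST", data = dat, time = time,
               span = span, fs = fs, lockEvent = "motion_onset",
               baseline = dat[, seq_len(nb), drop = FALSE],
               baselineTime = blTime,
               baselineSpan = c(blTime[1] + pad, blTime[nb] - pad),
               info = data.frame(trial = seq_len(nrow(dat))),
               skipped = integer(0))
}
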