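# Morlet wavelet family, TF decomposition and dB baseline normalization.

test_that("the default family spans 3-50 Hz in 0.5 Hz steps (95 wavelets)", {
  wl <- buildWavelets()
  expect_equal(length(wl@frequencies), 95)
  expect_equal(wl@frequencies, seq(3, 50, by = 0.5))
  expect_true(all(diff(wl@frequencies) == 0.5))
  expect_equal(length(buildWavelets(3, 3, 0.5)@frequencies), 1)
  expect_error(buildWavelets(fmax = 600, fs = 1000), "Nyquist")
})

test_that("kernel spectra peak at the nominal frequency within one FFT bin", {
  wl <- buildWavelets()
  nfft <- 2^14
  for (i in seq(1, 95, by = 9)) {
    w <- wl@kernels[[i]]
    S <- Mod(fft(c(w, rep(0, nfft - length(w)))))
    fpk <- (which.max(S) - 1) * wl@fs / nfft
    expect_lt(abs(fpk - wl@frequencies[i]), wl@fs / nfft + 1e-9)
  }
})

test_that("the Gaussian envelope has the closed-form FWHM", {
  wl <- buildWavelets(10, 10, 0.5, fs = 1000, cycles = 5)
  env <- Mod(wl@kernels[[1]])
  half <- max(env) / 2
  width <- sum(env >= half) / 1000           # seconds
  fwhm <- (5 / 10) * (2 * sqrt(2 * log(2)) / (2 * pi))
  expect_lt(abs(width - fwhm), 0.002)
})

test_that("a pure sinusoid localizes at its own frequency row", {
  tt <- seq_len(3000) / 1000
  x1 <- matrix(sin(2 * pi * 20 * tt), 1)
  x2 <- matrix(2 * sin(2 * pi * 20 * tt), 1)
  ep <- toyEpochSet(rbind(x1, x2))
  wl <- buildWavelets(10, 30, 1)
  tf <- tfPower(ep, wl)
  mid <- which.min(abs(tfTime(tf) - 1500))
  expect_equal(tfFreq(tf)[which.max(tf@power[, mid, 1])], 20)
  # doubling the amplitude quadruples the power
  expect_equal(tf@power[11, mid, 2] / tf@power[11, mid, 1], 4,
               tolerance = 1e-6)
})

test_that("white noise yields flat expected power (periodogram oracle)", {
  set.seed(42)
  dat <- matrix(rnorm(60 * 3000), 60)
  ep <- toyEpochSet(dat)
  wl <- buildWavelets(5, 45, 2.5)
  tf <- tfPower(ep, wl, timeStep = 25)
  perFreq <- apply(tf@power, 1, mean)
  # oracle: mean periodogram power of unit white noise = its variance
  oracle <- mean(apply(dat, 1, var))
  expect_true(all(abs(perFreq - oracle) / oracle < 0.1))
})

test_that("edge-contaminated analysis windows are refused", {
  ep <- toyEpochSet(matrix(rnorm(2 * 2000), 2), pad = 150)
  expect_error(tfPower(ep, buildWavelets(3, 10, 1)), "edge")
  expect_silent({                       # high frequencies have short kernels
    tf <- tfPower(ep, buildWavelets(30, 40, 5))
  })
})

test_that("dB normalization matches its closed forms and inverts", {
  base <- matrix(c(2, 5), 1)            # 1 freq x 2 trials
  pw <- array(c(2, 10 * 2, 0.5 * 2, 5, 10 * 5, 0.5 * 5), c(1, 3, 2))
  tf <- new("TFArray", power = aperm(pw, c(1, 2, 3)), freq = 5,
            time = c(0, 10, 20), lockEvent = "motion_onset", units = "raw",
            baselinePower = base, baselineMode = "none",
            info = data.frame(trial = 1:2))
  db <- dbNormalize(tf)
  expect_equal(db@power[1, , 1], c(0, 10, 10 * log10(0.5)), tolerance = 1e-9)
  expect_equal(db@power[1, 3, 2], -3.0103, tolerance = 1e-4)
  raw <- dbDenormalize(db)
  expect_equal(raw@power, tf@power, tolerance = 1e-12)
  expect_error(dbNormalize(db), "already")
  tf@baselinePower[1, 1] <- 0
  expect_error(dbNormalize(tf), "positive")
})

test_that("trial-average baseline mode uses a common denominator", {
  base <- matrix(c(1, 3), 1)
  tf <- new("TFArray", power = array(2, c(1, 1, 2)), freq = 5, time = 0,
            lockEvent = "motion_onset", units = "raw", baselinePower = base,
            baselineMode = "none", info = data.frame(trial = 1:2))
  db <- dbNormalize(tf, mode = "average")
  expect_equal(db@power[1, 1, 1], db@power[1, 1, 2])
  expect_equal(db@power[1, 1, 1], 10 * log10(2 / 2))
})

test_that("ERSP maps are trial means with subset support", {
  pw <- array(rnorm(4 * 5 * 6), c(4, 5, 6))
  tf <- new("TFArray", power = pw, freq = 1:4, time = 1:5,
            lockEvent = "motion_onset", units = "dB",
            baselinePower = matrix(1, 4, 6), baselineMode = "trial",
            info = data.frame(trial = 1:6))
  expect_equal(erspMap(tf, 3), pw[, , 3], ignore_attr = TRUE)
  expect_equal(erspMap(tf), apply(pw, c(1, 2), mean), ignore_attr = TRUE)
  expect_error(erspMap(tf, rep(FALSE, 6)), "empty")
})

test_that("injected deltas are recovered per band through the pipeline", {
  # dB change against a seed-paired null run, measured on each band's
  # interior (clear of the Morlet spectral/temporal smearing at the edges)
  bands <- list(theta = list(band = c(3.5, 7.5), fam = c(4, 7, 0.5, 5),
                             interior = c(4, 5.6), tsel = c(48, 252),
                             delta = -5),
                alpha = list(band = c(7.5, 12.5), fam = c(8, 12, 0.5, 9),
                             interior = c(9.4, 10.6), tsel = c(8, 292),
                             delta = 3),
                beta = list(band = c(12.5, 30), fam = c(13, 29.5, 0.5, 9),
                            interior = c(16.2, 25.8), tsel = c(-126, 426),
                            delta = -6),
                gamma = list(band = c(30, 50), fam = c(30, 50, 1, 9),
                             interior = c(37.5, 50), tsel = c(-248, 548),
                             delta = -10))
  nullCfg <- eegGenConfig(rois = "RSFG")
  tNull <- lapply(1:150, function(i)
    synthesizeTrial(nullCfg, list(type = "go", ssd = NA), "A", seed = 40000 + i))
  for (nm in names(bands)) {
    b <- bands[[nm]]
    cfg <- eegGenConfig(rois = "RSFG",
                        effects = erspEffect("RSFG", b$band, c(-400, 700),
                                             b$delta))
    tEff <- lapply(1:150, function(i)
      synthesizeTrial(cfg, list(type = "go", ssd = NA), "A", seed = 40000 + i))
    wl <- buildWavelets(b$fam[1], b$fam[2], b$fam[3], cycles = b$fam[4])
    getMap <- function(tE) {
      ep <- makeEpochs(tE, "RSFG", "motion_onset", c(-500, 800), padMs = 700)
      tf <- dbNormalize(tfPower(ep, wl, timeStep = 25))
      list(m = erspMap(tf), f = tfFreq(tf), t = tfTime(tf))
    }
    me <- getMap(tEff); m0 <- getMap(tNull)
    fs <- me$f >= b$interior[1] & me$f <= b$interior[2]
    ts <- me$t >= b$tsel[1] & me$t <= b$tsel[2]
    rec <- mean(me$m[fs, ts] - m0$m[fs, ts])
    expect_lt(abs(rec - b$delta), 0.5, label = sprintf("%s recovery %0.2f", nm, rec))
  }
})

test_that("null group differences vanish across all band cells", {
  cfg <- eegGenConfig(rois = "RSFG")
  gen <- function(s0) lapply(1:100, function(i)
    synthesizeTrial(cfg, list(type = "go", ssd = NA), "A", seed = s0 + i))
  info <- data.frame(group = rep(c("A", "B"), each = 100))
  ep <- makeEpochs(c(gen(0), gen(70000)), "RSFG", "motion_onset",
                   c(-500, 1000), info = info)
  tf <- dbNormalize(tfPower(ep, buildWavelets(), timeStep = 50))
  dd <- erspMap(tf, trialInfo(tf)$group == "A") -
    erspMap(tf, trialInfo(tf)$group == "B")
  f <- tfFreq(tf); tt <- tfTime(tf)
  for (b in list(c(3.5, 7.5), c(7.5, 12.5), c(12.5, 30), c(30, 50)))
    for (w in list(c(-500, 0), c(0, 1000))) {
      cell <- mean(dd[f >= b[1] & f <= b[2], tt >= w[1] & tt <= w[2]])
      expect_lt(abs(cell), 0.5)
    }
})
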