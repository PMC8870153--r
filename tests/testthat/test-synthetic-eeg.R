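# Synthetic source-EEG generator: spectral shape, effect injection,
# epoching and cohort construction.

nullTrial <- list(type = "go", ssd = NA_real_)

test_that("background spectrum follows the configured 1/f exponent", {
  cfg <- eegGenConfig(rois = "RSFG", bgVariance = 1,
                      oscillators = data.frame(low = numeric(0),
                                               high = numeric(0),
                                               amplitude = numeric(0)),
                      spanMs = c(0, 60000))
  tr <- synthesizeTrial(cfg, nullTrial, seed = 21)
  x <- tr$series[, 1]
  n <- length(x)
  P <- Mod(fft(x))^2 / n
  f <- (seq_len(n) - 1) * 1000 / n
  sel <- f >= 2 & f <= 80
  # bin-average the periodogram in log-f before fitting the slope
  bins <- cut(log10(f[sel]), 30)
  lp <- tapply(log10(P[sel]), bins, mean)
  lf <- tapply(log10(f[sel]), bins, mean)
  slope <- coef(lm(lp ~ lf))[2]
  expect_lt(abs(slope - (-1)), 0.15)
})

test_that("injected dB effects are linear in the requested delta (Welch oracle)", {
  for (delta in c(-10, -3, 0, 3)) {
    cfg <- eegGenConfig(rois = "RSFG",
                        effects = erspEffect("RSFG", c(30, 50), c(0, 800), delta))
    tE <- lapply(1:120, function(i)
      synthesizeTrial(cfg, nullTrial, "A", seed = 100 * delta + i))
    got <- welchBandChange(tE, "RSFG", c(30, 50), c(100, 700), -800)
    expect_lt(abs(got - delta), 0.5)
  }
})

test_that("disjoint effects act independently per band", {
  cfg <- eegGenConfig(rois = "RSFG",
                      effects = rbind(
                        erspEffect("RSFG", c(30, 50), c(-800, 0), -6),
                        erspEffect("RSFG", c(12.5, 30), c(200, 1000), 3)))
  tE <- lapply(1:120, function(i) synthesizeTrial(cfg, nullTrial, "A", seed = i))
  expect_lt(abs(welchBandChange(tE, "RSFG", c(30, 50), c(-740, -60),
                                -1700) - (-6)), 0.5)
  expect_lt(abs(welchBandChange(tE, "RSFG", c(12.5, 30), c(260, 940),
                                -1700) - 3), 0.5)
  # each band is untouched in the other's window
  expect_lt(abs(welchBandChange(tE, "RSFG", c(30, 50), c(260, 940),
                                -1700)), 0.5)
  expect_lt(abs(welchBandChange(tE, "RSFG", c(12.5, 30), c(-740, -60),
                                -1700)), 0.5)
})

test_that("stop-locked effects follow the trial's SSD and skip go trials", {
  cfg <- eegGenConfig(rois = "RSFG",
                      effects = erspEffect("RSFG", c(30, 50), c(0, 800), -8,
                                           lock = "stop_signal"))
  stopTrial <- list(type = "stop", ssd = 600)
  tE <- lapply(1:100, function(i) synthesizeTrial(cfg, stopTrial, "A", seed = i))
  expect_lt(abs(welchBandChange(tE, "RSFG", c(30, 50), c(700, 1300),
                                -800) - (-8)), 0.6)
  tG <- lapply(1:50, function(i) synthesizeTrial(cfg, nullTrial, "A", seed = i))
  expect_lt(abs(welchBandChange(tG, "RSFG", c(30, 50), c(700, 1300),
                                -800)), 0.5)
})

test_that("effect windows outside the generated span are rejected", {
  cfg <- eegGenConfig(rois = "RSFG",
                      effects = erspEffect("RSFG", c(30, 50), c(2000, 2500), -5))
  expect_error(synthesizeTrial(cfg, nullTrial, "A", seed = 1), "configuration")
})

test_that("epoching cuts the right trials, spans and baselines", {
  cfg <- eegGenConfig(rois = c("RSFG", "RMFG"))
  types <- c("go", "stop", "go", "stop", "go", "go")
  ssds <- c(NA, 500, NA, 650, NA, NA)
  tE <- lapply(1:6, function(i)
    synthesizeTrial(cfg, list(type = types[i], ssd = ssds[i]), "A", seed = i))
  info <- data.frame(type = types)
  epM <- makeEpochs(tE, "RSFG", "motion_onset", c(-500, 1000), info = info)
  expect_equal(nrow(epochData(epM)), 6)
  expect_equal(length(epM@skipped), 0)
  expect_message(epS <- makeEpochs(tE, "RSFG", "stop_signal", c(-500, 800),
                                   info = info), "skipped 4")
  expect_equal(nrow(epochData(epS)), 2)
  expect_true(all(trialInfo(epS)$type == "stop"))
  # relative time axes and baseline length contract
  expect_equal(epM@span, c(-500, 1000))
  expect_equal(diff(epM@baselineSpan), 200)
  expect_error(makeEpochs(tE, "RSFG", "motion_onset", c(-500, 2500)),
               "beyond generated samples")
})

test_that("epoch rows and metadata permute together", {
  cfg <- eegGenConfig(rois = "RSFG")
  tE <- lapply(1:8, function(i) synthesizeTrial(cfg, nullTrial, "A", seed = i))
  info <- data.frame(id = sprintf("t%d", 1:8))
  ep1 <- makeEpochs(tE, "RSFG", "motion_onset", c(-300, 300), info = info)
  prm <- c(5, 3, 8, 1, 2, 7, 4, 6)
  ep2 <- makeEpochs(tE[prm], "RSFG", "motion_onset", c(-300, 300),
                    info = info[prm, , drop = FALSE])
  expect_identical(epochData(ep2), epochData(ep1)[prm, ])
  expect_identical(trialInfo(ep2)$id, trialInfo(ep1)$id[prm])
  expect_identical(baselineData(ep2), baselineData(ep1)[prm, ])
})

test_that("clinical cohorts match the studied marginals and linkage", {
  d <- generateClinicalCohort(400, seed = 5)
  expect_true(all(d$age >= 10 & d$age <= 17))
  expect_lt(abs(mean(d$age) - 13.3), 0.5)
  expect_lt(abs(mean(d$ygtss_total_tic) - 23.4), 1.5)
  expect_true(all(d$ygtss_total_tic >= 0 & d$ygtss_total_tic <= 50))
  expect_true(all(d$puts_item10 %in% 1:4))
  # linked effect sizes correlate with tic severity as requested
  dl <- generateClinicalCohort(2000, seed = 6,
                               linkage = list(r = 0.66, deltaMean = -10,
                                              deltaSd = 3))
  expect_lt(abs(cor(dl$trueDelta, dl$ygtss_total_tic) - 0.66), 0.05)
  expect_error(generateClinicalCohort(1, seed = 1), "n >= 2")
  expect_error(generateClinicalCohort(10, 1,
                                      linkage = list(r = 1.2, deltaMean = 0,
                                                     deltaSd = 1)),
               "degenerate")
})

test_that("null-linkage cohorts carry no EEG/severity association", {
  rs <- vapply(1:100, function(i) {
    d <- generateClinicalCohort(14, seed = i,
                                linkage = list(r = 0, deltaMean = -10,
                                               deltaSd = 3))
    partialCorr(d$trueDelta, d$ygtss_total_tic, d$age)$r
  }, numeric(1))
  expect_lt(abs(mean(rs)), 0.05)
})

test_that("cohorts pool subjects' epochs with aligned metadata", {
  ck <- buildCohort(2, 2, taskConfig(nBlocks = 1, trialsPerBlock = 6),
                    eegGenConfig(rois = "RSFG"), seed = 3,
                    lockEvents = "motion_onset")
  expect_equal(nrow(ck$clinical), 4)
  expect_equal(sort(unique(ck$clinical$diagnosis)), c("CTD", "HC"))
  ep <- ck$epochs$RSFG$motion_onset
  expect_equal(nrow(epochData(ep)), 4 * 6)
  expect_equal(unname(table(trialInfo(ep)$group)), c(12L, 12L),
               ignore_attr = TRUE)
  expect_error(buildCohort(1, 5, seed = 1), "at least 2")
})
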