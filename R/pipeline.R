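# End-to-end orchestration: simulate -> decompose -> cluster-test ->
# correlate, with seeded determinism, cached intermediates and a
# reduced-scale self-validation suite.

#' Default demonstration effects
#'
#' A qualitative analogue of the studied group contrast: both groups show
#' gamma-band event-related desynchronization around motion onset in all
#' three right-frontal ROIs, the case group (A) shows additional ERD
#' (gamma in RSFG and RMFG; theta through gamma in RIFG, beta ERS in RMFG),
#' and both groups show theta/alpha ERS after the stop signal with no group
#' difference.
#'
#' @return effects data.frame (see [erspEffect()]).
#' @export
demoEffects <- function() {
  rbind(
    erspEffect("RSFG", c(30, 50), c(-100, 300), -3, group = "both"),
    erspEffect("RMFG", c(30, 50), c(-100, 300), -3, group = "both"),
    erspEffect("RIFG", c(30, 50), c(-100, 300), -3, group = "both"),
    erspEffect("RSFG", c(30, 50), c(-100, 300), -4, group = "A"),
    erspEffect("RMFG", c(30, 50), c(-100, 300), -3, group = "A"),
    erspEffect("RMFG", c(12.5, 30), c(0, 300), 2, group = "A"),
    erspEffect("RIFG", c(3.5, 7.5), c(0, 300), -2, group = "A"),
    erspEffect("RIFG", c(7.5, 12.5), c(0, 300), -2, group = "A"),
    erspEffect("RIFG", c(12.5, 30), c(0, 300), -2, group = "A"),
    erspEffect("RIFG", c(30, 50), c(-100, 300), -3, group = "A"),
    erspEffect("RSFG", c(3.5, 12.5), c(0, 400), 3, lock = "stop_signal"),
    erspEffect("RMFG", c(3.5, 12.5), c(0, 400), 3, lock = "stop_signal"),
    erspEffect("RIFG", c(3.5, 12.5), c(0, 400), 3, lock = "stop_signal"))
}

#' Assemble a pipeline run configuration
#'
#' Bundles every knob of the end-to-end run: cohort sizes, task and subject
#' models, generator configuration, wavelet family, epoch spans, statistical
#' analysis windows and permutation-test parameters. All stages derive
#' their randomness from \code{seed}.
#'
#' @param seed master integer seed.
#' @param nA,nB subjects per group (A = cases, B = controls).
#' @param taskCfg,subjectA,subjectB,eegCfg component configurations.
#' @param wavelets list(fmin, fmax, df, cycles) for [buildWavelets()].
#' @param epochSpans named list of epoch spans (ms) per lock event.
#' @param windows named list of statistical analysis windows (ms) per lock
#'   event. The motion-locked window 0-300 ms is the pre-stop-signal
#'   preparation period: the stop cue can only appear from 300 ms on, so
#'   earlier samples are uncontaminated by trial type.
#' @param nPerm,pixelAlpha,alpha,nRois permutation-test parameters
#'   (\code{nRois} defaults to the number of configured ROIs).
#' @param timeStep time decimation of the master arrays (ms).
#' @param linkage optional per-subject effect/severity linkage (see
#'   [buildCohort()]).
#' @param scales clinical scales entering the power correlations.
#' @return a validated configuration list of class \code{"pipelineConfig"}.
#' @export
pipelineConfig <- function(seed = 1, nA = 14, nB = 13,
                           taskCfg = taskConfig(),
                           subjectA = subjectModel(),
                           subjectB = subjectModel(goMu = 793, goSigma = 23),
                           eegCfg = eegGenConfig(effects = demoEffects()),
                           wavelets = list(fmin = 3, fmax = 50, df = 0.5,
                                           cycles = c(3, 10)),
                           epochSpans = list(motion_onset = c(-500, 1000),
                                             stop_signal = c(-500, 800)),
                           windows = list(motion_onset = c(0, 300),
                                          stop_signal = c(0, 500)),
                           nPerm = 1000, pixelAlpha = 0.05, alpha = 0.05,
                           nRois = length(eegCfg@rois), timeStep = 10,
                           linkage = NULL,
                           scales = c("ygtss_total_tic", "cybocs",
                                      "dupaul_adhd")) {
  validObject(taskCfg); validObject(subjectA); validObject(subjectB)
  validObject(eegCfg)
  if (nA < 2 || nB < 2) stopf("need at least 2 subjects per group")
  cfg <- list(seed = seed, nA = nA, nB = nB, taskCfg = taskCfg,
              subjectA = subjectA, subjectB = subjectB, eegCfg = eegCfg,
              wavelets = wavelets, epochSpans = epochSpans,
              windows = windows, nPerm = nPerm, pixelAlpha = pixelAlpha,
              alpha = alpha, nRois = nRois, timeStep = timeStep,
              linkage = linkage, scales = scales)
  class(cfg) <- "pipelineConfig"
  cfg
}

# Serialize a pipelineConfig to JSON (for provenance + hashing).
configJson <- function(cfg) {
  ser <- function(x) {
    if (isVirtualClass(class(x)) || !isS4(x)) return(x)
    sl <- methods::slotNames(class(x))
    stats::setNames(lapply(sl, function(s) methods::slot(x, s)), sl)
  }
  lst <- lapply(cfg, function(x) if (isS4(x)) ser(x) else x)
  jsonlite::toJSON(lst, auto_unbox = TRUE, digits = 10, dataframe = "columns",
                   null = "null")
}

# Re-throw any stage error with a stage-tagged message.
inStage <- function(stage, expr) {
  tryCatch(expr, error = function(e)
    stopf("%s stage: %s", stage, conditionMessage(e)))
}

logLine <- function(con, fmt, ...) {
  msg <- sprintf(fmt, ...)
  writeLines(sprintf("[%s] %s", format(Sys.time(), "%H:%M:%S"), msg), con)
  message(msg)
}

#' Run the full simulate / decompose / test / correlate pipeline
#'
#' Simulates a two-group cohort (sessions, per-trial source EEG, clinical
#' table), decomposes every trial into dB-normalized time-frequency power,
#' runs the trial-pooled permutation cluster-mass test per ROI and lock
#' event over the configured analysis windows, and -- for ROIs with a
#' significant motion-locked case-control difference -- correlates
#' cluster-masked power with the clinical scales (age-adjusted,
#' FDR-corrected) and SSRT with tic suppressibility. All outputs (TSV/CSV
#' tables, JSON provenance, a text report and a log) are written under
#' \code{outDir}; the run is deterministic given the seed.
#'
#' @param cfg a [pipelineConfig()].
#' @param outDir output directory.
#' @param cache cache the dB master arrays under \code{outDir/cache} and
#'   reuse them when re-running (e.g. with different \code{alpha} or
#'   \code{nRois}) without re-simulation.
#' @return invisibly, a list with the clinical table, behavioural
#'   summaries, per-ROI \linkS4class{ClusterResult}s and correlation
#'   tables.
#' @export
runPipeline <- function(cfg, outDir, cache = TRUE) {
  stopifnot(inherits(cfg, "pipelineConfig"))
  dir.create(outDir, showWarnings = FALSE, recursive = TRUE)
  for (d in c("behavior", "tf", "clusters", "correlations"))
    dir.create(file.path(outDir, d), showWarnings = FALSE)
  cj <- configJson(cfg)
  cfgPath <- file.path(outDir, "config.json")
  writeLines(cj, cfgPath)
  cfgHash <- unname(tools::md5sum(cfgPath))
  logCon <- file(file.path(outDir, "run.log"), "w")
  on.exit(close(logCon), add = TRUE)
  logLine(logCon, "pipeline start: seed %d, config %s", cfg$seed, cfgHash)

  rois <- cfg$eegCfg@rois
  locks <- names(cfg$epochSpans)
  cachePath <- file.path(outDir, "cache", "master.rds")
  simulated <- NULL
  if (cache && file.exists(cachePath)) {
    simulated <- readRDS(cachePath)
    logLine(logCon, "simulate/decompose: reused cached master arrays")
  }
  if (is.null(simulated)) {
    simulated <- inStage("simulate/decompose",
                         simulateAndDecompose(cfg, outDir, cfgHash, logCon))
    if (cache) {
      dir.create(file.path(outDir, "cache"), showWarnings = FALSE)
      saveRDS(simulated, cachePath)
    }
  }
  clinical <- simulated$clinical
  utils::write.table(clinical, file.path(outDir, "behavior", "clinical.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  utils::write.table(simulated$behavior,
                     file.path(outDir, "behavior", "behavior_summary.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)

  # --- permutation cluster tests per ROI x lock event -------------------
  clusters <- list(); reportLines <- character(0)
  for (r in rois) for (le in locks) {
    ma <- simulated$master[[r]][[le]]
    cr <- inStage("cluster-test",
                  clusterTest(ma$x, ma$groups, groupA = "A", nPerm = cfg$nPerm,
                              pixelAlpha = cfg$pixelAlpha, nRois = cfg$nRois,
                              alpha = cfg$alpha,
                              seed = deriveSeed(cfg$seed, 7000L +
                                                  match(r, rois) * 10L +
                                                  match(le, locks)),
                              freq = ma$freq, time = ma$time))
    clusters[[r]][[le]] <- cr
    writeClusterResult(cr, file.path(outDir, "clusters"),
                       sprintf("%s_%s", r, le))
    logLine(logCon, "cluster test %s/%s: %d cluster(s), %d significant",
            r, le, length(cr@mass), sum(cr@significant))
    reportLines <- c(reportLines,
                     sprintf("%s (%s): %d significant cluster(s) [mass threshold %.2f]",
                             r, le, sum(cr@significant), cr@massThreshold))
  }

  # --- correlations, gated on a significant case-control difference -----
  corrTables <- list()
  anySig <- FALSE
  for (r in rois) {
    cr <- clusters[[r]][["motion_onset"]]
    if (is.null(cr) || !any(cr@significant)) next
    anySig <- TRUE
    maps <- simulated$subjectMaps[[r]][["motion_onset"]]
    ctdIds <- clinical$id[clinical$diagnosis == "CTD"]
    scal <- inStage("correlate", extractMaskedPower(maps[ctdIds],
                                                    clusterMask(cr)))
    ct <- inStage("correlate",
                  correlateEegClinical(scal, clinical, scales = cfg$scales))
    ct$roi <- r
    corrTables[[r]] <- ct
    utils::write.table(ct, file.path(outDir, "correlations",
                                     sprintf("%s_power_clinical.tsv", r)),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    logLine(logCon, "correlations %s: %d scale(s), %d FDR rejection(s)",
            r, nrow(ct), sum(ct$reject))
  }
  if (!anySig) {
    reportLines <- c(reportLines,
                     "no significant clusters; correlation stage skipped")
    logLine(logCon, "no significant clusters; correlation stage skipped")
  }
  behCorr <- NULL
  if (anySig) {
    beh <- simulated$behavior
    ssrt <- stats::setNames(beh$ssrt[beh$unit == "overall"],
                            beh$subject[beh$unit == "overall"])
    behCorr <- inStage("correlate", behaviorClinicalCorr(ssrt, clinical))
    utils::write.table(behCorr,
                       file.path(outDir, "correlations", "ssrt_suppressibility.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
  }

  writeLines(reportLines, file.path(outDir, "report.txt"))
  prov <- list(seed = cfg$seed, config_md5 = cfgHash,
               package = as.character(utils::packageVersion("stopERSP")),
               n_subjects = cfg$nA + cfg$nB,
               rois = rois, lock_events = locks, n_perm = cfg$nPerm)
  jsonlite::write_json(prov, file.path(outDir, "provenance.json"),
                       auto_unbox = TRUE, digits = NA)
  logLine(logCon, "pipeline done")
  invisible(list(clinical = clinical, behavior = simulated$behavior,
                 clusters = clusters, correlations = corrTables,
                 behaviorCorrelation = behCorr))
}

# Stage 1+2: per-subject simulation and time-frequency decomposition.
# Returns clinical table, behavioural summary, per-ROI/lock master arrays
# (dB, decimated) and per-subject trial-mean maps.
simulateAndDecompose <- function(cfg, outDir, cfgHash, logCon) {
  rois <- cfg$eegCfg@rois
  locks <- names(cfg$epochSpans)
  wl <- do.call(buildWavelets,
                c(cfg$wavelets[c("fmin", "fmax", "df", "cycles")],
                  list(fs = cfg$eegCfg@fs)))
  clinA <- generateClinicalCohort(cfg$nA, deriveSeed(cfg$seed, 1L), "CTD",
                                  linkage = cfg$linkage)
  clinB <- generateClinicalCohort(cfg$nB, deriveSeed(cfg$seed, 2L), "HC")
  if (!is.null(cfg$linkage)) clinB$trueDelta <- NA_real_
  clinical <- rbind(clinA, clinB)
  groups <- rep(c("A", "B"), c(cfg$nA, cfg$nB))
  ids <- clinical$id
  models <- c(rep(list(cfg$subjectA), cfg$nA), rep(list(cfg$subjectB), cfg$nB))
  master <- subjMaps <- lapply(stats::setNames(rois, rois), function(r)
    lapply(stats::setNames(locks, locks), function(le) list()))
  behavior <- list()
  for (s in seq_along(ids)) {
    sSeed <- deriveSeed(cfg$seed, 100L + s)
    trials <- runSession(cfg$taskCfg, models[[s]], sSeed,
                         includePractice = FALSE)
    writeTrialLog(trials,
                  file.path(outDir, "behavior", sprintf("%s_trials.tsv", ids[s])),
                  meta = list(subject = ids[s], seed = sSeed,
                              config = cfgHash))
    bs <- summarizeBehavior(trials)
    bs$subject <- ids[s]; bs$group <- groups[s]
    behavior[[s]] <- bs
    cfgS <- cfg$eegCfg
    if (!is.null(cfg$linkage) && groups[s] == "A") {
      eIdx <- if (is.null(cfg$linkage$effect)) 1L else cfg$linkage$effect
      cfgS@effects$deltaDb[eIdx] <- clinA$trueDelta[s]
    }
    main <- trials[trials$phase == "main", , drop = FALSE]
    tEEG <- lapply(seq_len(nrow(main)), function(i)
      synthesizeTrial(cfgS, main[i, ], group = groups[s],
                      seed = deriveSeed(sSeed, i)))
    info <- data.frame(subject = ids[s], group = groups[s], type = main$type,
                       stringsAsFactors = FALSE)
    for (r in rois) for (le in locks) {
      ep <- suppressMessages(makeEpochs(tEEG, r, le, cfg$epochSpans[[le]],
                                        info = info))
      tf <- dbNormalize(tfPower(ep, wl, timeStep = cfg$timeStep))
      win <- cfg$windows[[le]]
      sel <- tfTime(tf) >= win[1] & tfTime(tf) <= win[2]
      x <- tfValues(tf)[, sel, , drop = FALSE]
      master[[r]][[le]][[s]] <- list(x = x, groups = trialInfo(tf)$group,
                                     time = tfTime(tf)[sel], freq = tfFreq(tf))
      subjMaps[[r]][[le]][[ids[s]]] <-
        rowMeans(x, dims = 2)              # trial-mean freq x time map
    }
    logLine(logCon, "subject %s (%s): %d main trials, %d stop epochs",
            ids[s], groups[s], nrow(main), sum(main$type == "stop"))
  }
  # concatenate per-subject arrays into pooled master arrays
  for (r in rois) for (le in locks) {
    parts <- master[[r]][[le]]
    x <- array(unlist(lapply(parts, `[[`, "x")),
               c(dim(parts[[1]]$x)[1:2], sum(vapply(parts, function(p)
                 dim(p$x)[3], numeric(1)))))
    master[[r]][[le]] <- list(x = x,
                              groups = unlist(lapply(parts, `[[`, "groups")),
                              freq = parts[[1]]$freq, time = parts[[1]]$time)
  }
  list(clinical = clinical, behavior = do.call(rbind, behavior),
       master = master, subjectMaps = subjMaps)
}

#' Reduced-scale self-validation suite
#'
#' Machine-checkable calibration report: type-I rate of the cluster test on
#' exchangeable null arrays, staircase convergence of the stop-success
#' probability, means-method SSRT recovery, injected-dB recovery through
#' the wavelet pipeline, and monotonicity of cluster mass in effect size.
#' Scales are reduced by default so the suite runs at desk scale.
#'
#' @param seed integer seed.
#' @param nDatasets null datasets for the type-I entry.
#' @param nPerm permutations per dataset.
#' @param nSessions task sessions for the staircase/SSRT entries.
#' @param nTrials trials for the dB-recovery entry.
#' @param outPath optional path for a JSON copy of the report.
#' @return list of entries, each with \code{value}, \code{band} (or
#'   \code{tolerance}) and \code{pass}.
#' @export
validateSuite <- function(seed = 1, nDatasets = 100, nPerm = 200,
                          nSessions = 50, nTrials = 60, outPath = NULL) {
  report <- list()
  # type-I calibration of the familywise cluster test on null data
  hits <- withSeed(deriveSeed(seed, 1L), {
    vapply(seq_len(nDatasets), function(i) {
      x <- array(stats::rnorm(20 * 30 * 40), c(20, 30, 40))
      cr <- clusterTest(x, rep(c("A", "B"), each = 20), nPerm = nPerm,
                        seed = NULL)
      any(cr@significant)
    }, logical(1))
  })
  rate <- mean(hits)
  se <- sqrt(0.017 * 0.983 / nDatasets)
  report$typeI <- list(value = rate, expected = 0.017,
                       band = c(max(0, 0.017 - 0.01 - 2 * se),
                                0.017 + 0.01 + 2 * se))
  report$typeI$pass <- rate >= report$typeI$band[1] &&
    rate <= report$typeI$band[2]
  # staircase convergence and SSRT recovery
  cfg <- taskConfig(); subj <- subjectModel()
  sums <- lapply(seq_len(nSessions), function(i)
    summarizeBehavior(runSession(cfg, subj, deriveSeed(seed, 200L + i),
                                 includePractice = FALSE)))
  pin <- mean(vapply(sums, function(s) s$p_inhibit[s$unit == "overall"],
                     numeric(1)))
  report$staircase <- list(value = pin, expected = 0.5,
                           band = c(0.45, 0.55))
  report$staircase$pass <- pin >= 0.45 && pin <= 0.55
  ssrt <- mean(vapply(sums, function(s) s$ssrt[s$unit == "overall"],
                      numeric(1)))
  report$ssrtRecovery <- list(value = ssrt, expected = subj@ssrtMu,
                              tolerance = 15,
                              pass = abs(ssrt - subj@ssrtMu) <= 15)
  # injected-dB recovery through the wavelet pipeline, measured as the dB
  # change against a seed-paired null run (cancels the single-trial
  # log-power offset) on the band interior (clear of spectral smearing)
  genCfg <- eegGenConfig(rois = "RSFG",
                         effects = erspEffect("RSFG", c(30, 50), c(0, 300), -10))
  nullCfg <- eegGenConfig(rois = "RSFG")
  wl <- buildWavelets(30, 50, 1, genCfg@fs, cycles = 9)
  oneMap <- function(cfg) {
    tEEG <- lapply(seq_len(nTrials), function(i)
      synthesizeTrial(cfg, list(type = "go", ssd = NA), "A",
                      seed = deriveSeed(seed, 400L + i)))
    ep <- makeEpochs(tEEG, "RSFG", "motion_onset", c(-400, 400))
    tf <- dbNormalize(tfPower(ep, wl, timeStep = 10))
    list(map = erspMap(tf), freq = tfFreq(tf), time = tfTime(tf))
  }
  me <- oneMap(genCfg); m0 <- oneMap(nullCfg)
  sel <- me$time >= 60 & me$time <= 240
  fsel <- me$freq >= 36 & me$freq <= 50
  rec <- mean(me$map[fsel, sel] - m0$map[fsel, sel])
  report$deltaRecovery <- list(value = rec, expected = -10, tolerance = 1,
                               pass = abs(rec + 10) <= 1)
  # cluster mass grows with injected effect size
  masses <- vapply(c(-3, -10), function(d) {
    x <- withSeed(deriveSeed(seed, 500L), {
      x <- array(stats::rnorm(20 * 30 * 60), c(20, 30, 60))
      x[5:12, 10:20, 1:30] <- x[5:12, 10:20, 1:30] + d
      x
    })
    obs <- observedStats(x, rep(c("A", "B"), each = 30))
    maxClusterMass(obs$t, stats::qt(0.975, 58))
  }, numeric(1))
  report$powerMonotonic <- list(value = masses, expected = "non-decreasing",
                                pass = masses[2] >= masses[1])
  if (!is.null(outPath))
    jsonlite::write_json(report, outPath, auto_unbox = TRUE, digits = NA)
  report
}
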