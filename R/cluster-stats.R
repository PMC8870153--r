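# Trial-pooled permutation cluster-mass statistic for group differences in
# time-frequency power, with multi-ROI corrected thresholding.

asPixelMatrix <- function(x) {
  d <- dim(x)
  if (length(d) != 3L) stopf("expected a freq x time x trials array")
  list(X = matrix(x, d[1] * d[2], d[3]), nf = d[1], nt = d[2], n = d[3])
}

groupIndicator <- function(labels, groupA = NULL) {
  labels <- as.character(labels)
  lev <- unique(labels)
  if (length(lev) != 2L) stopf("exactly two group labels are required")
  if (is.null(groupA)) groupA <- lev[1]
  if (!groupA %in% lev) stopf("groupA '%s' not among labels", groupA)
  gA <- labels == groupA
  if (sum(gA) < 2L || sum(!gA) < 2L) stopf("need >= 2 trials per group")
  list(gA = gA, groups = c(groupA, setdiff(lev, groupA)))
}

# Pooled-variance two-sample t per pixel, vectorized over pixels. `sumA`,
# `ssqA` may be matrices (pixels x permutations). A small epsilon guards
# zero-variance pixels (t collapses to 0 when the difference is also 0).
pooledT <- function(sumA, ssqA, sumTot, ssqTot, nA, nB) {
  mA <- sumA / nA
  mB <- (sumTot - sumA) / nB
  vA <- (ssqA - nA * mA^2) / (nA - 1)
  vB <- ((ssqTot - ssqA) - nB * mB^2) / (nB - 1)
  sp2 <- ((nA - 1) * vA + (nB - 1) * vB) / (nA + nB - 2)
  sp2[sp2 < 0] <- 0                       # numerical guard
  se <- sqrt(sp2 * (1 / nA + 1 / nB))
  (mA - mB) / pmax(se, 1e-12)
}

#' Observed group-difference and t maps of a master array
#'
#' Pools the trials of both groups into a single master array
#' (frequency x time x trials) and computes, per pixel, the difference of
#' group means and the pooled-variance two-sample t statistic across trials
#' (df = nA + nB - 2).
#'
#' @param x freq x time x trials array (dB-normalized power).
#' @param labels per-trial group labels (exactly two levels).
#' @param groupA which label plays group A in \code{meanA - meanB}
#'   (default: first label encountered).
#' @return list with \code{diff} and \code{t} (freq x time matrices),
#'   \code{df}, \code{nA}, \code{nB}, \code{groups}.
#' @export
observedStats <- function(x, labels, groupA = NULL) {
  p <- asPixelMatrix(x)
  g <- groupIndicator(labels, groupA)
  if (length(g$gA) != p$n) stopf("label count must equal trial count")
  nA <- sum(g$gA); nB <- p$n - nA
  XA <- p$X[, g$gA, drop = FALSE]
  sumA <- rowSums(XA); ssqA <- rowSums(XA^2)
  sumT <- rowSums(p$X); ssqT <- rowSums(p$X^2)
  tv <- pooledT(sumA, ssqA, sumT, ssqT, nA, nB)
  dv <- sumA / nA - (sumT - sumA) / nB
  nzv <- sum(abs(ssqT - sumT^2 / p$n) < 1e-12 * pmax(ssqT, 1))
  if (nzv > 0)
    message(sprintf("observedStats: %d zero-variance pixel(s); epsilon guard applied", nzv))
  list(diff = matrix(dv, p$nf, p$nt), t = matrix(tv, p$nf, p$nt),
       df = nA + nB - 2, nA = nA, nB = nB, groups = g$groups)
}

#' Label connected suprathreshold clusters (8-connectivity)
#'
#' Connected components of a 2-D logical mask in the time-frequency plane,
#' with pixels touching edge- or corner-wise belonging to the same cluster.
#' Labels are assigned in row-major discovery order and are stable.
#'
#' @param mask logical freq x time matrix.
#' @return list with \code{labels} (integer matrix, 0 = background),
#'   \code{n} (cluster count) and \code{sizes} (pixels per cluster).
#' @export
findClusters <- function(mask) {
  stopifnot(is.matrix(mask), is.logical(mask))
  nr <- nrow(mask); nc <- ncol(mask)
  lab <- matrix(0L, nr, nc)
  if (!any(mask)) return(list(labels = lab, n = 0L, sizes = integer(0)))
  ri <- seq_len(nr) + 1L; ci <- seq_len(nc) + 1L
  P <- matrix(Inf, nr + 2L, nc + 2L)
  init <- matrix(Inf, nr, nc)
  init[mask] <- which(mask)
  P[ri, ci] <- init
  bg <- !mask
  # iterative minimum-label propagation over the 8-neighbourhood
  repeat {
    cur <- P[ri, ci]
    nb <- cur
    for (dr in -1:1) for (dc in -1:1) if (dr != 0L || dc != 0L)
      nb <- pmin(nb, P[ri + dr, ci + dc])
    nb[bg] <- Inf
    if (identical(nb, cur)) break
    P[ri, ci] <- nb
  }
  fg <- which(mask)
  comp <- P[ri, ci][fg]
  rw <- ((fg - 1L) %% nr) + 1L
  cl <- ((fg - 1L) %/% nr) + 1L
  ord <- order((rw - 1L) * nc + cl)       # row-major scan order
  uc <- unique(comp[ord])
  lab[fg] <- match(comp, uc)
  list(labels = lab, n = length(uc),
       sizes = tabulate(lab[fg], nbins = length(uc)))
}

# Maximum cluster mass (sum of |t| over a connected suprathreshold cluster)
# of one t map; 0 when no pixel is suprathreshold.
maxClusterMass <- function(tMap, tCrit) {
  mask <- abs(tMap) > tCrit
  if (!any(mask)) return(0)
  fc <- findClusters(mask)
  fg <- which(mask)
  max(rowsum(abs(tMap)[fg], fc$labels[fg]))
}

#' Permutation null distribution of the maximum cluster mass
#'
#' For each permutation the per-trial group labels of the master array are
#' shuffled, the pixel-wise t map recomputed, thresholded at the two-tailed
#' pixel alpha, connected clusters labeled (8-connectivity), and the
#' maximum cluster mass (sum of |t|) recorded -- 0 when no pixel survives.
#' The maximum-statistic summary makes the derived threshold familywise
#' valid over the time-frequency plane. Deterministic given the seed.
#'
#' @param x freq x time x trials array.
#' @param labels per-trial group labels.
#' @param nPerm number of permutations (default 1000; below 100 the upper
#'   percentile is unstable and a warning is issued).
#' @param pixelAlpha two-tailed pixel threshold (default 0.05).
#' @param seed integer seed.
#' @param groupA see [observedStats()].
#' @param pooled if \code{TRUE}, record every cluster mass of every
#'   permutation instead of the per-permutation maximum (non-familywise
#'   variant, off by default).
#' @return numeric vector of null masses (length \code{nPerm}, or ragged
#'   total under \code{pooled}).
#' @export
permutationNull <- function(x, labels, nPerm = 1000, pixelAlpha = 0.05,
                            seed = NULL, groupA = NULL, pooled = FALSE) {
  if (nPerm < 100) warning("nPerm < 100: corrected percentile is unstable")
  p <- asPixelMatrix(x)
  g <- groupIndicator(labels, groupA)
  nA <- sum(g$gA); nB <- p$n - nA
  tCrit <- stats::qt(1 - pixelAlpha / 2, df = nA + nB - 2)
  X <- p$X; X2 <- X^2
  sumT <- rowSums(X); ssqT <- rowSums(X2)
  out <- if (pooled) list() else numeric(nPerm)
  withSeed(seed, {
    done <- 0L
    chunk <- max(1L, min(200L, nPerm))
    while (done < nPerm) {
      m <- min(chunk, nPerm - done)
      Z <- matrix(0, p$n, m)
      for (j in seq_len(m)) Z[sample(p$n, nA), j] <- 1
      tMat <- pooledT(X %*% Z, X2 %*% Z, sumT, ssqT, nA, nB)
      for (j in seq_len(m)) {
        tm <- matrix(tMat[, j], p$nf, p$nt)
        if (pooled) {
          mask <- abs(tm) > tCrit
          out[[done + j]] <- if (!any(mask)) 0 else {
            fc <- findClusters(mask)
            as.numeric(rowsum(abs(tm)[which(mask)], fc$labels[which(mask)]))
          }
        } else out[done + j] <- maxClusterMass(tm, tCrit)
      }
      done <- done + m
    }
  })
  if (pooled) unlist(out) else out
}

#' Multi-ROI corrected cluster-mass threshold
#'
#' The 100 (1 - alpha / nRois) percentile of the permutation null mass
#' distribution (98.3rd percentile for three regions of interest at alpha
#' 0.05), linearly interpolated at position n * p of the sorted masses.
#'
#' @param null numeric null distribution of cluster masses.
#' @param nRois number of regions sharing the correction (default 3).
#' @param alpha familywise alpha (default 0.05).
#' @return list with \code{threshold} and \code{percentile}.
#' @export
correctedThreshold <- function(null, nRois = 3, alpha = 0.05) {
  if (!length(null)) stopf("empty null distribution")
  pr <- alpha / nRois
  if (pr <= 0 || pr >= 1) stopf("alpha/nRois must lie in (0, 1)")
  # threshold at the exact probability 1 - alpha/nRois (position n*p with
  # linear interpolation); the reported percentile is rounded for display
  list(threshold = unname(stats::quantile(null, 1 - pr, type = 4)),
       percentile = round(100 * (1 - pr), 1))
}

#' Identify significant clusters against the permutation null
#'
#' Labels the observed suprathreshold clusters, computes their masses, and
#' marks as significant those whose mass reaches the corrected threshold;
#' per-cluster corrected p is the fraction of null masses at or above the
#' observed mass.
#'
#' @param obs output of [observedStats()] (observed t and difference maps).
#' @param null permutation null masses from [permutationNull()].
#' @param freq,time axis vectors for the maps.
#' @param pixelAlpha two-tailed pixel alpha used for thresholding (must
#'   match the null computation).
#' @param nRois,alpha correction parameters (see [correctedThreshold()]).
#' @param seed seed recorded in the result (provenance only).
#' @return a \linkS4class{ClusterResult}.
#' @export
significantClusters <- function(obs, null, freq = NULL, time = NULL,
                                pixelAlpha = 0.05, nRois = 3, alpha = 0.05,
                                seed = NA_real_) {
  tMap <- obs$t
  if (is.null(freq)) freq <- seq_len(nrow(tMap))
  if (is.null(time)) time <- seq_len(ncol(tMap))
  tCrit <- stats::qt(1 - pixelAlpha / 2, df = obs$df)
  thr <- correctedThreshold(null, nRois = nRois, alpha = alpha)
  mask <- abs(tMap) > tCrit
  fc <- findClusters(mask)
  if (fc$n > 0L) {
    fg <- which(mask)
    mass <- as.numeric(rowsum(abs(tMap)[fg], fc$labels[fg]))
    sig <- mass >= thr$threshold
    pc <- vapply(mass, function(m) mean(null >= m), numeric(1))
  } else {
    mass <- numeric(0); sig <- logical(0); pc <- numeric(0)
  }
  sigMask <- matrix(FALSE, nrow(tMap), ncol(tMap))
  if (any(sig)) sigMask <- matrix(fc$labels %in% which(sig), nrow(tMap), ncol(tMap))
  new("ClusterResult", diffMap = obs$diff, tMap = tMap, freq = freq,
      time = time, pixelThreshold = tCrit, labels = fc$labels, mass = mass,
      nullMasses = null, massThreshold = thr$threshold,
      percentile = thr$percentile, significant = sig, mask = sigMask,
      clusterP = pc, nPerm = length(null), alpha = alpha,
      nRois = as.integer(nRois), seed = seed, groups = obs$groups)
}

#' Run the full permutation cluster-mass test
#'
#' Convenience wrapper: observed statistics, permutation null of the maximum
#' cluster mass, corrected threshold and significant-cluster identification
#' in one call.
#'
#' @inheritParams permutationNull
#' @inheritParams significantClusters
#' @return a \linkS4class{ClusterResult}.
#' @examples
#' x <- array(rnorm(10 * 12 * 40), c(10, 12, 40))
#' cr <- clusterTest(x, rep(c("A", "B"), each = 20), nPerm = 200, seed = 1)
#' @export
clusterTest <- function(x, labels, groupA = NULL, nPerm = 1000,
                        pixelAlpha = 0.05, nRois = 3, alpha = 0.05,
                        seed = NULL, freq = NULL, time = NULL) {
  obs <- observedStats(x, labels, groupA)
  null <- permutationNull(x, labels, nPerm = nPerm, pixelAlpha = pixelAlpha,
                          seed = seed, groupA = groupA)
  significantClusters(obs, null, freq = freq, time = time,
                      pixelAlpha = pixelAlpha, nRois = nRois, alpha = alpha,
                      seed = if (is.null(seed)) NA_real_ else seed)
}

#' Extract cluster-masked mean power per subject
#'
#' Mean dB over the masked pixels of each subject's trial-averaged map --
#' the scalar entering power-versus-clinical-score correlations.
#'
#' @param maps a freq x time x subjects array, or a (possibly named) list
#'   of freq x time matrices.
#' @param mask logical freq x time mask (e.g. [clusterMask()] of a
#'   significant result); must be nonempty and match the map dimensions.
#' @return named numeric vector, one value per subject.
#' @export
extractMaskedPower <- function(maps, mask) {
  stopifnot(is.matrix(mask), is.logical(mask))
  if (!any(mask)) stopf("empty mask")
  if (is.list(maps)) {
    vapply(maps, function(m) {
      if (!all(dim(m) == dim(mask))) stopf("map/mask dimension mismatch")
      mean(m[mask])
    }, numeric(1))
  } else {
    d <- dim(maps)
    if (length(d) != 3L || any(d[1:2] != dim(mask)))
      stopf("map/mask dimension mismatch")
    out <- apply(maps, 3, function(m) mean(m[mask]))
    stats::setNames(out, dimnames(maps)[[3]])
  }
}
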