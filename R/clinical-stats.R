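# Clinical descriptives, age-adjusted (partial) correlations and
# false-discovery-rate correction.

#' Read a clinical table
#'
#' Tab-separated table with one subject per row. The package ships a
#' reference table for a chronic tic disorder cohort (n = 14) under
#' \code{system.file("extdata", "ctd_cohort_clinical.tsv", package =
#' "stopERSP")} with columns \code{participant}, \code{diagnosis},
#' \code{age}, \code{sex}, \code{handedness}, \code{ygtss_total_tic}
#' (Yale Global Tic Severity total tic score), \code{puts_total}
#' (Premonitory Urge for Tics Scale), \code{dupaul_adhd},
#' \code{cybocs} and \code{medications}.
#'
#' @param path file path.
#' @return data.frame.
#' @export
readClinicalTable <- function(path) {
  d <- utils::read.delim(path, stringsAsFactors = FALSE)
  if (!"diagnosis" %in% names(d)) stopf("clinical table must have a 'diagnosis' column")
  d
}

#' Descriptive statistics of a clinical score column
#'
#' Mean, standard deviation (n - 1 denominator) and median, reported both
#' raw and rounded to a chosen number of digits (even-n medians are midpoint
#' averages).
#'
#' @param x numeric vector (n >= 2, NAs dropped).
#' @param digits rounding for the \code{rounded} element (default 1).
#' @return list with \code{n}, \code{mean}, \code{sd}, \code{median} and a
#'   \code{rounded} sub-list.
#' @export
clinicalDescribe <- function(x, digits = 1) {
  x <- x[!is.na(x)]
  if (length(x) < 2L) stopf("need at least two observations")
  out <- list(n = length(x), mean = mean(x), sd = stats::sd(x),
              median = stats::median(x))
  out$rounded <- lapply(out[c("mean", "sd", "median")], round, digits = digits)
  out
}

#' Partial (covariate-adjusted) Pearson correlation
#'
#' Pearson correlation of the residuals of \code{x} and \code{y} after
#' least-squares regression on the covariates (with intercept). With a
#' single covariate \code{age} this is the age-adjusted correlation. The p
#' value uses t = r sqrt((n - k - 2) / (1 - r^2)) with k covariates,
#' two-sided.
#'
#' @param x,y numeric vectors.
#' @param covariates numeric vector, matrix or data.frame of covariates
#'   (NULL for a plain Pearson correlation).
#' @return data.frame row with \code{n}, \code{k}, \code{r},
#'   \code{statistic}, \code{df}, \code{p}.
#' @export
partialCorr <- function(x, y, covariates = NULL) {
  ok <- stats::complete.cases(x, y, if (is.null(covariates)) rep(0, length(x)) else covariates)
  x <- x[ok]; y <- y[ok]
  n <- length(x)
  if (!is.null(covariates)) {
    cv <- as.matrix(as.data.frame(covariates))[ok, , drop = FALSE]
    # a constant covariate carries no adjustment information; drop it so the
    # result degenerates to the plain Pearson correlation
    cv <- cv[, apply(cv, 2, stats::sd) > 1e-12, drop = FALSE]
    k <- ncol(cv)
  } else {
    cv <- NULL; k <- 0L
  }
  if (n <= k + 2) stopf("need n > number of covariates + 2")
  if (k > 0) {
    M <- cbind(1, cv)
    x <- stats::lsfit(M, x, intercept = FALSE)$residuals
    y <- stats::lsfit(M, y, intercept = FALSE)$residuals
  }
  if (stats::sd(x) < 1e-12 || stats::sd(y) < 1e-12)
    stopf("undefined correlation: zero residual variance")
  r <- stats::cor(x, y)
  df <- n - k - 2
  tstat <- r * sqrt(df / (1 - r^2))
  data.frame(n = n, k = k, r = r, statistic = tstat, df = df,
             p = 2 * stats::pt(-abs(tstat), df))
}

#' Benjamini-Hochberg false discovery rate adjustment
#'
#' Step-up adjusted p values (monotone-enforced) with rejection flags at the
#' given familywise error rate.
#'
#' @param p numeric p values in [0, 1].
#' @param fwer rejection level (default 0.05).
#' @return list with \code{p_adjusted} and \code{reject}.
#' @export
fdrAdjust <- function(p, fwer = 0.05) {
  if (any(!is.finite(p)) || any(p < 0 | p > 1))
    stopf("p values must lie in [0, 1]")
  adj <- stats::p.adjust(p, method = "BH")
  list(p_adjusted = adj, reject = adj <= fwer)
}

#' Correlate cluster-masked EEG power with clinical scales
#'
#' Age-adjusted (partial Pearson) correlation between per-subject extracted
#' dB power and each clinical scale, FDR-corrected across the scales. This
#' analysis is intended only for regions with a statistically significant
#' case-control difference (the pipeline gates it accordingly), and runs on
#' the CTD group.
#'
#' @param scalars named numeric vector of per-subject extracted dB power
#'   (names = subject ids), e.g. from [extractMaskedPower()].
#' @param clinical clinical table with \code{id}, \code{diagnosis},
#'   \code{age} and the scale columns.
#' @param scales scale column names (default tic severity,
#'   obsessive-compulsive and ADHD scores).
#' @param covariate adjustment covariate column (default \code{"age"}).
#' @param fwer FDR rejection level.
#' @return data.frame, one row per scale: \code{scale}, \code{n}, \code{r},
#'   \code{p}, \code{p_fdr}, \code{reject}.
#' @export
correlateEegClinical <- function(scalars, clinical,
                                 scales = c("ygtss_total_tic", "cybocs",
                                            "dupaul_adhd"),
                                 covariate = "age", fwer = 0.05) {
  ctd <- clinical[clinical$diagnosis == "CTD", , drop = FALSE]
  unmatched <- setdiff(names(scalars), ctd$id)
  if (length(unmatched))
    stopf("subjects not in the clinical table: %s",
          paste(unmatched, collapse = ", "))
  missing <- setdiff(ctd$id, names(scalars))
  if (length(missing))
    stopf("clinical subjects missing from the EEG set: %s",
          paste(missing, collapse = ", "))
  ctd <- ctd[match(names(scalars), ctd$id), , drop = FALSE]
  rows <- lapply(scales, function(sc) {
    pc <- partialCorr(scalars, ctd[[sc]], covariates = ctd[[covariate]])
    data.frame(scale = sc, n = pc$n, r = pc$r, p = pc$p,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  fa <- fdrAdjust(out$p, fwer = fwer)
  out$p_fdr <- fa$p_adjusted
  out$reject <- fa$reject
  out
}

#' Correlate SSRT with self-reported tic suppressibility
#'
#' Plain Pearson correlation (with p value) between per-subject stop signal
#' reaction times and the tic-suppressibility item of the premonitory-urge
#' scale, over CTD subjects. Faster (smaller) SSRT with better (higher)
#' suppressibility yields a negative r.
#'
#' @param ssrt named numeric vector of per-subject SSRT (ms), names =
#'   subject ids.
#' @param clinical clinical table with \code{id}, \code{diagnosis} and
#'   \code{puts_item10}.
#' @return data.frame row: \code{n}, \code{r}, \code{statistic}, \code{df},
#'   \code{p}.
#' @export
behaviorClinicalCorr <- function(ssrt, clinical) {
  ctd <- clinical[clinical$diagnosis == "CTD", , drop = FALSE]
  ctd <- ctd[ctd$id %in% names(ssrt), , drop = FALSE]
  y <- ctd$puts_item10
  x <- ssrt[ctd$id]
  ok <- stats::complete.cases(x, y)
  x <- x[ok]; y <- y[ok]
  if (length(x) < 4L) stopf("need at least 4 subjects with both measures")
  if (stats::sd(x) < 1e-12 || stats::sd(y) < 1e-12)
    stopf("undefined correlation: a measure is constant")
  ct <- stats::cor.test(x, y, method = "pearson")
  data.frame(n = length(x), r = unname(ct$estimate),
             statistic = unname(ct$statistic),
             df = unname(ct$parameter), p = ct$p.value)
}
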