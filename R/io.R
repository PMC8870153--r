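# Plain-text exporters for maps and cluster results.

#' Write a frequency x time map as CSV
#'
#' Frequencies as rows (first column \code{freq_hz}), time points as
#' columns (\code{t<ms>}).
#'
#' @param m freq x time matrix.
#' @param freq,time axis vectors.
#' @param path output path.
#' @return the path, invisibly.
#' @export
writeMatrixCsv <- function(m, freq, time, path) {
  d <- data.frame(freq_hz = freq, m, check.names = FALSE)
  names(d)[-1] <- sprintf("t%g", time)
  utils::write.csv(d, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Export a ClusterResult as plain-text files
#'
#' Writes \code{<prefix>_tmap.csv}, \code{<prefix>_diffmap.csv},
#' \code{<prefix>_mask.csv} (0/1), \code{<prefix>_clusters.tsv} (the
#' [clusterTable()]) and \code{<prefix>_meta.json} (seed, permutations,
#' thresholds).
#'
#' @param cr a \linkS4class{ClusterResult}.
#' @param dir output directory (created if needed).
#' @param prefix file-name prefix.
#' @return character vector of the written paths, invisibly.
#' @export
writeClusterResult <- function(cr, dir, prefix) {
  stopifnot(is(cr, "ClusterResult"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  p <- function(s) file.path(dir, paste0(prefix, s))
  writeMatrixCsv(cr@tMap, cr@freq, cr@time, p("_tmap.csv"))
  writeMatrixCsv(cr@diffMap, cr@freq, cr@time, p("_diffmap.csv"))
  writeMatrixCsv(cr@mask * 1L, cr@freq, cr@time, p("_mask.csv"))
  utils::write.table(clusterTable(cr), p("_clusters.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  meta <- list(seed = cr@seed, n_perm = cr@nPerm, alpha = cr@alpha,
               n_rois = cr@nRois, pixel_threshold = cr@pixelThreshold,
               mass_threshold = cr@massThreshold,
               percentile = cr@percentile, groups = cr@groups,
               n_clusters = length(cr@mass),
               n_significant = sum(cr@significant))
  jsonlite::write_json(meta, p("_meta.json"), auto_unbox = TRUE, digits = NA)
  invisible(vapply(c("_tmap.csv", "_diffmap.csv", "_mask.csv",
                     "_clusters.tsv", "_meta.json"), p, character(1)))
}
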