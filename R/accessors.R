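# Accessor generics and methods. Slot access from user code should go
# through these.

#' @name accessors
#' @title Accessors for stopERSP containers
#' @description Small accessor functions for the S4 containers:
#'   epoch matrices and axes, time-frequency values and axes, per-trial
#'   metadata, baseline power, and cluster summaries.
#' @param x an \linkS4class{EpochSet}, \linkS4class{TFArray} or
#'   \linkS4class{ClusterResult}.
#' @return The corresponding component (matrix, vector or data.frame).
NULL

#' @rdname accessors
#' @export
setGeneric("trialInfo", function(x) standardGeneric("trialInfo"))
#' @rdname accessors
#' @export
setMethod("trialInfo", "EpochSet", function(x) x@info)
#' @rdname accessors
#' @export
setMethod("trialInfo", "TFArray", function(x) x@info)

#' @rdname accessors
#' @export
epochData <- function(x) {
  stopifnot(is(x, "EpochSet"))
  x@data
}

#' @rdname accessors
#' @export
epochTime <- function(x) {
  stopifnot(is(x, "EpochSet"))
  x@time
}

#' @rdname accessors
#' @export
baselineData <- function(x) {
  stopifnot(is(x, "EpochSet"))
  x@baseline
}

#' @rdname accessors
#' @export
tfValues <- function(x) {
  stopifnot(is(x, "TFArray"))
  x@power
}

#' @rdname accessors
#' @export
tfFreq <- function(x) {
  stopifnot(is(x, "TFArray"))
  x@freq
}

#' @rdname accessors
#' @export
tfTime <- function(x) {
  stopifnot(is(x, "TFArray"))
  x@time
}

#' @rdname accessors
#' @export
tfUnits <- function(x) {
  stopifnot(is(x, "TFArray"))
  x@units
}

#' @rdname accessors
#' @export
baselinePower <- function(x) {
  stopifnot(is(x, "TFArray"))
  x@baselinePower
}

#' @rdname accessors
#' @export
clusterMask <- function(x) {
  stopifnot(is(x, "ClusterResult"))
  x@mask
}

#' @rdname accessors
#' @export
nullMasses <- function(x) {
  stopifnot(is(x, "ClusterResult"))
  x@nullMasses
}

#' Tabulate clusters of a ClusterResult
#'
#' One row per observed cluster: id, mass (sum of |t|), corrected p,
#' significance flag and the frequency/time bounding box.
#'
#' @param x a \linkS4class{ClusterResult}.
#' @return data.frame with columns \code{id}, \code{mass}, \code{p},
#'   \code{significant}, \code{fMin}, \code{fMax}, \code{tMin}, \code{tMax},
#'   \code{nPixels}.
#' @export
clusterTable <- function(x) {
  stopifnot(is(x, "ClusterResult"))
  k <- length(x@mass)
  if (k == 0L)
    return(data.frame(id = integer(0), mass = numeric(0), p = numeric(0),
                      significant = logical(0), fMin = numeric(0),
                      fMax = numeric(0), tMin = numeric(0), tMax = numeric(0),
                      nPixels = integer(0)))
  out <- lapply(seq_len(k), function(i) {
    ij <- which(x@labels == i, arr.ind = TRUE)
    data.frame(id = i, mass = x@mass[i], p = x@clusterP[i],
               significant = x@significant[i],
               fMin = min(x@freq[ij[, 1]]), fMax = max(x@freq[ij[, 1]]),
               tMin = min(x@time[ij[, 2]]), tMax = max(x@time[ij[, 2]]),
               nPixels = nrow(ij))
  })
  do.call(rbind, out)
}
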