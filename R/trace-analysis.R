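#' Bin a photon stream into a two-color time trace
#'
#' Counts donor- and acceptor-channel photons in consecutive half-open bins
#' over \code{[0, duration)}; a photon exactly on a bin edge belongs to the
#' right-hand bin. A trailing partial bin is dropped.
#'
#' @param stream a [PhotonStream-class].
#' @param binWidthMs bin width in ms.
#' @param moleculeId identifier for the resulting trace.
#' @return a [FretTrace-class].
#' @export
binPhotons <- function(stream, binWidthMs = 10, moleculeId = "mol1") {
  stopifnot(is(stream, "PhotonStream"), binWidthMs > 0)
  binTicks <- binWidthMs * 1e-3 / stream@tickSeconds
  nb <- floor(stream@durationS / (binWidthMs * 1e-3))
  if (nb < 1) stop("acquisition shorter than one bin")
  idx <- floor(stream@timestamps / binTicks) + 1
  ok <- idx >= 1 & idx <= nb
  don <- tabulate(idx[ok & stream@detector == "D"], nbins = nb)
  acc <- tabulate(idx[ok & stream@detector == "A"], nbins = nb)
  FretTrace(don, acc, binWidthMs = binWidthMs, moleculeId = moleculeId)
}

#' Quality-control parameters for binned traces
#'
#' Defaults follow the standard immobilized-molecule acceptance rules: more
#' than 50 time-bins, more than 10 photons per bin on average, and a clear
#' single photobleaching step.
#'
#' @param minBins minimum number of analyzed bins (exclusive, default 50).
#' @param minMeanPhotons minimum mean total photons per analyzed bin
#'   (exclusive, default 10).
#' @param requireBleachStep require a detectable bleach step (default TRUE).
#' @param noiseFraction the post-step mean must fall below this fraction of
#'   the pre-step mean to count as a bleach step (default 0.25).
#' @return a plain list of validated parameters.
#' @export
traceQcParams <- function(minBins = 50, minMeanPhotons = 10,
                          requireBleachStep = TRUE, noiseFraction = 0.25) {
  stopifnot(minBins >= 1, minMeanPhotons >= 0,
            noiseFraction > 0, noiseFraction < 1)
  list(minBins = minBins, minMeanPhotons = minMeanPhotons,
       requireBleachStep = requireBleachStep, noiseFraction = noiseFraction)
}

#' Quality-control a trace and locate its photobleaching step
#'
#' Bleach detection: the largest change-point of the total (donor +
#' acceptor) intensity, found by maximizing the between-segment CUSUM
#' statistic; it counts as a bleach step when the post-step mean falls below
#' \code{noiseFraction} times the pre-step mean. The analyzed region ends at
#' the bleach bin, and the bin-count and mean-intensity thresholds are
#' evaluated on that region. Failures are recorded in the QC record, never
#' raised.
#'
#' @param trace a [FretTrace-class].
#' @param params list from [traceQcParams()].
#' @return the trace with its \code{qc} record populated (\code{passed},
#'   \code{reasons}, \code{bleachBin}, \code{analyzedBins}).
#' @export
qcTrace <- function(trace, params = traceQcParams()) {
  stopifnot(is(trace, "FretTrace"))
  total <- trace@donorCounts + trace@acceptorCounts
  n <- length(total)
  reasons <- character()

  bleachBin <- detectBleachStep(total, params$noiseFraction)
  if (params$requireBleachStep && is.na(bleachBin))
    reasons <- c(reasons, "no_bleach_step")
  analyzedBins <- if (!is.na(bleachBin)) bleachBin - 1L else n

  if (analyzedBins <= params$minBins)
    reasons <- c(reasons, "min_bins")
  meanCounts <- if (analyzedBins > 0) mean(total[seq_len(analyzedBins)]) else 0
  if (meanCounts <= params$minMeanPhotons)
    reasons <- c(reasons, "min_mean_photons")

  trace@qc <- list(passed = length(reasons) == 0L, reasons = reasons,
                   bleachBin = bleachBin, analyzedBins = analyzedBins)
  trace
}

## Single change-point by CUSUM: b maximizing the weighted mean difference
## between bins [1, b) and [b, n]; NA when no candidate drops below the
## noise floor.
detectBleachStep <- function(total, noiseFraction = 0.25) {
  n <- length(total)
  if (n < 4) return(NA_integer_)
  cs <- cumsum(total)
  b <- 2:(n - 1)
  pre <- cs[b - 1] / (b - 1)
  post <- (cs[n] - cs[b - 1]) / (n - b + 1)
  w <- sqrt((b - 1) * (n - b + 1) / n)
  score <- w * (pre - post)               # signed: bleaching is a drop
  best <- which.max(score)
  bb <- b[best]
  if (pre[best] <= 0) return(NA_integer_)
  if (post[best] < noiseFraction * pre[best]) as.integer(bb) else NA_integer_
}

#' Apparent FRET efficiency per time-bin
#'
#' Acceptor (red) photons divided by total photons per bin, over the
#' QC-analyzed region (up to the bleach bin). Bins with zero total photons
#' are returned as NA and excluded downstream.
#'
#' @param trace a QC-passed [FretTrace-class] (a trace whose QC has not been
#'   run is accepted with a warning; a failed trace is an error).
#' @return numeric vector of per-bin apparent FRET (NA where undefined).
#' @export
apparentFretPerBin <- function(trace) {
  stopifnot(is(trace, "FretTrace"))
  if (is.na(trace@qc$passed))
    warning("trace QC has not been run; using all bins")
  else if (!isTRUE(trace@qc$passed))
    stop("trace failed QC (", paste(trace@qc$reasons, collapse = ", "), ")")
  nUse <- if (!is.null(trace@qc$analyzedBins) && !is.na(trace@qc$passed))
    trace@qc$analyzedBins else length(trace@donorCounts)
  don <- trace@donorCounts[seq_len(nUse)]
  acc <- trace@acceptorCounts[seq_len(nUse)]
  tot <- don + acc
  ifelse(tot > 0, acc / tot, NA_real_)
}
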