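#' Construct a PhotonStream
#'
#' Excitation labels, if not supplied, are assigned from the alternation
#' schedule: a photon at tick \code{t} is \code{"Dex"} iff
#' \code{(t mod 2*period) < period}.
#'
#' @param timestamps non-decreasing whole-number ticks.
#' @param detector per-photon channel, \code{"D"} or \code{"A"}.
#' @param excitation per-photon phase, \code{"Dex"}/\code{"Aex"}; derived
#'   from the schedule when \code{NULL}.
#' @param tickSeconds tick size in seconds (default 1e-6, i.e. 1 us).
#' @param alternationPeriodUs alternation half-period in us (default 50).
#' @param durationS total acquisition time in seconds; defaults to the time
#'   of the last photon (0 for an empty stream).
#' @return a validated [PhotonStream-class] object.
#' @examples
#' ps <- PhotonStream(c(10, 20, 60), c("D", "A", "A"))
#' excitation(ps)  # "Dex" "Dex" "Aex"
#' @export
PhotonStream <- function(timestamps, detector, excitation = NULL,
                         tickSeconds = 1e-6, alternationPeriodUs = 50,
                         durationS = NULL) {
  timestamps <- as.numeric(timestamps)
  detector <- as.character(detector)
  if (is.null(excitation))
    excitation <- excitationPhase(timestamps, alternationPeriodUs, tickSeconds)
  if (is.null(durationS))
    durationS <- if (length(timestamps)) timestamps[length(timestamps)] * tickSeconds else 0
  new("PhotonStream",
      timestamps = timestamps, detector = detector,
      excitation = as.character(excitation),
      tickSeconds = tickSeconds,
      alternationPeriodUs = alternationPeriodUs,
      durationS = durationS)
}

#' Excitation phase of photon timestamps under laser alternation
#'
#' @param timestamps ticks.
#' @param alternationPeriodUs half-period in us.
#' @param tickSeconds tick size in seconds.
#' @return character vector \code{"Dex"}/\code{"Aex"}.
#' @keywords internal
excitationPhase <- function(timestamps, alternationPeriodUs, tickSeconds = 1e-6) {
  periodTicks <- alternationPeriodUs * 1e-6 / tickSeconds
  ifelse((timestamps %% (2 * periodTicks)) < periodTicks, "Dex", "Aex")
}

#' Construct a FretTrace
#'
#' @param donorCounts,acceptorCounts integer counts per bin.
#' @param binWidthMs bin width in ms.
#' @param moleculeId molecule identifier.
#' @param qc optional QC record; defaults to "not yet assessed".
#' @return a validated [FretTrace-class] object.
#' @export
FretTrace <- function(donorCounts, acceptorCounts, binWidthMs = 10,
                      moleculeId = "mol1", qc = NULL) {
  if (is.null(qc))
    qc <- list(passed = NA, reasons = character(), bleachBin = NA_integer_)
  new("FretTrace",
      donorCounts = as.numeric(donorCounts),
      acceptorCounts = as.numeric(acceptorCounts),
      binWidthMs = binWidthMs,
      moleculeId = as.character(moleculeId),
      qc = qc)
}

#' Construct an InstrumentConfig
#'
#' Defaults describe a typical two-color confocal us-ALEX setup: 50 us
#' alternation, about 1 kHz background per stream, 5% donor leakage, 5%
#' direct acceptor excitation, gamma = 1 and the Alexa555/Alexa647 Forster
#' radius of 5.1 nm.
#'
#' @param alternationPeriodUs alternation half-period (us).
#' @param bgDD,bgDA,bgAA background rates (kHz) of the DD, DA, AA streams.
#' @param leakage donor leakage fraction.
#' @param directExcitation direct-excitation fraction.
#' @param gamma detection correction factor.
#' @param r0Nm Forster radius (nm); 5.1 for Alexa555/Alexa647, 6.2 for
#'   Cy3B/Atto647N.
#' @return a validated [InstrumentConfig-class] object.
#' @export
instrumentConfig <- function(alternationPeriodUs = 50,
                             bgDD = 1.2, bgDA = 0.8, bgAA = 1.0,
                             leakage = 0.05, directExcitation = 0.05,
                             gamma = 1.0, r0Nm = 5.1) {
  new("InstrumentConfig",
      alternationPeriodUs = alternationPeriodUs,
      bgDD = bgDD, bgDA = bgDA, bgAA = bgAA,
      leakage = leakage, directExcitation = directExcitation,
      gamma = gamma, r0Nm = r0Nm)
}

#' @describeIn PhotonStream-class number of photons
#' @param object,x a PhotonStream
#' @export
setMethod("length", "PhotonStream", function(x) length(x@timestamps))

#' Accessors for PhotonStream slots
#'
#' @param x a [PhotonStream-class].
#' @return the corresponding per-photon vector or scalar metadata.
#' @name photonstream-accessors
NULL

#' @rdname photonstream-accessors
#' @export
timestamps <- function(x) x@timestamps
#' @rdname photonstream-accessors
#' @export
detector <- function(x) x@detector
#' @rdname photonstream-accessors
#' @export
excitation <- function(x) x@excitation
#' @rdname photonstream-accessors
#' @export
acquisitionDuration <- function(x) x@durationS
#' @rdname photonstream-accessors
#' @export
tickSeconds <- function(x) x@tickSeconds
#' @rdname photonstream-accessors
#' @export
alternationPeriod <- function(x) x@alternationPeriodUs

#' Accessors for FretTrace slots
#'
#' @param x a [FretTrace-class].
#' @name frettrace-accessors
NULL

#' @rdname frettrace-accessors
#' @export
donorCounts <- function(x) x@donorCounts
#' @rdname frettrace-accessors
#' @export
acceptorCounts <- function(x) x@acceptorCounts
#' @rdname frettrace-accessors
#' @export
binWidth <- function(x) x@binWidthMs
#' @rdname frettrace-accessors
#' @export
moleculeId <- function(x) x@moleculeId
#' @rdname frettrace-accessors
#' @export
qcRecord <- function(x) x@qc
#' @rdname frettrace-accessors
#' @export
nBins <- function(x) length(x@donorCounts)

#' Accessors for fitted HMMs and dwell tables
#'
#' @param x a [FretHmm-class] or [DwellTable-class].
#' @name hmm-accessors
NULL

#' @rdname hmm-accessors
#' @export
emissionMeans <- function(x) x@means
#' @rdname hmm-accessors
#' @export
emissionVariances <- function(x) x@variances
#' @rdname hmm-accessors
#' @export
transitionMatrix <- function(x) x@transitionMatrix
#' @rdname hmm-accessors
#' @export
initialProbs <- function(x) x@initialProbs
#' @rdname hmm-accessors
#' @export
stateSeq <- function(x) x@states
#' @rdname hmm-accessors
#' @export
dwells <- function(x) x@dwells
#' @rdname hmm-accessors
#' @export
meanLifetime <- function(x) x@meanLifetimeMs
#' @rdname hmm-accessors
#' @export
semLifetime <- function(x) x@semLifetimeMs
#' @rdname hmm-accessors
#' @export
occupancyHigh <- function(x) x@occupancyHigh
#' @rdname hmm-accessors
#' @export
transitionsPerMinute <- function(x) x@transitionsPerMinute

setMethod("show", "PhotonStream", function(object) {
  cat("PhotonStream:", length(object@timestamps), "photons over",
      format(object@durationS, digits = 4), "s\n")
  cat("  tick:", object@tickSeconds * 1e6, "us; alternation half-period:",
      object@alternationPeriodUs, "us\n")
  if (length(object@timestamps)) {
    tab <- table(paste0(object@excitation, "/", object@detector))
    cat("  streams:", paste(names(tab), as.integer(tab), collapse = ", "), "\n")
  }
})

setMethod("show", "FretTrace", function(object) {
  cat("FretTrace", object@moleculeId, ":", length(object@donorCounts),
      "bins x", object@binWidthMs, "ms\n")
  cat("  mean counts/bin: donor", round(mean(object@donorCounts), 1),
      "acceptor", round(mean(object@acceptorCounts), 1), "\n")
  if (!is.na(object@qc$passed))
    cat("  QC:", if (isTRUE(object@qc$passed)) "passed" else
        paste("failed:", paste(object@qc$reasons, collapse = ", ")),
        if (!is.na(object@qc$bleachBin)) paste0("(bleach at bin ", object@qc$bleachBin, ")")
        else "", "\n")
})

setMethod("show", "InstrumentConfig", function(object) {
  cat("InstrumentConfig: alternation", object@alternationPeriodUs, "us;",
      "bg (kHz) DD", object@bgDD, "DA", object@bgDA, "AA", object@bgAA, "\n")
  cat("  leakage", object@leakage, "; direct excitation",
      object@directExcitation, "; gamma", object@gamma,
      "; R0", object@r0Nm, "nm\n")
})

setMethod("show", "FretHmm", function(object) {
  cat("FretHmm (2-state Gaussian emission)\n")
  cat("  means:", format(object@means, digits = 4),
      " sd:", format(sqrt(object@variances), digits = 4), "\n")
  cat("  stay probabilities:", format(diag(object@transitionMatrix), digits = 4), "\n")
  cat("  logLik:", format(object@logLik, digits = 8), "after",
      object@nIterations, "iterations",
      if (isTRUE(object@converged)) "(converged)" else "(not converged)", "\n")
  if (isTRUE(object@degenerate))
    cat("  WARNING: states not identifiable (indistinguishable emissions)\n")
})

setMethod("show", "StateTrajectory", function(object) {
  cat("StateTrajectory:", length(object@states), "bins, logProb",
      format(object@logProb, digits = 6), "\n")
})

setMethod("show", "DwellTable", function(object) {
  cat("DwellTable:", nrow(object@dwells), "dwells",
      sprintf("(%d used for lifetimes)", sum(object@nDwells)), "\n")
  for (s in 1:2) {
    lab <- c("open  (low FRET)", "closed (high FRET)")[s]
    cat(sprintf("  %s: mean lifetime %s +/- %s ms (n = %d)\n", lab,
                format(object@meanLifetimeMs[s], digits = 4),
                format(object@semLifetimeMs[s], digits = 3),
                object@nDwells[s]))
  }
  cat("  occupancy (high):", format(object@occupancyHigh, digits = 4),
      "; transitions/min:", format(object@transitionsPerMinute, digits = 4), "\n")
})

setMethod("show", "FretHistogramFit", function(object) {
  k <- length(object@means)
  cat("FretHistogramFit:", k, "Gaussian component(s),", object@nValues,
      "values, bin width", object@binWidth, "\n")
  for (i in seq_len(k)) {
    cat(sprintf("  mean %.4f [%.4f, %.4f]  sigma %.4f  area %.3f\n",
                object@means[i], object@meanCi95[i, 1], object@meanCi95[i, 2],
                object@sigmas[i], object@areaFractions[i]))
  }
})
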