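#' @import methods
#' @importFrom stats sd var dnorm lm coef confint vcov rexp rpois runif rnorm rbinom quantile median setNames complete.cases ks.test
#' @importFrom utils read.table write.table head tail
#' @importFrom graphics hist
#' @useDynLib alexFRET, .registration = TRUE
#' @importFrom Rcpp sourceCpp
NULL

## Timestamps are stored as numeric whole-number ticks (default tick = 1 us)
## so that >2^31 ticks never overflow; all window arithmetic is half-open
## [start, end) in exact tick units.

#' PhotonStream: timestamped photon events from a us-ALEX confocal measurement
#'
#' One record per detected photon: arrival time in integer ticks, detection
#' channel (donor \code{"D"} or acceptor \code{"A"}) and excitation phase
#' (\code{"Dex"} during the donor-laser half-period, \code{"Aex"} during the
#' acceptor-laser half-period). A photon at tick \code{t} is in the Dex phase
#' iff \code{(t mod 2*period) < period}, with the period expressed in ticks.
#'
#' @slot timestamps numeric vector of non-decreasing whole-number ticks.
#' @slot detector character vector, one of \code{"D"}, \code{"A"} per photon.
#' @slot excitation character vector, one of \code{"Dex"}, \code{"Aex"}.
#' @slot tickSeconds duration of one tick in seconds (default 1e-6).
#' @slot alternationPeriodUs laser alternation half-period in microseconds.
#' @slot durationS total acquisition time in seconds.
#'
#' @seealso [PhotonStream()], [readPhotonStream()], [simulateBursts()]
#' @export
setClass("PhotonStream",
  representation(
    timestamps = "numeric",
    detector = "character",
    excitation = "character",
    tickSeconds = "numeric",
    alternationPeriodUs = "numeric",
    durationS = "numeric"
  )
)

setValidity("PhotonStream", function(object) {
  msgs <- character()
  n <- length(object@timestamps)
  if (length(object@detector) != n || length(object@excitation) != n)
    msgs <- c(msgs, "timestamps, detector and excitation must have equal length")
  if (n > 0L) {
    if (any(object@timestamps < 0))
      msgs <- c(msgs, "timestamps must be non-negative")
    if (is.unsorted(object@timestamps))
      msgs <- c(msgs, "timestamps must be non-decreasing")
    if (any(object@timestamps != floor(object@timestamps)))
      msgs <- c(msgs, "timestamps must be whole-number ticks")
    if (!all(object@detector %in% c("D", "A")))
      msgs <- c(msgs, "detector labels must be 'D' or 'A'")
    if (!all(object@excitation %in% c("Dex", "Aex")))
      msgs <- c(msgs, "excitation labels must be 'Dex' or 'Aex'")
  }
  if (length(object@alternationPeriodUs) != 1L || object@alternationPeriodUs <= 0)
    msgs <- c(msgs, "alternationPeriodUs must be a single positive number")
  if (length(object@tickSeconds) != 1L || object@tickSeconds <= 0)
    msgs <- c(msgs, "tickSeconds must be a single positive number")
  if (length(object@durationS) != 1L || object@durationS < 0)
    msgs <- c(msgs, "durationS must be a single non-negative number")
  if (n > 0L && length(msgs) == 0L) {
    lastS <- object@timestamps[n] * object@tickSeconds
    if (object@durationS < lastS - 1e-12)
      msgs <- c(msgs, "durationS must cover the last timestamp")
    expected <- excitationPhase(object@timestamps,
                                object@alternationPeriodUs,
                                object@tickSeconds)
    if (!all(object@excitation == expected))
      msgs <- c(msgs, "excitation labels inconsistent with the alternation schedule")
  }
  if (length(msgs)) msgs else TRUE
})

#' FretTrace: binned two-color time trace of one immobilized molecule
#'
#' @slot donorCounts integer photon counts per bin (green channel).
#' @slot acceptorCounts integer photon counts per bin (red channel).
#' @slot binWidthMs bin width in milliseconds.
#' @slot moleculeId identifier of the molecule.
#' @slot qc list with elements \code{passed} (logical), \code{reasons}
#'   (character), \code{bleachBin} (integer index of the bleach step, or
#'   \code{NA}); populated by [qcTrace()].
#'
#' @seealso [qcTrace()], [apparentFretPerBin()], [simulateTraces()]
#' @export
setClass("FretTrace",
  representation(
    donorCounts = "numeric",
    acceptorCounts = "numeric",
    binWidthMs = "numeric",
    moleculeId = "character",
    qc = "list"
  ),
  prototype(qc = list(passed = NA, reasons = character(), bleachBin = NA_integer_))
)

setValidity("FretTrace", function(object) {
  msgs <- character()
  if (length(object@donorCounts) != length(object@acceptorCounts))
    msgs <- c(msgs, "donorCounts and acceptorCounts must have equal length")
  if (length(object@donorCounts) < 1L)
    msgs <- c(msgs, "trace must have at least one bin")
  if (any(object@donorCounts < 0) || any(object@acceptorCounts < 0))
    msgs <- c(msgs, "counts must be non-negative")
  if (any(object@donorCounts != floor(object@donorCounts)) ||
      any(object@acceptorCounts != floor(object@acceptorCounts)))
    msgs <- c(msgs, "counts must be integers")
  if (length(object@binWidthMs) != 1L || object@binWidthMs <= 0)
    msgs <- c(msgs, "binWidthMs must be a single positive number")
  if (!all(c("passed", "reasons", "bleachBin") %in% names(object@qc)))
    msgs <- c(msgs, "qc must have elements passed, reasons, bleachBin")
  if (length(msgs)) msgs else TRUE
})

#' InstrumentConfig: correction and instrument parameters
#'
#' Background count rates are per photon stream (DD, DA, AA), expressed in
#' kHz relative to total acquisition time, so background subtraction for a
#' burst is rate x burst duration. Leakage is the fraction of detected donor
#' photons that spill into the acceptor channel; direct excitation the
#' fraction of AA counts appearing as acceptor signal under donor excitation;
#' gamma the detection-efficiency/quantum-yield ratio of the two channels.
#'
#' @slot alternationPeriodUs laser alternation half-period (microseconds).
#' @slot bgDD,bgDA,bgAA background count rates (kHz) per stream.
#' @slot leakage donor leakage fraction, in [0, 1).
#' @slot directExcitation direct-excitation fraction, in [0, 1).
#' @slot gamma detection-correction factor, > 0.
#' @slot r0Nm Forster radius of the dye pair in nm (5.1 for
#'   Alexa555/Alexa647, 6.2 for Cy3B/Atto647N).
#'
#' @seealso [instrumentConfig()], [applyCorrections()]
#' @export
setClass("InstrumentConfig",
  representation(
    alternationPeriodUs = "numeric",
    bgDD = "numeric", bgDA = "numeric", bgAA = "numeric",
    leakage = "numeric", directExcitation = "numeric",
    gamma = "numeric", r0Nm = "numeric"
  )
)

setValidity("InstrumentConfig", function(object) {
  msgs <- character()
  if (object@alternationPeriodUs <= 0) msgs <- c(msgs, "alternationPeriodUs must be > 0")
  if (any(c(object@bgDD, object@bgDA, object@bgAA) < 0))
    msgs <- c(msgs, "background rates must be >= 0")
  if (object@leakage < 0 || object@leakage >= 1)
    msgs <- c(msgs, "leakage must be in [0, 1)")
  if (object@directExcitation < 0 || object@directExcitation >= 1)
    msgs <- c(msgs, "directExcitation must be in [0, 1)")
  if (object@gamma <= 0) msgs <- c(msgs, "gamma must be > 0")
  if (object@r0Nm <= 0) msgs <- c(msgs, "r0Nm must be > 0")
  if (length(msgs)) msgs else TRUE
})

#' FretHmm: two-state Gaussian-emission hidden Markov model
#'
#' States are ordered by ascending emission mean: state 1 is the open
#' (low-FRET) conformation, state 2 the closed (high-FRET) conformation.
#'
#' @slot means emission means (FRET units), ascending.
#' @slot variances emission variances (FRET^2), > 0.
#' @slot transitionMatrix 2x2 row-stochastic per-bin transition probabilities.
#' @slot initialProbs length-2 initial state distribution.
#' @slot logLik total log-likelihood at convergence.
#' @slot nIterations Baum-Welch iterations used.
#' @slot converged logical; FALSE if stopped at maxIter.
#' @slot degenerate logical; TRUE if the two states are not identifiable
#'   (indistinguishable emissions).
#'
#' @seealso [baumWelchFit()], [viterbiDecode()]
#' @export
setClass("FretHmm",
  representation(
    means = "numeric", variances = "numeric",
    transitionMatrix = "matrix", initialProbs = "numeric",
    logLik = "numeric", nIterations = "integer",
    converged = "logical", degenerate = "logical",
    logLikTrace = "numeric"
  ),
  prototype(converged = NA, degenerate = FALSE, logLikTrace = numeric(0))
)

setValidity("FretHmm", function(object) {
  msgs <- character()
  if (length(object@means) != 2L || length(object@variances) != 2L)
    msgs <- c(msgs, "model must have exactly two states")
  if (any(object@variances <= 0)) msgs <- c(msgs, "variances must be > 0")
  if (is.unsorted(object@means)) msgs <- c(msgs, "states must be ordered by ascending mean")
  if (!all(dim(object@transitionMatrix) == c(2L, 2L)))
    msgs <- c(msgs, "transitionMatrix must be 2x2")
  else if (any(abs(rowSums(object@transitionMatrix) - 1) > 1e-12))
    msgs <- c(msgs, "transitionMatrix rows must sum to 1 (tol 1e-12)")
  if (length(object@initialProbs) != 2L ||
      abs(sum(object@initialProbs) - 1) > 1e-8 || any(object@initialProbs < 0))
    msgs <- c(msgs, "initialProbs must be a length-2 probability vector")
  if (length(msgs)) msgs else TRUE
})

#' StateTrajectory: most probable per-bin state path of one trace
#'
#' @slot states integer vector of decoded states (1 = open/low FRET,
#'   2 = closed/high FRET), one per analyzed bin.
#' @slot logProb log-probability of the Viterbi path.
#'
#' @seealso [viterbiDecode()], [extractDwells()]
#' @export
setClass("StateTrajectory",
  representation(states = "integer", logProb = "numeric")
)

setValidity("StateTrajectory", function(object) {
  if (length(object@states) && !all(object@states %in% c(1L, 2L)))
    return("states must be 1 (open) or 2 (closed)")
  TRUE
})

#' DwellTable: per-state dwell durations and derived kinetic summaries
#'
#' @slot dwells data.frame with columns \code{trace}, \code{state} (1 open /
#'   2 closed), \code{nBins}, \code{durationMs}, \code{censored} (first/last
#'   dwell of a trace).
#' @slot binWidthMs bin width used for decoding, ms.
#' @slot meanLifetimeMs named numeric, mean dwell time per state (ms) over
#'   the dwells used for estimation.
#' @slot semLifetimeMs standard error of each mean lifetime (ms).
#' @slot nDwells number of dwells entering each lifetime estimate.
#' @slot occupancyHigh fraction of analyzed bins in the high-FRET state.
#' @slot transitionsPerMinute state changes per minute of analyzed time.
#' @slot includeCensored whether censored dwells entered the estimates.
#'
#' @seealso [extractDwells()], [kineticOrderTest()]
#' @export
setClass("DwellTable",
  representation(
    dwells = "data.frame", binWidthMs = "numeric",
    meanLifetimeMs = "numeric", semLifetimeMs = "numeric",
    nDwells = "integer", occupancyHigh = "numeric",
    transitionsPerMinute = "numeric", includeCensored = "logical"
  )
)

setValidity("DwellTable", function(object) {
  msgs <- character()
  need <- c("trace", "state", "nBins", "durationMs", "censored")
  if (!all(need %in% names(object@dwells)))
    msgs <- c(msgs, "dwells must have columns trace, state, nBins, durationMs, censored")
  if (length(object@occupancyHigh) == 1L && !is.na(object@occupancyHigh) &&
      (object@occupancyHigh < 0 || object@occupancyHigh > 1))
    msgs <- c(msgs, "occupancyHigh must be in [0, 1]")
  if (length(msgs)) msgs else TRUE
})

#' FretHistogramFit: Gaussian fit(s) to a FRET efficiency histogram
#'
#' Nonlinear least-squares fit of one or two Gaussian components to a binned
#' FRET efficiency histogram, with a 95% Wald confidence interval on each
#' fitted mean. Components are ordered by ascending mean; for two components
#' the area fraction of each (amplitude x sigma, normalized) is reported.
#'
#' @slot means fitted component means.
#' @slot sigmas fitted component standard deviations.
#' @slot amplitudes fitted peak amplitudes (counts).
#' @slot meanCi95 k x 2 matrix of 95% Wald confidence intervals on the means.
#' @slot areaFractions relative area of each component (sums to 1).
#' @slot nValues number of FRET values in the histogram.
#' @slot binWidth histogram bin width (FRET units).
#'
#' @seealso [fitEHistogram()], [populationFromHistogram()]
#' @export
setClass("FretHistogramFit",
  representation(
    means = "numeric", sigmas = "numeric", amplitudes = "numeric",
    meanCi95 = "matrix", areaFractions = "numeric",
    nValues = "integer", binWidth = "numeric"
  )
)

setValidity("FretHistogramFit", function(object) {
  msgs <- character()
  k <- length(object@means)
  if (length(object@sigmas) != k || length(object@amplitudes) != k)
    msgs <- c(msgs, "means, sigmas and amplitudes must have equal length")
  if (any(object@sigmas <= 0)) msgs <- c(msgs, "sigmas must be > 0")
  if (!all(dim(object@meanCi95) == c(k, 2L)))
    msgs <- c(msgs, "meanCi95 must be a k x 2 matrix")
  else if (any(object@means < object@meanCi95[, 1] - 1e-12) ||
           any(object@means > object@meanCi95[, 2] + 1e-12))
    msgs <- c(msgs, "each meanCi95 interval must contain its mean")
  if (length(msgs)) msgs else TRUE
})
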