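## Forward models of the measurement, used as ground-truth generators.
## One RNG per simulation, seeded from the config: fixing the seed fixes
## every output bit-exactly.

#' Configuration for the diffusing-molecule burst simulator
#'
#' Defaults describe a typical picomolar solution measurement: bursts of a
#' few hundred photons (250 kHz in-burst detection rate over an
#' exponentially distributed transit of mean 1.5 ms), about 20 detected
#' bursts per second, and roughly 1 kHz background per stream.
#'
#' @slot populations data.frame with columns \code{trueE} (transfer
#'   efficiency in [0,1]; NA for donor-only/acceptor-only species),
#'   \code{weight} (fractions summing to 1) and \code{species}
#'   (\code{"DA"}, \code{"Donly"} or \code{"Aonly"}).
#' @slot meanBurstPhotonRateKhz in-burst photon detection rate (kHz).
#' @slot burstDurationMeanMs mean diffusion transit time (ms).
#' @slot burstRatePerS burst arrival rate (s^-1).
#' @slot durationS acquisition time (s).
#' @slot bgDD,bgDA,bgAA background rates (kHz) per stream.
#' @slot leakage,directExcitation,gamma distortion factors applied by the
#'   forward model (see [applyCorrections()] for their inverses).
#' @slot alternationPeriodUs laser alternation half-period (us).
#' @slot seed RNG seed.
#' @export
setClass("BurstSimConfig",
  representation(
    populations = "data.frame",
    meanBurstPhotonRateKhz = "numeric",
    burstDurationMeanMs = "numeric",
    burstRatePerS = "numeric",
    durationS = "numeric",
    bgDD = "numeric", bgDA = "numeric", bgAA = "numeric",
    leakage = "numeric", directExcitation = "numeric", gamma = "numeric",
    alternationPeriodUs = "numeric",
    seed = "numeric"
  )
)

setValidity("BurstSimConfig", function(object) {
  msgs <- character()
  p <- object@populations
  if (!all(c("trueE", "weight", "species") %in% names(p)))
    msgs <- c(msgs, "populations needs columns trueE, weight, species")
  else {
    if (abs(sum(p$weight) - 1) > 1e-8) msgs <- c(msgs, "population weights must sum to 1")
    if (!all(p$species %in% c("DA", "Donly", "Aonly")))
      msgs <- c(msgs, "species must be DA, Donly or Aonly")
    da <- p$species == "DA"
    if (any(is.na(p$trueE[da])) || any(p$trueE[da] < 0 | p$trueE[da] > 1))
      msgs <- c(msgs, "trueE must be in [0,1] for DA species")
  }
  if (any(c(object@meanBurstPhotonRateKhz, object@burstDurationMeanMs,
            object@burstRatePerS, object@durationS) <= 0))
    msgs <- c(msgs, "rates and durations must be > 0")
  if (any(c(object@bgDD, object@bgDA, object@bgAA) < 0))
    msgs <- c(msgs, "background rates must be >= 0")
  if (object@leakage < 0 || object@leakage >= 1 ||
      object@directExcitation < 0 || object@directExcitation >= 1 ||
      object@gamma <= 0)
    msgs <- c(msgs, "leakage/directExcitation in [0,1), gamma > 0")
  if (length(msgs)) msgs else TRUE
})

#' @rdname BurstSimConfig-class
#' @param populations,meanBurstPhotonRateKhz,burstDurationMeanMs,burstRatePerS
#'   see slots.
#' @param durationS,bgDD,bgDA,bgAA,leakage,directExcitation,gamma see slots.
#' @param alternationPeriodUs,seed see slots.
#' @return a validated \code{BurstSimConfig}.
#' @export
burstSimConfig <- function(populations = data.frame(trueE = 0.5, weight = 1,
                                                    species = "DA"),
                           meanBurstPhotonRateKhz = 250,
                           burstDurationMeanMs = 1.5,
                           burstRatePerS = 20,
                           durationS = 30,
                           bgDD = 1.2, bgDA = 0.8, bgAA = 1.0,
                           leakage = 0.05, directExcitation = 0.05,
                           gamma = 1.0, alternationPeriodUs = 50,
                           seed = 1L) {
  new("BurstSimConfig", populations = populations,
      meanBurstPhotonRateKhz = meanBurstPhotonRateKhz,
      burstDurationMeanMs = burstDurationMeanMs,
      burstRatePerS = burstRatePerS, durationS = durationS,
      bgDD = bgDD, bgDA = bgDA, bgAA = bgAA,
      leakage = leakage, directExcitation = directExcitation, gamma = gamma,
      alternationPeriodUs = alternationPeriodUs, seed = seed)
}

#' Configuration for the immobilized-molecule trace simulator
#'
#' The conformational dynamics are a continuous-time two-state Markov chain
#' with closing rate \code{kCloseIntrinsic + kCloseBimolecular * ligandUm}
#' (first-order in ligand) and ligand-independent opening rate \code{kOpen}
#' (zeroth order) — the induced-fit kinetic scheme. A bin spanning a
#' transition uses the fractional closed-state occupancy to set its expected
#' acceptor/donor split; an exponential donor bleach time truncates the
#' usable trace, after which bins carry only background.
#'
#' @slot kCloseIntrinsic ligand-independent closing rate (s^-1).
#' @slot kCloseBimolecular bimolecular closing rate (s^-1 uM^-1).
#' @slot ligandUm ligand concentration (uM).
#' @slot kOpen opening rate (s^-1).
#' @slot eOpen,eClosed apparent FRET of the open / closed state.
#' @slot totalRatePerBin expected signal photons per bin (both channels).
#' @slot bgPerBin expected background photons per bin and channel.
#' @slot binWidthMs bin width (ms).
#' @slot nBinsMax trace length cap (bins).
#' @slot nTraces number of molecules.
#' @slot bleachRatePerS donor bleach rate (s^-1); 0 disables bleaching.
#' @slot seed RNG seed.
#' @export
setClass("TraceSimConfig",
  representation(
    kCloseIntrinsic = "numeric", kCloseBimolecular = "numeric",
    ligandUm = "numeric", kOpen = "numeric",
    eOpen = "numeric", eClosed = "numeric",
    totalRatePerBin = "numeric", bgPerBin = "numeric",
    binWidthMs = "numeric", nBinsMax = "numeric", nTraces = "numeric",
    bleachRatePerS = "numeric", seed = "numeric"
  )
)

setValidity("TraceSimConfig", function(object) {
  msgs <- character()
  if (any(c(object@kCloseIntrinsic, object@kCloseBimolecular, object@ligandUm,
            object@kOpen, object@bleachRatePerS, object@bgPerBin) < 0))
    msgs <- c(msgs, "rates and concentrations must be >= 0")
  if (object@eOpen >= object@eClosed)
    msgs <- c(msgs, "eOpen must be < eClosed")
  if (object@eOpen < 0 || object@eClosed > 1)
    msgs <- c(msgs, "state FRET values must be in [0,1]")
  if (object@binWidthMs <= 0) msgs <- c(msgs, "binWidthMs must be > 0")
  if (object@nBinsMax < 1 || object@nTraces < 1)
    msgs <- c(msgs, "nBinsMax and nTraces must be >= 1")
  if (object@totalRatePerBin <= 0) msgs <- c(msgs, "totalRatePerBin must be > 0")
  if (length(msgs)) msgs else TRUE
})

#' @rdname TraceSimConfig-class
#' @param kCloseIntrinsic,kCloseBimolecular,ligandUm,kOpen,eOpen,eClosed see slots.
#' @param totalRatePerBin,bgPerBin,binWidthMs,nBinsMax,nTraces see slots.
#' @param bleachRatePerS,seed see slots.
#' @return a validated \code{TraceSimConfig}.
#' @export
traceSimConfig <- function(kCloseIntrinsic = 0, kCloseBimolecular = 1,
                           ligandUm = 1, kOpen = 10,
                           eOpen = 0.35, eClosed = 0.75,
                           totalRatePerBin = 50, bgPerBin = 0.5,
                           binWidthMs = 10, nBinsMax = 400, nTraces = 100,
                           bleachRatePerS = 0.2, seed = 1L) {
  new("TraceSimConfig",
      kCloseIntrinsic = kCloseIntrinsic,
      kCloseBimolecular = kCloseBimolecular,
      ligandUm = ligandUm, kOpen = kOpen, eOpen = eOpen, eClosed = eClosed,
      totalRatePerBin = totalRatePerBin, bgPerBin = bgPerBin,
      binWidthMs = binWidthMs, nBinsMax = nBinsMax, nTraces = nTraces,
      bleachRatePerS = bleachRatePerS, seed = seed)
}

#' Simulate a us-ALEX photon stream of freely diffusing labeled molecules
#'
#' Bursts arrive as a Poisson process; each burst has an exponentially
#' distributed duration and a constant in-burst emission rate (the transit
#' envelope is not modeled further — the analysis chain, not the optics, is
#' under test). Photon routing encodes the instrument distortions so that
#' [applyCorrections()] is their exact inverse in expectation:
#' \itemize{
#'  \item a donor-excitation photon of a doubly labeled molecule is acceptor
#'    signal with probability \code{gamma*E / (gamma*E + 1 - E)}, otherwise
#'    donor signal;
#'  \item each detected donor photon spawns an extra acceptor-channel photon
#'    with probability \code{leakage};
#'  \item direct acceptor excitation adds Dex-phase acceptor photons with
#'    expectation \code{directExcitation} times the AA count;
#'  \item donor-only molecules are silent in the Aex phase, acceptor-only
#'    molecules contribute AA and direct-excitation photons only;
#'  \item per-stream background is uniform over the acquisition.
#' }
#'
#' @param config a [BurstSimConfig-class].
#' @return list with \code{stream} (a [PhotonStream-class]) and
#'   \code{truth}, a data.frame of burst intervals (ticks, half-open),
#'   population index, species and true E.
#' @export
simulateBursts <- function(config) {
  stopifnot(is(config, "BurstSimConfig"))
  validObject(config)
  set.seed(config@seed)
  tick <- 1e-6                                  # 1 us ticks
  periodTicks <- config@alternationPeriodUs     # us == ticks here
  durTicks <- config@durationS / tick
  pops <- config@populations

  nBursts <- rpois(1, config@burstRatePerS * config@durationS)
  startT <- sort(runif(nBursts, 0, durTicks))
  lenT <- rexp(nBursts, rate = 1 / (config@burstDurationMeanMs * 1e3))
  lenT <- pmin(lenT, durTicks - startT)         # clip at acquisition end
  popIdx <- sample.int(nrow(pops), nBursts, replace = TRUE, prob = pops$weight)
  species <- pops$species[popIdx]
  trueE <- pops$trueE[popIdx]
  rateTick <- config@meanBurstPhotonRateKhz * 1e3 * tick  # photons per tick

  allT <- numeric(0); allD <- character(0)

  addPhotons <- function(t, chan) {
    allT <<- c(allT, t)
    allD <<- c(allD, rep(chan, length(t)))
  }
  isDex <- function(t) (t %% (2 * periodTicks)) < periodTicks

  if (nBursts > 0) {
    ## base emission photons, uniform over each burst, thinned by phase
    nBase <- rpois(nBursts, rateTick * lenT)
    bid <- rep.int(seq_len(nBursts), nBase)
    tb <- startT[bid] + runif(length(bid)) * lenT[bid]
    dex <- isDex(tb)
    sp <- species[bid]

    ## doubly labeled: Aex -> AA; Dex -> acceptor signal w.p. q else donor
    da <- sp == "DA"
    q <- ifelse(da, config@gamma * trueE[bid] /
                  (config@gamma * trueE[bid] + 1 - trueE[bid]), NA)
    keep <- rep(TRUE, length(tb))
    chan <- character(length(tb))
    chan[da & !dex] <- "A"
    isAcc <- da & dex & (runif(length(tb)) < q)
    chan[isAcc] <- "A"
    chan[da & dex & !isAcc] <- "D"
    ## donor-only: emits only under donor excitation
    donly <- sp == "Donly"
    keep[donly & !dex] <- FALSE
    chan[donly & dex] <- "D"
    ## acceptor-only: emits only under acceptor excitation (direx added below)
    aonly <- sp == "Aonly"
    keep[aonly & dex] <- FALSE
    chan[aonly & !dex] <- "A"
    allT <- tb[keep]; allD <- chan[keep]

    ## leakage: each detected donor photon duplicated into the acceptor
    ## channel with probability `leakage`, at the same arrival time
    if (config@leakage > 0) {
      dIdx <- which(allD == "D")
      leakHit <- dIdx[runif(length(dIdx)) < config@leakage]
      addPhotons(allT[leakHit], "A")
    }

    ## direct excitation: Dex-phase acceptor photons for acceptor-bearing
    ## species, expectation directExcitation x (AA rate x Dex time)
    if (config@directExcitation > 0) {
      hasA <- species %in% c("DA", "Aonly")
      nDir <- rpois(nBursts, config@directExcitation * rateTick * lenT) * hasA
      did <- rep.int(seq_len(nBursts), nDir)
      td <- startT[did] + runif(length(did)) * lenT[did]
      td <- td[isDex(td)]                       # thin to the Dex phase
      addPhotons(td, "A")
    }
  }

  ## background: rates are per total acquisition time; sample 2x candidates
  ## uniformly then thin to the stream's phase
  bgAdd <- function(rateKhz, chan, wantDex) {
    nc <- rpois(1, 2 * rateKhz * 1e3 * config@durationS)
    t <- runif(nc, 0, durTicks)
    t <- t[isDex(t) == wantDex]
    addPhotons(t, chan)
  }
  bgAdd(config@bgDD, "D", TRUE)
  bgAdd(config@bgDA, "A", TRUE)
  bgAdd(config@bgAA, "A", FALSE)

  ord <- order(allT)
  ticks <- floor(allT[ord])
  stream <- PhotonStream(ticks, allD[ord],
                         tickSeconds = tick,
                         alternationPeriodUs = config@alternationPeriodUs,
                         durationS = config@durationS)
  truth <- data.frame(
    burst = seq_len(nBursts),
    startTick = floor(startT), endTick = ceiling(startT + lenT),
    population = popIdx, species = species, trueE = trueE)
  list(stream = stream, truth = truth)
}

#' Simulate binned two-color traces of surface-immobilized molecules
#'
#' See [TraceSimConfig-class] for the kinetic scheme. The chain starts in
#' its stationary distribution. Returns per-molecule ground truth: the
#' continuous-time dwell segments, the per-bin closed-state occupancy
#' fraction, and the bleach bin.
#'
#' @param config a [TraceSimConfig-class].
#' @return list with \code{traces} (list of [FretTrace-class]) and
#'   \code{truth} (list of per-molecule lists: \code{segments} data.frame
#'   with \code{state} (1 open / 2 closed), \code{startS}, \code{endS};
#'   \code{fClosed} per bin; \code{bleachBin}, NA if none).
#' @export
simulateTraces <- function(config) {
  stopifnot(is(config, "TraceSimConfig"))
  validObject(config)
  set.seed(config@seed)
  kc <- config@kCloseIntrinsic + config@kCloseBimolecular * config@ligandUm
  ko <- config@kOpen
  binS <- config@binWidthMs * 1e-3
  nB <- as.integer(config@nBinsMax)
  traceDurS <- nB * binS

  traces <- vector("list", config@nTraces)
  truth <- vector("list", config@nTraces)
  for (m in seq_len(config@nTraces)) {
    ## continuous-time two-state chain, stationary start
    pClosed <- if (kc + ko > 0) kc / (kc + ko) else 0
    state <- if (runif(1) < pClosed) 2L else 1L
    segState <- integer(0); segStart <- numeric(0); segEnd <- numeric(0)
    t <- 0
    while (t < traceDurS) {
      rate <- if (state == 1L) kc else ko
      dt <- if (rate > 0) rexp(1, rate) else Inf
      segState <- c(segState, state)
      segStart <- c(segStart, t)
      segEnd <- c(segEnd, min(t + dt, traceDurS))
      t <- t + dt
      state <- 3L - state
    }
    ## fractional closed occupancy per bin, via closed time at bin edges
    edges <- seq(0, traceDurS, by = binS)
    closedCum <- numeric(length(edges))
    cs <- segStart[segState == 2L]; ce <- segEnd[segState == 2L]
    if (length(cs)) {
      for (i in seq_along(edges)) {
        ov <- pmin(ce, edges[i]) - pmax(cs, 0)
        closedCum[i] <- sum(ov[ov > 0])
      }
    }
    fClosed <- diff(closedCum) / binS
    eBin <- config@eOpen + fClosed * (config@eClosed - config@eOpen)

    ## donor bleach truncates the signal
    bleachT <- if (config@bleachRatePerS > 0) rexp(1, config@bleachRatePerS) else Inf
    alive <- pmax(0, pmin(1, (bleachT - edges[-length(edges)]) / binS))
    bleachBin <- if (bleachT < traceDurS) floor(bleachT / binS) + 1L else NA_integer_

    lamA <- config@totalRatePerBin * eBin * alive + config@bgPerBin
    lamD <- config@totalRatePerBin * (1 - eBin) * alive + config@bgPerBin
    traces[[m]] <- FretTrace(rpois(nB, lamD), rpois(nB, lamA),
                             binWidthMs = config@binWidthMs,
                             moleculeId = sprintf("mol%04d", m))
    truth[[m]] <- list(
      segments = data.frame(state = segState, startS = segStart, endS = segEnd),
      fClosed = fClosed, bleachBin = bleachBin)
  }
  list(traces = traces, truth = truth)
}

#' Simulate series directly from a discrete-time two-state Gaussian HMM
#'
#' Used to validate the Baum-Welch/Viterbi machinery against known
#' parameters without the binning/bleaching layers of [simulateTraces()].
#'
#' @param nTraces,nBins number and length of the series.
#' @param means,sds state emission means and standard deviations (state 1
#'   low-FRET, state 2 high-FRET).
#' @param pStay per-bin probability of remaining in the current state
#'   (scalar or length 2).
#' @param seed RNG seed.
#' @return list with \code{series} (list of numeric vectors) and
#'   \code{states} (list of integer paths).
#' @export
simulateHmmTraces <- function(nTraces, nBins, means = c(0.3, 0.8),
                              sds = c(0.07, 0.07), pStay = 0.95, seed = 1L) {
  stopifnot(nTraces >= 1, nBins >= 1, length(means) == 2, means[1] < means[2])
  pStay <- rep_len(pStay, 2)
  set.seed(seed)
  A <- rbind(c(pStay[1], 1 - pStay[1]), c(1 - pStay[2], pStay[2]))
  ## stationary distribution of A
  pi1 <- (1 - pStay[2]) / ((1 - pStay[1]) + (1 - pStay[2]))
  series <- vector("list", nTraces); states <- vector("list", nTraces)
  for (m in seq_len(nTraces)) {
    s <- integer(nBins)
    s[1] <- if (runif(1) < pi1) 1L else 2L
    for (t in 2:nBins) s[t] <- if (runif(1) < A[s[t - 1], s[t - 1]]) s[t - 1] else 3L - s[t - 1]
    series[[m]] <- rnorm(nBins, means[s], sds[s])
    states[[m]] <- s
  }
  list(series = series, states = states)
}

#' Simulate a ligand titration
#'
#' At each ligand concentration L the closed-state population follows the
#' one-site binding isotherm \code{P = L / (L + KD)}. In burst mode each
#' concentration yields a photon stream whose doubly labeled molecules split
#' into an open (low-E) and closed (high-E) population with weights
#' \code{1 - P} and \code{P}. In trace mode the bimolecular closing rate is
#' set to \code{kOpen / trueKdUm}, which gives the same stationary closed
#' fraction.
#'
#' @param ligandGridUm ligand concentrations (uM), non-empty.
#' @param trueKdUm true dissociation constant (uM).
#' @param mode \code{"bursts"} or \code{"traces"}.
#' @param nBurstsPerPoint target number of detected bursts per concentration
#'   (burst mode; sets the acquisition duration).
#' @param eOpen,eClosed state FRET efficiencies.
#' @param config template [BurstSimConfig-class] or [TraceSimConfig-class];
#'   populations / kinetic rates are overwritten per concentration.
#' @param seed base RNG seed; each concentration uses \code{seed + i}.
#' @return named list, one element per concentration:
#'   \code{list(ligandUm, trueP, stream, truth)} in burst mode,
#'   \code{list(ligandUm, trueP, traces, truth)} in trace mode.
#' @export
simulateTitration <- function(ligandGridUm, trueKdUm, mode = c("bursts", "traces"),
                              nBurstsPerPoint = 2000,
                              eOpen = 0.35, eClosed = 0.75,
                              config = NULL, seed = 1L) {
  mode <- match.arg(mode)
  if (length(ligandGridUm) == 0) stop("ligand grid must be non-empty")
  if (trueKdUm <= 0) stop("trueKdUm must be > 0")
  out <- vector("list", length(ligandGridUm))
  names(out) <- sprintf("L%g", ligandGridUm)
  for (i in seq_along(ligandGridUm)) {
    L <- ligandGridUm[i]
    P <- L / (L + trueKdUm)
    if (mode == "bursts") {
      cfg <- if (is.null(config)) burstSimConfig() else config
      cfg@populations <- data.frame(
        trueE = c(eOpen, eClosed), weight = c(1 - P, P),
        species = c("DA", "DA"))
      if (P == 0) cfg@populations <- cfg@populations[1, , drop = FALSE]
      if (P == 1) {
        cfg@populations <- cfg@populations[2, , drop = FALSE]
        cfg@populations$weight <- 1
      }
      cfg@durationS <- nBurstsPerPoint / cfg@burstRatePerS
      cfg@seed <- seed + i
      sim <- simulateBursts(cfg)
      out[[i]] <- list(ligandUm = L, trueP = P,
                       stream = sim$stream, truth = sim$truth)
    } else {
      cfg <- if (is.null(config)) traceSimConfig() else config
      cfg@eOpen <- eOpen; cfg@eClosed <- eClosed
      cfg@kCloseIntrinsic <- 0
      cfg@kCloseBimolecular <- cfg@kOpen / trueKdUm
      cfg@ligandUm <- L
      cfg@seed <- seed + i
      sim <- simulateTraces(cfg)
      out[[i]] <- list(ligandUm = L, trueP = P,
                       traces = sim$traces, truth = sim$truth)
    }
  }
  out
}
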