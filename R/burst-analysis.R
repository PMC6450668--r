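#' Sliding-window burst search on a sorted photon timestamp vector
#'
#' A photon is "hot" when at least \code{m} photons (counting itself) fall in
#' the half-open window \code{[t - T/2, t + T/2)} centred on its arrival
#' time. Maximal runs of at least \code{minLength} consecutive hot photons
#' are returned as burst intervals \code{[first, last + 1)} in ticks.
#'
#' @param ts sorted photon timestamps, ticks.
#' @param m minimum photons in the window (default 15).
#' @param tWindowTicks window length T in ticks (default 500, i.e. 500 us at
#'   1 us ticks).
#' @param minLength minimum burst photon count L (default 25).
#' @return data.frame with columns \code{startTick}, \code{endTick}
#'   (half-open), \code{iStart}, \code{iEnd} (photon indices into \code{ts})
#'   and \code{nPhotons}.
#' @export
slidingWindowSearch <- function(ts, m = 15, tWindowTicks = 500, minLength = 25) {
  stopifnot(m >= 1, minLength >= m, tWindowTicks > 0)
  if (is.unsorted(ts)) stop("timestamps must be sorted")
  empty <- data.frame(startTick = numeric(0), endTick = numeric(0),
                      iStart = integer(0), iEnd = integer(0),
                      nPhotons = integer(0))
  n <- length(ts)
  if (n == 0L) return(empty)
  half <- tWindowTicks / 2
  ## photons with tj in [t - T/2, t + T/2): counts of tj < upper minus
  ## tj < lower; the -0.5 trick is exact for integer ticks and half-integer
  ## window edges
  nBelow <- function(x) findInterval(x - 0.5, ts)
  counts <- nBelow(ts + half) - nBelow(ts - half)
  hot <- counts >= m
  r <- rle(hot)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  keep <- r$values & r$lengths >= minLength
  if (!any(keep)) return(empty)
  iS <- starts[keep]; iE <- ends[keep]
  data.frame(startTick = ts[iS], endTick = ts[iE] + 1,
             iStart = iS, iEnd = iE, nPhotons = iE - iS + 1L)
}

#' Parameters of the dual-channel burst search
#'
#' @param m neighbor threshold M (photons, default 15).
#' @param tWindowUs window length T (us, default 500).
#' @param minLength minimum burst photons L (default 25).
#' @param minTotalPhotons post-search filter: bursts must have strictly more
#'   than this many photons across the three streams (default 150).
#' @return a plain list of validated parameters.
#' @export
burstSearchParams <- function(m = 15, tWindowUs = 500, minLength = 25,
                              minTotalPhotons = 150) {
  stopifnot(m >= 1, minLength >= m, tWindowUs > 0, minTotalPhotons >= 0)
  list(m = m, tWindowUs = tWindowUs, minLength = minLength,
       minTotalPhotons = minTotalPhotons)
}

#' Dual-channel burst search on a us-ALEX photon stream
#'
#' Runs one sliding-window search on all donor-excitation photons (DD and DA
#' merged) and a second on the acceptor photons detected under acceptor
#' excitation (AA); the returned bursts are the intersections of intervals
#' where both searches are simultaneously active, i.e. stretches where both
#' fluorophores are demonstrably active. Photon counts F_DD, F_DA, F_AA are
#' tallied within each intersection, apparent E and stoichiometry S computed,
#' and bursts with a total of \code{minTotalPhotons} photons or fewer are
#' dropped.
#'
#' @param stream a [PhotonStream-class] with both excitation phases.
#' @param params list from [burstSearchParams()].
#' @return data.frame with one row per burst: \code{startTick},
#'   \code{endTick} (half-open), \code{durationMs}, \code{fDD}, \code{fDA},
#'   \code{fAA}, \code{eApp}, \code{s}.
#' @seealso [computeES()], [applyCorrections()], [selectPopulation()]
#' @export
dualChannelBurstSearch <- function(stream, params = burstSearchParams()) {
  stopifnot(is(stream, "PhotonStream"))
  ts <- stream@timestamps
  tTicks <- params$tWindowUs * 1e-6 / stream@tickSeconds
  dex <- stream@excitation == "Dex"
  aexA <- !dex & stream@detector == "A"
  if (!any(!dex))
    stop("stream has no acceptor-excitation photons; ",
         "run slidingWindowSearch() on the donor-excitation photons instead")
  s1 <- slidingWindowSearch(ts[dex], params$m, tTicks, params$minLength)
  s2 <- slidingWindowSearch(ts[aexA], params$m, tTicks, params$minLength)
  iv <- intersectIntervals(s1$startTick, s1$endTick, s2$startTick, s2$endTick)
  if (nrow(iv) == 0L)
    return(data.frame(startTick = numeric(0), endTick = numeric(0),
                      durationMs = numeric(0), fDD = integer(0),
                      fDA = integer(0), fAA = integer(0),
                      eApp = numeric(0), s = numeric(0)))
  tDD <- ts[dex & stream@detector == "D"]
  tDA <- ts[dex & stream@detector == "A"]
  tAA <- ts[aexA]
  countIn <- function(tv, lo, hi) {   # photons with lo <= t < hi
    findInterval(hi - 0.5, tv) - findInterval(lo - 0.5, tv)
  }
  fDD <- countIn(tDD, iv$start, iv$end)
  fDA <- countIn(tDA, iv$start, iv$end)
  fAA <- countIn(tAA, iv$start, iv$end)
  keep <- (fDD + fDA + fAA) > params$minTotalPhotons
  es <- computeES(fDD[keep], fDA[keep], fAA[keep])
  data.frame(startTick = iv$start[keep], endTick = iv$end[keep],
             durationMs = (iv$end - iv$start)[keep] * stream@tickSeconds * 1e3,
             fDD = fDD[keep], fDA = fDA[keep], fAA = fAA[keep],
             eApp = es$eApp, s = es$s)
}

# intersection of two sets of sorted disjoint half-open intervals
intersectIntervals <- function(s1, e1, s2, e2) {
  if (!length(s1) || !length(s2))
    return(data.frame(start = numeric(0), end = numeric(0)))
  out_s <- numeric(0); out_e <- numeric(0)
  i <- 1L; j <- 1L
  while (i <= length(s1) && j <= length(s2)) {
    lo <- max(s1[i], s2[j]); hi <- min(e1[i], e2[j])
    if (lo < hi) { out_s <- c(out_s, lo); out_e <- c(out_e, hi) }
    if (e1[i] < e2[j]) i <- i + 1L else j <- j + 1L
  }
  data.frame(start = out_s, end = out_e)
}

#' Apparent FRET efficiency and stoichiometry of bursts
#'
#' \code{eApp = fDA / (fDA + fDD)} and
#' \code{s = (fDD + fDA) / (fDD + fDA + fAA)}. Bursts with a zero
#' denominator get \code{NA} (they are excluded from histograms).
#'
#' @param fDD,fDA,fAA photon counts per stream (vectors).
#' @return data.frame with columns \code{eApp} and \code{s}.
#' @export
computeES <- function(fDD, fDA, fAA) {
  stopifnot(length(fDD) == length(fDA), length(fDA) == length(fAA))
  if (any(c(fDD, fDA, fAA) < 0, na.rm = TRUE)) stop("counts must be >= 0")
  dexTot <- fDD + fDA
  allTot <- dexTot + fAA
  eApp <- ifelse(dexTot > 0, fDA / dexTot, NA_real_)
  s <- ifelse(allTot > 0, dexTot / allTot, NA_real_)
  data.frame(eApp = eApp, s = s)
}

#' Corrected FRET efficiency of bursts
#'
#' Applies the standard ALEX correction chain: per-stream background
#' subtraction (rate x burst duration), then removal of donor leakage
#' (\code{leakage x DD'}) and acceptor direct excitation
#' (\code{directExcitation x AA'}) from the DA counts, then the
#' detection-factor correction
#' \code{eCorr = DA'' / (DA'' + gamma x DD')}. The corrected efficiency may
#' fall slightly outside [0, 1]; bursts whose corrected denominators become
#' non-positive (over-subtraction) are flagged with \code{NA}.
#'
#' @param bursts data.frame from [dualChannelBurstSearch()].
#' @param cfg an [InstrumentConfig-class].
#' @return \code{bursts} with an added \code{eCorr} column.
#' @export
applyCorrections <- function(bursts, cfg) {
  stopifnot(is(cfg, "InstrumentConfig"))
  validObject(cfg)
  durS <- bursts$durationMs * 1e-3
  dd <- bursts$fDD - cfg@bgDD * 1e3 * durS
  da <- bursts$fDA - cfg@bgDA * 1e3 * durS
  aa <- bursts$fAA - cfg@bgAA * 1e3 * durS
  daCorr <- da - cfg@leakage * dd - cfg@directExcitation * aa
  den <- daCorr + cfg@gamma * dd
  eCorr <- ifelse(den > 0, daCorr / den, NA_real_)
  bursts$eCorr <- eCorr
  bursts
}

#' Select a burst population by an E/S rectangle
#'
#' Mirrors the 2D E/S histogram gating that isolates doubly labeled
#' molecules from donor-only (S near 1) and acceptor-only (S near 0)
#' species.
#'
#' @param bursts burst data.frame with \code{eApp} and \code{s} columns.
#' @param eRange,sRange inclusive selection intervals in [0, 1].
#' @return the selected subset of \code{bursts} (message reports the
#'   fraction kept; empty selections warn).
#' @export
selectPopulation <- function(bursts, eRange = c(0, 1), sRange = c(0.3, 0.8)) {
  stopifnot(length(eRange) == 2, length(sRange) == 2,
            all(c(eRange, sRange) >= 0), all(c(eRange, sRange) <= 1))
  keep <- !is.na(bursts$eApp) & !is.na(bursts$s) &
    bursts$eApp >= eRange[1] & bursts$eApp <= eRange[2] &
    bursts$s >= sRange[1] & bursts$s <= sRange[2]
  message(sprintf("selected %d of %d bursts (E in [%g, %g], S in [%g, %g])",
                  sum(keep), nrow(bursts), eRange[1], eRange[2],
                  sRange[1], sRange[2]))
  if (!any(keep)) warning("selection is empty")
  bursts[keep, , drop = FALSE]
}

#' Fit one or two Gaussians to a FRET efficiency histogram
#'
#' The values are binned at \code{binWidth} and the counts fitted by
#' nonlinear least squares with \code{A exp(-(x - mu)^2 / (2 sigma^2))} per
#' component. The 95% Wald confidence interval of each mean is
#' \code{mu +/- 1.96 SE(mu)} from the fit covariance. For two components
#' the relative areas \code{A_i sigma_i / sum(A sigma)} are reported and
#' components are ordered by ascending mean.
#'
#' @param eValues FRET efficiencies (NA dropped); at least 30.
#' @param nComponents 1 or 2.
#' @param binWidth histogram bin width (default 0.025 E-units).
#' @param anchors optional length-2 vector of approximate component means
#'   used to initialize the two-component fit (default: 10th/90th
#'   percentiles).
#' @return a [FretHistogramFit-class].
#' @export
fitEHistogram <- function(eValues, nComponents = 1, binWidth = 0.025,
                          anchors = NULL) {
  e <- eValues[!is.na(eValues)]
  if (length(e) < 30) stop("need at least 30 FRET values to fit")
  if (sd(e) < 1e-12) stop("degenerate input: all FRET values identical")
  stopifnot(nComponents %in% c(1, 2))
  lo <- floor(min(e) / binWidth) * binWidth
  hi <- ceiling(max(e) / binWidth) * binWidth
  breaks <- seq(lo, hi + binWidth / 2, by = binWidth)
  h <- graphics::hist(e, breaks = breaks, plot = FALSE)
  x <- h$mids; y <- h$counts

  if (nComponents == 1) {
    st <- list(A = max(y), mu = mean(e), sg = sd(e))
    fit <- minpack.lm::nlsLM(
      y ~ A * exp(-(x - mu)^2 / (2 * sg^2)),
      start = st, control = minpack.lm::nls.lm.control(maxiter = 500))
    cf <- coef(fit)
    if (cf[["sg"]] <= 0) cf[["sg"]] <- abs(cf[["sg"]])
    se <- sqrt(diag(vcov(fit)))[["mu"]]
    new("FretHistogramFit",
        means = cf[["mu"]], sigmas = abs(cf[["sg"]]), amplitudes = cf[["A"]],
        meanCi95 = matrix(cf[["mu"]] + c(-1.96, 1.96) * se, 1, 2),
        areaFractions = 1, nValues = length(e), binWidth = binWidth)
  } else {
    if (is.null(anchors)) anchors <- quantile(e, c(0.1, 0.9), names = FALSE)
    anchors <- sort(anchors)
    grp <- abs(e - anchors[1]) > abs(e - anchors[2])   # TRUE = high comp.
    sg0 <- max(min(sd(e[!grp]), sd(e[grp]), na.rm = TRUE), binWidth / 2,
               na.rm = TRUE)
    st <- list(A1 = max(y[x <= mean(anchors)], 1),
               mu1 = anchors[1], sg1 = sg0,
               A2 = max(y[x > mean(anchors)], 1),
               mu2 = anchors[2], sg2 = sg0)
    fit <- tryCatch(
      minpack.lm::nlsLM(
        y ~ A1 * exp(-(x - mu1)^2 / (2 * sg1^2)) +
            A2 * exp(-(x - mu2)^2 / (2 * sg2^2)),
        start = st, control = minpack.lm::nls.lm.control(maxiter = 1000)),
      error = function(e2) stop("two-component fit did not converge: ",
                                conditionMessage(e2)))
    cf <- coef(fit)
    se <- sqrt(diag(vcov(fit)))
    mus <- c(cf[["mu1"]], cf[["mu2"]])
    sgs <- abs(c(cf[["sg1"]], cf[["sg2"]]))
    amps <- c(cf[["A1"]], cf[["A2"]])
    ses <- c(se[["mu1"]], se[["mu2"]])
    ord <- order(mus)                      # components by ascending mean
    mus <- mus[ord]; sgs <- sgs[ord]; amps <- amps[ord]; ses <- ses[ord]
    areas <- amps * sgs
    new("FretHistogramFit",
        means = mus, sigmas = sgs, amplitudes = amps,
        meanCi95 = cbind(mus - 1.96 * ses, mus + 1.96 * ses),
        areaFractions = areas / sum(areas),
        nValues = length(e), binWidth = binWidth)
  }
}

#' Two-sample Kolmogorov-Smirnov comparison of FRET distributions
#'
#' @param a,b numeric samples (NA dropped), both non-empty; a warning is
#'   issued below n = 5 where the asymptotic p-value is unreliable.
#' @return list with \code{D} (max ECDF gap) and \code{p} (asymptotic
#'   two-sided p-value).
#' @export
ksTwoSample <- function(a, b) {
  a <- a[!is.na(a)]; b <- b[!is.na(b)]
  if (!length(a) || !length(b)) stop("both samples must be non-empty")
  if (length(a) < 5 || length(b) < 5)
    warning("sample size < 5: asymptotic KS p-value unreliable")
  kt <- suppressWarnings(ks.test(a, b, exact = FALSE))
  list(D = unname(kt$statistic), p = unname(kt$p.value))
}

#' Convert between FRET efficiency and inter-dye distance
#'
#' \code{E = 1 / (1 + (R / R0)^6)}, hence
#' \code{R = R0 ((1 - E) / E)^(1/6)}; the two functions are exact mutual
#' inverses. At \code{R = R0} the efficiency is exactly 0.5.
#'
#' @param e FRET efficiency, strictly inside (0, 1).
#' @param r distance, > 0 (same unit as \code{r0Nm}).
#' @param r0Nm Forster radius (nm); 5.1 for Alexa555/Alexa647, 6.2 for
#'   Cy3B/Atto647N.
#' @return distance in nm, or efficiency.
#' @export
efficiencyToDistance <- function(e, r0Nm = 5.1) {
  stopifnot(r0Nm > 0)
  if (any(e <= 0 | e >= 1))
    stop("E must be strictly inside (0, 1): E = 0 or 1 maps to an ",
         "infinite or zero distance")
  r0Nm * ((1 - e) / e)^(1 / 6)
}

#' @rdname efficiencyToDistance
#' @export
distanceToEfficiency <- function(r, r0Nm = 5.1) {
  stopifnot(r0Nm > 0)
  if (any(r <= 0)) stop("distance must be > 0")
  1 / (1 + (r / r0Nm)^6)
}
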