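#' Dwell-time statistics from decoded state trajectories
#'
#' A dwell is a maximal run of one state times the bin width. The first and
#' last dwell of each trace are censored (their true start or end was not
#' observed) and are excluded from the mean-lifetime estimates by default; a
#' constant trace is one fully censored dwell. Dwell durations always sum to
#' the analyzed trace duration exactly. Lifetime means and their standard
#' errors are computed over the pooled (un)censored dwells; occupancy is the
#' fraction of analyzed bins in the high-FRET state and the transition
#' frequency is state changes per minute of analyzed time.
#'
#' @param trajectories a [StateTrajectory-class] or list of them (one per
#'   trace); plain integer vectors of 1/2 states are also accepted.
#' @param binWidthMs bin width used for decoding (ms).
#' @param includeCensored include censored dwells in the lifetime estimates
#'   (default FALSE).
#' @return a [DwellTable-class].
#' @seealso [viterbiDecode()], [kineticOrderTest()]
#' @export
extractDwells <- function(trajectories, binWidthMs, includeCensored = FALSE) {
  stopifnot(binWidthMs > 0)
  if (is(trajectories, "StateTrajectory") || is.numeric(trajectories))
    trajectories <- list(trajectories)
  paths <- lapply(trajectories, function(tr) {
    s <- if (is(tr, "StateTrajectory")) tr@states else as.integer(tr)
    stopifnot(all(s %in% c(1L, 2L)))
    s
  })
  paths <- paths[vapply(paths, length, 0L) > 0]
  if (!length(paths)) stop("no non-empty trajectories")

  rows <- lapply(seq_along(paths), function(i) {
    r <- rle(paths[[i]])
    k <- length(r$lengths)
    data.frame(trace = i, state = r$values, nBins = r$lengths,
               durationMs = r$lengths * binWidthMs,
               censored = seq_len(k) %in% c(1L, k))
  })
  dw <- do.call(rbind, rows)

  use <- if (includeCensored) rep(TRUE, nrow(dw)) else !dw$censored
  mlt <- slt <- rep(NA_real_, 2); nd <- integer(2)
  for (s in 1:2) {
    d <- dw$durationMs[use & dw$state == s]
    nd[s] <- length(d)
    if (length(d) >= 1) mlt[s] <- mean(d)
    if (length(d) >= 2) slt[s] <- sd(d) / sqrt(length(d))
  }
  totalBins <- sum(vapply(paths, length, 0L))
  occHigh <- sum(vapply(paths, function(p) sum(p == 2L), 0L)) / totalBins
  nTrans <- sum(vapply(paths, function(p) sum(diff(p) != 0L), 0L))
  minutes <- totalBins * binWidthMs / 6e4

  new("DwellTable", dwells = dw, binWidthMs = binWidthMs,
      meanLifetimeMs = setNames(mlt, c("open", "closed")),
      semLifetimeMs = setNames(slt, c("open", "closed")),
      nDwells = nd, occupancyHigh = occHigh,
      transitionsPerMinute = nTrans / minutes,
      includeCensored = includeCensored)
}

#' Per-molecule bootstrap of the mean state lifetimes
#'
#' Alternative to the pooled standard error of [extractDwells()]: resamples
#' whole molecules with replacement and returns the bootstrap standard
#' error of each mean lifetime.
#'
#' @param dwellTable a [DwellTable-class].
#' @param nBoot bootstrap replicates (default 200).
#' @param seed RNG seed.
#' @return named numeric, bootstrap s.e. of the open and closed lifetimes.
#' @export
bootstrapLifetimeSem <- function(dwellTable, nBoot = 200, seed = 1L) {
  stopifnot(is(dwellTable, "DwellTable"))
  dw <- dwellTable@dwells
  use <- if (dwellTable@includeCensored) rep(TRUE, nrow(dw)) else !dw$censored
  dw <- dw[use, , drop = FALSE]
  ids <- unique(dw$trace)
  set.seed(seed)
  bootMeans <- matrix(NA_real_, nBoot, 2)
  for (b in seq_len(nBoot)) {
    pick <- sample(ids, length(ids), replace = TRUE)
    d <- do.call(rbind, lapply(pick, function(i) dw[dw$trace == i, ]))
    for (s in 1:2) {
      x <- d$durationMs[d$state == s]
      if (length(x)) bootMeans[b, s] <- mean(x)
    }
  }
  setNames(apply(bootMeans, 2, sd, na.rm = TRUE), c("open", "closed"))
}

#' Kinetic-order test across ligand concentrations
#'
#' For each concentration the closing rate is 1 / (mean open lifetime) and
#' the opening rate 1 / (mean closed lifetime). Each rate is regressed
#' linearly on ligand concentration. The verdict is \code{"induced fit"}
#' when the closing-rate slope is significantly positive (its 95% CI
#' excludes 0) while the opening-rate slope CI contains 0 — i.e. closing is
#' first-order in ligand and opening zeroth-order;
#' \code{"not concentration-dependent"} when both CIs contain 0; otherwise
#' \code{"indeterminate"} and both fits are simply reported.
#'
#' @param dwellTables list of [DwellTable-class], one per concentration.
#' @param ligandUm ligand concentrations (uM), same length, at least 3.
#' @return list with \code{closing} and \code{opening} (each: \code{rates},
#'   \code{slope}, \code{slopeCi95}, \code{intercept}, \code{r2}) and
#'   \code{verdict}.
#' @export
kineticOrderTest <- function(dwellTables, ligandUm) {
  if (length(dwellTables) != length(ligandUm) || length(ligandUm) < 3)
    stop("need dwell tables for at least 3 ligand concentrations")
  stopifnot(all(vapply(dwellTables, is, TRUE, "DwellTable")))
  kClose <- vapply(dwellTables, function(d) 1e3 / d@meanLifetimeMs[["open"]], 0)
  kOpen <- vapply(dwellTables, function(d) 1e3 / d@meanLifetimeMs[["closed"]], 0)
  fitOne <- function(rate) {
    fit <- lm(rate ~ ligandUm)
    ci <- confint(fit)["ligandUm", ]
    list(rates = rate, slope = unname(coef(fit)[["ligandUm"]]),
         slopeCi95 = unname(ci),
         intercept = unname(coef(fit)[["(Intercept)"]]),
         r2 = summary(fit)$r.squared)
  }
  closing <- fitOne(kClose)
  opening <- fitOne(kOpen)
  closePos <- closing$slopeCi95[1] > 0
  closeZero <- closing$slopeCi95[1] <= 0 && closing$slopeCi95[2] >= 0
  openZero <- opening$slopeCi95[1] <= 0 && opening$slopeCi95[2] >= 0
  verdict <- if (closePos && openZero) "induced fit"
  else if (closeZero && openZero) "not concentration-dependent"
  else "indeterminate"
  list(closing = closing, opening = opening, verdict = verdict)
}
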