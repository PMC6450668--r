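#' Dissociation constant from a closed-population fraction
#'
#' One-binding-site model: at ligand concentration L the closed fraction is
#' \code{P = L / (L + KD)}, hence \code{KD = L (1 - P) / P}.
#'
#' @param ligandUm ligand concentration L (uM), > 0.
#' @param p closed-population fraction, strictly inside (0, 1).
#' @return K_D in uM.
#' @seealso [kdFit()], [populationFromHistogram()]
#' @export
kdFromPopulation <- function(ligandUm, p) {
  stopifnot(ligandUm > 0)
  if (any(p <= 0 | p >= 1))
    stop("P must be strictly inside (0, 1); at P = 0 or 1 the single-point ",
         "K_D is undefined")
  ligandUm * (1 - p) / p
}

#' Fit the one-site binding isotherm to a titration
#'
#' Least squares of \code{P(L) = L / (L + KD)} over at least 3 titration
#' points, optionally weighted by \code{1 / sqrt(n)} counting error
#' (weights \code{sqrt(n)} in the regression). The 95% CI comes from the
#' fit covariance (Wald). On noise-free points the fit reproduces the
#' single-point formula exactly.
#'
#' @param points data.frame with columns \code{L} (uM), \code{P} and
#'   optionally \code{n} (bursts or traces per point).
#' @param weightByCounts weight points by their counts (default TRUE when an
#'   \code{n} column is present).
#' @return list with \code{kd} (uM), \code{ci95}, \code{se}.
#' @export
kdFit <- function(points, weightByCounts = "n" %in% names(points)) {
  stopifnot(all(c("L", "P") %in% names(points)))
  points <- points[complete.cases(points[, c("L", "P")]), , drop = FALSE]
  if (nrow(points) < 3) stop("need at least 3 titration points")
  if (any(points$L < 0) || any(points$P < 0 | points$P > 1))
    stop("require L >= 0 and P in [0, 1]")
  w <- if (isTRUE(weightByCounts) && "n" %in% names(points))
    sqrt(points$n) else rep(1, nrow(points))
  kd0 <- tryCatch(stats::median(kdFromPopulation(points$L[points$P > 0 & points$P < 1],
                                                 points$P[points$P > 0 & points$P < 1])),
                  error = function(e) 1)
  if (!is.finite(kd0) || kd0 <= 0) kd0 <- 1
  fit <- minpack.lm::nlsLM(P ~ L / (L + kd), data = points,
                           start = list(kd = kd0), weights = w,
                           lower = 1e-9,
                           control = minpack.lm::nls.lm.control(maxiter = 500))
  kd <- coef(fit)[["kd"]]
  se <- sqrt(vcov(fit)[1, 1])
  list(kd = kd, ci95 = kd + c(-1.96, 1.96) * se, se = se)
}

#' Closed-population fraction from a FRET histogram
#'
#' Fits a two-component Gaussian mixture to the burst FRET values (anchored
#' at the supplied open/closed means to fix component identity) and returns
#' the area fraction of the closed (high-mean) component. Errors when the
#' fitted components are unresolved (mean separation below one pooled
#' sigma).
#'
#' @param eValues burst FRET efficiencies.
#' @param openMean,closedMean approximate state means used to anchor the
#'   fit (e.g. from the ligand-free and saturating conditions).
#' @param binWidth histogram bin width (default 0.025).
#' @return list with \code{P} (closed-component area fraction) and
#'   \code{fit} (the [FretHistogramFit-class]).
#' @export
populationFromHistogram <- function(eValues, openMean, closedMean,
                                    binWidth = 0.025) {
  stopifnot(openMean < closedMean)
  fit <- fitEHistogram(eValues, nComponents = 2, binWidth = binWidth,
                       anchors = c(openMean, closedMean))
  sep <- diff(fit@means)
  pooledSigma <- sqrt(mean(fit@sigmas^2))
  if (sep < pooledSigma)
    stop(sprintf(paste0("components unresolved: mean separation %.3f below ",
                        "pooled sigma %.3f"), sep, pooledSigma))
  list(P = fit@areaFractions[2], fit = fit)
}

#' Steady-state fluorescence anisotropy
#'
#' \code{G = I_HV / I_HH} corrects the polarization sensitivity of the
#' detection path; the anisotropy is
#' \code{r = (I_VV - G I_VH) / (I_VV + 2 G I_VH)}. High r means restricted
#' dye rotation, which would invalidate a distance reading of E.
#'
#' @param iVV,iVH intensities with vertical excitation, vertical/horizontal
#'   emission.
#' @param iHV,iHH intensities with horizontal excitation.
#' @return list with \code{G} and \code{r}.
#' @export
anisotropy <- function(iVV, iVH, iHV, iHH) {
  if (any(c(iVV, iVH, iHV, iHH) < 0)) stop("intensities must be >= 0")
  if (iHH <= 0) stop("I_HH must be > 0 to compute G")
  G <- iHV / iHH
  den <- iVV + 2 * G * iVH
  if (den <= 0) stop("zero denominator in anisotropy")
  list(G = G, r = (iVV - G * iVH) / den)
}

#' Ensemble apparent FRET efficiency
#'
#' Bulk-fluorimeter proxy: \code{E = I_acceptor / (I_acceptor + I_donor)}.
#'
#' @param iDonor,iAcceptor emission intensities, non-negative with a
#'   positive sum.
#' @return apparent FRET efficiency in [0, 1].
#' @export
ensembleFret <- function(iDonor, iAcceptor) {
  if (any(c(iDonor, iAcceptor) < 0)) stop("intensities must be >= 0")
  if (iDonor + iAcceptor <= 0) stop("total intensity must be > 0")
  iAcceptor / (iAcceptor + iDonor)
}
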