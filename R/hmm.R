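#' Fit a two-state Gaussian-emission HMM by Baum-Welch
#'
#' Expectation-maximization over one or more FRET series jointly (one global
#' model per experimental condition), with Rabiner per-step scaling so that
#' long series never underflow. The log-likelihood is non-decreasing at
#' every iteration; fitting stops when it improves by less than \code{tol}
#' or after \code{maxIter} iterations. States are relabeled by ascending
#' emission mean on return (state 1 = open/low FRET, state 2 =
#' closed/high FRET).
#'
#' Default initialization is deterministic: emission means at the 10th/90th
#' percentiles of the pooled values, both variances at the pooled variance,
#' stay probability 0.95, uniform initial distribution. If a state's
#' responsibility mass collapses the fit restarts from a perturbed
#' initialization (up to 3 times) before failing.
#'
#' @param fretSeries numeric vector or list of numeric vectors (per-bin
#'   apparent FRET, one vector per molecule); NA bins are dropped.
#' @param init optional [FretHmm-class] to start from.
#' @param tol log-likelihood convergence tolerance (default 1e-6).
#' @param maxIter maximum EM iterations (default 1000).
#' @return a [FretHmm-class]; slot \code{logLikTrace} holds the per-iteration
#'   log-likelihood, \code{degenerate} is TRUE when the two states ended up
#'   with indistinguishable emissions (transition estimates unidentifiable).
#' @seealso [viterbiDecode()], [forwardLogLik()], [simulateHmmTraces()]
#' @export
baumWelchFit <- function(fretSeries, init = NULL, tol = 1e-6, maxIter = 1000) {
  series <- normalizeSeries(fretSeries)
  pooled <- unlist(series)
  if (length(pooled) < 2) stop("need at least one series with >= 2 bins")

  makeInit <- function(perturb = 0) {
    if (!is.null(init) && perturb == 0) {
      list(means = init@means, vars = init@variances,
           trans = init@transitionMatrix, pi = init@initialProbs)
    } else {
      mns <- quantile(pooled, c(0.1, 0.9), names = FALSE)
      if (perturb > 0)
        mns <- mns + rnorm(2, 0, 0.05 * perturb * max(diff(mns), 0.1))
      if (diff(mns) < 1e-6) mns <- mns + c(-0.05, 0.05)
      v <- max(var(pooled), 1e-6)
      list(means = sort(mns), vars = c(v, v),
           trans = rbind(c(0.95, 0.05), c(0.05, 0.95)), pi = c(0.5, 0.5))
    }
  }

  for (attempt in 0:3) {
    par <- makeInit(attempt)
    res <- tryCatch(bwRun(series, par, tol, maxIter),
                    error = function(e) e)
    if (!inherits(res, "error")) {
      return(bwFinalize(res))
    }
    if (attempt == 3) stop("Baum-Welch failed after 3 perturbed restarts: ",
                           conditionMessage(res))
  }
}

normalizeSeries <- function(fretSeries) {
  if (is.numeric(fretSeries)) fretSeries <- list(fretSeries)
  stopifnot(is.list(fretSeries), length(fretSeries) > 0)
  series <- lapply(fretSeries, function(s) as.numeric(s[!is.na(s)]))
  series[vapply(series, length, 0L) >= 2]
}

bwRun <- function(series, par, tol, maxIter) {
  means <- par$means; vars <- par$vars; trans <- par$trans; piv <- par$pi
  llTrace <- numeric(0)
  llPrev <- -Inf
  for (iter in seq_len(maxIter)) {
    gSum <- c(0, 0); gObs <- c(0, 0); gObs2 <- c(0, 0); g1 <- c(0, 0)
    xiS <- matrix(0, 2, 2); ll <- 0
    for (s in series) {
      es <- .hmmEStepCpp(s, means, vars, trans, piv)
      ll <- ll + es$logLik
      gSum <- gSum + es$gammaSum; gObs <- gObs + es$gammaObs
      gObs2 <- gObs2 + es$gammaObs2; g1 <- g1 + es$gamma1
      xiS <- xiS + es$xiSum
    }
    llTrace <- c(llTrace, ll)
    if (any(gSum < 1e-8))
      stop("state responsibility mass collapsed to zero")
    ## M step
    means <- gObs / gSum
    vars <- pmax(gObs2 / gSum - means^2, 1e-8)
    rs <- rowSums(xiS)
    if (all(rs > 0)) trans <- xiS / rs
    piv <- g1 / sum(g1)
    if (is.finite(llPrev) && abs(ll - llPrev) < tol) {
      return(list(means = means, vars = vars, trans = trans, pi = piv,
                  logLik = ll, iter = iter, converged = TRUE,
                  llTrace = llTrace))
    }
    llPrev <- ll
  }
  list(means = means, vars = vars, trans = trans, pi = piv,
       logLik = llPrev, iter = maxIter, converged = FALSE, llTrace = llTrace)
}

bwFinalize <- function(res) {
  ord <- order(res$means)
  means <- res$means[ord]; vars <- res$vars[ord]
  trans <- res$trans[ord, ord, drop = FALSE]
  piv <- res$pi[ord]
  trans <- trans / rowSums(trans)           # exact row-stochasticity
  degen <- abs(diff(means)) < 1e-6 ||
    abs(diff(res$means)) / sqrt(mean(vars)) < 1e-3
  if (degen)
    warning("emission distributions indistinguishable: ",
            "transition probabilities are not identifiable")
  new("FretHmm", means = means, variances = vars,
      transitionMatrix = trans, initialProbs = piv,
      logLik = res$logLik, nIterations = as.integer(res$iter),
      converged = res$converged, degenerate = degen,
      logLikTrace = res$llTrace)
}

#' Forward log-likelihood of FRET series under a fitted HMM
#'
#' Scaled forward recursion; summed over series when a list is given.
#'
#' @param model a [FretHmm-class].
#' @param fretSeries numeric vector or list of numeric vectors.
#' @return total log-likelihood.
#' @export
forwardLogLik <- function(model, fretSeries) {
  stopifnot(is(model, "FretHmm"))
  series <- normalizeSeries(fretSeries)
  sum(vapply(series, function(s)
    .hmmForwardCpp(s, model@means, model@variances,
                   model@transitionMatrix, model@initialProbs)$logLik, 0))
}

#' Most probable state path of one FRET series (Viterbi)
#'
#' Deterministic given model and data; ties are broken toward the open
#' (low-FRET) state.
#'
#' @param model a fitted [FretHmm-class].
#' @param fretSeries numeric vector (NA bins dropped).
#' @return a [StateTrajectory-class].
#' @export
viterbiDecode <- function(model, fretSeries) {
  stopifnot(is(model, "FretHmm"))
  s <- as.numeric(fretSeries[!is.na(fretSeries)])
  if (length(s) == 0)
    return(new("StateTrajectory", states = integer(0), logProb = 0))
  vt <- .hmmViterbiCpp(s, model@means, model@variances,
                       model@transitionMatrix, model@initialProbs)
  new("StateTrajectory", states = as.integer(vt$states), logProb = vt$logProb)
}
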