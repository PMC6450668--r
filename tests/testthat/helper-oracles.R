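# Independent reference implementations used to cross-check the package.
# These are deliberately naive (exhaustive / enumeration / tick-level) and
# share no code with the implementations they verify.

# O(n^2) neighbor count: photons with >= m neighbors (incl. self) in the
# half-open window [t - T/2, t + T/2), then maximal hot runs of >= minLength.
oracleSlidingSearch <- function(ts, m, tWindow, minLength) {
  n <- length(ts)
  if (n == 0) return(data.frame(startTick = numeric(0), endTick = numeric(0)))
  hot <- vapply(seq_len(n), function(i) {
    sum(ts >= ts[i] - tWindow / 2 & ts < ts[i] + tWindow / 2) >= m
  }, TRUE)
  out_s <- numeric(0); out_e <- numeric(0)
  i <- 1
  while (i <= n) {
    if (hot[i]) {
      j <- i
      while (j < n && hot[j + 1]) j <- j + 1
      if (j - i + 1 >= minLength) {
        out_s <- c(out_s, ts[i]); out_e <- c(out_e, ts[j] + 1)
      }
      i <- j + 1
    } else i <- i + 1
  }
  data.frame(startTick = out_s, endTick = out_e)
}

# tick-level dual-channel oracle: mark active ticks of each search, AND
# them, read off maximal runs, tally counts by exhaustive membership.
oracleDualSearch <- function(stream, m, tWindowTicks, minLength, minTotal) {
  ts <- timestamps(stream); det <- detector(stream); exc <- excitation(stream)
  s1 <- oracleSlidingSearch(ts[exc == "Dex"], m, tWindowTicks, minLength)
  s2 <- oracleSlidingSearch(ts[exc == "Aex" & det == "A"], m, tWindowTicks,
                            minLength)
  if (nrow(s1) == 0 || nrow(s2) == 0)
    return(data.frame(startTick = numeric(0), endTick = numeric(0),
                      fDD = integer(0), fDA = integer(0), fAA = integer(0)))
  maxTick <- max(ts) + 2
  act1 <- act2 <- rep(FALSE, maxTick)
  for (k in seq_len(nrow(s1))) act1[(s1$startTick[k] + 1):s1$endTick[k]] <- TRUE
  for (k in seq_len(nrow(s2))) act2[(s2$startTick[k] + 1):s2$endTick[k]] <- TRUE
  both <- act1 & act2
  r <- rle(both)
  ends <- cumsum(r$lengths); starts <- ends - r$lengths + 1
  iv <- data.frame(start = starts[r$values] - 1, end = ends[r$values])
  if (nrow(iv) == 0)
    return(data.frame(startTick = numeric(0), endTick = numeric(0),
                      fDD = integer(0), fDA = integer(0), fAA = integer(0)))
  res <- do.call(rbind, lapply(seq_len(nrow(iv)), function(k) {
    inIv <- ts >= iv$start[k] & ts < iv$end[k]
    data.frame(startTick = iv$start[k], endTick = iv$end[k],
               fDD = sum(inIv & exc == "Dex" & det == "D"),
               fDA = sum(inIv & exc == "Dex" & det == "A"),
               fAA = sum(inIv & exc == "Aex" & det == "A"))
  }))
  res[res$fDD + res$fDA + res$fAA > minTotal, , drop = FALSE]
}

# a clustered random photon stream (background + bursts) with labels forced
# by the 50 us alternation schedule
randomBurstyStream <- function(nBg = 300, nClusters = 3, clusterSize = 150,
                               spanTicks = 2e5) {
  t <- runif(nBg, 0, spanTicks)
  for (k in seq_len(nClusters)) {
    c0 <- runif(1, 0, spanTicks * 0.9)
    t <- c(t, c0 + runif(clusterSize, 0, 2000))
  }
  t <- sort(floor(t))
  det <- sample(c("D", "A"), length(t), replace = TRUE)
  PhotonStream(t, det, alternationPeriodUs = 50, durationS = spanTicks * 1e-6)
}

# exhaustive HMM likelihood: sum over all 2^T state paths
oracleHmmLik <- function(obs, means, vars, trans, init) {
  T <- length(obs)
  paths <- as.matrix(expand.grid(rep(list(1:2), T)))
  tot <- 0
  for (r in seq_len(nrow(paths))) {
    p <- paths[r, ]
    pr <- init[p[1]] * dnorm(obs[1], means[p[1]], sqrt(vars[p[1]]))
    if (T > 1) for (t in 2:T)
      pr <- pr * trans[p[t - 1], p[t]] * dnorm(obs[t], means[p[t]], sqrt(vars[p[t]]))
    tot <- tot + pr
  }
  tot
}

# exhaustive most-probable path
oracleViterbi <- function(obs, means, vars, trans, init) {
  T <- length(obs)
  paths <- as.matrix(expand.grid(rep(list(1:2), T)))
  best <- -Inf; bestPath <- NULL
  for (r in seq_len(nrow(paths))) {
    p <- paths[r, ]
    lp <- log(init[p[1]]) + dnorm(obs[1], means[p[1]], sqrt(vars[p[1]]), log = TRUE)
    if (T > 1) for (t in 2:T)
      lp <- lp + log(trans[p[t - 1], p[t]]) +
        dnorm(obs[t], means[p[t]], sqrt(vars[p[t]]), log = TRUE)
    if (lp > best) { best <- lp; bestPath <- p }
  }
  list(states = unname(bestPath), logProb = best)
}

# unscaled forward recursion (numerically safe only for short series)
oracleForwardUnscaled <- function(obs, means, vars, trans, init) {
  alpha <- init * dnorm(obs[1], means, sqrt(vars))
  if (length(obs) > 1) for (t in 2:length(obs))
    alpha <- (alpha %*% trans)[1, ] * dnorm(obs[t], means, sqrt(vars))
  log(sum(alpha))
}

# brute-force two-sample KS statistic: max ECDF gap over all data points
oracleKsD <- function(a, b) {
  pts <- sort(unique(c(a, b)))
  max(abs(vapply(pts, function(x) mean(a <= x) - mean(b <= x), 0)))
}

randomHmmParams <- function() {
  mns <- sort(runif(2, 0, 1))
  if (diff(mns) < 0.1) mns[2] <- mns[1] + 0.1
  v <- runif(2, 0.002, 0.02)
  p12 <- runif(1, 0.05, 0.5); p21 <- runif(1, 0.05, 0.5)
  list(means = mns, vars = v,
       trans = rbind(c(1 - p12, p12), c(p21, 1 - p21)),
       init = { p <- runif(1, 0.2, 0.8); c(p, 1 - p) })
}

makeHmm <- function(p) {
  new("FretHmm", means = p$means, variances = p$vars,
      transitionMatrix = p$trans, initialProbs = p$init,
      logLik = NA_real_, nIterations = 0L, converged = TRUE,
      degenerate = FALSE, logLikTrace = numeric(0))
}
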