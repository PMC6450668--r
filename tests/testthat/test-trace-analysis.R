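test_that("photon binning uses half-open bins and drops the partial tail", {
  # 10 donor photons inside one 10 ms bin
  st <- PhotonStream(sort(floor(runif(10, 0, 9999))), rep("D", 10),
                     durationS = 0.01)
  tr <- binPhotons(st, 10)
  expect_equal(donorCounts(tr), 10)
  # a photon exactly on the bin edge belongs to the right-hand bin
  st2 <- PhotonStream(10000, "A", durationS = 0.02)
  tr2 <- binPhotons(st2, 10)
  expect_equal(acceptorCounts(tr2), c(0, 1))
  # random stream equals an exhaustive histogram, tail bin dropped
  set.seed(3)
  t <- sort(floor(runif(5000, 0, 123456)))
  det <- sample(c("D", "A"), 5000, TRUE)
  st3 <- PhotonStream(t, det, durationS = 0.123456)
  tr3 <- binPhotons(st3, 10)
  expect_equal(nBins(tr3), 12L)
  for (i in 1:12) {
    inBin <- t >= (i - 1) * 10000 & t < i * 10000
    expect_equal(donorCounts(tr3)[i], sum(inBin & det == "D"))
    expect_equal(acceptorCounts(tr3)[i], sum(inBin & det == "A"))
  }
})

test_that("trace QC applies the bin-count and intensity thresholds", {
  set.seed(21)
  short <- FretTrace(rpois(40, 20), rpois(40, 20))
  q <- qcTrace(short, traceQcParams(requireBleachStep = FALSE))
  expect_false(qcRecord(q)$passed)
  expect_true("min_bins" %in% qcRecord(q)$reasons)

  dim <- FretTrace(rpois(200, 4), rpois(200, 4))
  q2 <- qcTrace(dim, traceQcParams(requireBleachStep = FALSE))
  expect_false(qcRecord(q2)$passed)
  expect_true("min_mean_photons" %in% qcRecord(q2)$reasons)

  flat <- FretTrace(rpois(200, 20), rpois(200, 20))
  q3 <- qcTrace(flat)
  expect_false(qcRecord(q3)$passed)
  expect_true("no_bleach_step" %in% qcRecord(q3)$reasons)
})

test_that("bleach steps are located within 2 bins in >= 95% of seeds", {
  hits <- 0L
  for (seed in 1:40) {
    set.seed(seed)
    don <- c(rpois(299, 25), rpois(101, 0.5))
    acc <- c(rpois(299, 25), rpois(101, 0.5))
    q <- qcTrace(FretTrace(don, acc))
    if (isTRUE(qcRecord(q)$passed) &&
        abs(qcRecord(q)$bleachBin - 300L) <= 2) hits <- hits + 1L
  }
  expect_gte(hits, 38L)
})

test_that("per-bin apparent FRET is the red fraction with degenerate flags", {
  tr <- FretTrace(c(5, 0, 0), c(15, 7, 0))
  expect_warning(fr <- apparentFretPerBin(tr), "QC has not been run")
  expect_equal(fr[1:2], c(0.75, 1))
  expect_true(is.na(fr[3]))

  failed <- qcTrace(FretTrace(rpois(10, 3), rpois(10, 3)))
  expect_error(apparentFretPerBin(failed), "failed QC")

  # QC-passed trace: only the pre-bleach region is analyzed
  set.seed(4)
  tr2 <- qcTrace(FretTrace(c(rpois(199, 25), rpois(101, 0.4)),
                           c(rpois(199, 25), rpois(101, 0.4))))
  expect_true(qcRecord(tr2)$passed)
  expect_equal(length(apparentFretPerBin(tr2)), qcRecord(tr2)$analyzedBins)
})

test_that("forward likelihood and Viterbi equal exhaustive enumeration", {
  set.seed(77)
  for (rep in 1:30) {
    p <- randomHmmParams()
    T <- sample(2:10, 1)
    obs <- runif(T)
    model <- makeHmm(p)
    expect_equal(forwardLogLik(model, obs),
                 log(oracleHmmLik(obs, p$means, p$vars, p$trans, p$init)),
                 tolerance = 1e-8)
    vt <- viterbiDecode(model, obs)
    want <- oracleViterbi(obs, p$means, p$vars, p$trans, p$init)
    expect_equal(stateSeq(vt), as.integer(want$states))
    expect_equal(vt@logProb, want$logProb, tolerance = 1e-8)
  }
})

test_that("scaled and unscaled forward recursions agree on safe inputs", {
  set.seed(6)
  for (rep in 1:10) {
    p <- randomHmmParams()
    obs <- runif(20)
    model <- makeHmm(p)
    expect_equal(forwardLogLik(model, obs),
                 oracleForwardUnscaled(obs, p$means, p$vars, p$trans, p$init),
                 tolerance = 1e-10)
  }
})

test_that("Baum-Welch recovers known parameters and never decreases logLik", {
  sim <- simulateHmmTraces(100, 200, means = c(0.3, 0.8), sds = c(0.07, 0.07),
                           pStay = 0.95, seed = 15)
  m <- baumWelchFit(sim$series)
  expect_lt(max(abs(emissionMeans(m) - c(0.3, 0.8))), 0.02)
  expect_lt(max(abs(diag(transitionMatrix(m)) - 0.95)), 0.02)
  expect_lt(max(abs(sqrt(emissionVariances(m)) - 0.07)), 0.01)
  expect_true(all(diff(m@logLikTrace) > -1e-8))
  expect_true(all(abs(rowSums(transitionMatrix(m)) - 1) < 1e-12))
})

test_that("indistinguishable emissions are flagged as unidentifiable", {
  set.seed(8)
  obs <- lapply(1:5, function(i) rnorm(100, 0.5, 0.05))
  same <- new("FretHmm", means = c(0.5, 0.5), variances = c(0.0025, 0.0025),
              transitionMatrix = rbind(c(0.9, 0.1), c(0.1, 0.9)),
              initialProbs = c(0.5, 0.5), logLik = NA_real_,
              nIterations = 0L, converged = NA, degenerate = FALSE,
              logLikTrace = numeric(0))
  expect_warning(m <- baumWelchFit(obs, init = same), "not identifiable")
  expect_true(m@degenerate)
  # the degenerate model's likelihood equals the single-Gaussian likelihood
  single <- sum(vapply(obs, function(s)
    sum(dnorm(s, emissionMeans(m)[1], sqrt(emissionVariances(m)[1]),
              log = TRUE)), 0))
  expect_equal(forwardLogLik(m, obs), single, tolerance = 1e-6)
})

test_that("Viterbi with far-separated states is nearest-mean assignment", {
  p <- list(means = c(0, 1), vars = c(1e-4, 1e-4),
            trans = rbind(c(0.9, 0.1), c(0.1, 0.9)), init = c(0.5, 0.5))
  set.seed(10)
  obs <- sample(c(0, 1), 50, TRUE) + rnorm(50, 0, 0.01)
  vt <- viterbiDecode(makeHmm(p), obs)
  expect_equal(stateSeq(vt), ifelse(obs > 0.5, 2L, 1L))
  # decoded path beats 1000 random paths
  set.seed(11)
  lps <- replicate(1000, {
    s <- sample(1:2, 50, TRUE)
    lp <- log(p$init[s[1]]) + dnorm(obs[1], p$means[s[1]],
                                    sqrt(p$vars[s[1]]), log = TRUE)
    for (t in 2:50) lp <- lp + log(p$trans[s[t - 1], s[t]]) +
      dnorm(obs[t], p$means[s[t]], sqrt(p$vars[s[t]]), log = TRUE)
    lp
  })
  expect_true(all(vt@logProb >= lps))
})
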