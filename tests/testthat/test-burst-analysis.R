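test_that("sliding-window search handles forced and empty cases", {
  expect_equal(nrow(slidingWindowSearch(numeric(0))), 0L)
  # 25 photons at 1 us spacing: every window of 500 us holds all of them
  ts <- seq(0, 24)
  b <- slidingWindowSearch(ts, m = 15, tWindowTicks = 500, minLength = 25)
  expect_equal(nrow(b), 1L)
  expect_equal(b$startTick, 0)
  expect_equal(b$endTick, 25)
  expect_equal(b$nPhotons, 25L)
  expect_error(slidingWindowSearch(c(5, 1)), "sorted")
})

test_that("sliding-window search equals the exhaustive O(n^2) oracle", {
  set.seed(31)
  for (rep in 1:30) {
    n <- sample(50:300, 1)
    ts <- sort(floor(runif(n, 0, sample(c(2e3, 2e4, 2e5), 1))))
    m <- sample(3:15, 1); tw <- sample(c(100, 500, 1000), 1)
    L <- m + sample(0:10, 1)
    got <- slidingWindowSearch(ts, m, tw, L)
    want <- oracleSlidingSearch(ts, m, tw, L)
    expect_equal(got$startTick, want$startTick)
    expect_equal(got$endTick, want$endTick)
  }
})

test_that("burst boundaries are translation invariant", {
  set.seed(5)
  ts <- sort(floor(runif(400, 0, 5e4)))
  b0 <- slidingWindowSearch(ts, 10, 500, 15)
  shift <- 73210
  b1 <- slidingWindowSearch(ts + shift, 10, 500, 15)
  expect_equal(b1$startTick, b0$startTick + shift)
  expect_equal(b1$endTick, b0$endTick + shift)
})

test_that("raising L never adds bursts; widening T only extends intervals", {
  set.seed(17)
  for (rep in 1:10) {
    ts <- sort(floor(runif(500, 0, 1e5)))
    nB <- vapply(c(10, 15, 25, 40), function(L)
      nrow(slidingWindowSearch(ts, 10, 500, L)), 0L)
    expect_true(all(diff(nB) <= 0))
    # hot set grows with T, so every T1-interval lies inside a T2-interval
    b1 <- slidingWindowSearch(ts, 10, 300, 15)
    b2 <- slidingWindowSearch(ts, 10, 900, 15)
    if (nrow(b1)) {
      covered <- vapply(seq_len(nrow(b1)), function(i)
        any(b2$startTick <= b1$startTick[i] & b2$endTick >= b1$endTick[i]),
        TRUE)
      expect_true(all(covered))
    }
  }
})

test_that("interval intersection follows the dual-channel combination rule", {
  ii <- alexFRET:::intersectIntervals
  got <- ii(0, 100, 50, 150)
  expect_equal(got$start, 50)
  expect_equal(got$end, 100)
  expect_equal(nrow(ii(0, 40, 50, 150)), 0L)   # disjoint -> no burst
  got2 <- ii(c(0, 200), c(100, 300), c(50, 250), c(150, 260))
  expect_equal(got2$start, c(50, 250))
  expect_equal(got2$end, c(100, 260))
})

test_that("dual-channel search matches a tick-level oracle on random streams", {
  set.seed(23)
  for (rep in 1:10) {
    st <- randomBurstyStream()
    p <- burstSearchParams(m = 10, tWindowUs = 500, minLength = 15,
                           minTotalPhotons = 30)
    got <- dualChannelBurstSearch(st, p)
    want <- oracleDualSearch(st, 10, 500, 15, 30)
    expect_equal(nrow(got), nrow(want))
    expect_equal(got$startTick, want$startTick)
    expect_equal(got$endTick, want$endTick)
    expect_equal(got$fDD, want$fDD)
    expect_equal(got$fDA, want$fDA)
    expect_equal(got$fAA, want$fAA)
  }
})

test_that("donor-only molecules yield no dual-channel bursts", {
  cfg <- burstSimConfig(populations = data.frame(trueE = NA, weight = 1,
                                                 species = "Donly"),
                        durationS = 10, seed = 8)
  sim <- simulateBursts(cfg)
  b <- dualChannelBurstSearch(sim$stream, burstSearchParams(minTotalPhotons = 30))
  expect_equal(nrow(b), 0L)

  noAex <- PhotonStream(c(1, 2, 3), c("D", "D", "A"))
  expect_error(dualChannelBurstSearch(noAex), "no acceptor-excitation")
})

test_that("E and S are the stream-count ratios, with degenerate flags", {
  es <- computeES(25, 75, 100)
  expect_equal(es$eApp, 0.75)
  expect_equal(es$s, 0.5)
  expect_equal(computeES(50, 50, 0)$s, 1)          # A-only channel silent
  expect_equal(computeES(80, 0, 40)$eApp, 0)
  expect_true(is.na(computeES(0, 0, 10)$eApp))     # zero Dex photons
  expect_true(is.na(computeES(0, 0, 0)$s))
  expect_error(computeES(-1, 0, 0), ">= 0")
  # in [0,1] whenever defined, over random counts
  set.seed(2)
  es <- computeES(rpois(500, 30), rpois(500, 30), rpois(500, 30))
  ok <- !is.na(es$eApp)
  expect_true(all(es$eApp[ok] >= 0 & es$eApp[ok] <= 1))
  expect_true(all(es$s[ok] >= 0 & es$s[ok] <= 1))
})

test_that("the correction chain is the identity at zero factors", {
  b <- data.frame(durationMs = 2, fDD = 100, fDA = 60, fAA = 80,
                  eApp = 60 / 160, s = 2)
  cfg0 <- instrumentConfig(bgDD = 0, bgDA = 0, bgAA = 0, leakage = 0,
                           directExcitation = 0, gamma = 1)
  expect_equal(applyCorrections(b, cfg0)$eCorr, b$eApp)
  # leakage removal forced to zero: DA entirely explained by leakage
  b2 <- data.frame(durationMs = 1, fDD = 100, fDA = 10, fAA = 0)
  cfgL <- instrumentConfig(bgDD = 0, bgDA = 0, bgAA = 0, leakage = 0.1,
                           directExcitation = 0, gamma = 1)
  expect_equal(applyCorrections(b2, cfgL)$eCorr, 0)
  # over-subtracted burst is flagged
  b3 <- data.frame(durationMs = 100, fDD = 1, fDA = 1, fAA = 1)
  expect_true(is.na(applyCorrections(b3, instrumentConfig(bgDD = 5,
                                                          bgDA = 5,
                                                          bgAA = 5))$eCorr))
})

test_that("corrections invert the simulator's forward distortions", {
  cfg <- burstSimConfig(populations = data.frame(trueE = 0.6, weight = 1,
                                                 species = "DA"),
                        leakage = 0.08, directExcitation = 0.06, gamma = 1.3,
                        durationS = 40, seed = 19)
  sim <- simulateBursts(cfg)
  b <- dualChannelBurstSearch(sim$stream)
  ic <- instrumentConfig(bgDD = 1.2, bgDA = 0.8, bgAA = 1.0,
                         leakage = 0.08, directExcitation = 0.06, gamma = 1.3)
  b <- applyCorrections(b, ic)
  expect_gt(nrow(b), 400)
  expect_lt(abs(mean(b$eCorr, na.rm = TRUE) - 0.6), 0.01)
  # without the correction the apparent E is visibly off
  expect_gt(abs(mean(b$eApp) - 0.6), 0.03)
})

test_that("population selection gates the E/S rectangle", {
  b <- data.frame(eApp = c(0.2, 0.5, 0.9, 0.5), s = c(0.5, 0.55, 0.6, 0.95))
  expect_message(all <- selectPopulation(b, c(0, 1), c(0, 1)), "4 of 4")
  expect_equal(nrow(all), 4L)
  suppressMessages({
    mid <- selectPopulation(b, c(0, 1), c(0.3, 0.8))
  })
  expect_equal(nrow(mid), 3L)          # the S = 0.95 donor-only burst is out
  suppressMessages(expect_warning(none <- selectPopulation(b, c(0, 0.05),
                                                           c(0, 0.05)),
                                  "empty"))
  expect_equal(nrow(none), 0L)
})

test_that("Gaussian histogram fits recover sample parameters with Wald CIs", {
  set.seed(12)
  e <- rnorm(1e5, 0.75, 0.05)
  f <- fitEHistogram(e, 1, binWidth = 0.02)
  expect_lt(abs(f@means - 0.75), 0.001)
  expect_lt(abs(f@sigmas - 0.05), 0.002)
  expect_true(f@meanCi95[1] < f@means & f@means < f@meanCi95[2])
  # CI half-width is 1.96 x SE, so the interval is symmetric about the mean
  expect_equal(f@means - f@meanCi95[1], f@meanCi95[2] - f@means, tolerance = 1e-9)

  e2 <- c(rnorm(1e4, 0.3, 0.05), rnorm(1e4, 0.7, 0.05))
  f2 <- fitEHistogram(e2, 2, binWidth = 0.02)
  expect_lt(max(abs(f2@means - c(0.3, 0.7))), 0.005)
  expect_lt(abs(f2@areaFractions[1] - 0.5), 0.02)
  expect_true(all(diff(f2@means) > 0))   # components ordered by mean

  expect_error(fitEHistogram(rep(0.5, 100)), "degenerate")
  expect_error(fitEHistogram(rnorm(10)), "at least 30")
})

test_that("two-sample KS statistic matches ECDF geometry and an oracle", {
  set.seed(9)
  a <- runif(1000)
  expect_equal(ksTwoSample(a, a)$D, 0)
  b <- runif(1000, 0.5, 1.5)
  expect_lt(abs(ksTwoSample(a, b)$D - 0.5), 0.05)
  for (rep in 1:20) {
    x <- rnorm(sample(5:30, 1)); y <- rnorm(sample(5:30, 1), 0.5)
    expect_equal(ksTwoSample(x, y)$D, oracleKsD(x, y), tolerance = 1e-12)
  }
  expect_warning(ksTwoSample(rnorm(3), rnorm(10)), "unreliable")
  expect_error(ksTwoSample(numeric(0), 1), "non-empty")
})

test_that("FRET/distance conversion is exact and self-inverse", {
  expect_equal(distanceToEfficiency(5.1, 5.1), 0.5)
  expect_equal(efficiencyToDistance(0.5, 5.1), 5.1)
  expect_equal(efficiencyToDistance(0.5, 6.2), 6.2)
  es <- seq(0.01, 0.99, by = 0.01)
  expect_lt(max(abs(distanceToEfficiency(efficiencyToDistance(es, 5.1), 5.1) - es)),
            1e-12)
  expect_error(efficiencyToDistance(1), "strictly inside")
  expect_error(efficiencyToDistance(0), "strictly inside")
  expect_error(distanceToEfficiency(0), "> 0")
})
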