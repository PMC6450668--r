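onePop <- function(e) data.frame(trueE = e, weight = 1, species = "DA")

cleanCfg <- function(e, seed = 1) {
  burstSimConfig(populations = onePop(e), bgDD = 0, bgDA = 0, bgAA = 0,
                 leakage = 0, directExcitation = 0, gamma = 1,
                 durationS = 5, seed = seed)
}

test_that("a fixed seed fixes every simulator output bit-exactly", {
  a <- simulateBursts(burstSimConfig(seed = 42))
  b <- simulateBursts(burstSimConfig(seed = 42))
  expect_identical(timestamps(a$stream), timestamps(b$stream))
  expect_identical(detector(a$stream), detector(b$stream))
  expect_identical(a$truth, b$truth)
  c <- simulateBursts(burstSimConfig(seed = 43))
  expect_false(identical(timestamps(a$stream), timestamps(c$stream)))

  ta <- simulateTraces(traceSimConfig(nTraces = 5, seed = 9))
  tb <- simulateTraces(traceSimConfig(nTraces = 5, seed = 9))
  expect_identical(lapply(ta$traces, donorCounts), lapply(tb$traces, donorCounts))
  expect_identical(ta$truth, tb$truth)
})

test_that("extreme transfer efficiencies force the photon routing", {
  sim1 <- simulateBursts(cleanCfg(1))
  st <- sim1$stream
  dex <- excitation(st) == "Dex"
  expect_gt(sum(dex), 100)
  expect_true(all(detector(st)[dex] == "A"))   # E = 1: all Dex photons red

  sim0 <- simulateBursts(cleanCfg(0))
  st0 <- sim0$stream
  dex0 <- excitation(st0) == "Dex"
  expect_true(all(detector(st0)[dex0] == "D")) # E = 0: all Dex photons green
})

test_that("simulated photon totals match their Poisson expectations", {
  sim <- simulateBursts(cleanCfg(0.5, seed = 3))
  st <- sim$stream
  # conditional on the realized burst envelope, the base photon total is
  # Poisson(rate x total burst time)
  lenTicks <- sum(pmin(sim$truth$endTick, 5e6) - sim$truth$startTick)
  lambda <- 250e3 * 1e-6 * lenTicks
  expect_lt(abs(length(st) - lambda), 5 * sqrt(lambda) + 2 * nrow(sim$truth))

  # background-only acquisition: per-stream counts Poisson(rate x duration)
  bgCfg <- burstSimConfig(populations = onePop(0.5),
                          meanBurstPhotonRateKhz = 1e-6,
                          bgDD = 2, bgDA = 1, bgAA = 3, leakage = 0,
                          directExcitation = 0, durationS = 20, seed = 5)
  bg <- simulateBursts(bgCfg)$stream
  dd <- sum(excitation(bg) == "Dex" & detector(bg) == "D")
  da <- sum(excitation(bg) == "Dex" & detector(bg) == "A")
  aa <- sum(excitation(bg) == "Aex" & detector(bg) == "A")
  for (pair in list(c(dd, 2), c(da, 1), c(aa, 3))) {
    lam <- pair[2] * 1e3 * 20
    expect_lt(abs(pair[1] - lam), 5 * sqrt(lam))
  }
})

test_that("trace ground-truth occupancy matches the stationary distribution", {
  cfg <- traceSimConfig(kCloseIntrinsic = 5, kCloseBimolecular = 0,
                        ligandUm = 0, kOpen = 10, bleachRatePerS = 0,
                        nTraces = 60, nBinsMax = 500, seed = 11)
  sim <- simulateTraces(cfg)
  fC <- mean(unlist(lapply(sim$truth, `[[`, "fClosed")))
  expect_lt(abs(fC - 5 / 15), 0.02)    # kc/(kc+ko) = 1/3
})

test_that("closing switched off yields constant open traces at eOpen", {
  cfg <- traceSimConfig(kCloseIntrinsic = 0, kCloseBimolecular = 0,
                        ligandUm = 0, kOpen = 10, bleachRatePerS = 0,
                        nTraces = 10, seed = 2)
  sim <- simulateTraces(cfg)
  for (t in sim$truth) {
    expect_true(all(t$segments$state == 1L))
    expect_true(all(t$fClosed == 0))
  }
  fr <- unlist(lapply(sim$traces, function(tr)
    acceptorCounts(tr) / (acceptorCounts(tr) + donorCounts(tr))))
  expect_lt(abs(mean(fr, na.rm = TRUE) - 0.35), 0.02)
})

test_that("ligand-free intrinsic closing occurs at the configured rate", {
  cfg <- traceSimConfig(kCloseIntrinsic = 2, kCloseBimolecular = 5,
                        ligandUm = 0, kOpen = 10, bleachRatePerS = 0,
                        nTraces = 80, nBinsMax = 500, seed = 13)
  sim <- simulateTraces(cfg)
  # closing events per unit open time ~ kCloseIntrinsic (ligand term off)
  nClose <- openTime <- 0
  for (t in sim$truth) {
    seg <- t$segments
    op <- seg$state == 1L
    openTime <- openTime + sum(seg$endS[op] - seg$startS[op])
    nClose <- nClose + sum(op & seg$endS < max(seg$endS))
  }
  expect_lt(abs(nClose / openTime - 2) / 2, 0.15)
})

test_that("titration generates the one-site isotherm populations", {
  expect_error(simulateTitration(numeric(0), 1), "non-empty")
  expect_error(simulateTitration(1, 0), "trueKdUm")
  tit <- simulateTitration(c(0, 3.4), trueKdUm = 3.4, nBurstsPerPoint = 30,
                           seed = 4)
  expect_equal(tit[[1]]$trueP, 0)
  expect_equal(tit[[2]]$trueP, 0.5)
  # at L = 0 only the open population is generated
  expect_true(all(tit[[1]]$truth$trueE == 0.35))
  # at L = KD the two populations are drawn with equal weight
  tab <- table(tit[[2]]$truth$trueE)
  expect_setequal(as.numeric(names(tab)), c(0.35, 0.75))

  # trace mode: stationary closed fraction equals the isotherm
  titT <- simulateTitration(2, trueKdUm = 2, mode = "traces",
                            config = traceSimConfig(nTraces = 40,
                                                    bleachRatePerS = 0,
                                                    nBinsMax = 400),
                            seed = 6)
  fC <- mean(unlist(lapply(titT[[1]]$truth, `[[`, "fClosed")))
  expect_lt(abs(fC - 0.5), 0.03)
})
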