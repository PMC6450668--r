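# alexFRET

Single-molecule FRET analysis of substrate-binding-protein conformational
states and dynamics, for spectroscopists working with two-color confocal
data: µs-ALEX burst analysis of freely diffusing molecules, two-state
hidden-Markov dwell-time analysis of surface-immobilized molecules, and the
binding and spectroscopic quantities derived from both.

Substrate-binding proteins (SBPs) of ABC importers switch between an open
(ligand-free, low-FRET) and a closed (ligand-bound, high-FRET) conformation.
With a donor on one lobe and an acceptor on the other, the FRET efficiency
`E = 1 / (1 + (R/R0)^6)` reports the inter-lobe distance `R` against the
Förster radius `R0` of the dye pair. The package turns raw photon records
into the quantities that characterize this switch:

* **Burst mode** — dual-channel sliding-window burst search (defaults
  `M = 15`, `T = 500 µs`, `L = 25`, >150 photons per burst) on alternating
  laser excitation photon streams; per burst
  `E* = F_DA / (F_DA + F_DD)` and stoichiometry
  `S = (F_DD + F_DA) / (F_DD + F_DA + F_AA)`; background / leakage /
  direct-excitation / γ corrections; E/S population gating; Gaussian
  histogram fits with 95% Wald confidence intervals; two-sample
  Kolmogorov–Smirnov comparison; E ↔ distance conversion.
* **Trace mode** — trace QC (>50 bins, >10 photons/bin, clear bleach step),
  per-bin apparent FRET, a two-state Gaussian-emission HMM fitted by
  Baum–Welch with Rabiner scaling (C++ inner loops), Viterbi decoding,
  dwell-time / lifetime / occupancy / transition-frequency statistics, and
  a kinetic-order test that distinguishes induced-fit binding (closing
  first-order in ligand, opening zeroth-order) from its alternatives.
* **Binding & spectroscopy** — one-site `K_D = L (1 − P) / P` from
  closed-population fractions, isotherm fits over titrations, fluorescence
  anisotropy `r = (I_VV − G·I_VH) / (I_VV + 2 G·I_VH)` with
  `G = I_HV / I_HH`, ensemble FRET.
* **Synthetic data** — seeded forward models of both measurement modes
  (Poisson bursts with ALEX photon routing and instrument distortions;
  continuous-time two-state traces with binning blur, background and
  photobleaching), so the whole chain is testable without microscope data.

## Worked example

Simulate a solution measurement of a protein with two conformations (true
E = 0.4 and 0.8, equal weight) under realistic distortions, then recover
them:

```r
library(alexFRET)

cfg <- burstSimConfig(
  populations = data.frame(trueE = c(0.4, 0.8), weight = c(0.5, 0.5),
                           species = "DA"),
  durationS = 60, seed = 42)
sim <- simulateBursts(cfg)
sim$stream
#> PhotonStream: 673696 photons over 60 s
#>   tick: 1 us; alternation half-period: 50 us
#>   streams: Aex/A 298480, Dex/A 205439, Dex/D 169777

bursts <- dualChannelBurstSearch(sim$stream)
nrow(bursts)
#> [1] 837

sel <- selectPopulation(bursts)            # S-gate removes single-dye species
#> selected 837 of 837 bursts (E in [0, 1], S in [0.3, 0.8])
sel <- applyCorrections(sel, instrumentConfig())
fit <- fitEHistogram(sel$eCorr, nComponents = 2, anchors = c(0.4, 0.8))
fit
#> FretHistogramFit: 2 Gaussian component(s), 837 values, bin width 0.025
#>   mean 0.3959 [0.3920, 0.3998]  sigma 0.0345  area 0.529
#>   mean 0.7993 [0.7960, 0.8027]  sigma 0.0287  area 0.471

efficiencyToDistance(fit@means[2], r0Nm = 5.1)
#> [1] 4.052...
```

In one minute of simulated acquisition, 837 bursts pass the dual-channel
search and photon filter; the two fitted Gaussian components recover the
true efficiencies (0.396 [0.392, 0.400] and 0.799 [0.796, 0.803]) and the
equal population split (0.53/0.47), and the closed state's mean inter-dye
distance is 4.05 nm for the Alexa555/Alexa647 pair (`R0` = 5.1 nm).

For the trace side, see `?simulateTraces`, `?baumWelchFit`,
`?extractDwells` and `?kineticOrderTest`; the methods vignette
(`vignettes/smfret-analysis-methods.Rmd`) documents the models, parameter
choices and limitations.

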