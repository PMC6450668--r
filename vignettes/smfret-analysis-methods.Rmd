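---
title: "Methods: smFRET burst and trace analysis in alexFRET"
author: "alexFRET authors"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: smFRET burst and trace analysis in alexFRET}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(alexFRET)
```

# The measurement and the model

Substrate-binding proteins (SBPs) of ABC importers capture ligand in a cleft
between two lobes and deliver it to the membrane translocator; ligand binding
is coupled to a switch from an open to a closed conformation. Labeling the
two lobes with a donor and an acceptor dye makes this switch readable as a
change in Förster resonance energy transfer: the FRET efficiency

$$E = \frac{1}{1 + (R/R_0)^6}$$

reports the inter-dye distance $R$ relative to the Förster radius $R_0$ of
the dye pair (5.1 nm for Alexa555/Alexa647, 6.2 nm for Cy3B/Atto647N). The
package implements the two complementary observation geometries used for
such proteins, plus everything needed to turn raw photon records into
conformational-state populations and kinetics:

1. **Solution (burst) mode.** Picomolar labeled protein diffuses through a
   confocal volume; each transit yields a photon burst. Microsecond
   alternating laser excitation (µs-ALEX, 50 µs half-period) splits detected
   photons into three streams — DD (donor emission under donor excitation),
   DA (acceptor emission under donor excitation) and AA (acceptor emission
   under acceptor excitation) — so each burst yields an apparent efficiency
   $E^* = F_{DA}/(F_{DA}+F_{DD})$ and a stoichiometry
   $S = (F_{DD}+F_{DA})/(F_{DD}+F_{DA}+F_{AA})$ that separates doubly
   labeled molecules from donor-only ($S \to 1$) and acceptor-only
   ($S \to 0$) species.

2. **Immobilized (trace) mode.** Surface-tethered molecules are imaged over
   seconds, binned into two-color count traces; a two-state hidden Markov
   model on the per-bin FRET series recovers open/closed dwell times,
   occupancies and transition frequencies — the quantities that decide
   between induced-fit and conformational-selection binding.

# Burst detection and corrections

## Dual-channel sliding-window search

A photon is *hot* when at least $M$ photons (counting itself) fall inside a
half-open window $[t - T/2,\, t + T/2)$ centred on its arrival time; maximal
runs of at least $L$ consecutive hot photons form a burst. Defaults are
$M = 15$, $T = 500$ µs, $L = 25$. The search runs twice — once on all
donor-excitation photons, once on the AA stream — and a burst is retained
only where both searches are simultaneously active (interval intersection),
which restricts analysis to stretches where both fluorophores are
demonstrably photoactive and suppresses bleaching artifacts. Bursts with
150 photons or fewer in total are discarded.

Numerical choices worth stating: timestamps are integer ticks (1 µs by
default) and every interval is half-open, so window membership and interval
intersection are exact integer comparisons with no floating-point drift. A
photon whose window contains $M-1$ *other* photons is hot — the count
includes the photon itself. The excitation phase of a photon at tick $t$ is
donor iff $(t \bmod 2P) < P$ with $P$ the alternation half-period; this
deterministic convention is what both the readers and the simulator use.

## From apparent to accurate E

Counts are corrected in the standard order: per-stream background
subtraction (rate × burst duration), removal of donor leakage
($l \cdot F_{DD}'$) and acceptor direct excitation ($d \cdot F_{AA}'$) from
the DA stream, then the detection-factor correction

$$E = \frac{F_{DA}''}{F_{DA}'' + \gamma F_{DD}'}.$$

$E$ may leave $[0,1]$ slightly after subtraction; bursts whose corrected
denominator becomes non-positive are flagged and excluded. Background rates,
$l$, $d$ and $\gamma$ arrive via `instrumentConfig()` — they are instrument
properties estimated outside this package, and the simulator's forward model
applies exactly these distortions so the correction chain can be validated
as their inverse.

Selected populations (default gate $S \in [0.3, 0.8]$, configurable; the
gate is reported, not silent) are histogrammed at 0.025 E-units and fitted
with one or two Gaussians by nonlinear least squares
(`minpack.lm::nlsLM`); each mean carries a 95% Wald confidence interval
($\hat\mu \pm 1.96\,\mathrm{SE}$). Distributions are compared with the
two-sample Kolmogorov–Smirnov test (`stats::ks.test`), which is insensitive
to the Gaussian fitting choices.

# Trace analysis

## Quality control

A trace is analysed only if it is longer than 50 bins, averages more than
10 photons per bin, and shows a clear single photobleaching step. "Clear
bleaching step" is operationalized as the largest CUSUM change-point of the
total intensity whose post-step mean falls below 25% of the pre-step mean
(the `noiseFraction` parameter); the analysed region ends at that bin. This
is a stated convention — in manual practice the judgment is visual — and
the threshold matters little for well-behaved traces because a genuine
donor bleach drops the intensity to background.

## Two-state Gaussian-emission HMM

The per-bin apparent FRET series $y_t = n_{red}/(n_{red}+n_{green})$ is
modelled as a hidden two-state Markov chain with Gaussian emissions
$\mathcal N(\mu_i, \sigma_i^2)$, fitted by Baum–Welch (EM) with Rabiner's
per-step scaling so that series of arbitrary length never underflow. One
global model is fitted jointly across all traces of a condition — with only
a handful of transitions per molecule, per-trace models are poorly
identified — and each trace is then decoded with the Viterbi algorithm.
Design choices:

* Initialization is deterministic (means at the pooled 10th/90th
  percentiles, variances at the pooled variance, stay probability 0.95,
  uniform initial distribution), so a fixed dataset always gives the same
  fit; collapsed states trigger up to three perturbed restarts.
* Convergence at $|\Delta \log L| < 10^{-6}$, at most 1000 iterations; the
  log-likelihood trace is stored and is non-decreasing by construction
  (asserted in the tests).
* States are relabeled by ascending mean: state 1 is open/low-FRET, state 2
  closed/high-FRET. Viterbi ties break toward the open state.
* If the two emission distributions coincide the model is flagged
  `degenerate`: its likelihood equals the single-state model and the
  transition estimates mean nothing.

The inner loops (forward, backward, E-step, Viterbi) are implemented in
C++ (Rcpp) because EM over hundreds of traces × hundreds of bins × hundreds
of iterations is the one hot path in the package; the tests verify them
against exhaustive $2^T$ path enumeration in R.

## Dwells, lifetimes, kinetic order

A dwell is a maximal single-state run times the bin width, so dwell
durations sum exactly to the analysed duration. The first and last dwell of
every trace are *censored* — their true start or end was not observed — and
are excluded from mean-lifetime estimates by default (`includeCensored`
restores them for comparison). The standard error of a mean lifetime is
computed over the pooled uncensored dwells; a per-molecule bootstrap
(`bootstrapLifetimeSem`) is offered as the alternative, since pooling and
per-molecule resampling answer slightly different questions.

For the kinetic-order test, the closing rate at each ligand concentration
is $1/\bar\tau_{open}$ and the opening rate $1/\bar\tau_{closed}$; each is
regressed linearly on concentration. *Induced fit* is reported when the
closing slope is significantly positive (95% CI excludes 0) while the
opening slope CI contains 0 — closing first-order in ligand, opening
zeroth-order. If both CIs contain zero the verdict is "not
concentration-dependent"; anything else is "indeterminate" and both fits
are simply reported.

**Resolution rule.** Decode-then-count dwell estimation suffers
missed-event bias: dwells shorter than about a bin are invisible, and every
missed dwell merges its two neighbors, inflating the estimated lifetime of
the *other* state. The bias scales with (bin width)/(shortest mean dwell),
so rate experiments should be binned at a few percent of the shortest dwell
they are meant to resolve. The packaged kinetics experiments therefore use
5 ms bins for dwells of 100–1000 ms; at the default 10 ms bins the same
rates come back ~15–20% low, which is the expected size of the effect, not
an implementation error.

# Binding quantities

For one binding site the closed-state population at ligand concentration
$L$ follows $P = L/(L + K_D)$, so a single titration point gives
$K_D = L(1-P)/P$ (`kdFromPopulation`, the default) and several points give
a least-squares isotherm fit (`kdFit`, weighted by $\sqrt{n}$ when counts
are supplied; both agree exactly on noise-free input). $P$ itself comes
from the area fraction of the closed component in a two-Gaussian histogram
fit, with component identity anchored at the ligand-free and saturating
means to prevent label switching; fits whose components are separated by
less than one pooled sigma are refused rather than reported.

Fluorescence anisotropy, $r = (I_{VV} - G I_{VH})/(I_{VV} + 2 G I_{VH})$
with $G = I_{HV}/I_{HH}$, and the ensemble proxy
$E = I_A/(I_A + I_D)$ are provided as the spectroscopic sanity checks that
accompany such measurements: $r$ well below ~0.3 supports reading $E$ as
distance.

# The synthetic-data generators

No raw photon data accompanies the measurements this pipeline targets, so
the package carries forward models that generate data with exactly the
statistical structure the analyses assume:

* `simulateBursts()` places transits as a Poisson process (default
  20 s⁻¹), gives each an exponential duration (mean 1.5 ms) and a constant
  in-burst detection rate (250 kHz, i.e. ≈375 photons per mean transit —
  typical confocal values), routes each donor-excitation photon to the
  acceptor with probability $\gamma E/(\gamma E + 1 - E)$, duplicates
  detected donor photons into the acceptor channel with the leakage
  probability, adds Dex-phase acceptor photons at the direct-excitation
  rate, and lays uniform per-stream background (≈1 kHz) over the
  acquisition. Donor-only species are dark under acceptor excitation and
  acceptor-only species dark under donor excitation (up to direct
  excitation), so the stoichiometry gate has something to reject. By
  construction `applyCorrections()` is the exact inverse of these
  distortions in expectation.
* `simulateTraces()` draws a continuous-time two-state chain with closing
  rate $k_{c,0} + k_{c,b}[L]$ and opening rate $k_o$, starts it at
  stationarity, discretizes by *fractional occupancy* (a bin spanning a
  transition takes an intermediate expected FRET — the binning blur the HMM
  must tolerate), emits Poisson counts (default 50 per 10 ms bin plus 0.5
  background per channel), and truncates at an exponential donor-bleach
  time (0.2 s⁻¹) after which bins carry background only, giving the QC
  change-point detector a realistic step.
* `simulateHmmTraces()` samples directly from a discrete two-state Gaussian
  HMM, bypassing the photon layer, to validate the estimator against known
  parameters.
* `simulateTitration()` ties either generator to the one-site isotherm.

All generators consume a single seeded RNG: one seed fixes every output
bit-exactly.

**What the simulations do not contain** — and hence what passing recovery
tests do and do not show: no diffusion physics or point-spread function
(burst envelopes are rectangular, so real burst-size and brightness
distributions are broader), no triplet blinking or spectral fluctuations,
no acceptor bleaching inside bursts, no drift, and Gaussian rather than
shot-noise-skewed emission in the HMM sense. Recovery on these simulations
validates the estimators against their own model assumptions; on real data
the corrections and the two-state assumption must still be justified per
experiment.

# Problem sizes used in the packaged experiments

The shipped tests and the acceptance script run at sizes chosen to make
sampling error comfortably smaller than the effects being checked: ~5000
simulated transits (~3200 detected bursts) for population recovery, 2000
transits per titration point over six concentrations, 200 traces × 300 bins
per HMM recovery seed (20 seeds), and 200 traces per concentration at four
concentrations for the kinetic-order experiment. These are ordinary
desk-scale runs (a few minutes end to end).

# Known limitations

* The burst search assumes a single threshold set (M, T, L) per analysis;
  no multi-scale or adaptive search.
* Dwell-based rates carry the missed-event bias described above; no
  explicit missed-event correction is applied.
* The HMM is strictly two-state with Gaussian emissions on binned FRET;
  photon-by-photon inference and model selection over state numbers are out
  of scope.
* Background rates, leakage, direct excitation and γ are taken as known
  config rather than estimated internally.
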