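---
title: "Probe-directed single-molecule sensing of PFCAs: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Probe-directed single-molecule sensing of PFCAs: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(pfcapore)
```

## The measurement this package models

A protein nanopore (wild-type aerolysin in the default configuration) in a
lipid bilayer passes a steady open-pore ionic current — about −100 pA at
−50 mV in 4 M KCl. Per- and polyfluoroalkyl carboxylic acids (PFCAs) are
too small and too weakly charged to produce usable signals on their own,
so each analyte is conjugated to a polycationic hexa-arginine peptide
probe. The probe drives the conjugate into the pore and parks it at a
reproducible position, where it excludes electrolyte volume and partially
blocks the current. Each capture event is a resistive pulse characterized
by its blockade magnitude ΔI/I₀ (%), dwell time τ_on (ms), and arrival
statistics.

Three quantitative regularities make the method work, and each is a
module of this package:

1. **Volume–blockade linearity.** Because the probe fixes the residence
   position, the blockade is set by steric exclusion alone and grows as
   an affine function of the conjugate's molecular volume (supplied as an
   input, typically from all-atom MD). One -CF₂- unit (73.5 Å³) adds
   1.68% of blockade; extrapolating the line to 100% blockade recovers an
   effective transduction volume of 4.82 nm³, matching the pore lumen.
   This permits *standard-free* prediction of the blockade of an analyte
   that has never been measured.
2. **Multi-dimensional event features.** Single events carry far more
   information than their mean blockade. Re-deriving eight base features
   under six signal conditionings (low-pass at 2000/800/500/200/100 Hz
   and wavelet denoising) yields a 43-dimension feature vector per event
   (dwell time is invariant to conditioning and stored once), enough for
   a bagged-tree classifier to resolve analytes whose blockade
   histograms overlap completely.
3. **Poisson digital quantification.** Captures are a Poisson process
   with rate k·C, with the capture constant k set by the probe rather
   than by the analyte. Counting classified events over time therefore
   quantifies every component of a mixture against a single universal
   calibration, and rates of components add.

## The synthetic-data generator

Every downstream stage is testable without experimental recordings
because the generator reproduces the statistical structure the analysis
assumes:

- baseline Gaussian noise (σ = 2 pA by default) around the open-pore
  current (−100 pA at −50 mV, 20 kHz sampling);
- rectangular blockade excursions toward zero with per-event depths drawn
  from the analyte's Gaussian blockade distribution (σ = 0.198% by
  default, the spread of experimental blockade histograms);
- blockade means that are an exact affine function of conjugate volume
  with the 1.68%-per-unit slope and the 4.82 nm³ intercept; the built-in
  C2 conjugate volume (1757.5 ų) places C2 at 30.0% blockade;
- log-normal dwell times whose location increases with chain length
  (log-mean `log(1.5 ms) + 0.18 · n_CF2`, log-sd 0.35). The field's
  literature reports that dwell grows with chain length but publishes no
  per-analyte values, so these defaults are plausible placeholders chosen
  once, not calibrated quantities;
- Poisson arrivals per analyte at rate k·C with k = 2×10⁵ s⁻¹ M⁻¹ for
  every conjugate (probe-determined universality); a shared exponential
  voltage dependence `k(V) = k₀·exp(−(V−V_ref)/V_s)` with V_s = 20 mV is
  provided as a simulator convention for voltage-scan studies;
- sequential placement from the merged arrival stream, rejecting arrivals
  that would overlap the previous event. Single-channel recordings
  essentially never contain overlaps; if more than half of the arrivals
  are rejected, the requested density is unphysical and the generator
  errors instead of silently distorting the rates;
- H-/Cl-substituted and fluorotelomer conjugates carry a modestly larger
  within-event noise scale (e.g. 1.25× for the 3:3 fluorotelomer acid):
  these flexible conjugates sit less rigidly in the pore. This is the
  physical handle that lets multi-feature classification resolve the
  FTA/C5/C6 group whose blockade histograms overlap.

What the generator does **not** emulate: baseline drift and 1/f noise,
capacitance transients at event edges, multi-level substructure within
events, and matrix effects. Passing tests on synthetic data therefore
demonstrate the correctness of the algorithms under the stated model, not
robustness to every artifact of real recordings.

## Event detection and baseline estimation

The open-pore level is estimated from the all-points histogram of the
trace (bin width σ/4 from a robust MAD scale). Blockades always displace
current toward zero, so among strong histogram modes the one furthest
from zero is the open-pore level; the estimate is refined twice by
averaging samples in symmetric windows around the running center, which
removes the bin-center offset. The estimator tolerates event occupancies
up to roughly half the recording.

Detection finds maximal runs deviating toward zero by more than
`threshold_sigma` (default 5) baseline noise units and discards runs
shorter than `min_dwell_ms` (default 0.5 ms, clamped to two sampling
periods). These two defaults are declared conventions — the acquisition
software criteria they emulate are not published — and are exposed as
parameters everywhere. The event's blockade is computed from the
2000 Hz-conditioned signal, the base condition of the feature scheme.

Interval time is defined as `total_time / count` per label rather than
the mean gap: the two coincide asymptotically for Poisson streams, and
the count form remains well defined when several labels interleave in a
mixture. A zero-count label reports frequency 0 and an interval censored
at the observation time instead of infinity.

## Feature extraction choices

- **Low-pass conditioning** is zero-phase with the squared-magnitude
  Butterworth gain `1/(1+(f/f_c)^8)` (the response of a 4th-order
  Butterworth applied forward and backward), realized spectrally on a
  reflectively padded segment. The spectral form is exactly zero phase
  and unconditionally stable even when the event (a few ms) is far
  shorter than the filter's impulse response (10 ms at 100 Hz), where a
  recursive implementation breaks down numerically.
- **Events are conditioned in isolation**, not as part of the whole
  trace, so the baseline-to-event step never enters the filter: a
  noiseless rectangular event reproduces its depth exactly under every
  condition, which keeps the blockade feature unbiased.
- **Wavelet denoising** uses a periodic sym4 transform, 4 levels, soft
  universal threshold (σ√(2 log n), σ from the MAD of the finest detail
  level). The transform is orthogonal, so the inverse is the transpose
  of the analysis operator and reconstruction is exact when no
  thresholding occurs; approximation coefficients are untouched, so the
  DC level is preserved exactly.
- **Histogram features** use Freedman–Diaconis binning floored at 10
  bins; the full width at half maximum is linearly interpolated at half
  the modal count; kurtosis is reported as excess kurtosis (Gaussian
  → 0). A constant segment degenerates to `(value, 0, 0, 0)` rather than
  crashing.
- **Internal-standard normalization** divides every feature by its mean
  over the standard's events per recording batch. All 43 features are
  normalized by default, τ_on included; a switch exempts τ_on because the
  field's practice is ambiguous on whether duration should be rescaled by
  a current standard.

The Gaussian *feature library* used for feature-space simulation and
unknown-flagging is calibrated against the extractor itself: a
deterministic Monte Carlo pushes unit white-noise segments of the
analyte's typical dwell length through the actual conditioning operator
and records the resulting feature statistics. This keeps the library
consistent with extraction at every cutoff, including the strong
small-segment attenuation at 100–200 Hz that a naive bandwidth-ratio
model misses.

## Classification choices

The ensemble is 100 bagged decision trees (bootstrap fraction 1.0,
√d features per split, fully grown leaves), with stratified 10-fold
cross-validation accuracy recorded at training. A `nodesize` control is
exposed because fully grown trees are not Bayes-consistent on heavily
overlapped low-dimensional problems; the test suite uses it to verify
that the smoothed ensemble reaches the closed-form Bayes accuracy on a
two-Gaussian problem.

Feature importance is out-of-bag permutation importance floored at zero.
Greedy forward selection adds, at each dimension, the feature that
maximizes cross-validated accuracy (ties broken by canonical feature
order), reproducing the "highest accuracy at any given dimension"
ordering; shortlisting across training scales {20, 200, 2000} unions the
selections capped at 21 by combined rank. The exact membership of a
shortlist is data-dependent by construction; the procedure, not a fixed
set, is the specified behavior.

The blockade-only baseline (an ensemble-analysis mimic) is a 1-D
Gaussian-mixture EM fit to the base-condition blockade with up to five
restarts on degeneracy; exhausting the iteration budget on a finite
likelihood is treated as a slow fit on an overlapped mixture, not a
failure. Out-of-library flagging uses the root-mean-square z-score
(diagonal Mahalanobis distance) to each library class; an event farther
than 3σ from every class is excluded from PFCA counting. This is how
probe-tethered fatty acids with PFCA-like blockades but ~10× dwell are
rejected.

## Quantification choices

Calibration is fitted on frequency versus concentration (errors are
approximately Gaussian at high counts), with the interval-time view
available for display. Two LOD conventions are reported side by side:
the operational one (lowest calibrated point, the convention under which
the 0.5 nM and 0.1 nM figures for trifluoroacetic acid are quoted) and a
blank + 3σ criterion, because the field rarely states which rule a
quoted LOD follows. Concentration estimates carry Poisson counting CIs;
zero observed events return a below-detection object with the ~3/(kT)
zero-count bound instead of dividing by zero. Molar-to-mass conversion
parses elemental formulas against standard atomic weights — 0.1 nM of
trifluoroacetic acid (C2HF3O2, 114.02 g mol⁻¹) is 11.4 ng L⁻¹.

## Pipeline identification order

The end-to-end workflow identifies each event in two steps mirroring the
standard-free narrative: a blockade-window pre-assignment (window =
3×(σ_measured + σ_analyte), the sum of the two 3σ spreads) resolves
events whose predicted blockade is unambiguous; events with multi-label
candidate sets (e.g. the FTA/C5/C6 group) go to the multi-feature
classifier; unknown-flagging runs last and overrides any assignment.
When an internal standard of known concentration is declared, its
observed event frequency recalibrates the universal capture constant at
run time, so concentration estimates do not depend on a configured k.
With fewer than three analytes in the library, the volume-blockade fit
is skipped and configured blockade means are used directly.

All stage seeds derive deterministically from one global seed; the same
configuration and seed reproduce a byte-identical report.

## Problem sizes used in the tests

The shipped tests run the full stack at deliberately small scale: traces
of 1–40 s at 20 kHz, tens to hundreds of events, classifier experiments
with 20–600 events per class, selection studies on 7–10 features,
1000-replicate parameter-recovery loops only where each replicate is a
closed-form fit. These sizes were chosen so that every statistical check
retains enough power to fail loudly (3σ or CI-based bounds throughout)
while the whole suite stays desk-scale. The full experimental design of
the original measurements (2400 events per analyte across 14 classes,
43-dimension greedy scans) is supported by the same functions at larger
arguments.

## Known limitations

- Isomers of indistinguishable volume are not resolvable by the
  volume-blockade route; they enter the library only through measured
  feature tables.
- The dwell-time model is a placeholder distribution; absolute dwell
  values in simulations should not be compared to instruments.
- The voltage dependence of capture is a single shared exponential — a
  simulator convention for generating voltage-scan studies, not a fitted
  electrokinetic model.
- No baseline drift, flicker noise or event substructure is simulated;
  detection on real recordings may need retuned thresholds.
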