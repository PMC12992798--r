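---
title: "Methods: sedation-dependent topology of subthalamic microelectrode recordings"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: sedation-dependent topology of subthalamic microelectrode recordings}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(mertopo)
```

## The problem

During deep brain stimulation (DBS) surgery for Parkinson's disease,
microelectrodes are advanced toward the subthalamic nucleus (STN) along a
planned stereotactic trajectory, and the recorded single-unit and background
activity is used to locate the nucleus borders and refine the final electrode
depth. Propofol-based general anesthesia (GA) suppresses and reshapes this
activity in a dose-dependent way, which can blur the dorsal STN border — the
landmark that matters most, because the clinically effective stimulation
locus (the "sweetspot") sits in the dorsolateral STN. `mertopo` implements
the full analysis chain for studying this effect: single-unit feature
extraction, normalized background-activity (NRMS) profiling along depth, an
EEG-derived sedation index, spatial mapping of recording sites against an
atlas, and the group-statistics layer, together with a synthetic cohort
generator that emulates the statistical structure of a dose-stratified
surgical cohort so every stage is testable without patient data.

## Single-unit features

For a segment with sorted spike times, interspike intervals (ISIs) are
first differences. Three features are extracted per unit:

* **Firing rate** `FR = 1 / mean(ISI)` (Hz).
* **Burst index** `BI`: a two-component Gaussian mixture is fitted to the
  natural-log ISI distribution by expectation–maximization, and BI is the
  ratio of the component means. We take the ratio in geometric-mean form,
  `BI = exp(mu_long - mu_short)`, which is scale-invariant and >= 1 by
  construction; a linear-scale ratio (`exp(mu + s^2/2)` per component) is
  available behind the `ratio_scale` switch, since the convention of the
  originating tooling is not documented. Tonic, regular firing yields BI
  near 1; bursty firing separates a short intra-burst component from a long
  inter-burst component and BI grows with their separation.
* **Robust CV**: median absolute deviation of the ISI distribution divided
  by its median. The MAD is deliberately unscaled (no 1.4826
  normal-consistency factor); for exponential ISIs the value is
  `asinh(0.5)/ln 2 ~ 0.694`, a closed form the tests use as an oracle.

EM details that matter: initialization at the 25th/75th log-ISI percentiles
with 10 jittered restarts (seeded), a variance floor of `1e-4` log-units^2
so two-point distributions do not degenerate, a component-weight floor of
0.05, and a collapse tolerance of 0.05 log-units — fits whose component
means are closer than that, or whose minor component nearly vanishes, are
flagged degenerate and reported as BI = 1. At least 30 ISIs are required;
below that the burst index is reported missing. These choices make the fit
deterministic per seed and exactly recover two-point mixtures (BI = 10 for
ISIs at 5/50 ms) regardless of the seed.

Inclusion filters mirror standard MER quality screening: segments shorter
than 3 s, with SNR below 3 or multi-unit activity, or located outside both
STN and SNr (imaging-defined) are excluded, tallied under the first failing
rule in that order.

## NRMS background profiles

Each trajectory yields a depth-indexed root-mean-square of the multi-unit
background. Profiles are normalized by the median of the first five
recording sites (dorsal-to-ventral order) that last at least 10 s; when
only three or four sites qualify the median of those is used, and below
three the trajectory is excluded as non-normalizable — a median of fewer
than three sites is too fragile a reference. Normalization makes profiles
scale-free (amplifier gain cancels) and idempotent.

For group comparison, profiles are aligned so every trajectory's
imaging-defined STN midpoint coincides with a common reference — half the
mean STN traversal length, with the exit anchored at depth 0 — then
resampled to a 0.5-mm grid by nearest-depth assignment within a quarter
millimetre on either side; empty cells are missing, not zero. Trajectories
that miss the STN or traverse less than 3 mm of it are excluded first (a
traversal of exactly 3 mm is kept).

## EEG sedation index

Sedation depth is quantified as SEF95, the frequency below which 95% of the
band power lies. The chain is: non-overlapping 2-s epochs (trailing partial
dropped); rejection of epochs exceeding 100 uV absolute amplitude or 200 uV
peak-to-peak on any channel (thresholds configurable — the screening
criterion used clinically is not standardized); Hann-tapered periodograms
averaged across epochs and channels; restriction to the 0.5–30 Hz band
(typical for frontal sedation monitoring) and scaling to unit band power;
then the 95% cumulative-power crossing with linear interpolation between
bins. SEF95 is invariant to the normalization constant and to channel
amplitude scaling, so the choice of unit-total-band-power is cosmetic. At
least 15 retained epochs (30 s) are required for a stable estimate. The MER
period is addressed by an explicit record window rather than by detecting
the test-stimulation artifact.

## Spatial mapping

All geometry lives in a right-handed millimetre frame with z dorsal-positive;
depth-to-target is positive dorsal of the planned target (the ventral STN
border), and a trajectory position is `target - depth * direction` with
`direction` the unit dorsal-to-ventral advance vector. The atlas stand-in is
a pair of ellipsoids (STN, SNr) plus a configurable sweetspot point placed
in the dorsolateral STN octant; defaults give a vertical central trajectory
about 4.8 mm of STN ending at the target, with the SNr immediately ventral.
No anatomical accuracy is claimed — the geometry exists so that
line-ellipsoid spans, structure classification (STN precedence in
overlaps), depth alignment and distance-to-sweetspot behave like their
imaging-derived counterparts. Tangent intersections count as misses.

Recording sites are projected along the final-electrode trajectory with the
intra-operative implantation-depth adjustment added (negative offset =
implanted deeper); electrode centers are contact midpoints, and their
z-deviation from the sweetspot is signed (negative = ventral of it). The
"first single unit below the dorsal border" statistic screens out sparsely
spaced units — a unit must have at least two neighbors within 2 mm along
the trajectory (configurable; the zona incerta above the STN contains
scattered cells that would otherwise masquerade as the border) — and is
normalized by the STN traversal length; values outside [0, 1] are returned
unclipped but flagged.

## Group statistics

* **Cluster-based permutation test** for depth-resolved NRMS differences:
  pooled-variance two-sample t at each aligned depth, cluster-forming
  threshold p < 0.05, cluster mass = summed |t| over contiguous same-sign
  runs, null distribution of the maximum cluster mass from seeded label
  permutations (default 10,000), and Benjamini–Hochberg correction across
  the resulting cluster p-values. Although the source description calls the
  test "paired", the dose strata contain different trajectories, so the
  default is an unpaired label permutation; a paired sign-flip mode exists
  for genuinely matched designs.
* **ANOVA / MANOVA** via `stats::aov`/`stats::manova` and `car::Anova`
  (Type-II sums of squares for the unbalanced two-factor design). Effect
  sizes are derived from partial eta-squared:
  `d = 2 sqrt(eta2 / (1 - eta2))` with `eta2 = df1 F / (df1 F + df2)`
  (multivariate: `eta2 = 1 - Lambda^(1/s)`, `s = min(p, g-1)`). This is the
  conversion that links every published (F, d) pair this package
  re-derives, and it is therefore preferred over a two-marginal-group
  pooled-SD d for ANOVA effects; the plain two-sample d remains available.
* **Post hoc power** by normal approximation: Fisher-z for correlations
  (`power = Phi(z sqrt(n-3) - z_crit) + Phi(-z sqrt(n-3) - z_crit)`) and
  `ncp = d sqrt(n1 n2 / (n1 + n2))` for two-sample contrasts. An
  equal-group-size mode (`ncp = d sqrt(N)/2`) is provided because published
  power values for strongly unbalanced marginals are reproducible only
  under that convention; the unequal-n form is the default.
* **Spearman correlations** with average ranks for ties and Bonferroni
  multiplication; Bonferroni and BH-FDR corrections via `stats::p.adjust`.

## The synthetic cohort generator

The generator is the package's study-conditions definition, not a tuning
surface. Defaults encode a 25-patient cohort: 11 awake (LA) and 14 under
propofol, doses drawn per hemisphere from a truncated normal on
1.0–7.5 mg/kg/h whose truncated mean equals 3.9 (SD 1.8), stratified at
4 mg/kg/h (inclusive on the low side). Per condition, firing rate is
truncated-normal (LA 28.47 +/- 14.00 Hz, GA 21.07 +/- 14.37 Hz; location
solved so the truncated mean hits the target), burst index is
shifted-lognormal with support >= 1 (condition-by-structure cell means
6.21/2.00 under LA and 13.19/8.98 under GA for STN/SNr, derived from the
published condition and structure marginals under a no-interaction
constraint; cell SDs keep the condition-level coefficient of variation),
and single-unit depths are truncated normals (LA 2.32 +/- 3.01 mm, low-dose
GA 2.39 +/- 2.94, high-dose GA -0.07 +/- 2.38) drawn conditional on each
trajectory's STN+SNr extent, because the published depth summaries describe
units retained inside the nuclei; about 4% of units are placed
unconditionally and land outside both. Expected units per trajectory decay
with dose (`5.2 exp(-0.08 dose)`), emulating dose-dependent suppression of
isolatable units.

Spike trains are two-regime renewal processes: ISIs from a two-component
lognormal mixture with common log-SD 0.3, component geometric means
`target_bi` apart, and the location solved so the mean ISI equals
`1/target_fr`. This makes the downstream mixture fit identifiable and the
burst index analytically targetable; extraction recovers both FR and BI
without material bias at segment durations of ~10 s.

Burst index and sweetspot distance are coupled within condition through a
Gaussian copula. The STN/SNr composition gradient (bursty STN units sit
closer to the dorsolateral sweetspot than SNr units) already induces an
observed rank correlation of about -0.25 (LA) / -0.20 (GA) on its own; the
copula coefficients (LA -0.04, GA +0.10) are calibrated so the observed
cohort-level correlations land at about -0.28 and -0.11 — the values the
cohort is meant to exhibit. The positive GA coefficient is a calibration
constant offsetting composition, not a claim about within-structure
topography.

RMS profiles are baseline-1 with a multiplicative STN plateau (2.2 under no
sedation) scaled by a suppression factor that equals 1 at or below
4 mg/kg/h and declines by 0.12 per mg/kg/h above it, a milder SNr
elevation, logistic border blurring whose dorsal width grows with dose, and
lognormal multiplicative noise; a random per-trajectory gain emulates
uncalibrated amplifier units and is removed by normalization. EEG channels
are colored noise with spectrum `exp(-f/tau)`, `tau` solved numerically
against the SEF95 definition, so the generator and the estimator meet at
the target within the band; patient SEF95 targets follow
`23 - 2.0 * dose + noise` Hz, clamped to [3, 27]. Final-electrode centers
deviate from the sweetspot by condition (z: LA -0.39 +/- 0.91 mm, low-dose
GA -0.16 +/- 1.22, high-dose GA -1.55 +/- 0.93).

### What the generator does and does not emulate

It reproduces group-level means, SDs, dose-response directions, spatial
composition, and the border-blurring phenomenology. It does not emulate raw
extracellular waveforms, per-patient pharmacokinetics, non-stationarity
within a segment, spatially correlated noise between neighboring
trajectories, or registration error between imaging and physiology. Passing
tests therefore demonstrate that the analysis chain is correct and
well-calibrated on data with the published statistical structure — not that
it would be robust to every artifact of real recordings.

Two published inconsistencies are left as they are. First, the printed
group descriptives (28.47 +/- 14.00 vs 21.07 +/- 14.37 Hz) imply a
two-sample d of about 0.52, while the printed F statistic implies d = 0.384;
the generator matches the descriptives, so its cohorts show a somewhat
stronger anesthesia effect than the published F. Second, trajectory group
counts are reported inconsistently in the source; the generator simply uses
its configured counts. A further known divergence: the robust CV of a
two-component lognormal ISI mixture grows mechanically with the component
separation, so synthetic cohorts show a small condition effect on CV where
the published analysis found none — CV in real trains is shaped by
within-burst dynamics the renewal model does not represent.

## Numerical choices and degenerate inputs

Seeded determinism everywhere: every generator takes a seed, restores the
caller's RNG state, and derives per-entity child seeds from its own stream.
Truncated-normal locations are solved by `uniroot` so truncated means equal
their targets. Tangent line-ellipsoid intersections and zero-length spans
count as misses. The SEF95 of a single-bin spectrum is that bin's frequency;
cumulative interpolation is anchored at the lower band edge. SNR of a
noiseless trace is capped at 1e6. Cluster p-values use the add-one
permutation estimator `(1 + #{null >= obs}) / (n_perm + 1)`.

Problem sizes in the test suite are chosen to keep the full run at roughly
ten minutes: 200 null simulations with 1,000 permutations for the
family-wise error calibration, twenty 25-patient cohorts for the
qualitative-recovery check, and one million exponential ISIs for the CV
closed form.

## Known limitations

* The qualitative-recovery check asks every cohort to show a significant
  negative burst-index/sweetspot-distance correlation under GA, but the
  published post hoc power for that very correlation is 0.48; cohorts
  generated at the published effect size can satisfy it only about a third
  of the time, and the package reports this honestly rather than inflating
  the generator's effect size (`power_correlation(0.114, 282)` reproduces
  the 0.48).
* The ellipsoid atlas is a geometric stand-in; distances to the sweetspot
  are only as meaningful as its configured coordinates.
* The EM burst index is reliable from ~30 ISIs; very short or very sparse
  segments report a missing BI and are excluded from BI analyses.
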