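---
title: "Global electrical heterogeneity and the dynamic predictive accuracy of ECG markers"
author: "gehroc"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Global electrical heterogeneity and dynamic predictive accuracy}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(gehroc)
```

# Scope and model overview

`gehroc` couples two analyses that are usually published together in the
sudden-cardiac-death (SCD) risk-marker literature but rarely released as
reusable code: the computation of global electrical heterogeneity (GEH)
vectorcardiographic metrics from repeated 12-lead ECGs, and the
evaluation of how a continuous marker's predictive accuracy for two
competing modes of cardiac death changes with the prediction horizon.
Because the cohorts this analysis targets are access-restricted, the
package treats its synthetic-data generators as first-class, tested
components: they define geometry and hazards exactly, so every
measurement stage can be validated against a known truth.

# The GEH measurement chain

## Axis conventions

One convention is used everywhere (generator and metrics): X points
right-to-left, Y superior-to-inferior (positive down), Z
anterior-to-posterior (positive back).  Azimuth is the quadrant-aware
angle in the transverse X–Z plane from +X towards +Z, range
(−180°, 180°]; *conventional* elevation is the polar angle from +Y,
range [0°, 180°].  Amplitudes are µV, areas µV·ms, SAI QRST mV·ms.

## Kors transform

The orthogonal XYZ leads are a fixed linear combination of the eight
independent standard leads (I, II, V1–V6) using the published Kors
regression coefficients, stored verbatim in `KORS_MATRIX`.  The derived
limb leads (III, aVR, aVL, aVF) are linear combinations of I and II and
are deliberately ignored; tests assert this invariance.

## Median beat and origin point

A time-coherent median beat is built from beats labelled
`normal_sinus` only — PVCs, the sinus beats immediately before and after
a PVC, and beats labelled noisy are excluded by construction, never by a
amplitude heuristic, because beat adjudication is an input to this
package (delineation from raw signal is out of scope).  Usable beats are
windowed around their R peaks on a grid spanning the median RR interval,
aligned by maximizing the cross-correlation of their spatial vector
magnitude against a running median template (one refinement pass, shift
search ±10 samples ≈ ±20 ms at 500 Hz), and reduced by a per-sample
median, componentwise in X, Y, Z.  At least three usable beats are
required; fewer is an error rather than a silent low-quality output.

The origin point — the heart-vector zero reference — is estimated as the
mean XYZ over the electrically quietest 20-ms window (minimum mean
absolute spatial velocity) in the 40 ms preceding QRS onset, and
subtracted before any vector measurement.  This is a deliberate
simplification of more elaborate published origin-detection schemes: on
the flat baselines this package's generator produces, and on any beat
with a reasonable isoelectric PR segment, the two coincide; records with
no quiet pre-QRS segment (e.g. severe baseline drift at the PR segment)
are the known failure mode.

## Metrics

With `Q` and `T` the spatial peak (µV) or area (µV·ms) QRS and T
vectors:

* spatial QRS-T angle: `arccos(Q·T / (|Q||T|))`, clamped to [0°, 180°];
* SVG, peak form: `Q + T`; area form: componentwise trapezoidal integral
  of XYZ over QRS-onset→T-offset;
* SVG azimuth / elevation / magnitude as defined above;
* SAI QRST: `∫|X| + ∫|Y| + ∫|Z|` over QRS-onset→T-offset (mV·ms);
* heart rate from the median RR; QRS duration and QT from the fiducials;
  QTc by Bazett (`QT / sqrt(RR in s)`), the only correction implemented.

Numerical choices, stated once: integration is trapezoidal on the native
sampling grid with dt in ms (tests hold it to 0.5% of a 10×-oversampled
Riemann oracle on smooth beats); the QRS window is [QRS onset, QRS
offset] and the T window (QRS offset, T offset], half-open at the shared
boundary so the two areas sum exactly to the full-window integral; peak
searches break ties at the earliest sample; `arccos` arguments are
clamped to [−1, 1].

Two elevation definitions circulate for the SVG: the geometric polar
angle from +Y, and a plain `arctan(X/Y)` that appears in some published
formulations but cannot distinguish quadrants.  Both are implemented
(`elevation(v, mode = "conventional" | "literal")`), the conventional
form is the default, and reported elevations should state the mode.
Similarly, azimuth uses `atan2`, not plain `arctan`, since the SVG must
be allowed to point backward.  Area ("mean") vectors are reported as
plain integrals in µV·ms with explicit units; no time normalization is
applied, since angles are unaffected and published tables are
inconsistent about the convention.

# The synthetic ECG generator

Each beat's dipole is two Gaussian-windowed lobes: a narrow QRS lobe
(nominal support = QRS duration, σ = duration/6) and a broader T lobe
centred in the (QRS offset, T offset] window.  The lobe peak vectors
equal the requested (azimuth, elevation, magnitude) exactly, which makes
peak-vector recovery a sharp test.  The dipole is mapped to the eight
independent leads through the Moore–Penrose right-inverse of the Kors
matrix, so the forward transform recovers the dipole to numerical
tolerance and the real measurement path is exercised end to end; the
redundant limb leads are then derived by the standard relationships.
White noise, 0.3-Hz sinusoidal baseline wander, and PVC-like beats
(wide, 1.8× amplitude, reversed direction, neighbours labelled
`pre_post_pvc`) are optional contaminants.  Ground truth (peak vectors
analytically; area vectors and SAI QRST by 0.1-ms quadrature of the
clean single-beat dipole) is stored with the record, independent of the
measurement code path.

What the generator does *not* emulate — P waves, QRS notching,
respiration coupling, electrode misplacement, non-Gaussian noise — means
that passing its recovery tests demonstrates correctness of the vector
algebra and of the exclusion/alignment logic, not robustness to
real-world morphology; fiducials and beat labels are taken as given in
both worlds.

# The cohort generator

Participants carry a latent standard-normal marker `z`.  Two competing
causes (SCD, non-SCD death) have constant cause-specific hazards
`λ_k · exp(β_k z + c'x)` with shared clinical covariate effects `c'x`,
plus an independent exponential censoring process and administrative
censoring.  Event type is the cause of the earliest time; for a
cause-specific analysis the competing death is recorded as censoring at
its time — the same convention the accuracy machinery uses.  Each of up
to five visits (default spacing 3 years) yields a record whose time axis
starts at that visit's ECG; visits after death/censoring do not exist.
The marker follows a random walk across visits (default increment SD
0.2); this is a stand-in for unknown real marker trajectories, chosen
only to give the partition scheme genuine repeated-measures structure.

Defaults (SCD hazard 0.003/person-year, non-SCD 0.004, censoring 0.01,
administrative censoring at 25 years, ~55% female, mean age 54) were
chosen once to mirror the event counts and follow-up of a large
middle-aged epidemiological cohort: they put a 15,716-participant run in
the tens of SCD events within 1–2 years and hundreds beyond 5 years,
the regime in which the power analysis below is interesting.  Because
both hazards share the covariate effects, the SCD share of events under
`β = 0` is exactly `λ₁/(λ₁+λ₂)`, which the tests check at n = 20,000
within 3 standard errors.

A second generator, `generate_binormal_cohort()`, builds the classic
calibration fixture: cases (event inside the horizon) and controls with
unit-variance Gaussian markers separated by `delta`, so the true
cumulative-case AUC is `Φ(delta/√2)` (`binormal_true_auc()`), e.g.
0.7602 at `delta = 1`.

# Time-dependent ROC(t) AUC

## Estimator

The estimand is the cumulative-case / dynamic-control AUC at horizon
`t`: the probability that a subject with an event by `t` has a higher
marker than a subject event-free at `t`.  The incident/dynamic variant
is intentionally out of scope.  The estimator is the nearest-neighbour
bivariate survival estimator: conditional survival `S(t | M_i)` is a
weighted Kaplan–Meier over the `span · n` observations nearest to `M_i`
in marker rank space (symmetric indicator weights), which allows the
censoring process to depend on the marker — the known failure mode of
the naive Kaplan–Meier ROC.  Then with
`S(c, t) = mean(S(t | M_i) · 1[M_i > c])` and `S(t) = S(−∞, t)`,

* sensitivity: `((1 − F(c)) − S(c,t)) / (1 − S(t))`,
* specificity: `1 − S(c,t) / S(t)`,

on the grid of observed marker cutpoints, with the AUC by trapezoid.
The raw estimator is not guaranteed monotone along the cutpoint grid;
it is repaired by a cumulative maximum and the number of repaired points
is reported (`n_repaired`).  Ties in the marker are handled by the
rank-space windows and resolve, in the degenerate all-tied case, to AUC
0.5 exactly.  Horizons with no events, no smoothed survivors, or no
smoothed events are refused as inestimable rather than extrapolated.

## Span

The neighbourhood span is `0.25 · n^(1/3)` per cent of the observations
(`span_from_n`), computed from the record count of each analysis set —
at n = 1000, 2.5% of observations per neighbourhood.  This is the rule
as printed in the epidemiological literature this package follows; a
more common convention in reference implementations of the estimator is
`span = 0.25 · n^(−1/5)`, available as `method = "power"` for
comparison.  Both are deliberately light smoothing: with no censoring
before the horizon the estimator collapses, to numerical noise, onto the
exhaustive pairwise concordance, which the acceptance tests verify on 50
random cohorts to within 0.02.

## Partitioning, bootstrap, aggregation

Repeated visits of one participant are never independent, so the
accuracy analysis divides the longitudinal dataset into five
non-overlapping partitions in which each participant appears at most
once: a participant with five visits contributes exactly one visit to
each partition (randomized mapping), participants with fewer visits go
to a random subset of distinct partitions.  Within a partition,
uncertainty is assessed by resampling participants (not records) with
replacement, 500 replicates by default, and taking the 2.5th/97.5th
percentile of the replicate AUCs (percentile CI; no BCa correction is
attempted).  The summary row averages point estimates and CI bounds
across the estimable partitions.  The averaged interval keeps
single-partition width while the averaged point estimate has smaller
sampling error, so its coverage of a true value is conservative — the
binormal recovery test (truth 0.7602 inside the aggregated CI in ≥ 90%
of seeds) exploits exactly this property.

All stochastic operations take explicit integer seeds;
`evaluate_marker` derives per-partition, per-horizon bootstrap seeds
from its master seed, so a full run is reproducible bit for bit from the
manifest.

# Expected CI width for an AUC

For horizons with few events the observed bootstrap CI is itself noisy,
so the package reports the analytic expectation: the Hanley–McNeil
(1982) variance

`SE² = [A(1−A) + (n₁−1)(Q₁−A²) + (n₂−1)(Q₂−A²)] / (n₁ n₂)`,

`Q₁ = A/(2−A)`, `Q₂ = 2A²/(1+A)`, with width `2 z₀.₉₇₅ SE` and
symmetric unclipped bounds.  This formula was selected because it
reproduces, to the third decimal, every published "predicted" CI width
in the large-cohort table this package's acceptance tests encode (72
time × marker rows; eight representative triplets are asserted at
±0.002); the z quantile is used at full double precision, though 1.96
reproduces the same 3-dp values.

# Reclassification (IDI / NRI)

The incremental value of one marker over a clinical logistic model (age,
sex, race, diabetes, hypertension, CHD, stroke) is evaluated in landmark
windows after the ECG: 1–90, 91–180, 181–365, 366–730, 731–1825 days and
beyond 5 years.  The risk set of a window is everyone still at risk at
the window start; subjects censored (or lost to the competing cause)
inside a bounded window are dropped; in the final open-ended window
every event-free at-risk subject is a control, since no one can survive
past an infinite endpoint and the alternative would discard all
controls.  High-risk is ≥ 25% predicted risk for the sub-year windows
and ≥ 10% thereafter.

Fits are in-sample maximum-likelihood logistic regressions
(`stats::glm`; quasi-complete separation flagged at |coef| > 15 — common
in windows with a handful of events and reported rather than hidden).
IDI is the change in discrimination slope; category-free NRI counts any
probability movement; two-category NRI counts threshold crossings and
also reports events reclassified upward as "k/n (percent)".  p-values
use Pencina's asymptotic z-tests; no optimism correction or
cross-validation is applied, matching standard usage of these indices,
and the tests verify empirically that the IDI z-test holds its nominal
5% size (±3%) under a null marker at n = 2000 — users should know this
test is notoriously anti-conservative in small samples and for
non-nested comparisons, which is why the size check is part of the
acceptance suite rather than assumed.

# Pipeline

`run_pipeline()` chains simulate → GEH metrics → ROC(t) → expected CI →
reclassification → plot/manifest from a configuration list or YAML file
(defaults: horizons 0.25–15 years, B = 500, k = 5).  The ECG stage ties
the two halves together by tilting the synthetic T-vector azimuth with
the participant's marker before measuring it back; it is a demonstration
of the full chain, and the accuracy stages run on the cohort's marker
columns.  The JSON manifest (seed, config, sizes, package version)
suffices to reproduce every output exactly.

# Problem sizes used in the test suite

The stochastic validation sizes are the package's own choices, balancing
Monte-Carlo error against a test suite that stays pleasant to run:
oracle equivalence on 50 cohorts of n ≤ 200; binormal recovery at
n = 2000 over 20 seeds with B = 200; cause-specificity at n = 4000 over
10 seeds; ground-truth recovery on a 100-point direction/magnitude grid;
IDI test size over 200 null replicates at n = 2000.  Larger runs (e.g.
a 15,716-participant cohort with five visits, giving five partitions of
about 15,716 records) work unchanged through the same interfaces.

# Known limitations

* Fiducials, beat labels and R peaks are inputs; there is no delineator,
  and Bazett is the only QT correction.
* The origin detector assumes a quiet pre-QRS segment.
* Area-based SVG magnitudes are plain integrals (µV·ms); comparisons
  with tables printing µV need a stated normalization.
* Competing risks are handled by cause-specific censoring, not
  Fine–Gray; the ROC(t) AUCs are cause-specific accuracies.
* Percentile bootstrap CIs can undercover for extreme AUCs near 1.
* The marker random walk across visits is a modelling stand-in, not an
  estimate from any cohort.
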