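---
title: "Volumetric assessment of LV diastolic function: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Volumetric assessment of LV diastolic function: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(lvdiastole)
```

## The measurement problem

Diastolic dysfunction — impaired relaxation and filling of the left
ventricle — is routinely graded from echocardiography: transmitral inflow
velocities (E, A, deceleration time), tissue-Doppler annular relaxation
velocities (septal and lateral e′), and their ratio E/e′. Cine CMR, the
reference standard for volumes and systolic function, acquires the whole
cardiac cycle anyway; a model-based segmentation yields one LV cavity
volume per reconstructed phase, i.e. a time–volume curve V(t) with
temporal resolution RR/(number of phases) — about 30 ms for a typical
30-phase acquisition. The physiology that echocardiography reads from
velocities can be read from V(t) and from the motion of the mitral
annulus relative to the apex, with no extra sequences.

`lvdiastole` takes the curves and tracks as *inputs* (CSV; a simple
mask-stack slice-summation reducer is provided for binary short-axis
segmentations) and computes the volumetric diastolic parameter set, the
echo-based dysfunction grade used as the reference standard, and the
statistics with which such a method is validated against
echocardiography. Producing the curves from images — the 3D model fit —
is out of scope.

## Index definitions

With end-diastole at the R-wave trigger (frame 1) and end-systole (ES) at
the volume minimum:

| Index | Definition | Units |
|---|---|---|
| E | first maximum of dV/dt after ES | mL/s |
| A | first maximum of dV/dt after the post-E trough (absent if fused) | mL/s |
| NE, NA | E/EDV, A/EDV | s⁻¹ |
| E/A | ratio | — |
| RTPE, RTPA | time from ES to the E (A) peak | ms |
| DT | zero crossing of a line fitted to the E-wave downslope, minus the E-peak time | ms |
| DVR | time from ES until V first reaches ESV + 0.8·SV | ms |
| E′ (septal/lateral) | maximal early-diastolic rate of increase of the apex–annulus distance | mm/s |
| E/E′ | volumetric E over E′ | mL/mm |

The units contract is deliberate: volumetric rates are mL/s, not cm/s, so
CMR E/E′ carries mL/mm and is *not* numerically comparable to the
dimensionless echo E/e′ — they are correlates, compared by correlation and
ROC, never by Bland–Altman (which the package reserves for same-unit
pairs such as the two E/A ratios).

## Numerical choices

**Differentiation.** The cycle is periodic, so `derive_filling_rate()`
uses central differences with cyclic wrap: frame 1 and the last frame use
periodic neighbours. On a uniform grid the cyclic integral of the result
telescopes to zero exactly, which is the volume-conservation invariant
(violations beyond 1% of stroke volume warn — real curves may not close).

**Sub-frame refinement.** Sampled central differences act as a moving
average over ±1 frame, which attenuates a narrow filling lobe's peak by
(1 + sinc(πh/w))/2 — about 7% for a 105 ms half-width lobe at h ≈ 31 ms.
Since a cine reconstruction is uniformly sampled and periodic, the volume
curve has an exact trigonometric interpolant; `dense_filling_rate()`
differentiates it spectrally and `analyze_curve()` refines peak values
and times on that dense grid (within one frame of the sampled maximum).
Coefficients are shrunk by a spectral-subtraction noise floor estimated
from the top harmonics, which costs an exact signal almost nothing.

**End-systole.** `locate_end_systole()` returns the minimum-volume frame
(earliest on ties) — the conventional frame-level answer. For the timing
indices (RTPE/RTPA/DVR measured *from* ES) frame quantisation is the
dominant error at 30 ms resolution, so `analyze_curve()` refines the ES
time (config `refine_es`, default on): a smooth ejection tail vanishes
quadratically, so √(−dV/dt) is nearly linear in time over the tail; a
line fitted where ejection is between 2% and 30% of its peak magnitude is
extrapolated to its root. This stays clear of both interpolation ripple
around the zero-flow baseline and contamination by the early-filling
upstroke, and is exact for a raised-cosine ejection lobe.

**DT fit window.** All samples from the E peak (inclusive) to the first
subsequent local minimum (exclusive), requiring at least two points and a
negative slope; the baseline is rate = 0. Least squares over the window
is the default; a two-point chord (first/last window sample) is exposed
as `dt_method = "chord"` since the convention used by interactive
software is not standardised.

**DVR crossing.** Linear interpolation between the samples bracketing the
first upward crossing of ESV + 0.8·SV after ES; on clean curves the
crossing is bracketed on the dense interpolant for sub-frame accuracy.

**Local extrema on coarse grids.** A local maximum is a sample strictly
greater than both neighbours; a plateau counts once, at its first sample.
A monotonically decreasing post-ES rate (no interior maximum) takes the
first post-ES sample as E with a warning rather than failing a batch; a
cycle with no positive post-ES rate raises a classed no-filling error.
An absent A wave (fused filling) is a valid outcome: all A-derived fields
are `NA`, never zero-filled, and cohort statistics skip them pairwise.

**Noise adaptivity.** The volume-noise level is estimated from the power
of the highest Fourier harmonics. When the implied rate noise exceeds
0.4% of the peak rate, `analyze_curve()` switches to robust mode:
sampled-grid peak detection with 3-point parabolic refinement, a
prominence guard of three times the estimated rate noise, and coarse-grid
DT and DVR. The threshold separates clean synthetic curves from curves
with ≳0.4 mL Gaussian volume noise at 30 frames. First-local-maximum
detection inevitably degrades under heavy noise (≳0.8 mL at 30 frames):
a noise bump on the rising E limb can be taken for the peak. The 3-point
moving-average option (`smooth = TRUE`, off by default because smoothing
shifts peaks) is the mitigation for such data.

**E′ window.** The early-diastolic window runs from ES to
ES + 0.6·(RR − ES), shortened to the detected A-lobe onset (the post-E
trough of the filling rate) when one exists. The fraction is a declared
convention — "early diastole" has no standardised endpoint for annular
kinematics — chosen to exclude atrial-phase lengthening so that E′ is a
correlate of tissue-Doppler e′. It is a config parameter
(`eprime_window_frac`).

**E/e′ averaging.** Two conventions coexist. For the *grading criterion*
the default is E divided by the mean of septal and lateral e′ ("average E
over average e′"); for the *CMR mean E/E′* the default is the mean of the
two site ratios. Both are switchable (`echo_ratio_mode`, `ee_mean_mode`);
group means of ratios and ratios of group means do not commute, so the
choice is documented rather than hidden.

## Grading

Criteria: septal e′ < 8 cm/s, lateral e′ < 10 cm/s, mean E/e′ ≥ 10 — all
strict as written, with boundary values (8.0, 10.0, 9.99) pinned in the
unit tests. LV hypertrophy is LVMi > 115 g/m² (men) / > 95 g/m² (women),
strict. All three criteria → type II (reduced); exactly two, or one plus
hypertrophy → type I (impaired); otherwise normal. Hypertrophy never
promotes past type I: type II is reserved for the full three-criterion
pattern. Grading is a pure function of the flags — permutation-invariant
in which single criterion is met, and monotone (adding a criterion never
lowers the grade). A restrictive (type III) grade is out of scope.
Subjects whose heart rate differs by more than 15 beats/min between the
same-day echo and CMR studies are flagged for exclusion with a report,
never dropped silently.

## Statistics

- `anova_oneway()` / `anova_oneway_summary()`: classical equal-variance
  omnibus F. The summary form reconstructs the between-group sum of
  squares from group means and the within-group sum from (nᵢ−1)sᵢ², so it
  is *exactly* the raw-data ANOVA whenever the moments match — that
  equivalence is a tested invariant, and it is what lets published
  mean ± SD tables be re-analysed. Bonferroni pairwise contrasts are
  secondary output (`bonferroni_pairwise()`).
- `fisher_exact_rxc()`: two-sided exact p in the Freeman–Halton sense
  (sum of probabilities of all margin-preserving tables no more probable
  than the observed one), enumerated exactly up to a configurable total
  and by seeded Monte Carlo beyond it. Tested against a brute-force
  enumeration oracle on all small tables.
- `pearson_linear()`: Pearson r with the two-sided t-transform p, plus
  least-squares slope/intercept with the echo measure as predictor.
- `bland_altman()`: bias = mean(y−x), limits ± 1.96·SD. Unit mismatch is
  a contract error.
- `roc_auc_with_band()`: AUC as the tie-corrected rank statistic
  U/(n₁n₀) (ties count one half), p from the normal approximation with
  tie correction; bands poor < 0.7 ≤ good < 0.9 ≤ excellent. The intended
  contrast is reduced (positive) versus normal (negative), with
  intermediate subjects excluded first; `direction = "lower"` orients
  markers like E′ that fall with disease.
- `icc_two_way_random()`: single-measure, absolute-agreement ICC(2,1)
  from the two-way mean squares, with bands poor < 0.40 ≤ fair-to-good ≤
  0.75 < excellent, and Bland–Altman bias/limits attached for two raters.
  The two-way random *form* is fixed by convention here; reports should
  state it.
- `paired_mean_comparison()`: paired t, with the t = 0, p = 1 convention
  for identical series. Used for the modality comparison of the time
  intervals and cycle length, where subjects are their own controls.
- p-values are reported raw; the display convention (two decimals above
  0.01, four below, "<0.0001" under 10⁻⁴) only affects rendered output.

`cohort_report()` assembles these over a graded cohort (descriptives with
omnibus p per grade; echo-vs-CMR correlations; per-index ROC; the E/A
Bland–Altman; paired modality comparisons), collecting component failures
(e.g. a single-grade cohort making ROC degenerate) into an error table
instead of aborting.

## The synthetic cohort

Two layers, both with closed-form ground truth:

**Curves and tracks.** The filling-rate model is a sum of raised-cosine
lobes — one negative ejection lobe, an E lobe, and an optional A lobe —
integrated from EDV. Compact support makes every derived index analytic
(the least-squares DT of a raised-cosine downslope is
width·(π²+12)/24; the 80% crossing solves a closed-form cumulative), and
the lobe areas balance exactly, so cycles close by construction. Defaults
(RR 940 ms, 30 frames, EDV 106.8 mL, SV 73 mL, ES at 330 ms, E half-width
180 ms, A half-width 105 ms, E filling fraction 0.65) describe a normal
adult ventricle; the published summary moments are mutually inconsistent
for a single compact-support curve (peaks near 190/180 mL/s cannot refill
73 mL within a ~600 ms diastole), so the volumetric anchors (RR, EDV, SV)
are kept and the default peak amplitudes (~260/240 mL/s) follow from the
lobe areas — inside the physiological peak-filling-rate range of 2.5–3.5
EDV/s. Annulus tracks use the same lobe machinery for velocity, so the
continuous maximum early lengthening rate equals the requested E′
exactly. Gaussian volume noise / distance jitter are optional and off by
default.

**Cohort draws.** Each subject gets a true grade (defaults 64.7 / 20.6 /
14.7% normal / impaired / reduced) and grade-conditional truncated-normal
draws (±3 SD, positive) for every echo and CMR variable; echo and CMR E/A
are drawn jointly with a configurable cross-modality correlation (default
0.71); A, NE/NA, e′ means and E/e′ ratios are derived so the internal
identities hold exactly; the two same-day heart rates differ by a small
Gaussian amount (SD 4 beats/min) so the 15 beats/min exclusion rule is
rarely triggered, as in a same-day protocol. Each subject has a
deterministic seed substream, so cohorts are byte-reproducible and
individual subjects can be regenerated.

What the generator does *not* emulate: cross-variable covariance beyond
the E/A pair (published tables fix marginals only — all other
correlations default to zero and are configurable); beat-to-beat
variability (CMR curves average many cycles, echo reads single beats);
valve disease, arrhythmia, or restrictive physiology; and any image-level
artefact. Passing recovery tests on this generator therefore demonstrates
the *numerics* of the index extraction, not robustness to real-world
segmentation error. The pseudonormal pattern is represented — the
impaired group's E/A is drawn below the normal group's — so label
recovery by grading is intentionally imperfect for type I.

## Problem sizes used in the test suite

Parameter-recovery properties run on ≥100 seeded random curves at ~30 ms
sampling (tolerances: E and A within 2%, RTPE/RTPA within one frame, DVR
within half a frame, DT within one frame of the dense-grid value);
statistical oracles run on dozens of random instances (all-pairs AUC up
to n = 50, full Freeman–Halton enumeration up to table totals of 30);
cohort-level checks use n = 2 000–10 000 subjects. These sizes give
Monte-Carlo headroom well beyond the asserted tolerances while keeping
the default suite fast.

## Known limitations

- End-systole, and everything timed from it, is ill-conditioned when flow
  is near zero for tens of milliseconds; the √-tail extrapolation assumes
  a smoothly vanishing ejection tail.
- DT inherits the non-standardised downslope-window convention; the two
  exposed modes can differ by tens of ms on asymmetric lobes.
- First-local-maximum peak detection degrades under heavy volume noise
  (see *Noise adaptivity*); enable smoothing for such data.
- The package grades from echocardiographic measures only; it deliberately
  defines no CMR-side cutoffs — CMR indices are evaluated against the echo
  grade by ROC, which is how a validation study uses them.
- The mask-stack reducer is plain slice summation (pixel count × pixel
  area × slice spacing); it is a convenience for binary segmentations,
  not a replacement for model-based volume analysis.
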