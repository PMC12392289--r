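---
title: "Simulating and measuring elastogram-to-B-mode ratios with visreb"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Simulating and measuring elastogram-to-B-mode ratios with visreb}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(visreb)
```

## The problem

The elastogram-to-B-mode ratio (E/B) compares the apparent size of a
breast lesion in a mechanical parameter image against its size in the
anatomical B-mode image.  Malignant lesions tend to show E/B > 1 —
their margins stiffen (desmoplasia) and become more viscous
(vascularization, edema), so the mechanically altered region extends
beyond the echogenic boundary — whereas benign lesions tend to show
E/B < 1.  Viscoelastic-response (VisR) ultrasound estimates relative
elasticity (RE) and relative viscosity (RV) on axis from the tissue
displacement response to a pair of acoustic radiation force (ARFI)
pushes, while the conventional displacement surrogate, peak
displacement (PD), mixes the two properties: both a stiffer and a more
viscous tissue displace less, so distinct materials can produce
identical PD.  `visreb` builds a fully synthetic, seeded version of
this measurement problem — lesion phantoms, displacement physics, RF
speckle tracking, parametric imaging, automated E/B measurement and
classifier evaluation — so the mechanistic claim (elasticity- and
viscosity-derived E/B should outclassify displacement-derived E/B when
viscosity confounds displacement) can be exercised end to end under
known ground truth.

## Displacement model

Tissue at each pixel is a Voigt body: spring `E` (kPa) and damper `mu`
(Pa·s) in parallel, relaxation time `tau = mu/E` (ms when `E` is in
kPa and `mu` in Pa·s).  The acquisition timeline places two reference
pulses, a first push, 8 tracking pulses, a second push and 43 more
tracking pulses on consecutive slots of an 11.5 kHz pulse-repetition
clock; each push is a boxcar of 300 cycles at 4.21 MHz (71.26 µs,
shorter than the 86.96 µs slot, so pushes never collide with samples).
A unit push of duration `Tp` starting at `t0` displaces the pixel by
`A (1 - exp(-(t - t0)/tau))` during the push and
`A (1 - exp(-Tp/tau)) exp(-(t - t0 - Tp)/tau)` afterwards, with
`A = k F / E`; the double-push response is the superposition of the
two.  The absolute force `F` is unknown in practice, which is why the
fitted parameters are *relative*: the package folds the applied force
and a fixed scale constant (`1e5` µm·Pa per unit amplitude, chosen so
that soft-tissue parameters give peaks of a few microns) into the
amplitude, and reports `RE = 1/A` and `RV = tau · RE`.

Design choices worth knowing:

* **Inertia-free forward model and fit.**  Sub-millisecond ARFI
  responses in soft tissue are overdamped; the mass term exists only
  in the numerically integrated oracle (`msd_response_numeric`, via
  `deSolve`), which doubles as the independent check that the closed
  form is correct to < 1e-6 relative error.
* **Variable-projection fit.**  The two-parameter fit is linear in `A`
  given `tau`, so `fit_visr` projects the profile onto the
  unit-amplitude model shape and minimizes over `log(tau)` only
  (coarse scan of 48 log-spaced values in [1 µs, 50 ms], then Brent
  refinement).  This is exactly the least-squares optimum, is immune
  to starting-value failures, and vectorizes over pixels
  (`fit_visr_grid` shares the scan across an entire image and refines
  per pixel by parabolic interpolation).  A fit is `converged` when
  the residual RMS is below 20 % of the profile's peak.
* **Sampled peak displacement.**  PD is the maximum over the *sampled*
  timeline.  Because tracking samples sit in their own PRF slots, a
  nearly elastic pixel (`tau -> 0`) relaxes before the first post-push
  sample: sampled PD is non-monotone in viscosity, rising from zero to
  a ceiling of about 0.56 `A` (for the default timing) and decaying
  for large `tau`.  `pd_matched_pair` therefore solves for PD-matched
  material pairs on the decreasing (more viscous) branch, and
  `confound_pair(E, mu)` returns the member with half the elasticity —
  the constructive form of the PD confound.

## Phantoms and cohorts

A phantom is a 2-D (axial x lateral) pair of `E` and `mu` maps: default
geometry 2049 x 40 samples over roughly 40 x 20 mm (0.0195 mm axial,
0.5 mm lateral spacing), matching the printed image grid.  The lesion
is a rotated ellipse; the B-mode-visible lesion is always the full
ellipse.  A signed `margin_width` adds an elliptical annulus of
mechanically altered material *outside* the boundary (positive widths,
the malignant pattern — parametric lesion larger than B-mode) or
replaces the outer lesion ring with background material (negative
widths, the benign pattern — parametric lesion smaller).  Margin
material is expressed as multiples of the background.  Multiplicative
lognormal heterogeneity with a configurable coefficient of variation
(spatially white, unit mean) stands in for the parameter noise of real
VisR images.  Scatterer sets (24 per mm per line) provide fully
developed speckle for RF synthesis.

The cohort generator draws lesions from class-conditional
distributions and realizes one phantom per probe rotation (default 0,
30, 60, 90 degrees, rotating the lesion about its center with the
heterogeneity field re-sampled per rotation).  Defaults define the
study conditions:

* 40 lesions, 65 % benign (exactly `round(n * 0.65)`, mirroring the
  ~65/35 clinical balance), semi-major axis U(4.5, 6) mm, aspect ratio
  U(1.2, 1.6), center depth U(14, 26) mm, orientation U(0, 180)°.
* Background 5 kPa, 2 Pa·s (`tau` = 0.4 ms).  The mid-range
  relaxation time matters: it keeps both directions of the sampled-PD
  level set reachable, so PD-matched margins can be built stiffer *or*
  more viscous than background.
* Benign: core factors U(1.5, 2) on both `E` and `mu`; margin width
  U(-2, -0.3) mm with unit margin factors (the parametric lesion is
  simply smaller).
* Malignant: core factors U(1.8, 2.4); margin width U(0.5, 2.5) mm.
  Margin mechanics come in three kinds with an exact, seed-shuffled
  composition (deterministic counting, like the label rule): one third
  "plain" margins, stiffer and more viscous (factors U(2.5, 3) —
  the upper half of the plausible desmoplastic range, which keeps the
  margin on the lesion side of the measurement's half level given the
  core contrast); and two thirds PD-confounded margins built with
  `pd_matched_pair`, split evenly between a stiff branch (margin
  elasticity U(2.2, 2.6) x background, viscosity solved — the
  sampled-PD ceiling caps reachable stiff margins near 2.8x) and a
  viscous branch (margin elasticity background/8, viscosity solved,
  about 1.9x background).  Confounded margins are invisible in PD by
  construction while remaining contrasted in RE or RV — the mechanism
  by which displacement-derived E/B underperforms.
* Heterogeneity CV 0.3.  This was calibrated so that the CNR-based
  unsure rate of the default cohort falls in the 15–25 % band reported
  for human readers of clinical VisR images, and it is the dominant
  source of E/B measurement noise in ideal mode.

`null_cohort_spec()` zeroes the margin widths and factors for both
classes: every lesion then has parametric extent equal to its B-mode
extent and classifiers should collapse to chance — the negative
control.

## From phantoms to parametric images

`compute_images` runs per pixel: the displacement profile (analytic
Voigt response in `"ideal"` mode; normalized-cross-correlation
tracking of synthesized RF in `"rf"` mode), PD as the profile maximum,
RE/RV from the vectorized fit, and a B-mode rendering (echogenicity
with -6 dB hypoechoic lesions plus speckle-like noise in ideal mode;
log-compressed envelope in RF mode).  The push amplitude decays with
depth as one-way intensity attenuation
(`10^(-att · f_push · z / 10)`, default 0.5 dB/cm/MHz), which biases
fitted RE upward with depth (a weaker push reads as "stiffer per unit
force").  `build_calibration` simulates a homogeneous phantom to
record median RE/RV/PD per depth row, plus a grid of known materials
at the focal depth for an RV-bias-versus-fitted-RE table;
`apply_corrections` divides the images by the normalized depth curves
and the interpolated bias factor.  The exact functional form of the
corrections used clinically is not public; this row-median
normalization is a declared substitute that provably flattens what the
simulated attenuation bends (the tests close that loop and check
idempotence).  RF mode is the fidelity reference for the tracking
chain; cohort studies default to ideal mode, which isolates the
measurement geometry from tracking noise.

RF synthesis is a 1-D per-line convolution model (Gaussian-windowed
2-cycle 6.15 MHz tone over point scatterers, 40 MHz sampling, additive
white noise at a configurable SNR); it deliberately omits lateral beam
coupling, diffraction and aberration.  Tracking uses 1.5-wavelength
kernels with 50 % overlap, +/- 8 samples search, parabolic subsample
interpolation with ties broken toward the smaller lag.

## Automated E/B measurement

The B-mode diameter is the largest extent of the annotation polygon
(brute force over ≥ 256 evenly spaced boundary vertices; ties broken
toward the most lateral segment).  The line is copied, fixed in place,
onto each parametric image and each endpoint is adjusted along it:

* The lesion level `L` is the median parametric value inside the
  B-mode boundary along the line; the background level `B` is the
  median over a surrounding annulus (one equivalent radius wide,
  starting half an equivalent radius out).  Two deliberate deviations
  from the obvious choices are worth recording.  First, `B` is *not*
  estimated from the line tails: margins may legally fill most of the
  search window, in which case tail medians estimate the margin, not
  the background, and the half level inverts.  Second, the annulus
  standoff exists because material immediately outside the boundary is
  exactly where an altered margin may sit; without the standoff, the
  background estimate (and the CNR below) is contaminated by the very
  signal being measured, and the clearest malignant lesions get
  flagged as unreadable.
* Each endpoint then walks along the line from its B-mode position:
  outward while the profile stays on the lesion side of the half level
  `(L + B)/2`, inward otherwise, stopping at the first crossing that
  *persists* for 0.5 mm (one lateral pixel).  The persistence
  requirement encodes that a perceived boundary is a sustained
  transition, not a single noisy pixel, and is what keeps benign
  (receded) measurements from being dragged to the B-mode boundary by
  isolated noise excursions.  The window is capped at 50 % of the
  B-mode radius beyond each endpoint; without a crossing the endpoint
  stays put.  Profiles are sampled at quarter-pixel steps with
  bilinear interpolation, so measured lengths are accurate to about
  one pixel — with 0.5 mm lines, the lateral spacing dominates the E/B
  error budget, which is also why cohort grids can use 256 axial rows
  (0.156 mm) without losing measurement accuracy while cutting
  simulation cost by a factor of eight relative to the full 2049-row
  grid.
* E/B is the adjusted length over the B-mode length.  The B-mode
  diameter itself is never adjusted, so an image measured against its
  own annotation gives exactly 1, and the rule is scale-free (any
  positive rescaling of the image leaves E/B unchanged).
* Image quality: `CNR = |mean_in - mean_out| / sqrt(var_in +
  var_out)` between the lesion interior and the background annulus;
  images under the threshold (default 0.5) are flagged "unsure" and
  excluded from classifier fitting, mirroring the reader protocol.

Lesion characteristics are computed from the annotation (depth =
centroid depth, shoelace area, circularity `4·pi·A/P²`) and from the
rotation stack (degree of anisotropy per modality = max/min over
rotations of the median in-lesion value; reported absent with fewer
than two rotations).

## Classifiers and statistics

`run_study` measures every lesion view, then fits ridge-stabilized
(1e-6 on standardized slopes) logistic regressions for the seven E/B
feature subsets {PD}, {RE}, {RV}, {PD,RE}, {PD,RV}, {RE,RV},
{PD,RE,RV}, excluding records unsure in any member modality.  Models
are fit and evaluated in-sample (no split is used by the clinical
protocol being emulated; the in-sample optimism is visible in the null
cohort, whose AUCs sit slightly above 0.5 but inside [0.4, 0.6]).
ROC analysis uses the Mann-Whitney rank form of the AUC with midrank
tie handling and reports sensitivity/specificity at the Youden
optimum.  Pearson/Spearman correlations (E/B and unsure counts versus
lesion characteristics) and the two-sided Wilcoxon rank-sum test
(exact for combined n ≤ 10 without ties) round out the statistics.

## Determinism and numerical choices

Every stochastic step draws from a seed derived from the master seed,
a stage tag and an index (three multiplicative-congruential mixing
rounds; naive sequential seeds leave R's Mersenne-Twister warm-up
correlated across nearby streams, which showed up as skewed
margin-type compositions before the mixing was added).  Tie-breaks are
explicit everywhere: diameter ties toward the lateral axis,
correlation-peak ties toward the smaller lag, Youden ties toward the
lower threshold.  Degenerate inputs are handled, not patched over:
`tau = 0` is the step-response limit, constant classifier scores
return AUC 0.5 with a degenerate flag, zero-variance correlation
inputs raise errors naming the offending argument.

## What the synthetic cohorts do and do not show

The phantoms reproduce the *structure* the measurement relies on —
class-conditional margin mechanics, the PD level-set confound, probe
rotation geometry, depth-dependent push amplitude, parameter-map noise
— under known ground truth, so passing tests demonstrate that the
pipeline measures what it claims to measure and that the comparative
claim (RE/RV-derived E/B beats PD-derived E/B when margins are
PD-confounded) follows from the stated mechanism.  They do not
emulate real breast tissue: no 3-D geometry, no acoustic beam physics
beyond the amplitude-depth profile, no reader variability (the
endpoint rule is one deterministic surrogate for a perceptual
judgement), no biopsy ground-truth uncertainty, and lesion size/depth
distributions are free parameters rather than clinical estimates.
Absolute AUC values from synthetic cohorts are therefore not
comparable to clinical AUCs; only orderings and trends are
meaningful.  Problem sizes used by the shipped tests (256-row cohort
grids, 40 lesions x 4 rotations, 10 replicate seeds) keep a full
study under half a minute on one core.
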