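---
title: "Methods: zebrafish ocular phenotyping with zfocular"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: zebrafish ocular phenotyping with zfocular}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(zfocular)
```

# Overview

`zfocular` analyzes the four assays of an in vivo zebrafish ocular
phenotyping pipeline — SD-OCT biometry, eccentric infrared photorefraction,
rebound tonometry and the optokinetic response (OKR) — and provides the
repeated-measures statistics that tie them together. Because no public raw
data exist for these assays, the package also contains a first-class
synthetic generator that renders all four raw-data streams from
parameterized model eyes, so every analysis stage can be validated by round
trip against known ground truth.

# SD-OCT biometry

## Model

Spectral-domain OCT measures optical path length: a structure of geometric
thickness $t$ inside a medium of refractive index $n$ occupies $t \cdot n$
micrometres of depth in the scan. The depth axis of an `OctVolume` is
therefore *optical-path space*, sampled at 2 µm per pixel by default, and
the geometric thickness of each ocular compartment is its optical extent
divided by the compartment index:

$$t_i = \frac{z_{i+1} - z_i}{n_i}$$

with the standard index values cornea 1.33, anterior chamber 1.34, lens
1.40 (a bulk value for the gradient-index fish lens), vitreous chamber
1.34 and retina 1.38. No separate RPE index is established for zebrafish;
the RPE inherits the retinal index (`refractiveIndices()` exposes it as a
separate parameter for sensitivity analyses). Treating the correction as a
per-compartment division is the only reading under which "correcting for
the refractive index" is a well-defined linear operation on optical-path
pixels, and it is what the generator inverts: the forward model places
interface $k$ at the cumulative sum $\sum_{i<k} t_i n_i$.

## Segmentation

Seven interfaces are segmented along the central axis: cornea outer/inner,
lens anterior/posterior, retina inner, retina/RPE and RPE outer. The
algorithm is deliberately simple and testable:

1. the central A-scan is the lateral position maximizing the
   anterior-to-posterior extent of supra-threshold signal (operationally:
   the centroid of the near-maximal plateau, because gently curved
   interfaces make many columns tie at the maximal pixel extent);
2. a median intensity profile over a ±10-column band suppresses speckle;
3. interfaces are the ordered intensity peaks of that profile above a
   prominence floor (25% of the background-to-maximum range, minimum
   separation 3 pixels), refined by three-point parabolic interpolation.

Sub-pixel interpolation is not optional: the corneal-thickness differences
of interest are ~5 µm at a 2 µm pixel pitch. On noiseless synthetic
renders every interface is recovered to well under one pixel; at the
default speckle level the mean absolute boundary error stays below 2 µm.

Axial length is defined as the sum of the six compartments (the RPE is
included; whether the original instrument convention includes it is not
externally fixed, so the choice is documented here and used consistently
on both the generator and analysis sides). Eye volume uses an ellipsoid
$(4/3)\pi abc$ with the axial semi-axis from segmentation and the two
equatorial semi-axes measured between the outermost intensity peaks of the
mid-depth en-face slice; this reduces to the sphere formula within 0.1% on
a rendered spherical eye. A near-zero anterior chamber (the adult
zebrafish lens can touch the cornea) merges two reflections into one peak;
the six-peak case is interpreted as cornea–lens contact and reported as
ACD 0 with an `acd_at_floor` qc flag rather than failing.

# Eccentric photorefraction

Under eccentric infrared illumination the pupil shows a vertical
brightness gradient whose slope is proportional to defocus.
`brightnessSlope()` fits intensity against vertical position (normalized
to the pupil radius) along the central vertical chord, excluding a 10%
rim. Slopes convert to diopters through an ophthalmic-lens calibration
(`calibrateRefraction()`, OLS `D = gain * slope + offset`) persisted as a
first-class object. The per-eye result averages 100 frames.

The calibration constants of the physical instrument are device-specific
and not externally available, so the package default
(`defaultCalibration()`, gain 0.5 D per a.u./pupil-radius) is the
calibration of its own forward model; genotype *differences* — the
quantities validated here — are invariant to the shared gain. Absolute
diopters in small eyes also carry the small-eye retinoscopic artifact
(reflection at the nerve fiber layer biases readings hyperopic), which is
a further reason the package's acceptance surface is differences against
wild type, not absolute values.

The relative refractive error complements the instrument measurement from
biometry alone: $RRE = 1 - r_{ret}/f$ with the idealized focal length
$f = 2.182\, r_{lens} + 11.699$ µm, a Matthiessen-type linear lens model
calibrated on emmetropic wild-type eyes. Negative values are myopic,
positive hyperopic. Two conventions had to be fixed: the published
coefficient pair is used as printed with the intercept in micrometres
(the same unit as the lens radius), and the retinal radius is
operationalized as lens centre to inner retina, i.e. lens radius plus
vitreous chamber depth (`rreFromBiometry()`).

# Optokinetic response

Traces are binocular eye-angle time series under a rotating drum (defaults:
20 deg/s, 0.15 cycles/deg). Saccades are samples where the Savitzky–Golay
smoothed derivative (0.2 s window) exceeds 100 deg/s opposite the stimulus
direction; slow phases are the intervals between saccades, each fitted by
least squares, with segments shorter than 0.3 s or with $r^2 < 0.8$
discarded. None of these three thresholds is externally fixed; they were
chosen once so that a 20 deg/s slow phase can never be misclassified as a
saccade (a 20-degree reset completes within two samples and produces a
smoothed peak velocity above 130 deg/s, while the slow phase stays near
20), and all three are exposed in the configuration. The per-eye velocity
is the median of segment slopes; per fish, temporally and nasally directed
movements are averaged. Optokinetic gain is eye velocity over drum
velocity; ETMs (eye-tracking movements, one slow-phase/saccade cycle) are
counted per consecutive 15 s window with a partial trailing window
dropped. A fish with no segment passing the $r^2$ floor in either eye is a
non-responder: gains undefined, ETM count zero. Whether an ETM counts
saccades or full cycles is a convention; saccade-delimited cycles are used,
making the per-window totals equal the saccade counts.

`trackEyeAngles()` recovers angles from dorsal-view frames (threshold, two
largest dark components, orientation from second-order image moments,
left/right by lateral position, temporal unwrapping modulo 180°); on
rendered frames the RMS angle error is below 1 degree.

# Statistics

The two eyes of one fish are not independent. Per-eye metrics are analyzed
with a linear mixed model, `value ~ genotype + (1 | fish)`, fitted by REML
(`nlme::lme`); the random fish intercept induces exactly the
compound-symmetry covariance between eyes, with the variance components
constrained non-negative. Genotype is a between-fish effect, so the fixed
effect is tested on between-fish degrees of freedom, $n_{fish} - k$; in
the balanced two-eyes design this choice makes the REML test identical to
the closed-form GLS solution — a pooled t-test on fish means — which the
test suite asserts to numerical precision, along with a 3–7% empirical
type-I error over 2000 simulated null cohorts. The exact denominator-df
convention of the original analysis software is not published;
between-fish df is the conservative choice consistent with the
repeated-measures structure. If the REML fit fails the same closed-form
between-fish analysis is reported with `converged = FALSE`.

Per-fish metrics (optokinetic gain, ETM counts, body length) use Welch's
heteroscedastic ANOVA (`stats::oneway.test`), cross-checked in the tests
against an independent transcription of the published Welch formula and
against the $F = t^2$ identity for two groups.

`sizeMatchFilter()` enforces the body-length matching rule: each mutant
group's mean body length must be within 1% (inclusive) of the wild-type
mean, isolating intraocular from whole-body size differences.

`powerSim()` replaces closed-form power software with Monte Carlo under
the same compound-symmetry model: the user supplies the variance
components (the study's own within-group variances are not published, so
no printed power value is treated as reproducible), and the balanced-design
identity above lets the simulation use the fish-means t-test for speed;
`method = "reml"` runs the full model per replicate.

# The synthetic generator: what it emulates, and what it does not

Presets (`makeEyeGeometry()`, `assayPresets()`) encode wild-type baselines
and mutant deltas for two lines: `prss56` (posterior microphthalmia: short
axial length driven by vitreous chamber and lens, thicker retina, late
corneal thickening) and `fbn1` (Marfan-type lens subluxation: deeper
anterior chamber, late vitreous shortening, unchanged axial length).
Wild-type retinal thickness follows the measured thinning 152 → 137 → 126
µm over 2 → 6 months post-fertilization. Other wild-type absolute
baselines are not externally fixed; they are plausible adult-zebrafish
constants declared in `R/presets.R`, and only genotype differences are
asserted against measured values. Two consistency constraints pin them
down: wild-type eyes must be emmetropic under the focal-length model
(the 2.182/11.699 regression was calibrated on wild-type eyes, so their
lens-centre-to-retina distance must sit at the idealized focal length —
with a 600 µm lens at 6 mpf that forces a ~366 µm vitreous chamber), and
the wild-type vitreous chamber must exceed the largest mutant VCD
reduction (−288 µm) by enough that every mutant preset keeps a positive,
optically resolvable vitreous chamber. The printed per-compartment deltas for
`prss56` do not sum exactly to the printed axial-length effect (per-panel
rounding); the residual (≤ 4 µm) is absorbed into the VCD delta so the
preset axial delta equals the printed axial effect, axial length being the
headline endpoint.

Cohort noise (`cohortSpec()`): between-fish SD 1% and between-eye SD 0.5%
of the age-matched wild-type component mean. The 1% figure mirrors the
study design itself — cohorts are selected to be body-length matched
within 1%, which bounds residual between-fish ocular size variation at
about that relative scale; the generator emulates the post-selection
cohort, not an unselected population. Body lengths are drawn from one
common distribution (30 ± 0.1 mm) for all genotypes, so the matching rule
passes by construction. Refraction noise is 1 D between fish and 0.5 D
between eyes; tonometer readings get 1.5 mmHg of noise, six per eye; OKR
traces carry 0.5 deg of angle noise.

The OCT renderer draws interface caps (Gaussian axial profile, σ = 2.5 µm,
sub-pixel centre placement) near the axis — anterior interfaces bowing
posteriorly off-axis, posterior ones anteriorly, so the central A-scan has
the maximal extent — and an ellipsoidal globe shell in the periphery for
the en-face equatorial measurement. Lateral curvature is cosmetic (40 mm
cap radius): all biometric endpoints are axial, and the flat-enough caps
keep the band-median bias well under one pixel. Speckle is emulated as
additive Gaussian noise (SD 800 a.u. against interface peaks of 20,000).

Passing round trips therefore demonstrate that the analysis inverts the
stated physics (optical-path scaling, ramp slopes, sawtooth kinematics)
under realistic noise and the study's sampling design. They do not
demonstrate robustness to what the generator omits: real speckle is
multiplicative and correlated, real interfaces have tissue-dependent
reflectivity and shadowing, real eyes have motion artifacts, off-axis
alignment and non-spherical lenses, real pupil frames have corneal
reflexes and iris texture, and real OKR traces contain blinks and drift.
Those belong to instrument-specific validation on real recordings.

# Numerical choices and degenerate inputs

* Peak detection: prominence floor 25% of the background-to-maximum range,
  minimum peak separation 3 z-pixels; more than the expected number of
  peaks keeps the tallest, fewer is a qc failure naming the count.
* Parabolic sub-pixel offsets are clamped to ±0.5 pixel.
* Background intensity is estimated as the median of a strided ~200k-voxel
  subsample.
* Uniform (contrast-free) volumes, blank pupil frames, all-failed frame
  sets, empty tonometer reading lists and sub-minimum designs (fewer than
  2 genotypes or 3 fish per genotype) raise errors rather than returning
  values; zero-variance measurement tables return a zero effect with `NA`
  p-values.
* Saccade events closer than 0.1 s are merged; segment fits are guarded
  0.05 s away from each saccade.
* `aggregateIop` applies no outlier rejection beyond dropping non-finite
  and non-positive readings: the protocol specifies plain averaging.

# Problem sizes

The acceptance analyses use the full study design: 10 fish / 20 eyes per
genotype, volumes covering the full 1.7 × 1.7 × 2.2 mm field of view at
2 µm depth pitch (85 × 85 × 1100 voxels at 20 µm lateral pitch), 100
pupil frames per eye, 60 s traces at 60 Hz, and 2000 null replicates for
the type-I calibration. The unit-test suite exercises the same code on
reduced cohorts (3–5 fish, 61 × 61 × 920 voxels) to keep it fast.

# Known limitations

* Axial-only biometry: no B-scan flattening, motion correction or retinal
  sublayer segmentation; the segmentation assumes one dominant axis.
* The cornea–lens-contact fallback assumes a missing seventh peak means a
  collapsed anterior chamber; other missing interfaces would be
  misattributed (the qc flag marks every such record).
* Absolute diopters are only meaningful relative to the calibration in
  use; the small-eye retinoscopic artifact is reported as a caveat, not
  modeled.
* Welch ANOVA requires at least two values per group and positive variance
  in the statistic's denominator.
* The mixed model covers the two-genotype-and-more, one-age cohort layout;
  longitudinal (multi-age) covariance structures are out of scope.
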