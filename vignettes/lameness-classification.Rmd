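---
title: "Movement-asymmetry features and SVM lame-limb classification at the trot"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Movement-asymmetry features and SVM lame-limb classification at the trot}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(equigait)
```

## The problem

A horse lame in one limb unloads it at the trot, and the resulting
left–right asymmetry propagates to the vertical motion of the head, withers
and pelvis. Clinicians read this asymmetry by eye; inertial sensors measure
it. `equigait` implements the full quantitative chain: simulated (or
imported) 200 Hz trot recordings are segmented into strides, summarized by
27 movement-asymmetry features, and classified into five groups — sound, or
lame in the right fore (RF), left fore (LF), right hind (RH) or left hind
(LH) limb — by a class-weighted RBF-kernel support-vector machine validated
by bootstrapping.

Because clinical recordings of this kind are not publicly deposited, the
package ships a seeded synthetic-gait generator as a first-class module. It
also carries two published summary tables from a 287-horse clinical
validation cohort (a 5×5 confusion matrix and a grade-distribution table) so
that every derived statistic of that study can be recomputed exactly from
counts.

## The signal model

At the trot the two diagonal limb pairs strike alternately, so upper-body
vertical displacement oscillates twice per stride. The generator models each
sensor $s \in \{H, W, P\}$ (head, withers, pelvis) as a two-harmonic
sinusoid

$$y_s(t) = -A_s \cos(4\pi f t) \;+\; a_s \sin(2\pi f t + \psi_s) \;+\;
\varepsilon(t),$$

where $f$ is the stride frequency, $A_s$ the symmetric (second-harmonic)
amplitude, and $\varepsilon$ white Gaussian noise. Lameness enters purely
through the stride-frequency (first-harmonic) term: its amplitude is

$$a_s = g \cdot \text{grade} \cdot w_{\ell s} \cdot A_s,$$

with $g$ the asymmetry gain per grade unit and $w_{\ell s}$ a signed weight
coupling the lame limb $\ell$ to sensor $s$. The phase $\psi_s$ is fixed per
sensor so that a positive weight produces a *shallower* displacement minimum
during the stance of the sensor's right reference limb (right forelimb for
head and withers, right hindlimb for the pelvis) — that is, positive
asymmetry indices for right-limb lameness and, by sign flip, negative ones
for left-limb lameness.

Limb protraction–retraction angles are single sinusoids
$\theta_\ell(t) = \Theta_\ell \sin(2\pi f t + \phi_\ell)$ with trot phasing
(diagonal limbs in phase, contralateral limbs half a stride apart). The lame
limb's amplitude is reduced by a per-grade retraction deficit. Stance onset
is defined at maximal protraction and lift-off at maximal retraction, which
makes gait events exact on the sinusoid model; events are stored as sample
indices.

This model was chosen because every downstream feature — the asymmetry
indices, the harmonic energy ratio and phase difference — has a closed form
on it, so the whole pipeline can be checked analytically. A real
accelerometer-derived signal contains transients, broadband noise, and
stride-to-stride variability that this model deliberately omits (see
*Limitations*).

### Compensation weights

The default weight matrix (rows RF, LF, RH, LH; columns H, W, P) is

```{r}
default_compensation_matrix()
```

Signs encode the side; magnitudes encode the classic compensatory pattern:
forelimb lameness expresses mainly at the head and withers, hindlimb
lameness mainly at the pelvis with a smaller *ipsilateral* head component —
which is exactly why right-hind lameness can be mistaken for right-fore
lameness by both clinicians and classifiers. The values are a configurable
modelling choice, not a clinical estimate; no quantitative compensation
magnitudes are available to calibrate them against.

### Between-horse variability

`simulate_trial()` is strictly deterministic in its parameters: a zero-noise
`SOUND` trial is exactly symmetric. Realism at the cohort level comes from
`simulate_cohort()`, which draws per-horse parameters around the shared
baseline:

| parameter | default | what it emulates |
|---|---|---|
| `amplitude_cv` | 0.15 | horses differ in overall vertical displacement |
| `compensation_jitter_sd` | 0.25 | individual compensation strategies; the source of fore–hind confusions |
| `physio_asymmetry_sd` | 0.3 grade-equiv. | physiological asymmetry present in *all* horses, including sound ones |
| `retraction_jitter_cv` | 0.03 | small natural left–right retraction imbalance |
| `stride_frequency_cv` | 0.05 | horses trot at different cadences (a constant cadence would make the stride-frequency feature degenerate) |

These values were fixed once, on biomechanical plausibility, as part of the
generator's design. Lame grades are drawn from the empirical grade-2..7
distribution of the reference cohort's grade table; sound horses draw grades
from {0, 1}. Set all five parameters to zero for perfectly clean cohorts.

## From signal to features

**Segmentation.** One stride is one full cycle of a reference limb (default:
right hind), delimited by successive stance onsets; at least 3 complete
strides are required and stride durations must agree to 10 % (an
aperiodicity guard). Each stride is linearly resampled to 101 points on the
0–100 % stride grid (the odd count keeps the 50 % midpoint exact), centred
by removing its mean level (a drift guard that leaves amplitudes untouched),
and averaged pointwise into a mean stride curve per sensor.

**Landmarks.** The trot-pattern mean curve has two minima (the two diagonal
stances) and two maxima. Extrema are detected on the circular curve by
neighbour comparison, with a prominence filter (default 2 % of the curve
range) that removes noise ripples; anything other than exactly 2 + 2 extrema
is an error that reports the counts found. Each minimum is assigned to the
half-stride in which the sensor's right or left reference limb is in stance
(by circular distance to the limb's mid-stance fraction, computed from the
stance events). For the half assigned to side $X$: `up_X` is the following
local maximum minus the minimum, `down_X` the preceding maximum minus the
minimum, and `diffTmax_X` the following maximum minus the curve's global
minimum — the last definition is ours, since the literature it descends from
does not state one; it is isolated behind the landmark layer. `ROM` is the
global range.

**Asymmetry indices.** Two normalization dialects exist in the field and
both are implemented:

* `"caption"` (default): the five classic contralateral-denominator
  formulas, e.g. $\mathrm{AsI_{up}} = 100\,(up_L - up_R)/up_L$ and
  $\mathrm{AsI_{min}} = 100\,(min_R - min_L)/up_L$. This is the only fully
  explicit formula set in the source material, hence the default.
* `"rom_normalized"`: the same numerators divided by ROM. This dialect is
  exactly antisymmetric under a left–right mirror and is the one used by the
  package's mirror-symmetry tests.

Every output file records which dialect produced it. Zero denominators raise
an error naming the offending index.

**Fourier features.** A least-squares two-harmonic fit
$c_0 + c_1\cos 2\pi u + s_1 \sin 2\pi u + c_2 \cos 4\pi u + s_2 \sin 4\pi u$
on the mean curve yields amplitudes and phases. The energy ratio is
$\mathrm{ERz} = 100\,a_2^2/a_1^2$ (large = symmetric); the phase difference
is $\Delta\phi = \phi_1 - \phi_2$ wrapped into $(-180°, 180°]$, computed
without harmonic-order rescaling (the historical convention is not
recoverable; ours is documented and stable). A perfectly symmetric signal
has $a_1 = 0$: its ERz is reported at a configurable ceiling (default
$10^6$) and flagged degenerate rather than infinite; phases of vanishing
amplitudes are 0 by convention.

**Retraction asymmetry.** Per limb, the retraction angle is the mean over
strides of $|\theta|$ at lift-off; the index is
$100\,(\text{left}-\text{right})/\tfrac{1}{2}(\text{left}+\text{right})$.
The pair mean is used as denominator because no contralateral-denominator
convention exists for this feature. The feature table lists a fore pair and
a hind pair index — retraction is measured by the cannon sensors, so it is a
property of a limb pair, not of an upper-body sensor.

Together: 5 asymmetry indices × 3 sensors, ERz and Δφ × 3, ROM × 3, two
retraction indices, and stride frequency — 27 features, in a fixed order
(`feature_names()`).

## Classification protocol

All features are standardized (centred, unit sample SD); the parameters are
stored and reapplied to any new data. The SVM uses the kernel
$K(x, x') = \exp(-\sigma\|x - x'\|^2)$ with $\sigma = 0.036$ held fixed —
note this $\sigma$ *is* the `gamma` of libsvm-style parameterizations. The
cost parameter is tuned over the doubling grid
$\{0.25, 0.5, \dots, 128\}$ (10 values) by bootstrap resampling: per
candidate cost, the model is fitted on a resample and scored on the
out-of-bag rows, averaged over 25 tuning repetitions (the same resamples are
reused across costs); ties go to the smallest cost, favouring
regularization. Class weights $w_c = N/(K n_c)$ counteract the 92:31 class
imbalance. Multiclass is one-vs-one voting (the kernlab default, and the de
facto standard of the toolchain this protocol descends from).

Final validation refits the *entire* pipeline — standardization, weights,
SVM at the selected cost — inside each of 400 seeded bootstrap repetitions
and scores out-of-bag rows; a resample missing a class is redrawn (and
counted). Two confusion reports are produced and labelled: the
resubstitution matrix (refit on all data, applied to the same data) and the
pooled out-of-bag matrix; the provenance of a published confusion matrix is
often ambiguous between the two, so both are available.

Per-class variable importance is model-agnostic filter importance: for each
feature and class, the ROC AUC of the raw feature separating that class from
the rest, folded as $\max(\mathrm{AUC}, 1-\mathrm{AUC})$, then min–max
rescaled globally to 0–100. Global (rather than per-column) scaling is a
design choice: it preserves cross-class comparability at the price of
guaranteeing a 0 and a 100 only globally. Constant features have no ROC
curve and are reported at 0.

## Numerical choices

* Exactness of the null property: a zero-noise sound trial yields asymmetry
  indices that are *exactly* zero only when the sampling grid is
  commensurate with the stride (integer samples per half-stride). The test
  suite uses 1.25 Hz at 200 Hz (160 samples/stride) for machine-precision
  assertions; at the default 1.4 Hz the 101-point linear resampling leaves
  interpolation residues of order $10^{-2}$ % — far below any biological
  signal, but not zero.
* Stance events are integer sample indices; stride frequency recovered from
  them is exact at commensurate cadences and accurate to ~$10^{-4}$
  relative at 1.4 Hz/200 Hz (rounding of onsets).
* The acceleration-to-displacement path (`displacement_from_acceleration()`)
  is optional plumbing: zero-phase second-order Butterworth high-pass
  (default 0.5 Hz, well below any trot stride frequency) around trapezoidal
  double integration. It is an approximation for stride-periodic signals and
  is not used by the synthetic pipeline.
* Single-horse grade rows have no sample SD; it is defined as 0.
* Grid-search and bootstrap determinism: every resampling draw is governed
  by the configuration seed; rerunning with the same seed reproduces the
  selected cost, the accuracy vector and the confusion counts bit-for-bit.

## Problem sizes used by the tests

The test suite validates the classifier on a 287-trial cohort with the
reference composition (92 RF / 89 LF / 39 RH / 36 LH / 31 sound), tuning
over the full 10-cost grid and validating with the full 400 bootstrap
repetitions; the bit-for-bit reproducibility check of the 400-repetition
protocol runs on a reduced 60-horse balanced cohort, and the
permutation-null check on a 125-horse balanced cohort with 60 repetitions.
Unit tests use cohorts of 3–40 trials with 4–10 strides each.

## What passing tests do and do not show

On the synthetic model, the pipeline recovers the planted structure
essentially perfectly at high grades, and the default between-horse
variability produces the clinically familiar error anatomy: lateral
(right–left) confusions are essentially absent, fore–hind confusions and
sound-vs-mildly-lame confusions dominate. That demonstrates internal
consistency — the features measure what the generator plants, and the
classifier protocol is implemented faithfully. It does *not* demonstrate
clinical performance: the generator contains no skin-motion artifact, no
head tosses or transient behaviours, no multi-limb lameness, no
surface/handler effects, and its compensation weights are stylized. The
published per-class accuracies shipped in `reference_confusion()` are
recomputed from counts, not reproduced from raw data.

## Limitations

* Straight-line trot only; no circles, no walk/canter detection.
* Single-limb lameness only (multi-limb cases are out of scope by design).
* Trial-level features only (per-stride distributions are averaged away).
* The exact stride-segmentation and `diffTmax` conventions of the commercial
  processing chain this emulates are not public; ours are documented above
  and kept behind configuration so they can be swapped.
* Table-4-style importance values from the clinical study are not
  reproducible without the clinical recordings; only the scheme is
  implemented.
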