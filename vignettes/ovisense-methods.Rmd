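---
title: "Classifying sheep behaviour and lame gait from tri-axial accelerometry"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Classifying sheep behaviour and lame gait from tri-axial accelerometry}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ovisense)
```

## The problem

Lameness is one of the most common health problems in extensively farmed
sheep, and detecting it currently means a person watching animals walk.
Animal-borne tri-axial accelerometers (ear tag, neck collar or foreleg
mount, sampling at 12 Hz) record the static and dynamic acceleration the
animal's movement imposes on the sensor, and lame locomotion has a
recognisable signature: the "head bobbing" of a quadruped refusing weight on
one limb increases the amplitude of the stride-frequency oscillation and
distorts its sinusoidal shape.

`ovisense` implements the full classification pipeline from raw signal to
validated performance report:

1. segment the annotated record into mutually exclusive 10 s behaviour
   epochs, discarding unknown/transitional windows;
2. compute fourteen movement metrics per epoch;
3. rank the metrics by random-forest mean decrease in Gini impurity and keep
   the top three;
4. classify epochs with quadratic discriminant analysis (QDA) on those three
   metrics;
5. validate by leave-one-out cross-validation (LOOCV) and summarise the
   confusion matrix with sensitivity, specificity, accuracy and precision.

Because no raw field recordings are publicly deposited for this kind of
study, the package also ships a seeded synthetic gait-signal generator that
reproduces the statistical structure the pipeline relies on, so every stage
is testable end to end.

## Epochs and features

A behaviour epoch is 10 s of signal — 120 samples at 12 Hz — carrying a
single behaviour label. Windows are non-overlapping and phase-locked to the
record start; a window is kept only if *every* sample falls inside annotated
intervals of one non-reserved behaviour. Mixed-label windows are excluded
entirely rather than majority-voted, mirroring the exclusion of
transitional behaviour in the field protocol. Record-start alignment (rather
than alignment to annotation boundaries) was an open design choice; it makes
segmentation independent of annotation phrasing and keeps the conservation
property `kept epochs × 120 + dropped samples = total samples` trivial to
audit.

Per epoch, with $x_t, y_t, z_t$ the raw (gravity-inclusive) accelerations in
g over $T$ samples:

* per-axis means $A_x, A_y, A_z$ and extrema $\max/\min$ per axis;
* movement variation
  $\mathrm{MV} = \tfrac1T\sum_i (|x_{i+1}-x_i| + |y_{i+1}-y_i| + |z_{i+1}-z_i|)$;
* signal magnitude area
  $\mathrm{SMA} = \tfrac1T (\sum|x_t| + \sum|y_t| + \sum|z_t|)$;
* average intensity
  $\mathrm{AI} = \tfrac1T \sum \sqrt{x_t^2+y_t^2+z_t^2}$;
* entropy $S = \tfrac1T \sum (1+\mathrm{Ts}_i)\ln(1+\mathrm{Ts}_i)$ with
  $\mathrm{Ts}_i = x_i+y_i+z_i$;
* energy $E = \tfrac1T \sum (x_i^2+y_i^2+z_i^2)^2$.

Two conventions required a decision. First, the published entropy/energy
definitions list the $z$ axis twice and omit $x$; by symmetry with every
other tri-axial metric we read $\mathrm{Ts}$ and the squared sum as running
over $x, y, z$. Second, because axes are signed g values, $1+\mathrm{Ts}_i$
can be non-positive, where the entropy logarithm is undefined; the default
guard evaluates such terms as $(1+\mathrm{Ts}_i)\ln|1+\mathrm{Ts}_i|$ with a
warning, and `entropy_guard = "reject"` turns them into errors instead. All
metrics act on raw g values — the pipeline applies no gravity separation or
filtering anywhere, and no standardisation before QDA (QDA is
affine-equivariant, so rescaling features cannot change its decisions, as a
property test verifies).

## Feature ranking

Feature selection is a seeded random forest grown only for its importance
scores: 500 trees (`ntree`), 4 features tried per split (`mtry`, roughly the
square root of 14), bootstrap resampling, Gini-impurity CART splits,
unlimited depth, no pruning. Importance of a feature is the total weighted
impurity decrease of the splits made on it, averaged over trees; the
implementation tracks the ensemble-total decrease separately so
`sum(importance) * ntree == total_decrease` is asserted as an internal
conservation check. Ranking ties are broken by the canonical feature-name
order, so the selected subset is a pure function of data and seed. Ranking is
performed once on the full data set before cross-validation — matching the
procedure the pipeline follows, where selection precedes classifier fitting —
which is mildly optimistic relative to within-fold re-ranking; this is a
known property of the design, not an accident.

The forest core is compiled (C++), with its own deterministic RNG: the
mt19937 engine is fully specified by the C++ standard, while the standard
library's *distributions* are not, so bounded draws and Fisher–Yates
shuffles are hand-rolled to make a seed mean the same forest on every
platform.

## The classifier

QDA models each class $k$ as a multivariate Gaussian over the selected
features, with sample mean $\mu_k$, sample covariance $\Sigma_k$
(denominator $n_k - 1$) and prior $\pi_k = n_k/n$ (training frequencies;
uniform priors are a switch). Classification maximises

$$\delta_k(v) = -\tfrac12 \ln\det\Sigma_k
  - \tfrac12 (v-\mu_k)^\top \Sigma_k^{-1} (v-\mu_k) + \ln\pi_k,$$

computed in the log domain through Cholesky factors (triangular solves; no
explicit inverse), with posteriors as the softmax of $\delta$ and ties
broken by class order. Synthetic static behaviours can make a class
covariance nearly singular — a standing epoch's selected features barely
vary — so each $\Sigma_k$ receives diagonal shrinkage
$\lambda\,(\mathrm{tr}\,\Sigma_k/d)\,I$ with $\lambda = 10^{-6}$ by default
(falling back to scale 1 when the trace is zero). The shrinkage is small
enough to be irrelevant for well-conditioned classes and exists purely as a
numerical floor.

## Validation and reporting

Validation is leave-one-*epoch*-out: each epoch in turn is held out, the
model is refit on the rest, and the prediction is tallied into a confusion
matrix stored with rows = predicted, columns = observed. (Leaving out whole
animals would estimate generalisation to new animals, but it is not the
procedure this pipeline defines; epoch totals in the reference matrices
confirm per-epoch folds.)

From the matrix, one-vs-rest counts give per class: sensitivity
$TP/(TP+FN)$, specificity $TN/(TN+FP)$, accuracy $(TP+TN)/n$, precision
$TP/(TP+FP)$, plus the per-observed-class prediction accuracy (the diagonal
over the observed-column total), which coincides with sensitivity by
construction and is asserted to. Specificity uses the standard
true-negative-rate definition; the formula as printed in the source material
divides by false negatives, which contradicts its own name and cannot
reproduce its own worked example, so the standard form is used and noted in
the report metadata. Metrics are reported both as exact fractions and as
integer percentages rounded half away from zero, the convention the
published tables use. Divisions by zero (a class never observed or never
predicted) are reported as missing, never as 0.

Two analysis configurations are built in. **Analysis I** discriminates all
sound behaviours plus lame walking *and* lame grazing; **Analysis II** drops
lame grazing, which field data showed collapsing into sound grazing. Lame
standing and lame lying are excluded from both: a static posture does not
betray lameness, and their inclusion only confuses the classifier with the
sound counterparts.

## The synthetic generator

The generator's purpose is to emulate the signal structure the pipeline's
assumptions rest on — not sheep biomechanics. Each behaviour is

$$a(t) = g + A\left[\sin(2\pi f t + \phi) +
  \alpha \sin(4\pi f t + 2\phi)\right] + \varepsilon(t)$$

per axis: a gravity projection $g$ for posture, a two-harmonic oscillation
for periodic movement, and white Gaussian noise. Axis phase offsets (0,
$2\pi/3$, $4\pi/3$) keep channels non-collinear. Defaults, fixed once:

| behaviour | orientation | $f$ (Hz) | amplitude (g, x/y/z) | $\alpha$ | noise sd |
|---|---|---|---|---|---|
| sound standing | upright | — | 0 | — | 0.03 |
| sound lying | recumbent | — | 0 | — | 0.02 |
| sound grazing | head down | 1.0 | 0.16/0.10/0.12 | 0.05 | 0.08 |
| sound walking | upright | 2.0 | 0.45/0.25/0.35 | 0.10 | 0.10 |
| lame walking | upright | 2.0 | 1.8 × walking | 0.40 | 0.10 |
| lame grazing | head down | 1.0 | 0.5 × grazing | 0.05 | 0.08 |
| lame standing / lying | as sound | — | 0 | — | as sound |

The lameness encoding — amplitude ×1.8 plus second-harmonic asymmetry 0.4 at
the *same* stride frequency — captures the two published qualitative
contrasts: greater acceleration amplitude in all three planes during lame
walking, and distortion of the sinusoidal stride signal by uneven weight
bearing. A 2 Hz stride is a realistic quadruped walking cadence, and 1 Hz a
plausible grazing head-swing; no absolute amplitudes are published for these
deployments, so the defaults preserve ordinal relations (lame > sound
amplitude; walking > grazing intensity) rather than claiming absolute
fidelity. Lame grazing halves the step component of grazing — a lame animal
steps less while grazing — which *deliberately* overlaps sound grazing:
reproducing the known Analysis-I failure mode (lame grazing misclassified as
sound grazing) is part of what the generator must emulate. Lame standing and
lying are distributionally identical to their sound counterparts for the
same reason: the field study excluded them precisely because they are
indistinguishable.

Per-animal variation multiplies each animal's oscillation amplitudes by a
log-normal factor (log-sd 0.12), so cross-validation cannot memorise a
single waveform. Every draw derives from the study's master seed; a fixed
configuration and seed reproduce the study byte-for-byte on disk.

What the generator does *not* model: biomechanically faithful gait, pain
behaviours such as head flicking, sensor mounting slippage, drift or
magnetometer/GPS channels, and the deployment-site differences (an ear tag
versus a collar experiencing the same behaviour differently). Consequently a
passing pipeline on synthetic data demonstrates the *software* recovers
separable classes and reproduces the arithmetic of the published reports —
it says nothing further about classification accuracy on real sheep.

## Problem sizes and test design

The packaged checks run the pipeline at sizes chosen to exercise every code
path while staying desk-scale: balanced synthetic studies of 110 epochs per
class across 5 animals (660 epochs, ~79,000 samples) for the end-to-end
recovery properties, the default Table-shaped ear study (2,134 epochs) for
count conservation, and 100 seeded 500-tree forests on a 200-row planted
design for ranking recovery. Published-scale performance numbers are checked
on the bundled reference confusion matrices, whose metric arithmetic the
package recomputes exactly; end-to-end reproduction of the field study's
percentages is impossible without its raw recordings, which were never
deposited, and is not claimed.

## Known limitations

* Leave-one-epoch-out overestimates performance on new animals; the
  `animal_id` grouping is carried through the feature matrix so grouped CV
  can be added, but it is not this pipeline's defined procedure.
* Full-data feature ranking before CV leaks a little selection information
  into the folds (see above).
* The entropy feature's domain guard is a pragmatic convention; epochs with
  strongly negative axis sums are rare in g-scale data but the guarded value
  is not the printed formula's (undefined) value.
* The synthetic generator's parameters are ordinal stand-ins, not calibrated
  to any sensor.
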