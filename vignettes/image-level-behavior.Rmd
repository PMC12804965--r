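---
title: "Image-level behavioral metrics for 2AFC categorization"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Image-level behavioral metrics for 2AFC categorization}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(i1metrics)
```

## The problem

In a two-alternative forced-choice (2AFC) categorization task, an observer —
a human subject, a marmoset working on a touchscreen, or a linear classifier
reading out feature activations — sees an image and chooses one of two
categories. Average accuracy is a blunt summary: two observer pools can match
on overall performance while finding entirely different *images* hard or
easy. This package implements the image-level analysis that exposes that
finer structure, together with a generative simulation module that makes
every stage testable end to end.

The stimulus design it targets is a two-category set rendered under fully
crossed viewing contexts: 2 in-plane orientations (upright, inverted) × 3
lighting contexts (lit from above, lit from below, contrast reversed), with
25 images per (category, orientation, lighting) cell plus one canonical
"token" image per category — 151 images per category, 302 in total. Latent
rendering parameters (size 4.5–9° of visual angle, azimuth ±90°, elevation
±45°, one of 10 shared backgrounds) are drawn i.i.d. uniform.

## Per-image d′, i1 and i1n

For image $j$ with category $c(j)$,

$$ d'_j = z(\mathrm{HR}_j) - z(\mathrm{FA}_{c(j)}), $$

where $z$ is the standard-normal quantile, $\mathrm{HR}_j$ is the proportion
of $j$'s presentations answered with $j$'s own category, and
$\mathrm{FA}_{c(j)}$ is the proportion of *other*-category trials answered
with $c(j)$. The false-alarm pool is shared across all images of a category,
a deliberate property of the metric: within a category, image-to-image
differences in $d'_j$ are driven by hit rates alone. The vector of $d'_j$
over all images is **i1**; subtracting each category's mean gives **i1n**,
which removes any overall difficulty offset between the two classes and is
the quantity compared across observer pools.

Empirical rates of exactly 0 or 1 are clipped to $1/(2N)$ and $1 - 1/(2N)$
with $N$ the relevant denominator before applying $z$. This is the standard
convention that keeps $d'$ finite and monotone in the counts; clipping never
touches interior rates.

## Lapse rate and correction

Real observers make errors unrelated to perception (attention slips, motor
errors). The lapse rate is estimated as the cross-validated error rate of
the best image: trials are split into random halves, the image with the
highest accuracy in one half is selected (ties broken by trial count, then
id), and its error rate is measured in the held-out half. Both directions of
`estimate_lapse()`'s default 50 random partitions are averaged; averaging
over partitions reduces estimator variance relative to a single split while
leaving the estimand unchanged.

The measured floor $\lambda$ feeds one of two correction models in
`lapse_corrected_accuracy()`:

* `always_wrong` (default): every lapse is an error, $p_\mathrm{corr} =
  p_\mathrm{obs} / (1-\lambda)$. The measured best-image error floor *is*
  the lapse rate.
* `guess`: a lapse guesses and is correct half the time, so the observed
  floor corresponds to an effective lapse $\lambda^* = 2\lambda$ and
  $p_\mathrm{corr} = (p_\mathrm{obs} - \lambda^*/2)/(1-\lambda^*)$.

The measurement procedure is well defined either way; which correction
formula published analyses used is generally not recoverable from a paper's
text, so both are exposed and the choice is recorded in every report.

Note the selection step makes the estimate an upper bound when no image is
truly at ceiling: the estimator equals the lapse rate only if the best
images' latent accuracy is 1. The synthetic-observer module can generate
exactly that situation, which is how the estimator's recovery is tested.

## Split-half reliability and the noise-corrected correlation

Comparing two pools' i1n vectors with a raw Pearson correlation conflates
disagreement with trial noise. The package's `noise_corrected_correlation()`
splits each pool's trials into stratified halves (per image, trials are
shuffled and alternated, so half sizes differ by at most one trial per
image), computes i1n per half, and forms

$$ R_{nc} = \frac{\tfrac12\left(r(V_{a0}, V_{b1}) + r(V_{a1},
V_{b0})\right)}{\mathrm{ceiling}(r(V_{a0}, V_{a1}),\; r(V_{b0}, V_{b1}))}. $$

Two ceiling conventions exist in the literature's notation for this
quantity: the geometric mean $\sqrt{r_a r_b}$ (the standard split-half
ceiling, and this package's default) and a literal sum-under-the-radical
$\sqrt{r_a + r_b}$. Both are always computed and reported
(`r_nc_geometric`, `r_nc_printed_sum`); the default follows the geometric
mean because it is the convention under which $R_{nc}$ recovers the latent
cross-pool correlation in the generative model (verified by the recovery
tests at $\rho \in \{0, 0.4, 0.8, 1\}$).

Components are averaged over `n_partitions` (default 100) random partitions
before the ratio is taken, which stabilizes the denominator. The same
partition seeds are applied to both pools, so byte-identical inputs give
$R_{nc} = 1$ exactly. Images unscorable in any half are dropped pairwise.

## Condition effects

The canonical conditions restrict to one lighting context each so that
orientation and lighting do not interact: *upright* = (upright, lit from
above), *inverted* = (inverted, lit from below), *reversed* = (upright,
contrast reversed) — 50 images each (25 per category) under the default
design. The inversion effect is the difference in mean per-image d′,
inverted minus upright; the contrast-reversal effect likewise for reversed
minus upright. Negative values are deficits.

Uncertainty comes from an image-subsampling bootstrap: each replicate draws
25 of the 50 images per condition without replacement and recomputes the
mean per-image d′ within the subsample. Two numerical choices matter here:

* **False-alarm pools are recomputed within each subsample.** The category
  reference rate is itself an estimate; freezing it across replicates would
  understate the variance of the mean d′ difference. Recomputing it inside
  the subsample propagates that uncertainty, and drawing *half* of the
  images without replacement gives the subsample mean the same sampling
  variance as the full-condition mean under an image superpopulation —
  which is what makes the 95% percentile interval approximately calibrated
  (the coverage test in the suite checks 93–97% at 500 simulation
  replicates).
* **Subsample draws are made per condition in lexicographic label order**,
  so swapping the two conditions under the same seed pairs identical
  subsamples and negates every replicate exactly — a cheap, exact
  antisymmetry guarantee.

A with-replacement mode exists for a conventional image bootstrap.
`compare_effects()` contrasts two effects either by the bootstrap
sign-crossing probability (default, purely resampling-based) or a Welch t
over replicate arrays; the latter emulates t-statistic reporting
conventions and is labeled with the caveat that bootstrap replicates are
not independent observations.

## The model observer (linear readout)

`train_readout()` turns per-image feature matrices (e.g. 2048-dimensional
penultimate-layer activations of a vision network, supplied from disk — no
network code or weights are involved) into the same currency as behavior:
per resample it draws a training set per class, standardizes each feature
dimension using training statistics only (leakage-free), fits a linear SVM
(L2 regularization, hinge loss, cost `C` = 1 by default, exposed), and
scores held-out test images. Per-image signed distances to the hyperplane
are oriented so positive means "on the correct side", which makes the
fraction of positive margins per resample *identically* equal to that
resample's accuracy — an exact invariant the tests assert. Margins averaged
over all resamples (default; a single-fit mode exists) give a model i1
vector, and category-mean subtraction a model i1n. Because features are
standardized per fit, margins are in standardized units and are not
calibrated across feature scalings.

`learning_curve()` sweeps the training-set size and reports the smallest
size within 0.005 of the maximum accuracy — the saturation point used to
pick a training budget.

## The synthetic-data generator

The generator exists so that every estimator above can be validated by
parameter recovery. It emulates:

* the stimulus design (302-image metadata table, uniform latent parameters);
* observer pools with per-image latent difficulty: latent d′ drawn normal
  with mean/sd, mapped to probability correct via $p = \Phi(d'/2)$ — the
  symmetric-criterion convention under which hits and correct rejections
  are exchangeable;
* cross-pool structure: two latent d′ vectors from a bivariate normal
  (`make_linked_observers()`), the generative alternative the
  noise-corrected correlation should recover. `rho` targets the
  correlation of the pools' *final* latent vectors: context shifts shared
  by both pools are themselves image-level correlation, so the base draw's
  correlation is solved internally to keep the shift-inclusive population
  correlation at `rho` — without this, two pools that both carry an
  inversion deficit would be more correlated than requested;
* condition deficits: additive latent-d′ shifts per (orientation, lighting)
  context, the simplest mechanism producing inversion/reversal effects;
* lapses: a per-trial lapse coin with a configurable response rule
  (always-wrong, guessing, or a category bias);
* two-class Gaussian feature clouds of configurable dimension and mean
  separation, whose Bayes accuracy $\Phi(\mathrm{sep}/2)$ is known in
  closed form.

One attenuation property is worth knowing. Because the behavioral metric
pools false alarms at the category level, the estimator applied to this
generator returns $\hat d'_j \approx (d'_j + \bar d')/2$: per-image
*deviations* are halved relative to the latent values. This does not affect
correlation-based analyses (Pearson r is scale-invariant) and it does not
affect condition effects (a context shift moves hit and false-alarm pools
of a condition together, so mean differences are recovered at full scale),
but absolute per-image deviations are compressed. Tests that assert latent
recovery account for this.

Default generator settings used by the packaged study simulation, chosen
once as realistic for this class of experiment and then left alone:

* image-level latent d′ sd = 0.4 — per-image accuracies spanning roughly
  ±8 percentage points around the pool mean, enough image signal for
  reliable i1n while keeping a marmoset-scale inversion deficit (−0.31)
  detectable at 50 images per condition (a power consideration evaluated
  from the binomial/normal error propagation before any tests were run);
* lapse rate 0.02 per pool (always-wrong), matching the ~2% floor typical
  of trained primate observers;
* 1000 trials per image per pool in the end-to-end simulation — of the
  order of the per-image counts that chronic touchscreen testing yields,
  and necessary for the scale of the analysis: with image-level d′ sd 0.4,
  a −0.31 condition deficit over 50-image conditions is only reliably
  significant in a *single* simulated study when trial noise is well below
  the image heterogeneity (at a few hundred trials per image, an unlucky
  image draw plus binomial noise can dilute the measured deficit enough
  for its CI to touch zero);
* human-like baseline latent accuracy 0.91 and marmoset-like 0.78, with
  context shifts (−0.9, −0.4) and (−0.31, −0.6) respectively and latent
  image-level correlation 0.4 in the two-pool simulation.

What the generator does *not* emulate: session/learning dynamics, subject
heterogeneity within a pool (pools are exchangeable trial streams),
reaction times, stimulus-specific perceptual confusions beyond a scalar
difficulty, and any actual image rendering. Passing recovery tests
therefore show the estimators are correct under the stated statistical
structure, not that real data satisfy that structure.

## Degenerate inputs and numerical conventions

* Images whose category has an empty false-alarm pool are flagged
  `unscorable` (d′ = NA), never silently dropped.
* Correlations over fewer than 3 jointly finite image pairs, or against a
  zero-variance vector, return NA; a non-positive reliability ceiling
  yields `r_nc = NA` with a warning while raw components are still
  returned.
* Best-image ties in the lapse estimator break by larger trial count, then
  lexicographic id; a best image absent from the held-out half causes the
  partition to be redrawn (bounded retries).
* All randomized operations take explicit integer seeds, derive any
  internal streams deterministically from them, and restore the caller's
  RNG state.

## Known limitations

* The shared false-alarm convention means i1/i1n carry no within-category
  criterion information; observers with image-specific response biases on
  distractors are summarized only through the pooled rate.
* The percentile CI of the effect bootstrap inherits the usual small-sample
  caveats of percentile intervals; the coverage guarantee is demonstrated
  at the packaged study scale (50 images/condition, 200+ trials/image).
* The Welch comparison of bootstrap arrays is an emulation of a published
  reporting convention, not a calibrated test; the sign-crossing method is
  the one to trust.
* Margins from the readout are not comparable across feature spaces or
  scalings; only their image-level *pattern* (margin i1n) is.
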