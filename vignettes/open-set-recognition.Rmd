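---
title: "Open-set recognition with Weibull distance tails: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Open-set recognition with Weibull distance tails: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(openmosq)
library(dplyr)
```

## The problem

A classifier trained on ten mosquito species will, by construction, assign
one of those ten labels to *anything* it is shown — a bee, a butterfly, a
fly, even a human. In surveillance deployments that is worse than useless:
confidently mislabelled non-targets corrupt downstream counts. Open-set
recognition (OSR) extends a closed-set classifier with the ability to say
"unknown": samples whose activation pattern is atypical for every known
class are rejected rather than forced into the vocabulary.

`openmosq` implements the extreme-value-theory route to OSR on top of *any*
closed-set model. The package never trains a network; it consumes activation
(logit) tables — one row per sample, one column per class — produced by an
external model or by the built-in toy extractor, and provides everything
around them: synthetic data with known structure, corpus engineering
(deduplication, splitting, balancing), the open-set calibration itself, and
an evaluation battery over the extended label set.

## The model

For each known class $c$ with $N_c$ training activation vectors
$\mathbf z_{i,c} \in \mathbb R^M$:

1. **Mean activation vector.**
   $\mathrm{MAV}_c = \frac{1}{N_c}\sum_{i=1}^{N_c} \mathbf z_{i,c}$.
   By default every vector labelled $c$ contributes; the
   `mav_source = "correct_only"` option restricts to vectors whose argmax is
   $c$, the convention of the original OpenMax work. Both are exposed
   because the two conventions genuinely differ on imperfect classifiers.

2. **Distances.** $d_{i,c} = \lVert \mathbf z_{i,c} - \mathrm{MAV}_c
   \rVert_2$. Typical samples sit near their MAV; the *largest* distances
   describe how far a sample can stray while still belonging.

3. **Weibull tail.** The $\eta$ largest distances are fitted with a Weibull
   CDF
   $F(d) = 1 - \exp\!\left[-\left(\frac{d - \mu}{\gamma}\right)^{b}\right]$,
   shape $b$, scale $\gamma$, location $\mu$. This is the standard
   meta-recognition move: extreme-value theory says the tail of a bounded
   score distribution is Weibull-like regardless of the bulk.

4. **Recalibrated score.** $r_c = 1 - F(d_c)$ for a new sample's distance
   $d_c$ to class $c$. $r_c$ is 1 at the MAV, decays monotonically with
   distance, and is an outlier probability complement rather than a softmax
   confidence.

Two decision rules are provided, because both are in live use and they are
*not* equivalent:

* **`score_threshold`** (the default): reject as unknown when
  $\max_c r_c < \varepsilon$, otherwise predict $\arg\max_c r_c$.
* **`openmax`**: rank classes by activation, down-weight the top $\beta$
  activations by $\theta_{r(j)} = 1 - \frac{\beta - j}{\beta} F_{r(j)}(d)$,
  give the removed mass $\tilde a_0 = \sum_j a_j (1-\theta_j)$ to a
  synthetic unknown class, softmax over $M{+}1$ entries, and reject when
  the unknown class wins or the winning probability is below $\varepsilon$.

On the down-weighting multiplier: a formulation sometimes written with an
exponential factor $e^{(d/\lambda)^{\kappa}}$ cannot be what is meant — it
is $\ge 1$ and unbounded, so $\theta$ leaves $[0,1]$ and the softmax
overflows. The package implements the Weibull-CDF weighting, which is the
form consistent with the recalibration equation $r_c = 1 - F(d_c)$; the
divergent exponential form is kept behind `literal = TRUE` in
`openmax_probabilities()` purely as a diagnostic for comparison.

## Parameters that matter

| Parameter | Default | Meaning and rationale |
|---|---|---|
| `tail_size` ($\eta$) | `min(20, N_c)` | distances in the fitted tail; 20 is the conventional meta-recognition size. Larger $\eta$ fits more of the bulk (less "extreme"), smaller $\eta$ is noisier. |
| `beta` ($\beta$) | $M$ | classes down-weighted by OpenMax; with no principled value available the default modifies all classes rather than guessing a subset. |
| `threshold` ($\varepsilon$) | 0.1 | rejection cutoff in $[0,1]$; sweeps over $0.5 \dots 0.1$ are first-class via `threshold_sweep()`. |
| `location_mode` | `"zero"` | Weibull location $\mu$. Zero keeps the support at all nonnegative distances; `"tail_min"` anchors just below the smallest tail point, concentrating the CDF on the tail span. |
| `mav_source` | `"all_samples"` | which vectors define the MAV (see above). |

The threshold applies to `max(r_c)` in `score_threshold` mode and to the
OpenMax probability in `openmax` mode; these are different scales, and a
sweep row is only meaningful together with the decision mode that produced
it, which the model object carries.

## What the synthetic generator emulates — and what it does not

`synth_spec()` places class $c$'s activations on an isotropic Gaussian
around $s\sigma\,\mathbf e_c$ (separation $s$ in spread units $\sigma$):
the geometry of a *well-trained* logit space, where each class has a
dedicated direction and a single knob controls separability. At the default
separation 6 a nearest-centroid rule is already better than 99% accurate,
so any open-set failure observed downstream is attributable to the
calibration layer, not to inseparable fixtures.

Out-of-distribution samples come in three flavours: `shifted_cluster`
(default — a coherent cluster equidistant from every known mean, mirroring
the realistic "other insect species" scenario), `uniform_box` (structureless
noise spanning the known range), and `low_margin` (points near decision
boundaries, the hard case).

Real logit spaces are not isotropic, classes are not equally spread, and
real OOD data is not equidistant from the known classes. Passing tests on
this generator therefore demonstrate correctness of the calibration
machinery under its stated assumptions, not performance on any real insect
corpus. The toy image corpus (geometric shapes plus Gaussian pixel noise)
plays the same role for the dataset-engineering stages.

## Dataset engineering choices

* **Deduplication** uses 64-bit difference/average hashes; the
  near-duplicate threshold defaults to Hamming distance 5 of 64, common
  perceptual-hash practice, and is configurable. Groups are the transitive
  closure at the threshold; the lexicographically smallest id in each group
  is the keeper, so the operation is deterministic.
* **Splitting** holds out 20% for test, then 20% of the remainder for
  validation (64/16/20 overall). Per-class counts use round-half-up on the
  test count first, then on the validation count; for class sizes divisible
  by 25 the 64/16/20 identity is exact (10 classes × 500 images give
  3200/800/1000).
* **Augmentation** magnitudes written as bare "0.20" in common framework
  configurations are dimensionally ambiguous; here shear is ±0.20 *radians*,
  zoom is multiplicative in $[0.8, 1.2]$, and shifts are fractions of
  width/height — documented and configurable. Rotation is capped at ±20°
  so the anatomical cues that species identification depends on (wing
  position, antenna orientation) are preserved. Transforms act about the
  image centre with pixel centres at integer coordinates, nearest-neighbour
  resampling, nearest-edge fill.
* **Balance-then-split versus split-then-balance.** Balancing *before*
  splitting makes augmented near-copies of one photograph land in different
  partitions — leakage — but reproduces the arithmetic in which the test
  set is 20% of the *balanced* total. Splitting first avoids leakage but
  changes the partition sizes. Both orderings are provided
  (`balance_first` in the pipeline config); the default is split-first, and
  no claim is made about which ordering any particular study used.

## Numerical choices

* Weibull shape solves the profile-likelihood equation by safeguarded
  Newton (bisection fallback inside a sign-changing bracket), tolerance
  $10^{-10}$, at most 200 iterations, from a method-of-moments start; data
  are rescaled by their maximum so $x^k$ cannot overflow at large shapes.
  A tail whose values are all equal is refused as degenerate, as is
  $\eta < 2$.
* $r_c$ is computed through the log-survival function, so extreme distances
  underflow cleanly to 0 instead of losing precision in `1 - CDF`.
* The OpenMax softmax subtracts the maximum activation before
  exponentiation.
* Ties everywhere break to the lowest vocabulary index; the vocabulary is
  the sorted label set unless supplied explicitly.
* Metric conventions: precision/recall/F1 with zero denominators are 0;
  macro averages run over labels present in truth or predictions; weighted
  averages weight by support; balanced accuracy averages recall over labels
  with support; MCC uses the covariance form and is 0 when its denominator
  vanishes. ROC areas are trapezoidal over unique-score thresholds; PR
  areas are step-wise with no interpolation; the micro average pools every
  (sample, label) decision. In sweep tables the `f1` column is micro-F1,
  which for single-label classification equals accuracy — the two columns
  agree by identity, not by coincidence.
* Model JSON is written at 17 significant digits so write → read → write is
  byte-stable.

## Problem sizes in the test suite

The suite exercises the full corpus arithmetic (1749 images balanced to
5000 at 16×16 pixels, split 3200/800/1000), OpenMax-versus-transcription
agreement on over a hundred random instances across $M \in \{2, 3, 10\}$
and $\beta \in \{0, 1, M\}$, Weibull recovery on 20 replicates of 1000
draws, and an end-to-end discrimination experiment with 10 classes × 50
training samples, 100 known and 100 OOD test samples. These sizes were
chosen to make every statistical check stable at fixed seeds while keeping
the whole suite in the tens of seconds on one core.

One caveat worth stating plainly: in that discrimination experiment the
score-threshold rule at $\varepsilon = 0.1$ with $\eta = 20$ of 50
training distances places the acceptance boundary near the 96th percentile
of the known-distance distribution *by construction* — the expected
correct-known rate is therefore in the 94–96% band and fluctuates a few
percent across seeds, while OOD rejection is essentially always 100%. A
95% correct-known bar under exactly these conditions sits on that boundary
and will not be cleared at every seed; larger training sets per class (so
the tail is a smaller quantile of the within-class distribution) move the
rate up quickly.

## Limitations

* The Gaussian-cluster generator is a stand-in for real activation
  geometry; nothing here validates transfer to any particular network.
* Perceptual hashing catches near-duplicates up to small shifts and noise,
  not rotations beyond the hash's natural robustness.
* The package evaluates and calibrates; it does not train, fine-tune, or
  search hyperparameters of the upstream classifier.
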