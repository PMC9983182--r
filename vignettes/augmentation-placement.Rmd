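---
title: "Where augmentation meets the split: methods and design of augsplit"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Where augmentation meets the split: methods and design of augsplit}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The question

Geometric augmentation — here the eight dihedral transforms of a square
image (the identity, three quarter rotations, and the flip of each) — can
be applied at several points relative to the division of a dataset into
training, validation and test subsets, and to any combination of those
subsets. Starting from one pool of original images, the distinct choices
reduce to six model-building ways:

| Way | Placement |
|-----|-----------|
| A | make the three sets, then augment the validation set |
| B | make the three sets; no augmentation |
| C | make the three sets, then augment the training set |
| D | make the three sets, then augment training and validation independently |
| E | separate the test set, augment the remainder, then split train/validation |
| F | augment the whole dataset before any splitting |

Ways A–E can each be evaluated on the non-augmented or the augmented test
set, while way F's test set is inherently augmented — eleven testing
protocols in all, and with four classifier configurations 24 model groups
and 44 testing groups.

Ways E and F split an *augmented* pool at the individual-image level, so
derivatives of one parent can land on both sides of a split. That is
information leakage: evaluation on one subset becomes optimistically
dependent on another. `augsplit` exists to construct these protocols
exactly, audit the leakage they induce, and measure its consequences under
controlled conditions.

## The synthetic benchmark

Real histopathology benchmarks confound placement effects with content
effects and require days of GPU training. The generator substitutes a
parametric image population in which every assumption the analysis relies
on is explicit. Each original image of side $n$ (default $32$, grayscale in
$[0,1]$) is composed as

$$x \;=\; 0.5 \;+\; s\,\mu_c \;+\; \beta\,\nu \;+\; \phi\,(w_s S + w_a A) \;+\; \varepsilon,$$

with the following parts.

* **Class signal** $\mu_c$: a radially symmetric texture
  $\cos(2\pi f_c r/n)$ about the image centre, with $f_c = 4$ cycles for
  the negative (inflammation-analog) class and $f_c = 6$ for the positive
  (carcinoma-analog) class. Because the pattern depends only on the
  distance from the centre, it is *pointwise* invariant under all eight
  transforms, so the class-conditional distribution is unchanged by
  augmentation — the analog of histological diagnosis being
  orientation-free. The amplitude is
  $s = 0.03 \times \texttt{class\_signal\_strength}$; at strength 0 the
  classes are indistinguishable and the benchmark AUC is 0.5 (a property
  the test suite checks by simulation).
* **Identity fingerprint** $S$: a white-noise field averaged over its own
  eight transforms, then renormalized. Every member of an orbit carries
  *exactly* the same $S$, which is what makes derivatives of one parent
  mutually predictive: a model that has partly memorized a training image
  recognizes its rotated siblings wherever they land. Without this
  component, leakage would be invisible to any measurement.
* **Plane-wave clutter** $A$: a random combination of horizontal and
  vertical waves at the two class frequencies (8 basis patterns, iid
  coefficients). The subspace is closed under the dihedral group and the
  coefficient distribution is isotropic within it, so this component is
  also distribution-invariant under augmentation. Its role is to be
  *overfittable*: it is low-dimensional and high-variance, so a model
  trained on few originals wastes capacity on it, while augmentation —
  which spreads each parent's coefficients around the subspace — forces
  the model to ignore it. This is the channel through which training-set
  augmentation genuinely improves generalization here.
* **Oriented bias field** $\nu$: one fixed horizontal wave mixture (class
  frequencies, phases 1.1 and 2.3, amplitude $\beta = 0.18$) added
  identically to *every* image. It is the stand-in for the orientation
  statistics of real photographic data — illumination gradients, scanning
  direction, camera anisotropies. A model trained only on originals
  silently calibrates its decision boundary to this constant background;
  any rotation or flip displaces it, systematically shifting the margins
  of transformed inputs. This is deliberately the one non-invariant
  ingredient of the population, and the only channel by which augmented
  and non-augmented test sets can differ in expectation for a fixed
  model.
* **Pixel noise** $\varepsilon$: iid $N(0, \texttt{noise\_sd}^2)$,
  default sd $0.05$.

The fingerprint mixes its two random parts with weights $w_s = 0.8$ and
$w_a = 0.6$ at overall amplitude
$\phi = 0.12 \times \texttt{fingerprint\_strength}$. Amplitudes were fixed
once, by two requirements stated in advance of any comparison between
protocols: at default strengths at least 95% of derivatives must have
their nearest pixel-space neighbour inside their own orbit (identity is
unambiguous), and the no-augmentation baseline (way B) must sit well away
from both chance and ceiling — it lands near 0.70–0.75 pooled accuracy —
so that placement effects have room to move metrics in either direction.
Pixel values are clamped to $[0,1]$ after composition and quantized to
8 bits when written as PNG.

What the generator does *not* emulate: stain color distributions,
slide-level or patient-level structure (images are independent draws, as
the image-level splitting it feeds assumes), class imbalance, or an
"invalid" third category. Passing tests on this benchmark demonstrate the
*mechanics and direction* of placement effects — leakage arithmetic,
optimism of validation or test estimates, the cost of unaugmented
training — not the absolute metric levels any real dataset would produce.

## Splitting protocols

Test allocation uses stratified k-fold cross-validation (default $k=5$):
each class is shuffled and dealt into k parts whose sizes differ by at
most one, the parts serving as non-intersecting test sets. The remaining
originals are combined, shuffled and split 3:1 into training and
validation, again per class. Non-divisible class sizes are rounded by a
largest-remainder rule; the only possible tie (class size ≡ 2 mod 4) is
broken by a seeded coin. Whether the 3:1 rounding should be per class or
global is not determined by the design being reproduced; the per-class
rule was adopted because it keeps stratification exact, and it is flagged
here as a choice.

Ways A–D augment the named subsets only *after* all allocation, so their
leakage is structurally zero — way D augments training and validation
independently after their separation, which is why it leaks nothing
despite both subsets being augmented. Way E augments after test
allocation but before the train/validation split, and performs that split
at the individual-image level; way F augments before everything. The
image-level splitting in E and F is precisely what produces leakage, and
the audit counts, per subset pair, the parents whose orbit members occupy
both subsets. The expected zero patterns (A–D all zero; E train↔validation
only; F potentially all three pairs) are asserted exactly in the tests.

All randomness descends from one master seed through a deterministic
sub-seed derivation (per stage, per fold, per epoch), so any single fold
is reproducible in isolation and identical configurations give identical
results end to end. The k-fold and train/validation seeds depend on the
fold but not on the way, so ways sharing a split structure (A–D) see the
same original-image partitions: comparisons between them are paired, and
the A-vs-B contrast in particular evaluates the *same* trained models on
differently augmented validation sets.

## Training harness

The harness trains any classifier satisfying a small contract —
`featurize`, `init`, one mini-batch `train_epoch` pass, and a
side-effect-free `predict_proba` in $[0,1]$ — under a fixed schedule:
mini-batches of 10, stochastic gradient descent with momentum 0.9 and
learning rate $10^{-4}$, L2 factor $10^{-4}$, the training set reshuffled
each epoch, at most 50 epochs. After every epoch the validation accuracy
at the 0.5 threshold is computed; "improving the model" is interpreted as
strictly exceeding the best validation accuracy seen so far, and training
stops after 5 consecutive non-improving epochs. Two conventions are
deliberate and documented rather than forced by the problem: the model
returned is the best-validation checkpoint (not the last epoch's), and a
probability exactly at the threshold counts as positive. A never-improving
classifier therefore stops after exactly $1 + \text{patience} = 6$ epochs
and an always-improving one at exactly 50 — both asserted with stub
classifiers.

The bundled reference classifier is a regularized logistic regression on
centred raw pixels. A small convolutional network had been the natural
candidate, but a pure-R implementation would spend minutes per fold where
the linear model spends tens of milliseconds, and the phenomena under
study require only two capacities the linear model has: it can partly
memorize training images (through the invariant fingerprint component,
giving leakage transfer), and it is orientation-sensitive (through the
bias field, giving the augmented-test penalty). The contract keeps any
stronger model pluggable. Training time is recorded as wall-clock seconds
and used only relatively, in the time-cost correlation; nothing asserts
absolute times.

## Statistics

Per-fold confusion counts are pooled by summation before any ratio is
taken (micro-averaging):

$$\text{Accuracy} = \frac{\sum_k (TP_k + TN_k)}{\sum_k (TP_k+TN_k+FP_k+FN_k)},\quad
\text{Sensitivity} = \frac{\sum_k TP_k}{\sum_k (TP_k+FN_k)},\quad
\text{Specificity} = \frac{\sum_k TN_k}{\sum_k (TN_k+FP_k)}.$$

Each estimate carries a Clopper–Pearson exact binomial 95% interval with
the formula's denominator as trials and numerator as successes, computed
through the beta-quantile closed form and tested against a tail-sum
bisection oracle to $10^{-6}$. The positive class is the carcinoma-analog
("positive for malignancy"). A metric whose pooled denominator is zero is
reported as undefined, not as a number.

ROC AUC is computed on the *pooled* probabilities of all folds' test
images — equivalently the probability that a random positive outranks a
random negative across folds, ties counting one half (verified against
exhaustive pair counting). Pooling penalizes models whose probability
scales drift between folds, unlike averaging per-fold AUCs; the test
suite constructs two perfectly-separated folds on disjoint probability
ranges whose pooled AUC falls below 1 to pin this down. The AUC interval
defaults to the DeLong placement-variance estimate (cross-checked against
an independent implementation); an exact-binomial mode treating the AUC
as a proportion of concordant pairs is available behind a flag, because
the original analysis named an "exact binomial" AUC interval without a
formula and the two readings bracket the reasonable choices.

Epoch counts and training times are summarized as means with Student-t
intervals on $k-1$ degrees of freedom (4 under five-fold CV). The
time-cost analysis excludes the augment-first groups and the
non-augmented-test metrics (leaving 20 of 44 groups when four classifiers
are present — the exclusion is exposed as a filter helper), stratifies by
classifier, and reports Pearson's r between each metric and the *natural*
logarithm of mean training time, with the two-sided p from the t-test on
r and the fitted line. The natural log (rather than log10) changes only
the slope's scale, never r or p. No multiple-testing adjustment is
applied; p-values are reported raw.

Directional claims on the benchmark (replicate seeds, paired by seed) use
an exact one-sided sign-flip test: all $2^n$ sign assignments of the
paired differences are enumerated and the p-value is the fraction with a
mean at least the observed one.

## What the benchmark reproduces

With ten replicate seeds of the default benchmark (200 originals, 32×32,
five folds, reference classifier), the framework reproduces — as
directions with sign-flip p < 0.05, not as absolute levels — the expected
placement effects: way F's test accuracy exceeds way E's (leakage into
the test set); way E's validation accuracy exceeds its own test accuracy
(leakage into validation) while ways C–E all beat way B's validation
accuracy (training augmentation helps); way A's validation accuracy falls
below way B's (an unaugmented model degrades on transformed inputs); for
unaugmented-training models the augmented-test metrics fall below the
non-augmented ones; and test-set augmentation multiplies trials by 8,
shrinking exact interval widths by a factor near $1/\sqrt{8} \approx 0.35$.
The acceptance script recomputes all of these from scratch.

## Numerical and degenerate-input conventions

* Rotation is counter-clockwise and the flip horizontal; either choice
  composed with the four rotations generates the same 8-element group, so
  the convention matters only for bit-exact reproducibility.
* Transforms are pure pixel permutations — no interpolation — so orbits
  are closed exactly. Resizing (bilinear, via EBImage) commutes with the
  transforms for square images to machine precision, which the tests
  check; images are resized only when a protocol or classifier requires a
  different side length.
* Augmenting an already-augmented dataset is an error, preventing a
  silent 64-fold inflation; augmenting an empty subset cannot occur
  because stratification requires both classes with at least k records.
* The composition table of the transforms is derived at load time by
  brute force on an asymmetric probe and tested for the full group
  structure (closure, identity, inverses, non-commutativity).
* Problem sizes in the shipped tests — up to 500 originals for the
  structural audits and 10 × 6 ways × 5 folds trainings for the
  directional block — were chosen so the whole suite completes in a few
  minutes on one CPU core; every quantity scales up by changing
  `synth_params` and `experiment_config` alone.

## Known limitations

The benchmark is linear-model-friendly by construction; a classifier with
no capacity to memorize (heavy regularization, tiny feature space) will
show weaker leakage signals, and one with perfect dihedral invariance
will show none of the augmented-test penalty — both correctly, since the
phenomena live in the interaction between model capacity and data
structure. Splitting is at the image level throughout, faithfully
reproducing the design under study; grouping constraints (slide- or
patient-level) are out of scope and would in fact remove part of the
leakage being measured. Absolute metric levels, training times and epoch
counts depend on the synthetic difficulty settings and carry no external
meaning.
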