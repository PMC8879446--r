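---
title: "Mutual distillation for class-incremental learning: model, benchmark, and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Mutual distillation for class-incremental learning}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
library(mdcl)
```

## The problem

A classifier deployed in a screening setting — baggage inspection,
radiograph triage, retinal disease grading — rarely sees its full label
space up front. New classes and new imaging modalities arrive over time,
and retraining on everything from scratch is often impossible (data
retention limits, memory, compute). Sequential fine-tuning on each new
task, however, overwrites what the network knew: *catastrophic
forgetting*. `mdcl` implements and dissects one remedy: a continual
learning objective that couples old and new knowledge through
class-conditional Gaussian models of their joint soft representations.

## The model

### Soft representations and streams

At increment $k$ the previous model instance is frozen as a **teacher**.
For an image $x$ the teacher produces $f_{old}(x)$, the student
$f_{new}(x)$: class probabilities obtained by dividing logits by a
temperature $\tau$ before the softmax (`soften()`). The teacher's vector
is zero-padded to the student's current width so both streams share one
registry; padded positions carry no mass and never receive one-hot
targets. Temperatures above 1 flatten the distributions, exposing the
"dark knowledge" in the relative probabilities of wrong classes.

### Class-conditional Gaussians and the Bayes posterior

The concatenation $y = [f_{old}(x), f_{new}(x)]$ (dimension
$d = w_{old} + w_{new}$) is modelled per class with a multivariate
Gaussian: mean and unbiased ($n-1$ denominator) covariance per class
(`fit_gaussian()`, `fit_class_conditionals()`), priors from class counts
(`class_prior()`), and Bayes' rule in log space (`class_posterior()`),
using the standard multivariate normal constant
$(2\pi)^{-d/2}\lvert\Sigma\rvert^{-1/2}$ and a Cholesky factorisation —
no explicit inverse. For Gaussians, the joint density of the
concatenation equals both conditional-times-marginal factorisations
(old given new, new given old), so a single per-class fit serves both
directions of the coupling; this is also why permuting the concatenation
order leaves all densities unchanged (a property the tests check).

Because soft representations live on the probability simplex, each
stream's covariance is rank-deficient by construction, and with
per-class sample counts below $d$ the estimate is additionally singular.
A diagonal ridge $\lambda$ is therefore always added *at evaluation
time* (the raw estimate stays inspectable). The default is
$\lambda = 0.05$: it bounds the per-dimension precision at
$1/\lambda = 20$, which keeps both log-densities and their gradients on
the scale of the other loss terms. Much smaller ridges (say $10^{-4}$)
make the posterior an effectively hard nearest-centroid assignment with
gradient magnitudes in the thousands; in our experiments this drowns the
acquisition signal and collapses training, so we treat the ridge as a
first-class model parameter rather than a numerical afterthought.

### The three loss terms

For a batch of size $bs$ containing $n_1$ replayed exemplars and $n_2$
current-increment samples:

* **Acquisition** $L_N$ (`new_knowledge_loss()`): KL divergence from the
  new samples' one-hot labels to the student's softened outputs,
  averaged over $bs$. With one-hot targets this equals cross-entropy;
  the general KL form also accepts soft targets.
* **Retention** $L_O$ (`old_knowledge_loss()`): cross-entropy of the
  teacher's padded soft targets against the student's softened outputs,
  over all batch rows, averaged over $bs$. Read one way (true labels
  scored against the *teacher's* probabilities) this term is constant in
  the student and cannot be minimised to retain anything; we therefore
  adopt the knowledge-distillation standard (teacher targets, student
  predictions), which gives the term a gradient and matches its role as
  the retention pressure. The exported kernel accepts either reading.
* **Mutual distillation** $L_{MD}$ (`mutual_distillation_loss()`): the
  sum over old and new samples of the negative log posterior of each
  sample's true class under the joint-representation Gaussians, scaled
  by $1/\tau^2$. The printed objective divides both the indicator and
  the log term by $\tau$; taken literally that is exactly a
  $1/\tau^2$-rescaled pair of cross-entropies, which is how it is
  implemented (`scale = "tau_sq"`; `"none"` gives the unscaled reading).
  Exemplar true labels enter the objective *only* here, so ablating
  $L_{MD}$ (`include_md = FALSE`) removes all true-label supervision of
  old classes — which is what makes the ablation informative.

$L_{CL} = L_N + L_{MD} + L_O$ (`continual_loss()`), with the invariant
checked on every logged step. Note the deliberate scale asymmetry:
$L_{MD}$ is an unnormalised sum while $L_N, L_O$ are batch means, so the
coupling term's relative weight grows as $bs/\tau$. This is part of why
the temperature sweep is U-shaped (below).

### Gradient flow

Within a training step the Gaussian conditionals, priors and teacher
outputs are constants; they are refit once per epoch from the current
teacher/student representations. Gradients flow through the student's
softened outputs in $L_N$ and $L_O$, and through the new-stream half of
each joint point in $L_{MD}$ (chain rule through the
temperature-scaled softmax Jacobian and the Gaussian quadratic forms;
`continual_loss_grad()`). Differentiating through the fits themselves
would make every step quadratic in the dataset and is not part of the
method. The analytic gradients are verified against central finite
differences to $10^{-9}$ relative error in the test suite.

## The training protocol

`run_sequence()` drives, per increment: label-space growth (append-only;
existing class indices never move, `expand_label_space()` /
`widen_head()`), training (`train_increment()`), teacher snapshotting
(`snapshot_teacher()`, a frozen deep copy), exemplar selection
(`select_exemplars()`, uniform without replacement, deterministic per
seed), and evaluation on the cumulative test set of all classes seen so
far. The first increment has no teacher and trains with $L_N$ only.

Key parameters (`train_config()`), with defaults and rationale:

| parameter | default | role |
|---|---|---|
| `epochs` | 20 | passes per increment; the bundled experiments use 5 for speed |
| `optimizer` | `adadelta` | ADADELTA with $\rho = 0.95$, $\epsilon = 10^{-6}$; no learning rate to tune |
| `batch_size` | 8 | minibatch size; 8 gives enough optimisation steps at desk-scale sample sizes |
| `temperature` | 2 | the empirically ideal softening (see the sweep) |
| `exemplars_per_class` | 20 | replay budget: a small, configurable memory rather than full data retention |
| `ridge` | 0.05 | Gaussian regulariser, see above |
| `variant` | `lcl` | objective: `lcl`, `lcl_no_md`, `cross_entropy` (plain fine-tuning, $\tau = 1$, no teacher/replay), `kl_distill` (classic distillation: new-label loss plus KL against teacher targets, no replay) |

All randomness derives from a single integer seed through a
counter-based expansion, so histories are bit-reproducible; the package
is pure serial R, so there is no backend nondeterminism to contend with.

The **reference backbone** is deliberately minimal: images are expanded
to three channels, block-average-pooled to an $8\times 8$ grid per
channel (192 features), then passed through one tanh hidden layer (width
32) and a linear head. The design goal is a backbone that trains in
seconds on one CPU while exercising every part of the continual
machinery — snapshotting, head widening, gradient checks, replay. Deep
convolutional backbones are intentionally out of scope; any model
exposing logits and gradient-by-logits updates could be substituted.

## The synthetic benchmark

`generate_domain()` renders simple geometric shapes (disc, bar, cross,
ring, wedge, blob) at random position, scale and rotation with additive
Gaussian pixel noise, in grayscale or colour. Structural features of
real screening datasets are emulated: a composite **multiple** class
(two or more distinct positive shapes in one image, single-labelled), a
**normal** distractor class, and exact negative:positive **imbalance
ratios** (10, 100, 1000 reproduce the usual screening-set designs). A
benchmark (`generate_benchmark()`) is a schedule of increments over
domains, with a per-class stratified 20/80 train/test split — the small-train,
large-test regime typical of screening studies.

The bundled three-increment benchmark (`bundled_benchmark()`) crosses a
grayscale transmission-scan-like domain, a colour domain, and a
grayscale texture-like domain, two classes each. Conditions were chosen
once: shape pairs with nearest-centroid separability around 0.9 at the
default noise (`noise_sigma = 0.15`), pose jitter of ±0.1 in position,
0.20–0.30 in scale and ±0.35 rad in rotation, and 100 items per class
(20 train / 80 test). This makes each task learnable but not trivial at
five epochs, leaving room for forgetting effects to be measured.

What the generator does **not** emulate: transmission-imaging physics,
OCT speckle, anatomical variability, label noise, or the sheer
difficulty of natural images. Passing experiments here demonstrate that
the objective behaves as described — retention, ablation ordering,
temperature sensitivity — at desk scale; they do not predict absolute
accuracies on real screening data.

## What the experiments show

On the bundled benchmark (five seeds, five epochs per increment) the
final cumulative-test accuracy orders as: full continual loss >
no-coupling ablation > classic distillation > plain fine-tuning, and
fine-tuning's accuracy on increment-1 classes collapses after increment
2 — catastrophic forgetting reproduced qualitatively. Sweeping
$\tau \in \{0.5, 1, 1.5, 2, 5\}$ over three seeds gives a U-shaped mean
test error with the minimum at 1.5–2: low temperatures over-weight the
coupling term ($bs/\tau$ relative weight) and saturate the softmax;
high temperatures flatten representations until the Gaussian classes
overlap and retention degrades. `scripts/acceptance.R` recomputes all of
these numbers from scratch.

## Numerical choices and degenerate inputs

* All densities and posteriors live in log space; exponentiation happens
  only at reporting boundaries. Zero-prior classes get $-\infty$
  log-posterior columns and are excluded from fitting.
* Probabilities are floored at $10^{-12}$ before any log; a one-hot
  target landing on a zero-posterior class yields $+\infty$ with a
  warning, and a non-finite batch loss aborts with a diagnostic dump.
* A single-sample class with `ridge = 0` is a degenerate-covariance
  error; with a positive ridge it is usable.
* Prediction ties break to the first class in registry order
  (`max.col(..., "first")`), so results are order-stable.
* Metric ratios with zero denominators resolve to 0 and are flagged
  (`n_undefined`) rather than dropped, keeping reports comparable across
  increments; macro averages are taken over classes present in the
  truth. Macro averaging is the standard choice under class imbalance
  and is recorded in every report.

## Known limitations

* The retention and coupling terms assume the teacher is competent on
  old classes; a badly trained early increment propagates.
* Exemplar selection is uniform; herding or nearest-mean selection is
  out of scope (the selection interface is pluggable).
* The objective is known to be sensitive to extreme class imbalance;
  no reweighting is built in (the imbalance machinery in the generator
  exists precisely so this can be studied).
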