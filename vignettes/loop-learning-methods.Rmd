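---
title: "Loop-based adversarial learning for connectivity classification: models and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Loop-based adversarial learning for connectivity classification: models and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(loopgan)
```

This vignette explains the models implemented in `loopgan`, the
assumptions behind them, the tunable parameters and their defaults, and
the choices we made where the design was genuinely open.  It states no
empirical result that the package's tests do not themselves compute.

## 1. The classification problem

The unit of analysis is a subject's brain connectivity profile: one or
more square symmetric matrices over a fixed parcellation of $R$ brain
regions, stacked as channels of an $R \times R \times n$ tensor.  Two
modalities are supported out of the box:

* **functional connectivity** — the Pearson correlation
  $r(X,Y) = \frac{\sum_i (X_i - \bar X)(Y_i - \bar Y)}
  {\sqrt{\sum_i (X_i - \bar X)^2 \sum_i (Y_i - \bar Y)^2}}$
  between regional time series.  Population and sample normalization
  cancel in this ratio, so the implementation delegates the arithmetic to
  `stats::cor` and adds the domain contract on top: zero-variance regions
  raise an error naming the region (rather than silently emitting `NaN`),
  results are clamped to $[-1, 1]$ against rounding, and the diagonal is
  exactly 1.
* **structural connectivity** — tractography streamline counts divided by
  the subject's brain volume.  Self-connections are undefined for
  tractography, so the structural diagonal is set to 0; the functional
  diagonal is 1 by definition.  Keeping each modality's convention
  explicit makes both testable.

Region order is taken from the input files and must agree across a
subject's modalities; the package never re-sorts silently, because silent
reordering corrupts networks.  $R$ is a configuration value, not a
constant: the reference architecture uses $R = 164$ (a standard cortical
parcellation), the desk-scale test geometry $R = 40$.

Negative functional correlations are passed through to min-max scaling
without thresholding.  Nothing downstream requires non-negative inputs,
and thresholding would discard anticorrelation structure that may carry
class information.

## 2. Augmentation

One augmentation step moves a matrix's first column to the last column
and then its first row to the last row — a simultaneous cyclic relabeling
of rows and columns, so symmetry is preserved exactly and the entry
multiset and eigenvalue spectrum are invariant.  Repeating the step on
each newly produced matrix yields the full cyclic orbit: $R - 1$
additional matrices per original (163 at $R = 164$).  All channels of a
sample are shifted simultaneously so that cross-modal correspondence of
entries is kept.

Min-max scaling maps each channel to $[0, 1]$.  We scale **per subject,
per channel**, not over the whole dataset: per-sample scaling cannot leak
training statistics into the test set, and it matches the generator's
Sigmoid output range.  Augmentation is applied after scaling; shifts do
not change entry values, so the order is immaterial for the values, but
fixing it makes pipelines reproducible.

`split_dataset` offers two modes.  `matrix_level` splits over individual
(possibly augmented) matrices, mirroring an 80/20 pool over all enhanced
matrices; because augmented copies of one subject can then straddle the
split, this mode carries a leakage risk that we surface rather than hide.
`subject_level` keeps every variant of a subject on one side and is the
mode used in the package's own end-to-end evaluation.  Train size is
$\lfloor f \cdot N \rfloor$ with a seeded shuffle, so counts are
reproducible.

## 3. The adversarial model

Three convolutional networks are specified declaratively
(`build_generator`, `build_discriminator`, `build_classifier`) and
instantiated on a purpose-built dense-array engine (`nn_build`,
`nn_forward`): convolution and transposed convolution are realized as
im2col/col2im plus one BLAS matrix product, with hand-derived
reverse-mode gradients.  The engine is validated against naive-loop and
finite-difference oracles in the test suite.

At the reference geometry the generator maps a latent 1 x 1 map with
$100n$ channels through seven transposed convolutions
(4, 8, 16, 32, 41, 82, 164 spatial; 512, 256, 128, 64, 32, 16, $n$
channels; ReLU interior, Sigmoid output), the critic maps
$164 \times 164 \times n$ through six convolutions to an unbounded
$5 \times 5 \times n$ patch map (LeakyReLU, slope 0.2, no final
activation), and the classifier shares the critic's trunk but ends in a
$2 \times 2 \times 1$ map.  The tabulated channel progression of the
critic (16, 64, 128, 256, 512) is taken verbatim even though
16, 32, 64, ... would be more conventional.  The latent input is
interpreted as a $1 \times 1$ spatial map with $100n$ channels — the only
interpretation under which the first transposed convolution (kernel 4,
stride 1, padding 0) produces the tabulated $4 \times 4 \times 512$ map.

**Conditioning.**  The mechanism is deliberately minimal, chosen for
shape compatibility with the tabulated architecture: the generator
receives a 2-value one-hot class label appended to its latent vector
(HC = $(1,0)$, AB = $(0,1)$); the critic receives the label broadcast as
one constant-valued extra input channel, so it sees $n + 1$ channels.
The classifier is unconditioned.  A configuration switch disables
conditioning entirely, reducing the networks exactly to the tabulated
channel counts.

**Critic objective.**  With $\tilde x$ generated and $x$ real,

$$L_D = \mathbb E[D(\tilde x)] - \mathbb E[D(x)]
      + \lambda\, \mathbb E[(\lVert \nabla_{\hat x} D(\hat x) \rVert_2 - 1)^2],
\qquad \hat x = \epsilon x + (1 - \epsilon) \tilde x,$$

$\epsilon$ uniform per sample.  The critic's scalar for the loss is the
**mean** over its patch map (scale-invariant in the patch count; the
alternative, a sum, only rescales $\lambda$), and the penalty gradient
flows through this scalar.  The gradient norm is taken over all data
coordinates of a sample; the condition channel is held fixed and not
penalized, since it is not interpolated.  $\lambda$ defaults to 10, the
standard choice for this penalty.

**Differentiating the penalty.**  The penalty's *value* is exact: one
reverse-mode pass to the input.  Its gradient with respect to the critic
parameters involves second derivatives; we compute it with a directional
central difference.  Writing $g_i = \nabla_{\hat x_i} D(\hat x_i)$ and
$v_i = g_i / \lVert g_i \rVert$, the scalar
$s_i(\theta) = [D_\theta(\hat x_i + \varepsilon v_i) -
D_\theta(\hat x_i - \varepsilon v_i)] / 2\varepsilon$ approximates
$\lVert g_i \rVert$, and
$\partial_\theta\, \mathrm{mean}[(s_i - 1)^2]$ requires only two extra
forward/backward passes.  The step $\varepsilon$ defaults to $10^{-4}$ on
the $[0,1]$ input scale.  The test suite validates this against a full
finite-difference-in-$\theta$ oracle on a smooth critic (tolerance
$10^{-3}$) and the penalty value itself against a coordinate-wise
finite-difference gradient-norm oracle ($10^{-4}$).

**Normalization placement.**  Batch normalization sits on every layer
except each network's first and last.  Batch statistics couple samples,
which makes per-sample gradient penalties inexact; the critic therefore
accepts `d_norm = "instance"` (per-sample statistics, penalty exact) or
`"none"`.  The reference configuration keeps batch normalization as
tabulated; the desk-scale configuration uses `d_norm = "none"`, the
common practice for gradient-penalized critics.

**Optimization.**  Adam with learning rate $10^{-4}$ and
$\beta = (0.5, 0.9)$, five critic steps per generator step — the
customary companion settings for this objective, all overridable in
`gan_config`.  LeakyReLU slope is 0.2.  Weights are initialized
$\mathcal N(0, 0.02)$.  Non-finite losses abort with a diagnostic naming
the offending step.  All randomness flows from a single integer seed;
runs are bit-reproducible on a fixed platform.

## 4. Multiple-loop-learning

The loop algorithm turns batch training into incremental learning:

1. **Assemble** a class-balanced batch: the previous loop's carryover is
   topped up to `batch_per_class` per class by a seeded uniform draw from
   the database (drawn samples leave the database).
2. **Generate** fresh class-conditioned fakes from the frozen generator.
3. **Rank**: each real sample's score is the Euclidean distance between
   its flattened critic patch map and the *centroid* of the fake patch
   maps of its class, ascending within class, ties broken by sample id.
   The centroid — rather than, say, a pairwise minimum — is cheap,
   deterministic, and consistent with measuring distance to the learned
   distribution as a whole.
4. **Partition** per class: ranks $1..\lceil m/2 \rceil$ train the
   classifier this loop; ranks $\lceil m/2 \rceil + 1..\lceil 3m/4
   \rceil$ carry over; the rest return to the database.  Ceilings make
   the counts reproducible; partitioning per class keeps the training
   batch balanced.
5. **Train** the classifier (binary cross-entropy on the mean of its
   $2 \times 2$ map) for `classifier_epochs` epochs, optimizer state
   persisting across loops.
6. **Converge**: stop when validation accuracy has not improved by more
   than $10^{-3}$ for `patience` (default 3) consecutive loops; at
   `max_loops` the best checkpoint is returned with a flag, not an error.

Ranking direction is a modelling choice made explicit: "top-ranked" means
*smallest* critic-space distance, operationalizing the selection of
samples with an easier-to-learn distribution; `easy_first = FALSE`
inverts it for ablation.  Three further choices the algorithm leaves
open: trained-on samples return to the database after the loop and may be
redrawn (only the bottom quarter's routing is prescribed; random
selection from the database each loop implies a replenished pool);
carryover samples are re-ranked together with the fresh draws next loop;
and fake batches are regenerated from fresh noise each loop rather than
cached.  The generator and critic are frozen inside the loop by default
(`refresh_gan` optionally fine-tunes them each loop).

Pool bookkeeping is audited in the tests: after every loop the database,
carryover and selected pools are pairwise disjoint and jointly exhaustive
over the training samples, and every ranked batch is class-balanced.

## 5. The synthetic cohort

`generate_connectomes` emulates a balanced case/control cohort: per
modality one **base connectome** shared by all subjects, a class effect of
`effect_size` standard deviations added on a `effect_edges` fraction of
edges for the AB class, and symmetric Gaussian edge noise
(`noise_sd`).  Drawing the base once per dataset means within-class
variability comes only from noise — the simplest structure under which
"easier-to-learn" samples are well defined for ranking tests.  Effect
masks are drawn independently per channel, so the modalities carry
complementary signal, which is the rationale for stacking them.
Functional channels are clamped to $[-1,1]$ with unit diagonal,
structural ones to non-negative values with zero diagonal.

Defaults are the package's desk-scale study conditions: $R = 40$, 40 + 40
subjects, two modalities, `effect_size = 2`, `noise_sd = 0.5`, and
`effect_edges = 0.1` — a 10% affected-edge fraction, a plausible scale
for a focal disease effect and small enough that the classifier must
locate the signal rather than read a global mean shift.  The
command-line `synth --reference-geometry` flag emits the reference geometry
instead ($R = 164$, 42 + 42 subjects).

What this generator deliberately does **not** emulate: realistic
connectome topology (small-worldness, modular community structure,
distance-dependent edge weights), site or scanner effects, age/sex
covariates, or subject-specific global connectivity differences.  Tests
passing on this cohort therefore demonstrate the correctness and
learning behaviour of the pipeline, not clinical-grade performance on
real imaging data.

`generate_timeseries` feeds the Pearson pipeline from a latent-factor
model: series $= L f + \sigma e$ with the loadings encoding a target
correlation structure $\mathrm{cov2cor}(LL^\top + \sigma^2 I)$ that is
shrunk toward zero on the effect edges for the AB class (followed by an
eigenvalue-clipped projection back to positive definiteness; the realized
targets are returned so Monte-Carlo checks compare against what was
actually sampled).

## 6. Numerical choices and problem sizes

* Pearson results clamped to $[-1, 1]$; symmetry tolerance $10^{-8}$ for
  input matrices.
* Min-max scaling of a constant matrix is undefined and raises an error
  rather than returning zeros.
* ROC curves sweep all distinct score values as thresholds, grouping
  ties; AUC is trapezoidal and equals the Mann-Whitney concordance
  statistic with half-credit for ties (asserted on random instances, and
  cross-checked against the `pROC` package).
* The positive class is AB throughout, fixing the orientation of
  sensitivity and specificity in every output.
* Ties in ranking resolve by sample id, so all orderings are stable.

The package's own end-to-end evaluation runs at the desk-scale geometry:
$R = 40$, 40 + 40 subjects, channel widths halved, 120 generator steps of
pretraining, and up to 10 loops of 20 classifier epochs — sizes chosen so
the whole suite runs comfortably on one CPU while still exhibiting the
behaviours of interest (a strong effect is separated to high held-out
accuracy; a null effect stays at chance).  The classifier's per-loop
accuracy can fluctuate at this scale — incremental training on small
ranked batches can partially forget earlier batches — which is why
convergence tracks the *best* checkpoint rather than the last.

## 7. Known limitations

* The convolutional engine is CPU-only, dense, and single-threaded apart
  from BLAS; the reference 164-region geometry trains slowly in R and is
  intended for architecture-faithful construction and shape verification,
  with training at reduced width/size.
* Only two classes are supported; the loop algorithm's balance constraint
  (equal AB and HC per batch) is hard-wired.
* Multi-channel datasets beyond functional + structural round-trip
  through the CSV manifest only partially (channels are keyed by modality
  name).
* HDF5 input is not supported; matrices are delimited text.
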