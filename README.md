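# loopgan

Multiple-loop adversarial learning for brain connectivity classification.

`loopgan` classifies subjects into two groups — abnormal (AB, e.g.
Alzheimer's disease) versus healthy control (HC) — from multi-modal brain
connectivity matrices.  Instead of training a classifier on one random
batch, it couples a conditional Wasserstein GAN to a *multiple-loop-
learning* algorithm: each loop selects the training samples whose critic
representation is closest to the generator's learned distribution (the
"easier-to-learn" samples) and feeds them to a convolutional classifier
incrementally until it converges.

## The model

**Networks.** Three convolutional sub-networks share one architecture
family (164 x 164 x *n* inputs, *n* = number of modalities):

* a **generator** of seven transposed convolutions mapping a latent vector
  of 100 *n* values (plus a one-hot class condition) to a 164 x 164 x *n*
  matrix in [0, 1] (final Sigmoid);
* a **patch critic** of six convolutions ending in an unbounded
  5 x 5 x *n* patch map (PatchGAN-style local discrimination; the class
  condition enters as one constant input channel);
* a **classifier** of six convolutions ending in a 2 x 2 x 1 map whose
  mean is the AB-vs-HC logit.

**Critic objective.** The critic *D* is trained with the gradient-penalized
Wasserstein loss

```
L_D = E[D(x~)] - E[D(x)] + lambda * E[(|| grad_x^ D(x^) ||_2 - 1)^2]
```

with `x^ = eps x + (1 - eps) x~` sampled uniformly on real-fake lines
(`lambda = 10`), and the generator minimizes `L_G = -E[D(x~)]`.

**Multiple-loop-learning.** After pretraining, each loop (i) draws a
class-balanced batch from the database, topping up the previous loop's
carryover; (ii) generates class-conditioned fakes; (iii) scores every real
sample by the Euclidean distance between its flattened critic patch map and
the fake centroid of its class; (iv) per class, trains the classifier on
ranks `1..ceil(m/2)`, carries ranks `ceil(m/2)+1..ceil(3m/4)` to the next
loop, and returns the bottom quarter to the database.  The loop stops when
validation accuracy stops improving.

**Around the core** the package provides Pearson functional connectivity
(`pearson_connectivity`), volume-normalized structural connectivity
(`normalize_structural`), channel stacking (`stack_modalities`),
symmetry-preserving cyclic augmentation (`augment`: R - 1 extra matrices
per subject; 163 at the reference 164-region parcellation), min-max
scaling, ACC/SEN/SPE and ROC/AUC metrics, and a synthetic two-class
connectome generator (`generate_connectomes`) so everything is testable
without imaging data.

## Worked example

```r
library(loopgan)

spec <- synthetic_spec(n_regions = 40, n_per_class = 40, n_modalities = 2,
                       effect_size = 2, seed = 7)
samples <- generate_connectomes(spec)
sp <- split_dataset(samples, 0.8, "subject_level", seed = 8)

fit <- loopgan(sp$train,
               gan = gan_config(steps = 60, critic_steps = 5,
                                batch_size = 16, width = 0.5,
                                d_norm = "none"),
               loop = loop_config(batch_per_class = 16,
                                  classifier_epochs = 20, lr = 5e-4,
                                  max_loops = 8),
               seed = 1)
print(fit)
#> Loop-learning GAN classifier
#>   input: 40 x 40 x 2 connectivity samples
#>   GAN pretraining: 60 generator steps (lambda_gp = 10)
#>   loops: 7 (converged)
#>   best validation accuracy: 1

ev <- evaluate_model(fit, sp$test)
round(ev$metrics, 3)
#>   ACC   SEN   SPE
#> 0.875 1.000 0.667
ev$auc
#> 0.9333333   # on the 16 held-out subjects
```

The synthetic cohort has a standardized mean difference of 2 on 10% of
edges, so the fitted model separates the held-out subjects well: 87.5%
accuracy, perfect sensitivity (all AB found), and an AUC of 0.93.
`plot(fit)` shows the per-loop accuracy trajectory; `simulate(fit, 5)`
draws class-conditioned connectomes from the trained generator.

A thin command-line interface (`inst/cli/loopgan`) exposes the same
pipeline as `synth`, `construct`, `augment`, `pretrain`, `train` and
`evaluate` subcommands; every run writes a resolved config + seed sidecar
that replays to identical results.

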