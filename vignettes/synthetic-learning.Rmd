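---
title: "Synthetic learning for spine radiographs: models, choices, and limits"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Synthetic learning for spine radiographs: models, choices, and limits}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

## The problem

Sharing medical images across institutions is heavily restricted, which
keeps spine-imaging datasets small and models trained on them poorly
generalizable. *Synthetic learning* sidesteps the restriction: train a
generative model on the private images, release only synthetic images,
and let downstream models train on those. The endpoint is concrete — a
classifier trained **only** on synthetic images is evaluated on held-out
**real** images, and the gap to a real-data-trained classifier measures
how much task-relevant information the generator preserved.

This package implements that full pipeline for grayscale spine
radiographs with a binary normal/abnormal label (optionally the detailed
8-way abnormality category): DICOM ingestion, conditional GAN training
with a classifier-guided loss variant, conditional sampling with quality
filters, downstream classifier training, and generative-quality metrics.

## The models

### Conditional GAN

A generator $G(z, c)$ maps a latent vector $z \sim \mathcal N(0, I)$
and a class label $c$ to an image; a discriminator $D(x, c)$ scores
image–label pairs. Both train adversarially with the non-saturating
losses

$$G_\ell = -\log \sigma(D(G(z,c), c)), \qquad
  D_\ell = \mathrm{softplus}(-D(x_{real},c)) +
           \mathrm{softplus}(D(G(z,c),c)) + w_{R1} \cdot
           \tfrac1m \sum_i \lVert \nabla_x D(x_i, c_i) \rVert^2 ,$$

the last term being the R1 gradient penalty on real images (applied
lazily every `r1_interval` steps with compensating weight, the usual
practice for this regularizer family).

### The classifier-guided (SpineGAN) generator loss

Before GAN training, an abnormality classifier $S$ is trained on the
real training set and **frozen**. The SpineGAN generator loss adds the
cross-entropy between the conditioning labels and $S$'s predictions on
the generated batch:

$$\mathrm{SpineGAN}(G_\ell) = -\log\sigma(D(\vec x, \vec c))
  \;+\; \gamma \cdot \Big[-\tfrac1m \sum_{i=1}^m c_i \log S(\vec x_i) +
  (1-c_i)\log(1 - S(\vec x_i))\Big].$$

The term pushes generated images to carry the clinical features their
conditioning label promises, injecting domain knowledge the adversarial
game alone does not enforce. Two reading notes, both implemented:

* **Sign convention.** The method is described as a *standard
  cross-entropy measuring whether the conditional label matches the
  prediction*, and that is the default here. A widely circulated
  printed form of the loss carries the opposite sign on the matched
  term, which would *reward* disagreement; the
  `literal_printed_loss = TRUE` switch reproduces that form for
  comparison, but it contradicts the term's stated purpose and is not
  the default.
* **Batch normalization.** The sums are divided by the batch size $m$
  so that $\gamma$'s meaning does not depend on $m$.
* $\gamma$ defaults to 1.0; no published value exists for it. `gamma = 0`
  reduces the SpineGAN loss to the plain loss *exactly* (a tested
  contract).

The 8-way multi-conditional variant uses the same machinery with
`n_classes = 8` and categorical cross-entropy against $S$'s softmax; it
is functional but secondary, mirroring its proof-of-concept role.

### Network backbones

No deep-learning framework is assumed: the generator, discriminator and
classifiers are compact fully-connected networks with leaky-ReLU hidden
units, authored in-package with hand-written reverse-mode gradients
(BLAS-backed matrix products). Every gradient path — including the R1
penalty, which requires differentiating through the backward pass — has
a closed form that the test suite verifies against central finite
differences. The design choices that matter:

* **Projection discriminator.** The label enters $D$ as a learned
  class embedding whose inner product with the penultimate features is
  added to the score, rather than as a one-hot vector concatenated to
  thousands of pixels. The inner product couples label and image
  features directly and is, in our experiments, the difference between
  a conditional generator that obeys its label and one that ignores it.
* **Matching-aware discriminator term.** Each discriminator step also
  scores real images paired with deliberately *wrong* labels as fakes
  (`mismatch_weight`, default 1). This explicitly teaches label–image
  consistency; disabling it measurably degrades the label fidelity of
  the plain GAN's samples.
* **Class-template generator head.** The generator adds a learned
  per-class template to its output pre-activation, so class-mean
  structure (a lesion's typical appearance) does not have to be carried
  through the dense trunk.
* **Classifier backbone** (`pooled_mlp`): non-overlapping average
  pooling (factor 2 by default) followed by dense layers
  (128 hidden units) and a sigmoid or softmax head. Pooling is linear,
  so the guidance gradient passes through it exactly. Classifiers train
  with Adam at learning rate 0.001 and batch size 32 — the published
  settings for this task — with early stopping on a training-loss
  plateau (patience 3) under a hard epoch cap, since no epoch budget is
  published.

GAN learning rates ($3\times10^{-4}$ for both networks, Adam
$\beta = (0.5, 0.999)$) were chosen once on the phantom task for stable
convergence of *both* loss variants within the desk-scale budget and
are not tuned per experiment. A generator-weight moving average
(`ema_decay`) is available for long runs but disabled by default: at
desk-scale budgets the average spans the still-improving early
trajectory and degrades samples.

## Preprocessing

The DICOM ingestion pipeline reproduces the published preprocessing
exactly: extract the pixel array and the label via the image ID
(rejecting, with structured causes rather than exceptions, files that
are unparseable, lack pixel data, or lack a label); center-crop the
largest square (top/left-biased for odd margins — the dominant image
library convention; the source is silent); drop images whose smallest
dimension is below 128 pixels (strict inequality); resize by nearest
neighbour (`src = floor(i * src_side / target_side)`, the canonical
index map) to 256×256 by default; split 80–20. Stratification by label
is the default — it prevents degenerate test sets at desk scale — and
can be disabled for the literal unstratified reading, which is equally
consistent with the published description. Intensities rescale by the
stored bit-depth maximum and MONOCHROME1 files are inverted.

Classifier-side augmentation implements the published chain: horizontal
flip (p = 0.3), rotation within ±5°, random resized crop (scale 0.8–1.0,
ratio 1.0), resize to 224, replication of the grayscale image to 3
channels, and standardization with means (0.485, 0.456, 0.406) and
standard deviations (0.229, 0.224, 0.225). The same configuration
object is shared by every experimental arm ("the same CNN"). At phantom
scale the chain is **off by default**: lesions occupy few pixels and a
random crop can excise them, which measurably hurts the endpoint; the
chain remains available (`classifier_config(augment = augment_config())`)
and fully tested.

## The phantom generator

Desk-scale experiments need data whose ground truth is verifiable by
geometry, so the package renders phantom radiographs: `n_vertebrae`
bright rectangles (intensity 0.7 ± jitter) stacked with uniform gaps on
a dark background (0.1), with the class label encoded by exactly one
lesion operator — one gap halved (disc space narrowing), one vertebra
shifted laterally by 25% of its width (spondylolisthesis), a
maximum-intensity rod spanning three vertebrae (surgical implant), or
one vertebra halved in height (vertebral collapse) — followed by
Gaussian pixel noise (sd 0.05 by default) and clipping to [0, 1].
Intensity values were chosen once for high signal-to-noise; no
published intensity model exists for the real images, and phantom
realism is explicitly a non-goal. Four of the eight abnormality
categories are rendered — the four with unambiguous 2-D geometric
renderings; the rest remain valid label values everywhere else in the
package.

What the phantoms *do* share with the real task: a label-determined
structural difference learnable by a classifier, nuisance variation
(noise, jitter, lesion position), class imbalance (the default cohort
mirrors the real 2303:1470 normal:abnormal ratio), and a DICOM
serialization path with deliberately corrupted and undersized files to
exercise ingestion. What they do not: anatomy, intensity statistics,
beam geometry, annotation noise. A passing phantom experiment therefore
validates the *machinery* (losses, conditioning, filters, metrics, and
that the SpineGAN term preserves label information better than the
plain loss); it says nothing about radiograph realism at full scale.

## Generative metrics

FID is computed from first principles on embeddings: fit Gaussians to
the two embedding sets and evaluate
$\lVert\mu_a-\mu_b\rVert^2 + \mathrm{tr}(\Sigma_a + \Sigma_b -
2(\Sigma_a\Sigma_b)^{1/2})$, taking the matrix square root through the
symmetric form $\Sigma_a^{1/2}\Sigma_b\Sigma_a^{1/2}$; eigenvalues in
$[-10^{-8}, 0)$ clip to zero, substantially negative ones raise.
k-NN manifold precision/recall: precision is the fraction of generated
embeddings inside the union of balls around each real embedding with
radius its distance to its k-th nearest real neighbour (self excluded,
ties inside, Euclidean metric, k = 3 by default — no published value);
recall swaps the roles.

Because no canonical pretrained embedder is bundled, the default
embedder is a seeded random projection of flattened pixels (d = 64); a
trained classifier's penultimate layer is the alternative. FID values
are comparable only within one embedder, so every report carries the
embedder identifier. Reproducing published absolute FID values would
require the original dataset and embedding network and is a non-goal.

## Sampling filters

Two sample-quality filters are implemented as proposed qualitatively:

* **Latent thresholding** keeps noise vectors with
  $\lVert z\rVert \le r\sqrt{d}$ (rejection sampling). The radius is
  parameterized relative to the chi mean scale so $r$ is
  dimension-free; $r = 1$ keeps roughly the central half of draws
  (exactly the chi-squared(d) CDF at $d$ — a tested contract at
  d = 64). Thresholding never changes class counts.
* **Realism filtering** passes generated images through an
  in-domain/out-of-domain classifier and rejects below a threshold,
  topping up until the requested per-class counts are met exactly
  (largest-remainder rounding for the `match_real_prior` scheme).

Neither filter has a published quantitative target; tests pin their
mechanical contracts (acceptance-rate law, count preservation, no-op
and reject-all limits, noise rejection ≥ 95% for a filter trained on
phantoms vs noise).

## Numerical choices

Probabilities are clamped to $[10^{-7}, 1-10^{-7}]$ before logarithms.
Losses use stable softplus forms. All randomness flows through
per-stage seeds derived by a stable hash of (global seed, stage name),
so stages are decoupled and every artifact is reproducible bit-for-bit
from its configuration; serialization round-trips reproduce forward
passes bit-identically. Degenerate inputs (empty latent batches,
single-class training sets, zero-acceptance thresholds, unwritable
directories) are rejected with errors naming the offending value.

## Problem sizes

The bundled end-to-end experiment uses a 750-phantom cohort (458
normal / 292 abnormal — the real class ratio at desk scale) split
600/150, a 50,000-images-shown budget per GAN at 64×64, 2,000 synthetic
images per arm, three classifier seeds, and 300 images per side for the
generative metrics. These sizes were chosen as the smallest at which
the endpoint stabilizes across seeds; the configuration objects scale
every one of them up (256×256 images and multi-million-image budgets
are configuration changes, not code changes).

## Known limitations

* Dense backbones, not convolutional ones: adequate for 64-pixel
  phantoms and the method's contracts, but a full-scale radiograph run
  would want a convolutional or attention backbone behind the same
  interfaces.
* The DICOM dialect is the minimal secondary-capture grayscale layout
  (Explicit VR Little Endian, 8/16-bit, single frame, linear rescale,
  no windowing/LUT or multi-frame support).
* Phantom experiments bound what desk-scale evidence can show (see
  above); published full-scale AUC/FID values are not reproducible
  without the original dataset and GPU-scale budgets.
* The multi-class SpineGAN generalization is provided but experimental;
  only the binary form is exercised end to end.
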