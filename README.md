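# spinegan

Synthetic learning for spine radiographs: conditional GAN generation of
labeled medical images with a classifier-guided generator loss
(SpineGAN), plus the full surrounding pipeline — DICOM preprocessing,
downstream classifier training on real vs. synthetic data, and
generative-quality metrics — exercisable end to end at desk scale
through a built-in phantom-radiograph generator.

## The problem

Privacy restrictions keep medical imaging datasets siloed per
institution, which limits both dataset size and model generalizability.
*Synthetic learning* trains a generative model on the private images
and releases only synthetic images; downstream models train on the
synthetic data and are judged on held-out **real** data. The endpoint
is the AUC gap between a classifier trained on real images and one
trained only on synthetic images.

## The method

A conditional GAN learns `G(z, c)` mapping latent noise `z` and a
normal/abnormal label `c` to an image, against a projection
discriminator `D(x, c)`, with non-saturating losses and an R1 gradient
penalty. The SpineGAN variant first trains an abnormality classifier
`S` on the real data, freezes it, and adds a guidance term to the
generator loss:

    SpineGAN(Gl) = -log sigma(D(x, c))
                   + gamma * BCE(c, S(x)),
    BCE(c, s) = -(1/m) * sum_i [ c_i log s_i + (1 - c_i) log(1 - s_i) ]

so generated images are pushed to carry the clinical features their
conditioning label promises. `gamma = 0` recovers the plain loss
exactly. Sampling supports latent thresholding (`||z|| <= r sqrt(d)`)
and an in-domain realism filter; generative quality is measured by FID
(Fréchet distance between embedding Gaussians) and k-NN manifold
precision/recall, all implemented from first principles and tested
against brute-force oracles.

All networks are compact dense nets authored in-package with
hand-written reverse-mode gradients (finite-difference-verified,
BLAS-backed); no deep-learning framework is required.

## Worked example

```r
library(spinegan)

# a phantom cohort with the real data's class imbalance, split 80-20
cohort <- generate_cohort(458, 292, phantom_config(noise_sd = 0.05), seed = 42)
split  <- split_dataset(cohort, ingest_config(split_seed = 7))

# pretrain and freeze the abnormality network S
s <- pretrain_label_network(split$train, classifier_config(seed = 1))

# plain conditional GAN vs SpineGAN (same budget, same seed)
gan   <- train_gan(split$train, gan_config(total_images_shown = 50000, seed = 5))
spine <- train_gan(split$train, gan_config(total_images_shown = 50000, seed = 5), s = s)

# synthetic-learning endpoint: same classifier on real vs synthetic data
ex <- synthetic_learning_experiment(split$train, split$test,
                                    list(gan = gan, spinegan = spine),
                                    n_synthetic = 2000, seeds = 1:2)
ex
#> Synthetic-learning experiment (AUC on shared real test set)
#>       arm  auc_mean      auc_sd n_seeds
#>      real 0.9963456 0.004638069       2
#>       gan 0.9164168 0.008481041       2
#>  spinegan 0.9553973 0.017757179       2
```

A classifier trained purely on SpineGAN-synthetic images comes within
~0.04 AUC of real-data training on the held-out real test set, and
closes most of the gap the plain GAN leaves — the label information the
classifier-guided loss exists to preserve. (Numbers from this 64×64
phantom configuration on one CPU; each GAN trains in a few minutes.)

Sampling and metrics:

```r
syn <- simulate(spine, nsim = 100, seed = 3)        # labeled synthetic images
table(dataset_labels(syn))
#>
#> abnormal   normal
#>       50       50

metrics_report(split$test, list(spinegan = syn), k = 3)
#>       arm      fid precision recall embedder_id k n_real n_generated
#>  spinegan 87.44128         0   0.98  rp64_seed1 3    150         100
```

A thin CLI mirrors the pipeline (`inst/cli/spinegan`): subcommands
`phantom`, `ingest`, `pretrain-s`, `train-gan` (`--spinegan --gamma`),
`generate` (`--n --class-scheme --latent-r`), `train-clf`, `metrics`,
and `run` for the full experiment from a YAML config.

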