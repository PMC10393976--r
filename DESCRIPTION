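Package: spinegan
Title: Synthetic Learning for Spine Radiographs with Classifier-Guided
    Conditional GANs
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.com", role = c("aut", "cre"))
Description: Toolkit for synthetic learning on spine radiographs: a
    conditional generative adversarial network with a classifier-guided
    generator loss (SpineGAN) that injects clinical abnormality
    information from a frozen pretrained classifier into generator
    training, together with the full surrounding pipeline.  Includes
    DICOM radiograph ingestion (rejection rules, center square crop,
    nearest-neighbour resize, stratified splitting, augmentation),
    downstream abnormality classifiers trained on real or synthetic
    data and scored by AUC, generative-quality metrics (Frechet
    distance between embedding Gaussians, k-NN manifold precision and
    recall), latent-threshold and realism filters for conditional
    sampling, and a phantom-radiograph generator that renders
    class-conditional structural lesions for desk-scale experiments.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    tools,
    grDevices,
    graphics,
    png,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr,
    jsonlite,
    optparse
Config/testthat/edition: 3
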