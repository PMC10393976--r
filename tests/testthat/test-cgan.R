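# Loss contracts are checked against independent closed-form scalar
# arithmetic; training contracts (determinism, frozen S, budget
# accounting) on deliberately tiny runs.

oracle_plain <- function(lg) mean(-log(1 / (1 + exp(-lg))))
oracle_bce <- function(c, s) {
  s <- pmin(pmax(s, 1e-7), 1 - 1e-7)
  -mean(c * log(s) + (1 - c) * log(1 - s))
}

test_that("plain generator loss matches its closed form", {
  expect_equal(plain_generator_loss(0), log(2), tolerance = 1e-12)
  expect_equal(plain_generator_loss(c(1, -1)),
               (log(1 + exp(-1)) + log(1 + exp(1))) / 2, tolerance = 1e-12)
  expect_equal(plain_generator_loss(c(1, -1)), 0.8132617, tolerance = 1e-6)
  expect_lt(plain_generator_loss(rep(40, 3)), 1e-12)   # limit at +inf
  # decreasing in each logit
  expect_gt(plain_generator_loss(c(0, 0)), plain_generator_loss(c(0.5, 0)))
})

test_that("SpineGAN loss equals plain loss plus gamma times cross-entropy", {
  # worked example: logits (0,0), c = (1,0), s = (0.8, 0.3), gamma = 1
  got <- spinegan_generator_loss(c(0, 0), c(0.8, 0.3), c(1, 0), gamma = 1)
  expect_equal(got, log(2) - (log(0.8) + log(0.7)) / 2, tolerance = 1e-12)
  expect_equal(got, 0.9830, tolerance = 1e-4)

  # gamma = 0 reduction is exact
  lg <- rnorm(8)
  s <- runif(8)
  cc <- rbinom(8, 1, 0.5)
  expect_identical(spinegan_generator_loss(lg, s, cc, gamma = 0),
                   plain_generator_loss(lg))

  # perfect-label limit: classifier term vanishes under clamping
  expect_equal(spinegan_generator_loss(lg, cc, cc, gamma = 1),
               plain_generator_loss(lg), tolerance = 1e-5)

  # monotone non-decreasing in gamma when the BCE is positive
  g1 <- spinegan_generator_loss(lg, s, cc, gamma = 0.5)
  g2 <- spinegan_generator_loss(lg, s, cc, gamma = 1.5)
  expect_gte(g2, g1)

  expect_error(spinegan_generator_loss(c(0, 0), c(0.5), c(1, 0)),
               "length mismatch")
})

test_that("the literal printed sign variant flips the matched-label term", {
  lg <- c(0.2, -0.4)
  s <- c(0.9, 0.2)
  cc <- c(1, 0)
  lit <- spinegan_generator_loss(lg, s, cc, gamma = 2,
                                 literal_printed_loss = TRUE)
  expect_equal(lit, oracle_plain(lg) +
                 2 * (mean(cc * log(s)) - mean((1 - cc) * log(1 - s))),
               tolerance = 1e-12)
})

test_that("loss arithmetic matches the scalar oracle on random batches", {
  set.seed(77)
  for (i in 1:25) {
    m <- sample(1:16, 1)
    lg <- rnorm(m, sd = 3)
    lr <- rnorm(m, sd = 3)
    s <- runif(m)
    cc <- rbinom(m, 1, 0.5)
    gam <- runif(1, 0, 3)
    expect_equal(plain_generator_loss(lg), oracle_plain(lg),
                 tolerance = 1e-6)
    expect_equal(spinegan_generator_loss(lg, s, cc, gam),
                 oracle_plain(lg) + gam * oracle_bce(cc, s),
                 tolerance = 1e-6)
    pen <- runif(1)
    w <- runif(1, 0, 10)
    expect_equal(discriminator_loss(lr, lg, pen, w),
                 mean(log(1 + exp(-lr))) + mean(log(1 + exp(lg))) +
                   w * pen, tolerance = 1e-6)
  }
})

test_that("discriminator loss closed forms and limits hold", {
  expect_equal(discriminator_loss(0, 0), 2 * log(2), tolerance = 1e-12)
  expect_lt(discriminator_loss(rep(40, 2), rep(-40, 2)), 1e-12)
  expect_equal(discriminator_loss(rep(40, 2), rep(-40, 2),
                                  r1_penalty = 0.02, r1_weight = 10),
               0.2, tolerance = 1e-12)
})

test_that("multi-class guidance uses categorical cross-entropy", {
  P <- matrix(c(0.7, 0.2, 0.1,
                0.1, 0.8, 0.1), 2, 3, byrow = TRUE)
  got <- spinegan_generator_loss(c(0, 0), P, c(1L, 2L), gamma = 1)
  expect_equal(got, log(2) - (log(0.7) + log(0.8)) / 2, tolerance = 1e-12)
})

tiny_gan_fit <- function(seed = 3, images = 64, s = NULL, gamma = 1) {
  coh <- tiny_cohort(16, 16, seed = 400 + seed)
  train_gan(coh, gan_config(total_images_shown = images, seed = seed,
                            gamma = gamma, log_interval = 1L), s = s)
}

test_that("a one-batch budget takes exactly one step of each network", {
  fit <- tiny_gan_fit(images = 32)
  expect_equal(nrow(fit$history), 1L)
  expect_equal(fit$history$step, 1L)
  expect_equal(fit$generator$step_count, 1L)
})

test_that("training is deterministic under identical seeds and configs", {
  a <- tiny_gan_fit(seed = 5)
  b <- tiny_gan_fit(seed = 5)
  expect_identical(spinegan:::param_hash(a$generator$net),
                   spinegan:::param_hash(b$generator$net))
  expect_identical(spinegan:::param_hash(a$discriminator$net),
                   spinegan:::param_hash(b$discriminator$net))
  c <- tiny_gan_fit(seed = 6)
  expect_false(identical(spinegan:::param_hash(a$generator$net),
                         spinegan:::param_hash(c$generator$net)))
})

test_that("generator forward pass honours its contracts", {
  fit <- tiny_gan_fit()
  gen <- fit$generator
  z <- matrix(rnorm(6 * 64), 6)
  b1 <- latent_batch(z, rep("normal", 6))
  out1 <- generator_forward(gen, b1)
  expect_equal(dim(out1), c(64L, 64L, 6L))
  expect_true(all(out1 >= 0 & out1 <= 1))
  expect_identical(out1, generator_forward(gen, b1))

  # conditioning reaches the output after training steps
  out2 <- generator_forward(gen, latent_batch(z, rep("abnormal", 6)))
  expect_false(identical(out1, out2))

  # vacuous batch
  empty <- generator_forward(gen, latent_batch(matrix(numeric(0), 0, 64),
                                               character(0)))
  expect_equal(dim(empty), c(64L, 64L, 0L))

  expect_error(
    generator_forward(gen, latent_batch(matrix(0, 2, 8), rep("normal", 2))),
    "expected 64, got 8")
  expect_error(generator_forward(gen, latent_batch(z, rep("stenosis?", 6))),
               "class inventory")
})

test_that("discriminator logits are finite, per-sample, and side-checked", {
  fit <- tiny_gan_fit()
  d <- fit$discriminator
  imgs <- array(runif(64 * 64 * 5), dim = c(64, 64, 5))
  labs <- c("normal", "abnormal", "normal", "abnormal", "normal")
  l1 <- discriminator_forward(d, imgs, labs)
  expect_length(l1, 5L)
  expect_true(all(is.finite(l1)))
  expect_true(all(is.finite(discriminator_forward(
    d, array(0, dim = c(64, 64, 2)), c("normal", "abnormal")))))
  expect_true(all(is.finite(discriminator_forward(
    d, array(1, dim = c(64, 64, 2)), c("normal", "abnormal")))))

  perm <- c(3, 1, 5, 2, 4)
  expect_equal(discriminator_forward(d, imgs[, , perm], labs[perm]),
               l1[perm], tolerance = 1e-12)

  expect_error(discriminator_forward(d, array(0, dim = c(32, 32, 2)),
                                     c("normal", "abnormal")),
               "side mismatch")
})

test_that("pretrained S is frozen and probability-valued", {
  coh <- tiny_cohort(40, 40, seed = 88)
  s <- pretrain_label_network(coh, classifier_config(seed = 2, epochs = 4))
  expect_true(s$meta$frozen)
  h0 <- spinegan:::param_hash(s$net)
  expect_identical(h0, s$meta$hash)

  fit <- train_gan(coh, gan_config(total_images_shown = 128, seed = 1),
                   s = s)
  expect_identical(spinegan:::param_hash(s$net), h0)
  expect_false(is.na(fit$history$classifier_term[1]))

  p <- predict_probabilities(s, matrix(runif(3 * 64^2), 3))
  expect_true(all(p >= 0 & p <= 1))

  solo <- coh[dataset_labels(coh) == "normal"]
  expect_error(pretrain_label_network(solo, classifier_config()),
               "single class")
  expect_error(pretrain_label_network(
    coh, classifier_config(augment = augment_config())), "augmentation")
})

test_that("S trained on a different inventory is refused", {
  coh <- tiny_cohort(16, 16, seed = 21)
  s8 <- train_classifier(coh, classifier_config(seed = 1, epochs = 2),
                         classes = coh$classes)
  expect_error(train_gan(coh, gan_config(total_images_shown = 32), s = s8),
               "class inventory")
})

test_that("guidance gradients point toward the conditioning labels", {
  # moving the images a small step against the guidance gradient must
  # reduce the classifier cross-entropy term
  coh <- tiny_cohort(30, 30, seed = 55)
  s <- pretrain_label_network(coh, classifier_config(seed = 3, epochs = 4))
  X <- dataset_pixel_matrix(coh)[1:10, ]
  idx <- rep(c(1L, 2L), 5)            # deliberately mismatched labels
  g <- spinegan:::s_guidance(s, X, idx, gamma = 1)
  X2 <- spinegan:::clamp01(X - 0.05 * g$dX / max(abs(g$dX)))
  g2 <- spinegan:::s_guidance(s, X2, idx, gamma = 1)
  expect_lt(g2$term, g$term)
})

test_that("generator and discriminator serialization round-trips", {
  fit <- tiny_gan_fit()
  p <- withr::local_tempfile(fileext = ".rds")
  save_network_state(fit$generator, p)
  g2 <- load_network_state(p)
  z <- matrix(rnorm(3 * 64), 3)
  b <- latent_batch(z, c("normal", "abnormal", "normal"))
  expect_identical(generator_forward(fit$generator, b),
                   generator_forward(g2, b))
})

test_that("the classifier guidance term decreases over SpineGAN training", {
  coh <- tiny_cohort(60, 60, seed = 71)
  s <- pretrain_label_network(coh, classifier_config(seed = 5))
  wins <- 0L
  for (seed in 1:3) {
    fit <- train_gan(coh, gan_config(total_images_shown = 3200, seed = seed,
                                     log_interval = 10L), s = s)
    h <- fit$history$classifier_term
    early <- mean(h[seq_len(ceiling(length(h) / 4))])
    late <- mean(h[seq(length(h) - floor(length(h) / 4), length(h))])
    if (late < early) wins <- wins + 1L
  }
  expect_gte(wins, 2L)
})

test_that("the multi-conditional variant trains over the full category inventory", {
  coh <- tiny_cohort(20, 20, seed = 601)           # 5 classes present
  fit <- train_gan(coh, gan_config(n_classes = 5L,
                                   total_images_shown = 64, seed = 2))
  expect_setequal(fit$classes, coh$classes)
  z <- matrix(rnorm(5 * 64), 5)
  out <- generator_forward(fit, latent_batch(z, coh$classes))
  expect_equal(dim(out), c(64L, 64L, 5L))
  expect_true(all(out >= 0 & out <= 1))

  # categorical guidance: multi-class S feeds softmax cross-entropy
  s5 <- train_classifier(coh, classifier_config(seed = 1, epochs = 2),
                         classes = coh$classes)
  expect_equal(s5$meta$out_dim, 5L)
  P <- predict_probabilities(s5, dataset_pixel_matrix(coh)[1:4, ])
  expect_equal(dim(P), c(4L, 5L))
  expect_equal(rowSums(P), rep(1, 4), tolerance = 1e-9)
  s5$meta$frozen <- TRUE
  s5$meta$hash <- spinegan:::param_hash(s5$net)
  fit2 <- train_gan(coh, gan_config(n_classes = 5L,
                                    total_images_shown = 64, seed = 3),
                    s = s5)
  expect_true(is.finite(fit2$history$classifier_term[1]))

  # multi-class synthesis with explicit per-class counts
  counts <- stats::setNames(c(4L, 2L, 2L, 1L, 1L), fit$classes)
  syn <- generate_synthetic_dataset(
    fit, sampling_config(10, class_scheme = counts, seed = 5))
  expect_equal(as.integer(table(factor(dataset_labels(syn),
                                       levels = fit$classes))[fit$classes]),
               unname(counts))
})
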