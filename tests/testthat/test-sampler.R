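test_that("unthresholded latents are exactly the seeded normal draws", {
  z <- sample_latents(10, 8, r = NULL, seed = 5)
  expect_equal(dim(z), c(10L, 8L))
  expect_identical(z, spinegan:::with_seed(5, matrix(rnorm(80), 10)))
})

test_that("thresholded latents respect the radius and stay seeded", {
  z <- sample_latents(50, 16, r = 1.0, seed = 9)
  expect_equal(dim(z), c(50L, 16L))
  expect_true(all(sqrt(rowSums(z^2)) <= sqrt(16)))
  expect_identical(z, sample_latents(50, 16, r = 1.0, seed = 9))
})

test_that("degenerate and hopeless thresholds raise informative errors", {
  expect_error(sample_latents(5, 8, r = 0, seed = 1), "empty")
  expect_error(sample_latents(50, 64, r = 0.3, seed = 1, max_attempts = 5),
               "acceptance rate")
})

test_that("the empirical acceptance rate follows the chi-squared law", {
  # P(||z|| <= sqrt(64)) for z in R^64 equals the chi-squared(64) CDF at 64
  z <- sample_latents(10000, 64, r = NULL, seed = 202)
  acc <- mean(rowSums(z^2) <= 64)
  expect_lt(abs(acc - stats::pchisq(64, df = 64)), 0.03)
})

test_that("largest-remainder apportionment hits requested totals exactly", {
  lr <- spinegan:::largest_remainder
  expect_equal(lr(c(1, 1), 100), c(50L, 50L))
  expect_equal(lr(c(1, 1, 1), 100), c(34L, 33L, 33L))
  # the real training prior 1470 abnormal / 2303 normal at n = 10,000:
  # quotas 3896.104 and 6103.896; the larger remainder takes the seat
  expect_equal(lr(c(1470, 2303), 10000), c(3896L, 6104L))
  expect_equal(sum(lr(runif(5), 977)), 977L)
})

test_that("synthetic datasets honour class schemes and provenance", {
  coh <- tiny_cohort(16, 16, seed = 501)
  fit <- train_gan(coh, gan_config(total_images_shown = 64, seed = 2))

  bal <- generate_synthetic_dataset(
    fit, sampling_config(100, class_scheme = "balanced", seed = 4))
  expect_length(bal$records, 100L)
  expect_equal(sum(dataset_labels(bal) == "normal"), 50L)
  expect_true(all(vapply(bal$records, function(r) r$provenance,
                         character(1)) == "synthetic"))

  pri <- generate_synthetic_dataset(
    fit, sampling_config(100, class_scheme = "match_real_prior", seed = 4))
  expect_equal(sum(dataset_labels(pri) == "normal"), 50L)  # 16/16 prior

  ex <- generate_synthetic_dataset(
    fit, sampling_config(10, class_scheme = c(normal = 7L, abnormal = 3L),
                         seed = 4))
  expect_equal(sum(dataset_binary_labels(ex)), 3L)
})

test_that("generation is reproducible and latent thresholding keeps counts", {
  coh <- tiny_cohort(16, 16, seed = 502)
  fit <- train_gan(coh, gan_config(total_images_shown = 64, seed = 3))
  a <- generate_synthetic_dataset(
    fit, sampling_config(40, class_scheme = "balanced", seed = 11))
  b <- generate_synthetic_dataset(
    fit, sampling_config(40, class_scheme = "balanced", seed = 11))
  expect_identical(dataset_pixel_matrix(a), dataset_pixel_matrix(b))

  thr <- generate_synthetic_dataset(
    fit, sampling_config(40, class_scheme = "balanced", latent_r = 1.0,
                         seed = 11))
  expect_equal(table(dataset_labels(thr)), table(dataset_labels(a)))
})

test_that("an accept-everything realism filter is a no-op", {
  coh <- tiny_cohort(16, 16, seed = 503)
  fit <- train_gan(coh, gan_config(total_images_shown = 64, seed = 5))
  clf <- train_classifier(coh, classifier_config(seed = 1, epochs = 1))
  plain <- generate_synthetic_dataset(
    fit, sampling_config(30, class_scheme = "balanced", seed = 6))
  filtered <- generate_synthetic_dataset(
    fit, sampling_config(30, class_scheme = "balanced", seed = 6,
                         realism_filter = list(state = clf, threshold = 0)))
  expect_identical(dataset_pixel_matrix(plain),
                   dataset_pixel_matrix(filtered))

  # threshold 1 with clamped probabilities rejects everything
  expect_error(generate_synthetic_dataset(
    fit, sampling_config(5, class_scheme = "balanced", seed = 6,
                         max_attempts = 3,
                         realism_filter = list(state = clf, threshold = 1))),
    "realism filter")
})

test_that("realism filtering separates phantoms from pure noise", {
  mk_noise <- function(i) image_record(
    matrix(spinegan:::with_seed(7000 + i, runif(64 * 64)), 64, 64),
    sprintf("nz_%03d", i), "noise")
  mk_spine <- function(i) generate_phantom(
    "normal", phantom_config(), seed = 7100 + i,
    image_id = sprintf("sp_%03d", i))
  spines <- lapply(lapply(1:60, mk_spine), function(r) {
    r$label <- "spine"                # relabel into the filter inventory
    r
  })
  train <- labeled_dataset(c(lapply(1:60, mk_noise), spines),
                           classes = c("noise", "spine"))
  filt <- train_classifier(train, classifier_config(seed = 3, epochs = 4),
                           classes = c("noise", "spine"))
  held_noise <- t(vapply(1:40, function(i)
    as.numeric(mk_noise(500 + i)$pixels), numeric(64 * 64)))
  held_spine <- t(vapply(1:40, function(i)
    as.numeric(mk_spine(500 + i)$pixels), numeric(64 * 64)))
  expect_gte(mean(!realism_filter(held_noise, filt, 0.5)), 0.95)
  expect_gte(mean(realism_filter(held_spine, filt, 0.5)), 0.9)

  # threshold-0 accepts all
  expect_true(all(realism_filter(held_noise, filt, 0)))
})

test_that("simulate() on a fit draws a labeled synthetic dataset", {
  coh <- tiny_cohort(16, 16, seed = 504)
  fit <- train_gan(coh, gan_config(total_images_shown = 64, seed = 7))
  syn <- simulate(fit, nsim = 12, seed = 2)
  expect_s3_class(syn, "labeled_dataset")
  expect_length(syn$records, 12L)
  expect_equal(sum(dataset_labels(syn) == "normal"), 6L)
})

test_that("synthetic datasets export as PNG files with a label manifest", {
  ds <- tiny_cohort(3, 2, seed = 505)
  d <- withr::local_tempdir()
  mf <- write_image_dataset(ds, d)
  expect_equal(nrow(mf), 5L)
  expect_true(all(file.exists(mf$path)))
  back <- png::readPNG(mf$path[1])
  orig <- ds$records[[1]]$pixels
  expect_equal(dim(back), dim(orig))
  expect_lt(max(abs(back - orig)), 1 / 255)
  labs <- utils::read.table(file.path(d, "labels.tsv"), header = TRUE,
                            sep = "\t", stringsAsFactors = FALSE)
  expect_equal(labs$label, dataset_labels(ds))
})
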