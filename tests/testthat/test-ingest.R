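test_that("center square crop follows the floor-offset index map", {
  # 300x200 -> rows 51..250 (0-based offset floor((300-200)/2) = 50)
  m <- matrix(seq_len(300 * 200), 300, 200)
  out <- center_square_crop(m)
  expect_equal(dim(out), c(200L, 200L))
  expect_identical(out, m[51:250, ])

  sq <- matrix(runif(49), 7, 7)
  expect_identical(center_square_crop(sq), sq)

  # odd margin: top-biased, so the dropped row is the bottom one
  m2 <- matrix(seq_len(201 * 200), 201, 200)
  expect_identical(center_square_crop(m2), m2[1:200, ])
  m3 <- matrix(seq_len(200 * 201), 200, 201)
  expect_identical(center_square_crop(m3), m3[, 1:200])
})

test_that("nearest-neighbour resize preserves values and follows the index map", {
  const <- matrix(0.4, 512, 512)
  expect_equal(resize_nearest(const, 256), matrix(0.4, 256, 256))

  cb <- outer(1:4, 1:4, function(i, j) (i + j) %% 2)
  down <- resize_nearest(cb, 2)
  expect_true(all(down %in% c(0, 1)))

  up <- resize_nearest(matrix(c(0, 1, 1, 0), 2, 2), 4)
  idx <- floor((0:3) * 2 / 4) + 1         # explicit nearest-index map
  expect_identical(up, matrix(c(0, 1, 1, 0), 2, 2)[idx, idx])
  expect_identical(up[1:2, 1:2], matrix(0, 2, 2) + up[1, 1])

  # no new intensities, any shape
  for (i in 1:10) {
    src <- matrix(runif(36), 6, 6)
    out <- resize_nearest(src, sample(1:12, 1))
    expect_true(all(out %in% src))
  }

  # idempotence on already-square, already-target-side inputs
  sq <- matrix(runif(64), 8, 8)
  expect_identical(resize_nearest(center_square_crop(sq), 8), sq)
})

test_that("size filter uses a strict less-than threshold", {
  mk <- function(id, h, w) image_record(matrix(0.5, h, w), id, "normal")
  ds <- labeled_dataset(list(mk("a", 127, 400), mk("b", 128, 128),
                             mk("c", 500, 90)))
  res <- apply_size_filter(ds, 128)
  expect_equal(vapply(res$kept$records, function(r) r$image_id,
                      character(1)), "b")
  expect_setequal(res$dropped$image_id, c("a", "c"))
})

test_that("stratified split matches per-class floor arithmetic", {
  cfg <- phantom_config(image_side = 32)
  recs <- c(lapply(1:5, function(i)
    image_record(matrix(0.2, 4, 4), paste0("n", i), "normal")),
    lapply(1:5, function(i)
      image_record(matrix(0.8, 4, 4), paste0("a", i), "abnormal")))
  ds <- labeled_dataset(recs)
  sp <- split_dataset(ds, ingest_config(split_fraction = 0.8,
                                        split_seed = 3))
  expect_length(sp$train$records, 8L)
  expect_length(sp$test$records, 2L)
  expect_equal(sum(dataset_labels(sp$train) == "normal"), 4L)
  expect_equal(sum(dataset_labels(sp$test) == "abnormal"), 1L)

  sp2 <- split_dataset(ds, ingest_config(split_fraction = 0.8,
                                         split_seed = 3))
  expect_identical(dataset_labels(sp2$train), dataset_labels(sp$train))
  expect_identical(
    vapply(sp2$train$records, function(r) r$image_id, character(1)),
    vapply(sp$train$records, function(r) r$image_id, character(1)))

  # union of label multisets is preserved
  expect_equal(sort(c(dataset_labels(sp$train), dataset_labels(sp$test))),
               sort(dataset_labels(ds)))
})

test_that("the study-scale split arithmetic reproduces the printed counts", {
  # 1470 abnormal / 2303 normal at fraction 0.8 -> train 1176 + 1842 = 3018
  mk <- function(lab, n) lapply(seq_len(n), function(i)
    image_record(matrix(0, 2, 2), paste0(lab, i), lab))
  ds <- labeled_dataset(c(mk("abnormal", 1470), mk("normal", 2303)))
  sp <- split_dataset(ds, ingest_config(split_fraction = 0.8,
                                        split_seed = 11))
  expect_length(sp$train$records, 3018L)
  expect_equal(sum(dataset_labels(sp$train) == "abnormal"), 1176L)
  expect_equal(sum(dataset_labels(sp$train) == "normal"), 1842L)
})

test_that("stratification refuses single-member classes by name", {
  ds <- labeled_dataset(list(
    image_record(matrix(0, 2, 2), "x1", "normal"),
    image_record(matrix(0, 2, 2), "x2", "normal"),
    image_record(matrix(0, 2, 2), "y1", "abnormal")))
  expect_error(split_dataset(ds, ingest_config()), "abnormal")
})

test_that("augmentation identity chain reduces to replicate-and-normalize", {
  px <- matrix(runif(64 * 64), 64, 64)
  cfg <- augment_config(hflip_probability = 0, rotation_range = 0,
                        rrc_scale = c(1, 1), rrc_ratio = c(1, 1),
                        resize_side = 64)
  out <- augment(px, cfg, seed = 5)
  for (ch in 1:3) {
    expect_equal(out[, , ch], (px - cfg$norm_mean[ch]) / cfg$norm_sd[ch])
  }
  # constant image at a channel's mean centres that channel at zero
  flat <- matrix(cfg$norm_mean[2], 64, 64)
  expect_equal(max(abs(augment(flat, cfg, seed = 1)[, , 2])), 0)
})

test_that("horizontal flip is an involution", {
  px <- matrix(runif(32 * 32), 32, 32)
  cfg <- augment_config(hflip_probability = 1, rotation_range = 0,
                        rrc_scale = c(1, 1), rrc_ratio = c(1, 1),
                        resize_side = 32, norm_mean = rep(0, 3),
                        norm_sd = rep(1, 3))
  once <- augment(px, cfg, seed = 3)[, , 1]
  twice <- augment(once, cfg, seed = 8)[, , 1]
  expect_equal(twice, px)
})

test_that("augmentation is deterministic under seed and eval path is static", {
  rec <- generate_phantom("normal", phantom_config(), seed = 2)
  cfg <- augment_config(resize_side = 64)
  expect_identical(augment(rec, cfg, seed = 9), augment(rec, cfg, seed = 9))
  expect_false(identical(augment(rec, cfg, seed = 9),
                         augment(rec, cfg, seed = 10)))
  expect_identical(eval_transform(rec, cfg), eval_transform(rec, cfg))
})

test_that("DICOM ingestion pipeline counts add up and never raises", {
  coh <- generate_cohort(9, 6, phantom_config(image_side = 128), seed = 51)
  d <- withr::local_tempdir()
  fx <- write_dicom_fixtures(coh, d, corrupt_fraction = 1 / 15,
                             undersized_fraction = 0.2, seed = 3)
  lookup <- stats::setNames(fx$manifest$label, fx$manifest$image_id)
  # drop one label to force a "missing label" rejection
  intact <- fx$manifest$image_id[fx$manifest$altered == "none"]
  lookup <- lookup[names(lookup) != intact[1]]
  res <- ingest_directory(d, lookup,
                          ingest_config(min_dim_threshold = 128,
                                        target_side = 64))
  rep <- res$report
  expect_equal(rep$scanned, 15L)
  expect_equal(rep$kept + rep$dropped_size + rep$rejected, rep$scanned)
  expect_equal(rep$rejected, 2L)   # 1 corrupt + 1 missing label
  expect_equal(rep$dropped_size, 3L)
  expect_equal(rep$kept, 10L)
  expect_setequal(names(rep$rejection_causes),
                  c("missing pixel array", "missing label"))
  expect_true(all(vapply(res$dataset$records, function(r)
    all(dim(r$pixels) == c(64L, 64L)), logical(1))))
})

test_that("load_dicom rescales stored bit range to the unit interval", {
  d <- withr::local_tempdir()
  px <- matrix(c(0, 0.5, 1, 0.25), 2, 2)
  p <- file.path(d, "r.dcm")
  write_dicom_gray(px, p, "r")
  rec <- load_dicom(p, c(r = "normal"))
  expect_s3_class(rec, "image_record")
  expect_equal(max(rec$pixels), 1.0)
  expect_equal(min(rec$pixels), 0.0)

  writeLines("not dicom at all", file.path(d, "bad.dcm"))
  rej <- load_dicom(file.path(d, "bad.dcm"), c(r = "normal"))
  expect_s3_class(rej, "ingest_rejection")
  expect_equal(rej$cause, "unparseable")
})
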