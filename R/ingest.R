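# DICOM ingestion: extraction with structured rejection, center square
# crop, size filter, nearest-neighbour resize, stratified splitting, and
# the classifier-side augmentation/normalization transforms.

#' Ingestion configuration
#'
#' @param min_dim_threshold images whose smallest dimension is below
#'   this many pixels are dropped (strict inequality).
#' @param target_side side of the square output after nearest-neighbour
#'   resize.
#' @param split_fraction train fraction of the train/test split.
#' @param split_seed seed for the split.
#' @param stratified if `TRUE`, split each stratum separately.
#' @param stratify_by `"binary"` (default) strata are the
#'   normal/abnormal status (lesion categories collapse to
#'   "abnormal"); `"label"` strata are the raw record labels.
#' @return an object of class `ingest_config`.
#' @export
ingest_config <- function(min_dim_threshold = 128, target_side = 256,
                          split_fraction = 0.8, split_seed = 1L,
                          stratified = TRUE,
                          stratify_by = c("binary", "label")) {
  stratify_by <- match.arg(stratify_by)
  stopifnot(split_fraction > 0, split_fraction < 1,
            min_dim_threshold >= 1, target_side >= 1)
  structure(list(min_dim_threshold = as.integer(min_dim_threshold),
                 target_side = as.integer(target_side),
                 split_fraction = split_fraction,
                 split_seed = as.integer(split_seed),
                 stratified = isTRUE(stratified),
                 stratify_by = stratify_by),
            class = "ingest_config")
}

#' Augmentation and normalization configuration
#'
#' The classifier-side transform chain: random horizontal flip, random
#' rotation, random resized crop, resize, grayscale-to-3-channel
#' replication, then per-channel standardization.
#'
#' @param hflip_probability probability of a horizontal flip.
#' @param rotation_range maximal absolute rotation in degrees (the angle
#'   is uniform on `[-rotation_range, rotation_range]`).
#' @param rrc_scale length-2 interval of the crop area fraction.
#' @param rrc_ratio length-2 interval of the crop aspect ratio.
#' @param resize_side output side in pixels.
#' @param norm_mean,norm_sd per-channel normalization constants.
#' @return an object of class `augment_config`.
#' @export
augment_config <- function(hflip_probability = 0.3, rotation_range = 5,
                           rrc_scale = c(0.8, 1.0), rrc_ratio = c(1.0, 1.0),
                           resize_side = 224,
                           norm_mean = c(0.485, 0.456, 0.406),
                           norm_sd = c(0.229, 0.224, 0.225)) {
  stopifnot(hflip_probability >= 0, hflip_probability <= 1,
            length(rrc_scale) == 2, all(rrc_scale > 0), all(rrc_scale <= 1),
            diff(rrc_scale) >= 0, length(rrc_ratio) == 2,
            all(rrc_ratio > 0), length(norm_mean) == 3,
            length(norm_sd) == 3, all(norm_sd > 0), rotation_range >= 0)
  structure(list(hflip_probability = hflip_probability,
                 rotation_range = rotation_range, rrc_scale = rrc_scale,
                 rrc_ratio = rrc_ratio, resize_side = as.integer(resize_side),
                 norm_mean = norm_mean, norm_sd = norm_sd),
            class = "augment_config")
}

#' Center square crop
#'
#' Crops the largest centered square: output side is the smaller image
#' dimension; for odd margins the window is top/left-biased
#' (offset = `floor(margin / 2)`).
#'
#' @param pixels non-empty numeric matrix.
#' @return square numeric matrix.
#' @export
center_square_crop <- function(pixels) {
  stopifnot(is.matrix(pixels), nrow(pixels) >= 1, ncol(pixels) >= 1)
  s <- min(dim(pixels))
  r0 <- floor((nrow(pixels) - s) / 2)
  c0 <- floor((ncol(pixels) - s) / 2)
  pixels[(r0 + 1L):(r0 + s), (c0 + 1L):(c0 + s), drop = FALSE]
}

#' Nearest-neighbour resize
#'
#' Square-to-square resize with the canonical index map
#' `src = floor(i * src_side / target_side)` (0-based), so every output
#' value equals some input value.
#'
#' @param pixels square numeric matrix.
#' @param target_side output side in pixels.
#' @return `target_side x target_side` matrix.
#' @export
resize_nearest <- function(pixels, target_side) {
  stopifnot(is.matrix(pixels), nrow(pixels) == ncol(pixels),
            target_side >= 1)
  src <- nrow(pixels)
  idx <- floor((seq_len(target_side) - 1L) * src / target_side) + 1L
  pixels[idx, idx, drop = FALSE]
}

# general (possibly rectangular) nearest resize, used by augmentation
resize_nearest_rect <- function(pixels, out_rows, out_cols) {
  ri <- floor((seq_len(out_rows) - 1L) * nrow(pixels) / out_rows) + 1L
  ci <- floor((seq_len(out_cols) - 1L) * ncol(pixels) / out_cols) + 1L
  pixels[ri, ci, drop = FALSE]
}

#' Load one DICOM file
#'
#' Extracts the pixel array and looks up the abnormality label by image
#' ID.  Never raises on bad files: failures produce a rejection record
#' with a cause among `"unparseable"`, `"missing pixel array"`,
#' `"missing label"`.
#'
#' @param path DICOM file path.
#' @param label_lookup named character vector (or data frame with
#'   columns `image_id`, `label`) mapping image ID to label.
#' @return an [image_record()] (pixels rescaled to `[0, 1]` from the
#'   stored bit range, MONOCHROME1 inverted) or an `ingest_rejection`.
#' @export
load_dicom <- function(path, label_lookup) {
  if (is.data.frame(label_lookup)) {
    label_lookup <- stats::setNames(as.character(label_lookup$label),
                                    label_lookup$image_id)
  }
  reject <- function(cause, image_id = NA_character_) {
    structure(list(path = path, image_id = image_id, cause = cause),
              class = "ingest_rejection")
  }
  parsed <- tryCatch(read_dicom_gray(path), error = function(e) NULL)
  if (is.null(parsed)) return(reject("unparseable"))
  if (is.null(parsed$pixels)) {
    return(reject("missing pixel array", parsed$image_id %||% NA_character_))
  }
  id <- parsed$image_id
  if (is.null(id) || !id %in% names(label_lookup)) {
    return(reject("missing label", id %||% NA_character_))
  }
  image_record(clamp01(parsed$pixels), id, unname(label_lookup[id]),
               provenance = "real")
}

#' Filter records by minimum dimension
#'
#' Keeps records whose smallest pixel dimension is at least `threshold`
#' (images strictly below are dropped).
#'
#' @param records a [labeled_dataset()].
#' @param threshold pixels.
#' @return list with `kept` (a `labeled_dataset`) and `dropped` (a data
#'   frame of image_id, min_dim, reason).
#' @export
apply_size_filter <- function(records, threshold = 128) {
  min_dims <- vapply(records$records, function(r) min(dim(r$pixels)),
                     numeric(1))
  keep <- min_dims >= threshold
  dropped <- data.frame(
    image_id = vapply(records$records[!keep], function(r) r$image_id,
                      character(1)),
    min_dim = min_dims[!keep],
    reason = sprintf("min dimension %d < %d", as.integer(min_dims[!keep]),
                     as.integer(threshold)),
    stringsAsFactors = FALSE
  )
  list(kept = records[keep], dropped = dropped)
}

#' Train/test split
#'
#' Seeded random split.  When stratified, each stratum (the binary
#' abnormality status by default, see [ingest_config()]) is split
#' separately with train count `floor(split_fraction * n_class + 0.5)`,
#' so the per-class train fraction is within one record of
#' `split_fraction`.
#'
#' @param dataset a [labeled_dataset()].
#' @param cfg an [ingest_config()].
#' @return list with `train` and `test` datasets (split tags set).
#' @export
split_dataset <- function(dataset, cfg = ingest_config()) {
  labs <- dataset_labels(dataset)
  if (identical(cfg$stratify_by %||% "binary", "binary")) {
    labs <- collapse_binary(labs, BINARY_CLASSES)
  }
  n <- length(dataset)
  idx_train <- integer(0)
  with_seed(cfg$split_seed, {
    if (cfg$stratified) {
      for (cl in unique(labs)) {
        members <- which(labs == cl)
        if (length(members) < 2L) {
          stop(sprintf("class '%s' has fewer than 2 members; cannot stratify",
                       cl))
        }
        n_tr <- floor(cfg$split_fraction * length(members) + 0.5)
        n_tr <- min(max(n_tr, 1L), length(members) - 1L)
        idx_train <- c(idx_train, sample(members, n_tr))
      }
    } else {
      n_tr <- floor(cfg$split_fraction * n + 0.5)
      n_tr <- min(max(n_tr, 1L), n - 1L)
      idx_train <- sample.int(n, n_tr)
    }
  })
  idx_train <- sort(idx_train)
  train <- dataset[idx_train]
  test <- dataset[setdiff(seq_len(n), idx_train)]
  train$split <- rep("train", length(train))
  test$split <- rep("test", length(test))
  list(train = train, test = test)
}

# rotate by `angle` degrees about the image center, nearest-neighbour
# sampling, out-of-range source pixels filled with `fill`
rotate_nearest <- function(pixels, angle, fill = 0) {
  if (angle == 0) return(pixels)
  h <- nrow(pixels); w <- ncol(pixels)
  th <- angle * pi / 180
  cy <- (h + 1) / 2; cx <- (w + 1) / 2
  ro <- rep(seq_len(h), times = w) - cy
  co <- rep(seq_len(w), each = h) - cx
  # inverse map: source = R(-theta) applied to output coordinates
  sr <- round(cos(th) * ro - sin(th) * co + cy)
  sc <- round(sin(th) * ro + cos(th) * co + cx)
  ok <- sr >= 1 & sr <= h & sc >= 1 & sc <= w
  out <- rep(fill, h * w)
  out[ok] <- pixels[cbind(sr[ok], sc[ok])]
  matrix(out, h, w)
}

#' Training-time augmentation transform
#'
#' Applies, in order: random horizontal flip, random rotation, random
#' resized crop, nearest resize to `resize_side`, grayscale-to-3-channel
#' replication, and per-channel standardization
#' `(x - norm_mean[c]) / norm_sd[c]`.  Deterministic under `seed`.
#'
#' @param record an [image_record()] (or a numeric matrix in `[0, 1]`).
#' @param cfg an [augment_config()].
#' @param seed integer seed.
#' @return `resize_side x resize_side x 3` numeric array.
#' @export
augment <- function(record, cfg = augment_config(), seed = 1L) {
  px <- if (inherits(record, "image_record")) record$pixels else record
  stopifnot(is.matrix(px), min(px) >= 0, max(px) <= 1)
  with_seed(seed, {
    if (stats::runif(1) < cfg$hflip_probability) {
      px <- px[, rev(seq_len(ncol(px))), drop = FALSE]
    }
    if (cfg$rotation_range > 0) {
      px <- rotate_nearest(px, stats::runif(1, -cfg$rotation_range,
                                            cfg$rotation_range))
    }
    if (cfg$rrc_scale[1] < 1 || cfg$rrc_ratio[1] != 1 ||
        cfg$rrc_ratio[2] != 1) {
      area <- nrow(px) * ncol(px) *
        stats::runif(1, cfg$rrc_scale[1], cfg$rrc_scale[2])
      ratio <- stats::runif(1, cfg$rrc_ratio[1], cfg$rrc_ratio[2])
      ch <- min(nrow(px), max(1L, round(sqrt(area / ratio))))
      cw <- min(ncol(px), max(1L, round(sqrt(area * ratio))))
      r0 <- sample.int(nrow(px) - ch + 1L, 1L) - 1L
      c0 <- sample.int(ncol(px) - cw + 1L, 1L) - 1L
      px <- px[(r0 + 1L):(r0 + ch), (c0 + 1L):(c0 + cw), drop = FALSE]
    }
    px <- resize_nearest_rect(px, cfg$resize_side, cfg$resize_side)
    out <- array(0, dim = c(cfg$resize_side, cfg$resize_side, 3L))
    for (ch in 1:3) {
      out[, , ch] <- (px - cfg$norm_mean[ch]) / cfg$norm_sd[ch]
    }
    out
  })
}

#' Evaluation-time transform
#'
#' Resize to `resize_side`, replicate to 3 channels, standardize.  No
#' random components.
#'
#' @inheritParams augment
#' @return `resize_side x resize_side x 3` numeric array.
#' @export
eval_transform <- function(record, cfg = augment_config()) {
  px <- if (inherits(record, "image_record")) record$pixels else record
  px <- resize_nearest_rect(px, cfg$resize_side, cfg$resize_side)
  out <- array(0, dim = c(cfg$resize_side, cfg$resize_side, 3L))
  for (ch in 1:3) {
    out[, , ch] <- (px - cfg$norm_mean[ch]) / cfg$norm_sd[ch]
  }
  out
}

#' Read an image-label table
#'
#' Delimited text with columns `image_id` and `label` (and optionally
#' `category`); returns a named character vector keyed by image ID.
#'
#' @param path file path.
#' @param sep field separator (default tab).
#' @return named character vector.
#' @export
read_label_table <- function(path, sep = "\t") {
  tab <- utils::read.table(path, header = TRUE, sep = sep,
                           stringsAsFactors = FALSE)
  stopifnot(all(c("image_id", "label") %in% names(tab)))
  stats::setNames(as.character(tab$label), tab$image_id)
}

#' Ingest a directory of DICOM radiographs
#'
#' Full preprocessing pipeline: load each file (structured rejection on
#' corrupt files), center square crop, minimum-dimension filter,
#' nearest-neighbour resize to `cfg$target_side`.  Never raises on bad
#' files; `kept + dropped + rejected` always equals the number of files
#' scanned.
#'
#' @param directory directory scanned for `*.dcm` files.
#' @param label_lookup mapping image ID to label (named vector or data
#'   frame).
#' @param cfg an [ingest_config()].
#' @param classes optional class inventory for the resulting dataset.
#' @return list with `dataset` (a [labeled_dataset()]), and `report`
#'   (counts: scanned, kept, dropped_size, rejected; cause tables).
#' @export
ingest_directory <- function(directory, label_lookup, cfg = ingest_config(),
                             classes = NULL) {
  files <- sort(list.files(directory, pattern = "\\.dcm$",
                           full.names = TRUE))
  records <- list()
  rejections <- list()
  for (f in files) {
    r <- load_dicom(f, label_lookup)
    if (inherits(r, "ingest_rejection")) {
      rejections[[length(rejections) + 1L]] <- r
    } else {
      r$pixels <- center_square_crop(r$pixels)
      records[[length(records) + 1L]] <- r
    }
  }
  ds <- labeled_dataset(records, classes = classes)
  filt <- apply_size_filter(ds, cfg$min_dim_threshold)
  kept <- filt$kept
  for (i in seq_along(kept$records)) {
    kept$records[[i]]$pixels <-
      resize_nearest(kept$records[[i]]$pixels, cfg$target_side)
  }
  report <- list(
    scanned = length(files),
    kept = length(kept),
    dropped_size = nrow(filt$dropped),
    rejected = length(rejections),
    rejection_causes = table(vapply(rejections, function(r) r$cause,
                                    character(1))),
    dropped = filt$dropped
  )
  stopifnot(report$kept + report$dropped_size + report$rejected ==
              report$scanned)
  list(dataset = kept, report = report)
}
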