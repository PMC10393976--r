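# Conditional synthesis of labeled synthetic datasets, with the two
# quality filters: latent thresholding near the center of the noise
# distribution, and an optional in-domain realism filter.

#' Sampling configuration
#'
#' @param n_images number of synthetic images to produce.
#' @param class_scheme `"match_real_prior"` (largest-remainder rounding
#'   of the real training prior), `"balanced"`, or a named integer
#'   vector of explicit per-class counts summing to `n_images`.
#' @param latent_r latent threshold: accepted noise vectors satisfy
#'   `||z|| <= latent_r * sqrt(latent_dim)` (`NULL` disables).  The
#'   radius is parameterized relative to the chi mean scale so the
#'   multiplier is dimension-free; 1.0 keeps roughly the central half
#'   of draws.
#' @param realism_filter optional list `list(state = <classifier
#'   network_state>, threshold = <probability>)`: generated images whose
#'   in-domain probability falls below the threshold are rejected and
#'   regenerated.
#' @param seed integer seed.
#' @param max_attempts rejection-sampling budget as a multiple of the
#'   requested count.
#' @return an object of class `sampling_config`.
#' @export
sampling_config <- function(n_images, class_scheme = "match_real_prior",
                            latent_r = NULL, realism_filter = NULL,
                            seed = 1L, max_attempts = 100L) {
  stopifnot(n_images >= 1, max_attempts >= 1)
  if (!is.null(latent_r)) stopifnot(is.numeric(latent_r))
  if (!is.null(realism_filter)) {
    stopifnot(is.list(realism_filter),
              inherits(realism_filter$state, "network_state"),
              realism_filter$threshold >= 0, realism_filter$threshold <= 1)
  }
  structure(list(n_images = as.integer(n_images),
                 class_scheme = class_scheme, latent_r = latent_r,
                 realism_filter = realism_filter, seed = as.integer(seed),
                 max_attempts = as.integer(max_attempts)),
            class = "sampling_config")
}

#' Sample latent vectors with optional thresholding
#'
#' Rows are standard-normal draws.  With `r` set, rejection sampling
#' keeps only vectors with `||z|| <= r * sqrt(latent_dim)` until `n`
#' rows are accepted.  Deterministic under `seed`.
#'
#' @param n number of vectors (at least 1).
#' @param latent_dim vector dimension.
#' @param r threshold multiplier or `NULL` for no thresholding.
#' @param seed integer seed.
#' @param max_attempts budget: more than `max_attempts * n` proposals
#'   raises an error reporting the empirical acceptance rate.
#' @return `n x latent_dim` numeric matrix.
#' @export
sample_latents <- function(n, latent_dim, r = NULL, seed = 1L,
                           max_attempts = 100L) {
  stopifnot(n >= 1, latent_dim >= 1)
  with_seed(seed, {
    if (is.null(r)) {
      return(matrix(stats::rnorm(n * latent_dim), n))
    }
    if (r <= 0) {
      stop("latent threshold r = ", r,
           ": acceptance region is empty, no vector can be accepted")
    }
    radius <- r * sqrt(latent_dim)
    accepted <- matrix(numeric(0), 0L, latent_dim)
    proposed <- 0
    while (nrow(accepted) < n) {
      if (proposed > max_attempts * n) {
        stop(sprintf(
          "latent rejection sampling exceeded %d proposals (empirical acceptance rate %.4f)",
          as.integer(max_attempts * n), nrow(accepted) / proposed))
      }
      chunk <- max(n - nrow(accepted), 64L)
      z <- matrix(stats::rnorm(chunk * latent_dim), chunk)
      proposed <- proposed + chunk
      keep <- sqrt(rowSums(z^2)) <= radius
      if (any(keep)) accepted <- rbind(accepted, z[keep, , drop = FALSE])
    }
    accepted[seq_len(n), , drop = FALSE]
  })
}

# largest-remainder apportionment of n into parts proportional to w
largest_remainder <- function(w, n) {
  quota <- w / sum(w) * n
  base <- floor(quota)
  left <- n - sum(base)
  if (left > 0) {
    extra <- order(quota - base, decreasing = TRUE)[seq_len(left)]
    base[extra] <- base[extra] + 1
  }
  as.integer(base)
}

resolve_class_counts <- function(scheme, classes, n_images, prior_counts) {
  K <- length(classes)
  if (is.character(scheme) && length(scheme) == 1L) {
    if (scheme == "balanced") {
      return(stats::setNames(largest_remainder(rep(1, K), n_images),
                             classes))
    }
    if (scheme == "match_real_prior") {
      if (is.null(prior_counts)) {
        stop("match_real_prior needs the real training class counts")
      }
      return(stats::setNames(largest_remainder(prior_counts[classes],
                                               n_images), classes))
    }
    stop("unknown class scheme: ", scheme)
  }
  counts <- scheme
  stopifnot(setequal(names(counts), classes), sum(counts) == n_images)
  stats::setNames(as.integer(counts[classes]), classes)
}

#' Realism filter
#'
#' Applies an in-domain/out-of-domain classifier to images and keeps
#' those whose in-domain probability is at least `threshold`.
#' Probabilities are clamped to `[1e-7, 1 - 1e-7]`, so a threshold of 0
#' accepts everything and a threshold of 1 rejects everything.
#'
#' @param images images in any accepted form.
#' @param filter_state classifier `network_state` trained to emit the
#'   in-domain probability (its positive class).
#' @param threshold acceptance threshold in `[0, 1]`.
#' @return logical mask, `TRUE` where in-domain probability >= threshold.
#' @export
realism_filter <- function(images, filter_state, threshold = 0.5) {
  p <- clamp_prob(predict_probabilities(filter_state, images))
  if (is.matrix(p)) p <- p[, 1L]   # in-domain = first class
  p >= threshold
}

#' Generate a labeled synthetic dataset
#'
#' Draws latents (optionally thresholded), generates images conditioned
#' on each class, and (optionally) applies the realism filter, topping
#' up rejected images until the requested per-class counts are met
#' exactly.  Latent thresholding never changes the class counts.
#'
#' @param gen a [train_gan()] fit or a generator `network_state`.
#' @param cfg a [sampling_config()].
#' @param prior a [labeled_dataset()] or named counts supplying the real
#'   class prior (required by `class_scheme = "match_real_prior"` when
#'   `gen` is a bare state; fits carry their training counts).
#' @return a [labeled_dataset()] of exactly `cfg$n_images` records with
#'   provenance `"synthetic"`, each labeled with its conditioning class.
#' @export
generate_synthetic_dataset <- function(gen, cfg, prior = NULL) {
  if (inherits(gen, "cgan_fit")) {
    prior_counts <- gen$class_counts
    gen <- gen$generator
  } else {
    prior_counts <- NULL
  }
  stopifnot(inherits(gen, "network_state"), gen$role == "generator")
  classes <- gen$meta$classes
  if (!is.null(prior)) {
    if (inherits(prior, "labeled_dataset")) {
      idx <- dataset_class_index(prior, classes)
      prior_counts <- stats::setNames(
        tabulate(idx, nbins = length(classes)), classes)
    } else {
      prior_counts <- prior
    }
  }
  counts <- resolve_class_counts(cfg$class_scheme, classes, cfg$n_images,
                                 prior_counts)
  side <- gen$meta$image_side
  latent_dim <- gen$meta$latent_dim
  records <- vector("list", cfg$n_images)
  pos <- 1L
  serial <- 1L
  for (k in seq_along(classes)) {
    need <- counts[k]
    attempts <- 0L
    while (need > 0L) {
      if (attempts > cfg$max_attempts) {
        stop(sprintf(
          "realism filter rejected too many images for class '%s' (%d attempts, %d still missing)",
          classes[k], attempts, need))
      }
      z <- sample_latents(need, latent_dim, r = cfg$latent_r,
                          seed = stage_seed(cfg$seed,
                                            sprintf("lat_%d_%d", k, attempts)),
                          max_attempts = cfg$max_attempts * 100L)
      X <- gen_forward_flat(gen, z, rep(k, need))
      keep <- rep(TRUE, need)
      if (!is.null(cfg$realism_filter)) {
        keep <- realism_filter(X, cfg$realism_filter$state,
                               cfg$realism_filter$threshold)
      }
      for (i in which(keep)) {
        records[[pos]] <- image_record(
          matrix(X[i, ], side, side),
          sprintf("syn_%s_%06d", classes[k], serial),
          classes[k], provenance = "synthetic")
        pos <- pos + 1L
        serial <- serial + 1L
      }
      need <- need - sum(keep)
      attempts <- attempts + 1L
    }
    serial <- 1L
  }
  labeled_dataset(records, classes = classes)
}

#' Write a synthetic dataset as image files
#'
#' 8-bit grayscale PNG files plus a tab-delimited label manifest
#' (image_id, path, label, provenance).
#'
#' @param dataset a [labeled_dataset()].
#' @param directory output directory (created if needed).
#' @return invisibly, the manifest data frame.
#' @export
write_image_dataset <- function(dataset, directory) {
  if (!dir.exists(directory)) {
    dir.create(directory, recursive = TRUE, showWarnings = FALSE)
  }
  paths <- character(length(dataset))
  for (i in seq_along(dataset$records)) {
    rec <- dataset$records[[i]]
    paths[i] <- file.path(directory, paste0(rec$image_id, ".png"))
    png::writePNG(rec$pixels, paths[i])
  }
  manifest <- data.frame(
    image_id = vapply(dataset$records, function(r) r$image_id, character(1)),
    path = paths, label = dataset_labels(dataset),
    provenance = vapply(dataset$records, function(r) r$provenance,
                        character(1)),
    stringsAsFactors = FALSE
  )
  utils::write.table(manifest, file.path(directory, "labels.tsv"),
                     sep = "\t", row.names = FALSE, quote = FALSE)
  invisible(manifest)
}
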