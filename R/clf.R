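# Downstream abnormality classifiers and the AUC endpoint.
#
# The backbone is a compact pooled dense network: non-overlapping
# average pooling shrinks the image, then fully-connected layers with a
# sigmoid (binary) or softmax (categorical) head.  Pooling is linear, so
# gradients pass through it exactly — which the classifier-guided
# generator loss relies on.

#' Classifier configuration
#'
#' Defaults follow the study design for classifier training: Adam with
#' learning rate 0.001 and batch size 32.  The epoch count is an upper
#' cap; training stops early when the epoch-mean loss plateaus
#' (`patience` epochs without improvement).
#'
#' @param backbone named architecture; `"pooled_mlp"` (the compact
#'   default) is currently provided.
#' @param hidden integer vector of hidden-layer widths.
#' @param pool average-pooling factor applied to the input image (must
#'   divide the input side).
#' @param learning_rate Adam learning rate.
#' @param batch_size minibatch size.
#' @param epochs hard cap on training epochs.
#' @param patience early-stop patience (epochs without loss improvement).
#' @param augment optional [augment_config()]; when supplied, training
#'   images pass through the augmentation chain (evaluation always uses
#'   the deterministic resize + normalize path).
#' @param seed integer seed.
#' @return an object of class `classifier_config`.
#' @export
classifier_config <- function(backbone = "pooled_mlp", hidden = c(128),
                              pool = 2L, learning_rate = 0.001,
                              batch_size = 32L, epochs = 12L, patience = 3L,
                              augment = NULL, seed = 1L) {
  stopifnot(identical(backbone, "pooled_mlp"), learning_rate > 0,
            batch_size >= 1, epochs >= 1, patience >= 1, pool >= 1)
  if (!is.null(augment)) stopifnot(inherits(augment, "augment_config"))
  structure(list(backbone = backbone, hidden = as.integer(hidden),
                 pool = as.integer(pool), learning_rate = learning_rate,
                 batch_size = as.integer(batch_size),
                 epochs = as.integer(epochs), patience = as.integer(patience),
                 augment = augment, seed = as.integer(seed)),
            class = "classifier_config")
}

# ---- network state container -----------------------------------------

#' Network state
#'
#' Opaque parameter container for a generator, discriminator, or
#' classifier, with serialization helpers.  `save_network_state` /
#' `load_network_state` round-trip the state so that forward passes
#' reproduce bit-identically.
#'
#' @param role one of `"generator"`, `"discriminator"`, `"classifier"`.
#' @param net internal parameter list.
#' @param meta role-specific metadata (class inventory, image side, ...).
#' @param step_count training steps taken.
#' @return an object of class `network_state`.
#' @export
network_state <- function(role = c("generator", "discriminator",
                                   "classifier"),
                          net, meta = list(), step_count = 0L) {
  role <- match.arg(role)
  structure(list(role = role, net = net, meta = meta,
                 step_count = as.integer(step_count)),
            class = "network_state")
}

#' @export
print.network_state <- function(x, ...) {
  cat(sprintf("<network_state: role=%s, layers=%s, steps=%d>\n", x$role,
              paste(x$net$sizes, collapse = "-"), x$step_count))
  invisible(x)
}

#' @rdname network_state
#' @param state a `network_state`.
#' @param path file path.
#' @export
save_network_state <- function(state, path) {
  stopifnot(inherits(state, "network_state"))
  saveRDS(state, path)
  invisible(path)
}

#' @rdname network_state
#' @export
load_network_state <- function(path) {
  state <- readRDS(path)
  stopifnot(inherits(state, "network_state"))
  state
}

# ---- pooling ----------------------------------------------------------

.pool_cache <- new.env(parent = emptyenv())

# side^2 x (side/p)^2 matrix averaging non-overlapping p x p blocks of a
# column-major-flattened image
pool_matrix <- function(side, p) {
  key <- paste0(side, "_", p)
  if (!is.null(.pool_cache[[key]])) return(.pool_cache[[key]])
  stopifnot(side %% p == 0)
  out_side <- side %/% p
  P <- matrix(0, side^2, out_side^2)
  rows <- rep(seq_len(side), times = side)
  cols <- rep(seq_len(side), each = side)
  src_block <- (ceiling(cols / p) - 1L) * out_side + ceiling(rows / p)
  P[cbind(seq_len(side^2), src_block)] <- 1 / p^2
  .pool_cache[[key]] <- P
  P
}

# ---- feature extraction ----------------------------------------------

# coerce dataset / array / list / matrix to an n x side^2 flat matrix
as_flat_images <- function(images) {
  if (inherits(images, "labeled_dataset")) return(dataset_pixel_matrix(images))
  if (is.array(images) && length(dim(images)) == 3L) {
    d <- dim(images)
    return(t(matrix(images, d[1] * d[2], d[3])))
  }
  if (is.list(images)) {
    return(t(vapply(images, as.numeric,
                    numeric(length(images[[1]])))))
  }
  stopifnot(is.matrix(images))
  images
}

# evaluation-path features for a classifier state
clf_features_eval <- function(state, X) {
  m <- state$meta
  if (is.null(m$augment)) {
    X %*% pool_matrix(m$input_side, m$pool)
  } else {
    rs <- m$augment$resize_side
    P <- pool_matrix(rs, m$pool)
    t(apply(X, 1L, function(row) {
      arr <- eval_transform(matrix(row, m$input_side, m$input_side),
                            m$augment)
      as.numeric(crossprod(P, matrix(arr, rs * rs, 3L)))
    }))
  }
}

# training-path features (augmented when configured); returns n x d
clf_features_train <- function(meta, X, seeds) {
  if (is.null(meta$augment)) {
    X %*% pool_matrix(meta$input_side, meta$pool)
  } else {
    rs <- meta$augment$resize_side
    P <- pool_matrix(rs, meta$pool)
    t(vapply(seq_len(nrow(X)), function(i) {
      arr <- augment(matrix(X[i, ], meta$input_side, meta$input_side),
                     meta$augment, seed = seeds[i])
      as.numeric(crossprod(P, matrix(arr, rs * rs, 3L)))
    }, numeric(3L * (rs %/% meta$pool)^2)))
  }
}

clf_feature_dim <- function(meta) {
  if (is.null(meta$augment)) {
    (meta$input_side %/% meta$pool)^2
  } else {
    3L * (meta$augment$resize_side %/% meta$pool)^2
  }
}

# ---- training ---------------------------------------------------------

softmax_rows <- function(A) {
  A <- A - apply(A, 1L, max)
  E <- exp(A)
  E / rowSums(E)
}

#' Train an abnormality classifier
#'
#' Binary (normal vs abnormal) by default; when `classes` has more than
#' two entries a softmax head over the full inventory is trained.
#' Training is seeded and deterministic for a given platform; the
#' augmentation chain (if configured) is applied during training only.
#'
#' @param train a [labeled_dataset()] containing every class in
#'   `classes` (single-class input is an error).
#' @param cfg a [classifier_config()].
#' @param classes class inventory; default binary.
#' @return a `network_state` with role `"classifier"`.
#' @export
train_classifier <- function(train, cfg = classifier_config(),
                             classes = NULL) {
  if (is.null(classes)) classes <- BINARY_CLASSES
  y_idx <- dataset_class_index(train, classes)
  if (length(unique(y_idx)) < 2L) {
    stop("training set contains a single class; need every class in: ",
         paste(classes, collapse = ", "))
  }
  X <- dataset_pixel_matrix(train)
  side <- as.integer(sqrt(ncol(X)))
  stopifnot(side * side == ncol(X))
  K <- length(classes)
  out_dim <- if (K == 2L) 1L else K
  meta <- list(input_side = side, pool = cfg$pool, classes = classes,
               out_dim = out_dim, augment = cfg$augment)
  d_feat <- clf_feature_dim(meta)
  n <- nrow(X)
  steps <- 0L
  loss_history <- numeric(0)
  with_seed(cfg$seed, {
    net <- nn_new(c(d_feat, cfg$hidden, out_dim),
                  seed = sample.int(2147483646L, 1L))
    opt <- adam_new(net)
    best <- Inf
    stall <- 0L
    for (epoch in seq_len(cfg$epochs)) {
      ord <- sample.int(n)
      aug_seeds <- sample.int(2147483646L, n)
      epoch_loss <- 0
      n_batch <- 0L
      for (start in seq(1L, n, by = cfg$batch_size)) {
        idx <- ord[start:min(start + cfg$batch_size - 1L, n)]
        Fb <- clf_features_train(meta, X[idx, , drop = FALSE],
                                 aug_seeds[idx])
        fwd <- nn_forward(net, Fb, cache = TRUE)
        m <- length(idx)
        if (out_dim == 1L) {
          yb <- as.numeric(y_idx[idx] == 2L)   # classes[2] is "abnormal"
          a <- fwd$out[, 1L]
          loss <- mean(softplus(a) - yb * a)
          dA <- matrix((sigmoid(a) - yb) / m, ncol = 1L)
        } else {
          Pr <- softmax_rows(fwd$out)
          loss <- -mean(log(clamp_prob(Pr[cbind(seq_len(m), y_idx[idx])])))
          Yb <- matrix(0, m, K)
          Yb[cbind(seq_len(m), y_idx[idx])] <- 1
          dA <- (Pr - Yb) / m
        }
        g <- nn_backward(net, fwd, dA)
        upd <- adam_step(opt, net, g, lr = cfg$learning_rate)
        opt <- upd$opt
        net <- upd$net
        epoch_loss <- epoch_loss + loss
        n_batch <- n_batch + 1L
        steps <- steps + 1L
      }
      epoch_loss <- epoch_loss / n_batch
      loss_history <- c(loss_history, epoch_loss)
      if (epoch_loss < best - 1e-4) {
        best <- epoch_loss
        stall <- 0L
      } else {
        stall <- stall + 1L
        if (stall >= cfg$patience) break
      }
    }
    meta$loss_history <- loss_history
    network_state("classifier", net, meta, step_count = steps)
  })
}

#' Predict abnormality probabilities
#'
#' Evaluation-mode transforms only (deterministic resize + normalize; no
#' flips, rotations, or random crops).
#'
#' @param state a classifier `network_state`.
#' @param images a [labeled_dataset()], an `n x side^2` matrix, a
#'   `side x side x n` array, or a list of matrices.
#' @return numeric vector of abnormality probabilities in `[0, 1]`
#'   (binary head), or an `n x K` matrix of class probabilities
#'   (softmax head).
#' @export
predict_probabilities <- function(state, images) {
  stopifnot(inherits(state, "network_state"), state$role == "classifier")
  X <- as_flat_images(images)
  if (nrow(X) == 0L) return(numeric(0))
  Fm <- clf_features_eval(state, X)
  A <- nn_forward(state$net, Fm)
  if (state$meta$out_dim == 1L) {
    as.numeric(sigmoid(A[, 1L]))
  } else {
    softmax_rows(A)
  }
}

#' @export
predict.network_state <- function(object, newdata, ...) {
  stopifnot(object$role == "classifier")
  predict_probabilities(object, newdata)
}

#' Area under the ROC curve
#'
#' Rank-based (Mann-Whitney) AUC: the probability that a random positive
#' outscores a random negative, ties counted half.
#'
#' @param scores numeric scores, higher = more positive.
#' @param labels binary labels (0/1, logical, or a factor with two
#'   levels where the second level is positive).
#' @return AUC in `[0, 1]`.
#' @export
auc <- function(scores, labels) {
  if (is.factor(labels)) labels <- as.integer(labels) - 1L
  labels <- as.integer(labels)
  stopifnot(length(scores) == length(labels), all(labels %in% c(0L, 1L)))
  n_pos <- sum(labels == 1L)
  n_neg <- sum(labels == 0L)
  if (n_pos == 0L) stop("no positive labels present")
  if (n_neg == 0L) stop("no negative labels present")
  r <- rank(scores)
  (sum(r[labels == 1L]) - n_pos * (n_pos + 1) / 2) / (n_pos * n_neg)
}

# ---- synthetic-learning experiment ------------------------------------

#' Synthetic-learning experiment
#'
#' The synthetic-learning endpoint: train the same classifier
#' configuration on real data and on each generator's synthetic data,
#' evaluate every arm by AUC on the one shared real test set, averaged
#' over seeds.  Synthetic data never enters a test set (asserted on
#' provenance tags).
#'
#' @param real_train,real_test [labeled_dataset()]s of real (or
#'   phantom) provenance.
#' @param generators named list of trained generators ([train_gan()]
#'   fits or generator `network_state`s); may also contain a
#'   `labeled_dataset` to act as a replay "oracle generator".
#' @param n_synthetic synthetic training images per generator arm.
#' @param cfg shared [classifier_config()] (identical across arms).
#' @param seeds integer vector of classifier/sampling seeds.
#' @param class_scheme synthetic class composition, see
#'   [sampling_config()]; default matches the real training prior.
#' @return an object of class `sl_experiment`: `$runs` (one row per arm
#'   and seed) and `$summary` (AUC mean and sd per arm).
#' @export
synthetic_learning_experiment <- function(real_train, real_test, generators,
                                          n_synthetic = 2000L,
                                          cfg = classifier_config(),
                                          seeds = 1:3,
                                          class_scheme = "match_real_prior") {
  stopifnot(all(vapply(real_test$records, function(r)
    r$provenance != "synthetic", logical(1))))
  y_test <- dataset_binary_labels(real_test)
  arms <- c("real", names(generators))
  rows <- list()
  for (seed in seeds) {
    for (arm in arms) {
      if (arm == "real") {
        train_ds <- real_train
      } else {
        g <- generators[[arm]]
        if (inherits(g, "labeled_dataset")) {
          train_ds <- g                       # replay oracle
        } else {
          scfg <- sampling_config(
            n_images = n_synthetic, class_scheme = class_scheme,
            seed = stage_seed(seed, paste0("sample_", arm))
          )
          train_ds <- generate_synthetic_dataset(g, scfg,
                                                 prior = real_train)
        }
      }
      cfg_run <- cfg
      cfg_run$seed <- stage_seed(seed, paste0("clf_", arm))
      clf <- train_classifier(train_ds, cfg_run)
      p <- predict_probabilities(clf, real_test)
      rows[[length(rows) + 1L]] <- data.frame(
        arm = arm, seed = seed, auc = auc(p, y_test),
        n_train = length(train_ds), n_test = length(real_test),
        stringsAsFactors = FALSE
      )
    }
  }
  runs <- do.call(rbind, rows)
  agg <- do.call(rbind, lapply(split(runs, runs$arm), function(d) {
    data.frame(arm = d$arm[1], auc_mean = mean(d$auc),
               auc_sd = stats::sd(d$auc), n_seeds = nrow(d),
               stringsAsFactors = FALSE)
  }))
  agg <- agg[match(arms, agg$arm), ]
  rownames(agg) <- NULL
  structure(list(runs = runs, summary = agg), class = "sl_experiment")
}

#' @export
print.sl_experiment <- function(x, ...) {
  cat("Synthetic-learning experiment (AUC on shared real test set)\n")
  print(x$summary, row.names = FALSE)
  invisible(x)
}
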