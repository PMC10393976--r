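# Conditional GAN training with two generator-loss variants.
#
# The plain variant uses the non-saturating conditional loss
# -log sigma(D(x, c)).  The SpineGAN variant adds, with weight gamma, a
# cross-entropy term from a frozen pretrained abnormality classifier S,
# pushing generated images to carry the clinical features of their
# conditioning label.  The discriminator trains on the softplus form of
# the same game with an (optionally lazy) R1 gradient penalty on real
# images.

#' GAN configuration
#'
#' @param latent_dim dimension of the latent noise vector.
#' @param n_classes number of conditioning classes (at least 2; 2 means
#'   the binary normal/abnormal task).
#' @param image_side generated image side in pixels.
#' @param gamma non-negative weight of the classifier-guidance term;
#'   `gamma = 0` reduces the SpineGAN loss to the plain loss exactly.
#' @param batch_size minibatch size m.
#' @param lr_g,lr_d Adam learning rates for generator/discriminator.
#' @param beta1,beta2 Adam moment decays.
#' @param mismatch_weight weight of the matching-aware discriminator
#'   term (real images paired with wrong labels scored as fake);
#'   0 disables it.
#' @param r1_weight R1 gradient-penalty weight on real images.
#' @param r1_interval apply the penalty every this many discriminator
#'   steps, scaled by the interval (lazy regularization).
#' @param ema_decay exponential-moving-average decay for the generator
#'   weights used at sampling time.  The default 1 disables averaging,
#'   which is the right choice at short desk-scale budgets (the average
#'   otherwise spans the still-improving trajectory); long runs can set
#'   e.g. 0.999.
#' @param total_images_shown training budget counted in real images
#'   shown to the discriminator.
#' @param g_hidden,d_hidden hidden-layer widths.
#' @param literal_printed_loss reproduce the literal printed sign of the
#'   guidance term instead of standard cross-entropy (see
#'   [spinegan_generator_loss()]).
#' @param log_interval history logging interval in steps.
#' @param seed integer seed.
#' @return an object of class `gan_config`.
#' @export
gan_config <- function(latent_dim = 64L, n_classes = 2L, image_side = 64L,
                       gamma = 1.0, batch_size = 32L, lr_g = 3e-4,
                       lr_d = 3e-4, beta1 = 0.5, beta2 = 0.999,
                       mismatch_weight = 1.0, r1_weight = 5, r1_interval = 8L,
                       ema_decay = 1.0, total_images_shown = 50000L,
                       g_hidden = c(128L, 512L), d_hidden = c(256L, 64L),
                       literal_printed_loss = FALSE, log_interval = 50L,
                       seed = 1L) {
  stopifnot(gamma >= 0, n_classes >= 2, latent_dim >= 1, batch_size >= 1,
            mismatch_weight >= 0, r1_weight >= 0, r1_interval >= 1,
            lr_g > 0, lr_d > 0, ema_decay > 0, ema_decay <= 1,
            total_images_shown >= batch_size)
  structure(list(latent_dim = as.integer(latent_dim),
                 n_classes = as.integer(n_classes),
                 image_side = as.integer(image_side), gamma = gamma,
                 batch_size = as.integer(batch_size), lr_g = lr_g,
                 lr_d = lr_d, beta1 = beta1, beta2 = beta2,
                 mismatch_weight = mismatch_weight,
                 r1_weight = r1_weight, r1_interval = as.integer(r1_interval),
                 ema_decay = ema_decay,
                 total_images_shown = as.double(total_images_shown),
                 g_hidden = as.integer(g_hidden),
                 d_hidden = as.integer(d_hidden),
                 literal_printed_loss = isTRUE(literal_printed_loss),
                 log_interval = as.integer(log_interval),
                 seed = as.integer(seed)),
            class = "gan_config")
}

#' Latent batch
#'
#' A matrix of noise vectors paired with their condition labels: the
#' generator's input contract.
#'
#' @param z `m x latent_dim` numeric matrix.
#' @param labels length-m condition labels (class names or 1-based
#'   indices into the generator's class inventory).
#' @return an object of class `latent_batch`.
#' @export
latent_batch <- function(z, labels) {
  if (!is.matrix(z)) z <- matrix(z, nrow = length(labels))
  stopifnot(nrow(z) == length(labels))
  structure(list(z = z, labels = labels), class = "latent_batch")
}

onehot <- function(idx, K) {
  Y <- matrix(0, length(idx), K)
  if (length(idx)) Y[cbind(seq_along(idx), idx)] <- 1
  Y
}

resolve_labels <- function(labels, classes) {
  if (is.numeric(labels)) {
    idx <- as.integer(labels)
  } else {
    labs <- collapse_binary(as.character(labels), classes)
    idx <- match(labs, classes)
  }
  if (length(idx) && (anyNA(idx) || any(idx < 1 | idx > length(classes)))) {
    stop("labels outside the generator's class inventory: ",
         paste(classes, collapse = ", "))
  }
  idx
}

# flat generator pass: returns m x side^2 images in [0,1] (sigmoid
# output) plus the cache needed for backprop.  Conditioning enters
# twice: the one-hot label is concatenated to the latent input, and a
# learned per-class template (net$E, K x side^2) is added to the output
# pre-activation, so class-mean structure does not have to be carried
# through the dense trunk.
gen_forward_flat <- function(state, z, idx, cache = FALSE) {
  K <- length(state$meta$classes)
  if (ncol(z) != state$meta$latent_dim) {
    stop(sprintf("latent dimension mismatch: expected %d, got %d",
                 state$meta$latent_dim, ncol(z)))
  }
  inp <- cbind(z, onehot(idx, K))
  fwd <- nn_forward(state$net, inp, cache = TRUE)
  pre <- fwd$out
  if (!is.null(state$net$E)) {
    pre <- pre + state$net$E[idx, , drop = FALSE]
  }
  if (cache) {
    fwd$X <- sigmoid(pre)
    fwd$idx <- idx
    fwd
  } else {
    sigmoid(pre)
  }
}

#' Generator forward pass
#'
#' Maps a latent batch to images with values in `[0, 1]` (bounded
#' sigmoid output).  Deterministic given `(state, batch)`.
#'
#' @param state a generator `network_state` (or a [train_gan()] fit).
#' @param batch a [latent_batch()].
#' @return `side x side x m` numeric array.
#' @export
generator_forward <- function(state, batch) {
  if (inherits(state, "cgan_fit")) state <- state$generator
  stopifnot(inherits(state, "network_state"), state$role == "generator",
            inherits(batch, "latent_batch"))
  side <- state$meta$image_side
  m <- nrow(batch$z)
  if (m == 0L) return(array(numeric(0), dim = c(side, side, 0L)))
  idx <- resolve_labels(batch$labels, state$meta$classes)
  X <- gen_forward_flat(state, batch$z, idx)
  array(t(X), dim = c(side, side, m))
}

# ---- projection discriminator -----------------------------------------
#
# The discriminator scores the image through the dense trunk and adds a
# class-conditional projection term: logit = psi(phi(x)) + e_c . phi(x),
# where phi is the penultimate activation and e_c a learned per-class
# embedding.  The inner product couples the label to the image features
# directly, which makes conditioning pressure much stronger than
# concatenating a one-hot vector to thousands of pixels.

# forward on flat images; returns logits and (optionally) the cache
disc_forward_flat <- function(net, X, idx, cache = FALSE) {
  fwd <- nn_forward(net, X, cache = TRUE)
  nl <- length(net$W)
  h <- fwd$H[[nl]]
  logits <- fwd$out[, 1L] + rowSums(h * net$E[idx, , drop = FALSE])
  if (!cache) return(logits)
  fwd$logits <- logits
  fwd$idx <- idx
  fwd
}

# reverse pass from d loss / d logit; returns W/b/E grads and dX
disc_backward <- function(net, fwd, dlogit) {
  nl <- length(net$W)
  idx <- fwd$idx
  K <- nrow(net$E)
  h <- fwd$H[[nl]]
  delta <- matrix(dlogit, ncol = 1L)
  gW <- vector("list", nl)
  gb <- vector("list", nl)
  gW[[nl]] <- crossprod(h, delta)
  gb[[nl]] <- colSums(delta)
  gE <- crossprod(onehot(idx, K) * dlogit, h)
  dH <- tcrossprod(delta, net$W[[nl]]) +
    net$E[idx, , drop = FALSE] * dlogit
  for (l in rev(seq_len(nl - 1L))) {
    delta <- dH * lrelu_grad(fwd$A[[l]])
    gW[[l]] <- crossprod(fwd$H[[l]], delta)
    gb[[l]] <- colSums(delta)
    dH <- tcrossprod(delta, net$W[[l]])
  }
  list(W = gW, b = gb, E = gE, dX = dH)
}

# R1 penalty (mean squared input-gradient norm of the logit) and its
# exact parameter gradient for the projection discriminator
disc_r1 <- function(net, fwd) {
  nl <- length(net$W)
  idx <- fwd$idx
  K <- nrow(net$E)
  n <- nrow(fwd$H[[1L]])
  # per-sample gradient at the penultimate activation
  V <- matrix(net$W[[nl]][, 1L], n, length(net$b[[nl - 1L]]),
              byrow = TRUE) + net$E[idx, , drop = FALSE]
  R <- vector("list", nl - 1L)       # R[[l]] = d logit / d A_l
  R[[nl - 1L]] <- V * lrelu_grad(fwd$A[[nl - 1L]])
  if (nl > 2L) {
    for (l in rev(seq_len(nl - 2L))) {
      R[[l]] <- tcrossprod(R[[l + 1L]], net$W[[l + 1L]]) *
        lrelu_grad(fwd$A[[l]])
    }
  }
  G <- tcrossprod(R[[1L]], net$W[[1L]])
  penalty <- sum(G^2) / n
  U <- (2 / n) * G
  gW <- vector("list", nl)
  gb <- lapply(net$b, function(b) b * 0)
  gW[[1L]] <- crossprod(U, R[[1L]])
  S <- U %*% net$W[[1L]]
  if (nl > 2L) {
    for (l in 2:(nl - 1L)) {
      Tm <- S * lrelu_grad(fwd$A[[l - 1L]])
      gW[[l]] <- crossprod(Tm, R[[l]])
      S <- Tm %*% net$W[[l]]
    }
  }
  T_top <- S * lrelu_grad(fwd$A[[nl - 1L]])
  gW[[nl]] <- matrix(colSums(T_top), ncol = 1L)
  gE <- crossprod(onehot(idx, K), T_top)
  list(penalty = penalty, W = gW, b = gb, E = gE)
}

#' Discriminator forward pass
#'
#' Returns pre-sigmoid logits (the sigmoid is applied inside the
#' losses).  The score is class-conditional: the dense trunk's output
#' plus the inner product of the class embedding with the penultimate
#' features.
#'
#' @param state a discriminator `network_state`.
#' @param images images in any form accepted by the package (`side x
#'   side x m` array, `m x side^2` matrix, list of matrices, or a
#'   [labeled_dataset()]).
#' @param labels condition labels, one per image.
#' @return numeric vector of m logits.
#' @export
discriminator_forward <- function(state, images, labels) {
  if (inherits(state, "cgan_fit")) state <- state$discriminator
  stopifnot(inherits(state, "network_state"),
            state$role == "discriminator")
  X <- as_flat_images(images)
  side <- state$meta$image_side
  if (nrow(X) > 0L && ncol(X) != side^2) {
    stop(sprintf("image side mismatch: expected %d pixels, got %d",
                 side^2, ncol(X)))
  }
  idx <- resolve_labels(labels, state$meta$classes)
  stopifnot(nrow(X) == length(idx))
  if (nrow(X) == 0L) return(numeric(0))
  as.numeric(disc_forward_flat(state$net, X, idx))
}

# ---- losses -----------------------------------------------------------

#' Plain non-saturating generator loss
#'
#' Batch mean of `-log sigma(logit)`; positive and decreasing in each
#' logit.
#'
#' @param fake_logits discriminator logits on generated images (m >= 1).
#' @return scalar loss.
#' @export
plain_generator_loss <- function(fake_logits) {
  stopifnot(length(fake_logits) >= 1)
  mean(neglog_sigmoid(fake_logits))
}

#' SpineGAN generator loss
#'
#' Plain non-saturating loss plus `gamma` times the cross-entropy
#' between the conditioning labels and the frozen pretrained abnormality
#' classifier's probabilities on the generated images:
#' `BCE = -(1/m) sum(c_i log s_i + (1 - c_i) log(1 - s_i))` for the
#' binary head, categorical cross-entropy against the softmax for
#' multi-class `s_probs`.  `gamma = 0` recovers the plain loss exactly.
#'
#' The printed form of the guidance term in the source method carries
#' the opposite sign on its first sum, which would reward the classifier
#' disagreeing with the conditioning label; since the term is described
#' as a standard cross-entropy measuring whether the conditional label
#' matches the prediction, standard cross-entropy is the default.
#' `literal_printed_loss = TRUE` reproduces the literal printed signs
#' (`+ sum c_i log s_i - sum (1 - c_i) log(1 - s_i)`, batch-normalized)
#' for comparison.
#'
#' @param fake_logits discriminator logits on generated images.
#' @param s_probs classifier probabilities on the generated images:
#'   numeric vector (binary abnormality probability) or `m x K` matrix
#'   (softmax head).  Clamped to `[1e-7, 1 - 1e-7]` before logs.
#' @param c conditioning labels: 0/1 for the binary case, or 1-based
#'   class indices for the multi-class case.
#' @param gamma non-negative guidance weight.
#' @param literal_printed_loss see description.
#' @return scalar loss.
#' @export
spinegan_generator_loss <- function(fake_logits, s_probs, c, gamma = 1.0,
                                    literal_printed_loss = FALSE) {
  stopifnot(gamma >= 0)
  base <- plain_generator_loss(fake_logits)
  m <- length(fake_logits)
  if (is.matrix(s_probs)) {
    stopifnot(nrow(s_probs) == m, length(c) == m)
    p <- clamp_prob(s_probs[cbind(seq_len(m), as.integer(c))])
    term <- -mean(log(p))
    if (literal_printed_loss) {
      stop("literal_printed_loss is defined for the binary head only")
    }
  } else {
    if (length(s_probs) != m || length(c) != m) {
      stop(sprintf(
        "length mismatch: fake_logits %d, s_probs %d, labels %d",
        m, length(s_probs), length(c)))
    }
    ci <- as.numeric(c)
    stopifnot(all(ci %in% c(0, 1)))
    s <- clamp_prob(s_probs)
    if (literal_printed_loss) {
      term <- mean(ci * log(s)) - mean((1 - ci) * log(1 - s))
    } else {
      term <- -mean(ci * log(s) + (1 - ci) * log(1 - s))
    }
  }
  base + gamma * term
}

#' Discriminator loss
#'
#' `mean softplus(-real_logits) + mean softplus(fake_logits) +
#' r1_weight * r1_penalty`, where `r1_penalty` is the mean squared
#' gradient norm of the real logits with respect to the real images
#' (supplied by the training loop).
#'
#' @param real_logits,fake_logits discriminator logits.
#' @param r1_penalty non-negative penalty value.
#' @param r1_weight non-negative weight.
#' @return scalar loss.
#' @export
discriminator_loss <- function(real_logits, fake_logits, r1_penalty = 0,
                               r1_weight = 0) {
  mean(softplus(-real_logits)) + mean(softplus(fake_logits)) +
    r1_weight * r1_penalty
}

# ---- pretrained abnormality network S ---------------------------------

#' Pretrain the abnormality network S
#'
#' Trains a classifier on real data to classify abnormal radiographs,
#' then freezes it for use as the guidance network in SpineGAN training.
#' S consumes raw `[0, 1]` images at the generator's resolution (no
#' augmentation), so its gradient can flow into the generator.  A
#' parameter hash is stored so the frozen contract is checkable after
#' GAN training.
#'
#' @param train a [labeled_dataset()] with both classes.
#' @param cfg a [classifier_config()]; its `augment` must be `NULL`.
#' @param classes class inventory (binary default).
#' @return a frozen classifier `network_state` (meta fields `frozen` and
#'   `hash` set).
#' @export
pretrain_label_network <- function(train, cfg = classifier_config(),
                                   classes = NULL) {
  if (!is.null(cfg$augment)) {
    stop("the guidance network S must be trained without augmentation")
  }
  s <- train_classifier(train, cfg, classes = classes)
  s$meta$frozen <- TRUE
  s$meta$hash <- param_hash(s$net)
  s
}

# gradient of the guidance cross-entropy w.r.t. the flat images, plus
# the term's value; S is a pooled dense classifier on raw pixels
s_guidance <- function(s, X, idx, gamma, literal = FALSE) {
  m <- nrow(X)
  P <- pool_matrix(s$meta$input_side, s$meta$pool)
  Fm <- X %*% P
  fwd <- nn_forward(s$net, Fm, cache = TRUE)
  if (s$meta$out_dim == 1L) {
    ci <- as.numeric(idx == 2L)                # classes[2] = abnormal
    p <- clamp_prob(sigmoid(fwd$out[, 1L]))
    if (literal) {
      term <- mean(ci * log(p)) - mean((1 - ci) * log(1 - p))
      dA <- matrix((ci * (1 - p) + (1 - ci) * p) / m, ncol = 1L)
    } else {
      term <- -mean(ci * log(p) + (1 - ci) * log(1 - p))
      dA <- matrix((p - ci) / m, ncol = 1L)
    }
  } else {
    Pr <- softmax_rows(fwd$out)
    term <- -mean(log(clamp_prob(Pr[cbind(seq_len(m), idx)])))
    Y <- onehot(idx, s$meta$out_dim)
    dA <- (Pr - Y) / m
  }
  bk <- nn_backward(s$net, fwd, dA)
  list(term = term, dX = gamma * (bk$dX %*% t(P)))
}

# ---- training loop ----------------------------------------------------

#' Train a conditional GAN
#'
#' Alternates one discriminator step and one generator step per batch
#' until `total_images_shown` real images have been shown to the
#' discriminator.  When a frozen pretrained abnormality network `s` is
#' supplied the generator trains under the SpineGAN loss
#' ([spinegan_generator_loss()] with `cfg$gamma`); otherwise under the
#' plain non-saturating loss.  Fully seeded: identical `(train, cfg, s)`
#' reproduce identical parameters.
#'
#' @param train a [labeled_dataset()].
#' @param cfg a [gan_config()].
#' @param s optional frozen classifier from [pretrain_label_network()];
#'   must share the GAN's class inventory and image side.
#' @return an object of class `cgan_fit`: generator and discriminator
#'   `network_state`s, the config, the conditioning class inventory and
#'   empirical class counts, and a training history data frame (step,
#'   images_shown, d_loss, g_loss, classifier_term).
#' @export
train_gan <- function(train, cfg = gan_config(), s = NULL) {
  stopifnot(cfg$total_images_shown >= cfg$batch_size)
  classes <- if (cfg$n_classes == 2L) BINARY_CLASSES else train$classes
  if (length(classes) != cfg$n_classes) {
    stop(sprintf("dataset inventory has %d classes but n_classes = %d",
                 length(classes), cfg$n_classes))
  }
  K <- cfg$n_classes
  side <- cfg$image_side
  y <- dataset_class_index(train, classes)
  X <- dataset_pixel_matrix(train)
  stopifnot(ncol(X) == side^2)
  if (!is.null(s)) {
    stopifnot(inherits(s, "network_state"), s$role == "classifier")
    if (!identical(s$meta$classes, classes)) {
      stop("guidance network S was trained on a different class inventory")
    }
    if (!is.null(s$meta$augment) || s$meta$input_side != side) {
      stop("S must consume raw images at the GAN's image side")
    }
    s_hash_before <- param_hash(s$net)
  }
  n <- nrow(X)
  m <- cfg$batch_size
  n_steps <- ceiling(cfg$total_images_shown / m)
  history <- list()

  with_seed(cfg$seed, {
    g_net <- nn_new(c(cfg$latent_dim + K, cfg$g_hidden, side^2),
                    seed = sample.int(2147483646L, 1L))
    g_net$E <- matrix(0, K, side^2)            # per-class output template
    d_net <- nn_new(c(side^2, cfg$d_hidden, 1L),
                    seed = sample.int(2147483646L, 1L))
    d_h <- cfg$d_hidden[length(cfg$d_hidden)]
    d_net$E <- matrix(stats::rnorm(K * d_h, sd = 1 / sqrt(d_h)), K, d_h)
    g_state <- network_state("generator", g_net,
                             list(latent_dim = cfg$latent_dim,
                                  classes = classes, image_side = side))
    opt_g <- adam_new(g_net)
    opt_d <- adam_new(d_net)
    g_ema <- g_net                    # sampling-time weight average

    for (step in seq_len(n_steps)) {
      # --- discriminator step ---
      idx_r <- sample.int(n, m, replace = n < m)
      Xr <- X[idx_r, , drop = FALSE]
      z <- matrix(stats::rnorm(m * cfg$latent_dim), m)
      yf <- sample(y, m, replace = TRUE)
      g_state$net <- g_net
      Xf <- gen_forward_flat(g_state, z, yf)
      need_r1 <- cfg$r1_weight > 0 && (step - 1L) %% cfg$r1_interval == 0L
      fwd_r <- disc_forward_flat(d_net, Xr, y[idx_r], cache = TRUE)
      fwd_f <- disc_forward_flat(d_net, Xf, yf, cache = TRUE)
      lr_ <- fwd_r$logits
      lf_ <- fwd_f$logits
      gr <- disc_backward(d_net, fwd_r, -sigmoid(-lr_) / m)
      gf <- disc_backward(d_net, fwd_f, sigmoid(lf_) / m)
      gd <- grads_add(gr, gf)
      if (cfg$mismatch_weight > 0) {
        # matching-aware term: real images with shuffled (wrong) labels
        # are scored as fakes, which teaches label-image consistency
        y_wrong <- (y[idx_r] + sample.int(K - 1L, m, replace = TRUE) - 1L) %%
          K + 1L
        fwd_w <- disc_forward_flat(d_net, Xr, y_wrong, cache = TRUE)
        gw <- disc_backward(d_net, fwd_w,
                            cfg$mismatch_weight * sigmoid(fwd_w$logits) / m)
        gd <- grads_add(gd, gw)
      }
      r1_pen <- 0
      if (need_r1) {
        r1 <- disc_r1(d_net, fwd_r)
        r1_pen <- r1$penalty
        gd <- grads_add(gd, grads_scale(r1, cfg$r1_weight * cfg$r1_interval))
      }
      upd <- adam_step(opt_d, d_net, gd, lr = cfg$lr_d,
                       beta1 = cfg$beta1, beta2 = cfg$beta2)
      opt_d <- upd$opt
      d_net <- upd$net
      d_loss <- discriminator_loss(lr_, lf_, r1_pen, cfg$r1_weight)

      # --- generator step ---
      z <- matrix(stats::rnorm(m * cfg$latent_dim), m)
      yc <- sample(y, m, replace = TRUE)
      g_state$net <- g_net
      gfwd <- gen_forward_flat(g_state, z, yc, cache = TRUE)
      Xg <- gfwd$X
      dfwd <- disc_forward_flat(d_net, Xg, yc, cache = TRUE)
      lg <- dfwd$logits
      bk <- disc_backward(d_net, dfwd, -sigmoid(-lg) / m)
      d_img <- bk$dX
      cls_term <- NA_real_
      if (!is.null(s) && cfg$gamma > 0) {
        guid <- s_guidance(s, Xg, yc, cfg$gamma,
                           literal = cfg$literal_printed_loss)
        d_img <- d_img + guid$dX
        cls_term <- guid$term
      }
      dA <- d_img * Xg * (1 - Xg)              # through the output sigmoid
      gg <- nn_backward(g_net, gfwd, dA)
      gg$dX <- NULL
      gg$E <- crossprod(onehot(yc, K), dA)     # class template gradient
      upd <- adam_step(opt_g, g_net, gg, lr = cfg$lr_g,
                       beta1 = cfg$beta1, beta2 = cfg$beta2)
      opt_g <- upd$opt
      g_net <- upd$net
      if (cfg$ema_decay < 1) {
        a <- 1 - cfg$ema_decay
        for (l in seq_along(g_net$W)) {
          g_ema$W[[l]] <- g_ema$W[[l]] + a * (g_net$W[[l]] - g_ema$W[[l]])
          g_ema$b[[l]] <- g_ema$b[[l]] + a * (g_net$b[[l]] - g_ema$b[[l]])
        }
        g_ema$E <- g_ema$E + a * (g_net$E - g_ema$E)
      } else {
        g_ema <- g_net
      }
      g_loss <- plain_generator_loss(lg) +
        if (is.na(cls_term)) 0 else cfg$gamma * cls_term

      if (step %% cfg$log_interval == 0L || step == n_steps) {
        history[[length(history) + 1L]] <- data.frame(
          step = step, images_shown = min(step * m,
                                          cfg$total_images_shown),
          d_loss = d_loss, g_loss = g_loss, classifier_term = cls_term
        )
      }
    }
  })

  if (!is.null(s) && param_hash(s$net) != s_hash_before) {
    stop("internal error: guidance network S was modified during training")
  }
  counts <- table(factor(classes[y], levels = classes))
  structure(list(
    generator = network_state("generator", g_ema,
                              list(latent_dim = cfg$latent_dim,
                                   classes = classes, image_side = side,
                                   ema_decay = cfg$ema_decay),
                              step_count = n_steps),
    discriminator = network_state("discriminator", d_net,
                                  list(classes = classes,
                                       image_side = side),
                                  step_count = n_steps),
    config = cfg, classes = classes,
    class_counts = stats::setNames(as.integer(counts), classes),
    history = do.call(rbind, history),
    spinegan = !is.null(s) && cfg$gamma > 0
  ), class = "cgan_fit")
}

#' @export
print.cgan_fit <- function(x, ...) {
  cat(sprintf("<%s fit: %d classes, %dx%d images, %d steps>\n",
              if (x$spinegan) "SpineGAN" else "conditional GAN",
              length(x$classes), x$config$image_side, x$config$image_side,
              x$generator$step_count))
  invisible(x)
}

#' @export
summary.cgan_fit <- function(object, ...) {
  h <- object$history
  cat(sprintf("%s trained for %d steps (%.0f images shown)\n",
              if (object$spinegan) "SpineGAN" else "Conditional GAN",
              max(h$step), max(h$images_shown)))
  cat(sprintf("  classes: %s (counts %s)\n",
              paste(object$classes, collapse = "/"),
              paste(object$class_counts, collapse = "/")))
  cat(sprintf("  final d_loss %.4f, g_loss %.4f", h$d_loss[nrow(h)],
              h$g_loss[nrow(h)]))
  if (object$spinegan) {
    cat(sprintf(", classifier term %.4f", h$classifier_term[nrow(h)]))
  }
  cat("\n")
  invisible(h)
}

#' @export
plot.cgan_fit <- function(x, ...) {
  h <- x$history
  graphics::matplot(h$images_shown, cbind(h$d_loss, h$g_loss),
                    type = "l", lty = 1, col = c("steelblue", "firebrick"),
                    xlab = "images shown", ylab = "loss", ...)
  graphics::legend("topright", c("discriminator", "generator"), lty = 1,
                   col = c("steelblue", "firebrick"), bty = "n")
  invisible(x)
}

#' Simulate labeled synthetic images from a fit
#'
#' `simulate()` on a [train_gan()] fit draws a labeled synthetic dataset
#' (balanced classes by default) — a thin wrapper over
#' [generate_synthetic_dataset()].
#'
#' @param object a `cgan_fit`.
#' @param nsim number of images.
#' @param seed integer seed.
#' @param class_scheme see [sampling_config()].
#' @param ... passed to [sampling_config()].
#' @return a [labeled_dataset()] with provenance `"synthetic"`.
#' @export
simulate.cgan_fit <- function(object, nsim = 1, seed = 1L,
                              class_scheme = "balanced", ...) {
  generate_synthetic_dataset(
    object, sampling_config(n_images = nsim, class_scheme = class_scheme,
                            seed = seed, ...)
  )
}
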