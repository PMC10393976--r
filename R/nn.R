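# Dense feed-forward networks with hand-written reverse-mode gradients.
#
# All networks in the package (generator, discriminator, abnormality
# classifiers) are compact multi-layer perceptrons: matrix products are
# BLAS-backed, so desk-scale training is fast without compiled code, and
# every gradient path (including the R1 input-gradient regularizer, which
# needs differentiation through the backward pass) has a closed form that
# tests verify against finite differences.
#
# Conventions: a batch is an n x d matrix (one row per sample).  Layer l
# maps H_{l-1} (n x d_{l-1}) to A_l = H_{l-1} W_l + b_l, H_l = phi(A_l).
# Hidden activation is leaky ReLU (slope 0.2); the output layer is linear
# (losses apply sigmoid/softmax themselves where needed).

LRELU_SLOPE <- 0.2

lrelu <- function(a) {
  pos <- a > 0
  a * (LRELU_SLOPE + (1 - LRELU_SLOPE) * pos)
}
lrelu_grad <- function(a) LRELU_SLOPE + (1 - LRELU_SLOPE) * (a > 0)

# He-style initialization; biases zero
nn_new <- function(sizes, seed) {
  stopifnot(length(sizes) >= 2)
  with_seed(seed, {
    n_layer <- length(sizes) - 1L
    W <- vector("list", n_layer)
    b <- vector("list", n_layer)
    for (l in seq_len(n_layer)) {
      fan_in <- sizes[l]
      W[[l]] <- matrix(stats::rnorm(sizes[l] * sizes[l + 1L], sd = sqrt(2 / fan_in)),
                       nrow = sizes[l], ncol = sizes[l + 1L])
      b[[l]] <- numeric(sizes[l + 1L])
    }
    list(W = W, b = b, sizes = sizes)
  })
}

# Forward pass.  Returns the linear output A_L; with cache = TRUE also the
# per-layer inputs and pre-activations needed by nn_backward / nn_r1.
nn_forward <- function(net, X, cache = FALSE) {
  n_layer <- length(net$W)
  if (!is.matrix(X)) X <- matrix(X, nrow = 1L)
  if (ncol(X) != net$sizes[1L]) {
    stop(sprintf("input dimension mismatch: expected %d, got %d",
                 net$sizes[1L], ncol(X)))
  }
  H <- vector("list", n_layer + 1L)  # H[[l+1]] = activation after layer l
  A <- vector("list", n_layer)
  H[[1L]] <- X
  for (l in seq_len(n_layer)) {
    A[[l]] <- H[[l]] %*% net$W[[l]]
    A[[l]] <- A[[l]] + rep(net$b[[l]], each = nrow(A[[l]]))
    H[[l + 1L]] <- if (l < n_layer) lrelu(A[[l]]) else A[[l]]
  }
  out <- H[[n_layer + 1L]]
  if (!cache) return(out)
  list(out = out, H = H, A = A)
}

# Reverse pass from dL/dA_L.  Returns parameter gradients and dL/dX.
nn_backward <- function(net, fwd, dout) {
  n_layer <- length(net$W)
  gW <- vector("list", n_layer)
  gb <- vector("list", n_layer)
  delta <- dout                      # dL/dA_l, starting at l = L
  for (l in rev(seq_len(n_layer))) {
    gW[[l]] <- crossprod(fwd$H[[l]], delta)
    gb[[l]] <- colSums(delta)
    if (l > 1L) {
      delta <- tcrossprod(delta, net$W[[l]]) * lrelu_grad(fwd$A[[l - 1L]])
    } else {
      delta <- tcrossprod(delta, net$W[[l]])
    }
  }
  list(W = gW, b = gb, dX = delta)
}

# Gradient of the scalar output w.r.t. the input, per row, for a network
# with a single linear output unit.  Returns the n x d0 Jacobian rows and
# the intermediate delta matrices (needed by nn_r1_grads).
nn_input_grad <- function(net, fwd) {
  n_layer <- length(net$W)
  n <- nrow(fwd$H[[1L]])
  R <- vector("list", n_layer)       # R[[l]] = d out / d A_l
  R[[n_layer]] <- matrix(1, nrow = n, ncol = 1L)
  for (l in rev(seq_len(n_layer))) {
    if (l > 1L) {
      R[[l - 1L]] <- tcrossprod(R[[l]], net$W[[l]]) *
        lrelu_grad(fwd$A[[l - 1L]])
    }
  }
  G <- tcrossprod(R[[1L]], net$W[[1L]])
  list(G = G, R = R)
}

# R1 penalty P = mean_i || G_i[cols] ||^2 and its exact parameter gradient.
# With piecewise-linear activations the activation masks are locally
# constant, so P is quadratic in the weights; its gradient is obtained by
# propagating the adjoint of the backward pass forward through the layers.
nn_r1_grads <- function(net, fwd, cols = NULL) {
  n_layer <- length(net$W)
  ig <- nn_input_grad(net, fwd)
  G <- ig$G
  n <- nrow(G)
  mask <- if (is.null(cols)) rep(TRUE, ncol(G)) else seq_len(ncol(G)) %in% cols
  Gm <- G
  Gm[, !mask] <- 0
  penalty <- sum(Gm^2) / n
  U <- (2 / n) * Gm                  # dP/dG
  gW <- vector("list", n_layer)
  gb <- vector("list", n_layer)
  # layer 1: G = R_1 W_1^T
  gW[[1L]] <- crossprod(U, ig$R[[1L]])
  gb[[1L]] <- numeric(length(net$b[[1L]]))
  S <- U %*% net$W[[1L]]             # dP/dR_1
  if (n_layer > 1L) {
    for (l in 2:n_layer) {
      Tm <- S * lrelu_grad(fwd$A[[l - 1L]])   # dP/d(R_l W_l^T)
      gW[[l]] <- crossprod(Tm, ig$R[[l]])
      gb[[l]] <- numeric(length(net$b[[l]]))
      S <- Tm %*% net$W[[l]]
    }
  }
  list(penalty = penalty, W = gW, b = gb)
}

# ---- Adam optimizer ---------------------------------------------------

adam_new <- function(net) {
  zero_like <- function(p) lapply(p, function(x) x * 0)
  opt <- list(mW = zero_like(net$W), vW = zero_like(net$W),
              mb = zero_like(net$b), vb = zero_like(net$b), t = 0L)
  if (!is.null(net$E)) {
    opt$mE <- net$E * 0
    opt$vE <- net$E * 0
  }
  opt
}

adam_step <- function(opt, net, grads, lr, beta1 = 0.9, beta2 = 0.999,
                      eps = 1e-8) {
  opt$t <- opt$t + 1L
  c1 <- 1 - beta1^opt$t
  c2 <- 1 - beta2^opt$t
  for (l in seq_along(net$W)) {
    opt$mW[[l]] <- beta1 * opt$mW[[l]] + (1 - beta1) * grads$W[[l]]
    opt$vW[[l]] <- beta2 * opt$vW[[l]] + (1 - beta2) * grads$W[[l]]^2
    net$W[[l]] <- net$W[[l]] -
      lr * (opt$mW[[l]] / c1) / (sqrt(opt$vW[[l]] / c2) + eps)
    opt$mb[[l]] <- beta1 * opt$mb[[l]] + (1 - beta1) * grads$b[[l]]
    opt$vb[[l]] <- beta2 * opt$vb[[l]] + (1 - beta2) * grads$b[[l]]^2
    net$b[[l]] <- net$b[[l]] -
      lr * (opt$mb[[l]] / c1) / (sqrt(opt$vb[[l]] / c2) + eps)
  }
  if (!is.null(net$E) && !is.null(grads$E)) {
    opt$mE <- beta1 * opt$mE + (1 - beta1) * grads$E
    opt$vE <- beta2 * opt$vE + (1 - beta2) * grads$E^2
    net$E <- net$E - lr * (opt$mE / c1) / (sqrt(opt$vE / c2) + eps)
  }
  list(opt = opt, net = net)
}

# sum two gradient containers of matching shape
grads_add <- function(a, b) {
  out <- list(W = Map(`+`, a$W, b$W), b = Map(`+`, a$b, b$b))
  if (!is.null(a$E) || !is.null(b$E)) {
    out$E <- if (is.null(a$E)) b$E else if (is.null(b$E)) a$E else a$E + b$E
  }
  out
}

grads_scale <- function(a, s) {
  out <- list(W = lapply(a$W, `*`, s), b = lapply(a$b, `*`, s))
  if (!is.null(a$E)) out$E <- a$E * s
  out
}
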