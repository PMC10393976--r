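# Generative-quality metrics from first principles: Frechet distance
# between Gaussian fits of embeddings, and k-NN manifold precision /
# recall.  FID values are only comparable within one embedder, so every
# report carries the embedder identifier.

#' Embedding set
#'
#' @param vectors `n x d` numeric matrix of embeddings (n >= 2 for
#'   covariance estimation; no non-finite entries).
#' @param source `"real"` or `"generated"`.
#' @param embedder_id identifier of the embedder that produced the
#'   vectors.
#' @return an object of class `embedding_set`.
#' @export
embedding_set <- function(vectors, source = c("real", "generated"),
                          embedder_id = "unknown") {
  source <- match.arg(source)
  stopifnot(is.matrix(vectors), nrow(vectors) >= 2)
  if (!all(is.finite(vectors))) stop("embeddings contain non-finite entries")
  structure(list(vectors = vectors, source = source,
                 embedder_id = embedder_id),
            class = "embedding_set")
}

as_embedding_matrix <- function(x) {
  if (inherits(x, "embedding_set")) x$vectors else as.matrix(x)
}

#' Random-projection embedder
#'
#' A seeded fixed Gaussian projection of flattened pixels to `d`
#' dimensions: a deterministic, architecture-free embedding for
#' desk-scale comparisons.  (A pretrained classifier's penultimate layer
#' can be used instead via [embed_images()].)
#'
#' @param input_dim flattened image length (side^2).
#' @param d embedding dimension.
#' @param seed integer seed.
#' @return an object of class `rp_embedder`.
#' @export
random_projection_embedder <- function(input_dim, d = 64L, seed = 1L) {
  W <- with_seed(seed, matrix(stats::rnorm(input_dim * d) / sqrt(d),
                              input_dim, d))
  structure(list(W = W, input_dim = as.integer(input_dim),
                 d = as.integer(d),
                 id = sprintf("rp%d_seed%d", d, seed)),
            class = "rp_embedder")
}

#' Embed images
#'
#' Maps images to fixed-length vectors, row order matching input order.
#' The embedder is either a [random_projection_embedder()] or a
#' classifier `network_state` (whose penultimate-layer activations are
#' used).
#'
#' @param images images in any accepted form.
#' @param embedder see description.
#' @param source `"real"` or `"generated"` tag for the result.
#' @return an [embedding_set()].
#' @export
embed_images <- function(images, embedder, source = "real") {
  X <- as_flat_images(images)
  if (inherits(embedder, "rp_embedder")) {
    stopifnot(ncol(X) == embedder$input_dim)
    V <- X %*% embedder$W
    id <- embedder$id
  } else if (inherits(embedder, "network_state") &&
             embedder$role == "classifier") {
    Fm <- clf_features_eval(embedder, X)
    fwd <- nn_forward(embedder$net, Fm, cache = TRUE)
    nl <- length(embedder$net$W)
    V <- fwd$H[[nl]]                  # penultimate activations
    id <- sprintf("clf_penultimate_%s", param_hash(embedder$net))
  } else {
    stop("unsupported embedder")
  }
  embedding_set(V, source = source, embedder_id = id)
}

# symmetric PSD square root with tolerance for small negative eigenvalues
psd_sqrt <- function(S, tol = 1e-8) {
  e <- eigen((S + t(S)) / 2, symmetric = TRUE)
  lam <- e$values
  if (any(lam < -tol * max(1, abs(lam[1])))) {
    stop("covariance matrix has substantially negative eigenvalues; ",
         "use more samples (n) relative to the embedding dimension")
  }
  lam[lam < 0] <- 0
  e$vectors %*% (sqrt(lam) * t(e$vectors))
}

#' Frechet distance between embedding Gaussians (FID)
#'
#' `||mu_a - mu_b||^2 + tr(S_a + S_b - 2 (S_a S_b)^{1/2})`, with the
#' matrix square root computed via the symmetric form
#' `S_a^{1/2} S_b S_a^{1/2}` and small negative eigenvalues clipped at
#' tolerance.  Lower values mean the generated embedding distribution
#' is closer to the real one.
#'
#' @param a,b [embedding_set()]s (or plain matrices) with n >= 2 and
#'   equal dimension.
#' @return non-negative scalar (up to numerical tolerance).
#' @export
fid <- function(a, b) {
  A <- as_embedding_matrix(a)
  B <- as_embedding_matrix(b)
  stopifnot(nrow(A) >= 2, nrow(B) >= 2, ncol(A) == ncol(B))
  mu_a <- colMeans(A)
  mu_b <- colMeans(B)
  Sa <- stats::cov(A)
  Sb <- stats::cov(B)
  Ra <- psd_sqrt(Sa)
  M <- Ra %*% Sb %*% Ra
  e <- eigen((M + t(M)) / 2, symmetric = TRUE, only.values = TRUE)
  lam <- e$values
  if (any(lam < -1e-8 * max(1, abs(lam[1])))) {
    stop("cross-covariance product has substantially negative eigenvalues; ",
         "use more samples (n)")
  }
  lam[lam < 0] <- 0
  sum((mu_a - mu_b)^2) + sum(diag(Sa)) + sum(diag(Sb)) - 2 * sum(sqrt(lam))
}

#' k-NN manifold precision and recall
#'
#' Precision: fraction of generated vectors lying within the union of
#' balls centered at each real vector with radius equal to that vector's
#' distance to its k-th nearest real neighbour (self excluded).  Recall:
#' the symmetric quantity with roles swapped.  Distances are Euclidean;
#' ties at the radius count as inside.
#'
#' @param real,generated [embedding_set()]s or matrices with more than
#'   `k` rows each.
#' @param k neighbourhood size.
#' @return named numeric vector `c(precision = , recall = )`.
#' @export
knn_precision_recall <- function(real, generated, k = 3L) {
  R <- as_embedding_matrix(real)
  G <- as_embedding_matrix(generated)
  stopifnot(ncol(R) == ncol(G))
  if (nrow(R) <= k || nrow(G) <= k) {
    stop(sprintf("need more than k = %d points in each set (real %d, generated %d)",
                 k, nrow(R), nrow(G)))
  }
  kth_radius <- function(M) {
    D <- as.matrix(stats::dist(M))
    diag(D) <- Inf                   # exclude self
    apply(D, 1L, function(row) sort(row)[k])
  }
  inside_fraction <- function(points, centers, radii) {
    # ||p - c||^2 via the expanded form; ties (<=) count as inside
    cross <- points %*% t(centers)
    d2 <- outer(rowSums(points^2), rowSums(centers^2), `+`) - 2 * cross
    d2[d2 < 0] <- 0
    inside <- sweep(sqrt(d2), 2L, radii, `<=`)
    mean(apply(inside, 1L, any))
  }
  c(precision = inside_fraction(G, R, kth_radius(R)),
    recall = inside_fraction(R, G, kth_radius(G)))
}

#' Generative metrics report
#'
#' One row per generator arm with FID, precision, recall and the
#' embedder/k configuration that produced them.
#'
#' @param real_images real reference images (any accepted form).
#' @param generated_images named list of generated image sets, one per
#'   arm.
#' @param embedder embedder accepted by [embed_images()]; defaults to a
#'   seeded random projection sized to the images.
#' @param k neighbourhood size for precision/recall.
#' @return data frame with columns arm, fid, precision, recall,
#'   embedder_id, k, n_real, n_generated.
#' @export
metrics_report <- function(real_images, generated_images, embedder = NULL,
                           k = 3L) {
  X_real <- as_flat_images(real_images)
  if (is.null(embedder)) {
    embedder <- random_projection_embedder(ncol(X_real))
  }
  e_real <- embed_images(X_real, embedder, source = "real")
  rows <- lapply(names(generated_images), function(arm) {
    e_gen <- embed_images(generated_images[[arm]], embedder,
                          source = "generated")
    pr <- knn_precision_recall(e_real, e_gen, k = k)
    data.frame(arm = arm, fid = fid(e_real, e_gen),
               precision = unname(pr["precision"]),
               recall = unname(pr["recall"]),
               embedder_id = e_real$embedder_id, k = as.integer(k),
               n_real = nrow(e_real$vectors),
               n_generated = nrow(e_gen$vectors),
               stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}
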