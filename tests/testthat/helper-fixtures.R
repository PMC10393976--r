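# Shared fixtures, built in code at test time.

# quiet phantom config for geometric oracles
noise_free_config <- function(side = 64) {
  phantom_config(image_side = side, noise_sd = 0, contrast_jitter = 0)
}

# a small phantom cohort cached per session (cheap to regenerate)
tiny_cohort <- function(n_normal = 30, n_abnormal = 30, noise_sd = 0.05,
                        seed = 101) {
  generate_cohort(n_normal, n_abnormal,
                  phantom_config(noise_sd = noise_sd), seed = seed)
}

# segment a noise-free phantom's vertical profile into vertebra/gap runs
# (independent row-profile oracle used by the lesion-geometry tests)
row_profile_runs <- function(pixels, thresh = 0.4) {
  bright <- rowMeans(pixels) > thresh * max(rowMeans(pixels))
  r <- rle(bright)
  # interior runs only: drop background margins at top and bottom
  first_true <- which(r$values)[1]
  last_true <- max(which(r$values))
  list(vertebrae = r$lengths[r$values][],
       gaps = r$lengths[!r$values][-c(1, sum(!r$values))],
       lengths = r$lengths[first_true:last_true],
       values = r$values[first_true:last_true])
}

gap_heights <- function(pixels) {
  rr <- row_profile_runs(pixels)
  rr$lengths[!rr$values]
}

vertebra_heights <- function(pixels) {
  rr <- row_profile_runs(pixels)
  rr$lengths[rr$values]
}

# brute-force O(n^2) oracle for k-NN manifold precision/recall
brute_precision_recall <- function(R, G, k) {
  d <- function(a, b) sqrt(sum((a - b)^2))
  radii <- function(M) {
    vapply(seq_len(nrow(M)), function(i) {
      ds <- vapply(seq_len(nrow(M)), function(j) {
        if (i == j) Inf else d(M[i, ], M[j, ])
      }, numeric(1))
      sort(ds)[k]
    }, numeric(1))
  }
  inside <- function(P, C, rad) {
    mean(vapply(seq_len(nrow(P)), function(i) {
      any(vapply(seq_len(nrow(C)), function(j) {
        d(P[i, ], C[j, ]) <= rad[j]
      }, logical(1)))
    }, logical(1)))
  }
  c(precision = inside(G, R, radii(R)), recall = inside(R, G, radii(G)))
}

# exhaustive pair-enumeration oracle for AUC
brute_auc <- function(scores, labels) {
  pos <- scores[labels == 1]
  neg <- scores[labels == 0]
  tot <- 0
  for (p in pos) for (q in neg) {
    tot <- tot + (p > q) + 0.5 * (p == q)
  }
  tot / (length(pos) * length(neg))
}
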