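# Internal numeric and RNG helpers shared across modules.

EPS_PROB <- 1e-7

sigmoid <- function(x) 1 / (1 + exp(-x))

# numerically stable log(1 + exp(x))
softplus <- function(x) pmax(x, 0) + log1p(exp(-abs(x)))

# -log sigmoid(x) = softplus(-x), stable for large |x|
neglog_sigmoid <- function(x) softplus(-x)

clamp_prob <- function(p) pmin(pmax(p, EPS_PROB), 1 - EPS_PROB)

clamp01 <- function(x) pmin(pmax(x, 0), 1)

#' Evaluate an expression under a temporary RNG seed
#'
#' Sets the seed, runs `expr`, and restores the caller's RNG state, so
#' seeded operations never perturb the global random stream.
#' @param seed integer seed.
#' @param expr expression to evaluate.
#' @return the value of `expr`.
#' @keywords internal
with_seed <- function(seed, expr) {
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  } else {
    NULL
  }
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
        rm(".Random.seed", envir = globalenv())
      }
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  }, add = TRUE)
  set.seed(as.integer(seed))
  expr
}

#' Derive a stage seed from a global seed
#'
#' Stable integer hash of (seed, stage name) so that pipeline stages draw
#' from decoupled random streams.  Always in `[0, 2^31 - 2]`.
#' @param seed integer global seed.
#' @param stage character stage name.
#' @return integer seed.
#' @export
stage_seed <- function(seed, stage) {
  stopifnot(is.character(stage), length(stage) == 1L)
  h <- as.double(seed) %% 2147483647
  for (code in utf8ToInt(stage)) {
    h <- (h * 31 + code) %% 2147483647
  }
  as.integer(h)
}

# md5 of a parameter container; used to assert frozen-network contracts
param_hash <- function(params) {
  f <- tempfile(fileext = ".rds")
  on.exit(unlink(f), add = TRUE)
  con <- file(f, "wb")
  serialize(params, con, version = 2)
  close(con)
  unname(tools::md5sum(f))
}

`%||%` <- function(a, b) if (is.null(a)) b else a
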