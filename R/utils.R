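# Internal helpers shared across modules.

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Derive a reproducible child seed from a master seed
#'
#' Every stochastic step in the pipeline (split, folds, learner fits,
#' permutation repeats) draws its own seed from the single user-supplied seed,
#' so that one integer reproduces the whole run. Kept below 2^31 - 1.
#' @keywords internal
#' @noRd
child_seed <- function(seed, offset) {
  (as.integer(seed) %% 1000003L) * 2017L + as.integer(offset) %% 104729L
}

#' Content checksum of an R object
#'
#' Lightweight polynomial rolling hash (mod 2^31 - 1) over the serialized
#' object, used for holdout-hygiene bookkeeping: the test rows are hashed
#' before Phase I and verified unchanged before evaluation.
#' @param x any serializable object
#' @return hex string
#' @export
content_hash <- function(x) {
  bytes <- as.integer(serialize(x, NULL, version = 2L))
  m <- 2147483647 # 2^31 - 1; 31 * h + b stays exact in doubles
  h <- 0
  for (b in bytes) h <- (h * 31 + b) %% m
  sprintf("%08x", h)
}

stop_daplex <- function(fmt, ...) {
  stop(sprintf(fmt, ...), call. = FALSE)
}

is_binary01 <- function(x) {
  is.numeric(x) && all(x %in% c(0, 1))
}

#' Run an expression with a local RNG seed
#'
#' Leaves the caller's RNG state untouched.
#' @keywords internal
#' @noRd
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
  })
  set.seed(seed)
  force(expr)
}
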