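#' @keywords internal
"_PACKAGE"

# Deterministic RNG substreams -------------------------------------------
#
# All stochastic components derive their seeds by hashing a base seed
# together with a structural key (subject id, day, slot, content, ...).
# Adding subjects or reordering generation therefore never perturbs the
# draws of existing units.

#' Derive a deterministic substream seed from a base seed and a key
#'
#' Hashes the base seed together with an arbitrary set of key components
#' (coerced to character) into an integer seed in `[1, 2^31 - 2]`. Used
#' throughout the package so that every sampled unit owns an independent,
#' reproducible random substream.
#'
#' @param seed Integer base seed.
#' @param ... Key components (subject id, day, slot, ...); coerced to
#'   character and hashed together with `seed`.
#' @return A single integer suitable for [set.seed()].
#' @export
#' @examples
#' substream_seed(1, "S001", 3, "answer")
substream_seed <- function(seed, ...) {
  key <- paste(c(format(seed, scientific = FALSE), as.character(unlist(list(...)))),
               collapse = "\r")
  bytes <- utf8ToInt(key)
  # Polynomial hash kept in double precision; the multiplier is small
  # enough that h * mult + b stays below 2^53, so every byte contributes
  # exactly. Modulus 2^31 - 1 keeps the result a valid 32-bit seed.
  m <- 2147483647
  h <- 2166136261 %% m
  for (b in bytes) {
    h <- (h * 69069 + b) %% m
  }
  as.integer(h %% (m - 2L) + 1L)
}

# Evaluate an expression under a local RNG state, restoring the caller's
# stream afterwards.
with_local_seed <- function(seed, expr) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) {
      assign(".Random.seed", old, envir = globalenv())
    } else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  }, add = TRUE)
  set.seed(seed)
  expr
}

# Truncated, discretized Gaussian item scores in {0, ..., k_max}.
sample_item_scores <- function(n, mean, sd, k_max) {
  x <- stats::rnorm(n, mean = mean, sd = sd)
  pmin(pmax(round(x), 0), k_max)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

stop_if_not <- function(cond, msg) {
  if (!isTRUE(cond)) stop(msg, call. = FALSE)
}
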