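#' @keywords internal
#' @useDynLib decolle, .registration = TRUE
#' @importFrom Rcpp sourceCpp
"_PACKAGE"

# Internal argument checking helpers. All user-facing errors are raised with
# stop(call. = FALSE) so the message names the offending argument, not the
# internal frame.

abort <- function(...) stop(..., call. = FALSE)

check_scalar_number <- function(x, name, positive = FALSE, nonneg = FALSE) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x)) {
    abort(sprintf("`%s` must be a single finite number", name))
  }
  if (positive && x <= 0) abort(sprintf("`%s` must be > 0", name))
  if (nonneg && x < 0) abort(sprintf("`%s` must be >= 0", name))
  invisible(x)
}

check_count <- function(x, name, min = 1L) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x) || x != round(x) || x < min) {
    abort(sprintf("`%s` must be an integer >= %d", name, min))
  }
  as.integer(x)
}

check_binary <- function(x, name) {
  if (!all(x %in% c(0, 1))) abort(sprintf("`%s` must be binary (0/1)", name))
  invisible(x)
}

# Coerce a vector or matrix to a batch-major matrix (batch x units). Vectors
# are treated as a single batch element.
as_batch <- function(x) {
  if (is.matrix(x)) x else matrix(x, nrow = 1L)
}

check_same_shape <- function(a, b, name_a, name_b) {
  if (!identical(dim(as_batch(a)), dim(as_batch(b)))) {
    abort(sprintf("`%s` and `%s` must have the same shape", name_a, name_b))
  }
  invisible(NULL)
}

#' Derive a reproducible sub-seed from a master seed
#'
#' All randomness in the package flows from a single master seed; independent
#' purposes (weight init, readout init, data generation, dropout, ...) use
#' sub-seeds derived deterministically with a multiplicative hash, so adding a
#' new consumer of randomness does not perturb the streams of existing ones.
#'
#' @param seed master seed (integer).
#' @param index sub-stream index (integer >= 0).
#' @return an integer seed in `[0, 2^31 - 2]`.
#' @export
derive_seed <- function(seed, index) {
  check_scalar_number(seed, "seed")
  check_scalar_number(index, "index", nonneg = TRUE)
  m <- 2147483647 # 2^31 - 1, prime
  s <- (abs(seed) %% m)
  # two rounds of a Lehmer-style mix keep nearby (seed, index) pairs apart
  s <- (s * 48271 + index * 16807 + 12345) %% m
  s <- (s * 48271 + 7919) %% m
  as.integer(s)
}

# Evaluate `expr` under a fixed RNG seed without disturbing the caller's RNG
# state.
with_seed <- function(seed, expr) {
  withr::with_seed(seed, expr)
}
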