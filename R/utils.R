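#' Derive a stream-specific seed from a master seed
#'
#' Deterministically mixes a master seed with integer tags (stage index,
#' subject index, ...) so that every stochastic stage of the pipeline draws
#' from its own reproducible stream. Result is always in [1, 2^31 - 2].
#'
#' @param seed master integer seed.
#' @param ... integer tags identifying the stream.
#' @return a single integer seed.
#' @export
derive_seed <- function(seed, ...) {
  tags <- c(...)
  m <- 2147483647  # 2^31 - 1, Mersenne prime
  x <- as.double(seed %% m)
  for (t in tags) {
    x <- (x * 48271 + as.double(t) * 104729 + 7919) %% m
  }
  as.integer(max(1, x))
}

# internal: validate a square symmetric nonnegative weight matrix
.check_weights <- function(W) {
  if (!is.matrix(W) || !is.numeric(W)) stop("weights must be a numeric matrix")
  if (nrow(W) != ncol(W)) stop("weight matrix must be square")
  if (any(!is.finite(W))) stop("weights must be finite")
  if (any(W < 0)) stop("weights must be nonnegative")
  if (max(abs(W - t(W))) > 1e-12 * max(1, max(abs(W)))) {
    stop("weight matrix must be symmetric")
  }
  if (any(diag(W) != 0)) stop("weight matrix must have a zero diagonal")
  invisible(W)
}

# internal: extract the weight matrix from a weighted_network or plain matrix
.as_weights <- function(x) {
  if (inherits(x, "weighted_network")) x$weights else x
}
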