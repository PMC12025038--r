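# Internal helpers shared across modules.

clamp <- function(x, lo, hi) pmin(pmax(x, lo), hi)

#' Evaluate code under a private, explicitly seeded RNG stream
#'
#' Saves and restores the global `.Random.seed`, so callers never leak RNG
#' state into (or depend on) the session. All stochastic operations in the
#' package route through this helper.
#'
#' @param seed Single non-negative number; reduced modulo 2^31 - 1.
#' @param code Expression to evaluate.
#' @return The value of `code`.
#' @keywords internal
with_rng <- function(seed, code) {
  if (!is.numeric(seed) || length(seed) != 1L || !is.finite(seed) || seed < 0)
    stop("`seed` must be a single non-negative number", call. = FALSE)
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  }, add = TRUE)
  set.seed(as.integer(seed %% 2147483647))
  code
}

# Deterministic per-item substream seed; stays below 2^31 (exact in doubles).
derive_seed <- function(seed, i) {
  as.integer((as.numeric(seed) * 48271 + as.numeric(i) * 16807 + 1) %% 2147483629)
}

# Row-wise softmax of a numeric matrix.
softmax_mat <- function(m) {
  m <- m - apply(m, 1L, max)
  e <- exp(m)
  e / rowSums(e)
}

one_hot <- function(idx, n_classes) {
  m <- matrix(0, length(idx), n_classes)
  m[cbind(seq_along(idx), as.integer(idx))] <- 1
  m
}

`%||%` <- function(a, b) if (is.null(a)) b else a
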