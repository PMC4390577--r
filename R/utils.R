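#' Derive a reproducible child seed from a master seed and a purpose string
#'
#' All randomness in the package flows from one top-level seed; every module
#' draws from a stream whose seed is a deterministic hash of
#' `(seed, purpose)`. This keeps results identical whether steps run in
#' sequence or independently.
#'
#' @param seed master integer seed
#' @param purpose character tag naming the consumer (e.g. "folds/rep3")
#' @return an integer in `[1, 2^31 - 2]`
#' @export
derive_seed <- function(seed, purpose) {
  stopifnot(is.numeric(seed), length(seed) == 1L, length(purpose) == 1L)
  h <- as.double(seed %% 2147483647L)
  for (b in utf8ToInt(paste0("#", purpose))) {
    h <- (h * 31 + b) %% 2147483647
  }
  as.integer(h) + 1L
}

#' Guard a relationship matrix against round-off negative eigenvalues
#'
#' Adds diagonal jitter `1e-8 * mean(diag(K))` when the smallest eigenvalue
#' falls below `-1e-8` times the largest, and reports the event via a
#' message. Used before any factorization of G, S or T.
#'
#' @param K symmetric matrix
#' @param label name used in the log message
#' @return K, possibly with jitter added (attribute `jitter_applied`)
#' @export
ensure_psd <- function(K, label = "K") {
  ev <- eigen(K, symmetric = TRUE, only.values = TRUE)$values
  tol <- 1e-8 * max(abs(ev[1]), 1e-12)
  jit <- 0
  if (min(ev) < -tol) {
    jit <- 1e-8 * mean(diag(K))
    if (jit <= 0) jit <- 1e-10
    K <- K + diag(jit, nrow(K))
    message(sprintf("PSD guard: added jitter %.3e to diagonal of %s", jit, label))
  }
  attr(K, "jitter_applied") <- jit
  K
}

`%||%` <- function(a, b) if (is.null(a)) b else a

stop_blupga <- function(fmt, ...) stop(sprintf(fmt, ...), call. = FALSE)
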