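#' Derive a deterministic child seed from a parent seed and a label path
#'
#' Every stochastic routine in the package draws its randomness from a seed
#' derived from one user-facing integer seed plus a string path naming the
#' consumer (e.g. `derive_seed(1, "screen", set_id)`). Adding a new consumer
#' therefore never perturbs the streams of existing ones, and any sub-result
#' (one gene set's validation, one leave-one-out subset) is reproducible in
#' isolation.
#'
#' The fold is an FNV-style byte hash computed in double arithmetic modulo
#' 2147483647, so the result always fits a 32-bit R integer.
#'
#' @param seed Integer master seed.
#' @param ... Character or numeric components naming the consumer.
#' @return A positive integer seed (< 2^31).
#' @export
#' @examples
#' derive_seed(1, "bulk")
#' derive_seed(1, "cycle", 3, "GENE017")
derive_seed <- function(seed, ...) {
  stopifnot(length(seed) == 1L, is.finite(seed))
  parts <- paste(c(format(seed, scientific = FALSE), ...), collapse = "\r")
  bytes <- utf8ToInt(parts)
  m <- 2147483647
  h <- 2166136261 %% m
  for (b in bytes) {
    h <- (h * 127 + b + 1) %% m
  }
  as.integer(h %% 2147483629L + 1L)
}

# Run code under a temporary RNG seed, restoring global RNG state afterwards.
local_seed_eval <- function(seed, code) {
  withr::with_seed(as.integer(seed), code)
}
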