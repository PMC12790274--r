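#' Derive a child seed from a master seed and a stream label
#'
#' All randomness in the package flows through labelled child streams derived
#' from one master seed, so that adding a new random component never perturbs
#' the draws of an existing one, and so that the two comparator arms of a run
#' can regenerate identical natural-history streams (common random numbers).
#'
#' @param seed master seed (integer).
#' @param label character stream label, e.g. `"population"` or `"death"`.
#' @param index optional integer sub-index (cycle number, PSA draw, ...).
#' @return an integer in `[0, 2^31 - 2]` suitable for [set.seed()].
#' @export
child_seed <- function(seed, label, index = 0L) {
  stopifnot(is.character(label), length(label) == 1L)
  h <- 0
  for (ch in utf8ToInt(label)) h <- (h * 31 + ch) %% 1000003
  m <- .Machine$integer.max # 2^31 - 1
  val <- ((abs(seed) %% 96557) * 20011 + h * 1009 + (index %% 65521) * 97 + 1) %% m
  as.integer(val)
}

# n uniforms from the (seed, label, index) stream; identical across calls.
stream_runif <- function(n, seed, label, index = 0L) {
  if (n == 0L) return(numeric(0))
  set.seed(child_seed(seed, label, index))
  stats::runif(n)
}
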