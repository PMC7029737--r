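#' Round half away from zero
#'
#' Commercial rounding used wherever the package converts a continuous value
#' to an integer quantity (averaged hyperparameters, weight-index mapping).
#' Unlike [base::round()], which rounds half to even, 10.5 becomes 11 and
#' -10.5 becomes -11.
#'
#' @param x Numeric vector.
#' @return Integer-valued numeric vector.
#' @examples
#' round_half_away(c(10.5, 11.5, -10.5))
#' @export
round_half_away <- function(x) {
  sign(x) * floor(abs(x) + 0.5)
}

# Deterministic stream of derived seeds: replicate/epoch seeds depend only on
# (base seed, index), so changing the number of replicates never reshuffles
# earlier ones. Kept strictly below 2^31 - 1.
derive_seed <- function(base_seed, k) {
  base_seed <- as.numeric(base_seed) %% 2147483647
  as.integer((base_seed * 7919 + 104729 * as.numeric(k)) %% 2147483629 + 1)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

stopf <- function(fmt, ...) stop(sprintf(fmt, ...), call. = FALSE)

msgf <- function(verbose, fmt, ...) {
  if (isTRUE(verbose)) message(sprintf(fmt, ...))
}
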