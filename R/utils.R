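#' @keywords internal
"_PACKAGE"

# Every stochastic operation routes its randomness through one seeded
# generator and restores the caller's RNG state afterwards.
with_op_seed <- function(seed, code) {
  if (is.null(seed)) return(force(code))
  stopifnot(is.numeric(seed), length(seed) == 1L, is.finite(seed))
  withr::with_seed(as.integer(seed), code)
}

# Derive a child seed from a master seed and a stage index, kept < 2^31.
derive_seed <- function(seed, stage) {
  as.integer((as.double(seed) * 69069 + 12345 * as.double(stage)) %% 2147483647) + 1L
}

`%||%` <- function(a, b) if (is.null(a)) b else a

stop_nla <- function(fmt, ...) stop(sprintf(fmt, ...), call. = FALSE)

assert_that <- function(ok, fmt, ...) if (!isTRUE(ok)) stop_nla(fmt, ...)

clamp <- function(x, lo, hi) pmin(pmax(x, lo), hi)
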