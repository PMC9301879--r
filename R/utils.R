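#' @importFrom rlang .data
#' @importFrom stats dnorm pnorm qnorm rnorm runif optim oneway.test
#'   sd cor aov p.adjust ptukey pt qtukey t.test setNames
#' @importFrom utils head
NULL

# Run `code` under a temporarily seeded RNG, restoring global RNG state after.
with_seed <- function(seed, code) {
  withr::with_seed(as.integer(seed), code, .rng_kind = "Mersenne-Twister")
}

# Derive a reproducible child seed from a parent seed and a stream label.
# Keeps results independent across streams while staying below 2^31.
derive_seed <- function(seed, ...) {
  key <- paste(c(seed, ...), collapse = "/")
  h <- 0
  for (ch in utf8ToInt(key)) h <- (h * 131 + ch) %% 2147483629
  as.integer(h)
}

`%||%` <- function(x, y) if (is.null(x)) y else x
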