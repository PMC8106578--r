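#' @importFrom stats median rnorm rbinom rnbinom rpois rbeta rlnorm runif
#'   setNames quantile p.adjust pnorm pchisq wilcox.test binom.test glm
#'   binomial lm coef vcov optimize kmeans prcomp var sd rmultinom
#'   complete.cases dnbinom dpois ave
#' @importFrom utils read.delim write.table head
NULL

clip <- function(x, lo, hi) pmin(pmax(x, lo), hi)

## Derive a stream of reproducible sub-seeds (< 2^31) from one master seed.
deriveSeeds <- function(seed, n) {
  withr::with_seed(seed, sample.int(.Machine$integer.max - 1L, n))
}

`%||%` <- function(a, b) if (is.null(a)) b else a

stopUnlessIn <- function(x, allowed, what) {
  bad <- setdiff(unique(x), allowed)
  if (length(bad))
    stop(sprintf("unknown %s: %s", what, paste(bad, collapse = ", ")), call. = FALSE)
  invisible(x)
}
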