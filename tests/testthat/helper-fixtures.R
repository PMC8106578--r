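# Small fixtures built in code; all randomness seeded per call.

suppressPackageStartupMessages({
  library(SummarizedExperiment)
  library(Matrix)
})

tinyAnnotation <- function(n_auto = 200, ...)
  buildFixtureAnnotation(n_autosome = n_auto, n_x_nonpar = 10, ...)

# sample table spanning the five LOY bins with alternating batches
binSpanningSamples <- function(n = 40, batches = c("b1", "b2")) {
  data.frame(subject = sprintf("s%02d", seq_len(n)),
             cell_type = "NK",
             batch = rep(batches, length.out = n),
             f = rep(c(0, 0.25, 0.45, 0.65, 0.85), length.out = n))
}

# brute-force BH step-up from the definition: q_(i) = min_{j >= i} m p_(j)/j
bhOracle <- function(p) {
  m <- length(p)
  o <- order(p)
  ps <- p[o]
  q <- numeric(m)
  for (i in seq_len(m)) {
    best <- Inf
    for (j in i:m) best <- min(best, m * ps[j] / j)
    q[i] <- min(best, 1)
  }
  q[order(o)]
}
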