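test_that("median-of-ratios size factors behave on constructed toys", {
  k <- matrix(rpois(200 * 4, 50), 200, 4,
              dimnames = list(paste0("g", 1:200), paste0("s", 1:4)))
  # identical columns -> all 1
  same <- k[, c(1, 1, 1)]
  colnames(same) <- paste0("s", 1:3)
  expect_equal(unname(computeSizeFactors(same)), rep(1, 3))
  # doubling one column doubles its factor relative to the others
  dbl <- cbind(k[, 1], k[, 1], 2 * k[, 1])
  colnames(dbl) <- paste0("s", 1:3)
  s <- computeSizeFactors(dbl)
  expect_equal(unname(s[3] / s[1]), 2, tolerance = 1e-9)
  # single sample: scaling convention s = 1
  expect_equal(unname(computeSizeFactors(k[, 1, drop = FALSE])), 1)
  expect_error(computeSizeFactors(matrix(c(0, 1, 1, 0), 2, 2)), "no genes")
})

test_that("size factors agree with the reference median-of-ratios oracle", {
  skip_if_not_installed("DESeq2")
  set.seed(50)
  k <- matrix(rnbinom(500 * 8, mu = outer(rlnorm(500, 4, 1), runif(8, 0.5, 2)),
                      size = 10), 500, 8)
  rownames(k) <- paste0("g", 1:500)
  mine <- computeSizeFactors(k)
  ref <- DESeq2::estimateSizeFactorsForMatrix(k)
  ref <- ref / exp(mean(log(ref)))   # same geometric-mean-1 convention
  expect_equal(unname(mine), unname(ref), tolerance = 1e-6)
})

test_that("dispersion trend recovers simulated parameters", {
  ann <- buildFixtureAnnotation(n_autosome = 3000, n_x_nonpar = 0,
                                n_msy = 0, n_par = 0, n_mito = 0)
  st <- data.frame(subject = sprintf("s%02d", 1:30), cell_type = "NK",
                   batch = "b1", f = 0)
  sim <- simulateBulkCounts(st, ann, dispersion = c(0.05, 2), seed = 51)
  tr <- fitDispersionTrend(assay(sim$bulk, "counts"))
  expect_lt(abs(tr$a0 - 0.05) / 0.05, 0.3)
  # Poisson data: asymptotic dispersion collapses
  set.seed(52)
  pois <- matrix(rpois(2000 * 30, rep(rlnorm(2000, 5, 1), 30)), 2000, 30)
  rownames(pois) <- paste0("g", 1:2000)
  trp <- fitDispersionTrend(pois)
  expect_lte(trp$a0, 0.01)
  # constant means leave a1 unidentifiable -> fallback with warning
  const <- matrix(rpois(100 * 10, 100), 100, 10,
                  dimnames = list(paste0("g", 1:100), NULL))
  expect_warning(trc <- fitDispersionTrend(const, size_factors = rep(1, 10)),
                 "falling back|fewer than")
  expect_equal(trc$a1, 0)
})

test_that("the VST maps 0 to 0, tracks log2 for large counts and flattens variance", {
  trend <- list(a0 = 0.05, a1 = 2)
  v <- function(k) (2 / log(2)) * asinh(sqrt(trend$a0 * k))
  expect_equal(v(0), 0)
  # large-count slope in log2(K) tends to 1
  slope <- (v(1e5 * 2) - v(1e5)) / 1
  expect_equal(slope, 1, tolerance = 0.01)
  # strictly increasing, hence rank-preserving per sample
  k <- sort(rlnorm(100, 4, 2))
  expect_true(all(diff(v(k)) > 0))
  # variance flattening across mean-expression deciles on NB data
  set.seed(53)
  mu <- rlnorm(3000, log(100), 1.5)
  alpha <- 0.05 + 2 / mu
  raw <- matrix(rnbinom(3000 * 20, mu = rep(mu, 20), size = rep(1 / alpha, 20)),
                3000, 20, dimnames = list(paste0("g", 1:3000), NULL))
  tr <- fitDispersionTrend(raw, size_factors = rep(1, 20))
  vst <- vstTransform(raw, size_factors = rep(1, 20), trend = tr)
  dec <- cut(mu, quantile(mu, 0:10 / 10), include.lowest = TRUE)
  ratio <- function(m) {
    bv <- tapply(seq_len(3000), dec, function(i) median(apply(m[i, ], 1, var)))
    max(bv) / min(bv)
  }
  expect_gt(ratio(raw), 30)
  expect_lt(ratio(vst), 3)
})

test_that("bulk Y-expression fraction tracks the true cell fraction", {
  ann <- tinyAnnotation(n_auto = 400)
  st <- data.frame(subject = sprintf("s%02d", 1:27), cell_type = "NK",
                   batch = "b1", f = rep(seq(0, 0.8, by = 0.1), 3))
  sim <- simulateBulkCounts(st, ann, seed = 54)
  est <- bulkYFractionLoy(sim$bulk)
  expect_gte(cor(est$raw_stat, 1 - st$f, method = "spearman"), 0.9)
  # min-max endpoints
  expect_equal(min(est$rescaled), 0)
  expect_equal(max(est$rescaled), 100)
  # invariant to per-sample library rescaling (absorbed by size factors)
  fac <- rep(c(2, 0.5), length.out = 26)          # geometric mean 1
  sub <- sim$bulk[, 1:26]
  base <- bulkYFractionLoy(sub)
  counts2 <- sweep(assay(sub, "counts"), 2, fac, "*")
  bulk2 <- LoyBulkExperiment(counts2, as.data.frame(colData(sub)), ann)
  est2 <- bulkYFractionLoy(bulk2)
  expect_equal(est2$raw_stat, base$raw_stat, tolerance = 1e-9)
  # invariant to relabeling autosomal genes
  auto <- genesInRegion(ann, "AUTOSOME")
  k3 <- assay(sim$bulk, "counts")
  perm <- c(setdiff(rownames(k3), auto), sample(auto))
  bulk3 <- LoyBulkExperiment(k3[perm, ], as.data.frame(colData(sim$bulk)), ann)
  expect_equal(sort(bulkYFractionLoy(bulk3)$raw_stat), sort(est$raw_stat),
               tolerance = 1e-9)
  expect_error(bulkYFractionLoy(sim$bulk[, 1]), "fewer than 2")
})

test_that("normally-expressed filter requires >75% of reference samples", {
  ann <- tinyAnnotation(n_auto = 5)
  genes <- annotationTable(ann)$gene_id
  counts <- matrix(0, length(genes), 4,
                   dimnames = list(genes, paste0("s", 1:4)))
  counts["AUT0001", ] <- c(10, 10, 10, 0)    # 3/4 = 75% exactly -> excluded
  counts["AUT0002", ] <- 10                  # 4/4 -> included
  counts["AUT0003", ] <- c(9, 10, 10, 10)    # 3/4 above threshold -> excluded
  counts["AUT0004", ] <- 50                  # included
  counts[genes[!genes %in% paste0("AUT000", 1:4)], ] <- 1
  bulk <- LoyBulkExperiment(counts,
    data.frame(subject = paste0("s", 1:4), cell_type = "NK", batch = "b1",
               dna_loy_fraction = 0), ann)
  expr <- normallyExpressedGenesBulk(bulk)
  expect_setequal(intersect(expr, paste0("AUT000", 1:5)),
                  c("AUT0002", "AUT0004"))
  bulk0 <- LoyBulkExperiment(counts,
    data.frame(subject = paste0("s", 1:4), cell_type = "NK", batch = "b1",
               dna_loy_fraction = 0.5), ann)
  expect_error(normallyExpressedGenesBulk(bulk0), "reference")
})

test_that("expression-vs-LOY regression recovers exact dosage slopes", {
  loy_pct <- seq(0, 100, by = 10)
  msy_expr <- 1 - loy_pct / 100          # full loss of the Y copy
  par_expr <- 1 - loy_pct / 200          # retained X copy
  # lm warns the noise-free fit is "essentially perfect" - that is the point
  fit_msy <- suppressWarnings(expressionVsLoyRegression(msy_expr, loy_pct))
  fit_par <- suppressWarnings(expressionVsLoyRegression(par_expr, loy_pct))
  expect_equal(fit_msy$beta, -0.01, tolerance = 1e-12)
  expect_equal(fit_par$beta, -0.005, tolerance = 1e-12)
  expect_error(expressionVsLoyRegression(c(1, 2, 3), c(5, 5, 5)), "constant")
  expect_error(expressionVsLoyRegression(1:2, 1:2), "3 samples")
  # exponential model reports a comparable initial slope on linear data
  fit_exp <- suppressWarnings(
    expressionVsLoyRegression(exp(-0.01 * loy_pct), loy_pct,
                              model = "exponential"))
  expect_equal(fit_exp$beta, -0.01, tolerance = 0.001)
})
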