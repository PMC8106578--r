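test_that("LOY binning follows the fixed 20-percent mapping", {
  expect_equal(binLoy(c(0, 15, 20, 45, 79.9, 80, 100)),
               c(0, 0, 1, 2, 3, 4, 4))
  expect_error(binLoy(-1), "outside")
  expect_error(binLoy(101), "outside")
})

test_that("the NB GLM matches an independent ML fit and flags bad designs", {
  skip_if_not_installed("MASS")
  set.seed(60)
  n <- 60
  design <- data.frame(loy_bin = rep(0:4, 12),
                       batch = rep(c("b1", "b2"), 30))
  mu <- exp(4 + 0.3 * design$loy_bin)
  y <- rnbinom(n, mu = mu, size = 10)
  mine <- fitNbGlm(y, design, "loy_bin", shrink = 0)
  ref <- MASS::glm.nb(y ~ loy_bin + batch, data = design)
  expect_equal(mine$de * log(2), unname(coef(ref)["loy_bin"]),
               tolerance = 0.02)
  expect_equal(mine$se * log(2),
               unname(sqrt(vcov(ref)["loy_bin", "loy_bin"])),
               tolerance = 0.1)
  # singular design names the aliased column
  bad <- data.frame(loy_bin = rep(0:4, 12), copy = rep(0:4, 12))
  expect_error(fitNbGlm(y, bad, "loy_bin"), "copy")
})

test_that("injected effects are recovered per bin unit", {
  ann <- tinyAnnotation(n_auto = 200)
  st <- binSpanningSamples(40)
  late <- setNames(rep(0.5, 20), sprintf("AUT%04d", 1:20))
  est <- unlist(lapply(1:5, function(r) {
    sim <- simulateBulkCounts(st, ann, late_spec = late, seed = 600 + r)
    res <- runLateAnalysis(sim$bulk)
    res$de[match(names(late), res$gene_id)]
  }))
  expect_equal(mean(est, na.rm = TRUE), 0.5, tolerance = 0.1)
})

test_that("BH adjustment matches hand-computed step-up and propagates NaN", {
  expect_equal(bhAdjust(c(0.01, 0.02, 0.03)), c(0.03, 0.03, 0.03))
  expect_equal(bhAdjust(0.2), 0.2)
  expect_equal(bhAdjust(rep(1, 5)), rep(1, 5))
  q <- bhAdjust(c(0.01, NaN, 0.5))
  expect_true(is.na(q[2]))
  expect_equal(q[c(1, 3)], bhAdjust(c(0.01, 0.5)))
})

test_that("independent filtering never loses rejections and handles edge cases", {
  set.seed(61)
  # low-mean genes carry no signal; filtering must not reduce discoveries
  n_sig <- 100
  res <- data.frame(
    wald_p = c(runif(n_sig, 0, 1e-4), runif(900)),
    mean_reads = c(rlnorm(n_sig, 6, 0.3), rlnorm(900, 2, 0.5)))
  filtered <- independentFilter(res, alpha = 0.1)
  base_rej <- sum(bhAdjust(res$wald_p) < 0.1)
  expect_gte(sum(filtered$fdr_q < 0.1), base_rej)
  # identically powered genes: threshold stays at the minimum
  res2 <- data.frame(wald_p = runif(500), mean_reads = rep(100, 500))
  expect_equal(attr(independentFilter(res2), "n_removed"), 0)
  empty <- independentFilter(data.frame(wald_p = numeric(0),
                                        mean_reads = numeric(0)))
  expect_equal(nrow(empty), 0)
})

test_that("stringency tiers apply the p, FDR and 100-read rules", {
  res <- data.frame(wald_p = c(0.04, 0.001, 0.001, 0.5),
                    fdr_q = c(0.2, 0.05, 0.05, 0.9),
                    mean_reads = c(500, 99, 100, 500))
  out <- classifyLateTiers(res)
  expect_equal(out$tier, c("NOMINAL", "FDR", "HIGH_EXPR", "NONE"))
})

test_that("fold-change conversion matches printed flagship values", {
  fc <- foldChangeFromDe(c(3.11, -1.30, 0))
  expect_equal(round(fc$fold, 1), c(8.6, 2.5, 1.0))
  expect_equal(fc$direction, c("up", "down", "up"))
  expect_equal(fc$neutral, c(FALSE, FALSE, TRUE))
})

test_that("sign concordance uses the exact binomial test", {
  a <- data.frame(gene_id = paste0("g", 1:10), de = rep(1, 10))
  b <- data.frame(gene_id = paste0("g", 1:10), de = rep(2, 10))
  out <- signConcordance(a, b)
  expect_equal(out$n_agree, 10)
  expect_equal(out$p_value, 2 * 0.5^10)
  b$de[1:5] <- -1
  expect_equal(signConcordance(a, b)$p_value, 1)
  b$de[1] <- 0
  expect_warning(out2 <- signConcordance(a, b), "zero effect")
  expect_equal(out2$n_total, 9)
  expect_error(signConcordance(a, data.frame(gene_id = "x", de = 1)),
               "no shared")
})

test_that("shared-fraction analysis separates private from shared signal", {
  expressed <- list(NK = paste0("g", 1:100), Mono = paste0("g", 1:100))
  # identical LATE sets: within equals shared
  same <- list(NK = paste0("g", 1:10), Mono = paste0("g", 1:10))
  out <- sharedFractionAnalysis(same, expressed, n_perm = 200)
  expect_equal(unique(out$fractions$fraction), 0.1)
  # disjoint sets: all shared fractions zero, within clearly larger
  disj <- list(NK = paste0("g", 1:10), Mono = paste0("g", 11:20))
  out2 <- sharedFractionAnalysis(disj, expressed, n_perm = 200)
  expect_equal(out2$fractions$fraction[out2$fractions$kind == "shared"], 0)
  expect_error(sharedFractionAnalysis(disj, list(NK = character(0),
                                                 Mono = "g1")), "empty")
})
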