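test_that("generators are bit-identical under a fixed seed", {
  ann <- tinyAnnotation(n_auto = 50)
  a <- simulateSnpArray(c(0, 0.3), seed = 42)
  b <- simulateSnpArray(c(0, 0.3), seed = 42)
  expect_identical(assay(a$lrr, "lrr"), assay(b$lrr, "lrr"))

  d1 <- simulateDdpcr(0.2, seed = 42)
  d2 <- simulateDdpcr(0.2, seed = 42)
  expect_identical(d1$positive_y, d2$positive_y)

  st <- binSpanningSamples(10)
  k1 <- simulateBulkCounts(st, ann, seed = 42)
  k2 <- simulateBulkCounts(st, ann, seed = 42)
  expect_identical(assay(k1$bulk, "counts"), assay(k2$bulk, "counts"))

  s1 <- simulateScCounts(c(B = 20, Monocyte = 20, NK = 20, T = 20), ann,
                         seed = 42)
  s2 <- simulateScCounts(c(B = 20, Monocyte = 20, NK = 20, T = 20), ann,
                         seed = 42)
  expect_identical(assay(s1$cells, "counts"), assay(s2$cells, "counts"))
})

test_that("SNP-array generator means follow log2(1 - f)/2 plus batch offset", {
  # closed form of the generator mean at f = 0.5 and 0.75
  sim <- simulateSnpArray(rep(c(0.5, 0.75), each = 200), n_msy_probes = 200,
                          noise_sd = 0.05, seed = 1)
  m <- computeMlrry(sim$lrr)
  expect_equal(mean(m[1:200]), -0.5, tolerance = 0.01)
  expect_equal(mean(m[201:400]), -1.0, tolerance = 0.01)
  expect_equal(unname(sim$truth$expected_mlrry[1]), log2(0.5) / 2)
  expect_error(simulateSnpArray(1), "log")
  # batch offsets shift both MSY and non-MSY probes
  sim2 <- simulateSnpArray(rep(0, 100), batch = rep(c("a", "b"), 50),
                           batch_offsets = c(a = 0.1, b = -0.1),
                           noise_sd = 0.05, seed = 2)
  m2 <- computeMlrry(sim2$lrr)
  expect_equal(mean(m2[seq(1, 100, 2)]) - mean(m2[seq(2, 100, 2)]), 0.2,
               tolerance = 0.01)
})

test_that("ddPCR generator follows Poisson partitioning", {
  # E[positive_x] = n (1 - exp(-templates/n)) = 20000 (1 - e^-0.2)
  sim <- simulateDdpcr(rep(0.5, 300), n_droplets = 20000,
                       templates_x = 4000, seed = 3)
  expect_equal(mean(sim$positive_x), 20000 * (1 - exp(-0.2)),
               tolerance = 3 * sd(sim$positive_x) / sqrt(300) /
                 (20000 * (1 - exp(-0.2))))
  # f = 0: equal template load on both channels
  s0 <- simulateDdpcr(rep(0, 300), seed = 4)
  expect_lt(abs(mean(s0$positive_y) - mean(s0$positive_x)),
            3 * sd(s0$positive_y - s0$positive_x) / sqrt(300))
  # f = 1: no Y templates
  s1 <- simulateDdpcr(1, seed = 5)
  expect_equal(s1$positive_y, 0)
  expect_error(simulateDdpcr(0.5, templates_x = 0))
})

test_that("bulk generator applies MSY/PAR dosage and LATE effects", {
  ann <- tinyAnnotation(n_auto = 100)
  mu <- setNames(rep(1000, nrow(annotationTable(ann))),
                 annotationTable(ann)$gene_id)
  st <- data.frame(subject = c("a", "b"), cell_type = "NK", batch = "b1",
                   f = c(0, 0.5))
  sim <- simulateBulkCounts(st, ann, baseline_means = mu,
                            dispersion = c(1e-4, 0), seed = 6)
  counts <- assay(sim$bulk, "counts")
  msy <- genesInRegion(ann, "MSY"); par <- genesInRegion(ann, "PAR")
  # MSY dosage (1 - f), PAR dosage (1 - f/2), autosomes unchanged
  expect_equal(mean(counts[msy, 2]) / mean(counts[msy, 1]), 0.5,
               tolerance = 0.02)
  expect_equal(mean(counts[par, 2]) / mean(counts[par, 1]), 0.75,
               tolerance = 0.02)
  auto <- genesInRegion(ann, "AUTOSOME")
  expect_equal(mean(counts[auto, 2]) / mean(counts[auto, 1]), 1,
               tolerance = 0.02)
  # LATE spec scales by 2^(de * bin)
  late <- c(AUT0001 = 1)
  sim2 <- simulateBulkCounts(st, ann, late_spec = late, baseline_means = mu,
                             dispersion = c(1e-4, 0), seed = 7)
  k2 <- assay(sim2$bulk, "counts")
  expect_equal(k2["AUT0001", 2] / k2["AUT0001", 1], 2^binLoy(50),
               tolerance = 0.05)
  expect_error(simulateBulkCounts(st, ann, late_spec = c(NOPE = 1)),
               "NOPE")
})

test_that("single-cell generator records truth and respects LOY zeroing", {
  ann <- tinyAnnotation(n_auto = 100)
  sim <- simulateScCounts(c(B = 50, Monocyte = 50, NK = 50, T = 50), ann,
                          seed = 8)
  truth <- sim$truth$cell
  counts <- assay(sim$cells, "counts")
  msy <- intersect(genesInRegion(ann, "MSY"), rownames(counts))
  msy_umis <- Matrix::colSums(counts[msy, , drop = FALSE])
  # LOY cells never express MSY genes
  expect_true(all(msy_umis[truth$loy] == 0))
  # zero LOY fraction produces no LOY cells in truth
  s0 <- simulateScCounts(c(B = 30, Monocyte = 30, NK = 30, T = 30), ann,
                         loy_fractions = c(B = 0, Monocyte = 0, NK = 0, T = 0),
                         seed = 9)
  expect_false(any(s0$truth$cell$loy))
  # per-type frequencies within binomial error of the defaults
  big <- simulateScCounts(c(B = 400, Monocyte = 400, NK = 400, T = 400), ann,
                          seed = 10)
  fr <- tapply(big$truth$cell$loy, big$truth$cell$cell_type, mean)
  pars <- c(B = 0.07, Monocyte = 0.23, NK = 0.27, T = 0.03)
  for (ty in names(pars))
    expect_lt(abs(fr[[ty]] - pars[[ty]]),
              3 * sqrt(pars[[ty]] * (1 - pars[[ty]]) / 400))
  expect_error(simulateScCounts(c(B = 10, Monocyte = 10, NK = 10, T = 10),
                                ann, doublet_rate = 1), "doublet_rate")
})

test_that("LCL generator enforces the single-donor LOY design", {
  ann <- tinyAnnotation(n_auto = 30)
  sim <- simulateLclClones(ann, seed = 11)
  expect_equal(ncol(sim$bulk), 13)
  expect_equal(length(unique(sim$design$individual_id)), 6)
  loy_donors <- unique(sim$design$individual_id[sim$design$loy_status == "LOY"])
  expect_length(loy_donors, 1)
  # that donor also has a non-LOY clone
  expect_true(any(sim$design$loy_status == "NORMAL" &
                    sim$design$individual_id == loy_donors))
  expect_error(simulateLclClones(ann, loy_clones = c(1, 4), seed = 1),
               "more than one individual")
  # confounded genes are flagged
  both <- simulateLclClones(ann,
    inter_individual_genes = list(AUT0001 = c(1, 0, 0, 0, 0, 0)),
    loy_genes = c(AUT0001 = 1, AUT0002 = 1), seed = 12)
  expect_equal(both$truth$confounded_genes, "AUT0001")
})

test_that("cohort generator matches requested design", {
  sim <- simulateCohort(seed = 13)
  expect_equal(nrow(sim$table), (156 + 121 + 107) * 6)
  expect_equal(as.vector(table(sim$table$group)[c("CONTROL", "AD", "PC")]),
               c(156, 121, 107) * 6)
  expect_true(all(sim$table$loy_fraction >= 0 & sim$table$loy_fraction <= 1))
  # a targeted shift moves only that stratum
  shift <- matrix(0, 3, 2, dimnames = list(c("CONTROL", "AD", "PC"),
                                           c("NK", "B")))
  shift["AD", "NK"] <- 1.5
  s2 <- simulateCohort(n_control = 300, n_ad = 300, n_pc = 50,
                       cell_types = c("NK", "B"), shift_matrix = shift,
                       seed = 14)
  mAD <- with(s2$table, mean(loy_fraction[group == "AD" & cell_type == "NK"]))
  mCT <- with(s2$table, mean(loy_fraction[group == "CONTROL" & cell_type == "NK"]))
  mB <- with(s2$table, mean(loy_fraction[group == "AD" & cell_type == "B"]) -
               mean(loy_fraction[group == "CONTROL" & cell_type == "B"]))
  expect_gt(mAD - mCT, 0.05)
  expect_lt(abs(mB), 0.05)
})
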