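mkCellExperiment <- function(counts, ann, sample_id = "s1") {
  LoyCellExperiment(counts, sample_id, ann)
}

test_that("QC filter applies the 800/2000/5% boundaries inclusively", {
  ann <- tinyAnnotation(n_auto = 2500)
  auto <- genesInRegion(ann, "AUTOSOME")
  mito <- genesInRegion(ann, "MITO")
  genes <- c(auto, mito)
  mk <- function(n_auto_genes, mito_umis = 0, auto_per_gene = 1) {
    v <- setNames(numeric(length(genes)), genes)
    v[auto[seq_len(n_auto_genes)]] <- auto_per_gene
    if (mito_umis > 0) v[mito[1]] <- mito_umis
    v
  }
  counts <- cbind(
    a799 = mk(799),                       # too few genes
    a800 = mk(800),                       # boundary, kept
    a2000 = mk(2000),                     # boundary, kept
    a2001 = mk(2001),                     # doublet-like, removed
    mito5 = mk(1900, mito_umis = 100),    # 100/2000 = 5.0%, kept
    mito65 = mk(1870, mito_umis = 130)    # 130/2000 = 6.5%, removed
  )
  rownames(counts) <- genes
  cm <- mkCellExperiment(counts, ann)
  kept <- colnames(qcFilterCells(cm))
  expect_setequal(kept, c("a800", "a2000", "mito5"))
  expect_warning(qcFilterCells(cm, min_genes = 1e6), "every cell")
})

test_that("LOY calling needs >2500 UMIs, zero MSY and autosomal evidence", {
  ann <- tinyAnnotation(n_auto = 50)
  genes <- annotationTable(ann)$gene_id
  msy <- genesInRegion(ann, "MSY")[1]
  auto <- genesInRegion(ann, "AUTOSOME")
  mk <- function(total, msy_umis) {
    v <- setNames(numeric(length(genes)), genes)
    v[auto[1:10]] <- (total - msy_umis) / 10
    v[msy] <- msy_umis
    v
  }
  counts <- cbind(loy = mk(3000, 0), normal = mk(3000, 1),
                  at_threshold = mk(2500, 0), above = mk(2501, 0))
  rownames(counts) <- genes
  cm <- callLoyCells(mkCellExperiment(counts, ann))
  st <- setNames(colData(cm)$loy_status, colnames(cm))
  expect_equal(unname(st[c("loy", "normal", "at_threshold", "above")]),
               c("LOY", "NORMAL", "UNCALLED", "LOY"))
  # raising the threshold never increases LOY calls
  thresholds <- c(1000, 2500, 4000)
  calls <- vapply(thresholds, function(u)
    sum(colData(callLoyCells(cm, min_umis = u))$loy_status == "LOY"),
    numeric(1))
  expect_true(all(diff(calls) <= 0))
  noY <- mkCellExperiment(counts[!rownames(counts) %in%
                                   genesInRegion(ann, "MSY"), ], ann)
  expect_error(callLoyCells(noY), "MSY")
})

test_that("per-sample LOY fractions exclude uncalled cells", {
  ann <- tinyAnnotation(n_auto = 20)
  sim <- simulateScCounts(c(B = 30, Monocyte = 30, NK = 30, T = 30), ann,
                          seed = 40)
  cells <- sim$cells
  colData(cells)$loy_status <- rep(c("LOY", "NORMAL", "NORMAL", "UNCALLED"),
                                   length.out = ncol(cells))
  colData(cells)$cell_type <- "all"
  fr <- sampleLoyFraction(cells)
  expect_equal(fr$loy_fraction, 1 / 3)
  expect_equal(fr$n_called, sum(colData(cells)$loy_status != "UNCALLED"))
  colData(cells)$loy_status <- rep("UNCALLED", ncol(cells))
  expect_warning(fr2 <- sampleLoyFraction(cells), "zero called")
  expect_true(is.na(fr2$loy_fraction))
  # invariant to cell order
  colData(cells)$loy_status <- rep(c("LOY", "NORMAL"), length.out = ncol(cells))
  perm <- sample(ncol(cells))
  expect_equal(sampleLoyFraction(cells)$loy_fraction,
               sampleLoyFraction(cells[, perm])$loy_fraction)
})

test_that("normally expressed genes use the 10%-of-normal-cells rule", {
  ann <- tinyAnnotation(n_auto = 30)
  genes <- annotationTable(ann)$gene_id
  n <- 100
  counts <- matrix(0, length(genes), n, dimnames = list(genes, paste0("c", 1:n)))
  counts["AUT0001", 1:10] <- 1   # exactly 10% -> included
  counts["AUT0002", 1:9] <- 1    # 9% -> excluded
  counts["AUT0003", ] <- 5
  cm <- mkCellExperiment(counts, ann)
  colData(cm)$loy_status <- "NORMAL"
  expr <- normallyExpressedGenesSc(cm)$all
  expect_true("AUT0001" %in% expr)
  expect_false("AUT0002" %in% expr)
  colData(cm)$loy_status <- "LOY"
  expect_error(normallyExpressedGenesSc(cm), "NORMAL")
})

test_that("marker-based typing labels clusters by argmax with tie warnings", {
  ann <- tinyAnnotation(n_auto = 300)
  sim <- simulateScCounts(c(B = 60, Monocyte = 60, NK = 60, T = 60), ann,
                          seed = 41)
  truth <- sim$truth$cell
  cl <- as.integer(factor(truth$cell_type))   # perfect clusters
  typed <- assignCellTypes(sim$cells, defaultMarkerTable(ann), cl)
  acc <- mean(colData(typed)$cell_type == truth$cell_type)
  expect_gte(acc, 0.95)
  # all-zero marker expression -> unknown; ties -> first by name + warning
  genes <- annotationTable(ann)$gene_id
  counts <- matrix(0, length(genes), 4, dimnames = list(genes, paste0("c", 1:4)))
  counts["AUT0050", ] <- 3
  cm <- mkCellExperiment(counts, ann)
  expect_equal(unique(colData(assignCellTypes(cm,
    list(NK = "AUT0001", T = "AUT0002"), rep(1, 4)))$cell_type), "unknown")
  expect_warning(
    typed2 <- assignCellTypes(cm, list(b_type = "AUT0050", a_type = "AUT0050"),
                              rep(1, 4)), "tied")
  expect_equal(unique(colData(typed2)$cell_type), "a_type")
})

test_that("fallback clustering separates simulated types deterministically", {
  ann <- tinyAnnotation(n_auto = 200)
  sim <- simulateScCounts(c(NK = 80, T = 80), ann,
                          marker_table = list(NK = genesInRegion(ann, "AUTOSOME")[1:5],
                                              T = genesInRegion(ann, "AUTOSOME")[6:10]),
                          marker_fold = 40,
                          loy_fractions = c(NK = 0.2, T = 0.2), seed = 42)
  cl <- fallbackCluster(sim$cells, k = 2, seed = 7)
  truth <- sim$truth$cell$cell_type
  agree <- max(mean((cl == 1) == (truth == "NK")),
               mean((cl == 2) == (truth == "NK")))
  expect_gte(agree, 0.9)
  expect_identical(cl, fallbackCluster(sim$cells, k = 2, seed = 7))
  expect_error(fallbackCluster(sim$cells, k = 1000), "exceeds")
  expect_equal(fallbackCluster(sim$cells, k = ncol(sim$cells)),
               seq_len(ncol(sim$cells)))
})

test_that("single-cell DE recovers injected effects and excludes MSY genes", {
  ann <- tinyAnnotation(n_auto = 150)
  late <- setNames(c(1, -1), c("AUT0010", "AUT0011"))
  sim <- simulateScCounts(c(NK = 500), ann,
                          marker_table = list(NK = genesInRegion(ann, "AUTOSOME")[1:3]),
                          loy_fractions = c(NK = 0.5), late_spec = late,
                          umi_meanlog = log(5000), seed = 43)
  cells <- callLoyCells(sim$cells)
  expr <- normallyExpressedGenesSc(cells)$all
  res <- scDifferentialExpression(cells, genes = c(expr,
                                  genesInRegion(ann, "MSY")[1]))
  expect_false(any(res$region_class == "MSY"))
  hit <- res[match(names(late), res$gene_id), ]
  expect_equal(hit$de, unname(late), tolerance = 0.35)
  expect_true(all(hit$fdr_q < 0.1))
  null_p <- res$wald_p[!res$gene_id %in% names(late) &
                         res$region_class == "AUTOSOME"]
  expect_lt(mean(null_p < 0.05, na.rm = TRUE), 0.12)
})
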