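## Single-cell stage: QC filtering, marker-based cell typing, per-cell LOY
## calls from absent MSY transcripts, per-sample LOY fractions, the
## normally-expressed-gene filter and NB differential expression between
## LOY and normal cells.

#' Quality-control filter for single cells
#'
#' Keeps cells with at least \code{min_genes} and no more than
#' \code{max_genes} expressed genes (removing low-quality cells and
#' doublets) and at most \code{max_mito} mitochondrial UMI fraction
#' (removing apoptotic/damaged cells). Boundaries are inclusive at
#' min_genes, max_genes and max_mito ("more than 5\%" is excluded).
#'
#' @param cells [LoyCellExperiment-class].
#' @param min_genes,max_genes detected-gene bounds (defaults 800, 2000).
#' @param max_mito mitochondrial fraction bound (default 0.05).
#' @return the filtered [LoyCellExperiment-class].
#' @export
qcFilterCells <- function(cells, min_genes = 800, max_genes = 2000,
                          max_mito = 0.05) {
  cd <- colData(cells)
  keep <- cd$n_genes_detected >= min_genes &
    cd$n_genes_detected <= max_genes &
    cd$mito_fraction <= max_mito
  if (!any(keep)) warning("QC filter removed every cell")
  cells[, keep]
}

#' Assign cell types to clusters by marker expression
#'
#' For each cluster, each candidate type is scored by the mean normalized
#' expression (counts per 10k, log1p) of that type's marker genes over the
#' cluster's cells; the cluster is labelled with the argmax type. Ties are
#' broken by lexicographic type name with a warning; clusters with zero
#' expression of every marker are labelled "unknown".
#'
#' @param cells [LoyCellExperiment-class].
#' @param markers named list cell_type -> marker gene_ids.
#' @param cluster_ids per-cell cluster labels (default colData
#'   \code{cluster_id}, or [fallbackCluster()] output).
#' @return the experiment with \code{cell_type} (and \code{cluster_id})
#'   filled in colData.
#' @export
assignCellTypes <- function(cells, markers, cluster_ids = NULL) {
  cluster_ids <- cluster_ids %||% colData(cells)$cluster_id
  if (is.null(cluster_ids))
    stop("no cluster_ids; supply them or run fallbackCluster()", call. = FALSE)
  counts <- as.matrix(assay(cells, "counts"))
  norm <- log1p(t(t(counts) / pmax(colData(cells)$n_umis, 1)) * 1e4)
  labels <- character(length(unique(cluster_ids)))
  names(labels) <- sort(unique(as.character(cluster_ids)))
  for (cl in names(labels)) {
    i <- which(as.character(cluster_ids) == cl)
    score <- vapply(markers, function(g) {
      g <- intersect(g, rownames(counts))
      if (!length(g)) return(0)
      mean(norm[g, i, drop = FALSE])
    }, numeric(1))
    if (all(score == 0)) {
      labels[cl] <- "unknown"
    } else {
      top <- names(score)[score == max(score)]
      if (length(top) > 1)
        warning("cluster ", cl, ": tied marker scores (",
                paste(top, collapse = ", "), "); first by name used")
      labels[cl] <- sort(top)[1]
    }
  }
  colData(cells)$cluster_id <- as.character(cluster_ids)
  colData(cells)$cell_type <- unname(labels[as.character(cluster_ids)])
  cells
}

#' Call LOY status per cell from absent MSY transcripts
#'
#' A cell is \code{UNCALLED} unless it has more than \code{min_umis} UMIs
#' (strictly more; exactly 2500 is not enough). Called cells with autosomal
#' expression but not a single MSY transcript are \code{LOY}; any MSY UMI
#' makes the cell \code{NORMAL}. Requiring at least one autosomal UMI
#' excludes empty barcodes.
#'
#' @param cells [LoyCellExperiment-class] (QC-filtered).
#' @param min_umis UMI threshold (default 2500).
#' @return the experiment with \code{loy_status} in colData.
#' @export
callLoyCells <- function(cells, min_umis = 2500) {
  rc <- rowData(cells)$region_class
  if (!any(rc == "MSY"))
    stop("annotation contains no MSY genes", call. = FALSE)
  counts <- assay(cells, "counts")
  msy_umis <- Matrix::colSums(counts[rc == "MSY", , drop = FALSE])
  auto_umis <- Matrix::colSums(counts[rc == "AUTOSOME", , drop = FALSE])
  n_umis <- colData(cells)$n_umis
  status <- rep("UNCALLED", ncol(counts))
  called <- n_umis > min_umis
  status[called & msy_umis == 0 & auto_umis >= 1] <- "LOY"
  status[called & msy_umis > 0] <- "NORMAL"
  colData(cells)$loy_status <- status
  cells
}

#' Per-sample, per-cell-type LOY fractions from single-cell calls
#'
#' loy_fraction = #LOY / (#LOY + #NORMAL); UNCALLED cells enter neither
#' numerator nor denominator. Groups with no called cells get a missing
#' fraction with a warning.
#'
#' @param cells [LoyCellExperiment-class] with \code{loy_status} (and
#'   optionally \code{cell_type}) in colData.
#' @return data.frame with sample_id, cell_type, method, n_loy, n_called,
#'   loy_fraction, normal_percent.
#' @export
sampleLoyFraction <- function(cells) {
  cd <- as.data.frame(colData(cells))
  if (is.null(cd$loy_status)) stop("run callLoyCells() first", call. = FALSE)
  ct <- cd$cell_type %||% rep("all", nrow(cd))
  groups <- unique(data.frame(sample_id = cd$sample_id, cell_type = ct))
  out <- do.call(rbind, lapply(seq_len(nrow(groups)), function(i) {
    sel <- cd$sample_id == groups$sample_id[i] & ct == groups$cell_type[i]
    n_loy <- sum(cd$loy_status[sel] == "LOY")
    n_norm <- sum(cd$loy_status[sel] == "NORMAL")
    frac <- if (n_loy + n_norm == 0) NA_real_ else n_loy / (n_loy + n_norm)
    data.frame(sample_id = groups$sample_id[i],
               cell_type = groups$cell_type[i], method = "SC",
               n_loy = n_loy, n_called = n_loy + n_norm,
               loy_fraction = frac)
  }))
  if (anyNA(out$loy_fraction))
    warning("group(s) with zero called cells; fraction missing")
  out$normal_percent <- 100 * (1 - out$loy_fraction)
  rownames(out) <- NULL
  out
}

#' Normally expressed genes among cells without LOY
#'
#' A gene is normally expressed in a cell type when it has at least one UMI
#' in at least \code{threshold} (default 10\%) of that type's NORMAL cells.
#'
#' @param cells [LoyCellExperiment-class] with loy_status.
#' @param threshold required fraction of NORMAL cells (default 0.10,
#'   inclusive).
#' @param min_cells minimum NORMAL cells per type (default 10).
#' @return named list cell_type -> character vector of gene_ids.
#' @export
normallyExpressedGenesSc <- function(cells, threshold = 0.10,
                                     min_cells = 10) {
  cd <- as.data.frame(colData(cells))
  if (is.null(cd$loy_status)) stop("run callLoyCells() first", call. = FALSE)
  ct <- cd$cell_type %||% rep("all", nrow(cd))
  counts <- assay(cells, "counts")
  out <- list()
  for (t in unique(ct)) {
    sel <- which(ct == t & cd$loy_status == "NORMAL")
    if (length(sel) < min_cells)
      stop("cell type '", t, "' has fewer than ", min_cells,
           " NORMAL cells", call. = FALSE)
    frac <- Matrix::rowSums(counts[, sel, drop = FALSE] >= 1) / length(sel)
    out[[t]] <- rownames(counts)[frac >= threshold]
  }
  out
}

#' Differential expression between LOY and normal cells
#'
#' Per gene, an NB log-link regression of UMI counts on the LOY indicator
#' with a log total-UMI offset ([fitNbGlm()]); the LOY coefficient is
#' reported as a log2 fold change with a Wald p-value and BH adjustment
#' within the tested gene set. MSY genes are excluded (no expression in
#' cells without chromosome Y).
#'
#' @param cells [LoyCellExperiment-class] with loy_status.
#' @param genes gene set to test (e.g. one entry of
#'   [normallyExpressedGenesSc()]); MSY genes are dropped.
#' @param cell_type restrict to one cell type (NULL = all cells).
#' @param min_cells minimum cells per status group (default 10).
#' @param shrink dispersion shrinkage toward the per-gene trend value
#'   (default 0.25).
#' @return LateGeneResult data.frame with gene_id, region_class, cell_type,
#'   method, de, se, wald_p, fdr_q, mean_reads, tier.
#' @export
scDifferentialExpression <- function(cells, genes, cell_type = NULL,
                                     min_cells = 10, shrink = 0.25) {
  cd <- as.data.frame(colData(cells))
  if (is.null(cd$loy_status)) stop("run callLoyCells() first", call. = FALSE)
  sel <- cd$loy_status %in% c("LOY", "NORMAL")
  if (!is.null(cell_type)) sel <- sel & cd$cell_type == cell_type
  sub <- cells[, sel]
  cd <- as.data.frame(colData(sub))
  loy <- as.integer(cd$loy_status == "LOY")
  if (sum(loy) < min_cells || sum(1 - loy) < min_cells)
    stop("fewer than ", min_cells, " cells in a status group", call. = FALSE)
  rc <- rowData(sub)$region_class
  genes <- setdiff(intersect(genes, rownames(sub)),
                   rownames(sub)[rc == "MSY"])
  counts <- as.matrix(assay(sub, "counts")[genes, , drop = FALSE])
  offset_sf <- cd$n_umis / exp(mean(log(cd$n_umis)))
  design <- data.frame(loy = loy)
  trend <- fitDispersionTrend(counts, offset_sf)
  res <- do.call(rbind, lapply(genes, function(g) {
    y <- counts[g, ]
    mu_hat <- mean(y / offset_sf)
    a_tr <- trend$a0 + trend$a1 / max(mu_hat, 1e-8)
    fitNbGlm(y, design, coef = "loy", size_factors = offset_sf,
             trend_dispersion = a_tr, shrink = shrink)
  }))
  res <- cbind(data.frame(gene_id = genes,
                          region_class = rc[match(genes, rownames(sub))],
                          cell_type = cell_type %||% "all",
                          method = "SC"), res)
  rownames(res) <- NULL
  res$fdr_q <- bhAdjust(res$wald_p)
  classifyLateTiers(res)
}

#' Fallback clustering when external cluster labels are unavailable
#'
#' A deterministic stand-in for graph-based clustering: k-means on the top
#' principal components of log-normalized counts of the most variable
#' genes. Intended only to exercise the typing stage; real analyses should
#' supply their own cluster labels.
#'
#' @param cells [LoyCellExperiment-class].
#' @param k number of clusters (2 <= k <= number of cells).
#' @param n_pcs principal components used (default 10).
#' @param n_var_genes most variable genes used (default 500).
#' @param seed integer seed (k-means initialization).
#' @return integer cluster labels, one per cell.
#' @export
fallbackCluster <- function(cells, k, n_pcs = 10, n_var_genes = 500,
                            seed = 1) {
  n <- ncol(cells)
  if (k < 2) stop("k must be at least 2", call. = FALSE)
  if (k > n) stop("k exceeds the number of cells", call. = FALSE)
  if (k == n) return(seq_len(n))
  counts <- assay(cells, "counts")
  norm <- log1p(t(t(as.matrix(counts)) /
                    pmax(colData(cells)$n_umis, 1)) * 1e4)
  vars <- apply(norm, 1, var)
  top <- order(vars, decreasing = TRUE)[seq_len(min(n_var_genes, nrow(norm)))]
  pcs <- prcomp(t(norm[top, , drop = FALSE]), center = TRUE, scale. = FALSE)
  np <- min(n_pcs, ncol(pcs$x))
  withr::with_seed(seed,
    kmeans(pcs$x[, seq_len(np), drop = FALSE], centers = k,
           nstart = 10, iter.max = 50)$cluster)
}
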