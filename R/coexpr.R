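## Co-expression contrast: do autosomal genes normally co-expressed with
## MSY genes shift more in LOY cells than non-co-expressed control genes?

#' Contrast fold changes of MSY-co-expressed versus control genes
#'
#' Per gene, the fold change is the ratio of mean normalized expression
#' (per-cell counts scaled to equal totals) in LOY cells over NORMAL cells,
#' guarded by a small pseudocount. The top-k genes of an externally supplied
#' co-expression ranking are compared with a control set by a two-sided
#' Wilcoxon rank-sum test on |log2 fold change| (direction-agnostic by
#' default; \code{signed = TRUE} tests the signed log2 fold changes).
#'
#' @param cells [LoyCellExperiment-class] with loy_status.
#' @param coexpr_ranking autosomal gene_ids ordered by decreasing
#'   co-expression with MSY genes (external input).
#' @param control_genes control gene set (non-co-expressed autosomal genes).
#' @param k number of top-ranked genes used (default 300).
#' @param cell_type restrict to one cell type (NULL = all).
#' @param expressed_genes optional restriction (normally-expressed set).
#' @param signed test signed log2 fold changes instead of magnitudes.
#' @return list with \code{fold_changes} (data.frame gene_id, set,
#'   log2_fc), \code{p_value}, \code{n_top}, \code{n_control}.
#' @export
coexpressionContrast <- function(cells, coexpr_ranking, control_genes,
                                 k = 300, cell_type = NULL,
                                 expressed_genes = NULL, signed = FALSE) {
  if (k > length(coexpr_ranking))
    stop("k exceeds the co-expression ranking length", call. = FALSE)
  if (!length(control_genes)) stop("empty control set", call. = FALSE)
  cd <- as.data.frame(colData(cells))
  if (is.null(cd$loy_status)) stop("run callLoyCells() first", call. = FALSE)
  sel <- cd$loy_status %in% c("LOY", "NORMAL")
  if (!is.null(cell_type)) sel <- sel & cd$cell_type == cell_type
  sub <- cells[, sel]
  cd <- as.data.frame(colData(sub))

  top <- coexpr_ranking[seq_len(k)]
  sets <- list(coexpressed = top, control = setdiff(control_genes, top))
  if (!is.null(expressed_genes))
    sets <- lapply(sets, intersect, expressed_genes)
  sets <- lapply(sets, intersect, rownames(sub))
  if (!length(sets$control)) stop("empty control set", call. = FALSE)

  counts <- assay(sub, "counts")
  norm <- t(t(as.matrix(counts)) / pmax(cd$n_umis, 1)) *
    mean(cd$n_umis)                       # equal-total scaling
  loy <- cd$loy_status == "LOY"
  eps <- 1e-9
  fc <- function(g) {
    m1 <- rowMeans(norm[g, loy, drop = FALSE])
    m0 <- rowMeans(norm[g, !loy, drop = FALSE])
    log2((m1 + eps) / (m0 + eps))
  }
  tab <- rbind(
    data.frame(gene_id = sets$coexpressed, set = "coexpressed",
               log2_fc = fc(sets$coexpressed)),
    data.frame(gene_id = sets$control, set = "control",
               log2_fc = fc(sets$control)))
  rownames(tab) <- NULL
  x <- tab$log2_fc[tab$set == "coexpressed"]
  y <- tab$log2_fc[tab$set == "control"]
  if (!signed) { x <- abs(x); y <- abs(y) }
  w <- wilcox.test(x, y, alternative = "two.sided", exact = FALSE)
  list(fold_changes = tab, p_value = w$p.value,
       n_top = length(sets$coexpressed), n_control = length(sets$control))
}
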