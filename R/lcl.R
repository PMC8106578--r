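## LCL clone contrast: the List1/List2 subtraction that separates
## donor-driven from LOY-driven differential expression. List1 gathers
## inter-individual effects among non-LOY clones; List2 intersects the
## within-donor LOY contrast with the overall LOY contrast; the final LATE
## list is List2 minus List1.

## Two-group NB DE over all genes; returns gene_ids at FDR < fdr. Size
## factors and the dispersion trend come from autosomal genes only (the
## norm_genes argument) so chromosome-Y dosage does not bias normalization.
## With at most a handful of clones per contrast, per-gene dispersions are
## not estimable; the fits lean almost entirely on the trend (shrink 0.9)
## and use the likelihood-ratio test, which keeps power for large effects
## in tiny groups where the Wald statistic degenerates.
lclDeGenes <- function(counts, group, fdr = 0.1, shrink = 0.9,
                       norm_genes = NULL) {
  keep <- rowSums(counts) > 0 & apply(counts, 1, var) > 0
  counts <- counts[keep, , drop = FALSE]
  norm <- counts[intersect(norm_genes %||% rownames(counts),
                           rownames(counts)), , drop = FALSE]
  s <- computeSizeFactors(norm)
  trend <- fitDispersionTrend(norm, s)
  design <- data.frame(grp = as.integer(group))
  p <- vapply(rownames(counts), function(g) {
    mu_hat <- mean(counts[g, ] / s)
    a_tr <- trend$a0 + trend$a1 / max(mu_hat, 1e-8)
    fitNbGlm(counts[g, ], design, coef = "grp", size_factors = s,
             trend_dispersion = a_tr, shrink = shrink, test = "lrt")$wald_p
  }, numeric(1))
  rownames(counts)[!is.na(p) & bhAdjust(p) < fdr]
}

#' List1: inter-individual differential expression among non-LOY clones
#'
#' For each donor, that donor's non-LOY clones are tested against all other
#' non-LOY clones; List1 is the union of the per-donor discoveries at
#' FDR < \code{fdr}. These genes vary between subjects irrespective of LOY
#' and are later subtracted. Donors contributing a single clone are still
#' tested (dispersion comes from the trend) with a warning.
#'
#' @param bulk [LoyBulkExperiment-class] of LCL clones (colData needs
#'   \code{individual_id} and \code{loy_status}).
#' @param fdr per-comparison FDR threshold (default 0.1).
#' @return character vector of gene_ids.
#' @export
list1InterIndividual <- function(bulk, fdr = 0.1) {
  cd <- as.data.frame(colData(bulk))
  normal <- cd$loy_status == "NORMAL"
  counts <- assay(bulk, "counts")[, normal, drop = FALSE]
  auto <- rownames(bulk)[rowData(bulk)$region_class == "AUTOSOME"]
  ind <- cd$individual_id[normal]
  donors <- unique(ind)
  if (length(donors) < 2)
    stop("need non-LOY clones from at least 2 individuals", call. = FALSE)
  out <- character(0)
  for (d in donors) {
    if (sum(ind == d) < 2)
      warning("individual '", d, "' has a single non-LOY clone; ",
              "dispersion relies on the trend")
    out <- union(out, lclDeGenes(counts, ind == d, fdr = fdr, norm_genes = auto))
  }
  out
}

#' List2: LOY-associated differential expression in LCL clones
#'
#' The intersection of two contrasts at FDR < \code{fdr}: (1) non-LOY versus
#' LOY clones within the donor that carries both, and (2) all non-LOY versus
#' all LOY clones. Genes driven only by donor imbalance in the overall
#' contrast are removed by the intersection.
#'
#' @inheritParams list1InterIndividual
#' @return character vector of gene_ids.
#' @export
list2Loy <- function(bulk, fdr = 0.1) {
  cd <- as.data.frame(colData(bulk))
  counts <- assay(bulk, "counts")
  auto <- rownames(bulk)[rowData(bulk)$region_class == "AUTOSOME"]
  loy <- cd$loy_status == "LOY"
  mixed <- intersect(unique(cd$individual_id[loy]),
                     unique(cd$individual_id[!loy]))
  if (!length(mixed))
    stop("no individual carries both LOY and non-LOY clones", call. = FALSE)
  within_sel <- cd$individual_id %in% mixed
  within <- lclDeGenes(counts[, within_sel, drop = FALSE],
                       loy[within_sel], fdr = fdr, norm_genes = auto)
  overall <- lclDeGenes(counts, loy, fdr = fdr, norm_genes = auto)
  intersect(within, overall)
}

#' Final LCL LATE genes: List2 minus List1
#'
#' @param list1,list2 gene-id sets from [list1InterIndividual()] and
#'   [list2Loy()].
#' @return character vector, \code{setdiff(list2, list1)}.
#' @export
finalLclLate <- function(list1, list2) setdiff(list2, list1)

#' Run the complete LCL clone contrast
#'
#' @inheritParams list1InterIndividual
#' @return list with \code{list1}, \code{list2} and \code{final_late}.
#' @export
runLclContrast <- function(bulk, fdr = 0.1) {
  l1 <- list1InterIndividual(bulk, fdr = fdr)
  l2 <- list2Loy(bulk, fdr = fdr)
  list(list1 = l1, list2 = l2, final_late = finalLclLate(l1, l2))
}
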