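#' @import methods
#' @importFrom S4Vectors DataFrame metadata metadata<-
#' @importFrom SummarizedExperiment SummarizedExperiment assay assays rowData
#'   colData rowData<- colData<-
#' @importFrom SingleCellExperiment SingleCellExperiment
NULL

REGION_CLASSES <- c("MSY", "PAR", "X_NONPAR", "AUTOSOME", "MITO")
LOY_STATUSES <- c("LOY", "NORMAL", "UNCALLED")

#' Gene annotation with chromosome-Y region classes
#'
#' Holds one row per gene with its genomic interval and a region class that
#' drives every LOY computation in the package: \code{MSY} (male-specific
#' region of chromosome Y), \code{PAR} (pseudo-autosomal, present on X and Y),
#' \code{X_NONPAR}, \code{AUTOSOME} or \code{MITO}. Coordinates are 1-based
#' inclusive. The pseudo-autosomal intervals used for classification are kept
#' alongside the table so the classification is reproducible.
#'
#' @slot genes data.frame with columns \code{gene_id}, \code{symbol},
#'   \code{chromosome} (one of 1-22, X, Y, MT), \code{start}, \code{end},
#'   \code{region_class}, \code{protein_coding}.
#' @slot par_intervals data.frame with columns \code{chromosome},
#'   \code{start}, \code{end} giving the PAR intervals on X and Y.
#'
#' @seealso [buildFixtureAnnotation()], [classifyRegion()]
#' @export
setClass("GeneAnnotation",
  slots = c(genes = "data.frame", par_intervals = "data.frame"))

setValidity("GeneAnnotation", function(object) {
  g <- object@genes
  need <- c("gene_id", "symbol", "chromosome", "start", "end",
            "region_class", "protein_coding")
  if (!all(need %in% names(g)))
    return(paste("missing columns:", paste(setdiff(need, names(g)), collapse = ", ")))
  if (anyDuplicated(g$gene_id))
    return("duplicated gene_id")
  if (any(g$start > g$end))
    return("start > end for some genes")
  if (!all(g$region_class %in% REGION_CLASSES))
    return("invalid region_class value")
  ok_chrom <- c(as.character(1:22), "X", "Y", "MT")
  if (!all(g$chromosome %in% ok_chrom))
    return(paste("unknown chromosome:",
                 paste(unique(setdiff(g$chromosome, ok_chrom)), collapse = ", ")))
  TRUE
})

#' SNP-array log R ratio experiment
#'
#' A \linkS4class{SummarizedExperiment} with one assay \code{"lrr"} holding
#' probes (rows) by samples (columns) log2 R ratios. \code{rowData} carries
#' the probe annotation (\code{probe_id}, \code{chromosome}, \code{position},
#' \code{in_msy}); \code{colData} carries at least \code{batch}.
#'
#' @seealso [simulateSnpArray()], [computeMlrry()]
#' @export
setClass("LoyLrrExperiment", contains = "SummarizedExperiment")

setValidity("LoyLrrExperiment", function(object) {
  if (!"lrr" %in% names(assays(object)))
    return("assay 'lrr' required")
  rd <- rowData(object)
  if (!all(c("chromosome", "position", "in_msy") %in% names(rd)))
    return("rowData must have chromosome, position, in_msy")
  if (!"batch" %in% names(colData(object)))
    return("colData must have batch")
  if (any(!is.finite(assay(object, "lrr")) & !is.na(assay(object, "lrr"))))
    return("non-finite LRR values")
  TRUE
})

#' Bulk RNA-seq count experiment with LOY metadata
#'
#' A \linkS4class{SummarizedExperiment} with one assay \code{"counts"}
#' (genes x samples, non-negative integers). \code{rowData} carries the gene
#' annotation columns (at least \code{region_class}); \code{colData} carries
#' \code{subject}, \code{cell_type}, \code{batch} and, when available, the
#' DNA-derived \code{dna_loy_fraction}.
#'
#' @seealso [simulateBulkCounts()], [runLateAnalysis()]
#' @export
setClass("LoyBulkExperiment", contains = "SummarizedExperiment")

setValidity("LoyBulkExperiment", function(object) {
  if (!"counts" %in% names(assays(object)))
    return("assay 'counts' required")
  k <- assay(object, "counts")
  if (any(k < 0)) return("negative counts")
  if (ncol(k) > 0 && any(colSums(k) <= 0))
    return("every sample must have positive total counts")
  if (!"region_class" %in% names(rowData(object)))
    return("rowData must have region_class")
  TRUE
})

#' Single-cell UMI count experiment with LOY metadata
#'
#' A \linkS4class{SingleCellExperiment} with assay \code{"counts"}
#' (genes x cells, UMIs). \code{colData} carries \code{sample_id} and the
#' derived per-cell QC columns \code{n_umis}, \code{n_genes_detected},
#' \code{mito_fraction}, plus optional \code{cluster_id}, \code{cell_type}
#' and \code{loy_status}. \code{rowData} carries \code{region_class}.
#' Per-cell QC columns are recomputed by the constructor so the invariants
#' (row sums, detected-gene counts, mitochondrial fraction) always hold.
#'
#' @seealso [simulateScCounts()], [qcFilterCells()], [callLoyCells()]
#' @export
setClass("LoyCellExperiment", contains = "SingleCellExperiment")

setValidity("LoyCellExperiment", function(object) {
  if (!"counts" %in% names(assays(object)))
    return("assay 'counts' required")
  cd <- colData(object)
  need <- c("sample_id", "n_umis", "n_genes_detected", "mito_fraction")
  if (!all(need %in% names(cd)))
    return(paste("colData missing:", paste(setdiff(need, names(cd)), collapse = ", ")))
  if (!"region_class" %in% names(rowData(object)))
    return("rowData must have region_class")
  if (any(cd$mito_fraction < 0 | cd$mito_fraction > 1))
    return("mito_fraction outside [0,1]")
  if ("loy_status" %in% names(cd) &&
      !all(cd$loy_status %in% LOY_STATUSES))
    return("invalid loy_status")
  TRUE
})
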