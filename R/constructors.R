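#' Construct a LoyLrrExperiment
#'
#' @param lrr numeric matrix, probes x samples.
#' @param probes data.frame probe annotation (probe_id, chromosome, position);
#'   \code{in_msy} is computed with [annotateProbes()] if absent.
#' @param batch per-sample batch labels (recycled if length 1).
#' @param par_intervals PAR configuration for probe annotation.
#' @return [LoyLrrExperiment-class]
#' @export
LoyLrrExperiment <- function(lrr, probes, batch = "batch1",
                             par_intervals = defaultParIntervals()) {
  if (!"in_msy" %in% names(probes))
    probes <- annotateProbes(probes, par_intervals)
  stopifnot(nrow(lrr) == nrow(probes))
  rownames(lrr) <- probes$probe_id
  if (is.null(colnames(lrr)))
    colnames(lrr) <- sprintf("sample%03d", seq_len(ncol(lrr)))
  se <- SummarizedExperiment(
    assays = list(lrr = lrr),
    rowData = DataFrame(probes),
    colData = DataFrame(sample_id = colnames(lrr),
                        batch = rep_len(as.character(batch), ncol(lrr)),
                        row.names = colnames(lrr)))
  new("LoyLrrExperiment", se)
}

#' Construct a LoyBulkExperiment
#'
#' @param counts integer matrix, genes x samples (rownames = gene_ids).
#' @param sample_data data.frame keyed to columns: subject, cell_type, batch,
#'   optionally dna_loy_fraction.
#' @param annotation [GeneAnnotation-class]; genes are matched by gene_id and
#'   unmatched genes get region_class \code{AUTOSOME} with a warning.
#' @return [LoyBulkExperiment-class]
#' @export
LoyBulkExperiment <- function(counts, sample_data, annotation) {
  stopifnot(!is.null(rownames(counts)))
  ann <- annotationTable(annotation)
  idx <- match(rownames(counts), ann$gene_id)
  if (anyNA(idx))
    warning(sum(is.na(idx)), " genes not in annotation; treated as AUTOSOME")
  rd <- DataFrame(gene_id = rownames(counts),
                  symbol = ifelse(is.na(idx), rownames(counts), ann$symbol[idx]),
                  region_class = ifelse(is.na(idx), "AUTOSOME",
                                        ann$region_class[idx]),
                  row.names = rownames(counts))
  if (is.null(colnames(counts)))
    colnames(counts) <- sprintf("sample%03d", seq_len(ncol(counts)))
  rownames(sample_data) <- colnames(counts)
  new("LoyBulkExperiment",
      SummarizedExperiment(assays = list(counts = counts),
                           rowData = rd, colData = DataFrame(sample_data)))
}

#' Construct a LoyCellExperiment
#'
#' Per-cell QC metadata (\code{n_umis}, \code{n_genes_detected},
#' \code{mito_fraction}) is always recomputed from the counts so the class
#' invariants hold by construction.
#'
#' @param counts UMI count matrix genes x cells (dense or \pkg{Matrix} sparse),
#'   rownames = gene_ids.
#' @param sample_id per-cell sample labels.
#' @param annotation [GeneAnnotation-class].
#' @param cell_data optional extra per-cell columns (cluster_id, cell_type,
#'   loy_status, ...).
#' @return [LoyCellExperiment-class]
#' @export
LoyCellExperiment <- function(counts, sample_id, annotation, cell_data = NULL) {
  stopifnot(!is.null(rownames(counts)))
  ann <- annotationTable(annotation)
  idx <- match(rownames(counts), ann$gene_id)
  region <- ifelse(is.na(idx), "AUTOSOME", ann$region_class[idx])
  if (is.null(colnames(counts)))
    colnames(counts) <- sprintf("cell%05d", seq_len(ncol(counts)))
  n_umis <- Matrix::colSums(counts)
  n_det <- Matrix::colSums(counts >= 1)
  mito <- Matrix::colSums(counts[region == "MITO", , drop = FALSE])
  cd <- DataFrame(sample_id = rep_len(as.character(sample_id), ncol(counts)),
                  n_umis = as.numeric(n_umis),
                  n_genes_detected = as.numeric(n_det),
                  mito_fraction = ifelse(n_umis > 0, mito / n_umis, 0),
                  row.names = colnames(counts))
  if (!is.null(cell_data))
    for (nm in names(cell_data)) cd[[nm]] <- cell_data[[nm]]
  rd <- DataFrame(gene_id = rownames(counts), region_class = region,
                  row.names = rownames(counts))
  new("LoyCellExperiment",
      SingleCellExperiment(assays = list(counts = counts),
                           rowData = rd, colData = cd))
}

#' @export
setMethod("show", "LoyCellExperiment", function(object) {
  callNextMethod()
  if ("loy_status" %in% names(colData(object))) {
    tab <- table(factor(colData(object)$loy_status, levels = LOY_STATUSES))
    cat("LOY calls:", paste(names(tab), tab, sep = ":", collapse = "  "), "\n")
  }
})
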