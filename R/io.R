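## File formats and the end-to-end driver. Single-cell matrices use the
## CellRanger-style Matrix-Market triplet layout (matrix.mtx + features.tsv
## + barcodes.tsv, optionally gzipped); tabular outputs are plain TSV;
## simulation truth is JSON.

#' Read a Matrix-Market triplet directory into a LoyCellExperiment
#'
#' Expects \code{matrix.mtx}, \code{features.tsv} and \code{barcodes.tsv}
#' (or their .gz variants) in \code{dir}. Genes are matched to the
#' annotation by gene_id; unmatched genes are reported.
#'
#' @param dir directory path.
#' @param annotation [GeneAnnotation-class].
#' @param sample_id sample label for all cells (default the directory name).
#' @return [LoyCellExperiment-class].
#' @export
readMtxTriplet <- function(dir, annotation, sample_id = basename(dir)) {
  pick <- function(base) {
    for (f in file.path(dir, c(base, paste0(base, ".gz"))))
      if (file.exists(f)) return(f)
    stop("missing ", base, " in ", dir, call. = FALSE)
  }
  m <- Matrix::readMM(pick("matrix.mtx"))
  feats <- read.delim(pick("features.tsv"), header = FALSE,
                      stringsAsFactors = FALSE)
  bcs <- read.delim(pick("barcodes.tsv"), header = FALSE,
                    stringsAsFactors = FALSE)[[1]]
  if (nrow(m) != nrow(feats) || ncol(m) != length(bcs))
    stop(sprintf(paste0("dimension mismatch: matrix %d x %d vs ",
                        "%d features, %d barcodes"),
                 nrow(m), ncol(m), nrow(feats), length(bcs)), call. = FALSE)
  rownames(m) <- feats[[1]]
  colnames(m) <- bcs
  unmatched <- setdiff(feats[[1]], annotationTable(annotation)$gene_id)
  if (length(unmatched))
    message(length(unmatched), " gene(s) not in annotation")
  LoyCellExperiment(m, sample_id, annotation)
}

#' Write a LoyCellExperiment as a Matrix-Market triplet directory
#'
#' @param cells [LoyCellExperiment-class].
#' @param dir output directory (created).
#' @return the directory path, invisibly.
#' @export
writeMtxTriplet <- function(cells, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  m <- assay(cells, "counts")
  Matrix::writeMM(Matrix::Matrix(m, sparse = TRUE),
                  file.path(dir, "matrix.mtx"))
  write.table(data.frame(rownames(m), rownames(m)),
              file.path(dir, "features.tsv"), sep = "\t", quote = FALSE,
              row.names = FALSE, col.names = FALSE)
  write.table(colnames(m), file.path(dir, "barcodes.tsv"), sep = "\t",
              quote = FALSE, row.names = FALSE, col.names = FALSE)
  invisible(dir)
}

#' Write a counts matrix (genes x samples) as TSV
#' @param counts matrix or [LoyBulkExperiment-class]
#' @param file output path
#' @export
writeCountsTsv <- function(counts, file) {
  if (is(counts, "SummarizedExperiment")) counts <- assay(counts, "counts")
  write.table(data.frame(gene_id = rownames(counts), counts,
                         check.names = FALSE),
              file, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(file)
}

#' Read a counts TSV (gene_id column + one column per sample)
#' @param file path
#' @return integer matrix with gene_id rownames
#' @export
readCountsTsv <- function(file) {
  d <- read.delim(file, check.names = FALSE, stringsAsFactors = FALSE)
  m <- as.matrix(d[, -1, drop = FALSE])
  rownames(m) <- d[[1]]
  m
}

#' Serialize a simulation truth object to JSON (and reload it)
#'
#' @param truth truth list from a simulator.
#' @param file output path.
#' @export
writeTruthJson <- function(truth, file) {
  jsonlite::write_json(truth, file, auto_unbox = TRUE, digits = NA,
                       null = "null", dataframe = "columns")
  invisible(file)
}

#' @rdname writeTruthJson
#' @export
readTruthJson <- function(file)
  jsonlite::read_json(file, simplifyVector = TRUE)

#' Run a configured simulate-and-analyse pipeline
#'
#' Drives the stages end to end from a configuration list or YAML file:
#' \code{simulate_sc} (single-cell simulation), \code{loy_sc} (QC, LOY
#' calls, per-sample fractions), \code{simulate_bulk} and \code{late}
#' (bulk LATE discovery). Writes stage outputs as TSV plus a JSON manifest
#' recording parameters, row/column counts per stage and filter tallies.
#' Deterministic for a fixed seed.
#'
#' @param config list or YAML file path. Recognised top-level keys:
#'   \code{stages} (character vector), \code{seed}, \code{annotation}
#'   (counts passed to [buildFixtureAnnotation()]), \code{sc} and
#'   \code{bulk} (parameter lists for the simulators).
#' @param out_dir output directory (default tempdir subdirectory).
#' @return list of stage results (invisibly also written to disk).
#' @export
runPipeline <- function(config, out_dir = tempfile("loyate_run")) {
  if (is.character(config)) config <- yaml::read_yaml(config)
  stages <- config$stages %||% c("simulate_sc", "loy_sc")
  valid <- c("simulate_sc", "loy_sc", "simulate_bulk", "late")
  bad <- setdiff(stages, valid)
  if (length(bad))
    stop("unknown stage(s): ", paste(bad, collapse = ", "),
         "; valid: ", paste(valid, collapse = ", "), call. = FALSE)
  seed <- config$seed %||% 1L
  seeds <- deriveSeeds(seed, 4)
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  ann <- do.call(buildFixtureAnnotation, config$annotation %||% list())
  manifest <- list(seed = seed, stages = stages,
                   annotation = as.list(table(regionClass(ann))))
  res <- list(annotation = ann)

  if ("simulate_sc" %in% stages) {
    args <- config$sc %||% list()
    args$annotation <- ann
    args$seed <- seeds[1]
    args$n_cells_per_type <- unlist(args$n_cells_per_type %||%
      c(B = 100, Monocyte = 100, NK = 100, T = 100))
    sim <- do.call(simulateScCounts, args)
    res$sc_sim <- sim
    writeMtxTriplet(sim$cells, file.path(out_dir, "sc_counts"))
    writeTruthJson(sim$truth[setdiff(names(sim$truth), "cell")],
                   file.path(out_dir, "sc_truth.json"))
    manifest$simulate_sc <- list(n_cells = ncol(sim$cells),
                                 n_genes = nrow(sim$cells))
  }
  if ("loy_sc" %in% stages) {
    stopifnot(!is.null(res$sc_sim))
    cells <- res$sc_sim$cells
    n0 <- ncol(cells)
    cells <- qcFilterCells(cells)
    cells <- callLoyCells(cells)
    frac <- sampleLoyFraction(cells)
    res$sc_loy <- list(cells = cells, fractions = frac)
    write.table(frac, file.path(out_dir, "sc_loy_fractions.tsv"),
                sep = "\t", quote = FALSE, row.names = FALSE)
    manifest$loy_sc <- list(cells_in = n0, cells_after_qc = ncol(cells),
                            cells_removed_qc = n0 - ncol(cells),
                            calls = as.list(table(colData(cells)$loy_status)))
  }
  if ("simulate_bulk" %in% stages) {
    args <- config$bulk %||% list()
    args$annotation <- ann
    args$seed <- seeds[2]
    if (is.null(args$sample_table)) {
      n <- args$n_samples %||% 24
      args$n_samples <- NULL
      f <- rep(seq(0, 0.8, length.out = 6), length.out = n)
      args$sample_table <- data.frame(
        subject = sprintf("s%02d", seq_len(n)), cell_type = "NK",
        batch = rep(c("b1", "b2"), length.out = n), f = f)
    }
    sim <- do.call(simulateBulkCounts, args)
    res$bulk_sim <- sim
    writeCountsTsv(sim$bulk, file.path(out_dir, "bulk_counts.tsv"))
    manifest$simulate_bulk <- list(n_genes = nrow(sim$bulk),
                                   n_samples = ncol(sim$bulk))
  }
  if ("late" %in% stages) {
    stopifnot(!is.null(res$bulk_sim))
    expressed <- normallyExpressedGenesBulk(res$bulk_sim$bulk)
    late <- runLateAnalysis(res$bulk_sim$bulk, genes = expressed)
    res$late <- late
    write.table(late, file.path(out_dir, "late_results.tsv"),
                sep = "\t", quote = FALSE, row.names = FALSE)
    manifest$late <- list(
      n_expressed = length(expressed),
      n_tested = nrow(late),
      n_removed_by_filter = attr(late, "n_removed"),
      n_fdr_tier = sum(late$tier %in% c("FDR", "HIGH_EXPR")))
  }
  writeTruthJson(manifest, file.path(out_dir, "manifest.json"))
  res$manifest <- manifest
  res$out_dir <- out_dir
  invisible(res)
}
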