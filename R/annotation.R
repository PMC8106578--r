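#' Default pseudo-autosomal region intervals (GRCh37)
#'
#' PAR1 and PAR2 coordinates on X and their Y homologs, 1-based inclusive.
#' These are configuration values: pass a modified table to
#' [classifyRegion()] or [buildFixtureAnnotation()] to change them.
#'
#' @return data.frame with columns \code{chromosome}, \code{start}, \code{end}.
#' @export
defaultParIntervals <- function() {
  data.frame(
    chromosome = c("X", "X", "Y", "Y"),
    start = c(60001, 154931044, 10001, 59034050),
    end   = c(2699520, 155260560, 2649520, 59363566),
    stringsAsFactors = FALSE)
}

#' Classify a gene interval into a chromosome-Y region class
#'
#' Assigns exactly one of \code{MSY}, \code{PAR}, \code{X_NONPAR},
#' \code{AUTOSOME}, \code{MITO}. A gene on X or Y is \code{PAR} when its
#' interval lies wholly inside a configured PAR interval; a gene straddling
#' a PAR boundary is classified by its midpoint. Y genes outside the PARs
#' are \code{MSY}, X genes outside are \code{X_NONPAR}.
#'
#' @param chromosome character vector of chromosome names (1-22, X, Y, MT).
#' @param start,end 1-based inclusive coordinates.
#' @param par_intervals data.frame as [defaultParIntervals()].
#' @return character vector of region classes.
#' @examples
#' classifyRegion("Y", 100000, 200000)   # inside PAR1 -> "PAR"
#' classifyRegion("Y", 5e6, 5.1e6)       # -> "MSY"
#' classifyRegion("7", 1, 1000)          # -> "AUTOSOME"
#' @export
classifyRegion <- function(chromosome, start, end,
                           par_intervals = defaultParIntervals()) {
  chromosome <- as.character(chromosome)
  stopUnlessIn(chromosome, c(as.character(1:22), "X", "Y", "MT"), "chromosome")
  if (any(start > end)) stop("start > end", call. = FALSE)
  n <- max(length(chromosome), length(start), length(end))
  chromosome <- rep_len(chromosome, n)
  start <- rep_len(start, n); end <- rep_len(end, n)

  inPar <- function(chrom, s, e) {
    pars <- par_intervals[par_intervals$chromosome == chrom, , drop = FALSE]
    if (!nrow(pars)) return(FALSE)
    whole <- any(s >= pars$start & e <= pars$end)
    if (whole) return(TRUE)
    straddle <- any(s <= pars$end & e >= pars$start)
    if (!straddle) return(FALSE)
    mid <- (s + e) / 2                      # boundary-straddling: midpoint rule
    any(mid >= pars$start & mid <= pars$end)
  }

  vapply(seq_len(n), function(i) {
    ch <- chromosome[i]
    if (ch == "MT") return("MITO")
    if (!ch %in% c("X", "Y")) return("AUTOSOME")
    if (inPar(ch, start[i], end[i])) return("PAR")
    if (ch == "Y") "MSY" else "X_NONPAR"
  }, character(1))
}

#' Construct a GeneAnnotation from a gene table
#'
#' Computes \code{region_class} from coordinates unless already present.
#'
#' @param genes data.frame with gene_id, symbol, chromosome, start, end,
#'   protein_coding (and optionally region_class).
#' @param par_intervals PAR configuration, see [defaultParIntervals()].
#' @return [GeneAnnotation-class] object.
#' @export
GeneAnnotation <- function(genes, par_intervals = defaultParIntervals()) {
  if (!"region_class" %in% names(genes))
    genes$region_class <- classifyRegion(genes$chromosome, genes$start,
                                         genes$end, par_intervals)
  if (!"symbol" %in% names(genes)) genes$symbol <- genes$gene_id
  if (!"protein_coding" %in% names(genes)) genes$protein_coding <- TRUE
  rownames(genes) <- NULL
  new("GeneAnnotation", genes = genes, par_intervals = par_intervals)
}

#' Synthetic gene annotation fixture
#'
#' Builds a deterministic annotation table with a configurable number of
#' genes per region class. The defaults reflect the human gene complement
#' relevant to LOY analysis: 45 protein-coding MSY genes, 19 PAR genes,
#' 13 mitochondrial genes, plus simulated autosomal and X-non-PAR genes.
#'
#' @param n_msy,n_par,n_autosome,n_x_nonpar,n_mito gene counts per class.
#' @param par_intervals PAR configuration.
#' @return [GeneAnnotation-class] object.
#' @examples
#' ann <- buildFixtureAnnotation()
#' table(regionClass(ann))
#' @export
buildFixtureAnnotation <- function(n_msy = 45, n_par = 19, n_autosome = 3000,
                                   n_x_nonpar = 100, n_mito = 13,
                                   par_intervals = defaultParIntervals()) {
  counts <- c(n_msy, n_par, n_autosome, n_x_nonpar, n_mito)
  if (any(counts < 0)) stop("gene counts must be non-negative", call. = FALSE)

  mk <- function(prefix, n, chrom, start) {
    if (n == 0) return(NULL)
    width <- 10000L
    data.frame(
      gene_id = sprintf("%s%04d", prefix, seq_len(n)),
      symbol  = sprintf("%s%04d", prefix, seq_len(n)),
      chromosome = chrom,
      start = start + (seq_len(n) - 1L) * 2L * width,
      end   = start + (seq_len(n) - 1L) * 2L * width + width - 1L,
      protein_coding = TRUE,
      stringsAsFactors = FALSE)
  }
  parY <- par_intervals[par_intervals$chromosome == "Y", , drop = FALSE]
  msy <- mk("MSY", n_msy, "Y", as.integer(max(parY$end[1], 2649521) + 1e6))
  par1 <- mk("PAR", n_par, "Y", as.integer(parY$start[1] + 1000))
  auto <- if (n_autosome > 0) {
    chrom <- as.character(rep_len(1:22, n_autosome))
    d <- mk("AUT", n_autosome, "1", 1e6L); d$chromosome <- chrom
    d$start <- 1e6L + (ave(seq_len(n_autosome), chrom, FUN = seq_along) - 1L) * 20000L
    d$end <- d$start + 9999L
    d
  } else NULL
  xnp <- mk("XNP", n_x_nonpar, "X", 5e6L)
  mito <- if (n_mito > 0) {
    ## the mitochondrial genome is 16.6 kb; keep fixture genes inside it
    s <- 100L + (seq_len(n_mito) - 1L) * (16000L %/% max(n_mito, 1L))
    data.frame(gene_id = sprintf("MT-%04d", seq_len(n_mito)),
               symbol = sprintf("MT-%04d", seq_len(n_mito)),
               chromosome = "MT", start = s,
               end = s + min(800L, 16000L %/% max(n_mito, 1L) - 10L),
               protein_coding = TRUE, stringsAsFactors = FALSE)
  } else NULL
  GeneAnnotation(rbind(msy, par1, auto, xnp, mito), par_intervals)
}

## ---- accessors -------------------------------------------------------------

#' @describeIn GeneAnnotation-class the gene table as a data.frame
#' @param x,object a GeneAnnotation
#' @export
setGeneric("annotationTable", function(x) standardGeneric("annotationTable"))

#' @export
setMethod("annotationTable", "GeneAnnotation", function(x) x@genes)

#' @describeIn GeneAnnotation-class named vector of region classes
#' @export
setGeneric("regionClass", function(x) standardGeneric("regionClass"))

#' @export
setMethod("regionClass", "GeneAnnotation",
  function(x) setNames(x@genes$region_class, x@genes$gene_id))

#' Gene identifiers belonging to one region class
#' @param x a [GeneAnnotation-class]
#' @param class one of MSY, PAR, X_NONPAR, AUTOSOME, MITO
#' @return character vector of gene_ids
#' @export
genesInRegion <- function(x, class) {
  stopUnlessIn(class, REGION_CLASSES, "region class")
  x@genes$gene_id[x@genes$region_class %in% class]
}

#' @export
setMethod("show", "GeneAnnotation", function(object) {
  tab <- table(factor(object@genes$region_class, levels = REGION_CLASSES))
  cat("GeneAnnotation with", nrow(object@genes), "genes\n")
  cat(" ", paste(names(tab), tab, sep = ":", collapse = "  "), "\n")
})

## ---- I/O -------------------------------------------------------------------

#' Read a gene annotation from a GTF-subset TSV and a PAR interval file
#'
#' The gene TSV needs columns gene_id, symbol, chrom, start, end, biotype;
#' the PAR file is BED-like TSV (chromosome, start, end; 1-based inclusive).
#'
#' @param gene_file,par_file paths; \code{par_file = NULL} uses the GRCh37
#'   defaults.
#' @return [GeneAnnotation-class]
#' @export
readGeneAnnotation <- function(gene_file, par_file = NULL) {
  g <- read.delim(gene_file, stringsAsFactors = FALSE)
  names(g)[names(g) == "chrom"] <- "chromosome"
  g$protein_coding <- if ("biotype" %in% names(g))
    g$biotype == "protein_coding" else TRUE
  pars <- if (is.null(par_file)) defaultParIntervals() else {
    p <- read.delim(par_file, stringsAsFactors = FALSE)
    names(p)[1:3] <- c("chromosome", "start", "end"); p
  }
  keep <- c("gene_id", "symbol", "chromosome", "start", "end", "protein_coding")
  GeneAnnotation(g[, keep], pars)
}

#' Write the annotated gene table as TSV
#' @param x a [GeneAnnotation-class]
#' @param file output path
#' @export
writeGeneAnnotation <- function(x, file) {
  write.table(annotationTable(x), file, sep = "\t", quote = FALSE,
              row.names = FALSE)
  invisible(file)
}

#' Annotate SNP-array probes with MSY membership
#'
#' \code{in_msy} is true iff the probe is on Y and outside every PAR interval.
#'
#' @param probes data.frame with probe_id, chromosome, position.
#' @param par_intervals PAR configuration.
#' @return the input with an \code{in_msy} logical column.
#' @export
annotateProbes <- function(probes, par_intervals = defaultParIntervals()) {
  stopUnlessIn(probes$chromosome, c(as.character(1:22), "X", "Y", "MT"),
               "chromosome")
  parY <- par_intervals[par_intervals$chromosome == "Y", , drop = FALSE]
  inPar <- rep(FALSE, nrow(probes))
  for (i in seq_len(nrow(parY)))
    inPar <- inPar | (probes$position >= parY$start[i] &
                      probes$position <= parY$end[i])
  probes$in_msy <- probes$chromosome == "Y" & !inPar
  probes
}
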