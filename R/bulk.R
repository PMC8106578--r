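## Bulk RNA-seq stage: median-of-ratios normalization, a closed-form
## variance-stabilizing transformation for the dispersion trend
## alpha(mu) = a0 + a1/mu, the Y-expression-fraction LOY estimate, the
## normally-expressed-gene filter and the expression-versus-LOY regressions.

#' Median-of-ratios size factors
#'
#' s_j is the median over genes (with nonzero geometric mean) of the ratio
#' of sample j's count to the gene's geometric mean, rescaled so the size
#' factors themselves have geometric mean 1.
#'
#' @param counts genes x samples count matrix (or [LoyBulkExperiment-class]).
#' @return named numeric vector, one factor per sample.
#' @export
computeSizeFactors <- function(counts) {
  if (is(counts, "SummarizedExperiment")) counts <- assay(counts, "counts")
  if (ncol(counts) == 1) return(setNames(1, colnames(counts)))
  logg <- rowMeans(log(counts))
  use <- is.finite(logg)
  if (!any(use))
    stop("no genes with nonzero counts in every sample", call. = FALSE)
  s <- apply(counts[use, , drop = FALSE], 2, function(col)
    exp(median(log(col) - logg[use])))
  s / exp(mean(log(s)))
}

#' Fit the dispersion-mean trend alpha(mu) = a0 + a1/mu
#'
#' Per-gene moment dispersions alpha_g = (var_g - mu_g) / mu_g^2 on
#' normalized counts are regressed onto 1/mu by trimmed least squares
#' (the most extreme residuals are refit-excluded once). Negative estimates
#' are floored: a0 at 1e-4, a1 at 0. Degenerate fits (no spread in 1/mu)
#' fall back to (median dispersion, 0) with a warning.
#'
#' @param counts genes x samples count matrix or [LoyBulkExperiment-class].
#' @param size_factors from [computeSizeFactors()] (computed if NULL).
#' @param trim fraction of extreme residuals dropped in the refit
#'   (default 0.1).
#' @return list with \code{a0}, \code{a1} and the per-gene moment estimates.
#' @export
fitDispersionTrend <- function(counts, size_factors = NULL, trim = 0.1) {
  if (is(counts, "SummarizedExperiment")) counts <- assay(counts, "counts")
  s <- size_factors %||% computeSizeFactors(counts)
  k <- sweep(counts, 2, s, "/")
  mu <- rowMeans(k)
  v <- apply(k, 1, var)
  keep <- mu > 0
  if (sum(keep) < 50)
    warning("fewer than 50 genes with positive mean; trend may be unstable")
  mu <- mu[keep]; v <- v[keep]
  disp <- (v - mu) / mu^2
  x <- 1 / mu
  fallback <- function(msg) {
    warning(msg, "; falling back to constant trend")
    list(a0 = max(median(disp), 1e-4), a1 = 0, dispersions = disp)
  }
  ## a1 needs spread in 1/mu; near-constant gene means leave it unidentified
  if (sd(x) < 0.1 * mean(x)) return(fallback("near-constant gene means"))
  fit <- lm(disp ~ x)
  r <- abs(stats::residuals(fit))
  keep2 <- r <= quantile(r, 1 - trim)
  if (sum(keep2) >= 10 && sd(x[keep2]) > 1e-12)
    fit <- lm(disp[keep2] ~ x[keep2])
  a0 <- max(unname(coef(fit)[1]), 1e-4)
  a1 <- max(unname(coef(fit)[2]), 0)
  list(a0 = a0, a1 = a1, dispersions = disp)
}

#' Closed-form variance-stabilizing transformation
#'
#' For size-factor-normalized counts K and an asymptotic dispersion a0, the
#' transform (2/ln 2) * asinh(sqrt(a0 * K)) is strictly increasing, maps 0
#' to 0, and approaches log2(K) plus a constant for large K, flattening the
#' count variance across the expression range.
#'
#' @param counts genes x samples count matrix or [LoyBulkExperiment-class].
#' @param size_factors from [computeSizeFactors()] (computed if NULL).
#' @param trend from [fitDispersionTrend()] (fitted if NULL).
#' @return transformed real matrix of the same dimensions.
#' @export
vstTransform <- function(counts, size_factors = NULL, trend = NULL) {
  if (is(counts, "SummarizedExperiment")) counts <- assay(counts, "counts")
  s <- size_factors %||% computeSizeFactors(counts)
  trend <- trend %||% fitDispersionTrend(counts, s)
  k <- sweep(counts, 2, s, "/")
  (2 / log(2)) * asinh(sqrt(trend$a0 * k))
}

#' RNA-based LOY estimates from the chromosome-Y expression fraction
#'
#' For each sample, the mean VST expression over MSY genes divided by the
#' mean over autosomal genes gives a Y-expression fraction; fractions are
#' min-max rescaled to [0, 100] within each cell type (100 = most Y
#' expression). The LOY cell fraction is calibrated against non-LOY
#' reference samples: 1 - raw_stat / median(raw_stat of references),
#' clipped to [0, 1].
#'
#' @param bulk [LoyBulkExperiment-class] (colData needs \code{cell_type};
#'   references use \code{dna_loy_fraction} when present).
#' @param vst precomputed matrix from [vstTransform()] (computed if NULL).
#' @param reference_threshold samples with dna_loy_fraction below this are
#'   the non-LOY reference (default 0.05); without dna_loy_fraction all
#'   samples serve as reference.
#' @return data.frame with sample_id, cell_type, method, raw_stat,
#'   rescaled (0-100), normal_percent, loy_fraction.
#' @export
bulkYFractionLoy <- function(bulk, vst = NULL, reference_threshold = 0.05) {
  cd <- as.data.frame(colData(bulk))
  ct_all <- cd$cell_type %||% rep("all", ncol(bulk))
  if (any(table(ct_all) < 2))
    stop("fewer than 2 samples for cell type '",
         names(which(table(ct_all) < 2))[1],
         "'; min-max rescaling undefined", call. = FALSE)
  v <- vst %||% vstTransform(bulk)
  rc <- rowData(bulk)$region_class
  msy <- rc == "MSY"; auto <- rc == "AUTOSOME"
  if (!any(msy)) stop("no MSY genes in the experiment", call. = FALSE)
  raw <- colMeans(v[msy, , drop = FALSE]) / colMeans(v[auto, , drop = FALSE])
  ct <- cd$cell_type %||% rep("all", ncol(v))
  out <- data.frame(sample_id = colnames(v), cell_type = ct,
                    method = "BULK", raw_stat = raw, row.names = NULL)
  out$rescaled <- NA_real_
  out$loy_fraction <- NA_real_
  for (t in unique(ct)) {
    i <- which(ct == t)
    if (length(i) < 2)
      stop("fewer than 2 samples for cell type '", t,
           "'; min-max rescaling undefined", call. = FALSE)
    r <- raw[i]
    rng <- range(r)
    out$rescaled[i] <- if (diff(rng) > 0)
      100 * (r - rng[1]) / diff(rng) else 50
    ref <- if (!is.null(cd$dna_loy_fraction))
      i[!is.na(cd$dna_loy_fraction[i]) &
          cd$dna_loy_fraction[i] < reference_threshold] else i
    if (!length(ref)) ref <- i[which.max(r)]
    out$loy_fraction[i] <- clip(1 - r / median(raw[ref]), 0, 1)
  }
  out$normal_percent <- 100 * (1 - out$loy_fraction)
  out
}

#' Normally expressed genes in bulk data
#'
#' A gene is normally expressed when it has at least \code{min_reads} reads
#' in more than \code{min_fraction} of the non-LOY reference samples
#' (strictly more than; 75.0\% exactly does not qualify).
#'
#' @param bulk [LoyBulkExperiment-class].
#' @param min_reads read threshold (default 10).
#' @param min_fraction required fraction of reference samples (default 0.75).
#' @param reference_threshold dna_loy_fraction cutoff defining non-LOY
#'   reference samples (default 0.05).
#' @return character vector of gene_ids.
#' @export
normallyExpressedGenesBulk <- function(bulk, min_reads = 10,
                                       min_fraction = 0.75,
                                       reference_threshold = 0.05) {
  counts <- assay(bulk, "counts")
  cd <- as.data.frame(colData(bulk))
  ref <- if (!is.null(cd$dna_loy_fraction))
    which(!is.na(cd$dna_loy_fraction) &
            cd$dna_loy_fraction < reference_threshold)
  else seq_len(ncol(counts))
  if (!length(ref)) stop("no non-LOY reference samples", call. = FALSE)
  frac <- rowMeans(counts[, ref, drop = FALSE] >= min_reads)
  rownames(counts)[frac > min_fraction]
}

#' Regression of gene-set expression on LOY percentage
#'
#' Per-sample mean expression over a gene set is divided by the maximum
#' across samples (so values lie in (0, 1]) and regressed on the LOY
#' percentage. The default is ordinary linear least squares; \code{model =
#' "exponential"} fits a decaying exponential a * exp(b * loy) by nonlinear
#' least squares and reports the initial slope a * b.
#'
#' @param expression per-sample mean expression of the gene set.
#' @param loy_percent per-sample LOY percentage (0-100).
#' @param model "linear" (default) or "exponential".
#' @return list with beta (slope per percent LOY), se, p_value, model.
#' @export
expressionVsLoyRegression <- function(expression, loy_percent,
                                      model = c("linear", "exponential")) {
  model <- match.arg(model)
  stopifnot(length(expression) == length(loy_percent))
  if (length(expression) < 3)
    stop("at least 3 samples required", call. = FALSE)
  if (sd(loy_percent) == 0)
    stop("LOY percentage is constant; slope undefined", call. = FALSE)
  y <- expression / max(expression)
  if (model == "linear") {
    fit <- lm(y ~ loy_percent)
    sm <- summary(fit)$coefficients
    list(beta = unname(sm[2, 1]), se = unname(sm[2, 2]),
         p_value = unname(sm[2, 4]), model = model)
  } else {
    fit <- stats::nls(y ~ a * exp(b * loy_percent),
                      start = list(a = max(y), b = -0.005),
                      control = stats::nls.control(warnOnly = TRUE))
    sm <- summary(fit)$coefficients
    a <- sm["a", 1]; b <- sm["b", 1]
    se_b <- sm["b", 2]
    list(beta = a * b, se = abs(a) * se_b, p_value = sm["b", 4],
         model = model)
  }
}
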