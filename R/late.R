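## The LATE discovery engine: negative-binomial log-link GLM on binned LOY
## with batch covariates, Cox-Reid adjusted ML dispersion with shrinkage
## toward a fitted mean-dispersion trend, Wald tests, independent filtering
## and Benjamini-Hochberg FDR, plus the stringency tiers and cross-method
## comparisons built on top.

#' Bin a LOY percentage into 20-percent ordinal bins
#'
#' Mapping: [0,20) -> 0, [20,40) -> 1, [40,60) -> 2, [60,80) -> 3,
#' [80,100] -> 4. The bin codes are entered into the GLM as a numeric
#' covariate, so effect sizes are log2 fold changes per bin unit.
#'
#' @param loy_percent numeric in [0, 100].
#' @return integer bin codes 0-4.
#' @export
binLoy <- function(loy_percent) {
  if (any(loy_percent < 0 | loy_percent > 100))
    stop("loy_percent outside [0, 100]", call. = FALSE)
  pmin(loy_percent %/% 20, 4)
}

## NB2 log-likelihood; alpha ~ 0 collapses to Poisson.
nbLoglik <- function(y, mu, alpha) {
  if (alpha < 1e-10) sum(dpois(y, mu, log = TRUE))
  else sum(dnbinom(y, mu = mu, size = 1 / alpha, log = TRUE))
}

## Iteratively reweighted least squares for the NB log-link GLM with offset.
nbIrls <- function(y, X, offset, alpha, maxit = 25L, tol = 1e-8) {
  mu <- pmax(y, 0.5)
  eta <- log(mu)
  dev_old <- Inf
  it <- 0L
  repeat {
    it <- it + 1L
    w <- mu / (1 + alpha * mu)
    z <- eta - offset + (y - mu) / mu
    fit <- stats::lm.wfit(X, z, w)
    eta <- clip(drop(X %*% fit$coefficients) + offset, -30, 30)
    mu <- exp(eta)
    dev <- -2 * nbLoglik(y, mu, alpha)
    if (abs(dev - dev_old) < tol * (abs(dev) + 0.1) || it >= maxit) break
    dev_old <- dev
  }
  w <- mu / (1 + alpha * mu)
  list(beta = fit$coefficients, mu = mu, loglik = nbLoglik(y, mu, alpha),
       XtWX = crossprod(X, X * w), converged = it < maxit)
}

## Cox-Reid adjusted profile ML dispersion given fitted means. The CR term
## -0.5 log det(X'WX) compensates the degrees of freedom absorbed by the
## coefficient fit; without it small-sample dispersions are biased low and
## Wald tests run anticonservative.
crmlDispersion <- function(y, mu, X, lower = 1e-8, upper = 10) {
  negapl <- function(la) {
    a <- exp(la)
    w <- mu / (1 + a * mu)
    cr <- 0.5 * determinant(crossprod(X, X * w), logarithm = TRUE)$modulus
    -(nbLoglik(y, mu, a) - cr)
  }
  exp(optimize(negapl, c(log(lower), log(upper)))$minimum)
}

#' Fit the negative-binomial GLM for one gene
#'
#' Log-link NB regression of counts on a design (typically LOY bin plus
#' batch) with a log size-factor offset. Dispersion is estimated per gene by
#' Cox-Reid adjusted maximum likelihood (moment start, floored at 1e-8,
#' capped at 10) and optionally shrunk toward a trend value on the log scale.
#' The tested coefficient is reported as a log2 fold change per covariate
#' unit with a Wald z test; if the IRLS fails to converge the p-value falls
#' back to a likelihood-ratio test against the null design.
#'
#' @param y integer count vector.
#' @param design data.frame of covariates; the model is \code{~ .} with the
#'   tested covariate named by \code{coef}.
#' @param coef name of the tested column of \code{design}.
#' @param size_factors per-sample normalization factors (default 1).
#' @param dispersion fixed dispersion; when NULL it is estimated.
#' @param trend_dispersion trend value alpha(mu) to shrink toward.
#' @param shrink weight on the trend on the log-dispersion scale
#'   (default 0.25; 0 disables shrinkage).
#' @param test "wald" (default) or "lrt". The likelihood-ratio test avoids
#'   the Wald test's loss of power for large effects in very small groups
#'   and is the default inside the LCL contrasts.
#' @return one-row data.frame: de (log2 per unit), se, wald_p, dispersion,
#'   mean_reads, converged.
#' @export
fitNbGlm <- function(y, design, coef, size_factors = NULL, dispersion = NULL,
                     trend_dispersion = NULL, shrink = 0.25,
                     test = c("wald", "lrt")) {
  test <- match.arg(test)
  stopifnot(coef %in% names(design))
  X <- stats::model.matrix(~ ., data = design)
  qrX <- qr(X)
  if (qrX$rank < ncol(X)) {
    aliased <- colnames(X)[qrX$pivot[(qrX$rank + 1):ncol(X)]]
    stop("singular design; aliased columns: ",
         paste(aliased, collapse = ", "), call. = FALSE)
  }
  s <- rep_len(size_factors %||% 1, length(y))
  offset <- log(s)
  jcoef <- which(colnames(X) == coef)
  if (!length(jcoef)) jcoef <- grep(paste0("^", coef), colnames(X))[1]

  if (is.null(dispersion)) {
    pois <- nbIrls(y, X, offset, alpha = 0)
    mom <- sum((y - pois$mu)^2 - pois$mu) / sum(pois$mu^2)
    a0 <- clip(mom, 1e-8, 10)
    fit0 <- nbIrls(y, X, offset, a0)
    a_ml <- clip(crmlDispersion(y, fit0$mu, X), 1e-8, 10)
    dispersion <- if (!is.null(trend_dispersion) && shrink > 0)
      exp((1 - shrink) * log(a_ml) + shrink * log(clip(trend_dispersion, 1e-8, 10)))
    else a_ml
  }
  fit <- nbIrls(y, X, offset, dispersion)
  cov <- tryCatch(solve(fit$XtWX), error = function(e) NULL)
  beta <- fit$beta[jcoef]
  se <- if (is.null(cov)) NA_real_ else sqrt(cov[jcoef, jcoef])
  if (test == "lrt" || is.null(cov) || !fit$converged) {
    ## likelihood-ratio against the null design (also the fallback when the
    ## Wald fit fails or does not converge)
    X0 <- X[, -jcoef, drop = FALSE]
    fit0 <- nbIrls(y, X0, offset, dispersion)
    lrt <- 2 * (fit$loglik - fit0$loglik)
    p <- pchisq(pmax(lrt, 0), df = 1, lower.tail = FALSE)
    if (is.null(cov)) {
      warning("NB fit failed; likelihood-ratio p-value reported")
    }
  } else {
    ## t reference with residual df: the normal reference is too thin in the
    ## far tail at a few dozen samples, which inflates the FDR among
    ## top-ranked genes
    p <- 2 * stats::pt(-abs(beta / se), df = max(length(y) - ncol(X), 1))
  }
  data.frame(de = beta / log(2), se = se / log(2), wald_p = p,
             dispersion = dispersion,
             mean_reads = mean(y / s), converged = fit$converged)
}

#' Benjamini-Hochberg step-up adjustment
#'
#' Standard BH with monotonicity enforcement; the number of tests is the
#' number of non-missing p-values and missing p-values propagate as missing.
#'
#' @param p p-values in [0, 1] (NA/NaN allowed).
#' @return q-values of the same length.
#' @export
bhAdjust <- function(p) {
  q <- rep(NA_real_, length(p))
  ok <- !is.na(p)
  q[ok] <- p.adjust(p[ok], method = "BH")
  q
}

#' Independent filtering on mean expression
#'
#' Scans mean-expression quantile thresholds (0-95\% by 1\%) and keeps the
#' threshold that maximizes the number of BH rejections at \code{alpha};
#' genes below the chosen threshold are removed before the final BH
#' adjustment, which can only increase the number of discoveries.
#'
#' @param results data.frame with columns \code{wald_p} and
#'   \code{mean_reads}.
#' @param alpha FDR level driving the scan (default 0.1).
#' @return the retained subset with a \code{fdr_q} column; the chosen
#'   threshold and number of removed genes are attached as attributes
#'   \code{"threshold"} and \code{"n_removed"}.
#' @export
independentFilter <- function(results, alpha = 0.1) {
  if (!nrow(results)) {
    results$fdr_q <- numeric(0)
    return(results)
  }
  qs <- seq(0, 0.95, by = 0.01)
  thr <- quantile(results$mean_reads, qs, na.rm = TRUE, names = FALSE)
  rej <- vapply(thr, function(t) {
    sum(bhAdjust(results$wald_p[results$mean_reads >= t]) < alpha,
        na.rm = TRUE)
  }, numeric(1))
  best <- thr[which.max(rej)]
  keep <- results$mean_reads >= best
  out <- results[keep, , drop = FALSE]
  out$fdr_q <- bhAdjust(out$wald_p)
  attr(out, "threshold") <- best
  attr(out, "n_removed") <- sum(!keep)
  out
}

#' Stringency tiers for LATE genes
#'
#' Three nested stringency levels: \code{NOMINAL} (p < 0.05), \code{FDR}
#' (BH q < 0.1), and \code{HIGH_EXPR} (q < 0.1 and a mean of at least 100
#' reads per gene). Genes meeting none are \code{NONE}.
#'
#' @param results data.frame with wald_p, fdr_q, mean_reads.
#' @return the input with a \code{tier} column.
#' @export
classifyLateTiers <- function(results) {
  tier <- rep("NONE", nrow(results))
  tier[!is.na(results$wald_p) & results$wald_p < 0.05] <- "NOMINAL"
  fdr <- !is.na(results$fdr_q) & results$fdr_q < 0.1
  tier[fdr] <- "FDR"
  tier[fdr & results$mean_reads >= 100] <- "HIGH_EXPR"
  results$tier <- tier
  results
}

#' Convert a log2 differential-expression value to a fold change
#'
#' @param de log2 fold change (per LOY unit).
#' @return data.frame with \code{fold} (2^|de|, >= 1), \code{direction}
#'   ("up" iff de > 0, "up" by convention at 0) and \code{neutral}
#'   (TRUE iff de == 0).
#' @examples
#' foldChangeFromDe(c(3.11, -1.30))
#' @export
foldChangeFromDe <- function(de) {
  stopifnot(all(is.finite(de)))
  data.frame(fold = 2^abs(de),
             direction = ifelse(de < 0, "down", "up"),
             neutral = de == 0)
}

#' Sign concordance of effect directions between two result sets
#'
#' Exact two-sided binomial sign test of direction agreement (against 0.5)
#' over the genes shared by two LATE result tables. Genes with a zero effect
#' in either set are excluded with a warning.
#'
#' @param a,b data.frames with \code{gene_id} and \code{de}.
#' @return list with n_agree, n_total, p_value.
#' @export
signConcordance <- function(a, b) {
  shared <- intersect(a$gene_id, b$gene_id)
  if (!length(shared)) stop("no shared genes", call. = FALSE)
  da <- a$de[match(shared, a$gene_id)]
  db <- b$de[match(shared, b$gene_id)]
  zero <- da == 0 | db == 0
  if (any(zero)) {
    warning(sum(zero), " gene(s) with zero effect excluded from sign test")
    da <- da[!zero]; db <- db[!zero]
  }
  n <- length(da)
  if (!n) stop("no shared genes with nonzero effects", call. = FALSE)
  agree <- sum(sign(da) == sign(db))
  list(n_agree = agree, n_total = n,
       p_value = binom.test(agree, n, 0.5)$p.value)
}

#' Within-cell-type versus shared LATE-gene fractions
#'
#' For each cell type, the within fraction is |LATE| / |expressed|; for each
#' pair of types the shared fraction is |LATE intersection| / |expressed
#' intersection|. The two groups of fractions are compared by a one-way
#' F statistic with a label-permutation p-value.
#'
#' @param late_sets named list of LATE gene-id sets per cell type.
#' @param expressed_sets named list of expressed gene-id sets per cell type.
#' @param n_perm permutations (default 1000).
#' @param seed integer seed for the permutation draw.
#' @return list with \code{fractions} (data.frame kind/name/fraction),
#'   \code{f_stat} and \code{p_value}.
#' @export
sharedFractionAnalysis <- function(late_sets, expressed_sets, n_perm = 1000,
                                   seed = 1) {
  types <- names(late_sets)
  stopifnot(length(types) >= 2, setequal(types, names(expressed_sets)))
  if (any(!vapply(expressed_sets, length, 1L)))
    stop("empty expressed set", call. = FALSE)
  within <- vapply(types, function(t)
    length(late_sets[[t]]) / length(expressed_sets[[t]]), numeric(1))
  pairs <- utils::combn(types, 2)
  shared <- apply(pairs, 2, function(p) {
    denom <- length(intersect(expressed_sets[[p[1]]], expressed_sets[[p[2]]]))
    if (!denom) stop("empty expressed intersection", call. = FALSE)
    length(intersect(late_sets[[p[1]]], late_sets[[p[2]]])) / denom
  })
  vals <- c(within, shared)
  grp <- factor(rep(c("within", "shared"), c(length(within), length(shared))))
  fstat <- function(v) {
    m <- tapply(v, grp, mean); nk <- tapply(v, grp, length)
    ssb <- sum(nk * (m - mean(v))^2)
    ssw <- sum((v - m[grp])^2)
    (ssb / (nlevels(grp) - 1)) / (ssw / (length(v) - nlevels(grp)))
  }
  f_obs <- fstat(vals)
  perm <- withr::with_seed(seed, vapply(seq_len(n_perm), function(i)
    fstat(sample(vals)), numeric(1)))
  list(fractions = data.frame(
         kind = as.character(grp),
         name = c(types, apply(pairs, 2, paste, collapse = ":")),
         fraction = vals, row.names = NULL),
       f_stat = f_obs,
       p_value = (sum(perm >= f_obs) + 1) / (n_perm + 1))
}

#' Genome-wide LATE analysis of a bulk experiment
#'
#' Runs the full discovery chain: size factors, dispersion trend, per-gene
#' NB GLM of counts on the 20-percent LOY bin (numeric covariate) plus
#' covariates, independent filtering at \code{alpha}, BH adjustment, and
#' stringency tiers. MSY genes are excluded from testing (they have no
#' expression in cells without a Y chromosome); PAR and X-non-PAR genes are
#' tested and labelled by their region class.
#'
#' @param bulk [LoyBulkExperiment-class].
#' @param loy_percent per-sample LOY percentage (default
#'   100 * dna_loy_fraction from colData).
#' @param covariates colData columns entered as covariates
#'   (default "batch"; set \code{character(0)} for none).
#' @param genes genes to test (default all non-MSY genes with any count;
#'   pass e.g. [normallyExpressedGenesBulk()] output).
#' @param alpha independent-filtering / FDR level (default 0.1).
#' @param shrink dispersion shrinkage weight toward the trend (default 0.25).
#' @param exclude_msy drop MSY genes from testing (default TRUE).
#' @return LateGeneResult data.frame: gene_id, region_class, cell_type,
#'   method, de, se, wald_p, fdr_q, mean_reads, tier. Genes removed by
#'   independent filtering keep their Wald p but have \code{fdr_q = NA};
#'   the chosen threshold is attached as attribute "filter_threshold".
#' @export
runLateAnalysis <- function(bulk, loy_percent = NULL,
                            covariates = "batch", genes = NULL,
                            alpha = 0.1, shrink = 0.25, exclude_msy = TRUE) {
  counts <- assay(bulk, "counts")
  cd <- as.data.frame(colData(bulk))
  loy_percent <- loy_percent %||% (100 * cd$dna_loy_fraction)
  stopifnot(length(loy_percent) == ncol(counts), ncol(counts) >= 6)
  bins <- binLoy(loy_percent)
  rc <- rowData(bulk)$region_class
  genes <- genes %||% rownames(counts)[rowSums(counts) > 0]
  if (exclude_msy)
    genes <- setdiff(genes, rownames(counts)[rc == "MSY"])
  genes <- intersect(genes, rownames(counts)[rowSums(counts) > 0])

  ## normalize and fit the dispersion trend on autosomal genes only: MSY and
  ## PAR genes carry the LOY dosage signal and would bias size factors
  ## toward the tested covariate
  auto <- rowSums(counts) > 0 & rc == "AUTOSOME"
  s <- computeSizeFactors(counts[auto, , drop = FALSE])
  trend <- fitDispersionTrend(counts[auto, , drop = FALSE], s)
  design <- data.frame(loy_bin = bins)
  for (v in covariates) design[[v]] <- cd[[v]]

  res <- do.call(rbind, lapply(genes, function(g) {
    mu_hat <- mean(counts[g, ] / s)
    a_tr <- trend$a0 + trend$a1 / max(mu_hat, 1e-8)
    fitNbGlm(counts[g, ], design, coef = "loy_bin", size_factors = s,
             trend_dispersion = a_tr, shrink = shrink)
  }))
  res <- cbind(data.frame(gene_id = genes,
                          region_class = rc[match(genes, rownames(counts))],
                          cell_type = cd$cell_type[1] %||% NA_character_,
                          method = "BULK"), res)
  rownames(res) <- NULL
  kept <- independentFilter(res, alpha = alpha)
  ## genes removed by the filter keep their Wald p but get no q-value
  res$fdr_q <- kept$fdr_q[match(res$gene_id, kept$gene_id)]
  res <- classifyLateTiers(res)
  attr(res, "filter_threshold") <- attr(kept, "threshold")
  attr(res, "n_removed") <- attr(kept, "n_removed")
  res
}
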