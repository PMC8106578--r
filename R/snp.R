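## LOY estimation from SNP-array log R ratios: median LRR over MSY probes
## (mLRRY), per-batch centring, and conversion to a cell fraction.

#' Median log R ratio over MSY probes (mLRRY)
#'
#' For each sample, the median of the LRR values of probes located in the
#' male-specific region of chromosome Y. Values near zero indicate a normal
#' chromosome Y state; increasing LOY mosaicism pushes mLRRY negative.
#'
#' @param lrr [LoyLrrExperiment-class]; missing probe values are excluded.
#' @return named numeric vector, one mLRRY per sample.
#' @export
computeMlrry <- function(lrr) {
  msy <- rowData(lrr)$in_msy
  if (!any(msy)) stop("no MSY probes in the experiment", call. = FALSE)
  vals <- assay(lrr, "lrr")[msy, , drop = FALSE]
  n_ok <- colSums(!is.na(vals))
  if (any(n_ok == 0))
    stop("sample(s) with zero non-missing MSY probes: ",
         paste(colnames(vals)[n_ok == 0], collapse = ", "), call. = FALSE)
  apply(vals, 2, median, na.rm = TRUE)
}

#' Batch-correct mLRRY values by the per-batch median
#'
#' Each sample's mLRRY is corrected by the centre of its genotyping batch
#' (the batch median by default), removing batch-specific intensity bias.
#' Batches smaller than \code{min_batch} fall back to the global median with
#' a warning. \code{method = "running"} instead centres on a running median
#' over processing order within each batch (window \code{window}), for
#' settings where the batch bias drifts over time.
#'
#' @param mlrry named numeric vector.
#' @param batch batch label per sample.
#' @param min_batch smallest batch size centred on its own median (default 3).
#' @param method "median" (default) or "running".
#' @param window running-median window (odd; used by method "running").
#' @return corrected numeric vector.
#' @export
batchCorrectMlrry <- function(mlrry, batch, min_batch = 3,
                              method = c("median", "running"), window = 11) {
  method <- match.arg(method)
  batch <- rep_len(as.character(batch), length(mlrry))
  out <- mlrry
  global <- median(mlrry, na.rm = TRUE)
  for (b in unique(batch)) {
    i <- which(batch == b)
    if (length(i) < min_batch) {
      warning("batch '", b, "' has fewer than ", min_batch,
              " samples; using global median centre")
      out[i] <- mlrry[i] - global
    } else if (method == "median") {
      out[i] <- mlrry[i] - median(mlrry[i], na.rm = TRUE)
    } else {
      w <- min(window, length(i) - (length(i) + 1) %% 2)
      centre <- stats::runmed(mlrry[i], k = max(3, w %/% 2 * 2 + 1))
      out[i] <- mlrry[i] - centre
    }
  }
  out
}

#' Convert mLRRY to the percentage of cells with a normal chromosome Y
#'
#' Uses the closed-form inversion normal(\%) = 100 * 2^(2 * mLRRY), clipped
#' to [0, 100] (noise can push mLRRY above zero); the LOY cell fraction is
#' 1 - normal/100.
#'
#' @param mlrry numeric vector of (batch-corrected) mLRRY values.
#' @return data.frame with \code{normal_percent} and \code{loy_fraction}.
#' @examples
#' normalFractionFromMlrry(c(0, -0.5, 0.1))
#' @export
normalFractionFromMlrry <- function(mlrry) {
  stopifnot(all(is.finite(mlrry)))
  normal <- clip(100 * 2^(2 * mlrry), 0, 100)
  data.frame(normal_percent = normal, loy_fraction = 1 - normal / 100)
}

#' SNP-array LOY estimates for every sample
#'
#' Runs the full chain mLRRY -> batch correction -> cell-fraction conversion
#' and returns one row per sample in the common LoyEstimate layout.
#'
#' @param lrr [LoyLrrExperiment-class].
#' @param batch_correct apply [batchCorrectMlrry()] (default TRUE).
#' @param ... passed to [batchCorrectMlrry()].
#' @return data.frame with sample_id, method, raw_stat (corrected mLRRY),
#'   normal_percent, loy_fraction.
#' @export
snpLoyEstimates <- function(lrr, batch_correct = TRUE, ...) {
  m <- computeMlrry(lrr)
  if (batch_correct) m <- batchCorrectMlrry(m, colData(lrr)$batch, ...)
  conv <- normalFractionFromMlrry(m)
  data.frame(sample_id = colnames(lrr), method = "SNP", raw_stat = m,
             normal_percent = conv$normal_percent,
             loy_fraction = conv$loy_fraction, row.names = NULL)
}
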