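## LOY quantification from droplet digital PCR: Poisson-corrected template
## concentrations per channel, then the AMELY/AMELX ratio.

#' Poisson-corrected template concentration from droplet counts
#'
#' In ddPCR, templates partition into droplets as Poisson, so the fraction p
#' of positive droplets gives the mean template load per droplet as
#' lambda = -ln(1 - p).
#'
#' @param positive positive-droplet count (0 <= positive < total).
#' @param total total droplets (> 0).
#' @return lambda, templates per droplet.
#' @examples
#' poissonConcentration(5000, 20000)   # -log(0.75)
#' @export
poissonConcentration <- function(positive, total) {
  if (any(total <= 0)) stop("total droplets must be positive", call. = FALSE)
  if (any(positive < 0)) stop("negative positive count", call. = FALSE)
  if (any(positive >= total))
    stop("saturated channel: every droplet positive", call. = FALSE)
  -log(1 - positive / total)
}

#' LOY estimate from AMELY/AMELX droplet counts
#'
#' The ratio of Poisson-corrected AMELY to AMELX concentrations estimates the
#' fraction of genomes retaining chromosome Y; the LOY cell fraction is
#' 1 - ratio, clipped to [0, 1]. \code{raw_ratio = TRUE} skips the Poisson
#' correction and uses the positive-count ratio directly (adequate at low
#' positive fractions).
#'
#' @param droplets data.frame with columns n_droplets, positive_y,
#'   positive_x (one row per well), e.g. from [simulateDdpcr()].
#' @param raw_ratio use raw positive counts instead of concentrations.
#' @return data.frame with sample_id, method, raw_stat (the Y/X ratio),
#'   normal_percent, loy_fraction.
#' @export
ddpcrLoyEstimates <- function(droplets, raw_ratio = FALSE) {
  if (any(droplets$positive_x == 0))
    stop("no X amplification in well(s): ",
         paste(which(droplets$positive_x == 0), collapse = ", "),
         call. = FALSE)
  ratio <- if (raw_ratio) {
    droplets$positive_y / droplets$positive_x
  } else {
    poissonConcentration(droplets$positive_y, droplets$n_droplets) /
      poissonConcentration(droplets$positive_x, droplets$n_droplets)
  }
  loy <- clip(1 - ratio, 0, 1)
  data.frame(sample_id = droplets$well %||% sprintf("well%02d", seq_len(nrow(droplets))),
             method = "DDPCR", raw_stat = ratio,
             normal_percent = 100 * (1 - loy), loy_fraction = loy,
             row.names = NULL)
}
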