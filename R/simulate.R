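## Synthetic data generators. Each returns the simulated object plus a
## `truth` list that fully determines the expected value of every
## observation, so downstream estimators can be tested against known ground
## truth. All randomness is confined to withr::with_seed(seed, ...), so the
## same seed gives bit-identical output.

#' Simulate SNP-array log R ratios with known LOY cell fractions
#'
#' MSY-probe LRR values for a sample with LOY cell fraction f are drawn
#' Normal(log2(1 - f)/2 + batch offset, noise_sd); probes outside the MSY are
#' centred at the batch offset alone. The factor 1/2 compresses the log ratio
#' so that the standard inversion 100 * 2^(2 * mLRRY) recovers exactly
#' 100 * (1 - f) in expectation.
#'
#' @param loy_fractions numeric vector in [0, 1), one per sample.
#' @param n_msy_probes,n_other_probes probes inside / outside the MSY.
#' @param batch per-sample batch labels (default one batch).
#' @param batch_offsets named numeric, LRR offset per batch level (default 0).
#' @param noise_sd per-probe LRR standard deviation (> 0; default 0.15).
#' @param seed integer seed.
#' @return list with \code{lrr} ([LoyLrrExperiment-class]) and \code{truth}.
#' @examples
#' sim <- simulateSnpArray(c(0, 0.5), seed = 1)
#' computeMlrry(sim$lrr)
#' @export
simulateSnpArray <- function(loy_fractions, n_msy_probes = 120,
                             n_other_probes = 60, batch = NULL,
                             batch_offsets = NULL, noise_sd = 0.15,
                             seed = NULL) {
  f <- loy_fractions
  if (any(f < 0 | f >= 1))
    stop("loy_fractions must lie in [0, 1): f = 1 has no finite log ratio",
         call. = FALSE)
  stopifnot(noise_sd > 0, n_msy_probes >= 1)
  n <- length(f)
  batch <- rep_len(batch %||% "batch1", n)
  off <- if (is.null(batch_offsets))
    setNames(rep(0, length(unique(batch))), unique(batch)) else batch_offsets
  offs <- off[batch]

  probes <- data.frame(
    probe_id = sprintf("probe%04d", seq_len(n_msy_probes + n_other_probes)),
    chromosome = c(rep("Y", n_msy_probes), rep("7", n_other_probes)),
    position = c(seq(3e6, 28e6, length.out = n_msy_probes),
                 seq(1e6, 50e6, length.out = max(n_other_probes, 1))[seq_len(n_other_probes)]))

  gen <- function() {
    msy_mean <- log2(1 - f) / 2 + offs
    vals <- rbind(
      matrix(rnorm(n_msy_probes * n, rep(msy_mean, each = n_msy_probes),
                   noise_sd), n_msy_probes, n),
      matrix(rnorm(n_other_probes * n, rep(offs, each = n_other_probes),
                   noise_sd), n_other_probes, n))
    vals
  }
  vals <- if (is.null(seed)) gen() else withr::with_seed(seed, gen())
  lrr <- LoyLrrExperiment(vals, probes, batch = batch)
  truth <- list(loy_fraction = f, batch = batch, batch_offsets = off,
                noise_sd = noise_sd, expected_mlrry = log2(1 - f) / 2 + offs,
                seed = seed)
  list(lrr = lrr, truth = truth)
}

#' Simulate droplet digital PCR counts for the AMELY/AMELX assay
#'
#' X-channel template load is \code{templates_x}; Y templates are reduced by
#' the LOY fraction to \code{templates_x * (1 - f)}. Templates partition into
#' droplets as Poisson, so each channel's positive-droplet count is
#' Binomial(n_droplets, 1 - exp(-templates / n_droplets)).
#'
#' @param loy_fraction f in [0, 1].
#' @param n_droplets droplets generated (default 20000).
#' @param templates_x X-chromosome template molecules loaded (default 4000).
#' @param seed integer seed.
#' @return data.frame with n_droplets, positive_y, positive_x and the truth
#'   attributes \code{loy_fraction}, \code{lambda_x}, \code{lambda_y}.
#' @export
simulateDdpcr <- function(loy_fraction, n_droplets = 20000,
                          templates_x = 4000, seed = NULL) {
  stopifnot(templates_x > 0, n_droplets > 0,
            loy_fraction >= 0, loy_fraction <= 1)
  m <- length(loy_fraction)
  lam_x <- templates_x / n_droplets
  lam_y <- templates_x * (1 - loy_fraction) / n_droplets
  gen <- function()
    data.frame(
      well = sprintf("well%02d", seq_len(m)),
      n_droplets = n_droplets,
      positive_y = rbinom(m, n_droplets, 1 - exp(-lam_y)),
      positive_x = rbinom(m, n_droplets, 1 - exp(-lam_x)))
  d <- if (is.null(seed)) gen() else withr::with_seed(seed, gen())
  attr(d, "truth") <- list(loy_fraction = loy_fraction, lambda_x = lam_x,
                           lambda_y = lam_y, seed = seed)
  d
}

## Dosage multiplier for a gene's region class at LOY fraction f: MSY genes
## are lost with the Y (1 - f); PAR genes keep their X copy (1 - f/2).
dosageFactor <- function(region, f) {
  switch(region, MSY = 1 - f, PAR = 1 - f / 2, 1)
}

#' Simulate bulk RNA-seq counts with MSY/PAR dosage and injected LATE genes
#'
#' Expected count for gene g in sample j is
#' \code{s_j * mu_g * dosage(g, f_j) * 2^(de_g * bin(f_j))}, where dosage is
#' (1 - f) for MSY genes, (1 - f/2) for PAR genes and 1 otherwise, and
#' \code{bin} is the 20-percent LOY bin code ([binLoy()]). Counts are drawn
#' negative-binomial with dispersion alpha(mu) = a0 + a1/mu.
#'
#' @param sample_table data.frame with columns \code{subject},
#'   \code{cell_type}, \code{batch}, \code{f} (LOY cell fraction in [0,1]).
#' @param annotation [GeneAnnotation-class].
#' @param late_spec named numeric: log2 effect per LOY-bin unit for injected
#'   LATE genes (names must be gene_ids in the annotation).
#' @param baseline_means named per-gene means at size factor 1; default drawn
#'   log-normal(meanlog log 100, sdlog 1).
#' @param dispersion c(a0, a1) of the dispersion-mean trend (default 0.05, 2).
#' @param library_sizes per-sample size factors s_j (default 1).
#' @param batch_effects named list: batch level -> named numeric of per-gene
#'   log2 offsets (genes absent get 0).
#' @param seed integer seed.
#' @return list with \code{bulk} ([LoyBulkExperiment-class]) and \code{truth}.
#' @export
simulateBulkCounts <- function(sample_table, annotation, late_spec = NULL,
                               baseline_means = NULL,
                               dispersion = c(a0 = 0.05, a1 = 2),
                               library_sizes = NULL, batch_effects = NULL,
                               seed = NULL) {
  ann <- annotationTable(annotation)
  genes <- ann$gene_id
  if (!is.null(late_spec)) {
    bad <- setdiff(names(late_spec), genes)
    if (length(bad))
      stop("late_spec genes not in annotation: ",
           paste(head(bad, 5), collapse = ", "), call. = FALSE)
  }
  n <- nrow(sample_table)
  s <- rep_len(library_sizes %||% 1, n)
  f <- sample_table$f
  stopifnot(all(f >= 0 & f <= 1))
  bins <- binLoy(100 * f)

  gen <- function() {
    mu <- baseline_means %||%
      setNames(rlnorm(length(genes), log(100), 1), genes)
    mu <- mu[genes]
    alpha <- dispersion[1] + dispersion[2] / pmax(mu, 1e-8)
    dos <- vapply(ann$region_class, function(r)
      vapply(f, function(fi) dosageFactor(r, fi), numeric(1)),
      numeric(n))                           # n x genes
    mean_mat <- t(dos) * mu                 # genes x n
    mean_mat <- sweep(mean_mat, 2, s, "*")
    if (!is.null(late_spec)) {
      de_fac <- outer(rep(0, length(genes)), bins)   # genes x n of zeros
      ii <- match(names(late_spec), genes)
      de_fac[ii, ] <- outer(unname(late_spec), bins)
      mean_mat <- mean_mat * 2^de_fac
    }
    if (!is.null(batch_effects)) {
      for (b in names(batch_effects)) {
        cols <- which(sample_table$batch == b)
        if (!length(cols)) next
        offs <- rep(0, length(genes))
        ii <- match(names(batch_effects[[b]]), genes)
        offs[ii[!is.na(ii)]] <- batch_effects[[b]][!is.na(ii)]
        mean_mat[, cols] <- mean_mat[, cols] * 2^offs
      }
    }
    counts <- matrix(rnbinom(length(mean_mat), mu = mean_mat,
                             size = rep(1 / alpha, n)),
                     nrow = length(genes),
                     dimnames = list(genes, sprintf("sample%03d", seq_len(n))))
    list(counts = counts, mu = mu, alpha = alpha)
  }
  out <- if (is.null(seed)) gen() else withr::with_seed(seed, gen())
  sd2 <- sample_table
  sd2$dna_loy_fraction <- f
  bulk <- LoyBulkExperiment(out$counts, sd2, annotation)
  truth <- list(loy_fraction = f, loy_bin = bins,
                late_spec = late_spec %||% setNames(numeric(0), character(0)),
                batch_effects = batch_effects, baseline_mean = out$mu,
                dispersion = out$alpha, trend = dispersion,
                library_sizes = s, seed = seed)
  list(bulk = bulk, truth = truth)
}

#' Default PBMC cell-type marker table
#'
#' Assigns marker genes (taken from the autosomal fixture genes) to the four
#' PBMC populations used throughout: NK cells, monocytes, B and T
#' lymphocytes.
#'
#' @param annotation [GeneAnnotation-class]
#' @param n_markers markers per cell type (>= 2)
#' @return named list cell_type -> character vector of gene_ids
#' @export
defaultMarkerTable <- function(annotation, n_markers = 3) {
  auto <- genesInRegion(annotation, "AUTOSOME")
  types <- c("B", "Monocyte", "NK", "T")
  stopifnot(length(auto) >= n_markers * length(types), n_markers >= 2)
  setNames(lapply(seq_along(types), function(i)
    auto[((i - 1) * n_markers + 1):(i * n_markers)]), types)
}

#' Simulate single-cell UMI counts with per-cell LOY ground truth
#'
#' Each cell belongs to one of the marker-defined PBMC types and is LOY with
#' the type-specific probability. LOY cells have zero expected MSY
#' expression; cells retaining Y allocate \code{msy_share} of their UMIs to
#' the expressed MSY genes. Mitochondrial content is a Beta-distributed
#' fraction of each cell's UMI total, with a high-mito mixture component
#' emulating apoptotic cells; doublets are emulated by summing two random
#' cells' count vectors. Defaults for the per-type LOY frequencies follow the
#' leukocyte averages reported for aged men (NK 27\%, monocytes 23\%,
#' B 7\%, T 3\%).
#'
#' @param n_cells_per_type named integer: cells per type per sample.
#' @param annotation [GeneAnnotation-class].
#' @param loy_fractions named per-type LOY probabilities.
#' @param n_samples number of donors.
#' @param marker_table named list type -> marker gene_ids
#'   (default [defaultMarkerTable()]).
#' @param marker_fold expression fold-up of a type's markers in its own cells.
#' @param msy_share expected fraction of a Y-bearing cell's UMIs from MSY
#'   genes (default 0.002, concentrated in \code{n_expressed_msy} genes).
#' @param n_expressed_msy number of MSY genes expressed at all (default 6).
#' @param mito_beta shape1/shape2 of the baseline mitochondrial fraction.
#' @param apoptotic_rate,apoptotic_beta high-mito mixture component.
#' @param umi_meanlog,umi_sdlog log-normal per-cell UMI depth.
#' @param doublet_rate fraction of cells replaced by summed pairs, in [0, 1).
#' @param late_spec named numeric: log2 shift applied in LOY cells (injected
#'   LOY-associated transcriptional effects).
#' @param seed integer seed.
#' @return list with \code{cells} ([LoyCellExperiment-class]) and
#'   \code{truth} (per-cell type and LOY flag, parameters).
#' @export
simulateScCounts <- function(n_cells_per_type, annotation,
                             loy_fractions = c(B = 0.07, Monocyte = 0.23,
                                               NK = 0.27, T = 0.03),
                             n_samples = 1,
                             marker_table = NULL, marker_fold = 20,
                             msy_share = 0.002, n_expressed_msy = 6,
                             mito_beta = c(2, 60),
                             apoptotic_rate = 0.05, apoptotic_beta = c(10, 40),
                             umi_meanlog = log(4000), umi_sdlog = 0.35,
                             doublet_rate = 0, late_spec = NULL, seed = NULL) {
  if (doublet_rate < 0 || doublet_rate >= 1)
    stop("doublet_rate must lie in [0, 1)", call. = FALSE)
  marker_table <- marker_table %||% defaultMarkerTable(annotation)
  stopifnot(all(vapply(marker_table, length, 1L) >= 2))
  types <- names(marker_table)
  stopifnot(all(names(n_cells_per_type) %in% types),
            all(names(loy_fractions) %in% types))

  ann <- annotationTable(annotation)
  genes <- ann$gene_id
  msy <- genesInRegion(annotation, "MSY")
  mito <- genesInRegion(annotation, "MITO")
  stopifnot(length(msy) >= n_expressed_msy, length(mito) >= 1)

  gen <- function() {
    base_w <- setNames(rlnorm(length(genes), 0, 1), genes)
    base_w[msy] <- 0
    base_w[mito] <- 0
    expressed_msy <- msy[seq_len(n_expressed_msy)]
    base_w <- base_w / sum(base_w)
    msy_w <- setNames(rep(0, length(genes)), genes)
    msy_w[expressed_msy] <- rlnorm(n_expressed_msy, 0, 0.5)
    msy_w <- msy_w / sum(msy_w) * msy_share
    mito_w <- setNames(rep(0, length(genes)), genes)
    mito_w[mito] <- rlnorm(length(mito), 0, 0.3)
    mito_w <- mito_w / sum(mito_w)

    typeProb <- function(type, loy) {
      w <- base_w
      w[marker_table[[type]]] <- w[marker_table[[type]]] * marker_fold
      if (loy && !is.null(late_spec)) {
        ii <- match(names(late_spec), genes)
        w[ii] <- w[ii] * 2^late_spec
      }
      w <- w / sum(w)
      if (loy) w else w * (1 - msy_share) + msy_w
    }
    probs <- list()
    for (ty in types) for (loy in c(FALSE, TRUE))
      probs[[paste(ty, loy)]] <- {
        p <- typeProb(ty, loy); p / sum(p)
      }

    cells <- do.call(rbind, lapply(seq_len(n_samples), function(s)
      do.call(rbind, lapply(names(n_cells_per_type), function(ty)
        data.frame(sample_id = sprintf("donor%02d", s), cell_type = ty,
                   n = n_cells_per_type[[ty]])))))
    meta <- cells[rep(seq_len(nrow(cells)), cells$n), c("sample_id", "cell_type")]
    ncell <- nrow(meta)
    meta$loy <- rbinom(ncell, 1, loy_fractions[meta$cell_type]) == 1
    meta$apoptotic <- runif(ncell) < apoptotic_rate
    meta$mito_fraction <- ifelse(meta$apoptotic,
                                 rbeta(ncell, apoptotic_beta[1], apoptotic_beta[2]),
                                 rbeta(ncell, mito_beta[1], mito_beta[2]))
    depth <- pmax(200, round(rlnorm(ncell, umi_meanlog, umi_sdlog)))

    counts <- matrix(0L, length(genes), ncell,
                     dimnames = list(genes, sprintf("cell%05d", seq_len(ncell))))
    for (i in seq_len(ncell)) {
      p <- probs[[paste(meta$cell_type[i], meta$loy[i])]]
      p_i <- p * (1 - meta$mito_fraction[i]) + mito_w * meta$mito_fraction[i]
      counts[, i] <- rmultinom(1, depth[i], p_i)
    }
    if (doublet_rate > 0) {
      nd <- round(doublet_rate * ncell)
      if (nd > 0) {
        tgt <- sample.int(ncell, nd)
        src <- sample.int(ncell, nd, replace = TRUE)
        counts[, tgt] <- counts[, tgt] + counts[, src]
        meta$doublet <- FALSE; meta$doublet[tgt] <- TRUE
      }
    } else meta$doublet <- FALSE
    list(counts = counts, meta = meta, expressed_msy = expressed_msy)
  }
  out <- if (is.null(seed)) gen() else withr::with_seed(seed, gen())
  cells <- LoyCellExperiment(Matrix::Matrix(out$counts, sparse = TRUE),
                             out$meta$sample_id, annotation)
  truth <- list(
    cell = data.frame(cell_id = colnames(cells),
                      sample_id = out$meta$sample_id,
                      cell_type = out$meta$cell_type,
                      loy = out$meta$loy, doublet = out$meta$doublet,
                      apoptotic = out$meta$apoptotic),
    loy_fractions = loy_fractions, msy_share = msy_share,
    expressed_msy = out$expressed_msy,
    late_spec = late_spec %||% setNames(numeric(0), character(0)),
    seed = seed)
  list(cells = cells, truth = truth)
}

#' Simulate lymphoblastoid cell-line (LCL) clones
#'
#' Default design: 13 clones from 6 donors, with every LOY clone derived from
#' a single donor who also contributes one non-LOY clone (donor 1: two LOY
#' clones plus one normal; donors 2-6: two normal clones each). Donor-specific
#' genes vary between individuals regardless of LOY; LOY genes vary with LOY
#' status; genes in both sets are flagged confounded in the truth.
#'
#' @param annotation [GeneAnnotation-class].
#' @param n_individuals,n_clones design size (defaults 6 and 13).
#' @param loy_clones indices of LOY clones (default the first two clones of
#'   donor 1). Spreading LOY clones over several donors errors unless
#'   \code{allow_multi_individual = TRUE}.
#' @param inter_individual_genes named list: gene_id -> numeric vector of
#'   per-donor log2 offsets (length n_individuals).
#' @param loy_genes named numeric: log2 effect in LOY clones.
#' @param baseline_means,dispersion,seed as in [simulateBulkCounts()].
#' @param allow_multi_individual override the single-donor LOY design check.
#' @return list with \code{bulk}, \code{design} and \code{truth}.
#' @export
simulateLclClones <- function(annotation, n_individuals = 6, n_clones = 13,
                              loy_clones = c(1, 2),
                              inter_individual_genes = NULL,
                              loy_genes = NULL, baseline_means = NULL,
                              dispersion = c(0.05, 2), seed = NULL,
                              allow_multi_individual = FALSE) {
  stopifnot(n_clones >= n_individuals + 1)
  ## donor 1 takes the surplus clones, remaining clones spread evenly
  extra <- n_clones - 2 * (n_individuals - 1)
  stopifnot(extra >= 1)
  individual <- c(rep(1L, extra), rep(2:n_individuals, each = 2))
  loy <- seq_len(n_clones) %in% loy_clones
  if (length(unique(individual[loy])) > 1 && !allow_multi_individual)
    stop("LOY clones span more than one individual; set ",
         "allow_multi_individual = TRUE to override", call. = FALSE)
  if (any(loy) && !any(!loy & individual %in% individual[loy]))
    stop("the LOY donor must also contribute a non-LOY clone", call. = FALSE)

  ann <- annotationTable(annotation)
  genes <- ann$gene_id
  gen <- function() {
    mu <- baseline_means %||% setNames(rlnorm(length(genes), log(100), 1), genes)
    mu <- mu[genes]
    alpha <- dispersion[1] + dispersion[2] / pmax(mu, 1e-8)
    f <- ifelse(loy, 1, 0)   # LCL clones are clonal: ~0% or ~100% LOY
    dos <- vapply(seq_len(n_clones), function(j)
      vapply(ann$region_class, dosageFactor, numeric(1), f = f[j]),
      numeric(length(genes)))
    mean_mat <- mu * dos
    rownames(mean_mat) <- genes
    if (!is.null(inter_individual_genes))
      for (g in names(inter_individual_genes)) {
        offs <- inter_individual_genes[[g]]
        mean_mat[g, ] <- mean_mat[g, ] * 2^offs[individual]
      }
    if (!is.null(loy_genes))
      for (g in names(loy_genes))
        mean_mat[g, loy] <- mean_mat[g, loy] * 2^loy_genes[[g]]
    counts <- matrix(rnbinom(length(mean_mat), mu = mean_mat,
                             size = rep(1 / alpha, n_clones)),
                     nrow = length(genes),
                     dimnames = list(genes, sprintf("clone%02d", seq_len(n_clones))))
    counts
  }
  counts <- if (is.null(seed)) gen() else withr::with_seed(seed, gen())
  design <- data.frame(clone_id = colnames(counts),
                       individual_id = sprintf("donor%02d", individual),
                       loy_status = ifelse(loy, "LOY", "NORMAL"))
  sd <- data.frame(subject = design$individual_id, cell_type = "LCL",
                   batch = "batch1", f = ifelse(loy, 1, 0))
  bulk <- LoyBulkExperiment(counts, cbind(sd, design), annotation)
  confounded <- intersect(names(inter_individual_genes %||% list()),
                          names(loy_genes %||% numeric(0)))
  truth <- list(design = design,
                inter_individual_genes = names(inter_individual_genes %||% list()),
                loy_genes = loy_genes %||% setNames(numeric(0), character(0)),
                confounded_genes = confounded, seed = seed)
  list(bulk = bulk, design = design, truth = truth)
}

#' Simulate a disease cohort with per-cell-type LOY fractions
#'
#' One row per subject and leukocyte cell type. LOY fractions follow a
#' zero-inflated Beta: with probability \code{zero_inflation} a subject-type
#' has no detectable LOY; otherwise the fraction is Beta-distributed with a
#' cell-type baseline mean shifted on the log-odds scale by the group-by-type
#' entry of \code{shift_matrix}. Defaults mirror a case-control design of 156
#' controls, 121 Alzheimer's and 107 prostate-cancer patients over six sorted
#' leukocyte populations.
#'
#' @param n_control,n_ad,n_pc group sizes.
#' @param cell_types leukocyte populations.
#' @param baseline_mean named per-type Beta mean of the LOY fraction.
#' @param shift_matrix numeric matrix groups x cell types of additive
#'   log-odds shifts (default all zero).
#' @param precision Beta precision (shape1 + shape2).
#' @param zero_inflation probability of exactly zero LOY.
#' @param age_mean,age_sd named per-group age distributions.
#' @param smoking_prob probability of smoking.
#' @param seed integer seed.
#' @return list with \code{table} (CohortTable data.frame) and \code{truth}.
#' @export
simulateCohort <- function(n_control = 156, n_ad = 121, n_pc = 107,
                           cell_types = c("NK", "Monocyte", "Granulocyte",
                                          "B", "CD4T", "CD8T"),
                           baseline_mean = NULL, shift_matrix = NULL,
                           precision = 8, zero_inflation = 0.35,
                           age_mean = c(CONTROL = 74, AD = 76, PC = 71),
                           age_sd = c(CONTROL = 5, AD = 6, PC = 6),
                           smoking_prob = 0.25, seed = NULL) {
  groups <- c("CONTROL", "AD", "PC")
  ns <- c(CONTROL = n_control, AD = n_ad, PC = n_pc)
  baseline_mean <- baseline_mean %||%
    setNames(rep(0.12, length(cell_types)), cell_types)
  if (is.null(shift_matrix)) {
    shift_matrix <- matrix(0, 3, length(cell_types),
                           dimnames = list(groups, cell_types))
  }
  gen <- function() {
    subj <- data.frame(
      subject_id = sprintf("subj%03d", seq_len(sum(ns))),
      group = rep(groups, ns))
    subj$age <- rnorm(nrow(subj), age_mean[subj$group], age_sd[subj$group])
    subj$smoking <- runif(nrow(subj)) < smoking_prob
    tab <- merge(subj, data.frame(cell_type = cell_types), by = NULL)
    logit <- function(p) log(p / (1 - p))
    m0 <- logit(baseline_mean[tab$cell_type])
    shift <- shift_matrix[cbind(tab$group, tab$cell_type)]
    mu <- 1 / (1 + exp(-(m0 + shift)))
    tab$loy_fraction <- rbeta(nrow(tab), mu * precision, (1 - mu) * precision)
    tab$loy_fraction[runif(nrow(tab)) < zero_inflation] <- 0
    tab[order(tab$subject_id, tab$cell_type), ]
  }
  tab <- if (is.null(seed)) gen() else withr::with_seed(seed, gen())
  rownames(tab) <- NULL
  truth <- list(baseline_mean = baseline_mean, shift_matrix = shift_matrix,
                precision = precision, zero_inflation = zero_inflation,
                seed = seed)
  list(table = tab, truth = truth)
}
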