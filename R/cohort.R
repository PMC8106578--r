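## Cohort stage: per-cell-type LOY distributions in disease groups versus
## controls, unadjusted (rank-based) and adjusted (logistic regression with
## age and smoking).

#' Unadjusted group comparison of LOY fractions
#'
#' Two-sided Wilcoxon rank-sum test of loy_fraction between two groups
#' within one cell type. The rank-based test is robust to the zero-inflated
#' LOY distributions typical of cohort data.
#'
#' @param cohort CohortTable data.frame (see [simulateCohort()]).
#' @param group_a,group_b group labels to compare.
#' @param cell_type cell type stratum.
#' @return list with p_value, median_a, median_b, n_a, n_b.
#' @export
compareUnadjusted <- function(cohort, group_a, group_b, cell_type) {
  a <- cohort$loy_fraction[cohort$group == group_a &
                             cohort$cell_type == cell_type]
  b <- cohort$loy_fraction[cohort$group == group_b &
                             cohort$cell_type == cell_type]
  if (length(a) < 3 || length(b) < 3)
    stop("fewer than 3 subjects in a stratum", call. = FALSE)
  p <- if (sd(c(a, b)) == 0) 1
  else wilcox.test(a, b, exact = FALSE)$p.value
  list(p_value = p, median_a = median(a), median_b = median(b),
       n_a = length(a), n_b = length(b))
}

## Firth-penalized logistic regression (Jeffreys prior): Newton iterations
## on the score adjusted by half the leverage. Used when the ML fit shows
## separation.
firthLogistic <- function(X, y, maxit = 50, tol = 1e-8) {
  beta <- rep(0, ncol(X))
  for (i in seq_len(maxit)) {
    eta <- clip(drop(X %*% beta), -30, 30)
    p <- 1 / (1 + exp(-eta))
    W <- p * (1 - p)
    XtWX <- crossprod(X, X * W)
    inv <- solve(XtWX)
    h <- rowSums((X %*% inv) * X) * W      # leverages
    U <- crossprod(X, y - p + h * (0.5 - p))
    step <- drop(inv %*% U)
    beta <- beta + step
    if (max(abs(step)) < tol) break
  }
  list(beta = beta, cov = inv)
}

#' Logistic regression of disease status on LOY with covariate adjustment
#'
#' Fits disease (one group versus controls) on the LOY fraction within a
#' cell type, optionally adjusted for age and smoking. The odds ratio is
#' reported per 10-percentage-point LOY increment with a Wald confidence
#' interval. On (quasi-)separation the fit falls back to Firth-penalized
#' likelihood with a warning.
#'
#' @param cohort CohortTable data.frame.
#' @param disease_group label of the case group (compared to "CONTROL").
#' @param cell_type cell type stratum.
#' @param adjust covariate names among c("age", "smoking")
#'   (default both; use character(0) for unadjusted).
#' @param control_group label of the reference group (default "CONTROL").
#' @return list with or (per 10 points LOY), ci (95\%), p_value, beta, se,
#'   n, firth (whether the penalized fallback was used).
#' @export
logisticLoyDisease <- function(cohort, disease_group, cell_type,
                               adjust = c("age", "smoking"),
                               control_group = "CONTROL") {
  d <- cohort[cohort$cell_type == cell_type &
                cohort$group %in% c(disease_group, control_group), ]
  d <- d[complete.cases(d[, c("loy_fraction", adjust), drop = FALSE]), ]
  y <- as.integer(d$group == disease_group)
  d$loy10 <- d$loy_fraction / 0.10        # per 10-percentage-point unit
  form <- stats::reformulate(c("loy10", adjust), response = "y")
  env <- cbind(y = y, d)
  fit <- suppressWarnings(glm(form, family = binomial(), data = env))
  separated <- !fit$converged ||
    any(abs(coef(fit)) > 15) ||
    any(sqrt(diag(vcov(fit))) > 100)
  if (separated) {
    warning("separation detected; Firth-penalized fit used")
    X <- stats::model.matrix(form, data = env)
    ff <- firthLogistic(X, y)
    beta <- ff$beta[2]; se <- sqrt(ff$cov[2, 2]); firth <- TRUE
  } else {
    beta <- coef(fit)[["loy10"]]
    se <- sqrt(vcov(fit)["loy10", "loy10"]); firth <- FALSE
  }
  z <- beta / se
  list(or = exp(beta), ci = exp(beta + c(-1, 1) * 1.96 * se),
       p_value = 2 * pnorm(-abs(z)), beta = beta, se = se,
       n = nrow(d), firth = firth)
}
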