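#' Greedy LD clumping of exposure summary statistics
#'
#' Applies the instrument-selection filters (MAF strictly above `maf_min`,
#' exposure p strictly below `p_max`), sorts the survivors by ascending
#' p-value, and accepts each SNP only if its squared dosage correlation with
#' every already-accepted SNP (computed on the reference genotypes) is at
#' most `r2_max`.
#'
#' @param stats SummaryStats data.frame (SNP, A1, A2, EAF, BETA, SE, P, ...)
#' @param ref_geno a `genotype_matrix` providing the LD reference
#' @param r2_max clumping r-squared cap (default 0.05)
#' @param maf_min minor allele frequency floor (default 0.05)
#' @param p_max exposure p-value ceiling (default 5e-6)
#' @return character vector of selected SNP ids (possibly empty, with a
#'   warning)
#' @export
clump_select <- function(stats, ref_geno, r2_max = 0.05, maf_min = 0.05,
                         p_max = 5e-6) {
  stopifnot(inherits(ref_geno, "genotype_matrix"))
  maf <- pmin(stats$EAF, 1 - stats$EAF)
  cand <- stats[maf > maf_min & stats$P < p_max, , drop = FALSE]
  cand <- cand[cand$SNP %in% ref_geno$snps$id, , drop = FALSE]
  if (nrow(cand) == 0) {
    warning("no candidate instruments survive the MAF/p filters")
    return(character(0))
  }
  cand <- cand[order(cand$P), , drop = FALSE]
  D <- ref_geno$dosage[, match(cand$SNP, ref_geno$snps$id), drop = FALSE]
  sel <- integer(0)
  for (j in seq_len(nrow(cand))) {
    if (length(sel) == 0) { sel <- j; next }
    r2 <- suppressWarnings(
      cor(D[, j], D[, sel, drop = FALSE], use = "pairwise.complete.obs"))^2
    r2[is.na(r2)] <- 0
    if (all(r2 <= r2_max)) sel <- c(sel, j)
  }
  cand$SNP[sel]
}

#' Per-instrument outcome associations in the echo cohort
#'
#' For each instrument SNP, a linear regression of log LV mass on dosage
#' plus covariates, fitted within the requested sex stratum. Effect alleles
#' follow the genotype file's allele1.
#'
#' @param snp_ids instrument SNP ids
#' @param geno a `genotype_matrix`
#' @param phenotype data.frame from [build_lv_mass_phenotype()]
#' @param covariates per-subject covariate data.frame (rownames = ids), or
#'   NULL
#' @param sex_stratum `"male"`, `"female"` or `"all"`
#' @return summary-stats-style data.frame for the outcome
#' @export
outcome_assoc <- function(snp_ids, geno, phenotype, covariates = NULL,
                          sex_stratum = c("all", "male", "female")) {
  sex_stratum <- match.arg(sex_stratum)
  ph <- phenotype
  if (sex_stratum != "all") ph <- ph[ph$sex == sex_stratum, , drop = FALSE]
  assert_that(nrow(ph) >= 30,
              sprintf("sex stratum '%s' has fewer than 30 subjects", sex_stratum))
  g <- subset_genotypes(geno, i = intersect(sample_ids(geno), ph$subject_id),
                        j = snp_ids)
  res <- run_gwas(g, ph, covariates)
  as_summary_stats(res)
}

#' Harmonize exposure and outcome summary statistics
#'
#' Matches SNPs by id and aligns the outcome effects to the exposure's
#' effect allele: when the outcome counts the exposure's other allele the
#' outcome beta's sign is flipped (allowing for strand complements).
#' Strand-ambiguous A/T and C/G SNPs are dropped when their allele
#' frequency is uninformative (|EAF - 0.5| < 0.08); irreconcilable allele
#' pairs are dropped with a count in the attributes.
#'
#' @param exposure SummaryStats data.frame for the exposure
#' @param outcome SummaryStats data.frame for the outcome
#' @return `instrument_set` data.frame: snp, beta_x, se_x, p_x, beta_y,
#'   se_y, eaf
#' @export
harmonize <- function(exposure, outcome) {
  comp <- function(a) chartr("ACGT", "TGCA", a)
  m <- match(exposure$SNP, outcome$SNP)
  keep <- !is.na(m)
  ex <- exposure[keep, , drop = FALSE]
  ou <- outcome[m[keep], , drop = FALSE]
  palindromic <- ex$A1 == comp(ex$A2)
  ambiguous <- palindromic & abs(ex$EAF - 0.5) < 0.08
  same <- (ou$A1 == ex$A1 & ou$A2 == ex$A2) |
    (!palindromic & ou$A1 == comp(ex$A1) & ou$A2 == comp(ex$A2))
  swap <- (ou$A1 == ex$A2 & ou$A2 == ex$A1) |
    (!palindromic & ou$A1 == comp(ex$A2) & ou$A2 == comp(ex$A1))
  ok <- (same | swap) & !ambiguous
  n_dropped <- sum(!ok) + sum(!keep)
  beta_y <- ifelse(swap, -ou$BETA, ou$BETA)
  out <- data.frame(snp = ex$SNP[ok], beta_x = ex$BETA[ok], se_x = ex$SE[ok],
                    p_x = ex$P[ok], beta_y = beta_y[ok], se_y = ou$SE[ok],
                    eaf = ex$EAF[ok], stringsAsFactors = FALSE)
  attr(out, "n_dropped") <- n_dropped
  class(out) <- c("instrument_set", "data.frame")
  out
}

#' Inverse-variance weighted causal estimate
#'
#' The fixed-effect IVW average of the per-instrument Wald ratios:
#' theta = sum(bx by / sy^2) / sum(bx^2 / sy^2), SE =
#' (sum bx^2/sy^2)^(-1/2), two-sided normal p. First-order weights
#' (exposure betas treated as fixed).
#'
#' @param inst an `instrument_set` (or data.frame with beta_x, beta_y, se_y)
#' @return one-row data.frame: method, estimate, se, p, n_inst, Q, Q_df,
#'   het_p
#' @export
ivw_estimate <- function(inst) {
  assert_that(nrow(inst) >= 2,
              "IVW needs >= 2 instruments; use the single Wald ratio instead")
  w <- inst$beta_x^2 / inst$se_y^2
  theta <- sum(inst$beta_x * inst$beta_y / inst$se_y^2) / sum(w)
  se <- 1 / sqrt(sum(w))
  q <- cochran_q(inst, theta)
  data.frame(method = "IVW", estimate = theta, se = se,
             p = 2 * pnorm(-abs(theta / se)), n_inst = nrow(inst),
             Q = q$Q, Q_df = q$df, het_p = q$p, stringsAsFactors = FALSE)
}

#' Cochran's Q heterogeneity statistic over instrument ratios
#'
#' Q = sum w_j (theta_j - theta)^2 with theta_j = beta_y/beta_x and
#' w_j = (se_y/beta_x)^(-2); p from chi-square with J - 1 df. A small p
#' flags instruments whose ratio estimates disagree (possible pleiotropy).
#'
#' @param inst an `instrument_set`
#' @param theta the IVW estimate (computed if missing)
#' @return list: Q, df, p
#' @export
cochran_q <- function(inst, theta = NULL) {
  assert_that(nrow(inst) >= 2, "Cochran's Q needs >= 2 instruments")
  w <- (inst$beta_x / inst$se_y)^2
  ratio <- inst$beta_y / inst$beta_x
  if (is.null(theta)) theta <- sum(w * ratio) / sum(w)
  Q <- sum(w * (ratio - theta)^2)
  df <- nrow(inst) - 1
  list(Q = Q, df = df, p = pchisq(Q, df, lower.tail = FALSE))
}

#' MR-Egger regression
#'
#' Weighted least squares of the outcome betas on the exposure betas with
#' an unconstrained intercept, weights 1/se_y^2, after orienting alleles so
#' every exposure beta is non-negative (the Egger identifiability
#' convention). The slope estimates the causal effect; the intercept
#' estimates the average directional pleiotropy. Standard errors use the
#' weighted-regression dispersion, floored at 1 (multiplicative
#' random-effects convention).
#'
#' @param inst an `instrument_set`
#' @return one-row data.frame: method, estimate, se, p, n_inst, intercept,
#'   intercept_se, intercept_p
#' @export
egger_estimate <- function(inst) {
  assert_that(nrow(inst) >= 3, "MR-Egger needs >= 3 instruments")
  flip <- sign(inst$beta_x) < 0
  bx <- abs(inst$beta_x)
  by <- ifelse(flip, -inst$beta_y, inst$beta_y)
  w <- 1 / inst$se_y^2
  fit <- lm(by ~ bx, weights = w)
  sm <- summary(fit)
  disp <- max(1, sm$sigma)
  co <- sm$coefficients
  df <- nrow(inst) - 2
  se_slope <- co["bx", "Std. Error"] / sm$sigma * disp
  se_int <- co["(Intercept)", "Std. Error"] / sm$sigma * disp
  t_slope <- co["bx", "Estimate"] / se_slope
  t_int <- co["(Intercept)", "Estimate"] / se_int
  data.frame(method = "Egger", estimate = co["bx", "Estimate"], se = se_slope,
             p = 2 * pt(-abs(t_slope), df), n_inst = nrow(inst),
             intercept = co["(Intercept)", "Estimate"], intercept_se = se_int,
             intercept_p = 2 * pt(-abs(t_int), df), stringsAsFactors = FALSE)
}

#' Weighted-median causal estimate
#'
#' Per-instrument Wald ratios theta_j = beta_y/beta_x with normalized
#' weights w_j proportional to beta_x^2/se_y^2; the estimate is the value at
#' which the cumulative weight crosses one half, interpolating linearly
#' between adjacent order statistics. Consistent when instruments carrying
#' a majority of the weight are valid. The standard error comes from a
#' seeded parametric bootstrap over the instrument-level estimates.
#'
#' @param inst an `instrument_set`
#' @param n_boot bootstrap draws (default 1000)
#' @param seed bootstrap seed
#' @return one-row data.frame: method, estimate, se, p, n_inst
#' @export
weighted_median_estimate <- function(inst, n_boot = 1000, seed = 1L) {
  nz <- inst$beta_x != 0
  if (any(!nz)) {
    message(sum(!nz), " instrument(s) dropped: zero exposure beta")
    inst <- inst[nz, , drop = FALSE]
  }
  assert_that(nrow(inst) >= 3, "weighted median needs >= 3 instruments")
  est <- weighted_median(inst$beta_y / inst$beta_x, inst$beta_x^2 / inst$se_y^2)
  set.seed(as.integer(seed))
  boot <- replicate(n_boot, {
    bx <- rnorm(nrow(inst), inst$beta_x, inst$se_x)
    by <- rnorm(nrow(inst), inst$beta_y, inst$se_y)
    ok <- bx != 0
    weighted_median(by[ok] / bx[ok], bx[ok]^2 / inst$se_y[ok]^2)
  })
  se <- sd(boot)
  data.frame(method = "WeightedMedian", estimate = est, se = se,
             p = 2 * pnorm(-abs(est / se)), n_inst = nrow(inst),
             stringsAsFactors = FALSE)
}

# weighted median with linear interpolation at the 0.5 crossing
weighted_median <- function(x, w) {
  ord <- order(x)
  x <- x[ord]; w <- w[ord] / sum(w)
  cw <- cumsum(w) - w / 2
  if (cw[1] >= 0.5) return(x[1])
  if (cw[length(cw)] <= 0.5) return(x[length(x)])
  j <- which(cw >= 0.5)[1]
  x[j - 1] + (x[j] - x[j - 1]) * (0.5 - cw[j - 1]) / (cw[j] - cw[j - 1])
}

#' Drop instruments associated with a secondary exposure
#'
#' Removes instruments whose p-value in the secondary summary statistics is
#' below `p_max` (e.g. a T2D instrument set with BMI-associated SNPs
#' removed). Instruments missing from the secondary statistics are retained
#' with a warning.
#'
#' @param inst an `instrument_set`
#' @param secondary SummaryStats data.frame for the secondary exposure
#' @param p_max association threshold (default 0.05)
#' @return the filtered `instrument_set`
#' @export
exclude_exposure_correlated <- function(inst, secondary, p_max = 0.05) {
  m <- match(inst$snp, secondary$SNP)
  if (anyNA(m))
    warning(sum(is.na(m)), " instrument(s) missing from secondary stats; retained")
  drop <- !is.na(m) & secondary$P[m] < p_max
  out <- inst[!drop, , drop = FALSE]
  attr(out, "n_dropped") <- attr(inst, "n_dropped") %||% 0L
  class(out) <- c("instrument_set", "data.frame")
  out
}

#' Validate a genetic risk score against its own phenotype
#'
#' Builds the weighted GRS (sum of exposure betas times dosage) and
#' regresses the observed exposure phenotype on it — linear for continuous
#' phenotypes, logistic for binary.
#'
#' @param stats SummaryStats rows for the GRS SNPs (BETA used as weights)
#' @param geno a `genotype_matrix`
#' @param phenotype named per-subject exposure phenotype
#' @return one-row data.frame: estimate, se, p, n, family
#' @export
grs_validate <- function(stats, geno, phenotype) {
  ids <- intersect(sample_ids(geno), names(phenotype))
  assert_that(length(ids) >= 30, "fewer than 30 subjects with the phenotype")
  m <- match(stats$SNP, geno$snps$id)
  ok <- !is.na(m)
  assert_that(any(ok), "no GRS SNPs found in genotypes")
  D <- geno$dosage[ids, m[ok], drop = FALSE]
  if (anyNA(D)) {
    mu <- colMeans(D, na.rm = TRUE)
    idx <- which(is.na(D), arr.ind = TRUE)
    D[idx] <- mu[idx[, 2]]
  }
  grs <- drop(D %*% stats$BETA[ok])
  y <- as.numeric(phenotype[ids])
  binary <- all(y %in% c(0, 1))
  grs_z <- (grs - mean(grs)) / safe_sd(grs)
  fit <- if (binary) glm(y ~ grs_z, family = binomial()) else lm(y ~ grs_z)
  co <- summary(fit)$coefficients
  data.frame(estimate = co["grs_z", 1], se = co["grs_z", 2],
             p = co["grs_z", 4], n = length(y),
             family = if (binary) "logistic" else "linear",
             stringsAsFactors = FALSE)
}

#' All three MR estimators plus diagnostics
#'
#' Convenience wrapper returning IVW (with Cochran's Q), MR-Egger (with the
#' intercept test) and the weighted median for one instrument set.
#'
#' @param inst an `instrument_set`
#' @param seed bootstrap seed for the weighted median
#' @return data.frame with one row per method
#' @export
mr_all <- function(inst, seed = 1L) {
  ivw <- ivw_estimate(inst)
  eg <- egger_estimate(inst)
  wm <- weighted_median_estimate(inst, seed = seed)
  cols <- c("method", "estimate", "se", "p", "n_inst")
  out <- rbind(ivw[cols], eg[cols], wm[cols])
  out$het_p <- c(ivw$het_p, NA, NA)
  out$intercept <- c(NA, eg$intercept, NA)
  out$intercept_p <- c(NA, eg$intercept_p, NA)
  out
}
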