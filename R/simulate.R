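#' Simulation configuration for the synthetic cohort
#'
#' Bundles and validates every knob of the synthetic-cohort generator. The
#' defaults describe the emulated study population: a clinical echo cohort
#' with mean log LV mass around log(185) g, total log-mass variance ~0.11
#' (log-scale s.d. ~0.33, matching a coefficient of variation of roughly a
#' third), 53% male with a +0.3 log-scale male shift, a weak positive age
#' effect, and a sparse-plus-polygenic genetic architecture explaining
#' `pve_total` of the total log-mass variance.
#'
#' @param n_subjects number of subjects
#' @param n_snps number of SNPs
#' @param maf_range range of per-SNP minor allele frequencies, in (0, 0.5]
#' @param ld_block_size SNPs per correlated block (1 = independent SNPs)
#' @param ld_rho latent equicorrelation within a block, in \[0, 1)
#' @param n_causal_sparse number of large-effect causal SNPs
#' @param pve_total fraction of total log LV mass variance explained by the
#'   genetic value (sparse + polygenic), in \[0, 1)
#' @param pve_sparse_share share of the genetic variance carried by the
#'   sparse component, in \[0, 1\]
#' @param covariate_effects named list of covariate effects on log mass:
#'   `sex_male` (additive shift for males) and `age` (per year)
#' @param total_logmass_var target variance of simulated log LV mass
#' @param mean_logmass grand mean of log LV mass (log grams)
#' @param phecode_specs data.frame with columns `phecode`, `prevalence`,
#'   `loading`: baseline prevalence and liability loading on the
#'   standardized true genetic value
#' @param case_completeness probability an affected subject accrues >= 2
#'   code instances (others get exactly 1)
#' @param n_sites number of EHR sites
#' @param repeat_exam_fraction fraction of subjects given a later second exam
#' @param seed master integer seed
#' @return a validated list of class `sim_config`
#' @export
sim_config <- function(n_subjects = 3000,
                       n_snps = 3000,
                       maf_range = c(0.05, 0.5),
                       ld_block_size = 1,
                       ld_rho = 0,
                       n_causal_sparse = 10,
                       pve_total = 0.4,
                       pve_sparse_share = 0.5,
                       covariate_effects = list(sex_male = 0.3, age = 0.003),
                       total_logmass_var = 0.11,
                       mean_logmass = log(185),
                       phecode_specs = default_phecode_specs(),
                       case_completeness = 0.9,
                       n_sites = 3,
                       repeat_exam_fraction = 0.1,
                       seed = 1L) {
  cfg <- list(n_subjects = n_subjects, n_snps = n_snps, maf_range = maf_range,
              ld_block_size = ld_block_size, ld_rho = ld_rho,
              n_causal_sparse = n_causal_sparse, pve_total = pve_total,
              pve_sparse_share = pve_sparse_share,
              covariate_effects = covariate_effects,
              total_logmass_var = total_logmass_var,
              mean_logmass = mean_logmass,
              phecode_specs = phecode_specs,
              case_completeness = case_completeness, n_sites = n_sites,
              repeat_exam_fraction = repeat_exam_fraction,
              seed = as.integer(seed))
  assert_that(n_subjects > 0 && n_snps > 0, "n_subjects and n_snps must be positive")
  assert_that(maf_range[1] > 0 && maf_range[2] <= 0.5 && maf_range[1] <= maf_range[2],
              "maf_range must lie in (0, 0.5]")
  assert_that(ld_rho >= 0 && ld_rho < 1, "ld_rho must be in [0, 1)")
  assert_that(ld_block_size >= 1, "ld_block_size must be >= 1")
  assert_that(pve_total >= 0 && pve_total < 1, "pve_total must be in [0, 1)")
  assert_that(pve_sparse_share >= 0 && pve_sparse_share <= 1,
              "pve_sparse_share must be in [0, 1]")
  assert_that(n_causal_sparse <= n_snps, "n_causal_sparse cannot exceed n_snps")
  assert_that(all(phecode_specs$prevalence > 0 & phecode_specs$prevalence < 1),
              "phecode prevalences must be in (0, 1)")
  assert_that(case_completeness >= 0 && case_completeness <= 1,
              "case_completeness must be in [0, 1]")
  class(cfg) <- "sim_config"
  cfg
}

#' Default phecode specifications for the synthetic cohort
#'
#' A cardiomegaly-like code (416) and a sibling sub-code load on the genetic
#' value; a hypertension-like code loads weakly; the remainder are null.
#' A prostate-cancer-like code (185) exercises the sex-specific exclusion.
#'
#' @export
default_phecode_specs <- function() {
  data.frame(
    phecode    = c("416", "416.2", "401", "250.2", "272", "185"),
    prevalence = c(0.15, 0.05, 0.30, 0.10, 0.20, 0.05),
    loading    = c(0.40, 0.30, 0.15, 0.00, 0.00, 0.00),
    stringsAsFactors = FALSE
  )
}

#' Simulate an allele-dosage matrix
#'
#' Dosages are drawn as two latent-Gaussian allele indicators per subject:
#' each haplotype's latent variable is thresholded at the normal quantile of
#' the SNP's allele frequency, so marginally each dosage is binomial(2, maf).
#' Within a block of `ld_block_size` SNPs the latents share an
#' equicorrelation `ld_rho`, inducing LD of roughly that magnitude (the
#' thresholding attenuates it slightly, more so for rare alleles).
#'
#' @param config a `sim_config`
#' @return a `genotype_matrix` with MAFs drawn uniformly over `maf_range`
#' @export
simulate_genotypes <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  n <- config$n_subjects; p <- config$n_snps
  set.seed(stage_seed(config$seed, "genotypes"))
  maf <- runif(p, config$maf_range[1], config$maf_range[2])
  thr <- qnorm(maf)
  rho <- config$ld_rho; bs <- config$ld_block_size
  block <- rep(seq_len(ceiling(p / bs)), each = bs)[seq_len(p)]
  dos <- matrix(0, n, p)
  for (hap in 1:2) {
    eps <- matrix(rnorm(n * p), n, p)
    if (rho > 0 && bs > 1) {
      nb <- max(block)
      shared <- matrix(rnorm(n * nb), n, nb)
      z <- sqrt(rho) * shared[, block, drop = FALSE] + sqrt(1 - rho) * eps
    } else {
      z <- eps
    }
    dos <- dos + (z < matrix(thr, n, p, byrow = TRUE))
  }
  snps <- data.frame(id = sprintf("rs%06d", seq_len(p)),
                     chrom = block %% 22 + 1,
                     pos = seq_len(p) * 1000L,
                     allele1 = "A", allele2 = "G",
                     stringsAsFactors = FALSE)
  rownames(dos) <- sprintf("subj%05d", seq_len(n))
  genotype_matrix(dos, snps)
}

# standardize dosage columns; zero-variance columns become all-zero
standardize_dosage <- function(d) {
  d <- scale(d)
  d[, attr(d, "scaled:scale") == 0 | is.na(attr(d, "scaled:scale"))] <- 0
  d[is.na(d)] <- 0
  d
}

#' Simulate echo exams carrying a genetically structured log LV mass
#'
#' Draws log LV mass = intercept + covariates + sparse genetic + polygenic
#' genetic + noise, with the genetic components rescaled so that the realized
#' variance of the total genetic value is exactly `pve_total` times the
#' target total log-mass variance (and split `pve_sparse_share` /
#' `1 - pve_sparse_share` between sparse and polygenic parts). Echo
#' dimensions are then back-solved so that the Devereux formula reproduces
#' each subject's target mass exactly: LVEDd is drawn from N(4.8, 0.5) cm
#' (truncated to \[3, 7\] cm) and the summed wall thickness solved from the
#' cube relation, split equally between IVSd and PWd. Masses are constrained
#' to (50, 500) g by redrawing the subject's noise term.
#'
#' @param geno a `genotype_matrix` from [simulate_genotypes()]
#' @param config the same `sim_config`
#' @param extra_logmass optional per-subject additive shift on log mass
#'   (e.g. an exposure-mediated effect), recycled or named by subject
#' @return list with `exams` (one or two rows per subject: subject_id,
#'   exam_date, lvedd_cm, ivsd_cm, pwd_cm, age_at_exam, sex) and `truth`
#'   (per-SNP effects, per-subject genetic value, realized variance shares)
#' @export
simulate_echo_exams <- function(geno, config, extra_logmass = NULL) {
  stopifnot(inherits(geno, "genotype_matrix"), inherits(config, "sim_config"))
  n <- nrow(geno$dosage); p <- ncol(geno$dosage)
  set.seed(stage_seed(config$seed, "echo"))
  V <- config$total_logmass_var
  eff <- config$covariate_effects

  age <- pmin(pmax(rnorm(n, 64, 12), 18), 95)
  sex <- ifelse(runif(n) < 0.53, "male", "female")
  cov_term <- (eff$sex_male %||% 0) * (sex == "male") + (eff$age %||% 0) * (age - 64)

  X <- standardize_dosage(geno$dosage)
  b_sparse <- numeric(p)
  causal <- if (config$n_causal_sparse > 0)
    sample.int(p, config$n_causal_sparse) else integer(0)
  v_g <- config$pve_total * V
  v_sp <- v_g * config$pve_sparse_share
  v_po <- v_g - v_sp
  g_sparse <- numeric(n); g_poly <- numeric(n)
  if (length(causal) > 0 && v_sp > 0) {
    b_sparse[causal] <- rnorm(length(causal))
    g_sparse <- drop(X[, causal, drop = FALSE] %*% b_sparse[causal])
    sc <- sqrt(v_sp / var(g_sparse))
    g_sparse <- g_sparse * sc; b_sparse <- b_sparse * sc
  }
  b_poly <- numeric(p)
  if (v_po > 0) {
    b_poly <- rnorm(p) / sqrt(p)
    g_poly <- drop(X %*% b_poly)
    sc <- sqrt(v_po / var(g_poly))
    g_poly <- g_poly * sc; b_poly <- b_poly * sc
  }
  g <- g_sparse + g_poly

  v_cov <- var(cov_term)
  v_noise <- V - v_g - v_cov
  assert_that(v_noise > 0,
              "covariate effects and pve_total exceed the total variance budget")
  noise <- rnorm(n)
  noise <- noise * sqrt(v_noise / var(noise))

  shift <- if (is.null(extra_logmass)) 0 else rep_len(extra_logmass, n)
  y <- config$mean_logmass + cov_term + g + noise + shift

  # constrain masses to (50, 500) g by redrawing the noise term
  n_resampled <- 0L
  for (tries in 1:200) {
    bad <- which(exp(y) <= 50 | exp(y) >= 500)
    if (length(bad) == 0) break
    n_resampled <- n_resampled + length(bad)
    y[bad] <- config$mean_logmass + cov_term[bad] + g[bad] +
      rnorm(length(bad), 0, sqrt(v_noise)) + (if (length(shift) > 1) shift[bad] else shift)
  }
  mass <- exp(y)

  ids <- sample_ids(geno)
  exam_date <- as.Date("2005-01-01") + sample.int(3650, n, replace = TRUE)
  exams <- backsolve_echo_dims(mass)
  exams <- data.frame(subject_id = ids, exam_date = exam_date,
                      exams, age_at_exam = round(age, 1), sex = sex,
                      stringsAsFactors = FALSE)

  # later repeat exams with a perturbed mass, to exercise the first-exam rule
  n_rep <- round(config$repeat_exam_fraction * n)
  if (n_rep > 0) {
    ri <- sample.int(n, n_rep)
    mass2 <- pmin(pmax(mass[ri] * exp(rnorm(n_rep, 0, 0.08)), 51), 499)
    gap <- sample(180:2000, n_rep, replace = TRUE)
    rep_ex <- data.frame(subject_id = ids[ri], exam_date = exam_date[ri] + gap,
                         backsolve_echo_dims(mass2),
                         age_at_exam = round(age[ri] + gap / 365.25, 1),
                         sex = sex[ri], stringsAsFactors = FALSE)
    exams <- rbind(exams, rep_ex)
  }
  exams <- exams[order(exams$subject_id, exams$exam_date), ]
  rownames(exams) <- NULL

  truth <- list(
    snp_effects = data.frame(id = geno$snps$id, sparse = b_sparse,
                             polygenic = b_poly, stringsAsFactors = FALSE),
    causal_ids = geno$snps$id[causal],
    genetic_value = setNames(g, ids),
    log_mass = setNames(y, ids),
    pve_target = config$pve_total,
    pve_realized = var(g) / var(y),
    pve_adjusted = var(g) / (var(g) + var(noise)),
    scaling = "standardized",
    n_mass_resampled = n_resampled
  )
  list(exams = exams, truth = truth)
}

# invert the Devereux formula for a target mass: fix LVEDd, solve the summed
# wall thickness from the cube relation, split it equally between IVSd and PWd
backsolve_echo_dims <- function(mass) {
  assert_that(all(mass > 0.6), "target mass below the 0.6 g formula floor")
  m <- length(mass)
  lvedd <- pmin(pmax(rnorm(m, 4.8, 0.5), 3), 7)
  outer_cube <- (mass - 0.6) / (0.8 * 1.04) + lvedd^3
  wall <- outer_cube^(1 / 3) - lvedd
  data.frame(lvedd_cm = lvedd, ivsd_cm = wall / 2, pwd_cm = wall / 2)
}

#' Simulate phecode diagnosis tables under a liability-threshold model
#'
#' For each phecode, liability = loading x standardized genetic value +
#' sqrt(1 - loading^2) x normal noise (unit liability variance); subjects
#' whose liability exceeds the upper `prevalence` quantile are affected.
#' Affected subjects accrue >= 2 code instances with probability
#' `case_completeness` and exactly 1 otherwise; unaffected subjects get 0
#' rows. Site labels and birth decades are assigned per subject.
#'
#' @param genetic_value named per-subject true genetic value
#' @param subjects data.frame with subject_id, age, sex
#' @param config a `sim_config` (supplies phecode_specs, n_sites,
#'   case_completeness, seed)
#' @return list with `phecodes` (subject_id, phecode, n_instances, site,
#'   birth_decade) and `subjects` (subject_id, sex, site, birth_decade,
#'   max_age)
#' @export
simulate_phecodes <- function(genetic_value, subjects, config) {
  stopifnot(inherits(config, "sim_config"))
  specs <- config$phecode_specs
  set.seed(stage_seed(config$seed, "phecodes"))
  ids <- subjects$subject_id
  n <- length(ids)
  gz <- as.numeric(scale(genetic_value[ids]))
  site <- paste0("site", sample.int(config$n_sites, n, replace = TRUE))
  birth_year <- 2015 - subjects$age
  birth_decade <- floor(birth_year / 10) * 10
  max_age <- round(pmin(subjects$age + runif(n, 0, 8), 100), 1)

  rows <- list()
  for (k in seq_len(nrow(specs))) {
    lam <- specs$loading[k]
    liab <- lam * gz + sqrt(1 - lam^2) * rnorm(n)
    affected <- liab > qnorm(1 - specs$prevalence[k])
    n_aff <- sum(affected)
    if (n_aff == 0 || n_aff == n)
      warning(sprintf("phecode %s has sample prevalence %d/%d", specs$phecode[k], n_aff, n))
    if (n_aff > 0) {
      multi <- runif(n_aff) < config$case_completeness
      n_inst <- ifelse(multi, 2 + stats::rpois(n_aff, 2), 1)
      rows[[k]] <- data.frame(subject_id = ids[affected],
                              phecode = specs$phecode[k],
                              n_instances = n_inst,
                              stringsAsFactors = FALSE)
    }
  }
  ph <- do.call(rbind, rows)
  sub_tab <- data.frame(subject_id = ids, sex = subjects$sex, site = site,
                        birth_decade = birth_decade, max_age = max_age,
                        stringsAsFactors = FALSE)
  ph <- merge(ph, sub_tab[, c("subject_id", "site", "birth_decade")],
              by = "subject_id", sort = TRUE)
  list(phecodes = ph, subjects = sub_tab)
}

#' Simulate external GWAS summary statistics for an exposure
#'
#' Picks `n_instruments` instrument SNPs with true per-standardized-allele
#' exposure effects, realizes the exposure in the cohort, and emits
#' summary statistics consistent with an external GWAS of size `n_gwas`
#' (per-allele scale; SE = 1/sqrt(n 2f(1-f)) for unit exposure variance).
#' The exposure acts on log LV mass with causal effect `theta`; a fraction
#' `invalid_fraction` of instruments additionally carry direct (horizontally
#' pleiotropic) effects on the outcome drawn from
#' N(`direct_mean`, `direct_sd`), bypassing the exposure.
#'
#' @param geno a `genotype_matrix`
#' @param n_instruments number of true instrument SNPs
#' @param theta causal effect of the exposure on log LV mass (per exposure
#'   s.d.)
#' @param exposure_h2 variance of the exposure explained by its instruments
#' @param n_gwas external GWAS sample size
#' @param invalid_fraction fraction of instruments with direct effects
#' @param direct_mean,direct_sd distribution of direct effects (outcome
#'   scale, per standardized allele)
#' @param exposure_name label written into the stats table
#' @param seed integer seed
#' @return list: `stats` (SummaryStats data.frame: SNP, CHR, POS, A1, A2,
#'   EAF, BETA, SE, P, N), `exposure_value` per subject (unit variance),
#'   `outcome_shift` per subject (theta x exposure + direct effects),
#'   `truth` (instrument ids, true betas, direct effects, theta)
#' @export
simulate_external_summary_stats <- function(geno, n_instruments = 50,
                                            theta = 0.3, exposure_h2 = 0.3,
                                            n_gwas = 100000,
                                            invalid_fraction = 0,
                                            direct_mean = 0, direct_sd = 0,
                                            exposure_name = "exposure",
                                            seed = 1L) {
  stopifnot(inherits(geno, "genotype_matrix"))
  assert_that(invalid_fraction >= 0 && invalid_fraction <= 1,
              "invalid_fraction must be in [0, 1]")
  set.seed(stage_seed(seed, paste0("sumstats_", exposure_name)))
  n <- nrow(geno$dosage); p <- ncol(geno$dosage)
  assert_that(n_instruments <= p, "more instruments than SNPs")
  inst <- sort(sample.int(p, n_instruments))
  X <- standardize_dosage(geno$dosage[, inst, drop = FALSE])

  b_std <- rnorm(n_instruments)                      # standardized-allele scale
  gval <- drop(X %*% b_std)
  sc <- sqrt(exposure_h2 / var(gval))
  b_std <- b_std * sc
  gval <- gval * sc
  expo <- gval + rnorm(n, 0, sqrt(1 - exposure_h2))  # unit-variance exposure
  expo <- as.numeric(scale(expo))

  n_inv <- round(invalid_fraction * n_instruments)
  direct_std <- numeric(n_instruments)
  if (n_inv > 0)
    direct_std[seq_len(n_inv)] <- rnorm(n_inv, direct_mean, direct_sd)
  direct_shift <- drop(X %*% direct_std)
  outcome_shift <- theta * expo + direct_shift

  af <- snp_maf(geno, folded = FALSE)[inst]
  sd_g <- sqrt(2 * af * (1 - af))
  beta_true <- b_std / sd_g                          # per-allele scale
  se <- 1 / (sqrt(n_gwas) * sd_g)
  beta_hat <- rnorm(n_instruments, beta_true, se)
  pval <- 2 * pnorm(-abs(beta_hat / se))
  stats <- data.frame(SNP = geno$snps$id[inst], CHR = geno$snps$chrom[inst],
                      POS = geno$snps$pos[inst], A1 = geno$snps$allele1[inst],
                      A2 = geno$snps$allele2[inst], EAF = af, BETA = beta_hat,
                      SE = se, P = pval, N = n_gwas, stringsAsFactors = FALSE)
  list(stats = stats,
       exposure_value = setNames(expo, sample_ids(geno)),
       outcome_shift = setNames(outcome_shift, sample_ids(geno)),
       truth = list(instrument_ids = geno$snps$id[inst], beta_std = b_std,
                    beta_per_allele = beta_true, direct_std = direct_std,
                    theta = theta, exposure_name = exposure_name))
}

#' Simulate a two-sample MR summary dataset directly
#'
#' Generates harmonized per-SNP exposure and outcome effect estimates for
#' estimator studies: beta_X ~ N(b_j, SE_X^2), beta_Y ~ N(theta b_j + d_j,
#' SE_Y^2), where d_j is a direct (pleiotropic) effect for the invalid
#' instruments. This sidesteps cohort genotypes entirely and is the
#' workhorse for sampling-distribution studies of IVW, MR-Egger and the
#' weighted median.
#'
#' @param n_instruments number of instruments
#' @param theta true causal effect
#' @param beta_x_mean,beta_x_sd distribution of true exposure effects
#'   (absolute values are used so instruments start consistently oriented)
#' @param se_x,se_y instrument-level standard errors (recycled)
#' @param invalid_fraction fraction of instruments with direct effects
#' @param direct_mean,direct_sd direct-effect distribution
#' @param seed integer seed
#' @return data.frame: snp, beta_x, se_x, beta_y, se_y, true_direct
#' @export
simulate_mr_summary_data <- function(n_instruments = 50, theta = 0.3,
                                     beta_x_mean = 0.15, beta_x_sd = 0.05,
                                     se_x = 0.01, se_y = 0.02,
                                     invalid_fraction = 0,
                                     direct_mean = 0, direct_sd = 0,
                                     seed = 1L) {
  assert_that(invalid_fraction >= 0 && invalid_fraction <= 1,
              "invalid_fraction must be in [0, 1]")
  set.seed(stage_seed(seed, "mr_summary"))
  b <- abs(rnorm(n_instruments, beta_x_mean, beta_x_sd))
  d <- numeric(n_instruments)
  n_inv <- round(invalid_fraction * n_instruments)
  if (n_inv > 0) d[seq_len(n_inv)] <- rnorm(n_inv, direct_mean, direct_sd)
  se_x <- rep_len(se_x, n_instruments)
  se_y <- rep_len(se_y, n_instruments)
  data.frame(snp = sprintf("iv%03d", seq_len(n_instruments)),
             beta_x = rnorm(n_instruments, b, se_x), se_x = se_x,
             beta_y = rnorm(n_instruments, theta * b + d, se_y), se_y = se_y,
             true_direct = d, stringsAsFactors = FALSE)
}

#' Simulate a mediated-pleiotropy exposure study
#'
#' Emulates a secondary exposure (a T2D-like disease) whose instruments act
#' on log LV mass only through a primary exposure (a BMI-like trait): a set
#' of shared SNPs drives the primary exposure, which carries the entire
#' causal effect on the outcome; the secondary exposure's GWAS also tags
#' those shared SNPs (strongly, so they pass instrument selection) plus its
#' own specific SNPs that have no outcome effect. Removing SNPs associated
#' with the primary exposure from the secondary instrument set should
#' therefore abolish the secondary exposure's apparent causal effect.
#'
#' @param geno a `genotype_matrix`
#' @param n_shared SNPs shared by both exposures (the mediated pathway)
#' @param n_specific SNPs specific to the secondary exposure
#' @param theta_primary causal effect of the primary exposure on log LV mass
#'   (per exposure s.d.)
#' @param primary_h2 variance of the primary exposure explained by the
#'   shared SNPs
#' @param n_gwas external GWAS sample size for both exposures
#' @param seed integer seed
#' @return list: `primary_stats`, `secondary_stats` (SummaryStats covering
#'   the union of SNPs), `outcome_shift` per subject, `truth`
#' @export
simulate_mediated_exposure_study <- function(geno, n_shared = 30,
                                             n_specific = 30,
                                             theta_primary = 0.15,
                                             primary_h2 = 0.3,
                                             n_gwas = 100000, seed = 1L) {
  stopifnot(inherits(geno, "genotype_matrix"))
  set.seed(stage_seed(seed, "mediated"))
  p <- ncol(geno$dosage); n <- nrow(geno$dosage)
  pick <- sample.int(p, n_shared + n_specific)
  shared <- sort(pick[seq_len(n_shared)])
  specific <- sort(pick[n_shared + seq_len(n_specific)])

  Xs <- standardize_dosage(geno$dosage[, shared, drop = FALSE])
  b_shared <- rnorm(n_shared)
  gval <- drop(Xs %*% b_shared)
  b_shared <- b_shared * sqrt(primary_h2 / var(gval))
  gval <- drop(Xs %*% b_shared)
  primary <- as.numeric(scale(gval + rnorm(n, 0, sqrt(1 - primary_h2))))
  outcome_shift <- theta_primary * primary

  af <- snp_maf(geno, folded = FALSE)
  mk_stats <- function(idx, b_std) {
    sd_g <- sqrt(2 * af[idx] * (1 - af[idx]))
    se <- 1 / (sqrt(n_gwas) * sd_g)
    bh <- rnorm(length(idx), b_std / sd_g, se)
    data.frame(SNP = geno$snps$id[idx], CHR = geno$snps$chrom[idx],
               POS = geno$snps$pos[idx], A1 = geno$snps$allele1[idx],
               A2 = geno$snps$allele2[idx], EAF = af[idx], BETA = bh, SE = se,
               P = 2 * pnorm(-abs(bh / se)), N = n_gwas,
               stringsAsFactors = FALSE)
  }
  # secondary-exposure effects: strong on its own SNPs, and strong on the
  # shared SNPs (through its dependence on the primary exposure)
  b_specific <- rnorm(n_specific, 0, 0.08) + 0.08 * sign(rnorm(n_specific))
  primary_stats <- rbind(mk_stats(shared, b_shared),
                         mk_stats(specific, rep(0, n_specific)))
  secondary_stats <- rbind(mk_stats(shared, 0.8 * b_shared),
                           mk_stats(specific, b_specific))
  list(primary_stats = primary_stats, secondary_stats = secondary_stats,
       outcome_shift = setNames(outcome_shift, sample_ids(geno)),
       truth = list(shared_ids = geno$snps$id[shared],
                    specific_ids = geno$snps$id[specific],
                    theta_primary = theta_primary, b_shared = b_shared))
}

# ---- flat-file writers/readers ---------------------------------------------

#' Write / read the echo exam table
#' @param exams echo exam data.frame
#' @param path CSV path
#' @export
write_echo_csv <- function(exams, path) {
  write.csv(exams, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname write_echo_csv
#' @export
read_echo_csv <- function(path) {
  x <- read.csv(path, stringsAsFactors = FALSE)
  x$exam_date <- as.Date(x$exam_date)
  x
}

#' Write / read the phecode table
#' @param phecodes phecode data.frame
#' @param path CSV path
#' @export
write_phecode_csv <- function(phecodes, path) {
  write.csv(phecodes, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname write_phecode_csv
#' @export
read_phecode_csv <- function(path) {
  x <- read.csv(path, stringsAsFactors = FALSE)
  x$phecode <- as.character(x$phecode)
  x
}

#' Write / read GWAS summary statistics (SNP, CHR, POS, A1, A2, EAF, BETA,
#' SE, P, N)
#' @param stats summary statistics data.frame
#' @param path TSV path
#' @export
write_summary_stats <- function(stats, path) {
  write.table(stats, path, sep = "\t", row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname write_summary_stats
#' @export
read_summary_stats <- function(path) {
  read.delim(path, stringsAsFactors = FALSE,
             colClasses = c(SNP = "character", A1 = "character", A2 = "character"))
}
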