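test_that("generators are deterministic under the seed", {
  cfg <- sim_config(n_subjects = 120, n_snps = 60, seed = 9)
  g1 <- simulate_genotypes(cfg)
  g2 <- simulate_genotypes(cfg)
  expect_identical(g1$dosage, g2$dosage)
  e1 <- simulate_echo_exams(g1, cfg)
  e2 <- simulate_echo_exams(g2, cfg)
  expect_identical(e1$exams, e2$exams)
  subj <- data.frame(subject_id = sample_ids(g1),
                     age = rep(60, 120), sex = rep(c("male", "female"), 60))
  p1 <- simulate_phecodes(e1$truth$genetic_value, subj, cfg)
  p2 <- simulate_phecodes(e2$truth$genetic_value, subj, cfg)
  expect_identical(p1$phecodes, p2$phecodes)
  s1 <- simulate_external_summary_stats(g1, n_instruments = 10, seed = 3)
  s2 <- simulate_external_summary_stats(g1, n_instruments = 10, seed = 3)
  expect_identical(s1$stats, s2$stats)
})

test_that("dosages are binomial(2, maf) marginally", {
  cfg <- sim_config(n_subjects = 5000, n_snps = 50,
                    maf_range = c(0.3, 0.3), seed = 5)
  g <- simulate_genotypes(cfg)
  expect_true(all(g$dosage %in% 0:2))
  expect_lt(abs(mean(snp_maf(g)) - 0.3), 0.01)
  # genotype frequencies near HWE proportions
  expect_lt(abs(mean(g$dosage == 1) - 2 * 0.3 * 0.7), 0.02)
})

test_that("unit blocks give independent SNPs; LD blocks give correlated ones", {
  cfg <- sim_config(n_subjects = 800, n_snps = 40, ld_block_size = 1,
                    seed = 6)
  g <- simulate_genotypes(cfg)
  r2 <- cor(g$dosage)^2
  off <- r2[upper.tri(r2)]
  # under independence E[r^2] = 1/(n-1)
  expect_lt(abs(mean(off) - 1 / 799), 3e-3)

  cfgb <- sim_config(n_subjects = 800, n_snps = 40, ld_block_size = 5,
                     ld_rho = 0.8, seed = 6)
  gb <- simulate_genotypes(cfgb)
  r2b <- cor(gb$dosage)^2
  block <- rep(1:8, each = 5)
  same <- outer(block, block, "==") & upper.tri(r2b)
  diff <- !outer(block, block, "==") & upper.tri(r2b)
  expect_gt(mean(r2b[same]), 10 * mean(r2b[diff]))
  expect_gt(mean(r2b[same]), 0.2)
})

test_that("invalid simulation configs are rejected", {
  expect_error(sim_config(n_subjects = 0), "positive")
  expect_error(sim_config(pve_total = 1), "pve_total")
  expect_error(sim_config(n_causal_sparse = 10, n_snps = 5), "exceed")
  expect_error(sim_config(maf_range = c(0, 0.5)), "maf_range")
  specs <- default_phecode_specs(); specs$prevalence[1] <- 1
  expect_error(sim_config(phecode_specs = specs), "prevalence")
})

test_that("echo back-solve reproduces the target mass exactly", {
  cc <- small_cohort()
  ex <- cc$echo$exams
  first <- ex[!duplicated(ex$subject_id), ]
  m <- devereux_lv_mass(first$lvedd_cm, first$ivsd_cm, first$pwd_cm)
  target <- exp(cc$echo$truth$log_mass[first$subject_id])
  expect_lt(max(abs(m - target)), 1e-9)
  expect_true(all(m > 50 & m < 500))
  # wall thickness split equally between septum and posterior wall
  expect_equal(first$ivsd_cm, first$pwd_cm)
})

test_that("genetic variance hits the configured share of log-mass variance", {
  cfg <- sim_config(n_subjects = 2000, n_snps = 1000, pve_total = 0.4,
                    seed = 21)
  g <- simulate_genotypes(cfg)
  e <- simulate_echo_exams(g, cfg)
  expect_gt(e$truth$pve_realized, 0.35)
  expect_lt(e$truth$pve_realized, 0.45)
  # component bookkeeping: genetic + covariate + noise variances add up
  y <- e$truth$log_mass
  gv <- e$truth$genetic_value
  expect_lt(abs(var(y - gv) + var(gv) - var(y)) / var(y), 0.12)
})

test_that("a sex shift of +0.3 on the log scale shows up as a geometric-mean ratio", {
  cfg <- sim_config(n_subjects = 4000, n_snps = 200, seed = 8,
                    covariate_effects = list(sex_male = 0.3, age = 0))
  g <- simulate_genotypes(cfg)
  e <- simulate_echo_exams(g, cfg)
  first <- e$exams[!duplicated(e$exams$subject_id), ]
  lm_m <- mean(log(devereux_lv_mass(first$lvedd_cm, first$ivsd_cm,
                                    first$pwd_cm))[first$sex == "male"])
  lm_f <- mean(log(devereux_lv_mass(first$lvedd_cm, first$ivsd_cm,
                                    first$pwd_cm))[first$sex == "female"])
  expect_lt(abs((lm_m - lm_f) - 0.3), 0.05)
})

test_that("phecode prevalence and case-instance rules behave as configured", {
  specs <- data.frame(phecode = c("401", "250.2"), prevalence = c(0.1, 0.3),
                      loading = c(0, 0.5), stringsAsFactors = FALSE)
  cfg <- sim_config(n_subjects = 5000, n_snps = 50, phecode_specs = specs,
                    case_completeness = 1, seed = 13)
  g <- simulate_genotypes(cfg)
  gv <- setNames(rnorm(5000), sample_ids(g))
  subj <- data.frame(subject_id = sample_ids(g), age = rnorm(5000, 60, 10),
                     sex = sample(c("male", "female"), 5000, TRUE))
  ps <- simulate_phecodes(gv, subj, cfg)
  tab <- ps$phecodes
  n401 <- sum(tab$phecode == "401")
  # affected count within the binomial 99% interval around 500
  expect_lt(abs(n401 - 500), 2.58 * sqrt(5000 * 0.1 * 0.9) + 1)
  # case_completeness = 1: every affected subject has >= 2 instances
  expect_true(all(tab$n_instances >= 2))
  # zero loading: affected status independent of the genetic value
  aff <- subj$subject_id %in% tab$subject_id[tab$phecode == "401"]
  expect_gt(t.test(gv[aff], gv[!aff])$p.value, 0.001)
  # positive loading: cases carry higher genetic values
  aff2 <- subj$subject_id %in% tab$subject_id[tab$phecode == "250.2"]
  expect_lt(t.test(gv[aff2], gv[!aff2])$p.value, 1e-10)

  cfg2 <- sim_config(n_subjects = 2000, n_snps = 50, phecode_specs = specs,
                     case_completeness = 0.7, seed = 14)
  ps2 <- simulate_phecodes(gv[1:2000], subj[1:2000, ], cfg2)
  expect_gt(sum(ps2$phecodes$n_instances == 1), 0)
})

test_that("external summary statistics encode the causal structure", {
  cc <- small_cohort()
  # noise-free limit: enormous GWAS, ratios of true effects equal theta
  ss <- simulate_external_summary_stats(cc$geno, n_instruments = 20,
                                        theta = 0.3, n_gwas = 1e12, seed = 4)
  expect_equal(unname(sd(ss$exposure_value)), 1, tolerance = 1e-9)
  # outcome shift for valid instruments is theta * exposure exactly
  expect_equal(unname(ss$outcome_shift), unname(0.3 * ss$exposure_value),
               tolerance = 1e-12)
  # per-allele betas match the standardized truth through the allele s.d.
  af <- snp_maf(cc$geno, folded = FALSE)
  m <- match(ss$truth$instrument_ids, cc$geno$snps$id)
  expect_equal(ss$stats$BETA,
               unname(ss$truth$beta_std / sqrt(2 * af[m] * (1 - af[m]))),
               tolerance = 1e-4)
  expect_error(
    simulate_external_summary_stats(cc$geno, invalid_fraction = 1.2),
    "invalid_fraction")
  # directional pleiotropy lands only on the invalid fraction
  ss2 <- simulate_external_summary_stats(cc$geno, n_instruments = 20,
                                         theta = 0.2, invalid_fraction = 0.5,
                                         direct_mean = 0.05, direct_sd = 0,
                                         seed = 5)
  expect_equal(sum(ss2$truth$direct_std != 0), 10)
  expect_equal(unique(ss2$truth$direct_std[ss2$truth$direct_std != 0]), 0.05)
})
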