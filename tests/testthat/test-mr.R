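# instrument set built directly
inst_set <- function(beta_x, beta_y, se_y, se_x = 0.01) {
  out <- data.frame(snp = sprintf("iv%02d", seq_along(beta_x)),
                    beta_x = beta_x, se_x = se_x, p_x = 1e-9,
                    beta_y = beta_y, se_y = se_y, stringsAsFactors = FALSE)
  class(out) <- c("instrument_set", "data.frame")
  out
}

test_that("clumping keeps the best SNP of each correlated pair", {
  set.seed(111)
  n <- 400
  a <- rbinom(n, 2, 0.3)
  # B correlated with A (r2 ~ 0.2); C independent of both
  b <- ifelse(runif(n) < 0.55, a, rbinom(n, 2, 0.3))
  cc <- rbinom(n, 2, 0.4)
  g <- toy_geno(cbind(a, b, cc))
  r2ab <- cor(a, b)^2
  expect_gt(r2ab, 0.05); expect_lt(cor(a, cc)^2, 0.05)
  expect_lt(cor(b, cc)^2, 0.05)
  stats <- data.frame(SNP = c("s1", "s2", "s3"), A1 = "A", A2 = "G",
                      EAF = c(0.3, 0.3, 0.4), BETA = 0.1, SE = 0.01,
                      P = c(1e-8, 1e-7, 1e-6))
  expect_setequal(clump_select(stats, g, r2_max = 0.05, p_max = 5e-6),
                  c("s1", "s3"))
  # MAF and p filters are strict boundaries
  stats2 <- stats
  stats2$EAF[1] <- 0.04
  expect_false("s1" %in% clump_select(stats2, g))
  stats3 <- stats
  stats3$P[3] <- 1e-5
  expect_false("s3" %in% clump_select(stats3, g))
  stats4 <- stats; stats4$P[] <- 0.5
  expect_warning(out <- clump_select(stats4, g), "no candidate")
  expect_length(out, 0)
})

test_that("harmonization aligns effect alleles and drops ambiguous SNPs", {
  ex <- data.frame(SNP = c("r1", "r2", "r3", "r4"),
                   A1 = c("A", "A", "A", "A"), A2 = c("G", "G", "G", "T"),
                   EAF = c(0.3, 0.3, 0.3, 0.5),
                   BETA = c(0.2, 0.2, 0.2, 0.2), SE = 0.02,
                   P = 1e-8, N = 1e5)
  ou <- data.frame(SNP = c("r1", "r2", "r3", "r4"),
                   A1 = c("A", "G", "T", "A"), A2 = c("G", "A", "C", "T"),
                   EAF = c(0.3, 0.7, 0.3, 0.5),
                   BETA = c(0.1, 0.1, 0.1, 0.1), SE = 0.05, P = 0.01, N = 500)
  h <- harmonize(ex, ou)
  # r1 matches directly; r2 counts the other allele -> sign flip;
  # r3 matches on the opposite strand; r4 is palindromic with EAF 0.5 -> drop
  expect_setequal(h$snp, c("r1", "r2", "r3"))
  expect_equal(h$beta_y[h$snp == "r1"], 0.1)
  expect_equal(h$beta_y[h$snp == "r2"], -0.1)
  expect_equal(h$beta_y[h$snp == "r3"], 0.1)
  expect_equal(attr(h, "n_dropped"), 1L)
})

test_that("IVW reproduces hand-computed estimates", {
  # consensus ratio: both Wald ratios are 0.5
  r1 <- ivw_estimate(inst_set(c(0.2, 0.4), c(0.1, 0.2), c(0.05, 0.05)))
  expect_equal(r1$estimate, 0.5, tolerance = 1e-12)
  # closed form: theta = 0.3, SE = 1/sqrt(80)
  r2 <- ivw_estimate(inst_set(c(0.2, 0.4), c(0.1, 0.1), c(0.05, 0.05)))
  expect_equal(r2$estimate, 0.3, tolerance = 1e-12)
  expect_equal(r2$se, 1 / sqrt(80), tolerance = 1e-12)
  expect_equal(r2$se, 0.1118, tolerance = 1e-3)
  expect_error(ivw_estimate(inst_set(0.2, 0.1, 0.05)), "Wald")
})

test_that("Cochran's Q matches hand evaluation and is null-calibrated", {
  # identical ratios -> Q = 0, p = 1
  q0 <- cochran_q(inst_set(c(0.2, 0.4), c(0.06, 0.12), c(0.05, 0.05)))
  expect_equal(q0$Q, 0, tolerance = 1e-12)
  expect_equal(q0$p, 1)
  # ratios 0.1 and 0.5 with weights 100 each: Q = 100*0.04 + 100*0.04 = 8
  qh <- cochran_q(inst_set(c(1, 1), c(0.1, 0.5), c(0.1, 0.1)))
  expect_equal(qh$Q, 8, tolerance = 1e-12)
  expect_equal(qh$df, 1)
  # homogeneous simulation: E[Q/df] ~ 1
  set.seed(112)
  qr <- replicate(200, {
    d <- simulate_mr_summary_data(n_instruments = 20, theta = 0.3,
                                  se_x = 1e-6, se_y = 0.02,
                                  seed = sample.int(1e6, 1))
    q <- cochran_q(inst_set(d$beta_x, d$beta_y, d$se_y))
    q$Q / q$df
  })
  expect_lt(abs(mean(qr) - 1), 0.1)
})

test_that("Egger regression matches exact constructions and a WLS oracle", {
  bx <- c(0.1, 0.15, 0.2, 0.3, 0.4)
  by <- 0.05 + 0.3 * bx
  r <- egger_estimate(inst_set(bx, by, se_y = 0.02))
  expect_equal(r$estimate, 0.3, tolerance = 1e-10)
  expect_equal(r$intercept, 0.05, tolerance = 1e-10)
  set.seed(113)
  by2 <- 0.05 + 0.3 * bx + rnorm(5, 0, 0.01)
  sey <- runif(5, 0.01, 0.05)
  r2 <- egger_estimate(inst_set(bx, by2, sey))
  o <- oracle_wls(by2, bx, 1 / sey^2)
  expect_equal(r2$intercept, o[1], tolerance = 1e-10)
  expect_equal(r2$estimate, o[2], tolerance = 1e-10)
  expect_error(egger_estimate(inst_set(bx[1:2], by[1:2], 0.02)), ">= 3")
})

test_that("weighted median crosses half the weight with interpolation", {
  r <- weighted_median_estimate(inst_set(c(1, 1, 1), c(0.1, 0.3, 0.5), 0.1),
                                n_boot = 50)
  expect_equal(r$estimate, 0.3, tolerance = 1e-12)
  # identical ratios are invariant to the weights
  r2 <- weighted_median_estimate(
    inst_set(c(0.1, 0.2, 0.4), 0.25 * c(0.1, 0.2, 0.4),
             c(0.01, 0.05, 0.02)), n_boot = 50)
  expect_equal(r2$estimate, 0.25, tolerance = 1e-12)
  # zero exposure betas are dropped with a message
  expect_message(
    r3 <- weighted_median_estimate(
      inst_set(c(0, 1, 1, 1), c(1, 0.1, 0.3, 0.5), 0.1), n_boot = 50),
    "dropped")
  expect_equal(r3$estimate, 0.3, tolerance = 1e-12)
  # bootstrap SE is seeded
  a <- weighted_median_estimate(inst_set(c(1, 2, 3), c(.2, .5, .8), .1),
                                n_boot = 200, seed = 7)
  b <- weighted_median_estimate(inst_set(c(1, 2, 3), c(.2, .5, .8), .1),
                                n_boot = 200, seed = 7)
  expect_identical(a$se, b$se)
})

test_that("estimators agree with the true effect in the noise-free limit", {
  set.seed(114)
  d <- simulate_mr_summary_data(n_instruments = 12, theta = 0.3,
                                se_x = 1e-9, se_y = 1e-9, seed = 1)
  inst <- inst_set(d$beta_x, d$beta_y, d$se_y, se_x = d$se_x)
  expect_equal(ivw_estimate(inst)$estimate, 0.3, tolerance = 1e-6)
  expect_equal(egger_estimate(inst)$estimate, 0.3, tolerance = 1e-6)
  expect_equal(weighted_median_estimate(inst, n_boot = 10)$estimate, 0.3,
               tolerance = 1e-6)
})

test_that("estimates scale inversely with the exposure unit", {
  set.seed(115)
  d <- simulate_mr_summary_data(n_instruments = 20, theta = 0.25, seed = 2)
  inst <- inst_set(d$beta_x, d$beta_y, d$se_y)
  inst_c <- inst; inst_c$beta_x <- inst$beta_x * 4; inst_c$se_x <- inst$se_x * 4
  expect_equal(ivw_estimate(inst_c)$estimate, ivw_estimate(inst)$estimate / 4,
               tolerance = 1e-10)
  expect_equal(egger_estimate(inst_c)$estimate,
               egger_estimate(inst)$estimate / 4, tolerance = 1e-10)
  expect_equal(weighted_median_estimate(inst_c, n_boot = 10)$estimate,
               weighted_median_estimate(inst, n_boot = 10)$estimate / 4,
               tolerance = 1e-8)
})

test_that("estimation after harmonization is invariant to allele flips", {
  set.seed(116)
  m <- 15
  bx <- abs(rnorm(m, 0.15, 0.04))
  by <- 0.3 * bx + rnorm(m, 0, 0.01)
  ex <- data.frame(SNP = sprintf("f%02d", 1:m), A1 = "A", A2 = "G",
                   EAF = runif(m, 0.1, 0.45), BETA = bx, SE = 0.01,
                   P = 1e-9, N = 1e5)
  ou <- data.frame(SNP = ex$SNP, A1 = "A", A2 = "G", EAF = ex$EAF,
                   BETA = by, SE = 0.012, P = 0.01, N = 5e3)
  flip <- seq(1, m, by = 3)
  ou2 <- ou
  ou2$A1[flip] <- "G"; ou2$A2[flip] <- "A"
  ou2$BETA[flip] <- -ou2$BETA[flip]; ou2$EAF[flip] <- 1 - ou2$EAF[flip]
  h1 <- harmonize(ex, ou); h2 <- harmonize(ex, ou2)
  expect_equal(ivw_estimate(h1)$estimate, ivw_estimate(h2)$estimate,
               tolerance = 1e-12)
  expect_equal(egger_estimate(h1)$estimate, egger_estimate(h2)$estimate,
               tolerance = 1e-12)
  expect_equal(weighted_median_estimate(h1, n_boot = 20)$estimate,
               weighted_median_estimate(h2, n_boot = 20)$estimate,
               tolerance = 1e-10)
})

test_that("secondary-exposure exclusion removes associated instruments only", {
  inst <- inst_set(c(0.1, 0.2, 0.3), c(0.02, 0.04, 0.06), 0.02)
  sec <- data.frame(SNP = c("iv01", "iv02"), P = c(0.04, 0.5))
  expect_warning(out <- exclude_exposure_correlated(inst, sec), "missing")
  expect_setequal(out$snp, c("iv02", "iv03"))
  sec2 <- data.frame(SNP = inst$snp, P = 1)
  expect_equal(nrow(exclude_exposure_correlated(inst, sec2)), 3)
})

test_that("outcome associations match the scan and respect stratification", {
  cc <- small_cohort()
  snps <- cc$geno$snps$id[1:10]
  cov <- data.frame(age = cc$pheno$age, row.names = cc$pheno$subject_id)
  oa <- outcome_assoc(snps, cc$geno, cc$pheno, cov, sex_stratum = "male")
  ph_m <- cc$pheno[cc$pheno$sex == "male", ]
  gw <- run_gwas(subset_genotypes(cc$geno, i = ph_m$subject_id, j = snps),
                 ph_m, cov[ph_m$subject_id, , drop = FALSE])
  expect_equal(oa$BETA, gw$beta, tolerance = 1e-12)
  expect_equal(oa$SE, gw$se, tolerance = 1e-12)
  tiny <- cc$pheno[1:20, ]
  expect_error(outcome_assoc(snps, cc$geno, tiny, NULL, "female"),
               "fewer than 30")
})

test_that("GRS validation recovers a real exposure and nulls a permuted one", {
  set.seed(117)
  cfg <- sim_config(n_subjects = 2000, n_snps = 300, seed = 117)
  g <- simulate_genotypes(cfg)
  ss <- simulate_external_summary_stats(g, n_instruments = 30, theta = 0,
                                        exposure_h2 = 0.3, seed = 8)
  v <- grs_validate(ss$stats, g, ss$exposure_value)
  expect_lt(v$p, 0.05)
  expect_gt(v$estimate, 0)
  # linear case equals the least-squares oracle
  ids <- sample_ids(g)
  D <- g$dosage[, match(ss$stats$SNP, g$snps$id)]
  grs_z <- as.numeric(scale(D %*% ss$stats$BETA))
  o <- oracle_ols(unname(ss$exposure_value[ids]), cbind(grs_z))
  expect_equal(v$estimate, unname(o$coef[2]), tolerance = 1e-10)
  # weights reassigned to non-instrument SNPs destroy the association
  set.seed(9)
  ss_perm <- ss$stats
  ss_perm$SNP <- sample(setdiff(g$snps$id, ss$stats$SNP), nrow(ss_perm))
  vp <- grs_validate(ss_perm, g, ss$exposure_value)
  expect_gt(vp$p, 0.001)
})

test_that("binary phenotypes are validated with logistic regression", {
  set.seed(118)
  cfg <- sim_config(n_subjects = 800, n_snps = 100, seed = 118)
  g <- simulate_genotypes(cfg)
  ss <- simulate_external_summary_stats(g, n_instruments = 20, theta = 0,
                                        exposure_h2 = 0.4, seed = 10)
  yb <- setNames(as.numeric(ss$exposure_value > 0.5), names(ss$exposure_value))
  v <- grs_validate(ss$stats, g, yb)
  expect_equal(v$family, "logistic")
  expect_lt(v$p, 0.05)
})
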