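#!/usr/bin/env Rscript
# Stage 4 — BSLMM SNP weights on the training split.
#
# Residualizes log LV mass on age, sex and 5 PCs, fits the Bayesian sparse
# linear mixed model on the LD-reduced predictor set, and writes per-SNP
# weights w = alpha + beta * gamma plus the PVE chain summary. A second,
# permuted-phenotype fit provides the negative-control weight set.

suppressPackageStartupMessages(library(lvprs))

seed <- 2026L
geno <- read_plink("results/data/cohort")
pheno <- read_phenotype("results/phenotype.tsv")
kept <- readLines("results/unrelated_samples.txt")
pred <- readLines("results/predictor_snps.txt")
pcs <- read.csv("results/pcs.csv", row.names = 1)

pheno <- pheno[pheno$subject_id %in% kept, ]
set.seed(seed)
train <- sort(sample(pheno$subject_id, round(0.5 * nrow(pheno))))
writeLines(train, "results/train_subjects.txt")

ph_tr <- pheno[pheno$subject_id %in% train, ]
cov <- data.frame(age = ph_tr$age, sex = as.integer(ph_tr$sex == "male"),
                  pcs[ph_tr$subject_id, 1:5])
y <- residualize(setNames(ph_tr$log_lv_mass, ph_tr$subject_id), cov)

g_tr <- subset_genotypes(geno, i = ph_tr$subject_id, j = pred)
fit <- fit_bslmm(g_tr, y, n_steps = 20000, burn_in = 10000, seed = seed)
cat(sprintf("BSLMM: PVE estimate %.3f (median of %d retained steps)\n",
            pve_estimate(fit), length(fit$chains$pve)))
cat(sprintf("posterior mean inclusion count: %.1f SNPs\n",
            mean(fit$chains$n_included)))

write_weights(snp_weights(fit), "results/weights.tsv")
write.table(data.frame(step = seq_along(fit$chains$pve),
                       pve = fit$chains$pve,
                       n_included = fit$chains$n_included),
            "results/bslmm_chain.tsv", sep = "\t", row.names = FALSE,
            quote = FALSE)

wperm <- permuted_control_weights(g_tr, y, seed = seed,
                                  n_steps = 20000, burn_in = 10000)
write_weights(wperm, "results/weights_permuted.tsv")
cat("permuted-phenotype control weights written\n")
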