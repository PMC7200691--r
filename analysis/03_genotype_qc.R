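#!/usr/bin/env Rscript
# Stage 3 — genotype QC, relatedness, predictor SNP set, PCs, GWAS.
#
# Sample missingness < 2%, SNP missingness < 4%, MAF > 1%, exact HWE
# p >= 1e-6; LD-reduced predictor set at r2 < 0.9; pairwise pi-hat with
# greedy removal of one member of each related pair (> 0.05, or the
# estimator's noise ceiling on a small panel); principal components; then a
# single-SNP GWAS of log LV mass adjusted for age, sex and 10 PCs.

suppressPackageStartupMessages(library(lvprs))

geno <- read_plink("results/data/cohort")
pheno <- read_phenotype("results/phenotype.tsv")

qc <- qc_filter(geno)
cat(sprintf("QC: %d/%d samples, %d/%d SNPs retained\n",
            qc$report$n_samples_retained, qc$report$n_samples_in,
            qc$report$n_snps_retained, qc$report$n_snps_in))

pred <- ld_prune(qc$geno, r2_max = 0.9, window = 500, step = 50)
writeLines(pred, "results/predictor_snps.txt")
cat(sprintf("predictor set: %d LD-reduced SNPs (r2 < 0.9)\n", length(pred)))

rel <- pi_hat(subset_genotypes(qc$geno, j = pred))
ceiling_thr <- qnorm(1 - 0.01 / choose(nrow(rel), 2)) / sqrt(length(pred))
kept <- prune_related(rel, max(0.05, ceiling_thr))
writeLines(kept, "results/unrelated_samples.txt")
cat(sprintf("relatedness: %d samples kept (threshold %.3f)\n",
            length(kept), max(0.05, ceiling_thr)))

gq <- subset_genotypes(qc$geno, i = kept)
pcs <- principal_components(gq, 10)
write.csv(data.frame(subject_id = rownames(pcs), pcs),
          "results/pcs.csv", row.names = FALSE)

pheno <- pheno[pheno$subject_id %in% kept, ]
cov <- data.frame(age = pheno$age, sex = as.integer(pheno$sex == "male"),
                  pcs[pheno$subject_id, ], row.names = pheno$subject_id)
gwas <- run_gwas(gq, pheno, cov)
write_summary_stats(as_summary_stats(gwas), "results/gwas.tsv")
hits <- genomewide_hits(gwas, alpha = 5e-8)
cat(sprintf("GWAS: %d SNPs scanned, %d genome-wide hits at p < 5e-8\n",
            nrow(gwas), nrow(hits)))
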