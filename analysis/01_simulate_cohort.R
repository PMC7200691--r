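#!/usr/bin/env Rscript
# Stage 1 — synthetic cohort.
#
# Generates the genotype panel, external exposure summary statistics (the
# exposure acts causally on log LV mass), echo exams whose Devereux mass
# carries the configured sparse-plus-polygenic architecture, and phecode
# tables with liability loadings on the true genetic value. Everything is
# written as flat files under results/data/ so the later stages read only
# files, exactly as they would with real inputs.

suppressPackageStartupMessages(library(lvprs))

seed <- 2026L
dir.create("results/data", recursive = TRUE, showWarnings = FALSE)

cfg <- sim_config(n_subjects = 2000, n_snps = 1000, seed = seed)
geno <- simulate_genotypes(cfg)
expo <- simulate_external_summary_stats(geno, n_instruments = 50,
                                        theta = 0.08, n_gwas = 1e5,
                                        exposure_name = "bmi_like",
                                        seed = seed)
echo <- simulate_echo_exams(geno, cfg, extra_logmass = expo$outcome_shift)

write_plink(geno, "results/data/cohort")
write_echo_csv(echo$exams, "results/data/echo_exams.csv")
write_summary_stats(expo$stats, "results/data/exposure_stats.tsv")
saveRDS(list(config = cfg, truth = echo$truth, exposure = expo),
        "results/data/truth.rds")  # simulation ground truth, for comparison only

ph <- simulate_phecodes(echo$truth$genetic_value,
                        data.frame(subject_id = sample_ids(geno),
                                   age = echo$exams$age_at_exam[
                                     !duplicated(echo$exams$subject_id)],
                                   sex = echo$exams$sex[
                                     !duplicated(echo$exams$subject_id)]),
                        cfg)
write_phecode_csv(ph$phecodes, "results/data/phecodes.csv")
write.csv(ph$subjects, "results/data/subjects.csv", row.names = FALSE)

cat(sprintf("cohort: %d subjects x %d SNPs; %d echo exams; %d phecode rows\n",
            nrow(geno$dosage), ncol(geno$dosage), nrow(echo$exams),
            nrow(ph$phecodes)))
cat(sprintf("true PVE of log LV mass: %.3f (target %.2f)\n",
            echo$truth$pve_realized, cfg$pve_total))
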