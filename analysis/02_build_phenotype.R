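#!/usr/bin/env Rscript
# Stage 2 — LV-mass phenotype.
#
# Reads the raw echo exams, keeps each subject's first exam, computes the
# Devereux mass, applies the 50-500 g filter and log-transforms. No indexing
# to body size: adjusting by another heritable trait invites collider bias.

suppressPackageStartupMessages(library(lvprs))

exams <- read_echo_csv("results/data/echo_exams.csv")
pheno <- build_lv_mass_phenotype(exams, mass_min = 50, mass_max = 500)
write_phenotype(pheno, "results/phenotype.tsv")

cat(sprintf("%d exams -> %d phenotyped subjects\n", nrow(exams), nrow(pheno)))
cat(sprintf("mean LV mass: males %.0f g, females %.0f g\n",
            mean(pheno$lv_mass_g[pheno$sex == "male"]),
            mean(pheno$lv_mass_g[pheno$sex == "female"])))
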