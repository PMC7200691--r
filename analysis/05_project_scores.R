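#!/usr/bin/env Rscript
# Stage 5 — project the genetic predictor into the held-out cohort.
#
# Scores every subject outside the training split with the fitted weights
# (and with the permuted-control weights), standardizing within the scored
# cohort so downstream odds ratios are per 1 s.d. of predictor.

suppressPackageStartupMessages(library(lvprs))

geno <- read_plink("results/data/cohort")
kept <- readLines("results/unrelated_samples.txt")
train <- readLines("results/train_subjects.txt")
target <- setdiff(kept, train)
g_target <- subset_genotypes(geno, i = target)

for (tag in c("", "_permuted")) {
  w <- read_weights(sprintf("results/weights%s.tsv", tag))
  sc <- project_scores(w, g_target)
  write_scores(sc, sprintf("results/scores%s.tsv", tag))
  cat(sprintf("scores%s: %d subjects, raw s.d. %.4g, %d weight SNPs dropped\n",
              tag, nrow(sc), sd(sc$raw), attr(sc, "n_dropped")))
}
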