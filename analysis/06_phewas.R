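#!/usr/bin/env Rscript
# Stage 6 — phecode scan of the genetic predictor.
#
# Cases need >= 2 code instances; controls exclude carriers of the code or
# any closely related code and must fall inside the cases' birth-decade
# range; per-site logistic fits (score + sex + birth decade + 5 PCs) are
# pooled by fixed-effect inverse-variance meta-analysis and B-H adjusted.
# The cardiomegaly-like positive control additionally uses the sensitive
# one-instance case definition. The permuted-weight score provides the
# negative control.

suppressPackageStartupMessages(library(lvprs))

phecodes <- read_phecode_csv("results/data/phecodes.csv")
subjects <- read.csv("results/data/subjects.csv",
                     colClasses = c(subject_id = "character"))
train <- readLines("results/train_subjects.txt")
pcs <- read.csv("results/pcs.csv", row.names = 1)
map <- read_phecode_map()

subjects <- subjects[!(subjects$subject_id %in% train), ]
covs <- data.frame(sex = as.integer(subjects$sex == "male"),
                   birth_decade = subjects$birth_decade,
                   pcs[subjects$subject_id, 1:5],
                   row.names = subjects$subject_id)
ccsets <- assemble_case_control(phecodes, map, subjects, min_cases = 60,
                                case_min_instances = 2,
                                age_match = "birth_decade")

for (tag in c("", "_permuted")) {
  score <- read_scores(sprintf("results/scores%s.tsv", tag))
  scan <- phewas_scan(score, ccsets, covs, subjects)
  write.table(scan, sprintf("results/phewas%s.tsv", tag), sep = "\t",
              row.names = FALSE, quote = FALSE)
  cat(sprintf("scan%s: %d phecodes, %d at q < 0.05 (%s)\n", tag, nrow(scan),
              sum(scan$q < 0.05),
              paste(significant_at(scan), collapse = ", ")))
}

cardio <- cardiomegaly_control_set(phecodes, map, subjects)
strict <- ccsets[["416"]]
cat(sprintf("cardiomegaly: %d sensitive-definition vs %d strict cases\n",
            cardio$n_case, if (is.null(strict)) 0L else strict$n_case))
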