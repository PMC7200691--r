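#' Single-SNP association scan of log LV mass
#'
#' Per SNP, ordinary least squares of the phenotype on allele dosage plus
#' covariates under an additive model, computed by
#' Frisch-Waugh-Lovell projection (phenotype and dosages residualized on the
#' covariate block, then simple regression) — numerically identical to the
#' full-design fit, including standard errors, with the residual degrees of
#' freedom of the full model. Sporadically missing dosages are mean-imputed
#' per SNP. Monomorphic SNPs are flagged with beta = 0 and p = 1.
#'
#' @param geno a `genotype_matrix`
#' @param phenotype data.frame from [build_lv_mass_phenotype()] (needs
#'   `subject_id`, `log_lv_mass`) or a named numeric vector
#' @param covariates data.frame/matrix of per-subject covariates with
#'   rownames = subject ids (e.g. age, sex indicator, PCs); an intercept is
#'   always added. `NULL` fits dosage-only models.
#' @return data.frame: snp, chrom, pos, effect_allele, other_allele, eaf,
#'   beta, se, p, n, monomorphic
#' @export
run_gwas <- function(geno, phenotype, covariates = NULL) {
  stopifnot(inherits(geno, "genotype_matrix"))
  if (is.data.frame(phenotype)) {
    y <- setNames(phenotype$log_lv_mass, phenotype$subject_id)
  } else y <- phenotype
  ids <- intersect(sample_ids(geno), names(y))
  assert_that(length(ids) > 0, "no overlapping subjects between genotypes and phenotype")
  G <- geno$dosage[ids, , drop = FALSE]
  yv <- as.numeric(y[ids])
  n <- length(ids)

  C <- cbind(`(Intercept)` = rep(1, n))
  if (!is.null(covariates)) {
    cm <- as.matrix(as.data.frame(covariates)[ids, , drop = FALSE])
    storage.mode(cm) <- "double"
    C <- cbind(C, cm)
  }
  qrC <- qr(C)
  assert_that(qrC$rank == ncol(C), "covariate block is rank-deficient")
  yr <- qr.resid(qrC, yv)

  # mean-impute missing dosages per SNP
  if (anyNA(G)) {
    mu <- colMeans(G, na.rm = TRUE)
    idx <- which(is.na(G), arr.ind = TRUE)
    G[idx] <- mu[idx[, 2]]
  }
  mono <- apply(G, 2, function(g) var(g) == 0)
  Gr <- qr.resid(qrC, G)
  gss <- colSums(Gr^2)
  beta <- ifelse(gss > 0, colSums(Gr * yr) / gss, 0)
  df <- n - ncol(C) - 1
  assert_that(df > 0, "too few subjects for the covariate model")
  rss <- pmax(sum(yr^2) - beta^2 * gss, 0)
  se <- sqrt(rss / df / gss)
  tstat <- beta / se
  p <- 2 * pt(-abs(tstat), df)
  beta[mono] <- 0; se[mono] <- Inf; p[mono] <- 1
  data.frame(snp = geno$snps$id, chrom = geno$snps$chrom, pos = geno$snps$pos,
             effect_allele = geno$snps$allele1, other_allele = geno$snps$allele2,
             eaf = colMeans(G) / 2, beta = beta, se = se, p = p, n = n,
             monomorphic = mono, stringsAsFactors = FALSE, row.names = NULL)
}

#' Genome-wide significant hits
#'
#' @param results data.frame from [run_gwas()]
#' @param alpha significance threshold (default the conventional 5e-8)
#' @return the rows with p < alpha, sorted by ascending p
#' @export
genomewide_hits <- function(results, alpha = 5e-8) {
  hits <- results[results$p < alpha, , drop = FALSE]
  hits[order(hits$p), , drop = FALSE]
}

#' Convert a GWAS result table to the summary-statistics dialect
#'
#' Maps the scan output onto the (SNP, CHR, POS, A1, A2, EAF, BETA, SE, P,
#' N) layout consumed by the MR instrument-selection code and written by
#' [write_summary_stats()].
#'
#' @param results data.frame from [run_gwas()]
#' @export
as_summary_stats <- function(results) {
  data.frame(SNP = results$snp, CHR = results$chrom, POS = results$pos,
             A1 = results$effect_allele, A2 = results$other_allele,
             EAF = results$eaf, BETA = results$beta, SE = results$se,
             P = results$p, N = results$n, stringsAsFactors = FALSE)
}
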