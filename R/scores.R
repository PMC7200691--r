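#' Project SNP weights onto target-cohort genotypes
#'
#' Computes, per subject, the genetically predicted phenotype
#' \deqn{score_i = \sum_j w_j \times dosage_{ij}} with dosages coded as the
#' 0/1/2 count of the weight's effect allele. Effect alleles are harmonized
#' first: where the genotype file counts the other allele, the dosage is
#' flipped (2 - dosage). SNPs absent from the target genotypes, or with
#' irreconcilable alleles, are dropped with a count in the attributes.
#' Missing dosages are imputed as 2 x MAF of the target cohort. The
#' standardized score is (raw - mean)/s.d. within the projected cohort.
#'
#' @param weights a `weight_set` (per-allele scaling expected; standardized
#'   weights are divided by the target-cohort dosage s.d. instead)
#' @param geno a `genotype_matrix` of the target cohort
#' @return data.frame of class `score_vector`: subject_id, raw,
#'   standardized; dropped-SNP counts in `attr(, "n_dropped")`
#' @export
project_scores <- function(weights, geno) {
  stopifnot(inherits(geno, "genotype_matrix"))
  m <- match(weights$snp, geno$snps$id)
  present <- !is.na(m)
  if (mean(present) < 0.5)
    stop(sprintf("only %.0f%% of weight SNPs found in target genotypes; %s",
                 100 * mean(present),
                 "check SNP id and allele conventions"), call. = FALSE)
  w <- weights[present, , drop = FALSE]
  gi <- m[present]
  D <- geno$dosage[, gi, drop = FALSE]

  same <- w$effect_allele == geno$snps$allele1[gi] &
    w$other_allele == geno$snps$allele2[gi]
  flipped <- w$effect_allele == geno$snps$allele2[gi] &
    w$other_allele == geno$snps$allele1[gi]
  bad <- !(same | flipped)
  if (any(bad)) {
    D <- D[, !bad, drop = FALSE]; w <- w[!bad, , drop = FALSE]
    same <- same[!bad]; flipped <- flipped[!bad]
  }
  if (any(flipped))
    D[, flipped] <- 2 - D[, flipped, drop = FALSE]
  if (anyNA(D)) {
    af2 <- colMeans(D, na.rm = TRUE)
    idx <- which(is.na(D), arr.ind = TRUE)
    D[idx] <- af2[idx[, 2]]
  }
  wv <- w$w
  if (identical(attr(weights, "scaling"), "standardized")) {
    sdv <- apply(D, 2, sd)
    wv <- ifelse(sdv > 0, wv / sdv, 0)
  }
  raw <- drop(D %*% wv)
  s <- sd(raw)
  out <- data.frame(subject_id = sample_ids(geno), raw = raw,
                    standardized = if (s > 0) (raw - mean(raw)) / s
                                   else rep(0, length(raw)),
                    stringsAsFactors = FALSE)
  attr(out, "n_dropped") <- sum(!present) + sum(bad)
  class(out) <- c("score_vector", "data.frame")
  out
}

#' Negative-control weights from a permuted phenotype
#'
#' Permutes the phenotype across subjects (seeded) and reruns the full
#' weight-fitting procedure. A score built from these weights is the
#' pipeline's negative control: it should show no association with any
#' genuinely score-driven phenotype.
#'
#' @param geno a `genotype_matrix` (predictor SNP set)
#' @param y adjusted phenotype as passed to [fit_bslmm()]
#' @param seed integer seed (controls both the permutation and the sampler)
#' @param ... further arguments to [fit_bslmm()]
#' @return a `weight_set` (per-allele scale)
#' @export
permuted_control_weights <- function(geno, y, seed = 1L, ...) {
  set.seed(stage_seed(seed, "permute"))
  perm <- sample(length(y))
  yp <- as.numeric(y)[perm]
  if (!is.null(names(y))) names(yp) <- names(y)
  fit <- fit_bslmm(geno, yp, seed = stage_seed(seed, "permute_fit"), ...)
  snp_weights(fit)
}

#' Write / read a score TSV
#' @param scores a `score_vector`
#' @param path TSV path
#' @export
write_scores <- function(scores, path) {
  write.table(as.data.frame(scores), path, sep = "\t", row.names = FALSE,
              quote = FALSE)
  invisible(path)
}

#' @rdname write_scores
#' @export
read_scores <- function(path) {
  out <- read.delim(path, stringsAsFactors = FALSE)
  class(out) <- c("score_vector", "data.frame")
  out
}
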