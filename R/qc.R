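#' Exact test of Hardy-Weinberg equilibrium
#'
#' Exact conditional test: given the observed allele counts, the p-value is
#' the sum of the probabilities of all heterozygote counts whose conditional
#' probability does not exceed that of the observed count. Robust at low
#' counts where the chi-square approximation fails, and unambiguous to
#' enumerate, which makes it its own oracle.
#'
#' @param n_AA,n_Aa,n_aa genotype counts (non-negative, total > 0)
#' @return two-sided exact p-value; 1 for a monomorphic site
#' @export
hwe_test <- function(n_AA, n_Aa, n_aa) {
  assert_that(n_AA >= 0 && n_Aa >= 0 && n_aa >= 0, "counts must be non-negative")
  n <- n_AA + n_Aa + n_aa
  assert_that(n > 0, "total genotype count must be positive")
  nA <- 2 * n_AA + n_Aa
  na <- 2 * n_aa + n_Aa
  if (nA == 0 || na == 0) return(1)
  n_minor <- min(nA, na)
  # feasible heterozygote counts share the parity of the minor allele count
  hs <- seq(n_minor %% 2, n_minor, by = 2)
  logp <- hs * log(2) - lfactorial((nA - hs) / 2) - lfactorial(hs) -
    lfactorial((na - hs) / 2)
  pr <- exp(logp - max(logp))
  pr <- pr / sum(pr)
  p_obs <- pr[match(n_Aa, hs)]
  min(1, sum(pr[pr <= p_obs * (1 + 1e-12)]))
}

# per-SNP HWE p-values from hard-called dosages (NAs ignored)
hwe_pvalues <- function(dosage) {
  g <- round(dosage)
  apply(g, 2, function(col) {
    col <- col[!is.na(col)]
    if (length(col) == 0) return(1)
    hwe_test(sum(col == 2), sum(col == 1), sum(col == 0))
  })
}

#' Variant- and sample-level genotype quality control
#'
#' Removes samples with missingness at or above `sample_miss_max`, then SNPs
#' with missingness at or above `snp_miss_max`, MAF at or below `maf_min`,
#' or an exact Hardy-Weinberg p-value below `hwe_p_min` — in that order
#' (SNP statistics are recomputed on the retained samples).
#'
#' @param geno a `genotype_matrix`
#' @param sample_miss_max retained samples have missingness strictly below
#'   this (default 2%)
#' @param snp_miss_max retained SNPs have missingness strictly below this
#'   (default 4%)
#' @param maf_min retained SNPs have MAF strictly above this (default 1%)
#' @param hwe_p_min retained SNPs have exact HWE p at or above this
#'   (default 1e-6)
#' @return list: `geno` (filtered `genotype_matrix`), `report` (thresholds
#'   and per-filter removal counts; removed + retained = input)
#' @export
qc_filter <- function(geno, sample_miss_max = 0.02, snp_miss_max = 0.04,
                      maf_min = 0.01, hwe_p_min = 1e-6) {
  stopifnot(inherits(geno, "genotype_matrix"))
  n0 <- nrow(geno$dosage); p0 <- ncol(geno$dosage)
  smiss <- rowMeans(is.na(geno$dosage))
  keep_s <- smiss < sample_miss_max
  if (!any(keep_s)) {
    warning("all samples removed by the missingness filter")
    return(list(geno = subset_genotypes(geno, i = keep_s),
                report = list(n_samples_in = n0, n_snps_in = p0,
                              n_samples_removed_miss = n0, n_snps_removed = p0)))
  }
  g1 <- subset_genotypes(geno, i = keep_s)
  vmiss <- colMeans(is.na(g1$dosage))
  maf <- snp_maf(g1)
  fail_miss <- vmiss >= snp_miss_max
  fail_maf <- maf <= maf_min
  hwe_p <- rep(1, ncol(g1$dosage))
  todo <- !(fail_miss | fail_maf)
  hwe_p[todo] <- hwe_pvalues(g1$dosage[, todo, drop = FALSE])
  fail_hwe <- hwe_p < hwe_p_min
  keep_v <- !(fail_miss | fail_maf | fail_hwe)
  report <- list(
    thresholds = list(sample_miss_max = sample_miss_max,
                      snp_miss_max = snp_miss_max, maf_min = maf_min,
                      hwe_p_min = hwe_p_min),
    n_samples_in = n0, n_snps_in = p0,
    n_samples_removed_miss = sum(!keep_s),
    n_snps_removed_miss = sum(fail_miss),
    n_snps_removed_maf = sum(fail_maf & !fail_miss),
    n_snps_removed_hwe = sum(fail_hwe & !fail_miss & !fail_maf),
    n_samples_retained = sum(keep_s),
    n_snps_retained = sum(keep_v))
  list(geno = subset_genotypes(g1, j = keep_v), report = report)
}

#' Pairwise relatedness (pi-hat) by method of moments
#'
#' Estimates the expected genome-wide allele-sharing coefficient for every
#' sample pair from the standardized-genotype cross-product given sample
#' allele frequencies (the genetic-relationship-matrix estimator). Under
#' Hardy-Weinberg equilibrium its expectation equals the kinship-based
#' pi-hat: ~1 for duplicates/MZ twins, ~0.5 for first-degree relatives,
#' ~0 for unrelated pairs. Missing dosages are mean-imputed.
#'
#' @param geno a `genotype_matrix` (ideally an LD-reduced SNP subset)
#' @return symmetric n x n matrix with sample ids as dimnames
#' @export
pi_hat <- function(geno) {
  stopifnot(inherits(geno, "genotype_matrix"))
  d <- geno$dosage
  if (nrow(d) < 2) return(matrix(numeric(0), 0, 0))
  af <- colMeans(d, na.rm = TRUE) / 2
  poly <- af > 0 & af < 1
  d <- d[, poly, drop = FALSE]; af <- af[poly]
  Z <- sweep(d, 2, 2 * af, "-")
  Z <- sweep(Z, 2, sqrt(2 * af * (1 - af)), "/")
  Z[is.na(Z)] <- 0
  K <- tcrossprod(Z) / ncol(Z)
  dimnames(K) <- list(rownames(d), rownames(d))
  K
}

#' Prune related samples
#'
#' Builds the graph of pairs with relatedness above `threshold` and removes,
#' repeatedly, the sample in the most above-threshold pairs (ties broken by
#' sample id) until no pair remains — the deterministic "one of each pair"
#' rule that minimizes removals.
#'
#' @param relatedness symmetric matrix from [pi_hat()]
#' @param threshold pi-hat above which a pair is considered related
#'   (default 0.05)
#' @return character vector of retained sample ids
#' @export
prune_related <- function(relatedness, threshold = 0.05) {
  ids <- rownames(relatedness)
  if (is.null(ids)) ids <- as.character(seq_len(nrow(relatedness)))
  adj <- relatedness > threshold
  diag(adj) <- FALSE
  keep <- rep(TRUE, length(ids))
  repeat {
    deg <- rowSums(adj[keep, keep, drop = FALSE])
    if (all(deg == 0)) break
    pool <- ids[keep]
    worst <- pool[order(-deg, pool)][1]
    keep[ids == worst] <- FALSE
  }
  ids[keep]
}

#' Greedy windowed LD pruning
#'
#' Slides a window of `window` SNPs in steps of `step`; within each window a
#' SNP is dropped if its squared dosage correlation with any lower-index
#' retained SNP exceeds `r2_max`. The output therefore contains no retained
#' pair above `r2_max` within any window, which the function verifies before
#' returning.
#'
#' @param geno a `genotype_matrix`
#' @param r2_max maximum allowed pairwise r-squared
#' @param window window size in SNPs
#' @param step window step in SNPs
#' @return character vector of retained SNP ids
#' @export
ld_prune <- function(geno, r2_max = 0.9, window = 500, step = 50) {
  stopifnot(inherits(geno, "genotype_matrix"))
  assert_that(window >= 2, "window must span at least 2 SNPs")
  assert_that(step >= 1 && step <= window, "step must be in [1, window]")
  d <- geno$dosage
  p <- ncol(d)
  keep <- rep(TRUE, p)
  starts <- seq(1, max(1, p - 1), by = step)
  for (s in starts) {
    w <- s:min(s + window - 1, p)
    wk <- w[keep[w]]
    if (length(wk) < 2) next
    r2 <- suppressWarnings(cor(d[, wk, drop = FALSE],
                               use = "pairwise.complete.obs"))^2
    r2[is.na(r2)] <- 0
    for (jj in 2:length(wk)) {
      if (!keep[wk[jj]]) next
      prev <- wk[seq_len(jj - 1)]
      prev <- prev[keep[prev]]
      if (length(prev) > 0 &&
          any(r2[match(prev, wk), jj] > r2_max))
        keep[wk[jj]] <- FALSE
    }
    if (s + window - 1 >= p) break
  }
  # postcondition self-check within each window
  ret <- which(keep)
  for (s in starts) {
    w <- s:min(s + window - 1, p)
    wk <- intersect(ret, w)
    if (length(wk) < 2) next
    r2 <- suppressWarnings(cor(d[, wk, drop = FALSE],
                               use = "pairwise.complete.obs"))^2
    diag(r2) <- 0
    assert_that(all(r2 <= r2_max | is.na(r2)),
                "internal error: pruning postcondition violated")
    if (s + window - 1 >= p) break
  }
  geno$snps$id[keep]
}

#' Principal components of the genotype matrix
#'
#' Computes orthonormal left singular vectors of the per-SNP centered and
#' variance-scaled dosage matrix (monomorphic SNPs contribute zeros; missing
#' dosages are mean-imputed, i.e. zero after standardization). The sign of
#' each component is fixed so that its largest-magnitude SNP loading is
#' positive.
#'
#' @param geno a `genotype_matrix` (QC'd)
#' @param k number of components
#' @return n x k matrix of PC coordinates (orthonormal columns), sample ids
#'   as rownames
#' @export
principal_components <- function(geno, k) {
  stopifnot(inherits(geno, "genotype_matrix"))
  n <- nrow(geno$dosage); p <- ncol(geno$dosage)
  assert_that(k <= min(n, p), "k cannot exceed min(n_samples, n_snps)")
  if (k == 0)
    return(matrix(numeric(0), n, 0, dimnames = list(sample_ids(geno), NULL)))
  Z <- standardize_dosage(geno$dosage)
  sv <- svd(Z, nu = k, nv = k)
  U <- sv$u
  for (j in seq_len(k)) {
    ld <- sv$v[, j]
    if (ld[which.max(abs(ld))] < 0) U[, j] <- -U[, j]
  }
  rownames(U) <- sample_ids(geno)
  colnames(U) <- paste0("PC", seq_len(k))
  U
}
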