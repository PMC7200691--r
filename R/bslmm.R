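#' Residualize a phenotype on covariates
#'
#' Least-squares residuals of the phenotype on an intercept plus the given
#' covariates, re-centered to mean zero. The BSLMM is fitted to this
#' adjusted phenotype (age at the echo exam, sex and 5 PCs by default in the
#' pipeline).
#'
#' @param y numeric phenotype (named by subject id, or aligned with rows of
#'   `covariates`)
#' @param covariates data.frame or matrix of covariates; an intercept is
#'   always added
#' @return numeric residual vector (names preserved)
#' @export
residualize <- function(y, covariates) {
  C <- cbind(`(Intercept)` = rep(1, length(y)))
  if (!is.null(covariates) && NCOL(covariates) > 0) {
    cm <- as.matrix(as.data.frame(covariates))
    storage.mode(cm) <- "double"
    assert_that(nrow(cm) == length(y), "covariates must align with the phenotype")
    C <- cbind(C, cm)
  }
  qrC <- qr(C)
  if (qrC$rank < ncol(C)) {
    dropped <- colnames(C)[qrC$pivot[(qrC$rank + 1):ncol(C)]]
    stop("collinear covariate columns: ", paste(dropped, collapse = ", "),
         call. = FALSE)
  }
  r <- qr.resid(qrC, as.numeric(y))
  r <- r - mean(r)
  names(r) <- names(y)
  r
}

#' Fit a Bayesian sparse linear mixed model by MCMC
#'
#' Models the adjusted phenotype as y = Xb + e on column-standardized
#' genotypes, where each SNP effect comes from a two-component normal
#' mixture: a dense "polygenic" component shared by all SNPs (equivalent to
#' a random effect with genomic-relatedness covariance) and, with posterior
#' probability gamma, an additional large sparse component. A
#' systematic-scan Gibbs sampler with rank-one residual updates draws the
#' effects; inclusion probability, component variances and the noise
#' variance get conjugate updates, with the prior on the inclusion
#' probability log-uniform over the expected included count. One sampling
#' step is one full sweep over all SNPs.
#'
#' Per retained step the sampler records PVE = var(Xb)/var(y) on the
#' observed sample. Per SNP it accumulates the posterior decomposition into
#' alpha (small polygenic part), beta (large sparse part, averaged over the
#' steps in which the SNP was in the large-effect group) and gamma (the
#' inclusion frequency), so that w = alpha + beta * gamma equals the
#' posterior-mean total effect.
#'
#' @param geno a `genotype_matrix` restricted to the predictor SNP set
#' @param y adjusted (residualized) phenotype, named by subject id or
#'   aligned with `geno` rows
#' @param n_steps total sampling steps (default 20000; the original
#'   full-scale analysis convention is 100000)
#' @param burn_in discarded initial steps (default half of `n_steps`)
#' @param seed integer seed
#' @param slab if `FALSE` the sparse component is disabled and the model
#'   reduces to the dense polygenic (ridge / random-effect) model
#' @return object of class `bslmm_posterior`: `snp` data.frame (id,
#'   effect_allele, alpha, beta, gamma, dosage_sd), `chains` (pve,
#'   n_included, component variances, pi), and sampler metadata
#' @export
fit_bslmm <- function(geno, y, n_steps = 20000, burn_in = n_steps / 2,
                      seed = 1L, slab = TRUE) {
  stopifnot(inherits(geno, "genotype_matrix"))
  assert_that(all(is.finite(y)), "phenotype must be finite")
  assert_that(n_steps > burn_in && burn_in >= 0,
              "need n_steps > burn_in >= 0")
  if (!is.null(names(y))) {
    ids <- intersect(sample_ids(geno), names(y))
    assert_that(length(ids) > 1, "no overlapping subjects")
    G <- geno$dosage[ids, , drop = FALSE]
    yv <- as.numeric(y[ids])
  } else {
    G <- geno$dosage
    yv <- as.numeric(y)
    assert_that(length(yv) == nrow(G), "phenotype length must match genotypes")
  }
  if (anyNA(G)) {
    mu <- colMeans(G, na.rm = TRUE)
    idx <- which(is.na(G), arr.ind = TRUE)
    G[idx] <- mu[idx[, 2]]
  }
  dosage_sd <- apply(G, 2, sd)
  X <- standardize_dosage(G)
  yv <- yv - mean(yv)
  p <- ncol(X)
  vy <- var(yv)

  set.seed(as.integer(seed))
  fit <- .bslmm_gibbs(X, yv, as.integer(n_steps), as.integer(burn_in),
                      isTRUE(slab), pi_init = min(0.5, 10 / p),
                      s1_init = 0.1 * vy / p, s2_init = 0.1 * vy,
                      se_init = vy)
  structure(list(
    snp = data.frame(id = geno$snps$id, effect_allele = geno$snps$allele1,
                     other_allele = geno$snps$allele2,
                     alpha = fit$alpha, beta = fit$beta, gamma = fit$gamma,
                     dosage_sd = dosage_sd, stringsAsFactors = FALSE,
                     row.names = NULL),
    chains = list(pve = fit$pve, n_included = fit$n_included,
                  spike_var = fit$s1, slab_var = fit$s2,
                  noise_var = fit$se, pi = fit$pi),
    n_steps = n_steps, burn_in = burn_in, seed = seed, slab = slab,
    n_subjects = nrow(X), scaling = "standardized"),
    class = "bslmm_posterior")
}

#' @export
print.bslmm_posterior <- function(x, ...) {
  cat(sprintf(paste0("bslmm_posterior: %d SNPs, %d subjects, %d steps ",
                     "(%d burn-in)\n  PVE estimate: %.3f\n"),
              nrow(x$snp), x$n_subjects, x$n_steps, x$burn_in,
              pve_estimate(x)))
  invisible(x)
}

#' Proportion of variance explained by the modeled SNPs
#'
#' The median of the per-step PVE values over the retained (post-burn-in)
#' sampling steps. For an even number of steps the median is the mean of the
#' two central order statistics.
#'
#' @param posterior a `bslmm_posterior`
#' @return PVE estimate as a fraction
#' @export
pve_estimate <- function(posterior) {
  chain <- if (inherits(posterior, "bslmm_posterior"))
    posterior$chains$pve else as.numeric(posterior)
  assert_that(length(chain) > 0, "empty PVE chain")
  median(chain)
}

#' Per-SNP predictive weights w = alpha + beta * gamma
#'
#' Combines the posterior summaries into one weight per SNP. Weights are
#' natively on the standardized-genotype scale (effect per 1 s.d. of
#' dosage); `scale = "per_allele"` divides by the training-sample dosage
#' s.d. so the weight applies directly to 0/1/2 allele counts.
#'
#' @param posterior a `bslmm_posterior`
#' @param scale `"per_allele"` (default; matches projection onto raw allele
#'   counts) or `"standardized"`
#' @return data.frame of class `weight_set`: snp, effect_allele,
#'   other_allele, w, alpha, beta, gamma, with the scaling convention in
#'   `attr(, "scaling")`
#' @export
snp_weights <- function(posterior, scale = c("per_allele", "standardized")) {
  scale <- match.arg(scale)
  s <- posterior$snp
  w <- s$alpha + s$beta * s$gamma
  if (scale == "per_allele") {
    sdv <- ifelse(s$dosage_sd > 0, s$dosage_sd, Inf)
    w <- w / sdv
  }
  assert_that(all(is.finite(w) | s$dosage_sd == 0), "non-finite weights")
  out <- data.frame(snp = s$id, effect_allele = s$effect_allele,
                    other_allele = s$other_allele, w = w,
                    alpha = s$alpha, beta = s$beta, gamma = s$gamma,
                    stringsAsFactors = FALSE)
  attr(out, "scaling") <- scale
  class(out) <- c("weight_set", "data.frame")
  out
}

#' Write / read a weight set TSV
#' @param weights a `weight_set`
#' @param path TSV path
#' @export
write_weights <- function(weights, path) {
  df <- as.data.frame(weights)
  df$scaling <- attr(weights, "scaling") %||% "per_allele"
  write.table(df, path, sep = "\t", row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname write_weights
#' @export
read_weights <- function(path) {
  df <- read.delim(path, stringsAsFactors = FALSE,
                   colClasses = c(snp = "character"))
  scaling <- unique(df$scaling) %||% "per_allele"
  df$scaling <- NULL
  attr(df, "scaling") <- scaling[1]
  class(df) <- c("weight_set", "data.frame")
  df
}
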