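# shared small synthetic cohort, built once per test run
small_cohort <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) {
      cfg <- sim_config(n_subjects = 600, n_snps = 300, seed = 42)
      geno <- simulate_genotypes(cfg)
      echo <- simulate_echo_exams(geno, cfg)
      pheno <- build_lv_mass_phenotype(echo$exams)
      cache <<- list(cfg = cfg, geno = geno, echo = echo, pheno = pheno)
    }
    cache
  }
})

# genotype matrix from a plain dosage matrix with default metadata
toy_geno <- function(dosage, ids = NULL) {
  p <- ncol(dosage)
  if (!is.null(ids)) rownames(dosage) <- ids
  genotype_matrix(dosage, data.frame(
    id = paste0("s", seq_len(p)), chrom = 1, pos = seq_len(p) * 100,
    allele1 = "A", allele2 = "G", stringsAsFactors = FALSE))
}

# a weight_set built by hand
toy_weights <- function(snp, w, effect = "A", other = "G",
                        scaling = "per_allele") {
  out <- data.frame(snp = snp, effect_allele = effect, other_allele = other,
                    w = w, alpha = w, beta = 0, gamma = 0,
                    stringsAsFactors = FALSE)
  attr(out, "scaling") <- scaling
  class(out) <- c("weight_set", "data.frame")
  out
}
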