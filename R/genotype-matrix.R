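#' Genotype matrix container
#'
#' A light S3 container for a subjects-by-SNPs allele-dosage matrix with SNP
#' metadata. Dosages count the `allele1` (effect/counted) allele and lie in
#' \[0, 2\]; `NA` marks a missing call. Most of the pipeline operates on
#' hard calls in \{0, 1, 2\}, but fractional (imputed) dosages are accepted
#' everywhere except the exact Hardy-Weinberg test, which rounds.
#'
#' @param dosage numeric matrix, subjects in rows (rownames = sample ids),
#'   SNPs in columns (colnames = SNP ids)
#' @param snps data.frame with columns `id`, `chrom`, `pos`, `allele1`,
#'   `allele2`; rows aligned with the columns of `dosage`
#' @return an object of class `genotype_matrix`
#' @export
genotype_matrix <- function(dosage, snps) {
  stopifnot(is.matrix(dosage), is.data.frame(snps))
  assert_that(ncol(dosage) == nrow(snps),
              "snp metadata rows must match dosage columns")
  assert_that(all(c("id", "chrom", "pos", "allele1", "allele2") %in% names(snps)),
              "snps needs columns id, chrom, pos, allele1, allele2")
  if (is.null(rownames(dosage)))
    rownames(dosage) <- paste0("S", seq_len(nrow(dosage)))
  colnames(dosage) <- as.character(snps$id)
  rng <- range(dosage, na.rm = TRUE)
  assert_that(rng[1] >= 0 && rng[2] <= 2, "dosages must lie in [0, 2]")
  structure(list(dosage = dosage, snps = snps), class = "genotype_matrix")
}

#' @export
print.genotype_matrix <- function(x, ...) {
  cat(sprintf("genotype_matrix: %d subjects x %d SNPs\n",
              nrow(x$dosage), ncol(x$dosage)))
  invisible(x)
}

#' @export
dim.genotype_matrix <- function(x) dim(x$dosage)

#' Subset a genotype matrix by subjects and/or SNPs
#'
#' @param x a `genotype_matrix`
#' @param i subject index (ids, logical or integer)
#' @param j SNP index (ids, logical or integer)
#' @param ... unused
#' @export
subset_genotypes <- function(x, i = NULL, j = NULL, ...) {
  stopifnot(inherits(x, "genotype_matrix"))
  d <- x$dosage
  s <- x$snps
  if (!is.null(i)) d <- d[i, , drop = FALSE]
  if (!is.null(j)) {
    if (is.character(j)) j <- match(j, colnames(d))
    d <- d[, j, drop = FALSE]
    s <- s[j, , drop = FALSE]
  }
  genotype_matrix(d, s)
}

#' Sample ids of a genotype matrix
#' @param x a `genotype_matrix`
#' @export
sample_ids <- function(x) rownames(x$dosage)

#' Per-SNP minor allele frequency
#'
#' The allele-1 frequency is `mean(dosage)/2`; the MAF folds it onto
#' \[0, 0.5\].
#'
#' @param x a `genotype_matrix`
#' @param folded if `FALSE`, return the allele-1 frequency unfolded
#' @export
snp_maf <- function(x, folded = TRUE) {
  af <- colMeans(x$dosage, na.rm = TRUE) / 2
  if (folded) pmin(af, 1 - af) else af
}

#' Per-SNP and per-sample missingness rates
#' @param x a `genotype_matrix`
#' @return list with `snp` and `sample` rates
#' @export
missingness <- function(x) {
  miss <- is.na(x$dosage)
  list(snp = colMeans(miss), sample = rowMeans(miss))
}

# ---- PLINK bed/bim/fam ------------------------------------------------------
# SNP-major bed v1: magic 0x6c 0x1b 0x01, then per SNP ceil(n/4) bytes, two
# bits per sample: 00 = hom allele1 (dosage 2), 10 = het, 11 = hom allele2
# (dosage 0), 01 = missing. No installed R package provides this codec, so it
# is implemented here; dosages are hard-called on write.

#' Write a genotype matrix as PLINK bed/bim/fam
#'
#' @param x a `genotype_matrix`
#' @param prefix path prefix; writes `<prefix>.bed/.bim/.fam`
#' @export
write_plink <- function(x, prefix) {
  stopifnot(inherits(x, "genotype_matrix"))
  n <- nrow(x$dosage)
  g <- round(x$dosage)
  codes <- matrix(1L, nrow(g), ncol(g))  # 01 = missing
  codes[!is.na(g) & g == 2] <- 0L
  codes[!is.na(g) & g == 1] <- 2L
  codes[!is.na(g) & g == 0] <- 3L
  npad <- 4L * ceiling(n / 4L)
  con <- file(paste0(prefix, ".bed"), "wb")
  on.exit(close(con))
  writeBin(as.raw(c(0x6c, 0x1b, 0x01)), con)
  for (j in seq_len(ncol(g))) {
    cj <- c(codes[, j], rep(0L, npad - n))
    byte <- cj[seq(1, npad, 4)] + 4L * cj[seq(2, npad, 4)] +
      16L * cj[seq(3, npad, 4)] + 64L * cj[seq(4, npad, 4)]
    writeBin(as.raw(byte), con)
  }
  bim <- data.frame(chrom = x$snps$chrom, id = x$snps$id, cm = 0,
                    pos = x$snps$pos, a1 = x$snps$allele1, a2 = x$snps$allele2)
  write.table(bim, paste0(prefix, ".bim"), sep = "\t", quote = FALSE,
              row.names = FALSE, col.names = FALSE)
  fam <- data.frame(fid = rownames(x$dosage), iid = rownames(x$dosage),
                    pat = 0, mat = 0, sex = 0, phen = -9)
  write.table(fam, paste0(prefix, ".fam"), sep = "\t", quote = FALSE,
              row.names = FALSE, col.names = FALSE)
  invisible(prefix)
}

#' Read PLINK bed/bim/fam into a genotype matrix
#'
#' @param prefix path prefix of the `.bed/.bim/.fam` triplet
#' @return a `genotype_matrix`
#' @export
read_plink <- function(prefix) {
  bim <- read.delim(paste0(prefix, ".bim"), header = FALSE,
                    col.names = c("chrom", "id", "cm", "pos", "allele1", "allele2"))
  fam <- read.delim(paste0(prefix, ".fam"), header = FALSE,
                    col.names = c("fid", "iid", "pat", "mat", "sex", "phen"))
  n <- nrow(fam); p <- nrow(bim)
  con <- file(paste0(prefix, ".bed"), "rb")
  on.exit(close(con))
  magic <- readBin(con, "raw", 3)
  assert_that(identical(as.integer(magic), c(108L, 27L, 1L)),
              "not a SNP-major PLINK bed file")
  bps <- ceiling(n / 4)
  raw <- readBin(con, "raw", bps * p)
  assert_that(length(raw) == bps * p, "truncated bed file")
  ints <- as.integer(raw)
  # expand each byte into 4 two-bit codes
  codes <- rbind(ints %% 4L, (ints %/% 4L) %% 4L,
                 (ints %/% 16L) %% 4L, (ints %/% 64L) %% 4L)
  dim(codes) <- c(4L * bps, p)
  codes <- codes[seq_len(n), , drop = FALSE]
  dos <- matrix(NA_real_, n, p)
  dos[codes == 0L] <- 2
  dos[codes == 2L] <- 1
  dos[codes == 3L] <- 0
  rownames(dos) <- as.character(fam$iid)
  genotype_matrix(dos, bim[, c("id", "chrom", "pos", "allele1", "allele2")])
}

#' Read genotypes from a VCF file
#'
#' Uses the DS FORMAT field when present, otherwise counts ALT alleles in GT.
#' The counted allele (`allele1`) is the ALT allele.
#'
#' @param path path to an (uncompressed or bgzipped) VCF
#' @return a `genotype_matrix`
#' @export
read_genotypes_vcf <- function(path) {
  if (!requireNamespace("vcfR", quietly = TRUE))
    stop("reading VCF requires the vcfR package", call. = FALSE)
  v <- vcfR::read.vcfR(path, verbose = FALSE)
  fix <- vcfR::getFIX(v)
  has_ds <- "DS" %in% vcfR::vcf_field_names(v, tag = "FORMAT")$ID
  if (has_ds) {
    ds <- vcfR::extract.gt(v, element = "DS", as.numeric = TRUE)
  } else {
    gt <- vcfR::extract.gt(v, element = "GT")
    ds <- apply(gt, 2, function(col) {
      vapply(strsplit(col, "[/|]"), function(a) {
        if (anyNA(a) || any(a == ".")) return(NA_real_)
        sum(a != "0")
      }, numeric(1))
    })
  }
  snps <- data.frame(id = fix[, "ID"], chrom = fix[, "CHROM"],
                     pos = as.integer(fix[, "POS"]),
                     allele1 = fix[, "ALT"], allele2 = fix[, "REF"])
  genotype_matrix(t(ds), snps)
}
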