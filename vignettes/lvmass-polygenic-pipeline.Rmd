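---
title: "Methods: polygenic modeling of left ventricular mass"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: polygenic modeling of left ventricular mass}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

# Overview

`lvprs` implements an analysis chain for studying the polygenic
architecture of echocardiographically measured left ventricular (LV) mass:

1. an LV-mass phenotype built from routine echo measurements,
2. genotype quality control with relatedness pruning and principal
   components,
3. a single-SNP GWAS of log LV mass,
4. a Bayesian sparse linear mixed model (BSLMM) that assigns predictive
   weights to a genome-wide SNP panel,
5. projection of those weights into a genotyped cohort without echo
   measurements, giving a genetically predicted LV mass,
6. a phenome-wide scan (PheWAS) of phecode-defined diagnoses against the
   predictor, with per-site logistic models, fixed-effect meta-analysis and
   Benjamini-Hochberg FDR, and
7. two-sample Mendelian randomization (MR) testing whether genetic risk
   scores for candidate risk factors associate with measured LV mass.

Because the motivating data are protected EHR-linked biobank cohorts, every
stage is exercised on synthetic cohorts produced by the package's own
generator, which reproduces the statistical structure the analysis assumes
(not the biology of any real population). Everything below describes
choices the package makes and why.

# The phenotype

LV mass in grams is computed from linear echo dimensions (cm) by the
Devereux linear-cube formula

$$\mathrm{LV\ mass} = 0.8\,\{1.04\,[(\mathrm{LVEDd}+\mathrm{IVSd}+\mathrm{PWd})^3 - \mathrm{LVEDd}^3]\} + 0.6 ,$$

where LVEDd is the internal diameter at end diastole and IVSd/PWd the
septal and posterior wall thicknesses. Per subject only the **first** exam
by date is used (clinical follow-up exams are enriched for disease
progression); ties on the date break by record order. Masses outside
[50, 500] g are discarded — the interval is treated as **closed**, since
boundary membership is unstated in the convention this follows and the
closed interval keeps more data. The retained mass is natural-log
transformed. Mass is deliberately *not* indexed to body surface area or
height: conditioning a phenotype on another heritable trait can induce
collider-bias associations at body-size loci. The echo table is assumed to
be in centimetres; a table in millimetres would produce masses ~1000-fold
off and fail the 50–500 g filter loudly rather than silently.

# Genotype QC

Filters run samples first, then SNPs (SNP statistics are recomputed on the
retained samples): sample missingness < 2%, SNP missingness < 4%,
MAF > 1%, and an **exact conditional** Hardy-Weinberg test at p ≥ 1e-6.
The exact test (enumeration over heterozygote counts conditional on allele
counts) rather than the chi-square approximation is used because it is
well behaved at low counts and can be checked against brute-force
enumeration.

Relatedness uses the standardized-genotype method-of-moments estimator
(the GRM entry), whose expectation under Hardy-Weinberg equals pi-hat.
Pairs above 0.05 are pruned by repeatedly removing the sample in the most
flagged pairs (ties by id) — this "one of each pair" rule is deterministic
and minimizes removals. One adaptation matters at simulation scale: the
estimator's sampling noise has s.d. ≈ 1/sqrt(#SNPs), so on a small panel
the 0.05 cutoff would flag unrelated pairs wholesale. The pipeline
therefore raises the cutoff to the family-wise 1% noise ceiling of the
estimator when that ceiling exceeds 0.05; at real-study marker counts
(10^5–10^6 SNPs) the ceiling is far below 0.05 and the rule reduces to the
nominal one. Relatedness is computed on the LD-reduced predictor panel
(r² < 0.9), a choice the original description leaves open.

LD pruning is greedy and windowed (default window 500 SNPs, step 50 —
only the two r² thresholds, 0.9 for the predictor set and 0.05 for MR
clumping, are externally fixed); the function re-verifies its own
postcondition (no retained pair above the cap within a window) before
returning. Principal components are left singular vectors of the
standardized dosage matrix, sign-fixed so each component's
largest-magnitude SNP loading is positive.

# GWAS

Per SNP, ordinary least squares of log LV mass on dosage under an additive
model, adjusted for age at exam, sex and 10 PCs; p < 5e-8 declares
genome-wide significance. The scan residualizes the phenotype and the
dosages on the covariate block once (Frisch–Waugh–Lovell), which is
algebraically identical to the full design — including standard errors —
and two orders of magnitude faster. Sporadically missing dosages are
mean-imputed per SNP; monomorphic SNPs are flagged with β = 0, p = 1.
Different stages use different PC counts (10 for GWAS, 5 elsewhere),
mirroring the analysis convention this follows; both are configuration
knobs.

# BSLMM weights

The model for the covariate-adjusted phenotype (residuals of log LV mass
on age at exam, sex and 5 PCs, re-centered) on column-standardized
genotypes X is

$$y = X\beta + u + \varepsilon, \qquad u \sim N(0, \sigma_b^2 K),$$

with spike-and-slab sparse effects β and a polygenic random effect u whose
covariance is the genomic relatedness matrix K = XXᵀ/p. The sampler uses
the exact reparameterization u = Xa with i.i.d. a_j ~ N(0, σ_b²/p): each
SNP's total effect is then a two-component normal mixture — a "small"
component every SNP has, plus, with probability π, a "large" component.
A systematic-scan Gibbs sweep updates each effect by a rank-one residual
update; the component variances and the noise variance get conjugate
inverse-gamma updates; π gets a conjugate truncated-Beta update under a
prior proportional to 1/π on [1/p, 1] (log-uniform on the expected
included count). **One sampling step is one full sweep over all SNPs.**
The ordering constraint σ²_slab ≥ σ²_spike resolves label switching.

Per retained step the sampler records PVE = var(Xb)/var(y) on the observed
sample — an operational, testable definition. The reported PVE is the
**median** over retained steps (for an even count, the mean of the two
central order statistics). Per SNP the posterior is summarized as α (the
small polygenic part), β (the large part, averaged over the steps in which
the SNP occupied the large-effect group), and γ (the inclusion frequency),
decomposed so that the predictive weight

$$w = \alpha + \beta\gamma$$

equals the posterior-mean total effect exactly. Weights are natively on
the standardized-genotype scale; because the projection equation applies
weights to raw 0/1/2 allele counts, the default export divides by the
training-sample dosage s.d. (the `per_allele` convention), and the scaling
flag travels with the weight file so either convention can be reproduced.

Default chain length is 20,000 steps with 10,000 burn-in — at the
simulated panel sizes used throughout (≈10³ subjects × 10³–2×10³ SNPs) the
PVE chain stabilizes well within that budget — with the 100,000/50,000
convention of the full-scale analysis available via the `full` profile.

Calibration checks built into the suite: with the slab disabled the
posterior PVE matches a variance-component (eigendecomposition ML) oracle;
PVE estimates increase across true PVE ∈ {0, 0.2, 0.4}; a pure-noise
phenotype collapses to PVE < 0.1 and near-zero inclusion.

# Score projection and the permuted control

Predicted LV mass is the inner product of weights with allele counts.
Effect alleles are harmonized first (dosage flipped when the target file
counts the other allele); SNPs missing from the target cohort are dropped
with a count, and an error fires if under half the weight SNPs match —
that pattern almost always means an identifier or allele-convention
mismatch, not genuine missingness. Missing dosages impute to 2×MAF of the
target cohort (expectation-preserving). Scores are standardized within the
scanned cohort, so downstream odds ratios are per 1 s.d. of predictor in
that cohort.

The negative control repeats the *entire* weight-fitting procedure on a
seeded permutation of the phenotype; a scan of that score against
genuinely score-driven phecodes should be uniformly null, and the test
suite checks exactly that.

# PheWAS

Cases carry ≥ 2 instances of a phecode; carriers with fewer instances, and
carriers of any closely related code (the map's numeric exclusion range),
are excluded from controls; remaining controls must fall inside the cases'
observed range of birth decade (or maximum recorded age — "maximum age" is
taken as the largest age in the subject's record, one reading of an
underspecified covariate). The age/birth-decade rule is a closed interval,
read literally. Sex-specific phecodes are dropped. Phenotypes with fewer
cases than the floor (300 at full scale; 100 in the desk profile, scaled
to the synthetic cohort sizes) are not scanned. The cardiomegaly-like
positive control (code 416) additionally uses the **sensitive** definition
— one instance suffices — so the standard cases nest inside it.

Associations are per-site logistic regressions of case status on the
standardized score plus sex, 5 PCs and birth decade (or maximum age);
separated or non-convergent site fits are flagged and dropped from
meta-analysis rather than aborting a multi-hundred-phenotype scan. Sites
are pooled by **fixed-effect inverse-variance** weighting — chosen over
the sample-size-weighted alternative because odds ratios with confidence
intervals are the reported quantity — and B-H adjusted; q < 0.05 declares
significance.

# Mendelian randomization

Instruments come from external exposure summary statistics: MAF > 5%,
exposure p < 5e-6, then greedy p-ordered clumping at r² < 0.05 against the
cohort genotypes. Outcome effects are sex-stratified per-SNP regressions
of log LV mass in the echo cohort (the sex-stratified reading of the
outcome model is an assumption, documented here). Harmonization aligns
effect alleles, allowing strand complements, and drops palindromic SNPs
whose allele frequency is uninformative (|EAF − 0.5| < 0.08).

Estimators, all first-order weighted:

* **IVW** (fixed-effect): θ = Σβ_Xβ_Y/SE_Y² / Σβ_X²/SE_Y², SE =
  (Σβ_X²/SE_Y²)^{-1/2}. Fixed- rather than random-effect because a single
  pooled estimate plus a separate heterogeneity p is the reporting
  convention followed here.
* **Cochran's Q** over Wald ratios with weights (SE_Y/β_X)^{-2},
  chi-square with J−1 df.
* **MR-Egger**: WLS of β_Y on β_X with intercept, weights 1/SE_Y², after
  orienting alleles so all β_X ≥ 0 (the standard identifiability
  convention); the intercept estimates average directional pleiotropy.
  SEs use the regression dispersion floored at 1.
* **Weighted median**: ratio estimates weighted by β_X²/SE_Y²; the
  estimate interpolates linearly where cumulative weight crosses ½; the SE
  comes from a seeded parametric bootstrap (default 1000 draws) since no
  closed form exists.

The sensitivity analysis for a mediated exposure removes instruments
associated with the upstream trait at p < 0.05 before re-estimating.

Two caveats the test suite makes explicit rather than hiding: MR-Egger is
only unbiased when exposure effects are estimated with error negligible
against their spread (the NOME condition), and the weighted median's
contamination bias under 40% invalid instruments is approximately
z₀.₈₃ × SE_Y/β_X — both therefore are evaluated in the strong-instrument,
precise-outcome regime of modern consortium GWAS, where the theoretical
guarantees actually hold.

# The synthetic cohort

The generator emulates, with one seeded RNG stream per stage:

* **Genotypes**: per-SNP MAFs uniform on [0.05, 0.5]; two latent-Gaussian
  allele draws per subject thresholded at the normal quantile of the MAF,
  so dosages are marginally binomial(2, maf); optional block
  equicorrelation of the latents induces LD ≈ ρ within blocks
  (thresholding attenuates it slightly, more for rare alleles). This is
  controllable, not haplotype-realistic — the pipeline only needs
  LD-reduced subsets to be meaningful.
* **Log LV mass**: intercept log(185) g; +0.3 for males (53% of the
  cohort), +0.003 per year of age; total variance 0.11 (log-scale s.d.
  ≈ 0.33, consistent with clinical echo populations whose coefficient of
  variation is roughly a third); a sparse component (default 10 causal
  SNPs) plus a dense polygenic component, rescaled so the realized genetic
  share of total log-mass variance equals `pve_total` (default 0.4)
  exactly, split half/half by default. Echo dimensions are back-solved so
  the Devereux formula reproduces each target mass bit-exactly: LVEDd ~
  N(4.8, 0.5) cm truncated to [3, 7], summed wall thickness from the cube
  relation, split equally between IVSd and PWd (only their sum enters the
  formula). The joint distribution of real echo dimensions is not modeled
  — the back-solve is a synthetic-only device. Out-of-range masses redraw
  their noise term. A tenth of subjects receive a later, perturbed repeat
  exam so the first-exam rule is exercised.
* **Phecodes**: liability = loading × standardized genetic value +
  Gaussian noise at unit total variance; affected above the prevalence
  quantile; affected subjects accrue ≥ 2 instances with probability 0.9,
  else exactly one — so both the ≥2-instance case rule and the
  single-instance exclusion have traffic. Defaults: a cardiomegaly-like
  code (416, prevalence 0.15, loading 0.4), a related sub-code, a weakly
  loaded hypertension-like code, null codes, and a sex-specific code.
* **Exposure GWAS**: instrument effects realized in the cohort; summary
  SEs follow 1/sqrt(n·2f(1−f)) for a unit-variance exposure; the exposure
  shifts log mass by θ per s.d.; configurable fractions of instruments
  carry direct (pleiotropic) outcome effects. A separate generator builds
  the mediated-pleiotropy scenario (a T2D-like trait whose instruments act
  only through a BMI-like pathway).

What passing on these cohorts does **not** show: robustness to haplotype
LD structure, allele-frequency misspecification across ancestries,
imputation uncertainty, phenotyping error correlated with utilization, or
ICD-mapping noise — none of which the generator models.

# Numerical and design notes

* All derived seeds stay below 2³¹; every stochastic stage takes its own
  stream from the master seed, so stages re-run reproducibly in isolation.
* Masses are filtered in double precision without rounding.
* The BSLMM prior means put ~10% of phenotypic variance in each variance
  component a priori (weak, shape-2 inverse-gamma); posterior inferences
  at the tested sizes are insensitive to doubling or halving these.
* Degenerate inputs fail loudly: rank-deficient covariates name the
  collinear columns; chains no longer than burn-in, invalid fractions
  outside [0,1], windows below 2 SNPs and empty PVE chains are errors;
  an all-zero score standardizes to zeros instead of dividing by zero.
* `pipeline_config(profile = "full")` restores every full-scale setting
  (100k/50k chain, 300-case floor); the desk profile only shortens the
  chain and lowers the case floor in proportion to the synthetic cohort
  sizes (defaults n = 3000 subjects, p = 3000 SNPs).
* The package is organized as an analysis: the numbered scripts under
  `analysis/` are thin file-driven drivers over the exported functions, and
  the orchestrated `run_pipeline()` reproduces the same chain in memory.

# Known limitations

* The BSLMM is the standard model class but not a bit-for-bit re-creation
  of any particular legacy sampler; only distributional behavior (PVE
  recovery, inclusion enrichment, null collapse) is guaranteed by tests.
* Binary (probit) BSLMM, mixed-model GWAS, multivariable MR, correlated
  instruments and multi-ancestry handling are out of scope.
* The phecode map shipped is a small hierarchical toy sufficient for the
  exclusion rules; real phecode tables are a drop-in replacement with the
  same columns.
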