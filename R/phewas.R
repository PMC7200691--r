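#' Read a phecode map
#'
#' The map gives, per phecode, the numeric exclusion range of closely
#' related codes (carriers of any code in the range are excluded from the
#' phecode's controls) and whether the code is sex-specific. A toy
#' hierarchical map ships with the package:
#' `system.file("extdata", "phecode_map_toy.csv", package = "lvprs")`.
#'
#' @param path CSV path with columns phecode, exclude_low, exclude_high,
#'   sex_specific
#' @export
read_phecode_map <- function(path = system.file("extdata",
                                                "phecode_map_toy.csv",
                                                package = "lvprs")) {
  map <- read.csv(path, stringsAsFactors = FALSE,
                  colClasses = c(phecode = "character"))
  map
}

#' Assemble phecode case/control sets
#'
#' Cases are subjects with at least `case_min_instances` instances of the
#' phecode. Excluded from controls are carriers of the phecode with fewer
#' instances and carriers of any closely related code (the map's exclusion
#' range). Controls are the remaining subjects whose age variable falls
#' within the range observed among cases (closed interval; birth decade or
#' maximum recorded age, per `age_match`). Sex-specific phecodes are
#' dropped, as are phecodes with fewer than `min_cases` cases.
#'
#' @param phecode_table data.frame: subject_id, phecode, n_instances
#' @param phecode_map data.frame from [read_phecode_map()]
#' @param subjects data.frame: subject_id, sex, site, birth_decade, max_age
#' @param min_cases minimum case count for a phecode to be scanned
#'   (default 300)
#' @param case_min_instances minimum code instances to be a case (default 2)
#' @param age_match `"birth_decade"`, `"max_age"` or `"none"`
#' @param codes optional character vector restricting the scanned phecodes
#' @return named list of `case_control_set` lists (phecode, cases,
#'   controls, excluded, n_case, n_control)
#' @export
assemble_case_control <- function(phecode_table, phecode_map, subjects,
                                  min_cases = 300, case_min_instances = 2,
                                  age_match = c("birth_decade", "max_age", "none"),
                                  codes = NULL) {
  age_match <- match.arg(age_match)
  phecode_table$phecode <- as.character(phecode_table$phecode)
  all_codes <- codes %||% sort(unique(phecode_table$phecode))
  num <- suppressWarnings(as.numeric(phecode_table$phecode))
  out <- list()
  for (code in all_codes) {
    mrow <- phecode_map[phecode_map$phecode == code, , drop = FALSE]
    if (nrow(mrow) > 0 && mrow$sex_specific[1] != "none") next
    rows <- phecode_table[phecode_table$phecode == code, , drop = FALSE]
    cases <- rows$subject_id[rows$n_instances >= case_min_instances]
    if (length(cases) < min_cases) next
    # carriers of the code with too few instances
    excl <- rows$subject_id[rows$n_instances < case_min_instances]
    # carriers of closely related codes
    if (nrow(mrow) > 0) {
      rel <- !is.na(num) & num >= mrow$exclude_low[1] & num <= mrow$exclude_high[1]
      excl <- union(excl, setdiff(phecode_table$subject_id[rel], cases))
    } else {
      warning(sprintf("phecode %s absent from map; no related-code exclusion", code))
    }
    ctrl <- subjects[!(subjects$subject_id %in% c(cases, excl)), , drop = FALSE]
    if (age_match != "none") {
      av <- subjects[[age_match]][subjects$subject_id %in% cases]
      rng <- range(av, na.rm = TRUE)
      ctrl <- ctrl[ctrl[[age_match]] >= rng[1] & ctrl[[age_match]] <= rng[2], ,
                   drop = FALSE]
    }
    out[[code]] <- structure(
      list(phecode = code, cases = cases, controls = ctrl$subject_id,
           excluded = setdiff(excl, cases), n_case = length(cases),
           n_control = nrow(ctrl)),
      class = "case_control_set")
  }
  out
}

#' Sensitive case definition for the cardiomegaly positive control
#'
#' Identical to [assemble_case_control()] but with a single code instance
#' sufficing for case status (a more sensitive definition, used only for
#' the predictor-validation phenotype), and no minimum case count.
#'
#' @param phecode_table,phecode_map,subjects,age_match as in
#'   [assemble_case_control()]
#' @param code the positive-control phecode (default "416")
#' @return a `case_control_set` (or NULL if the code is absent)
#' @export
cardiomegaly_control_set <- function(phecode_table, phecode_map, subjects,
                                     code = "416",
                                     age_match = "birth_decade") {
  sets <- assemble_case_control(phecode_table, phecode_map, subjects,
                                min_cases = 1, case_min_instances = 1,
                                age_match = age_match, codes = code)
  sets[[code]]
}

#' Per-site logistic association of a phecode with the score
#'
#' Maximum-likelihood logistic regression of case status on the
#' standardized score plus covariates, fitted separately within each site;
#' Wald standard errors and two-sided p-values. Sites where the fit does
#' not converge, or shows separation (unstable Wald SE), are flagged
#' `converged = FALSE` so the meta-analysis can drop them.
#'
#' @param score a `score_vector`
#' @param ccset a `case_control_set`
#' @param covariates data.frame of per-subject covariates with rownames =
#'   subject ids (e.g. sex indicator, PCs, birth decade or max age)
#' @param subjects data.frame with subject_id and site
#' @return data.frame: phecode, site, logor, se, p, n_case, n_control,
#'   converged
#' @export
logistic_assoc <- function(score, ccset, covariates, subjects) {
  ids <- c(ccset$cases, ccset$controls)
  y <- c(rep(1L, length(ccset$cases)), rep(0L, length(ccset$controls)))
  site <- subjects$site[match(ids, subjects$subject_id)]
  sv <- score$standardized[match(ids, score$subject_id)]
  keep <- !is.na(sv) & !is.na(site)
  ids <- ids[keep]; y <- y[keep]; site <- site[keep]; sv <- sv[keep]
  out <- list()
  for (s in sort(unique(site))) {
    i <- site == s
    dat <- data.frame(y = y[i], score = sv[i])
    if (!is.null(covariates)) {
      cm <- as.data.frame(covariates)[ids[i], , drop = FALSE]
      cm <- cm[, vapply(cm, function(col) length(unique(col)) > 1, TRUE),
               drop = FALSE]
      dat <- cbind(dat, cm)
    }
    conv <- TRUE
    fit <- withCallingHandlers(
      glm(y ~ ., data = dat, family = binomial()),
      warning = function(w) {
        if (grepl("fitted probabilities|did not converge", conditionMessage(w)))
          conv <<- FALSE
        invokeRestart("muffleWarning")
      })
    co <- summary(fit)$coefficients
    if (!("score" %in% rownames(co))) next
    se <- co["score", "Std. Error"]
    conv <- conv && fit$converged && is.finite(se) && se < 100
    out[[s]] <- data.frame(phecode = ccset$phecode, site = s,
                           logor = co["score", "Estimate"], se = se,
                           p = co["score", "Pr(>|z|)"],
                           n_case = sum(dat$y == 1), n_control = sum(dat$y == 0),
                           converged = conv, stringsAsFactors = FALSE)
  }
  if (length(out) == 0) return(NULL)
  do.call(rbind, c(out, list(make.row.names = FALSE)))
}

#' Fixed-effect inverse-variance meta-analysis
#'
#' Pools per-site log odds ratios: beta = sum(b_s/SE_s^2)/sum(1/SE_s^2),
#' SE = (sum 1/SE_s^2)^(-1/2), with a two-sided normal p-value.
#'
#' @param rows data.frame with columns logor, se (and optionally
#'   converged — non-converged rows are dropped)
#' @return one-row data.frame: logor, se, p, n_sites
#' @export
meta_fixed_effect <- function(rows) {
  if ("converged" %in% names(rows)) rows <- rows[rows$converged, , drop = FALSE]
  assert_that(nrow(rows) >= 1, "no converged site results to meta-analyze")
  assert_that(all(rows$se > 0), "site standard errors must be positive")
  wt <- 1 / rows$se^2
  b <- sum(rows$logor * wt) / sum(wt)
  se <- sqrt(1 / sum(wt))
  data.frame(logor = b, se = se, p = 2 * pnorm(-abs(b / se)),
             n_sites = nrow(rows))
}

#' Benjamini-Hochberg q-values
#'
#' Step-up q_i = min over j >= rank(i) of m p_(j) / j, in input order
#' (the B-H adjusted p-values).
#'
#' @param p vector of p-values
#' @return q-values aligned with `p`
#' @export
bh_fdr <- function(p) {
  p.adjust(p, method = "BH")
}

#' Phecodes significant at an FDR threshold
#' @param scan data.frame with `phecode` and `q` columns
#' @param q_max FDR threshold (default 0.05)
#' @export
significant_at <- function(scan, q_max = 0.05) {
  scan$phecode[scan$q < q_max]
}

#' Run the full phecode scan
#'
#' Per phecode: per-site logistic association of case status with the
#' standardized score, fixed-effect meta-analysis over converged sites, and
#' B-H FDR over the meta-analysis p-values. Odds ratios are the risk per
#' 1 s.d. increase of the score.
#'
#' @param score a `score_vector`
#' @param ccsets list from [assemble_case_control()]
#' @param covariates per-subject covariate data.frame (rownames = ids)
#' @param subjects data.frame with subject_id and site
#' @return data.frame: phecode, logor, se, or, or_lo, or_hi, p, q, n_case,
#'   n_control, n_sites — one row per scanned phecode
#' @export
phewas_scan <- function(score, ccsets, covariates, subjects) {
  rows <- lapply(ccsets, function(cc) {
    site_rows <- logistic_assoc(score, cc, covariates, subjects)
    if (is.null(site_rows) || !any(site_rows$converged)) return(NULL)
    m <- meta_fixed_effect(site_rows)
    data.frame(phecode = cc$phecode, logor = m$logor, se = m$se,
               or = exp(m$logor), or_lo = exp(m$logor - 1.96 * m$se),
               or_hi = exp(m$logor + 1.96 * m$se), p = m$p,
               n_case = cc$n_case, n_control = cc$n_control,
               n_sites = m$n_sites, stringsAsFactors = FALSE)
  })
  rows <- Filter(Negate(is.null), rows)
  if (length(rows) == 0) return(NULL)
  out <- do.call(rbind, c(rows, list(make.row.names = FALSE)))
  out$q <- bh_fdr(out$p)
  out[order(out$p), c("phecode", "logor", "se", "or", "or_lo", "or_hi",
                      "p", "q", "n_case", "n_control", "n_sites")]
}
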