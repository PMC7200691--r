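#' Left ventricular mass from linear echo dimensions
#'
#' The Devereux linear-cube formula:
#' \deqn{LV mass = 0.8 \{1.04 [(LVEDd + IVSd + PWd)^3 - LVEDd^3]\} + 0.6}
#' with all dimensions in centimetres and the result in grams. LVEDd is the
#' LV internal diameter at end diastole, IVSd the interventricular septal
#' thickness, and PWd the posterior wall thickness.
#'
#' @param lvedd_cm LV end-diastolic internal diameter (cm), > 0
#' @param ivsd_cm interventricular septal thickness (cm), >= 0
#' @param pwd_cm posterior wall thickness (cm), >= 0
#' @return LV mass in grams (vectorized)
#' @examples
#' devereux_lv_mass(5.0, 1.0, 1.0)  # 181.976
#' @export
devereux_lv_mass <- function(lvedd_cm, ivsd_cm, pwd_cm) {
  assert_that(all(lvedd_cm > 0), "lvedd_cm must be positive")
  assert_that(all(ivsd_cm >= 0) && all(pwd_cm >= 0),
              "wall thicknesses must be non-negative")
  0.8 * (1.04 * ((lvedd_cm + ivsd_cm + pwd_cm)^3 - lvedd_cm^3)) + 0.6
}

#' Build the analysis phenotype: first-exam, filtered, log LV mass
#'
#' Per subject, the earliest exam by date is selected (ties broken by the
#' lowest row position, i.e. record order), LV mass computed by
#' [devereux_lv_mass()], subjects with mass outside the closed interval
#' \[`mass_min`, `mass_max`\] dropped, and the natural log of mass returned
#' together with age at that exam and sex. Mass is deliberately not indexed
#' to body surface area or height: indexing by a heritable trait can induce
#' spurious (collider) genetic associations.
#'
#' @param exams data.frame of echo exams (subject_id, exam_date, lvedd_cm,
#'   ivsd_cm, pwd_cm, age_at_exam, sex)
#' @param mass_min,mass_max retained mass range in grams (closed interval)
#' @return data.frame: subject_id, log_lv_mass, lv_mass_g, age, sex —
#'   one row per retained subject
#' @export
build_lv_mass_phenotype <- function(exams, mass_min = 50, mass_max = 500) {
  need <- c("subject_id", "exam_date", "lvedd_cm", "ivsd_cm", "pwd_cm",
            "age_at_exam", "sex")
  assert_that(all(need %in% names(exams)),
              paste("exams must have columns:", paste(need, collapse = ", ")))
  assert_that(!anyNA(exams$exam_date), "exam dates must be present")
  ord <- order(exams$subject_id, exams$exam_date, seq_len(nrow(exams)))
  first <- exams[ord, ][!duplicated(exams$subject_id[ord]), ]
  mass <- devereux_lv_mass(first$lvedd_cm, first$ivsd_cm, first$pwd_cm)
  keep <- mass >= mass_min & mass <= mass_max
  out <- data.frame(subject_id = first$subject_id[keep],
                    log_lv_mass = log(mass[keep]),
                    lv_mass_g = mass[keep],
                    age = first$age_at_exam[keep],
                    sex = first$sex[keep],
                    stringsAsFactors = FALSE)
  rownames(out) <- NULL
  if (nrow(out) == 0)
    warning("no subjects retained after the mass filter")
  out
}

#' Write / read the phenotype table
#' @param pheno phenotype data.frame from [build_lv_mass_phenotype()]
#' @param path TSV path
#' @export
write_phenotype <- function(pheno, path) {
  write.table(pheno, path, sep = "\t", row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname write_phenotype
#' @export
read_phenotype <- function(path) {
  read.delim(path, stringsAsFactors = FALSE)
}
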