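# Deterministic clinical calculators: CKD-EPI eGFR, renal strata, Wells score,
# YEARS criteria and the age-adjusted D-dimer comparator cutoff.

#' Wells score item names and weights
#'
#' The seven items of the two-level Wells clinical prediction rule for
#' pulmonary embolism with their standard weights.
#'
#' @return Named numeric vector of item weights (points).
#' @export
wells_item_weights <- function() {
  c(
    clinical_dvt_signs        = 3,
    pe_most_likely            = 3,
    tachycardia_gt100         = 1.5,
    surgery_or_immobilization = 1.5,
    previous_pe_dvt           = 1.5,
    hemoptysis                = 1,
    malignancy                = 1
  )
}

#' Estimate glomerular filtration rate (CKD-EPI, 2009 equation)
#'
#' Implements the Chronic Kidney Disease Epidemiology Collaboration equation
#' eGFR = 141 * min(Scr/kappa, 1)^alpha * max(Scr/kappa, 1)^-1.209 *
#' 0.993^Age * 1.018 (if female) * 1.159 (if black), where Scr is serum
#' creatinine in mg/dl, kappa is 0.7 (female) / 0.9 (male) and alpha is
#' -0.329 (female) / -0.411 (male). Creatinine is supplied in umol/l and
#' converted with 88.42 umol/l per mg/dl. The result is returned unrounded in
#' ml/min; no body-surface-area rescaling is applied.
#'
#' @param creatinine_umol_l Serum creatinine in umol/l, must be > 0.
#' @param age Age in years, must be >= 18 (adult equation).
#' @param sex Character vector, "female" or "male".
#' @param black Logical, ancestry multiplier term of the equation.
#' @return Numeric vector of eGFR values in ml/min.
#' @examples
#' ckd_epi_egfr(78, 66, "female")
#' @export
ckd_epi_egfr <- function(creatinine_umol_l, age, sex, black = FALSE) {
  sex <- check_sex(sex)
  if (any(!is.finite(creatinine_umol_l)) || any(creatinine_umol_l <= 0)) {
    stop("creatinine must be positive and finite", call. = FALSE)
  }
  if (any(!is.finite(age)) || any(age < 18)) {
    stop("age must be >= 18 years (adult CKD-EPI equation)", call. = FALSE)
  }
  female <- sex == "female"
  scr <- creatinine_umol_l / 88.42
  kappa <- ifelse(female, 0.7, 0.9)
  alpha <- ifelse(female, -0.329, -0.411)
  ratio <- scr / kappa
  141 *
    pmin(ratio, 1)^alpha *
    pmax(ratio, 1)^-1.209 *
    0.993^age *
    ifelse(female, 1.018, 1) *
    ifelse(black, 1.159, 1)
}

#' Classify eGFR into renal function strata
#'
#' Bands used throughout the analysis: `gte60` (eGFR >= 60 ml/min), `s30_59`
#' (moderate impairment, 30 <= eGFR < 60) and `lt30` (severe impairment).
#' The boundaries 60 and 30 belong to the upper band (60 -> `gte60`,
#' 30 -> `s30_59`).
#'
#' @param egfr Numeric vector of eGFR values in ml/min, must be > 0.
#' @return Factor with levels `gte60`, `s30_59`, `lt30`.
#' @export
classify_renal_stratum <- function(egfr) {
  if (any(!is.finite(egfr)) || any(egfr <= 0)) {
    stop("egfr must be positive and finite", call. = FALSE)
  }
  out <- ifelse(egfr >= 60, "gte60", ifelse(egfr >= 30, "s30_59", "lt30"))
  factor(out, levels = renal_stratum_levels())
}

renal_stratum_levels <- function() c("gte60", "s30_59", "lt30")

#' Two-level Wells score for pulmonary embolism
#'
#' Weighted sum of the seven Wells items (see [wells_item_weights()]); scores
#' are multiples of 0.5 in 0..12.5.
#'
#' @param items Data frame (or list of equal-length logical vectors) holding
#'   the seven item columns named as in [wells_item_weights()].
#' @return Numeric vector of scores.
#' @export
wells_score <- function(items) {
  w <- wells_item_weights()
  missing_items <- setdiff(names(w), names(items))
  if (length(missing_items)) {
    stop("missing Wells items: ", paste(missing_items, collapse = ", "),
         call. = FALSE)
  }
  score <- 0
  for (nm in names(w)) {
    v <- items[[nm]]
    if (any(is.na(v))) stop("Wells item '", nm, "' contains NA", call. = FALSE)
    score <- score + w[[nm]] * as.numeric(v)
  }
  score
}

#' Wells risk class from score
#'
#' `low` for score < 2, `moderate` for 2 <= score <= 6, `high` for score > 6.
#'
#' @param score Numeric Wells scores.
#' @return Factor with levels `low`, `moderate`, `high`.
#' @export
wells_class <- function(score) {
  out <- ifelse(score < 2, "low", ifelse(score <= 6, "moderate", "high"))
  factor(out, levels = c("low", "moderate", "high"))
}

#' YEARS rule-out decision
#'
#' The YEARS algorithm counts three items (clinical signs of DVT, hemoptysis,
#' PE the most likely diagnosis) and rules PE out without CT angiography when
#' no item is present and D-dimer < 1000 ug/l, or when at least one item is
#' present and D-dimer < 500 ug/l (strict inequalities).
#'
#' @param n_items Integer count of positive YEARS items (0..3).
#' @param ddimer D-dimer in ug/l, must be > 0.
#' @return Factor with levels `ruled_out`, `needs_cta`.
#' @export
years_class <- function(n_items, ddimer) {
  if (any(ddimer <= 0)) stop("ddimer must be positive", call. = FALSE)
  if (any(n_items < 0 | n_items > 3)) {
    stop("n_items must be in 0..3", call. = FALSE)
  }
  out <- ifelse((n_items == 0 & ddimer < 1000) | (n_items >= 1 & ddimer < 500),
                "ruled_out", "needs_cta")
  factor(out, levels = c("ruled_out", "needs_cta"))
}

#' Age-adjusted D-dimer cutoff
#'
#' The conventional age-adjusted rule: 500 ug/l up to age 50, age x 10 ug/l
#' above 50. The source analyses name this comparator without restating its
#' definition; the standard rule is used.
#'
#' @param age Age in years, must be >= 18.
#' @return Cutoff in ug/l (always >= 500).
#' @export
age_adjusted_cutoff <- function(age) {
  if (any(age < 18)) stop("age must be >= 18", call. = FALSE)
  ifelse(age <= 50, 500, age * 10)
}

check_sex <- function(sex) {
  sex <- as.character(sex)
  bad <- !sex %in% c("female", "male")
  if (any(bad)) {
    stop("sex must be 'female' or 'male' (got: ",
         paste(unique(sex[bad]), collapse = ", "), ")", call. = FALSE)
  }
  sex
}

#' Annotate a cohort with derived clinical quantities
#'
#' Adds to a patient-level data frame (see [generate_cohort()] for the
#' column contract): `egfr` (CKD-EPI, ml/min), `renal_stratum`,
#' `wells_score`, `wells_class`, `wells_lt_6_5`, `years_items`
#' (count of the three YEARS items) and `age_adjusted_cutoff` (ug/l).
#'
#' @param cohort Data frame of patient records.
#' @return The data frame with derived columns appended.
#' @export
annotate_cohort <- function(cohort) {
  validate_cohort(cohort)
  cohort$egfr <- ckd_epi_egfr(cohort$creatinine, cohort$age, cohort$sex,
                              cohort$black)
  cohort$renal_stratum <- classify_renal_stratum(cohort$egfr)
  cohort$wells_score <- wells_score(cohort)
  cohort$wells_class <- wells_class(cohort$wells_score)
  cohort$wells_lt_6_5 <- cohort$wells_score < 6.5
  cohort$years_items <- as.integer(cohort$clinical_dvt_signs) +
    as.integer(cohort$hemoptysis) + as.integer(cohort$pe_most_likely)
  cohort$age_adjusted_cutoff <- age_adjusted_cutoff(cohort$age)
  cohort
}
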