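# Strategy comparison: rule-out strategies as first-class objects, binary
# net reclassification improvement, avoided-CTA cost-effectiveness, and the
# regression / correlation analyses of D-dimer determinants.

#' Rule-out strategies
#'
#' A strategy maps each annotated record to a binary decision: negative
#' (D-dimer rules PE out, no CT angiography) or positive (proceed to CTA).
#'
#' * `strategy_fixed(cutoff)` -- one cutoff for everybody; negative iff
#'   `ddimer < cutoff`.
#' * `strategy_age_adjusted()` -- per-record cutoff 500 ug/l up to age 50,
#'   age x 10 above.
#' * `strategy_renal_adjusted(cutoffs)` -- per-stratum cutoffs, named
#'   `gte60`, `s30_59`, `lt30`.
#' * `strategy_refer_all()` -- every record positive (CTA for all), the
#'   no-D-dimer reference.
#'
#' @param cutoff Single positive cutoff in ug/l.
#' @return Object of class `ddimer_strategy`.
#' @export
strategy_fixed <- function(cutoff) {
  stopifnot(is.numeric(cutoff), length(cutoff) == 1, cutoff > 0)
  structure(list(type = "fixed", cutoff = cutoff), class = "ddimer_strategy")
}

#' @rdname strategy_fixed
#' @export
strategy_age_adjusted <- function() {
  structure(list(type = "age_adjusted"), class = "ddimer_strategy")
}

#' @rdname strategy_fixed
#' @param cutoffs Named vector of per-stratum cutoffs (`gte60`, `s30_59`,
#'   `lt30`), ug/l.
#' @export
strategy_renal_adjusted <- function(cutoffs) {
  if (!all(renal_stratum_levels() %in% names(cutoffs))) {
    stop("cutoffs must be named gte60, s30_59, lt30", call. = FALSE)
  }
  if (any(cutoffs <= 0)) stop("cutoffs must be positive", call. = FALSE)
  structure(list(type = "renal_adjusted",
                 cutoffs = cutoffs[renal_stratum_levels()]),
            class = "ddimer_strategy")
}

#' @rdname strategy_fixed
#' @export
strategy_refer_all <- function() {
  structure(list(type = "refer_all"), class = "ddimer_strategy")
}

#' Apply a rule-out strategy to a cohort
#'
#' @param records Annotated cohort (needs `ddimer`; `age` for the
#'   age-adjusted strategy, `renal_stratum` for the renal-adjusted one).
#' @param strategy A `ddimer_strategy`.
#' @return Logical vector, `TRUE` where the record is ruled out (negative).
#' @export
apply_strategy <- function(records, strategy) {
  stopifnot(inherits(strategy, "ddimer_strategy"))
  switch(strategy$type,
    fixed = records$ddimer < strategy$cutoff,
    age_adjusted = records$ddimer < age_adjusted_cutoff(records$age),
    renal_adjusted =
      unname(records$ddimer <
               strategy$cutoffs[as.character(records$renal_stratum)]),
    refer_all = rep(FALSE, nrow(records)),
    stop("unknown strategy type: ", strategy$type, call. = FALSE))
}

#' Parse / serialize the strategy mini-format (JSON)
#'
#' `{"type":"fixed","cutoff":500}` | `{"type":"age_adjusted"}` |
#' `{"type":"renal_adjusted","cutoffs":{"gte60":...,"s30_59":...,"lt30":...}}`
#' | `{"type":"refer_all"}`.
#'
#' @param x JSON string, file path, or already-parsed list.
#' @return A `ddimer_strategy`.
#' @export
strategy_from_json <- function(x) {
  spec <- if (is.list(x)) x else jsonlite::fromJSON(x, simplifyVector = TRUE)
  if (is.null(spec$type)) stop("strategy spec needs a 'type'", call. = FALSE)
  switch(spec$type,
    fixed = strategy_fixed(spec$cutoff),
    age_adjusted = strategy_age_adjusted(),
    renal_adjusted = strategy_renal_adjusted(unlist(spec$cutoffs)),
    refer_all = strategy_refer_all(),
    stop("unknown strategy type: ", spec$type, call. = FALSE))
}

#' Binary net reclassification improvement between two strategies
#'
#' Two-category NRI for the dichotomous decision CTA (positive) versus
#' rule-out (negative). "Up" means reclassified negative -> positive under
#' the new strategy, "down" positive -> negative. The event component is
#' P(up | PE) - P(down | PE) (events should move up), the non-event
#' component P(down | no PE) - P(up | no PE), and NRI is their sum. A
#' component with no records in its class is flagged undefined and NRI is
#' reported as NA.
#'
#' @param records Annotated cohort.
#' @param strategy_old,strategy_new `ddimer_strategy` objects (old =
#'   reference).
#' @return Object of class `nri_result`: `nri`, `event_component`,
#'   `nonevent_component`, `n_events`, `n_nonevents`, plus undefined flags.
#' @export
nri <- function(records, strategy_old, strategy_new) {
  neg_old <- apply_strategy(records, strategy_old)
  neg_new <- apply_strategy(records, strategy_new)
  up <- neg_old & !neg_new
  down <- !neg_old & neg_new
  pe <- records$pe
  n_ev <- sum(pe); n_ne <- sum(!pe)
  ev <- if (n_ev > 0) (sum(up & pe) - sum(down & pe)) / n_ev else NA_real_
  ne <- if (n_ne > 0) (sum(down & !pe) - sum(up & !pe)) / n_ne else NA_real_
  structure(
    list(nri = ev + ne, event_component = ev, nonevent_component = ne,
         n_events = n_ev, n_nonevents = n_ne,
         event_undefined = n_ev == 0, nonevent_undefined = n_ne == 0),
    class = "nri_result")
}

#' @export
print.nri_result <- function(x, ...) {
  cat(sprintf(
    "NRI %.4g (events %s, n=%d; non-events %s, n=%d)\n",
    x$nri,
    if (x$event_undefined) "undefined" else sprintf("%+.4g", x$event_component),
    x$n_events,
    if (x$nonevent_undefined) "undefined"
      else sprintf("%+.4g", x$nonevent_component),
    x$n_nonevents))
  invisible(x)
}

#' Avoided-CTA cost comparison between two strategies
#'
#' A "negative CTA" is a scan performed on a record the strategy sends to
#' imaging (test positive) that shows no PE. Switching from the old to the
#' new strategy avoids `cta_negative_old - cta_negative_new` such scans;
#' savings are `avoided x unit_cost`. `missed_pe` counts PE cases the new
#' strategy rules out. Callers should restrict records to Wells score < 6.5
#' (high clinical probability bypasses D-dimer and goes straight to CTA).
#'
#' @param records Annotated cohort, pre-filtered to Wells < 6.5.
#' @param strategy_old,strategy_new `ddimer_strategy` objects.
#' @param unit_cost Cost per CTA scan (CHF); default 488, the aggregate
#'   Swiss TARMED tariff.
#' @param stratum_label Carried into the result.
#' @return Object of class `cost_result`.
#' @export
cost_saved <- function(records, strategy_old, strategy_new, unit_cost = 488,
                       stratum_label = "") {
  if (!is.numeric(unit_cost) || unit_cost < 0) {
    stop("unit_cost must be >= 0", call. = FALSE)
  }
  neg_old <- apply_strategy(records, strategy_old)
  neg_new <- apply_strategy(records, strategy_new)
  pe <- records$pe
  cta_negative_old <- sum(!neg_old & !pe)
  cta_negative_new <- sum(!neg_new & !pe)
  avoided <- cta_negative_old - cta_negative_new
  structure(
    list(stratum_label = stratum_label,
         cta_negative_old = cta_negative_old,
         cta_negative_new = cta_negative_new,
         avoided = avoided,
         unit_cost = unit_cost,
         total_saved = avoided * unit_cost,
         missed_pe = sum(neg_new & pe)),
    class = "cost_result")
}

#' @export
print.cost_result <- function(x, ...) {
  cat(sprintf(
    "Cost [%s]: negative CTAs %d -> %d, avoided %d x %.0f CHF = %.0f CHF (missed PE: %d)\n",
    x$stratum_label, x$cta_negative_old, x$cta_negative_new, x$avoided,
    x$unit_cost, x$total_saved, x$missed_pe))
  invisible(x)
}

#' Multivariable linear model for ln(D-dimer)
#'
#' Ordinary least squares of ln(ddimer) on age, female sex, PE, malignancy,
#' pregnancy/perinatal state, ln(eGFR) and ln(CRP) (CRP floored at
#' `crp_floor` before the log), with intercept. Classical standard errors
#' and two-sided t-test p-values by default; heteroskedasticity-robust
#' (HC1) standard errors behind a flag.
#'
#' @param records Annotated cohort (needs `egfr`; run [annotate_cohort()]
#'   first).
#' @param crp_floor Floor for CRP before the log transform (mg/l).
#' @param robust Use HC1 robust standard errors.
#' @return Data frame with columns `term`, `estimate`, `std_error`,
#'   `t_value`, `p_value`; rows intercept, age, female, pe, malignancy,
#'   pregnancy, ln_egfr, ln_crp.
#' @export
fit_lnddimer_regression <- function(records, crp_floor = 1, robust = FALSE) {
  if (is.null(records$egfr)) {
    stop("records lack 'egfr'; call annotate_cohort() first", call. = FALSE)
  }
  X <- cbind(
    intercept  = 1,
    age        = records$age,
    female     = as.numeric(records$sex == "female"),
    pe         = as.numeric(records$pe),
    malignancy = as.numeric(records$malignancy),
    pregnancy  = as.numeric(records$pregnancy_perinatal),
    ln_egfr    = log(records$egfr),
    ln_crp     = log(pmax(records$crp, crp_floor)))
  y <- log(records$ddimer)
  n <- nrow(X); p <- ncol(X)
  if (n <= p) stop("need more records than covariates", call. = FALSE)
  qr_x <- qr(X)
  if (qr_x$rank < p) {
    dropped <- colnames(X)[qr_x$pivot[(qr_x$rank + 1):p]]
    stop("design matrix is rank deficient; collinear column(s): ",
         paste(dropped, collapse = ", "), call. = FALSE)
  }
  coef <- qr.coef(qr_x, y)
  resid <- y - X %*% coef
  xtx_inv <- chol2inv(qr.R(qr_x))
  if (robust) {
    meat <- crossprod(X * as.vector(resid))
    vc <- xtx_inv %*% meat %*% xtx_inv * n / (n - p)
  } else {
    s2 <- sum(resid^2) / (n - p)
    vc <- xtx_inv * s2
  }
  se <- sqrt(diag(vc))
  tval <- coef / se
  data.frame(term = colnames(X), estimate = unname(coef),
             std_error = unname(se), t_value = unname(tval),
             p_value = unname(2 * stats::pt(-abs(tval), df = n - p)),
             stringsAsFactors = FALSE)
}

#' Univariate Pearson correlation between two cohort fields
#'
#' Pearson correlation of two (optionally log-transformed) columns with the
#' t-based two-sided p-value. Mirrors the slope-sign/strength summary of a
#' univariable linear regression.
#'
#' @param records Cohort data frame.
#' @param x_field,y_field Column names.
#' @param log_x,log_y Apply a natural log first (values must be positive).
#' @return List `(r, p_value, n)`.
#' @export
univariate_r <- function(records, x_field, y_field,
                         log_x = FALSE, log_y = FALSE) {
  x <- records[[x_field]]
  y <- records[[y_field]]
  if (is.null(x) || is.null(y)) stop("unknown field name", call. = FALSE)
  if (log_x) {
    if (any(x <= 0)) stop("log_x requested but '", x_field,
                          "' has non-positive values", call. = FALSE)
    x <- log(x)
  }
  if (log_y) {
    if (any(y <= 0)) stop("log_y requested but '", y_field,
                          "' has non-positive values", call. = FALSE)
    y <- log(y)
  }
  n <- length(x)
  if (n < 3) stop("need at least 3 records", call. = FALSE)
  if (stats::sd(x) == 0 || stats::sd(y) == 0) {
    stop("zero variance in '", if (stats::sd(x) == 0) x_field else y_field,
         "'", call. = FALSE)
  }
  r <- stats::cor(x, y)
  tval <- r * sqrt((n - 2) / (1 - r^2))
  p <- if (abs(r) == 1) 0 else 2 * stats::pt(-abs(tval), df = n - 2)
  list(r = r, p_value = p, n = n)
}
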