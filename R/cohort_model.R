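# Patient data model and synthetic cohort generator. The generative backbone
# is a log-linear model for D-dimer: ln(ddimer) = beta.x + N(0, sigma^2) with
# covariates (1, age, female, pe, malignancy, pregnancy, ln eGFR, ln CRP).

#' Default coefficient vector of the ln(D-dimer) generative model
#'
#' Point estimates of the multivariable regression of ln(D-dimer) on
#' demographic, clinical and laboratory covariates that the generator uses as
#' ground truth. The intercept is not identified by published marginals and
#' was calibrated once (coarse grid, see the methods vignette) so that the
#' median synthetic D-dimer in the eGFR >= 60 ml/min stratum lands near
#' 1096 ug/l.
#'
#' @return Named numeric vector with elements `intercept`, `age`, `female`,
#'   `pe`, `malignancy`, `pregnancy`, `ln_egfr`, `ln_crp`.
#' @export
default_lnddimer_beta <- function() {
  c(
    intercept  = 7.60,
    age        = 0.012,
    female     = -0.07,
    pe         = 0.959,
    malignancy = 0.237,
    pregnancy  = 0.918,
    ln_egfr    = -0.3467,
    ln_crp     = 0.0297
  )
}

#' Configuration of the synthetic cohort generator
#'
#' Bundles every parameter of the generative model. Defaults emulate the
#' emergency-department population the analysis targets: n = 1369, 53%
#' female, age median 66 (IQR 54-79), renal strata 79% / 19% / 2%
#' (>= 60, 30-59, < 30 ml/min), PE prevalence 2% / 36% / 54% by Wells class,
#' and ln(D-dimer) following [default_lnddimer_beta()].
#'
#' @param n Cohort size (>= 1).
#' @param seed Integer seed; the generator is fully reproducible given the
#'   config (including seed).
#' @param beta Named coefficient vector, see [default_lnddimer_beta()].
#' @param sigma Residual SD of ln(D-dimer) (> 0). Default 0.90, calibrated
#'   once against the published stratum interquartile range (methods
#'   vignette).
#' @param age_dist List `(mean, sd, min, max)` of a truncated, rounded
#'   normal; default targets median 66, IQR 54-79, support 18..100.
#' @param female_frac Probability of female sex.
#' @param egfr_strata_probs Named probabilities of the renal strata
#'   (`gte60`, `s30_59`, `lt30`); must sum to 1.
#' @param creatinine_dist Per-stratum log-normal parameters for serum
#'   creatinine (umol/l): named list of `(meanlog, sdlog)`.
#' @param crp_dist Log-normal parameters `(meanlog, sdlog)` for CRP (mg/l).
#' @param crp_floor CRP floor (mg/l) applied before taking ln in the D-dimer
#'   model; ln(CRP) is undefined at 0.
#' @param wells_item_probs Named marginal probabilities of the seven Wells
#'   items (items are drawn independently). The `malignancy` entry is the
#'   probability of active malignancy, which enters both the Wells score and
#'   the D-dimer model.
#' @param pe_prev_by_class Named PE prevalences for Wells classes `low`,
#'   `moderate`, `high`.
#' @param pregnancy_prob Probability of pregnancy / perinatal state among
#'   women.
#' @param pe_location_probs Named probabilities of the PE location label
#'   among PE-positive records.
#' @param max_rejections Cap on creatinine rejection-sampling attempts per
#'   record before erroring (guards against a misconfigured creatinine_dist).
#' @return Object of class `generator_config`.
#' @export
generator_config <- function(n = 1369,
                             seed = 1L,
                             beta = default_lnddimer_beta(),
                             sigma = 0.90,
                             age_dist = list(mean = 66, sd = 18.5,
                                             min = 18, max = 100),
                             female_frac = 0.53,
                             egfr_strata_probs = c(gte60 = 0.79,
                                                   s30_59 = 0.19,
                                                   lt30 = 0.02),
                             creatinine_dist = list(
                               gte60  = list(meanlog = log(75),  sdlog = 0.20),
                               s30_59 = list(meanlog = log(130), sdlog = 0.25),
                               lt30   = list(meanlog = log(260), sdlog = 0.30)),
                             crp_dist = list(meanlog = log(10), sdlog = 1.5),
                             crp_floor = 1,
                             wells_item_probs = c(
                               clinical_dvt_signs        = 0.08,
                               pe_most_likely            = 0.28,
                               tachycardia_gt100         = 0.19,
                               surgery_or_immobilization = 0.14,
                               previous_pe_dvt           = 0.11,
                               hemoptysis                = 0.04,
                               malignancy                = 0.11),
                             pe_prev_by_class = c(low = 0.02,
                                                  moderate = 0.36,
                                                  high = 0.54),
                             pregnancy_prob = 0.01,
                             pe_location_probs = c(
                               peripheral_subsegmental = 0.19,
                               segmental = 0.33,
                               paracentral = 0.16,
                               central = 0.32),
                             max_rejections = 1000) {
  cfg <- structure(
    list(n = n, seed = as.integer(seed), beta = beta, sigma = sigma,
         age_dist = age_dist, female_frac = female_frac,
         egfr_strata_probs = egfr_strata_probs,
         creatinine_dist = creatinine_dist, crp_dist = crp_dist,
         crp_floor = crp_floor, wells_item_probs = wells_item_probs,
         pe_prev_by_class = pe_prev_by_class,
         pregnancy_prob = pregnancy_prob,
         pe_location_probs = pe_location_probs,
         max_rejections = max_rejections),
    class = "generator_config")
  validate_generator_config(cfg)
  cfg
}

#' @rdname generator_config
#' @param config Object to validate.
#' @export
validate_generator_config <- function(config) {
  stopifnot(inherits(config, "generator_config"))
  if (!is.numeric(config$n) || length(config$n) != 1 || config$n < 1 ||
      config$n != round(config$n)) {
    stop("n must be a positive integer", call. = FALSE)
  }
  if (!is.numeric(config$sigma) || config$sigma < 0) {
    stop("sigma must be >= 0", call. = FALSE)
  }
  beta_names <- names(default_lnddimer_beta())
  if (!all(beta_names %in% names(config$beta))) {
    stop("beta must carry names: ", paste(beta_names, collapse = ", "),
         call. = FALSE)
  }
  probs <- c(config$female_frac, config$egfr_strata_probs,
             config$wells_item_probs, config$pe_prev_by_class,
             config$pregnancy_prob, config$pe_location_probs)
  if (any(probs < 0 | probs > 1)) {
    stop("all probabilities must lie in [0, 1]", call. = FALSE)
  }
  if (abs(sum(config$egfr_strata_probs) - 1) > 1e-9) {
    stop("egfr_strata_probs must sum to 1", call. = FALSE)
  }
  if (!all(renal_stratum_levels() %in% names(config$egfr_strata_probs))) {
    stop("egfr_strata_probs must be named gte60, s30_59, lt30", call. = FALSE)
  }
  if (!all(names(wells_item_weights()) %in% names(config$wells_item_probs))) {
    stop("wells_item_probs must name all seven Wells items", call. = FALSE)
  }
  invisible(config)
}

# Truncated, rounded normal ages via rejection; degenerate when sd = 0.
draw_ages <- function(n, dist) {
  if (dist$sd == 0) return(rep(round(dist$mean), n))
  out <- numeric(0)
  while (length(out) < n) {
    cand <- round(stats::rnorm(n, dist$mean, dist$sd))
    out <- c(out, cand[cand >= dist$min & cand <= dist$max])
  }
  out[seq_len(n)]
}

# Creatinine within a target renal stratum: draw from the stratum's
# log-normal, keep draws whose CKD-EPI eGFR (given age/sex) falls in the
# stratum; resample the rest up to max_rejections rounds.
draw_creatinine <- function(stratum, age, sex, black, dist, max_rejections) {
  n <- length(stratum)
  creat <- rep(NA_real_, n)
  pending <- seq_len(n)
  for (attempt in seq_len(max_rejections)) {
    if (!length(pending)) break
    d_meanlog <- vapply(as.character(stratum[pending]),
                        function(s) dist[[s]]$meanlog, numeric(1))
    d_sdlog <- vapply(as.character(stratum[pending]),
                      function(s) dist[[s]]$sdlog, numeric(1))
    cand <- stats::rlnorm(length(pending), d_meanlog, d_sdlog)
    egfr <- ckd_epi_egfr(cand, age[pending], sex[pending], black[pending])
    ok <- classify_renal_stratum(egfr) == stratum[pending]
    creat[pending[ok]] <- cand[ok]
    pending <- pending[!ok]
  }
  if (length(pending)) {
    stop("creatinine rejection sampling failed for ", length(pending),
         " record(s) after ", max_rejections,
         " attempts; creatinine_dist is inconsistent with the target strata",
         call. = FALSE)
  }
  creat
}

#' Generate a synthetic emergency-department cohort
#'
#' Draws `config$n` post-exclusion patient records (adults, not
#' anticoagulated). Generation order: age, sex; renal stratum, then serum
#' creatinine rejection-sampled within the stratum so that the CKD-EPI eGFR
#' recomputed from the record falls in the drawn stratum; CRP; Wells items
#' (independent Bernoulli draws, the malignancy item doubling as the
#' malignancy covariate); pregnancy/perinatal state (women only); PE status
#' from the Wells-class-specific prevalence; finally
#' ln(ddimer) = beta.x + N(0, sigma^2) with
#' x = (1, age, female, pe, malignancy, pregnancy, ln eGFR,
#' ln max(CRP, crp_floor)).
#'
#' All randomness flows through R's Mersenne-Twister stream seeded from
#' `config$seed`; the caller's RNG state is restored on exit, so two calls
#' with identical configs yield identical cohorts.
#'
#' @param config A [generator_config()].
#' @return Data frame with one row per patient: `id`, `age`, `sex`, `black`,
#'   `creatinine` (umol/l), `crp` (mg/l), `ddimer` (ug/l), the seven Wells
#'   item columns, `pregnancy_perinatal`, `anticoagulated`, `pe`,
#'   `pe_location` (NA unless `pe`).
#' @export
generate_cohort <- function(config) {
  validate_generator_config(config)
  n <- config$n

  old_seed <- if (exists(".Random.seed", envir = globalenv()))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (is.null(old_seed)) {
      if (exists(".Random.seed", envir = globalenv()))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old_seed, envir = globalenv())
  })
  set.seed(config$seed, kind = "Mersenne-Twister")

  age <- draw_ages(n, config$age_dist)
  sex <- ifelse(stats::runif(n) < config$female_frac, "female", "male")
  black <- rep(FALSE, n)

  strata <- sample(names(config$egfr_strata_probs), n, replace = TRUE,
                   prob = config$egfr_strata_probs)
  strata <- factor(strata, levels = renal_stratum_levels())
  creatinine <- draw_creatinine(strata, age, sex, black,
                                config$creatinine_dist, config$max_rejections)
  crp <- stats::rlnorm(n, config$crp_dist$meanlog, config$crp_dist$sdlog)

  items <- lapply(names(wells_item_weights()), function(nm) {
    stats::runif(n) < config$wells_item_probs[[nm]]
  })
  names(items) <- names(wells_item_weights())
  pregnancy <- sex == "female" & stats::runif(n) < config$pregnancy_prob

  score <- wells_score(items)
  wclass <- wells_class(score)
  pe <- stats::runif(n) < config$pe_prev_by_class[as.character(wclass)]

  pe_location <- rep(NA_character_, n)
  if (any(pe)) {
    pe_location[pe] <- sample(names(config$pe_location_probs), sum(pe),
                              replace = TRUE,
                              prob = config$pe_location_probs)
  }

  egfr <- ckd_epi_egfr(creatinine, age, sex, black)
  b <- config$beta
  lp <- b[["intercept"]] +
    b[["age"]] * age +
    b[["female"]] * (sex == "female") +
    b[["pe"]] * pe +
    b[["malignancy"]] * items$malignancy +
    b[["pregnancy"]] * pregnancy +
    b[["ln_egfr"]] * log(egfr) +
    b[["ln_crp"]] * log(pmax(crp, config$crp_floor))
  ddimer <- exp(lp + stats::rnorm(n, 0, config$sigma))

  out <- data.frame(
    id = sprintf("S%06d", seq_len(n)),
    age = age, sex = sex, black = black,
    creatinine = creatinine, crp = crp, ddimer = ddimer,
    stringsAsFactors = FALSE)
  for (nm in names(items)) out[[nm]] <- items[[nm]]
  out$pregnancy_perinatal <- pregnancy
  out$anticoagulated <- FALSE
  out$pe <- pe
  out$pe_location <- pe_location
  out
}

cohort_bool_cols <- function() {
  c("black", names(wells_item_weights()), "pregnancy_perinatal",
    "anticoagulated", "pe")
}

#' Validate a patient-level cohort table
#'
#' Checks the column contract and record invariants: age >= 18, positive
#' creatinine and D-dimer, non-negative CRP, `pe_location` present only for
#' PE-positive records, and pregnancy/perinatal restricted to women. Errors
#' report offending row numbers.
#'
#' @param cohort Data frame of patient records.
#' @return The cohort, invisibly, if valid.
#' @export
validate_cohort <- function(cohort) {
  required <- c("id", "age", "sex", "creatinine", "crp", "ddimer",
                cohort_bool_cols(), "pe_location")
  missing_cols <- setdiff(required, names(cohort))
  if (length(missing_cols)) {
    stop("cohort is missing columns: ", paste(missing_cols, collapse = ", "),
         call. = FALSE)
  }
  check_sex(cohort$sex)
  fail <- function(rows, what) {
    if (length(rows)) {
      stop(what, " (rows ", paste(utils::head(rows, 10), collapse = ", "),
           if (length(rows) > 10) ", ..." else "", ")", call. = FALSE)
    }
  }
  fail(which(cohort$age < 18), "age < 18")
  fail(which(!(cohort$creatinine > 0)), "creatinine must be > 0")
  fail(which(!(cohort$ddimer > 0)), "ddimer must be > 0")
  fail(which(cohort$crp < 0), "crp must be >= 0")
  fail(which(!is.na(cohort$pe_location) & !cohort$pe),
       "pe_location present without pe")
  fail(which(cohort$pregnancy_perinatal & cohort$sex != "female"),
       "pregnancy_perinatal implies female sex")
  invisible(cohort)
}

#' Write / read a cohort as delimited text
#'
#' CSV with header, UTF-8, booleans serialized as 0/1 and missing
#' `pe_location` as an empty field. The reader validates invariants (with
#' row numbers) and can drop anticoagulated records, mirroring the study's
#' exclusion filter.
#'
#' @param cohort Data frame of patient records.
#' @param path File path.
#' @export
write_cohort <- function(cohort, path) {
  validate_cohort(cohort)
  out <- cohort
  for (nm in cohort_bool_cols()) out[[nm]] <- as.integer(out[[nm]])
  out$pe_location[is.na(out$pe_location)] <- ""
  utils::write.csv(out, path, row.names = FALSE, quote = FALSE,
                   fileEncoding = "UTF-8")
  invisible(path)
}

#' @rdname write_cohort
#' @param drop_anticoagulated Drop records with `anticoagulated = 1` on read.
#' @export
read_cohort <- function(path, drop_anticoagulated = FALSE) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE,
                        fileEncoding = "UTF-8",
                        colClasses = c(pe_location = "character"))
  for (nm in cohort_bool_cols()) {
    if (!nm %in% names(df)) next
    bad <- which(!df[[nm]] %in% c(0L, 1L))
    if (length(bad)) {
      stop("column '", nm, "' must be 0/1 (rows ",
           paste(utils::head(bad, 10), collapse = ", "), ")", call. = FALSE)
    }
    df[[nm]] <- df[[nm]] == 1L
  }
  if ("pe_location" %in% names(df)) {
    df$pe_location[df$pe_location == ""] <- NA_character_
  }
  validate_cohort(df)
  if (drop_anticoagulated) df <- df[!df$anticoagulated, , drop = FALSE]
  df
}

#' Serialize / deserialize a generator configuration as JSON
#'
#' @param config A [generator_config()].
#' @param path File path for the JSON document.
#' @export
write_generator_config <- function(config, path) {
  validate_generator_config(config)
  out <- unclass(config)
  # named atomic vectors must become JSON objects, not bare arrays
  for (nm in c("beta", "egfr_strata_probs", "wells_item_probs",
               "pe_prev_by_class", "pe_location_probs")) {
    out[[nm]] <- as.list(out[[nm]])
  }
  jsonlite::write_json(out, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(path)
}

#' @rdname write_generator_config
#' @export
read_generator_config <- function(path) {
  raw <- jsonlite::read_json(path, simplifyVector = TRUE)
  defaults <- generator_config()
  for (nm in c("beta", "egfr_strata_probs", "wells_item_probs",
               "pe_prev_by_class", "pe_location_probs")) {
    raw[[nm]] <- unlist(raw[[nm]])
  }
  cfg <- utils::modifyList(unclass(defaults), raw)
  cfg <- structure(cfg[names(defaults)], class = "generator_config")
  validate_generator_config(cfg)
  cfg
}
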