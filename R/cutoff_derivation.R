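# NPV-constrained D-dimer cutoff search. The rule-out rule is
# "negative iff ddimer < cutoff"; its NPV is a step function that changes
# only at observed D-dimer values, so the candidate grid is the sorted
# unique observed values plus one sentinel just above the maximum (the
# rule-out-everyone candidate).

cutoff_candidates <- function(ddimer) {
  v <- sort(unique(ddimer))
  c(v, max(v) + 1)
}

#' Derive the largest D-dimer cutoff meeting a target NPV
#'
#' Scans the candidate cutoffs (sorted unique observed D-dimer values plus a
#' sentinel above the maximum) and returns the largest cutoff whose
#' negative-predictive value -- the fraction of records with
#' `ddimer < cutoff` that are PE-free -- meets the target. The point
#' estimate (not a CI bound) is compared to the target. Candidates with zero
#' negatives have undefined NPV and are infeasible by definition. Among
#' equal-NPV candidates the largest wins (it maximizes rule-outs, hence
#' specificity, under the safety constraint).
#'
#' Callers intending the clinical rule-out use case should pre-filter
#' records to the stratum of interest and to Wells score < 6.5 (high
#' clinical probability goes straight to CT angiography); the search itself
#' is agnostic.
#'
#' @param records Non-empty annotated cohort (needs `ddimer`, `pe`).
#' @param target_npv Target NPV in (0, 1].
#' @param stratum_label Free-text label carried into the result.
#' @param ci_method Passed to [metrics()].
#' @return Object of class `cutoff_result`: list with `stratum_label`,
#'   `target_npv`, `cutoff`, `npv` (achieved, NA when infeasible),
#'   `n_negative`, `feasible`, `metrics_at_cutoff` and `empty = FALSE`.
#'   When no candidate is feasible, `feasible = FALSE` and the cutoff is the
#'   smallest candidate (rule out nobody).
#' @export
derive_cutoff <- function(records, target_npv, stratum_label = "",
                          ci_method = "wilson") {
  if (!is.data.frame(records) || nrow(records) == 0) {
    stop("records must be a non-empty data frame", call. = FALSE)
  }
  if (!is.numeric(target_npv) || length(target_npv) != 1 ||
      target_npv <= 0 || target_npv > 1) {
    stop("target_npv must lie in (0, 1]", call. = FALSE)
  }
  cand <- cutoff_candidates(records$ddimer)
  dd <- records$ddimer
  pe <- records$pe
  # negatives below each candidate, via the cumulative counts of the sorted
  # records; candidate k (the k-th unique value) admits exactly the records
  # strictly below it.
  ord <- order(dd)
  dd_s <- dd[ord]
  pe_s <- pe[ord]
  n_below <- findInterval(cand, dd_s, left.open = TRUE)  # records < cand
  cum_pe <- c(0, cumsum(pe_s))
  pe_below <- cum_pe[n_below + 1]
  npv <- ifelse(n_below > 0, (n_below - pe_below) / n_below, NA_real_)
  feasible_idx <- which(n_below > 0 & npv >= target_npv)
  if (length(feasible_idx)) {
    k <- max(feasible_idx)
    cutoff <- cand[k]
    res_npv <- npv[k]
    n_negative <- n_below[k]
    feasible <- TRUE
  } else {
    cutoff <- cand[1]
    res_npv <- NA_real_
    n_negative <- 0L
    feasible <- FALSE
  }
  structure(
    list(stratum_label = stratum_label, target_npv = target_npv,
         cutoff = cutoff, npv = res_npv, n_negative = as.integer(n_negative),
         feasible = feasible,
         metrics_at_cutoff = metrics(confusion_at_cutoff(records, cutoff),
                                     ci_method = ci_method),
         empty = FALSE),
    class = "cutoff_result")
}

#' Evaluate externally fixed D-dimer cutoffs
#'
#' No search: computes the full metrics set at each supplied cutoff and
#' flags feasibility against a target NPV (undefined NPV counts as
#' infeasible).
#'
#' @param records Non-empty annotated cohort.
#' @param cutoffs Positive cutoffs in ug/l.
#' @param target_npv Target the feasibility flag is checked against.
#' @inheritParams derive_cutoff
#' @return List of `cutoff_result` objects, one per cutoff.
#' @export
evaluate_fixed_cutoffs <- function(records, cutoffs, target_npv = 0.99,
                                   stratum_label = "", ci_method = "wilson") {
  if (!is.data.frame(records) || nrow(records) == 0) {
    stop("records must be a non-empty data frame", call. = FALSE)
  }
  if (any(cutoffs <= 0)) stop("cutoffs must be positive", call. = FALSE)
  lapply(cutoffs, function(ct) {
    m <- metrics(confusion_at_cutoff(records, ct), ci_method = ci_method)
    n_negative <- m$table$tn + m$table$fn
    npv <- if (m$npv$undefined) NA_real_ else m$npv$estimate
    structure(
      list(stratum_label = stratum_label, target_npv = target_npv,
           cutoff = ct, npv = npv, n_negative = as.integer(n_negative),
           feasible = !is.na(npv) && npv >= target_npv,
           metrics_at_cutoff = m, empty = FALSE),
      class = "cutoff_result")
  })
}

#' Derive CRP-adjusted D-dimer cutoffs
#'
#' For each C-reactive-protein threshold, restricts the cohort to records
#' with `crp >= threshold` and derives the NPV-constrained cutoff at each
#' target. An empty subset yields a flagged placeholder row
#' (`empty = TRUE`), not an error.
#'
#' @param records Annotated cohort.
#' @param crp_thresholds CRP thresholds in mg/l, ascending.
#' @param target_npvs Target NPVs, e.g. `c(0.99, 0.95)`.
#' @inheritParams derive_cutoff
#' @return List of `cutoff_result` objects (thresholds x targets, threshold
#'   varying slowest).
#' @export
crp_adjusted_cutoffs <- function(records, crp_thresholds = c(50, 100, 150),
                                 target_npvs = c(0.99, 0.95),
                                 ci_method = "wilson") {
  if (is.unsorted(crp_thresholds, strictly = TRUE)) {
    stop("crp_thresholds must be sorted ascending", call. = FALSE)
  }
  out <- list()
  for (thr in crp_thresholds) {
    subset <- records[records$crp >= thr, , drop = FALSE]
    for (target in target_npvs) {
      label <- sprintf("crp_gte_%g", thr)
      if (nrow(subset) == 0) {
        out[[length(out) + 1]] <- structure(
          list(stratum_label = label, target_npv = target,
               cutoff = NA_real_, npv = NA_real_, n_negative = 0L,
               feasible = NA, metrics_at_cutoff = NULL, empty = TRUE),
          class = "cutoff_result")
      } else {
        out[[length(out) + 1]] <-
          derive_cutoff(subset, target, stratum_label = label,
                        ci_method = ci_method)
      }
    }
  }
  out
}

#' @export
print.cutoff_result <- function(x, ...) {
  if (isTRUE(x$empty)) {
    cat(sprintf("Cutoff result [%s]: empty stratum (target NPV %.3g)\n",
                x$stratum_label, x$target_npv))
    return(invisible(x))
  }
  cat(sprintf(
    "Cutoff result [%s]: < %s ug/l (target NPV %.3g, achieved %s, %d rule-outs%s)\n",
    x$stratum_label, format(x$cutoff), x$target_npv,
    if (is.na(x$npv)) "undefined" else sprintf("%.4g", x$npv),
    x$n_negative, if (x$feasible) "" else ", INFEASIBLE"))
  invisible(x)
}

# Flatten a list of cutoff_result objects into a report table.
cutoff_results_table <- function(results) {
  rows <- lapply(results, function(r) {
    m <- r$metrics_at_cutoff
    get_est <- function(nm) if (is.null(m) || m[[nm]]$undefined) NA_real_
      else m[[nm]]$estimate
    data.frame(
      stratum = r$stratum_label, target_npv = r$target_npv,
      cutoff = r$cutoff, feasible = as.logical(r$feasible),
      n_negative = r$n_negative, npv = r$npv,
      sensitivity = get_est("sensitivity"),
      specificity = get_est("specificity"),
      ppv = get_est("ppv"),
      stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}
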