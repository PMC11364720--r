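# Confusion tables, standard-equation test performance with confidence
# intervals, empirical ROC AUC and 2x2 odds ratios.
#
# Conventions: test positive <=> ddimer >= cutoff (a value equal to the
# cutoff is positive; "negative" means rule-out), condition positive <=> PE
# confirmed on CT angiography.

#' Build a 2x2 confusion table for a D-dimer cutoff
#'
#' @param records Annotated cohort data frame (needs `ddimer` and `pe`).
#' @param cutoff D-dimer cutoff in ug/l (> 0); test positive iff
#'   `ddimer >= cutoff`.
#' @return Object of class `confusion_table`: list with integer counts `tp`,
#'   `fp`, `tn`, `fn` and the `cutoff`.
#' @export
confusion_at_cutoff <- function(records, cutoff) {
  if (!is.data.frame(records) || nrow(records) == 0) {
    stop("records must be a non-empty data frame", call. = FALSE)
  }
  if (!is.numeric(cutoff) || length(cutoff) != 1 || cutoff <= 0) {
    stop("cutoff must be a single positive number", call. = FALSE)
  }
  pos <- records$ddimer >= cutoff
  confusion_table(tp = sum(pos & records$pe),
                  fp = sum(pos & !records$pe),
                  tn = sum(!pos & !records$pe),
                  fn = sum(!pos & records$pe),
                  cutoff = cutoff)
}

#' @rdname confusion_at_cutoff
#' @param tp,fp,tn,fn Non-negative integer counts.
#' @export
confusion_table <- function(tp, fp, tn, fn, cutoff = NA_real_) {
  counts <- c(tp = tp, fp = fp, tn = tn, fn = fn)
  if (any(counts < 0) || any(counts != round(counts))) {
    stop("counts must be non-negative integers", call. = FALSE)
  }
  structure(list(tp = as.integer(tp), fp = as.integer(fp),
                 tn = as.integer(tn), fn = as.integer(fn),
                 cutoff = cutoff),
            class = "confusion_table")
}

# Wilson score interval for a binomial proportion.
ci_wilson <- function(x, n, conf = 0.95) {
  z <- stats::qnorm(1 - (1 - conf) / 2)
  p <- x / n
  denom <- 1 + z^2 / n
  centre <- (p + z^2 / (2 * n)) / denom
  half <- z * sqrt(p * (1 - p) / n + z^2 / (4 * n^2)) / denom
  c(lower = max(0, centre - half), upper = min(1, centre + half))
}

# Clopper-Pearson (exact) interval via the beta quantile representation.
ci_clopper_pearson <- function(x, n, conf = 0.95) {
  a <- (1 - conf) / 2
  lower <- if (x == 0) 0 else stats::qbeta(a, x, n - x + 1)
  upper <- if (x == n) 1 else stats::qbeta(1 - a, x + 1, n - x)
  c(lower = lower, upper = upper)
}

prop_with_ci <- function(x, n, ci_method, conf) {
  if (n == 0) {
    return(list(estimate = NA_real_, lower = NA_real_, upper = NA_real_,
                undefined = TRUE))
  }
  ci <- switch(ci_method,
               wilson = ci_wilson(x, n, conf),
               clopper_pearson = ci_clopper_pearson(x, n, conf),
               stop("unknown ci_method: ", ci_method, call. = FALSE))
  list(estimate = x / n, lower = unname(ci["lower"]),
       upper = unname(ci["upper"]), undefined = FALSE)
}

# Likelihood-ratio CI on the log scale (Simel et al.): the ratio is
# undefined at zero denominators and its CI is undefined at zero cells.
lr_with_ci <- function(num_x, num_n, den_x, den_n, conf) {
  if (num_n == 0 || den_n == 0 || den_x == 0) {
    return(list(estimate = NA_real_, lower = NA_real_, upper = NA_real_,
                undefined = TRUE))
  }
  est <- (num_x / num_n) / (den_x / den_n)
  if (num_x == 0) {
    return(list(estimate = 0, lower = NA_real_, upper = NA_real_,
                undefined = FALSE))
  }
  z <- stats::qnorm(1 - (1 - conf) / 2)
  se <- sqrt(1 / num_x - 1 / num_n + 1 / den_x - 1 / den_n)
  list(estimate = est, lower = est * exp(-z * se), upper = est * exp(z * se),
       undefined = FALSE)
}

#' Diagnostic performance metrics from a confusion table
#'
#' Standard equations: sensitivity tp/(tp+fn), specificity tn/(tn+fp),
#' PPV tp/(tp+fp), NPV tn/(tn+fn), accuracy (tp+tn)/n, PLR sens/(1-spec),
#' NLR (1-sens)/spec. Proportion CIs use the Wilson score interval by
#' default (Clopper-Pearson available), likelihood-ratio CIs the log method.
#' A metric whose denominator is zero is reported with an explicit
#' `undefined = TRUE` marker and `NA` estimate, never silently as 0.
#'
#' @param table A [confusion_table()].
#' @param ci_method `"wilson"` or `"clopper_pearson"`.
#' @param conf Two-sided confidence level.
#' @return Object of class `metrics_set`: named list of metric entries
#'   `(estimate, lower, upper, undefined)` plus the counts and `n`.
#' @export
metrics <- function(table, ci_method = c("wilson", "clopper_pearson"),
                    conf = 0.95) {
  stopifnot(inherits(table, "confusion_table"))
  ci_method <- match.arg(ci_method)
  tp <- table$tp; fp <- table$fp; tn <- table$tn; fn <- table$fn
  n <- tp + fp + tn + fn
  if (n == 0) stop("empty confusion table", call. = FALSE)
  out <- list(
    sensitivity = prop_with_ci(tp, tp + fn, ci_method, conf),
    specificity = prop_with_ci(tn, tn + fp, ci_method, conf),
    ppv         = prop_with_ci(tp, tp + fp, ci_method, conf),
    npv         = prop_with_ci(tn, tn + fn, ci_method, conf),
    accuracy    = prop_with_ci(tp + tn, n, ci_method, conf),
    plr         = lr_with_ci(tp, tp + fn, fp, fp + tn, conf),
    nlr         = lr_with_ci(fn, tp + fn, tn, fp + tn, conf),
    table       = table,
    n           = n)
  class(out) <- "metrics_set"
  out
}

#' @export
print.metrics_set <- function(x, digits = 3, ...) {
  cat(sprintf("Diagnostic metrics (n = %d, cutoff = %s)\n", x$n,
              format(x$table$cutoff)))
  for (nm in c("sensitivity", "specificity", "ppv", "npv", "accuracy",
               "plr", "nlr")) {
    m <- x[[nm]]
    if (m$undefined) {
      cat(sprintf("  %-12s undefined\n", nm))
    } else {
      cat(sprintf("  %-12s %s (CI %s-%s)\n", nm,
                  signif(m$estimate, digits), signif(m$lower, digits),
                  signif(m$upper, digits)))
    }
  }
  invisible(x)
}

#' Empirical ROC area under the curve for D-dimer against PE
#'
#' Computed as the Mann-Whitney probability that a PE-positive record's
#' D-dimer exceeds a PE-negative one's, ties counted one half (mid-rank
#' formulation). The confidence interval uses the Hanley-McNeil standard
#' error.
#'
#' @param records Annotated cohort (needs `ddimer` and `pe`); both classes
#'   must be present.
#' @param conf Confidence level.
#' @return List `(auc, lower, upper, n_pos, n_neg)`.
#' @export
empirical_auc <- function(records, conf = 0.95) {
  pe <- records$pe
  n1 <- sum(pe); n0 <- sum(!pe)
  if (n1 == 0 || n0 == 0) {
    stop("both PE and non-PE records are required", call. = FALSE)
  }
  r <- rank(records$ddimer)
  auc <- (sum(r[pe]) - n1 * (n1 + 1) / 2) / (n1 * n0)
  q1 <- auc / (2 - auc)
  q2 <- 2 * auc^2 / (1 + auc)
  se <- sqrt((auc * (1 - auc) + (n1 - 1) * (q1 - auc^2) +
                (n0 - 1) * (q2 - auc^2)) / (n1 * n0))
  z <- stats::qnorm(1 - (1 - conf) / 2)
  list(auc = auc, lower = max(0, auc - z * se), upper = min(1, auc + z * se),
       n_pos = n1, n_neg = n0)
}

#' Odds ratio of a 2x2 table with Wald log-scale CI
#'
#' OR = (a d)/(b c) for the table (a, b / c, d). When any cell is zero the
#' Haldane-Anscombe correction adds 0.5 to every cell (only then). The
#' p-value is the two-sided Wald test on log OR.
#'
#' @param a,b,c,d Non-negative counts; rows = exposure, columns = outcome.
#' @param conf Confidence level.
#' @return List `(or, lower, upper, p_value, corrected)`.
#' @export
odds_ratio_2x2 <- function(a, b, c, d, conf = 0.95) {
  counts <- c(a, b, c, d)
  if (any(counts < 0)) stop("counts must be >= 0", call. = FALSE)
  corrected <- any(counts == 0)
  if (corrected) counts <- counts + 0.5
  or <- (counts[1] * counts[4]) / (counts[2] * counts[3])
  se <- sqrt(sum(1 / counts))
  z <- stats::qnorm(1 - (1 - conf) / 2)
  p <- 2 * stats::pnorm(-abs(log(or)) / se)
  list(or = or, lower = or * exp(-z * se), upper = or * exp(z * se),
       p_value = p, corrected = corrected)
}

#' Per-item odds ratios of the Wells criteria for PE
#'
#' For each of the seven Wells items, the odds ratio of CTA-confirmed PE in
#' records with versus without the item.
#'
#' @param records Annotated cohort.
#' @return Data frame with one row per item: `item`, `or`, `lower`, `upper`,
#'   `p_value`.
#' @export
wells_item_odds_ratios <- function(records) {
  items <- names(wells_item_weights())
  rows <- lapply(items, function(nm) {
    v <- records[[nm]]
    res <- odds_ratio_2x2(sum(v & records$pe), sum(v & !records$pe),
                          sum(!v & records$pe), sum(!v & !records$pe))
    data.frame(item = nm, or = res$or, lower = res$lower, upper = res$upper,
               p_value = res$p_value, stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}
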