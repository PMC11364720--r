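# Fixture builders and independent brute-force oracles. The oracles share no
# code with the implementation paths they check.

# Minimal annotated-record table for metric / cutoff functions.
make_records <- function(ddimer, pe, crp = 10, age = 60, sex = "male",
                         renal_stratum = "gte60") {
  n <- length(ddimer)
  data.frame(
    ddimer = ddimer, pe = rep_len(pe, n), crp = rep_len(crp, n),
    age = rep_len(age, n), sex = rep_len(sex, n),
    renal_stratum = factor(rep_len(renal_stratum, n),
                           levels = c("gte60", "s30_59", "lt30")),
    stringsAsFactors = FALSE)
}

# A fully valid raw cohort row set, for pipeline / IO tests.
make_raw_cohort <- function(n = 6, age = 60, sex = "female",
                            creatinine = 70, crp = 10, ddimer = 800,
                            pe = FALSE, anticoagulated = FALSE) {
  df <- data.frame(
    id = sprintf("T%03d", seq_len(n)),
    age = rep_len(age, n), sex = rep_len(sex, n), black = FALSE,
    creatinine = rep_len(creatinine, n), crp = rep_len(crp, n),
    ddimer = rep_len(ddimer, n),
    clinical_dvt_signs = FALSE, pe_most_likely = FALSE,
    tachycardia_gt100 = FALSE, surgery_or_immobilization = FALSE,
    previous_pe_dvt = FALSE, hemoptysis = FALSE, malignancy = FALSE,
    pregnancy_perinatal = FALSE,
    anticoagulated = rep_len(anticoagulated, n),
    pe = rep_len(pe, n),
    pe_location = NA_character_,
    stringsAsFactors = FALSE)
  df$pe_location[df$pe] <- "segmental"
  df
}

# Brute-force NPV-constrained cutoff search: plain loop over candidates,
# recomputing the negative set from scratch each time.
bf_derive_cutoff <- function(ddimer, pe, target_npv) {
  cand <- c(sort(unique(ddimer)), max(ddimer) + 1)
  best <- NA_real_
  for (ct in cand) {
    neg <- ddimer < ct
    if (sum(neg) == 0) next
    if (mean(!pe[neg]) >= target_npv) best <- ct
  }
  list(cutoff = best, feasible = !is.na(best))
}

# All-pairs Mann-Whitney AUC, O(n^2), ties counted one half.
bf_auc <- function(ddimer, pe) {
  pos <- ddimer[pe]
  neg <- ddimer[!pe]
  total <- 0
  for (p in pos) total <- total + sum(p > neg) + 0.5 * sum(p == neg)
  total / (length(pos) * length(neg))
}
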