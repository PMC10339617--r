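#' Empirical percentile (pinned order-statistic convention)
#'
#' The q-th percentile of x is the value at the `ceiling(q * n / 100)`-th
#' order statistic. Pinned explicitly because quantile conventions differ
#' across ecosystems and the group boundaries depend on it.
#'
#' @param x numeric vector.
#' @param q percentile in (0, 100).
#' @return The percentile value.
#' @export
empirical_percentile <- function(x, q) {
  stopifnot(q > 0, q < 100, length(x) >= 1)
  sort(x)[ceiling(q * length(x) / 100)]
}

#' Assign low / intermediate / high percentile groups
#'
#' Groups scores by the 20th/80th percentiles (configurable) of a reference
#' distribution: `low` iff the score is strictly below the low-cut percentile
#' value, `high` iff strictly above the high-cut value, `intermediate`
#' otherwise (boundary ties fall inward). In `within_population` mode the
#' percentiles are computed separately inside each population's own score
#' distribution (the convention for the stratified association models); in
#' `cohort_wide` mode one pooled threshold is used (the convention for
#' between-population distribution-shift comparisons).
#'
#' @param scores numeric score vector (finite).
#' @param labels population label per sample; required in
#'   `within_population` mode.
#' @param low_cut,high_cut percentile cuts (defaults 20 and 80).
#' @param reference `"within_population"` or `"cohort_wide"`.
#' @return Factor with levels low, intermediate, high.
#' @export
percentile_groups <- function(scores, labels = NULL, low_cut = 20,
                              high_cut = 80,
                              reference = c("within_population",
                                            "cohort_wide")) {
  reference <- match.arg(reference)
  if (!all(is.finite(scores))) stop("scores must be finite")
  if (!(low_cut > 0 && low_cut < high_cut && high_cut < 100))
    stop("cuts must satisfy 0 < low_cut < high_cut < 100")
  # Rank-based thresholds: low iff strictly below the smallest value outside
  # the bottom low_cut%, high iff strictly above the ceil(high_cut*n/100)-th
  # order statistic. With n divisible by 100/low_cut and no ties this puts
  # exactly low_cut% in "low" and (100-high_cut)% in "high"; boundary ties
  # fall inward to "intermediate".
  assign_one <- function(x) {
    n <- length(x)
    xs <- sort(x)
    lo <- xs[floor(low_cut * n / 100) + 1]
    hi <- xs[ceiling(high_cut * n / 100)]
    ifelse(x < lo, "low", ifelse(x > hi, "high", "intermediate"))
  }
  if (reference == "cohort_wide") {
    g <- assign_one(scores)
  } else {
    if (is.null(labels)) stop("within_population mode requires labels")
    stopifnot(length(labels) == length(scores))
    small <- names(which(table(labels) < 5))
    if (length(small))
      stop("population stratum with < 5 samples in within_population mode: ",
           paste(small, collapse = ", "))
    g <- character(length(scores))
    for (lab in unique(labels)) {
      i <- labels == lab
      g[i] <- assign_one(scores[i])
    }
  }
  factor(g, levels = c("low", "intermediate", "high"))
}

#' Cross aPRS groups with family-history status
#'
#' Builds the six-level joint factor (three score groups x FH positive or
#' negative) used by the combined association model, with the reference
#' level fixed to intermediate score and negative FH. Samples with missing
#' FH become NA with a message (they are dropped by the model fit).
#'
#' @param groups factor from [percentile_groups()].
#' @param fh 0/1 family-history flags.
#' @return Factor with levels aPRS_int_FH_neg (reference), aPRS_low_FH_neg,
#'   aPRS_low_FH_pos, aPRS_int_FH_pos, aPRS_high_FH_neg, aPRS_high_FH_pos.
#' @export
joint_fh_groups <- function(groups, fh) {
  stopifnot(length(groups) == length(fh))
  if (!all(stats::na.omit(fh) %in% c(0, 1)))
    stop("fh must be coded 0/1")
  n_missing <- sum(is.na(fh) | is.na(groups))
  if (n_missing > 0)
    message(n_missing, " sample(s) with missing FH or group set to NA")
  short <- c(low = "low", intermediate = "int", high = "high")
  lab <- paste0("aPRS_", short[as.character(groups)],
                "_FH_", ifelse(fh == 1, "pos", "neg"))
  lab[is.na(fh) | is.na(groups)] <- NA
  factor(lab, levels = c("aPRS_int_FH_neg", "aPRS_low_FH_neg",
                         "aPRS_low_FH_pos", "aPRS_int_FH_pos",
                         "aPRS_high_FH_neg", "aPRS_high_FH_pos"))
}
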