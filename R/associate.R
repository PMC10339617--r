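#' Fit a logistic association model
#'
#' Maximum-likelihood logistic regression of a binary outcome on the supplied
#' covariate columns (e.g. `aPRS + sex + age + PC1..PC4`), with Wald standard
#' errors from the observed information. Odds ratios are `exp(beta)` with
#' 95% Wald confidence intervals; p-values below 0.01 are flagged with two
#' stars in the printed report.
#'
#' @param outcome 0/1 vector.
#' @param design data.frame of covariates (factors are dummy-coded against
#'   their first level).
#' @return An object of class `model_fit`: `table` (term, estimate, se, or,
#'   ci_low, ci_high, p), `loglik`, `n`, `converged`, and the underlying
#'   `glm` object for prediction.
#' @export
fit_logistic <- function(outcome, design) {
  design <- as.data.frame(design)
  if (!all(stats::na.omit(outcome) %in% c(0, 1)))
    stop("outcome must be coded 0/1")
  if (nrow(design) != length(outcome))
    stop("design rows must match outcome length")
  keep <- (if (ncol(design)) stats::complete.cases(design) else TRUE) &
    !is.na(outcome)
  design <- design[keep, , drop = FALSE]
  outcome <- outcome[keep]
  if (length(outcome) <= ncol(design) + 1)
    stop("too few complete observations for the design")
  dat <- if (ncol(design)) cbind(.y = outcome, design)
         else data.frame(.y = outcome)
  sep_warn <- FALSE
  fit <- withCallingHandlers(
    stats::glm(.y ~ ., data = dat, family = stats::binomial(),
               control = stats::glm.control(epsilon = 1e-8, maxit = 100)),
    warning = function(w) {
      if (grepl("fitted probabilities numerically 0 or 1", conditionMessage(w)))
        sep_warn <<- TRUE
      invokeRestart("muffleWarning")
    })
  if (anyNA(stats::coef(fit))) {
    bad <- names(stats::coef(fit))[is.na(stats::coef(fit))]
    stop("design is rank deficient; aliased term(s): ",
         paste(bad, collapse = ", "))
  }
  # a diverging slope (with or without R's fitted-probability warning) marks
  # complete or quasi-complete separation
  co_slopes <- stats::coef(fit)[-1]
  if (length(co_slopes) && any(abs(co_slopes) > 15)) {
    stop("complete or quasi-complete separation detected; ",
         "separating term: ", names(co_slopes)[which.max(abs(co_slopes))])
  }
  if (!fit$converged)
    stop("logistic fit did not converge within ", fit$iter, " iterations")
  s <- summary(fit)$coefficients
  tab <- data.frame(
    term = rownames(s),
    estimate = s[, "Estimate"],
    se = s[, "Std. Error"],
    or = exp(s[, "Estimate"]),
    ci_low = exp(s[, "Estimate"] - 1.96 * s[, "Std. Error"]),
    ci_high = exp(s[, "Estimate"] + 1.96 * s[, "Std. Error"]),
    p = s[, "Pr(>|z|)"],
    row.names = NULL, stringsAsFactors = FALSE)
  structure(list(table = tab, loglik = as.numeric(stats::logLik(fit)),
                 n = length(outcome), converged = fit$converged, glm = fit),
            class = "model_fit")
}

#' @export
print.model_fit <- function(x, digits = 3, ...) {
  tab <- x$table
  out <- data.frame(term = tab$term,
                    OR = signif(tab$or, digits),
                    CI = sprintf("[%.*g-%.*g]", digits, tab$ci_low,
                                 digits, tab$ci_high),
                    p = signif(tab$p, 2),
                    sig = ifelse(tab$p < 0.01, "**", ""))
  cat("logistic model fit (n =", x$n, ", logLik =",
      round(x$loglik, 2), ")\n")
  print(out, row.names = FALSE)
  invisible(x)
}

#' Fit the three-level percentile-group model
#'
#' Logistic model with the score group (low / intermediate / high) dummy
#' coded against the `intermediate` reference, plus any further covariates.
#' Reported ORs compare the low and high groups against intermediate.
#'
#' @param outcome 0/1 vector.
#' @param groups factor from [percentile_groups()].
#' @param covariates optional data.frame of additional columns.
#' @return A `model_fit`.
#' @export
fit_group_model <- function(outcome, groups, covariates = NULL) {
  groups <- factor(groups)
  empty <- setdiff(c("low", "intermediate", "high"), levels(droplevels(groups)))
  if (length(empty))
    stop("empty score group level(s): ", paste(empty, collapse = ", "))
  g <- stats::relevel(droplevels(groups), ref = "intermediate")
  design <- data.frame(group = g)
  if (!is.null(covariates)) design <- cbind(design, covariates)
  fit_logistic(outcome, design)
}

#' Fit the joint score-group-by-family-history model
#'
#' Logistic model on the six-level joint factor (reference: intermediate
#' score, negative FH) plus covariates. Joint cells absent from the data are
#' dropped from the dummy coding with a warning.
#'
#' @param outcome 0/1 vector.
#' @param joint factor from [joint_fh_groups()].
#' @param covariates optional data.frame of additional columns.
#' @return A `model_fit`.
#' @export
fit_fh_joint_model <- function(outcome, joint, covariates = NULL) {
  if (!is.factor(joint))
    joint <- factor(joint, levels = c("aPRS_int_FH_neg", "aPRS_low_FH_neg",
                                      "aPRS_low_FH_pos", "aPRS_int_FH_pos",
                                      "aPRS_high_FH_neg", "aPRS_high_FH_pos"))
  present <- levels(droplevels(joint))
  absent <- setdiff(levels(joint), present)
  if (length(absent))
    warning("empty joint group cell(s) dropped from the model: ",
            paste(absent, collapse = ", "))
  if (!"aPRS_int_FH_neg" %in% present)
    stop("reference cell aPRS_int_FH_neg is empty")
  g <- stats::relevel(droplevels(joint), ref = "aPRS_int_FH_neg")
  design <- data.frame(joint = g)
  if (!is.null(covariates)) design <- cbind(design, covariates)
  fit_logistic(outcome, design)
}

#' Likelihood-ratio test for score-group by family-history interaction
#'
#' Compares the additive logistic model (group + FH + covariates) against the
#' model with group-by-FH product terms.
#'
#' @param outcome 0/1 vector.
#' @param groups factor from [percentile_groups()].
#' @param fh 0/1 family-history flags.
#' @param covariates optional data.frame of additional columns.
#' @return list with `statistic`, `df`, `p`.
#' @export
interaction_lrt <- function(outcome, groups, fh, covariates = NULL) {
  g <- stats::relevel(factor(groups), ref = "intermediate")
  base <- data.frame(group = g, fh = fh)
  if (!is.null(covariates)) base <- cbind(base, covariates)
  fit0 <- fit_logistic(outcome, base)
  full <- base
  gm <- stats::model.matrix(~ group, data = base)[, -1, drop = FALSE]
  for (j in colnames(gm)) full[[paste0(j, "_x_fh")]] <- gm[, j] * fh
  fit1 <- fit_logistic(outcome, full)
  stat <- 2 * (fit1$loglik - fit0$loglik)
  df <- nrow(fit1$table) - nrow(fit0$table)
  list(statistic = stat, df = df,
       p = stats::pchisq(stat, df, lower.tail = FALSE))
}

#' Crude odds ratio from a 2x2 table
#'
#' `OR = a d / (b c)` with a 95% CI from `log(OR) +/- 1.96 *
#' sqrt(1/a + 1/b + 1/c + 1/d)`. A single zero cell triggers the
#' Haldane--Anscombe 0.5 correction (flagged); two zero cells in one margin
#' leave the OR undefined.
#'
#' @param a exposed cases.
#' @param b unexposed cases.
#' @param c exposed controls.
#' @param d unexposed controls.
#' @return list with `or`, `ci_low`, `ci_high`, `corrected`.
#' @export
crude_or_2x2 <- function(a, b, c, d) {
  counts <- c(a = a, b = b, c = c, d = d)
  if (any(counts < 0)) stop("counts must be >= 0")
  if ((a == 0 && b == 0) || (c == 0 && d == 0) ||
      (a == 0 && c == 0) || (b == 0 && d == 0))
    stop("two zero cells in one margin: odds ratio undefined")
  corrected <- any(counts == 0)
  if (corrected) counts <- counts + 0.5
  or <- counts["a"] * counts["d"] / (counts["b"] * counts["c"])
  se <- sqrt(sum(1 / counts))
  list(or = unname(or),
       ci_low = unname(or * exp(-1.96 * se)),
       ci_high = unname(or * exp(1.96 * se)),
       corrected = corrected)
}

#' Stratified train/test split
#'
#' Randomly divides samples into training (default 75%) and testing (25%)
#' sets, stratified by outcome so both sets contain cases and controls.
#'
#' @param outcome 0/1 vector.
#' @param train_fraction fraction assigned to training (default 0.75).
#' @param seed RNG seed.
#' @return list with integer index vectors `train` and `test`.
#' @export
split_train_test <- function(outcome, train_fraction = 0.75, seed = 1) {
  n <- length(outcome)
  if (n < 8) stop("need n >= 8 to split")
  if (!all(outcome %in% c(0, 1))) stop("outcome must be coded 0/1")
  train <- with_substream(seed, "split", {
    idx <- integer(0)
    for (cls in c(0, 1)) {
      i <- which(outcome == cls)
      k <- round(train_fraction * length(i))
      idx <- c(idx, sample(i, k))
    }
    sort(idx)
  })
  test <- setdiff(seq_len(n), train)
  for (set in list(train = train, test = test)) {
    if (sum(outcome[set]) == 0 || sum(outcome[set]) == length(set))
      stop("a split contains a single outcome class; ",
           "change the stratification seed or fractions")
  }
  list(train = train, test = sort(test))
}

#' Rank-based AUROC (Mann--Whitney)
#'
#' `AUROC = U / (n1 n0)` computed from midranks, so tied predictions count
#' one half.
#'
#' @param scores numeric prediction vector.
#' @param labels 0/1 outcome vector.
#' @return AUROC in [0, 1].
#' @export
auroc <- function(scores, labels) {
  stopifnot(length(scores) == length(labels))
  n1 <- sum(labels == 1); n0 <- sum(labels == 0)
  if (n1 == 0 || n0 == 0) stop("both classes required for AUROC")
  r <- rank(scores)
  (sum(r[labels == 1]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}

# DeLong variance of the AUROC via placement values.
auroc_ci <- function(scores, labels, level = 0.95) {
  auc <- auroc(scores, labels)
  cases <- scores[labels == 1]; controls <- scores[labels == 0]
  n1 <- length(cases); n0 <- length(controls)
  psi_case <- vapply(cases, function(x)
    mean((x > controls) + 0.5 * (x == controls)), numeric(1))
  psi_ctrl <- vapply(controls, function(y)
    mean((cases > y) + 0.5 * (cases == y)), numeric(1))
  v <- stats::var(psi_case) / n1 + stats::var(psi_ctrl) / n0
  z <- stats::qnorm(1 - (1 - level) / 2)
  c(auc = auc,
    ci_low = max(0, auc - z * sqrt(v)),
    ci_high = min(1, auc + z * sqrt(v)))
}

#' Area under the precision-recall curve
#'
#' Step-interpolated integration: thresholds sweep the distinct prediction
#' values from high to low and each recall increment contributes the
#' precision at that threshold.
#'
#' @inheritParams auroc
#' @return AUPRC in [0, 1].
#' @export
auprc <- function(scores, labels) {
  stopifnot(length(scores) == length(labels))
  n1 <- sum(labels == 1)
  if (n1 == 0 || n1 == length(labels)) stop("both classes required for AUPRC")
  ord <- order(scores, decreasing = TRUE)
  s <- scores[ord]; y <- labels[ord]
  tp <- cumsum(y); fp <- cumsum(1 - y)
  last <- c(s[-1] != s[-length(s)], TRUE) # group tied thresholds
  tp <- tp[last]; fp <- fp[last]
  precision <- tp / (tp + fp)
  recall <- tp / n1
  sum(diff(c(0, recall)) * precision)
}

#' Evaluate model discrimination on held-out data
#'
#' Predicts case probabilities on the test set with a fitted logistic model
#' and reports AUROC (with a DeLong 95% CI) and step-interpolated AUPRC.
#'
#' @param fit a `model_fit` from [fit_logistic()] or relatives.
#' @param test_design data.frame of test-set covariates (same columns the
#'   model was fitted on).
#' @param test_outcome 0/1 test-set outcomes.
#' @return list with `auroc`, `auroc_ci`, `auprc`, `n_test`, `prevalence`.
#' @export
evaluate_discrimination <- function(fit, test_design, test_outcome) {
  stopifnot(inherits(fit, "model_fit"))
  if (length(unique(test_outcome)) < 2)
    stop("test set contains a single outcome class")
  pred <- stats::predict(fit$glm, newdata = as.data.frame(test_design),
                         type = "response")
  ci <- auroc_ci(pred, test_outcome)
  list(auroc = unname(ci["auc"]),
       auroc_ci = unname(ci[c("ci_low", "ci_high")]),
       auprc = auprc(pred, test_outcome),
       n_test = length(test_outcome),
       prevalence = mean(test_outcome))
}

#' Downsample a table to a target case:control ratio
#'
#' Randomly removes samples from the over-represented side (seeded) until the
#' realized case:control ratio matches the target within one sample, for
#' comparing model performance across cohorts with different base rates.
#'
#' @param table data.frame with a case column.
#' @param case_col name of the 0/1 case column.
#' @param target_ratio target cases-per-control ratio (e.g. `1/9`).
#' @param seed RNG seed.
#' @return The subsampled data.frame.
#' @export
downsample_to_ratio <- function(table, case_col, target_ratio, seed = 1) {
  y <- table[[case_col]]
  if (is.null(y)) stop("no column '", case_col, "' in table")
  n_case <- sum(y == 1); n_ctrl <- sum(y == 0)
  if (n_case == 0 || n_ctrl == 0) stop("both classes required")
  current <- n_case / n_ctrl
  if (abs(current - target_ratio) < .Machine$double.eps * 4) return(table)
  with_substream(seed, "downsample", {
    if (current > target_ratio) {
      keep_cases <- round(target_ratio * n_ctrl)
      if (keep_cases < 1)
        stop("unachievable target: would remove every case")
      drop <- sample(which(y == 1), n_case - keep_cases)
    } else {
      keep_ctrl <- round(n_case / target_ratio)
      if (keep_ctrl < 1)
        stop("unachievable target: would remove every control")
      drop <- sample(which(y == 0), n_ctrl - keep_ctrl)
    }
    table[-drop, , drop = FALSE]
  })
}
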