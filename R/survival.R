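#' Fit a Cox proportional-hazards model on the age scale
#'
#' Partial-likelihood maximization with Efron handling of tied event times
#' (ages are coarse, so ties are expected). Time is age: diagnosis age for
#' events, age at the most recent visit for censored controls. Constant
#' covariate columns are dropped with a warning; monotone likelihood
#' (an infinite coefficient) is an error naming the covariate.
#'
#' @param time positive event/censoring ages.
#' @param event 0/1 event indicators (>= 2 events required).
#' @param design data.frame of covariates; factors are dummy coded.
#' @return An object of class `cox_fit`: `table` (term, estimate, se, hr,
#'   ci_low, ci_high, p), `basehaz` (Breslow-type baseline cumulative hazard
#'   at the reference covariate level), `n`, `n_event`, the fitted
#'   `survival::coxph` object, and the model data.
#' @export
fit_cox <- function(time, event, design) {
  design <- as.data.frame(design)
  if (any(time <= 0)) stop("event/censoring times must be > 0")
  if (!all(event %in% c(0, 1))) stop("event must be coded 0/1")
  if (sum(event) < 2) stop("need at least 2 events")
  constant <- vapply(design, function(x) length(unique(x)) == 1L, logical(1))
  if (any(constant)) {
    warning("dropping constant covariate(s): ",
            paste(names(design)[constant], collapse = ", "))
    design <- design[, !constant, drop = FALSE]
  }
  if (ncol(design) == 0) stop("no non-constant covariates")
  # unused factor levels would enter as all-zero dummy columns; drop them but
  # remember the full level sets so curve construction can report omissions
  full_levels <- list()
  for (nm in names(design)) {
    if (is.factor(design[[nm]])) {
      full_levels[[nm]] <- levels(design[[nm]])
      design[[nm]] <- droplevels(design[[nm]])
    }
  }
  dat <- cbind(data.frame(.time = time, .event = event), design)
  inf_warn <- character(0)
  fit <- withCallingHandlers(
    survival::coxph(survival::Surv(.time, .event) ~ ., data = dat,
                    ties = "efron", model = TRUE, x = TRUE),
    warning = function(w) {
      msg <- conditionMessage(w)
      if (grepl("infinite", msg)) inf_warn <<- c(inf_warn, msg)
      invokeRestart("muffleWarning")
    })
  co <- stats::coef(fit)
  if (length(inf_warn) || any(!is.finite(co)) || any(abs(co) > 15)) {
    bad <- names(co)[which.max(abs(co))]
    stop("monotone likelihood (coefficient diverging) for covariate: ", bad)
  }
  s <- summary(fit)$coefficients
  tab <- data.frame(
    term = rownames(s),
    estimate = s[, "coef"],
    se = s[, "se(coef)"],
    hr = exp(s[, "coef"]),
    ci_low = exp(s[, "coef"] - 1.96 * s[, "se(coef)"]),
    ci_high = exp(s[, "coef"] + 1.96 * s[, "se(coef)"]),
    p = s[, "Pr(>|z|)"],
    row.names = NULL, stringsAsFactors = FALSE)
  bh <- survival::basehaz(fit, centered = FALSE)
  structure(list(table = tab, basehaz = bh, n = nrow(dat),
                 n_event = sum(event), coxph = fit, data = dat,
                 full_levels = full_levels),
            class = "cox_fit")
}

#' @export
print.cox_fit <- function(x, digits = 3, ...) {
  cat("Cox proportional-hazards fit (n =", x$n, ",", x$n_event, "events)\n")
  tab <- x$table
  print(data.frame(term = tab$term, HR = signif(tab$hr, digits),
                   CI = sprintf("[%.*g-%.*g]", digits, tab$ci_low,
                                digits, tab$ci_high),
                   p = signif(tab$p, 2),
                   sig = ifelse(tab$p < 0.01, "**", "")),
        row.names = FALSE)
  invisible(x)
}

#' Schoenfeld tests of the proportional-hazards assumption
#'
#' Per-covariate tests based on the correlation of scaled Schoenfeld
#' residuals with event time (identity time transform, pinned for
#' determinism) plus the global chi-square test.
#'
#' @param fit a `cox_fit`.
#' @return data.frame with columns term, chisq, df, p; the last row is the
#'   GLOBAL test.
#' @export
test_proportional_hazards <- function(fit) {
  stopifnot(inherits(fit, "cox_fit"))
  if (fit$n_event < 3) stop("need at least 3 events to test PH")
  z <- survival::cox.zph(fit$coxph, transform = "identity", global = TRUE)
  data.frame(term = rownames(z$table),
             chisq = z$table[, "chisq"],
             df = z$table[, "df"],
             p = z$table[, "p"],
             row.names = NULL, stringsAsFactors = FALSE)
}

#' Covariate-adjusted cumulative incidence by stratum
#'
#' For each level of the stratum factor, evaluates `1 - S(t)` from the Cox
#' fit at the covariate pattern "this stratum, every other covariate at its
#' cohort mean" (the conditional-at-means convention) over a grid of ages.
#' Strata absent from the fitted data are omitted with a warning.
#'
#' @param fit a `cox_fit` whose design contains exactly one factor column
#'   (the stratum), or name it via `group_col`.
#' @param eval_ages ages at which to evaluate the curves.
#' @param group_col optional name of the stratum column.
#' @return data.frame with columns group, age, incidence; curves are
#'   non-decreasing in age and bounded in [0, 1].
#' @export
adjusted_cumulative_incidence <- function(fit, eval_ages = seq(40, 80, by = 1),
                                          group_col = NULL) {
  stopifnot(inherits(fit, "cox_fit"))
  dat <- fit$data
  covs <- dat[, setdiff(names(dat), c(".time", ".event")), drop = FALSE]
  fac <- vapply(covs, is.factor, logical(1))
  if (is.null(group_col)) {
    if (sum(fac) != 1)
      stop("specify group_col: design has ", sum(fac), " factor columns")
    group_col <- names(covs)[fac]
  }
  g <- covs[[group_col]]
  levels_all <- fit$full_levels[[group_col]] %||% levels(g)
  present <- levels(droplevels(g))
  absent <- setdiff(levels_all, present)
  if (length(absent))
    warning("stratum level(s) absent from the data, curve omitted: ",
            paste(absent, collapse = ", "))
  newdata <- covs[rep(1L, length(present)), , drop = FALSE]
  for (nm in names(covs)) {
    if (nm == group_col) {
      newdata[[nm]] <- factor(present, levels = present)
    } else if (is.numeric(covs[[nm]])) {
      newdata[[nm]] <- mean(covs[[nm]])
    } else {
      # non-stratum factor: most frequent level
      newdata[[nm]] <- names(which.max(table(covs[[nm]])))
    }
  }
  sf <- survival::survfit(fit$coxph, newdata = newdata)
  out <- do.call(rbind, lapply(seq_along(present), function(i) {
    surv <- if (is.matrix(sf$surv)) sf$surv[, i] else sf$surv
    step <- stats::stepfun(sf$time, c(1, surv), right = FALSE)
    data.frame(group = present[i], age = eval_ages,
               incidence = pmin(pmax(1 - step(eval_ages), 0), 1),
               stringsAsFactors = FALSE)
  }))
  rownames(out) <- NULL
  out
}
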