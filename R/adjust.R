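#' Ancestry-adjust a polygenic risk score by PC residualization
#'
#' Fits one pooled least-squares regression of the score on an intercept and
#' the supplied principal components (by default the first four), subtracts
#' the fitted values, and standardizes the residual: aPRS =
#' standardize(PRS - predicted PRS). Residuals are orthogonal to every PC by
#' construction; constant PC columns are dropped with a warning so degenerate
#' toy inputs still run.
#'
#' @param prs numeric score vector (raw or standardized; the result is
#'   invariant to positive affine transforms of the input).
#' @param pcs matrix or data.frame of PC coordinates, one row per sample.
#' @return Numeric aPRS vector (mean 0, sd 1, population convention) with
#'   attributes `coefficients` (intercept + PC slopes) and `dropped`
#'   (names of constant columns removed).
#' @export
adjust_prs <- function(prs, pcs) {
  pcs <- as.matrix(pcs)
  n <- length(prs)
  if (nrow(pcs) != n) stop("pcs must have one row per score")
  if (is.null(colnames(pcs))) colnames(pcs) <- paste0("PC", seq_len(ncol(pcs)))
  constant <- apply(pcs, 2, function(x) max(x) - min(x) == 0)
  dropped <- colnames(pcs)[constant]
  if (length(dropped)) {
    warning("dropping constant PC column(s): ", paste(dropped, collapse = ", "))
    pcs <- pcs[, !constant, drop = FALSE]
  }
  X <- cbind(`(Intercept)` = 1, pcs)
  if (n <= ncol(X))
    stop("need more samples than regression columns (n = ", n,
         ", columns = ", ncol(X), ")")
  qr_x <- qr(X)
  if (qr_x$rank < ncol(X)) {
    bad <- colnames(X)[qr_x$pivot[seq(qr_x$rank + 1L, ncol(X))]]
    stop("PC design matrix is rank deficient; collinear column(s): ",
         paste(bad, collapse = ", "))
  }
  beta <- qr.coef(qr_x, prs)
  resid <- prs - as.numeric(X %*% beta)
  if (sqrt(mean((resid - mean(resid))^2)) < 1e-12 * max(1, stats::sd(prs)))
    stop("zero residual variance: score is an exact linear function of the PCs")
  aprs <- standardize(resid)
  attr(aprs, "coefficients") <- beta
  attr(aprs, "dropped") <- dropped
  aprs
}

#' Fraction of each population above a cohort-wide percentile threshold
#'
#' Computes the cohort-wide empirical percentile threshold of the chosen
#' score and reports, per population, the fraction of samples strictly above
#' it. Before adjustment, structured scores place the populations on opposite
#' sides of the threshold; after PC residualization each population's
#' fraction returns to roughly `1 - threshold_percentile/100`.
#'
#' @param scores numeric score vector (raw PRS or aPRS).
#' @param labels population label per sample.
#' @param threshold_percentile cohort-wide percentile defining "high" (default
#'   80, i.e. the top quintile).
#' @return Named numeric vector: per-population fraction above the threshold.
#' @export
high_prs_fraction <- function(scores, labels, threshold_percentile = 80) {
  stopifnot(length(scores) == length(labels))
  if (length(unique(labels)) < 2)
    stop("need at least two populations to compare")
  thr <- empirical_percentile(scores, threshold_percentile)
  vapply(split(scores, labels), function(x) mean(x > thr), numeric(1))
}
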