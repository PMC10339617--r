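#' Fit a principal-component model on a reference panel
#'
#' Standard genotype PCA: each variant is centered by its mean reference
#' dosage (2 p-hat) and scaled by sqrt(2 p-hat (1 - p-hat)) with p-hat the
#' reference effect-allele frequency; monomorphic variants are dropped; the
#' loadings come from the singular value decomposition of the standardized
#' matrix. Per-population centroids of the reference scores support nearest-
#' centroid ancestry assignment of projected study samples.
#'
#' @param reference a [genotype_set()] with population labels.
#' @param K number of components to retain (default 4, the number used by
#'   all downstream adjustment and association models).
#' @return An object of class `pc_model`: variant ids, centers, scales,
#'   loadings (variants x K), component variances, reference scores, and
#'   population centroids.
#' @export
fit_reference_pca <- function(reference, K = 4) {
  stopifnot(inherits(reference, "genotype_set"))
  if (is.null(reference$population))
    stop("reference panel must carry population labels")
  X <- reference$dosages
  n <- nrow(X)
  if (n < K + 1) stop("reference needs at least K + 1 samples")
  p_hat <- colMeans(X, na.rm = TRUE) / 2
  informative <- p_hat > 0 & p_hat < 1
  if (sum(informative) < K)
    stop("fewer informative (polymorphic) variants than K = ", K)
  X <- X[, informative, drop = FALSE]
  p_hat <- p_hat[informative]
  center <- 2 * p_hat
  scale <- sqrt(2 * p_hat * (1 - p_hat))
  Z <- sweep(sweep(X, 2, center), 2, scale, "/")
  sv <- svd(Z, nu = 0, nv = K)
  loadings <- sv$v
  colnames(loadings) <- paste0("PC", seq_len(K))
  scores <- Z %*% loadings
  rownames(scores) <- reference$sample_ids
  centroids <- do.call(rbind, lapply(split(seq_len(n), reference$population),
                                     function(i) colMeans(scores[i, , drop = FALSE])))
  model <- structure(list(
    variant_id = colnames(X),
    center = center,
    scale = scale,
    loadings = loadings,
    variances = (sv$d[seq_len(K)]^2) / (n - 1),
    scores = scores,
    centroids = centroids,
    populations = reference$population), class = "pc_model")
  model
}

#' @export
print.pc_model <- function(x, ...) {
  cat("pc_model:", length(x$variant_id), "variants,",
      ncol(x$loadings), "components,",
      nrow(x$centroids), "reference populations\n")
  cat("component variances:", signif(x$variances, 4), "\n")
  invisible(x)
}

#' Project study samples into a reference PC space
#'
#' Study dosages are standardized with the reference means and scales (never
#' recomputed on the study data) and multiplied by the reference loadings.
#' Model variants absent from the study contribute zero after centering.
#'
#' @param model a `pc_model` from [fit_reference_pca()].
#' @param study a [genotype_set()].
#' @return Matrix of PC coordinates (samples x K).
#' @export
project_samples <- function(model, study) {
  stopifnot(inherits(model, "pc_model"), inherits(study, "genotype_set"))
  K <- ncol(model$loadings)
  common <- intersect(model$variant_id, study$variants$id)
  if (length(common) < K)
    stop("fewer than K = ", K, " variants overlap the PC model")
  mi <- match(common, model$variant_id)
  D <- study$dosages[, common, drop = FALSE]
  # missing dosages contribute 0 after centering, like absent variants
  if (anyNA(D)) {
    for (j in seq_along(common)) {
      miss <- is.na(D[, j])
      if (any(miss)) D[miss, j] <- model$center[mi[j]]
    }
  }
  Z <- sweep(sweep(D, 2, model$center[mi]), 2, model$scale[mi], "/")
  scores <- Z %*% model$loadings[mi, , drop = FALSE]
  rownames(scores) <- study$sample_ids
  scores
}

#' Assign ancestry by nearest reference centroid
#'
#' Each sample gets the label of the nearest reference population centroid in
#' Euclidean distance over the first K components. Exact ties break to the
#' lexicographically first label and are reported.
#'
#' @param coordinates PC coordinate matrix from [project_samples()].
#' @param model the `pc_model` providing the centroids.
#' @return data.frame with columns sample_id, ancestry, distance, tie.
#' @export
assign_ancestry <- function(coordinates, model) {
  stopifnot(inherits(model, "pc_model"))
  cen <- model$centroids[order(rownames(model$centroids)), , drop = FALSE]
  d2 <- vapply(seq_len(nrow(cen)), function(i) {
    rowSums(sweep(coordinates, 2, cen[i, ])^2)
  }, numeric(nrow(coordinates)))
  d2 <- matrix(d2, nrow = nrow(coordinates))
  best <- max.col(-d2, ties.method = "first")
  dist_best <- sqrt(d2[cbind(seq_len(nrow(d2)), best)])
  tie <- vapply(seq_len(nrow(d2)), function(i) {
    sum(d2[i, ] == d2[i, best[i]]) > 1L
  }, logical(1))
  if (any(tie))
    message(sum(tie), " sample(s) equidistant between centroids; ",
            "tie broken by lexicographic label order")
  data.frame(sample_id = rownames(coordinates) %||% seq_len(nrow(d2)),
             ancestry = rownames(cen)[best],
             distance = dist_best,
             tie = tie,
             stringsAsFactors = FALSE)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
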