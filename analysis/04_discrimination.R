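#!/usr/bin/env Rscript
# Stage 4: model discrimination on held-out data. 75/25 stratified split per
# population; AUROC (DeLong CI) and AUPRC for covariates-only versus
# covariates + aPRS, and a downsampled rerun that equalizes the case:control
# ratio across populations.

source("analysis/00_config.R")

cohort <- build_cohort()
sc <- score_cohort(cohort)
cov <- cohort$covariates
cov$aprs <- sc$aprs
pcs <- sc$pcs

eval_pop <- function(idx, label) {
  y <- cov$case_cad[idx]
  X_cov <- data.frame(sex = cov$sex[idx], age = cov$age[idx], pcs[idx, ])
  X_full <- cbind(data.frame(aprs = cov$aprs[idx]), X_cov)
  split <- split_train_test(y, 0.75,
                            seed = substream_seed(MASTER_SEED,
                                                  paste0("split.", label)))
  out <- lapply(list(covariates = X_cov, with_aprs = X_full), function(X) {
    fit <- fit_logistic(y[split$train], X[split$train, ])
    evaluate_discrimination(fit, X[split$test, ], y[split$test])
  })
  data.frame(population = label,
             model = names(out),
             auroc = round(vapply(out, `[[`, 0, "auroc"), 4),
             auroc_lo = round(vapply(out, function(e) e$auroc_ci[1], 0), 4),
             auroc_hi = round(vapply(out, function(e) e$auroc_ci[2], 0), 4),
             auprc = round(vapply(out, `[[`, 0, "auprc"), 4),
             n_test = out[[1]]$n_test)
}

res <- do.call(rbind, lapply(unique(cov$population), function(p)
  eval_pop(which(cov$population == p), p)))
write_tsv(res, "04_discrimination.tsv")
print(res, row.names = FALSE)

# downsample the higher-prevalence population to the other's case:control
# ratio and re-evaluate
rates <- tapply(cov$case_cad, cov$population, function(y) sum(y) / sum(1 - y))
hi <- names(which.max(rates)); lo <- names(which.min(rates))
idx_hi <- which(cov$population == hi)
dsub <- downsample_to_ratio(data.frame(row = idx_hi, case = cov$case_cad[idx_hi]),
                            "case", unname(rates[lo]),
                            seed = substream_seed(MASTER_SEED, "downsample"))
res_ds <- eval_pop(dsub$row, paste0(hi, "_downsampled"))
write_tsv(res_ds, "04_discrimination_downsampled.tsv")
print(res_ds, row.names = FALSE)
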