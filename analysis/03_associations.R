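#!/usr/bin/env Rscript
# Stage 3: the association models, per population. (i) continuous aPRS with
# age, sex and four PCs; (ii) aPRS percentile groups (low/intermediate/high,
# within-population percentiles, intermediate as reference); (iii) the six
# joint aPRS-by-family-history groups; plus the group-by-FH interaction test
# and crude 2x2 family-history odds ratios.

source("analysis/00_config.R")

cohort <- build_cohort()
sc <- score_cohort(cohort)
cov <- cohort$covariates
cov$aprs <- sc$aprs
pcs <- sc$pcs

cov$aprs_group <- percentile_groups(cov$aprs, cov$population,
                                    reference = "within_population")
cov$joint_group <- joint_fh_groups(cov$aprs_group, cov$fh_cad)

rows <- list()
for (popn in unique(cov$population)) {
  i <- cov$population == popn
  covars <- data.frame(sex = cov$sex[i], age = cov$age[i], pcs[i, ])

  fit_cont <- fit_logistic(cov$case_cad[i],
                           cbind(data.frame(aprs = cov$aprs[i]), covars))
  fit_grp <- fit_group_model(cov$case_cad[i], cov$aprs_group[i], covars)
  fit_joint <- fit_fh_joint_model(cov$case_cad[i], cov$joint_group[i], covars)
  lrt <- interaction_lrt(cov$case_cad[i], cov$aprs_group[i], cov$fh_cad[i],
                         covars)
  message(popn, ": aPRS-by-FH interaction LRT p = ", signif(lrt$p, 3))

  for (m in list(c("continuous", "fit_cont"), c("groups", "fit_grp"),
                 c("fh_joint", "fit_joint"))) {
    tab <- get(m[2])$table
    keep <- grepl("aprs|group|joint", tab$term)
    rows[[paste(popn, m[1])]] <- cbind(population = popn, model = m[1],
                                       tab[keep, ])
  }
}
or_table <- do.call(rbind, rows)
or_table[, c("estimate", "se", "or", "ci_low", "ci_high")] <-
  round(or_table[, c("estimate", "se", "or", "ci_low", "ci_high")], 4)
or_table$p <- signif(or_table$p, 3)
write_tsv(or_table, "03_odds_ratios.tsv")
print(or_table[or_table$model == "groups", ], row.names = FALSE)

# crude FH association per population
fh_rows <- lapply(unique(cov$population), function(popn) {
  d <- cov[cov$population == popn, ]
  t2 <- table(fh = d$fh_cad, case = d$case_cad)
  res <- crude_or_2x2(t2["1", "1"], t2["0", "1"], t2["1", "0"], t2["0", "0"])
  data.frame(population = popn, or = round(res$or, 3),
             ci_low = round(res$ci_low, 3), ci_high = round(res$ci_high, 3))
})
fh_tab <- do.call(rbind, fh_rows)
write_tsv(fh_tab, "03_fh_crude_or.tsv")
print(fh_tab, row.names = FALSE)
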