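#!/usr/bin/env Rscript
# Stage 1: simulate the study cohort and its paired reference panel, write
# the standard-format artifacts (VCF, dosage matrix, PGS-dialect scoring
# file, covariate table, relatedness pairs), and summarize the cohort the
# way a recruitment table would.

source("analysis/00_config.R")

cohort <- build_cohort()
write_cohort(cohort, DATA_DIR)

panel <- simulate_reference_panel(STUDY_SPECS, STUDY_CONFIG, n_samples = 500)
write_vcf(panel, file.path(DATA_DIR, "reference_panel.vcf"))

pairs <- simulate_relatedness_pairs(cohort$covariates$sample_id, 40,
                                    seed = substream_seed(MASTER_SEED, "pairs"))
write_relatedness_pairs(pairs, file.path(DATA_DIR, "relatedness.tsv"))

cov <- cohort$covariates
summarize_pop <- function(d) {
  data.frame(n = nrow(d),
             cases = sum(d$case_cad),
             case_pct = round(100 * mean(d$case_cad), 1),
             male_pct = round(100 * mean(d$sex), 1),
             age_mean = round(mean(d$age), 1),
             fh_pct = round(100 * mean(d$fh_cad), 1))
}
tab1 <- do.call(rbind, lapply(split(cov, cov$population), summarize_pop))
tab1 <- cbind(population = rownames(tab1), tab1)
write_tsv(tab1, "01_cohort_characteristics.tsv")

message("cohort: ", nrow(cov), " samples, ",
        ncol(cohort$genotypes$dosages), " variants; case fraction ",
        round(mean(cov$case_cad), 3))
print(tab1, row.names = FALSE)
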