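# Shared settings for the analysis scripts. Every script can be run on its
# own; stages that need the simulated cohort re-derive it deterministically
# from MASTER_SEED through the package's named RNG substreams.

library(aprs)

MASTER_SEED <- as.integer(Sys.getenv("APRS_SEED", "1"))

# study conditions: two populations with moderate differentiation, a
# published-score analogue whose weights are correlated with the
# between-population frequency differences (the non-portable case)
STUDY_SPECS <- list(population_spec("EUR", 5000, fst = 0.1),
                    population_spec("SAS", 5000, fst = 0.1))
STUDY_CONFIG <- sim_config(n_variants = 1000,
                           weight_freq_cor = 0.05,
                           prevalence = 0.1,
                           beta_prs = 0.5,
                           seed = MASTER_SEED)

DATA_DIR <- "scratch/data"     # bulky simulated artifacts (VCF, dosages)
RESULTS_DIR <- "results"       # small derived tables
dir.create(DATA_DIR, showWarnings = FALSE, recursive = TRUE)
dir.create(RESULTS_DIR, showWarnings = FALSE, recursive = TRUE)

write_tsv <- function(x, name) {
  path <- file.path(RESULTS_DIR, name)
  utils::write.table(x, path, sep = "\t", quote = FALSE, row.names = FALSE)
  message("wrote ", path)
  invisible(path)
}

# rebuild the fully annotated study cohort (genotypes, phenotype, family
# history) — cheap enough to recompute rather than serialize between stages
build_cohort <- function() {
  cohort <- simulate_study_cohort(STUDY_SPECS, STUDY_CONFIG)
  cohort <- simulate_phenotype(cohort, STUDY_CONFIG)
  simulate_family_history(cohort, STUDY_CONFIG)
}

# raw PRS and within-cohort PC scores for the cohort
score_cohort <- function(cohort) {
  h <- harmonize(cohort$scoring, cohort$genotypes)
  prs <- standardize(compute_prs(h$matched, cohort$genotypes))
  pcm <- fit_reference_pca(cohort$genotypes, K = 4)
  aprs <- adjust_prs(prs, pcm$scores)
  list(harmonization = h$report, prs = prs, pcs = pcm$scores,
       aprs = as.numeric(aprs))
}
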