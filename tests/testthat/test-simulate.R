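test_that("Balding-Nichols frequencies have the right moments and F=0 degenerates", {
  # pin the ancestral frequency at 0.5 so the Beta moments are known exactly
  specs <- two_pop_specs(n = 5, fst = 0.1)
  cfg <- sim_config(n_variants = 2000, ancestral_freq_range = c(0.5, 0.5),
                    seed = 3)
  panel <- simulate_reference_panel(specs, cfg)
  p <- panel$variants$freq_EUR
  # Var(p) = F p0 (1-p0) = 0.025; SE of the variance over 2000 Beta draws
  v <- var(p)
  se <- sd((p - 0.5)^2) / sqrt(length(p))
  expect_lt(abs(v - 0.025), 3 * se)
  expect_lt(abs(mean(p) - 0.5), 3 * sd(p) / sqrt(length(p)))

  # F = 0: population frequency equals the ancestral frequency exactly
  specs0 <- two_pop_specs(n = 5, fst = 0)
  panel0 <- simulate_reference_panel(specs0, sim_config(n_variants = 100, seed = 3))
  expect_identical(panel0$variants$freq_EUR, panel0$variants$freq_SAS)

  expect_error(population_spec("X", 10, fst = 1), "fst")
  expect_error(population_spec("X", 10, fst = -0.1), "fst")
})

test_that("reference and study draws are reproducible and share frequencies", {
  specs <- two_pop_specs(n = 30)
  cfg <- small_config()
  a <- simulate_reference_panel(specs, cfg)
  b <- simulate_reference_panel(specs, cfg)
  expect_identical(a$dosages, b$dosages)

  cohort1 <- simulate_study_cohort(specs, cfg)
  cohort2 <- simulate_study_cohort(specs, cfg)
  expect_identical(cohort1$genotypes$dosages, cohort2$genotypes$dosages)
  # paired: same frequency model, different genotype substream
  expect_identical(a$variants, cohort1$genotypes$variants)
  expect_false(identical(a$dosages[1:30, ], cohort1$genotypes$dosages[1:30, ]))
})

test_that("study cohort bookkeeping: sizes, labels, single population", {
  specs <- list(population_spec("EUR", 50, 0.1), population_spec("SAS", 50, 0.1))
  cohort <- simulate_study_cohort(specs, small_config())
  expect_equal(nrow(cohort$genotypes$dosages), 100)
  expect_equal(as.vector(table(cohort$covariates$population)), c(50L, 50L))

  solo <- simulate_study_cohort(list(population_spec("EUR", 40, 0.05)),
                                small_config())
  expect_equal(unique(solo$covariates$population), "EUR")
})

test_that("simulated scoring files have exact ambiguous/flip counts and round-trip", {
  specs <- two_pop_specs(n = 5)
  cfg <- sim_config(n_variants = 100, ambiguous_fraction = 0.1,
                    flip_fraction = 0.25, seed = 5)
  panel <- simulate_reference_panel(specs, cfg)
  sf <- simulate_scoring_file(cfg, panel$variants)
  amb <- is_strand_ambiguous(sf$effect_allele, sf$other_allele)
  expect_equal(sum(amb), 10)
  expect_equal(sum(attr(sf, "truth")$flipped), 25)

  # degenerate weight distribution
  cfg0 <- sim_config(n_variants = 100, weight_sd = 0, weight_mean = 0.3, seed = 5)
  sf0 <- simulate_scoring_file(cfg0, simulate_reference_panel(specs, cfg0)$variants)
  expect_true(all(abs(abs(sf0$effect_weight) - 0.3) < 1e-12))

  # serialization identity through the PGS-dialect writer/parser
  path <- withr::local_tempfile(fileext = ".txt")
  write_scoring_file(sf, path)
  back <- read_scoring_file(path)
  expect_equal(back$rsID, sf$rsID)
  expect_equal(back$effect_allele, sf$effect_allele)
  expect_equal(back$other_allele, sf$other_allele)
  expect_equal(back$effect_weight, sf$effect_weight, tolerance = 1e-12)

  expect_error(sim_config(ambiguous_fraction = 1.2), "ambiguous_fraction")
})

test_that("liability phenotypes calibrate to the target prevalence", {
  specs <- two_pop_specs(n = 3000)
  cfg <- small_config(beta_prs = 0, beta_sex = 0, beta_age = 0,
                      fh_shared_env = 0, prevalence = 0.1, seed = 21)
  cohort <- simulate_phenotype(simulate_study_cohort(specs, cfg), cfg)
  frac <- mean(cohort$covariates$case_cad)
  expect_lt(abs(frac - 0.1), 3 * sqrt(0.1 * 0.9 / 6000))

  # positive score effect: cases have higher liability than controls
  cfg2 <- small_config(beta_prs = 0.5, seed = 22)
  cohort2 <- simulate_phenotype(simulate_study_cohort(specs, cfg2), cfg2)
  y <- cohort2$covariates$case_cad
  expect_gt(mean(cohort2$truth$liability[y == 1]),
            mean(cohort2$truth$liability[y == 0]))

  # impossible variance decomposition is rejected up front
  expect_error(sim_config(beta_prs = 0.9, beta_age = 0.5, beta_sex = 0.5),
               "residual liability variance")
})

test_that("per-population prevalence thresholds are honoured", {
  specs <- two_pop_specs(n = 3000)
  cfg <- small_config(beta_prs = 0, beta_sex = 0, beta_age = 0,
                      fh_shared_env = 0,
                      prevalence = c(EUR = 0.05, SAS = 0.2), seed = 31)
  cohort <- simulate_phenotype(simulate_study_cohort(specs, cfg), cfg)
  frac <- tapply(cohort$covariates$case_cad, cohort$covariates$population, mean)
  expect_lt(abs(frac[["EUR"]] - 0.05), 3 * sqrt(0.05 * 0.95 / 3000))
  expect_lt(abs(frac[["SAS"]] - 0.20), 3 * sqrt(0.20 * 0.80 / 3000))
})

test_that("family history is null when sharing is removed and informative otherwise", {
  specs <- two_pop_specs(n = 4000)
  # all sharing removed: FH independent of case status
  cfg0 <- small_config(beta_prs = 0, beta_sex = 0, beta_age = 0,
                       fh_shared_env = 0, prevalence = 0.15, seed = 41)
  c0 <- simulate_family_history(
    simulate_phenotype(simulate_study_cohort(specs, cfg0), cfg0), cfg0)
  tab <- table(c0$covariates$fh_cad, c0$covariates$case_cad)
  or0 <- crude_or_2x2(tab["1", "1"], tab["0", "1"], tab["1", "0"], tab["0", "0"])
  expect_gt(or0$ci_high, 1)
  expect_lt(or0$ci_low, 1)

  # shared genetics: positive FH-disease association
  cfg1 <- small_config(beta_prs = 0.7, beta_sex = 0, beta_age = 0,
                       fh_shared_env = 0.1, prevalence = 0.15, seed = 42)
  c1 <- simulate_family_history(
    simulate_phenotype(simulate_study_cohort(specs, cfg1), cfg1), cfg1)
  tab1 <- table(c1$covariates$fh_cad, c1$covariates$case_cad)
  or1 <- crude_or_2x2(tab1["1", "1"], tab1["0", "1"], tab1["1", "0"], tab1["0", "0"])
  expect_gt(or1$ci_low, 1)

  expect_error(sim_config(n_relatives = 0), "n_relatives")
})

test_that("case probands exceed the independence bound for family history", {
  # with positively correlated liabilities, P(FH | case) must exceed the
  # 1 - (1 - prevalence)^n_relatives bound that holds under independence
  specs <- two_pop_specs(n = 4000)
  cfg <- small_config(beta_prs = 0.7, beta_sex = 0, beta_age = 0,
                      fh_shared_env = 0.1, prevalence = 0.5,
                      n_relatives = 3, seed = 43)
  cohort <- simulate_family_history(
    simulate_phenotype(simulate_study_cohort(specs, cfg), cfg), cfg)
  cov <- cohort$covariates
  p_fh_cases <- mean(cov$fh_cad[cov$case_cad == 1])
  expect_gt(p_fh_cases, 1 - (1 - 0.5)^3)
})

test_that("onset ages follow the hazard model and define events", {
  specs <- two_pop_specs(n = 2500)
  # null score effect: Cox HR for the true score covers 1
  cfg0 <- small_config(hazard_beta_prs = 0, hazard_beta_sex = 0, seed = 51)
  c0 <- simulate_onset_ages(
    simulate_phenotype(simulate_study_cohort(specs, cfg0), cfg0), cfg0)
  cov <- c0$covariates
  time <- ifelse(is.na(cov$onset_age), cov$visit_age, cov$onset_age)
  fit <- fit_cox(time, cov$case_cad, data.frame(g = c0$truth$score))
  expect_gt(fit$table$ci_high[1], 1)
  expect_lt(fit$table$ci_low[1], 1)

  # overwhelming baseline hazard: everyone is a case
  cfg1 <- small_config(hazard_baseline = 50, seed = 52)
  specs_small <- two_pop_specs(n = 50)
  c1 <- simulate_onset_ages(
    simulate_phenotype(simulate_study_cohort(specs_small, cfg1), cfg1), cfg1)
  expect_true(all(c1$covariates$case_cad == 1))
  expect_true(all(!is.na(c1$covariates$onset_age)))

  expect_error(sim_config(hazard_baseline = 0), "hazard_baseline")
})

test_that("onset-age parameter recovery: binary stratum log-hazard ratio", {
  # hazard_beta_sex = log 2 on the sex stratum: fitted HR near 2
  specs <- two_pop_specs(n = 5000)
  cfg <- small_config(hazard_beta_prs = 0, hazard_beta_sex = log(2),
                      hazard_baseline = 0.01, seed = 53)
  cohort <- simulate_onset_ages(
    simulate_phenotype(simulate_study_cohort(specs, cfg), cfg), cfg)
  cov <- cohort$covariates
  time <- ifelse(is.na(cov$onset_age), cov$visit_age, cov$onset_age)
  fit <- fit_cox(time, cov$case_cad, data.frame(sex = cov$sex))
  expect_lt(abs(fit$table$estimate[1] - log(2)), 0.12)
})

test_that("simulated relatedness pairs are reproducible and well formed", {
  ids <- paste0("s", 1:50)
  p1 <- simulate_relatedness_pairs(ids, 10, seed = 4)
  p2 <- simulate_relatedness_pairs(ids, 10, seed = 4)
  expect_identical(p1, p2)
  expect_true(all(p1$kinship > 0.0884))
  expect_equal(nrow(simulate_relatedness_pairs(ids, 0)), 0)
})
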