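#' Population specification for the cohort simulator
#'
#' Describes one population in the Balding--Nichols structure model: its
#' label, size, and differentiation parameter F (the fixation index against
#' the shared ancestral population).
#'
#' @param label population name (e.g. "EUR", "SAS").
#' @param n_samples number of samples (>= 1).
#' @param fst differentiation parameter F in [0, 1). F = 0 means the
#'   population frequencies equal the ancestral frequencies exactly.
#' @return An object of class `population_spec`.
#' @export
population_spec <- function(label, n_samples, fst = 0.1) {
  stopifnot(is.character(label), length(label) == 1L, nzchar(label))
  if (!is.numeric(n_samples) || length(n_samples) != 1L || n_samples < 1)
    stop("n_samples must be >= 1")
  if (!is.numeric(fst) || length(fst) != 1L || fst < 0 || fst >= 1)
    stop("fst must lie in [0, 1)")
  structure(list(label = label, n_samples = as.integer(n_samples), fst = fst),
            class = "population_spec")
}

#' Simulation configuration
#'
#' Collects every tunable of the synthetic-cohort generator. Defaults encode
#' a two-population biobank-style study: moderate population differentiation,
#' a disease whose liability loads on the true weighted score, recruitment
#' ages 40--69, and first-degree relatives generating a family-history flag.
#'
#' @param n_variants number of unlinked variants (>= 2).
#' @param ancestral_freq_range interval the ancestral allele frequencies are
#'   drawn from (uniform); kept away from 0/1 to avoid monomorphic variants.
#' @param weight_mean,weight_sd mean and sd of the per-variant effect weights.
#' @param weight_freq_cor correlation in (-1, 1) between a variant's weight
#'   and its between-population frequency difference. 0 gives portable
#'   weights; positive values induce a systematic between-population shift of
#'   the raw score, the distribution-shift phenomenon the PC adjustment is
#'   meant to remove.
#' @param ambiguous_fraction fraction of variants written with strand-ambiguous
#'   (A/T or C/G) allele pairs; exactly `round(fraction * n_variants)`
#'   variants are selected under the seed.
#' @param flip_fraction fraction of scoring records written with swapped
#'   effect/other allele columns (and sign-flipped weight), to exercise
#'   allele flipping during harmonization.
#' @param prevalence target disease prevalence; scalar, or a named vector
#'   keyed by population label.
#' @param beta_prs liability-scale effect of the standardized true score.
#' @param beta_sex,beta_age liability-scale covariate effects (age per SD).
#' @param fh_shared_env shared-environment liability variance common to a
#'   family (proband and relatives).
#' @param n_relatives number of first-degree relatives per proband (>= 1);
#'   default 3 = two parents plus one sibling, each with genetic
#'   correlation 0.5 to the proband.
#' @param hazard_baseline baseline hazard (per year of age) of the onset-age
#'   model; must be > 0.
#' @param hazard_beta_prs,hazard_beta_sex log-hazard-ratio effects in the
#'   proportional-hazards onset model.
#' @param qc_flag_rate per-flag probability that a sample carries a QC
#'   exclusion flag (sex discordance, aneuploidy, het/missing outlier).
#' @param disease short disease label used in covariate column names.
#' @param seed master RNG seed; all stages draw from named substreams
#'   derived from it.
#' @return An object of class `sim_config`.
#' @export
sim_config <- function(n_variants = 1000,
                       ancestral_freq_range = c(0.05, 0.95),
                       weight_mean = 0,
                       weight_sd = 1,
                       weight_freq_cor = 0,
                       ambiguous_fraction = 0.05,
                       flip_fraction = 0.2,
                       prevalence = 0.1,
                       beta_prs = 0.5,
                       beta_sex = 0.2,
                       beta_age = 0.3,
                       fh_shared_env = 0.05,
                       n_relatives = 3,
                       hazard_baseline = 0.005,
                       hazard_beta_prs = 0.4,
                       hazard_beta_sex = 0.3,
                       qc_flag_rate = 0.002,
                       disease = "cad",
                       seed = 1) {
  if (n_variants < 2) stop("n_variants must be >= 2")
  stopifnot(length(ancestral_freq_range) == 2L,
            ancestral_freq_range[1] > 0, ancestral_freq_range[2] < 1,
            ancestral_freq_range[1] <= ancestral_freq_range[2])
  if (ambiguous_fraction < 0 || ambiguous_fraction > 1)
    stop("ambiguous_fraction must lie in [0, 1]")
  if (flip_fraction < 0 || flip_fraction > 1)
    stop("flip_fraction must lie in [0, 1]")
  if (any(prevalence <= 0) || any(prevalence >= 1))
    stop("prevalence must lie in (0, 1)")
  if (weight_sd < 0) stop("weight_sd must be >= 0")
  if (abs(weight_freq_cor) >= 1) stop("weight_freq_cor must lie in (-1, 1)")
  if (fh_shared_env < 0) stop("fh_shared_env must be >= 0")
  if (n_relatives < 1) stop("n_relatives must be >= 1")
  if (hazard_baseline <= 0) stop("hazard_baseline must be > 0")
  cfg <- structure(as.list(environment()), class = "sim_config")
  v <- liability_residual_var(cfg)
  if (v <= 0)
    stop("beta/shared-environment configuration leaves non-positive ",
         "residual liability variance (", signif(v, 3), ")")
  cfg
}

# Age standardization inside the liability model: per-SD coding matched to
# the recruitment-age distribution (mean 54.5, sd 8.4).
AGE_CENTER <- 54.5
AGE_SCALE <- 8.4

standardize_age <- function(age) (age - AGE_CENTER) / AGE_SCALE

# Residual (independent) liability variance after the systematic terms:
# Var(L) = 1 with sex ~ Bern(0.5) (variance 1/4), age ~ U(40, 69)
# standardized by AGE_SCALE, plus the family-shared environment component.
liability_residual_var <- function(config) {
  var_age <- (69 - 40)^2 / 12 / AGE_SCALE^2
  1 - config$beta_prs^2 - config$beta_sex^2 * 0.25 -
    config$beta_age^2 * var_age - config$fh_shared_env
}

#' Construct a genotype set
#'
#' The container used throughout the pipeline: an effect-allele (ALT) dosage
#' matrix with variant metadata and optional per-sample population labels.
#'
#' @param dosages numeric matrix, samples x variants, values in [0, 2] or NA.
#' @param variants data.frame with columns id, chrom, pos, ref, alt (one row
#'   per dosage column).
#' @param sample_ids character vector, one per dosage row.
#' @param population optional character vector of population labels.
#' @return An object of class `genotype_set`.
#' @export
genotype_set <- function(dosages, variants, sample_ids, population = NULL) {
  dosages <- as.matrix(dosages)
  if (nrow(variants) != ncol(dosages))
    stop("variant metadata rows must match dosage columns")
  if (length(sample_ids) != nrow(dosages))
    stop("sample_ids must match dosage rows")
  stopifnot(all(c("id", "chrom", "pos", "ref", "alt") %in% names(variants)))
  if (anyDuplicated(variants$id)) stop("variant ids must be unique")
  rng <- range(dosages, na.rm = TRUE)
  if (rng[1] < 0 || rng[2] > 2) stop("dosages must lie in [0, 2]")
  rownames(dosages) <- sample_ids
  colnames(dosages) <- variants$id
  if (!is.null(population) && length(population) != length(sample_ids))
    stop("population labels must match sample_ids")
  structure(list(dosages = dosages, variants = as.data.frame(variants),
                 sample_ids = as.character(sample_ids),
                 population = population),
            class = "genotype_set")
}

#' @export
print.genotype_set <- function(x, ...) {
  cat("genotype_set:", nrow(x$dosages), "samples x", ncol(x$dosages),
      "variants\n")
  if (!is.null(x$population))
    print(table(population = x$population))
  invisible(x)
}

# Shared frequency model: ancestral frequencies plus Balding-Nichols
# per-population frequencies Beta(p0(1-F)/F, (1-p0)(1-F)/F), which has mean
# p0 and variance F p0 (1 - p0). Reference panel and study cohort both draw
# from these same frequencies (independent genotype draws).
simulate_population_frequencies <- function(specs, config) {
  n <- config$n_variants
  p0 <- with_substream(config$seed, "freq.ancestral",
                       stats::runif(n, config$ancestral_freq_range[1],
                                    config$ancestral_freq_range[2]))
  freq <- matrix(NA_real_, nrow = length(specs), ncol = n,
                 dimnames = list(vapply(specs, `[[`, "", "label"), NULL))
  for (i in seq_along(specs)) {
    f <- specs[[i]]$fst
    if (f == 0) {
      freq[i, ] <- p0
    } else {
      freq[i, ] <- with_substream(
        config$seed, paste0("freq.population.", specs[[i]]$label),
        stats::rbeta(n, p0 * (1 - f) / f, (1 - p0) * (1 - f) / f))
    }
  }
  list(p0 = p0, freq = freq)
}

# Variant metadata with allele pairs; exactly round(ambiguous_fraction * n)
# variants get strand-ambiguous (A/T or C/G) pairs.
simulate_variant_metadata <- function(specs, config, freqs) {
  n <- config$n_variants
  n_amb <- round(config$ambiguous_fraction * n)
  with_substream(config$seed, "alleles", {
    amb_idx <- if (n_amb > 0) sample.int(n, n_amb) else integer(0)
    ref <- alt <- character(n)
    amb_pairs <- list(c("A", "T"), c("T", "A"), c("C", "G"), c("G", "C"))
    nonamb_alt <- list(A = c("C", "G"), C = c("A", "T"),
                       G = c("A", "T"), T = c("C", "G"))
    for (j in seq_len(n)) {
      if (j %in% amb_idx) {
        pr <- amb_pairs[[sample.int(4L, 1L)]]
        ref[j] <- pr[1]; alt[j] <- pr[2]
      } else {
        ref[j] <- sample(c("A", "C", "G", "T"), 1L)
        alt[j] <- sample(nonamb_alt[[ref[j]]], 1L)
      }
    }
    v <- data.frame(id = paste0("rs", seq_len(n)),
                    chrom = rep_len(as.character(1:22), n),
                    pos = 10000L * seq_len(n),
                    ref = ref, alt = alt,
                    stringsAsFactors = FALSE)
    for (lab in rownames(freqs$freq)) v[[paste0("freq_", lab)]] <- freqs$freq[lab, ]
    v
  })
}

draw_genotypes <- function(specs, freqs, seed, stream) {
  n_var <- ncol(freqs$freq)
  mats <- list(); pops <- character(0); ids <- character(0)
  with_substream(seed, stream, {
    for (sp in specs) {
      p <- freqs$freq[sp$label, ]
      g <- matrix(stats::rbinom(sp$n_samples * n_var, 2L,
                                rep(p, each = sp$n_samples)),
                  nrow = sp$n_samples)
      mats[[sp$label]] <- g
      pops <- c(pops, rep(sp$label, sp$n_samples))
      ids <- c(ids, paste0(sp$label, "_", seq_len(sp$n_samples)))
    }
  })
  list(dosages = do.call(rbind, mats), population = pops, sample_ids = ids)
}

check_specs <- function(specs, require_two = TRUE) {
  stopifnot(is.list(specs), length(specs) >= 1L)
  if (require_two && length(specs) < 2L)
    stop("at least two populations are required")
  lapply(specs, function(s) stopifnot(inherits(s, "population_spec")))
  labs <- vapply(specs, `[[`, "", "label")
  if (anyDuplicated(labs)) stop("population labels must be unique")
  invisible(labs)
}

#' Simulate a reference genotype panel
#'
#' Draws a panel of unlinked variants under the Balding--Nichols model: per
#' variant an ancestral frequency p0, per population a frequency from
#' Beta(p0(1-F)/F, (1-p0)(1-F)/F) (mean p0, variance F p0 (1-p0)), and
#' genotypes binomial(2, p) within each population (Hardy--Weinberg). The
#' panel plays the role of an external reference (e.g. 1000 Genomes
#' superpopulations) for PCA projection and ancestry assignment.
#'
#' @param specs list of [population_spec()] (>= 2 populations).
#' @param config a [sim_config()].
#' @param n_samples optional per-population size override (reference panels
#'   are typically smaller than the paired study cohort); the frequency draws
#'   are unaffected, so the panel stays paired with the cohort.
#' @return A [genotype_set()] with population labels.
#' @export
simulate_reference_panel <- function(specs, config, n_samples = NULL) {
  check_specs(specs)
  if (!is.null(n_samples)) {
    specs <- lapply(seq_along(specs), function(i) {
      s <- specs[[i]]
      population_spec(s$label, n_samples, s$fst)
    })
  }
  freqs <- simulate_population_frequencies(specs, config)
  variants <- simulate_variant_metadata(specs, config, freqs)
  g <- draw_genotypes(specs, freqs, config$seed, "genotypes.reference")
  genotype_set(g$dosages, variants, g$sample_ids, g$population)
}

#' Simulate a study cohort
#'
#' Draws study genotypes from the same per-population frequencies as the
#' paired reference panel (same seed, independent genotype substream),
#' generates the published-score analogue via [simulate_scoring_file()], and
#' initializes the covariate table (ids, population truth labels, QC flags).
#' Sample-level truth (the standardized true weighted score) is carried in
#' `$truth` and is never read by downstream analysis modules.
#'
#' @inheritParams simulate_reference_panel
#' @return An object of class `simulated_cohort` with elements `genotypes`,
#'   `scoring`, `covariates`, `truth`.
#' @export
simulate_study_cohort <- function(specs, config) {
  check_specs(specs, require_two = FALSE)
  freqs <- simulate_population_frequencies(specs, config)
  variants <- simulate_variant_metadata(specs, config, freqs)
  g <- draw_genotypes(specs, freqs, config$seed, "genotypes.study")
  genotypes <- genotype_set(g$dosages, variants, g$sample_ids, g$population)
  scoring <- simulate_scoring_file(config, variants)
  truth_sf <- attr(scoring, "truth")
  attr(scoring, "truth") <- NULL
  score_raw <- as.numeric(genotypes$dosages %*% truth_sf$alt_weight)
  qc <- with_substream(config$seed, "qc.flags", {
    n <- length(g$sample_ids)
    data.frame(
      qc_sex_discordant = stats::rbinom(n, 1L, config$qc_flag_rate),
      qc_aneuploidy = stats::rbinom(n, 1L, config$qc_flag_rate),
      qc_het_missing_outlier = stats::rbinom(n, 1L, config$qc_flag_rate))
  })
  covariates <- cbind(
    data.frame(sample_id = g$sample_ids, population = g$population,
               stringsAsFactors = FALSE),
    qc)
  structure(list(genotypes = genotypes, scoring = scoring,
                 covariates = covariates,
                 truth = list(alt_weight = truth_sf$alt_weight,
                              flipped = truth_sf$flipped,
                              score_raw = score_raw,
                              score = standardize(score_raw))),
            class = "simulated_cohort")
}

#' @export
print.simulated_cohort <- function(x, ...) {
  cat("simulated_cohort:", nrow(x$genotypes$dosages), "samples,",
      ncol(x$genotypes$dosages), "variants,",
      ncol(x$covariates), "covariate columns\n")
  invisible(x)
}

#' Simulate a published scoring file
#'
#' Emulates a PGS-Catalog scoring file for the simulated variants: weights
#' drawn from the configured normal distribution, a configured fraction of
#' records written with swapped effect/other allele columns (weight sign
#' flipped accordingly, so the encoded signal is unchanged) to exercise
#' allele flipping, and strand-ambiguous variants present per the variant
#' metadata. When `weight_freq_cor` is non-zero, the weights are correlated
#' with the between-population frequency difference of the first two
#' populations, inducing a structured (non-portable) score.
#'
#' @param config a [sim_config()].
#' @param variants variant metadata from a simulated [genotype_set()]
#'   (columns id, chrom, pos, ref, alt and the simulated `freq_*` columns).
#' @return A `scoring_file` data.frame (columns rsID, chr_name, chr_position,
#'   effect_allele, other_allele, effect_weight) with the simulation truth
#'   (ALT-oriented weights, flip indicator) attached as attribute `truth`.
#' @export
simulate_scoring_file <- function(config, variants) {
  n <- nrow(variants)
  if (n != config$n_variants)
    stop("variant metadata does not match config$n_variants")
  w <- with_substream(config$seed, "weights", {
    z <- stats::rnorm(n)
    rho <- config$weight_freq_cor
    if (rho != 0) {
      fcols <- grep("^freq_", names(variants), value = TRUE)
      if (length(fcols) < 2)
        stop("weight_freq_cor requires frequency metadata for >= 2 populations")
      d <- variants[[fcols[1]]] - variants[[fcols[2]]]
      d <- standardize(d)
      z <- rho * d + sqrt(1 - rho^2) * z
    }
    config$weight_mean + config$weight_sd * z
  })
  n_flip <- round(config$flip_fraction * n)
  flip <- rep(FALSE, n)
  if (n_flip > 0)
    flip[with_substream(config$seed, "allele.flips", sample.int(n, n_flip))] <- TRUE
  sf <- data.frame(
    rsID = variants$id,
    chr_name = variants$chrom,
    chr_position = variants$pos,
    effect_allele = ifelse(flip, variants$ref, variants$alt),
    other_allele = ifelse(flip, variants$alt, variants$ref),
    effect_weight = ifelse(flip, -w, w),
    stringsAsFactors = FALSE)
  class(sf) <- c("scoring_file", "data.frame")
  attr(sf, "truth") <- list(alt_weight = w, flipped = flip)
  sf
}

prevalence_for <- function(config, population) {
  pr <- config$prevalence
  if (length(pr) == 1L && is.null(names(pr))) return(rep(pr, length(population)))
  if (is.null(names(pr)) || !all(population %in% names(pr)))
    stop("per-population prevalence must be named for every population")
  unname(pr[population])
}

#' Simulate disease phenotypes under a liability-threshold model
#'
#' Adds sex, recruitment age, BMI, case status, and visit age to the cohort's
#' covariate table. Liability is
#' `L = beta_prs * G + beta_sex * sex + beta_age * age_std + e_fam + e`,
#' with `G` the standardized true weighted score, `e_fam` the family-shared
#' environment (variance `fh_shared_env`, reused for relatives), and `e`
#' independent noise scaled so Var(L) = 1 under the default covariate coding.
#' A sample is a case iff `L > qnorm(1 - prevalence)` for its population's
#' target prevalence. Sex ~ Bernoulli(0.5); age ~ Uniform(40, 69).
#'
#' @param cohort a `simulated_cohort`.
#' @param config the [sim_config()] used to create it.
#' @return The cohort with updated `covariates` (columns sex, age, visit_age,
#'   bmi, `case_<disease>`) and `truth` (liability, shared_env, threshold).
#' @export
simulate_phenotype <- function(cohort, config) {
  stopifnot(inherits(cohort, "simulated_cohort"))
  v_res <- liability_residual_var(config)
  if (v_res <= 0) stop("non-positive residual liability variance")
  cov <- cohort$covariates
  n <- nrow(cov)
  G <- cohort$truth$score
  out <- with_substream(config$seed, "phenotype", {
    sex <- stats::rbinom(n, 1L, 0.5)
    age <- stats::runif(n, 40, 69)
    e_fam <- stats::rnorm(n, 0, sqrt(config$fh_shared_env))
    e <- stats::rnorm(n, 0, sqrt(v_res))
    bmi <- round(26.5 + 4 * stats::rnorm(n), 1)
    list(sex = sex, age = age, e_fam = e_fam, e = e, bmi = pmax(bmi, 15))
  })
  L <- config$beta_prs * G + config$beta_sex * out$sex +
    config$beta_age * standardize_age(out$age) + out$e_fam + out$e
  thr <- stats::qnorm(1 - prevalence_for(config, cov$population))
  cov$sex <- out$sex
  cov$age <- out$age
  cov$visit_age <- out$age
  cov$bmi <- out$bmi
  cov[[paste0("case_", config$disease)]] <- as.integer(L > thr)
  cohort$covariates <- cov
  cohort$truth$liability <- L
  cohort$truth$shared_env <- out$e_fam
  cohort$truth$threshold <- thr
  cohort
}

#' Simulate first-degree family history
#'
#' Each proband gets `n_relatives` first-degree relatives. A relative's
#' genetic score is `0.5 * g + sqrt(0.75) * g_new` on the standardized scale
#' (genetic correlation 0.5), its liability adds the family-shared
#' environment term drawn for the proband plus independent noise, and it is
#' affected under the same liability threshold. The family-history flag is 1
#' iff any relative is affected.
#'
#' @inheritParams simulate_phenotype
#' @return The cohort with an `fh_<disease>` column added and per-relative
#'   truth recorded.
#' @export
simulate_family_history <- function(cohort, config) {
  stopifnot(inherits(cohort, "simulated_cohort"))
  if (is.null(cohort$truth$liability))
    stop("run simulate_phenotype() before simulate_family_history()")
  if (config$n_relatives < 1) stop("n_relatives must be >= 1")
  n <- nrow(cohort$covariates)
  G <- cohort$truth$score
  e_fam <- cohort$truth$shared_env
  thr <- cohort$truth$threshold
  v_res <- liability_residual_var(config)
  any_affected <- rep(FALSE, n)
  with_substream(config$seed, "family", {
    for (r in seq_len(config$n_relatives)) {
      g_rel <- 0.5 * G + sqrt(0.75) * stats::rnorm(n)
      sex_rel <- stats::rbinom(n, 1L, 0.5)
      age_rel <- stats::runif(n, 40, 69)
      L_rel <- config$beta_prs * g_rel + config$beta_sex * sex_rel +
        config$beta_age * standardize_age(age_rel) + e_fam +
        stats::rnorm(n, 0, sqrt(v_res))
      any_affected <- any_affected | (L_rel > thr)
    }
  })
  cohort$covariates[[paste0("fh_", config$disease)]] <- as.integer(any_affected)
  cohort
}

#' Simulate onset ages under a proportional-hazards model
#'
#' Draws a latent onset age for every sample from an exponential
#' proportional-hazards model on the age scale, with hazard
#' `hazard_baseline * exp(hazard_beta_prs * G + hazard_beta_sex * sex)` and
#' `G` the standardized true score. Samples whose onset age exceeds their
#' recruitment-visit age are censored controls; the case indicator is
#' redefined to match the event indicator so the survival columns are
#' internally consistent (the onset model, when used, is the event-defining
#' mechanism).
#'
#' @inheritParams simulate_phenotype
#' @return The cohort with `onset_age` (NA for censored samples) and an
#'   updated `case_<disease>` column equal to the event indicator.
#' @export
simulate_onset_ages <- function(cohort, config) {
  stopifnot(inherits(cohort, "simulated_cohort"))
  if (is.null(cohort$covariates$visit_age))
    stop("run simulate_phenotype() before simulate_onset_ages()")
  if (config$hazard_baseline <= 0) stop("hazard_baseline must be > 0")
  cov <- cohort$covariates
  eta <- config$hazard_beta_prs * cohort$truth$score +
    config$hazard_beta_sex * cov$sex
  t_onset <- with_substream(config$seed, "onset",
                            stats::rexp(nrow(cov), config$hazard_baseline * exp(eta)))
  event <- t_onset <= cov$visit_age
  cov$onset_age <- ifelse(event, t_onset, NA_real_)
  cov[[paste0("case_", config$disease)]] <- as.integer(event)
  cohort$covariates <- cov
  cohort$truth$latent_onset <- t_onset
  cohort
}

#' Simulate a relatedness-pair table
#'
#' Picks random sample pairs and assigns them kinship coefficients typical of
#' first/second-degree relatives, for exercising relatedness pruning.
#'
#' @param sample_ids character vector of cohort sample ids.
#' @param n_pairs number of related pairs to generate.
#' @param seed RNG seed.
#' @param kinship_range range kinship coefficients are drawn from (uniform).
#' @return data.frame with columns id1, id2, kinship.
#' @export
simulate_relatedness_pairs <- function(sample_ids, n_pairs, seed = 1,
                                       kinship_range = c(0.09, 0.3)) {
  if (n_pairs < 0) stop("n_pairs must be >= 0")
  if (n_pairs == 0)
    return(data.frame(id1 = character(0), id2 = character(0),
                      kinship = numeric(0)))
  if (length(sample_ids) < 2) stop("need >= 2 samples to form pairs")
  with_substream(seed, "relatedness", {
    i <- replicate(n_pairs, sample(length(sample_ids), 2L))
    data.frame(id1 = sample_ids[i[1, ]], id2 = sample_ids[i[2, ]],
               kinship = stats::runif(n_pairs, kinship_range[1],
                                      kinship_range[2]),
               stringsAsFactors = FALSE)
  })
}
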