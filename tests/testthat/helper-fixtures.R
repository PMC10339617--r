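# Shared fixture builders; all randomness flows through explicit seeds.

two_pop_specs <- function(n = 200, fst = 0.1) {
  list(population_spec("EUR", n, fst), population_spec("SAS", n, fst))
}

small_config <- function(...) {
  args <- list(...)
  defaults <- list(n_variants = 60, seed = 11, ambiguous_fraction = 0.1,
                   flip_fraction = 0.2)
  do.call(sim_config, utils::modifyList(defaults, args))
}

# tiny deterministic genotype set for allele-bookkeeping tests
toy_genotypes <- function(dosages, ref, alt) {
  m <- matrix(dosages, ncol = length(ref))
  genotype_set(m,
               data.frame(id = paste0("v", seq_along(ref)),
                          chrom = "1", pos = seq_along(ref) * 100L,
                          ref = ref, alt = alt, stringsAsFactors = FALSE),
               paste0("s", seq_len(nrow(m))))
}

toy_scoring <- function(effect, other, weight, id = paste0("v", seq_along(effect))) {
  sf <- data.frame(rsID = id, chr_name = "1",
                   chr_position = seq_along(effect) * 100L,
                   effect_allele = effect, other_allele = other,
                   effect_weight = weight, stringsAsFactors = FALSE)
  class(sf) <- c("scoring_file", "data.frame")
  sf
}

# logistic-model sampler used by recovery/discrimination tests
sample_logistic <- function(n, beta, seed, prevalence_intercept = -2) {
  set.seed(seed)
  X <- data.frame(aprs = rnorm(n), sex = rbinom(n, 1, 0.5),
                  age = runif(n, 40, 69))
  for (k in 1:4) X[[paste0("PC", k)]] <- rnorm(n)
  eta <- prevalence_intercept + beta["aprs"] * X$aprs +
    beta["sex"] * X$sex + beta["age"] * (X$age - 54.5) / 8.4
  y <- rbinom(n, 1, stats::plogis(eta))
  list(X = X, y = y)
}
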