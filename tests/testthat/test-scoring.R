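test_that("PGS-dialect scoring files parse, with aliases and hard errors", {
  path <- withr::local_tempfile(fileext = ".txt")
  writeLines(c(
    "#pgs_id=PGS000027",
    "#genome_build=GRCh37",
    "rsID\tchr_name\tchr_position\teffect_allele\tother_allele\teffect_weight",
    "rs1\t1\t100\tA\tG\t0.5",
    "rs2\t1\t200\tC\tT\t-0.2",
    "rs3\t2\t300\tG\tA\t0.01"), path)
  sf <- read_scoring_file(path)
  expect_s3_class(sf, "scoring_file")
  expect_equal(nrow(sf), 3)
  expect_equal(sf$effect_weight, c(0.5, -0.2, 0.01))

  # rsid/beta alias headers
  path2 <- withr::local_tempfile(fileext = ".txt")
  writeLines(c("rsid\teffect_allele\tother_allele\tbeta",
               "rs9\tA\tC\t0.3"), path2)
  expect_equal(read_scoring_file(path2)$effect_weight, 0.3)

  # missing mandatory column is named
  path3 <- withr::local_tempfile(fileext = ".txt")
  writeLines(c("rsID\teffect_allele\teffect_weight", "rs1\tA\t0.5"), path3)
  expect_error(read_scoring_file(path3), "other_allele")

  # non-numeric weight reported with its line
  path4 <- withr::local_tempfile(fileext = ".txt")
  writeLines(c("rsID\teffect_allele\tother_allele\teffect_weight",
               "rs1\tA\tG\t0.5", "rs2\tC\tT\tnot_a_number"), path4)
  expect_error(read_scoring_file(path4), "line 3")

  # duplicate ids violate the invariant
  path5 <- withr::local_tempfile(fileext = ".txt")
  writeLines(c("rsID\teffect_allele\tother_allele\teffect_weight",
               "rs1\tA\tG\t0.5", "rs1\tC\tT\t0.1"), path5)
  expect_error(read_scoring_file(path5), "rs1")
})

test_that("harmonization reproduces the allele-configuration truth table", {
  # genotype variant ref = A, alt = G; enumerate all 12 ordered allele pairs
  pairs <- expand.grid(effect = c("A", "C", "G", "T"),
                       other = c("A", "C", "G", "T"),
                       stringsAsFactors = FALSE)
  pairs <- pairs[pairs$effect != pairs$other, ]
  # hand-written classification against ref A / alt G
  truth <- c("A/C" = "allele_mismatch",
             "A/G" = "flipped",
             "A/T" = "ambiguous_excluded",
             "C/A" = "allele_mismatch",
             "C/G" = "ambiguous_excluded",
             "C/T" = "complement_as_is",  # C->G (alt), T->A (ref)
             "G/A" = "as_is",
             "G/C" = "ambiguous_excluded",
             "G/T" = "allele_mismatch",
             "T/A" = "ambiguous_excluded",
             "T/C" = "complement_flipped", # T->A (ref), C->G (alt)
             "T/G" = "allele_mismatch")
  for (i in seq_len(nrow(pairs))) {
    e <- pairs$effect[i]; o <- pairs$other[i]
    gs <- toy_genotypes(c(0, 1, 2), ref = "A", alt = "G")
    sf <- toy_scoring(e, o, 0.5, id = "v1")
    expected <- truth[paste(e, o, sep = "/")]
    if (expected %in% c("as_is", "flipped", "complement_as_is",
                        "complement_flipped")) {
      h <- harmonize(sf, gs)
      expect_equal(nrow(h$matched), 1, info = paste(e, o))
      expect_equal(h$matched$flip,
                   expected %in% c("flipped", "complement_flipped"),
                   info = paste(e, o))
      expect_equal(h$matched$strand_complement,
                   startsWith(unname(expected), "complement"),
                   info = paste(e, o))
    } else {
      expect_error(harmonize(sf, gs), "no scoring record",
                   info = paste(e, o))
    }
  }
})

test_that("harmonization report counts every category", {
  gs <- toy_genotypes(rep(1, 5), ref = c("A", "A", "A", "A", "A"),
                      alt = c("G", "G", "G", "G", "G"))
  sf <- toy_scoring(effect = c("G", "A", "A", "C", "G"),
                    other = c("A", "G", "T", "A", "A"),
                    weight = rep(0.1, 5),
                    id = c("v1", "v2", "v3", "v4", "v99"))
  sf$chr_position[5] <- 99999L # absent from the panel entirely
  h <- harmonize(sf, gs)
  expect_equal(unname(h$report["matched"]), 2)
  expect_equal(unname(h$report["as_is"]), 1)
  expect_equal(unname(h$report["flipped"]), 1)
  expect_equal(unname(h$report["ambiguous_excluded"]), 1)
  expect_equal(unname(h$report["allele_mismatch"]), 1)
  expect_equal(unname(h$report["not_found"]), 1)
})

test_that("harmonization falls back to chrom+pos matching", {
  gs <- toy_genotypes(c(0, 1, 2, 1), ref = c("A", "C"), alt = c("G", "T"))
  sf <- toy_scoring(c("G", "T"), c("A", "C"), c(0.5, -0.2),
                    id = c("other_name_1", "other_name_2"))
  h <- harmonize(sf, gs)
  expect_equal(h$matched$variant_id, c("v1", "v2"))
})

test_that("PRS is the weighted dosage sum with mean imputation", {
  gs <- toy_genotypes(c(2, 1), ref = c("A", "C"), alt = c("G", "T"))
  sf <- toy_scoring(c("G", "T"), c("A", "C"), c(0.5, -0.2))
  h <- harmonize(sf, gs)
  expect_equal(unname(compute_prs(h$matched, gs)), 2 * 0.5 + 1 * (-0.2))

  # all-zero weights
  sf0 <- toy_scoring(c("G", "T"), c("A", "C"), c(0, 0))
  expect_true(all(compute_prs(harmonize(sf0, gs)$matched, gs) == 0))

  # one missing dosage with effect-allele frequency 0.25 contributes w * 0.5
  gs_na <- toy_genotypes(c(NA, 1, 0, 1, 0), ref = "A", alt = "G")
  sf1 <- toy_scoring("G", "A", 1)
  prs <- compute_prs(harmonize(sf1, gs_na)$matched, gs_na)
  expect_equal(unname(prs[1]), 0.5)

  # variant with every dosage missing is dropped with a warning
  gs_all_na <- toy_genotypes(c(NA, NA, 1, 0), ref = c("A", "C"),
                             alt = c("G", "T"))
  sf2 <- toy_scoring(c("G", "T"), c("A", "C"), c(1, 1))
  expect_warning(prs2 <- compute_prs(harmonize(sf2, gs_all_na)$matched,
                                     gs_all_na),
                 "all dosages missing")
  expect_equal(unname(prs2), c(1, 0))
})

test_that("PRS equals a brute-force loop on small instances", {
  set.seed(14)
  for (rep in 1:5) {
    n_var <- sample(1:5, 1); n_samp <- sample(2:4, 1)
    ref <- sample(c("A", "C"), n_var, replace = TRUE)
    alt <- ifelse(ref == "A", "G", "T")
    d <- matrix(sample(0:2, n_samp * n_var, replace = TRUE), nrow = n_samp)
    gs <- toy_genotypes(d, ref, alt)
    flip <- sample(c(TRUE, FALSE), n_var, replace = TRUE)
    w <- round(rnorm(n_var), 3)
    sf <- toy_scoring(ifelse(flip, ref, alt), ifelse(flip, alt, ref), w)
    h <- harmonize(sf, gs)
    got <- compute_prs(h$matched, gs)
    # independent brute force over samples and variants
    want <- numeric(n_samp)
    for (i in seq_len(n_samp)) {
      acc <- 0
      for (j in seq_len(n_var)) {
        dose <- if (flip[j]) 2 - d[i, j] else d[i, j]
        acc <- acc + w[j] * dose
      }
      want[i] <- acc
    }
    expect_equal(unname(got), want)
  }
})

test_that("standardization uses the population sd and is idempotent", {
  z <- standardize(c(1, 2, 3))
  expect_equal(z, c(-1, 0, 1) * sqrt(3 / 2), tolerance = 1e-12)
  expect_equal(z[3], 1.2247449, tolerance = 1e-6)
  expect_error(standardize(rep(2, 5)), "degenerate")
  expect_equal(standardize(z), z, tolerance = 1e-12)
})

test_that("scoring is permutation-equivariant and flip-consistent", {
  set.seed(15)
  d <- matrix(sample(0:2, 40, replace = TRUE), nrow = 8)
  ref <- c("A", "C", "A", "C", "A")
  alt <- c("G", "T", "G", "T", "G")
  gs <- toy_genotypes(d, ref, alt)
  w <- rnorm(5)
  sf <- toy_scoring(alt, ref, w)
  z <- standardize(compute_prs(harmonize(sf, gs)$matched, gs))

  # permute samples
  perm <- sample(8)
  gs_p <- toy_genotypes(d[perm, ], ref, alt)
  z_p <- standardize(compute_prs(harmonize(sf, gs_p)$matched, gs_p))
  expect_equal(unname(z_p), unname(z[perm]))

  # permute variants in the scoring file
  vperm <- sample(5)
  sf_v <- sf[vperm, ]
  z_v <- standardize(compute_prs(harmonize(sf_v, gs)$matched, gs))
  expect_equal(z_v, z)

  # negate a weight and swap its alleles: standardized PRS unchanged
  sf_f <- sf
  sf_f$effect_allele[2] <- ref[2]
  sf_f$other_allele[2] <- alt[2]
  sf_f$effect_weight[2] <- -w[2]
  z_f <- standardize(compute_prs(harmonize(sf_f, gs)$matched, gs))
  expect_equal(z_f, z, tolerance = 1e-12)
})
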