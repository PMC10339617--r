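#' Write a genotype set as a VCF file
#'
#' One record per variant with hard-call GT fields (dosage 0 -> 0/0,
#' 1 -> 0/1, 2 -> 1/1, missing -> ./.). Non-integer dosages cannot be
#' represented as genotype calls; use [write_dosage_matrix()] for those.
#'
#' @param genotypes a [genotype_set()].
#' @param path output path (plain text, uncompressed).
#' @return `path`, invisibly.
#' @export
write_vcf <- function(genotypes, path) {
  d <- genotypes$dosages
  if (any(abs(d - round(d)) > 1e-9, na.rm = TRUE))
    stop("VCF GT output requires integer dosages")
  v <- genotypes$variants
  header <- c(
    "##fileformat=VCFv4.2",
    "##source=aprs cohort simulator",
    '##FORMAT=<ID=GT,Number=1,Type=String,Description="Genotype">',
    paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER", "INFO",
            "FORMAT", genotypes$sample_ids), collapse = "\t"))
  gt_code <- c("0/0", "0/1", "1/1")
  body <- vapply(seq_len(nrow(v)), function(j) {
    g <- d[, j]
    gt <- ifelse(is.na(g), "./.", gt_code[g + 1L])
    paste(c(v$chrom[j], v$pos[j], v$id[j], v$ref[j], v$alt[j], ".", "PASS",
            ".", "GT", gt), collapse = "\t")
  }, character(1))
  writeLines(c(header, body), path)
  invisible(path)
}

#' Read genotypes from a VCF file
#'
#' Parses GT fields into ALT-allele dosages via the vcfR package.
#'
#' @param path VCF path.
#' @param population optional population labels, one per sample.
#' @return A [genotype_set()].
#' @export
read_genotypes_vcf <- function(path, population = NULL) {
  if (!requireNamespace("vcfR", quietly = TRUE))
    stop("reading VCF requires the vcfR package")
  vcf <- vcfR::read.vcfR(path, verbose = FALSE)
  gt <- vcfR::extract.gt(vcf, element = "GT")
  count_alt <- function(x) {
    out <- rep(NA_real_, length(x))
    ok <- !is.na(x) & !grepl("\\.", x)
    alleles <- strsplit(gsub("\\|", "/", x[ok]), "/")
    out[ok] <- vapply(alleles, function(a) sum(a != "0"), numeric(1))
    out
  }
  d <- matrix(NA_real_, nrow = ncol(gt), ncol = nrow(gt))
  for (j in seq_len(nrow(gt))) d[, j] <- count_alt(gt[j, ])
  fix <- as.data.frame(vcf@fix, stringsAsFactors = FALSE)
  variants <- data.frame(id = fix$ID, chrom = fix$CHROM,
                         pos = as.integer(fix$POS),
                         ref = fix$REF, alt = fix$ALT,
                         stringsAsFactors = FALSE)
  genotype_set(d, variants, colnames(gt), population)
}

#' Write a plain dosage matrix
#'
#' Tab-delimited samples x variants table: header row of variant ids, first
#' column `sample_id`.
#'
#' @param genotypes a [genotype_set()].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_dosage_matrix <- function(genotypes, path) {
  df <- data.frame(sample_id = genotypes$sample_ids,
                   genotypes$dosages, check.names = FALSE,
                   stringsAsFactors = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a plain dosage matrix
#'
#' @param path path to a file written by [write_dosage_matrix()].
#' @param variants optional variant metadata (id, chrom, pos, ref, alt);
#'   minimal placeholder metadata is constructed when omitted.
#' @param population optional population labels.
#' @return A [genotype_set()].
#' @export
read_dosage_matrix <- function(path, variants = NULL, population = NULL) {
  df <- utils::read.table(path, header = TRUE, sep = "\t", check.names = FALSE,
                          stringsAsFactors = FALSE)
  ids <- df$sample_id
  d <- as.matrix(df[, setdiff(names(df), "sample_id"), drop = FALSE])
  if (is.null(variants))
    variants <- data.frame(id = colnames(d), chrom = NA_character_,
                           pos = NA_integer_, ref = NA_character_,
                           alt = NA_character_, stringsAsFactors = FALSE)
  genotype_set(d, variants, ids, population)
}

#' Write the per-sample covariate/phenotype table
#'
#' Tab-delimited, one row per sample; missing onset ages are written as
#' empty fields.
#'
#' @param covariates data.frame.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_covariates <- function(covariates, path) {
  utils::write.table(covariates, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, na = "")
  invisible(path)
}

#' Read a covariate/phenotype table written by [write_covariates()]
#'
#' @param path input path.
#' @return data.frame.
#' @export
read_covariates <- function(path) {
  utils::read.table(path, header = TRUE, sep = "\t", check.names = FALSE,
                    na.strings = "", stringsAsFactors = FALSE)
}

#' Write relatedness pairs
#'
#' @param pairs data.frame with columns id1, id2, kinship.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_relatedness_pairs <- function(pairs, path) {
  utils::write.table(pairs, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read relatedness pairs
#'
#' @param path input path.
#' @return data.frame with columns id1, id2, kinship.
#' @export
read_relatedness_pairs <- function(path) {
  utils::read.table(path, header = TRUE, sep = "\t",
                    stringsAsFactors = FALSE)
}

#' Serialize a PC model as a tab-delimited loadings file
#'
#' Header lines (`#`-prefixed) carry the component variances and the
#' per-population centroids; the table body has one row per variant with its
#' center, scale, and loadings. Reference scores are not serialized; the
#' reconstructed model supports projection and ancestry assignment.
#'
#' @param model a `pc_model`.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_pc_model <- function(model, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(paste0("#variances=", paste(format(model$variances, digits = 17),
                                         collapse = ",")), con)
  for (lab in rownames(model$centroids)) {
    writeLines(paste0("#centroid=", lab, ":",
                      paste(format(model$centroids[lab, ], digits = 17),
                            collapse = ",")), con)
  }
  df <- data.frame(variant_id = model$variant_id,
                   center = model$center, scale = model$scale,
                   model$loadings, check.names = FALSE)
  utils::write.table(format(df, digits = 17), con, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' Read a PC model written by [write_pc_model()]
#'
#' @param path input path.
#' @return A `pc_model` (without reference scores).
#' @export
read_pc_model <- function(path) {
  lines <- readLines(path)
  hdr <- lines[startsWith(lines, "#")]
  body <- lines[!startsWith(lines, "#")]
  df <- utils::read.table(text = body, header = TRUE, sep = "\t",
                          check.names = FALSE, stringsAsFactors = FALSE)
  pc_cols <- grep("^PC", names(df), value = TRUE)
  loadings <- as.matrix(df[, pc_cols, drop = FALSE])
  variances <- as.numeric(strsplit(sub("^#variances=", "",
                                       hdr[startsWith(hdr, "#variances=")]),
                                   ",")[[1]])
  cen_lines <- hdr[startsWith(hdr, "#centroid=")]
  cen <- do.call(rbind, lapply(cen_lines, function(x) {
    kv <- strsplit(sub("^#centroid=", "", x), ":")[[1]]
    as.numeric(strsplit(kv[2], ",")[[1]])
  }))
  rownames(cen) <- vapply(cen_lines, function(x)
    strsplit(sub("^#centroid=", "", x), ":")[[1]][1], character(1),
    USE.NAMES = FALSE)
  colnames(cen) <- pc_cols
  structure(list(variant_id = df$variant_id, center = df$center,
                 scale = df$scale, loadings = loadings,
                 variances = variances, scores = NULL, centroids = cen,
                 populations = NULL), class = "pc_model")
}

#' Write all cohort artifacts to a directory
#'
#' Emits the standard pipeline inputs: `genotypes.vcf`, `dosages.tsv`,
#' `scoring.txt` (PGS dialect), and `covariates.tsv`.
#'
#' @param cohort a `simulated_cohort`.
#' @param dir output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_cohort <- function(cohort, dir) {
  stopifnot(inherits(cohort, "simulated_cohort"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  write_vcf(cohort$genotypes, file.path(dir, "genotypes.vcf"))
  write_dosage_matrix(cohort$genotypes, file.path(dir, "dosages.tsv"))
  write_scoring_file(cohort$scoring, file.path(dir, "scoring.txt"))
  write_covariates(cohort$covariates, file.path(dir, "covariates.tsv"))
  invisible(dir)
}
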