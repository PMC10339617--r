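#' Read a PGS-Catalog-format scoring file
#'
#' Parses the tab-separated dialect used by the PGS Catalog: any number of
#' '#'-prefixed header lines, then a column header and one record per
#' variant. Column aliases `rsID`/`rsid` and `effect_weight`/`beta` are
#' accepted.
#'
#' @param path path to the scoring file.
#' @return A `scoring_file` data.frame with columns rsID, chr_name,
#'   chr_position (where present), effect_allele, other_allele, effect_weight.
#' @export
read_scoring_file <- function(path) {
  lines <- readLines(path)
  body <- lines[!startsWith(lines, "#")]
  if (length(body) < 2) stop("scoring file has no records: ", path)
  df <- utils::read.table(text = body, header = TRUE, sep = "\t",
                          colClasses = "character", quote = "",
                          check.names = FALSE, stringsAsFactors = FALSE)
  nm <- names(df)
  nm[nm == "rsid"] <- "rsID"
  nm[nm == "beta"] <- "effect_weight"
  names(df) <- nm
  for (col in c("rsID", "effect_allele", "other_allele", "effect_weight")) {
    if (!col %in% names(df))
      stop("scoring file is missing mandatory column '", col, "'")
  }
  w <- suppressWarnings(as.numeric(df$effect_weight))
  if (anyNA(w)) {
    bad <- which(is.na(w))[1]
    stop("non-numeric effect_weight at record line ", bad + 1L,
         " of the table body: '", df$effect_weight[bad], "'")
  }
  df$effect_weight <- w
  if (!is.finite(sum(w))) stop("effect weights must be finite")
  if ("chr_position" %in% names(df))
    df$chr_position <- as.integer(df$chr_position)
  dup <- df$rsID[duplicated(df$rsID)]
  if (length(dup))
    stop("duplicate variant id(s) in scoring file: ",
         paste(unique(dup), collapse = ", "))
  bad_allele <- !(df$effect_allele %in% c("A", "C", "G", "T")) |
    !(df$other_allele %in% c("A", "C", "G", "T"))
  if (any(bad_allele))
    stop("non-ACGT alleles for variant(s): ",
         paste(df$rsID[bad_allele], collapse = ", "))
  class(df) <- c("scoring_file", "data.frame")
  df
}

#' Write a scoring file in the PGS Catalog dialect
#'
#' @param scoring a `scoring_file` data.frame.
#' @param path output path.
#' @param header_fields named character vector written as `#key=value` lines.
#' @return `path`, invisibly.
#' @export
write_scoring_file <- function(scoring, path,
                               header_fields = c(genome_build = "GRCh37")) {
  con <- file(path, "w")
  on.exit(close(con))
  if (length(header_fields))
    writeLines(paste0("#", names(header_fields), "=", header_fields), con)
  cols <- intersect(c("rsID", "chr_name", "chr_position", "effect_allele",
                      "other_allele", "effect_weight"), names(scoring))
  writeLines(paste(cols, collapse = "\t"), con)
  body <- do.call(paste, c(lapply(scoring[cols], as.character), sep = "\t"))
  writeLines(body, con)
  invisible(path)
}

COMPLEMENT <- c(A = "T", C = "G", G = "C", T = "A")

#' Identify strand-ambiguous allele pairs
#'
#' A variant is strand-ambiguous when its two alleles are complements (A/T
#' or C/G), so the strand convention of the discovery study cannot be
#' resolved; such records are excluded from scoring.
#'
#' @param effect,other allele vectors (A/C/G/T).
#' @return Logical vector.
#' @export
is_strand_ambiguous <- function(effect, other) {
  unname(COMPLEMENT[effect] == other)
}

#' Harmonize scoring records against genotype variants
#'
#' Matches each scoring record to a genotype variant (by id, falling back to
#' chromosome + position) and determines the dosage orientation:
#' strand-ambiguous records (A/T or C/G allele pairs) are excluded, since
#' their strand cannot be resolved; records whose effect allele is the
#' genotype ALT are used as-is; records whose effect allele is the REF are
#' flipped (dosage 2 - d); records matching only after strand complement are
#' complemented and then the same two rules apply; anything else is
#' unmatched and dropped.
#'
#' @param scoring a `scoring_file`.
#' @param genotypes a [genotype_set()].
#' @return A list with `matched` (data.frame: rsID, variant_id, effect_weight,
#'   flip, strand_complement) and `report` (named counts: matched, as_is,
#'   flipped, complemented, ambiguous_excluded, allele_mismatch, not_found).
#' @export
harmonize <- function(scoring, genotypes) {
  v <- genotypes$variants
  idx <- match(scoring$rsID, v$id)
  if ("chr_position" %in% names(scoring) && anyNA(idx)) {
    key_g <- paste(v$chrom, v$pos)
    key_s <- paste(scoring$chr_name, scoring$chr_position)
    idx[is.na(idx)] <- match(key_s[is.na(idx)], key_g)
  }
  n <- nrow(scoring)
  status <- character(n)
  status[is.na(idx)] <- "not_found"
  eff <- scoring$effect_allele
  oth <- scoring$other_allele
  amb <- is_strand_ambiguous(eff, oth)
  status[amb & is.na(status) | (amb & status == "")] <- "ambiguous_excluded"
  todo <- which(status == "")
  ref <- v$ref[idx[todo]]
  alt <- v$alt[idx[todo]]
  e <- eff[todo]; o <- oth[todo]
  ec <- unname(COMPLEMENT[e]); oc <- unname(COMPLEMENT[o])
  cls <- rep("allele_mismatch", length(todo))
  cls[e == alt & o == ref] <- "as_is"
  cls[e == ref & o == alt] <- "flipped"
  strand <- cls == "allele_mismatch" & ec == alt & oc == ref
  cls[strand] <- "complement_as_is"
  strand_fl <- cls == "allele_mismatch" & ec == ref & oc == alt
  cls[strand_fl] <- "complement_flipped"
  status[todo] <- cls
  keep <- status %in% c("as_is", "flipped", "complement_as_is",
                        "complement_flipped")
  if (!any(keep))
    stop("no scoring record could be matched to a genotype variant")
  matched <- data.frame(
    rsID = scoring$rsID[keep],
    variant_id = v$id[idx[keep]],
    effect_weight = scoring$effect_weight[keep],
    flip = status[keep] %in% c("flipped", "complement_flipped"),
    strand_complement = status[keep] %in% c("complement_as_is",
                                            "complement_flipped"),
    stringsAsFactors = FALSE)
  report <- c(matched = sum(keep),
              as_is = sum(status == "as_is"),
              flipped = sum(status == "flipped"),
              complemented = sum(startsWith(status, "complement")),
              ambiguous_excluded = sum(status == "ambiguous_excluded"),
              allele_mismatch = sum(status == "allele_mismatch"),
              not_found = sum(status == "not_found"))
  list(matched = matched, report = report)
}

#' Compute raw polygenic risk scores
#'
#' The canonical weighted sum `PRS_i = sum_j w_j d_ij` over harmonized
#' variants, with flipped records contributing `w_j (2 - d_ij)`. Missing
#' dosages are mean-imputed as `2 * f_j` with `f_j` the cohort effect-allele
#' frequency of the variant; variants with all dosages missing are dropped
#' with a warning.
#'
#' @param matched the `matched` table from [harmonize()].
#' @param genotypes a [genotype_set()].
#' @return Named numeric vector of raw scores, one per sample.
#' @export
compute_prs <- function(matched, genotypes) {
  if (nrow(matched) < 1) stop("need at least one matched variant")
  d <- genotypes$dosages[, matched$variant_id, drop = FALSE]
  # orient to the effect allele
  flip <- matched$flip
  d[, flip] <- 2 - d[, flip, drop = FALSE]
  if (anyNA(d)) {
    freq <- colMeans(d, na.rm = TRUE) / 2
    all_missing <- is.nan(freq)
    if (any(all_missing)) {
      warning("dropping variant(s) with all dosages missing: ",
              paste(matched$variant_id[all_missing], collapse = ", "))
      d <- d[, !all_missing, drop = FALSE]
      matched <- matched[!all_missing, , drop = FALSE]
      freq <- freq[!all_missing]
      if (nrow(matched) < 1) stop("no variant with observed dosages")
    }
    for (j in which(colSums(is.na(d)) > 0)) {
      d[is.na(d[, j]), j] <- 2 * freq[j]
    }
  }
  prs <- as.numeric(d %*% matched$effect_weight)
  names(prs) <- genotypes$sample_ids
  prs
}

#' Standardize a score vector
#'
#' Centers and scales by the whole-cohort mean and population
#' (n-denominator) standard deviation.
#'
#' @param x numeric vector, length >= 2.
#' @return z-scored vector (mean 0, sd 1 in the population convention).
#' @export
standardize <- function(x) {
  if (length(x) < 2) stop("need >= 2 values to standardize")
  if (anyNA(x)) stop("scores contain missing values")
  m <- mean(x)
  s <- sqrt(mean((x - m)^2))
  if (s == 0) stop("degenerate score distribution (zero variance)")
  (x - m) / s
}
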