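#' Expand a diagnosis-code pattern
#'
#' Two pattern forms beyond concrete codes are supported: bracketed numeric
#' ranges like `"K40.[1-4]"`, enumerated to `K40.1 ... K40.4`, and the `".X"`
#' wildcard like `"I21.X"`, retained as a prefix-match marker (it matches the
#' bare three-character rubric and any subcode, since diagnosis tables store
#' both). En dashes inside brackets are accepted.
#'
#' @param pattern a single code pattern.
#' @return Character vector of concrete codes and/or `".X"` prefix markers.
#' @export
expand_code_pattern <- function(pattern) {
  stopifnot(is.character(pattern), length(pattern) == 1L, nzchar(pattern))
  if (grepl("\\[", pattern)) {
    m <- regmatches(pattern,
                    regexec("^(.+)\\.\\[([0-9])[–-]([0-9])\\]$", pattern))[[1]]
    if (length(m) != 4)
      stop("malformed bracket range in pattern: '", pattern, "'")
    lo <- as.integer(m[3]); hi <- as.integer(m[4])
    if (lo > hi)
      stop("empty bracket range in pattern: '", pattern, "'")
    return(paste0(m[2], ".", lo:hi))
  }
  pattern
}

normalize_code <- function(code) gsub("\\.", "", toupper(trimws(code)))

# TRUE where `codes` matches any expanded pattern: ".X" patterns match the
# bare rubric or any suffix; concrete patterns match exactly (dots ignored).
codes_match <- function(codes, patterns) {
  expanded <- unlist(lapply(patterns, expand_code_pattern))
  wild <- grepl("\\.X$", expanded)
  prefixes <- normalize_code(sub("\\.X$", "", expanded[wild]))
  exact <- normalize_code(expanded[!wild])
  nc <- normalize_code(codes)
  hit <- nc %in% exact
  for (p in prefixes) hit <- hit | startsWith(nc, p)
  hit
}

#' Construct a diagnosis code set
#'
#' @param icd10,icd9,opcs4 character vectors of code patterns (concrete,
#'   `".X"` wildcard, or bracketed range).
#' @param self_report numeric self-reported illness codes.
#' @return An object of class `code_set`.
#' @export
code_set <- function(icd10 = character(0), icd9 = character(0),
                     opcs4 = character(0), self_report = numeric(0)) {
  lapply(c(icd10, icd9, opcs4), expand_code_pattern) # validate eagerly
  structure(list(icd10 = icd10, icd9 = icd9, opcs4 = opcs4,
                 self_report = self_report), class = "code_set")
}

#' Coronary artery disease code set
#'
#' ICD-10 I21.X/I22.X/I23.X/I24.1/I25.2, ICD-9 410.X/411.0/412.X/429.79,
#' OPCS-4 revascularization procedure ranges, self-report code 1075.
#'
#' @return A `code_set`.
#' @export
cad_code_set <- function() {
  code_set(
    icd10 = c("I21.X", "I22.X", "I23.X", "I24.1", "I25.2"),
    icd9 = c("410.X", "411.0", "412.X", "429.79"),
    opcs4 = c("K40.[1-4]", "K41.[1-4]", "K45.[1-5]", "K49.[1-2]",
              "K49.[8-9]", "K50.2", "K75.[1-4]", "K75.[8-9]"),
    self_report = 1075)
}

#' Type 2 diabetes code set
#'
#' ICD-10 E11.X and self-report code 1223.
#'
#' @return A `code_set`.
#' @export
t2d_code_set <- function() {
  code_set(icd10 = "E11.X", self_report = 1223)
}

#' Derive case status from long-format diagnosis records
#'
#' A sample is a case iff any of its records matches any pattern of the code
#' set within the record's own system (union across systems; self-reported
#' evidence counts the same as hospital codes).
#'
#' @param diagnoses data.frame with columns sample_id, system (ICD10, ICD9,
#'   OPCS4 or SELF), code.
#' @param codeset a [code_set()].
#' @param sample_ids ids of the full cohort (samples without matching records
#'   are controls).
#' @return Named 0/1 integer vector over `sample_ids`.
#' @export
derive_case_status <- function(diagnoses, codeset, sample_ids) {
  stopifnot(inherits(codeset, "code_set"))
  stopifnot(all(c("sample_id", "system", "code") %in% names(diagnoses)))
  known <- c("ICD10", "ICD9", "OPCS4", "SELF")
  bad <- setdiff(unique(diagnoses$system), known)
  if (length(bad))
    stop("unknown code system tag(s): ", paste(bad, collapse = ", "))
  hit <- rep(FALSE, nrow(diagnoses))
  sys_map <- c(ICD10 = "icd10", ICD9 = "icd9", OPCS4 = "opcs4")
  for (tag in names(sys_map)) {
    pats <- codeset[[sys_map[[tag]]]]
    i <- diagnoses$system == tag
    if (length(pats) && any(i))
      hit[i] <- codes_match(diagnoses$code[i], pats)
  }
  i <- diagnoses$system == "SELF"
  if (any(i) && length(codeset$self_report))
    hit[i] <- suppressWarnings(as.numeric(diagnoses$code[i])) %in%
      codeset$self_report
  case_ids <- unique(diagnoses$sample_id[hit])
  out <- as.integer(sample_ids %in% case_ids)
  names(out) <- sample_ids
  out
}

#' Obesity indicator from BMI
#'
#' 1 iff BMI is strictly greater than 25 kg/m^2; missing BMI yields NA so
#' the sample is excluded from the obesity analysis rather than coded 0.
#'
#' @param bmi numeric BMI values (kg/m^2).
#' @return 0/1/NA integer vector.
#' @export
derive_obesity <- function(bmi) {
  ok <- is.na(bmi) | (is.finite(bmi) & bmi > 0)
  if (!all(ok)) stop("BMI must be positive and finite (or NA)")
  ifelse(is.na(bmi), NA_integer_, as.integer(bmi > 25))
}

#' Apply sample quality-control exclusions
#'
#' Removes samples with any QC flag set (sex discordance, sex-chromosome
#' aneuploidy, heterozygosity/missingness outlier) and logs counts per
#' reason; a sample flagged for several reasons is removed once but counted
#' under each.
#'
#' @param table covariate data.frame with 0/1 columns whose names start with
#'   `qc_`.
#' @return list with `table` (filtered) and `log` (data.frame reason, n).
#' @export
apply_qc_filters <- function(table) {
  qc_cols <- grep("^qc_", names(table), value = TRUE)
  if (!length(qc_cols)) stop("no qc_ flag columns present")
  flags <- as.matrix(table[, qc_cols, drop = FALSE]) == 1
  log <- data.frame(reason = qc_cols, n = colSums(flags),
                    row.names = NULL, stringsAsFactors = FALSE)
  keep <- rowSums(flags) == 0
  list(table = table[keep, , drop = FALSE], log = log,
       n_excluded = sum(!keep))
}

#' Prune related samples to an unrelated set
#'
#' Considering the graph of sample pairs with kinship above the threshold
#' (default 0.0884, the second-degree boundary), removes samples until no
#' edge remains: components that are bare pairs lose one member at random
#' (seeded); in larger components the highest-degree sample is removed
#' iteratively (ties broken by seeded draw among id-sorted candidates),
#' guaranteeing an independent set. Pairs referencing unknown ids are
#' skipped with a warning.
#'
#' @param table covariate data.frame with a `sample_id` column.
#' @param pairs data.frame with columns id1, id2, kinship.
#' @param threshold kinship threshold (default 0.0884).
#' @param seed RNG seed for the random retention.
#' @return list with `table` (pruned) and `removed` (character ids).
#' @export
prune_relatedness <- function(table, pairs, threshold = 0.0884, seed = 1) {
  ids <- table$sample_id
  if (is.null(ids)) stop("table must contain a sample_id column")
  if (nrow(pairs) == 0)
    return(list(table = table, removed = character(0)))
  stopifnot(all(c("id1", "id2", "kinship") %in% names(pairs)))
  unknown <- !(pairs$id1 %in% ids) | !(pairs$id2 %in% ids)
  if (any(unknown)) {
    warning(sum(unknown), " relatedness pair(s) reference unknown ids; skipped")
    pairs <- pairs[!unknown, , drop = FALSE]
  }
  e <- pairs[pairs$kinship > threshold, c("id1", "id2"), drop = FALSE]
  # canonical edge order so the result is invariant to input permutation
  swap <- e$id1 > e$id2
  tmp <- e$id1[swap]; e$id1[swap] <- e$id2[swap]; e$id2[swap] <- tmp
  e <- unique(e[order(e$id1, e$id2), , drop = FALSE])
  removed <- character(0)
  with_substream(seed, "prune.relatedness", {
    while (nrow(e) > 0) {
      deg <- table(c(e$id1, e$id2))
      if (max(deg) > 1) {
        cand <- sort(names(deg)[deg == max(deg)])
        pick <- if (length(cand) == 1) cand else sample(cand, 1)
      } else {
        # only isolated pairs remain: drop a random member of the first edge
        pick <- sample(c(e$id1[1], e$id2[1]), 1)
      }
      removed <- c(removed, pick)
      e <- e[e$id1 != pick & e$id2 != pick, , drop = FALSE]
    }
  })
  list(table = table[!(ids %in% removed), , drop = FALSE], removed = removed)
}
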