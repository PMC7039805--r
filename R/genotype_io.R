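# Cohort table I/O, allele nomenclature normalisation, record validation.
#
# Cohort file dialect: tab-separated, one row per subject, columns
#   family_id, subject_id, role, disease, n_live_births,
#   born_before_diagnosis, then per-locus allele pairs <locus>_1, <locus>_2
#   (A_1, A_2, ..., DRB1_2, rs1051266_1, ..., rs3745526_2).
# Missing = "NA" (empty string also accepted on read).

MISSING_TOKENS <- c("", "NA")

#' Normalise an HLA or SNP allele name
#'
#' HLA names are uppercased, an optional `HLA-` prefix is stripped, and
#' names with more than two fields are truncated to two-field (protein
#' level) resolution, e.g. `"hla-b*07:02:01"` becomes `"B*07:02"`.
#' SNP alleles must be a single base in `A`, `C`, `G`, `T`. The missing
#' token `"NA"` (or an empty string) maps to `NA`.
#'
#' @param raw character vector of allele names as found in a genotype file.
#' @param locus single locus identifier: one of `"A"`, `"B"`, `"C"`,
#'   `"DPB1"`, `"DQA1"`, `"DQB1"`, `"DRB1"`, or an rsID for an mHag SNP.
#' @return character vector of canonical allele names (`NA` where missing).
#'   Normalisation is idempotent.
#' @examples
#' normalize_allele("hla-b*07:02:01", "B")  # "B*07:02"
#' normalize_allele(c("G", "NA"), "rs2074071")
#' @export
normalize_allele <- function(raw, locus) {
  res <- normalize_allele_quietly(raw, locus)
  if (any(res$bad)) {
    stop(sprintf("malformed allele name(s) at locus %s: %s", locus,
                 paste(unique(raw[res$bad]), collapse = ", ")), call. = FALSE)
  }
  res$value
}

# Vectorised worker: returns list(value=, bad=) so readers can collect
# validation failures instead of failing on the first one.
normalize_allele_quietly <- function(raw, locus) {
  x <- trimws(as.character(raw))
  miss <- is.na(x) | x %in% MISSING_TOKENS
  value <- rep(NA_character_, length(x))
  bad <- rep(FALSE, length(x))
  act <- !miss
  if (any(act)) {
    if (is_snp_locus(locus)) {
      v <- toupper(x[act])
      ok <- v %in% c("A", "C", "G", "T")
      value[act][ok] <- v[ok]
      bad[act][!ok] <- TRUE
    } else {
      v <- toupper(sub("^HLA-", "", x[act], ignore.case = TRUE))
      # two or more colon-separated numeric fields after "<LOCUS>*"
      pat <- sprintf("^%s\\*[0-9]+:[0-9]+(:[0-9A-Z]+)*[A-Z]?$", toupper(locus))
      ok <- grepl(pat, v)
      # truncate to two fields, dropping any expression suffix letter
      two <- sub(sprintf("^(%s\\*[0-9]+:[0-9]+).*$", toupper(locus)), "\\1",
                 v[ok])
      value[act][ok] <- two
      bad[act][!ok] <- TRUE
    }
  }
  list(value = value, bad = bad)
}

subject_columns <- function(hla_loci, snp_loci) {
  loci <- c(hla_loci, snp_loci)
  c("family_id", "subject_id", "role", "disease", "n_live_births",
    "born_before_diagnosis",
    as.vector(rbind(paste0(loci, "_1"), paste0(loci, "_2"))))
}

#' Construct a validated cohort object
#'
#' A cohort is a table of subjects (mothers and children) with unordered
#' two-allele genotypes at each locus. Children are linked to their mother
#' through `family_id`; each family must contain exactly one mother.
#'
#' @param subjects data.frame with the cohort-file columns (see
#'   [read_cohort()]).
#' @param hla_loci,snp_loci character vectors of locus names present as
#'   `<locus>_1`/`<locus>_2` column pairs.
#' @return an object of class `hla_cohort`: a list with elements
#'   `subjects` (the validated table), `hla_loci`, `snp_loci`.
#' @export
new_cohort <- function(subjects, hla_loci = HLA_LOCI, snp_loci = MHAG_SNPS) {
  cohort <- structure(list(subjects = subjects, hla_loci = hla_loci,
                           snp_loci = snp_loci),
                      class = "hla_cohort")
  problems <- validate_cohort(cohort)
  if (length(problems))
    stop("invalid cohort:\n  ", paste(problems, collapse = "\n  "),
         call. = FALSE)
  cohort
}

#' Validate a cohort, collecting all problems
#'
#' Checks structural integrity (required columns, unique subject ids,
#' every child resolving to exactly one mother, no half-called genotypes,
#' valid roles and disease labels, case mothers having at least as many
#' live births as enrolled pre-diagnosis children). All problems are
#' collected and reported together rather than failing at the first.
#'
#' @param cohort an `hla_cohort` (or a bare list with the same fields).
#' @return character vector of problem descriptions; empty if valid.
#' @export
validate_cohort <- function(cohort) {
  s <- cohort$subjects
  problems <- character()
  need <- subject_columns(cohort$hla_loci, cohort$snp_loci)
  miss_col <- setdiff(need, names(s))
  if (length(miss_col))
    return(paste("missing column(s):", paste(miss_col, collapse = ", ")))
  dup <- s$subject_id[duplicated(s$subject_id)]
  if (length(dup))
    problems <- c(problems,
                  paste("duplicate subject_id:", paste(unique(dup), collapse = ", ")))
  bad_role <- !s$role %in% c("mother", "child")
  if (any(bad_role))
    problems <- c(problems,
                  paste("invalid role for subject(s):",
                        paste(s$subject_id[bad_role], collapse = ", ")))
  mothers <- s[s$role == "mother", , drop = FALSE]
  children <- s[s$role == "child", , drop = FALSE]
  tab <- table(mothers$family_id)
  multi <- names(tab)[tab > 1]
  if (length(multi))
    problems <- c(problems,
                  paste("families with more than one mother:",
                        paste(multi, collapse = ", ")))
  orphan <- setdiff(unique(children$family_id), mothers$family_id)
  if (length(orphan))
    problems <- c(problems,
                  paste("children without a mother row (family_id):",
                        paste(orphan, collapse = ", ")))
  bad_dis <- !is.na(mothers$disease) &
    !mothers$disease %in% c("RA", "SLE", "control")
  if (any(bad_dis))
    problems <- c(problems,
                  paste("invalid disease label for mother(s):",
                        paste(mothers$subject_id[bad_dis], collapse = ", ")))
  if (any(!is.na(children$disease)))
    problems <- c(problems,
                  paste("children must not carry a disease label:",
                        paste(children$subject_id[!is.na(children$disease)],
                              collapse = ", ")))
  nlb <- mothers$n_live_births
  if (any(!is.na(nlb) & (nlb < 0 | nlb != round(nlb))))
    problems <- c(problems, "n_live_births must be a non-negative integer")
  # case mothers: live births >= enrolled children born before diagnosis
  case_m <- mothers[!is.na(mothers$disease) & mothers$disease != "control", ,
                    drop = FALSE]
  if (nrow(case_m)) {
    pre <- children[!is.na(children$born_before_diagnosis) &
                      children$born_before_diagnosis, , drop = FALSE]
    n_pre <- table(factor(pre$family_id, levels = case_m$family_id))
    short <- !is.na(case_m$n_live_births) &
      case_m$n_live_births < as.integer(n_pre)
    if (any(short))
      problems <- c(problems,
                    paste("case mother(s) with fewer live births than",
                          "enrolled pre-diagnosis children:",
                          paste(case_m$subject_id[short], collapse = ", ")))
  }
  # half-called genotypes
  for (locus in c(cohort$hla_loci, cohort$snp_loci)) {
    a1 <- s[[paste0(locus, "_1")]]
    a2 <- s[[paste0(locus, "_2")]]
    half <- xor(is.na(a1), is.na(a2))
    if (any(half))
      problems <- c(problems,
                    sprintf("half-called genotype at %s for subject(s): %s",
                            locus, paste(s$subject_id[half], collapse = ", ")))
  }
  problems
}

#' Read a cohort genotype table
#'
#' Reads the tab-separated cohort dialect (see [new_cohort()] for the
#' layout), normalises every allele name to canonical form, and validates
#' the result. Rows or cells that fail validation are collected into a
#' single error report naming each offending subject and column, rather
#' than being silently dropped.
#'
#' @param path path to a tab-separated cohort file.
#' @param hla_loci,snp_loci loci expected as column pairs.
#' @return an `hla_cohort`.
#' @seealso [write_cohort()] for the inverse; a write/read round trip is
#'   record-identical modulo normalisation.
#' @export
read_cohort <- function(path, hla_loci = HLA_LOCI, snp_loci = MHAG_SNPS) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  raw <- read.delim(path, colClasses = "character", na.strings = MISSING_TOKENS,
                    check.names = FALSE)
  need <- subject_columns(hla_loci, snp_loci)
  miss_col <- setdiff(need, names(raw))
  if (length(miss_col))
    stop("cohort file lacks column(s): ", paste(miss_col, collapse = ", "),
         call. = FALSE)
  problems <- character()
  s <- raw[need]
  s$n_live_births <- suppressWarnings(as.integer(s$n_live_births))
  s$born_before_diagnosis <- as.logical(s$born_before_diagnosis)
  for (locus in c(hla_loci, snp_loci)) {
    for (k in 1:2) {
      col <- paste0(locus, "_", k)
      res <- normalize_allele_quietly(s[[col]], locus)
      if (any(res$bad))
        problems <- c(problems,
                      sprintf("malformed allele in column %s, subject(s) %s: %s",
                              col,
                              paste(s$subject_id[res$bad], collapse = ", "),
                              paste(unique(s[[col]][res$bad]), collapse = ", ")))
      s[[col]] <- res$value
    }
  }
  if (length(problems))
    stop("cohort file failed validation:\n  ",
         paste(problems, collapse = "\n  "), call. = FALSE)
  new_cohort(s, hla_loci = hla_loci, snp_loci = snp_loci)
}

#' Write a cohort genotype table
#'
#' @param cohort an `hla_cohort`.
#' @param path output path (tab-separated; missing values written as `NA`).
#' @return `path`, invisibly.
#' @export
write_cohort <- function(cohort, path) {
  write.table(cohort$subjects, path, sep = "\t", quote = FALSE,
              row.names = FALSE, na = "NA")
  invisible(path)
}

#' Read HLA allele protein sequences from a FASTA file
#'
#' Headers are parsed for an allele name (e.g. the header
#' `"HLA:HLA00132 B*07:02:01:01"` yields the key `"B*07:02"`); names are
#' normalised to two-field resolution. When several records normalise to
#' the same two-field name the first is kept with a warning, matching the
#' convention that two-field resolution identifies the protein.
#'
#' @param fasta_path path to an amino-acid FASTA file; sequences used for
#'   SSM scoring must be pre-aligned to equal length within a locus.
#' @return named character vector mapping canonical allele names to
#'   amino-acid sequences.
#' @export
read_allele_sequences <- function(fasta_path) {
  # Biostrings drops invalid residue codes with a warning; that silently
  # shifts alignment columns, so treat it as an error instead
  seqs <- withCallingHandlers(
    Biostrings::readAAStringSet(fasta_path),
    warning = function(w) {
      if (grepl("invalid one-letter sequence codes", conditionMessage(w)))
        stop("non-amino-acid characters in ", fasta_path, call. = FALSE)
    })
  if (length(seqs) == 0) {
    warning("no sequences found in ", fasta_path)
    return(setNames(character(0), character(0)))
  }
  headers <- names(seqs)
  keys <- vapply(headers, function(h) {
    tokens <- strsplit(trimws(h), "\\s+")[[1]]
    hit <- grep("\\*[0-9]+:[0-9]+", tokens, value = TRUE)
    if (!length(hit)) return(NA_character_)
    v <- toupper(sub("^HLA-", "", hit[1], ignore.case = TRUE))
    sub("^([A-Z0-9]+\\*[0-9]+:[0-9]+).*$", "\\1", v)
  }, character(1), USE.NAMES = FALSE)
  if (anyNA(keys))
    stop("FASTA header(s) with no parseable allele name: ",
         paste(headers[is.na(keys)], collapse = "; "), call. = FALSE)
  sq <- toupper(as.character(seqs))
  bad <- grepl("[^ACDEFGHIKLMNPQRSTVWY]", sq)
  if (any(bad))
    stop("non-amino-acid characters in sequence(s): ",
         paste(keys[bad], collapse = ", "), call. = FALSE)
  if (anyDuplicated(keys)) {
    dup <- unique(keys[duplicated(keys)])
    warning("duplicate two-field allele name(s), keeping first occurrence: ",
            paste(dup, collapse = ", "))
    keep <- !duplicated(keys)
    keys <- keys[keep]
    sq <- sq[keep]
  }
  setNames(sq, keys)
}

#' @export
print.hla_cohort <- function(x, ...) {
  s <- x$subjects
  m <- s[s$role == "mother", , drop = FALSE]
  cat("<hla_cohort> ", nrow(m), " mothers, ", sum(s$role == "child"),
      " children\n", sep = "")
  if (nrow(m)) {
    tab <- table(factor(ifelse(is.na(m$disease), "control", m$disease),
                        levels = c("RA", "SLE", "control")))
    cat("  mothers by group: ",
        paste(names(tab), as.integer(tab), sep = "=", collapse = ", "), "\n",
        sep = "")
  }
  cat("  HLA loci: ", paste(x$hla_loci, collapse = ", "), "\n", sep = "")
  cat("  mHag SNPs: ", paste(x$snp_loci, collapse = ", "), "\n", sep = "")
  invisible(x)
}
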