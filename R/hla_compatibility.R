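# Paternal-allele inference from unphased mother-child genotypes and
# mother-perspective compatibility classification.
#
# The rule: a child is histocompatible from the mother's perspective at a
# locus when the paternally inherited allele is indistinguishable from one
# of the mother's two alleles. With unphased genotypes this collapses to:
# compatible <=> both child alleles are members of the mother's allele set
# (proved against a phase-enumeration oracle in the test suite).

# Vectorised inference over aligned allele vectors (mother a1/a2, child
# a1/a2). Matching consumes multiplicity: only one maternal allele is
# transmitted, so a homozygous mother {m,m} can transmit only m.
infer_paternal_vec <- function(m1, m2, c1, c2) {
  n <- length(m1)
  status <- rep("resolved", n)
  paternal <- rep(NA_character_, n)
  maternal_transmitted <- rep(NA_character_, n)
  noninherited <- rep(NA_character_, n)

  miss <- is.na(m1) | is.na(m2) | is.na(c1) | is.na(c2)
  in1 <- !miss & (c1 == m1 | c1 == m2)
  in2 <- !miss & (c2 == m1 | c2 == m2)

  status[miss] <- "missing"
  err <- !miss & !in1 & !in2
  status[err] <- "mendelian_error"

  # exactly one child allele matches the mother: forced assignment
  one1 <- in1 & !in2                    # c1 maternal, c2 paternal
  maternal_transmitted[one1] <- c1[one1]
  paternal[one1] <- c2[one1]
  noninherited[one1] <- ifelse(c1[one1] == m1[one1], m2[one1], m1[one1])
  one2 <- in2 & !in1
  maternal_transmitted[one2] <- c2[one2]
  paternal[one2] <- c1[one2]
  noninherited[one2] <- ifelse(c2[one2] == m1[one2], m2[one2], m1[one2])

  both <- in1 & in2
  # homozygous child within the mother's set: the unique Mendelian
  # assignment transmits that allele and the father contributed a copy too
  hom <- both & c1 == c2
  maternal_transmitted[hom] <- c1[hom]
  paternal[hom] <- c1[hom]
  noninherited[hom] <- ifelse(c1[hom] == m1[hom], m2[hom], m1[hom])
  # heterozygous child, both alleles maternal: phase cannot be resolved
  amb <- both & c1 != c2
  status[amb] <- "ambiguous_both_maternal"

  data.frame(status = status, paternal = paternal,
             maternal_transmitted = maternal_transmitted,
             noninherited = noninherited,
             compatible = ifelse(miss | err, NA, both),
             stringsAsFactors = FALSE)
}

#' Infer the paternally inherited allele for one mother-child pair
#'
#' Shared-allele logic over unordered genotypes with multiplicity: a child
#' allele found in the mother's set is a candidate maternal transmission;
#' the remaining child allele is the paternal candidate. When both child
#' alleles are maternal and distinct, phase cannot be resolved
#' (`ambiguous_both_maternal`) and both alleles are paternal candidates.
#' A child sharing no allele with the mother is a `mendelian_error`.
#'
#' @param mother,child length-2 character vectors of allele names at one
#'   locus (order irrelevant); `NA` marks a missing call.
#' @return a list of class `paternal_inference` with elements `status`
#'   (`"resolved"`, `"ambiguous_both_maternal"`, `"mendelian_error"` or
#'   `"missing"`), `paternal_candidates` (character set), and, when
#'   resolved, `maternal_transmitted` and `noninherited_maternal`.
#' @examples
#' infer_paternal(c("B*07:02", "B*08:01"), c("B*07:02", "B*44:02"))
#' @export
infer_paternal <- function(mother, child) {
  stopifnot(length(mother) == 2, length(child) == 2)
  v <- infer_paternal_vec(mother[1], mother[2], child[1], child[2])
  candidates <- switch(v$status,
    resolved = v$paternal,
    ambiguous_both_maternal = unique(c(child[1], child[2])),
    character(0))
  structure(list(status = v$status,
                 paternal_candidates = candidates,
                 maternal_transmitted = v$maternal_transmitted,
                 noninherited_maternal = v$noninherited),
            class = "paternal_inference")
}

#' @export
print.paternal_inference <- function(x, ...) {
  cat("<paternal_inference> status:", x$status, "\n")
  if (length(x$paternal_candidates))
    cat("  paternal candidate(s):",
        paste(x$paternal_candidates, collapse = ", "), "\n")
  if (!is.na(x$maternal_transmitted))
    cat("  maternal transmitted:", x$maternal_transmitted,
        "| noninherited maternal:", x$noninherited_maternal, "\n")
  invisible(x)
}

#' Classify one mother-child pair at one locus
#'
#' The child is `compatible` when every paternal candidate is a member of
#' the mother's allele set — equivalently, when both child alleles are in
#' the mother's set. Missing genotypes and Mendelian inconsistencies yield
#' `missing` and `mendelian_error` verdicts rather than errors.
#'
#' @inheritParams infer_paternal
#' @return a list with `verdict` (one of `"compatible"`, `"incompatible"`,
#'   `"missing"`, `"mendelian_error"`) and `inference` (see
#'   [infer_paternal()]).
#' @examples
#' classify_compatibility(c("DQB1*03:01", "DQB1*06:02"),
#'                        c("DQB1*03:01", "DQB1*06:02"))$verdict
#' @export
classify_compatibility <- function(mother, child) {
  inf <- infer_paternal(mother, child)
  verdict <- switch(inf$status,
    missing = "missing",
    mendelian_error = "mendelian_error",
    ambiguous_both_maternal = "compatible",
    resolved = if (inf$paternal_candidates %in% mother) "compatible"
               else "incompatible")
  list(verdict = verdict, inference = inf)
}

verdict_vec <- function(m1, m2, c1, c2) {
  v <- infer_paternal_vec(m1, m2, c1, c2)
  out <- ifelse(is.na(v$compatible),
                ifelse(v$status == "missing", "missing", "mendelian_error"),
                ifelse(v$compatible, "compatible", "incompatible"))
  v$verdict <- out
  v
}

# Align each child row with its mother's row; returns indices into subjects.
mother_index <- function(cohort) {
  s <- cohort$subjects
  mothers <- which(s$role == "mother")
  match(s$family_id, s$family_id[mothers])
}

#' Per-child compatibility calls across loci
#'
#' Runs the classifier for every child at each requested locus and flags
#' eligibility: for case mothers only children born before diagnosis count
#' (children with an unknown flag are excluded); all children of control
#' mothers are eligible.
#'
#' @param cohort an `hla_cohort`.
#' @param loci loci to classify (default: all HLA loci in the cohort).
#' @return data.frame with one row per child x locus: `family_id`,
#'   `child_id`, `mother_id`, `locus`, `verdict`, `paternal`,
#'   `noninherited`, `eligible`.
#' @export
compatibility_calls <- function(cohort, loci = cohort$hla_loci) {
  s <- cohort$subjects
  mothers <- s[s$role == "mother", , drop = FALSE]
  children <- s[s$role == "child", , drop = FALSE]
  mi <- match(children$family_id, mothers$family_id)
  m_disease <- ifelse(is.na(mothers$disease[mi]), "control",
                      mothers$disease[mi])
  eligible <- ifelse(m_disease == "control", TRUE,
                     !is.na(children$born_before_diagnosis) &
                       children$born_before_diagnosis)
  out <- lapply(loci, function(locus) {
    v <- verdict_vec(mothers[[paste0(locus, "_1")]][mi],
                     mothers[[paste0(locus, "_2")]][mi],
                     children[[paste0(locus, "_1")]],
                     children[[paste0(locus, "_2")]])
    data.frame(family_id = children$family_id,
               child_id = children$subject_id,
               mother_id = mothers$subject_id[mi],
               locus = locus,
               verdict = v$verdict,
               paternal = v$paternal,
               noninherited = v$noninherited,
               eligible = eligible,
               stringsAsFactors = FALSE)
  })
  do.call(rbind, out)
}

#' Per-mother any-compatible exposure at one locus
#'
#' The exposure of interest: does the mother have at least one eligible
#' child classified compatible at the locus? Children with missing
#' verdicts are excluded from the OR-over-children but tallied; a mother
#' with no eligible child carrying a usable verdict is `NA` (missing
#' exposure), never silently "no".
#'
#' @param cohort an `hla_cohort`.
#' @param locus a single locus name.
#' @param calls optional precomputed [compatibility_calls()] table.
#' @return data.frame with one row per mother: `mother_id`, `locus`,
#'   `any_compatible` (`"yes"`/`"no"`/`NA`), `n_children_used`,
#'   `n_children_missing`.
#' @export
mother_exposure <- function(cohort, locus, calls = NULL) {
  if (is.null(calls)) calls <- compatibility_calls(cohort, locus)
  cl <- calls[calls$locus == locus & calls$eligible, , drop = FALSE]
  mothers <- cohort$subjects[cohort$subjects$role == "mother", , drop = FALSE]
  usable <- cl[cl$verdict %in% c("compatible", "incompatible"), , drop = FALSE]
  f <- factor(usable$mother_id, levels = mothers$subject_id)
  n_used <- as.integer(table(f))
  any_comp <- as.integer(table(f[usable$verdict == "compatible"])) > 0
  fm <- factor(cl$mother_id[cl$verdict == "missing"],
               levels = mothers$subject_id)
  n_miss <- as.integer(table(fm))
  data.frame(mother_id = mothers$subject_id,
             locus = locus,
             any_compatible = ifelse(n_used == 0, NA_character_,
                                     ifelse(any_comp, "yes", "no")),
             n_children_used = n_used,
             n_children_missing = n_miss,
             stringsAsFactors = FALSE)
}

#' Wide per-mother exposure table over several loci
#'
#' @param cohort an `hla_cohort`.
#' @param loci loci to include.
#' @return data.frame with one row per mother: `mother_id`, `disease`
#'   (`NA` recoded to `"control"`), `n_live_births`, then one
#'   `any_<locus>` column per locus (`"yes"`/`"no"`/`NA`).
#' @export
exposure_table <- function(cohort, loci = cohort$hla_loci) {
  calls <- compatibility_calls(cohort, loci)
  mothers <- cohort$subjects[cohort$subjects$role == "mother", , drop = FALSE]
  out <- data.frame(mother_id = mothers$subject_id,
                    disease = ifelse(is.na(mothers$disease), "control",
                                     mothers$disease),
                    n_live_births = mothers$n_live_births,
                    stringsAsFactors = FALSE)
  for (locus in loci) {
    ex <- mother_exposure(cohort, locus, calls = calls)
    out[[paste0("any_", locus)]] <- ex$any_compatible[
      match(out$mother_id, ex$mother_id)]
  }
  out
}

#' Complete-case filter over a locus set
#'
#' Retains mothers whose any-compatible exposure is non-missing at every
#' requested locus (the complete-case analysis set), and tabulates
#' missingness by disease group at each locus for the selection-bias
#' chi-square test.
#'
#' @param exposures a wide table from [exposure_table()].
#' @param loci loci that must all be non-missing.
#' @return list with `complete` (the retained rows of `exposures`) and
#'   `missingness` (data.frame: `locus`, `group`, `n_missing`,
#'   `n_observed`).
#' @export
complete_case_filter <- function(exposures, loci) {
  cols <- paste0("any_", loci)
  stopifnot(all(cols %in% names(exposures)))
  keep <- rowSums(is.na(exposures[cols])) == 0
  groups <- unique(exposures$disease)
  missingness <- do.call(rbind, lapply(loci, function(locus) {
    m <- is.na(exposures[[paste0("any_", locus)]])
    do.call(rbind, lapply(groups, function(g) {
      sel <- exposures$disease == g
      data.frame(locus = locus, group = g,
                 n_missing = sum(m[sel]), n_observed = sum(!m[sel]),
                 stringsAsFactors = FALSE)
    }))
  }))
  if (!any(keep))
    warning("no mothers with complete exposure data at all requested loci")
  list(complete = exposures[keep, , drop = FALSE], missingness = missingness)
}
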