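# HLA-restricted minor histocompatibility antigen (mHag) compatibility.
#
# Each mHag is tagged by a SNP and presented only by a specific HLA
# restriction allele; mHag analyses are therefore restricted to mothers
# carrying that allele. SNP-level compatibility uses exactly the same
# mother-perspective rule as the HLA classifier, on a two-letter alphabet.

#' Shipped mHag definitions
#'
#' The six minor histocompatibility antigens analysed, their tag SNPs and
#' HLA restriction alleles: SLC19A1 (rs1051266, DRB1*15:01), LB-WNK1
#' (rs12828016, A*02:01), HA-3 (rs2061821, A*01:01), ZAPHIR (rs2074071,
#' B*07:02), HEATR1 (rs2275687, B*08:01), C19orf48 (rs3745526, A*02:01).
#'
#' @return data.frame with columns `name`, `rsid`, `restriction_allele`,
#'   `restriction_locus` (derived from the allele name).
#' @export
mhag_definitions <- function() {
  d <- data.frame(
    name = c("SLC19A1", "LB-WNK1", "HA-3", "ZAPHIR", "HEATR1", "C19orf48"),
    rsid = c("rs1051266", "rs12828016", "rs2061821", "rs2074071",
             "rs2275687", "rs3745526"),
    restriction_allele = c("DRB1*15:01", "A*02:01", "A*01:01", "B*07:02",
                           "B*08:01", "A*02:01"),
    stringsAsFactors = FALSE)
  d$restriction_locus <- sub("\\*.*$", "", d$restriction_allele)
  d
}

#' Does a mother carry an mHag's HLA restriction allele?
#'
#' Carriage-based (at least one copy), not dosage-based.
#'
#' @param mother_genotype length-2 character vector: the mother's alleles
#'   at the restriction locus.
#' @param restriction_allele the required HLA allele (e.g. `"B*07:02"`).
#' @return `TRUE`/`FALSE`, or `NA` when the genotype is missing (the
#'   mother is excluded from that mHag's analysis).
#' @export
carries_restriction <- function(mother_genotype, restriction_allele) {
  if (anyNA(mother_genotype)) return(NA)
  restriction_allele %in% mother_genotype
}

#' Classify mother-child compatibility at an mHag SNP
#'
#' Identical rule to [classify_compatibility()], applied to biallelic SNP
#' genotypes: the child is compatible from the mother's perspective iff
#' both child alleles are in the mother's set. In particular every
#' Mendelian child of a heterozygous mother is compatible.
#'
#' @param mother,child length-2 character vectors of SNP alleles
#'   (`A`/`C`/`G`/`T`).
#' @return as [classify_compatibility()].
#' @export
mhag_classify <- function(mother, child) classify_compatibility(mother, child)

#' Per-mother mHag exposures with HLA restriction
#'
#' For one mHag definition: flags restriction-allele carriage, and among
#' carriers computes two any-child exposures over eligible children
#' (eligibility as in [compatibility_calls()]):
#' `any_mhag_compatible` — any eligible child compatible at the SNP;
#' `any_hla_and_mhag_compatible` — any eligible child compatible at the
#' restriction HLA locus AND at the SNP, the conjunction evaluated per
#' child before OR-ing across children. The combined flag can therefore
#' never be "yes" when the mHag flag is not.
#'
#' @param cohort an `hla_cohort`.
#' @param def one row of [mhag_definitions()] (or a list with the same
#'   fields).
#' @return data.frame per mother: `mother_id`, `mhag`,
#'   `carries_restriction`, `any_mhag_compatible`,
#'   `any_hla_and_mhag_compatible` (the last two `NA` for non-carriers or
#'   mothers with no usable eligible child).
#' @export
mhag_exposure <- function(cohort, def) {
  s <- cohort$subjects
  mothers <- s[s$role == "mother", , drop = FALSE]
  carries <- vapply(seq_len(nrow(mothers)), function(i) {
    carries_restriction(
      c(mothers[[paste0(def$restriction_locus, "_1")]][i],
        mothers[[paste0(def$restriction_locus, "_2")]][i]),
      def$restriction_allele)
  }, logical(1))

  calls_snp <- compatibility_calls(cohort, def$rsid)
  calls_hla <- compatibility_calls(cohort, def$restriction_locus)
  stopifnot(identical(calls_snp$child_id, calls_hla$child_id))
  el <- calls_snp$eligible
  snp_ok <- calls_snp$verdict %in% c("compatible", "incompatible")
  both_ok <- snp_ok & calls_hla$verdict %in% c("compatible", "incompatible")

  lev <- mothers$subject_id
  or_over <- function(use, hit) {
    f <- factor(calls_snp$mother_id[use], levels = lev)
    n_used <- as.integer(table(f))
    n_hit <- as.integer(table(factor(calls_snp$mother_id[use & hit],
                                     levels = lev)))
    ifelse(n_used == 0, NA_character_, ifelse(n_hit > 0, "yes", "no"))
  }
  any_mhag <- or_over(el & snp_ok, calls_snp$verdict == "compatible")
  any_both <- or_over(el & both_ok,
                      calls_snp$verdict == "compatible" &
                        calls_hla$verdict == "compatible")
  any_mhag[!carries %in% TRUE] <- NA_character_
  any_both[!carries %in% TRUE] <- NA_character_
  data.frame(mother_id = mothers$subject_id, mhag = def$name,
             carries_restriction = carries,
             any_mhag_compatible = any_mhag,
             any_hla_and_mhag_compatible = any_both,
             stringsAsFactors = FALSE)
}
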