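# Sequence similarity matching (SSM) scores.
#
# The SSM score between two alleles is a positional sum of amino-acid
# dissimilarities over mismatched positions, optionally weighted by
# functional-position weights; lower = more similar. For a mother-child
# pair the relevant comparison is noninherited maternal allele vs the
# child's paternal allele; genotype-identical pairs score exactly 0.

#' Default amino-acid dissimilarity matrix
#'
#' A generic substitution-based dissimilarity over the 20 standard
#' residues, derived from the BLOSUM62 similarity matrix as
#' `d(a, b) = s(a, a) + s(b, b) - 2 s(a, b)`. The transform guarantees a
#' zero diagonal, symmetry and non-negative off-diagonal entries. Any
#' 20x20 symmetric zero-diagonal matrix (e.g. one encoding functional
#' dissimilarity between side chains) can be supplied to
#' [ssm_resources()] instead.
#'
#' @return a 20x20 numeric matrix with standard one-letter residue
#'   dimnames.
#' @export
default_aa_dissimilarity <- function() {
  aa <- c("A","R","N","D","C","Q","E","G","H","I",
          "L","K","M","F","P","S","T","W","Y","V")
  e <- new.env()
  utils::data("BLOSUM62", package = "Biostrings", envir = e)
  s <- e$BLOSUM62[aa, aa]
  d <- outer(diag(s), diag(s), "+") - 2 * s
  dimnames(d) <- list(aa, aa)
  d
}

#' Bundle the resources needed for SSM scoring
#'
#' @param sequences named character vector mapping allele names to
#'   pre-aligned amino-acid sequences (see [read_allele_sequences()]).
#' @param dissimilarity symmetric numeric matrix with zero diagonal and
#'   non-negative entries, rows/columns named by residue.
#' @param position_weights optional named list: locus -> numeric vector of
#'   per-position weights (>= 0). Positions beyond the vector, and loci
#'   not listed, default to weight 1.
#' @return an object of class `ssm_resources`.
#' @export
ssm_resources <- function(sequences,
                          dissimilarity = default_aa_dissimilarity(),
                          position_weights = NULL) {
  stopifnot(is.matrix(dissimilarity),
            nrow(dissimilarity) == ncol(dissimilarity))
  if (is.null(rownames(dissimilarity)) ||
      !identical(rownames(dissimilarity), colnames(dissimilarity)))
    stop("dissimilarity matrix must have matching row/column names")
  if (any(!is.finite(dissimilarity)) || any(dissimilarity < 0))
    stop("dissimilarity values must be finite and non-negative")
  if (any(abs(dissimilarity - t(dissimilarity)) > 1e-12))
    stop("dissimilarity matrix must be symmetric")
  if (any(abs(diag(dissimilarity)) > 1e-12))
    stop("dissimilarity matrix must have a zero diagonal")
  if (!is.null(position_weights)) {
    ok <- vapply(position_weights,
                 function(w) is.numeric(w) && all(is.finite(w)) && all(w >= 0),
                 logical(1))
    if (!all(ok)) stop("position weights must be finite and >= 0")
  }
  structure(list(sequences = sequences, dissimilarity = dissimilarity,
                 position_weights = position_weights),
            class = "ssm_resources")
}

locus_weights <- function(res, locus, len) {
  w <- rep(1, len)
  pw <- res$position_weights[[locus]]
  if (!is.null(pw)) {
    k <- min(len, length(pw))
    w[seq_len(k)] <- pw[seq_len(k)]
  }
  w
}

#' SSM score between two alleles
#'
#' Sum over positions where the two sequences differ of
#' `weight(locus, p) * dissimilarity(a1[p], a2[p])`. Identical alleles
#' score 0. Sequences must be pre-aligned to equal length; no alignment
#' is attempted.
#'
#' @param a1,a2 allele names present in `res$sequences`.
#' @param res an [ssm_resources()] object.
#' @param locus locus name used to look up position weights (defaults to
#'   the part of `a1` before `*`).
#' @return non-negative score, or `NA` when a sequence is unavailable.
#' @export
allele_ssm <- function(a1, a2, res, locus = sub("\\*.*$", "", a1)) {
  s1 <- res$sequences[a1]
  s2 <- res$sequences[a2]
  if (is.na(s1) || is.na(s2)) return(NA_real_)
  if (a1 == a2 || identical(unname(s1), unname(s2))) return(0)
  v1 <- strsplit(unname(s1), "")[[1]]
  v2 <- strsplit(unname(s2), "")[[1]]
  if (length(v1) != length(v2))
    stop(sprintf("sequences for %s (%d aa) and %s (%d aa) are not aligned",
                 a1, length(v1), a2, length(v2)), call. = FALSE)
  mism <- which(v1 != v2)
  if (!length(mism)) return(0)
  w <- locus_weights(res, locus, length(v1))
  sum(w[mism] * res$dissimilarity[cbind(v1[mism], v2[mism])])
}

#' SSM score for one mother-child pair at one locus
#'
#' Genotype-identical pairs (same allele set) score exactly 0. Otherwise
#' the score is the allele-level SSM between the noninherited maternal
#' allele and the child's paternal allele; when the Mendelian transmission
#' assignment is not unique, the assignment minimising the score is used.
#' Missing genotypes and Mendelian errors propagate as `NA`.
#'
#' @inheritParams infer_paternal
#' @param res an [ssm_resources()] object.
#' @param locus locus name for position-weight lookup.
#' @return non-negative score or `NA`.
#' @export
pair_ssm <- function(mother, child, res,
                     locus = sub("\\*.*$", "", mother[1])) {
  if (anyNA(mother) || anyNA(child)) return(NA_real_)
  if (setequal(mother, child)) return(0)
  inf <- infer_paternal(mother, child)
  if (inf$status %in% c("missing", "mendelian_error")) return(NA_real_)
  # enumerate Mendelian assignments: transmitted maternal allele t must be
  # a child allele; paternal is the other child allele; noninherited is
  # the mother's other copy
  scores <- c()
  for (i in 1:2) {
    t <- child[i]
    p <- child[3 - i]
    if (t == mother[1])
      scores <- c(scores, allele_ssm(mother[2], p, res, locus))
    if (t == mother[2])
      scores <- c(scores, allele_ssm(mother[1], p, res, locus))
  }
  if (!length(scores)) return(NA_real_)
  min(scores)
}

#' Per-mother mean SSM score at one locus
#'
#' Averages the pair scores of eligible children (eligibility as in
#' [compatibility_calls()]): children with unavailable scores are
#' excluded; mothers with no usable child are `NA` (quartile unassigned).
#'
#' @param cohort an `hla_cohort`.
#' @param locus a single HLA locus name.
#' @param res an [ssm_resources()] object.
#' @return data.frame per mother: `mother_id`, `locus`, `mean_ssm`,
#'   `n_children_scored`.
#' @export
mother_mean_ssm <- function(cohort, locus, res) {
  s <- cohort$subjects
  mothers <- s[s$role == "mother", , drop = FALSE]
  children <- s[s$role == "child", , drop = FALSE]
  mi <- match(children$family_id, mothers$family_id)
  m_disease <- ifelse(is.na(mothers$disease[mi]), "control",
                      mothers$disease[mi])
  eligible <- ifelse(m_disease == "control", TRUE,
                     !is.na(children$born_before_diagnosis) &
                       children$born_before_diagnosis)
  c1 <- paste0(locus, "_1"); c2 <- paste0(locus, "_2")
  scores <- vapply(seq_len(nrow(children)), function(i) {
    if (!eligible[i]) return(NA_real_)
    pair_ssm(c(mothers[[c1]][mi[i]], mothers[[c2]][mi[i]]),
             c(children[[c1]][i], children[[c2]][i]), res, locus)
  }, numeric(1))
  f <- factor(children$family_id[!is.na(scores)],
              levels = mothers$family_id)
  n <- as.integer(table(f))
  tot <- as.numeric(tapply(scores[!is.na(scores)], f, sum, default = 0))
  data.frame(mother_id = mothers$subject_id, locus = locus,
             mean_ssm = ifelse(n == 0, NA_real_, tot / pmax(n, 1L)),
             n_children_scored = n, stringsAsFactors = FALSE)
}

#' Quartile cutpoints from control-group scores
#'
#' Empirical 25th/50th/75th percentiles of the control mothers' mean SSM
#' scores (linear-interpolation percentile definition, [stats::quantile()]
#' type 7). Assignment intervals are left-closed, right-open, with the
#' last interval closed; quartile 1 holds the smallest scores ("most"
#' histocompatible), quartile 4 the largest ("least").
#'
#' @param control_scores numeric vector of control mothers' mean scores
#'   (`NA` dropped); at least 4 distinct values required.
#' @return numeric vector of 3 cutpoints.
#' @export
control_quartile_cutpoints <- function(control_scores) {
  x <- control_scores[!is.na(control_scores)]
  if (length(unique(x)) < 4)
    stop("need at least 4 distinct control scores to form quartiles; ",
         "the score distribution is degenerate - bin manually", call. = FALSE)
  unname(quantile(x, c(0.25, 0.5, 0.75), type = 7))
}

#' Assign SSM quartiles from cutpoints
#'
#' @param scores numeric vector of mean SSM scores.
#' @param cutpoints 3 cut values from [control_quartile_cutpoints()].
#' @return integer vector in 1..4 (`NA` for unassigned). Quartile 1 =
#'   most similar (lowest scores).
#' @export
assign_quartile <- function(scores, cutpoints) {
  stopifnot(length(cutpoints) == 3, !is.unsorted(cutpoints))
  q <- findInterval(scores, cutpoints) + 1L
  q[is.na(scores)] <- NA_integer_
  q
}
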