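# Independent oracles and small fixture builders used across tests.
# Oracles are deliberately written by brute force / enumeration, not by
# calling the package code they check.

# Enumerate every Mendelian phase assignment of an unphased mother/child
# genotype pair: the transmitted allele must be one of the child's two
# alleles AND a member of the mother's pair; the other child allele is
# paternal. Verdict: compatible iff every consistent assignment leaves the
# paternal allele inside the mother's allele set.
oracle_classify <- function(mother, child) {
  if (anyNA(mother) || anyNA(child)) return("missing")
  paternal <- character(0)
  for (i in 1:2) {
    transmitted <- child[i]
    if (transmitted %in% mother) paternal <- c(paternal, child[3 - i])
  }
  if (!length(paternal)) return("mendelian_error")
  if (all(paternal %in% mother)) "compatible" else "incompatible"
}

# All unordered genotype pairs over an allele alphabet.
all_genotypes <- function(alphabet) {
  g <- expand.grid(a1 = alphabet, a2 = alphabet, stringsAsFactors = FALSE)
  g[as.integer(factor(g$a1, levels = alphabet)) <=
      as.integer(factor(g$a2, levels = alphabet)), , drop = FALSE]
}

# Full-enumeration two-sided Fisher oracle: probabilities of all tables
# with the observed margins from the log-factorial formula.
oracle_fisher <- function(t) {
  r1 <- sum(t[1, ]); r2 <- sum(t[2, ])
  c1 <- sum(t[, 1]); c2 <- sum(t[, 2]); n <- sum(t)
  if (r1 == 0 || r2 == 0 || c1 == 0 || c2 == 0) return(1)
  a_vals <- max(0, r1 - c2):min(r1, c1)
  logp <- function(a) {
    b <- r1 - a; c <- c1 - a; d <- r2 - c
    lfactorial(r1) + lfactorial(r2) + lfactorial(c1) + lfactorial(c2) -
      lfactorial(n) - lfactorial(a) - lfactorial(b) - lfactorial(c) -
      lfactorial(d)
  }
  probs <- exp(vapply(a_vals, logp, numeric(1)))
  p_obs <- exp(logp(t[1, 1]))
  min(1, sum(probs[probs <= p_obs * (1 + 1e-7)]))
}

# Brute-force mother-child SSM: enumerate Mendelian assignments, score
# each noninherited-maternal vs paternal allele pair by direct positional
# summation, take the minimum; set-identical genotypes score 0.
oracle_pair_ssm <- function(mother, child, res, locus) {
  if (anyNA(mother) || anyNA(child)) return(NA_real_)
  if (setequal(mother, child)) return(0)
  raw_score <- function(x, y) {
    if (x == y) return(0)
    v1 <- strsplit(unname(res$sequences[x]), "")[[1]]
    v2 <- strsplit(unname(res$sequences[y]), "")[[1]]
    w <- res$position_weights[[locus]]
    if (is.null(w)) w <- rep(1, length(v1))
    s <- 0
    for (p in seq_along(v1))
      if (v1[p] != v2[p]) s <- s + w[p] * res$dissimilarity[v1[p], v2[p]]
    s
  }
  scores <- c()
  for (i in 1:2) for (j in 1:2) {
    transmitted <- child[i]
    if (transmitted == mother[j])
      scores <- c(scores, raw_score(mother[3 - j], child[3 - i]))
  }
  if (!length(scores)) return(NA_real_)
  min(scores)
}

# Analytic per-child compatibility probability under Hardy-Weinberg
# mating and uniform transmission: sum over mother genotypes of
# P(genotype) * P(paternal allele in mother's set).
analytic_child_compat_prob <- function(freqs) {
  alleles <- names(freqs)
  p <- 0
  for (i in seq_along(alleles)) for (j in seq_along(alleles)) {
    pg <- freqs[i] * freqs[j]
    p <- p + pg * sum(freqs[unique(c(alleles[i], alleles[j]))])
  }
  unname(p)
}

# Minimal hand-built cohort: one row per subject from a compact description.
# genotypes: named list subject_id -> named list locus -> c(a1, a2).
build_cohort <- function(subjects, genotypes, hla_loci, snp_loci = character(0)) {
  s <- do.call(rbind, lapply(subjects, function(x)
    data.frame(family_id = x$family_id, subject_id = x$subject_id,
               role = x$role,
               disease = if (is.null(x$disease)) NA_character_ else x$disease,
               n_live_births = if (is.null(x$n_live_births)) NA_integer_
                               else as.integer(x$n_live_births),
               born_before_diagnosis = if (is.null(x$born_before)) NA
                                       else x$born_before,
               stringsAsFactors = FALSE)))
  for (locus in c(hla_loci, snp_loci)) {
    s[[paste0(locus, "_1")]] <- vapply(s$subject_id, function(id) {
      g <- genotypes[[id]][[locus]]
      if (is.null(g)) NA_character_ else as.character(g[1])
    }, character(1), USE.NAMES = FALSE)
    s[[paste0(locus, "_2")]] <- vapply(s$subject_id, function(id) {
      g <- genotypes[[id]][[locus]]
      if (is.null(g)) NA_character_ else as.character(g[2])
    }, character(1), USE.NAMES = FALSE)
  }
  new_cohort(s, hla_loci = hla_loci, snp_loci = snp_loci)
}

# SSM resources with hand-set sequences for closed-form checks.
toy_ssm_resources <- function(sequences, dissim_pairs = NULL, weights = NULL) {
  aa <- c("A","R","N","D","C","Q","E","G","H","I",
          "L","K","M","F","P","S","T","W","Y","V")
  d <- matrix(1, 20, 20, dimnames = list(aa, aa))
  diag(d) <- 0
  if (!is.null(dissim_pairs))
    for (p in dissim_pairs) {
      d[p$a, p$b] <- p$value
      d[p$b, p$a] <- p$value
    }
  ssm_resources(sequences, dissimilarity = d, position_weights = weights)
}
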