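# Synthetic cohort generator: Hardy-Weinberg mating, uniform maternal
# transmission, parity-linked family size, a logistic disease model on
# true compatibility exposure, and configurable group-specific
# missingness. Ground truth is emitted alongside the cohort for recovery
# tests and is never consumed by the analysis pipeline.

#' Default per-locus allele frequency vectors
#'
#' Synthetic frequency vectors for the seven classical HLA loci (a
#' handful of common two-field alleles per locus with European-ancestry-
#' like relative frequencies, normalised to sum to 1) and plausible
#' allele frequencies for the six mHag tag SNPs. These are generator
#' defaults for simulation, not population estimates.
#'
#' @return named list: locus -> named numeric vector of allele
#'   frequencies summing to 1.
#' @export
default_allele_freqs <- function() {
  f <- list(
    A = c("A*02:01" = 28, "A*01:01" = 16, "A*03:01" = 13, "A*24:02" = 9,
          "A*11:01" = 6, "A*26:01" = 5, "A*32:01" = 4, "A*68:01" = 4,
          "A*29:02" = 3, "A*31:01" = 3, "A*23:01" = 2, "A*30:01" = 2,
          "A*25:01" = 2, "A*33:01" = 2, "A*68:02" = 1),
    B = c("B*07:02" = 14, "B*08:01" = 12, "B*44:02" = 9, "B*15:01" = 7,
          "B*40:01" = 6, "B*35:01" = 6, "B*44:03" = 5, "B*51:01" = 5,
          "B*57:01" = 4, "B*18:01" = 4, "B*27:05" = 4, "B*14:02" = 3,
          "B*13:02" = 3, "B*38:01" = 2, "B*39:06" = 2, "B*55:01" = 2),
    C = c("C*07:01" = 15, "C*07:02" = 14, "C*04:01" = 12, "C*05:01" = 9,
          "C*03:04" = 8, "C*06:02" = 8, "C*03:03" = 6, "C*02:02" = 5,
          "C*12:03" = 5, "C*01:02" = 4, "C*08:02" = 4, "C*16:01" = 3,
          "C*15:02" = 3, "C*14:02" = 2),
    DPB1 = c("DPB1*04:01" = 40, "DPB1*02:01" = 12, "DPB1*04:02" = 11,
             "DPB1*03:01" = 10, "DPB1*01:01" = 6, "DPB1*06:01" = 4,
             "DPB1*05:01" = 3, "DPB1*11:01" = 3, "DPB1*13:01" = 2,
             "DPB1*17:01" = 2, "DPB1*10:01" = 2),
    DQA1 = c("DQA1*05:01" = 22, "DQA1*01:02" = 18, "DQA1*03:01" = 14,
             "DQA1*01:01" = 12, "DQA1*02:01" = 12, "DQA1*01:03" = 7,
             "DQA1*05:05" = 6, "DQA1*04:01" = 4, "DQA1*06:01" = 1),
    DQB1 = c("DQB1*03:01" = 18, "DQB1*02:01" = 14, "DQB1*06:02" = 13,
             "DQB1*05:01" = 12, "DQB1*03:02" = 10, "DQB1*02:02" = 6,
             "DQB1*06:03" = 6, "DQB1*03:03" = 5, "DQB1*05:03" = 4,
             "DQB1*06:04" = 4, "DQB1*04:02" = 3, "DQB1*05:02" = 2),
    DRB1 = c("DRB1*15:01" = 14, "DRB1*03:01" = 12, "DRB1*07:01" = 11,
             "DRB1*04:01" = 9, "DRB1*01:01" = 8, "DRB1*11:01" = 7,
             "DRB1*13:01" = 6, "DRB1*13:02" = 4, "DRB1*04:04" = 4,
             "DRB1*11:04" = 3, "DRB1*08:01" = 3, "DRB1*12:01" = 3,
             "DRB1*09:01" = 2, "DRB1*10:01" = 2, "DRB1*14:01" = 2,
             "DRB1*16:01" = 2, "DRB1*04:02" = 2),
    rs1051266 = c(G = 0.56, A = 0.44),
    rs12828016 = c(G = 0.50, T = 0.50),
    rs2061821 = c(C = 0.68, T = 0.32),
    rs2074071 = c(A = 0.60, G = 0.40),
    rs2275687 = c(C = 0.72, T = 0.28),
    rs3745526 = c(G = 0.85, T = 0.15))
  lapply(f, function(v) v / sum(v))
}

#' Simulation configuration
#'
#' Defines the generative model for [simulate_cohort()]: mothers are drawn
#' under Hardy-Weinberg equilibrium at each locus; each child receives one
#' maternal allele uniformly and one paternal allele from the population
#' frequencies; family size follows a zero-truncated Poisson (every
#' enrolled mother has at least one child) with a cap on genotyped
#' children; disease is assigned by a logistic model on the mother's true
#' any-compatible exposure at designated loci and her number of live
#' births; missingness (whole-genotype, missing completely at random
#' within disease group) is applied after ground truth is captured.
#'
#' @param n_mothers number of families.
#' @param allele_freqs named list locus -> named frequency vector summing
#'   to 1 (default [default_allele_freqs()]).
#' @param mean_live_births mean of the zero-truncated live-birth
#'   distribution (default 2, echoing means near 2 in the motivating
#'   study).
#' @param max_children cap on genotyped children per family (default 2;
#'   the study genotyped ~1.3 children per mother).
#' @param disease case label assigned to affected mothers (`"RA"` or
#'   `"SLE"`).
#' @param intercept logistic intercept; default `qlogis(0.18)` gives
#'   roughly the case fraction of the motivating case-control sample.
#' @param exposure_log_or named numeric: per-locus log-OR of disease for
#'   any-compatible exposure (e.g. `c(B = log(1.8))`); empty for a null
#'   model.
#' @param live_births_log_or log-OR of disease per live birth (parity
#'   confounder; default `log(1.1)`).
#' @param missingness named list locus -> either a single rate or a named
#'   vector `c(case = , control = )` of per-subject whole-genotype
#'   missingness rates.
#' @param frac_born_after for case mothers, probability a child is
#'   flagged born after diagnosis (default 0: all children eligible).
#' @param seed optional integer seed; when set, generation is fully
#'   reproducible.
#' @return a validated list of class `sim_config`.
#' @export
sim_config <- function(n_mothers = 500,
                       allele_freqs = default_allele_freqs(),
                       mean_live_births = 2,
                       max_children = 2,
                       disease = "RA",
                       intercept = qlogis(0.18),
                       exposure_log_or = c(B = log(1.8)),
                       live_births_log_or = log(1.1),
                       missingness = list(),
                       frac_born_after = 0,
                       seed = NULL) {
  stopifnot(n_mothers >= 1, mean_live_births > 1, max_children >= 1,
            disease %in% c("RA", "SLE"),
            frac_born_after >= 0, frac_born_after <= 1)
  for (locus in names(allele_freqs)) {
    v <- allele_freqs[[locus]]
    if (is.null(names(v)) || any(v < 0) || abs(sum(v) - 1) > 1e-8)
      stop("allele frequencies at ", locus,
           " must be named, non-negative and sum to 1", call. = FALSE)
  }
  if (length(exposure_log_or) &&
      !all(names(exposure_log_or) %in% names(allele_freqs)))
    stop("exposure_log_or names must be simulated loci", call. = FALSE)
  for (locus in names(missingness)) {
    r <- missingness[[locus]]
    if (any(r < 0 | r > 1)) stop("missingness rates must be in [0, 1]",
                                 call. = FALSE)
  }
  structure(list(n_mothers = n_mothers, allele_freqs = allele_freqs,
                 mean_live_births = mean_live_births,
                 max_children = max_children, disease = disease,
                 intercept = intercept, exposure_log_or = exposure_log_or,
                 live_births_log_or = live_births_log_or,
                 missingness = missingness,
                 frac_born_after = frac_born_after, seed = seed),
            class = "sim_config")
}

# Poisson rate whose zero-truncated mean equals `mean`.
truncated_poisson_rate <- function(mean) {
  uniroot(function(l) l / (1 - exp(-l)) - mean,
          interval = c(1e-6, mean + 10))$root
}

#' Simulate a mother-child cohort with ground truth
#'
#' See [sim_config()] for the generative model. The returned truth
#' records, per mother, the true any-compatible exposure at every
#' simulated locus (over eligible children, before missingness) and, per
#' child, the true paternal allele at every locus — for recovery tests
#' only; the analysis pipeline never reads it.
#'
#' @param cfg a [sim_config()].
#' @return list with `cohort` (an `hla_cohort`) and `truth` (list:
#'   `exposure` per-mother data.frame of logicals, `paternal` per-child
#'   data.frame, `params` the disease-model parameters).
#' @export
simulate_cohort <- function(cfg) {
  stopifnot(inherits(cfg, "sim_config"))
  if (!is.null(cfg$seed)) set.seed(cfg$seed)
  n <- cfg$n_mothers
  loci <- names(cfg$allele_freqs)
  hla_loci <- loci[!is_snp_locus(loci)]
  snp_loci <- loci[is_snp_locus(loci)]

  lambda <- truncated_poisson_rate(cfg$mean_live_births)
  u <- runif(n, dpois(0, lambda), 1)
  live_births <- as.integer(qpois(u, lambda))
  n_children <- pmin(live_births, cfg$max_children)
  tot <- sum(n_children)
  mi <- rep(seq_len(n), n_children)           # mother index per child

  family_id <- sprintf("F%05d", seq_len(n))
  mother_id <- paste0(family_id, "_M")
  child_id <- paste0(family_id[mi], "_C",
                     sequence(n_children))

  # born-before-diagnosis indicator (latent for all children; only
  # reported for children of case mothers)
  born_before <- runif(tot) >= cfg$frac_born_after

  geno_m <- list(); geno_c <- list()
  compat <- matrix(NA, nrow = tot, ncol = length(loci),
                   dimnames = list(NULL, loci))
  paternal <- matrix(NA_character_, nrow = tot, ncol = length(loci),
                     dimnames = list(NULL, loci))
  for (locus in loci) {
    fr <- cfg$allele_freqs[[locus]]
    alleles <- names(fr)
    m1 <- sample(alleles, n, replace = TRUE, prob = fr)
    m2 <- sample(alleles, n, replace = TRUE, prob = fr)
    transmitted <- ifelse(runif(tot) < 0.5, m1[mi], m2[mi])
    pat <- sample(alleles, tot, replace = TRUE, prob = fr)
    geno_m[[locus]] <- cbind(m1, m2)
    geno_c[[locus]] <- cbind(transmitted, pat)
    compat[, locus] <- pat == m1[mi] | pat == m2[mi]
    paternal[, locus] <- pat
  }

  # true per-mother exposure: any compatible among eligible children
  true_exposure <- vapply(loci, function(locus) {
    hit <- compat[, locus] & born_before
    as.integer(table(factor(mi[hit], levels = seq_len(n)))) > 0
  }, logical(n))

  eta <- cfg$intercept + cfg$live_births_log_or * live_births
  for (locus in names(cfg$exposure_log_or))
    eta <- eta + cfg$exposure_log_or[[locus]] * true_exposure[, locus]
  case <- rbinom(n, 1, plogis(eta)) == 1
  disease_m <- ifelse(case, cfg$disease, "control")

  subjects <- data.frame(
    family_id = c(family_id, family_id[mi]),
    subject_id = c(mother_id, child_id),
    role = rep(c("mother", "child"), c(n, tot)),
    disease = c(disease_m, rep(NA_character_, tot)),
    n_live_births = c(live_births, rep(NA_integer_, tot)),
    born_before_diagnosis = c(rep(NA, n),
                              ifelse(case[mi], born_before, NA)),
    stringsAsFactors = FALSE)
  for (locus in loci) {
    subjects[[paste0(locus, "_1")]] <- c(geno_m[[locus]][, 1],
                                         geno_c[[locus]][, 1])
    subjects[[paste0(locus, "_2")]] <- c(geno_m[[locus]][, 2],
                                         geno_c[[locus]][, 2])
  }

  # group-specific MCAR whole-genotype missingness, after truth capture
  subj_case <- c(case, case[mi])
  for (locus in names(cfg$missingness)) {
    r <- cfg$missingness[[locus]]
    if (length(r) == 1 && is.null(names(r))) r <- c(case = r, control = r)
    rate <- ifelse(subj_case, r[["case"]], r[["control"]])
    drop <- runif(nrow(subjects)) < rate
    subjects[[paste0(locus, "_1")]][drop] <- NA_character_
    subjects[[paste0(locus, "_2")]][drop] <- NA_character_
  }

  cohort <- new_cohort(subjects, hla_loci = hla_loci, snp_loci = snp_loci)
  exposure_df <- data.frame(mother_id = mother_id,
                            stringsAsFactors = FALSE)
  for (locus in loci) exposure_df[[locus]] <- true_exposure[, locus]
  truth <- list(exposure = exposure_df,
                paternal = data.frame(child_id = child_id, paternal,
                                      stringsAsFactors = FALSE,
                                      check.names = FALSE),
                params = list(intercept = cfg$intercept,
                              exposure_log_or = cfg$exposure_log_or,
                              live_births_log_or = cfg$live_births_log_or))
  list(cohort = cohort, truth = truth)
}

#' Simulate aligned allele sequences and SSM resources
#'
#' Generates equal-length random amino-acid sequences for each allele
#' name, a valid random symmetric zero-diagonal dissimilarity matrix, and
#' per-locus position weights — everything needed to exercise SSM scoring
#' without external sequence data.
#'
#' @param alleles named list: locus -> character vector of allele names
#'   (e.g. a subset of `names(default_allele_freqs()[["B"]])`).
#' @param seq_length aligned sequence length per locus (default 50).
#' @param seed optional integer seed.
#' @param fasta_path optional path; when given, sequences are also written
#'   as FASTA.
#' @return list with `sequences` (named character vector) and `resources`
#'   (an [ssm_resources()] object with random weights).
#' @export
simulate_sequences <- function(alleles, seq_length = 50, seed = NULL,
                               fasta_path = NULL) {
  if (!is.null(seed)) set.seed(seed)
  stopifnot(is.list(alleles), all(lengths(alleles) >= 2))
  aa <- c("A","R","N","D","C","Q","E","G","H","I",
          "L","K","M","F","P","S","T","W","Y","V")
  seqs <- character(0)
  for (locus in names(alleles)) {
    nm <- alleles[[locus]]
    s <- vapply(nm, function(a)
      paste(sample(aa, seq_length, replace = TRUE), collapse = ""),
      character(1))
    seqs <- c(seqs, setNames(s, nm))
  }
  d <- matrix(runif(400, 0.5, 3), 20, 20, dimnames = list(aa, aa))
  d <- (d + t(d)) / 2
  diag(d) <- 0
  weights <- lapply(setNames(names(alleles), names(alleles)),
                    function(l) runif(seq_length, 0.5, 2))
  if (!is.null(fasta_path)) {
    writeLines(paste0(">", names(seqs), "\n", seqs), fasta_path)
  }
  list(sequences = seqs,
       resources = ssm_resources(seqs, dissimilarity = d,
                                 position_weights = weights))
}

#' Published case-control contingency tables
#'
#' The printed 2x2 counts from the motivating mother-child
#' histocompatibility case-control study of RA and SLE, embedded as a
#' versioned fixture: per-locus any-compatible tables for RA (`T2-*`) and
#' SLE (`T3-*`), the HLA-restricted mHag tables for SLE (`T6-*`), and the
#' combined HLA+mHag tables (`T7-*`). Each table is a [two_by_two()]
#' matrix (rows none/any, columns case/control) with attributes
#' `source_table`, and the printed `or` / `ci` / `p` where the source
#' reported them. Note: the `T3-DRB1` row is stored exactly as printed
#' although its case counts (103 + 35) exceed the SLE sample size — an
#' apparent typesetting error in the source.
#'
#' @return named list of 2x2 matrices.
#' @examples
#' published_tables()[["T7-ZAPHIR"]]
#' @export
published_tables <- function() {
  mk <- function(tag, none_case, none_ctrl, any_case, any_ctrl,
                 or = NA, ci = NA, p = NA) {
    t <- two_by_two(none_case, none_ctrl, any_case, any_ctrl)
    attr(t, "source_table") <- tag
    attr(t, "printed_or") <- or
    attr(t, "printed_ci") <- ci
    attr(t, "printed_p") <- p
    t
  }
  list(
    "T2-A"    = mk("T2", 104, 683, 34, 230, 1.0, c(0.6, 1.5), 1.00),
    "T2-B"    = mk("T2", 111, 814, 27, 99, 1.9, c(1.2, 3.1), 0.04),
    "T2-C"    = mk("T2", 105, 752, 33, 161, 1.4, c(0.9, 2.2), 0.77),
    "T2-DPB1" = mk("T2", 63, 555, 75, 358, 1.8, c(1.2, 2.6), 0.01),
    "T2-DQA1" = mk("T2", 74, 597, 64, 316, 1.6, c(1.1, 2.3), 0.10),
    "T2-DQB1" = mk("T2", 93, 725, 45, 188, 1.8, c(1.2, 2.7), 0.03),
    "T2-DRB1" = mk("T2", 103, 765, 35, 148, 1.6, c(1.0, 2.4), 0.28),
    "T3-A"    = mk("T3", 78, 683, 39, 230, 1.5, c(1.0, 2.3), 0.35),
    "T3-B"    = mk("T3", 101, 814, 16, 99, 1.2, c(0.7, 2.2), 1.00),
    "T3-C"    = mk("T3", 92, 752, 25, 161, 1.2, c(0.7, 1.9), 1.00),
    "T3-DPB1" = mk("T3", 64, 555, 53, 358, 1.3, c(0.9, 1.9), 1.00),
    "T3-DQA1" = mk("T3", 69, 597, 48, 316, 1.2, c(0.8, 1.9), 1.00),
    "T3-DQB1" = mk("T3", 85, 725, 32, 188, 1.4, c(0.9, 2.1), 1.00),
    "T3-DRB1" = mk("T3", 103, 765, 35, 148, 1.3, c(0.8, 2.2), 1.00),
    "T6-SLC19A1"  = mk("T6", 24, 111, 22, 98, 0.9, c(0.5, 1.7), 0.76),
    "T6-LB-WNK1"  = mk("T6", 45, 252, 50, 188, 1.5, c(0.9, 2.3), 0.11),
    "T6-HA-3"     = mk("T6", 32, 152, 34, 140, 1.2, c(0.7, 2.1), 0.50),
    "T6-ZAPHIR"   = mk("T6", 29, 117, 10, 106, 0.4, c(0.2, 0.8), 0.01),
    "T6-HEATR1"   = mk("T6", 31, 127, 26, 73, 1.5, c(0.8, 2.7), 0.22),
    "T6-C19orf48" = mk("T6", 44, 245, 51, 195, 1.4, c(0.9, 2.3), 0.13),
    "T7-SLC19A1"  = mk("T7", 44, 189, 2, 20, p = 0.39),
    "T7-LB-WNK1"  = mk("T7", 73, 384, 22, 56, p = 0.02),
    "T7-HA-3"     = mk("T7", 57, 251, 9, 41, p = 1.00),
    "T7-ZAPHIR"   = mk("T7", 39, 202, 0, 21, p = 0.05),
    "T7-HEATR1"   = mk("T7", 51, 189, 6, 11, p = 0.22),
    "T7-C19orf48" = mk("T7", 75, 366, 20, 74, p = 0.37))
}
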