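# Orchestration: run every analysis stage on a cohort and emit the
# report tables (per-locus any-compatible associations, SSM quartile
# associations, restricted mHag associations, combined HLA+mHag Fisher
# tests, missingness tests).

or_row <- function(res, p_adj = NA_real_) {
  cnt <- res$counts
  data.frame(n_none_case = if (is.null(cnt)) NA_integer_ else cnt[1, 1],
             n_any_case = if (is.null(cnt)) NA_integer_ else cnt[2, 1],
             n_none_control = if (is.null(cnt)) NA_integer_ else cnt[1, 2],
             n_any_control = if (is.null(cnt)) NA_integer_ else cnt[2, 2],
             or = res$odds_ratio, ci_low = res$ci_low,
             ci_high = res$ci_high, p_raw = res$p_raw,
             p_bonferroni = p_adj,
             flag = ifelse(is.na(res$flag), "", res$flag),
             stringsAsFactors = FALSE)
}

#' Run the full histocompatibility analysis
#'
#' Executes the complete pipeline on a validated cohort: any-compatible
#' exposure classification with complete-case filtering over the HLA
#' loci, live-birth-adjusted logistic ORs with Bonferroni correction over
#' the locus set, missingness chi-square tests, optional SSM quartile
#' analyses (most- vs least-similar quartile and ordinal trend), and
#' HLA-restricted mHag analyses (adjusted OR for any mHag-compatible
#' child; Fisher's exact test for combined HLA+mHag compatibility).
#' Deterministic given its inputs.
#'
#' @param cohort an `hla_cohort`.
#' @param resources optional [ssm_resources()]; when supplied the SSM
#'   quartile tables are computed.
#' @param hla_loci loci for the HLA analyses (and the Bonferroni factor).
#' @param mhags data.frame of mHag definitions (default: the shipped six,
#'   restricted to SNPs present in the cohort).
#' @return an object of class `histocompat_report`: list of data.frames
#'   `hla`, `ssm`, `mhag_restricted`, `mhag_combined`, `missingness`,
#'   plus `meta`.
#' @export
run_full_analysis <- function(cohort, resources = NULL,
                              hla_loci = cohort$hla_loci,
                              mhags = mhag_definitions()) {
  stopifnot(inherits(cohort, "hla_cohort"))
  exposures <- exposure_table(cohort, hla_loci)
  ccf <- complete_case_filter(exposures, hla_loci)
  complete <- ccf$complete
  groups <- intersect(c("RA", "SLE"), unique(complete$disease))
  m <- length(hla_loci)

  hla <- do.call(rbind, lapply(groups, function(g) {
    sub <- complete[complete$disease %in% c(g, "control"), , drop = FALSE]
    do.call(rbind, lapply(hla_loci, function(locus) {
      x <- as.integer(sub[[paste0("any_", locus)]] == "yes")
      res <- fit_logistic(sub$disease == g, x,
                          covariates = sub["n_live_births"],
                          label = paste0(g, ":", locus))
      cbind(data.frame(disease = g, locus = locus,
                       stringsAsFactors = FALSE),
            or_row(res, bonferroni(res$p_raw, m)))
    }))
  }))

  missingness <- do.call(rbind, lapply(groups, function(g) {
    do.call(rbind, lapply(hla_loci, function(locus) {
      mm <- ccf$missingness
      mc <- mm[mm$locus == locus & mm$group == g, , drop = FALSE]
      mo <- mm[mm$locus == locus & mm$group == "control", , drop = FALSE]
      t <- matrix(c(mc$n_missing, mc$n_observed,
                    mo$n_missing, mo$n_observed), 2,
                  dimnames = list(c("missing", "observed"),
                                  c("case", "control")))
      res <- missingness_test(t)
      data.frame(disease = g, locus = locus,
                 n_missing_case = mc$n_missing,
                 n_observed_case = mc$n_observed,
                 n_missing_control = mo$n_missing,
                 n_observed_control = mo$n_observed,
                 statistic = res$statistic, p = res$p_raw,
                 stringsAsFactors = FALSE)
    }))
  }))

  ssm <- NULL
  if (!is.null(resources)) {
    keep_ids <- complete$mother_id
    ssm <- do.call(rbind, lapply(hla_loci, function(locus) {
      ms <- mother_mean_ssm(cohort, locus, resources)
      ms <- ms[ms$mother_id %in% keep_ids, , drop = FALSE]
      info <- complete[match(ms$mother_id, complete$mother_id), ]
      ctrl <- ms$mean_ssm[info$disease == "control"]
      cut <- control_quartile_cutpoints(ctrl)
      q <- assign_quartile(ms$mean_ssm, cut)
      do.call(rbind, lapply(groups, function(g) {
        sel <- info$disease %in% c(g, "control")
        # most-similar (Q1) vs least-similar (Q4, reference)
        extreme <- sel & q %in% c(1L, 4L)
        res <- fit_logistic(info$disease[extreme] == g,
                            as.integer(q[extreme] == 1L),
                            covariates = info[extreme, "n_live_births",
                                              drop = FALSE],
                            label = paste0(g, ":", locus, ":Q1vsQ4"))
        tr <- trend_test(q[sel], info$disease[sel] == g,
                         covariates = info[sel, "n_live_births",
                                           drop = FALSE])
        cbind(data.frame(disease = g, locus = locus,
                         stringsAsFactors = FALSE),
              data.frame(n_q1_case = sum(q == 1 & info$disease == g,
                                         na.rm = TRUE),
                         n_q4_case = sum(q == 4 & info$disease == g,
                                         na.rm = TRUE),
                         n_q1_control = sum(q == 1 & info$disease == "control",
                                            na.rm = TRUE),
                         n_q4_control = sum(q == 4 & info$disease == "control",
                                            na.rm = TRUE),
                         or = res$odds_ratio, ci_low = res$ci_low,
                         ci_high = res$ci_high, p_trend = tr$p_raw,
                         flag = ifelse(is.na(res$flag), "", res$flag),
                         stringsAsFactors = FALSE))
      }))
    }))
  }

  mhag_restricted <- NULL
  mhag_combined <- NULL
  if (length(cohort$snp_loci)) {
    defs <- mhags[mhags$rsid %in% cohort$snp_loci &
                    mhags$restriction_locus %in% cohort$hla_loci, ,
                  drop = FALSE]
    mothers <- cohort$subjects[cohort$subjects$role == "mother", ,
                               drop = FALSE]
    disease <- ifelse(is.na(mothers$disease), "control", mothers$disease)
    mg <- intersect(c("RA", "SLE"), unique(disease))
    rows6 <- list(); rows7 <- list()
    for (i in seq_len(nrow(defs))) {
      def <- defs[i, ]
      ex <- mhag_exposure(cohort, def)
      for (g in mg) {
        sel <- disease %in% c(g, "control") & ex$carries_restriction %in% TRUE
        base <- data.frame(disease = g, mhag = def$name,
                           restriction_allele = def$restriction_allele,
                           stringsAsFactors = FALSE)
        y <- disease[sel] == g
        x6 <- ex$any_mhag_compatible[sel]
        ok6 <- !is.na(x6)
        if (sum(y[ok6]) > 0 && sum(!y[ok6]) > 0 &&
            length(unique(x6[ok6])) > 1) {
          res <- fit_logistic(y[ok6], as.integer(x6[ok6] == "yes"),
                              covariates = mothers[sel, ][ok6,
                                "n_live_births", drop = FALSE],
                              label = paste0(g, ":", def$name))
          rows6[[length(rows6) + 1]] <- cbind(base, or_row(res))
        } else {
          rows6[[length(rows6) + 1]] <-
            cbind(base, or_row(new_assoc_result(def$name, NULL, NA, NA, NA,
                                                NA, "adjusted_logistic",
                                                flag = "not estimable")))
        }
        x7 <- ex$any_hla_and_mhag_compatible[sel]
        ok7 <- !is.na(x7)
        t7 <- two_by_two(sum(x7[ok7] == "no" & y[ok7]),
                         sum(x7[ok7] == "no" & !y[ok7]),
                         sum(x7[ok7] == "yes" & y[ok7]),
                         sum(x7[ok7] == "yes" & !y[ok7]))
        rows7[[length(rows7) + 1]] <- cbind(
          base,
          data.frame(n_none_case = t7[1, 1], n_any_case = t7[2, 1],
                     n_none_control = t7[1, 2], n_any_control = t7[2, 2],
                     p_fisher = if (sum(t7) > 0)
                       fisher_exact_two_sided(t7) else NA_real_,
                     stringsAsFactors = FALSE))
      }
    }
    mhag_restricted <- do.call(rbind, rows6)
    mhag_combined <- do.call(rbind, rows7)
  }

  n_by_group <- table(factor(exposures$disease,
                             levels = c("RA", "SLE", "control")))
  structure(list(hla = hla, ssm = ssm, mhag_restricted = mhag_restricted,
                 mhag_combined = mhag_combined, missingness = missingness,
                 meta = list(hla_loci = hla_loci,
                             n_tests_bonferroni = m,
                             n_mothers = as.list(n_by_group),
                             n_complete_case = nrow(complete))),
            class = "histocompat_report")
}

#' @export
print.histocompat_report <- function(x, ...) {
  cat("<histocompat_report>\n")
  cat("  mothers:", paste(names(x$meta$n_mothers),
                          unlist(x$meta$n_mothers), sep = "=",
                          collapse = ", "),
      "| complete-case:", x$meta$n_complete_case, "\n")
  cat("\nAny-compatible associations (adjusted for live births):\n")
  h <- x$hla
  h$or <- sprintf("%.1f (%.1f-%.1f)", h$or, h$ci_low, h$ci_high)
  print(h[c("disease", "locus", "n_any_case", "n_any_control", "or",
            "p_bonferroni")], row.names = FALSE, digits = 2)
  if (!is.null(x$ssm)) {
    cat("\nSSM quartile associations (Q1 most similar vs Q4 reference):\n")
    s <- x$ssm
    s$or <- sprintf("%.1f (%.1f-%.1f)", s$or, s$ci_low, s$ci_high)
    print(s[c("disease", "locus", "or", "p_trend")], row.names = FALSE,
          digits = 2)
  }
  if (!is.null(x$mhag_restricted)) {
    cat("\nmHag associations among restriction-allele carriers:\n")
    print(x$mhag_restricted[c("disease", "mhag", "n_any_case",
                              "n_any_control", "or", "p_raw", "flag")],
          row.names = FALSE, digits = 2)
    cat("\nCombined HLA+mHag compatibility (Fisher's exact):\n")
    print(x$mhag_combined[c("disease", "mhag", "n_any_case",
                            "n_any_control", "p_fisher")],
          row.names = FALSE, digits = 2)
  }
  invisible(x)
}

#' Write a report as TSV tables plus a JSON summary
#'
#' Every reported estimate row carries its cell counts, so each number in
#' the output is traceable to counts also present in the output.
#' Regeneration from the same inputs is byte-identical.
#'
#' @param report a `histocompat_report`.
#' @param dir output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_report <- function(report, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  wt <- function(d, name) {
    if (!is.null(d))
      write.table(d, file.path(dir, name), sep = "\t", quote = FALSE,
                  row.names = FALSE, na = "NA")
  }
  wt(report$hla, "hla_associations.tsv")
  wt(report$ssm, "ssm_quartiles.tsv")
  wt(report$mhag_restricted, "mhag_restricted.tsv")
  wt(report$mhag_combined, "mhag_combined_fisher.tsv")
  wt(report$missingness, "missingness.tsv")
  jsonlite::write_json(unclass(report), file.path(dir, "summary.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE,
                       na = "null")
  invisible(dir)
}
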