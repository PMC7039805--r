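# Case-control association layer: adjusted logistic ORs with Wald CIs,
# crude ORs from 2x2 tables, two-sided Fisher's exact tests, Bonferroni
# correction over seven loci, ordinal trend tests over SSM quartiles, and
# missingness chi-square tests.
#
# 2x2 layout convention throughout: rows = exposure (none / any),
# columns = disease (case / control):
#     [none_case  none_control]
#     [any_case   any_control ]

#' Build a 2x2 exposure-by-status table
#'
#' @param none_case,none_control,any_case,any_control non-negative counts.
#' @return 2x2 integer matrix, rows `none`/`any`, columns
#'   `case`/`control`.
#' @export
two_by_two <- function(none_case, none_control, any_case, any_control) {
  cells <- c(none_case, any_case, none_control, any_control)
  stopifnot(all(cells >= 0), all(cells == round(cells)))
  matrix(as.integer(cells), nrow = 2,
         dimnames = list(exposure = c("none", "any"),
                         status = c("case", "control")))
}

new_assoc_result <- function(label, counts, or, ci_low, ci_high, p_raw,
                             method, covariates = character(0),
                             flag = NA_character_) {
  structure(list(label = label, counts = counts, odds_ratio = or,
                 ci_low = ci_low, ci_high = ci_high, p_raw = p_raw,
                 p_adjusted = NA_real_, method = method,
                 covariates = covariates, flag = flag),
            class = "assoc_result")
}

#' @export
print.assoc_result <- function(x, digits = 2, ...) {
  cat(sprintf("<assoc_result:%s> %s\n", x$method, x$label))
  if (!is.na(x$odds_ratio))
    cat(sprintf("  OR %.*f (95%% CI %.*f-%.*f)\n", digits, x$odds_ratio,
                digits, x$ci_low, digits, x$ci_high))
  if (!is.na(x$p_raw)) cat(sprintf("  p = %.4g", x$p_raw))
  if (!is.na(x$p_adjusted)) cat(sprintf(" (adjusted %.4g)", x$p_adjusted))
  if (!is.na(x$p_raw)) cat("\n")
  if (length(x$covariates))
    cat("  adjusted for:", paste(x$covariates, collapse = ", "), "\n")
  if (!is.na(x$flag)) cat("  flag:", x$flag, "\n")
  invisible(x)
}

#' Crude odds ratio from a 2x2 table
#'
#' Cross-product OR `(any_case * none_control) / (none_case *
#' any_control)` with a Woolf (log-scale) 95% confidence interval and a
#' Wald p-value. A zero cell leaves the estimate undefined and flags the
#' result; no continuity correction is applied.
#'
#' @param t a [two_by_two()] matrix.
#' @param label optional exposure label.
#' @return an `assoc_result`.
#' @export
crude_or <- function(t, label = "exposure") {
  stopifnot(identical(dim(t), c(2L, 2L)))
  a <- t[1, 1]; b <- t[1, 2]; c <- t[2, 1]; d <- t[2, 2]
  if (any(t == 0))
    return(new_assoc_result(label, t, NA_real_, NA_real_, NA_real_,
                            NA_real_, "crude",
                            flag = "zero cell: OR undefined (no continuity correction applied)"))
  or <- (c * b) / (a * d)
  se <- sqrt(1 / a + 1 / b + 1 / c + 1 / d)
  z <- qnorm(0.975)
  p <- 2 * pnorm(-abs(log(or) / se))
  new_assoc_result(label, t, or, exp(log(or) - z * se),
                   exp(log(or) + z * se), p, "crude")
}

#' Two-sided Fisher's exact test on a 2x2 table
#'
#' Conditional on both margins, sums the hypergeometric probabilities of
#' all tables whose probability does not exceed that of the observed table
#' (minimum-likelihood two-sided convention, with a `1 + 1e-7` relative
#' tolerance on the comparison). A zero margin gives p = 1.
#'
#' @param t a [two_by_two()] matrix (or any 2x2 of non-negative counts).
#' @return two-sided p-value in \[0, 1\].
#' @export
fisher_exact_two_sided <- function(t) {
  stopifnot(identical(dim(t), c(2L, 2L)), all(t >= 0))
  r1 <- sum(t[1, ]); c1 <- sum(t[, 1]); n <- sum(t)
  if (r1 == 0 || c1 == 0 || r1 == n || c1 == n) return(1)
  support <- max(0, r1 + c1 - n):min(r1, c1)
  probs <- dhyper(support, c1, n - c1, r1)
  p_obs <- dhyper(t[1, 1], c1, n - c1, r1)
  min(1, sum(probs[probs <= p_obs * (1 + 1e-7)]))
}

#' Bonferroni correction
#'
#' `min(1, p * m)`; the classical-HLA analyses use `m = 7` (seven loci).
#'
#' @param p p-value(s) in \[0, 1\].
#' @param m number of tests (default 7).
#' @return corrected p-value(s), capped at 1.
#' @export
bonferroni <- function(p, m = 7) {
  stopifnot(all(p >= 0 & p <= 1, na.rm = TRUE), m >= 1)
  pmin(1, p * m)
}

# Wald summary for one glm coefficient, with separation screening.
wald_row <- function(fit, term) {
  est <- unname(coef(fit)[term])
  se <- unname(sqrt(diag(vcov(fit)))[term])
  z <- qnorm(0.975)
  flag <- NA_character_
  if (!fit$converged || any(abs(coef(fit)) > 15) ||
      any(!is.finite(sqrt(diag(vcov(fit))))))
    flag <- "possible complete or quasi-separation: estimate unreliable"
  list(or = exp(est), ci_low = exp(est - z * se), ci_high = exp(est + z * se),
       p = 2 * pnorm(-abs(est / se)), flag = flag)
}

#' Covariate-adjusted logistic odds ratio
#'
#' Maximum-likelihood logistic regression of case status on a binary (or
#' ordinal) exposure, optionally adjusted for covariates (in the
#' motivating design, the mother's number of live births as a continuous
#' linear term). The OR is the exponentiated exposure coefficient with a
#' Wald 95% CI and Wald p-value. Fits showing signs of complete or
#' quasi-separation are flagged rather than reported as spuriously huge.
#'
#' @param outcome logical or 0/1 vector: case status per mother.
#' @param exposure binary (logical/0-1) or ordinal numeric exposure.
#' @param covariates optional data.frame of adjustment covariates.
#' @param label exposure label carried into the result.
#' @return an `assoc_result` (method `"adjusted_logistic"`, with the cell
#'   counts of the dichotomised exposure attached when the exposure is
#'   binary).
#' @export
fit_logistic <- function(outcome, exposure, covariates = NULL,
                         label = "exposure") {
  outcome <- as.integer(outcome)
  stopifnot(length(outcome) == length(exposure))
  if (sum(outcome, na.rm = TRUE) == 0 ||
      sum(1 - outcome, na.rm = TRUE) == 0)
    stop("need at least one case and one control", call. = FALSE)
  dat <- data.frame(.y = outcome, .x = as.numeric(exposure))
  if (!is.null(covariates)) dat <- cbind(dat, covariates)
  dat <- na.omit(dat)
  # glm's "fitted probabilities 0 or 1" warning is superseded by the
  # explicit separation screen below
  fit <- withCallingHandlers(
    glm(.y ~ ., family = binomial(), data = dat),
    warning = function(w) {
      if (grepl("fitted probabilities|did not converge",
                conditionMessage(w)))
        invokeRestart("muffleWarning")
    })
  w <- wald_row(fit, ".x")
  counts <- NULL
  if (all(dat$.x %in% 0:1))
    counts <- two_by_two(sum(dat$.x == 0 & dat$.y == 1),
                         sum(dat$.x == 0 & dat$.y == 0),
                         sum(dat$.x == 1 & dat$.y == 1),
                         sum(dat$.x == 1 & dat$.y == 0))
  res <- new_assoc_result(label, counts, w$or, w$ci_low, w$ci_high, w$p,
                          "adjusted_logistic",
                          covariates = setdiff(names(dat), c(".y", ".x")),
                          flag = w$flag)
  res$fit <- fit
  res
}

#' Ordinal trend test over SSM quartiles
#'
#' Logistic regression of case status on the quartile entered as a single
#' ordinal numeric term (1, 2, 3, 4), adjusted for covariates; the
#' p-value is the Wald p of that term. The p-value is invariant to affine
#' recoding of the quartile labels.
#'
#' @param quartile integer vector in 1..4 per mother.
#' @param outcome logical or 0/1 case status.
#' @param covariates optional data.frame of adjustment covariates.
#' @return an `assoc_result` (method `"trend"`; `odds_ratio` is the
#'   per-quartile OR).
#' @export
trend_test <- function(quartile, outcome, covariates = NULL) {
  keep <- !is.na(quartile) & !is.na(outcome)
  if (length(unique(quartile[keep])) < 2)
    return(new_assoc_result("SSM quartile trend", NULL, NA_real_, NA_real_,
                            NA_real_, NA_real_, "trend",
                            flag = "fewer than 2 occupied quartiles: trend undefined"))
  res <- fit_logistic(outcome[keep], as.numeric(quartile[keep]),
                      if (!is.null(covariates))
                        covariates[keep, , drop = FALSE],
                      label = "SSM quartile trend")
  res$method <- "trend"
  res
}

#' Case-control missingness chi-square test
#'
#' Pearson chi-square (no continuity correction) on a 2x2 of missing vs
#' observed exposure status by case-control group; used to probe whether
#' complete-case filtering could introduce selection bias (threshold
#' 0.05). Warns and suggests Fisher's exact test when an expected cell
#' count falls below 1.
#'
#' @param t 2x2 matrix, rows missing/observed, columns case/control.
#' @return an `assoc_result` (method `"chi2_missingness"`) with the
#'   p-value in `p_raw` and the X-squared statistic in `$statistic`.
#' @export
missingness_test <- function(t) {
  stopifnot(identical(dim(t), c(2L, 2L)), all(t >= 0))
  expected <- outer(rowSums(t), colSums(t)) / sum(t)
  flag <- NA_character_
  if (any(expected < 1))
    flag <- "expected cell count < 1: consider Fisher's exact test"
  if (any(rowSums(t) == 0) || any(colSums(t) == 0)) {
    res <- new_assoc_result("missingness by status", t, NA_real_, NA_real_,
                            NA_real_, 1, "chi2_missingness", flag = flag)
    res$statistic <- 0
    return(res)
  }
  ct <- suppressWarnings(chisq.test(t, correct = FALSE))
  res <- new_assoc_result("missingness by status", t, NA_real_, NA_real_,
                          NA_real_, unname(ct$p.value), "chi2_missingness",
                          flag = flag)
  res$statistic <- unname(ct$statistic)
  res
}
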