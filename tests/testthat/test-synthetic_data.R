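test_that("config validation rejects malformed frequencies and rates", {
  expect_error(sim_config(allele_freqs = list(B = c(0.6, 0.4))), "named")
  expect_error(sim_config(allele_freqs = list(B = c(x = 0.6, y = 0.3))),
               "sum to 1")
  expect_error(sim_config(missingness = list(B = 1.2)), "\\[0, 1\\]")
  expect_error(sim_config(exposure_log_or = c(ZZZ = 0.1)), "simulated loci")
})

test_that("a monomorphic locus makes every child compatible", {
  sim <- simulate_cohort(sim_config(
    n_mothers = 80, allele_freqs = list(B = c("B*07:02" = 1)),
    exposure_log_or = numeric(0), seed = 2))
  calls <- compatibility_calls(sim$cohort, "B")
  expect_true(all(calls$verdict == "compatible"))
})

test_that("the same seed reproduces the cohort byte for byte", {
  cfg <- sim_config(n_mothers = 60, seed = 99,
                    missingness = list(A = 0.05))
  p1 <- withr::local_tempfile(fileext = ".tsv")
  p2 <- withr::local_tempfile(fileext = ".tsv")
  write_cohort(simulate_cohort(cfg)$cohort, p1)
  write_cohort(simulate_cohort(cfg)$cohort, p2)
  expect_identical(readLines(p1), readLines(p2))
})

test_that("pipeline closure: classified exposures reproduce the simulated truth", {
  sim <- simulate_cohort(sim_config(n_mothers = 300, seed = 17))
  ex <- exposure_table(sim$cohort)
  truth <- sim$truth$exposure
  for (locus in sim$cohort$hla_loci) {
    got <- ex[[paste0("any_", locus)]] == "yes"
    expect_identical(got, truth[[locus]][match(ex$mother_id,
                                               truth$mother_id)],
                     info = locus)
  }
})

test_that("live-birth distribution is zero-truncated with the configured mean", {
  sim <- simulate_cohort(sim_config(n_mothers = 4000, mean_live_births = 2,
                                    exposure_log_or = numeric(0),
                                    allele_freqs = default_allele_freqs()["B"],
                                    seed = 23))
  lb <- sim$cohort$subjects$n_live_births[
    sim$cohort$subjects$role == "mother"]
  expect_true(all(lb >= 1))
  expect_lt(abs(mean(lb) - 2), 3 * sd(lb) / sqrt(length(lb)))
})

test_that("simulated sequence resources are valid and hand-checkable", {
  out <- simulate_sequences(list(B = c("B*07:02", "B*08:01")),
                            seq_length = 12, seed = 5)
  res <- out$resources
  expect_s3_class(res, "ssm_resources")
  expect_true(all(diag(res$dissimilarity) == 0))
  expect_true(isSymmetric(res$dissimilarity))
  # construct a single-mismatch pair and verify the weighted closed form
  s <- out$sequences[["B*07:02"]]
  v <- strsplit(s, "")[[1]]
  v[4] <- if (v[4] == "A") "R" else "A"
  res2 <- ssm_resources(c(out$sequences["B*07:02"],
                          setNames(paste(v, collapse = ""), "B*99:99")),
                        dissimilarity = res$dissimilarity,
                        position_weights = res$position_weights)
  expect_equal(allele_ssm("B*07:02", "B*99:99", res2, locus = "B"),
               res$position_weights$B[4] *
                 res$dissimilarity[strsplit(s, "")[[1]][4], v[4]])
  # identical duplicated sequences score zero
  res3 <- ssm_resources(c(X1 = s, X2 = s),
                        dissimilarity = res$dissimilarity)
  expect_equal(allele_ssm("X1", "X2", res3, locus = "B"), 0)
  # FASTA round trip through the reader
  fp <- withr::local_tempfile(fileext = ".fasta")
  simulate_sequences(list(B = c("B*07:02", "B*08:01")), seq_length = 12,
                     seed = 5, fasta_path = fp)
  expect_identical(read_allele_sequences(fp), out$sequences)
})

test_that("parity confounding moves the crude OR away from the adjusted OR", {
  # live births raise both disease odds and exposure opportunity (more
  # children); with a null direct exposure effect the crude OR sits above
  # the adjusted one
  cfg <- sim_config(n_mothers = 4000,
                    allele_freqs = default_allele_freqs()["B"],
                    exposure_log_or = numeric(0),
                    live_births_log_or = log(1.9),
                    mean_live_births = 2.5, max_children = 4, seed = 31)
  sim <- simulate_cohort(cfg)
  ex <- exposure_table(sim$cohort, "B")
  y <- ex$disease != "control"
  x <- as.integer(ex$any_B == "yes")
  crude <- fit_logistic(y, x)$odds_ratio
  adj <- fit_logistic(y, x, covariates = ex["n_live_births"])$odds_ratio
  expect_gt(crude, adj)
})

test_that("published tables have positive totals and the documented key counts", {
  tabs <- published_tables()
  expect_equal(length(tabs), 26)
  expect_true(all(vapply(tabs, sum, numeric(1)) > 0))
  expect_equal(as.integer(tabs[["T7-ZAPHIR"]]), c(39L, 0L, 202L, 21L))
  expect_equal(as.integer(tabs[["T6-ZAPHIR"]]), c(29L, 10L, 117L, 106L))
  # case columns of the RA tables sum to the analysed sample sizes
  expect_true(all(vapply(tabs[paste0("T2-", c("A", "B", "C", "DPB1",
                                              "DQA1", "DQB1", "DRB1"))],
                         function(t) sum(t[, "case"]), numeric(1)) == 138))
  expect_true(all(vapply(tabs[grep("^T2|^T3", names(tabs))],
                         function(t) sum(t[, "control"]), numeric(1)) == 913))
})
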