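test_that("allele-level SSM: identity, hand-summed mismatch, additivity", {
  seqs <- c(X1 = "ARND", X2 = "ARNE", X3 = "GRNE", X4 = "GKNE")
  res <- toy_ssm_resources(seqs,
                           dissim_pairs = list(list(a = "D", b = "E", value = 1.5),
                                               list(a = "A", b = "G", value = 2.5),
                                               list(a = "R", b = "K", value = 0.5)),
                           weights = list(X = c(1, 1, 1, 2)))
  expect_equal(allele_ssm("X1", "X1", res, locus = "X"), 0)
  # single mismatch at position 4: weight 2 x d(D,E) 1.5 = 3
  expect_equal(allele_ssm("X1", "X2", res, locus = "X"), 3.0)
  # three mismatches decompose into the three single-mismatch scores
  s_total <- allele_ssm("X1", "X4", res, locus = "X")
  s_parts <- allele_ssm("X1", "X2", res, locus = "X") +
    allele_ssm("X2", "X3", res, locus = "X") +
    allele_ssm("X3", "X4", res, locus = "X")
  expect_equal(s_total, s_parts)
})

test_that("allele SSM is symmetric, non-negative, zero iff identical", {
  sim <- simulate_sequences(list(B = paste0("B*0", 1:6, ":01")),
                            seq_length = 30, seed = 21)
  res <- sim$resources
  nm <- names(sim$sequences)
  for (i in seq_along(nm)) for (j in seq_along(nm)) {
    s <- allele_ssm(nm[i], nm[j], res, locus = "B")
    expect_equal(s, allele_ssm(nm[j], nm[i], res, locus = "B"))
    expect_gte(s, 0)
    if (sim$sequences[i] != sim$sequences[j]) expect_gt(s, 0)
    if (i == j) expect_equal(s, 0)
  }
})

test_that("unaligned sequences and missing sequences are handled explicitly", {
  res <- toy_ssm_resources(c(A1 = "ARND", A2 = "ARNDE"))
  expect_error(allele_ssm("A1", "A2", res, locus = "A"), "not aligned")
  expect_true(is.na(allele_ssm("A1", "A9", res, locus = "A")))
})

test_that("pair SSM: zero rule, forced assignment, min-score tie-break", {
  seqs <- c(m1 = "AAAA", m2 = "CCCC", p1 = "AACC")
  res <- toy_ssm_resources(seqs)
  # genotype-identical pairs score exactly 0 even though alleles differ
  expect_equal(pair_ssm(c("m1", "m2"), c("m2", "m1"), res, locus = "X"), 0)
  expect_equal(pair_ssm(c("m1", "m1"), c("m1", "m1"), res, locus = "X"), 0)
  # forced assignment: child {m1, p1} -> score(noninherited m2, paternal p1)
  expect_equal(pair_ssm(c("m1", "m2"), c("m1", "p1"), res, locus = "X"),
               allele_ssm("m2", "p1", res, locus = "X"))
  # homozygous child {m1, m1}: unique assignment -> score(m2, m1)
  expect_equal(pair_ssm(c("m1", "m2"), c("m1", "m1"), res, locus = "X"),
               allele_ssm("m2", "m1", res, locus = "X"))
  # Mendelian error and missing genotype propagate as NA
  expect_true(is.na(pair_ssm(c("m1", "m1"), c("m2", "p1"), res, locus = "X")))
  expect_true(is.na(pair_ssm(c("m1", NA), c("m1", "m1"), res, locus = "X")))
})

test_that("pair SSM equals exhaustive assignment enumeration on random trios", {
  sim <- simulate_sequences(list(B = paste0("B*0", 1:5, ":01")),
                            seq_length = 20, seed = 33)
  res <- sim$resources
  al <- names(sim$sequences)
  set.seed(14)
  for (k in 1:300) {
    mother <- sample(al, 2, replace = TRUE)
    transmitted <- sample(mother, 1)
    child <- sample(c(transmitted, sample(al, 1)))  # Mendelian by design
    expect_equal(pair_ssm(mother, child, res, locus = "B"),
                 oracle_pair_ssm(mother, child, res, "B"),
                 info = paste(paste(mother, collapse = "/"),
                              paste(child, collapse = "/")))
  }
})

test_that("per-mother means average eligible children's pair scores", {
  seqs <- c(m1 = "AAAA", m2 = "CCCC", p1 = "ACCC", p2 = "AAAC")
  res <- toy_ssm_resources(seqs)
  subs <- list(
    list(family_id = "F1", subject_id = "M1", role = "mother",
         disease = "control", n_live_births = 2),
    list(family_id = "F1", subject_id = "C1", role = "child"),
    list(family_id = "F1", subject_id = "C2", role = "child"))
  g <- list(M1 = list(B = c("m1", "m2")),
            C1 = list(B = c("m1", "m2")),   # set-identical: 0
            C2 = list(B = c("m1", "p1")))   # allele_ssm(m2, p1) = 1
  cohort <- build_cohort(subs, g, hla_loci = "B")
  ms <- mother_mean_ssm(cohort, "B", res)
  expect_equal(ms$mean_ssm, (0 + allele_ssm("m2", "p1", res, "B")) / 2)
  expect_equal(ms$n_children_scored, 2)
})

test_that("control quartile cutpoints use linear interpolation; assignment is left-closed", {
  expect_equal(control_quartile_cutpoints(0:7), c(1.75, 3.5, 5.25))
  expect_error(control_quartile_cutpoints(rep(2, 10)), "degenerate")
  cut <- c(1.75, 3.5, 5.25)
  expect_equal(assign_quartile(c(0, 1.74, 1.75, 3.49, 3.5, 5.25, 99), cut),
               c(1L, 1L, 2L, 2L, 3L, 4L, 4L))
  expect_true(is.na(assign_quartile(NA_real_, cut)))
  # monotonicity: a larger score never gets a smaller quartile
  set.seed(9)
  x <- sort(runif(200, 0, 8))
  expect_true(!is.unsorted(assign_quartile(x, cut)))
  # occupancy ~25% per quartile when scored on the control scores themselves
  q <- assign_quartile(x, control_quartile_cutpoints(x))
  expect_true(all(abs(as.integer(table(q)) / 200 - 0.25) <= 0.02))
})

test_that("mothers with a compatible child have lower mean SSM scores", {
  freqs <- default_allele_freqs()["B"]
  sim <- simulate_cohort(sim_config(n_mothers = 600, allele_freqs = freqs,
                                    exposure_log_or = numeric(0), seed = 19))
  seqres <- simulate_sequences(list(B = names(freqs$B)), seq_length = 40,
                               seed = 20)
  ms <- mother_mean_ssm(sim$cohort, "B", seqres$resources)
  ex <- mother_exposure(sim$cohort, "B")
  stopifnot(identical(ms$mother_id, ex$mother_id))
  mean_yes <- mean(ms$mean_ssm[ex$any_compatible == "yes"], na.rm = TRUE)
  mean_no <- mean(ms$mean_ssm[ex$any_compatible == "no"], na.rm = TRUE)
  expect_lt(mean_yes, mean_no)
})
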