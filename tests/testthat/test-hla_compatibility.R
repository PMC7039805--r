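test_that("paternal inference resolves, flags ambiguity and Mendelian errors", {
  inf <- infer_paternal(c("B*07:02", "B*08:01"), c("B*07:02", "B*44:02"))
  expect_equal(inf$status, "resolved")
  expect_equal(inf$paternal_candidates, "B*44:02")
  expect_equal(inf$noninherited_maternal, "B*08:01")

  inf <- infer_paternal(c("A*01:01", "A*02:01"), c("A*01:01", "A*02:01"))
  expect_equal(inf$status, "ambiguous_both_maternal")
  expect_setequal(inf$paternal_candidates, c("A*01:01", "A*02:01"))

  inf <- infer_paternal(c("A*01:01", "A*01:01"), c("A*02:01", "A*03:01"))
  expect_equal(inf$status, "mendelian_error")
  expect_length(inf$paternal_candidates, 0)

  # homozygous-child edge: the unique Mendelian assignment
  inf <- infer_paternal(c("A*01:01", "A*02:01"), c("A*01:01", "A*01:01"))
  expect_equal(inf$status, "resolved")
  expect_equal(inf$paternal_candidates, "A*01:01")
  expect_equal(inf$noninherited_maternal, "A*02:01")

  expect_equal(infer_paternal(c("A*01:01", NA), c("A*01:01", "A*02:01"))$status,
               "missing")
})

test_that("classification examples and homozygous-mother degeneracy", {
  expect_equal(classify_compatibility(c("DQB1*03:01", "DQB1*06:02"),
                                      c("DQB1*03:01", "DQB1*06:02"))$verdict,
               "compatible")
  expect_equal(classify_compatibility(c("B*07:02", "B*08:01"),
                                      c("B*07:02", "B*44:02"))$verdict,
               "incompatible")
  # homozygous mother m/m: child compatible iff child is m/m
  m <- c("A*01:01", "A*01:01")
  expect_equal(classify_compatibility(m, c("A*01:01", "A*01:01"))$verdict,
               "compatible")
  expect_equal(classify_compatibility(m, c("A*01:01", "A*02:01"))$verdict,
               "incompatible")
})

test_that("classifier equals the phase-enumeration oracle on all small alphabets", {
  for (size in 2:6) {
    alphabet <- paste0("X*0", seq_len(size), ":01")
    gts <- all_genotypes(alphabet)
    for (i in seq_len(nrow(gts))) for (j in seq_len(nrow(gts))) {
      mother <- c(gts$a1[i], gts$a2[i])
      child <- c(gts$a1[j], gts$a2[j])
      expect_equal(classify_compatibility(mother, child)$verdict,
                   oracle_classify(mother, child),
                   info = paste(size, paste(mother, collapse = "/"),
                                paste(child, collapse = "/")))
    }
  }
  # and compatible <=> both child alleles in the mother's set
  al <- paste0("X*0", 1:4, ":01")
  set.seed(1)
  for (k in 1:200) {
    mother <- sample(al, 2, replace = TRUE)
    child <- sample(al, 2, replace = TRUE)
    v <- classify_compatibility(mother, child)$verdict
    if (v %in% c("compatible", "incompatible"))
      expect_equal(v == "compatible", all(child %in% mother))
  }
})

test_that("mother exposure applies the born-before-diagnosis eligibility rule", {
  subs <- list(
    list(family_id = "F1", subject_id = "M1", role = "mother",
         disease = "RA", n_live_births = 2),
    list(family_id = "F1", subject_id = "C1", role = "child",
         born_before = TRUE),
    list(family_id = "F1", subject_id = "C2", role = "child",
         born_before = FALSE),
    list(family_id = "F2", subject_id = "M2", role = "mother",
         disease = "control", n_live_births = 3),
    list(family_id = "F2", subject_id = "C3", role = "child"),
    list(family_id = "F2", subject_id = "C4", role = "child"),
    list(family_id = "F2", subject_id = "C5", role = "child"))
  g <- list(
    M1 = list(B = c("B*07:02", "B*08:01")),
    C1 = list(B = c("B*07:02", "B*08:01")),   # compatible, born before
    C2 = list(B = c("B*08:01", "B*08:01")),   # compatible, born after
    M2 = list(B = c("B*07:02", "B*08:01")),
    C3 = list(B = c("B*07:02", "B*44:02")),
    C4 = list(B = c("B*08:01", "B*44:03")),
    C5 = list(B = c("B*07:02", "B*15:01")))
  cohort <- build_cohort(subs, g, hla_loci = "B")
  ex <- mother_exposure(cohort, "B")
  expect_equal(ex$any_compatible[ex$mother_id == "M1"], "yes")
  expect_equal(ex$n_children_used[ex$mother_id == "M1"], 1)  # C2 excluded
  # control mother, no compatible children
  expect_equal(ex$any_compatible[ex$mother_id == "M2"], "no")
  expect_equal(ex$n_children_used[ex$mother_id == "M2"], 3)

  # eligibility flags never affect control mothers
  flipped <- cohort
  kids <- flipped$subjects$role == "child" &
    flipped$subjects$family_id == "F2"
  flipped$subjects$born_before_diagnosis[kids] <- FALSE
  ex2 <- mother_exposure(flipped, "B")
  expect_identical(ex2[ex2$mother_id == "M2", ], ex[ex$mother_id == "M2", ])
})

test_that("missing child verdicts are excluded, not contagious", {
  subs <- list(
    list(family_id = "F1", subject_id = "M1", role = "mother",
         disease = "control", n_live_births = 2),
    list(family_id = "F1", subject_id = "C1", role = "child"),
    list(family_id = "F1", subject_id = "C2", role = "child"))
  g <- list(M1 = list(B = c("B*07:02", "B*08:01")),
            C1 = list(B = c("B*07:02", "B*08:01")),
            C2 = list(B = c(NA, NA)))
  cohort <- build_cohort(subs, g, hla_loci = "B")
  ex <- mother_exposure(cohort, "B")
  expect_equal(ex$any_compatible, "yes")
  expect_equal(ex$n_children_used, 1)
  expect_equal(ex$n_children_missing, 1)
  # no usable child at all -> missing exposure
  g$C1$B <- c(NA, NA)
  ex <- mother_exposure(build_cohort(subs, g, hla_loci = "B"), "B")
  expect_true(is.na(ex$any_compatible))
})

test_that("simulator output is Mendelian-consistent and matches analytic prevalence", {
  freqs <- c("X*01:01" = 0.5, "X*02:01" = 0.5)
  cfg <- sim_config(n_mothers = 3000, allele_freqs = list(X = freqs),
                    exposure_log_or = numeric(0), max_children = 1,
                    seed = 7)
  sim <- simulate_cohort(cfg)
  calls <- compatibility_calls(sim$cohort, "X")
  expect_equal(sum(calls$verdict == "mendelian_error"), 0)
  # per-child compatibility rate vs the mating-type enumeration (0.75 for
  # two equifrequent alleles), within Monte-Carlo error
  p_hat <- mean(calls$verdict == "compatible")
  p_exp <- analytic_child_compat_prob(freqs)
  expect_equal(p_exp, 0.75)
  expect_lt(abs(p_hat - p_exp), 3 * sqrt(p_exp * (1 - p_exp) / nrow(calls)))
})

test_that("complete-case filter drops exactly the locus-incomplete mothers", {
  sim <- simulate_cohort(sim_config(n_mothers = 1500, seed = 5,
                                    exposure_log_or = numeric(0),
                                    missingness = list(DQB1 = 0.1)))
  ex <- exposure_table(sim$cohort)
  ccf <- complete_case_filter(ex, sim$cohort$hla_loci)
  expect_true(all(!is.na(ccf$complete[paste0("any_", sim$cohort$hla_loci)])))
  # mothers complete everywhere but DQB1 are excluded
  others <- setdiff(sim$cohort$hla_loci, "DQB1")
  base_ok <- rowSums(is.na(ex[paste0("any_", others)])) == 0
  retained <- sum(base_ok & !is.na(ex$any_DQB1)) / sum(base_ok)
  expect_equal(nrow(ccf$complete), sum(base_ok & !is.na(ex$any_DQB1)))
  # retained fraction matches the closed form for per-subject MCAR
  # dropout at rate r: mother observed x at least one child observed,
  # i.e. (1-r) * (1 - r^k) for a family with k children
  kids <- sim$cohort$subjects[sim$cohort$subjects$role == "child", ]
  k <- as.integer(table(factor(kids$family_id,
                               levels = sub("_M$", "", ex$mother_id))))
  p_keep <- 0.9 * (1 - 0.1^k)
  expected <- mean(p_keep[base_ok])
  expect_lt(abs(retained - expected), 0.03)
  # missingness tally is consistent
  mm <- ccf$missingness
  expect_true(all(mm$n_missing + mm$n_observed ==
                    as.vector(table(ex$disease)[mm$group])))
})
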