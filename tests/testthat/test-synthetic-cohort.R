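test_that("latent sigma has the planted block structure", {
  diseases <- rbind(disease_spec("a", 0.2, 1), disease_spec("b", 0.2, 1),
                    disease_spec("c", 0.2, 2), disease_spec("d", 0.2, 2))
  strata <- data.frame(sex = "M", age_band = "0-2", n_patients = 10)
  # independence case: identity
  s0 <- build_latent_sigma(cohort_spec(strata, diseases, 0, 0))
  expect_equal(unname(s0), diag(4))
  # two blocks of two at rho_within = 0.5: block-diagonal
  s1 <- build_latent_sigma(cohort_spec(strata, diseases, 0.5, 0))
  expect_equal(unname(s1),
               rbind(c(1, 0.5, 0, 0), c(0.5, 1, 0, 0),
                     c(0, 0, 1, 0.5), c(0, 0, 0.5, 1)))
  expect_equal(rownames(s1), diseases$disease_id)
})

test_that("non-positive-definite specs are rejected naming the parameters", {
  diseases <- rbind(disease_spec("a", 0.2, 1), disease_spec("b", 0.2, 1),
                    disease_spec("c", 0.2, 1))
  strata <- data.frame(sex = "M", age_band = "0-2", n_patients = 10)
  # eigenvalues of an equicorrelation 3x3 block at rho = -0.6 include 1 + 2*(-0.6) < 0
  expect_lt(min(eigen(matrix(c(1, -.6, -.6, -.6, 1, -.6, -.6, -.6, 1), 3),
                      symmetric = TRUE, only.values = TRUE)$values), 0)
  expect_error(cohort_spec(strata, diseases, rho_within = -0.6),
               "not positive definite.*rho_within = -0.6")
})

test_that("cohort spec validation catches malformed inputs", {
  diseases <- rbind(disease_spec("a", 0.2, 1), disease_spec("b", 0.3, 1))
  strata <- data.frame(sex = "M", age_band = "0-2", n_patients = 10)
  expect_error(cohort_spec(strata[0, ], diseases), "at least one stratum")
  expect_error(cohort_spec(data.frame(sex = "X", age_band = "0-2", n_patients = 1),
                           diseases), "sex")
  expect_error(cohort_spec(data.frame(sex = "M", age_band = "2-10", n_patients = 1),
                           diseases), "age_band")
  bad <- diseases; bad$prevalence[1] <- 1.2
  expect_error(cohort_spec(strata, bad), "strictly in \\(0, 1\\)")
  dup <- rbind(diseases, disease_spec("a", 0.1, 2))
  expect_error(cohort_spec(strata, dup), "unique")
})

test_that("generation is deterministic and independent across strata", {
  spec <- planted_spec(200, seed = 5, n_blocks = 2, per_block = 3,
                       bands = c("0-2", "3-10"))
  c1 <- generate_cohort(spec)
  c2 <- generate_cohort(spec)
  expect_identical(c1$matrices, c2$matrices)
  # subsetting the strata leaves each stratum's draw unchanged
  sub <- spec
  sub$strata <- spec$strata[spec$strata$age_band == "0-2", ]
  c3 <- generate_cohort(sub)
  expect_identical(c3$matrices[["M:0-2"]], c1$matrices[["M:0-2"]])
})

test_that("empirical prevalences match their targets", {
  diseases <- rbind(disease_spec("a", 0.3, 1), disease_spec("b", 0.1, 1),
                    disease_spec("c", 0.5, 2))
  strata <- data.frame(sex = "M", age_band = "18-65", n_patients = 10000)
  cohort <- generate_cohort(cohort_spec(strata, diseases, 0.5, 0, seed = 9))
  prev <- prevalence(cohort$matrices[[1]])
  for (j in 1:3) {
    se <- sqrt(diseases$prevalence[j] * (1 - diseases$prevalence[j]) / 10000)
    expect_lt(abs(prev[j] - diseases$prevalence[j]), 3 * se)
  }
})

test_that("marginal calibration holds across seeds", {
  # 4-sigma binomial band violated in at most 1% of (seed, disease) draws
  diseases <- rbind(disease_spec("a", 0.05, 1), disease_spec("b", 0.2, 1),
                    disease_spec("c", 0.5, 2))
  n <- 2000
  bad <- 0L
  for (s in 1:100) {
    strata <- data.frame(sex = "F", age_band = ">65", n_patients = n)
    cohort <- generate_cohort(cohort_spec(strata, diseases, 0.4, 0, seed = s))
    prev <- prevalence(cohort$matrices[[1]])
    p <- diseases$prevalence
    bad <- bad + sum(abs(prev - p) >= 4 * sqrt(p * (1 - p) / n))
  }
  expect_lte(bad / 300, 0.01)
})

test_that("independent diseases produce near-zero tetrachoric correlations", {
  diseases <- rbind(disease_spec("a", 0.3, 1), disease_spec("b", 0.4, 2),
                    disease_spec("c", 0.5, 3))
  strata <- data.frame(sex = "M", age_band = "3-10", n_patients = 10000)
  cohort <- generate_cohort(cohort_spec(strata, diseases, 0, 0, seed = 21))
  ind <- cohort$matrices[[1]]$indicators
  for (pair in list(c(1, 2), c(1, 3), c(2, 3))) {
    a <- ind[, pair[1]]; b <- ind[, pair[2]]
    fit <- estimate_tetrachoric(contingency_table(
      sum(a & b), sum(a & !b), sum(!a & b), sum(!a & !b)))
    # rho_hat is asymptotically normal around 0 with the fitted se
    expect_lt(abs(fit$rho), 3 * fit$se)
  }
})

test_that("tetrachoric estimation recovers the planted latent correlation", {
  diseases <- rbind(disease_spec("a", 0.3, 1), disease_spec("b", 0.2, 1))
  strata <- data.frame(sex = "M", age_band = "11-17", n_patients = 5000)
  rhos <- vapply(1:20, function(s) {
    cohort <- generate_cohort(cohort_spec(strata, diseases, 0.5, 0, seed = 600 + s))
    ind <- cohort$matrices[[1]]$indicators
    a <- ind[, 1]; b <- ind[, 2]
    estimate_tetrachoric(contingency_table(
      sum(a & b), sum(a & !b), sum(!a & b), sum(!a & !b)))$rho
  }, numeric(1))
  expect_lt(abs(mean(rhos) - 0.5), 0.05)
})

test_that("stratum sizes follow the requested proportions exactly", {
  # men's age distribution with the published cohort's shares, scaled 1:10
  men <- data.frame(sex = "M", age_band = age_bands(),
                    n_patients = c(160, 895, 532, 599, 166))
  diseases <- rbind(disease_spec("a", 0.2, 1), disease_spec("b", 0.2, 1))
  cohort <- generate_cohort(cohort_spec(men, diseases, 0.3, 0, seed = 2))
  sizes <- vapply(cohort$matrices, function(m) nrow(m$indicators), integer(1))
  expect_equal(unname(sizes[paste0("M:", age_bands())]), men$n_patients)
})

test_that("median-split pairs have the closed-form cell fractions", {
  # rho = 0: all four cells near 1/4
  t0 <- median_split_pair(0, 40000, seed = 3)
  expect_lt(max(abs(c(t0$n11, t0$n10, t0$n01, t0$n00) / t0$n - 0.25)), 0.01)
  # rho = 0.5: joint-positive fraction near 1/4 + asin(0.5)/(2 pi) = 1/3
  t5 <- median_split_pair(0.5, 40000, seed = 4)
  expect_lt(abs(t5$n11 / t5$n - 1 / 3), 0.01)
  # comonotone limit: off-diagonal cells nearly empty
  t9 <- median_split_pair(0.999, 40000, seed = 5)
  expect_lt((t9$n10 + t9$n01) / t9$n, 0.02)
  expect_error(median_split_pair(1, 100), "\\|rho\\| < 1")
})

test_that("cohorts round-trip through delimited text and truth sidecar", {
  spec <- planted_spec(50, seed = 8, n_blocks = 2, per_block = 2,
                       bands = c("0-2", ">65"))
  cohort <- generate_cohort(spec)
  dir <- tempfile()
  write_cohort(cohort, dir)
  back <- read_cohort(dir)
  for (key in names(cohort$matrices)) {
    expect_identical(back$matrices[[key]]$indicators,
                     cohort$matrices[[key]]$indicators)
  }
  expect_equal(back$truth$sigma, cohort$truth$sigma)
  expect_equal(back$truth$seed, cohort$truth$seed)
})

test_that("flattened diagnosis records survive read_records unchanged", {
  spec <- planted_spec(40, seed = 12, n_blocks = 2, per_block = 2,
                       bands = "3-10")
  cohort <- generate_cohort(spec)
  recs <- as_diagnosis_records(cohort)
  path <- write_records_file(recs)
  rr <- read_records(path)
  expect_equal(nrow(rr$rejects), 0)
  got <- rr$records[order(rr$records$patient_id, rr$records$code), ]
  rownames(got) <- NULL
  rownames(recs) <- NULL
  expect_equal(got, recs)
})
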