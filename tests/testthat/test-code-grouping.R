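test_that("well-formed records are read and malformed rows are reported", {
  df <- data.frame(patient_id = c("p1", "p2", "p3"), sex = c("M", "F", "M"),
                   age_band = c("0-2", "3-10", ">65"),
                   code = c("C1", "C2", "C3"), coding_system = "ICD9CM")
  rr <- read_records(write_records_file(df))
  expect_equal(nrow(rr$records), 3)
  expect_equal(nrow(rr$rejects), 0)

  bad <- rbind(df, data.frame(patient_id = "p4", sex = "M", age_band = "2-10",
                              code = "C1", coding_system = "ICD9CM"))
  rr <- read_records(write_records_file(bad))
  expect_equal(nrow(rr$records), 3)
  expect_equal(rr$rejects$row, 4)
  expect_match(rr$rejects$reason, "unknown age band")

  bad2 <- rbind(df, data.frame(patient_id = "p5", sex = "U", age_band = "0-2",
                               code = "C1", coding_system = "ICD9CM"))
  rr2 <- read_records(write_records_file(bad2))
  expect_match(rr2$rejects$reason, "unknown sex")
})

test_that("a missing required column is a hard error naming it", {
  df <- data.frame(patient_id = "p1", sex = "M", age_band = "0-2", code = "C1")
  expect_error(read_records(write_records_file(df)), "coding_system")
})

test_that("en-dash age bands from copy-pasted tables are normalized", {
  df <- data.frame(patient_id = "p1", sex = "F",
                   age_band = "3–10",   # en dash
                   code = "C1", coding_system = "ICPC1")
  rr <- read_records(write_records_file(df))
  expect_equal(rr$records$age_band, "3-10")
})

test_that("chronic filtering keeps chronic codes and reports unmapped ones", {
  lk <- toy_lookup()
  recs <- data.frame(patient_id = paste0("p", 1:5), sex = "M",
                     age_band = "18-65",
                     code = c("C1", "C2", "C5", "C6", "C3"),
                     coding_system = "ICD9CM")
  fc <- filter_chronic(recs, lk)
  # C5, C6 mapped not_chronic: 3 of 5 retained
  expect_equal(nrow(fc$records), 3)
  expect_equal(sort(fc$records$code), c("C1", "C2", "C3"))
  expect_equal(nrow(fc$unmapped), 0)

  recs2 <- rbind(recs, data.frame(patient_id = c("p6", "p7"), sex = "M",
                                  age_band = "18-65", code = "ZZZ",
                                  coding_system = "ICD9CM"))
  fc2 <- filter_chronic(recs2, lk)
  expect_equal(nrow(fc2$records), 3)
  expect_equal(fc2$unmapped, data.frame(code = "ZZZ", n_records = 2L))
})

test_that("lookup invariants are enforced", {
  expect_error(code_lookup(
    chronic = data.frame(code = "C1", chronic_flag = "chronic"),
    category = data.frame(code = c("C1", "C2"), category_id = c(1L, 2L),
                          category_label = c("x", "y"))),
    "not chronic table")
  expect_error(code_lookup(
    chronic = data.frame(code = c("C1", "C1"), chronic_flag = "chronic"),
    category = data.frame(code = "C1", category_id = 1L, category_label = "x")),
    "duplicate")
  expect_error(code_lookup(
    chronic = data.frame(code = c("C1", "C2"), chronic_flag = "chronic"),
    category = data.frame(code = c("C1", "C2"), category_id = c(1L, 3L),
                          category_label = c("x", "y"))),
    "contiguous")
  expect_error(code_lookup(
    chronic = data.frame(code = "C1", chronic_flag = "sometimes"),
    category = data.frame(code = "C1", category_id = 1L, category_label = "x")),
    "chronic_flag")
})

test_that("matrix construction is idempotent over duplicate diagnoses", {
  lk <- toy_lookup()
  recs <- data.frame(patient_id = "p1", sex = "M", age_band = "3-10",
                     code = c("C1", "C1", "C5"),   # C5 groups into asthma too
                     coding_system = "ICD9CM")
  ms <- build_matrix(recs, lk)
  expect_equal(unname(ms[["M:3-10"]]$indicators[, "asthma"]), 1L)
  expect_equal(prevalence(ms[["M:3-10"]])[["asthma"]], 1)
  # duplicating every input row changes nothing
  ms2 <- build_matrix(rbind(recs, recs), lk)
  expect_identical(ms2[["M:3-10"]]$indicators, ms[["M:3-10"]]$indicators)
})

test_that("disjoint categories give an identity indicator grid", {
  lk <- toy_lookup()
  recs <- data.frame(patient_id = c("p1", "p2"), sex = "F", age_band = "0-2",
                     code = c("C1", "C2"), coding_system = "ICD9CM")
  ms <- build_matrix(recs, lk)
  expect_equal(unname(ms[["F:0-2"]]$indicators), diag(2))
})

test_that("an eight-patient fixture reproduces its hand-counted prevalences", {
  lk <- toy_lookup()
  # hand count over categories:
  #   asthma   (C1): p1 p2 p3 p4 p5  -> 5/8
  #   rhinitis (C2): p1 p6           -> 2/8
  #   anxiety  (C3): p2 p6 p7        -> 3/8
  #   obesity  (C4): p8              -> 1/8
  recs <- data.frame(
    patient_id = c("p1", "p1", "p2", "p2", "p3", "p4", "p5", "p6", "p6",
                   "p7", "p8"),
    sex = "F", age_band = "18-65",
    code = c("C1", "C2", "C1", "C3", "C1", "C1", "C1", "C2", "C3", "C3", "C4"),
    coding_system = "ICD9CM")
  ms <- build_matrix(recs, lk)
  expect_equal(prevalence(ms[["F:18-65"]]),
               c(anxiety = 3 / 8, asthma = 5 / 8, obesity = 1 / 8,
                 rhinitis = 2 / 8))
})

test_that("conflicting per-patient demographics are a hard error", {
  lk <- toy_lookup()
  recs <- data.frame(patient_id = c("p1", "p1"), sex = c("M", "F"),
                     age_band = "0-2", code = "C1", coding_system = "ICD9CM")
  expect_error(build_matrix(recs, lk), "conflicting sex/age_band.*p1")
})

test_that("strata partition the patients and row order is irrelevant", {
  lk <- toy_lookup()
  withr::with_seed(31, {
    n <- 40
    recs <- data.frame(
      patient_id = rep(sprintf("p%02d", 1:n), each = 2),
      sex = rep(sample(c("M", "F"), n, replace = TRUE), each = 2),
      age_band = rep(sample(age_bands(), n, replace = TRUE), each = 2),
      code = sample(paste0("C", 1:4), 2 * n, replace = TRUE),
      coding_system = "ICD9CM")
  })
  ms <- build_matrix(recs, lk)
  expect_equal(sum(vapply(ms, function(m) nrow(m$indicators), integer(1))),
               length(unique(recs$patient_id)))
  shuffled <- recs[rev(seq_len(nrow(recs))), ]
  ms2 <- build_matrix(shuffled, lk)
  expect_identical(ms2[names(ms)], ms[names(ms)],
                   ignore_attr = FALSE)
})

test_that("excluded categories and unmapped codes are handled explicitly", {
  lk <- toy_lookup()
  recs <- data.frame(patient_id = c("p1", "p1", "p2"), sex = "M",
                     age_band = "0-2", code = c("C1", "C3", "XX"),
                     coding_system = "ICD9CM")
  ms <- build_matrix(recs, lk, exclude_categories = "asthma")
  expect_false("asthma" %in% colnames(ms[["M:0-2"]]$indicators))
  expect_equal(attr(ms, "unmapped_codes"),
               data.frame(code = "XX", n_records = 1L))
})

test_that("ages map to the five inclusive bands", {
  expect_equal(as.character(assign_age_band(c(0, 2, 3, 10, 11, 17, 18, 65, 66, 90))),
               c("0-2", "0-2", "3-10", "3-10", "11-17", "11-17",
                 "18-65", "18-65", ">65", ">65"))
  expect_error(assign_age_band(-1), "non-negative")
})
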