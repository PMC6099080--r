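test_that("packaged clinical schema is complete and internally consistent", {
  sch <- tbi_schema()
  expect_length(sch, 37)
  expect_setequal(unique(vapply(sch, `[[`, "", "category")),
                  c("demographics", "medical_history", "mechanism", "ed_exam",
                    "blood_work", "vital_signs", "complications"))
  for (sp in sch) {
    if (sp$vtype == "binary") expect_identical(sp$levels, c(0L, 1L))
    if (sp$vtype == "ordinal")
      expect_identical(sp$levels, seq_along(sp$levels))
    if (!is.null(sp$bins)) {
      expect_true(all(diff(sp$bins) > 0))
      expect_length(sp$bins, length(sp$levels) - 1L)
    }
  }
  # the two numeric GCS variables
  numerics <- names(sch)[vapply(sch, `[[`, "", "vtype") == "numeric"]
  expect_setequal(numerics, c("gcs_ed_arrival", "gcs_ed_discharge"))
})

test_that("vital-sign binning honors the printed band boundaries", {
  sch <- tbi_schema()
  # diastolic: low < 60, normal 60-89, high >= 90
  expect_equal(bin_vital(c(59, 60, 89, 90), sch$dbp_ed), c(1, 2, 2, 3))
  # systolic high is "at least 140"
  expect_equal(bin_vital(c(139.5, 140), sch$sbp_ed), c(2, 3))
  # O2 saturation has two bands, normal is "at least 90"
  expect_equal(bin_vital(c(89.9, 90), sch$o2_saturation_ed), c(1, 2))
  # temperature high is "greater than 37.7": the cut point stays normal
  expect_equal(bin_vital(c(34.9, 35, 37.7, 37.71), sch$temperature_ed),
               c(1, 2, 2, 3))
  # heart rate normal 60-100, high at least 101 (values in the printed gap
  # between the integer bands stay normal)
  expect_equal(bin_vital(c(100, 100.5, 101), sch$heart_rate_ed), c(2, 2, 3))
})

test_that("binning is a monotone, exhaustive, exclusive step function", {
  sch <- tbi_schema()
  for (v in c("dbp_ed", "sbp_ed", "temperature_ed", "o2_saturation_ed",
              "respiratory_rate_ed")) {
    sp <- sch[[v]]
    x <- sort(runif(200, min(sp$bins) - 30, max(sp$bins) + 30))
    codes <- bin_vital(x, sp)
    expect_true(all(diff(codes) >= 0))          # monotone
    expect_true(all(codes %in% sp$levels))      # exhaustive over levels
  }
  expect_error(bin_vital(70, sch$gender), class = "configuration_error")
})

test_that("cohort CSV round trip is lossless including missingness", {
  cohort <- mixed_demo_cohort(n = 25, missing = 0.08)
  path <- withr::local_tempfile(fileext = ".csv")
  save_cohort(cohort, path)
  back <- load_cohort(path, tbi_schema(), provenance = cohort$provenance)
  expect_identical(back$patients, cohort$patients)
  expect_equal(back$values, cohort$values)
  expect_identical(missing_mask(back), missing_mask(cohort))
})

test_that("illegal codes and unknown columns are rejected with context", {
  sch <- binary_schema(2)
  vals <- matrix(c(0, 1, 5, 1, 0, 1), ncol = 2,
                 dimnames = list(NULL, c("b1", "b2")))
  err <- expect_error(cohort_table(vals, sch), class = "validation_error")
  expect_match(conditionMessage(err), "b1")
  expect_match(conditionMessage(err), "P3")   # offending patient named
  df <- data.frame(patient_id = "x1", b1 = 0, b2 = 1, mystery = 9)
  path <- withr::local_tempfile(fileext = ".csv")
  write.csv(df, path, row.names = FALSE)
  expect_error(load_cohort(path, sch), class = "schema_error")
})

test_that("inclusion keeps closed head injuries with arrival GCS 13-15", {
  cohort <- binary_cohort(matrix(c(0, 1, 0, 1, 1, 0, 1, 0), ncol = 2))
  gcs <- c(14, 12, 15, 13)
  injury <- c("closed", "closed", "penetrating", "closed")
  kept <- apply_inclusion(cohort, gcs, injury)
  expect_identical(kept$patients, c("P1", "P4"))   # order preserved
  expect_error(apply_inclusion(cohort, c(14, 2, 15, 13), injury),
               class = "validation_error")
})

test_that("summary counts conserve patients and ignore order", {
  cohort <- mixed_demo_cohort(n = 40, missing = 0.1)
  s <- summarize_cohort(cohort)
  for (v in unique(s$variable)) {
    sv <- s[s$variable == v, ]
    expect_equal(sum(sv$count) + sv$n_missing[1], 40)
  }
  shuffled <- subset_cohort(cohort, sample(cohort$patients))
  # counts are per-variable aggregates: patient order cannot matter
  s2 <- summarize_cohort(shuffled)
  expect_equal(s2$count, s$count)
})

test_that("compact summaries give slash strings and level fractions", {
  vals <- matrix(c(rep(0, 469), rep(1, 9)), ncol = 1)
  cohort <- binary_cohort(vals)
  s <- summarize_cohort(cohort)
  expect_identical(format_summary(s)$counts, "469/9")
  expect_equal(level_fraction(s, "b1", 0), 469 / 478)
  # all-missing variable yields all-zero counts
  vals2 <- cbind(vals, NA)
  cohort2 <- binary_cohort(vals2)
  s2 <- summarize_cohort(cohort2)
  expect_equal(s2$count[s2$variable == "b2"], c(0, 0))
})

test_that("missingness filter keeps shared low-missingness variables plus exceptions", {
  sch <- binary_schema(4)
  n <- 100
  va <- matrix(rbinom(4 * n, 1, 0.5), ncol = 4,
               dimnames = list(NULL, names(sch)))
  vb <- va
  va[1:12, 1] <- NA           # 12% missing in A
  vb[1:15, 2] <- NA           # 15% missing in B
  a <- cohort_table(va, sch)
  b <- cohort_table(vb, sch)
  keep <- missingness_filter(a, b, threshold = 0.1, exceptions = "b1")
  expect_setequal(names(keep), c("b1", "b3", "b4"))   # b1 excepted, b2 dropped
  # variable present only in A is never retained
  b_small <- cohort_table(vb[, 1:3], sch[1:3])
  keep2 <- missingness_filter(a, b_small, threshold = 0.1,
                              exceptions = character(0))
  expect_false("b4" %in% names(keep2))
  expect_error(missingness_filter(a, b, exceptions = "nope"),
               class = "schema_error")
})
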