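test_that("GOSE binarization splits 1-7 bad from 8 good", {
  expect_equal(binarize_gose(c(1, 7, 8)), c(1L, 1L, 0L))
  expect_true(is.na(binarize_gose(NA)))
  expect_error(binarize_gose(0), class = "validation_error")
  expect_error(binarize_gose(9), class = "validation_error")
})

test_that("BSI binarization uses strict 63 thresholds and the two-subscale rule", {
  subs <- function(...) matrix(c(...), nrow = 1)
  expect_equal(binarize_bsi(64, subs(50, 50, 50)), 1L)
  expect_equal(binarize_bsi(63, subs(70, 50, 50)), 0L)
  expect_equal(binarize_bsi(50, subs(64, 64, 50)), 1L)
  expect_equal(binarize_bsi(63.0, subs(63, 63, 63)), 0L)  # all at the line
  # missing GSI: bad only if the subscale rule already fires
  expect_equal(binarize_bsi(NA, subs(70, 70, 40)), 1L)
  expect_true(is.na(binarize_bsi(NA, subs(70, 40, 40))))
  expect_true(is.na(binarize_bsi(NA_real_, NULL)))
})

test_that("WAIS binarization is inclusive at one SD below the norm mean", {
  expect_equal(binarize_wais(c(85, 86, 70)), c(1L, 0L, 1L))
  expect_equal(binarize_wais(40, norm_mean = 50, norm_sd = 10), 1L)
  expect_equal(binarize_wais(41, norm_mean = 50, norm_sd = 10), 0L)
  expect_error(binarize_wais(90, norm_sd = 0), class = "configuration_error")
})

test_that("TMT binarization is bad when either part is at or above one SD", {
  expect_equal(binarize_tmt(1.0, -0.5), 1L)
  expect_equal(binarize_tmt(0.9, 0.9), 0L)
  expect_equal(binarize_tmt(-2, 2), 1L)
  expect_equal(binarize_tmt(NA, 2), 1L)        # bad is established
  expect_true(is.na(binarize_tmt(NA, 0)))      # good needs both parts
  expect_true(is.na(binarize_tmt(NA, NA)))
})

test_that("outcome tables binarize column-wise with missingness passed through", {
  raw <- data.frame(patient_id = c("p1", "p2", "p3"),
                    gose_90 = c(8, 5, NA), gose_180 = c(8, 8, 7),
                    bsi_gsi_t = c(50, 70, 60),
                    bsi_sub1_t = c(50, 50, 64), bsi_sub2_t = c(50, 50, 64),
                    wais_std = c(100, 84, NA),
                    tmt_a_z = c(0, 2, 0.5), tmt_b_z = c(0, 0, NA))
  bin <- binarize_outcomes(raw)
  expect_equal(bin$gose_90, c(0L, 1L, NA))
  expect_equal(bin$gose_180, c(0L, 0L, 1L))
  expect_equal(bin$bsi, c(0L, 1L, 1L))
  expect_equal(bin$wais, c(0L, 1L, NA))
  expect_equal(bin$tmt, c(0L, 1L, NA))
  # round trip through CSV keeps missing cells missing
  path <- withr::local_tempfile(fileext = ".csv")
  save_outcomes(raw, path)
  expect_equal(load_outcomes(path), raw)
})

test_that("two-group ANOVA on a 0/1 outcome equals the pooled t-test squared", {
  y <- c(rep(1, 12), rep(0, 18), rep(1, 5), rep(0, 25))
  g <- rep(c("A", "B"), each = 30)
  got <- anova_between_classes(y, g)
  tt <- stats::t.test(y[g == "A"], y[g == "B"], var.equal = TRUE)
  expect_equal(got$F, unname(tt$statistic)^2)
  expect_equal(got$p, tt$p.value)
  # constant outcomes: no between-class variance, p = 1 with a note
  flat <- anova_between_classes(rep(1, 40), rep(c("A", "B"), 20))
  expect_equal(flat$p, 1)
  expect_match(flat$note, "constant")
  expect_error(anova_between_classes(c(1, 0), c("A", "B")),
               class = "validation_error")
})

test_that("a strong class-outcome effect is detected", {
  pair <- generate_pair(preset_config("two_class", seed = 31))
  bin <- binarize_outcomes(pair$outcomes_a)
  lab <- LETTERS[pair$truth$labels_a]
  got <- anova_between_classes(bin$gose_90, lab)
  expect_lt(got$p, 0.001)
})

test_that("pairwise chi-square tests match the textbook statistic", {
  y <- c(rep(c(1, 0), c(10, 10)), rep(c(1, 0), c(10, 10)))
  g <- rep(c("A", "B"), each = 20)
  even <- pairwise_chisq(y, g)
  expect_equal(even$p, 1)
  # 90/10 vs 50/50 against the hand formula sum (O-E)^2 / E
  y2 <- c(rep(c(1, 0), c(10, 90)), rep(c(1, 0), c(50, 50)))
  g2 <- rep(c("A", "B"), c(100, 100))
  got <- pairwise_chisq(y2, g2)
  O <- rbind(c(90, 10), c(50, 50))
  E <- outer(rowSums(O), colSums(O)) / sum(O)
  expect_equal(got$statistic, sum((O - E)^2 / E))
  expect_equal(got$p, stats::pchisq(sum((O - E)^2 / E), 1, lower.tail = FALSE))
  # all-good everywhere: zero margin, skipped with a note
  skip_case <- pairwise_chisq(rep(0, 40), rep(c("A", "B"), 20))
  expect_true(is.na(skip_case$p))
  expect_match(skip_case$note, "skipped")
  # Holm correction never lowers a raw p-value
  y3 <- c(rbinom(30, 1, 0.2), rbinom(30, 1, 0.5), rbinom(30, 1, 0.8))
  g3 <- rep(c("A", "B", "C"), each = 30)
  raw <- pairwise_chisq(y3, g3)
  holm <- pairwise_chisq(y3, g3, p_adjust = "holm")
  expect_true(all(holm$p >= raw$p - 1e-12))
})

test_that("PPV/NPV tally prognosis within classes and reconcile their counts", {
  # class A: 10 bad90 of whom 9 stay bad, 10 good90 of whom 8 stay good
  g90 <- c(rep(1, 10), rep(0, 10), rep(1, 4), rep(0, 6))
  g180 <- c(rep(1, 9), 0, rep(0, 8), 1, 1, rep(1, 4), rep(0, 6))
  lab <- rep(c("A", "B"), c(20, 10))
  got <- ppv_npv(g90, g180, lab)
  a <- got[got$class == "A", ]
  expect_equal(a$ppv, 0.9)
  expect_equal(a$npv, 0.8)
  b <- got[got$class == "B", ]
  expect_equal(b$ppv, 1)
  expect_equal(b$npv, 1)
  # denominators partition each complete-case class
  expect_equal(got$ppv_den + got$npv_den, got$n)
  # empty conditioning set: NA with zero denominator
  none_bad <- ppv_npv(rep(0, 8), rbinom(8, 1, 0.5), rep("A", 8))
  expect_true(is.na(none_bad$ppv))
  expect_equal(none_bad$ppv_den, 0)
})

test_that("per-class outcome rates recover the generative model", {
  cfg <- preset_config("two_class", seed = 37)
  pair <- generate_pair(cfg)
  bin <- rbind(binarize_outcomes(pair$outcomes_a),
               binarize_outcomes(pair$outcomes_b))
  lab <- c(pair$truth$labels_a, pair$truth$labels_b)
  for (k in 1:2) {
    p_gen <- cfg$outcome_model[k, "tmt"]
    p_emp <- mean(bin$tmt[lab == k])
    se <- sqrt(p_gen * (1 - p_gen) / sum(lab == k))
    expect_lt(abs(p_emp - p_gen), 3 * se)
  }
})
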