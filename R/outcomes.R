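#' Binarize a Glasgow Outcome Scale Extended score
#'
#' GOSE 1-7 is a bad outcome (incomplete recovery), 8 good (full recovery).
#'
#' @param score Integer GOSE score(s) in 1-8 (`NA` allowed).
#' @return Integer vector: 1 = bad, 0 = good, `NA` = missing.
#' @export
binarize_gose <- function(score) {
  ok <- is.na(score) | (score >= 1 & score <= 8)
  assert_that(all(ok), "GOSE scores must be in 1-8",
              class = "validation_error")
  ifelse(is.na(score), NA_integer_, as.integer(score <= 7))
}

#' Binarize a Brief Symptom Inventory assessment
#'
#' Bad if the Global Severity Index T-score exceeds 63 or at least two
#' subscale T-scores exceed 63 (both inequalities strict).  When the GSI is
#' missing the result is bad if the subscale rule already fires, otherwise
#' missing; with no subscales the GSI rule alone decides.
#'
#' @param gsi_t GSI T-score(s).
#' @param subscale_ts Matrix of subscale T-scores (patients x subscales),
#'   or a vector for a single patient; `NULL` for none.
#' @return Integer vector: 1 = bad, 0 = good, `NA` = missing.
#' @export
binarize_bsi <- function(gsi_t, subscale_ts = NULL) {
  n <- length(gsi_t)
  if (is.null(subscale_ts)) {
    n_high <- rep(0L, n)
    any_sub <- rep(FALSE, n)
  } else {
    if (is.null(dim(subscale_ts)))
      subscale_ts <- matrix(subscale_ts, nrow = n)
    assert_that(nrow(subscale_ts) == n,
                "subscale_ts rows must match gsi_t length",
                class = "validation_error")
    n_high <- rowSums(subscale_ts > 63, na.rm = TRUE)
    any_sub <- rowSums(!is.na(subscale_ts)) > 0
  }
  bad <- (!is.na(gsi_t) & gsi_t > 63) | n_high >= 2
  out <- ifelse(bad, 1L, 0L)
  out[!bad & is.na(gsi_t)] <- NA_integer_   # cannot rule bad out without GSI
  out[is.na(gsi_t) & !any_sub] <- NA_integer_
  out
}

#' Binarize a WAIS standardized score
#'
#' Bad if the score is at least one standard deviation below the norm mean
#' (boundary inclusive).  The default norm is the standard index-score
#' scale, mean 100 / SD 15.
#'
#' @param score Standardized score(s).
#' @param norm_mean,norm_sd Norm parameters (`norm_sd > 0`).
#' @return Integer vector: 1 = bad, 0 = good, `NA` = missing.
#' @export
binarize_wais <- function(score, norm_mean = 100, norm_sd = 15) {
  assert_that(norm_sd > 0, "norm_sd must be positive",
              class = "configuration_error")
  ifelse(is.na(score), NA_integer_,
         as.integer(score <= norm_mean - norm_sd))
}

#' Binarize a Trail Making Test assessment
#'
#' Bad if either part's age-adjusted normalized time is at least one
#' standard deviation above the mean (z >= 1, boundary inclusive).  Good
#' requires both parts observed below 1; one sub-threshold part with the
#' other missing stays missing.
#'
#' @param z_a,z_b Age-adjusted normalized times for parts A and B, z-scale.
#' @return Integer vector: 1 = bad, 0 = good, `NA` = missing.
#' @export
binarize_tmt <- function(z_a, z_b) {
  bad <- (!is.na(z_a) & z_a >= 1) | (!is.na(z_b) & z_b >= 1)
  good <- !is.na(z_a) & !is.na(z_b) & z_a < 1 & z_b < 1
  out <- rep(NA_integer_, length(z_a))
  out[bad] <- 1L
  out[good] <- 0L
  out
}

#' Binarize a raw outcome table
#'
#' Applies the per-instrument good/bad rules to a raw outcome table in the
#' standard layout (`patient_id`, `gose_90`, `gose_180`, `bsi_gsi_t`,
#' `bsi_sub1_t..bsi_sub9_t`, `wais_std`, `tmt_a_z`, `tmt_b_z`; empty =
#' missing).
#'
#' @param outcomes Raw outcome data frame.
#' @param wais_norm_mean,wais_norm_sd WAIS norm parameters.
#' @return Data frame: `patient_id` plus columns `gose_90`, `gose_180`,
#'   `bsi`, `wais`, `tmt` coded 1 = bad, 0 = good, `NA` = missing.
#' @export
binarize_outcomes <- function(outcomes, wais_norm_mean = 100,
                              wais_norm_sd = 15) {
  assert_that("patient_id" %in% names(outcomes),
              "outcome table lacks patient_id", class = "schema_error")
  sub_cols <- grep("^bsi_sub[0-9]+_t$", names(outcomes), value = TRUE)
  subs <- if (length(sub_cols))
    as.matrix(outcomes[sub_cols]) else NULL
  data.frame(
    patient_id = outcomes$patient_id,
    gose_90 = binarize_gose(outcomes$gose_90),
    gose_180 = binarize_gose(outcomes$gose_180),
    bsi = binarize_bsi(outcomes$bsi_gsi_t, subs),
    wais = binarize_wais(outcomes$wais_std, wais_norm_mean, wais_norm_sd),
    tmt = binarize_tmt(outcomes$tmt_a_z, outcomes$tmt_b_z),
    stringsAsFactors = FALSE)
}

#' Read / write raw outcome CSVs
#'
#' Empty cells denote missing values.
#'
#' @param path CSV path.
#' @return `load_outcomes`: the raw outcome data frame.
#' @export
load_outcomes <- function(path) {
  utils::read.csv(path, check.names = FALSE, na.strings = "")
}

#' @rdname load_outcomes
#' @param outcomes Raw outcome data frame.
#' @export
save_outcomes <- function(outcomes, path) {
  utils::write.csv(outcomes, path, row.names = FALSE, na = "")
  invisible(path)
}

#' One-way ANOVA of a binarized outcome across sub-classes
#'
#' Linear-probability one-way ANOVA of the 0/1 outcome on sub-class,
#' complete cases only.  A constant outcome has no between-class variance
#' and is reported as `F = 0`, `p = 1` with a note.
#'
#' @param outcome Binarized 0/1 outcome per patient (`NA` = missing).
#' @param labels Sub-class label per patient.
#' @return List: `F`, `p`, `df_between`, `df_within`, `n`, `note`.
#' @export
anova_between_classes <- function(outcome, labels) {
  keep <- !is.na(outcome) & !is.na(labels)
  y <- outcome[keep]
  g <- factor(as.character(labels[keep]))
  tab <- table(g)
  assert_that(sum(tab >= 2) >= 2,
              "need at least two classes with two or more observed outcomes",
              class = "validation_error")
  if (stats::var(y) == 0) {
    return(list(F = 0, p = 1, df_between = nlevels(g) - 1L,
                df_within = length(y) - nlevels(g), n = length(y),
                note = "constant outcome: no between-class variance"))
  }
  av <- stats::anova(stats::lm(y ~ g))
  list(F = av$`F value`[1], p = av$`Pr(>F)`[1],
       df_between = av$Df[1], df_within = av$Df[2], n = length(y),
       note = "")
}

#' Pairwise chi-square comparison of a binarized outcome
#'
#' For each pair of sub-classes, a 2 x 2 chi-square test (no Yates
#' correction by default) of the good/bad split.  Raw p-values by default;
#' set `p_adjust = "holm"` for a family-wise correction.  Pairs whose table
#' has an expected zero are skipped with a note.
#'
#' @param outcome Binarized 0/1 outcome (`NA` = missing).
#' @param labels Sub-class label per patient.
#' @param pairs Two-column character matrix of class pairs (default: all
#'   pairs of observed classes).
#' @param correct Yates continuity correction (default `FALSE`).
#' @param p_adjust Multiplicity correction passed to [stats::p.adjust()]
#'   (default `"none"`).
#' @return Data frame: `class_1`, `class_2`, `bad_1`, `n_1`, `bad_2`,
#'   `n_2`, `statistic`, `p`, `note`.
#' @export
pairwise_chisq <- function(outcome, labels, pairs = NULL, correct = FALSE,
                           p_adjust = "none") {
  keep <- !is.na(outcome) & !is.na(labels)
  y <- outcome[keep]
  g <- as.character(labels[keep])
  classes <- sort(unique(g))
  if (is.null(pairs)) {
    assert_that(length(classes) >= 2, "need at least two classes")
    pairs <- t(utils::combn(classes, 2))
  }
  rows <- lapply(seq_len(nrow(pairs)), function(i) {
    k1 <- pairs[i, 1]; k2 <- pairs[i, 2]
    y1 <- y[g == k1]; y2 <- y[g == k2]
    tab <- rbind(c(sum(y1 == 0), sum(y1 == 1)),
                 c(sum(y2 == 0), sum(y2 == 1)))
    base <- data.frame(class_1 = k1, class_2 = k2,
                       bad_1 = sum(y1), n_1 = length(y1),
                       bad_2 = sum(y2), n_2 = length(y2))
    if (any(rowSums(tab) == 0) || any(colSums(tab) == 0)) {
      return(cbind(base, statistic = NA_real_, p = NA_real_,
                   note = "expected count zero: test skipped"))
    }
    ct <- suppressWarnings(stats::chisq.test(tab, correct = correct))
    cbind(base, statistic = unname(ct$statistic), p = ct$p.value, note = "")
  })
  out <- do.call(rbind, rows)
  out$p <- stats::p.adjust(out$p, method = p_adjust)
  rownames(out) <- NULL
  out
}

#' Sub-class-conditional prognosis of 180-day from 90-day outcome
#'
#' Within each sub-class (complete cases on both time points): PPV, the
#' proportion of patients with a bad 90-day global outcome who remain bad
#' at 180 days; NPV, the proportion with a good 90-day outcome who remain
#' good at 180 days.  An empty conditioning set yields `NA` with a zero
#' denominator.
#'
#' @param gose90_bin,gose180_bin Binarized GOSE (1 = bad, 0 = good, `NA`).
#' @param labels Sub-class label per patient.
#' @return A `prognosis_result` data frame: `class`, `ppv`, `ppv_num`,
#'   `ppv_den`, `npv`, `npv_num`, `npv_den`, `n`.
#' @export
ppv_npv <- function(gose90_bin, gose180_bin, labels) {
  keep <- !is.na(gose90_bin) & !is.na(gose180_bin) & !is.na(labels)
  g90 <- gose90_bin[keep]
  g180 <- gose180_bin[keep]
  lab <- as.character(labels[keep])
  classes <- sort(unique(lab))
  rows <- lapply(classes, function(k) {
    i <- lab == k
    ppv_den <- sum(g90[i] == 1)
    npv_den <- sum(g90[i] == 0)
    ppv_num <- sum(g90[i] == 1 & g180[i] == 1)
    npv_num <- sum(g90[i] == 0 & g180[i] == 0)
    data.frame(class = k,
               ppv = if (ppv_den > 0) ppv_num / ppv_den else NA_real_,
               ppv_num = ppv_num, ppv_den = ppv_den,
               npv = if (npv_den > 0) npv_num / npv_den else NA_real_,
               npv_num = npv_num, npv_den = npv_den, n = sum(i))
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  class(out) <- c("prognosis_result", class(out))
  out
}
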