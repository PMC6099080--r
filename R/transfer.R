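#' Per-sub-class centroids over a declared variable set
#'
#' The transferable artifact of a sub-classification: for each sub-class,
#' the arithmetic mean of each clinical variable over the patients in that
#' class (binary variables become proportions, ordinal variables mean
#' codes).  A new patient is later assigned to the sub-class with the
#' nearest centroid.
#'
#' @param cohort A `cohort_table` without missing values.
#' @param labels Per-patient sub-class labels (factor or character), named
#'   by patient ID or aligned with the cohort's patient order.
#' @param variable_set Variables to average over (default: all cohort
#'   variables).  Typically the features selected by [sparse_hclust()].
#' @return A `subclass_model`: `centroids` (classes x variables matrix),
#'   `variable_set`, `class_names`, `source_label`.
#' @export
compute_centroids <- function(cohort, labels, variable_set = NULL) {
  variable_set <- variable_set %||% names(cohort$schema)
  assert_that(all(variable_set %in% names(cohort$schema)),
              "variable_set contains variables absent from the cohort",
              class = "validation_error")
  if (is.factor(labels) && any(table(labels) == 0))
    stop_tbi("empty sub-class(es): ",
             paste(levels(labels)[table(labels) == 0], collapse = ", "),
             class = "validation_error")
  labels <- align_labels(labels, cohort$patients)
  vals <- cohort$values[, variable_set, drop = FALSE]
  assert_that(!anyNA(vals), "missing values present; impute first",
              class = "validation_error")
  classes <- sort(unique(as.character(labels)))
  cent <- t(vapply(classes, function(k) {
    colMeans(vals[labels == k, , drop = FALSE])
  }, numeric(length(variable_set))))
  dimnames(cent) <- list(classes, variable_set)
  structure(list(centroids = cent, variable_set = variable_set,
                 class_names = classes, source_label = cohort$provenance),
            class = "subclass_model")
}

# match labels to patients by name, or by position when unnamed
align_labels <- function(labels, patients) {
  if (!is.null(names(labels))) {
    assert_that(all(patients %in% names(labels)),
                "labels missing for some patients",
                class = "validation_error")
    labels <- labels[patients]
  } else {
    assert_that(length(labels) == length(patients),
                "labels must match cohort size", class = "validation_error")
  }
  assert_that(!anyNA(labels), "labels must partition the patients: NA found",
              class = "validation_error")
  as.character(labels)
}

#' @export
print.subclass_model <- function(x, ...) {
  cat(sprintf("<subclass_model> %d sub-classes x %d variables [from %s]\n",
              nrow(x$centroids), ncol(x$centroids), x$source_label))
  invisible(x)
}

#' Assign new patients to the nearest sub-class centroid
#'
#' Each cohort-B patient is classified to the sub-class whose centroid is
#' nearest in Euclidean distance over the model's variable set, ties going
#' to the alphabetically first class.  Sub-classes that receive no patients
#' are flagged: such a class is by definition not reproducible in B.
#'
#' @param model A [compute_centroids()] model.
#' @param cohort_b Target `cohort_table` without missing values; must
#'   contain the model's variable set.
#' @param distance Only `"euclidean"` is offered.
#' @return Named factor of assignments with levels `model$class_names`;
#'   attribute `"unassigned_classes"` lists classes that received nobody.
#' @export
classify_by_centroid <- function(model, cohort_b, distance = "euclidean") {
  distance <- match.arg(distance, "euclidean")
  missing_vars <- setdiff(model$variable_set, names(cohort_b$schema))
  assert_that(length(missing_vars) == 0,
              "cohort lacks model variable(s): ",
              paste(missing_vars, collapse = ", "),
              class = "validation_error")
  vals <- cohort_b$values[, model$variable_set, drop = FALSE]
  assert_that(!anyNA(vals), "missing values present; impute first",
              class = "validation_error")
  cent <- model$centroids[order(rownames(model$centroids)), , drop = FALSE]
  # squared distances patients x classes via the expansion trick
  cross <- vals %*% t(cent)
  d2 <- outer(rowSums(vals^2), rep(1, nrow(cent))) - 2 * cross +
    outer(rep(1, nrow(vals)), rowSums(cent^2))
  pick <- apply(d2, 1, which.min)          # first index wins ties ->
  assigned <- rownames(cent)[pick]          # alphabetically first class
  out <- factor(assigned, levels = model$class_names)
  names(out) <- cohort_b$patients
  attr(out, "unassigned_classes") <-
    setdiff(model$class_names, unique(assigned))
  out
}

#' Retain the largest sub-classes covering most of the target cohort
#'
#' Operationalizes the "focus on the well-populated sub-classes" step:
#' returns the minimal set of largest classes whose joint share of the
#' target cohort reaches `min_fraction` (default 0.95).  Ties in size are
#' resolved alphabetically.
#'
#' @param assignments Factor of per-patient assignments, or a named count
#'   vector.
#' @param min_fraction Required joint coverage, in (0, 1).
#' @return List: `retained` (class names, alphabetical), `excluded`,
#'   `coverage` (achieved fraction), `counts` (named, all classes), `n`.
#' @export
retention_rule <- function(assignments, min_fraction = 0.95) {
  assert_that(min_fraction > 0 && min_fraction < 1,
              "min_fraction must be in (0, 1)",
              class = "configuration_error")
  counts <- if (is.factor(assignments) || is.character(assignments)) {
    table(assignments)
  } else {
    assert_that(!is.null(names(assignments)), "counts must be named")
    assignments
  }
  counts <- stats::setNames(as.numeric(counts), names(counts))
  n <- sum(counts)
  ord <- order(-counts, names(counts))
  cum <- cumsum(counts[ord])
  k <- which(cum / n >= min_fraction)[1]
  retained <- sort(names(counts)[ord[seq_len(k)]])
  list(retained = retained,
       excluded = sort(setdiff(names(counts), retained)),
       coverage = unname(cum[k]) / n,
       counts = counts, n = n)
}

#' In-group proportion of transferred sub-classes
#'
#' IGP of class k: the fraction of target-cohort patients assigned to k
#' whose nearest neighbor within the target cohort (self excluded, same
#' distance and variable set as the classification) is also assigned to k.
#' Values near 1 indicate that the transferred class is a coherent group in
#' the new cohort rather than an artifact of the centroid assignment.
#'
#' @param cohort_b Target `cohort_table` without missing values.
#' @param assignments Factor from [classify_by_centroid()] (named by
#'   patient or aligned).
#' @param variable_set Variables the distance runs over (default: all).
#' @param distance Only `"euclidean"`.
#' @return Named numeric IGP per non-empty class, in `[0, 1]`.
#' @export
compute_igp <- function(cohort_b, assignments, variable_set = NULL,
                        distance = "euclidean") {
  distance <- match.arg(distance, "euclidean")
  variable_set <- variable_set %||% names(cohort_b$schema)
  assert_that(length(cohort_b$patients) >= 2,
              "IGP needs at least two patients", class = "validation_error")
  lab <- align_labels(assignments, cohort_b$patients)
  vals <- cohort_b$values[, variable_set, drop = FALSE]
  assert_that(!anyNA(vals), "missing values present; impute first",
              class = "validation_error")
  dm <- as.matrix(stats::dist(vals))
  diag(dm) <- Inf
  nn <- apply(dm, 1, which.min)   # first minimum: deterministic tie rule
  nn_lab <- lab[nn]
  classes <- sort(unique(lab))
  vapply(stats::setNames(classes, classes), function(k) {
    mean(nn_lab[lab == k] == k)
  }, 0)
}

#' Pearson correlation between source and target class profiles
#'
#' For each sub-class present in both models, correlates the source
#' centroid with the empirical centroid of the target-cohort patients
#' classified into that class, over the shared variable set.  High
#' correlations mean the "average patient" looks alike in the two cohorts.
#'
#' @param model_a Source [compute_centroids()] model.
#' @param model_b_empirical Target-side model computed from the classified
#'   patients.
#' @return Data frame: `class`, `r`, `p` (two-sided), `n_variables`.
#'   Classes with a zero-variance profile get `NA` with a note.
#' @export
profile_correlation <- function(model_a, model_b_empirical) {
  shared_vars <- intersect(model_a$variable_set,
                           model_b_empirical$variable_set)
  assert_that(length(shared_vars) >= 3,
              "need at least 3 shared variables for a profile correlation",
              class = "validation_error")
  shared_classes <- intersect(model_a$class_names,
                              model_b_empirical$class_names)
  rows <- lapply(shared_classes, function(k) {
    a <- model_a$centroids[k, shared_vars]
    b <- model_b_empirical$centroids[k, shared_vars]
    if (stats::sd(a) == 0 || stats::sd(b) == 0) {
      data.frame(class = k, r = NA_real_, p = NA_real_,
                 n_variables = length(shared_vars),
                 note = "zero-variance profile")
    } else {
      ct <- stats::cor.test(a, b)
      data.frame(class = k, r = unname(ct$estimate), p = ct$p.value,
                 n_variables = length(shared_vars), note = "")
    }
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Two-sample proportion z-test
#'
#' Plain pooled-variance two-sample test of equal proportions without
#' continuity correction (optionally with), the form used for comparing
#' bad-outcome fractions between matched sub-classes of two cohorts.
#'
#' @param x1,n1 Successes and size of sample 1.
#' @param x2,n2 Successes and size of sample 2.
#' @param correct Apply the continuity correction (default `FALSE`).
#' @return List: `p1`, `p2`, `z`, `p.value` (two-sided).
#' @export
prop_z_test <- function(x1, n1, x2, n2, correct = FALSE) {
  assert_that(n1 > 0 && n2 > 0 && x1 >= 0 && x2 >= 0 && x1 <= n1 && x2 <= n2,
              "invalid counts", class = "validation_error")
  p1 <- x1 / n1
  p2 <- x2 / n2
  pooled <- (x1 + x2) / (n1 + n2)
  if (pooled == 0 || pooled == 1) {
    return(list(p1 = p1, p2 = p2, z = 0, p.value = 1))
  }
  se <- sqrt(pooled * (1 - pooled) * (1 / n1 + 1 / n2))
  num <- p1 - p2
  if (correct) {
    cc <- 0.5 * (1 / n1 + 1 / n2)
    num <- sign(num) * max(abs(num) - cc, 0)
  }
  z <- num / se
  list(p1 = p1, p2 = p2, z = z, p.value = 2 * stats::pnorm(-abs(z)))
}

#' Between-cohort outcome agreement per sub-class
#'
#' For each class and binarized outcome instrument, tests whether the
#' bad-outcome proportion differs between the source-cohort patients in
#' that class and the target-cohort patients classified into it
#' (two-sample proportion z-test, complete cases per instrument).  A lack
#' of differences is evidence that a sub-class is reproducible.
#'
#' @param outcomes_a,outcomes_b Binarized outcome data frames from
#'   [binarize_outcomes()] (0 = good, 1 = bad, NA = missing).
#' @param labels_a Source-cohort class labels named by patient ID.
#' @param assignments_b Target-cohort assignments named by patient ID.
#' @param classes Classes to test (default: classes present on both sides).
#' @param instruments Outcome columns to test (default: the five standard
#'   instruments present in the tables).
#' @param correct Continuity correction flag for [prop_z_test()].
#' @return Data frame: `class`, `instrument`, `p_a`, `p_b`, `n_a`, `n_b`,
#'   `z`, `p`, `note` (tests with an empty side are skipped with a note).
#' @export
outcome_agreement <- function(outcomes_a, outcomes_b, labels_a,
                              assignments_b, classes = NULL,
                              instruments = NULL, correct = FALSE) {
  labels_a <- stats::setNames(as.character(labels_a), names(labels_a))
  assignments_b <- stats::setNames(as.character(assignments_b),
                                   names(assignments_b))
  classes <- classes %||%
    sort(intersect(unique(labels_a), unique(assignments_b)))
  instruments <- instruments %||%
    intersect(c("gose_90", "gose_180", "bsi", "wais", "tmt"),
              intersect(names(outcomes_a), names(outcomes_b)))
  one <- function(k, ins) {
    ya <- outcomes_a[[ins]][match(names(labels_a)[labels_a == k],
                                  outcomes_a$patient_id)]
    yb <- outcomes_b[[ins]][match(names(assignments_b)[assignments_b == k],
                                  outcomes_b$patient_id)]
    ya <- ya[!is.na(ya)]
    yb <- yb[!is.na(yb)]
    if (length(ya) == 0 || length(yb) == 0) {
      return(data.frame(class = k, instrument = ins, p_a = NA, p_b = NA,
                        n_a = length(ya), n_b = length(yb), z = NA, p = NA,
                        note = "no outcome-observed patients on one side"))
    }
    t <- prop_z_test(sum(ya), length(ya), sum(yb), length(yb),
                     correct = correct)
    data.frame(class = k, instrument = ins, p_a = t$p1, p_b = t$p2,
               n_a = length(ya), n_b = length(yb), z = t$z, p = t$p.value,
               note = "")
  }
  out <- do.call(rbind, lapply(classes, function(k)
    do.call(rbind, lapply(instruments, function(ins) one(k, ins)))))
  rownames(out) <- NULL
  out
}

#' Transfer sub-classes to an independent cohort and score reproducibility
#'
#' Convenience wrapper for the full transfer stage: nearest-centroid
#' assignment of cohort B, the retention rule, per-class IGP over the
#' retained classes, and the source-vs-target profile correlations.
#'
#' @param model_a Source [compute_centroids()] model.
#' @param cohort_b Target `cohort_table` (no missing values).
#' @param min_fraction Retention coverage threshold (default 0.95).
#' @return A `transfer_result`: `assignments`, `class_counts`, `retained`,
#'   `coverage`, `igp` (retained classes), `profile` (data frame),
#'   `unassigned_classes`.
#' @export
transfer_subclasses <- function(model_a, cohort_b, min_fraction = 0.95) {
  assignments <- classify_by_centroid(model_a, cohort_b)
  ret <- retention_rule(assignments, min_fraction = min_fraction)
  igp_all <- compute_igp(cohort_b, assignments,
                         variable_set = model_a$variable_set)
  in_ret <- as.character(assignments) %in% ret$retained
  model_b <- compute_centroids(
    subset_cohort(cohort_b, in_ret),
    droplevels(assignments[in_ret]),
    variable_set = model_a$variable_set)
  prof <- profile_correlation(model_a, model_b)
  structure(list(assignments = assignments,
                 class_counts = ret$counts,
                 retained = ret$retained, coverage = ret$coverage,
                 igp = igp_all[intersect(names(igp_all), ret$retained)],
                 igp_all = igp_all,
                 profile = prof[prof$class %in% ret$retained, ],
                 unassigned_classes = attr(assignments,
                                           "unassigned_classes")),
            class = "transfer_result")
}

#' @export
print.transfer_result <- function(x, ...) {
  cat("<transfer_result>\n")
  cat("  counts:", paste(sprintf("%s=%d", names(x$class_counts),
                                 as.integer(x$class_counts)),
                         collapse = ", "), "\n")
  cat(sprintf("  retained: %s (%.1f%% coverage)\n",
              paste(x$retained, collapse = ", "), 100 * x$coverage))
  if (length(x$igp))
    cat("  IGP:", paste(sprintf("%s=%.0f%%", names(x$igp), 100 * x$igp),
                        collapse = ", "), "\n")
  invisible(x)
}
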