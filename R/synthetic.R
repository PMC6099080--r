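#' Configure the synthetic twin-cohort generator
#'
#' The generator draws two cohorts ("A" and "B") from `k` shared latent
#' sub-classes.  Informative variables have class-specific categorical
#' distributions (`class_probs`); noise variables have a single
#' class-independent marginal (`marginals`).  An optional `shift` perturbs
#' the class-conditional distributions of selected classes in cohort B only,
#' creating deliberately non-reproducible classes.  Outcomes are drawn per
#' patient from class-specific bad-outcome probabilities (`outcome_model`)
#' and rendered as raw instrument scores that binarize back to the intended
#' good/bad status.
#'
#' @param n_a,n_b Cohort sizes.
#' @param k Number of latent sub-classes.
#' @param mixing Length-`k` class proportions (sum to 1).
#' @param schema Named list of [variable_spec()]s the cohorts conform to.
#' @param class_probs Named list (one entry per informative variable) of
#'   `k x L` probability matrices, rows = classes, columns = the variable's
#'   support (levels, or integer range for numeric variables).
#' @param marginals Named list (one entry per noise variable) of length-`L`
#'   probability vectors over the variable's support.
#' @param shift `NULL`, or `list(classes = <int vector>, delta = <0..1>)`:
#'   in cohort B the named classes' probability rows become
#'   `(1 - delta) * p + delta * rev(p)`; `delta = 1` fully reverses the
#'   profile.
#' @param missing_rate MCAR cell-missingness proportion applied to both
#'   cohorts (default 0.05, below the 10% retention rule).
#' @param outcome_model `k x 5` matrix of bad-outcome probabilities, columns
#'   `gose_90`, `gose_180`, `bsi`, `wais`, `tmt`.
#' @param seed Integer seed; all generator randomness flows from it.
#' @return A `generator_config` object.
#' @export
generator_config <- function(n_a, n_b, k, mixing = rep(1 / k, k), schema,
                             class_probs, marginals = list(), shift = NULL,
                             missing_rate = 0.05, outcome_model, seed = 1L) {
  assert_that(abs(sum(mixing) - 1) < 1e-8 && length(mixing) == k,
              "mixing must be length-k and sum to 1",
              class = "configuration_error")
  assert_that(missing_rate >= 0 && missing_rate < 1,
              "missing_rate must be in [0, 1)", class = "configuration_error")
  covered <- union(names(class_probs), names(marginals))
  assert_that(setequal(covered, names(schema)) &&
                !any(names(class_probs) %in% names(marginals)),
              "class_probs and marginals must partition the schema variables",
              class = "configuration_error")
  for (v in names(class_probs)) {
    P <- class_probs[[v]]
    assert_that(is.matrix(P) && nrow(P) == k &&
                  ncol(P) == length(variable_support(schema[[v]])),
                "class_probs for '", v, "' must be k x L",
                class = "configuration_error")
    assert_that(all(P >= 0) && all(abs(rowSums(P) - 1) < 1e-8),
                "class_probs rows for '", v, "' must be probabilities",
                class = "configuration_error")
  }
  for (v in names(marginals)) {
    p <- marginals[[v]]
    assert_that(all(p >= 0) && abs(sum(p) - 1) < 1e-8 &&
                  length(p) == length(variable_support(schema[[v]])),
                "marginal for '", v, "' must be a probability vector over ",
                "its support", class = "configuration_error")
  }
  if (!is.null(shift)) {
    assert_that(all(shift$classes %in% seq_len(k)) &&
                  shift$delta >= 0 && shift$delta <= 1,
                "shift must name classes in 1..k with delta in [0, 1]",
                class = "configuration_error")
  }
  instruments <- c("gose_90", "gose_180", "bsi", "wais", "tmt")
  outcome_model <- as.matrix(outcome_model)
  assert_that(nrow(outcome_model) == k && ncol(outcome_model) == 5 &&
                all(outcome_model >= 0 & outcome_model <= 1),
              "outcome_model must be k x 5 with probabilities",
              class = "configuration_error")
  colnames(outcome_model) <- instruments
  structure(list(n_a = n_a, n_b = n_b, k = k, mixing = mixing,
                 schema = schema, class_probs = class_probs,
                 marginals = marginals, shift = shift,
                 missing_rate = missing_rate, outcome_model = outcome_model,
                 seed = as.integer(seed)),
            class = "generator_config")
}

# integer support a variable's draws live on
variable_support <- function(spec) {
  if (spec$vtype == "numeric") seq(spec$range[1], spec$range[2]) else
    spec$levels
}

#' Built-in generator presets
#'
#' `"two_class"`: 2 classes, 200 patients per cohort, 5 informative binary
#' variables (within-class yes-probability 0.9 vs 0.1) and 20 pure-noise
#' binary variables (p = 0.5) -- the standard benchmark for feature-selection
#' and cluster-recovery checks.  `"paper_like"`: 7 classes at the scale of
#' the motivating cohorts (478 and 564 patients) over the full 37-variable
#' clinical schema, with 11 informative variables and 26 noise variables and
#' 5% missingness.
#'
#' @param name `"two_class"` or `"paper_like"`.
#' @param seed Integer seed stored in the config.
#' @param shift Optional shift specification passed through (see
#'   [generator_config()]).
#' @param missing_rate Overrides the preset's missingness proportion.
#' @return A `generator_config`.
#' @export
preset_config <- function(name = c("two_class", "paper_like"), seed = 1L,
                          shift = NULL, missing_rate = NULL) {
  name <- match.arg(name)
  if (name == "two_class") {
    vars <- c(paste0("inf", 1:5), paste0("noise", 1:20))
    schema <- lapply(vars, function(v)
      variable_spec(v, "demographics", "binary", labels = c("no", "yes")))
    names(schema) <- vars
    # class-1/class-2 yes-probabilities alternate 0.9/0.1 across the five
    # informative variables, giving each class a distinctive non-flat profile
    cp <- lapply(1:5, function(j) {
      p1 <- if (j %% 2 == 1) 0.9 else 0.1
      rbind(c(1 - p1, p1), c(p1, 1 - p1))
    })
    names(cp) <- paste0("inf", 1:5)
    mg <- lapply(1:20, function(j) c(0.5, 0.5))
    names(mg) <- paste0("noise", 1:20)
    om <- rbind(rep(0.2, 5), rep(0.6, 5))
    generator_config(n_a = 200, n_b = 200, k = 2, schema = schema,
                     class_probs = cp, marginals = mg, shift = shift,
                     missing_rate = missing_rate %||% 0,
                     outcome_model = om, seed = seed)
  } else {
    paper_like_config(seed = seed, shift = shift,
                      missing_rate = missing_rate %||% 0.05)
  }
}

# 7-class preset over the packaged 37-variable schema: 11 informative
# variables (the demographics / history / mechanism / ED variables most often
# implicated in mild-TBI subtyping) with distinct class profiles, remaining
# 26 variables drawn from cohort-scale marginal frequencies.
paper_like_config <- function(seed = 1L, shift = NULL, missing_rate = 0.05) {
  schema <- tbi_schema()
  k <- 7
  hi <- 0.9; lo <- 0.1
  # 7 distinct on/off profiles over the 8 informative binary variables
  pat <- rbind(
    c(0, 0, 0, 0, 0, 0, 0, 0),
    c(1, 1, 1, 0, 0, 0, 0, 0),
    c(0, 0, 0, 1, 1, 1, 0, 0),
    c(0, 0, 0, 0, 0, 1, 1, 1),
    c(1, 1, 0, 0, 1, 0, 0, 1),
    c(0, 1, 1, 1, 0, 0, 1, 0),
    c(1, 0, 1, 0, 1, 1, 0, 1))
  bin_inf <- c("gender", "education", "employment", "marital_status",
               "alcohol_use", "prior_psychiatric_disease", "mech_fall",
               "ct_result")
  cp <- list()
  for (j in seq_along(bin_inf)) {
    p1 <- ifelse(pat[, j] == 1, hi, lo)
    cp[[bin_inf[j]]] <- cbind(1 - p1, p1)
  }
  # 3 informative ordinals, each concentrated on a class-specific level
  conc <- function(main, L = 3, w = 0.8) {
    p <- rep((1 - w) / (L - 1), L); p[main] <- w; p
  }
  ord_inf <- list(age = c(1, 2, 3, 1, 2, 3, 2),
                  pta_duration = c(1, 3, 1, 3, 2, 1, 3),
                  sbp_ed = c(2, 3, 2, 2, 3, 2, 3))
  for (v in names(ord_inf))
    cp[[v]] <- t(vapply(ord_inf[[v]], conc, numeric(3)))
  # noise marginals at cohort-scale frequencies for everything else
  mg <- list(
    ethnicity = c(0.84, 0.16),
    prior_developmental_disease = c(0.89, 0.11),
    mech_bike = c(0.83, 0.17), mech_pedestrian = c(0.93, 0.07),
    mech_motorcycle = c(0.95, 0.05), mech_motor = c(0.82, 0.18),
    mech_other_person = c(0.85, 0.15), mech_striking = c(0.97, 0.03),
    mech_other = c(0.97, 0.03),
    gcs_ed_arrival = c(0.04, 0.21, 0.75),
    gcs_assessment_condition = c(0.98, 0.02),
    gcs_ed_discharge = c(rep(0.003, 10), 0.01, 0.09, 0.87),
    hospital_type = c(0.82, 0.18),
    pupil_reactivity = c(0.983, 0.013, 0.004),
    alcohol_intoxication = c(0.84, 0.16), drug_intoxication = c(0.89, 0.11),
    dbp_ed = c(0.05, 0.79, 0.16), heart_rate_ed = c(0.02, 0.83, 0.15),
    temperature_ed = c(0.02, 0.95, 0.03),
    o2_saturation_ed = c(0.02, 0.98),
    respiratory_rate_ed = c(0.01, 0.91, 0.08),
    blood_transfusion = c(0.96, 0.04), hypotension = c(0.95, 0.05),
    hypoxia = c(0.95, 0.05), intubation = c(0.98, 0.02),
    seizure = c(0.98, 0.02))
  mg$gcs_ed_discharge <- mg$gcs_ed_discharge / sum(mg$gcs_ed_discharge)
  # class proportions and per-class bad-outcome probabilities; outcome risk
  # rises with the injury-burden profile of the class
  mixing <- c(0.22, 0.12, 0.16, 0.14, 0.17, 0.10, 0.09)
  base <- c(0.15, 0.55, 0.35, 0.30, 0.10, 0.45, 0.60)
  om <- cbind(gose_90 = base, gose_180 = pmax(base - 0.05, 0.02),
              bsi = pmin(base + 0.05, 0.95), wais = base,
              tmt = pmin(base + 0.10, 0.95))
  generator_config(n_a = 478, n_b = 564, k = k, mixing = mixing,
                   schema = schema, class_probs = cp, marginals = mg,
                   shift = shift, missing_rate = missing_rate,
                   outcome_model = om, seed = seed)
}

# draw one cohort's value matrix given per-patient classes
draw_values <- function(config, labels, shifted = FALSE) {
  n <- length(labels)
  vals <- matrix(NA_real_, n, length(config$schema),
                 dimnames = list(NULL, names(config$schema)))
  for (v in names(config$schema)) {
    support <- variable_support(config$schema[[v]])
    if (v %in% names(config$class_probs)) {
      P <- config$class_probs[[v]]
      if (shifted && !is.null(config$shift)) {
        d <- config$shift$delta
        for (kk in config$shift$classes)
          P[kk, ] <- (1 - d) * P[kk, ] + d * rev(P[kk, ])
      }
      for (kk in seq_len(config$k)) {
        idx <- which(labels == kk)
        if (length(idx))
          vals[idx, v] <- sample(support, length(idx), replace = TRUE,
                                 prob = P[kk, ])
      }
    } else {
      vals[, v] <- sample(support, n, replace = TRUE,
                          prob = config$marginals[[v]])
    }
  }
  vals
}

# render per-patient good/bad draws as raw instrument scores that binarize
# back to the intended status
draw_outcomes <- function(config, labels, ids) {
  n <- length(labels)
  bad <- matrix(NA_integer_, n, 5,
                dimnames = list(NULL, colnames(config$outcome_model)))
  for (ins in colnames(config$outcome_model))
    bad[, ins] <- stats::rbinom(n, 1, config$outcome_model[labels, ins])
  gose_raw <- function(b) ifelse(b == 1, sample(3:7, n, replace = TRUE), 8L)
  out <- data.frame(patient_id = ids,
                    gose_90 = gose_raw(bad[, "gose_90"]),
                    gose_180 = gose_raw(bad[, "gose_180"]),
                    bsi_gsi_t = ifelse(bad[, "bsi"] == 1,
                                       stats::runif(n, 64, 80),
                                       stats::runif(n, 40, 60)))
  for (j in 1:9)
    out[[paste0("bsi_sub", j, "_t")]] <- stats::runif(n, 40, 55)
  out$wais_std <- ifelse(bad[, "wais"] == 1, stats::runif(n, 60, 85),
                         stats::runif(n, 86, 115))
  out$tmt_a_z <- ifelse(bad[, "tmt"] == 1, stats::runif(n, 1, 2.5),
                        stats::runif(n, -1, 0.9))
  out$tmt_b_z <- stats::runif(n, -1, 0.9)
  out
}

#' Generate a synthetic twin-cohort pair with ground truth
#'
#' Draws cohorts A and B from the shared latent sub-class model of the
#' config, applies the cohort-B shift (if any), draws class-conditional
#' outcomes, and masks cells completely at random at the configured
#' missingness rate.  Fully reproducible given `config$seed`.
#'
#' @param config A [generator_config()].
#' @return List with elements `cohort_a`, `cohort_b` (cohort tables),
#'   `outcomes_a`, `outcomes_b` (raw outcome data frames, see
#'   [binarize_outcomes()]), and `truth` (`labels_a`, `labels_b`,
#'   `informative_set`, `shifted_classes`).
#' @export
generate_pair <- function(config) {
  assert_that(inherits(config, "generator_config"),
              "config must be a generator_config",
              class = "configuration_error")
  res <- with_seed(config$seed, {
    lab_a <- sample(seq_len(config$k), config$n_a, replace = TRUE,
                    prob = config$mixing)
    lab_b <- sample(seq_len(config$k), config$n_b, replace = TRUE,
                    prob = config$mixing)
    ids_a <- sprintf("A%04d", seq_len(config$n_a))
    ids_b <- sprintf("B%04d", seq_len(config$n_b))
    va <- draw_values(config, lab_a, shifted = FALSE)
    vb <- draw_values(config, lab_b, shifted = TRUE)
    oa <- draw_outcomes(config, lab_a, ids_a)
    ob <- draw_outcomes(config, lab_b, ids_b)
    list(lab_a = stats::setNames(lab_a, ids_a),
         lab_b = stats::setNames(lab_b, ids_b),
         va = va, vb = vb, oa = oa, ob = ob, ids_a = ids_a, ids_b = ids_b)
  })
  cohort_a <- cohort_table(res$va, config$schema, patients = res$ids_a,
                           provenance = "synthetic-A")
  cohort_b <- cohort_table(res$vb, config$schema, patients = res$ids_b,
                           provenance = "synthetic-B")
  if (config$missing_rate > 0) {
    cohort_a <- inject_missingness(cohort_a, config$missing_rate,
                                   seed = config$seed + 101L)
    cohort_b <- inject_missingness(cohort_b, config$missing_rate,
                                   seed = config$seed + 202L)
  }
  list(cohort_a = cohort_a, cohort_b = cohort_b,
       outcomes_a = res$oa, outcomes_b = res$ob,
       truth = list(labels_a = res$lab_a, labels_b = res$lab_b,
                    informative_set = names(config$class_probs),
                    shifted_classes = if (is.null(config$shift)) integer(0)
                                      else config$shift$classes))
}

#' Mask cohort cells completely at random
#'
#' Each cell is masked independently with probability `rate` (MCAR).  The
#' original cohort is untouched, so masked values remain available for
#' recovery scoring against an imputation.
#'
#' @param cohort A `cohort_table`.
#' @param rate Masking probability in `[0, 1)`.
#' @param mechanism Only `"MCAR"` is implemented.
#' @param seed Integer seed.
#' @return A `cohort_table` with additional `NA` cells.
#' @export
inject_missingness <- function(cohort, rate, mechanism = "MCAR", seed = 1L) {
  mechanism <- match.arg(mechanism, "MCAR")
  assert_that(rate >= 0 && rate < 1, "rate must be in [0, 1)",
              class = "configuration_error")
  if (rate == 0) return(cohort)
  vals <- cohort$values
  mask <- with_seed(seed, matrix(stats::runif(length(vals)) < rate,
                                 nrow(vals), ncol(vals)))
  vals[mask] <- NA_real_
  cohort_table(vals, cohort$schema, patients = cohort$patients,
               provenance = cohort$provenance)
}
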