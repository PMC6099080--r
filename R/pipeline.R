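#' Run one direction of the cross-study workflow
#'
#' Executes the full pipeline with one cohort as the discovery set (A) and
#' the other as the validation set (B): variable filtering by shared
#' presence and missingness, chained-equation imputation of each cohort
#' separately, sparse hierarchical clustering of A, per-sub-class
#' centroids over the selected variables, optional pre-filtering of B,
#' nearest-centroid classification of B, the retention rule, per-class IGP
#' and profile correlations, between-cohort outcome-agreement tests,
#' pooled between-class ANOVA and pairwise chi-square tests, and pooled
#' PPV/NPV prognosis.  `direction = "B_to_A"` swaps the cohort roles.
#'
#' @param data List with `cohort_a`, `cohort_b` (cohort tables) and
#'   `outcomes_a`, `outcomes_b` (raw outcome tables), e.g. from
#'   [generate_pair()].
#' @param direction `"A_to_B"` (default) or `"B_to_A"`.
#' @param k Number of sub-classes (default 7).
#' @param s Fixed L1 bound; `NULL` tunes by permutation gap.
#' @param seed Seed driving imputation and tuning.
#' @param impute_iterations Chained-equation sweeps (default 10).
#' @param min_fraction Retention coverage threshold (default 0.95).
#' @param missing_threshold Variable missingness threshold (default 0.1).
#' @param missing_exceptions Variables kept regardless of missingness;
#'   defaults to none that are absent from the schema (pass explicitly for
#'   the clinical schema's PTA duration / pupil reactivity rule).
#' @param variable_policy `"selected"` (centroids over the SHC-selected
#'   variables, the default) or `"all"` (all filtered variables).
#' @param prefilter Optional one-sided filter for the validation cohort,
#'   given as a string evaluated against its variables (e.g.
#'   `"ct_result == 1"`); patients failing it are excluded before
#'   classification.
#' @param B_permutations Permutations for sparsity tuning.
#' @param out_dir If non-`NULL`, artifacts are written there: `model.json`,
#'   `dendrogram.nwk`, `transfer.json`, report CSVs and `run_log.txt`.
#' @return An artifact bundle (list): `model` (`shc_model`), `centroids`,
#'   `transfer` (`transfer_result`), `agreement`, `anova`, `pairwise`,
#'   `prognosis`, `variable_set`, `log` (character).
#' @export
run_direction <- function(data, direction = c("A_to_B", "B_to_A"), k = 7L,
                          s = NULL, seed = 1L, impute_iterations = 10L,
                          min_fraction = 0.95, missing_threshold = 0.1,
                          missing_exceptions = character(0),
                          variable_policy = c("selected", "all"),
                          prefilter = NULL, B_permutations = 10L,
                          out_dir = NULL) {
  direction <- match.arg(direction)
  variable_policy <- match.arg(variable_policy)
  log <- character(0)
  say <- function(...) {
    msg <- sprintf(...)
    log <<- c(log, msg)
    message(msg)
  }
  if (direction == "A_to_B") {
    src <- data$cohort_a; tgt <- data$cohort_b
    out_src <- data$outcomes_a; out_tgt <- data$outcomes_b
  } else {
    src <- data$cohort_b; tgt <- data$cohort_a
    out_src <- data$outcomes_b; out_tgt <- data$outcomes_a
  }
  say("direction %s: discovery %s (n=%d), validation %s (n=%d)",
      direction, src$provenance, nrow(src$values),
      tgt$provenance, nrow(tgt$values))

  schema_keep <- missingness_filter(src, tgt, threshold = missing_threshold,
                                    exceptions = missing_exceptions)
  dropped <- setdiff(names(src$schema), names(schema_keep))
  if (length(dropped))
    say("variables dropped by missingness filter: %s",
        paste(dropped, collapse = ", "))
  src <- restrict_schema(src, names(schema_keep))
  tgt <- restrict_schema(tgt, names(schema_keep))

  if (any(missing_mask(src)))
    src <- impute_cohort(src, imputation_config(impute_iterations,
                                                seed = seed))
  if (any(missing_mask(tgt)))
    tgt <- impute_cohort(tgt, imputation_config(impute_iterations,
                                                seed = seed + 1L))

  model <- sparse_hclust(src, K = k, s = s, B = B_permutations, seed = seed)
  say("SHC: s = %.3f, %d/%d features selected, class proportions %s",
      model$s, length(model$selected_features), length(model$weights$w),
      paste(sprintf("%s=%.0f%%", names(model$proportions),
                    100 * model$proportions), collapse = " "))

  variable_set <- if (variable_policy == "selected" &&
                        length(model$selected_features) >= 3)
    model$selected_features else names(schema_keep)
  centroids <- compute_centroids(src, model$labels,
                                 variable_set = variable_set)

  if (!is.null(prefilter)) {
    env <- as.data.frame(tgt$values)
    keep <- eval(parse(text = prefilter), envir = env)
    say("prefilter '%s': %d/%d validation patients retained", prefilter,
        sum(keep), length(keep))
    tgt <- subset_cohort(tgt, keep)
  }

  transfer <- transfer_subclasses(centroids, tgt,
                                  min_fraction = min_fraction)
  say("assignment counts: %s",
      paste(sprintf("%s=%d", names(transfer$class_counts),
                    as.integer(transfer$class_counts)), collapse = " "))
  say("retained %s (coverage %.1f%%); excluded classes held %.1f%%",
      paste(transfer$retained, collapse = ","), 100 * transfer$coverage,
      100 * (1 - transfer$coverage))
  if (length(transfer$igp))
    say("IGP: %s", paste(sprintf("%s=%.0f%%", names(transfer$igp),
                                 100 * transfer$igp), collapse = " "))

  bin_src <- binarize_outcomes(out_src)
  bin_tgt <- binarize_outcomes(out_tgt)
  agreement <- outcome_agreement(bin_src, bin_tgt, model$labels,
                                 transfer$assignments,
                                 classes = transfer$retained)

  # pooled analyses over retained classes: discovery labels + validation
  # assignments concatenated
  keep_src <- as.character(model$labels) %in% transfer$retained
  keep_tgt <- as.character(transfer$assignments) %in% transfer$retained
  pooled_labels <- c(
    stats::setNames(as.character(model$labels)[keep_src],
                    names(model$labels)[keep_src]),
    stats::setNames(as.character(transfer$assignments)[keep_tgt],
                    names(transfer$assignments)[keep_tgt]))
  pooled_bin <- rbind(bin_src, bin_tgt)
  pooled_bin <- pooled_bin[match(names(pooled_labels),
                                 pooled_bin$patient_id), ]
  instruments <- c("gose_90", "gose_180", "bsi", "wais", "tmt")
  anova_tab <- do.call(rbind, lapply(instruments, function(ins) {
    a <- anova_between_classes(pooled_bin[[ins]], pooled_labels)
    data.frame(instrument = ins, F = a$F, p = a$p, n = a$n, note = a$note)
  }))
  pairwise <- do.call(rbind, lapply(instruments, function(ins) {
    out <- pairwise_chisq(pooled_bin[[ins]], pooled_labels)
    cbind(instrument = ins, out)
  }))
  prognosis <- ppv_npv(pooled_bin$gose_90, pooled_bin$gose_180,
                       pooled_labels)
  say("prognosis: %s",
      paste(sprintf("%s PPV=%.1f%% NPV=%.1f%%", prognosis$class,
                    100 * prognosis$ppv, 100 * prognosis$npv),
            collapse = "; "))

  bundle <- list(direction = direction, model = model, centroids = centroids,
                 transfer = transfer, agreement = agreement,
                 anova = anova_tab, pairwise = pairwise,
                 prognosis = prognosis, variable_set = variable_set,
                 seed = seed, log = log)
  if (!is.null(out_dir)) write_bundle(bundle, out_dir)
  invisible(bundle)
}

# keep only the named variables in a cohort's schema (and value columns)
restrict_schema <- function(cohort, keep) {
  cohort_table(cohort$values[, keep, drop = FALSE],
               cohort$schema[keep], patients = cohort$patients,
               provenance = cohort$provenance)
}

# write the artifact bundle: model + transfer JSON, report CSVs, run log
write_bundle <- function(bundle, out_dir) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  write_shc_model(bundle$model, file.path(out_dir, "model.json"))
  export_newick(bundle$model, file.path(out_dir, "dendrogram.nwk"))
  tr <- bundle$transfer
  jsonlite::write_json(
    list(assignments = stats::setNames(as.character(tr$assignments),
                                       names(tr$assignments)),
         class_counts = as.list(tr$class_counts),
         retained = tr$retained, coverage = tr$coverage,
         igp = as.list(tr$igp),
         unassigned_classes = tr$unassigned_classes,
         variable_set = bundle$variable_set),
    file.path(out_dir, "transfer.json"), auto_unbox = TRUE, digits = NA,
    pretty = TRUE)
  utils::write.csv(bundle$transfer$profile,
                   file.path(out_dir, "profile_correlations.csv"),
                   row.names = FALSE)
  utils::write.csv(bundle$agreement,
                   file.path(out_dir, "outcome_agreement.csv"),
                   row.names = FALSE)
  utils::write.csv(bundle$anova, file.path(out_dir, "anova.csv"),
                   row.names = FALSE)
  utils::write.csv(bundle$pairwise, file.path(out_dir, "pairwise_tests.csv"),
                   row.names = FALSE)
  utils::write.csv(bundle$prognosis, file.path(out_dir, "prognosis.csv"),
                   row.names = FALSE)
  cent <- data.frame(variable = colnames(bundle$centroids$centroids),
                     t(bundle$centroids$centroids), check.names = FALSE)
  utils::write.csv(cent, file.path(out_dir, "centroid_profiles.csv"),
                   row.names = FALSE)
  writeLines(c(sprintf("tbisubclass %s",
                       as.character(utils::packageVersion("tbisubclass"))),
               sprintf("seed: %d", bundle$seed), bundle$log),
             file.path(out_dir, "run_log.txt"))
  invisible(out_dir)
}

#' Run the cross-study workflow in both directions
#'
#' Convenience wrapper calling [run_direction()] with `"A_to_B"` and
#' `"B_to_A"` on the same inputs; inputs are never mutated, so the reversed
#' direction sees the original cohorts with roles swapped.
#'
#' @param data As in [run_direction()].
#' @param out_dir If non-`NULL`, per-direction artifact subdirectories
#'   `a_to_b/` and `b_to_a/` are written.
#' @param ... Passed to [run_direction()].
#' @return List with elements `a_to_b` and `b_to_a`.
#' @export
run_crossstudy <- function(data, out_dir = NULL, ...) {
  list(
    a_to_b = run_direction(data, "A_to_B",
                           out_dir = if (is.null(out_dir)) NULL else
                             file.path(out_dir, "a_to_b"), ...),
    b_to_a = run_direction(data, "B_to_A",
                           out_dir = if (is.null(out_dir)) NULL else
                             file.path(out_dir, "b_to_a"), ...))
}
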