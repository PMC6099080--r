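#' Construct a cohort table
#'
#' A cohort table holds one row per patient and one column per clinical
#' variable, with values encoded according to the schema (binary 0/1,
#' ordinal 1..L, numeric in range).  Missing values are `NA`; the missing
#' mask is available via [missing_mask()].
#'
#' @param values Numeric matrix or data frame, patients x variables; column
#'   names must match schema names.
#' @param schema Named list of [variable_spec()] objects (see [tbi_schema()]).
#' @param patients Character patient IDs (unique).  Defaults to row names or
#'   `P1..Pn`.
#' @param provenance Free-text label carried through the pipeline (for
#'   example `"synthetic-A"`).
#' @return An object of class `cohort_table`.
#' @export
cohort_table <- function(values, schema, patients = NULL,
                         provenance = "unspecified") {
  values <- as.matrix(values)
  storage.mode(values) <- "double"
  assert_that(!is.null(colnames(values)), "values must have column names")
  missing_cols <- setdiff(names(schema), colnames(values))
  extra_cols <- setdiff(colnames(values), names(schema))
  assert_that(length(missing_cols) == 0,
              "columns absent from values: ",
              paste(missing_cols, collapse = ", "), class = "schema_error")
  assert_that(length(extra_cols) == 0,
              "columns not in schema: ", paste(extra_cols, collapse = ", "),
              class = "schema_error")
  values <- values[, names(schema), drop = FALSE]
  patients <- patients %||% rownames(values) %||%
    paste0("P", seq_len(nrow(values)))
  patients <- as.character(patients)
  assert_that(length(patients) == nrow(values),
              "patient IDs do not match row count")
  assert_that(!anyDuplicated(patients), "patient IDs must be unique")
  rownames(values) <- patients
  x <- structure(list(patients = patients, schema = schema, values = values,
                      provenance = provenance),
                 class = "cohort_table")
  validate_cohort(x)
  x
}

# check every non-missing cell against its variable_spec; error names offenders
validate_cohort <- function(x) {
  for (v in names(x$schema)) {
    spec <- x$schema[[v]]
    col <- x$values[, v]
    obs <- !is.na(col)
    if (!any(obs)) next
    bad <- if (spec$vtype == "numeric") {
      obs & (col < spec$range[1] | col > spec$range[2])
    } else {
      obs & !(col %in% spec$levels)
    }
    if (any(bad)) {
      who <- x$patients[which(bad)]
      stop_tbi("illegal code(s) for variable '", v, "': ",
               paste(sprintf("%s=%g", utils::head(who, 5),
                             col[which(bad)][seq_len(min(5, sum(bad)))]),
                     collapse = ", "),
               if (sum(bad) > 5) sprintf(" (+%d more)", sum(bad) - 5) else "",
               class = "validation_error")
    }
  }
  invisible(x)
}

#' @export
print.cohort_table <- function(x, ...) {
  cat(sprintf("<cohort_table> %d patients x %d variables [%s]\n",
              length(x$patients), length(x$schema), x$provenance))
  miss <- mean(is.na(x$values))
  cat(sprintf("  missing cells: %.1f%%\n", 100 * miss))
  invisible(x)
}

#' @export
dim.cohort_table <- function(x) dim(x$values)

#' Logical mask of missing cells
#' @param x A `cohort_table`.
#' @return Logical matrix, `TRUE` where the value is missing.
#' @export
missing_mask <- function(x) is.na(x$values)

#' Subset a cohort by patient
#' @param x A `cohort_table`.
#' @param keep Logical vector or patient IDs to retain (order preserved).
#' @return A `cohort_table` with the retained patients.
#' @export
subset_cohort <- function(x, keep) {
  if (is.logical(keep)) keep <- x$patients[keep]
  assert_that(all(keep %in% x$patients), "unknown patient IDs in subset")
  keep <- x$patients[x$patients %in% keep]  # preserve load order
  cohort_table(x$values[keep, , drop = FALSE], x$schema, patients = keep,
               provenance = x$provenance)
}

#' Read a cohort CSV
#'
#' The CSV must have a `patient_id` column plus one column per schema
#' variable; empty cells denote missing values.  Every value is validated
#' against the schema and illegal codes are reported with the offending
#' patient and variable.
#'
#' @param path CSV file path.
#' @param schema Named list of [variable_spec()]s.
#' @param provenance Label stored on the returned table (defaults to the
#'   file name).
#' @return A [cohort_table()].
#' @export
load_cohort <- function(path, schema, provenance = basename(path)) {
  df <- utils::read.csv(path, check.names = FALSE, colClasses = "character",
                        na.strings = "")
  assert_that("patient_id" %in% names(df), "CSV lacks a patient_id column",
              class = "schema_error")
  vals <- df[setdiff(names(df), "patient_id")]
  extra <- setdiff(names(vals), names(schema))
  assert_that(length(extra) == 0, "unknown column(s): ",
              paste(extra, collapse = ", "), class = "schema_error")
  m <- as.matrix(vals)
  suppressWarnings(storage.mode(m) <- "double")
  cohort_table(m, schema, patients = df$patient_id, provenance = provenance)
}

#' Write a cohort CSV
#'
#' Inverse of [load_cohort()]: missing cells are written as empty strings so
#' a save/load round trip is lossless including missingness.
#'
#' @param x A `cohort_table`.
#' @param path Output CSV path.
#' @export
save_cohort <- function(x, path) {
  df <- data.frame(patient_id = x$patients, x$values, check.names = FALSE)
  utils::write.csv(df, path, row.names = FALSE, na = "")
  invisible(path)
}

#' Apply the mild closed-head-injury inclusion criteria
#'
#' Retains patients with an arrival GCS of 13-15 and a closed (not
#' penetrating) head injury, preserving patient order.
#'
#' @param cohort A `cohort_table`.
#' @param gcs_arrival Numeric GCS at ED arrival, one per patient (3-15).
#' @param injury_type Character, `"closed"` or `"penetrating"`, one per
#'   patient.
#' @return The filtered `cohort_table`.
#' @export
apply_inclusion <- function(cohort, gcs_arrival, injury_type) {
  assert_that(length(gcs_arrival) == length(cohort$patients) &&
                length(injury_type) == length(cohort$patients),
              "per-patient vectors must match cohort size")
  assert_that(all(gcs_arrival >= 3 & gcs_arrival <= 15, na.rm = FALSE),
              "GCS must be within 3-15", class = "validation_error")
  assert_that(all(injury_type %in% c("closed", "penetrating")),
              "injury_type must be 'closed' or 'penetrating'",
              class = "validation_error")
  keep <- gcs_arrival >= 13 & gcs_arrival <= 15 & injury_type == "closed"
  subset_cohort(cohort, keep)
}

#' Per-variable level counts
#'
#' Tabulates non-missing values per variable, in long format: one row per
#' variable level with its count.  Numeric variables are tabulated over
#' their observed integer values.  Use [format_summary()] for the compact
#' "469/9"-style table.
#'
#' @param cohort A `cohort_table`.
#' @return Data frame with columns `variable`, `category`, `level`, `label`,
#'   `count`, `n_missing`.
#' @export
summarize_cohort <- function(cohort) {
  rows <- lapply(names(cohort$schema), function(v) {
    spec <- cohort$schema[[v]]
    col <- cohort$values[, v]
    n_miss <- sum(is.na(col))
    lv <- if (spec$vtype == "numeric") {
      seq(spec$range[1], spec$range[2])
    } else spec$levels
    cnt <- vapply(lv, function(l) sum(col == l, na.rm = TRUE), 0L)
    lab <- if (spec$vtype == "numeric") as.character(lv) else
      (spec$labels %||% as.character(lv))
    data.frame(variable = v, category = spec$category, level = lv,
               label = lab, count = cnt, n_missing = n_miss,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Compact per-variable summary strings
#'
#' Collapses [summarize_cohort()] output into one row per variable with a
#' slash-separated count string (for example `"469/9"` for a binary no/yes
#' variable), the standard layout for cohort summary tables.
#'
#' @param summary_long Output of [summarize_cohort()].
#' @return Data frame with `variable`, `category`, `counts`, `n_missing`
#'   plus numeric columns `count_1..count_L`.
#' @export
format_summary <- function(summary_long) {
  vars <- unique(summary_long$variable)
  max_l <- max(table(summary_long$variable))
  rows <- lapply(vars, function(v) {
    s <- summary_long[summary_long$variable == v, ]
    cnts <- c(s$count, rep(NA, max_l - nrow(s)))
    out <- data.frame(variable = v, category = s$category[1],
                      counts = paste(s$count, collapse = "/"),
                      n_missing = s$n_missing[1], stringsAsFactors = FALSE)
    out[paste0("count_", seq_len(max_l))] <- as.list(cnts)
    out
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Fraction of non-missing patients at one level of one variable
#'
#' Convenience accessor over [summarize_cohort()] output, e.g. the fraction
#' of a cohort with an abnormal CT.
#'
#' @param summary_long Output of [summarize_cohort()].
#' @param variable Variable name.
#' @param level Level code.
#' @return Proportion in `[0, 1]`.
#' @export
level_fraction <- function(summary_long, variable, level) {
  s <- summary_long[summary_long$variable == variable, ]
  assert_that(nrow(s) > 0, "variable '", variable, "' not in summary")
  assert_that(level %in% s$level, "level ", level, " not in '", variable, "'")
  s$count[s$level == level] / sum(s$count)
}

#' Select variables shared by two cohorts with acceptable missingness
#'
#' Keeps variables present in both cohorts whose missing fraction is below
#' `threshold` in each, plus any named exceptions regardless of their
#' missingness (used for variables judged exceptionally important for
#' sub-classification, by default post-traumatic amnesia duration and pupil
#' reactivity).
#'
#' @param cohort_a,cohort_b The two `cohort_table`s.
#' @param threshold Maximum tolerated missing fraction (default 0.1).
#' @param exceptions Variable names retained regardless of missingness.
#' @return Named list of [variable_spec()]s, in `cohort_a` schema order.
#' @export
missingness_filter <- function(cohort_a, cohort_b, threshold = 0.1,
                               exceptions = c("pta_duration",
                                              "pupil_reactivity")) {
  assert_that(threshold > 0 && threshold < 1,
              "threshold must be in (0, 1)", class = "configuration_error")
  shared <- intersect(names(cohort_a$schema), names(cohort_b$schema))
  missing_exc <- setdiff(exceptions, shared)
  assert_that(length(missing_exc) == 0,
              "exception variable(s) not in both schemas: ",
              paste(missing_exc, collapse = ", "), class = "schema_error")
  frac <- function(cohort, v) mean(is.na(cohort$values[, v]))
  ok <- vapply(shared, function(v) {
    frac(cohort_a, v) < threshold && frac(cohort_b, v) < threshold
  }, TRUE)
  keep <- union(shared[ok], exceptions)
  cohort_a$schema[names(cohort_a$schema) %in% keep]
}
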