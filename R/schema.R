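#' Define a clinical-variable specification
#'
#' A variable spec declares how one clinical variable is encoded: binary
#' variables use codes 0/1, ordinal variables consecutive integer codes
#' starting at 1, and numeric variables plain integers within a declared
#' range (used for the Glasgow Coma Scale scores).  Vital-sign variables may
#' additionally carry `bins`, the cut points used by [bin_vital()] to turn a
#' raw measurement into an ordinal code.
#'
#' @param name Variable identifier (used as CSV column name).
#' @param category One of `"demographics"`, `"medical_history"`,
#'   `"mechanism"`, `"ed_exam"`, `"blood_work"`, `"vital_signs"`,
#'   `"complications"`.
#' @param vtype `"binary"`, `"ordinal"` or `"numeric"`.
#' @param levels Ordered integer codes (binary: exactly `c(0, 1)`; ordinal:
#'   `1:L`).  Ignored for numeric variables.
#' @param labels Human-readable labels, one per level.
#' @param bins Strictly increasing numeric cut points for raw-to-ordinal
#'   conversion (`L - 1` values for `L` levels).
#' @param upper_open If `TRUE` the highest band is open at its cut point
#'   ("greater than x"); if `FALSE` it is closed ("at least x").  Only the
#'   temperature bands use the open convention.
#' @param range Length-2 integer range of legal values for numeric variables.
#' @param units Measurement units of the raw value feeding `bins`.
#' @return An object of class `variable_spec`.
#' @export
variable_spec <- function(name, category, vtype, levels = NULL, labels = NULL,
                          bins = NULL, upper_open = FALSE, range = NULL,
                          units = NULL) {
  categories <- c("demographics", "medical_history", "mechanism", "ed_exam",
                  "blood_work", "vital_signs", "complications")
  vtype <- match.arg(vtype, c("binary", "ordinal", "numeric"))
  assert_that(category %in% categories,
              "unknown variable category '", category, "'",
              class = "schema_error")
  if (vtype == "binary") {
    levels <- levels %||% c(0L, 1L)
    assert_that(identical(as.integer(levels), c(0L, 1L)),
                "binary variable '", name, "' must be coded 0/1",
                class = "schema_error")
  } else if (vtype == "ordinal") {
    assert_that(!is.null(levels) &&
                  identical(as.integer(levels), seq_along(levels)),
                "ordinal variable '", name,
                "' must use consecutive codes starting at 1",
                class = "schema_error")
  } else {
    assert_that(!is.null(range) && length(range) == 2L && range[1] < range[2],
                "numeric variable '", name, "' needs a length-2 range",
                class = "schema_error")
  }
  if (!is.null(bins)) {
    assert_that(all(diff(bins) > 0), "bins for '", name,
                "' must be strictly increasing", class = "schema_error")
    assert_that(length(bins) == length(levels) - 1L,
                "'", name, "': need one fewer bin cut point than levels",
                class = "schema_error")
  }
  if (!is.null(labels))
    assert_that(length(labels) == length(levels),
                "'", name, "': one label per level required",
                class = "schema_error")
  structure(
    list(name = name, category = category, vtype = vtype,
         levels = if (vtype == "numeric") NULL else as.integer(levels),
         labels = labels, bins = bins, upper_open = isTRUE(upper_open),
         range = if (vtype == "numeric") as.numeric(range) else NULL,
         units = units),
    class = "variable_spec")
}

#' @export
print.variable_spec <- function(x, ...) {
  cat(sprintf("<variable_spec> %s [%s/%s]\n", x$name, x$category, x$vtype))
  if (!is.null(x$levels))
    cat("  levels:", paste(x$levels, x$labels %||% x$levels,
                           sep = "=", collapse = ", "), "\n")
  if (!is.null(x$range)) cat("  range:", x$range[1], "-", x$range[2], "\n")
  if (!is.null(x$bins))
    cat("  bins:", paste(x$bins, collapse = ", "),
        if (!is.null(x$units)) x$units else "", "\n")
  invisible(x)
}

#' Load a variable schema from YAML
#'
#' Reads a list of variable specifications from a YAML file in the format of
#' the packaged default schema.
#'
#' @param path Path to a YAML schema file.
#' @return Named list of [variable_spec()] objects.
#' @export
read_schema <- function(path) {
  raw <- yaml::read_yaml(path)
  num <- function(x) if (is.null(x)) NULL else as.numeric(unlist(x))
  specs <- lapply(raw, function(v) {
    variable_spec(name = v$name, category = v$category, vtype = v$vtype,
                  levels = num(v$levels), labels = unlist(v$labels),
                  bins = num(v$bins), upper_open = v$upper_open %||% FALSE,
                  range = num(v$range), units = v$units)
  })
  names(specs) <- vapply(specs, `[[`, "", "name")
  assert_that(!anyDuplicated(names(specs)), "duplicate variable names",
              class = "schema_error")
  specs
}

#' The default 37-variable mild-TBI clinical schema
#'
#' The packaged schema covers the clinical variables recorded at the initial
#' Emergency Department evaluation of mild (GCS 13-15) closed-head-injury
#' patients: demographics, medical history, injury mechanism, ED examination
#' (including GCS, post-traumatic amnesia duration, CT result and pupil
#' reactivity), blood work, binned vital signs and ED complications.
#'
#' @return Named list of 37 [variable_spec()] objects.
#' @export
tbi_schema <- function() {
  path <- system.file("extdata", "tbi_schema.yaml", package = "tbisubclass",
                      mustWork = TRUE)
  read_schema(path)
}

#' Convert a raw vital-sign measurement to its ordinal code
#'
#' Bands follow the coding conventions of the clinical schema: the lowest
#' band is "less than" its cut point, the highest band "at least" its cut
#' point (or "greater than", for variables whose spec sets `upper_open`),
#' and middle bands are closed on both printed endpoints.  The mapping is a
#' monotone step function that is exhaustive and exclusive over the bands.
#'
#' @param value Numeric raw measurement(s) in the units of `spec$bins`.
#' @param spec A [variable_spec()] with `bins`.
#' @return Integer ordinal code(s) in `spec$levels`.
#' @examples
#' sch <- tbi_schema()
#' bin_vital(59, sch$dbp_ed)    # low
#' bin_vital(140, sch$sbp_ed)   # high
#' bin_vital(90, sch$o2_saturation_ed)  # normal
#' @export
bin_vital <- function(value, spec) {
  assert_that(inherits(spec, "variable_spec"), "spec must be a variable_spec",
              class = "configuration_error")
  assert_that(!is.null(spec$bins), "variable '", spec$name,
              "' has no bin cut points", class = "configuration_error")
  assert_that(all(is.finite(value)), "raw vital values must be finite",
              class = "validation_error")
  cuts <- spec$bins
  code <- findInterval(value, cuts) + 1L    # left-closed bands
  if (spec$upper_open) {
    # top band is strictly "greater than" its cut point
    top <- length(cuts) + 1L
    on_cut <- code == top & value == cuts[length(cuts)]
    code[on_cut] <- top - 1L
  }
  code
}
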