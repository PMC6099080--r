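# internal helpers shared across modules

`%||%` <- function(a, b) if (is.null(a)) b else a

# run expr under a temporary RNG state; seeds must stay below 2^31-1
with_seed <- function(seed, expr) {
  stopifnot(is.numeric(seed), length(seed) == 1L, is.finite(seed))
  withr::with_seed(as.integer(seed), expr)
}

stop_tbi <- function(..., class) {
  stop(errorCondition(paste0(...), class = c(class, "tbisubclass_error")))
}

assert_that <- function(cond, ..., class = "validation_error") {
  if (!isTRUE(cond)) stop_tbi(..., class = class)
  invisible(TRUE)
}
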