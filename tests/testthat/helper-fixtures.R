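# shared fixtures and independent oracles, all built in code

# schema of p generic binary variables b1..bp
binary_schema <- function(p, prefix = "b") {
  nm <- paste0(prefix, seq_len(p))
  out <- lapply(nm, function(v)
    variable_spec(v, "demographics", "binary", labels = c("no", "yes")))
  stats::setNames(out, nm)
}

# small cohort from a bare matrix of 0/1 codes
binary_cohort <- function(values, prefix = "b", provenance = "test") {
  values <- as.matrix(values)
  colnames(values) <- paste0(prefix, seq_len(ncol(values)))
  cohort_table(values, binary_schema(ncol(values), prefix),
               provenance = provenance)
}

# exhaustive O(n^2) nearest-neighbor IGP oracle
igp_oracle <- function(vals, labels) {
  n <- nrow(vals)
  nn_lab <- vapply(seq_len(n), function(i) {
    d <- colSums((t(vals) - vals[i, ])^2)
    d[i] <- Inf
    labels[which.min(d)]
  }, labels[1])
  classes <- sort(unique(labels))
  vapply(stats::setNames(classes, classes),
         function(k) mean(nn_lab[labels == k] == k), 0)
}

# dense grid-search oracle for the sparse weight problem at p <= 3:
# maximize ||D w||_2 over w >= 0, ||w||_2 <= 1, ||w||_1 <= s
grid_oracle_objective <- function(D, s, step = 0.01) {
  p <- ncol(D$d)
  stopifnot(p <= 3)
  g <- seq(0, 1, by = step)
  grid <- as.matrix(expand.grid(rep(list(g), p)))
  l2 <- sqrt(rowSums(grid^2))
  keep <- l2 > 0 & l2 <= 1 & rowSums(grid) <= s
  grid <- grid[keep, , drop = FALSE]
  # project onto the unit L2 sphere where the L1 bound allows: the optimum
  # has ||w||_2 = 1, so rescale feasible directions to the binding norm
  scale_up <- pmin(1 / sqrt(rowSums(grid^2)), s / rowSums(grid))
  grid <- grid * scale_up
  max(sqrt(colSums((D$d %*% t(grid))^2)))
}

# deterministic mixed-type cohort for round-trip style tests
mixed_demo_cohort <- function(n = 30, seed = 5, missing = 0) {
  sch <- tbi_schema()
  withr::with_seed(seed, {
    vals <- vapply(sch, function(sp) {
      support <- if (sp$vtype == "numeric")
        seq(sp$range[1], sp$range[2]) else sp$levels
      sample(support, n, replace = TRUE)
    }, numeric(n))
    colnames(vals) <- names(sch)
    if (missing > 0) vals[runif(length(vals)) < missing] <- NA
    cohort_table(vals, sch, provenance = "mixed-demo")
  })
}
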