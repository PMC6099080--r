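#' Per-feature dissimilarity decomposition
#'
#' Decomposes the pairwise patient dissimilarity into additive per-feature
#' contributions: for patients i < i' and feature j,
#' `d[(i,i'), j] = (x_ij - x_i'j)^2` (squared Euclidean) or `|x_ij - x_i'j|`
#' (absolute), computed on features standardized to zero mean and unit
#' variance within the cohort (the default; mixed binary/ordinal codes are
#' not on a common scale otherwise).  Summing the columns with unit weights
#' reproduces the usual full pairwise distance matrix, which is what the
#' feature-weighted clustering generalizes.
#'
#' Pairs are stored in lower-triangle column-major order, the same layout
#' [stats::dist()] uses, so a weighted sum of columns can be wrapped into a
#' `dist` object directly.
#'
#' @param x A `cohort_table` without missing values (impute first), or a
#'   numeric matrix.
#' @param metric `"squared_euclidean"` (default) or `"absolute"`.
#' @param standardize Standardize columns first (default `TRUE`).  Constant
#'   columns are left as all-zero contributions.
#' @return A `dissim_decomp` object: `d` (n(n-1)/2 x p contribution matrix),
#'   `pair_i`, `pair_j` (pair indices, `pair_i > pair_j` column-major),
#'   `n`, `labels`, `metric`.
#' @export
dissimilarity_decomposition <- function(x,
                                        metric = c("squared_euclidean",
                                                   "absolute"),
                                        standardize = TRUE) {
  metric <- match.arg(metric)
  if (inherits(x, "cohort_table")) {
    labels <- x$patients
    x <- x$values
  } else {
    x <- as.matrix(x)
    labels <- rownames(x) %||% as.character(seq_len(nrow(x)))
  }
  assert_that(!anyNA(x), "missing values present; impute the cohort before ",
              "computing dissimilarities", class = "validation_error")
  n <- nrow(x)
  assert_that(n >= 2, "need at least two patients")
  if (standardize) x <- standardize_columns(x)
  idx <- which(lower.tri(diag(n)))
  ai <- arrayInd(idx, c(n, n))
  pair_i <- ai[, 1]  # row index, > pair_j
  pair_j <- ai[, 2]
  d <- matrix(0, length(idx), ncol(x),
              dimnames = list(NULL, colnames(x)))
  for (j in seq_len(ncol(x))) {
    diffs <- x[pair_i, j] - x[pair_j, j]
    d[, j] <- if (metric == "squared_euclidean") diffs^2 else abs(diffs)
  }
  structure(list(d = d, pair_i = pair_i, pair_j = pair_j, n = n,
                 labels = labels, metric = metric),
            class = "dissim_decomp")
}

# zero-mean unit-variance columns; constant columns become all zero
standardize_columns <- function(x) {
  mu <- colMeans(x)
  sd <- apply(x, 2, stats::sd)
  sd[sd == 0] <- Inf
  sweep(sweep(x, 2, mu, "-"), 2, sd, "/")
}

#' @export
print.dissim_decomp <- function(x, ...) {
  cat(sprintf("<dissim_decomp> %d patients, %d features, %d pairs [%s]\n",
              x$n, ncol(x$d), nrow(x$d), x$metric))
  invisible(x)
}

#' Elementwise soft threshold
#'
#' `max(a - delta, 0)`, the positive-part shrinkage used inside the sparse
#' weight update.
#'
#' @param a Numeric vector.
#' @param delta Nonnegative scalar shrinkage.
#' @return Numeric vector of the same length.
#' @export
soft_threshold <- function(a, delta) {
  assert_that(delta >= 0, "delta must be nonnegative")
  pmax(a - delta, 0)
}

# w-update: argmax w' a  s.t. ||w||2 <= 1, ||w||1 <= s, w >= 0.
# Solution is S(a, delta) / ||S(a, delta)||2 with delta = 0 if that already
# satisfies the L1 bound, else delta > 0 found by bisection so the bound binds.
l1_bounded_unit <- function(a, s) {
  a <- pmax(a, 0)
  if (all(a == 0)) return(rep(0, length(a)))
  unit <- function(v) v / sqrt(sum(v^2))
  w <- unit(a)
  if (sum(w) <= s) return(w)
  lo <- 0
  hi <- max(a)
  for (iter in 1:60) {
    mid <- (lo + hi) / 2
    v <- soft_threshold(a, mid)
    if (all(v == 0)) { hi <- mid; next }
    if (sum(unit(v)) > s) lo <- mid else hi <- mid
  }
  v <- soft_threshold(a, hi)
  if (all(v == 0)) {
    # numerical corner: fall back to the single largest coordinate
    v <- as.numeric(a == max(a))
  }
  v[v < 1e-10 * max(v)] <- 0   # bisection leaves O(eps) residuals
  unit(v)
}

#' Optimize sparse feature weights
#'
#' Learns nonnegative feature weights under unit L2 norm and an L1 bound
#' `s`, maximizing the weighted between-patient dissimilarity criterion
#' `sum_j w_j (u' d_j)` over unit-norm `u` by alternating closed-form
#' updates: `u` proportional to `D w`, and `w` a soft-thresholded, L2
#' -normalized version of `D'u` with the threshold chosen by bisection so
#' the L1 bound holds.  Small `s` drives weights of uninformative features
#' exactly to zero; `s = sqrt(p)` leaves the problem unconstrained and (for
#' exchangeable features) uniform.  The objective is non-decreasing across
#' iterations.
#'
#' @param D A [dissimilarity_decomposition()].
#' @param s L1 bound, in `[1, sqrt(p)]`.
#' @param max_iter Maximum alternations (default 200).
#' @param tol Relative objective-change convergence tolerance.
#' @return A `feature_weights` object: `w` (named, nonnegative, unit L2
#'   norm, `sum(w) <= s`), `s`, `objective`, `iterations`, `converged`,
#'   and `trace` (objective per iteration).
#' @export
optimize_weights <- function(D, s, max_iter = 200L, tol = 1e-5) {
  assert_that(inherits(D, "dissim_decomp"), "D must be a dissim_decomp")
  p <- ncol(D$d)
  assert_that(s >= 1 - 1e-12 && s <= sqrt(p) + 1e-12,
              "s must lie in [1, sqrt(p)]", class = "configuration_error")
  w <- rep(1 / sqrt(p), p)
  obj <- -Inf
  trace <- numeric(0)
  converged <- FALSE
  for (it in seq_len(max_iter)) {
    Dw <- as.numeric(D$d %*% w)
    nrm <- sqrt(sum(Dw^2))
    if (nrm == 0) break   # degenerate: identical patients everywhere
    u <- Dw / nrm
    a <- as.numeric(crossprod(D$d, u))
    w_new <- l1_bounded_unit(a, s)
    obj_new <- sum(a * w_new)
    trace <- c(trace, obj_new)
    if (is.finite(obj) && abs(obj_new - obj) <= tol * (abs(obj) + 1e-12)) {
      w <- w_new; obj <- obj_new; converged <- TRUE
      break
    }
    w <- w_new
    obj <- obj_new
  }
  if (!converged && length(trace) == max_iter)
    warning("weight optimization did not converge in ", max_iter,
            " iterations; returning best iterate")
  structure(list(w = stats::setNames(w, colnames(D$d)), s = s,
                 objective = if (is.finite(obj)) obj else 0,
                 iterations = length(trace), converged = converged,
                 trace = trace),
            class = "feature_weights")
}

#' @export
print.feature_weights <- function(x, ...) {
  cat(sprintf(
    "<feature_weights> s = %.3f, objective = %.4f, %d/%d nonzero\n",
    x$s, x$objective, sum(x$w > 0), length(x$w)))
  invisible(x)
}

#' Agglomerate on the feature-weighted dissimilarity
#'
#' Builds the merge tree by standard agglomerative clustering on the
#' weighted pairwise dissimilarity `sum_j w_j d[.,.,j]`.  Average linkage
#' is the default: on coded clinical data the weighted dissimilarity takes
#' few distinct values, and complete linkage degrades badly under the
#' resulting ties, while average linkage recovers planted structure
#' reliably (see the methods vignette).
#'
#' @param D A [dissimilarity_decomposition()].
#' @param w A `feature_weights` object or bare nonnegative weight vector.
#' @param linkage `"average"` (default) or `"complete"`.
#' @return An [stats::hclust()] tree with patient labels.
#' @export
weighted_linkage <- function(D, w, linkage = c("average", "complete")) {
  linkage <- match.arg(linkage)
  if (inherits(w, "feature_weights")) w <- w$w
  assert_that(length(w) == ncol(D$d) && all(w >= 0),
              "w must be a nonnegative vector over the features")
  u <- as.numeric(D$d %*% w)
  dd <- structure(u, Size = D$n, Labels = D$labels, Diag = FALSE,
                  Upper = FALSE, method = "weighted", class = "dist")
  stats::hclust(dd, method = linkage)
}

#' Tune the L1 bound by a permutation gap criterion
#'
#' For each candidate bound `s`, compares the achieved clustering criterion
#' on the real data with its expectation under a feature-wise permutation
#' null (each variable's values independently shuffled across patients,
#' which preserves marginals but destroys between-feature class structure):
#' `Gap(s) = log O(s) - mean_b log O_b(s)`.  The bound with the largest gap
#' wins; ties go to the smaller (sparser) bound.
#'
#' @param x Data matrix or `cohort_table` (no missing values).
#' @param candidates Candidate bounds; default 10 log-spaced values in
#'   `[1.1, sqrt(p)]`.
#' @param B Number of permutations (default 10).
#' @param seed Integer seed for the permutations.
#' @param metric,standardize Passed to [dissimilarity_decomposition()].
#' @return List: `best_s`, and `trace` data frame with columns `s`,
#'   `objective`, `gap`, `se` (standard error of the permuted log
#'   objectives).
#' @export
tune_sparsity <- function(x, candidates = NULL, B = 10L, seed = 1L,
                          metric = "squared_euclidean", standardize = TRUE) {
  assert_that(B >= 1, "need at least one permutation")
  if (inherits(x, "cohort_table")) x <- x$values
  x <- as.matrix(x)
  p <- ncol(x)
  candidates <- candidates %||%
    exp(seq(log(1.1), log(sqrt(p)), length.out = 10))
  D <- dissimilarity_decomposition(x, metric = metric,
                                   standardize = standardize)
  obj_real <- vapply(candidates, function(s)
    optimize_weights(D, s)$objective, 0)
  perm_log <- with_seed(seed, {
    vapply(seq_len(B), function(b) {
      xp <- apply(x, 2, sample)
      Dp <- dissimilarity_decomposition(xp, metric = metric,
                                        standardize = standardize)
      vapply(candidates, function(s) log(optimize_weights(Dp, s)$objective), 0)
    }, numeric(length(candidates)))
  })
  perm_log <- matrix(perm_log, nrow = length(candidates))
  gap <- log(obj_real) - rowMeans(perm_log)
  se <- apply(perm_log, 1, stats::sd) / sqrt(B)
  best <- candidates[which.max(gap)]
  list(best_s = best,
       trace = data.frame(s = candidates, objective = obj_real, gap = gap,
                          se = se))
}

#' Cut a merge tree into K named sub-classes
#'
#' Cuts at the top `K - 1` merges and renames the groups `A`, `B`, ... in
#' decreasing size order (ties broken by the first patient index), the
#' conventional presentation for clinical sub-classes.
#'
#' @param hc An [stats::hclust()] tree.
#' @param K Number of sub-classes (1..n).
#' @return Named factor of sub-class labels, levels `A`, `B`, ...; the
#'   `"proportions"` attribute gives each class's share of patients.
#' @export
cut_tree_labels <- function(hc, K) {
  n <- length(hc$labels %||% hc$order)
  assert_that(K >= 1 && K <= n, "K must be between 1 and n",
              class = "configuration_error")
  assert_that(K <= 26, "more than 26 sub-classes are not supported")
  cl <- stats::cutree(hc, k = K)
  sizes <- tabulate(cl, nbins = K)
  first_idx <- vapply(seq_len(K), function(k) which(cl == k)[1], 0L)
  ord <- order(-sizes, first_idx)
  new_name <- character(K)
  new_name[ord] <- LETTERS[seq_len(K)]
  out <- factor(new_name[cl], levels = LETTERS[seq_len(K)])
  names(out) <- names(cl)
  attr(out, "proportions") <-
    stats::setNames(as.numeric(table(out)) / n, levels(out))
  out
}

#' Sparse hierarchical clustering of a cohort
#'
#' End-to-end fit: per-feature dissimilarity decomposition, sparse weight
#' optimization (with the L1 bound either fixed via `s` or tuned by the
#' permutation gap criterion), agglomeration on the weighted dissimilarity
#' ([weighted_linkage()], average linkage by default), and a cut into `K`
#' sub-classes named by decreasing size.  Features keeping nonzero weight
#' are the variables that significantly contribute to the
#' sub-classification.
#'
#' @param cohort A `cohort_table` without missing values, or numeric matrix.
#' @param K Number of sub-classes to cut (default 7).
#' @param s Fixed L1 bound; `NULL` (default) tunes it.
#' @param candidates,B Passed to [tune_sparsity()] when tuning.
#' @param seed Seed for the tuning permutations.
#' @param metric,standardize Passed to [dissimilarity_decomposition()].
#' @param linkage Passed to [weighted_linkage()] (default `"average"`).
#' @return An `shc_model`: `weights` (`feature_weights`), `hclust`, `labels`
#'   (named factor with size-ordered levels), `K`, `selected_features`,
#'   `tuning_trace` (`NULL` when `s` was fixed), `proportions`.
#' @export
sparse_hclust <- function(cohort, K = 7L, s = NULL, candidates = NULL,
                          B = 10L, seed = 1L, metric = "squared_euclidean",
                          linkage = c("average", "complete"),
                          standardize = TRUE) {
  linkage <- match.arg(linkage)
  tuning <- NULL
  if (is.null(s)) {
    tuning <- tune_sparsity(cohort, candidates = candidates, B = B,
                            seed = seed, metric = metric,
                            standardize = standardize)
    s <- tuning$best_s
  }
  D <- dissimilarity_decomposition(cohort, metric = metric,
                                   standardize = standardize)
  w <- optimize_weights(D, s)
  hc <- weighted_linkage(D, w, linkage = linkage)
  labels <- cut_tree_labels(hc, K)
  structure(list(weights = w, hclust = hc, labels = labels, K = K,
                 selected_features = names(w$w)[w$w > 0],
                 tuning_trace = if (is.null(tuning)) NULL else tuning$trace,
                 s = s, metric = metric, linkage = linkage,
                 standardize = standardize,
                 proportions = attr(labels, "proportions")),
            class = "shc_model")
}

#' @export
print.shc_model <- function(x, ...) {
  cat(sprintf("<shc_model> K = %d, s = %.3f, %d/%d features selected\n",
              x$K, x$s, length(x$selected_features), length(x$weights$w)))
  pr <- round(100 * x$proportions)
  cat("  sub-class proportions:",
      paste(sprintf("%s=%d%%", names(pr), pr), collapse = ", "), "\n")
  invisible(x)
}

#' Export a dendrogram as Newick
#'
#' Writes the merge tree with merge heights as branch lengths, readable by
#' any phylogenetics viewer.
#'
#' @param x An `shc_model` or [stats::hclust()] object.
#' @param file Output path.
#' @return The path, invisibly.
#' @export
export_newick <- function(x, file) {
  hc <- if (inherits(x, "shc_model")) x$hclust else x
  assert_that(inherits(hc, "hclust"), "x must be an shc_model or hclust")
  ape::write.tree(ape::as.phylo(hc), file = file)
  invisible(file)
}

#' Serialize a fitted model to JSON
#'
#' Stores weights, the merge list with heights, labels and the selected
#' feature set, sufficient to reproduce assignments and the dendrogram.
#'
#' @param model An `shc_model`.
#' @param file Output path.
#' @return The path, invisibly.
#' @export
write_shc_model <- function(model, file) {
  obj <- list(
    K = model$K, s = model$s, metric = model$metric,
    linkage = model$linkage, standardize = model$standardize,
    weights = as.list(model$weights$w),
    objective = model$weights$objective,
    merge = apply(model$hclust$merge, 1, as.integer, simplify = FALSE),
    height = model$hclust$height,
    order = model$hclust$order,
    patients = model$hclust$labels,
    labels = stats::setNames(as.character(model$labels),
                             names(model$labels)),
    selected_features = model$selected_features,
    proportions = as.list(model$proportions))
  jsonlite::write_json(obj, file, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(file)
}
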