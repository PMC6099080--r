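test_that("soft thresholding shrinks toward zero from below", {
  expect_equal(soft_threshold(c(2, 0.5, -1), 1), c(1, 0, 0))
  expect_equal(soft_threshold(c(-3, 0.2, 4), 0), c(0, 0.2, 4))
  a <- c(0.3, 0.9, 0.1)
  expect_equal(soft_threshold(a, max(a)), c(0, 0, 0))
})

test_that("per-feature contributions decompose the full squared distance", {
  x <- withr::with_seed(1, matrix(rbinom(60, 2, 0.5), 15, 4,
                                  dimnames = list(NULL, paste0("v", 1:4))))
  D <- dissimilarity_decomposition(x)
  full <- as.numeric(stats::dist(scale(x))^2)
  expect_equal(rowSums(D$d), full, tolerance = 1e-12)
  # identical patients have an all-zero row
  x2 <- rbind(x, x[1, ])
  D2 <- dissimilarity_decomposition(x2)
  pair_row <- which(D2$pair_i == 16 & D2$pair_j == 1)
  expect_equal(unname(D2$d[pair_row, ]), rep(0, 4))
  expect_error(dissimilarity_decomposition(rbind(x[1, ], NA)),
               class = "validation_error")
})

test_that("a differing binary feature contributes 1/var on standardized codes", {
  # three patients, one binary feature with values 0,1,1: sample variance 1/3,
  # so a disagreeing pair contributes (1-0)^2 / (1/3) = 3
  x <- matrix(c(0, 1, 1), ncol = 1, dimnames = list(NULL, "b"))
  D <- dissimilarity_decomposition(x)
  got <- data.frame(i = D$pair_i, j = D$pair_j, d = D$d[, 1])
  expect_equal(got$d[got$i == 2 & got$j == 1], 3)
  expect_equal(got$d[got$i == 3 & got$j == 1], 3)
  expect_equal(got$d[got$i == 3 & got$j == 2], 0)
})

test_that("exchangeable features receive uniform weights at the loose bound", {
  x <- withr::with_seed(2, matrix(rnorm(40), 20, 2))
  xx <- cbind(x[, 1], x[, 1], x[, 1])   # identical columns
  colnames(xx) <- paste0("v", 1:3)
  D <- dissimilarity_decomposition(xx, standardize = FALSE)
  w <- optimize_weights(D, sqrt(3))
  expect_equal(unname(w$w), rep(1 / sqrt(3), 3), tolerance = 1e-8)
})

test_that("optimized weights match the dense grid oracle at p = 3", {
  for (seed in 1:3) {
    x <- withr::with_seed(seed, cbind(c(rnorm(10, -2), rnorm(10, 2)),
                                      rnorm(20, 0, 0.5), rnorm(20, 0, 0.5)))
    colnames(x) <- paste0("v", 1:3)
    # raw scale: the separated first column dominates the dissimilarity
    D <- dissimilarity_decomposition(x, standardize = FALSE)
    for (s in c(1.2, 1.5)) {
      w <- optimize_weights(D, s)
      oracle <- grid_oracle_objective(D, s)
      expect_equal(w$objective, oracle, tolerance = 1e-4)
      # weight concentrates on the informative first column
      expect_equal(unname(which.max(w$w)), 1)
    }
  }
})

test_that("the unit L1 bound selects exactly the strongest feature", {
  x <- withr::with_seed(4, cbind(c(rnorm(8, -3), rnorm(8, 3)), rnorm(16),
                                 rnorm(16)))
  colnames(x) <- paste0("v", 1:3)
  D <- dissimilarity_decomposition(x, standardize = FALSE)
  w <- optimize_weights(D, 1)
  expect_equal(sum(w$w > 0), 1)
  # the surviving feature maximizes the column norm, the s = 1 optimum
  expect_equal(unname(which.max(w$w)),
               unname(which.max(sqrt(colSums(D$d^2)))))
  expect_equal(w$objective, max(sqrt(colSums(D$d^2))), tolerance = 1e-6)
})

test_that("weight iterates respect the constraint set and improve monotonically", {
  for (seed in 1:5) {
    x <- withr::with_seed(seed, matrix(rbinom(200, 1, 0.4), 25, 8,
                                       dimnames = list(NULL, paste0("v", 1:8))))
    D <- dissimilarity_decomposition(x)
    s <- runif(1, 1, sqrt(8))
    w <- optimize_weights(D, s)
    expect_true(all(w$w >= 0))
    expect_lte(sum(w$w^2), 1 + 1e-8)
    expect_lte(sum(w$w), s + 1e-8)
    expect_true(all(diff(w$trace) >= -1e-8 * abs(w$trace[-1])))
  }
  expect_error(optimize_weights(dissimilarity_decomposition(
    matrix(rnorm(20), 10, 2, dimnames = list(NULL, c("a", "b")))), s = 3),
    class = "configuration_error")
})

test_that("uniform weights reproduce standard agglomeration on the plain metric", {
  x <- withr::with_seed(6, matrix(rbinom(300, 2, 0.4), 50, 6,
                                  dimnames = list(NULL, paste0("v", 1:6))))
  D <- dissimilarity_decomposition(x)
  w <- rep(1 / sqrt(6), 6)
  for (linkage in c("complete", "average")) {
    hc <- weighted_linkage(D, w, linkage = linkage)
    ref <- stats::hclust(stats::dist(scale(x))^2 / sqrt(6), method = linkage)
    for (K in c(2, 3, 5, 10))
      expect_equal(unname(stats::cutree(hc, K)),
                   unname(stats::cutree(ref, K)))
  }
  # weight 1 on a single feature clusters on that feature alone
  w1 <- c(1, rep(0, 5))
  hc1 <- weighted_linkage(D, w1)
  ref1 <- stats::hclust(stats::dist(scale(x)[, 1, drop = FALSE])^2,
                        method = "average")
  expect_equal(unname(stats::cutree(hc1, 3)), unname(stats::cutree(ref1, 3)))
})

test_that("a four-point toy agglomerates with hand-computed heights", {
  # 1-d points 0, 1, 3, 7; squared distances; complete linkage:
  # merge {1,2} at 1, then {12,3} at max(9,4) = 9, then all at max(49,36,16)
  x <- matrix(c(0, 1, 3, 7), ncol = 1, dimnames = list(NULL, "v"))
  D <- dissimilarity_decomposition(x, standardize = FALSE)
  hc <- weighted_linkage(D, 1, linkage = "complete")
  expect_equal(hc$height, c(1, 9, 49))
})

test_that("permutation gap tuning is deterministic and honest on pure noise", {
  x <- withr::with_seed(7, matrix(rbinom(400, 1, 0.5), 40, 10,
                                  dimnames = list(NULL, paste0("v", 1:10))))
  t1 <- tune_sparsity(x, B = 6, seed = 3)
  t2 <- tune_sparsity(x, B = 6, seed = 3)
  expect_identical(t1$best_s, t2$best_s)
  expect_identical(t1$trace, t2$trace)
  # structureless data: every gap within permutation noise of zero
  sd_perm <- t1$trace$se * sqrt(6)
  expect_true(all(abs(t1$trace$gap) < 4 * sd_perm + 0.02))
})

test_that("tuning recovers the informative features on a strong signal", {
  pair <- generate_pair(preset_config("two_class", seed = 13))
  tun <- tune_sparsity(pair$cohort_a, B = 5, seed = 13)
  D <- dissimilarity_decomposition(pair$cohort_a)
  w <- optimize_weights(D, tun$best_s)
  selected <- names(w$w)[w$w > 0]
  expect_lt(length(selected), 25)
  recall <- mean(pair$truth$informative_set %in% selected)
  expect_gte(recall, 0.8)
})

test_that("tree cuts are renamed by decreasing class size", {
  # three tight 1-d blobs of sizes 5, 3, 2
  x <- matrix(c(rnorm(5, 0, 0.01), rnorm(3, 10, 0.01), rnorm(2, 30, 0.01)),
              ncol = 1, dimnames = list(NULL, "v"))
  D <- dissimilarity_decomposition(x)
  hc <- weighted_linkage(D, 1)
  labels <- cut_tree_labels(hc, 3)
  expect_equal(as.integer(table(labels)[c("A", "B", "C")]), c(5, 3, 2))
  expect_equal(sum(attr(labels, "proportions")), 1)
  expect_equal(nlevels(cut_tree_labels(hc, 1)), 1)
  expect_equal(length(unique(cut_tree_labels(hc, 10))), 10)
  expect_error(cut_tree_labels(hc, 0), class = "configuration_error")
})

test_that("fitted models serialize to JSON and Newick", {
  pair <- generate_pair(preset_config("two_class", seed = 17))
  model <- sparse_hclust(pair$cohort_a, K = 2, s = 2.2)
  json_path <- withr::local_tempfile(fileext = ".json")
  write_shc_model(model, json_path)
  back <- jsonlite::read_json(json_path)
  expect_equal(back$K, 2)
  expect_equal(length(back$weights), 25)
  expect_equal(length(back$labels), 200)
  nwk <- withr::local_tempfile(fileext = ".nwk")
  export_newick(model, nwk)
  tree <- ape::read.tree(nwk)
  expect_equal(ape::Ntip(tree), 200)
})
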