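test_that("mann_whitney_u reproduces hand-enumerated exact p-values", {
  r <- mann_whitney_u(c(1, 2, 3), c(4, 5, 6))
  expect_equal(r$u_statistic, 0)
  expect_equal(r$p_value, 0.1)  # 2 of the 20 arrangements are as extreme
  expect_identical(r$method, "exact")

  r2 <- mann_whitney_u(c(1, 2), c(3, 4))
  expect_equal(r2$u_statistic, 0)
  expect_equal(r2$p_value, 1 / 3)

  # identical constant samples: U = n^2/2, p = 1 (all ties)
  r3 <- mann_whitney_u(rep(2, 4), rep(2, 4))
  expect_equal(r3$u_statistic, 8)
  expect_equal(r3$p_value, 1)

  expect_error(mann_whitney_u(numeric(0), 1:3),
               class = "cpptools_error_empty_sample")
})

test_that("exact p-values match the exhaustive-permutation oracle (n <= 6)", {
  set.seed(21)
  for (n1 in 2:6) {
    for (n2 in 2:6) {
      vals <- sample(seq_len(50), n1 + n2)  # tie-free
      x <- vals[seq_len(n1)]; y <- vals[-seq_len(n1)]
      got <- mann_whitney_u(x, y)
      ref <- oracle_mwu_exact(x, y)
      expect_identical(got$method, "exact")
      expect_equal(got$u_statistic, ref$u)
      expect_equal(got$p_value, ref$p, tolerance = 1e-12)
    }
  }
})

test_that("the normal approximation agrees with the reference rank test", {
  set.seed(22)
  for (i in 1:20) {
    x <- rnorm(30); y <- rnorm(25, mean = runif(1, -1, 1))
    got <- mann_whitney_u(x, y)
    ref <- suppressWarnings(stats::wilcox.test(x, y, exact = FALSE,
                                               correct = TRUE))
    expect_equal(got$u_statistic, unname(ref$statistic))
    expect_equal(got$p_value, ref$p.value, tolerance = 1e-10)
  }
  # with heavy ties the tie-corrected variance still matches
  x <- sample(1:3, 40, TRUE); y <- sample(1:4, 35, TRUE)
  expect_equal(mann_whitney_u(x, y)$p_value,
               suppressWarnings(stats::wilcox.test(x, y, exact = FALSE)$p.value),
               tolerance = 1e-10)
})

test_that("filter_by_mwu keeps planted signal and drops noise and constants", {
  hits <- 0L
  for (seed in 1:20) {
    m <- tiny_labeled_matrix(n_per_class = 100L, d_noise = 1L, seed = seed)
    rep <- filter_by_mwu(m)
    if (rep$kept_mask[["signal"]] && !rep$kept_mask[["noise01"]]) {
      hits <- hits + 1L
    }
  }
  expect_gte(hits, 19L)  # >= 0.95 over seeds

  # alpha = 1 keeps every non-constant feature
  m <- tiny_labeled_matrix(seed = 3)
  expect_true(all(filter_by_mwu(m, alpha = 1)$kept_mask))

  # all-constant matrix keeps nothing (p = 1 for constants)
  const <- cpp_features(matrix(1, 10, 2, dimnames = list(letters[1:10],
                                                         c("c1", "c2"))),
                        rep(c(0L, 1L), 5))
  expect_length(filter_by_mwu(const)$kept_features, 0L)

  unlabeled <- cpp_features(m$x)
  expect_error(filter_by_mwu(unlabeled), class = "cpptools_error_missing_label")
  single <- cpp_features(m$x, rep(1L, nrow(m$x)))
  expect_error(filter_by_mwu(single), class = "cpptools_error_single_class")
})

test_that("kept set is invariant to monotone transforms of a feature", {
  m <- tiny_labeled_matrix(n_per_class = 50L, seed = 5)
  base <- filter_by_mwu(m)$kept_mask
  transforms <- list(function(v) exp(v), function(v) v^3,
                     function(v) atan(v) * 10, function(v) rank(v))
  for (tf in transforms) {
    x2 <- m$x
    x2[, "signal"] <- tf(x2[, "signal"])
    expect_identical(filter_by_mwu(cpp_features(x2, m$labels))$kept_mask, base)
  }
})

test_that("ert_select recovers a planted feature and is seed-deterministic", {
  set.seed(31)
  n <- 120L
  labels <- rep(c(0L, 1L), each = n / 2)
  x <- matrix(rnorm(n * 50), n,
              dimnames = list(sprintf("r%03d", 1:n), sprintf("n%02d", 1:50)))
  x <- cbind(x, planted = as.numeric(labels), constant = rep(1, n))
  m <- cpp_features(x, labels)

  rep1 <- ert_select(m, top_k = ncol(x))
  expect_identical(rep1$final_feature_names[1L], "planted")
  expect_equal(unname(rep1$importance[["constant"]]), 0)  # never splits
  expect_equal(sum(rep1$importance), 1)
  expect_setequal(rep1$final_feature_names, colnames(x))

  rep2 <- ert_select(m, top_k = ncol(x))
  expect_identical(rep1$final_feature_names, rep2$final_feature_names)
  expect_equal(rep1$importance, rep2$importance)

  expect_error(ert_select(m, top_k = ncol(x) + 1L),
               class = "cpptools_error_config")
})

test_that("run_selection filters first and ranks second", {
  m <- tiny_labeled_matrix(n_per_class = 100L, d_noise = 10L, seed = 6)
  # permissive filter so the ranking stage has a full slate to cut to 3
  rep <- run_selection(m, alpha = 1, top_k = 3L)
  # every final feature survived the filter
  expect_true(all(rep$final_feature_names %in%
                    names(which(rep$kept_mask))))
  expect_identical(rep$final_feature_names[1L], "signal")
  expect_length(rep$final_feature_names, 3L)
})

test_that("svd_reduce captures low rank exactly and projects new data", {
  set.seed(41)
  # rank-1 matrix: one component reconstructs it
  u <- rnorm(12); v <- rnorm(6)
  x <- outer(u, v)
  dimnames(x) <- list(sprintf("r%02d", 1:12), sprintf("f%d", 1:6))
  m <- cpp_features(x)
  dec <- suppressWarnings(svd_reduce(m, 2))  # centered rank-1 clamps from 2
  recon <- dec$reduced$x %*% t(dec$rotation)
  recon <- sweep(recon, 2, dec$center, `+`)
  expect_lt(max(abs(recon - x)), 1e-9)

  # full-rank capture: explained variance sums to 1
  x2 <- matrix(rnorm(80), 10, 8,
               dimnames = list(sprintf("r%02d", 1:10), sprintf("f%d", 1:8)))
  m2 <- cpp_features(x2)
  dec2 <- svd_reduce(m2, 8)
  expect_equal(sum(dec2$explained_variance), 1, tolerance = 1e-9)

  # projection of training rows equals the fitted scores, and the rank-k
  # reconstruction matches a brute-force eigendecomposition oracle
  dec3 <- svd_reduce(m2, 3)
  expect_equal(svd_project(dec3, m2)$x, dec3$reduced$x, tolerance = 1e-9)
  xc <- scale(x2, scale = FALSE)
  eig <- eigen(crossprod(xc), symmetric = TRUE)
  best3 <- xc %*% eig$vectors[, 1:3] %*% t(eig$vectors[, 1:3])
  ours3 <- dec3$reduced$x %*% t(dec3$rotation)
  expect_equal(unname(ours3), unname(best3), tolerance = 1e-9)

  expect_error(svd_reduce(m2, 0), class = "cpptools_error_config")
  expect_warning(svd_reduce(m, 5),
                 class = "cpptools_warning_rank_too_low")
})
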