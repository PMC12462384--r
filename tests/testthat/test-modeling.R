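make_separable <- function(n = 200L, seed = 7L) {
  set.seed(seed)
  labels <- rep(c(0L, 1L), each = n / 2)
  x <- matrix(rnorm(n * 10), n,
              dimnames = list(sprintf("r%03d", 1:n), sprintf("f%02d", 1:10)))
  x[, 1] <- labels * 4 + rnorm(n, sd = 0.1)  # planted, fully separable
  cpp_features(x, labels)
}

test_that("training interpolates a separable set and is seed-deterministic", {
  m <- make_separable(seed = 7)
  mod <- train(m)
  p <- predict(mod, m)
  expect_equal(p$label, m$labels)
  expect_equal(metrics_from_counts(confusion_from_labels(p$label, m$labels))$MCC, 1)

  p2 <- predict(train(m), m)
  expect_identical(p$score, p2$score)  # same seed, byte-identical

  single <- cpp_features(m$x, rep(1L, nrow(m$x)))
  expect_error(train(single), class = "cpptools_error_single_class")
})

test_that("predict refuses mismatched columns instead of reordering", {
  m <- make_separable()
  mod <- train(m)
  shuffled <- cpp_features(m$x[, rev(colnames(m$x))], m$labels)
  expect_error(predict(mod, shuffled),
               class = "cpptools_error_column_mismatch")
  dropped <- cpp_features(m$x[, -1], m$labels)
  expect_error(predict(mod, dropped),
               class = "cpptools_error_column_mismatch")
  one <- cpp_features(m$x[1, , drop = FALSE])
  p <- predict(mod, one)
  expect_identical(nrow(p), 1L)
})

test_that("stratified folds preserve class ratio within one sample", {
  labels <- c(rep(0L, 73), rep(1L, 47))
  fold <- stratified_folds(labels, 10L, seed = 1L)
  expect_identical(sort(unique(fold)), 1:10)
  for (f in 1:10) {
    expect_lte(abs(sum(labels[fold == f] == 1L) - 4.7), 1)
    expect_lte(abs(sum(labels[fold == f] == 0L) - 7.3), 1)
  }
  expect_error(stratified_folds(c(0L, 1L), 3L, 1L),
               class = "cpptools_error_too_few_per_class")
})

test_that("cross-validation separates signal from null", {
  m <- make_separable(n = 200L, seed = 11)
  cv <- cross_validate(m, k = 10L, seed = 11L)
  expect_gte(cv_mean(cv, "AUC"), 0.95)
  expect_identical(length(cv$folds), 10L)

  set.seed(11)
  null_x <- matrix(rnorm(200 * 10), 200,
                   dimnames = list(sprintf("r%03d", 1:200),
                                   sprintf("f%02d", 1:10)))
  null_m <- cpp_features(null_x, rep(c(0L, 1L), 100))
  null_cv <- cross_validate(null_m, k = 10L, seed = 11L)
  expect_gte(cv_mean(null_cv, "AUC"), 0.35)
  expect_lte(cv_mean(null_cv, "AUC"), 0.65)
})

test_that("tree predictions are invariant to monotone feature transforms", {
  m <- make_separable(n = 80L, seed = 13)
  mod <- train(m)
  base <- predict(mod, m)$score
  x2 <- m$x
  x2[, 1] <- exp(x2[, 1])  # strictly monotone, train and predict alike
  m2 <- cpp_features(x2, m$labels)
  mod2 <- train(m2)
  expect_equal(predict(mod2, m2)$score, base, tolerance = 1e-12)
})

test_that("alternative estimators run behind the same surface", {
  m <- make_separable(n = 60L, seed = 17)
  for (algo in c("RF", "GBT", "SVM", "MLP")) {
    params <- training_params(algorithm = algo, n_estimators = 50L)
    mod <- train(m, params)
    p <- predict(mod, m)
    expect_true(all(p$score >= 0 & p$score <= 1))
    expect_gte(mean(p$label == m$labels), 0.9)
  }
})

test_that("the two-stage bundle wires selection into stage 1 and atomic
          frequencies into stage 2", {
  cpp_ds <- generate_binary_dataset(generator_params(n_per_class = 60L,
                                                     seed = 19L))
  eff_ds <- generate_efficiency_dataset(
    generator_params(n_per_class = 30L, seed = 19L), atomic_shift = 3)
  cfg <- descriptor_config(blocks = c("AAC", "DPC", "PHYSCHEM", "ATOMIC",
                                      "LENGTH"))
  bundle <- fit_two_stage(cpp_ds, eff_ds, cfg, top_k = 50L)

  expect_identical(bundle$stage2$feature_names,
                   c("normnC", "normnH", "normnN", "normnO", "normnS"))
  expect_true(all(bundle$stage1$feature_names %in% cfg$feature_names))

  probe <- cpp_dataset(c("cat1", "an1"), c("RKKRRKKRGGR", "DDEEDDEEGG"))
  out <- predict_two_stage(bundle, probe)
  expect_identical(names(out), c("id", "stage1_score", "stage1_label",
                                 "stage2_score", "stage2_label"))
  # a stage-1 negative gets explicit NA efficiency, never a silent score
  neg <- out[out$stage1_label == 0L, ]
  if (nrow(neg)) {
    expect_true(all(is.na(neg$stage2_score)))
    expect_true(all(is.na(neg$stage2_label)))
  }
  pos <- out[out$stage1_label == 1L, ]
  if (nrow(pos)) expect_true(all(!is.na(pos$stage2_score)))
})

test_that("synthetic cationic peptides are called cell-penetrating", {
  hits <- 0L
  for (seed in 1:10) {
    ds <- generate_binary_dataset(generator_params(n_per_class = 50L,
                                                   seed = seed))
    cfg <- descriptor_config(blocks = c("AAC", "PHYSCHEM", "ATOMIC"))
    m <- featurize_all(ds, cfg)
    sel <- run_selection(m, top_k = 15L)
    mod <- train(select_features(m, sel$final_feature_names))
    probe <- cpp_dataset("rich", "RRKKRWRRKIKK")
    pm <- featurize_all(cpp_dataset("rich", "RRKKRWRRKIKK"), cfg)
    p <- predict(mod, select_features(pm, sel$final_feature_names))
    if (p$label == 1L) hits <- hits + 1L
  }
  expect_gte(hits, 9L)
})

test_that("model bundles round-trip through disk bit-stably", {
  m <- make_separable(n = 100L, seed = 23)
  mod <- train(m)
  probe <- cpp_features(m$x[1:50, , drop = FALSE])
  before <- predict(mod, probe)

  dir <- tempfile("bundle")
  save_model(mod, dir)
  back <- load_model(dir)
  expect_identical(predict(back, probe)$score, before$score)
  expect_identical(back$feature_names, mod$feature_names)
  expect_identical(back$params$seed, mod$params$seed)
})

test_that("tampered or future-version bundles are rejected", {
  m <- make_separable(n = 60L, seed = 29)
  dir <- tempfile("bundle")
  save_model(train(m), dir)

  mf <- file.path(dir, "manifest.json")
  manifest <- jsonlite::read_json(mf)

  # corrupt the estimator file -> hash mismatch
  saveRDS(list(), file.path(dir, manifest$files$model$file))
  expect_error(load_model(dir), class = "cpptools_error_hash_mismatch")

  # future format version -> version mismatch
  dir2 <- tempfile("bundle")
  save_model(train(m), dir2)
  mf2 <- file.path(dir2, "manifest.json")
  manifest2 <- jsonlite::read_json(mf2)
  manifest2$format_version <- 99L
  jsonlite::write_json(manifest2, mf2, auto_unbox = TRUE)
  expect_error(load_model(dir2), class = "cpptools_error_version_mismatch")

  # manifest/estimator disagreement on feature names
  dir3 <- tempfile("bundle")
  save_model(train(m), dir3)
  mf3 <- file.path(dir3, "manifest.json")
  manifest3 <- jsonlite::read_json(mf3, simplifyVector = TRUE,
                                   simplifyDataFrame = FALSE)
  manifest3$stages$model$feature_names <-
    manifest3$stages$model$feature_names[-1]
  jsonlite::write_json(manifest3, mf3, auto_unbox = TRUE)
  expect_error(load_model(dir3), class = "cpptools_error_hash_mismatch")
})
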