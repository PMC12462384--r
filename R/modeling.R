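# Classifier stage. The default estimator is an extremely-randomized-trees
# ensemble (random split thresholds, no bootstrap, full-sample trees);
# Random Forest, gradient-boosted trees, SVM and MLP are selectable for
# comparison experiments but carry no bespoke logic.

#' Training parameters
#'
#' Hyperparameters for the classifier stage. The defaults are the package's
#' reference configuration: 500 extra trees, Gini impurity, sqrt(d)
#' candidate features per split, one random threshold per candidate, no
#' bootstrap, seed 42. Everything is recorded verbatim in saved model
#' bundles for auditability.
#'
#' @param algorithm One of `"ERT"` (default), `"RF"`, `"GBT"`, `"SVM"`,
#'   `"MLP"`.
#' @param n_estimators Number of trees (tree methods) or boosting rounds.
#' @param seed Integer seed; always recorded.
#' @param class_weight `"none"` or `"balanced"` (inverse class frequencies).
#' @param mtry Candidate features per split; `NULL` means `floor(sqrt(d))`.
#' @param min_node_size Minimum node size for tree methods (1 grows trees
#'   to purity, so separable training sets are interpolated).
#' @param extra Named list of estimator-specific overrides, stored verbatim.
#' @return A `cpp_training_params` list.
#' @export
training_params <- function(algorithm = c("ERT", "RF", "GBT", "SVM", "MLP"),
                            n_estimators = 500L, seed = 42L,
                            class_weight = c("none", "balanced"),
                            mtry = NULL, min_node_size = 1L,
                            extra = list()) {
  algorithm <- match.arg(algorithm)
  class_weight <- match.arg(class_weight)
  structure(list(
    algorithm = algorithm,
    n_estimators = as.integer(n_estimators),
    seed = as.integer(seed),
    class_weight = class_weight,
    mtry = if (!is.null(mtry)) as.integer(mtry),
    min_node_size = as.integer(min_node_size),
    extra = extra
  ), class = "cpp_training_params")
}

need_pkg <- function(pkg, what) {
  if (!requireNamespace(pkg, quietly = TRUE)) {
    cpp_stop(sprintf("package %s is required for %s", sQuote(pkg), what),
             "config")
  }
}

# Fit the configured estimator on a plain matrix. Returns an opaque fit
# carrying everything predict_estimator() needs (including any scaler
# fitted on the training rows only, for SVM/MLP).
fit_estimator <- function(x, labels, params, importance = FALSE) {
  y <- factor(labels, levels = c(0L, 1L))
  mtry <- if (!is.null(params$mtry)) params$mtry else max(1L, floor(sqrt(ncol(x))))
  weights <- NULL
  if (params$class_weight == "balanced") {
    tab <- table(y)
    weights <- as.numeric(sum(tab) / (2 * tab[as.character(y)]))
  }
  fit <- switch(params$algorithm,
    ERT = ranger::ranger(
      x = x, y = y, probability = TRUE,
      num.trees = params$n_estimators,
      mtry = mtry, min.node.size = params$min_node_size,
      splitrule = "extratrees", num.random.splits = 1L,
      replace = FALSE, sample.fraction = 1,
      importance = if (importance) "impurity" else "none",
      case.weights = weights,
      seed = params$seed, num.threads = 1L
    ),
    RF = ranger::ranger(
      x = x, y = y, probability = TRUE,
      num.trees = params$n_estimators,
      mtry = mtry, min.node.size = params$min_node_size,
      importance = if (importance) "impurity" else "none",
      case.weights = weights,
      seed = params$seed, num.threads = 1L
    ),
    GBT = {
      need_pkg("xgboost", "gradient-boosted trees")
      set.seed(params$seed)
      xgboost::xgb.train(
        params = list(objective = "binary:logistic", nthread = 1L,
                      seed = params$seed),
        data = xgboost::xgb.DMatrix(x, label = as.integer(labels)),
        nrounds = params$n_estimators, verbose = 0)
    },
    SVM = {
      need_pkg("e1071", "the SVM estimator")
      set.seed(params$seed)
      e1071::svm(x = x, y = y, probability = TRUE, scale = TRUE)
    },
    MLP = {
      need_pkg("nnet", "the MLP estimator")
      ctr <- colMeans(x)
      sds <- apply(x, 2, stats::sd); sds[sds == 0] <- 1
      xs <- scale(x, center = ctr, scale = sds)
      set.seed(params$seed)
      list(net = nnet::nnet(xs, as.integer(labels), size = 16L, decay = 1e-3,
                            maxit = 200L, entropy = TRUE, trace = FALSE,
                            MaxNWts = 1e6),
           center = ctr, scale = sds)
    }
  )
  imp <- NULL
  if (importance && params$algorithm %in% c("ERT", "RF")) {
    imp <- fit$variable.importance
  }
  list(fit = fit, algorithm = params$algorithm, importance = imp)
}

predict_estimator <- function(est, x) {
  switch(est$algorithm,
    ERT = ,
    RF = {
      pr <- stats::predict(est$fit, data = x, num.threads = 1L)$predictions
      as.numeric(pr[, "1"])
    },
    GBT = as.numeric(stats::predict(est$fit, xgboost::xgb.DMatrix(x))),
    SVM = {
      pr <- attr(stats::predict(est$fit, x, probability = TRUE), "probabilities")
      as.numeric(pr[, "1"])
    },
    MLP = {
      xs <- scale(x, center = est$fit$center, scale = est$fit$scale)
      as.numeric(stats::predict(est$fit$net, xs))
    }
  )
}

#' Train a classifier on a labeled feature matrix
#'
#' @param m A labeled [cpp_features()] matrix.
#' @param params A [training_params()].
#' @param stage Stage tag recorded in the model (`"cpp"` for the
#'   cell-penetration classifier, `"efficiency"` for the uptake stage).
#' @return A `cpp_model` carrying the fitted estimator, the exact ordered
#'   feature-name list it expects, the parameters and training metadata.
#' @export
train <- function(m, params = training_params(), stage = c("cpp", "efficiency")) {
  stage <- match.arg(stage)
  check_two_classes(m)
  tab <- table(factor(m$labels, levels = c(0L, 1L)))
  if (any(tab < 2L)) {
    cpp_stop("each class needs at least 2 rows", "too_few_per_class")
  }
  est <- fit_estimator(m$x, m$labels, params)
  structure(list(
    stage = stage,
    params = params,
    feature_names = colnames(m$x),
    estimator = est,
    threshold = 0.5,
    metadata = list(
      n_rows = nrow(m$x),
      class_counts = as.integer(tab),
      dataset_hash = hash_object(list(m$x, m$labels))
    )
  ), class = "cpp_model")
}

#' @export
print.cpp_model <- function(x, ...) {
  cat(sprintf("<cpp_model> stage: %s | algorithm: %s | %d feature(s), %d training row(s)\n",
              x$stage, x$params$algorithm, length(x$feature_names),
              x$metadata$n_rows))
  invisible(x)
}

#' Predict with a trained classifier
#'
#' Columns of the input must match the model's expected feature names in
#' name, order and count; no silent reordering is performed.
#'
#' @param object A `cpp_model`.
#' @param m A [cpp_features()] matrix (labels, if any, are ignored).
#' @param threshold Score cut-off for the hard label (default the model's
#'   stored threshold, 0.5).
#' @param ... Unused.
#' @return A data frame with columns `id`, `score` (positive-class
#'   probability) and `label` (1 when `score >= threshold`).
#' @export
predict.cpp_model <- function(object, m, threshold = object$threshold, ...) {
  x <- if (inherits(m, "cpp_features")) m$x else m
  if (!identical(colnames(x), object$feature_names)) {
    cpp_stop("feature columns do not match the model (name, order and count must be identical)",
             "column_mismatch")
  }
  score <- predict_estimator(object$estimator, x)
  data.frame(id = rownames(x), score = score,
             label = as.integer(score >= threshold),
             stringsAsFactors = FALSE)
}

#' Stratified k-fold assignment
#'
#' @param labels 0/1 vector.
#' @param k Number of folds.
#' @param seed Integer seed for the shuffle.
#' @return Integer fold id per row; within each class, fold sizes differ by
#'   at most one, so the class ratio is preserved within one sample.
#' @export
stratified_folds <- function(labels, k, seed) {
  if (any(table(labels) < k)) {
    cpp_stop(sprintf("each class needs at least k = %d members", k),
             "too_few_per_class")
  }
  fold <- integer(length(labels))
  rng <- seeded_rng(seed)
  for (cl in unique(labels)) {
    idx <- which(labels == cl)
    idx <- rng(function() idx[sample.int(length(idx))])
    fold[idx] <- rep_len(seq_len(k), length(idx))
  }
  fold
}

# run `expr_fun` under a local RNG seeded with `seed`, restoring the
# caller's RNG state afterwards
seeded_rng <- function(seed) {
  function(expr_fun) {
    old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv())
    on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
    set.seed(seed)
    expr_fun()
  }
}

#' Stratified k-fold cross-validation
#'
#' @param m A labeled [cpp_features()] matrix.
#' @param params A [training_params()].
#' @param k Number of folds (default 10); each class must have >= k rows.
#' @param seed Seed for the fold shuffle (defaults to the training seed).
#' @return A `cpp_cv_result` with per-fold metric reports, a `summary`
#'   data frame (mean and sd per metric over folds), `k` and `seed`.
#' @export
cross_validate <- function(m, params = training_params(), k = 10L,
                           seed = params$seed) {
  check_two_classes(m)
  k <- as.integer(k)
  fold <- stratified_folds(m$labels, k, seed)
  reports <- lapply(seq_len(k), function(f) {
    tr <- fold != f
    fit <- fit_estimator(m$x[tr, , drop = FALSE], m$labels[tr], params)
    score <- predict_estimator(fit, m$x[!tr, , drop = FALSE])
    metrics_from_scores(score, m$labels[!tr])
  })
  metric_names <- c("SN", "SP", "ACC", "PR", "F1", "MCC", "AUC")
  vals <- sapply(metric_names, function(nm) {
    vapply(reports, function(r) r[[nm]], numeric(1L))
  })
  summary <- data.frame(
    metric = metric_names,
    mean = colMeans(vals, na.rm = TRUE),
    sd = apply(vals, 2, stats::sd, na.rm = TRUE),
    row.names = NULL
  )
  structure(list(folds = reports, summary = summary, k = k, seed = seed),
            class = "cpp_cv_result")
}

#' @export
print.cpp_cv_result <- function(x, ...) {
  cat(sprintf("<cpp_cv_result> %d-fold stratified cross-validation (seed %d)\n",
              x$k, x$seed))
  print(x$summary, row.names = FALSE, digits = 4)
  invisible(x)
}

#' Mean of one metric over cross-validation folds
#'
#' @param cv A `cpp_cv_result`.
#' @param metric Metric name (e.g. `"AUC"`, `"MCC"`).
#' @return The fold mean.
#' @export
cv_mean <- function(cv, metric) {
  cv$summary$mean[match(metric, cv$summary$metric)]
}

#' Cross-validate the full selection + training pipeline
#'
#' Runs the Mann-Whitney filter and the extra-trees importance ranking
#' inside each training fold (never on the held-out rows), then trains and
#' scores on the fold's selected descriptors. This avoids the selection
#' bias that inflates fold metrics when descriptors are chosen on the full
#' matrix: under a null generator this estimator sits at chance level,
#' whereas selecting once on all rows does not.
#'
#' @inheritParams cross_validate
#' @param alpha Mann-Whitney threshold for the per-fold filter.
#' @param top_k Descriptor count after the per-fold importance ranking
#'   (clamped to the number the filter keeps). If the filter keeps nothing
#'   in a fold (possible under a null), all descriptors are used unranked.
#' @return A `cpp_cv_result`.
#' @export
cross_validate_pipeline <- function(m, alpha = 0.05, top_k = 522L,
                                    params = training_params(), k = 10L,
                                    seed = params$seed) {
  check_two_classes(m)
  k <- as.integer(k)
  fold <- stratified_folds(m$labels, k, seed)
  reports <- lapply(seq_len(k), function(f) {
    tr <- fold != f
    mtr <- cpp_features(m$x[tr, , drop = FALSE], m$labels[tr])
    filt <- filter_by_mwu(mtr, alpha = alpha)
    feats <- if (length(filt$kept_features) >= 2L) {
      kept <- select_features(mtr, filt$kept_features)
      ert_select(kept, params = params,
                 top_k = min(as.integer(top_k), ncol(kept$x)))$final_feature_names
    } else {
      colnames(m$x)
    }
    fit <- fit_estimator(mtr$x[, feats, drop = FALSE], mtr$labels, params)
    score <- predict_estimator(fit, m$x[!tr, feats, drop = FALSE])
    metrics_from_scores(score, m$labels[!tr])
  })
  metric_names <- c("SN", "SP", "ACC", "PR", "F1", "MCC", "AUC")
  vals <- sapply(metric_names, function(nm) {
    vapply(reports, function(r) r[[nm]], numeric(1L))
  })
  summary <- data.frame(
    metric = metric_names,
    mean = colMeans(vals, na.rm = TRUE),
    sd = apply(vals, 2, stats::sd, na.rm = TRUE),
    row.names = NULL
  )
  structure(list(folds = reports, summary = summary, k = k, seed = seed),
            class = "cpp_cv_result")
}

#' Fit the two-stage classifier
#'
#' Stage 1 (cell penetration): descriptors are computed with `cfg`,
#' filtered by the Mann-Whitney test, ranked by extra-trees importance and
#' the top `top_k` are used to train the CPP/non-CPP classifier. Stage 2
#' (uptake efficiency): trained on the five atomic frequencies only, on the
#' high/low-efficiency dataset.
#'
#' @param train_cpp Labeled [cpp_dataset()] for CPP vs non-CPP.
#' @param train_eff Labeled [cpp_dataset()] of CPPs with high (1) vs low
#'   (0) uptake efficiency.
#' @param cfg A [descriptor_config()] for stage 1.
#' @param alpha Mann-Whitney threshold for the stage-1 filter.
#' @param top_k Stage-1 descriptor count after importance ranking.
#' @param params A [training_params()] used for both stages.
#' @return A `cpp_two_stage` bundle: `stage1`, `stage2` (both `cpp_model`),
#'   `selection` (the stage-1 selection report) and `config`.
#' @export
fit_two_stage <- function(train_cpp, train_eff, cfg = descriptor_config(),
                          alpha = 0.05, top_k = 522L,
                          params = training_params()) {
  m1 <- featurize_all(train_cpp, cfg)
  sel <- run_selection(m1, alpha = alpha, top_k = top_k, params = params)
  stage1 <- train(select_features(m1, sel$final_feature_names), params,
                  stage = "cpp")
  atomic_cfg <- descriptor_config(blocks = "ATOMIC",
                                  pka_table = cfg$pka_table,
                                  normalization = cfg$normalization)
  m2 <- featurize_all(train_eff, atomic_cfg)
  stage2 <- train(m2, params, stage = "efficiency")
  structure(list(stage1 = stage1, stage2 = stage2, selection = sel,
                 config = cfg, atomic_config = atomic_cfg),
            class = "cpp_two_stage")
}

#' @export
print.cpp_two_stage <- function(x, ...) {
  cat("<cpp_two_stage> CPP classifier + uptake-efficiency classifier\n")
  print(x$stage1); print(x$stage2)
  invisible(x)
}

#' Predict with the two-stage classifier
#'
#' Stage 2 is only evaluated for peptides stage 1 calls cell-penetrating;
#' for stage-1 negatives the efficiency columns are explicitly `NA`
#' ("not applicable"), never a silent score.
#'
#' @param bundle A `cpp_two_stage` from [fit_two_stage()].
#' @param ds A [cpp_dataset()] (labels, if any, are ignored).
#' @return A data frame with columns `id`, `stage1_score`, `stage1_label`,
#'   `stage2_score`, `stage2_label`.
#' @export
predict_two_stage <- function(bundle, ds) {
  m <- featurize_all(ds, bundle$config)
  p1 <- predict(bundle$stage1, select_features(m, bundle$stage1$feature_names))
  out <- data.frame(id = ds$id, stage1_score = p1$score,
                    stage1_label = p1$label,
                    stage2_score = NA_real_, stage2_label = NA_integer_,
                    stringsAsFactors = FALSE)
  pos <- p1$label == 1L
  if (any(pos)) {
    m2 <- featurize_all(ds[pos, , drop = FALSE], bundle$atomic_config)
    p2 <- predict(bundle$stage2, m2)
    out$stage2_score[pos] <- p2$score
    out$stage2_label[pos] <- p2$label
  }
  out
}
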