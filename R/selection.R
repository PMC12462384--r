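# Feature selection: a Mann-Whitney rank filter over all descriptors
# (alpha = 0.05, no multiplicity adjustment by default) followed by an
# extremely-randomized-trees importance ranking that keeps the top_k
# descriptors. The SVD reduction used in model exploration lives here too.

#' Mann-Whitney U test (two-sided)
#'
#' Rank-sum test for a location difference between two samples. The U
#' statistic reported is the one for the first sample. For small tie-free
#' samples (both sizes <= 8) the p-value comes from the exact U
#' distribution; otherwise a normal approximation with tie correction and
#' continuity correction is used.
#'
#' @param x,y Numeric samples (each non-empty).
#' @return A list with `u_statistic`, `p_value` and `method`
#'   (`"exact"` or `"normal-approximation"`).
#' @examples
#' mann_whitney_u(c(1, 2, 3), c(4, 5, 6))
#' @export
mann_whitney_u <- function(x, y) {
  if (!length(x) || !length(y)) cpp_stop("both samples must be non-empty", "empty_sample")
  n1 <- length(x); n2 <- length(y)
  r <- rank(c(x, y))
  u <- sum(r[seq_len(n1)]) - n1 * (n1 + 1) / 2
  has_ties <- anyDuplicated(c(x, y)) > 0L
  if (!has_ties && n1 <= 8L && n2 <= 8L) {
    # exact two-sided tail doubling; symmetry gives P(U >= u) = P(U <= n1*n2 - u)
    p <- min(1, 2 * min(stats::pwilcox(u, n1, n2),
                        stats::pwilcox(n1 * n2 - u, n1, n2)))
    return(list(u_statistic = u, p_value = p, method = "exact"))
  }
  p <- mwu_normal_p(u, n1, n2, r)
  list(u_statistic = u, p_value = p, method = "normal-approximation")
}

mwu_normal_p <- function(u, n1, n2, r) {
  n <- n1 + n2
  tie_lengths <- rle(sort(r))$lengths
  tiesum <- sum(tie_lengths^3 - tie_lengths)
  sigma2 <- (n1 * n2 / 12) * ((n + 1) - tiesum / (n * (n - 1)))
  if (sigma2 <= 0) return(1)
  mu <- n1 * n2 / 2
  diff <- u - mu
  z <- (diff - sign(diff) * 0.5) / sqrt(sigma2)  # continuity correction
  if (diff == 0) z <- 0
  min(1, 2 * stats::pnorm(-abs(z)))
}

#' Filter features by per-column Mann-Whitney tests
#'
#' Tests every descriptor for a distributional difference between the
#' positive and negative class and keeps those with p < `alpha`. No
#' multiple-testing adjustment is applied by default (an optional
#' Benjamini-Hochberg switch is provided); constant features get p = 1 and
#' are dropped.
#'
#' @param m A labeled [cpp_features()] matrix.
#' @param alpha Significance threshold (default 0.05).
#' @param adjust `"none"` (default) or `"fdr"` (Benjamini-Hochberg) applied
#'   before thresholding.
#' @return A `cpp_selection_report` with `p_values`, `kept_mask` and the
#'   kept feature names in original column order.
#' @export
filter_by_mwu <- function(m, alpha = 0.05, adjust = c("none", "fdr")) {
  adjust <- match.arg(adjust)
  check_two_classes(m)
  pos <- m$labels == 1L
  n1 <- sum(pos); n2 <- sum(!pos)
  p_values <- apply(m$x, 2, function(col) {
    if (max(col) == min(col)) return(1)
    r <- rank(col)
    u <- sum(r[pos]) - n1 * (n1 + 1) / 2
    mwu_normal_p(u, n1, n2, r)
  })
  p_eff <- if (adjust == "fdr") stats::p.adjust(p_values, "BH") else p_values
  kept_mask <- p_eff < alpha
  structure(list(
    p_values = p_values,
    kept_mask = kept_mask,
    alpha = alpha,
    adjust = adjust,
    kept_features = colnames(m$x)[kept_mask],
    importance = NULL,
    final_feature_names = NULL
  ), class = "cpp_selection_report")
}

#' Rank features by extremely-randomized-trees importance
#'
#' Fits an extra-trees ensemble on the full matrix, ranks descriptors by
#' mean impurity-decrease importance (normalized to sum to 1) and keeps the
#' `top_k` highest, descending, with ties broken alphabetically. The
#' ranking is deterministic under a fixed seed.
#'
#' @param m A labeled [cpp_features()] matrix.
#' @param params A [training_params()] (the seed and tree count are used).
#' @param top_k Number of descriptors to keep (<= number of columns).
#' @return A `cpp_selection_report` with `importance` (named, sums to 1
#'   over all columns) and `final_feature_names` (length `top_k`,
#'   descending importance).
#' @export
ert_select <- function(m, params = training_params(), top_k = 522L) {
  check_two_classes(m)
  top_k <- as.integer(top_k)
  if (top_k < 1L || top_k > ncol(m$x)) {
    cpp_stop("`top_k` must be between 1 and the number of features", "config")
  }
  fit <- fit_estimator(m$x, m$labels, params, importance = TRUE)
  imp <- fit$importance
  imp[imp < 0] <- 0
  total <- sum(imp)
  if (total > 0) imp <- imp / total
  ord <- order(-imp, names(imp))
  structure(list(
    p_values = NULL,
    kept_mask = stats::setNames(seq_along(imp) %in% ord[seq_len(top_k)],
                                names(imp)),
    alpha = NULL,
    importance = imp,
    final_feature_names = names(imp)[ord[seq_len(top_k)]]
  ), class = "cpp_selection_report")
}

#' Run the full two-step selection: Mann-Whitney filter, then ERT ranking
#'
#' @inheritParams filter_by_mwu
#' @inheritParams ert_select
#' @param top_k Number of descriptors retained after the importance
#'   ranking; when more than the filter keeps, all kept features are
#'   ranked and returned.
#' @return A `cpp_selection_report` combining the filter p-values and the
#'   ERT importances over the filtered features.
#' @export
run_selection <- function(m, alpha = 0.05, top_k = 522L,
                          params = training_params()) {
  filt <- filter_by_mwu(m, alpha = alpha)
  if (!length(filt$kept_features)) {
    cpp_stop("Mann-Whitney filter kept no features", "empty_sample")
  }
  kept <- select_features(m, filt$kept_features)
  k <- min(as.integer(top_k), ncol(kept$x))
  ranked <- ert_select(kept, params = params, top_k = k)
  structure(list(
    p_values = filt$p_values,
    kept_mask = filt$kept_mask,
    alpha = alpha,
    importance = ranked$importance,
    final_feature_names = ranked$final_feature_names
  ), class = "cpp_selection_report")
}

#' @export
print.cpp_selection_report <- function(x, ...) {
  cat("<cpp_selection_report>")
  if (!is.null(x$p_values)) {
    cat(sprintf(" filtered: %d/%d kept (alpha=%g)",
                sum(x$kept_mask), length(x$p_values), x$alpha))
  }
  if (!is.null(x$final_feature_names)) {
    cat(sprintf(" | final: %d features", length(x$final_feature_names)))
  }
  cat("\n")
  invisible(x)
}

check_two_classes <- function(m) {
  if (is.null(m$labels)) cpp_stop("feature matrix has no labels", "missing_label")
  if (length(unique(m$labels)) < 2L) {
    cpp_stop("both classes must be present", "single_class")
  }
}

#' Truncated SVD reduction
#'
#' Mean-centers columns, truncates the singular value decomposition at
#' `n_components`, and returns the projected rows plus a reusable
#' transform for unseen data. When `n_components` exceeds the numerical
#' rank it is clamped with a warning.
#'
#' @param m A [cpp_features()] matrix (labels, if any, are carried through).
#' @param n_components Number of singular vectors to keep
#'   (1 <= n_components <= min(rows, cols)).
#' @return A `cpp_svd` object with `reduced` (a [cpp_features()] of
#'   components `SV1..SVk`), `center`, `rotation`, `singular_values` and
#'   `explained_variance` (fractions of centered total variance).
#' @export
svd_reduce <- function(m, n_components) {
  n_components <- as.integer(n_components)
  if (n_components < 1L || n_components > min(dim(m$x))) {
    cpp_stop("`n_components` must lie in [1, min(rows, cols)]", "config")
  }
  center <- colMeans(m$x)
  xc <- sweep(m$x, 2, center)
  dec <- svd(xc)
  tol <- max(dim(xc)) * max(dec$d) * .Machine$double.eps
  rank <- sum(dec$d > tol)
  if (n_components > rank) {
    cpp_warn(sprintf("n_components (%d) exceeds matrix rank (%d); clamping",
                     n_components, rank), "rank_too_low")
    n_components <- rank
  }
  k <- seq_len(n_components)
  scores <- dec$u[, k, drop = FALSE] %*% diag(dec$d[k], nrow = n_components)
  dimnames(scores) <- list(rownames(m$x), paste0("SV", k))
  structure(list(
    reduced = cpp_features(scores, m$labels),
    center = center,
    rotation = dec$v[, k, drop = FALSE],
    singular_values = dec$d[k],
    explained_variance = dec$d[k]^2 / sum(dec$d^2)
  ), class = "cpp_svd")
}

#' Project new rows with a fitted SVD transform
#'
#' @param transform A `cpp_svd` object from [svd_reduce()].
#' @param m A [cpp_features()] with the same columns as the training matrix.
#' @return A [cpp_features()] of projected components.
#' @export
svd_project <- function(transform, m) {
  if (ncol(m$x) != length(transform$center)) {
    cpp_stop("column count does not match the fitted transform", "column_mismatch")
  }
  scores <- sweep(m$x, 2, transform$center) %*% transform$rotation
  colnames(scores) <- paste0("SV", seq_len(ncol(scores)))
  rownames(scores) <- rownames(m$x)
  cpp_features(scores, m$labels)
}
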