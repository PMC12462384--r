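# Interpretability reports: top importances, per-block contribution sums,
# class frequency/mean ratios, isoelectric-point/net-charge tables and
# misclassification distribution summaries. All outputs are tidy data
# frames so the reports are testable headless; plotting is left to the
# user.

#' Map descriptor names to their block
#'
#' Derived mechanically from the naming scheme: `AAC_*` -> "AAC", `DPC_*`
#' -> "dipeptides", `TPC_*` -> "tripeptides", `CKSAAGP_*` -> "CKSAAGP",
#' `normn*` -> "atomic", the five physicochemical scalars ->
#' "physicochemical", `length` -> "length".
#'
#' @param features Character vector of descriptor names.
#' @return Character vector of block labels, same length.
#' @export
feature_block_map <- function(features) {
  block <- rep(NA_character_, length(features))
  block[startsWith(features, "AAC_")] <- "AAC"
  block[startsWith(features, "DPC_")] <- "dipeptides"
  block[startsWith(features, "TPC_")] <- "tripeptides"
  block[startsWith(features, "CKSAAGP_")] <- "CKSAAGP"
  block[features %in% ATOMIC_NAMES] <- "atomic"
  block[features %in% PHYSCHEM_NAMES] <- "physicochemical"
  block[features == "length"] <- "length"
  if (anyNA(block)) {
    cpp_stop(sprintf("unmapped feature(s): %s",
                     paste(utils::head(features[is.na(block)], 5L),
                           collapse = ", ")),
             "unmapped_feature")
  }
  block
}

#' Top-k features by importance
#'
#' @param report A `cpp_selection_report` with importances (from
#'   [ert_select()] or [run_selection()]).
#' @param k How many features to return (clamped, with a warning, to the
#'   number available).
#' @return Data frame (`feature`, `importance`), descending importance,
#'   ties broken alphabetically so the ordering is deterministic.
#' @export
top_importances <- function(report, k = 20L) {
  imp <- report$importance
  if (is.null(imp)) cpp_stop("report carries no importances", "config")
  k <- as.integer(k)
  if (k > length(imp)) {
    cpp_warn(sprintf("k = %d exceeds the %d available features; clamping",
                     k, length(imp)), "clamped")
    k <- length(imp)
  }
  ord <- order(-imp, names(imp))[seq_len(k)]
  data.frame(feature = names(imp)[ord], importance = unname(imp[ord]),
             stringsAsFactors = FALSE)
}

#' Per-block importance contributions
#'
#' Sums normalized importances within each descriptor block; the block sums
#' conserve the total importance.
#'
#' @param report A `cpp_selection_report` with importances.
#' @param block Optional block label per feature; defaults to
#'   [feature_block_map()] of the importance names.
#' @return Data frame (`block`, `contribution`), descending contribution.
#' @export
block_contributions <- function(report, block = NULL) {
  imp <- report$importance
  if (is.null(imp)) cpp_stop("report carries no importances", "config")
  if (is.null(block)) block <- feature_block_map(names(imp))
  if (length(block) != length(imp)) {
    cpp_stop("`block` must map every feature", "unmapped_feature")
  }
  sums <- tapply(imp, block, sum)
  out <- data.frame(block = names(sums), contribution = as.numeric(sums),
                    stringsAsFactors = FALSE)
  out[order(-out$contribution), , drop = FALSE]
}

#' Class ratio of feature means
#'
#' For each requested feature, the ratio mean(positive rows) /
#' mean(negative rows). A zero denominator flags the ratio as undefined
#' (`NA` with `undefined = TRUE`); no epsilon is added.
#'
#' @param m A labeled [cpp_features()] matrix.
#' @param features Feature names to report (default: all columns).
#' @return Data frame (`feature`, `mean_positive`, `mean_negative`,
#'   `ratio`, `undefined`).
#' @export
class_ratio <- function(m, features = feature_names(m)) {
  check_two_classes(m)
  sub <- select_features(m, features)
  pos <- sub$labels == 1L
  mp <- colMeans(sub$x[pos, , drop = FALSE])
  mn <- colMeans(sub$x[!pos, , drop = FALSE])
  ratio <- ifelse(mn == 0, NA_real_, mp / mn)
  data.frame(feature = features, mean_positive = unname(mp),
             mean_negative = unname(mn), ratio = unname(ratio),
             undefined = mn == 0, stringsAsFactors = FALSE)
}

#' Isoelectric-point / net-charge scatter table
#'
#' Tidy per-peptide table of the two dominant physicochemical descriptors,
#' suitable for the classic pI-vs-charge scatter with its pH 7 reference
#' line (peptides with pI > 7 are cationic at physiological pH).
#'
#' @param m A labeled [cpp_features()] matrix containing the
#'   `isoelectric_point` and `net_charge` columns.
#' @return Data frame (`id`, `isoelectric_point`, `net_charge`, `label`),
#'   one row per matrix row.
#' @export
physchem_scatter <- function(m) {
  needed <- c("isoelectric_point", "net_charge")
  missing <- setdiff(needed, colnames(m$x))
  if (length(missing)) {
    cpp_stop(sprintf("feature(s) not in matrix: %s",
                     paste(missing, collapse = ", ")), "missing_feature")
  }
  if (is.null(m$labels)) cpp_stop("feature matrix has no labels", "missing_label")
  data.frame(id = rownames(m$x),
             isoelectric_point = unname(m$x[, "isoelectric_point"]),
             net_charge = unname(m$x[, "net_charge"]),
             label = m$labels, stringsAsFactors = FALSE)
}

#' Descriptor distributions of correct and incorrect predictions
#'
#' Five-number summaries (min, Q1, median, Q3, max) of each requested
#' feature within the four truth-by-prediction cells. Empty cells are
#' flagged (`n = 0`, summaries `NA`) rather than omitted.
#'
#' @param m A [cpp_features()] matrix.
#' @param truth,predicted 0/1 vectors aligned to the matrix rows.
#' @param features Feature names to summarize.
#' @return Data frame with one row per feature x cell: `feature`, `truth`,
#'   `predicted`, `n`, `min`, `q1`, `median`, `q3`, `max`.
#' @export
misclassification_profile <- function(m, truth, predicted,
                                      features = c("isoelectric_point",
                                                   "net_charge")) {
  if (length(truth) != nrow(m$x) || length(predicted) != nrow(m$x)) {
    cpp_stop("`truth` and `predicted` must align to matrix rows",
             "length_mismatch")
  }
  sub <- select_features(m, features)
  cells <- expand.grid(truth = 0:1, predicted = 0:1)
  rows <- lapply(features, function(f) {
    vals <- sub$x[, f]
    do.call(rbind, lapply(seq_len(nrow(cells)), function(i) {
      in_cell <- truth == cells$truth[i] & predicted == cells$predicted[i]
      n <- sum(in_cell)
      q <- if (n) stats::quantile(vals[in_cell], c(0, .25, .5, .75, 1),
                                  names = FALSE)
           else rep(NA_real_, 5L)
      data.frame(feature = f, truth = cells$truth[i],
                 predicted = cells$predicted[i], n = n,
                 min = q[1], q1 = q[2], median = q[3], q3 = q[4], max = q[5],
                 stringsAsFactors = FALSE)
    }))
  })
  do.call(rbind, rows)
}
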