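# Independent brute-force oracles and small fixture builders. These stay
# deliberately naive (string windows, explicit enumeration) so they check
# the optimized implementations from outside.

random_peptide <- function(len = NULL) {
  if (is.null(len)) len <- sample(3:30, 1L)
  paste(sample(AA_ALPHABET, len, replace = TRUE), collapse = "")
}

# slide a window and tally into a named map
oracle_kmer <- function(sequence, k) {
  L <- nchar(sequence)
  counts <- integer(0)
  for (i in seq_len(L - k + 1L)) {
    w <- substr(sequence, i, i + k - 1L)
    counts[w] <- (if (w %in% names(counts)) counts[[w]] else 0L) + 1L
  }
  out <- stats::setNames(numeric(20L^k),
                         sub("^[A-Z]+_", "", cpptools:::kmer_feature_names(
                           k, c("AAC", "DPC", "TPC")[k])))
  out[names(counts)] <- counts / L
  names(out) <- paste0(c("AAC", "DPC", "TPC")[k], "_", names(out))
  out
}

oracle_cksaagp <- function(sequence, grouping, max_gap) {
  chars <- strsplit(sequence, "")[[1L]]
  L <- length(chars)
  gn <- names(grouping)
  group_of <- function(a) gn[vapply(grouping, function(g) a %in% g, logical(1L))]
  out <- numeric(0)
  for (k in 0:max_gap) {
    slice <- stats::setNames(
      numeric(length(gn)^2),
      paste0("CKSAAGP_k", k, "_", as.vector(t(outer(gn, gn, paste, sep = ".")))))
    i <- 1L
    while (i + k + 1L <= L) {
      key <- paste0("CKSAAGP_k", k, "_", group_of(chars[i]), ".",
                    group_of(chars[i + k + 1L]))
      slice[key] <- slice[key] + 1L
      i <- i + 1L
    }
    out <- c(out, slice / L)
  }
  out
}

# exhaustive-permutation two-sided Mann-Whitney p-value (tie-free inputs)
oracle_mwu_exact <- function(x, y) {
  n1 <- length(x); n2 <- length(y)
  pooled <- c(x, y)
  u_of <- function(idx) {
    r <- rank(pooled)
    sum(r[idx]) - n1 * (n1 + 1) / 2
  }
  u_obs <- u_of(seq_len(n1))
  combos <- utils::combn(n1 + n2, n1)
  us <- apply(combos, 2, u_of)
  mu <- n1 * n2 / 2
  p <- mean(abs(us - mu) >= abs(u_obs - mu))
  list(u = u_obs, p = p)
}

# trapezoidal area under the full-threshold ROC polygon
oracle_auc_trapezoid <- function(scores, labels) {
  thr <- c(Inf, sort(unique(scores), decreasing = TRUE), -Inf)
  n1 <- sum(labels == 1); n2 <- sum(labels == 0)
  tpr <- vapply(thr, function(t) sum(scores >= t & labels == 1) / n1, 0)
  fpr <- vapply(thr, function(t) sum(scores >= t & labels == 0) / n2, 0)
  sum(diff(fpr) * (utils::head(tpr, -1) + utils::tail(tpr, -1)) / 2)
}

tiny_labeled_matrix <- function(n_per_class = 20L, d_noise = 5L, seed = 1L,
                                signal_sd = 0.1) {
  set.seed(seed)
  n <- 2L * n_per_class
  labels <- rep(c(1L, 0L), each = n_per_class)
  x <- matrix(rnorm(n * d_noise), n,
              dimnames = list(sprintf("p%03d", 1:n),
                              sprintf("noise%02d", 1:d_noise)))
  x <- cbind(signal = labels + rnorm(n, sd = signal_sd), x)
  cpp_features(x, labels)
}
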