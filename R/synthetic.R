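# Seeded synthetic peptide generator. Emulates the compositional structure
# that separates cell-penetrating from non-penetrating peptides: positives
# are cationic, arginine/lysine-enriched (hence nitrogen-rich) short
# chains; negatives are anionic/neutral, aspartate/glutamate-enriched
# (hence oxygen-rich). Residues are sampled i.i.d. per class, so the
# planted signal is purely compositional and physicochemical.

#' Synthetic generator parameters
#'
#' @param n_per_class Peptides per class.
#' @param length_range Integer `c(min, max)` chain length, uniform
#'   (default 5-30, the typical CPP size range); min must be >= 3.
#' @param enrichment Residue-weight multiplier e applied to R and K in the
#'   positive class and to D and E in the negative class (default 4);
#'   e = 1 makes the classes exchangeable (a null generator).
#' @param label_noise Fraction of labels flipped after generation, in
#'   \[0, 0.5).
#' @param seed Integer seed; generation is fully deterministic per seed.
#' @return A `cpp_generator_params` list carrying the normalized per-class
#'   residue weight vectors.
#' @export
generator_params <- function(n_per_class = 500L, length_range = c(5L, 30L),
                             enrichment = 4, label_noise = 0, seed = 42L) {
  length_range <- as.integer(length_range)
  if (length(length_range) != 2L || length_range[1L] < 3L ||
      length_range[2L] < length_range[1L]) {
    cpp_stop("`length_range` must be c(min, max) with min >= 3", "config")
  }
  if (enrichment <= 0) cpp_stop("`enrichment` must be positive", "config")
  if (label_noise < 0 || label_noise >= 0.5) {
    cpp_stop("`label_noise` must lie in [0, 0.5)", "config")
  }
  base <- stats::setNames(rep(1, 20L), AA_ALPHABET)
  pos <- base; pos[c("R", "K")] <- enrichment
  neg <- base; neg[c("D", "E")] <- enrichment
  structure(list(
    n_per_class = as.integer(n_per_class),
    length_range = length_range,
    enrichment = enrichment,
    positive_weights = pos / sum(pos),
    negative_weights = neg / sum(neg),
    label_noise = label_noise,
    seed = as.integer(seed)
  ), class = "cpp_generator_params")
}

sample_peptides <- function(n, length_range, weights, prefix) {
  lens <- sample(seq(length_range[1L], length_range[2L]), n, replace = TRUE)
  seqs <- vapply(lens, function(L) {
    paste(sample(AA_ALPHABET, L, replace = TRUE, prob = weights),
          collapse = "")
  }, character(1L))
  list(id = sprintf("%s%04d", prefix, seq_len(n)), sequence = seqs)
}

#' Generate a balanced synthetic CPP / non-CPP dataset
#'
#' Lengths are uniform over `length_range`; residues are i.i.d. from the
#' class weight vector (R/K up-weighted in positives, D/E in negatives).
#' With the default enrichment and n >= 200 the positive class's mean net
#' charge at pH 7 exceeds the negative class's by well over 2 units, and
#' the positive median isoelectric point is above 7.
#'
#' @param p A [generator_params()].
#' @return A labeled [cpp_dataset()] of `2 * n_per_class` peptides
#'   (positives first).
#' @export
generate_binary_dataset <- function(p = generator_params()) {
  run <- seeded_rng(p$seed)
  run(function() {
    pos <- sample_peptides(p$n_per_class, p$length_range,
                           p$positive_weights, "pos")
    neg <- sample_peptides(p$n_per_class, p$length_range,
                           p$negative_weights, "neg")
    label <- c(rep(1L, p$n_per_class), rep(0L, p$n_per_class))
    if (p$label_noise > 0) {
      flip <- stats::runif(length(label)) < p$label_noise
      label[flip] <- 1L - label[flip]
    }
    cpp_dataset(c(pos$id, neg$id), c(pos$sequence, neg$sequence), label)
  })
}

#' Generate a synthetic high/low uptake-efficiency dataset
#'
#' All peptides are CPP-like (cationic, R/K-enriched). The high-efficiency
#' class additionally up-weights the nitrogen-rich residues R, N, Q and H
#' by a factor `1 + atomic_shift`, so the per-residue nitrogen frequency
#' (normnN) separates the classes with an effect size controlled by
#' `atomic_shift`; `atomic_shift = 0` is an exact null (classes
#' exchangeable).
#'
#' @param p A [generator_params()] (its `enrichment` sets the shared
#'   cationic background).
#' @param atomic_shift Non-negative nitrogen-bias strength.
#' @return A labeled [cpp_dataset()]; label 1 = high efficiency.
#' @export
generate_efficiency_dataset <- function(p = generator_params(n_per_class = 140L),
                                        atomic_shift = 3) {
  if (atomic_shift < 0) cpp_stop("`atomic_shift` must be >= 0", "config")
  low_w <- p$positive_weights
  high_w <- low_w
  high_w[c("R", "N", "Q", "H")] <- high_w[c("R", "N", "Q", "H")] * (1 + atomic_shift)
  high_w <- high_w / sum(high_w)
  run <- seeded_rng(p$seed)
  run(function() {
    high <- sample_peptides(p$n_per_class, p$length_range, high_w, "high")
    low <- sample_peptides(p$n_per_class, p$length_range, low_w, "low")
    cpp_dataset(c(high$id, low$id), c(high$sequence, low$sequence),
                c(rep(1L, p$n_per_class), rep(0L, p$n_per_class)))
  })
}
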