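# Descriptor engine. Every composition count is divided by the chain length
# L (the default normalization), so blocks sum to L-dependent constants:
# AAC to 1, DPC to (L-1)/L, TPC to (L-2)/L, each CKSAAGP gap-k slice to
# max(L-k-1, 0)/L.

seq_codes <- function(sequence) {
  match(strsplit(sequence, "", fixed = TRUE)[[1L]], AA_ALPHABET)
}

#' k-mer composition (AAC, DPC, TPC)
#'
#' Frequencies of all 20^k length-k subsequences, counted over overlapping
#' windows and normalized by the chain length L (or by the window count
#' L-k+1 with `normalization = "windows"`). Entries are ordered
#' lexicographically over A < C < D < ... < Y.
#'
#' @param sequence A validated peptide sequence (see [validate_sequence()]).
#' @param k Window size: 1 (AAC), 2 (DPC) or 3 (TPC).
#' @param normalization `"length"` (default) or `"windows"`.
#' @return Named numeric vector of length `20^k`.
#' @examples
#' kmer_composition("ARAR", 2)[c("DPC_AR", "DPC_RA")]
#' @export
kmer_composition <- function(sequence, k, normalization = c("length", "windows")) {
  normalization <- match.arg(normalization)
  k <- as.integer(k)
  if (!k %in% 1:3) cpp_stop("`k` must be 1, 2 or 3", "config")
  codes <- seq_codes(sequence)
  L <- length(codes)
  if (L < 3L) cpp_stop("sequence length must be >= 3", "too_short")
  nwin <- L - k + 1L
  idx <- codes[seq_len(nwin)] - 1L
  if (k >= 2L) idx <- idx * 20L + codes[2:(nwin + 1L)] - 1L
  if (k >= 3L) idx <- idx * 20L + codes[3:(nwin + 2L)] - 1L
  counts <- tabulate(idx + 1L, nbins = 20L^k)
  denom <- if (normalization == "length") L else nwin
  out <- counts / denom
  names(out) <- kmer_feature_names(k, c("AAC", "DPC", "TPC")[k])
  out
}

#' Composition of k-spaced amino-acid group pairs (CKSAAGP)
#'
#' For each gap k in 0..`max_gap` and each ordered pair of residue groups
#' (G1, G2), the number of positions i with residue i in G1 and residue
#' i + k + 1 in G2, normalized by the chain length L. A gap with no valid
#' index pairs (k >= L - 1) contributes an all-zero slice.
#'
#' @inheritParams kmer_composition
#' @param grouping Named list partitioning the residues; see
#'   [default_cksaagp_grouping()].
#' @param max_gap Largest gap K (gaps 0..K are computed).
#' @return Named numeric vector of length `g^2 * (K + 1)` where g is the
#'   number of groups.
#' @export
cksaagp <- function(sequence, grouping = default_cksaagp_grouping(),
                    max_gap = 15L, normalization = c("length", "windows")) {
  normalization <- match.arg(normalization)
  resolved <- sort(unlist(grouping, use.names = FALSE))
  if (!identical(resolved, AA_ALPHABET)) {
    cpp_stop("`grouping` must partition the 20 canonical residues", "config")
  }
  codes <- seq_codes(sequence)
  L <- length(codes)
  if (L < 3L) cpp_stop("sequence length must be >= 3", "too_short")
  ng <- length(grouping)
  group_of <- integer(20L)
  for (g in seq_len(ng)) {
    group_of[match(grouping[[g]], AA_ALPHABET)] <- g
  }
  gcodes <- group_of[codes]
  max_gap <- as.integer(max_gap)
  out <- numeric(ng * ng * (max_gap + 1L))
  for (k in 0:max_gap) {
    npair <- L - k - 1L
    if (npair < 1L) next
    g1 <- gcodes[seq_len(npair)]
    g2 <- gcodes[seq_len(npair) + k + 1L]
    counts <- tabulate((g1 - 1L) * ng + g2, nbins = ng * ng)
    denom <- if (normalization == "length") L else npair
    out[k * ng * ng + seq_len(ng * ng)] <- counts / denom
  }
  names(out) <- cksaagp_feature_names(grouping, max_gap)
  out
}

#' Mean of a per-residue scale over a sequence
#'
#' The arithmetic mean of scale values across residues. With the
#' Kyte-Doolittle hydropathy scale this is the GRAVY index.
#'
#' @inheritParams kmer_composition
#' @param scale A scale name (`"kyte_doolittle"`, `"eisenberg"`) or a named
#'   numeric vector covering all 20 residues.
#' @return Numeric scalar.
#' @examples
#' scale_mean("AILV", "kyte_doolittle")  # GRAVY = 3.575
#' @export
scale_mean <- function(sequence, scale = "kyte_doolittle") {
  scale <- resolve_scale(scale)
  codes <- seq_codes(sequence)
  mean(scale[codes])
}

#' Average molecular mass of a peptide
#'
#' Sum of average residue masses plus one water (18.02 Da); each residue
#' mass is the free amino acid's average mass minus water (condensation).
#'
#' @inheritParams kmer_composition
#' @return Mass in daltons.
#' @export
molecular_mass <- function(sequence) {
  codes <- seq_codes(sequence)
  sum(AA_RESIDUE_MASS[codes]) + WATER_MASS
}

#' Net charge at a given pH
#'
#' Henderson-Hasselbalch sum of fractional protonation states: each basic
#' group (N-terminus and the side chains of K, R, H) contributes
#' `+1/(1 + 10^(pH - pKa))`; each acidic group (C-terminus and the side
#' chains of D, E, C, Y) contributes `-1/(1 + 10^(pKa - pH))`. Strictly
#' decreasing in pH.
#'
#' @inheritParams kmer_composition
#' @param ph pH value(s) in \[0, 14\] (vectorized).
#' @param pka_table Ionization constants; see [default_pka_table()].
#' @return Net charge, one value per element of `ph`.
#' @examples
#' net_charge("KKK", 7)
#' @export
net_charge <- function(sequence, ph = 7.0, pka_table = default_pka_table()) {
  if (any(ph < 0) || any(ph > 14)) cpp_stop("pH must lie in [0, 14]", "config")
  codes <- seq_codes(sequence)
  counts <- tabulate(codes, nbins = 20L)
  names(counts) <- AA_ALPHABET
  basic_pka <- c(pka_table$n_term, rep(pka_table$basic, counts[names(pka_table$basic)]))
  acidic_pka <- c(pka_table$c_term, rep(pka_table$acidic, counts[names(pka_table$acidic)]))
  vapply(ph, function(p) {
    sum(1 / (1 + 10^(p - basic_pka))) - sum(1 / (1 + 10^(acidic_pka - p)))
  }, numeric(1L))
}

#' Isoelectric point
#'
#' The pH in \[0, 14\] at which [net_charge()] crosses zero, located by
#' bisection until the residual charge is below 1e-6 or the bracketing
#' interval is narrower than 1e-6 pH units. Because both termini are always
#' ionizable, the net charge is positive at pH 0 and negative at pH 14, so
#' a root always exists and is unique (the charge is strictly decreasing).
#'
#' @inheritParams net_charge
#' @return The isoelectric point (pH units).
#' @export
isoelectric_point <- function(sequence, pka_table = default_pka_table()) {
  lo <- 0; hi <- 14
  f_lo <- net_charge(sequence, lo, pka_table)
  f_hi <- net_charge(sequence, hi, pka_table)
  stopifnot(f_lo > 0, f_hi < 0)  # guaranteed by the always-ionizable termini
  repeat {
    mid <- (lo + hi) / 2
    f_mid <- net_charge(sequence, mid, pka_table)
    if (abs(f_mid) < 1e-6 || (hi - lo) < 1e-6) return(mid)
    if (f_mid > 0) lo <- mid else hi <- mid
  }
}

#' Atomic frequencies (C, H, N, O, S per residue)
#'
#' Elemental composition of the whole molecule (sum of residue formulas
#' plus one water; residue formula = free amino-acid formula minus water),
#' divided by the chain length L.
#'
#' @inheritParams kmer_composition
#' @return Named numeric vector `c(normnC, normnH, normnN, normnO, normnS)`.
#' @examples
#' atomic_frequencies("GGG")
#' @export
atomic_frequencies <- function(sequence) {
  codes <- seq_codes(sequence)
  L <- length(codes)
  counts <- tabulate(codes, nbins = 20L)
  molecule <- as.vector(counts %*% AA_FORMULA) - (L - 1L) * WATER_FORMULA
  out <- molecule / L
  names(out) <- ATOMIC_NAMES
  out
}

featurize_one <- function(sequence, cfg) {
  blocks <- lapply(cfg$blocks, function(b) {
    switch(b,
      AAC = kmer_composition(sequence, 1L, cfg$normalization),
      DPC = kmer_composition(sequence, 2L, cfg$normalization),
      TPC = kmer_composition(sequence, 3L, cfg$normalization),
      CKSAAGP = cksaagp(sequence, cfg$cksaagp_grouping, cfg$cksaagp_max_gap,
                        cfg$normalization),
      PHYSCHEM = c(
        gravy = unname(scale_mean(sequence, cfg$gravy_scale)),
        mass = molecular_mass(sequence),
        isoelectric_point = isoelectric_point(sequence, cfg$pka_table),
        hydrophobicity = unname(scale_mean(sequence, cfg$hydrophobicity_scale)),
        net_charge = net_charge(sequence, cfg$net_charge_ph, cfg$pka_table)
      ),
      ATOMIC = atomic_frequencies(sequence),
      LENGTH = c(length = nchar(sequence))
    )
  })
  unlist(blocks, use.names = FALSE)
}

#' Compute the descriptor vector of a single peptide
#'
#' Concatenates the enabled blocks in configuration order. With the default
#' configuration the vector has 8831 entries.
#'
#' @inheritParams kmer_composition
#' @param cfg A [descriptor_config()].
#' @return Named numeric vector aligned to `cfg$feature_names`.
#' @export
featurize <- function(sequence, cfg = descriptor_config()) {
  sequence <- validate_sequence(sequence)
  out <- featurize_one(sequence, cfg)
  names(out) <- cfg$feature_names
  out
}

#' Compute the descriptor matrix of a peptide dataset
#'
#' Applies [featurize()] to every peptide, preserving row order and label
#' alignment.
#'
#' @param ds A [cpp_dataset()].
#' @param cfg A [descriptor_config()].
#' @return A [cpp_features()] matrix of `nrow(ds)` peptides by
#'   `length(cfg$feature_names)` descriptors.
#' @export
featurize_all <- function(ds, cfg = descriptor_config()) {
  n <- nrow(ds)
  d <- length(cfg$feature_names)
  x <- matrix(0, nrow = n, ncol = d,
              dimnames = list(ds$id, cfg$feature_names))
  for (i in seq_len(n)) {
    x[i, ] <- featurize_one(ds$sequence[i], cfg)
  }
  cpp_features(x, labels = ds$label)
}
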