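kmer_feature_names <- function(k, prefix) {
  grid <- expand.grid(replicate(k, AA_ALPHABET, simplify = FALSE),
                      stringsAsFactors = FALSE)
  # expand.grid varies the first column fastest; reverse so the last
  # character of the k-mer varies fastest, i.e. lexicographic order
  paste0(prefix, "_", do.call(paste0, rev(as.list(grid))))
}

cksaagp_feature_names <- function(grouping, max_gap) {
  gn <- names(grouping)
  pair <- as.vector(t(outer(gn, gn, paste, sep = ".")))
  unlist(lapply(0:max_gap, function(k) {
    paste0("CKSAAGP_k", k, "_", pair)
  }), use.names = FALSE)
}

PHYSCHEM_NAMES <- c("gravy", "mass", "isoelectric_point",
                    "hydrophobicity", "net_charge")
ATOMIC_NAMES <- c("normnC", "normnH", "normnN", "normnO", "normnS")

#' Descriptor configuration
#'
#' Declares which descriptor blocks are computed and with which parameters.
#' The configuration fully determines the feature-name ordering, so saved
#' models can verify column alignment. With the defaults the total
#' dimension is 20 (AAC) + 400 (DPC) + 8000 (TPC) + 400 (CKSAAGP, 5 groups
#' x gaps 0..15) + 5 (physicochemical) + 5 (atomic) + 1 (length) = 8831.
#'
#' @param blocks Ordered subset of
#'   `c("AAC","DPC","TPC","CKSAAGP","PHYSCHEM","ATOMIC","LENGTH")`.
#' @param cksaagp_grouping Named list partitioning the 20 residues into
#'   groups; see [default_cksaagp_grouping()].
#' @param cksaagp_max_gap Largest gap K; gaps k = 0..K are computed.
#' @param pka_table Ionization constants; see [default_pka_table()].
#' @param gravy_scale Per-residue scale for the GRAVY descriptor: a name in
#'   `c("kyte_doolittle","eisenberg")` or a named numeric vector over the 20
#'   residues.
#' @param hydrophobicity_scale Scale for the separate hydrophobicity
#'   descriptor (default Eisenberg consensus).
#' @param net_charge_ph pH at which the net-charge descriptor is evaluated
#'   (default 7.0, physiological).
#' @param normalization `"length"` divides every composition count by the
#'   chain length L; `"windows"` divides by the number of windows instead.
#' @return A `cpp_descriptor_config` object carrying the resolved parameters
#'   and the full ordered feature-name vector.
#' @export
descriptor_config <- function(blocks = c("AAC", "DPC", "TPC", "CKSAAGP",
                                         "PHYSCHEM", "ATOMIC", "LENGTH"),
                              cksaagp_grouping = default_cksaagp_grouping(),
                              cksaagp_max_gap = 15L,
                              pka_table = default_pka_table(),
                              gravy_scale = "kyte_doolittle",
                              hydrophobicity_scale = "eisenberg",
                              net_charge_ph = 7.0,
                              normalization = c("length", "windows")) {
  normalization <- match.arg(normalization)
  known <- c("AAC", "DPC", "TPC", "CKSAAGP", "PHYSCHEM", "ATOMIC", "LENGTH")
  blocks <- as.character(blocks)
  if (!length(blocks) || !all(blocks %in% known) || anyDuplicated(blocks)) {
    cpp_stop("`blocks` must be a non-empty subset (no repeats) of the known blocks",
             "config")
  }
  resolved <- sort(unlist(cksaagp_grouping, use.names = FALSE))
  if (!identical(resolved, AA_ALPHABET)) {
    cpp_stop("`cksaagp_grouping` must partition the 20 canonical residues",
             "config")
  }
  cksaagp_max_gap <- as.integer(cksaagp_max_gap)
  if (cksaagp_max_gap < 0L) cpp_stop("`cksaagp_max_gap` must be >= 0", "config")
  pk <- unlist(pka_table)
  if (any(pk <= 0) || any(pk >= 14)) {
    cpp_stop("all pKa values must lie in (0, 14)", "config")
  }
  gravy_scale <- resolve_scale(gravy_scale)
  hydrophobicity_scale <- resolve_scale(hydrophobicity_scale)
  if (net_charge_ph < 0 || net_charge_ph > 14) {
    cpp_stop("`net_charge_ph` must lie in [0, 14]", "config")
  }

  names_by_block <- list(
    AAC      = kmer_feature_names(1L, "AAC"),
    DPC      = kmer_feature_names(2L, "DPC"),
    TPC      = kmer_feature_names(3L, "TPC"),
    CKSAAGP  = cksaagp_feature_names(cksaagp_grouping, cksaagp_max_gap),
    PHYSCHEM = PHYSCHEM_NAMES,
    ATOMIC   = ATOMIC_NAMES,
    LENGTH   = "length"
  )
  cfg <- structure(list(
    blocks = blocks,
    cksaagp_grouping = cksaagp_grouping,
    cksaagp_max_gap = cksaagp_max_gap,
    pka_table = pka_table,
    gravy_scale = gravy_scale,
    hydrophobicity_scale = hydrophobicity_scale,
    net_charge_ph = net_charge_ph,
    normalization = normalization,
    feature_names = unlist(names_by_block[blocks], use.names = FALSE),
    names_by_block = names_by_block[blocks]
  ), class = "cpp_descriptor_config")
  cfg
}

resolve_scale <- function(scale) {
  if (is.character(scale) && length(scale) == 1L) {
    if (!scale %in% names(AA_SCALES)) {
      cpp_stop(sprintf("unknown scale %s", sQuote(scale)), "config")
    }
    return(AA_SCALES[[scale]])
  }
  if (!is.numeric(scale) || !all(AA_ALPHABET %in% names(scale))) {
    cpp_stop("a scale must name a value for all 20 residues", "config")
  }
  scale[AA_ALPHABET]
}

#' @export
print.cpp_descriptor_config <- function(x, ...) {
  cat(sprintf("<cpp_descriptor_config> blocks: %s | dimension: %d\n",
              paste(x$blocks, collapse = "+"), length(x$feature_names)))
  invisible(x)
}
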