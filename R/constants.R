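# Amino-acid reference tables. All tables are keyed by the 20 canonical
# one-letter codes in lexicographic order; every exported computation that
# iterates over residues relies on this ordering being stable.

#' The 20 canonical amino acids
#'
#' One-letter codes of the proteinogenic amino acids, in lexicographic order.
#' This ordering defines the column order of all composition blocks.
#'
#' @export
AA_ALPHABET <- c("A", "C", "D", "E", "F", "G", "H", "I", "K", "L",
                 "M", "N", "P", "Q", "R", "S", "T", "V", "W", "Y")

# Kyte-Doolittle hydropathy (GRAVY is its sequence mean).
KYTE_DOOLITTLE <- c(
  A =  1.8, C =  2.5, D = -3.5, E = -3.5, F =  2.8,
  G = -0.4, H = -3.2, I =  4.5, K = -3.9, L =  3.8,
  M =  1.9, N = -3.5, P = -1.6, Q = -3.5, R = -4.5,
  S = -0.8, T = -0.7, V =  4.2, W = -0.9, Y = -1.3
)

# Eisenberg consensus hydrophobicity, the default for the "hydrophobicity"
# descriptor (kept distinct from GRAVY).
EISENBERG <- c(
  A =  0.62, C =  0.29, D = -0.90, E = -0.74, F =  1.19,
  G =  0.48, H = -0.40, I =  1.38, K = -1.50, L =  1.06,
  M =  0.64, N = -0.78, P =  0.12, Q = -0.85, R = -2.53,
  S = -0.18, T = -0.05, V =  1.08, W =  0.81, Y =  0.26
)

#' Named per-residue scales shipped with the package
#' @keywords internal
AA_SCALES <- list(
  kyte_doolittle = KYTE_DOOLITTLE,
  eisenberg      = EISENBERG
)

# Average residue masses (Da): free amino-acid average mass minus one water.
# Peptide mass = sum of residue masses + 18.01524 (one water per chain).
AA_RESIDUE_MASS <- c(
  A =  71.0788, C = 103.1388, D = 115.0886, E = 129.1155, F = 147.1766,
  G =  57.0519, H = 137.1411, I = 113.1594, K = 128.1741, L = 113.1594,
  M = 131.1926, N = 114.1038, P =  97.1167, Q = 128.1307, R = 156.1875,
  S =  87.0782, T = 101.1051, V =  99.1326, W = 186.2132, Y = 163.1760
)

WATER_MASS <- 18.01524

# Elemental formulas of the free amino acids (C, H, N, O, S). Residue
# formula within a chain = free formula - H2O; the whole-molecule formula
# adds one water back.
AA_FORMULA <- matrix(
  c(
    # C   H   N   O   S
      3,  7,  1,  2,  0,   # A
      3,  7,  1,  2,  1,   # C
      4,  7,  1,  4,  0,   # D
      5,  9,  1,  4,  0,   # E
      9, 11,  1,  2,  0,   # F
      2,  5,  1,  2,  0,   # G
      6,  9,  3,  2,  0,   # H
      6, 13,  1,  2,  0,   # I
      6, 14,  2,  2,  0,   # K
      6, 13,  1,  2,  0,   # L
      5, 11,  1,  2,  1,   # M
      4,  8,  2,  3,  0,   # N
      5,  9,  1,  2,  0,   # P
      5, 10,  2,  3,  0,   # Q
      6, 14,  4,  2,  0,   # R
      3,  7,  1,  3,  0,   # S
      4,  9,  1,  3,  0,   # T
      5, 11,  1,  2,  0,   # V
     11, 12,  2,  2,  0,   # W
      9, 11,  1,  3,  0    # Y
  ),
  nrow = 20, byrow = TRUE,
  dimnames = list(AA_ALPHABET, c("C", "H", "N", "O", "S"))
)

WATER_FORMULA <- c(C = 0, H = 2, N = 0, O = 1, S = 0)

#' Default pKa table for net-charge and isoelectric-point calculations
#'
#' Ionization constants for the peptide termini and the ionizable side
#' chains, following a widely used sequence-analysis default. Basic groups:
#' N-terminus and the side chains of K, R, H; acidic groups: C-terminus and
#' the side chains of D, E, C, Y.
#'
#' @return A list with elements `n_term`, `c_term`, `basic` (named vector for
#'   K, R, H) and `acidic` (named vector for D, E, C, Y).
#' @export
default_pka_table <- function() {
  list(
    n_term = 8.6,
    c_term = 3.6,
    basic  = c(K = 10.8, R = 12.5, H = 6.5),
    acidic = c(D = 3.9, E = 4.1, C = 8.5, Y = 10.1)
  )
}

#' Default residue grouping for k-spaced amino-acid group pairs
#'
#' Partition of the 20 residues into five physicochemical groups: aliphatic
#' (ALI), aromatic (ARO), positively charged (PC), negatively charged (NC)
#' and polar non-charged (PNC).
#'
#' @return Named list of character vectors forming a partition of
#'   [AA_ALPHABET].
#' @export
default_cksaagp_grouping <- function() {
  list(
    ALI = c("G", "A", "V", "L", "M", "I"),
    ARO = c("F", "Y", "W"),
    PC  = c("K", "R", "H"),
    NC  = c("D", "E"),
    PNC = c("S", "T", "C", "P", "N", "Q")
  )
}

# classed conditions -------------------------------------------------------

cpp_stop <- function(msg, class, call. = FALSE, ...) {
  stop(errorCondition(msg, ..., class = c(paste0("cpptools_error_", class),
                                          "cpptools_error", "error", "condition")))
}

cpp_warn <- function(msg, class) {
  warning(warningCondition(msg, class = c(paste0("cpptools_warning_", class),
                                          "cpptools_warning", "warning", "condition")))
}
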