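# Residue-level reference tables. All tables are keyed by the 20 canonical
# one-letter amino-acid codes; everything downstream refuses other letters.

#' The 20 canonical amino-acid one-letter codes
#' @format Character vector of length 20.
#' @export
AA_ALPHABET <- c("A", "R", "N", "D", "C", "Q", "E", "G", "H", "I",
                 "L", "K", "M", "F", "P", "S", "T", "V", "W", "Y")

#' Kyte-Doolittle hydropathy scale
#'
#' Per-residue hydropathy values (Kyte & Doolittle 1982). Positive values are
#' hydrophobic; the mean over a sequence is the H_Y statistic used throughout
#' the package, and windowed means drive the fallback TM caller.
#' @format Named numeric vector over the 20 canonical residues.
#' @export
KD_HYDROPATHY <- c(
  A =  1.8, R = -4.5, N = -3.5, D = -3.5, C =  2.5,
  Q = -3.5, E = -3.5, G = -0.4, H = -3.2, I =  4.5,
  L =  3.8, K = -3.9, M =  1.9, F =  2.8, P = -1.6,
  S = -0.8, T = -0.7, V =  4.2, W = -0.9, Y = -1.3
)

#' Average residue masses (Da)
#'
#' Average-isotopic masses of amino-acid residues (i.e. minus one water);
#' molecular weight of a chain is the residue-mass sum plus one water.
#' @format Named numeric vector, Daltons.
#' @export
AA_AVG_MASS <- c(
  G =  57.0519, A =  71.0788, S =  87.0782, P =  97.1167, V =  99.1326,
  T = 101.1051, C = 103.1388, L = 113.1594, I = 113.1594, N = 114.1038,
  D = 115.0886, Q = 128.1307, K = 128.1741, E = 129.1155, M = 131.1926,
  H = 137.1411, F = 147.1766, R = 156.1875, Y = 163.1760, W = 186.2132
)

# mass of one water molecule, Da
WATER_MASS <- 18.01524

#' Chou-Fasman alpha-helix propensities
#'
#' Classical P-alpha conformational propensities; > 1 marks helix formers,
#' Gly/Pro (0.57) are the canonical breakers. Used by the helix-retention
#' filter of the library designer.
#' @format Named numeric vector over the 20 canonical residues.
#' @export
CHOU_FASMAN_HELIX <- c(
  A = 1.42, R = 0.98, N = 0.67, D = 1.01, C = 0.70,
  Q = 1.11, E = 1.51, G = 0.57, H = 1.00, I = 1.08,
  L = 1.21, K = 1.16, M = 1.45, F = 1.13, P = 0.57,
  S = 0.77, T = 0.83, V = 1.06, W = 1.08, Y = 0.69
)

# Bjellqvist/ExPASy pKa set used by the default pI calculation.
# N-/C-terminal pKa values are residue-specific where the set defines them.
PKA_BJELLQVIST <- list(
  side_pos = c(H = 5.98, K = 10.00, R = 12.00),
  side_neg = c(D = 4.05, E = 4.45, C = 9.00, Y = 10.00),
  nterm_default = 7.50,
  nterm = c(A = 7.59, M = 7.00, S = 6.93, P = 8.36, T = 6.82, V = 7.44, E = 7.70),
  cterm_default = 3.55,
  cterm = c(D = 4.55, E = 4.75)
)

# Default Tm-index weight matrix: indicator weights for the IVYWREL residue
# set, whose compositional fraction is a published sequence-level correlate of
# thermostability. Pluggable: any complete named numeric vector may be passed.
TM_INDEX_IVYWREL <- {
  w <- setNames(numeric(20), AA_ALPHABET)
  w[c("I", "V", "Y", "W", "R", "E", "L")] <- 1
  w
}
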