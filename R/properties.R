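# Sequence-based physicochemical profiling: MW, pI, hydropathy H_Y,
# helix ratio R_H, and a pluggable sequence-composition Tm index.

#' Molecular weight of a protein sequence (kDa)
#'
#' Sum of average-isotopic residue masses plus one water, divided by 1000.
#' Display rounding (2 decimals) is left to the report layer.
#'
#' @param sequence Sequence string or `qty_record`.
#' @return Numeric, kilodaltons.
#' @export
molecular_weight <- function(sequence) {
  s <- as_sequence(sequence)
  (sum(AA_AVG_MASS[seq_chars(s)]) + WATER_MASS) / 1000
}

#' Net charge of a protein at given pH
#'
#' Henderson-Hasselbalch net charge over the ionizable groups (side chains of
#' D, E, C, Y, H, K, R plus the termini), vectorized over `pH`.
#'
#' @param sequence Sequence string or `qty_record`.
#' @param pH Numeric vector of pH values.
#' @param pka pKa set (defaults to the Bjellqvist/ExPASy set).
#' @return Numeric vector of net charges.
#' @export
net_charge <- function(sequence, pH, pka = PKA_BJELLQVIST) {
  s <- seq_chars(as_sequence(sequence))
  counts <- table(factor(s, levels = AA_ALPHABET))
  # (pKa, count, sign) triples for every ionizable group present
  pos_pka <- c(unname(pka$nterm[s[1]]) %||% NA_real_)
  pos_pka <- c(if (is.na(pos_pka)) pka$nterm_default else pos_pka)
  pos_n <- 1
  for (r in names(pka$side_pos)) {
    if (counts[[r]] > 0) { pos_pka <- c(pos_pka, pka$side_pos[[r]]); pos_n <- c(pos_n, counts[[r]]) }
  }
  last <- s[length(s)]
  ct <- pka$cterm[last]
  neg_pka <- if (is.na(ct) || is.null(ct) || length(ct) == 0) pka$cterm_default else unname(ct)
  neg_n <- 1
  for (r in names(pka$side_neg)) {
    if (counts[[r]] > 0) { neg_pka <- c(neg_pka, pka$side_neg[[r]]); neg_n <- c(neg_n, counts[[r]]) }
  }
  vapply(pH, function(p) {
    sum(pos_n / (1 + 10^(p - pos_pka))) - sum(neg_n / (1 + 10^(neg_pka - p)))
  }, numeric(1))
}

#' Isoelectric point by bisection
#'
#' Finds the pH where [net_charge()] crosses zero by bisection on (0, 14);
#' the charge function is strictly decreasing in pH, so the root is unique.
#'
#' @inheritParams net_charge
#' @param tol Bisection tolerance in pH units.
#' @return Numeric pH.
#' @export
isoelectric_point <- function(sequence, pka = PKA_BJELLQVIST, tol = 0.001) {
  s <- as_sequence(sequence)
  lo <- 0; hi <- 14
  while (hi - lo > tol) {
    mid <- (lo + hi) / 2
    if (net_charge(s, mid, pka) > 0) lo <- mid else hi <- mid
  }
  (lo + hi) / 2
}

#' Mean hydropathy H_Y
#'
#' Arithmetic mean of per-residue hydropathy values over the whole sequence
#' (Kyte-Doolittle scale by default). Negative values indicate predicted
#' water solubility.
#'
#' @param sequence Sequence string or `qty_record`.
#' @param scale Named per-residue numeric table.
#' @return Numeric.
#' @export
hydropathy <- function(sequence, scale = KD_HYDROPATHY) {
  s <- seq_chars(as_sequence(sequence))
  missing <- setdiff(unique(s), names(scale))
  if (length(missing) > 0L)
    qty_stop(sprintf("residue(s) missing from hydropathy scale: %s",
                     paste(missing, collapse = ", ")), "qty_table_error")
  mean(scale[s])
}

#' Helix ratio R_H of an SS3 string
#'
#' Fraction of residues in helical state: count of `H` divided by length.
#'
#' @param ss3 SS3 string.
#' @return Numeric in `[0, 1]`.
#' @export
helix_ratio <- function(ss3) {
  s <- seq_chars(validate_ss3(ss3))
  mean(s == "H")
}

#' Sequence-composition Tm index
#'
#' Composition-weighted mean score: mean of `weights[residue]` over the
#' sequence. The default weight matrix scores the IVYWREL residue fraction, a
#' sequence-level thermostability correlate; any complete per-residue weight
#' vector may be substituted (the index is a qualitative, pluggable hook).
#'
#' @param sequence Sequence string or `qty_record`.
#' @param weights Named numeric vector of per-residue weights.
#' @return Numeric.
#' @export
tm_index <- function(sequence, weights = TM_INDEX_IVYWREL) {
  s <- seq_chars(as_sequence(sequence))
  missing <- setdiff(unique(s), names(weights))
  if (length(missing) > 0L)
    qty_stop(sprintf("residue(s) missing from Tm weight matrix: %s",
                     paste(missing, collapse = ", ")), "qty_table_error")
  mean(weights[s])
}

#' Full property profile of a sequence
#'
#' @param sequence Sequence string or `qty_record`.
#' @param ss3 Optional SS3 string for the helix ratio; when absent, `rh` is
#'   `NA`.
#' @param scale Hydropathy scale.
#' @param pka pKa set for the pI.
#' @param tm_weights Weight matrix for the Tm index.
#' @return A list of class `qty_profile` with `mw_kda`, `pi`, `hy`, `rh`,
#'   `tm_index`.
#' @export
property_profile <- function(sequence, ss3 = NULL, scale = KD_HYDROPATHY,
                             pka = PKA_BJELLQVIST, tm_weights = TM_INDEX_IVYWREL) {
  s <- as_sequence(sequence)
  structure(list(
    mw_kda = molecular_weight(s),
    pi = isoelectric_point(s, pka),
    hy = hydropathy(s, scale),
    rh = if (is.null(ss3)) NA_real_ else helix_ratio(validate_ss3(ss3, nchar(s))),
    tm_index = tm_index(s, tm_weights)
  ), class = "qty_profile")
}

#' @export
print.qty_profile <- function(x, ...) {
  cat(sprintf("<qty_profile> MW %.2f kDa | pI %.2f | H_Y %.4f | R_H %s | Tm index %.4f\n",
              x$mw_kda, x$pi, x$hy,
              if (is.na(x$rh)) "NA" else sprintf("%.4f", x$rh), x$tm_index))
  invisible(x)
}
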