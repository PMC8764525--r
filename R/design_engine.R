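# The QTY/NTY substitution itself, WT/variant diffing, and the change
# metrics R_ACT (fraction of TM residues changed) and R_SC (fraction of
# positions whose secondary-structure state changes).

#' Construct a substitution code
#'
#' A residue-to-residue mapping applied inside TM segments. Keys and values
#' must be canonical residues, no key may map to itself, and no value may
#' itself be a key -- this guarantees that applying the code twice equals
#' applying it once.
#'
#' @param mapping Named character vector, e.g. `c(L = "Q", I = "T")`.
#' @param name Code name.
#' @return Object of class `qty_code`.
#' @export
substitution_code <- function(mapping, name = "custom") {
  keys <- names(mapping); vals <- unname(mapping)
  if (is.null(keys) || any(!nzchar(keys)))
    qty_stop("substitution mapping must be a named character vector", "qty_code_error")
  if (!all(keys %in% AA_ALPHABET) || !all(vals %in% AA_ALPHABET))
    qty_stop("substitution code uses non-canonical residues", "qty_code_error")
  if (any(keys == vals))
    qty_stop("substitution code maps a residue to itself", "qty_code_error")
  if (any(vals %in% keys))
    qty_stop("substitution code value is also a key (code not idempotent)",
             "qty_code_error")
  if (anyDuplicated(keys))
    qty_stop("duplicate keys in substitution code", "qty_code_error")
  structure(list(mapping = setNames(vals, keys), name = name),
            class = "qty_code")
}

#' The QTY code: L->Q, I->T, V->T, F->Y
#' @return A `qty_code`.
#' @export
qty_code <- function() {
  substitution_code(c(L = "Q", I = "T", V = "T", F = "Y"), name = "QTY")
}

#' The NTY code: like QTY but N replaces L
#' @return A `qty_code`.
#' @export
nty_code <- function() {
  substitution_code(c(L = "N", I = "T", V = "T", F = "Y"), name = "NTY")
}

#' @export
print.qty_code <- function(x, ...) {
  cat(sprintf("<qty_code> %s: %s\n", x$name,
              paste(sprintf("%s->%s", names(x$mapping), x$mapping), collapse = ", ")))
  invisible(x)
}

#' Apply a substitution code inside TM segments
#'
#' Every residue at an in-segment position whose letter is a code key (and,
#' if `mask` is given, whose position is in `mask`) is replaced by the coded
#' residue; all other positions are untouched. Length is always preserved.
#'
#' @param record `qty_record` or sequence string.
#' @param topology `qty_topology` valid for the record.
#' @param code `qty_code`; default [qty_code()].
#' @param mask Optional integer vector of positions to restrict the
#'   substitution to; every mask position must lie inside a segment.
#' @return Object of class `qty_design`: `wt_sequence`, `mt_sequence`,
#'   `topology`, `changed_positions` (sorted, 1-based),
#'   `per_segment_changes` (named by segment label), `code_name`, `masked`.
#' @export
qty_substitute <- function(record, topology, code = qty_code(), mask = NULL) {
  wt <- as_sequence(record)
  n <- nchar(wt)
  if (!is.na(attr(topology, "seq_len")) && attr(topology, "seq_len") != n)
    qty_stop("topology was built for a different sequence length", "qty_topology_error")
  if (nrow(topology) > 0L && max(topology$end) > n)
    qty_stop("topology extends beyond the sequence", "qty_topology_error")
  inside <- topology_mask(topology, n)
  if (!is.null(mask)) {
    mask <- as.integer(mask)
    if (any(mask < 1L | mask > n) || any(!inside[mask]))
      qty_stop("mask position outside all TM segments", "qty_mask_error")
  }
  chars <- seq_chars(wt)
  eligible <- inside & chars %in% names(code$mapping)
  if (!is.null(mask)) eligible <- eligible & seq_len(n) %in% mask
  changed <- which(eligible)
  mt <- chars
  mt[changed] <- unname(code$mapping[chars[changed]])
  per_seg <- vapply(seq_len(nrow(topology)), function(i) {
    sum(changed >= topology$start[i] & changed <= topology$end[i])
  }, 0L)
  names(per_seg) <- topology$label
  structure(list(
    wt_sequence = wt,
    mt_sequence = paste(mt, collapse = ""),
    topology = topology,
    changed_positions = changed,
    per_segment_changes = per_seg,
    code_name = code$name,
    code = code,
    masked = !is.null(mask)
  ), class = "qty_design")
}

#' @export
print.qty_design <- function(x, ...) {
  cat(sprintf("<qty_design> %s code, %d/%d residues changed in %d TM segment(s)%s\n",
              x$code_name, length(x$changed_positions), nchar(x$wt_sequence),
              nrow(x$topology), if (x$masked) " (masked design)" else ""))
  invisible(x)
}

#' R_ACT: changed-residue fraction of the TM regions
#'
#' Number of changeable residues actually changed by the full (unmasked)
#' design divided by the summed length of all TM segments. For a masked
#' design, R_ACT is recomputed from the full substitution so its meaning
#' ("changeable residues") stays fixed; see [realized_change_rate()] for the
#' rate the masked design achieved.
#'
#' @param design A `qty_design`.
#' @return Numeric in `[0, 1]`.
#' @export
r_act <- function(design) {
  tot <- total_tm_length(design$topology)
  if (tot == 0L)
    qty_stop("R_ACT undefined for an empty topology", "qty_topology_error")
  n_changed <- if (design$masked) {
    length(qty_substitute(design$wt_sequence, design$topology,
                          design$code)$changed_positions)
  } else {
    length(design$changed_positions)
  }
  n_changed / tot
}

#' Realized change rate of a (possibly masked) design
#' @param design A `qty_design`.
#' @return `|changed positions| / total TM length`.
#' @export
realized_change_rate <- function(design) {
  tot <- total_tm_length(design$topology)
  if (tot == 0L)
    qty_stop("change rate undefined for an empty topology", "qty_topology_error")
  length(design$changed_positions) / tot
}

#' R_SC: secondary-structure change fraction
#'
#' Hamming distance between the WT and variant SS3 strings divided by the
#' protein length.
#'
#' @param ss3_wt,ss3_mt SS3 strings of equal length.
#' @return Numeric in `[0, 1]`.
#' @export
r_sc <- function(ss3_wt, ss3_mt) {
  a <- validate_ss3(ss3_wt); b <- validate_ss3(ss3_mt)
  if (nchar(a) != nchar(b))
    qty_stop("SS3 strings differ in length", "qty_input_error")
  mean(seq_chars(a) != seq_chars(b))
}

#' Per-position diff of a design
#'
#' Gapless columnar alignment of WT vs variant.
#'
#' @param design A `qty_design`.
#' @return Data frame with columns `position`, `wt`, `mt`, `changed`,
#'   `in_tm`.
#' @export
diff_alignment <- function(design) {
  n <- nchar(design$wt_sequence)
  wt <- seq_chars(design$wt_sequence)
  mt <- seq_chars(design$mt_sequence)
  data.frame(
    position = seq_len(n),
    wt = wt,
    mt = mt,
    changed = wt != mt,
    in_tm = topology_mask(design$topology, n),
    stringsAsFactors = FALSE
  )
}

#' Restrict a topology to user-selected fragments
#'
#' Segments are clipped to the union of the given fragments: segments fully
#' outside are dropped, partial overlaps are trimmed to the intersection.
#' Supports partial-region designs where only selected parts of a protein
#' are substituted.
#'
#' @param topology A `qty_topology`.
#' @param fragments List of `c(start, end)` pairs (1-based inclusive).
#' @return A `qty_topology` (relabeled `TM1..` in order).
#' @export
restrict_topology <- function(topology, fragments) {
  frs <- lapply(fragments, function(f) {
    f <- as.integer(f)
    if (length(f) != 2L || any(is.na(f)) || f[1] > f[2] || f[1] < 1L)
      qty_stop("malformed fragment range", "qty_topology_error")
    f
  })
  starts <- integer(0); ends <- integer(0)
  for (i in seq_len(nrow(topology))) {
    for (f in frs) {
      s <- max(topology$start[i], f[1]); e <- min(topology$end[i], f[2])
      if (s <= e) { starts <- c(starts, s); ends <- c(ends, e) }
    }
  }
  # merge any duplicate/adjacent clips arising from overlapping fragments
  if (length(starts) > 1L) {
    ord <- order(starts, ends)
    starts <- starts[ord]; ends <- ends[ord]
    ks <- starts[1]; ke <- ends[1]; ms <- integer(0); me <- integer(0)
    for (j in 2:length(starts)) {
      if (starts[j] <= ke + 1L) { ke <- max(ke, ends[j]) }
      else { ms <- c(ms, ks); me <- c(me, ke); ks <- starts[j]; ke <- ends[j] }
    }
    starts <- c(ms, ks); ends <- c(me, ke)
  }
  sl <- attr(topology, "seq_len")
  tm_topology(starts, ends, seq_len = if (is.na(sl)) NULL else sl)
}
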