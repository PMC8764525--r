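# Pluggable TM-region and secondary-structure prediction: parsers for
# external predictor outputs plus simple built-in fallbacks (hydropathy-plot
# TM caller, Chou-Fasman helix propensity) so the toolkit runs offline.

#' Fallback predictor configuration
#'
#' Parameters of the hydropathy-window TM caller and the helix-retention
#' filter. Window 19 / cutoff 1.6 / minimum length 18 follow the classical
#' hydropathy-plot convention for membrane-spanning segments.
#'
#' @param window Odd sliding-window width (residues), >= 5.
#' @param tm_threshold Mean-hydropathy cutoff for a window center to count
#'   as membrane-like.
#' @param min_tm_len Minimum called segment length.
#' @param helix_propensity_threshold Minimum mean Chou-Fasman P-alpha for a
#'   segment to pass the helix-retention filter. The default 0.85 sits just
#'   below the mean propensity of a fully QTY-substituted helix (Q/T/T/Y,
#'   0.865) and well above the Gly/Pro breaker level (0.57).
#' @param merge_gap Center-runs separated by fewer than this many
#'   below-threshold centers are merged before extension.
#' @param embed_len Number of serine residues added on each side when testing
#'   an isolated segment for residual TM character.
#' @param trim_threshold Called segments are trimmed inward while their
#'   terminal residue's hydropathy is below this value.
#' @return A list of class `qty_predictor_config`.
#' @export
predictor_config <- function(window = 19L, tm_threshold = 1.6,
                             min_tm_len = 18L,
                             helix_propensity_threshold = 0.85,
                             merge_gap = 3L, embed_len = 10L,
                             trim_threshold = 0) {
  window <- as.integer(window)
  if (window < 5L || window %% 2L == 0L)
    qty_stop("window must be odd and >= 5", "qty_config_error")
  stopifnot(is.finite(tm_threshold), is.finite(helix_propensity_threshold))
  structure(list(window = window, tm_threshold = tm_threshold,
                 min_tm_len = as.integer(min_tm_len),
                 helix_propensity_threshold = helix_propensity_threshold,
                 merge_gap = as.integer(merge_gap),
                 embed_len = as.integer(embed_len),
                 trim_threshold = trim_threshold),
            class = "qty_predictor_config")
}

#' Load a predictor configuration from a YAML file
#' @param path YAML file with any subset of the [predictor_config()] fields.
#' @return A `qty_predictor_config`.
#' @export
read_predictor_config <- function(path) {
  vals <- yaml::read_yaml(path)
  known <- names(formals(predictor_config))
  unknown <- setdiff(names(vals), known)
  if (length(unknown) > 0L)
    qty_stop(sprintf("unknown predictor config field(s): %s",
                     paste(unknown, collapse = ", ")), "qty_config_error")
  do.call(predictor_config, vals)
}

# sliding-window means of per-residue hydropathy; centers are positions
# (k+1)..(n-k) for half-width k
window_means <- function(values, window) {
  n <- length(values)
  cs <- cumsum(c(0, values))
  k <- (window - 1L) %/% 2L
  centers <- (k + 1L):(n - k)
  (cs[centers + k + 1L] - cs[centers - k]) / window
}

#' Fallback TM-segment caller (hydropathy plot)
#'
#' Sliding-window mean hydropathy is computed at each center position;
#' maximal runs of above-threshold centers (runs separated by fewer than
#' `merge_gap` below-threshold centers are merged) are extended to the
#' window edges, trimmed inward while the terminal residue's hydropathy is
#' below `trim_threshold`, and reported as TM segments if at least
#' `min_tm_len` residues long. A simple surrogate for an HMM-based TM
#' predictor, deliberately parameter-transparent.
#'
#' @param sequence Sequence string or `qty_record` (length >= `window`).
#' @param config A `qty_predictor_config`.
#' @return A `qty_topology` (possibly empty).
#' @export
predict_tm_fallback <- function(sequence, config = predictor_config()) {
  s <- as_sequence(sequence)
  n <- nchar(s)
  if (n < config$window)
    qty_stop(sprintf("sequence (%d aa) shorter than window (%d)", n, config$window),
             "qty_input_error")
  kd <- unname(KD_HYDROPATHY[seq_chars(s)])
  predict_tm_kd(kd, n, config)
}

# core caller on a precomputed per-residue hydropathy vector (fast path used
# by the variant generator, which screens hundreds of candidate segments)
predict_tm_kd <- function(kd, n, config) {
  k <- (config$window - 1L) %/% 2L
  wm <- window_means(kd, config$window)
  above <- wm >= config$tm_threshold
  if (!any(above)) return(tm_topology(integer(0), integer(0), seq_len = n))
  r <- rle(above)
  ends <- cumsum(r$lengths); starts <- ends - r$lengths + 1L
  runs <- cbind(starts[r$values], ends[r$values])     # center indices (1-based)
  # merge runs separated by short below-threshold gaps
  if (nrow(runs) > 1L) {
    merged <- runs[1, , drop = FALSE]
    for (i in 2:nrow(runs)) {
      gap <- runs[i, 1] - merged[nrow(merged), 2] - 1L
      if (gap < config$merge_gap) merged[nrow(merged), 2] <- runs[i, 2]
      else merged <- rbind(merged, runs[i, ])
    }
    runs <- merged
  }
  # center index c sits at residue c + k; extend each run by +-k residues
  starts <- pmax(1L, (runs[, 1] + k) - k)
  ends2 <- pmin(n, (runs[, 2] + k) + k)
  # merge extended segments that overlap
  keep_s <- starts[1]; keep_e <- ends2[1]
  out_s <- integer(0); out_e <- integer(0)
  if (length(starts) > 1L) {
    for (i in 2:length(starts)) {
      if (starts[i] <= keep_e) keep_e <- max(keep_e, ends2[i])
      else { out_s <- c(out_s, keep_s); out_e <- c(out_e, keep_e)
             keep_s <- starts[i]; keep_e <- ends2[i] }
    }
  }
  out_s <- c(out_s, keep_s); out_e <- c(out_e, keep_e)
  # trim polar overhangs
  for (i in seq_along(out_s)) {
    while (out_s[i] <= out_e[i] && kd[out_s[i]] < config$trim_threshold)
      out_s[i] <- out_s[i] + 1L
    while (out_e[i] >= out_s[i] && kd[out_e[i]] < config$trim_threshold)
      out_e[i] <- out_e[i] - 1L
  }
  ok <- out_e - out_s + 1L >= config$min_tm_len
  tm_topology(out_s[ok], out_e[ok], seq_len = n)
}

#' Mean alpha-helix propensity of a segment
#'
#' Mean per-residue Chou-Fasman P-alpha value. Stands in for a full
#' secondary-structure predictor when asking whether a modified TM segment
#' can still form a helix.
#'
#' @param segment_sequence Non-empty segment string.
#' @param table Propensity table.
#' @return Numeric.
#' @export
helix_propensity <- function(segment_sequence, table = CHOU_FASMAN_HELIX) {
  s <- seq_chars(as_sequence(segment_sequence))
  missing <- setdiff(unique(s), names(table))
  if (length(missing) > 0L)
    qty_stop(sprintf("residue(s) missing from propensity table: %s",
                     paste(missing, collapse = ", ")), "qty_table_error")
  mean(table[s])
}

#' Is an isolated segment water-soluble?
#'
#' The segment is embedded in `embed_len` serine residues on each side (to
#' avoid window edge effects) and passed to [predict_tm_fallback()]; it is
#' called soluble iff no TM segment is found.
#'
#' @param segment_sequence Segment string.
#' @param config A `qty_predictor_config`.
#' @return Logical scalar.
#' @export
is_soluble_segment <- function(segment_sequence, config = predictor_config()) {
  s <- as_sequence(segment_sequence)
  soluble_chars(seq_chars(s), config)
}

# fast path: segment given as a residue character vector
soluble_chars <- function(chars, config) {
  pad <- rep(KD_HYDROPATHY[["S"]], config$embed_len)
  kd <- c(pad, unname(KD_HYDROPATHY[chars]), pad)
  topo <- predict_tm_kd(kd, length(kd), config)
  nrow(topo) == 0L
}

#' Load an external TM-predictor short-format summary
#'
#' Parses lines of the dialect `TMhelix <start> <end>`.
#'
#' @param path File path.
#' @param seq_len Optional host sequence length for bounds checking.
#' @return A `qty_topology`.
#' @export
load_external_tm <- function(path, seq_len = NULL) {
  lines <- readLines(path, warn = FALSE)
  hits <- grep("TMhelix", lines, value = TRUE, fixed = TRUE)
  if (length(hits) == 0L)
    qty_stop(sprintf("'%s' contains no 'TMhelix' lines (unsupported dialect)", path),
             "qty_io_error")
  coords <- lapply(hits, function(ln) {
    nums <- regmatches(ln, gregexpr("[0-9]+", ln))[[1]]
    if (length(nums) < 2L)
      qty_stop(sprintf("malformed TMhelix line: %s", ln), "qty_io_error")
    as.integer(utils::tail(nums, 2L))
  })
  tm_topology(vapply(coords, `[`, 0L, 1L), vapply(coords, `[`, 0L, 2L),
              seq_len = seq_len)
}

#' Load an external 3-state secondary-structure (SS3) file
#'
#' Plain text holding one H/E/C string, possibly wrapped over several lines,
#' with an optional FASTA-like `>` header.
#'
#' @param path File path.
#' @param sequence Optional sequence (string or `qty_record`) the SS3 length
#'   must match.
#' @return The validated SS3 string.
#' @export
load_external_ss3 <- function(path, sequence = NULL) {
  lines <- readLines(path, warn = FALSE)
  lines <- lines[!startsWith(lines, ">")]
  s <- paste(lines, collapse = "")
  validate_ss3(s, seq_len = if (is.null(sequence)) NULL else nchar(as_sequence(sequence)))
}

#' Fallback SS3 estimate from the TM caller
#'
#' Labels residues inside predicted TM segments `H` and everything else `C`.
#' A coarse stand-in used when no external secondary-structure prediction is
#' supplied; values derived from it are flagged "fallback-estimated" in
#' reports.
#'
#' @param sequence Sequence string or `qty_record`.
#' @param config A `qty_predictor_config`.
#' @return An SS3 string.
#' @export
fallback_ss3 <- function(sequence, config = predictor_config()) {
  s <- as_sequence(sequence)
  topo <- predict_tm_fallback(s, config)
  states <- rep("C", nchar(s))
  if (nrow(topo) > 0L) states[topology_mask(topo, nchar(s))] <- "H"
  paste(states, collapse = "")
}
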