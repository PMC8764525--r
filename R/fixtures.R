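# Synthetic multi-pass membrane-protein generator with ground-truth
# topologies, so every module is testable with no external data. The
# compositions are declared tables chosen to emulate the hydropathy contrast
# of real alpha-helical TM proteins (strongly hydrophobic helix cores,
# polar/charged loops); they make no claim to mimic GPCR statistics.

# default residue distributions
TM_COMPOSITION_DEFAULT <- c(L = 0.20, I = 0.13, V = 0.15, F = 0.12,
                            A = 0.20, G = 0.08, M = 0.07, W = 0.05)
LOOP_COMPOSITION_DEFAULT <- c(S = 0.12, T = 0.10, N = 0.10, Q = 0.10,
                              D = 0.12, E = 0.12, K = 0.12, R = 0.12,
                              G = 0.06, P = 0.04)
# helix ends are drawn from the strong hydrophobics only, so called segment
# boundaries are sharp under the terminal-trim rule
TM_EDGE_RESIDUES <- c("L", "I", "V", "F", "A", "M")

#' Specification of a synthetic k-TM protein
#'
#' @param k_tm Number of TM helices (>= 1).
#' @param tm_len TM helix length (default 21 residues).
#' @param loop_len Loop length between helices (default 12).
#' @param terminal_len N-/C-terminal tail length (default 25).
#' @param seed RNG seed.
#' @param tm_composition Named probability vector over hydrophobic residues.
#' @param loop_composition Named probability vector over polar residues.
#' @return List of class `qty_synthetic_spec`.
#' @export
synthetic_tm_spec <- function(k_tm, tm_len = 21L, loop_len = 12L,
                              terminal_len = 25L, seed = 1L,
                              tm_composition = TM_COMPOSITION_DEFAULT,
                              loop_composition = LOOP_COMPOSITION_DEFAULT) {
  stopifnot(k_tm >= 1L, tm_len >= 1L, loop_len >= 0L, terminal_len >= 0L)
  for (comp in list(tm_composition, loop_composition)) {
    if (abs(sum(comp) - 1) > 1e-6)
      qty_stop("composition table does not sum to 1", "qty_config_error")
    if (!all(names(comp) %in% AA_ALPHABET))
      qty_stop("composition table uses non-canonical residues", "qty_config_error")
  }
  structure(list(k_tm = as.integer(k_tm), tm_len = as.integer(tm_len),
                 loop_len = as.integer(loop_len),
                 terminal_len = as.integer(terminal_len), seed = as.integer(seed),
                 tm_composition = tm_composition,
                 loop_composition = loop_composition),
            class = "qty_synthetic_spec")
}

#' Generate a synthetic TM protein with ground-truth topology
#'
#' Builds `2*terminal_len + k*tm_len + (k-1)*loop_len` residues: k
#' hydrophobic helix blocks separated by polar loops. Each TM block is
#' rejection-sampled until every full hydropathy window inside it clears the
#' fallback caller's threshold (for blocks shorter than the window, the
#' block mean must clear it), so the ground-truth segments are recoverable
#' by construction. Deterministic per seed.
#'
#' @param spec A `qty_synthetic_spec`.
#' @param config `qty_predictor_config` supplying the window/threshold the
#'   hydropathy invariant is checked against.
#' @return List with `record` (`qty_record`) and `topology`
#'   (`qty_topology`, the exact block coordinates).
#' @export
make_synthetic_tm_protein <- function(spec, config = predictor_config()) {
  withr::with_seed(spec$seed, {
    draw <- function(n, comp) {
      if (n == 0L) return(character(0))
      sample(names(comp), n, replace = TRUE, prob = comp)
    }
    tm_block <- function() {
      for (try in 1:1000) {
        block <- draw(spec$tm_len, spec$tm_composition)
        n_edge <- min(2L, spec$tm_len)
        block[seq_len(n_edge)] <- sample(TM_EDGE_RESIDUES, n_edge, replace = TRUE)
        if (spec$tm_len > n_edge)
          block[(spec$tm_len - n_edge + 1L):spec$tm_len] <-
            sample(TM_EDGE_RESIDUES, n_edge, replace = TRUE)
        kd <- unname(KD_HYDROPATHY[block])
        ok <- if (spec$tm_len >= config$window) {
          all(window_means(kd, config$window) >= config$tm_threshold)
        } else {
          mean(kd) >= config$tm_threshold
        }
        if (ok) return(block)
      }
      qty_stop("could not sample a TM block satisfying the hydropathy invariant",
               "qty_config_error")
    }
    pieces <- list(draw(spec$terminal_len, spec$loop_composition))
    starts <- integer(spec$k_tm); ends <- integer(spec$k_tm)
    pos <- spec$terminal_len
    for (i in seq_len(spec$k_tm)) {
      blk <- tm_block()
      starts[i] <- pos + 1L; ends[i] <- pos + spec$tm_len
      pos <- pos + spec$tm_len
      pieces[[length(pieces) + 1L]] <- blk
      if (i < spec$k_tm) {
        pieces[[length(pieces) + 1L]] <- draw(spec$loop_len, spec$loop_composition)
        pos <- pos + spec$loop_len
      }
    }
    pieces[[length(pieces) + 1L]] <- draw(spec$terminal_len, spec$loop_composition)
    sequence <- paste(unlist(pieces), collapse = "")
    list(
      record = protein_record(
        id = sprintf("synTM%d_seed%d", spec$k_tm, spec$seed),
        sequence = sequence,
        description = sprintf("synthetic %d-TM protein", spec$k_tm)),
      topology = tm_topology(starts, ends, seq_len = nchar(sequence))
    )
  })
}

#' Jaccard overlap of two 1-based inclusive ranges
#' @param a,b Length-2 integer vectors `c(start, end)`.
#' @return Intersection length / union length.
#' @export
range_jaccard <- function(a, b) {
  inter <- max(0L, min(a[2], b[2]) - max(a[1], b[1]) + 1L)
  union <- (a[2] - a[1] + 1L) + (b[2] - b[1] + 1L) - inter
  inter / union
}
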