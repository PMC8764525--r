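# Directed combinatorial library construction: fragmentation of the protein
# into alternating NTM/TM pieces, per-TM variant generation under solubility
# and helix-retention filters, balance scoring, assembly bookkeeping, and
# the two TXT library dialects.

#' Partition a protein into alternating NTM/TM fragments
#'
#' For k TM segments the sequence is split into exactly 2k+1 fragments:
#' N-term, TM1, loop, TM2, ..., TMk, C-term, whose concatenation equals the
#' input sequence. Loops alternate intracellular/extracellular labels
#' (ICL1, ECL1, ICL2, ...) following the usual type-I 7-TM convention;
#' boundary fragments of length zero are kept as empty records so the 2k+1
#' count and the partition invariant stay exact.
#'
#' @param record `qty_record` or sequence string.
#' @param topology `qty_topology` with at least one segment.
#' @return Data frame of class `qty_fragments` with columns `kind`
#'   (`"NTM"`/`"TM"`), `label`, `start`, `end`, `sequence` (zero-length
#'   fragments have `start > end` and an empty sequence).
#' @export
fragment_protein <- function(record, topology) {
  s <- as_sequence(record)
  n <- nchar(s)
  if (nrow(topology) == 0L)
    qty_stop("cannot fragment with an empty topology", "qty_topology_error")
  if (max(topology$end) > n)
    qty_stop("topology extends beyond the sequence", "qty_topology_error")
  k <- nrow(topology)
  loop_labels <- if (k > 1L) {
    paste0(ifelse(seq_len(k - 1L) %% 2L == 1L, "ICL", "ECL"),
           (seq_len(k - 1L) + 1L) %/% 2L)
  } else character(0)
  kinds <- character(0); labels <- character(0)
  starts <- integer(0); ends <- integer(0)
  add <- function(kind, label, a, b) {
    kinds <<- c(kinds, kind); labels <<- c(labels, label)
    starts <<- c(starts, a); ends <<- c(ends, b)
  }
  add("NTM", "N-term", 1L, topology$start[1] - 1L)
  for (i in seq_len(k)) {
    add("TM", topology$label[i], topology$start[i], topology$end[i])
    if (i < k) add("NTM", loop_labels[i], topology$end[i] + 1L, topology$start[i + 1L] - 1L)
  }
  add("NTM", "C-term", topology$end[k] + 1L, n)
  seqs <- vapply(seq_along(starts), function(i) {
    if (starts[i] > ends[i]) "" else substr(s, starts[i], ends[i])
  }, "")
  structure(
    data.frame(kind = kinds, label = labels, start = starts, end = ends,
               sequence = seqs, stringsAsFactors = FALSE),
    class = c("qty_fragments", "data.frame"),
    seq_len = n
  )
}

#' Score the solubility / integrity balance of a TM variant
#'
#' The composite score trades the hydropathy drop achieved (normalized by
#' the drop of the full substitution, so the full variant scores 1 on that
#' axis) against the fraction of changeable residues actually changed:
#' `composite = w_s * delta_hy/delta_hy_full + w_f * (1 - change_fraction)`.
#' Defaults `w_s = w_f = 0.5`. A declared surrogate for an unspecified
#' balance score; its exact values carry no claim beyond this definition.
#'
#' @param wt_tm WT TM fragment sequence.
#' @param variant Variant sequence of equal length.
#' @param code `qty_code` defining the full substitution used for
#'   normalization.
#' @param config A `qty_predictor_config` (helix filter threshold).
#' @param w_s,w_f Weights of the solubility and integrity terms.
#' @return List of class `qty_variant_score`: `n_changes`,
#'   `change_fraction`, `delta_hy`, `helix_propensity`,
#'   `passes_solubility`, `passes_helix`, `composite`.
#' @export
score_variant <- function(wt_tm, variant, code = qty_code(),
                          config = predictor_config(),
                          w_s = 0.5, w_f = 0.5) {
  wt <- as_sequence(wt_tm); mt <- as_sequence(variant)
  if (nchar(wt) != nchar(mt))
    qty_stop("variant length differs from WT fragment", "qty_input_error")
  wt_ch <- seq_chars(wt); mt_ch <- seq_chars(mt)
  changeable <- which(wt_ch %in% names(code$mapping))
  n_changes <- sum(wt_ch != mt_ch)
  change_fraction <- if (length(changeable) > 0L) n_changes / length(changeable) else 0
  full <- qty_substitute(wt, tm_topology(1L, nchar(wt)), code)$mt_sequence
  dhy <- hydropathy(wt) - hydropathy(mt)
  dhy_full <- hydropathy(wt) - hydropathy(full)
  norm_dhy <- if (dhy_full > 0) dhy / dhy_full else 0
  structure(list(
    n_changes = n_changes,
    change_fraction = change_fraction,
    delta_hy = dhy,
    helix_propensity = helix_propensity(mt),
    passes_solubility = is_soluble_segment(mt, config),
    passes_helix = helix_propensity(mt) >= config$helix_propensity_threshold,
    composite = w_s * norm_dhy + w_f * (1 - change_fraction)
  ), class = "qty_variant_score")
}

#' Generate filtered, scored variants of one TM fragment
#'
#' Candidate substitution masks are random subsets of the changeable
#' positions (`n_samples` draws, deduplicated) plus the full mask. Each
#' candidate must pass both in-silico filters -- no residual TM call
#' ([is_soluble_segment()]) and retained helix propensity -- and survivors
#' are ranked by the composite balance score. The full-substitution variant
#' is force-included (when it passes) as the guaranteed-soluble anchor.
#' Deterministic for a fixed seed.
#'
#' @param tm_fragment WT TM fragment sequence (>= 1 changeable residue).
#' @param code `qty_code`.
#' @param config `qty_predictor_config`.
#' @param n_keep Maximum number of variants returned (default 8 per TM).
#' @param n_samples Number of random masks drawn.
#' @param seed RNG seed.
#' @return Character vector of variant sequences (<= `n_keep`), with a
#'   `scores` attribute (data frame, one row per variant). Throws a
#'   condition of class `qty_design_failure` when no candidate survives
#'   both filters.
#' @export
generate_tm_variants <- function(tm_fragment, code = qty_code(),
                                 config = predictor_config(),
                                 n_keep = 8L, n_samples = 1000L, seed = 1L) {
  wt <- as_sequence(tm_fragment)
  wt_ch <- seq_chars(wt)
  changeable <- which(wt_ch %in% names(code$mapping))
  if (length(changeable) == 0L)
    qty_stop("TM fragment has no changeable residues", "qty_design_failure")
  masks <- withr::with_seed(seed, {
    lapply(seq_len(n_samples), function(i) {
      size <- sample.int(length(changeable), 1L)
      sort(changeable[sample.int(length(changeable), size)])
    })
  })
  masks <- c(masks, list(changeable))              # full mask always a candidate
  keys <- vapply(masks, paste, "", collapse = ",")
  masks <- masks[!duplicated(keys)]
  full_key <- paste(changeable, collapse = ",")
  # scoring inlined on residue vectors: the loop screens hundreds of
  # candidates, so per-candidate string validation would dominate runtime;
  # values are identical to score_variant() (property-tested)
  hy_wt <- mean(KD_HYDROPATHY[wt_ch])
  full_ch <- wt_ch
  full_ch[changeable] <- unname(code$mapping[wt_ch[changeable]])
  dhy_full <- hy_wt - mean(KD_HYDROPATHY[full_ch])
  rows <- lapply(masks, function(mask) {
    mt_ch <- wt_ch
    mt_ch[mask] <- unname(code$mapping[wt_ch[mask]])
    prop <- mean(CHOU_FASMAN_HELIX[mt_ch])
    if (prop < config$helix_propensity_threshold) return(NULL)
    if (!soluble_chars(mt_ch, config)) return(NULL)
    cf <- length(mask) / length(changeable)
    dhy <- hy_wt - mean(KD_HYDROPATHY[mt_ch])
    data.frame(
      variant = paste(mt_ch, collapse = ""),
      key = paste(mask, collapse = ","),
      n_changes = length(mask), change_fraction = cf, delta_hy = dhy,
      helix_propensity = prop,
      composite = 0.5 * (if (dhy_full > 0) dhy / dhy_full else 0) + 0.5 * (1 - cf),
      stringsAsFactors = FALSE)
  })
  rows <- do.call(rbind, rows[!vapply(rows, is.null, TRUE)])
  if (is.null(rows) || nrow(rows) == 0L)
    qty_stop("no variant of this TM fragment passes both in-silico filters",
             "qty_design_failure")
  rows <- rows[order(-rows$composite, rows$n_changes, rows$variant), , drop = FALSE]
  take <- seq_len(min(n_keep, nrow(rows)))
  if (full_key %in% rows$key && !(full_key %in% rows$key[take])) {
    take[length(take)] <- which(rows$key == full_key)  # keep the full-sub anchor
  }
  out <- rows$variant[take]
  attr(out, "scores") <- rows[take, c("n_changes", "change_fraction", "delta_hy",
                                      "helix_propensity", "composite")]
  attr(out, "wt") <- wt
  out
}

#' Assemble a library specification
#'
#' @param fragments A `qty_fragments` partition.
#' @param per_tm_variants Named list: for every TM fragment label, a
#'   non-empty character vector of same-length variant sequences.
#' @param rng_seed Seed recorded for downstream sampling provenance.
#' @return List of class `qty_library`: `fragments`, `variants`,
#'   `combination_count`, `rng_seed`.
#' @export
build_library <- function(fragments, per_tm_variants, rng_seed = NULL) {
  tm_labels <- fragments$label[fragments$kind == "TM"]
  missing <- setdiff(tm_labels, names(per_tm_variants))
  if (length(missing) > 0L)
    qty_stop(sprintf("missing variant list(s) for: %s", paste(missing, collapse = ", ")),
             "qty_library_error")
  for (lab in tm_labels) {
    v <- per_tm_variants[[lab]]
    if (length(v) == 0L)
      qty_stop(sprintf("empty variant list for %s", lab), "qty_library_error")
    wt_len <- nchar(fragments$sequence[fragments$label == lab])
    if (any(nchar(v) != wt_len))
      qty_stop(sprintf("variant of %s differs in length from the WT fragment", lab),
               "qty_library_error")
  }
  structure(list(
    fragments = fragments,
    variants = per_tm_variants[tm_labels],
    combination_count = prod(vapply(per_tm_variants[tm_labels], length, 0L)),
    rng_seed = rng_seed
  ), class = "qty_library")
}

#' @export
print.qty_library <- function(x, ...) {
  cat(sprintf("<qty_library> %d fragments (%d TM), %s combinations\n",
              nrow(x$fragments), length(x$variants),
              format(x$combination_count, big.mark = ",", scientific = FALSE)))
  invisible(x)
}

# assemble one full-length sequence given an index choice per TM
assemble_one <- function(spec, choice) {
  pieces <- character(nrow(spec$fragments))
  for (i in seq_len(nrow(spec$fragments))) {
    fr <- spec$fragments[i, ]
    pieces[i] <- if (fr$kind == "TM") spec$variants[[fr$label]][choice[[fr$label]]]
                 else fr$sequence
  }
  paste(pieces, collapse = "")
}

#' Sample random full-length assemblies from a library
#'
#' Each draw concatenates the invariant NTM fragments with one uniformly
#' chosen variant per TM, in fragment order. Deterministic per seed.
#'
#' @param spec A `qty_library`.
#' @param m Number of assemblies.
#' @param seed RNG seed.
#' @return Character vector of `m` full-length sequences.
#' @export
sample_assemblies <- function(spec, m, seed = 1L) {
  stopifnot(m >= 1)
  labs <- names(spec$variants)
  withr::with_seed(seed, {
    vapply(seq_len(m), function(j) {
      choice <- lapply(spec$variants, function(v) sample.int(length(v), 1L))
      names(choice) <- labs
      assemble_one(spec, choice)
    }, "")
  })
}

#' Enumerate all assemblies of a small library
#'
#' Refuses above `cap` combinations (combinatorial libraries are synthesized
#' wet-lab, not enumerated in silico); use [sample_assemblies()] instead.
#'
#' @param spec A `qty_library`.
#' @param cap Maximum combination count to enumerate.
#' @return Character vector of all `combination_count` sequences.
#' @export
enumerate_assemblies <- function(spec, cap = 10000L) {
  if (spec$combination_count > cap)
    qty_stop(sprintf("library has %s combinations (> cap %d); use sample_assemblies()",
                     format(spec$combination_count, scientific = FALSE), cap),
             "qty_library_error")
  labs <- names(spec$variants)
  grid <- expand.grid(lapply(spec$variants, seq_along), KEEP.OUT.ATTRS = FALSE)
  vapply(seq_len(nrow(grid)), function(i) {
    choice <- as.list(grid[i, , drop = FALSE])
    names(choice) <- labs
    assemble_one(spec, choice)
  }, "")
}

# all library fragment sequences in emission order: NTMs once (in fragment
# order) interleaved with every variant of each TM
library_fragment_table <- function(spec) {
  rows <- list()
  for (i in seq_len(nrow(spec$fragments))) {
    fr <- spec$fragments[i, ]
    if (fr$kind == "TM") {
      v <- spec$variants[[fr$label]]
      rows[[length(rows) + 1L]] <- data.frame(
        label = sprintf("%s_v%d", fr$label, seq_along(v)),
        kind = "TM", sequence = v, stringsAsFactors = FALSE)
    } else {
      rows[[length(rows) + 1L]] <- data.frame(
        label = fr$label, kind = "NTM", sequence = fr$sequence,
        stringsAsFactors = FALSE)
    }
  }
  do.call(rbind, rows)
}

#' Write the two TXT library files plus a JSON manifest
#'
#' Emits `library_multiline.txt` (headed records, sequences wrapped at 60
#' characters), `library_singleline.txt` (one `label<TAB>sequence` line per
#' fragment), and `library_manifest.json` (fragment order, per-TM variant
#' counts, combination count, seed). Optionally appends `emit_sample`
#' sampled full-length assemblies to both TXT files.
#'
#' @param spec A `qty_library`.
#' @param outdir Output directory (created if needed).
#' @param emit_sample Number of sampled full-length assemblies to append.
#' @param seed Seed for the appended sample.
#' @return Named character vector of the three paths, invisibly.
#' @export
write_library_files <- function(spec, outdir, emit_sample = 0L, seed = 1L) {
  dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
  tab <- library_fragment_table(spec)
  if (emit_sample > 0L) {
    samples <- sample_assemblies(spec, emit_sample, seed = seed)
    tab <- rbind(tab, data.frame(label = sprintf("assembly_%d", seq_along(samples)),
                                 kind = "ASSEMBLY", sequence = samples,
                                 stringsAsFactors = FALSE))
  }
  wrap60 <- function(s) {
    if (nchar(s) == 0L) return(character(0))
    substring(s, seq(1L, nchar(s), 60L), pmin(seq(1L, nchar(s), 60L) + 59L, nchar(s)))
  }
  multi <- unlist(lapply(seq_len(nrow(tab)), function(i)
    c(paste0(">", tab$label[i]), wrap60(tab$sequence[i]))))
  single <- paste0(tab$label, "\t", tab$sequence)
  p_multi <- file.path(outdir, "library_multiline.txt")
  p_single <- file.path(outdir, "library_singleline.txt")
  p_manifest <- file.path(outdir, "library_manifest.json")
  writeLines(multi, p_multi)
  writeLines(single, p_single)
  manifest <- list(
    fragment_order = spec$fragments$label,
    fragment_kinds = spec$fragments$kind,
    variant_counts = lapply(spec$variants, length),
    combination_count = spec$combination_count,
    rng_seed = spec$rng_seed,
    emitted_samples = emit_sample
  )
  writeLines(jsonlite::toJSON(manifest, auto_unbox = TRUE, pretty = TRUE,
                              digits = NA), p_manifest)
  invisible(c(multiline = p_multi, singleline = p_single, manifest = p_manifest))
}

#' Re-read a multi-line library file
#' @param path Path to a `library_multiline.txt`-dialect file.
#' @return Data frame with `label`, `sequence`.
#' @export
read_library_multiline <- function(path) {
  lines <- readLines(path, warn = FALSE)
  idx <- grep("^>", lines)
  if (length(idx) == 0L) qty_stop("no records found", "qty_io_error")
  bounds <- c(idx, length(lines) + 1L)
  data.frame(
    label = sub("^>", "", lines[idx]),
    sequence = vapply(seq_along(idx), function(i) {
      lo <- idx[i] + 1L; hi <- bounds[i + 1L] - 1L
      if (lo > hi) "" else paste(lines[lo:hi], collapse = "")
    }, ""),
    stringsAsFactors = FALSE
  )
}
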