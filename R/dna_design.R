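# Reverse translation of designed proteins/fragments and overlap design for
# synthesis-ready DNA fragment sets (overlap-extension PCR style assembly).

#' Load a codon-usage table
#'
#' TSV with columns `aa`, `codon`, `freq`; relative frequencies must sum to
#' 1 (+- 1e-6) within each amino acid and all 20 canonical amino acids must
#' be covered.
#'
#' @param path TSV path; defaults to the bundled E. coli K-12 table.
#' @return Data frame of class `qty_codon_usage`.
#' @export
load_codon_usage <- function(path = NULL) {
  if (is.null(path))
    path <- system.file("extdata", "ecoli_k12_codon_usage.tsv",
                        package = "qtykit", mustWork = TRUE)
  tab <- utils::read.delim(path, stringsAsFactors = FALSE)
  if (!all(c("aa", "codon", "freq") %in% names(tab)))
    qty_stop("codon table needs columns aa, codon, freq", "qty_table_error")
  if (!all(grepl("^[ACGT]{3}$", tab$codon)))
    qty_stop("invalid codon triplet in table", "qty_table_error")
  missing <- setdiff(AA_ALPHABET, unique(tab$aa))
  if (length(missing) > 0L)
    qty_stop(sprintf("codon table misses amino acid(s): %s",
                     paste(missing, collapse = ", ")), "qty_table_error")
  sums <- tapply(tab$freq, tab$aa, sum)
  if (any(abs(sums - 1) > 1e-6))
    qty_stop(sprintf("codon frequencies do not sum to 1 for: %s",
                     paste(names(sums)[abs(sums - 1) > 1e-6], collapse = ", ")),
             "qty_table_error")
  structure(tab, class = c("qty_codon_usage", "data.frame"))
}

#' Reverse translate a protein sequence
#'
#' `most_frequent` mode picks the top codon per amino acid
#' (deterministic); `weighted` mode draws codons by their relative
#' frequency under a fixed seed.
#'
#' @param protein_sequence Sequence string or `qty_record`.
#' @param usage `qty_codon_usage` table.
#' @param mode `"most_frequent"` or `"weighted"`.
#' @param seed Seed for weighted mode.
#' @return DNA string of length `3 * nchar(protein)`.
#' @export
reverse_translate <- function(protein_sequence, usage = load_codon_usage(),
                              mode = c("most_frequent", "weighted"),
                              seed = 1L) {
  mode <- match.arg(mode)
  s <- seq_chars(as_sequence(protein_sequence))
  by_aa <- split(usage[, c("codon", "freq")], usage$aa)
  missing <- setdiff(unique(s), names(by_aa))
  if (length(missing) > 0L)
    qty_stop(sprintf("amino acid(s) absent from codon table: %s",
                     paste(missing, collapse = ", ")), "qty_table_error")
  codons <- if (mode == "most_frequent") {
    top <- vapply(by_aa, function(d) d$codon[which.max(d$freq)], "")
    top[s]
  } else {
    withr::with_seed(seed, vapply(s, function(aa) {
      d <- by_aa[[aa]]
      sample(d$codon, 1L, prob = d$freq)
    }, ""))
  }
  paste(codons, collapse = "")
}

#' Translate a DNA string (standard genetic code)
#' @param dna DNA string over A/C/G/T, length divisible by 3.
#' @return Protein string.
#' @export
translate_dna <- function(dna) {
  if (nchar(dna) %% 3L != 0L)
    qty_stop("DNA length not divisible by 3", "qty_input_error")
  as.character(Biostrings::translate(Biostrings::DNAString(dna),
                                     no.init.codon = TRUE))
}

#' Add assembly overlaps to an ordered set of DNA fragments
#'
#' Two conventions are supported. Default (`kinds = NULL`): each fragment's
#' 3'-overlap is the first `overlap_len` nt of the next fragment's core
#' (5'-overlaps empty); terminal ends get empty overlaps. With `kinds`
#' (`"NTM"`/`"TM"` per fragment): only TM fragments carry overlaps, drawn
#' from both invariant NTM neighbors (5' = suffix of the previous core,
#' 3' = prefix of the next core), so all variants of one TM share identical
#' flanks and the variant DNA pools stay mix-and-match compatible.
#'
#' @param dna_fragments Character vector of core DNA sequences, in order.
#' @param overlap_len Overlap length in nt (default 20, typical for
#'   overlap-extension PCR). Truncated with a warning when a neighbor is
#'   shorter.
#' @param kinds Optional character vector (`"NTM"`/`"TM"`) matching
#'   `dna_fragments`.
#' @param labels Optional fragment labels.
#' @return Data frame of class `qty_dna_fragments`: `label`, `core`,
#'   `overlap5`, `overlap3`.
#' @export
add_overlaps <- function(dna_fragments, overlap_len = 20L, kinds = NULL,
                         labels = NULL) {
  n <- length(dna_fragments)
  if (n < 2L) qty_stop("need at least two fragments", "qty_input_error")
  if (!all(grepl("^[ACGT]*$", dna_fragments)))
    qty_stop("fragments must be A/C/G/T strings", "qty_input_error")
  if (is.null(labels)) labels <- sprintf("frag%d", seq_len(n))
  grab <- function(s, len, from_start) {
    if (nchar(s) < len) {
      warning(sprintf("neighbor shorter than overlap length (%d < %d); overlap truncated",
                      nchar(s), len))
      len <- nchar(s)
    }
    if (len == 0L) return("")
    if (from_start) substr(s, 1L, len) else substr(s, nchar(s) - len + 1L, nchar(s))
  }
  o5 <- character(n); o3 <- character(n)
  if (is.null(kinds)) {
    for (i in seq_len(n - 1L))
      o3[i] <- grab(dna_fragments[i + 1L], overlap_len, TRUE)
  } else {
    stopifnot(length(kinds) == n)
    for (i in which(kinds == "TM")) {
      if (i > 1L) o5[i] <- grab(dna_fragments[i - 1L], overlap_len, FALSE)
      if (i < n) o3[i] <- grab(dna_fragments[i + 1L], overlap_len, TRUE)
    }
  }
  structure(
    data.frame(label = labels, core = dna_fragments,
               overlap5 = o5, overlap3 = o3, stringsAsFactors = FALSE),
    class = c("qty_dna_fragments", "data.frame")
  )
}

#' Verify junctions and assemble a DNA fragment set
#'
#' Checks every declared overlap against the adjacent core (a fragment's
#' 3'-overlap must equal the prefix of the next core; its 5'-overlap the
#' suffix of the previous core) and returns the junction-merged single
#' sequence (the concatenation of cores -- overlaps are junction copies and
#' add no length).
#'
#' @param fragments A `qty_dna_fragments` data frame.
#' @return Assembled DNA string.
#' @export
verify_assembly <- function(fragments) {
  n <- nrow(fragments)
  for (i in seq_len(n)) {
    o3 <- fragments$overlap3[i]
    if (nzchar(o3)) {
      if (i == n)
        qty_stop("last fragment declares a 3'-overlap", "qty_junction_error")
      nxt <- fragments$core[i + 1L]
      if (substr(nxt, 1L, nchar(o3)) != o3)
        qty_stop(sprintf("junction mismatch after fragment %d (%s)",
                         i, fragments$label[i]), "qty_junction_error")
    }
    o5 <- fragments$overlap5[i]
    if (nzchar(o5)) {
      if (i == 1L)
        qty_stop("first fragment declares a 5'-overlap", "qty_junction_error")
      prv <- fragments$core[i - 1L]
      if (substr(prv, nchar(prv) - nchar(o5) + 1L, nchar(prv)) != o5)
        qty_stop(sprintf("junction mismatch before fragment %d (%s)",
                         i, fragments$label[i]), "qty_junction_error")
    }
  }
  paste(fragments$core, collapse = "")
}

#' Design synthesis-ready DNA for a library sample
#'
#' Convenience pipeline: reverse translate each protein fragment of an
#' assembly choice (NTM fragments once, the chosen TM variant per slot),
#' attach TM-side overlaps from the invariant NTM flanks, and verify the
#' assembly translates back to the intended protein.
#'
#' @param spec A `qty_library`.
#' @param choice Named integer vector/list: variant index per TM label
#'   (default 1 for every TM).
#' @param usage Codon-usage table.
#' @param mode,seed Passed to [reverse_translate()].
#' @param overlap_len Overlap length.
#' @return List: `fragments` (`qty_dna_fragments`), `assembled_dna`,
#'   `protein`.
#' @export
design_library_dna <- function(spec, choice = NULL,
                               usage = load_codon_usage(),
                               mode = "most_frequent", seed = 1L,
                               overlap_len = 20L) {
  labs <- names(spec$variants)
  if (is.null(choice)) choice <- setNames(rep(1L, length(labs)), labs)
  prot_frags <- vapply(seq_len(nrow(spec$fragments)), function(i) {
    fr <- spec$fragments[i, ]
    if (fr$kind == "TM") spec$variants[[fr$label]][[choice[[fr$label]]]]
    else fr$sequence
  }, "")
  nonempty <- nzchar(prot_frags)
  dna <- vapply(which(nonempty), function(i)
    reverse_translate(prot_frags[i], usage, mode = mode, seed = seed + i), "")
  frs <- add_overlaps(dna, overlap_len = overlap_len,
                      kinds = spec$fragments$kind[nonempty],
                      labels = spec$fragments$label[nonempty])
  assembled <- verify_assembly(frs)
  protein <- translate_dna(assembled)
  intended <- paste(prot_frags, collapse = "")
  if (protein != intended)
    qty_stop("assembled DNA does not translate to the intended variant",
             "qty_junction_error")
  list(fragments = frs, assembled_dna = assembled, protein = protein)
}
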