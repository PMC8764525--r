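# Sequence / topology data model and readers for the three TM-input modes:
# explicit ranges, SS3 strings, UniProt TRANSMEM feature lines.

MAX_SEQ_LEN <- 8000L

#' Validate and normalize a raw amino-acid sequence
#'
#' Strips whitespace, uppercases, and checks that the result is a non-empty
#' string of at most 8,000 canonical residues. Ambiguity codes (B, J, O, U,
#' X, Z) are rejected: every downstream property table is defined only for
#' the 20 canonical residues.
#'
#' @param raw Character scalar; may contain whitespace/newlines.
#' @return The normalized sequence string.
#' @export
validate_sequence <- function(raw) {
  if (!is.character(raw) || length(raw) != 1L || is.na(raw))
    qty_stop("sequence must be a single character string", "qty_input_error")
  s <- toupper(gsub("[[:space:]]", "", raw))
  if (nchar(s) == 0L)
    qty_stop("sequence is empty", "qty_input_error")
  if (nchar(s) > MAX_SEQ_LEN)
    qty_stop(sprintf("sequence has %d residues; at most %d are supported",
                     nchar(s), MAX_SEQ_LEN), "qty_length_error")
  bad <- setdiff(unique(seq_chars(s)), AA_ALPHABET)
  if (length(bad) > 0L)
    qty_stop(sprintf("non-canonical residue letter(s): %s",
                     paste(bad, collapse = ", ")), "qty_alphabet_error")
  s
}

#' Construct a protein record
#'
#' @param id Short identifier.
#' @param sequence Amino-acid sequence (validated via [validate_sequence()]).
#' @param description Optional free text.
#' @return An object of class `qty_record` with fields `id`, `description`,
#'   `sequence`.
#' @export
protein_record <- function(id, sequence, description = "") {
  stopifnot(is.character(id), length(id) == 1L, nzchar(id))
  structure(
    list(id = id, description = description,
         sequence = validate_sequence(sequence)),
    class = "qty_record"
  )
}

#' @export
print.qty_record <- function(x, ...) {
  cat(sprintf("<qty_record> %s (%d aa)%s\n", x$id, nchar(x$sequence),
              if (nzchar(x$description)) paste0(" - ", x$description) else ""))
  invisible(x)
}

#' Construct a transmembrane topology
#'
#' Segments are 1-based inclusive, sorted by start, non-overlapping, and
#' (when `seq_len` is given) bounded by the host sequence length.
#'
#' @param start,end Integer vectors of equal length.
#' @param seq_len Optional host sequence length for bounds checking.
#' @param labels Optional segment labels; default `TM1..TMk` after sorting.
#' @return A data frame of class `qty_topology` with columns
#'   `start`, `end`, `label` and attribute `seq_len`.
#' @export
tm_topology <- function(start, end, seq_len = NULL, labels = NULL) {
  start <- as.integer(start); end <- as.integer(end)
  if (length(start) != length(end))
    qty_stop("start/end length mismatch", "qty_topology_error")
  if (any(is.na(start)) || any(is.na(end)))
    qty_stop("non-numeric coordinate in TM segment", "qty_topology_error")
  if (any(start < 1L))
    qty_stop("TM segment start below 1", "qty_topology_error")
  if (any(start > end))
    qty_stop("TM segment with start > end", "qty_topology_error")
  ord <- order(start, end)
  start <- start[ord]; end <- end[ord]
  if (length(start) > 1L && any(start[-1L] <= end[-length(end)]))
    qty_stop("overlapping TM segments", "qty_topology_error")
  if (!is.null(seq_len) && length(start) > 0L && any(end > seq_len))
    qty_stop("TM segment extends beyond sequence end", "qty_topology_error")
  if (is.null(labels)) {
    labels <- if (length(start) > 0L) paste0("TM", seq_along(start)) else character(0)
  } else {
    labels <- labels[ord]
  }
  structure(
    data.frame(start = start, end = end, label = labels,
               stringsAsFactors = FALSE),
    class = c("qty_topology", "data.frame"),
    seq_len = if (is.null(seq_len)) NA_integer_ else as.integer(seq_len)
  )
}

#' @export
print.qty_topology <- function(x, ...) {
  cat(sprintf("<qty_topology> %d segment(s), total length %d\n",
              nrow(x), total_tm_length(x)))
  if (nrow(x) > 0L) print.data.frame(x, row.names = FALSE)
  invisible(x)
}

#' Total residue count covered by a topology
#' @param topology A `qty_topology`.
#' @return Integer.
#' @export
total_tm_length <- function(topology) {
  if (nrow(topology) == 0L) return(0L)
  sum(topology$end - topology$start + 1L)
}

# logical mask over 1..seq_len of positions inside any segment
topology_mask <- function(topology, seq_len) {
  m <- logical(seq_len)
  for (i in seq_len(nrow(topology)))
    m[topology$start[i]:topology$end[i]] <- TRUE
  m
}

#' Read protein records from a FASTA file
#'
#' Thin wrapper over `Biostrings::readAAStringSet()`; each sequence is
#' normalized and checked by [validate_sequence()].
#'
#' @param path Path to a FASTA file.
#' @return List of `qty_record`.
#' @export
read_fasta <- function(path) {
  set <- tryCatch(Biostrings::readAAStringSet(path),
                  error = function(e) qty_stop(
                    sprintf("cannot read FASTA '%s': %s", path, conditionMessage(e)),
                    "qty_io_error"))
  if (length(set) == 0L)
    qty_stop(sprintf("no FASTA records in '%s'", path), "qty_io_error")
  headers <- names(set)
  lapply(seq_along(set), function(i) {
    s <- as.character(set[[i]])
    if (nchar(s) == 0L)
      qty_stop(sprintf("FASTA record '%s' has an empty sequence", headers[i]),
               "qty_io_error")
    id <- sub("\\s.*$", "", headers[i])
    desc <- sub("^\\S+\\s*", "", headers[i])
    protein_record(id = id, sequence = s, description = desc)
  })
}

#' Write protein records to FASTA (wrap width 60)
#'
#' @param records A `qty_record` or list thereof.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_fasta <- function(records, path) {
  if (inherits(records, "qty_record")) records <- list(records)
  set <- Biostrings::AAStringSet(vapply(records, function(r) r$sequence, ""))
  names(set) <- vapply(records, function(r) {
    if (nzchar(r$description)) paste(r$id, r$description) else r$id
  }, "")
  Biostrings::writeXStringSet(set, filepath = path, width = 60L)
  invisible(path)
}

#' Parse an explicit TM-range specification
#'
#' Accepts the CLI dialect `"a-b,c-d"` of 1-based inclusive ranges.
#'
#' @param spec Range string, e.g. `"20-42,55-77"`.
#' @param seq_len Host sequence length.
#' @return A `qty_topology` labeled `TM1..TMk` in sequence order.
#' @export
parse_tm_ranges <- function(spec, seq_len) {
  tokens <- strsplit(gsub("[[:space:]]", "", spec), ",", fixed = TRUE)[[1]]
  tokens <- tokens[nzchar(tokens)]
  if (length(tokens) == 0L)
    qty_stop("empty TM range specification", "qty_topology_error")
  m <- regmatches(tokens, regexec("^([0-9]+)-([0-9]+)$", tokens))
  bad <- vapply(m, length, 0L) != 3L
  if (any(bad))
    qty_stop(sprintf("malformed range token(s): %s",
                     paste(tokens[bad], collapse = ", ")), "qty_topology_error")
  start <- vapply(m, function(g) as.integer(g[2]), 0L)
  end   <- vapply(m, function(g) as.integer(g[3]), 0L)
  tm_topology(start, end, seq_len = seq_len)
}

#' Serialize a topology back to the range-string dialect
#' @param topology A `qty_topology`.
#' @return String like `"20-42,55-77"`.
#' @export
format_tm_ranges <- function(topology) {
  paste(sprintf("%d-%d", topology$start, topology$end), collapse = ",")
}

#' Parse UniProt TRANSMEM feature lines
#'
#' Accepts UniProt flat-file feature lines (`FT   TRANSMEM   40..63`) and the
#' tab-separated feature dialect (`TRANSMEM<TAB>40<TAB>63`).
#'
#' @param feature_text Character scalar or vector of lines.
#' @param seq_len Optional host sequence length for bounds checking.
#' @return A `qty_topology`, one segment per TRANSMEM feature.
#' @export
parse_uniprot_transmem <- function(feature_text, seq_len = NULL) {
  lines <- unlist(strsplit(feature_text, "\n", fixed = TRUE), use.names = FALSE)
  lines <- grep("TRANSMEM", lines, value = TRUE, fixed = TRUE)
  if (length(lines) == 0L)
    qty_stop("no TRANSMEM features found (no TM annotation)",
             "qty_no_tm_annotation")
  coords <- lapply(lines, function(ln) {
    tail <- sub("^.*TRANSMEM", "", ln)
    m <- regmatches(tail, regexec("([0-9]+)\\.\\.([0-9]+)", tail))[[1]]
    if (length(m) == 3L) return(as.integer(m[2:3]))
    nums <- regmatches(tail, gregexpr("[0-9]+", tail))[[1]]
    if (length(nums) < 2L)
      qty_stop(sprintf("malformed TRANSMEM coordinate pair in line: %s", ln),
               "qty_topology_error")
    as.integer(nums[1:2])
  })
  tm_topology(vapply(coords, `[`, 0L, 1L), vapply(coords, `[`, 0L, 2L),
              seq_len = seq_len)
}

#' Validate an SS3 secondary-structure string
#'
#' @param states String over `{H, E, C}`.
#' @param seq_len Optional host sequence length the string must match.
#' @return The normalized (uppercased) SS3 string.
#' @export
validate_ss3 <- function(states, seq_len = NULL) {
  if (!is.character(states) || length(states) != 1L)
    qty_stop("SS3 must be a single string", "qty_input_error")
  s <- toupper(gsub("[[:space:]]", "", states))
  if (nchar(s) == 0L) qty_stop("empty SS3 string", "qty_input_error")
  bad <- setdiff(unique(seq_chars(s)), c("H", "E", "C"))
  if (length(bad) > 0L)
    qty_stop(sprintf("SS3 states must be H/E/C; found: %s",
                     paste(bad, collapse = ", ")), "qty_input_error")
  if (!is.null(seq_len) && nchar(s) != seq_len)
    qty_stop(sprintf("SS3 length %d does not match sequence length %d",
                     nchar(s), seq_len), "qty_input_error")
  s
}

#' Convert an SS3 string into a candidate TM topology
#'
#' Maximal runs of `H` of length at least `min_run` become candidate TM
#' segments (typical TM helices span >= 18 residues). An empty topology is a
#' legitimate result.
#'
#' @param ss3 SS3 string (validated via [validate_ss3()]).
#' @param min_run Minimum helix run length to call a TM segment.
#' @return A `qty_topology`.
#' @export
ss3_to_topology <- function(ss3, min_run = 18L) {
  s <- validate_ss3(ss3)
  r <- rle(seq_chars(s) == "H")
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  keep <- r$values & r$lengths >= min_run
  tm_topology(starts[keep], ends[keep], seq_len = nchar(s))
}
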