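# internal helpers

# Signal a classed error so callers can distinguish input problems
# (qty_*_error) from design failures (qty_design_failure).
qty_stop <- function(msg, class, call. = FALSE) {
  stop(structure(
    class = c(class, "qty_error", "error", "condition"),
    list(message = msg, call = if (call.) sys.call(-1) else NULL)
  ))
}

# split a sequence string into a character vector of residues
seq_chars <- function(sequence) strsplit(sequence, "", fixed = TRUE)[[1]]

# extract the raw sequence string from a qty_record or pass a string through
as_sequence <- function(x) {
  if (inherits(x, "qty_record")) x$sequence else validate_sequence(x)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
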