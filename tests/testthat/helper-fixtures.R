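# shared fixture builders; all randomness goes through withr::with_seed

random_peptide <- function(n, seed = NULL) {
  draw <- function() paste(sample(AA_ALPHABET, n, replace = TRUE), collapse = "")
  if (is.null(seed)) draw() else withr::with_seed(seed, draw())
}

# random sequence plus a random valid (sorted, non-overlapping) topology
random_design_fixture <- function(seed, min_len = 60, max_len = 160) {
  withr::with_seed(seed, {
    n <- sample(min_len:max_len, 1)
    s <- paste(sample(AA_ALPHABET, n, replace = TRUE), collapse = "")
    k <- sample(1:3, 1)
    bounds <- sort(sample(seq_len(n), 2 * k))
    starts <- bounds[seq(1, 2 * k, 2)]
    ends <- bounds[seq(2, 2 * k, 2)]
    # enforce strict separation between consecutive segments
    keep <- c(TRUE, starts[-1] > ends[-k] + 1)
    list(sequence = s,
         topology = tm_topology(starts[keep], ends[keep], seq_len = n))
  })
}

# brute-force changed-in-TM recount, independent of the design engine
brute_force_changes <- function(wt, mt, topology) {
  a <- strsplit(wt, "")[[1]]; b <- strsplit(mt, "")[[1]]
  tot <- 0L
  for (i in seq_len(nrow(topology))) {
    idx <- topology$start[i]:topology$end[i]
    tot <- tot + sum(a[idx] != b[idx])
  }
  tot
}

cxcr4_path <- function() {
  system.file("extdata", "P61073_cxcr4.fasta", package = "qtykit", mustWork = TRUE)
}
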