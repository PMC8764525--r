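test_that("substitution codes are validated for idempotence", {
  expect_equal(qty_code()$mapping, c(L = "Q", I = "T", V = "T", F = "Y"))
  expect_equal(nty_code()$mapping["L"], c(L = "N"))
  expect_error(substitution_code(c(L = "L")), class = "qty_code_error")
  expect_error(substitution_code(c(L = "Q", Q = "N")), class = "qty_code_error")
  expect_error(substitution_code(c(L = "X")), class = "qty_code_error")
})

test_that("QTY and NTY substitution follow the worked example", {
  topo <- parse_tm_ranges("3-6", 8)
  expect_equal(qty_substitute("AQLIVFWA", topo)$mt_sequence, "AQQTTYWA")
  expect_equal(qty_substitute("AQLIVFWA", topo, nty_code())$mt_sequence, "AQNTTYWA")
})

test_that("substitution is idempotent: re-designing a variant changes nothing", {
  fx <- random_design_fixture(7)
  d1 <- qty_substitute(fx$sequence, fx$topology)
  d2 <- qty_substitute(d1$mt_sequence, fx$topology)
  expect_equal(d2$mt_sequence, d1$mt_sequence)
  expect_length(d2$changed_positions, 0)
})

test_that("designs preserve length, touch only in-TM {L,I,V,F}, and record changes exactly", {
  for (seed in 1:30) {
    fx <- random_design_fixture(seed)
    d <- qty_substitute(fx$sequence, fx$topology)
    expect_equal(nchar(d$mt_sequence), nchar(d$wt_sequence))
    a <- strsplit(d$wt_sequence, "")[[1]]
    b <- strsplit(d$mt_sequence, "")[[1]]
    diff <- which(a != b)
    expect_equal(diff, d$changed_positions)
    inside <- logical(nchar(fx$sequence))
    for (i in seq_len(nrow(fx$topology)))
      inside[fx$topology$start[i]:fx$topology$end[i]] <- TRUE
    # locality: everything outside TM segments untouched
    expect_true(all(inside[diff]))
    # substrate set: exactly the in-segment L/I/V/F occurrences
    expect_setequal(diff, which(inside & a %in% c("L", "I", "V", "F")))
  }
})

test_that("QTY and NTY designs differ exactly at in-TM leucines", {
  for (seed in 31:40) {
    fx <- random_design_fixture(seed)
    q <- qty_substitute(fx$sequence, fx$topology, qty_code())
    n <- qty_substitute(fx$sequence, fx$topology, nty_code())
    a <- strsplit(q$mt_sequence, "")[[1]]
    b <- strsplit(n$mt_sequence, "")[[1]]
    wt <- strsplit(fx$sequence, "")[[1]]
    inside <- logical(length(wt))
    for (i in seq_len(nrow(fx$topology)))
      inside[fx$topology$start[i]:fx$topology$end[i]] <- TRUE
    expect_equal(which(a != b), which(inside & wt == "L"))
  }
})

test_that("QTY design never increases hydropathy", {
  for (seed in 41:60) {
    fx <- random_design_fixture(seed)
    d <- qty_substitute(fx$sequence, fx$topology)
    if (length(d$changed_positions) > 0) {
      expect_lt(hydropathy(d$mt_sequence), hydropathy(d$wt_sequence))
    } else {
      expect_equal(hydropathy(d$mt_sequence), hydropathy(d$wt_sequence))
    }
  }
})

test_that("r_act follows the worked examples and the brute-force recount", {
  d <- qty_substitute("LIVFAAAA", parse_tm_ranges("1-8", 8))
  expect_equal(r_act(d), 0.5)
  d0 <- qty_substitute("AAAA", parse_tm_ranges("1-4", 4))
  expect_equal(r_act(d0), 0)
  for (seed in 61:80) {
    fx <- random_design_fixture(seed)
    d <- qty_substitute(fx$sequence, fx$topology)
    tot <- sum(fx$topology$end - fx$topology$start + 1)
    expect_equal(r_act(d),
                 brute_force_changes(d$wt_sequence, d$mt_sequence, fx$topology) / tot)
  }
})

test_that("masked designs keep Table-1 R_ACT semantics but report their realized rate", {
  topo <- parse_tm_ranges("1-8", 8)
  full <- qty_substitute("LIVFAAAA", topo)
  masked <- qty_substitute("LIVFAAAA", topo, mask = c(1, 2))
  expect_equal(masked$mt_sequence, "QTVFAAAA")
  expect_equal(r_act(masked), r_act(full))       # changeable-residue rate
  expect_equal(realized_change_rate(masked), 2 / 8)
  expect_error(qty_substitute("LIVFAAAA", parse_tm_ranges("1-4", 8), mask = 6),
               class = "qty_mask_error")
})

test_that("r_sc is the normalized SS3 Hamming distance", {
  expect_equal(r_sc("HHHC", "HHHC"), 0)
  expect_equal(r_sc("HHHC", "HHCC"), 0.25)
  expect_error(r_sc("HHH", "HH"), class = "qty_input_error")
})

test_that("diff_alignment is consistent with the design", {
  d <- qty_substitute("AQLIVFWA", parse_tm_ranges("3-6", 8))
  al <- diff_alignment(d)
  expect_equal(nrow(al), 8)
  expect_equal(sum(al$changed), 4)
  expect_equal(which(al$in_tm), 3:6)
  # identity design
  d0 <- qty_substitute("AAAA", parse_tm_ranges("1-4", 4))
  expect_equal(sum(diff_alignment(d0)$changed), 0)
  for (seed in 81:85) {
    fx <- random_design_fixture(seed)
    d <- qty_substitute(fx$sequence, fx$topology)
    expect_equal(sum(diff_alignment(d)$changed), length(d$changed_positions))
  }
})
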