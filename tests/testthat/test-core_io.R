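test_that("validate_sequence normalizes case/whitespace and is idempotent", {
  expect_equal(validate_sequence("mkli"), "MKLI")
  expect_equal(validate_sequence(" mK\nlI\t"), "MKLI")
  expect_equal(validate_sequence(validate_sequence("mkli")), "MKLI")
})

test_that("validate_sequence enforces the 8,000-residue cap and the canonical alphabet", {
  expect_error(validate_sequence(strrep("A", 8001)), class = "qty_length_error")
  expect_silent(validate_sequence(strrep("A", 8000)))
  expect_error(validate_sequence("MKX"), class = "qty_alphabet_error")
  for (bad in c("B", "J", "O", "U", "Z")) {
    expect_error(validate_sequence(paste0("MK", bad)), class = "qty_alphabet_error")
  }
  expect_error(validate_sequence("  "), class = "qty_input_error")
})

test_that("FASTA reading handles single and multi-record files and rejects empty sequences", {
  f <- withr::local_tempfile(fileext = ".fasta")
  writeLines(c(">a", "MK"), f)
  recs <- read_fasta(f)
  expect_length(recs, 1)
  expect_equal(recs[[1]]$id, "a")
  expect_equal(recs[[1]]$sequence, "MK")

  writeLines(c(">a", "MK", ">b desc here", "LI"), f)
  recs <- read_fasta(f)
  expect_length(recs, 2)
  expect_equal(recs[[2]]$id, "b")
  expect_equal(recs[[2]]$description, "desc here")

  writeLines(c(">a", ""), f)
  expect_error(read_fasta(f), class = "qty_io_error")
})

test_that("FASTA write/read round trip is the identity and wraps at 60", {
  recs <- list(protein_record("long1", random_peptide(150, seed = 11)),
               protein_record("short", "MK", description = "tiny"))
  f <- withr::local_tempfile(fileext = ".fasta")
  write_fasta(recs, f)
  lines <- readLines(f)
  expect_true(all(nchar(lines[!startsWith(lines, ">")]) <= 60))
  back <- read_fasta(f)
  expect_equal(vapply(back, `[[`, "", "sequence"),
               vapply(recs, `[[`, "", "sequence"))
  expect_equal(vapply(back, `[[`, "", "id"), c("long1", "short"))
})

test_that("parse_tm_ranges builds sorted labeled topologies and rejects bad specs", {
  t1 <- parse_tm_ranges("3-6", 8)
  expect_equal(nrow(t1), 1)
  expect_equal(c(t1$start, t1$end), c(3, 6))
  expect_equal(t1$label, "TM1")

  t2 <- parse_tm_ranges("55-77,20-42", 100)   # unsorted input
  expect_equal(t2$start, c(20, 55))
  expect_equal(t2$label, c("TM1", "TM2"))

  expect_error(parse_tm_ranges("3-6,5-9", 20), class = "qty_topology_error")
  expect_error(parse_tm_ranges("6-3", 20), class = "qty_topology_error")
  expect_error(parse_tm_ranges("3-30", 20), class = "qty_topology_error")
  expect_error(parse_tm_ranges("3-x", 20), class = "qty_topology_error")
})

test_that("range spec parse -> serialize -> parse is the identity", {
  for (spec in c("3-6", "20-42,55-77", "1-18,30-47,90-100")) {
    topo <- parse_tm_ranges(spec, 100)
    expect_equal(format_tm_ranges(topo), spec)
    expect_equal(parse_tm_ranges(format_tm_ranges(topo), 100), topo)
  }
})

test_that("UniProt TRANSMEM features parse from flat-file and tab dialects", {
  t1 <- parse_uniprot_transmem("FT   TRANSMEM        40..63")
  expect_equal(c(t1$start, t1$end), c(40, 63))

  seven <- paste(sprintf("FT   TRANSMEM        %d..%d",
                         seq(10, 310, 50), seq(30, 330, 50)), collapse = "\n")
  expect_equal(nrow(parse_uniprot_transmem(seven)), 7)

  t2 <- parse_uniprot_transmem("TRANSMEM\t40\t63\tHelical")
  expect_equal(c(t2$start, t2$end), c(40, 63))

  expect_error(parse_uniprot_transmem("FT   CHAIN   1..100"),
               class = "qty_no_tm_annotation")
  expect_error(parse_uniprot_transmem("FT   TRANSMEM   forty"),
               class = "qty_topology_error")
})

test_that("ss3_to_topology keeps only helix runs of at least min_run", {
  s <- paste0(strrep("C", 5), strrep("H", 20), strrep("C", 5))
  topo <- ss3_to_topology(s, min_run = 18)
  expect_equal(c(topo$start, topo$end), c(6, 25))
  expect_equal(nrow(ss3_to_topology(strrep("C", 40))), 0)
  expect_equal(nrow(ss3_to_topology(paste0(strrep("H", 17), "C"), min_run = 18)), 0)
})

test_that("ss3_to_topology output is always sorted and non-overlapping", {
  for (seed in 1:25) {
    s <- withr::with_seed(seed, paste(
      sample(c("H", "E", "C"), 200, replace = TRUE, prob = c(0.5, 0.2, 0.3)),
      collapse = ""))
    topo <- ss3_to_topology(s, min_run = 5)
    if (nrow(topo) > 1) {
      expect_true(all(diff(topo$start) > 0))
      expect_true(all(topo$start[-1] > topo$end[-nrow(topo)]))
    }
    expect_true(all(topo$start <= topo$end))
  }
})

test_that("restrict_topology clips segments to the fragment union", {
  topo <- parse_tm_ranges("3-6,10-14", 20)
  r1 <- restrict_topology(topo, list(c(1, 8)))
  expect_equal(c(r1$start, r1$end), c(3, 6))
  r2 <- restrict_topology(parse_tm_ranges("3-6", 20), list(c(5, 20)))
  expect_equal(c(r2$start, r2$end), c(5, 6))
  r3 <- restrict_topology(topo, list(c(1, 20)))
  expect_equal(r3$start, topo$start)
  expect_equal(r3$end, topo$end)
  expect_error(restrict_topology(topo, list(c(8, 2))), class = "qty_topology_error")
})
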