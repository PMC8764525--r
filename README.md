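# qtykit

Desk-scale toolkit for **QTY protein solubilization design**: turning
water-insoluble alpha-helical membrane proteins (GPCRs, transporters,
channels) into water-soluble variants by a deterministic residue code, and
preparing the combinatorial variant libraries and synthesis-ready DNA that
go with it.

The QTY code replaces the dominant hydrophobic residues inside
transmembrane (TM) helices with hydrophilic residues of similar size and
shape — L→Q, I→T, V→T, F→Y (the NTY variant uses L→N) — which lowers the
mean Kyte–Doolittle hydropathy H_Y of the protein below the
solubility line while preserving helix geometry. The package implements:

* **Inputs**: FASTA; TM annotation as explicit ranges (`"40-63,77-96"`),
  SS3 strings, UniProt `TRANSMEM` feature lines, external TM-predictor
  summaries, or a built-in hydropathy-plot fallback caller (window 19,
  cutoff 1.6, min length 18).
* **Simple design**: full in-TM substitution (`qty_substitute()`), change
  metrics R_ACT (changed / total TM residues) and R_SC (SS3 Hamming
  fraction), per-position diffs, and a five-section comparison report
  (general characteristics, TM regions, per-helix, alignments, helical
  wheels at 100°/residue) as JSON / text / SVG.
* **Properties**: MW (average masses), pI (bisection on the
  Henderson–Hasselbalch net charge, Bjellqvist pKa set), H_Y
  (Kyte–Doolittle mean), helix ratio R_H, and a pluggable composition Tm
  index.
* **Library design**: 2k+1 fragmentation, per-TM variant generation under
  solubility + helix-retention filters with a balance score, 8 variants
  per TM by default (8^7 ≈ 2.1 M combinations for a 7-TM receptor),
  seeded assembly sampling, and the two TXT library dialects plus a JSON
  manifest.
* **DNA design**: reverse translation against a bundled E. coli K-12
  codon-usage table, 20-nt overlap design drawn from invariant non-TM
  flanks (variant pools stay mix-and-match compatible), and in-silico
  assembly verification.
* **Fixtures**: a seeded synthetic k-TM protein generator with exact
  ground-truth topologies, so everything is testable offline.

## Worked example

```r
library(qtykit)

rec  <- read_fasta(system.file("extdata", "P61073_cxcr4.fasta", package = "qtykit"))[[1]]
topo <- predict_tm_fallback(rec)       # or parse_tm_ranges("40-63,...", nchar(rec$sequence))
d    <- qty_substitute(rec, topo)      # full QTY design
d
#> <qty_design> QTY code, 85/352 residues changed in 6 TM segment(s)

c(mw_wt = round(molecular_weight(rec), 2),
  mw_qty = round(molecular_weight(d$mt_sequence), 2),
  hy_wt = round(hydropathy(rec), 4),
  hy_qty = round(hydropathy(d$mt_sequence), 4),
  r_act = round(r_act(d), 4))
#>   mw_wt  mw_qty   hy_wt  hy_qty   r_act
#> 39.7500 40.0700  0.3994 -0.9733  0.5280
```

The wild-type chemokine receptor CXCR4 weighs 39.75 kDa with a positive
mean hydropathy (0.3994, insoluble); the QTY design is barely heavier
(+0.32 kDa — the replacements are near-isosteric) but its hydropathy drops
to −0.97, i.e. predicted water-soluble, with 53% of TM residues changed.

A library for a synthetic 7-TM protein:

```r
fx  <- make_synthetic_tm_protein(synthetic_tm_spec(7, seed = 1))
fr  <- fragment_protein(fx$record, fx$topology)      # 15 fragments
tms <- fr$label[fr$kind == "TM"]
vs  <- setNames(lapply(seq_along(tms), function(i)
         generate_tm_variants(fr$sequence[fr$label == tms[i]], seed = i)), tms)
lib <- build_library(fr, vs, rng_seed = 1)
lib
#> <qty_library> 15 fragments (7 TM), 2,097,152 combinations
write_library_files(lib, "library_out", emit_sample = 3, seed = 1)
```

A thin CLI wraps the same functions:

```sh
Rscript "$(Rscript -e 'cat(system.file("cli","qtykit.R",package="qtykit"))')" \
  design --fasta my.fasta --tm "40-63,77-96" --code qty --out mydesign
```

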