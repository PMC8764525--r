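---
title: "QTY design of water-soluble membrane-protein variants: methods and choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{QTY design: methods and choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(qtykit)
```

## The problem and the method

Alpha-helical membrane proteins — GPCRs, transporters, channels — are
notoriously hard to express and purify because their transmembrane (TM)
helices present a hydrophobic surface to water. The QTY code is a
deterministic protein-engineering recipe that replaces the four dominant
hydrophobic residues of a TM helix with hydrophilic residues of similar
size and shape:

| WT residue | replacement | Kyte–Doolittle change |
|---|---|---|
| Leu (L) | Gln (Q) | 3.8 → −3.5 |
| Ile (I) | Thr (T) | 4.5 → −0.7 |
| Val (V) | Thr (T) | 4.2 → −0.7 |
| Phe (F) | Tyr (Y) | 2.8 → −1.3 |

The NTY variant of the code uses Asn instead of Gln for leucine. Because
every replacement strictly lowers the Kyte–Doolittle value, the mean
hydropathy H_Y of a designed protein can never increase — this
monotonicity is a package-wide tested invariant. Both codes are
value-disjoint from their key set, so applying a code twice equals applying
it once; `substitution_code()` enforces this at construction.

The package implements two work modes. The *simple design* substitutes every
changeable residue inside the annotated TM segments and reports WT/variant
comparisons. The *library design* generates, for each TM helix, a small set
(default 8) of partially substituted variants that pass two in-silico
filters, and tracks the combinatorics of assembling them (8 variants ×
7 helices → 8^7 ≈ 2.1 million combinations for a typical GPCR).

## Input modes and coordinates

TM annotation can come from explicit 1-based inclusive ranges
(`"40-63,77-96"`), an SS3 secondary-structure string (helix runs ≥ 18
residues become candidate TMs), UniProt-style `TRANSMEM` feature lines, an
external TM-predictor summary (`TMhelix a b` lines), or the built-in
fallback caller. When several sources could apply, the CLI uses the most
explicit one: ranges > SS3 > UniProt features > fallback prediction — the
user's manual annotation should always win over derived ones. Sequences are
capped at 8,000 residues and restricted to the 20 canonical letters;
ambiguity codes are rejected rather than passed through because every
downstream property table (masses, hydropathy, propensities, pKa) is defined
only for the canonical alphabet. A single sequence per design call is
assumed throughout (for multi-isoform accessions, supply the canonical
sequence).

## Property calculations

* **Molecular weight** is the sum of average-isotopic residue masses plus
  one water, reported in kDa and rounded to 2 decimals for display.
* **Hydropathy H_Y** is the unweighted Kyte–Doolittle mean over the whole
  sequence. Negative values indicate predicted water solubility.
* **Isoelectric point** is found by bisection (tolerance 0.001 pH) on the
  Henderson–Hasselbalch net-charge function over D, E, C, Y, H, K, R and the
  termini, using the Bjellqvist/ExPASy pKa set by default (alternate sets
  may be passed). The charge function is strictly decreasing in pH, so the
  root is unique; the test suite cross-checks bisection against a dense
  exhaustive scan of the charge function.
* **Helix ratio R_H** is the fraction of `H` states in an SS3 string.
* **Tm index** is a pluggable composition score: the mean of a per-residue
  weight vector over the sequence. The default weights score the IVYWREL
  fraction, a published sequence-level correlate of thermostability. The
  index is qualitative; no quantitative claim is attached to it and users
  with a calibrated weight matrix can supply their own.

Change metrics for a design: **R_ACT** is the number of changed residues
divided by the summed TM length. For masked (partial) designs R_ACT is
still computed against the *full* substitution, so its meaning ("fraction
of TM residues that are changeable") does not drift with the mask; the rate
a masked design actually achieved is reported separately by
`realized_change_rate()`. **R_SC** is the per-position Hamming fraction
between WT and variant SS3 strings; when no external secondary-structure
prediction is supplied, reports derive both strings from the fallback
caller and label the value `"fallback-estimated"`.

## The fallback TM caller

External predictions (TMHMM-style summaries, SS3 files) are first-class
inputs. So that the toolkit also works offline, a classical hydropathy-plot
caller is built in: sliding-window (width 19) Kyte–Doolittle means are
computed per center; maximal runs of centers at or above 1.6 (runs
separated by fewer than 3 below-threshold centers are merged) are extended
to their window edges; each extended segment is then trimmed inward while
its terminal residue's own hydropathy is below 0; segments of at least 18
residues are reported.

The trim step is a deliberate boundary refinement: raw extension to window
edges systematically over-calls each end by up to half a window (an
implanted 30-residue poly-Ile helix in a serine context would otherwise be
called as the whole 50-mer), while per-residue trimming recovers the
implanted core exactly. The trim threshold (0), window (19), cutoff (1.6),
merge gap (3) and minimum length (18) are all exposed in
`predictor_config()`.

```{r}
s <- paste0(strrep("S", 10), strrep("I", 30), strrep("S", 10))
predict_tm_fallback(s)
```

`is_soluble_segment()` asks whether a segment, embedded in 10 serines on
each side (a fixed, neutral-polar context that avoids window edge effects),
still triggers a TM call. This is the solubility filter of the library
designer. No fidelity to any specific external predictor's output is
claimed; the caller is a transparent, parameter-exposed surrogate.

## Library design: filters and scoring

For each TM fragment, candidate masks are random subsets of the changeable
(L/I/V/F) positions — `n_samples` draws (default 1000), deduplicated, plus
the full mask. A candidate survives iff

1. **solubility**: the substituted segment no longer triggers a TM call, and
2. **helix retention**: its mean Chou–Fasman P-alpha stays at or above the
   configured threshold.

The helix threshold default is 0.85. The conventional former/breaker
boundary (1.0) is deliberately *not* used: the QTY replacements Q/T/T/Y have
propensities 1.11/0.83/0.83/0.69, so a fully substituted helix core has a
mean near 0.865 and would be rejected by a 1.0 cutoff — yet the full
substitution is the method's guaranteed-soluble anchor and has been shown
experimentally to retain helical structure. 0.85 sits just below that
anchor while still excluding Gly/Pro-rich breaker segments (propensity
0.57).

Survivors are ranked by a composite balance score,

```
composite = w_s * (delta_HY / delta_HY_full) + w_f * (1 - change_fraction)
```

with `w_s = w_f = 0.5`: the first term rewards hydropathy reduction
(normalized so the full substitution scores 1), the second rewards leaving
residues untouched (function preservation). `change_fraction` is changed
residues over changeable residues. The top `n_keep` (default 8, following
the 8-variants-per-TM library layout) are returned, with the
full-substitution variant force-included whenever it passes. This scoring
rule is this package's own declared surrogate for an otherwise unspecified
"balance" criterion; tests pin its definition, not any external value.
Generation is deterministic per seed, and an explicit
`qty_design_failure` condition is raised when no candidate survives — a TM
with a lone changeable residue in a breaker-rich context is a genuine
design failure, not an empty list.

Fragmentation of a k-TM protein produces exactly 2k+1 pieces (N-term, TMs,
loops alternating ICL/ECL labels, C-term) whose concatenation is the input
sequence; zero-length boundary pieces are kept as empty records so the
count law and the partition invariant stay exact. A 7-TM library therefore
emits 8 invariant NTM fragments plus 56 TM variants = 64 fragment
sequences, in two TXT dialects (60-column wrapped with headers, and
single-line for copy/paste into synthesis order forms) plus a JSON
manifest. In-silico enumeration refuses above a cap (default 10,000):
million-scale libraries are mixed at the bench by assembly PCR, not listed.

## DNA design

Reverse translation uses a bundled E. coli K-12 codon-usage table
(most-frequent codon, or frequency-weighted draws under a seed); round-trip
translation is verified with the standard genetic code. Overlap design
(default 20 nt, the usual scale for overlap-extension PCR) attaches flanks
to TM fragments *from the invariant NTM neighbors* — so all 8 variants of
one TM carry identical flanks and the variant pools stay mix-and-match
compatible. `verify_assembly()` checks every junction and confirms the
merged product translates to the intended protein. Overlap length and
junction placement are vendor-specific in practice; both are explicit
configuration here.

## The synthetic fixture generator

`make_synthetic_tm_protein()` builds k hydrophobic helix blocks (21
residues; composition biased over L/I/V/F/A/G/M/W, mean hydropathy ≈ 2.7)
separated by polar loops (12 residues; S/T/N/Q/D/E/K/R/G/P, mean ≈ −2.8)
with 25-residue termini — geometry in the range of real multi-pass
membrane proteins. Two construction details make ground truth recoverable
by design: every TM block is rejection-sampled until all full hydropathy
windows inside it clear the caller's threshold, and block edges are drawn
from the strongly hydrophobic subset (L/I/V/F/A/M) so the terminal-trim
rule lands exactly on the block boundary (all loop residues have negative
hydropathy).

What the generator does *not* emulate: real TM helices contain polar and
aromatic-interface residues (Trp/Tyr at membrane boundaries), re-entrant
helices, and loops with hydrophobic patches; real annotations disagree
between databases and predictors. Passing the recovery tests therefore
shows the caller is self-consistent on idealized contrast, not that it
matches curated annotations — on the bundled CXCR4 sequence it finds 6 of
the 7 curated helices, which is the expected behavior of a plain
hydropathy plot on a real GPCR.

## Reference data

`inst/extdata/P61073_cxcr4.fasta` carries the canonical human CXCR4
sequence (UniProt P61073), bundled so property checks run offline. It is
verified in the test suite against two independent published values
(MW 39.75 kDa, H_Y 0.3994, both reproduced exactly by this package's
calculators; the default pKa set also reproduces the published pI 8.46).
Design metrics for CXCR4 computed here use the fallback-predicted topology
and are reported as such — they are diagnostics on the method's scale, not
reproductions of annotation-based published cells.

## Problem sizes and determinism

Every stochastic step (mask sampling, weighted codon draws, fixture
generation, assembly sampling) is scoped under `withr::with_seed`, so
identical seeds give byte-identical outputs, including library files. The
shipped acceptance script profiles a 7-TM fixture library at 120 candidate
masks per TM (ample to fill 8 variant slots on fixture helices; the package
default stays at 1000 for real targets), checks fallback recovery on 50
fixtures spanning 1–12 TM helices, and recomputes the CXCR4 reference
properties. The test suite uses 100–200 random fixtures for the
property-style suites and a 0.001-pH scan grid for the pI oracle
(tolerance 0.01 pH).

## Known limitations

* The method targets alpha-helical TM proteins only; beta-barrels are out
  of scope, and the fallback caller will simply find nothing useful there.
* The fallback caller is a windowed hydropathy plot — no HMM, no topology
  (in/out) model; users wanting predictor-faithful pipelines should supply
  external predictor outputs, which are first-class inputs.
* The helix filter is table arithmetic (Chou–Fasman means), not a
  structure prediction; it cannot see tertiary contacts.
* pI depends on the pKa set; values are comparable within one set only.
* The Tm index is a pluggable qualitative hook, not a calibrated melting
  temperature.
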