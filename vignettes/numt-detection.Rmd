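---
title: "Detecting nuclear mitochondrial insertions (NUMTs): methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Detecting nuclear mitochondrial insertions (NUMTs): methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(numtscan)
```

## The problem

NUMTs are fragments of mitochondrial DNA that have integrated into nuclear
chromosomes, where they decay as pseudogenes. Because the mitochondrial
*cox1* (COI) gene is the standard animal barcoding marker, *cox1*-derived
NUMTs are a persistent source of artefacts in barcoding: a PCR or an
assembly scan that picks up the nuclear pseudogene instead of the organellar
gene reports a diverged, sometimes frame-shifted sequence as if it were the
species' barcode. Screening a genome assembly for *cox1* homologues — and
separating genuine nuclear insertions from leftover mitochondrial
contamination in the assembly — is therefore a routine task whose details
(alignment thresholds, exclusion rules, what counts as one insertion event)
materially change the reported counts.

`numtscan` implements this screen as a reusable, fully tested pipeline:

1. local alignment of a *cox1* query against every scaffold, both strands
   (built-in seed-and-extend aligner, or ingestion of a precomputed
   `blastn -outfmt 6` table);
2. a three-stage exclusion filter on the raw hits;
3. merging of surviving hits into *insertion sites* (the countable unit),
   extraction of their sequences;
4. a reference-anchored multiple alignment, Jukes–Cantor distances, a
   neighbour-joining tree, and per-species monophyly tests;
5. a synthetic-genome generator that plants ground-truthed NUMTs so every
   stage is verifiable without any external data.

## Coordinates and formats

Internally every interval is 0-based, half-open, on the forward strand of
its scaffold; conversions happen only at format boundaries (BLAST tabular
is 1-based inclusive with strand encoded by subject coordinate order; BED
is 0-based half-open). A single internal convention removes the usual
off-by-one error class. `N` never counts as a match anywhere, and seeds
containing `N` are skipped — conservative against false homology.
The E-value column of ingested BLAST tables is carried as metadata but
never used in filtering: no E-value cutoff is part of the method, and the
built-in aligner deliberately reports raw scores only (Karlin–Altschul
calibration is out of scope).

## The aligner

The built-in search indexes all exact k-mers (default `k = 11`, blastn's
default word size) of the query and its reverse complement, scans each
scaffold once, and extends every seed with an anchored, affine-gap,
x-drop-banded dynamic programme. Scoring defaults mirror blastn:
match +2, mismatch −3, gap of length *L* costs 5 + 2*L*. Extension stops
when every cell of the active band falls more than `x_drop = 50` below the
running best; a hit is reported when the total score reaches
`score_min = 60` (a perfect 30-bp match). The score floor is deliberately
far below the 100-nt exclusion filter so that the *filter*, not the
aligner, governs the length cutoff. Overlapping hits on the same scaffold
and strand are deduplicated, keeping the best score — BLAST-style HSP
lists contain shadow alignments that would otherwise inflate site counts.

Correctness is anchored by a separate full Smith–Waterman oracle (Gotoh
three-state recurrence with traceback, guarded to 10^7 cells). The test
suite and the acceptance script verify that on seeded random instances
containing a planted, diverged copy (guaranteed to share an 11-mer), the
search's best score equals the oracle's optimum in 200/200 instances. The
oracle is additionally cross-checked against
`Biostrings::pairwiseAlignment(type = "local")` scores, so the two routes
(package DP vs. independent library DP) never collapse into one.

Deterministic tie-breaking throughout: equal-scoring alignments prefer the
longer one, then the leftmost; gap-open is preferred over gap-extend at
ties; hits are emitted in scaffold-position order. Identical inputs give
byte-identical outputs.

## The exclusion filters

Raw hits are filtered by three criteria, each recorded separately so a hit
can carry several removal reasons:

* **`min_length`** — alignment length (columns) < 100 nt. The boundary is
  strict: a 100-column alignment is kept.
* **`scaffold_span`** — the subject span `(se − ss)` covers ≥ 95% of its
  scaffold. Such a "scaffold" is almost certainly a piece of the
  mitochondrial genome itself that survived assembly post-processing, not
  a nuclear insertion. The numerator is scaffold coverage, not alignment
  columns, because the criterion is a statement about the scaffold; the
  boundary (exactly 95%) is removed, since the rule targets contamination.
* **`edge`** — the hit starts within `edge_tol` of position 0 or ends
  within `edge_tol` of the scaffold end (default 10 bp; 0 demands exact
  abutment). Edge alignments may be truncated assembly artefacts whose
  true extent — and hence their classification — is unknowable. Polished
  assemblies rarely place an alignment at exactly base 0, so a small
  tolerance captures "at the edge" without swallowing interior hits; the
  value is exposed (`--edge-tol`) because reasonable people can disagree.

Filtering is a pure partition (kept ∪ removed = input), idempotent, and
monotone in each threshold; these invariants are property-tested.

Surviving hits on the same scaffold merge transitively into one insertion
site when the gap between them is ≤ `merge_gap` (default 1000 bp). One
integration event decays into several nearby HSPs as indels and
low-identity stretches interrupt the alignment; 1 kb reunites those
fragments while staying far below the distance between independent
insertions in practice (the synthetic truth separates plants by ≥ 3 kb so
the two scales never interact). Merging is strand-agnostic: an inverted
duplication inside one insertion would otherwise be counted twice. The
merge is compared against a brute-force O(n²) transitive-closure oracle in
the tests. `merge_gap` is the method's one genuinely free parameter when
replicating published counts, and it is exposed for sensitivity sweeps.

## The phylogeny stand-in

The classical workflow aligns extracted NUMTs with an external progressive
aligner and fits a maximum-likelihood tree with an external inference
tool. To keep this package self-contained and deterministic, it instead
builds a **reference-anchored alignment**: every NUMT already carries a
column trace against the query from the aligner, so each sequence is
projected into query coordinates (matches/mismatches fill the column,
deletions leave `-`, insertions relative to the query are dropped). This
is exact, reproducible, and needs no heuristic alignment — at the cost of
discarding NUMT-specific insertions and any signal outside the query.
The extracted NUMT FASTA is always written, so users who want the
classical MAFFT + ML route can run it on exactly the same sequences.

Distances are Jukes–Cantor, `d = −(3/4)·ln(1 − (4/3)·p)`, with `p`
computed over columns where both rows are resolved. Pairs sharing fewer
than `min_shared_sites = 100` columns (matching the hit-length filter) are
excluded — distances on fewer sites are noise-dominated — and pairs at
`p ≥ 0.75` are flagged saturated. JC matches the simulator's uniform
substitution model, making parameter recovery a closed loop; it is
cross-checked against `ape::dist.dna` in the tests.

Trees are neighbour joining (`ape::nj`, the Studier–Keppler formulation),
which recovers additive matrices exactly — property-tested on 100 random
trees of 5–12 taxa. Negative branch lengths are clamped to zero (standard
practice; the clamped deficit is recorded in the `"clamped"` attribute).
Monophyly of a label set on the unrooted tree means the set, or its
complement, is one side of a single-edge bipartition.

A caveat the package inherits from the underlying study design: when
NUMTs from several species are placed in one tree, a shared query
coordinate system is assumed. This is validated on simulation only, where
it holds by construction.

## The synthetic generator

`plant_numts()` emulates the features of real assemblies the filters are
designed around: multi-scaffold backgrounds of configurable GC, planted
query fragments at controlled divergence (uniform substitutions, matching
the JC model downstream), indels (events at a per-site rate, geometric
lengths 1–3), both strands, and the four placement classes — `interior`
(the detectable case), `edge_start`/`edge_end` (abutting a scaffold end),
and `contamination` (a dedicated scaffold that is ~98% planted sequence,
above the 95% filter threshold). Plants never overlap and interior plants
are separated by ≥ 3 kb, so truth intervals are unambiguous for
precision/recall scoring. `expected_detectable` is precomputed from the
same rules the filters apply (interior *and* planted length ≥ 100 nt), so
recall is measured only over plants the method is supposed to find —
separating filter semantics from aligner sensitivity.

What the generator does **not** emulate: transposable-element and
low-complexity background, assembly gaps (`N` runs), sequencing error,
empirical mitochondrial mutation spectra (transition bias, codon
structure), and NUMT-in-NUMT nesting. Passing the synthetic benchmarks
therefore demonstrates the machinery is correct under the stated model,
not that real assemblies contain no harder cases — notably, ancient NUMTs
beyond ~30% divergence lose 11-mer seeds and saturate JC distances, and
both effects are by design out of reach.

The multispecies generator (`plant_multispecies()`) uses a two-level
model: a species ancestor diverges from the query at 0.15 substitutions
per site, and each of that species' NUMTs diverges from the ancestor at
0.02. Under this star-shaped model each species should be monophyletic in
the NJ tree; the package recovers all-species monophyly in ≥ 95% of 40
seeded replicates (observed: 40/40).

## Numerical choices and degenerate inputs

* Seeds: every stochastic entry point takes an integer seed and restores
  the caller's RNG state. One practical warning: generate the query and
  the assembly from *different* seeds. Two `sample()` streams started
  from the same seed produce nearly identical base sequences even at
  slightly different base frequencies, which plants an unintended
  full-length homologue (this failure mode is why the packaged example
  uses seeds 42 and 1001).
* Zero hits is a success, not an error, end to end.
* Two-taxon "trees" are returned as a single edge; fewer than two usable
  rows after distance pruning is an error.
* Labels with Newick grammar characters are sanitised to `_` before
  writing; duplicate labels are an error.
* The x-drop extension examines at most `2·Lq + x_drop + 64` scaffold bp
  around a seed anchor — further cells cannot stay within `x_drop` of the
  best under the affine scores — which is what keeps the scan linear in
  scaffold length.

## Validation scale

The shipped validation runs at desk scale, chosen so the whole suite
completes in minutes on one CPU: a ~5-Mb, 25-scaffold assembly with 50
interior plants (150–800 bp, divergence 0.02–0.20) for recovery
(precision and recall ≥ 0.95 required, 1.0 observed); 200 instances for
aligner/oracle equivalence; 20 seeded configurations for filter-branch
coverage; 100 matrices for NJ; 40 replicates for monophyly. The same
quantities are recomputed from scratch by `scripts/acceptance.R`.
Full-scale replication against deposited multi-Gbp assemblies uses the
`blast_tab` ingestion path with an externally produced blastn table and
the same downstream defaults; exact replication of published per-species
counts additionally depends on the unpublished merge/edge conventions
discussed above, which is why both knobs are first-class parameters.
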