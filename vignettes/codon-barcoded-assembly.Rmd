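---
title: "Codon-barcoded variant libraries: design, simulation and de novo assembly"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Codon-barcoded variant libraries: design, simulation and de novo assembly}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(codasm)
```

## The problem

Pooled gene variant libraries (error-prone PCR mutagenesis, programmed
site-directed mutagenesis, synthetic combinatorial designs) are cheap to
build but hard to read out: short-read sequencing fragments every molecule
into 150 bp pieces, and when hundreds to thousands of near-identical
full-length variants are sheared together, reads can no longer be assigned
to the molecule they came from. Distant mutations on the same molecule —
exactly the information needed to study epistasis — are lost.

`codasm` implements the codon-barcoding strategy for this problem. A
protein is reverse-translated into a *degenerate* DNA template that places
an IUPAC symbol at every third codon position where the genetic code
permits it (`N` = A/C/G/T, `R` = A/G, `Y` = C/T). Every concrete molecule
synthesised from that template carries its own random combination of
synonymous codons: a dense, intrinsic barcode spread along the whole gene.
Random shearing then no longer destroys molecule identity, because any
sufficiently long read window contains enough barcode positions to be
unique to one molecule, and full-length variants can be reassembled *de
novo* from short reads.

## The codon-frame de Bruijn graph

Assembly uses a modified de Bruijn graph in which **nodes are
`(k-3)`-mers** and **edges are `k`-mers**: an edge connects the node formed
by its first `k-3` bases to the node formed by its last `k-3` bases, so
every traversal step advances exactly 3 nt — one codon. The frame-locked
step keeps path extension aligned with the codon barcodes.

The pipeline (`assemble()`) runs:

1. **Trimming** (`trim_reads()`): terminal bases with Phred quality < 20
   are removed, then a 3' homopolymer run of more than three `A`s; reads
   shorter than `k-3` are dropped.
2. **Optional backbone filtering** (`filter_backbone_reads()`): reads whose
   best alignment lies entirely inside the vector backbone, outside the two
   150 nt junction windows, are discarded.
3. **Graph construction** (`build_graph()`): every `(k-3)`-mer and `k`-mer
   window of every read *and of its reverse complement* increments a depth
   counter. Both strands are inserted because plasmid shearing yields both;
   the graph is oriented later by the seeds. Construction is partitionable
   into bins whose maps merge associatively (`merge_graphs()`), with a
   result identical to a single pass.
4. **Pruning** (`prune_graph()`): depth-1 nodes and edges are treated as
   sequencing errors and removed; then at each node, outgoing edges weaker
   than 1/50 of the strongest outgoing edge at that node are pruned, and
   dangling nodes dropped.
5. **Seed detection** (`detect_seeds()`): a node is an *initial seed* when
   its first `b` bases exactly match the 3' end of the forward backbone
   flank for some `b` between `min_seed_anchor` (30) and `k-6`; *terminal
   seeds* are symmetric against the start of the reverse flank. Seeds with
   depth below 1/200 of the strongest seed are discarded (1/150 is a
   common relaxed preset for right-skewed pools; both are presets of
   `seed_prune_ratio`). Seed matching is pure exact suffix/prefix
   anchoring — no external aligner is involved; because the anchor window
   slides, junction bases beyond the anchor may mismatch without losing
   the seed.
6. **Traversal** (`traverse_graph()`): exhaustive depth-first exploration
   from initial to terminal seeds, 3 nt per step, cycle budget zero (a
   node may appear once per path). A candidate's insert is the path string
   minus the recorded flank overlaps; its copy-number estimate is the
   minimum node depth along the path. Initial seeds reachable from another
   initial seed in one step are redundant roots — their paths are suffixes
   of the longer root's paths and trim to identical inserts — and are
   skipped; with 150 nt flanks this leaves about three roots per molecule
   (one per codon phase), and candidates are deduplicated by insert.
7. **CV chimera filter** (`cv_filter()`): raw reads are re-aligned to each
   candidate by exact substring matching (forward or reverse complement);
   the per-base depth profile over the insert is summarised as CV =
   sd/mean. Randomly sheared true molecules give flat profiles; a chimera
   joining a `d1`-deep left half to a `d2`-deep right half gives a step
   profile with CV close to `|d1-d2|/(d1+d2)`, and is rejected above the
   cut-off 0.2163. That cut-off was calibrated for `k = 120`; any other
   `k` triggers a log flag.

Contig-versus-reference differences (`call_variants()`) come from global
Needleman–Wunsch alignment with match +2, mismatch −1, gap initiation −3
and gap propagation −1 (implemented via `Biostrings::pairwiseAlignment`
with `gapOpening = 2, gapExtension = 1`, which reproduces exactly that
run-length cost; an exhaustive alignment enumerator serves as the
independent oracle in the tests).

### Re-alignment context for the CV filter

Two numerical choices make the published CV cut-off meaningful:

* Candidates are re-aligned **with flank context attached**. Against the
  bare insert, no read can span an insert boundary, so every true contig
  would carry a triangular end-ramp (CV ≈ 0.27 for a 1.5 kb insert at
  150 bp reads — above the cut-off).
* The context is limited to `read_len − 30` nt (default
  `cv_flank_context = 120`). With full-length flanks attached, reads
  overlapping the insert by fewer than ~30 nt match *every* candidate in
  the pool, because flanks are shared; the insert-edge depth then reflects
  pool-total abundance rather than the candidate's own, and rare variants
  fail spuriously. Requiring ≥ 30 nt of insert overlap (~10 codon
  barcodes) makes read assignment molecule-specific, and the profile over
  the insert span is flat up to Poisson noise, i.e. CV ≈ 1/sqrt(mean
  depth).

A consequence of the "assign each read to every exactly matching
candidate" semantics: in designs with long *fixed* (barcode-free) windows,
the window's reads match all candidates and create a depth bump on every
true contig. The CV stage is optional by design, and the fixed-region
experiment driver disables it; barcode-dense designs are unaffected.

## The simulator and what it emulates

`generate_library()` realizes the degenerate template uniformly at random
per position, injects independent per-base substitutions at the
error-prone-PCR rate, and attaches fixed 150 nt flanks.
`assign_copy_numbers()` models clone abundance: `uniform` (no growth bias)
or zero-truncated negative binomial (`size = 2` by default), reproducing
the right-skewed abundance of transformed pools. `simulate_reads()` shears
each molecule into 200–400 bp fragments and reads 150 bp from each end
(mate 2 reverse-complemented), applies substitution-only sequencing
errors, and emits constant Q37 qualities.

Fragment positions are drawn on the *plasmid* axis: a fragment may
overhang the retained flank+insert window, and a mate is emitted only when
its read lies entirely inside the window — the overhanging mate is a
backbone read that the real pipeline discards. This detail matters. If
fragments are instead forced to fit inside the linear template, coverage
ramps down over the outer ~250–400 nt at both ends; for an 816 nt gene
nearly the entire insert then sits in a bowl-shaped depth profile and true
contigs fail the CV filter at CV ≈ 0.22 despite healthy depth. Whole
plasmids are sheared precisely because that equalises depth across the
gene, and the simulator reproduces it: read starts are uniform across the
window for both mates, and true-contig CV returns to the Poisson
1/sqrt(depth) regime the cut-off was calibrated for.

Not emulated: indel sequencing errors, quality-score profiles, GC bias,
optical duplicates, adapter read-through, and chimeric PCR artefacts.
Passing tests therefore demonstrate correctness of the method's logic
under its own stated noise model, not robustness to every artefact of real
instruments.

### Coverage units

All experiment-level coverage settings are expressed as **mean molecule
depth** — the expected number of template molecules (cell population /
plasmid copies) carrying each graph window, which is the scale on which
the depth thresholds (singleton pruning, seed cut-off, copy number) act.
Read-base coverage is larger by `read_len / (read_len - (k-3) + 1)`
(≈ 4.4× at `k = 120` and 150 bp reads), because a read of length 150
contains only 34 complete 117-mer windows; `coverage_for_depth()` performs
the conversion, and `simulate_reads()` itself takes literal read-base
coverage. This distinction matters: quoting a "60×" pool in read-base
units would give every 117-mer window a mean depth of only ~14 and the
depth-≥2 chain over ~480 consecutive windows of a 1.5 kb gene would break
with near certainty, whereas uniform molecule depth 12 already assembles
such genes reliably — which is the regime the method's published operating
points describe.

## Default parameters

| Parameter | Default | Meaning |
|---|---|---|
| `k` | 120 | edge k-mer (nodes `k-3`); multiples of 3 only |
| `min_depth` | 2 | singleton elimination threshold |
| `edge_prune_ratio` | 1/50 | per-node relative outgoing-edge cut |
| `seed_prune_ratio` | 1/200 | relative seed depth cut (1/150 = relaxed preset) |
| `min_seed_anchor` | 30 nt | minimum exact flank overlap of a seed |
| `cv_cutoff` | 0.2163 | CV rejection threshold, calibrated for k = 120 |
| `cv_flank_context` | 120 nt | flank context for exact-match re-alignment |
| read length | 150 bp | paired-end |
| fragments | 200–400 bp | uniform shearing |
| sequencing error | 0.1% | substitution only |
| NB dispersion | size = 2 | right-skewed pool abundance |
| flanks | 150 nt | backbone seed-anchoring windows |

`max_contig_len` defaults to the expected insert length plus `2k + 300`;
`max_steps`/`max_candidates` bound exploration in barcode-poor graphs
(truncation is reported in the run log, never silent).

## Design choices on open points

* **Degenerate codon table**: six-codon residues use their four-fold box
  (Leu `CTN`, Ser `TCN`, Arg `CGN`) to maximise diversity; Ile uses `ATY`
  (`ATN` would encode Met); the appended stop is fixed `TAA`; ties go to
  the lexicographically smallest codon prefix. In `n_only` mode residues
  without a fully synonymous `N` family fall back to the same R/Y/fixed
  rule, so on the standard code both modes coincide (the mode is kept for
  provenance).
* **Strand handling**: reads and their reverse complements are both
  counted at build time; the gene orientation is imposed by the seeds.
* **Copy weights**: the negative-binomial draw is used as a relative
  weight; fragments are allocated multinomially in the weights, so "depth"
  can be read interchangeably as cell population or plasmid copy number.
  Zero truncation keeps every variant in the truth set; rarity is
  exercised through low weights, not silent dropout.
* **Saturating count filter**: at `min_count = 2` graph construction may
  first pass windows through a saturating counting sketch and only
  materialise keys that can reach the threshold. A sketch can only
  over-count (collisions), never under-count, so the keys it drops are
  exactly singletons and the result equals build-then-prune — the
  equivalence is asserted by a test.
* **Synthetic stand-in genes**: the bundled experiment drivers use
  deterministic synthetic proteins (`synthetic_protein()`, E. coli-like
  residue frequencies) of 493 aa and 271 aa — 1482 nt and 816 nt genes
  with their stop codons — because no real gene sequence is bundled.

## Problem sizes used by the bundled reproductions

The test suite runs the study designs at reduced size (pools of ~120–200
variants); `scripts/acceptance.R` re-runs them at 500 variants (1,000
combinations for the two-region design). The two-region layout places its
34-codon windows at codons 50–83 and 400–433, > 800 bp apart. These sizes
were chosen so each experiment completes in minutes while keeping the
per-variant statistics (coverage, barcode density, mutation load)
identical to the full-scale designs.

## Known limitations

* Recovery of a variant requires an unbroken depth-≥2 chain of ~L/3 nodes
  in at least one codon phase, so recovery versus molecule depth has a
  sharp knee near depth ~10–13 for 1.5 kb genes; below it variants are
  irrecoverably absent from the graph, above it recovery saturates. Under
  the right-skewed negative-binomial pool (size = 2) a few percent of
  variants sit below the knee even at mean depth 60, which bounds recall
  on such pools at roughly 90–95% — deeper sequencing, not parameter
  tuning, is the remedy.
* With an error-prone-PCR mutation load, a small *coverage-independent*
  fraction of variants is lost at the junctions: pool-shared junction
  seeds (flank plus the first codons, common to every molecule) are
  hundreds of times deeper than any variant-private seed, so the relative
  seed cut-off discards all private seeds; a variant whose divergence
  edge off the shared junction trunk is removed by the per-node 1/50 rule
  — which happens when a mutation sits in the first or last few codons —
  then has no surviving entry point at any depth. At mutation rate 0.01
  on a 1.5 kb gene this caps uniform-coverage recovery near 94–95%. The
  same mechanism is why skewed real pools lose contigs carrying rare
  junction-proximal mutations unless the seed cut-off is relaxed.
* Sensitivity collapse under barcode down-sampling is driven by
  inter-molecule k-mer window collisions, whose probability per pair is
  ~4^-(retained barcodes per window). With 100,000-molecule libraries this
  bites at P = 0.6; desk-scale pools of a few hundred variants keep ~28
  retained barcodes per 117-mer window and do not collide, so the
  collapse cannot be observed at reduced scale.
* One design per run: multi-gene pools must be assembled per gene with
  their own flanks.
* The CV cut-off is a constant calibrated for `k = 120`; other `k`
  require recalibration against validated contigs.
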