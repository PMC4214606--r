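---
title: "Ortholog-guided scaffold curation, chromosome placement and annotation QC"
author: "scaftier"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Ortholog-guided scaffold curation, chromosome placement and annotation QC}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

## The problem

Draft mammalian genome assemblies arrive as thousands of scaffolds, some
of them chimeric (erroneously joining sequence from different
chromosomes), none of them assigned to chromosomes, and none annotated.
When a closely related, well-annotated species exists — the motivating
case is a macaque draft curated against the human annotation — the
reference species supplies three independent kinds of evidence that can
be exploited both to *repair* scaffolds and to *place* them:

1. **Ortholog gene structure.** The exons of a conserved protein-coding
   gene must land on one scaffold, on one strand, in transcript order.
   We call this the *contiguity rule*; any violation is diagnostic of an
   assembly (or annotation) problem.
2. **Experimentally ordered markers** (radiation-hybrid maps), which
   order scaffolds along chromosomes independently of any sequence
   assembly.
3. **Cytogenetic synteny blocks** (FISH maps), which tie intervals of
   the reference genome to target chromosomes, including orientation.

`scaftier` implements the full procedure as composable functions: exon
mapping, contiguity checking and chimera breaking, three-tier placement
with AGP/FASTA output, ortholog-based gene-model acceptance, GTF
validation, and an mRNA contamination read filter, plus a simulator that
generates complete truth-annotated test worlds.

## The procedure

### Exon placement

Reference exon sequences (transcript orientation) are placed on
scaffolds by a seed-and-extend mapper: exact k-mers (default `k = 15`)
are matched on both strands, seeds sharing a diagonal are chained (at
least two colinear seeds unless the query is shorter than `2k`), and
each candidate is scored by direct base comparison over the full
query–scaffold overlap. A hit must cover at least `min_cov = 0.5` of
the query at `min_identity = 95` percent — a default reflecting typical
coding-sequence divergence between human and macaque; both are
configurable. The mapper is deliberately **ungapped**: exon placement
for ordering needs loci and orientation, not base-perfect alignments.
Indel-containing alignments can be imported instead from any aligner
emitting 12-column tabular output (`read_aln_table()`), and a
single-best-hit policy (`best_hit()`: score, then identity, then
alignment length, then lexicographically smallest target) mirrors
single-target reporting in common aligner configurations.

### Contiguity rule and chimera breaking

`detect_violations()` classifies genes with at least two placed exons
as `split_gene` (multiple scaffolds), `orientation_violation` (mixed
strands) or `order_violation` (positions not strictly monotone in
transcript order: increasing on `+`, decreasing on `-`).

`detect_chimeras()` gives every gene a chromosome vote by locating its
reference position in the synteny table, orders the genes along each
scaffold, and flags scaffolds whose votes form two or more maximal runs.
Two refinements keep the detector conservative:

* a run shorter than `min_run_genes = 2` that disagrees with the
  scaffold's majority vote is treated as single-gene noise — reported
  for curation, never a break trigger (automatic breaking on single-gene
  evidence is fragile);
* order violations *within* one scaffold (inversions) are reported but
  not broken: breaks exist to fix chromosome-level assignment, and small
  inversions are a documented limitation of reference-order placement.

`propose_breakpoints()` puts one break between each adjacent cluster
pair, at the midpoint of the longest N-run strictly between the
clusters — assembly gaps are where scaffolders err — falling back to the
midpoint of the inter-cluster interval. The source data does not
prescribe where inside a conflict region to cut; this rule is the
package's own choice. `apply_breaks()` names parts `<id>.1, <id>.2,
...` left to right and returns a provenance table; concatenating the
parts always reproduces the parent (sequence conservation is asserted in
the tests).

### Tiered placement

Each tier only sees scaffolds the previous tiers left unplaced, so a
scaffold placed at tier *t* is never re-placed later:

* **Tier 1 — markers.** A scaffold inherits its markers' chromosome;
  its order key is the median marker `order_index` and its orientation
  the sign of the correlation between marker order and scaffold offset.
  Markers disagreeing on the chromosome leave the scaffold unplaced with
  a recorded conflict.
* **Tier 2 — synteny + ortholog positions.** Each gene's reference
  position selects a synteny block, voting for a target chromosome and
  block. Within a block the scaffold is keyed by the median reference
  position of its genes, negated for minus-orientation blocks (the
  block's reading direction is reversed). Orientation is block
  orientation times the majority of (exon-hit strand × reference gene
  strand) over the genes — the second factor removes each gene's own
  strandedness, which is why the exon metadata carries a `ref_strand`
  column.
* **Tier 3 — reference tiling.** Reference chromosomes are cut into
  10,000-bp segments (terminal segments shorter, still voting); each
  segment's best hit on a still-unplaced scaffold votes, and the median
  voting segment positions the scaffold inside the corresponding synteny
  block. Coverage for segment hits is deliberately loose
  (`min_cov = 0.25`) so segments overhanging scaffold ends still count.

`merge_placements()` linearizes each chromosome. Marker keys (ranks
along a chromosome) and block keys (reference base-pair positions) are
incommensurate, so the merge is anchor-based: marker-bearing scaffolds
are ordered by marker key; block-only scaffolds are inserted between
them using scaffolds that carry *both* kinds of evidence as anchors.
Where marker order and synteny order disagree, marker order wins and a
conflict is recorded — the markers are assembly-independent
measurements. An override table (curation file) is applied last and
always wins. `build_agp()` emits AGP v2.0 with 100-N scaffold gaps
(`gap_type=scaffold`, `linkage=no`; the gap length is a convention, not
data, and is configurable), and `build_chromosomes()` reverse-complements
minus components.

### Annotation QC

`extract_cds()` concatenates CDS intervals 5'→3' (reverse-complemented
on `-`), trims leading bases per the first interval's phase;
`translate_cds()` applies the standard code, removes the terminal stop,
and *flags* (never throws) `internal_stop`, `no_start` and
`incomplete_codon`.

`global_align()` is Needleman–Wunsch with affine gaps — BLOSUM62, gap
open 10, gap extension 0.5, **free end gaps** (the EMBOSS needle
default; the end-gap convention changes gap counts for length-discrepant
pairs, so it is stated here explicitly). Statistics are computed over
the reconstructed end-to-end alignment: identity = identical columns /
alignment length; similarity = columns with a positive substitution
score (identities included); `gap_positions` = gap characters summed
over both rows, end gaps included — a *count*, not a percent (a percent
is also reported). Under the scoring convention used here a gap of
length L costs `open + extend × L`.

The acceptance rule (`evaluate_model()`): **accept** iff the protein
length difference is strictly less than 5 aa *and* similarity is
strictly greater than 92 percent. Everything else is
`flag_for_review` — the pipeline never silently rejects, mirroring a
workflow in which borderline models go to manual inspection and
fast-evolving gene families (immune, reproductive) are judged by relaxed
cutoffs (`fast_evolving` class: < 15 aa, > 80 percent; configurable).
Structural translation flags also force review: this extension of the
bare length/similarity rule is what guarantees that a 1-bp frameshift —
which shifts the frame, creates premature stops and an incomplete
codon — can never be accepted even when its aligned similarity happens
to stay high.

Terminal-exon repair: when the penultimate exon's 3' end and the
terminal exon are both non-coding and within 1 kb, the two exons and the
intervening sequence merge into one terminal exon (CDS untouched).
The companion 3'-UTR extension projects the ortholog UTR *by length*
(not alignment) and only through gap-free sequence — an alignment-free
simplification, and a documented limitation. `validate_gtf()` checks
CDS-in-exon containment, exon overlaps and strand sanity, and removes
duplicate transcripts keeping the lexicographically smallest id; it is
idempotent.

### Read contamination filter

mRNA reads are kept only when their best alignment length against the
reference transcript set strictly exceeds a per-read-length threshold:
70 bp for 76-bp reads, 90 bp for 100-bp reads. Lengths not covered by
those two stated values fall back to `floor(0.90 × read length)`, an
interpolation of the two published ratios (70/76 ≈ 0.921, 90/100 =
0.90). A read with no alignment counts as length 0. In paired mode a
pair survives only if both mates survive, and output files stay
synchronized. "Alignment length" is the alignment column count as
reported in tabular aligner output (column 4), gaps included.

## The simulator

`simulate_world()` emulates the study design: a human-like annotated
reference guiding a diverged macaque-like draft. Defaults (the
conditions under which the package's recovery claims are tested): 3
chromosomes × 2 Mb, 150 genes (3–8 exons of 90–240 bp, introns 200–2000
bp, stratified placement so gene evidence covers every fragment), 1%
per-site substitution, 2 synteny blocks per reference chromosome
shuffled with random orientation onto the target, 40 scaffold fragments
cut at intergenic points, 5 cross-chromosome chimeras joined by 100-N
gaps, markers every ~20 kb (50/Mb, 120 bp), 2000 error-free 76-bp reads
with 10% intergenic contamination. Substitutions that would create a
premature stop or destroy the start/stop codon are reverted — a crude
but effective stand-in for purifying selection that keeps true gene
models translatable, isolating the curation logic under test.
Divergence is substitution-only by default so exon order and protein
lengths are conserved; inversion planting (`n_inversions`) exists for
stress tests.

What the simulator deliberately does **not** model: repeats and
segmental duplications (the dominant source of real mis-mappings),
sequencing error, indel divergence, GC bias, and assembly gaps inside
fragments. Passing recovery tests therefore demonstrates the logic is
correct *given adequate unique evidence*, not that real-genome accuracy
will match; on real data the conflict reports and the override file are
the expected workflow.

All randomness flows from the single mandatory seed; the same seed
reproduces a byte-identical world. Read simulation reseeds with
`seed + 1` so reads are reproducible independently of how much of the
world has been consumed.

## Numerical choices and degenerate inputs

* k-mer size 15 (4^15 fits exactly in a double; index on numeric
  codes); k is validated to 8–26.
* Hit score `2·matches − 3·mismatches`; any monotone score works — it
  only drives best-hit selection.
* Orientation ties (exactly balanced strand evidence, or a single
  marker) resolve to `+` with a recorded conflict: deterministic output
  is worth more than a coin flip.
* Break coordinates count bases kept in the left part; a break at `c`
  yields `seq[1..c]` and `seq[(c+1)..n]`.
* Chromosome labels for real assemblies follow the bundled
  nomenclature table's `M` column (including `2a`/`2b`); FASTA headers
  are `chr<label>`.
* Internal coordinates are 1-based inclusive throughout (the
  R/Bioconductor convention); external formats keep their native
  conventions (GTF/AGP/tabular alignments: 1-based; minus-strand hits
  encoded by `t_start > t_end`). Conversions happen only at I/O
  boundaries.
* Empty inputs: an empty read set has no defined mappability (error);
  an empty comparison set has no means (error); a query with no hits is
  an empty table, not an error.

## Problem sizes

The shipped tests exercise a compact world (2 × 300 kb, 20 genes, 8
fragments, 2 chimeras) for unit-level checks and the full default world
above for end-to-end recovery; the acceptance script runs the default
world twice (with and without markers) plus 200 oracle-checked protein
alignments, together around two minutes on one CPU.

## Worked example

```{r example}
library(scaftier)

world <- simulate_world(sim_config(seed = 42))
res <- run_world_pipeline(world)

nrow(res$curation$breakpoints)      # breaks introduced
res$placement$table                 # chromosome / position / orientation / tier
compute_assembly_stats(world$scaffolds)

qc <- qc_gene_models(world$truth$models, world$scaffolds,
                     world$reference$proteome, world$reference$pairing)
qc$summary
```

## Known limitations

* The internal mapper is ungapped and k-mer seeded: diverged or
  repeat-rich regions need an external aligner via the import path.
* Tier-3 placement inherits reference order inside blocks, so small
  inversions and translocations relative to the reference are not
  represented.
* The 3'-UTR projection is length-based, not alignment-based.
* Marker/synteny disagreements are resolved by a fixed precedence
  (markers win) rather than joint optimization; the conflict log plus
  the override file is the intended curation loop.
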