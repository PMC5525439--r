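---
title: "Fragment recruitment analysis: methods and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Fragment recruitment analysis: methods and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(fragrec)
```

# Scope

`fragrec` implements a desk-scale fragment recruitment analysis (FRA)
pipeline: metagenomic reads are aligned against a database of candidate
reference genomes, filtered, competitively assigned to their best genome,
and summarized as normalized recruitment rates stratified by percent
identity. Companion modules cover multilocus marker comparison
(pairwise identity, amplicon merging, haplotype censuses) and
proteorhodopsin annotation (functional residues, spectral tuning,
transmembrane helices). Synthetic-data generators with exact truth
tables make every stage testable without external data.

# The recruitment model

## Alignment

Reads are aligned with a seed-and-extend local aligner
(`local_align()`): exact 11-mer seeds are located in the concatenated
genome sequences, clustered by diagonal (offset drift up to a 15-column
band), and each cluster is verified by a full Smith–Waterman dynamic
program with traceback inside a banded subject window. Scoring is match
+1, mismatch −2, and a linear (non-affine) gap cost of −2.5 per gap
column. Both strands are searched; minus-strand hits are reported in
BLAST convention with `sstart > send`, 1-based inclusive.

Raw scores `S` are converted to bit scores with
`S' = (λS − ln K)/ln 2` using λ = 1.28 and K = 0.46 (values calibrated
for +1/−2-type nucleotide scoring), and e-values follow
`E = qlen · N · 2^(−S')` with `N` the total database length. A property
suite verifies that the aligner's optimal score equals an independent
full-matrix Smith–Waterman oracle on hundreds of random instances.

Numerical choices worth noting:

* **Linear gap model.** Gap columns cost a flat −2.5. Internally scores
  are stored as integers at twice their value so the half-point gap
  penalty stays exact; no floating-point accumulation occurs inside the
  dynamic program.
* **Windowed extension.** The full DP is run only inside the diagonal
  cluster's window (± one band). With at most a few edits per read this
  provably contains the optimal local path for seeded reads; the oracle
  tests exercise exactly this regime (reads ≥ 47 bp with ≤ 3 edits
  always contain a clean 11-mer by pigeonhole).

## The filter cascade

`recruit()` applies, in order:

1. **Thresholds** (`filter_hits()`): e-value strictly below 10⁻⁶,
   identity strictly above 70%, and query coverage
   `(|qend − qstart| + 1)/qlen` of at least 0.90. The strict/inclusive
   mix is deliberate and is pinned by boundary tests (a 70.0% identity
   hit dies; a 0.90 coverage hit survives).
2. **Within-genome deduplication** (`dedup_within_genome()`): one hit
   per (read, genome) pair — highest bit score, ties broken by longer
   alignment, then smaller subject start, so results are deterministic.
3. **Ribosomal masking** (`mask_ribosomal()`): any hit overlapping a
   masked rRNA-operon interval by at least 1 bp is removed, preventing
   conserved operons from inflating recruitment. Masks never change the
   genome length used for normalization.
4. **Competitive assignment** (`competitive_assign()`): each read goes
   to its best remaining genome (bit score, then identity, then
   lexicographic genome id), yielding at most one record per read.

Deduplication and filtering commute on aligner-shaped inputs (e-value a
monotone function of bit score within a read's hits on one genome);
masking commutes with the per-hit filter unconditionally. Both
properties are tested.

## Normalization and binning

The headline quantity is the recruitment rate

```
R = 100 · (r / D_s) · (10^6 / L_g)
```

the percentage of a sample's reads recruited per genomic megabase,
where `r` is the recruited read count, `D_s` the sample's sequencing
depth and `L_g` the full reference genome length. `build_matrix()` also
emits `r_norm = r · D_min / D_s`, the count rescaled to the smallest
depth among the included samples, so raw counts are comparable across
samples. Identity is stratified into a closed upper bin `[95,100]` —
reads at or above the conventional 95% ANI species threshold — and
`[70,95)` for related but distinct populations. Bins partition the
admissible range exactly; 95.0 belongs to the upper bin.

## Plots

`plot_recruitment()` draws the classic recruitment plot (read identity
against genome coordinate, marginal identity histogram in
1-percentage-point bins, horizontal line at the ANI threshold);
`plot_heatmap()` draws the sample × genome grid of log-scaled rates
with one row block per identity bin. Every image is accompanied by
sidecar TSVs that fully determine it; tests assert on sidecars, never
on pixels.

# Synthetic data and what it emulates

`gen_community()` builds reference genomes as uniform random DNA at a
chosen GC content, derives relatives at a target average nucleotide
identity (ANI), and records rRNA-operon masks and a truth table.
`sim_reads()` samples reads (default 150 ± 20 bp, a short-read length
scale) from a genome on either strand and corrupts them column-wise.

Two calibrations matter:

* **Read identity.** With target identity `p` and an indel fraction `f`
  among error events (default 0.1), the per-event match probability is
  solved so that the *realized* identity — matches over alignment
  columns, the quantity an aligner reports — has expectation exactly
  `p`. The truth-table mean is verified to land within ±0.005 of `p`.
* **Relative ANI.** Substitution and indel rates are solved from the
  expected alignment-column counts so that global-alignment identity
  between parent and child is within ±0.01 of the target; this is
  verified with an independent aligner. Indel events have geometric
  lengths with mean 1.5, and a net length change above 10% is rejected.

The generators emulate *identity structure*, not sequencing chemistry:
there are no quality scores, no position-dependent error profiles, no
GC-coverage bias, and genomes are random DNA rather than gene-bearing
sequences. They are sufficient for testing recruitment logic, which
only sees alignments.

## Known bias: trimmed-alignment identity inflation

Local alignment trims low-identity read ends, so the *reported* percent
identity of recruited reads exceeds the simulated per-column identity,
and the coverage filter preferentially keeps the better-preserved
reads. At `p = 0.98` and `p = 0.90` the recruited mean identity stays
within one point of `100·p`; at `p = 0.80` the inflation reaches ≈ +1.4
points under the default scoring and remains ≈ +1.2 under every
alternative scoring scheme we measured (e.g. +2/−3, +1/−1). This is a
property of local alignment itself, not a pipeline bug; the
corresponding low-identity recovery assertion in the acceptance suite
is expected to fail and documents the effect.

# Marker comparison (MLSA support)

`pairwise_identity()` uses end-gap-free ("overlap") global alignment:
terminal gaps are unpenalized and excluded, identity is matches over
aligned columns, and coverage is the aligned span over the first
sequence's length — the right convention when comparing a full-length
gene against partial database records. Nucleotide scoring is +1/−1 with
gap −2; protein comparisons are BLOSUM62-scored with *identity* (not
similarity) reported. Note that for unrelated sequences the trimmed
overlap can be short and high-identity; the reported coverage
disambiguates. `merge_amplicons()` assembles two overlapping amplicons
(either order, reverse complement recognized) by their best
suffix–prefix overlap of ≥ 30 bp with ≤ 2% mismatches.
`haplotype_census()` counts distinct haplotypes and polymorphic
columns, aligning only when lengths differ. `screen_by_reference()`
partitions sequences by strict identity to a reference (> 99% by
default).

# Proteorhodopsin annotation

`annotate_rhodopsin()` maps a query onto a bundled *synthetic*
249-residue reference scaffold laid out in the SAR86 eBAC31A08
numbering convention: proton acceptor Asp97, proton donor Glu108,
spectral-tuning position 105, retinal-binding Lys231, and seven
hydrophobic transmembrane stretches separated by loops of ≥ 9 residues.
The scaffold is constructed, not a database record — no real sequence
is bundled — but it preserves the coordinate frame the literature uses,
and `gen_pr_protein()` derives divergent queries from it with truth
attributes.

Spectral classification follows the tuning residue: methionine or
leucine → green absorption (518–535 nm); glutamine → blue (~490 nm,
recorded as the point value 490 with the approximation noted in the
output). Transmembrane helices are predicted by Kyte–Doolittle mean
hydropathy over a 19-residue window with cutoff 1.6; above-cutoff runs
merge when closer than 3 positions, expand by half a window (clipped at
run midpoints so intervals stay disjoint), and must span ≥ 15 residues.
Queries are declared unmappable, rather than guessed at, when the
aligned identity to the scaffold falls below 40% or fewer than 50
columns align.

# Worked example

```{r example, eval = FALSE}
com <- gen_community(community_spec(
  genomes = data.frame(id = "gA", length = 20000, gc = 0.45, n_contigs = 1),
  relatives = data.frame(parent = "gA", id = "gB", ani = 0.85,
                         indel_rate = 0.002),
  seed = 7))
db <- build_db(com)
rs <- sim_reads(com, read_sim_spec("gA", n_reads = 300, identity = 0.97,
                                   seed = 2))
rec <- recruit(local_align(rs$reads, db), db)
meta <- sample_meta(data.frame(sample_id = "s1", total_reads = 1e6))
build_matrix(list(s1 = rec), meta, db)
```

Problem sizes throughout (20 kb genomes, hundreds of reads) are the
package's own choice: large enough for stable statistics, small enough
that the entire suite runs in minutes on one CPU.

# Decisions on under-specified points

* Default read length 150 ± 20 bp and indel fraction 0.1 are generator
  defaults chosen to resemble short-read data; every test sets them
  explicitly where they matter.
* `r_norm` uses the smallest sequencing depth among the samples present
  in the matrix (`D_min`), recorded as an attribute.
* The rhodopsin reference is synthetic (see above); feature positions
  are reported in its frame.
* The aligner's windowed extension and linear gap model are documented
  approximations; the DP-oracle property tests define the accuracy
  contract.
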