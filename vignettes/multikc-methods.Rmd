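---
title: "Methods: Multiple-k/Multiple-C assembly, depletion, annotation and depth-based abundance"
author: "multikc"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: Multiple-k/Multiple-C assembly, depletion, annotation and depth-based abundance}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(multikc)
```

# The problem

De novo transcriptome assembly of short single-end RNA-seq reads from an
organism without a reference genome faces a dilemma: any single de Bruijn
assembly is tuned by two coupled parameters — the hash length $k$ (the
k-mer size of the graph) and the coverage cutoff $C$ (the minimum k-mer
multiplicity a node must *exceed* to survive pruning) — and no single
$(k, C)$ recovers both tails of a heavily skewed expression distribution.
Rare transcripts survive only permissive settings (small $k$, low $C$),
while very abundant transcripts accumulate so many recurrent sequencing
errors that their graphs at low $C$ are riddled with spurious branches and
only a higher cutoff yields clean paths. The Multiple-k/Multiple-C
strategy runs the assembler over a grid of $(k, C)$ settings, depletes
each contig set of redundancy, pools the survivors, depletes again, and
annotates the merged set — trading compute for sensitivity.

In the aphid system this package emulates, the sequenced RNA additionally
mixes three sources: the insect host (polyadenylated mRNA), an obligate
primary endosymbiont (*Buchnera*-like: AT-rich, abundant, and **not**
polyadenylated, so depleted by each round of polyA selection), and rare
facultative secondary endosymbionts visible essentially only through
rRNA-like fragments.

# Pipeline stages

## De Bruijn assembly (`build_graph`, `apply_coverage_cutoff`, `assemble`)

Nodes are canonical k-mers — the lexicographic minimum of a k-mer and its
reverse complement, since strand is unobservable in unstranded RNA-seq —
with multiplicity equal to the number of read k-mers mapping to them.
Edges record strand-aware $(k{-}1)$-overlap adjacencies observed between
consecutive read k-mers. The coverage cutoff removes every node with
multiplicity $\le C$ ($C = 0$ is the identity). Dead-end paths shorter
than `tip_clip_len` (default $2k$) whose mean multiplicity is below the
graph median are clipped iteratively; then maximal unambiguous paths
(unitigs) are compressed and emitted as contigs of at least
`min_contig_len` (default 100 nt). No bubble popping or scaffolding is
attempted: unitigs only, which keeps every emitted contig a literal walk
of the surviving graph.

Determinism is part of the contract: contigs are reported in their
lexicographically smaller orientation, ordered by decreasing length then
sequence, with ids `{sample}_k{k}_C{C}_{serial}` so provenance survives
pooling. k-mers are 2-bit packed (A<C<G<T keeps integer order equal to
lexicographic order), supporting $k \le 63$.

## Redundancy depletion (`deplete`, `pool_and_deplete`)

Greedy incremental clustering in the CD-HIT style: contigs are processed
in decreasing length order (ties by id), and each contig joins the first
existing cluster whose representative it matches at identity $\ge$
`identity_threshold` (default 0.95), otherwise it founds a new cluster.
Identity is computed from an exact end-free alignment (+1 match, −1
mismatch, −2 gap, both strands) as **matches divided by the full length
of the shorter sequence** — the CD-HIT global-identity convention. We
deliberately do not divide by the aligned span: under a span denominator
any chance 15–20 nt exact match between unrelated contigs scores identity
1.0, and on pooled multi-cell sets this merges unrelated contigs wholesale
(in development it halved read-back coverage). With the global
denominator a contained contig still scores 1 and collapses, while a
partial overlap is penalised by its unaligned remainder.

Candidate representatives are pre-filtered by exact `word_size`-mers
(default 8 nt): a representative is aligned only when it shares at least
`min_shared_words` (default 8, capped by what either sequence can
contain) distinct words with the query. A substitution-bounded match at
95% identity over ≥ 100 nt shares dozens of 8-mers, so the filter is
conservative there; it exists because at word size 8 the $4^8$ word space
saturates on pooled sets and a single-shared-word rule filters nothing.
The alignment itself is an exact full dynamic program rather than a
banded one — desk-scale contig lengths (≤ a few knt) do not need the
band, and exactness keeps the clustering identical to its brute-force
oracle.

## The Multiple-k/Multiple-C merge (`run_multikc`)

Default grid: $k \in \{21, 25, 31, 41\}$, $C \in \{2, 6\}$, bracketing
the single best-performing cell reported for this kind of data
($k = 31$, $C = 6$) on both sides. Each cell is assembled and depleted,
the per-cell survivors are pooled per sample and depleted again, and the
result is length-filtered. Depleting per cell *before* pooling follows
the published procedure verbatim. By construction the merged set's
transcript recovery (distinct reference transcripts that are the top
annotation hit of at least one contig) is a superset of every single
cell's recovery; the scientific claim tested on synthetic data is that it
is *strictly* larger than the best cell's when abundance is heterogeneous.

## Read-back mapping and depth (`map_reads`, `compute_depth`)

Each read counts toward exactly one contig: its minimum-mismatch
placement within `max_mismatches` (default 3, the bounded-mismatch regime
of MAQ-generation mappers), both strands, ties broken by (fewest
mismatches, lexicographically smallest contig id, smallest start,
forward strand first). Mapping is seed-and-verify with a pigeonhole
guarantee: the read is split into `max_mismatches + 1` non-overlapping
exact seed chunks of length `min(seed_length, floor(read_len /
(max_mismatches + 1)))` (18 nt for 75-nt reads at 3 mismatches), so every
placement within the limit is found and the mapper is provably equivalent
to an exhaustive scan — the property its oracle test asserts. Unmapped
reads are counted separately; mapped + unmapped always equals the total.

Relative abundance is the per-nucleotide depth
$\mathrm{depth} = n_\mathrm{reads} \times \mathrm{read\_length} /
\mathrm{contig\_length}$, rounded half-even to 2 decimals; top-N tables
report the fold range (max/min of the listed read counts, 1 decimal).
RPKM-style normalisation is deliberately out of scope: without a genome
the transcript universe is unknown, and the source analysis rejected it.

## Cascade homology annotation (`annotate_contigs` and reporters)

Tier 1 (translated): the six-frame translation of each contig is searched
against frame-0 reference peptides with exact 4-mer seeds, ungapped
X-drop-20 extension and BLOSUM62 scoring. Tier 2 (nucleotide, +2/−3,
11-mer seeds) is attempted only for contigs with no tier-1 hit — the
cascade is exclusive, so {translated, nucleotide, none} partitions the
contig set. E-values use the Karlin–Altschul form
$E = K m n e^{-\lambda S}$ with $m$ the query length, $n$ the total
database length, and published ungapped defaults
(protein $\lambda = 0.3176$, $K = 0.134$; nucleotide $\lambda = 1.28$,
$K = 0.46$); any calibration honouring the cutoff semantics
(e-value ≤ 1e−3, HSP length ≥ 33) would serve, so the constants are
configuration recorded in the run manifest. Exactly one top hit is
reported per contig (lowest e-value, ties by higher score then hit id).
Frame-0 peptides are a legitimate reference proteome here because the
synthetic references are generated as plain nucleotide strings and their
frame-0 translation is, by construction, the protein the translated tier
should recover; stop codons translate to `*`, which BLOSUM62 scores.

Reporting operations are plain arithmetic with fixed printed precision:
non-redundant hit counting (distinct hit ids), overlap summaries
(percentages of the union, 1 decimal), taxon distributions (2 decimals),
gene-set recovery (2 decimals, totals row), and reference coverage (union
of aligned intervals via `IRanges::reduce`, integer percent). Internal
coordinates are 0-based half-open; everything user-visible is 1-based
closed.

# The synthetic transcriptome generator

`generate_reference()` + `simulate_reads()` define the study conditions
for every test:

* **Host**: 60 transcripts by default, 400–2500 nt, GC 0.50,
  polyadenylated, log-normal abundance (meanlog 0, sdlog
  `abundance_sigma` = 1.5 — heavy-tailed, reproducing the orders-of-
  magnitude depth spread real top-10 tables show).
* **Primary endosymbiont**: 15 transcripts, 300–1500 nt, GC 0.30
  (AT-rich, so taxon separation is learnable by alignment), not
  polyadenylated, abundance multiplied by 6 — abundant in the raw RNA
  pool, depleted by polyA selection.
* **Secondary endosymbiont**: 5 rRNA-like fragments, 150–800 nt, GC
  0.30, weight factor 0.05 — rare, detectable chiefly at the nucleotide
  tier.
* **Selection and reads**: each polyA round retains
  `nonpolyA_retention_per_round` (default 0.46) of non-polyadenylated
  molecules; the default library does 2 rounds. The default retention is
  calibrated so that with one selection round and the expected class
  weight shares (host ≈ 52% of the raw sequence mass, primary
  endosymbiont ≈ 48%) the expected non-polyA read fraction is ≈ 30%, the
  regime a single-round library exhibits; two rounds push it to ≈ 16%.
  `calibrate_retention()` solves the retention for a target fraction on
  a realised reference.
  Reads are drawn by fragment sampling — transcript selection probability
  proportional to abundance x length x retention, the standard RNA-seq
  model under which the expected per-nucleotide depth of a transcript is
  proportional to its molar abundance — with uniform start positions.
  Reads are fixed-length (75 nt), single-end, substitution errors only at
  `error_rate` 0.005 (indels are out of scope because the emulated
  mappers count mismatches only), constant placeholder qualities, truth
  labels carried in the FASTQ description.

RNG consumption order is documented in `?generate_reference` and
`?simulate_reads` so each stream can be re-drawn independently in tests;
the reference uses `seed`, the read simulator `seed + 1`.

What the generator does **not** emulate — and what passing tests therefore
do not show about real data: shared domains, gene families and isoforms
(sequences are i.i.d., so cross-transcript k-mer collisions are rare and
real-repeat fragmentation is untested), coverage bias along transcripts,
quality-correlated errors, indels, variable read lengths, rRNA secondary
structure, and any real phylogenetic signal in the taxon labels.

# Numerical and design choices

* **Depth rounding**: half-even to 2 decimals via `round()`; fold range
  1 decimal; percentage precisions as printed in the tables each
  reporter mirrors.
* **Tip definition**: dead-end path < `tip_clip_len` (default $2k$) with
  mean multiplicity below the median of the post-cutoff graph, clipped
  iteratively to a fixed point. The median is computed once, before
  clipping.
* **Cycles**: a perfectly circular component is spelled linearly starting
  from its lexicographically smallest node.
* **Degenerate inputs**: empty contig sets produce all-zero statistics,
  not errors; empty references and empty grids are validation errors
  naming the offending field.
* **"Best single cell"**: where the multi-k/multi-C gain is measured,
  the comparator is the cell with the highest transcript recovery (the
  strongest competitor), and the merged set is additionally asserted to
  dominate every cell individually.
* **Problem sizes in the checks**: the stochastic acceptance properties
  run 10 seeded replicates each — 20 host + 5 primary + 2 secondary
  transcripts at 12k reads (abundance sdlog 2.0) for the recovery-gain
  property, and 30 + 7 + 3 at 15k reads (defaults otherwise) for the
  abundance-recovery property, where the Spearman correlation is computed
  per replicate over the transcripts recovered as single contigs and the
  criterion is applied to the mean across replicates (per-replicate
  sample sizes of ~12–20 make the individual estimates noisy). The
  end-to-end demonstration uses the full default conditions
  (80 transcripts, 50,000 reads, 4×2 grid). Sizes were chosen so an
  assembly sits near the coverage regimes of interest (both tails
  populated) while a complete run stays desk-scale.
* **Determinism**: stage logs (timings) go to messages, never into the
  report bundle, so two runs with one configuration are byte-identical;
  the manifest records parameters, seed and MD5 checksums of every file.

# Known limitations

Unitig-only assembly understates contiguity relative to Velvet's full
heuristics (no bubble popping means every recurrent error splits a
contig); the clustering is greedy and order-dependent by design, matching
CD-HIT semantics rather than an optimal clustering; translated-tier
sensitivity below ~100 nt of overlap is intentionally zero (HSP length
cutoff 33 residues), which is what pushes short true homologies to the
nucleotide tier; and e-values are calibrated for ungapped local
alignments on i.i.d. sequences, so they are comparable within a run, not
across databases. Genome-scale counts from real libraries (hundreds of
thousands of contigs, tens of thousands of non-redundant hits) are out of
reach at desk scale and are covered qualitatively, not numerically, by
the synthetic experiments.
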