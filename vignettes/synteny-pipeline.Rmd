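---
title: "Multi-genome synteny detection and visualization with synviz"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Multi-genome synteny detection and visualization with synviz}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

## The problem

Synteny — conservation of the order of loci along chromosomes — is the most
direct genome-scale evidence for shared ancestry, and its interruptions mark
inversions, translocations, expansions and horizontal transfer. Given two or
more annotated genome assemblies, `synviz` predicts ortholog groups from
all-vs-all protein similarity, chains collinear ortholog pairs into syntenic
blocks, lays out each genome's scaffolds so the blocks between vertically
adjacent genome tracks cross as little as possible, and draws the result as
a ribbon figure in PDF. Every graphical choice is recorded in a config file
that the first run generates and the user may edit and re-apply.

## Pipeline model

The pipeline is a fixed sequence of stages, each independently invokable and
each writing a fixed-name intermediate into the working directory:

1. **validate** — the repository specification (Repo_spec) names, per
   genome, a genome FASTA, cds FASTA, pep FASTA and GFF3 annotation. The
   four files must be mutually consistent: every peptide/cds id must resolve
   (after stripping a final `.t<N>` transcript suffix) to a gene feature,
   every gene must have a peptide and a cds, every feature must lie on a
   scaffold of the genome FASTA within its length, and gene ids must be
   unique. Validation never throws: it returns a report of failures so the
   user sees all problems at once.
2. **build db** — per-genome summaries (scaffold count, gene count, total
   bp) plus the feature and scaffold-length tables downstream stages use.
3. **cluster** — either reciprocal best hits followed by single-linkage
   clustering (`rbh`, the scalable path), or Markov clustering of the
   weighted hit graph (`mcl`, the gene-family path). See below.
4. **chain** — a DAGchainer-style dynamic program per scaffold pair groups
   ortholog pairs into maximal-scoring collinear chains (forward or
   reversed), serialized as `aligncoords` (per-pair lines) and
   `aligncoords.spans` (per-chain genomic spans).
5. **layout** — scaffold order and orientation per genome, chosen to reduce
   ribbon crossings between adjacent tracks; serialized into the editable
   config file together with all graphical parameters.
6. **render** — the figure: one horizontal track per genome with scaffold
   border ticks, scaffold labels suffixed `+`/`-`, gene boxes above the
   track line, and one translucent quadrilateral ribbon per span between
   adjacent tracks (default color `azure4`; up to three gene-category
   highlight colors; per-scaffold highlight colors override ribbon fill).

Clustering and chaining are cached by a content+parameter hash, so editing
the config and re-running the pipeline re-renders without re-clustering.

## Orthology

**Best hits.** For each query gene and each target genome the hit with the
maximal bitscore is kept; ties break by smaller e-value, then by
lexicographically smaller subject id, making the result deterministic.
Bitscore rather than e-value is the primary criterion because e-values
saturate at zero on strong hits while bitscores keep discriminating.
Within-genome and self hits never enter best-hit selection. A pair is a
reciprocal best hit (RBH) when each gene is the other's best hit into its
genome; single-linkage clusters are then simply the connected components of
the RBH graph. No e-value or identity cut-off is applied before best-hit
selection by default — on the data regimes this tool targets the reciprocal
requirement already filters weak hits — but an optional pre-filter is
exposed (`--rbh-max-evalue`).

**Markov clustering.** The `mcl` path builds an undirected graph over genes
with edge weight `-log10(evalue)` (e-values floored at 1e-250 so weights
stay finite; the floor is applied only at graph construction, never at
parse time). Within-genome hits are kept here — MCL is the path intended to
group in-paralogs into families — while self hits are always discarded. The
classic MCL loop is implemented directly on column-stochastic sparse
matrices: self loops at each node's maximum incident weight, then
expansion (matrix self-product), inflation (entry-wise power, default 1.5,
with column renormalization), and pruning of entries below 1e-5, iterated
until the largest entry change falls below 1e-6 (default cap 100
iterations; non-convergence warns and clusters the current state). Clusters
are the connected components of the converged nonzero structure; singletons
are dropped. The original OrthoMCL wrapper additionally normalizes
inter-species weights before running mcl; that normalization is not
reproduced here — the graph is clustered on raw `-log10(evalue)` weights —
because no formula for it is part of this package's contract and the
clustering character is preserved without it.

## Chaining

Chaining runs in gene-rank space: each gene gets a dense 0-based index
along its scaffold by start coordinate, and gaps are counted in skipped
gene ranks, which makes scoring robust to intergenic-length variation.
Defaults: minimum 5 pairs per chain, maximum rank gap 20, gap penalty -3
per skipped rank, match score `min(50, -log10(evalue))` (50 when no hit
evidence exists), pair-inclusion e-value ceiling 1e-5. All are CLI-exposed;
the values follow common practice for gene-rank collinearity chaining since
the underlying publication prints none, so the exact blocks of its figures
are not claimed to be reproduced.

The DP considers predecessors with strictly smaller ranks on both axes
within the gap limit; the reverse orientation is handled by negating the
B-axis ranks. Chains are extracted greedily — the best-scoring endpoint
first, forward and reverse passes competing, each match consumed by at most
one chain, DP recomputed on the remainder — which is deterministic;
simultaneous optimal multi-chain extraction is out of scope. Tandem
duplicates (several matches sharing a rank) are legal input; strict
inequality in the DP uses at most one per chain. Chains shorter than
`min_pairs` or with non-positive score are discarded after their matches
are consumed.

## Layout

"Clearest image with minimum overlap" is operationalized as the
ribbon-crossing count between adjacent tracks: each span projects to its
midpoint plot coordinate on both tracks and crossings are counted as order
inversions (merge-sort count, identical to the O(n^2) pairwise
definition). Exact one-sided crossing minimization is NP-hard, so the
layout uses a single top-down barycenter pass: the top genome is placed by
descending scaffold length, all `+`; each subsequent genome's scaffolds are
sorted by the span-length-weighted median of their partners' plotted
midpoints on the track above, with spanless scaffolds appended by
descending length.

Orientation is a weighted vote: every span votes with its pair count,
`forward` spans voting to keep the placed orientation of the upper partner
scaffold and `reverse` spans voting to flip it; a scaffold is drawn `-`
when flip votes win, ties resolving to `+`. The vote is span-level rather
than a between-span Kendall count because a wholly inverted scaffold
typically produces a *single* reverse chain — there is nothing pairwise to
count — while the span's own orientation carries exactly the needed signal.
Because votes are taken relative to the upper track's placed orientation,
inversion states propagate down the track stack consistently.

The descending-length baseline is intentionally *not* used as a fallback
when it happens to score fewer midpoint crossings: midpoint projection is
blind to the within-span twisting that orientation recovery fixes, and on
rearranged genomes the barycenter layout empirically dominates the baseline
(asserted over 20 seeded replicates in the acceptance suite) while
preserving recovered inversions.

Genome (track) order is the Repo_spec order; the config may permute it, and
per-genome `order = sc1:+,sc3:-,...` lines override scaffold order and
orientation verbatim, even when that worsens crossings — manual control
wins. Config parsing ignores unknown keys with a warning, fills missing
keys with defaults, and hard-errors on malformed orientations, unknown
scaffolds, or more than three category colors.

## Rendering

Coordinates stay 1-based inclusive (the GFF3 convention) through the whole
pipeline; only `compute_geometry` converts to continuous plot units, with an
affine map per scaffold (`offset + (bp-1)/scale` for `+`, mirrored for
`-`). This removes off-by-one churn at every format boundary. Page size
defaults to 11 x (2 + 1.5 per genome) inches; ribbons are straight-edged
translucent quadrilaterals; category-colored gene boxes draw after black
ones so highlights are never occluded; colors are the full R color
vocabulary plus `#RRGGBB` hex. The PDF is written uncompressed so tests can
inventory its drawing operators (rectangles, filled polygons, stroked
segments, text runs) and compare them against the expected element counts;
determinism is asserted on this inventory and on byte-identical
intermediates, not on PDF bytes, which embed a creation timestamp.

## The simulator and what a green test establishes

The generator models gene-level evolution only: an ancestor of `n_genes`
genes is dealt in order onto `n_scaffolds` scaffolds, and each genome
derives from it by per-gene loss (probability, default 0.05), tandem
duplications, inversions and translocations (Poisson-sampled expected
counts per lineage, defaults 2 and 1). An inversion reverses a contiguous
gene block and flips strands; with probability 0.25 it covers the whole
scaffold — chromosome-scale inversions are a common feature of the fungal
comparisons this tool family targets, and the whole-scaffold case is what
the layout's orientation recovery must detect, so it is exercised
deliberately. Intergenic gaps are resampled per genome (100-400 bp), cds
lengths are 300-900 bp, and every descendant of one ancestral gene reuses
that family's cds/pep sequence, so sequence similarity between true
homologs is maximal while sequences remain decorative — the m8 tables, not
the sequences, drive the pipeline.

Hit tables are generated from the truth ledger: every true homolog pair
yields a reciprocal record pair with bitscore `400 - offset(family) +
N(0, sd)` where the per-family divergence offset is Uniform(0, 100), and
e-value `10^(-bitscore/2)` floored at 1e-250 (any monotone link suffices to
test best-hit logic; this one spans realistic magnitudes). A true match is
dropped *as a whole* — both directions — with `missing_hit_rate`: the
dropout models the aligner failing to report a similarity, and dropping
directions independently would make the nominal 5% missing rate imply an
RBH recall floor of 0.9025, at odds with the 0.9 recovery contract the
noisy-recovery test asserts. Spurious cross-family hits (bitscore
Uniform(50, 80)) are added at a configurable rate per true hit. All
randomness flows from one integer seed; equal parameters give byte-identical
output files.

A green suite therefore establishes: exact agreement with brute-force
oracles for best hits, RBH, single-linkage, chain scoring and crossing
counts; exact truth recovery on noise-free simulations; >= 0.9
precision/recall under the stated noise; and format round-trip identity. It
does *not* establish behavior on real aligner output (score ties, partial
alignments, fragmented annotations), nucleotide-level evolution, or layout
quality beyond the crossing metric.

## Numerical and degenerate-input choices

* Numeric fields round-trip through text at 1e-9 relative tolerance
  (`%.10g`); e-values of exactly 0 are parsed and preserved, floored only
  when log-transformed.
* Parsers never silently drop lines; every parse error carries the line
  number.
* MCL columns are renormalized after pruning so the matrix stays stochastic
  (the acceptance suite asserts column sums within 1e-9 at every
  iteration).
* Empty inputs are legal everywhere they can be: empty chain lists write
  empty files that read back empty; a genome without spans to its upper
  neighbor falls back to descending-length order with a warning.
* `threads` parallelizes chaining over scaffold-pair groups with
  order-preserving collection, so output is byte-identical for any thread
  count.

## Known limitations

* OrthoMCL's inter-species weight normalization is simplified away (above).
* Ribbons connect vertically adjacent tracks only; all-pairs ribbons and
  circular layouts are out of scope.
* Ordering is heuristic; pathological span sets can defeat the barycenter
  pass even though the acceptance replicates do not.
* The aligncoords/spans/Repo_spec/config dialects are fixed by this package
  and are not claimed byte-compatible with other tools' private formats.
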