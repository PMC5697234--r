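# synviz

Multi-genome synteny detection and visualization in R.

`synviz` is for comparative genomicists who have two or more annotated
genome assemblies (genome/cds/pep FASTA + GFF3 per genome) plus all-vs-all
protein similarity in 12-column tabular ("m8") format, and want a
publication-style overview of genome-wide synteny: which blocks of gene
order are conserved between genomes, where inversions and translocations
broke them, and which genes of interest sit inside them. A built-in
simulator generates fully in-silico repositories with a known evolutionary
truth, so the entire pipeline is testable without any downloads.

## What it computes

1. **Ortholog clusters.** Either reciprocal best hits (RBH) — for each gene
   and target genome keep the maximal-bitscore hit; pair genes that are
   mutually best; take connected components (single linkage) — or Markov
   clustering (MCL) of the hit graph weighted by `-log10(evalue)`:
   alternate expansion `M %*% M` and inflation (entry-wise `M^r`, default
   `r = 1.5`, with column renormalization and pruning at 1e-5) until the
   column-stochastic matrix converges; clusters are the components of the
   nonzero structure.
2. **Syntenic chains.** A DAGchainer-style dynamic program in gene-rank
   space per scaffold pair: `score(i) = match(i) + max(0, max_j score(j) +
   g * (Δrank_a - 1 + Δrank_b - 1))` over predecessors `j` with strictly
   increasing ranks on both axes and rank gaps ≤ 20, gap penalty `g = -3`,
   match score `min(50, -log10(evalue))`; reverse-orientation chains come
   from the same DP with negated B ranks. Chains need ≥ 5 pairs by default.
3. **Layout.** Scaffold order per genome by a barycenter pass
   (span-length-weighted median of partner midpoints on the track above);
   orientation by a pair-count-weighted vote of span orientations; crossing
   quality measured as the inversion count of span midpoints between
   adjacent tracks.
4. **Figure.** One track per genome, scaffold border ticks, `+`/`-`
   suffixed scaffold labels, gene boxes, and translucent ribbons (default R
   color `azure4`) between adjacent tracks, written as PDF. Everything is
   driven by a generated, hand-editable config file.

## Worked example

Simulate three related genomes (120 ancestral genes on 2 scaffolds; one
expected inversion and translocation per lineage, 5% gene loss), generate
consistent hit tables, and run the whole pipeline:

```r
library(synviz)

sim <- simulate_repository(
  simulation_params(n_genomes = 3, n_genes = 120, n_scaffolds = 2,
                    inversions = 1, translocations = 1, gene_loss = 0.05,
                    seed = 2026),
  "demo")
simulate_hits(sim$ledger, "demo/m8")
res <- run_pipeline(sim$spec_path, "demo/m8", "demo/work")

res$db
#> <repo_db: 3 genomes, 340 genes, 6 scaffolds>
#>   genome_id n_scaffolds n_genes total_bp
#> 1        G1           2     115    94956
#> 2        G2           2     113    93959
#> 3        G3           2     112    92267

res$n_clusters   # ortholog clusters recovered from the hit tables
#> [1] 119
res$n_chains     # collinear blocks across the three genome pairs
#> [1] 16

res$plan
#> <layout_plan: 3 genomes, scale 1.005e+04 bp/unit>
#>   G1: sc1:+,sc2:+
#>   G2: sc1:+,sc2:+
#>   G3: sc1:+,sc2:-
```

The per-genome gene counts reflect the simulated 5% loss; the 119 clusters
are the 120 ancestral families minus one lost from every genome. `sc2:-` on
G3 is the layout recovering a simulated scaffold inversion: G3's sc2 is
drawn mirrored so its ribbons to G2 run parallel instead of crossing. The
figure lands in `demo/work/synteny.pdf`; its element inventory can be
verified directly:

```r
unlist(pdf_inventory(res$files$pdf))
#>    n_rect n_polygon n_segment    n_text     valid
#>       340         9        15         9         1
```

340 gene boxes (one per annotated gene), 9 ribbons (spans between adjacent
tracks), 15 segments (3 track lines + 12 scaffold border ticks), 9 text
labels (6 scaffold labels + 3 isolate names).

The first run wrote `demo/work/synteny.config`:

```
# synteny figure configuration
# edit values and re-run the render stage; '#' lines are comments
[global]
width = 11
height = auto
ribbon_color = azure4
ribbon_alpha = 0.6
gene_box_color = black
...
[genome:G3]
order = sc1:+,sc2:-
```

Edit it (re-order or re-orient scaffolds, change colors, highlight up to
three gene categories or individual scaffolds) and re-run `run_pipeline()`
with the same working directory: clustering and chaining are cached, only
layout and rendering re-execute, and your edits are applied verbatim.

Chains are plain text in `demo/work/aligncoords` (one header plus one line
per ortholog pair):

```
## alignment G1:sc1 vs G2:sc1 Alignment #1 score = 2074 (forward)
sc1  G1_g00001  180   839   sc1  G2_g00001  141   800   50
...
```

## Command line

```sh
Rscript -e 'synviz::main()' -- pipeline --repo-spec repo_spec.txt \
    --m8-dir m8/ --work-dir out --clusterer rbh
Rscript -e 'synviz::main()' -- simulate --n-genomes 4 --n-genes 300 --seed 1 --out-dir sim
```

Subcommands: `validate`, `simulate`, `cluster`, `chain`, `layout`,
`render`, `pipeline`. Stage-level runs consume the previous stage's files,
so externally produced `aligncoords` files can enter at the render step.

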