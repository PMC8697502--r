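# pathsift

Interpreting a transcriptomic experiment usually ends with three loosely
coupled artifacts: an expression matrix, a differential-expression (DE)
table, and a functional-enrichment table produced by one of many tools,
each in its own export format. The interesting questions — *which pathways
move, in which direction, driven by which genes, and which of these hundred
overlapping terms actually say the same thing?* — live at the intersection
of all three. `pathsift` is an R toolkit for that interpretation step. It is
aimed at analysts and core facilities who already ran quantification, DE
testing and enrichment testing elsewhere and now need to harmonize, score,
summarize and report the results reproducibly.

## What it computes

**Harmonization.** "Shaker" converters turn the native outputs of topGO,
clusterProfiler, DAVID, Enrichr, g:Profiler and fgsea (plus GMT collections
and a generic dialect) into one schema: `gs_id`, `gs_description`,
`gs_pvalue`, member genes, and DE-membership counts. The four inputs —
counts, DE table, enrichment table, annotation — combine into a validated,
JSON-serializable `geneset_bundle`.

**Expression-aware geneset scores.** With `up` and `down` the number of a
geneset's up- and down-regulated DE members (padj ≤ threshold, direction by
sign of log2FC), the direction Z-score is

    z = (up − down) / √(up + down)

and the aggregate score is the mean (or median) log2FC over the DE members.
Sample-wise activity follows a GSVA-like construction: counts are
transformed toward homoscedasticity (size-factor-normalized shifted log by
default), each gene row is standardized, Z<sub>ij</sub> = (T<sub>ij</sub> −
T̄<sub>i</sub>)/sd<sub>i</sub>, and the score of geneset *k* in sample *j*
is the mean of Z<sub>ij</sub> over the geneset's DE members P<sub>k</sub>:
GS<sub>kj</sub> = |P<sub>k</sub>|⁻¹ Σ<sub>i∈P_k</sub> Z<sub>ij</sub>.

**Graphs.** Gene–geneset bipartite membership graphs; weighted unipartite
projections with a disparity-filter backbone (retain an edge of weight w at
an endpoint of degree k and strength s when (1 − w/s)^(k−1) < α); enrichment
maps over Jaccard / overlap / Cohen-kappa similarity with greedy-modularity
or label-propagation communities and per-community representative sets.

**Redundancy reduction.** DAVID-style kappa fuzzy clustering (seeding +
multilinkage merging), greedy overlap-coefficient term reduction, classical
MDS layouts and average/complete-linkage dendrograms (Newick export).

**Reporting.** Every visual summary (geneset volcano, per-gene contribution
strips, score heatmaps, summary heat matrices, signature volcano/heatmap,
spider traces) is computed as a testable `plot_data` object, serializable to
JSON and renderable to SVG/PNG/PDF. `happy_hour()` assembles a
self-contained, byte-deterministic HTML report around bookmarked genes and
genesets, embedding for each figure the exact command that regenerates it.
A `cli()` entry point wires `fixture | validate | shake | score | graph |
distill | viz | report` for scripted use.

A seeded synthetic-data generator (`generate_fixture()`) produces complete
bundles with planted DE genes and planted enriched genesets plus a truth
file, and backs the test suite end to end.

## Worked example

```r
library(pathsift)

fx <- generate_fixture(fixture_spec(seed = 42))   # 500 genes, 4 vs 4, 40 sets
b  <- fx$bundle
b
#> geneset_bundle: 500 genes x 8 samples, 24 DE (padj <= 0.05), 40 genesets

enr <- compute_aggregate_scores(b$enrichment, b$de, b$annotation)
top <- top_genesets(enr, 5)
data.frame(gs_id = top$gs_id, p = signif(top$gs_pvalue, 3),
           z = round(top$z_score, 3), aggr = round(top$aggr_score, 3))
#>   gs_id        p     z  aggr
#> 1 GS003 6.46e-09 3.162 2.174
#> 2 GS001 2.52e-06 1.633 1.427
#> 3 GS002 3.67e-06 2.828 2.233
#> 4 GS004 4.88e-06 1.633 1.397
#> 5 GS032 3.61e-02 0.577 0.706

fx$truth$planted_enriched
#> [1] "GS001" "GS002" "GS003" "GS004"
```

The four genesets planted as enriched in the up-regulated DE pool rank at
the top and carry positive direction Z-scores (`z > 0` means more
up-regulated than down-regulated DE members; 3.162 = (10 − 0)/√10 for a set
with ten concordant members). Sample-wise scores separate the groups —
control samples sit below the gene-wise mean for the planted sets:

```r
z  <- compute_gene_z(transform_counts(b))
sc <- compute_geneset_scores(z, enr, b$de, b$annotation)
round(sc$values[1:3, 1:4], 3)
#>       sample_01 sample_02 sample_03 sample_04
#> GS001    -0.696    -0.578    -0.661    -0.423
#> GS002    -0.998    -1.073    -0.728    -0.737
#> GS003    -0.909    -1.014    -0.869    -0.732

em <- detect_communities(build_enrichment_map(enr, n_gs = 10), seed = 1)
attr(em, "representatives")
#>   community gs_id n_members
#> 1         1 GS004         3
#> 2         2 GS003         3
#> 3         3 GS005         1
#> ...
```

The planted sets collapse into two redundant communities represented by
their most significant members; the remaining singletons are background.
A report around the strongest hit:

```r
bm <- bookmark(bookmarks(), "geneset", "GS003", b)
happy_hour(b, bm, list(bundle_path = "bundle.json"), "report.html",
           timestamp = "2026-01-01")
```

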