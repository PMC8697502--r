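---
title: "Methods: scoring, graphing and distilling enrichment results"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: scoring, graphing and distilling enrichment results}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(pathsift)
```

This vignette documents the models and procedures implemented in
`pathsift`, the assumptions behind them, the defaults and why they were
chosen, and the places where the design was genuinely open. It states no
empirical result that the test suite does not itself compute.

## The data model

A `geneset_bundle` holds the four artifacts of a finished transcriptomic
analysis: a non-negative counts matrix with a sample table, a DE result
table (`gene_id`, `log2fc`, `pvalue`, `padj`), a harmonized enrichment
table, and an annotation bridging stable gene identifiers to the symbols
enrichment tools emit. Expression and DE are keyed by stable ids; genesets
by symbols; the annotation is the only bridge. When a symbol maps to several
ids, the first match in annotation order is used and the ambiguity is
surfaced by `validate_bundle()` — the data cannot resolve it, so the rule is
deterministic rather than clever.

One DE-calling rule is used everywhere: a gene is DE when `padj <=
de_threshold` (default 0.05), with a missing `padj` treated as 1. Treating
filtered genes as never-DE is the conservative choice and mirrors how
independent-filtering pipelines intend their NAs to be read. Direction is
the sign of `log2fc`; a gene with `log2fc == 0` counts in neither direction.

Bundles serialize to a single versioned JSON container. Doubles are written
with 17 significant digits because the default JSON formatting is not
bit-exact, and `read_bundle(write_bundle(b))` is contractually `identical()`
to `b`; integer-looking columns are coerced back to double on read for the
same reason.

## Geneset scores

Two summaries inject DE information into the enrichment table
(`compute_aggregate_scores()`):

* the direction Z-score `z = (up − down)/sqrt(up + down)` over the
  geneset's up- and down-regulated DE members. It is a signed,
  size-discounted vote: `z > 0` reads "predominantly activated". Genesets
  with no DE member get `NA`, not 0 — absence of evidence is not a neutral
  direction.
* an aggregate effect size: mean (default) or median `log2fc` over DE
  members. The mean matches the "average shift" reading; the median is the
  robust alternative.

Sample-wise activity (`compute_geneset_scores()`) follows a GSVA-like
construction without rank transformation: transform the counts, standardize
each gene row, average member rows per geneset. The default transform is a
size-factor-normalized shifted log, `log2(count/sf + 1)` with median-of-ratios
size factors. A dispersion-model variance-stabilizing transform would need
the full DESeq2 machinery; the shifted log preserves what downstream steps
actually rely on (monotone per gene, roughly homoscedastic, finite) and a
`custom` hook accepts any pre-transformed matrix when the user has a better
one. The size-factor estimator is the textbook median-of-ratios; note that
rescaling one sample rescales the per-gene geometric-mean reference by the
m-th root of the factor, so individual size factors are only defined up to
that uniform shift — the test suite checks the estimator against DESeq2's
implementation and asserts the invariance in its exact (ratio) form.

Standardization uses the sample (n−1) standard deviation; that denominator
is a convention that must be fixed for exact tests, nothing more. Constant
rows would produce NaN; they are set to all-zero and flagged instead, which
keeps them neutral inside geneset means without poisoning them.

The membership set P_k defaults to the geneset's **DE** members
(`members = "de_only"`), which matches the score's definition as a summary
of the differential signal; `members = "all"` averages over every
resolvable member for users who want the looser "activity of the whole
set" reading. Both are implemented because the two phrasings circulate in
the field; the discrepancy is documented rather than resolved. The two
coincide exactly when every member is DE, which the tests exploit.

## Harmonization

Each supported tool ships a `dialect_spec`: a column map, a member-gene
separator, and optional "k/n" ratio columns. The specs are data, not code —
a user can override any field. The harmonized `gs_pvalue` takes the tool's
*adjusted* p-value when one exists (clusterProfiler, Enrichr, fgsea;
g:Profiler's `p_value` is already corrected) and the raw one otherwise
(topGO's elim p, DAVID); the choice is recorded in a `pvalue_kind`
attribute. Ranking on an adjusted quantity is the safer default when tools
are mixed. fgsea has no description column, so the description defaults to
the id. Gene symbols keep their case unless `case_insensitive = TRUE`
(mouse symbols are mixed-case; uppercasing by default would corrupt them).

`gs_genes` holds whatever the tool reports — full annotated membership for
GMT-derived tools, the DE intersection for g:Profiler, the leading edge for
fgsea. Membership counts and similarity measures therefore operate on the
tool's view of the set, which is the only view available without re-running
the enrichment.

## Graphs

The gene–geneset graph connects the top `n_gs` genesets (default 15, a
readability bound, not a statistical one) to their resolved DE members.
Ranking ties on `gs_pvalue` are broken by larger `gs_de_count`, then
lexicographic `gs_id`, so outputs are deterministic.

Similarity measures: Jaccard `|A∩B|/|A∪B|`, overlap coefficient
`|A∩B|/min(|A|,|B|)`, and Cohen's kappa on the 2×2 membership table over a
gene universe. Kappa needs the universe size; the default universe for
clustering is the union of all member lists, which is self-contained —
callers with a real background (e.g. all tested genes) should pass it. The
enrichment map uses overlap with edge threshold 0.25 by default: GO-style
redundancy is dominated by small-in-large nesting, which overlap detects
and Jaccard dilutes.

The backbone applies the disparity filter to the weighted projection
(weight = shared-member count): an edge survives when
`(1 − w/s)^(k−1) < alpha` at either endpoint. A degree-1 endpoint has an
undefined score (`k − 1 = 0`); its only edge is always retained, the
standard convention. The projection weights are dual-checked in the tests
against the incidence-matrix product.

Community detection wraps greedy modularity and (seeded) label propagation;
the per-community representative is the lowest-p member, ties again by id.

## Distillation

`fuzzy_cluster_genesets()` implements the DAVID-style heuristic the field's
fuzzy-clustering functions are modeled on: each geneset seeds a candidate
cluster of its kappa-neighbors at `similarity_threshold` (default 0.35);
a seed is valid when it has at least `seed_size` (default 3) neighbors and
more than half of all within-seed pairs clear the threshold; seeds sharing
at least `multilinkage` (default 0.5) of the smaller seed's members merge
iteratively to a fixpoint; leftovers become singletons. The merge fraction
is measured against the smaller seed because the merging step targets the
same nesting asymmetry as the overlap coefficient. The output is fuzzy —
a geneset may sit in several clusters — with `hard = TRUE` forcing a
unique assignment by best kappa to the representatives, since both
behaviors exist in the wild. The algorithm is fully deterministic;
permuting input rows can only renumber clusters.

`reduce_by_overlap()` is a greedy pass in significance order, dropping any
set whose overlap coefficient with an already-retained set reaches the
threshold (default 0.75). Greedy-in-p-order makes the retained set
well-defined and maximal for that order, which the tests verify against a
brute-force trace.

MDS is classical metric scaling on `1 − similarity`; with all-identical
inputs the double-centered matrix has no positive eigenvalue and the
coordinates collapse to the origin (padded to two columns). Dendrograms use
average linkage by default, checked against a brute-force UPGMA
agglomeration.

## Plot data and the report

Every visual summary is computed as a `plot_data` object — coordinates,
orderings, labels, aesthetic mapping — and that object, not the rendered
pixels, is the tested surface. Rendering never mutates plot data. Volcano
y-axes use the harmonized `gs_pvalue` (adjusted where the tool provided
it), consistent with the ingestion decision.

`happy_hour()` writes a single self-contained HTML file. Figures are
emitted as hand-built inline SVG with fixed-format numbers rather than
through a graphics device: the report's byte-determinism contract (given a
pinned `timestamp`) must not depend on cairo availability or device
metadata. Each figure section embeds the exact `Rscript` command that
regenerates its plot-data JSON, plus a hash of the configuration, so a
report is also a recipe. External-database links (AmiGO, NCBI, GeneCards,
GTEx) are URL templates built from ids and never fetched.

## The synthetic world

`generate_fixture()` emulates a small two-group bulk RNA-seq experiment:
log-normal baseline means (log2-mean 5, sd 1.5 — a few counts to a few
thousand), negative-binomial counts with dispersion 0.1 (typical for
laboratory replicates), 4 vs 4 samples, 10% DE genes with |log2FC| = 2 and
random sign, 40 genesets of 10–30 members, and 4 planted enriched sets
drawing at least 70% of their members from the up-regulated DE pool. The DE
table is filled by a per-gene Welch test on shifted-log values with BH
correction; the enrichment p-values by a one-sided hypergeometric tail on
DE overlap. Both are fixture plumbing — the package does not ship DE or
enrichment testing as analysis methods, and the hypergeometric filler is
quarantined in the fixture module for that reason.

What a green test on this world establishes: the algebra and the plumbing
are right, planted signal of realistic effect size is recovered, and the
pipeline is deterministic. What it does not establish: behavior under
batch effects, correlated genes within sets, library-size extremes,
annotation drift between tool versions, or organisms whose symbol
conventions break the annotation bridge. The fixture's gene universe is
also closed — every geneset member exists in the annotation — so
resolution-failure paths are exercised by dedicated corrupted fixtures in
the unit tests, not by the generator.

## Numerical choices and edge cases

* Z-score identity enforced at 1e-9 when both the score and the counts are
  present in an input table; standardization contract at 1e-9.
* p-values are constrained to (0, 1]; fixture p-values are floored at the
  smallest positive double to respect that bound.
* `validate_bundle()` in lax mode drops unresolvable symbols (with a
  count); repair is idempotent. Strict mode aborts on the first
  inconsistency, naming it.
* Empty enrichment tables are legal bundles; score and graph builders
  refuse them with explicit errors rather than returning empty shells.
* All randomized procedures (label propagation, the fixture) take explicit
  seeds; everything else is deterministic by construction.

## Known limitations

No semantic (information-content) GO similarity; no rank-based GSVA/ssGSEA
scoring; no dispersion-model VST; no live interactive widgets — the static
report plus serialized plot data replace them. Config files are JSON (no
YAML dependency). These bounds are deliberate: the package covers the
interpretation layer, not the testing layers above or the UI layer beside
it.
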