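---
title: "Disease-module depletion analysis: models, conventions and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Disease-module depletion analysis: models, conventions and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(admod)
```

## The scientific problem

Complex diseases such as Alzheimer's disease are not single-gene defects:
the implicated genes and proteins cluster in topologically coherent regions
of the interactome — *disease modules*. A therapeutic that downregulates one
protein (for instance a synthetic microRNA mimic delivered against its
mRNA) perturbs not just that protein but the communication structure of the
module it is embedded in. `admod` operationalises this idea as a pipeline:

1. assemble a high-confidence protein–protein interaction network from
   evidence-filtered exports of the standard source databases;
2. build a disease module as the first neighbourhood of a small set of
   seed proteins;
3. overlay experimentally supported miRNA→target regulation;
4. characterise every candidate node by centrality and by an *in silico*
   knock-out (single-node depletion); and
5. test whether the module is enriched in independently curated
   disease-associated genes.

Nodes whose removal barely perturbs the network but which sit on
disease-relevant branches are attractive mimic targets: focused effect,
small collateral damage. Nodes whose removal fragments the network are
flagged as risky bottlenecks.

## Graph model and centrality conventions

The network is a simple undirected graph: no self-loops, no duplicate
edges, all edges of unit length (the underlying experiments say *that* two
proteins interact, not how strongly). Duplicates and self-loops are
collapsed silently at construction with a logged count, and edge
provenance (which databases attest an interaction) survives the collapse
as a set union.

**Degree** is the number of incident edges. **Betweenness** is

$$C_b(v) = \sum_{s \neq v \neq t} \frac{\sigma_{st}(v)}{\sigma_{st}},$$

with $\sigma_{st}$ the number of shortest $s$–$t$ paths and
$\sigma_{st}(v)$ those passing through $v$. Each unordered pair is counted
once; endpoints are excluded; pairs in different components contribute
nothing. The implementation uses Brandes' dependency accumulation (one BFS
per source, dividing the undirected double count by two) and is tested for
exact agreement with brute-force enumeration of all shortest paths on
hundreds of random graphs, and against igraph as an independent
implementation.

**Closeness** is $C_c(v) = (n-1) / \sum_{u \neq v} d(v,u)$ where — and
this matters in fragmented interactomes — $n$ is the size of $v$'s
connected component and the sum runs only over that component. An isolated
node gets closeness 0 by convention. Reports also carry
`closeness_norm`, closeness divided by the network-wide maximum, so the
most central node scores exactly 1 (ties allowed).

**Average path length** is averaged over *connected unordered pairs
only*: disconnected pairs are excluded from numerator and denominator.
Real curated interactomes have hundreds of components, yet a finite mean
path length is still meaningful under this convention; an "infinite
distances count" convention would make every baseline infinite. A network
with no connected pair reports `NA`, never 0.

Ego networks are induced subgraphs on all nodes within a geodesic radius
(default 2) of a seed, each node labelled with its ring level (0 = seed,
1, 2, ...). All iteration is over sorted node identifiers, so every report
is byte-stable.

## Source filtering

Each interaction dialect gets the filter its database semantics support:

* **PSI-MITAB 2.5** (IntAct-style): both interactors restricted to the
  configured taxon (default 9606), `intact-miscore` at or above the
  configured threshold, and the interaction-type CV term among the
  allowed labels (default *direct interaction* and *physical
  association*, matched by MI identifier or lowercased name). Rows with
  conflicting taxon annotations, malformed column counts, or no parsable
  score are skipped with logged warnings — a conservative stance:
  unscorable evidence never enters a thresholded network.
* **STRING-like tables**: combined score at or above 0.9; the 0–1000
  versus 0–1 dialect is auto-detected from the column maximum.
* **BioGRID-like tables**: grouped by unordered pair; a pair survives
  with at least two *distinct* publication identifiers on physical,
  low-throughput rows. Repeated reporting of one paper is not replicated
  evidence.

Identifiers are normalized (uppercase, UniProt isoform suffixes stripped)
so the same gene product merges across databases. Filtering is monotone in
every threshold, and merging is idempotent and order-independent — both
properties are asserted in the test suite.

## The miRNA evidence filter

Regulatory claims are kept when the assay method contains "luciferase"
(case-insensitive) — the reporter assay being the accepted direct-binding
evidence — in at least two distinct publications. Duplicate
(miRNA, gene) rows are pooled by PMID union *before* thresholding, so the
same claim split across source files is not undercounted. Per-gene
overrides can lower (never raise) the threshold where a curator judges a
single strong study sufficient. Mature names are normalized to lowercase
with the `hsa-` prefix, so `miR-34a-5p` and `hsa-miR-34a-5p` unify.

## Enrichment statistics

Module-versus-disease-gene overlap is tested on the 2×2 table with the
module size, disease-set size and background as margins. The two-sided
p-value follows the probability-mass rule: the sum of hypergeometric
probabilities of all tables (same margins) whose probability does not
exceed the observed table's, with a relative slack of $1+10^{-7}$ when
comparing masses — the convention of the standard reference
implementations. All masses are computed in log space via log-gamma and
combined by log-sum-exp, so the log p-value stays exact even when the
p-value itself underflows; reports then show an upper bound rather
than 0.

Two odds-ratio estimates are reported and labelled explicitly, because
they differ in the third significant digit at realistic margins:

* the raw cross-product $\hat\psi = ad/bc$ (with an `Inf` sentinel when
  $bc = 0$), and
* the **conditional MLE**, the $\psi$ at which the expected first cell of
  Fisher's noncentral hypergeometric distribution equals the observed
  one, solved by bracketed root finding plus Newton polishing until the
  expectation matches to $10^{-8}$.

At the margins (156, 26, 292, 19435) the conditional MLE is
`r round(fisher_exact(contingency_from_counts(156, 26, 292, 19435))$odds_ratio_cmle, 4)`
and the cross-product 14.2955 — rounding to 14.29 and 14.30 respectively;
the conditional estimate shrinks towards 1, a property asserted on random
tables. The package reports one test per run; no multiplicity correction
is applied or needed.

## Node depletion and role classification

A depletion removes one node and its incident edges and recomputes the
topology summary; deltas are signed as (after − before), so fragmentation
shows as positive `delta_components` and negative `delta_lcc`. Scans
always re-baseline: every node is removed from the pristine network, never
cumulatively. `delta_components > 0` exactly at articulation points, a
property cross-checked against an independent articulation-point
implementation. Note that `delta_path` can be *negative* for a
well-connected network: removing the root of an elongated peripheral
branch deletes the longest-distance pairs from the average and compacts
the surviving core.

Roles are assigned by an explicit, configurable rule
(`role_config(top_fraction, peripheral_degree)`), echoed in the output:

* **peripheral** — degree at most `peripheral_degree` (default 3) *and*
  closeness below the median of the assessed universe;
* **bottleneck** — degree and betweenness ranks both within the top
  `top_fraction` (default 0.10), *or* a fragmenting removal
  (`delta_components > 0`) whose absolute path-length change ranks in the
  top fraction;
* **local hub** — everything else.

Two deliberate choices here. First, the peripheral test uses *closeness*,
not betweenness: a node guarding a pendant chain is an articulation point
and inherits all of its subtree's traffic, so its raw betweenness can sit
well above the network median even though the branch it guards is
marginal; low closeness — being far from everything — is the actual
topological signature of a peripheral branch. Second, the peripheral test
runs *first*, for the same reason: chain guards would otherwise qualify as
bottlenecks through their inflated path impact. Under these defaults (with
`top_fraction = 1/3`, appropriate when the assessed universe is a
hand-picked candidate set of nine rather than a whole network) the
published centrality and knock-out profiles of nine Alzheimer candidate
proteins classify as expected: the three
high-degree, high-betweenness kinase adaptors as bottlenecks, the two
low-closeness branch proteins as peripheral, the rest as local hubs. The
thresholds live in configuration, not code, because no published numeric
rule exists; they are calibrated so that planted bridges and pendant
chains in the synthetic benchmark — and the published qualitative
assignments — are both reproduced.

When ranking fragmentation impact, ties in `delta_components` are broken
by the more negative `delta_lcc`: a chain guard and an inter-module bridge
both add one component, but the bridge detaches a whole module while the
guard clips a short tail.

## The synthetic benchmark

The generator plants a fully known topology so every stage is testable
offline, with defaults chosen once to represent a small but structured
disease-module neighbourhood:

* three dense modules of eight proteins (within-module edge probability
  0.8, resampled until connected, with a retry cap);
* two bridge nodes, each the *only* connection between consecutive
  modules, attached to two nodes per side so that no single module node
  becomes an inter-module articulation point;
* one pendant chain of three nodes on the first (outermost) module — the
  peripheral branch;
* signal edges carry MI scores in (0.70, 0.95); inter-module noise edges
  in (0.30, 0.62), a range that straddles the 0.56 cutoff but stays below
  0.65, so the strict threshold recovers exactly the signal while the
  relaxed one admits noise — mirroring the two confidence regimes a
  curator would compare;
* a 10% contaminant fraction of mouse-taxon rows and a few
  "colocalization"-typed rows exercise the taxon and type filters;
* the miRNA plan gives three heavily regulated nodes, a 15% chance of
  light regulation elsewhere, a 60% luciferase fraction, publication
  counts straddling the two-paper threshold, and one planted multi-target
  miRNA with four module targets;
* the disease list draws its module overlap from Fisher's noncentral
  hypergeometric distribution at a planted odds ratio (default 15), with
  association scores straddling the 0.38 cutoff.

Every generator call derives its own child seed deterministically from the
run seed, so adding a generator never perturbs earlier draws, and
regeneration under one seed is byte-identical. Rows are emitted in
shuffled order to catch order-dependent parsing bugs.

What the benchmark does *not* emulate: the heavy-tailed degree
distribution of the real human interactome, database-specific identifier
quirks beyond isoform suffixes, sequence-level miRNA target matching, and
the sheer scale (thousands of nodes) of curated interactomes. Passing the
recovery suites therefore demonstrates correctness of the filtering,
merging, depletion and classification logic — not that any particular
biological conclusion transfers to a given real dataset.

## Numerical and engineering choices

* All probability masses in log space; log-sum-exp for totals; p-value
  underflow reported as a bound, never 0.
* Betweenness accumulates in doubles; agreement with brute force is
  asserted to $10^{-9}$ (observed error is at machine precision).
* Undefined average path lengths (no connected pair) are `NA` sentinels
  and propagate to `NA` deltas, never 0.
* Rank ties in role classification share the better rank, so tied nodes
  straddling a cutoff are treated symmetrically.
* Problem sizes in the test and acceptance suites — 200 random graphs of
  up to 12 nodes for oracle equivalence, exhaustive table enumeration to
  total 30, 100 seeded interactomes of 29 nodes, 200 noncentral draws for
  estimator recovery — were chosen as the smallest sizes at which every
  property is non-trivially exercised, keeping the whole suite fast
  enough to run on every change.
* Every output TSV carries a header comment naming the package version
  and the MD5 of the run configuration, so a result can always be traced
  to its thresholds.

## Known limitations

* The first-neighbourhood module rule excludes edges between two
  non-seed neighbours by design (the module is seed-incident); analyses
  needing the full induced subgraph should build it from the merged
  network directly with `induced_subnetwork()`.
* Betweenness on graphs with tens of thousands of nodes is beyond the
  pure-R implementation's comfortable range; the package targets
  module-scale networks (up to a few thousand nodes).
* Weighted or directed interactions, eigenvector-style centralities,
  multi-node simultaneous knock-outs and percolation curves are out of
  scope.
* The reference counts of published source-database snapshots are not
  reproducible from fresh downloads (databases move); the package
  reproduces layouts, statistics and properties, not dated node counts.
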