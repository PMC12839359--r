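# admod

Network-medicine analysis of disease modules for miRNA-mimic target
prioritization.

Complex diseases perturb tightly interconnected subnetworks of the
interactome rather than single genes. When a candidate drug is a
microRNA mimic — a synthetic RNA that downregulates the mRNAs a miRNA
binds — the question is not only *which* protein to hit but *what its
loss does to the module around it*. `admod` answers that question
computationally, for bioinformaticians and systems biologists working on
network-based target prioritization:

* **Interactome assembly** from evidence-filtered exports: PSI-MITAB 2.5
  (taxon, `intact-miscore` threshold, interaction-type CV terms),
  STRING-like tables (combined score ≥ 0.9, dialect auto-detection) and
  BioGRID-like tables (≥ 2 distinct publications on physical,
  low-throughput rows), merged into one deduplicated network with
  per-edge provenance.
* **Disease-module construction**: the first neighbourhood of a seed
  protein set, with disease-gene flagging from an association-score list
  (strict cutoff, default 0.38).
* **miRNA regulatory overlay**: luciferase-assay evidence with at least
  two distinct supporting papers (per-gene overrides can relax this),
  attached to the module through a symbol/accession mapping.
* **Topology and perturbation**: degree, betweenness
  Cb(v) = Σ<sub>s≠v≠t</sub> σ<sub>st</sub>(v)/σ<sub>st</sub>,
  component-restricted closeness Cc(v) = (n−1)/Σ d(v,u), ego networks
  with ring labels, and single-node depletion scans reporting
  Δcomponents, ΔLCC and Δ mean shortest-path length against the pristine
  baseline, with rule-based classification of each node as
  *bottleneck*, *local hub* or *peripheral*.
* **Exact enrichment statistics**: two-sided Fisher test by the
  probability-mass rule, computed in log space, with both the sample
  odds ratio and the conditional-MLE odds ratio of the noncentral
  hypergeometric model.
* **A seeded synthetic benchmark** that plants modules, bridges, pendant
  chains, score-separated noise, contaminant taxa, a skewed miRNA plan
  and a true enrichment odds ratio — so the entire pipeline is testable
  offline with known ground truth.

## Worked example

Generate a synthetic interactome with two planted inter-module bridges
and a pendant chain, recover it through the MITAB reader at the
high-confidence threshold, and scan every node:

```r
library(admod)

spec <- synthetic_spec(rng_seed = 42)
gen  <- generate_interactome(spec, "interactome.mitab")
net  <- merge_records(read_mitab("interactome.mitab",
                                 filter_policy(min_mi_score = 0.65)))
net
#> ppi_network: 29 nodes, 80 edges

scan <- depletion_scan(net)
scan$baseline
#>   n_nodes n_edges n_components lcc_size avg_path_length
#> 1      29      80            1       29        3.830049

head(rank_fragmentation(scan$results)[, c("node", "delta_components",
                                          "delta_lcc", "delta_path")], 3)
#>     node delta_components delta_lcc delta_path
#> 1 B01001                1       -12 -1.5944472
#> 2 B02001                1        -9 -1.1832603
#> 3 P01004                1        -4 -0.5198182

roles <- classify_roles(centrality_report(net), scan$results)
table(roles$role)
#> bottleneck  local_hub peripheral
#>          4         22          3
```

The two planted bridges (`B01001`, `B02001`) top the fragmentation
ranking — removing either one splits off a whole module (ΔLCC −12 and
−9) and shortens the surviving network's mean path because the longest
inter-module distances disappear with it. The three pendant-chain nodes
come out `peripheral`: low degree, far from the core, safe to deplete.

Enrichment of a 156-node module overlapping 26 of 292 disease genes on a
19,435-gene background:

```r
fe <- fisher_exact(contingency_from_counts(156, 26, 292, 19435))
sprintf("OR (cmle) = %.2f, p = %.3g", fe$odds_ratio_cmle, fe$p_value)
#> "OR (cmle) = 14.29, p = 6.48e-20"
```

The conditional-MLE odds ratio (14.29) and the raw cross-product (14.30)
are both reported because they differ at realistic margins; the p-value
is the exact two-sided probability-mass sum.

A YAML-configured front end ties the stages together
(`run_simulate()`, `run_build_module()`, `run_mirna()`, `run_analyze()`);
every output TSV carries the package version and the MD5 of the
configuration that produced it, and runs are byte-reproducible under a
fixed seed. See the vignette in `vignettes/admod-methods.Rmd` for the
models, conventions and design rationale.

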