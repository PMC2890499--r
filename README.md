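# hfnet

Biomarker-seeded protein–protein interaction (PPI) network analysis for
heart-failure (HF) biomarker discovery.

Known HF biomarkers (CRP, MPO, natriuretic peptides, matrix
metalloproteinases, ...) do not act in isolation: they sit inside an
interaction network whose structure carries prognostic information that
differential gene expression alone misses. `hfnet` implements the full
network-centred discovery workflow around that idea:

1. **Assembly** — merge edge-list exports of curated interaction databases
   (HPRD/BioGRID/MINT-style TSVs) into one simple undirected graph, restrict
   it to the seed proteins (known biomarkers ∪ prioritized candidates) and
   their first-level partners, and split it into the *core network* (largest
   connected component) and small *islands*.
2. **Topology** — per-node degree and *traffic* (betweenness centrality):
   for node *x*, the sum over all other node pairs (s, t) of the fraction of
   shortest s–t paths passing through *x*. Degree histograms are fitted with
   the classical log–log law D(k) ∝ k^(−γ) by ordinary least squares on
   (ln k, ln D(k)).
3. **Modules** — greedy agglomerative maximization of Newman–Girvan
   modularity Q = Σ_c [L_c/numE − (d_c/2·numE)²] (L_c intra-module edges,
   d_c total module degree, numE total edges), followed by structural
   profiling: module sizes, intra-module edges, median traffic, and
   inter-module interactions (IMIs).
4. **Enrichment** — two-tailed Fisher exact tests of module gene sets
   against GMT term maps (GO BP/CC, TF targets, miRNA targets), with
   Benjamini–Hochberg correction per module × category family.
5. **Prioritization** — order-statistics rank aggregation: a candidate with
   rank ratios r₁..r_N across N evidence sources scores
   RS = P(U₍ᵢ₎ ≤ r₍ᵢ₎ ∀i) for independent uniforms U, computed by the
   closed-form recursion; plus Fisher's omnibus −2Σln p combination.
6. **Association statistics** — biomarker-vs-rest contrasts on degree and
   traffic (Student's t), degree–traffic and IMI–traffic correlations.
7. **Expression classification** — per-gene differential-expression screens
   and leave-one-out (LOO) evaluation of a linear SVM on gene panels, with
   strictly fold-wise standardization.
8. **Synthetic data** — seeded generators (planted-partition networks with
   hub "biomarkers", power-law configuration models, module-aligned term
   maps, two-class expression matrices, per-source rankings) so that every
   stage is testable offline against known ground truth.

## Worked example

```r
library(hfnet)

## a synthetic study: 4 planted modules of 15 proteins, 8 hub biomarkers
pp <- sim_planted_partition(sizes = rep(15, 4), p_in = 0.4, p_out = 0.02,
                            n_biomarkers = 8, biomarker_boost = 8,
                            seed = 42, ensure_connected = TRUE)
report <- run_pipeline(list(
  network  = pp$network,
  seeds    = seed_set(pp$biomarkers),
  term_map = sim_term_map(pp$membership, purity = 0.8,
                          n_noise_terms = 5, seed = 7)))
report
```

```
== hfnet pipeline report ==
network: 58 nodes, 252 edges; core 58/252; 0 island(s) (), 0 singleton(s)
degree distribution: gamma = 0.55 (R^2 = 0.17)
modules: 4, Q = 0.378; sizes: 16, 15, 14, 13
degree-traffic correlation: r = 0.92 (P = 1.3e-24)
module IMI-traffic correlation: r = 0.11 (P = 0.89)
biomarkers vs rest: degree t = 10.22 (P = 2.1e-14); traffic t = 12.32 (P = 1.4e-17)
enrichment: 34 records, 4 significant
reference self-checks: core size 746; IMI-traffic r = 0.81; seed union 105
```

Reading the output: the seed-centred subnetwork (biomarkers plus first-level
partners, 58 of the 60 generated nodes) recovers the four planted modules at
Q ≈ 0.38; the planted hub biomarkers show strongly positive degree and
traffic contrasts (the direction expected of disease biomarkers); degree and
traffic are tightly correlated, so hubs are also bottlenecks; the
module-level signature terms are flagged by the enrichment stage. With only
4 modules the IMI–traffic correlation is noise (it needs the 17-module scale
of a real network), and the power-law fit is meaningless here — a dense
planted-partition graph is not scale-free; use `sim_powerlaw_network()` for
that regime. The self-check line recomputes
three facts from the shipped reference tables of the HF study that motivates
the package: the 17 module sizes sum to the 746-protein core network, the
per-module IMI counts correlate with median traffic at r = 0.81, and the
seed arithmetic 37 biomarkers ∪ 100 candidates (32 shared) = 105.

Individual stages are plain functions returning classed objects —
`node_centrality()`, `greedy_modules()`, `enrich_modules()`,
`combine_rankings()`, `loo_linear_classify()`, ... — see the methods
vignette (`vignettes/hfnet-methods.Rmd`) for the models, parameter choices
and validation design.

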