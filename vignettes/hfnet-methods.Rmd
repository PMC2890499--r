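---
title: "Methods: biomarker-seeded PPI network analysis with hfnet"
author: "hfnet authors"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: biomarker-seeded PPI network analysis with hfnet}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(hfnet)
```

`hfnet` implements a network-centred workflow for studying disease
biomarkers — developed around heart failure (HF) — in which the unit of
analysis is not the single differentially expressed gene but the structure
of the protein–protein interaction (PPI) network that known biomarkers and
their candidates span. This vignette documents the models and procedures,
the parameters that matter and their defaults, the numerical choices, what
the synthetic-data generators do and do not emulate, and the known
limitations.

## Network assembly

Interaction tables are tab-separated edge lists (protein A, protein B,
optional source label), the common export shape of curated repositories
such as HPRD, BioGRID and MINT. Symbols are normalized by upper-casing and
whitespace stripping (an optional alias map handles gene/protein naming
mismatches); the merged network is the **union** of the per-database edge
sets, with per-edge provenance retained. Two conventions keep all later
topology well defined: self-interactions are dropped (and counted), and
duplicate unordered pairs are collapsed — the network is a simple graph.

The analysis is **seed-centred**: the seeds are the union of known
biomarkers and prioritized candidates, and the analysed network contains
the seeds plus their first-level interaction partners. Two restriction
modes are provided because "all interactions of the seeds" is ambiguous:

* `induced` (default): all edges among seeds ∪ partners. Chosen as the
  default because observed disconnected "islands" in seed networks carry
  more edges than a star around a seed could (up to 8 proteins with 14
  interactions), which requires neighbour–neighbour edges.
* `seed-incident`: only edges touching at least one seed. Strictly a
  subgraph of the induced mode; kept as a flag.

Components are split into the **core network** (largest connected
component), **islands** (components with ≥ 2 nodes) and logged singletons.
Ties for the core — never observed in practice but required for
determinism — are broken by node count, then edge count, then the
lexicographically smallest member. All outputs are canonically ordered
(endpoints sorted within an edge, edges sorted), so identical inputs give
byte-identical artifacts.

## Degree, traffic and the power law

**Traffic** is betweenness centrality: for node $x$,
$T(x) = \sum_{s<t}\sigma_{st}(x)/\sigma_{st}$, where $\sigma_{st}$ counts
shortest $s$–$t$ paths and $\sigma_{st}(x)$ those passing through $x$
(endpoints excluded, credit split fractionally across tied paths). This is
the standard convention; it is computed exactly with Brandes' algorithm,
per connected component when the input is disconnected. Leaves and
isolated nodes have traffic 0. A `traffic_scale` multiplier (default 1) is
provided because published traffic magnitudes sometimes carry an
unspecified scaling; it affects reported numbers only, never rankings or
test statistics.

The degree distribution $D(k)$ is the exact histogram over $k \ge 1$
(degree-0 nodes are tracked separately — $\ln 0$ is undefined). The
power-law exponent of $D(k) \sim k^{-\gamma}$ is estimated, following the
classical graphical procedure, by ordinary least squares on
$(\ln k, \ln D(k))$ over all observed degrees, with $\gamma$ = −slope and
the regression $R^2$ as fit quality; at least 3 positive-frequency degrees
are required. OLS on raw frequencies is the procedure being emulated and
is kept deliberately; a maximum-likelihood estimator would be the modern
choice but answers a different question. On noiseless histograms the fit
recovers the exponent to machine precision (this is a shipped test).

## Module detection

Modularity of a partition is the Newman–Girvan score
$$Q = \sum_c \left[\frac{L_c}{numE} -
      \left(\frac{d_c}{2\,numE}\right)^2\right],$$
with $L_c$ the intra-module edge count of module $c$ (its share of
*numIME*), $d_c$ the total degree of its members and $numE$ the network's
edge count; the second term is the closed-form expectation under
degree-preserving random rewiring.

Modules are found by the greedy agglomerative scheme in the style of
Clauset–Newman–Moore: start from singletons, repeatedly merge the
*connected* module pair with the largest gain
$\Delta Q = w_{ij} - 2a_ia_j$, stop when no gain is positive, and return
the partition at peak $Q$. Only connected pairs are candidates (merging
disconnected modules cannot raise $Q$, so components of a disconnected
network never merge). Determinism is guaranteed by the tie rule: equal
gains are broken towards the lexicographically smallest pair of module
labels, a module being labelled by its smallest member symbol.

Greedy agglomeration is a heuristic. On small arbitrary graphs it can and
does miss the global optimum: in our enumeration experiments it attains
the exhaustive-search maximum on all 728 connected 5-node graphs but on
roughly 90% of random connected 6-node graphs, exactly matching the
behaviour of reference implementations of the same algorithm. The shipped
tests therefore assert exhaustive-oracle *equality* on modular graphs (the
algorithm's target regime: cliques joined by bridges), the oracle *bound*
$Q_{greedy} \le Q_{max}$ everywhere, and planted-partition recovery
(below) — not universal optimality, which no greedy scheme has.

Module profiles report member count, intra-module edges, median member
traffic and the number of **inter-module interactions** (IMIs: edges with
exactly one endpoint inside). Module–module adjacency is recorded once per
pair regardless of interaction multiplicity. One well-definedness note: in
the published module overview that ships as a reference table, the
"interactions" column's semantics are unrecoverable (its total matches
neither $numE$ nor $2\,numE$), so `profile_modules()` reports the
unambiguous intra-module edge count instead of emulating that column.

## Enrichment

Term maps are flat gene sets in GMT format (GO DAG propagation is out of
scope — terms are consumed as given). For each (module, term) pair with at
least one annotated member, a 2×2 table against the background universe is
tested with a **two-tailed Fisher exact test**, the two-sided $P$ defined
as the total probability of tables (at fixed margins) whose point
probability does not exceed the observed one — the common convention, and
the one whose enumeration oracle the implementation matches on every table
with margins ≤ 30. Benjamini–Hochberg correction is applied within each
module × category family by default (BP, CC, TF and miRNA analyses are
separate families), with a `global` pooling option. Terms with zero
annotated module genes are suppressed so the BH families stay meaningful.
The default background is the analysed (core) network's gene set;
a genome-wide universe can be supplied — published analyses are ambiguous
on this point, so both are supported and neither asserted.

## Prioritization by order statistics

Each evidence source contributes a rank ratio $r = $ rank / (number of
genes ranked by that source). The combined score of a gene with ratios
$r_1 \le \dots \le r_N$ is the joint probability that $N$ independent
uniforms would dominate them,
$RS = P(U_{(i)} \le r_{(i)}\ \forall i)$, computed by the recursion
$$V_k = \sum_{i=1}^{k} (-1)^{i-1}\frac{V_{k-i}}{i!}\,r_{N-k+1}^i,
  \qquad RS = N!\,V_N,$$
which reduces to $r$ at $N = 1$. Two documented choices: genes missing
from a source are imputed the worst ratio 1 (conservative: absence is no
evidence), and $RS$ is reported as the raw joint probability without any
gamma-recalibration — the scores order candidates within one analysis but
are not calibrated $P$ values, so no absolute threshold is attached to
them. Fisher's omnibus method ($X = -2\sum\ln p$ against $\chi^2_{2N}$) is
provided for combining genuine $P$ values.

## Association statistics

Group comparisons use Student's $t$ (pooled variance) by default — matching
the named test of the emulated workflow — with Welch available because
expression data are often heteroscedastic. All $P$ values are two-sided.
Sign conventions are fixed so published directions are reproducible:
biomarker-vs-rest contrasts are biomarker minus rest (positive $t$ =
biomarkers larger), and differential expression is case minus control.
Correlations are Pearson product-moment with the $t$-transform $P$
($n-2$ df); Spearman is defined as Pearson on mid-ranks (average ranks for
ties) with the same transform.

## Expression classification

Gene panels are evaluated as patient classifiers under leave-one-out
cross-validation: for each sample, a **linear SVM** ($C = 1$, `e1071`) is
trained on the remaining samples, with features z-scored using training
folds only — the held-out sample never contributes to preprocessing, which
a shipped test asserts by recomputing a fold by hand. Accuracy is the
fraction of correct held-out predictions; AUC comes from the held-out
decision values oriented towards the case class, via the rank
(Mann–Whitney) formula. The protocol is the contract; the margin solver is
a standard library. Kernel and $C$ were unreported in the emulated study,
so linear and $C = 1$ are documented defaults, not claims about the
original analysis.

A subtlety worth knowing: under label permutation, LOO accuracy with
balanced classes centres slightly *below* 50% (~42% in our runs), the
well-known pessimistic bias of leave-one-out — removing one sample makes
the training majority class the opposite of the held-out label. The null
tests account for a ±0.1 band around chance rather than "fixing" this
property of the protocol.

## Synthetic data: what it emulates, and what not

The generators are pure functions of their parameters and a mandatory
seed (the global RNG stream is saved and restored around every call).

* `sim_planted_partition()` — blocks of sizes $s$ with within-probability
  `p_in` and between-probability `p_out`; defaults 4 × 15, 0.4, 0.02: a
  regime where greedy modularity recovers the plant with adjusted Rand
  index ≥ 0.9 (verified over many seeds). Planted biomarkers get
  Poisson(`biomarker_boost`) extra *cross-module* edges — this single
  mechanism makes them simultaneously hubs and bottlenecks, the joint
  property claimed of disease biomarkers, rather than merely raising
  within-module degree. Note the trade-off: boosted cross-edges blur block
  boundaries, so recovery guarantees apply to the boost-free design.
* `sim_powerlaw_network()` — configuration model on a truncated power-law
  degree sequence, simplified by discarding self-loops and duplicate
  edges. The degree cap defaults to $\max(6, \lfloor (n/3)^{1/\gamma}
  \rfloor)$ so the rarest degree bin keeps an expected occupancy of a few
  nodes; with sparser tails the log–log OLS fit is biased shallow by rows
  of singleton bins. At $n = 2000$, $\gamma = 2.5$, fitted exponents stay
  within ±0.4 of the target (20-seed check, calibrated by Monte Carlo at
  design time).
* `sim_term_map()` — one signature term per planted module (a `purity`
  fraction of members, padded with outsiders to the module's size), plus
  uniform noise terms; at purity 1 the signature is exactly the member
  set.
* `sim_expression()` — independent N(0, 1) noise per gene and sample;
  differentially expressed genes shifted by Δ (in σ units) in the case
  class; default design 16 + 16, mirroring a small two-arm patient study.
  Gaussianity is a modelling choice: no array-specific noise, batch
  effects or correlation structure are emulated. At Δ = 1σ a two-gene
  panel yields mean LOO accuracies near 70% — the moderate-accuracy regime
  of small-panel prognosis.
* `sim_rankings()` — permutation rankings with one gene forced into every
  source's top decile.

Consequently, passing tests show that each stage recovers the structure it
is designed to detect when that structure is present and detectable; they
do not show robustness to literature bias, false-positive interactions,
isoform ambiguity or array artefacts, all of which real interactome and
expression data contain.

## Numerical and degenerate-input choices

* Fisher tables with a zero margin return $P = 1$; negative or
  non-integer counts are errors.
* $P = 0$ inputs to the omnibus combination are errors (floor upstream).
* Edgeless networks: every node its own module, $Q = 0$, with a warning.
* Constant-and-equal samples: $t = 0$, $P = 1$ with a warning; constant
  samples make correlations an error.
* Zero-variance features inside an SVM training fold are left unscaled
  rather than dividing by zero.
* Greedy merge gains use an absolute tie/stop tolerance of $10^{-12}$.
* `top_nodes()` breaks ties lexicographically and truncates with a warning
  when $k$ exceeds the table.

## Problem sizes in the shipped checks

The test-suite and acceptance-script simulations use: exhaustive oracle
enumeration for betweenness on all connected graphs with ≤ 5 nodes plus
sampled graphs on 6–8 nodes; Bell-number partition enumeration on 6-node
graphs; the full Fisher-table sweep to margins 30; 60-node planted
networks; 2000-node power-law graphs over 20 seeds; 50 replicate
expression studies for the LOO regime and 100–200 permutations for its
null. These sizes make every stochastic claim a multi-seed statement while
keeping a complete run in the minutes range.

## Known limitations

* The analysed network is only as good as its input edge lists; no
  confidence scoring, orthology mapping or PSI-MI parsing is attempted.
* Greedy modularity has the resolution limit and local-optimum behaviour
  of its family; Louvain/Leiden variants are out of scope.
* $RS$ scores are uncalibrated joint probabilities.
* The reference tables shipped with the package are summaries of a
  published HF network study used for arithmetic self-checks; the
  underlying patient-level and database-level inputs are not public, so
  the original network itself is not reconstructable and is not claimed.
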