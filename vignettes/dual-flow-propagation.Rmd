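---
title: "Dual-flow network propagation for disease gene prioritization"
author: "dualflow package"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Dual-flow network propagation for disease gene prioritization}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(dualflow)
```

## The problem

Given a hereditary disease with a handful of verified disease genes, gene
prioritization ranks candidate genes by their similarity to the known
disease genes on a protein–protein interaction (PPI) network.  Global
propagation methods (random walk with restart, kernel diffusion, network
propagation) outperform local neighbor counts because they integrate all
paths between a candidate and the training genes.  They share a failure
mode, however: a high-degree *hub* that happens to touch several disease
proteins accumulates a large share of the propagated flow and is promoted
over the true disease gene, even when everything else about the hub says
"housekeeping".  Empirically, disease proteins are *not* well connected to
essential (housekeeping) proteins, so a candidate surrounded by essential
proteins is an unlikely disease gene.

`dualflow` turns that observation into a scoring rule: known disease genes
inject **positive** flow, non-disease essential genes inject **negative**
flow, and the two flows compete on the network.  Candidates are ranked by
their steady-state net flow.

## The model

Let $G = (V, L)$ be the undirected, unweighted interaction network with
adjacency matrix $A$ and degrees $k(x)$.  A node pumps its current flow in
equal parts to its neighbors, so the flow passed from $x$ to $y$ in one
step is $A(x,y)/k(x)$.  With prior information $Y$ and a restart fraction
$\alpha \in (0, 1]$, propagation iterates

$$F^{t+1} = (1-\alpha)\, W F^t + \alpha Y, \qquad F^1 = Y,$$

whose fixed point has the closed form

$$F^{\infty} = \alpha \left(I - (1-\alpha) W\right)^{-1} Y
            = S\, Y .$$

$S(x, y)$ is the steady-state flow at $x$ from one unit injected at $y$ —
a global similarity between $x$ and $y$.

Three priors are supported, for a disease with training genes $T$ and the
non-disease essential class $E^- = E \setminus D$:

* **NP_D** — $+$ flow on $T$ only: the classical propagation score
  $\sum_{y \in T} S(x,y)$.
* **NP_E** — $-$ flow on $E^-$ only: $-\sum_{y \in E^-} S(x,y)$, the
  penalty a candidate pays for sitting near essential genes.
* **NP_DE** (dual flow) — both sides together, balanced so positive and
  negative flow are equal in total:
  $$\mathrm{score}(x) = \frac{1}{|T|}\sum_{y \in T} S(x,y)
    - \frac{1}{|E^-|}\sum_{y \in E^-} S(x,y).$$

Because $F^\infty$ is linear in $Y$, the NP_DE score is exactly the
weighted NP_D score plus the weighted NP_E score; the package exploits
this in its tests.

### Operator orientation and normalization

The update above is stated as a matrix product, but the narrative is about
nodes *pumping* flow outward.  The two readings differ by a transpose when
degrees are heterogeneous.  The default, `normalization = "pump"`, applies
the column-normalized operator $W = (D^{-1}A)^\top$, so each node
distributes its current flow equally over its neighbors and **total flow
is conserved** at the fixed point ($\sum F^\infty = \sum Y$ on graphs
without isolated nodes).  Conservation is what makes the competition
between positive and negative flow meaningful, so we treat it as the
canonical reading.  Two alternatives are selectable: `"average"`
(row-normalized: each node adopts the mean of its neighbors) and
`"symmetric"` ($D^{-1/2} A D^{-1/2}$, the form common in the propagation
literature).  Degree-0 nodes have zero rows and columns in every mode:
they retain $\alpha Y$ and pump nothing.

### Parameters

* `alpha` (default **0.5**): the restart fraction.  Small values smooth
  over longer paths, `alpha = 1` disables the network entirely
  ($F^\infty = Y$).  The method's published description never states the
  value used, so the default is the neutral midpoint and every run should
  report it.  Runs through the CLI log it in the provenance file.
* `priorMode` (default `"normalized"`): `"normalized"` gives each
  on-network training gene $+1/|T|$ and each essential $-1/|E^-|$, so the
  two sides carry equal total flow — the operational scoring definition
  above.  `"unit"` assigns literal $\pm 1$ per gene; both are provided
  because the method's prose describes unit flows while its scoring
  formula normalizes, and which variant produced the published tables is
  not decidable from the text.
* `solver` (default `"auto"`): sparse direct solve up to 20 000 nodes,
  fixed-point iteration above, with `tolerance = 1e-8` (L1 change between
  iterates) and `maxIterations = 10000`.  For $\alpha \in (0,1]$ the
  spectral radius of $(1-\alpha)W$ is at most $1-\alpha < 1$ under every
  supported normalization, so the linear system is always solvable and the
  iteration always converges; a singular solve is treated as a bug, not a
  condition to handle.

### Scope choices

Identifiers are opaque case-sensitive strings; no gene-to-protein mapping
is performed.  Scoring runs on the full loaded graph by default —
restricting to the largest connected component is available (it is what
network summary tables conventionally report) but opt-in, because nothing
in the method requires discarding small components and off-component
candidates simply receive zero flow.  Edge confidence scores are used only
for load-time filtering (`scoreThreshold`, e.g. 0.4 for STRING-style
lists); propagation itself is unweighted.

## Shell analysis

The topology analysis behind the negative prior compares, for each node
$i$, the proportion of non-disease essential genes among its $n$-neighbors
$Q_i^n$ (the nodes at shortest-path distance exactly $n$):
$p_i^n = |Q_i^n \cap E^-| / |Q_i^n|$.  The claim under test is that the
median of $p_i^n$ over non-essential disease genes ($D^-$) is below the
median over unannotated genes ($O$) across the informative range of $n$.

Conventions: nodes whose shell $n$ is empty are excluded from the
collection (not counted as zero) — at large $n$ most shells are empty and
a zero-imputation would drag every median to 0 and manufacture spurious
ties.  Significance uses the two-sided Wilcoxon rank-sum test: exhaustive
permutation enumeration when the combined sample size is at most 12,
otherwise the normal approximation with midrank tie correction and a
continuity correction of $1/2$.  Exhaustive enumeration over all rank
configurations shows the approximation's worst-case error against the
exact distribution is about 0.03 at group sizes around 4–6 and shrinks
quickly with size, which is why small samples are routed to the exact
path.

## Evaluation harness

Leave-one-out cross-validation follows the standard protocol: for each
disease with $m \ge 2$ genes, each gene is held out in turn and re-ranked
with the remaining $m-1$ genes as the training prior.  The candidate list
is the test gene plus its 99 closest genes on the same chromosome
("closest" = absolute difference of the single supplied coordinate; users
may pass start positions or midpoints — the choice only permutes
near-ties).  Rules applied exactly:

* the enrichment score of a trial is $50/r$ where $r$ is the test gene's
  rank in its candidate list;
* a test gene with the same flow as other candidates is ranked **last**
  among the tied group (pessimistic tie rule);
* a test gene whose protein is absent from the network receives rank 100
  (enrichment 0.5); *Enrichment score 1* averages over all trials,
  *Enrichment score 2* over on-network trials only.  Both are averaged
  per disease first, then across diseases;
* $E^-$ is derived once from the full disease annotation and **not**
  recomputed per fold: the held-out gene is still a known disease gene in
  the evaluation setting, and letting it drift into $E^-$ would inject
  negative flow onto the very gene being recovered.

When no position table is supplied, candidate lists fall back to 99
decoys drawn uniformly from non-disease network genes under the caller's
seed; this is a deliberate deviation that enables position-free runs and
is flagged in the documentation rather than silently standing in for the
chromosome-local protocol.

ROC analysis treats prioritization as classification under a rank
threshold $t = 0, \dots, 100$: sensitivity is the fraction of test genes
ranked $\le t$; specificity is the mean over trials of the fraction of
non-test candidates ranked $> t$; AUC integrates the curve by trapezoids.
The published prose defines "specificity" twice, inconsistently; the
definitions here follow the rank-threshold convention of the candidate-set
protocol the evaluation descends from, and an independent pairwise
(Mann–Whitney) AUC is provided as a cross-check — the two agree within
0.01 on simulated trials.  Off-network trials are excluded from ROC, as
their rank is an imputation rather than a measurement.

## The synthetic benchmark

Real PPI/annotation data are behind downloads, so the generator builds
networks with the structural features the method's reasoning depends on,
all from one integer seed:

1. a connected preferential-attachment base graph (hub-dominated degree
   distribution);
2. essential genes sampled degree-weighted, plus extra
   essential–essential edges (`essentialInterconnect`) forming an
   interconnected, hub-heavy essential core;
3. disease modules, also degree-weighted (disease proteins are
   topologically central), densified with a spanning cycle plus random
   within-module edges, then *decoupled* from the essentials: edges
   between a module's avoidance region and essential genes are rewired
   onto ordinary nodes.  The avoidance radius cycles 0/1/2 across
   modules.  Heterogeneity matters: rewiring displaces essential contact
   outward, and if every module were displaced by the same amount the
   missing essential mass would reappear at one specific shell distance
   and invert the comparison there; spreading the radius over modules
   reproduces the empirically observed pattern of uniformly lower $D^-$
   medians over $n = 2..4$;
4. decoy hubs — reserved top-degree nodes wired to at least half of one
   disease module and to several essentials: the adversarial pattern that
   positive-only propagation over-ranks;
5. a position table assigning genes to chromosomes in contiguous blocks,
   so chromosome-local candidate lists are nontrivial.

Two standard instances are used throughout the tests, chosen once as the
package's study conditions:

* **prioritization benchmark** — the defaults: 2000 nodes, attachment 2,
  5 diseases × 6 genes, 150 essentials.  Six genes per disease mirrors
  the small per-disease training sets of curated disease–gene catalogues,
  and 30 LOOCV folds keep the full three-mode comparison fast.
* **topology benchmark** — 2000 nodes with 20 modules × 10 genes
  (`moduleDensity = 0.3`): the shell comparison needs class sizes near
  the real annotation proportions (disease-only and essential-only
  classes are each on the order of 10–15% of interactors) for the
  rank-sum comparison to have power at the far shells.

What the generator does **not** emulate: quantitative degree
distributions of any specific interactome, edge confidence structure,
overlapping disease modules, or correlated annotation noise.  Passing
tests on these fixtures demonstrate that the implementation realizes the
method's mechanism — not that the mechanism holds on any particular real
interactome.

A note on the negative-flow mechanism: the drain on a candidate scales
with its *number of essential neighbors*.  Densifying the essential core
itself does not monotonically deepen the drain — each essential's
negative outflow splits over more edges, so less of it reaches any one
adjacent decoy — and the property suite therefore pins the mechanism by
adding essential neighbors to a decoy one at a time and asserting its net
score falls strictly.

```{r toy}
toy <- decoyHubToy()
part <- partitionGenes(toy$network)
em <- classMembers(toy$network, part, "Eminus")
cfg <- propagationConfig(alpha = 0.5)
d  <- scoreCandidates(toy$network, "NP_D",  toy$train, em, cfg,
                      networkNodes(toy$network))
de <- scoreCandidates(toy$network, "NP_DE", toy$train, em, cfg,
                      networkNodes(toy$network))
subset(d,  gene %in% c("c", "e"))   # positive-only: the decoy hub e wins
subset(de, gene %in% c("c", "e"))   # dual flow: the disease gene c wins
```

## Numerical choices and degenerate inputs

* Iterative convergence is measured in L1; the reported residual is the
  final iterate change, and exceeding `maxIterations` is an error that
  reports it, never a silent truncation.
* Exact score ties rank pessimistically everywhere (worst rank in the
  tied group), so reported enrichment never benefits from tie luck;
  off-network candidates score $-\infty$ and share the worst rank.
* Distance ties at the candidate-list cutoff break by identifier order,
  making lists deterministic.
* Empty networks, empty candidate lists, empty rank-sum samples, diseases
  with one gene, and train/test overlaps are rejected with specific
  errors or skipped with warnings naming the offender — never imputed.
* Test-suite problem sizes: oracle comparisons use graphs of up to 50
  nodes against dense base-R solves and a Floyd–Warshall distance oracle;
  the end-to-end benchmarks use the two 2000-node instances above.

## Known limitations

* Propagation is unweighted; confidence scores act only as a load-time
  filter.
* No identifier translation: gene/protein mapping must happen upstream.
* The ROC construction resolves a genuinely ambiguous published
  description; the pairwise-AUC cross-check bounds, but cannot eliminate,
  that interpretive freedom.
* `alpha` and the operator orientation used for the published results are
  unknown; defaults are documented choices, and both alternatives remain
  selectable rather than hidden.
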