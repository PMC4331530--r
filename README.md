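# dualflow

Disease-gene prioritization on protein–protein interaction networks by
**dual-flow network propagation**: known disease genes inject positive
flow, non-disease essential (housekeeping) genes inject negative flow, and
candidate genes are ranked by their steady-state net flow.  The package is
aimed at computational biologists evaluating network-based prioritization
methods: it bundles the propagation core, the neighbor-shell topology
statistics that motivate the negative prior, a full leave-one-out /
train-test evaluation harness with enrichment and ROC/AUC reporting, and a
synthetic benchmark generator, plus a `dualflow` command-line front end.

## The method

On a network $G=(V,L)$ with adjacency $A$ and degrees $k$, each node pumps
its flow equally to its neighbors ($W(x,y) = A(x,y)/k(x)$, applied so that
total flow is conserved).  With prior $Y$ and restart fraction
$\alpha \in (0,1]$,

$$F^{t+1} = (1-\alpha) W F^t + \alpha Y, \qquad
  F^\infty = \alpha\,(I-(1-\alpha)W)^{-1} Y .$$

Writing $S = \alpha (I-(1-\alpha)W)^{-1}$, a disease $h$ with training
genes $T_h$ and the essential-not-disease class $E^-$ give the score

$$\mathrm{score}(x) \;=\; \frac{1}{|T_h|}\sum_{y\in T_h} S(x,y)
  \;-\; \frac{1}{|E^-|}\sum_{y\in E^-} S(x,y),$$

the **NP_DE** (dual-flow) ranking; positive-only (**NP_D**) and
negative-only (**NP_E**) variants are available for comparison.  The
negative term demotes hub proteins that sit in essential-rich
neighborhoods — the classical failure mode of positive-only propagation.

## Worked example

The bundled 12-node toy network contains a disease module `a, b, c`
(train on `a`, `b`, hold out `c`) and a decoy hub `e` that touches both
training genes *and* a ring of five essential proteins:

```r
library(dualflow)
toy  <- decoyHubToy()
part <- partitionGenes(toy$network)
em   <- classMembers(toy$network, part, "Eminus")
cfg  <- propagationConfig(alpha = 0.5)

d  <- scoreCandidates(toy$network, "NP_D",  toy$train, em, cfg,
                      networkNodes(toy$network))
subset(d, gene %in% c("c", "e"))
#>   gene      score rank onNetwork
#> 4    e 0.10863192    3      TRUE
#> 3    c 0.09957062    4      TRUE

de <- scoreCandidates(toy$network, "NP_DE", toy$train, em, cfg,
                      networkNodes(toy$network))
subset(de, gene %in% c("c", "e"))
#>   gene       score rank onNetwork
#> 3    c  0.09594610    3      TRUE
#> 4    e -0.02272777    7      TRUE
```

Positive-only propagation ranks the decoy hub `e` above the held-out
disease gene `c`; adding the negative essential flow drives `e`'s net
score below zero and recovers `c`.  The same machinery scales to a
cross-validated benchmark:

```r
sim  <- generateSynthetic(syntheticSpec(seed = 7))
part <- partitionGenes(sim$network, unique(sim$diseaseMap$gene),
                       sim$essentials)
loocv(sim$diseaseMap, sim$network, part, propagationConfig(),
      sim$positions, mode = "NP_DE")
#> EvaluationReport (NP_DE): 30 trials over 5 diseases
#>   mean enrichment score 1 = 45.000, score 2 = 45.000
#>   AUC = 0.9980
```

Enrichment score is `50 / rank` of the held-out gene within its
100-gene chromosome-local candidate list (so 50 means every held-out gene
ranked first; an off-network gene counts rank 100, score 0.5).  Score 1
averages all trials, score 2 only on-network ones.

From a shell, the same steps are:

```sh
dualflow simulate  --out-dir fixtures/ --seed 7
dualflow prioritize --network fixtures/edges.tsv \
    --disease-genes d.txt --essential-genes fixtures/essentials.txt \
    --mode np_de --alpha 0.5 --out ranks.tsv
dualflow evaluate  --network fixtures/edges.tsv \
    --associations fixtures/associations.tsv \
    --essential-genes fixtures/essentials.txt \
    --positions fixtures/positions.tsv --report report.json
dualflow shells    --network fixtures/edges.tsv \
    --disease-genes d.txt --essential-genes fixtures/essentials.txt \
    --classes Dminus,O --max-n 6 --out shells.tsv
```

Every run writes a `.config.json` provenance file with the resolved
parameters and input checksums.

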