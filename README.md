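# CoModMap

Cross-species refinement of gene co-expression modules with single-cell
expression data.

## What it is for

Human co-expression networks implicate large sets of genes in disease —
for epilepsy, a 320-gene brain co-expression network — but offer little
guidance on which members to test experimentally. CoModMap implements a
refinement strategy for that problem: expand the human gene list into a
model-organism ortholog catalog, ask which catalog genes remain tightly
co-expressed across neurons of a whole-brain single-cell atlas, extract
that conserved module, and quantify how strongly it concentrates
disease-associated genes. The package is aimed at systems-biology groups
doing cross-species network analysis, and at fly labs quantifying
seizure susceptibility.

The core machinery:

* **Ortholog expansion** — score-thresholded (DIOPT-style, `score >= 3`)
  mapping with the three standard categories: one-to-one, many-to-one
  (one fly gene representing several human genes) and one-to-many (all
  fly partners within a score tie-window of the best are kept).
* **Co-expression module detection** — pairwise Spearman r_s across
  selected neuronal cells on the log2(x+1) matrix, agglomerative
  clustering on d = 1 − r_s (complete linkage by default), and flat-cut
  module extraction with explicit size and mean-intra-r thresholds in
  place of by-eye heatmap reading.
* **Hypergeometric statistics** — upper-tail P(X ≥ k) for
  module-vs-network category enrichment with fold (k/n)/(K/N), generic
  ORA on GMT collections with Benjamini–Hochberg FDR, and the
  terms-as-genes overlap test between two enriched-term lists.
* **Seizure T50** — bounded Levenberg–Marquardt fit of the variable-slope
  logistic in log10 time, f(t) = top / (1 + 10^((log10 T50 − log10 t)·β)),
  to cumulative fraction-seized time courses; T50 (logEC50) per genotype,
  normalized against same-day controls.
* **Synthetic data with planted truth** — latent-factor negative-binomial
  count matrices, composition-exact ortholog tables, gene-set collections
  with planted enrichment, and binomial seizure time courses, so the
  entire pipeline is testable end to end without any external download.

## Worked example

Plant a 26-gene module among 200 genes over 2000 cells, recover it, and
test disease-category enrichment:

```r
library(CoModMap)

sim <- simulateExpression(nGenes = 200, nCells = 2000,
                          moduleSpecs = list(list(size = 26, loading = 1)),
                          seed = 1)
cm <- spearmanMatrix(log2Transform(sim$expr))
hc <- hierarchicalCluster(cm)                 # complete linkage on 1 - r
extractModules(hc, cm)
#> ModuleSet with 1 module(s)
#>   module_id size min_intra_r mean_intra_r max_intra_r
#> 1  module_1   26   0.4103086    0.5206119   0.6075857
```

The one extracted module is exactly the planted one (Jaccard = 1), with
mean intra-module Spearman r of 0.52 — the "highly co-expressed, distinct
from background" regime the method is built to isolate. Enrichment of a
26-gene module containing 13 disease-associated genes against a 320-gene
network containing 53:

```r
categoryEnrichment(module, background, categories)
#> $k 13   $n 26   $K 53   $N 320
#> $fold 3.02        # threefold enrichment over the parent network
#> $p    3.45e-05    # upper-tail hypergeometric
#> $percent_module 50   $percent_background 17
```

Fit a seizure time course simulated at a true T50 of 40 min:

```r
fitSigmoid(simulateSeizureAssay(trueT50 = 40, hillSlope = 3, seed = 7))
#> SigmoidFit [genotype]: T50 = 42.378 min (logEC50 = 1.6271), slope = 2.909
#>   bottom = 0.000, top = 1.000, rss = 5.779, n = 192, converged
```

The full pipeline (orthologs → filter → select cells → correlate →
cluster → modules → enrichment) runs from one YAML config via
`runPipeline(validateConfig("config.yaml"))`, persisting every
intermediate (catalog, retained genes, correlation TSV, Newick
dendrogram, module table, enrichment tables, JSON report).

## License

MIT.
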