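---
title: "Cross-species co-expression module refinement: models and methods"
author: "CoModMap"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Cross-species co-expression module refinement: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(CoModMap)
```

# The problem

Human gene co-expression networks implicate hundreds of genes in disease,
but validating members one by one is slow. A productive shortcut is
cross-species refinement: project the human network onto a genetically
tractable model organism, ask which of the mapped genes remain tightly
co-expressed in that organism's single-cell expression data, and treat the
conserved core as the functionally coherent — and experimentally testable —
heart of the network. CoModMap implements that pipeline for the concrete
case of a human epilepsy-associated network refined against a whole-brain
fly single-cell atlas, together with the downstream statistics
(disease-category enrichment, gene-set over-representation, term-list
overlap) and the seizure-assay T50 analysis used to phenotype candidate
genes.

# Pipeline stages and their models

## Ortholog expansion

The human gene list is expanded through a scored ortholog table
(`human_gene`, `fly_gene`, `score`), where the score is an integer vote
count across orthology-prediction tools (a DIOPT-style score). Records
below `minScore` (default 3, inclusive) are discarded; the remaining
records are classified per human gene:

* exactly one fly partner, serving only that human gene → **one_to_one**;
* one fly gene that is the sole partner of several human genes →
  **many_to_one** (a conserved family collapsed in the fly);
* several fly partners with "high and similar" scores → **one_to_many**;
  all partners scoring within `tieWindow` of that human gene's best
  partner are kept.

"Similar" is not a self-defining notion, so the tie rule is an explicit
parameter: `score >= max − tieWindow`, default `tieWindow = 1`. A fly gene
reachable through conflicting paths keeps the category of its first
assignment in input order, and the conflict is reported. Human genes whose
best score falls below the threshold contribute nothing — which is why a
320-gene network can legitimately expand to a 287-gene catalog.

## Expression filtering and cell selection

The expression substrate is a genes × cells count matrix with per-cell
type labels (`ExpressionCounts`, a SummarizedExperiment). Candidate genes
are filtered on their *total* count across cells — default threshold 5000,
inclusive (a `inclusive = FALSE` flag gives the strict reading). By
default the filter is applied to the **full dataset** before any cell
selection, so the retained gene list is invariant to the subsequent
subsetting; `filter_scope = "selected_cells"` reverses the order for users
who want totals over the analysis cells only. The filter operates on
whatever values the matrix holds — the package does **not** normalize;
if you want the filter on normalized counts, pass normalized counts.

Cell selection is a plain include/exclude on type labels, matched
case-sensitively. A 45-label neuronal include list (projection neurons,
monoamine and peptidergic populations, clock and lamina neurons) ships as
a config asset (`defaultNeuronalTypes()`); populations with strongly
distinct transcriptomes — glia, optic-lobe neurons, photoreceptors, Kenyon
cells — are deliberately absent because they would dominate the
correlation structure.

## Co-expression, clustering, modules

Pairwise gene–gene similarity is Spearman's rank correlation \(r_s\)
computed across all selected cells, with average ranks for ties (zero
counts tie heavily in sparse single-cell data, so the tie treatment
matters). The matrix is computed after `log2(x + 1)`; since the transform
is strictly increasing this cannot change \(r_s\) on tie-free data, and it
is kept for fidelity to the conventional preprocessing. Genes constant
across cells have undefined correlations: they surface as `NA` with a
warning and must be removed before clustering — the package refuses to
cluster around missing values silently.

Genes are clustered agglomeratively on the dissimilarity \(d = 1 - r_s\)
(`hclust`). The linkage is configurable and defaults to complete linkage —
the `hclust` default, and the natural choice here because a complete-
linkage cluster cut at height \(h\) guarantees *every* intra-cluster pair
has \(r_s \ge 1 - h\).

Module extraction replaces by-eye heatmap delineation with explicit
parameters: a flat cut (height or cluster count), a minimum size, and a
minimum mean intra-module \(r_s\). Defaults: `cutHeight = 0.7` (all
intra-module pairs at \(r_s \ge 0.3\) under complete linkage),
`minSize = 10`, `minMeanIntraR = 0.3` — brackets chosen so a strongly
co-expressed module of ~26 genes with pairwise \(r_s\) in roughly 0.35–0.85
is isolated from an uncorrelated background. Passing clusters are returned
sorted by mean intra-module \(r_s\), each with its min/mean/max internal
correlation, all recomputable from the stored correlation matrix.

## Hypergeometric statistics

All enrichment questions reduce to the upper tail of the hypergeometric
distribution, \(P(X \ge k)\) with the observed count included (the
over-representation convention; evaluated in log space so that extreme
tails like \(10^{-183}\) remain accurate):

* **Category enrichment** of a module against a background network:
  \(k\) positives among \(n\) module genes vs \(K\) among \(N\), with fold
  enrichment \((k/n)/(K/N)\). With 13 epilepsy-associated genes in a
  26-gene module against 53 in a 320-gene network this gives
  \(P = 3.45\times10^{-5}\) and a threefold enrichment.
* **ORA** against a GMT collection: the same test per term, BH-adjusted
  across all terms of the collection in one family (no cross-collection
  pooling), significance at FDR < 0.05, results sorted by raw p. The
  background defaults to the collection's universe and is overridable.
  Fold values depend on the annotation database and universe, so folds
  printed by external web services are not reproduction targets for this
  formula — only the test's logic is.
* **Term-list overlap**: whether two enriched-term lists share more terms
  than expected when drawn from a universe of candidate terms — the same
  tail probability with terms playing the role of genes (an identity the
  test suite checks explicitly).

## Seizure T50 fitting

Heat-induced seizure assays record, per vial, the cumulative number of
animals showing seizure-like behaviour at fixed intervals. The package
fits the Hill-form logistic in \(\log_{10}\) time,

\[
f(t) = \mathrm{bottom} + \frac{\mathrm{top} - \mathrm{bottom}}
{1 + 10^{(\log_{10} T_{50} - \log_{10} t)\,\beta}},
\]

to the per-vial fractions of one genotype, all vials jointly (per-vial
fits are available by subsetting). \(T_{50}\) is the half-response time;
its base-10 log is the quantity conventionally reported as logEC50, and
\(\beta\) is the variable Hill slope. The bottom asymptote is fixed at 0
(no animal seizes at \(t=0\)); the top is free in \((0,1]\) by default
because not every animal seizes within the 80-minute window, with
`topFixed = TRUE` available since the constraint choice is genuinely open.
Optimization is bounded Levenberg–Marquardt least squares with a
deterministic start (logT50 at the linearly interpolated first crossing of
half the maximum pooled fraction; slope 1; top at the maximum pooled
fraction): the fit is seedless and reproducible. Fits whose pooled
response never reaches 0.5 are flagged `extrapolated`; flat responses are
refused as degenerate rather than silently fitted. Genotype T50s are
normalized as plain ratios against same-day background controls
(`normalizeT50`), absorbing day-to-day assay variation; ratios above 1
mean protection, below 1 susceptibility.

# The synthetic-data generator

Every input the pipeline consumes can be generated with known ground
truth, so all downstream stages are testable without any external
download.

**Expression.** Counts are negative binomial (gamma-Poisson) with mean
\(\mu_{gc} = b_g \cdot f_c^{\lambda} \cdot \ell_c\): a per-gene baseline
\(b_g = 2^{U(1,5)}\) (means of 2–32 counts), a per-module per-cell latent
factor \(f_c \sim \mathrm{lognormal}(0,1)\) raised to the module's loading
\(\lambda\), and a per-cell library multiplier \(\ell_c\), lognormal with
unit mean and CV 0.1. The shared dispersion is the NB size parameter
(default 2), so `dispersion = Inf` reaches the Poisson limit. The latent
factor construction yields tunable rank correlations without dictating a
marginal: at the default \(\lambda = 1\), a 26-gene module over 2000 cells
shows intra-module \(r_s \approx 0.42\)–0.63 — inside the 0.3–0.85 band
typical of strongly co-expressed neuronal modules — while \(\lambda = 0\)
gives a calibrated null (mean \(|r_s| \approx 0.02\) between random gene
pairs). The library CV default of 0.1 is deliberately modest: a shared
depth factor correlates *all* genes, and 0.1 keeps that nuisance
correlation an order of magnitude below the module signal while still
exercising the code path. Cell-type labels partition cells for selection
logic but carry no expression effect, again so the null stays calibrated.
What this generator does **not** emulate: marker-gene structure, doublets,
ambient RNA, batch effects, or the empirical count law of any real atlas —
passing tests show the algorithms are correct, not that any particular
biological dataset will yield a particular module.

**Ortholog tables** realize an exact composition of the three categories
(with tied partners sharing a score so any tie window keeps them);
**gene-set collections** mix a controlled fraction of target genes into
planted terms over random ones, with `excess_fraction = 0` giving an
exactly null collection; **seizure assays** draw each interval's newly
seizing animals binomially from the conditional hazard implied by the
logistic CDF, which makes cumulative counts monotone by construction and
the marginal curve exactly logistic. All generators take explicit seeds
and touch no global state beyond R's RNG, which they seed themselves.

# Numerical and design choices

* Hypergeometric tails via the log-scale survival function; exact
  symmetric in the \((K, n)\) exchange.
* Spearman ties: average ranks; correlations clamped to \([-1, 1]\) and
  symmetrized against floating-point asymmetry at \(10^{-12}\).
* Agglomeration ties: delegated to `hclust`; merge *heights* are the
  tested contract (they are linkage-determined), leaf order is only
  reproducible, not canonical.
* The null calibration of over-representation p-values is checked as
  super-uniformity (empirical false-positive rate at nominal levels)
  rather than a distributional equality test, because discrete
  hypergeometric p-values are conservative by construction and a
  two-sided uniformity test would reject for reasons unrelated to
  miscalibration.
* Degenerate inputs fail loudly: empty queries, flat seizure responses,
  missing correlations, selections that empty the matrix, non-cumulative
  count series.

# Problem sizes in the shipped tests

The test suite regenerates everything in code: module recovery at 200
genes × 2000 cells over 10 seeds (planted 26-gene module recovered at
Jaccard ≥ 0.9), the null arm at 60 genes × 300 cells over 100 replicates
(no module in ≥ 95% of runs), T50 recovery over 200 simulated assays of
12 vials × 5 flies (median within 5% of truth), oracle equivalences
(enumeration, rank-Pearson, brute-force agglomeration, textbook BH) at
small n. These sizes were chosen as the smallest at which the respective
statistical contracts are sharp.

# Known limitations

The module boundary in real data was drawn by visual inspection in the
original analyses this pipeline mechanizes; explicit cut parameters can
bracket but not byte-reproduce such a boundary from raw data. Fold
enrichments from annotation services depend on their universe and are not
comparable across databases. The T50 model assumes a monotone logistic
hazard; bimodal seizure dynamics would be mis-summarized by any single
T50. Ortholog ids are opaque strings — no symbol/accession conversion is
attempted.
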