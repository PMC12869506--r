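Package: CoModMap
Title: Cross-Species Refinement of Gene Co-Expression Modules with
    Single-Cell Expression Data
Version: 0.99.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Refines a human disease-associated gene co-expression network
    against whole-brain single-cell RNA-seq data from a model organism.
    Expands a human gene list into an ortholog catalog using score
    thresholds and one-to-one/many-to-one/one-to-many mapping categories,
    filters genes by total expression, subsets cells by annotated type,
    computes the pairwise Spearman co-expression matrix, hierarchically
    clusters genes on 1-r distance, extracts high-co-expression modules,
    and quantifies disease-category enrichment and gene-set
    over-representation with hypergeometric statistics and
    Benjamini-Hochberg FDR control. Also fits variable-slope log-logistic
    curves to cumulative seizure time courses to estimate the time at
    which half of the animals respond (T50/logEC50). A synthetic-data
    generator with planted ground truth (latent-factor negative-binomial
    counts, scored ortholog tables, gene-set collections, binomial seizure
    time courses) makes the whole pipeline testable without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.3)
Imports:
    methods,
    stats,
    utils,
    tools,
    Matrix,
    S4Vectors,
    SummarizedExperiment,
    minpack.lm,
    ape,
    fgsea,
    yaml,
    jsonlite
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
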