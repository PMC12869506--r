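test_that("expression generator is deterministic and structurally sound", {
  a <- simulateExpression(nGenes = 40, nCells = 100, nCellTypes = 3, seed = 9,
                          moduleSpecs = list(list(size = 8, loading = 1)))
  b <- simulateExpression(nGenes = 40, nCells = 100, nCellTypes = 3, seed = 9,
                          moduleSpecs = list(list(size = 8, loading = 1)))
  expect_identical(SummarizedExperiment::assay(a$expr),
                   SummarizedExperiment::assay(b$expr))
  expect_identical(a$truth, b$truth)

  m <- SummarizedExperiment::assay(a$expr, "counts")
  expect_true(all(m >= 0))
  expect_true(all(m == round(m)))
  expect_true(all(cellTypes(a$expr) %in% paste0("type_", 1:3)))
  # planted truth names genes that exist, memberships disjoint
  genes <- unlist(a$truth$modules, use.names = FALSE)
  expect_true(all(genes %in% rownames(m)))
  expect_false(anyDuplicated(genes) > 0)
})

test_that("Poisson limit and parameter validation behave", {
  p <- simulateExpression(nGenes = 10, nCells = 50, dispersion = Inf,
                          moduleSpecs = list(), seed = 2)
  expect_true(all(SummarizedExperiment::assay(p$expr) >= 0))
  expect_error(simulateExpression(nGenes = 10, moduleSpecs =
                 list(list(size = 11, loading = 1))), "exceed")
  expect_error(simulateExpression(nGenes = 10, dispersion = 0,
                                  moduleSpecs = list()), "dispersion")
  expect_error(simulateExpression(nGenes = 10, moduleSpecs =
                 list(list(size = 2, loading = -1))), "loading")
})

test_that("zero loading gives a calibrated null, positive loading a module", {
  null <- simulateExpression(nGenes = 60, nCells = 2000,
                             moduleSpecs = list(list(size = 20, loading = 0)),
                             seed = 4)
  m <- log2(SummarizedExperiment::assay(null$expr) + 1)
  set.seed(41)
  pairs <- cbind(sample(60, 200, replace = TRUE),
                 sample(60, 200, replace = TRUE))
  pairs <- pairs[pairs[, 1] != pairs[, 2], ]
  rs <- apply(pairs, 1L, function(ij)
    stats::cor(m[ij[1], ], m[ij[2], ], method = "spearman"))
  expect_lt(mean(abs(rs)), 0.05)

  sim <- simulateExpression(nGenes = 80, nCells = 2000,
                            moduleSpecs = list(list(size = 20, loading = 1)),
                            seed = 5)
  cm <- corValues(spearmanMatrix(log2Transform(sim$expr)))
  mod <- sim$truth$modules$module_1
  bg <- setdiff(rownames(cm), mod)
  intra <- cm[mod, mod][upper.tri(diag(length(mod)))]
  backg <- cm[bg, bg][upper.tri(diag(length(bg)))]
  expect_gte(mean(intra), 0.4)
  expect_lte(mean(intra), 0.8)
  expect_gte(mean(intra) - mean(backg), 0.3)
})

test_that("ortholog table generator realizes the requested composition", {
  expect_identical(
    orthologRecords(simulateOrthologTable(163, c(37, 17), c(31, 107),
                                          seed = 3)),
    orthologRecords(simulateOrthologTable(163, c(37, 17), c(31, 107),
                                          seed = 3)))
  pure <- simulateOrthologTable(5, seed = 1)
  expect_equal(length(pure), 5L)
  expect_equal(length(unique(orthologRecords(pure)$fly_gene)), 5L)

  shared <- simulateOrthologTable(0, manyToOne = c(4, 2), seed = 1)
  expect_equal(length(shared), 4L)
  expect_equal(length(unique(orthologRecords(shared)$fly_gene)), 2L)

  multi <- simulateOrthologTable(0, oneToMany = c(3, 8), seed = 1)
  df <- orthologRecords(multi)
  expect_equal(nrow(df), 8L)
  expect_true(all(table(df$human_gene) >= 2))
  # tied partners share a score, so any tie window keeps them all
  expect_true(all(tapply(df$score, df$human_gene,
                         function(s) max(s) - min(s)) == 0))
  expect_true(all(df$score >= 3))

  expect_error(simulateOrthologTable(0, manyToOne = c(3, 2)), "manyToOne")
  expect_error(simulateOrthologTable(0, oneToMany = c(3, 4)), "oneToMany")
})

test_that("gene-set generator plants recoverable enrichment", {
  universe <- sprintf("g%03d", 1:400)
  query <- sample(universe, 30)
  coll <- simulateGeneSets(universe, nTerms = 50,
                           planted = list(list(term_id = "planted",
                                               target_genes = query,
                                               excess_fraction = 0.8)),
                           seed = 6)
  expect_identical(
    geneSets(simulateGeneSets(universe, nTerms = 5, seed = 8)),
    geneSets(simulateGeneSets(universe, nTerms = 5, seed = 8)))
  expect_true(all(unlist(geneSets(coll)) %in% universe))
  res <- ora(query, coll)
  expect_identical(res$term_id[1L], "planted")
  expect_true(res$significant[1L])
  expect_error(simulateGeneSets(universe[1:5], termSizeRange = c(2, 10)),
               "universe")
  expect_error(simulateGeneSets(universe, planted = list(
    list(term_id = "x", target_genes = "not_there",
         excess_fraction = 0.5))), "universe")
})

test_that("a term equal to the query attains the minimal possible p", {
  universe <- sprintf("g%03d", 1:200)
  query <- universe[1:20]
  coll <- TermCollection(list(exact = query), universe = universe)
  res <- ora(query, coll)
  # k = n = K = 20: no draw could overlap more
  expect_equal(res$k[1L], 20L)
  expect_equal(res$p[1L], hypergeomUpperTail(20, 20, 20, 200))
})

test_that("null gene-set collections yield no excess of small p-values", {
  universe <- sprintf("g%03d", 1:500)
  ps <- unlist(lapply(1:25, function(s) {
    coll <- simulateGeneSets(universe, nTerms = 20,
                             termSizeRange = c(20, 80), seed = 100 + s)
    set.seed(500 + s)
    ora(sample(universe, 40), coll)$p
  }))
  # discrete hypergeometric p-values are super-uniform under the null
  expect_lte(mean(ps <= 0.05), 0.075)
  expect_lte(mean(ps <= 0.20), 0.25)
})

test_that("seizure assay simulation respects the logistic law", {
  a <- simulateSeizureAssay(40, 3, seed = 12)
  b <- simulateSeizureAssay(40, 3, seed = 12)
  expect_identical(timeCourseData(a), timeCourseData(b))
  df <- timeCourseData(a)
  expect_true(all(tapply(df$n_seized_cum, df$vial_id,
                         function(x) all(diff(x) >= 0))))

  # logistic midpoint: the marginal fraction seized at t = T50 is 1/2
  big <- simulateSeizureAssay(40, 3, nVials = 400, fliesPerVial = 25,
                              seed = 13)
  bd <- timeCourseData(big)
  at40 <- bd[bd$time_min == 40, ]
  expect_equal(sum(at40$n_seized_cum) / sum(at40$n_total), 0.5,
               tolerance = 0.03)

  # T50 far beyond the window with a steep slope: nothing seizes
  quiet <- simulateSeizureAssay(500, 20, timepoints = seq(5, 80, 5),
                                seed = 14)
  expect_true(all(timeCourseData(quiet)$n_seized_cum == 0))

  expect_error(simulateSeizureAssay(40, 3, timepoints = c(5, 5, 10)),
               "strictly increasing")
  expect_error(simulateSeizureAssay(40, 3, fliesPerVial = 0), "fliesPerVial")
})
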