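rand_expr <- function(nGenes, nCells, seed = 1, continuous = FALSE) {
  set.seed(seed)
  vals <- if (continuous) runif(nGenes * nCells, 0, 100)
          else rpois(nGenes * nCells, 8)
  m <- matrix(vals, nGenes, nCells,
              dimnames = list(sprintf("g%03d", seq_len(nGenes)),
                              sprintf("c%03d", seq_len(nCells))))
  ExpressionCounts(m, rep("n", nCells))
}

test_that("log2 transform maps values as documented and keeps shape", {
  m <- matrix(c(0, 7, 3, 15), 2, 2,
              dimnames = list(c("a", "b"), c("x", "y")))
  ec <- ExpressionCounts(m, c("t", "t"))
  lt <- log2Transform(ec, 1)
  expect_equal(SummarizedExperiment::assay(lt)[1, 1], 0)
  expect_equal(SummarizedExperiment::assay(lt)[2, 1], 3)  # log2(8)
  expect_identical(dimnames(lt), dimnames(ec))
  expect_error(log2Transform(ec, 0), "pseudocount")
})

test_that("Spearman matches the rank-then-Pearson oracle", {
  expect_equal(spearman_naive(1:4, c(1, 3, 2, 4)), 0.8)
  ec <- rand_expr(20, 200, seed = 11, continuous = TRUE)
  r <- corValues(spearmanMatrix(ec))
  m <- SummarizedExperiment::assay(ec)
  for (i in c(1, 5, 12)) for (j in c(3, 9, 20)) if (i != j)
    expect_equal(r[i, j], spearman_naive(m[i, ], m[j, ]),
                 tolerance = 1e-12)
  expect_equal(diag(r), setNames(rep(1, 20), rownames(m)))
  expect_lte(max(abs(r - t(r))), 1e-12)

  y <- rbind(x = 1:10, y = exp(1:10 / 3))  # strictly increasing map
  ecy <- ExpressionCounts(y, rep("t", 10),
                          cellIds = sprintf("c%02d", 1:10))
  expect_equal(corValues(spearmanMatrix(ecy))["x", "y"], 1)
})

test_that("Spearman is invariant under strictly increasing transforms", {
  ec <- rand_expr(15, 80, seed = 12, continuous = TRUE)  # tie-free
  r1 <- corValues(spearmanMatrix(ec))
  m <- SummarizedExperiment::assay(ec)
  ec2 <- ExpressionCounts(exp(m / 50), cellTypes(ec))
  expect_equal(corValues(spearmanMatrix(ec2)), r1, tolerance = 1e-12)
  r3 <- corValues(spearmanMatrix(log2Transform(ec, 1)))
  expect_equal(r3, r1, tolerance = 1e-12)
})

test_that("constant genes surface as NA and block clustering loudly", {
  m <- rbind(flat = rep(5, 10), a = rpois(10, 5) + (1:10) / 7,
             b = rpois(10, 5) + (10:1) / 7)
  colnames(m) <- sprintf("c%02d", 1:10)
  ec <- ExpressionCounts(m, rep("t", 10))
  expect_warning(cm <- spearmanMatrix(ec), "flat")
  expect_true(all(is.na(corValues(cm)["flat", c("a", "b")])))
  expect_false(anyNA(corValues(cm)[c("a", "b"), c("a", "b")]))
  expect_error(hierarchicalCluster(cm), "missing")
  expect_error(spearmanMatrix(ec[, 1:2]), "3 cells")
})

test_that("clustering reproduces a hand agglomeration on 3 genes", {
  v <- matrix(c(1, 0.9, 0.2, 0.9, 1, 0.1, 0.2, 0.1, 1), 3, 3,
              dimnames = list(c("A", "B", "C"), c("A", "B", "C")))
  cm <- new("CorrelationMatrix", values = v)
  hc <- hierarchicalCluster(cm, "complete")
  expect_equal(hc$height, c(0.1, 0.9))
  first <- rownames(v)[-hc$merge[1, ]]
  expect_setequal(first, c("A", "B"))
})

test_that("merge heights equal the brute-force agglomeration oracle", {
  for (seed in c(7, 8)) {
    ec <- rand_expr(15, 60, seed = seed, continuous = TRUE)
    cm <- spearmanMatrix(ec)
    d <- 1 - corValues(cm)
    for (linkage in c("complete", "average", "single")) {
      hc <- hierarchicalCluster(cm, linkage)
      expect_equal(sort(hc$height),
                   sort(agglom_heights_naive(stats::as.dist(d), linkage)),
                   tolerance = 1e-12)
    }
    hc <- hierarchicalCluster(cm, "complete")
    expect_true(all(diff(hc$height) >= -1e-12))  # monotone heights
  }
})

test_that("identical genes merge at height zero", {
  base <- runif(30, 0, 10)
  m <- rbind(g1 = base, g2 = base, g3 = rev(base))
  colnames(m) <- sprintf("c%02d", 1:30)
  cm <- spearmanMatrix(ExpressionCounts(m, rep("t", 30)))
  hc <- hierarchicalCluster(cm)
  expect_equal(min(hc$height), 0)
})

test_that("module extraction recovers the planted module and respects cuts", {
  sim <- simulateExpression(nGenes = 120, nCells = 1200,
                            moduleSpecs = list(list(size = 26, loading = 1)),
                            seed = 17)
  cm <- spearmanMatrix(log2Transform(sim$expr))
  hc <- hierarchicalCluster(cm)
  ms <- extractModules(hc, cm)
  expect_gte(jaccard(modules(ms)[[1L]], sim$truth$modules$module_1), 0.9)
  st <- moduleTable(ms)
  s <- moduleStats(modules(ms)[[1L]], cm)
  expect_equal(st$mean_intra_r[1L], unname(s$intra["mean"]))

  everything <- extractModules(hc, cm, cutHeight = 2, minMeanIntraR = -1,
                               minSize = 1)
  expect_length(modules(everything), 1L)
  expect_setequal(modules(everything)[[1L]], rownames(corValues(cm)))
  expect_error(extractModules(hc, cm, cutHeight = 0.5, nClusters = 4),
               "exactly one")
})

test_that("independent data yields no module at the default thresholds", {
  hits <- vapply(1:20, function(s) {
    sim <- simulateExpression(nGenes = 60, nCells = 300,
                              moduleSpecs = list(), seed = 700 + s)
    cm <- spearmanMatrix(log2Transform(sim$expr))
    hc <- hierarchicalCluster(cm)
    suppressWarnings(length(extractModules(hc, cm)) > 0)
  }, NA)
  expect_lte(mean(hits), 0.05)
})

test_that("recovery degrades monotonically as the loading decreases", {
  stats_at <- function(loading) {
    sim <- simulateExpression(nGenes = 100, nCells = 800,
                              moduleSpecs = list(list(size = 20,
                                                      loading = loading)),
                              seed = 23)
    cm <- spearmanMatrix(log2Transform(sim$expr))
    hc <- hierarchicalCluster(cm)
    ms <- suppressWarnings(extractModules(hc, cm))
    jc <- if (length(ms)) jaccard(modules(ms)[[1L]],
                                  sim$truth$modules$module_1) else 0
    intra <- moduleStats(sim$truth$modules$module_1, cm)$intra["mean"]
    c(jc = jc, intra = unname(intra))
  }
  res <- vapply(c(0.25, 0.6, 1.2), stats_at, c(jc = 0, intra = 0))
  expect_true(all(diff(res["intra", ]) > 0))
  expect_true(all(diff(res["jc", ]) >= 0))
})

test_that("module statistics match pair enumeration and reject overlap", {
  v <- diag(6); v[upper.tri(v)] <- seq(0.05, 0.75, by = 0.05)
  v <- v + t(v); diag(v) <- 1
  ids <- sprintf("g%d", 1:6); dimnames(v) <- list(ids, ids)
  cm <- new("CorrelationMatrix", values = v)
  g <- c("g1", "g2", "g5")
  pairs <- combn(g, 2)
  rs <- apply(pairs, 2, function(p) v[p[1], p[2]])
  s <- moduleStats(g, cm, other = c("g3", "g6"))
  expect_equal(unname(s$intra), c(min(rs), mean(rs), max(rs)))
  cross <- as.vector(v[g, c("g3", "g6")])
  expect_equal(unname(s$cross), c(min(cross), mean(cross), max(cross)))
  expect_error(moduleStats(g, cm, other = c("g1", "g6")), "disjoint")
  two <- new("CorrelationMatrix", values = matrix(
    c(1, .5, .5, 1), 2, 2, dimnames = list(c("a", "b"), c("a", "b"))))
  expect_equal(unname(moduleStats(c("a", "b"), two)$intra), rep(0.5, 3))
  expect_true(all(is.na(moduleStats("a", two)$intra)))
})

test_that("gene order permutation only relabels the analysis", {
  ec <- rand_expr(12, 100, seed = 31)
  cm1 <- corValues(spearmanMatrix(ec))
  set.seed(32); perm <- sample(nrow(ec))
  cm2 <- corValues(spearmanMatrix(ec[perm, ]))
  expect_equal(cm2[rownames(cm1), colnames(cm1)], cm1)
})

test_that("correlation matrices and dendrograms round-trip to disk", {
  ec <- rand_expr(8, 50, seed = 33)
  cm <- spearmanMatrix(ec)
  path <- withr::local_tempfile(fileext = ".tsv")
  writeCorrelation(cm, path)
  expect_equal(corValues(readCorrelation(path)), corValues(cm),
               tolerance = 1e-9)
  hc <- hierarchicalCluster(cm)
  nwk <- dendroToNewick(hc)
  tr <- ape::read.tree(text = nwk)
  expect_setequal(tr$tip.label, rownames(corValues(cm)))
})
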