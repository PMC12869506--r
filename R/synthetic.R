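#' Simulate a cell-type-labelled count matrix with planted modules
#'
#' Generates a genes x cells negative-binomial (gamma-Poisson) count
#' matrix that emulates the statistical structure this pipeline consumes:
#' cells carry type labels, genes have lognormally spread baseline means,
#' per-cell library sizes vary multiplicatively, and each planted module
#' shares a per-cell lognormal latent factor that induces a known,
#' tunable rank correlation among its members while background genes stay
#' uncorrelated.
#'
#' The mean model for gene g in cell c is
#' `mu = baseline_g * factor_c^loading * libsize_c` with
#' `factor_c ~ lognormal(0, 1)` per module and `libsize_c` lognormal with
#' unit mean and the stated coefficient of variation; counts are drawn
#' from a negative binomial with that mean and the shared `dispersion` as
#' its size (shape) parameter, so `dispersion = Inf` gives the Poisson
#' limit. With the default `loading = 1` the intra-module Spearman r of a
#' 26-gene module over 2000 cells falls in roughly 0.4-0.65, inside the
#' 0.3-0.85 range typical of strongly co-expressed neuronal modules in
#' whole-brain single-cell atlases.
#'
#' @param nGenes,nCells matrix dimensions (defaults 200 x 2000).
#' @param nCellTypes number of cell-type labels, assigned uniformly at
#'   random (default 5). Labels partition cells for selection tests but do
#'   not themselves shift expression.
#' @param moduleSpecs list of `list(size=, loading=)` per planted module;
#'   sizes must sum to at most `nGenes`, loadings must be >= 0. Default:
#'   one 26-gene module with loading 1.
#' @param baselineLogMeanRange range (log2 counts) of per-gene baseline
#'   means, default `c(1, 5)` i.e. means of 2-32.
#' @param dispersion negative-binomial size parameter, > 0; `Inf` gives
#'   Poisson counts. Default 2.
#' @param librarySizeCV coefficient of variation of the per-cell library
#'   multiplier, >= 0. Default 0.1.
#' @param seed integer seed; identical seeds give bit-identical output.
#' @return A list: `expr` (an \linkS4class{ExpressionCounts}) and `truth`
#'   (list with `modules` — named list of member gene ids — and
#'   `factors` — the modules x cells latent activity matrix).
#' @export
simulateExpression <- function(nGenes = 200, nCells = 2000, nCellTypes = 5,
                               moduleSpecs = list(list(size = 26, loading = 1)),
                               baselineLogMeanRange = c(1, 5),
                               dispersion = 2, librarySizeCV = 0.1,
                               seed = 1) {
  sizes <- vapply(moduleSpecs, function(s) as.numeric(s$size), 0)
  loadings <- vapply(moduleSpecs, function(s) as.numeric(s$loading), 0)
  if (sum(sizes) > nGenes)
    stop("module sizes (", sum(sizes), ") exceed nGenes (", nGenes, ")")
  if (any(loadings < 0)) stop("loadings must be >= 0")
  if (!(dispersion > 0)) stop("dispersion must be > 0")
  if (librarySizeCV < 0) stop("librarySizeCV must be >= 0")

  set.seed(as.integer(seed))
  gene_ids <- sprintf("gene_%04d", seq_len(nGenes))
  cell_ids <- sprintf("cell_%05d", seq_len(nCells))
  types <- sprintf("type_%d", sample.int(nCellTypes, nCells, replace = TRUE))

  baseline <- 2^stats::runif(nGenes, baselineLogMeanRange[1L],
                             baselineLogMeanRange[2L])
  if (librarySizeCV > 0) {
    sig <- sqrt(log(1 + librarySizeCV^2))
    libsize <- exp(stats::rnorm(nCells, -sig^2 / 2, sig))
  } else libsize <- rep(1, nCells)

  # disjoint module memberships over randomly placed genes
  pool <- sample.int(nGenes)
  memberships <- list()
  factors <- matrix(0, nrow = length(sizes), ncol = nCells)
  offset <- 0L
  mu <- outer(baseline, libsize)
  for (j in seq_along(sizes)) {
    idx <- pool[seq_len(sizes[j]) + offset]
    offset <- offset + sizes[j]
    memberships[[paste0("module_", j)]] <- sort(gene_ids[idx])
    f <- exp(stats::rnorm(nCells))
    factors[j, ] <- f
    mu[idx, ] <- mu[idx, ] * rep(f^loadings[j], each = length(idx))
  }
  counts <- if (is.finite(dispersion)) {
    matrix(stats::rnbinom(length(mu), mu = mu, size = dispersion),
           nrow = nGenes)
  } else {
    matrix(stats::rpois(length(mu), lambda = mu), nrow = nGenes)
  }
  dimnames(counts) <- list(gene_ids, cell_ids)
  list(expr = ExpressionCounts(counts, types),
       truth = list(modules = memberships, factors = factors))
}

#' Simulate a scored ortholog table with a fixed mapping composition
#'
#' Builds an \linkS4class{OrthologTable} realizing exactly the requested
#' composition of the three mapping categories: `oneToOne` human genes
#' each with a unique fly partner; `manyToOne = c(n_human, n_fly)` human
#' genes sharing `n_fly` fly genes (each fly gene representing at least
#' two humans); `oneToMany = c(n_human, n_fly)` human genes each carrying
#' at least two tied fly partners, `n_fly` fly genes in total. All scores
#' are at least `minScore`, and the partners of a one-to-many human gene
#' share the same score so that they fall inside any tie window.
#'
#' @param oneToOne count of one-to-one human genes.
#' @param manyToOne integer pair `c(n_human, n_fly)` with
#'   `n_fly <= floor(n_human / 2)` so every shared fly gene represents at
#'   least two human genes (use `c(0, 0)` to omit).
#' @param oneToMany integer pair `c(n_human, n_fly)` with
#'   `n_fly >= 2 * n_human` so every such human gene gets at least two
#'   tied partners (use `c(0, 0)` to omit).
#' @param minScore minimum score to assign, default 3.
#' @param seed integer seed.
#' @return An \linkS4class{OrthologTable}. Running [classifyAndExpand()]
#'   on it recovers the requested composition; e.g. the composition
#'   `(163, c(37, 17), c(31, 107))` expands to a catalog of 287 unique
#'   fly genes.
#' @export
simulateOrthologTable <- function(oneToOne, manyToOne = c(0, 0),
                                  oneToMany = c(0, 0), minScore = 3,
                                  seed = 1) {
  o2o <- as.integer(oneToOne)
  m2o_h <- as.integer(manyToOne[1L]); m2o_f <- as.integer(manyToOne[2L])
  o2m_h <- as.integer(oneToMany[1L]); o2m_f <- as.integer(oneToMany[2L])
  if (o2o < 0 || m2o_h < 0 || m2o_f < 0 || o2m_h < 0 || o2m_f < 0)
    stop("all composition counts must be non-negative")
  if ((m2o_h == 0) != (m2o_f == 0) ||
      (m2o_f > 0 && m2o_h < 2 * m2o_f))
    stop("manyToOne requires n_human >= 2 * n_fly (each shared fly gene ",
         "must represent at least two human genes)")
  if ((o2m_h == 0) != (o2m_f == 0) ||
      (o2m_h > 0 && o2m_f < 2 * o2m_h))
    stop("oneToMany requires n_fly >= 2 * n_human (each such human gene ",
         "must carry at least two tied partners)")
  set.seed(as.integer(seed))
  hi <- 0L; fi <- 0L
  next_h <- function(n) sprintf("HSAP%04d", seq_len(n) + hi)
  next_f <- function(n) sprintf("FBgn%07d", seq_len(n) + fi)
  rows <- list()

  if (o2o > 0) {
    h <- next_h(o2o); hi <- hi + o2o
    f <- next_f(o2o); fi <- fi + o2o
    rows[[length(rows) + 1L]] <- data.frame(
      human_gene = h, fly_gene = f,
      score = sample(minScore:(minScore + 12), o2o, replace = TRUE))
  }
  if (m2o_h > 0) {
    h <- next_h(m2o_h); hi <- hi + m2o_h
    f <- next_f(m2o_f); fi <- fi + m2o_f
    # each fly gene gets >= 2 humans; spread the remainder evenly
    assign <- c(rep(seq_len(m2o_f), 2),
                if (m2o_h > 2 * m2o_f)
                  sort(rep_len(seq_len(m2o_f), m2o_h - 2 * m2o_f)))
    rows[[length(rows) + 1L]] <- data.frame(
      human_gene = h, fly_gene = f[assign],
      score = sample(minScore:(minScore + 12), m2o_h, replace = TRUE))
  }
  if (o2m_h > 0) {
    h <- next_h(o2m_h); hi <- hi + o2m_h
    f <- next_f(o2m_f); fi <- fi + o2m_f
    # each human gets >= 2 fly partners; spread the remainder evenly
    assign <- c(rep(seq_len(o2m_h), 2),
                if (o2m_f > 2 * o2m_h)
                  sort(rep_len(seq_len(o2m_h), o2m_f - 2 * o2m_h)))
    assign <- sort(assign)
    per_h <- sample(minScore:(minScore + 12), o2m_h, replace = TRUE)
    rows[[length(rows) + 1L]] <- data.frame(
      human_gene = h[assign], fly_gene = f,
      score = per_h[assign])
  }
  if (!length(rows))
    return(OrthologTable(data.frame(human_gene = character(),
                                    fly_gene = character(),
                                    score = numeric())))
  OrthologTable(do.call(rbind, rows))
}

#' Simulate a gene-set collection with planted enriched terms
#'
#' Draws `nTerms` random term sets from the universe (sizes uniform in
#' `termSizeRange`), then appends one term per entry of `planted`, whose
#' members are a controlled mixture of target genes and random filler:
#' a fraction `excess_fraction` of the term is taken from `target_genes`
#' (capped at the target and term sizes) and the rest is drawn from the
#' remaining universe. `excess_fraction = 0` yields a pure random term,
#' so a null collection is calibrated by construction.
#'
#' @param universe character vector of background gene ids.
#' @param nTerms number of random terms, default 100.
#' @param termSizeRange integer pair, default `c(10, 100)`; must not
#'   exceed the universe size.
#' @param planted list of `list(term_id=, target_genes=, excess_fraction=)`.
#'   Target genes must lie in the universe.
#' @param seed integer seed.
#' @return A \linkS4class{TermCollection} over `universe`.
#' @export
simulateGeneSets <- function(universe, nTerms = 100,
                             termSizeRange = c(10, 100), planted = list(),
                             seed = 1) {
  universe <- unique(as.character(universe))
  if (max(termSizeRange) > length(universe))
    stop("term sizes cannot exceed the universe size")
  for (p in planted)
    if (!all(p$target_genes %in% universe))
      stop("planted target genes must lie in the universe")
  set.seed(as.integer(seed))
  sets <- list()
  for (i in seq_len(nTerms)) {
    sz <- sample(termSizeRange[1L]:termSizeRange[2L], 1L)
    sets[[sprintf("term_%03d", i)]] <- sample(universe, sz)
  }
  for (p in planted) {
    sz <- sample(termSizeRange[1L]:termSizeRange[2L], 1L)
    target <- unique(as.character(p$target_genes))
    m <- min(round(p$excess_fraction * sz), length(target), sz)
    members <- if (m > 0) sample(target, m) else character()
    filler <- sample(setdiff(universe, members), sz - m)
    sets[[as.character(p$term_id)]] <- c(members, filler)
  }
  TermCollection(sets, universe = universe)
}

#' Logistic (Hill-form) seizure curve in log10 time
#'
#' `f(t) = bottom + (top - bottom) / (1 + 10^((log10(t50) - log10(t)) * slope))`,
#' the variable-slope sigmoid used throughout the assay module. `f(0)` is
#' taken as `bottom` (the limit for positive slope).
#'
#' @param t time (minutes), >= 0.
#' @param t50 half-response time (minutes).
#' @param slope Hill slope.
#' @param bottom,top asymptotes, defaults 0 and 1.
#' @return Response fraction(s).
#' @export
logisticFraction <- function(t, t50, slope, bottom = 0, top = 1) {
  out <- ifelse(t <= 0, bottom,
                bottom + (top - bottom) /
                  (1 + 10^((log10(t50) - log10(pmax(t, .Machine$double.xmin))) * slope)))
  out
}

#' Simulate a heat-seizure assay from a logistic hazard
#'
#' For each vial, the number of newly seizing animals in each observation
#' interval is drawn binomially from the conditional hazard implied by
#' the logistic CDF at `(trueT50, hillSlope)`:
#' `p_k = (F(t_k) - F(t_{k-1})) / (1 - F(t_{k-1}))` applied to the
#' animals not yet seizing. Cumulative counts are therefore monotone by
#' construction, and the marginal probability of having seized by time t
#' follows the logistic curve exactly.
#'
#' @param trueT50 true half-response time, minutes.
#' @param hillSlope Hill slope of the logistic curve.
#' @param nVials number of replicate vials, default 12.
#' @param fliesPerVial animals per vial, default 5.
#' @param timepoints strictly increasing observation times (minutes);
#'   default `seq(5, 80, by = 5)`, the conventional 5-min-interval,
#'   80-min protocol.
#' @param genotype label stored with the records.
#' @param seed integer seed.
#' @return A \linkS4class{SeizureTimeCourse}.
#' @export
simulateSeizureAssay <- function(trueT50, hillSlope, nVials = 12,
                                 fliesPerVial = 5,
                                 timepoints = seq(5, 80, by = 5),
                                 genotype = "genotype", seed = 1) {
  if (any(diff(timepoints) <= 0) || any(timepoints <= 0))
    stop("timepoints must be positive and strictly increasing")
  if (fliesPerVial < 1) stop("fliesPerVial must be >= 1")
  set.seed(as.integer(seed))
  Fcdf <- logisticFraction(c(0, timepoints), trueT50, hillSlope)
  rows <- vector("list", nVials)
  for (v in seq_len(nVials)) {
    alive <- fliesPerVial  # not yet seizing
    cum <- integer(length(timepoints))
    for (i in seq_along(timepoints)) {
      denom <- 1 - Fcdf[i]
      p <- if (denom <= 0) 1 else (Fcdf[i + 1L] - Fcdf[i]) / denom
      p <- min(max(p, 0), 1)
      new_seized <- stats::rbinom(1L, alive, p)
      alive <- alive - new_seized
      cum[i] <- fliesPerVial - alive
    }
    rows[[v]] <- data.frame(
      vial_id = sprintf("%s_vial_%02d", genotype, v), genotype = genotype,
      time_min = timepoints, n_total = fliesPerVial, n_seized_cum = cum)
  }
  new("SeizureTimeCourse", data = do.call(rbind, rows))
}
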