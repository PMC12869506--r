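#' Log2-transform an expression matrix
#'
#' Applies `x -> log2(x + pseudocount)` elementwise. Shape and identifiers
#' are unchanged and the transformation is recorded in `metadata()`. The
#' transform is strictly increasing, so downstream Spearman correlations
#' are unaffected on tie-free data; it is kept for fidelity to the
#' conventional log2 preprocessing of count matrices.
#'
#' @param expr an \linkS4class{ExpressionCounts}.
#' @param pseudocount numeric(1); must be > 0 when zeros are present.
#' @return An \linkS4class{ExpressionCounts} holding transformed values.
#' @export
log2Transform <- function(expr, pseudocount = 1) {
  stopifnot(is(expr, "ExpressionCounts"))
  m <- assay(expr, "counts")
  if (pseudocount <= 0 && any(m == 0))
    stop("pseudocount must be > 0 when zero counts are present")
  out <- expr
  assay(out, "counts") <- log2(m + pseudocount)
  metadata(out)$log2_transformed <- TRUE
  metadata(out)$pseudocount <- pseudocount
  out
}

#' Pairwise Spearman correlation matrix over genes
#'
#' Computes Spearman rank correlation (average ranks for ties — the
#' conventional treatment, relevant here because zero counts tie heavily
#' in sparse data) between every pair of genes across all cells of the
#' matrix. Genes whose expression is constant across cells have undefined
#' correlations; their entries are `NA` and a warning names them so they
#' can be removed upstream.
#'
#' @param expr an \linkS4class{ExpressionCounts} with >= 2 genes and
#'   >= 3 cells.
#' @return A \linkS4class{CorrelationMatrix}.
#' @export
spearmanMatrix <- function(expr) {
  stopifnot(is(expr, "ExpressionCounts"))
  m <- assay(expr, "counts")
  if (ncol(m) < 3L) stop("need at least 3 cells")
  if (nrow(m) < 2L) stop("need at least 2 genes")
  const <- apply(m, 1L, function(x) max(x) == min(x))
  r <- suppressWarnings(stats::cor(t(m), method = "spearman"))
  if (any(const)) {
    warning("constant gene(s) with undefined correlations recorded as NA: ",
            paste(rownames(m)[const], collapse = ", "))
    r[const, ] <- NA_real_
    r[, const] <- NA_real_
  }
  diag(r) <- 1
  r[!is.na(r)] <- pmin(pmax(r[!is.na(r)], -1), 1)
  new("CorrelationMatrix", values = (r + t(r)) / 2)
}

#' Hierarchically cluster genes on correlation distance
#'
#' Agglomerative clustering of genes on the distance `d = 1 - r`, the
#' standard co-expression dissimilarity. The default linkage is complete
#' (the `hclust` default); average and single linkage are available since
#' the choice materially shapes flat cuts.
#'
#' @param cor a \linkS4class{CorrelationMatrix} without missing entries.
#' @param linkage `"complete"`, `"average"` or `"single"`.
#' @return A [stats::hclust] tree over the genes.
#' @seealso [extractModules()], [dendroToNewick()]
#' @export
hierarchicalCluster <- function(cor,
                                linkage = c("complete", "average", "single")) {
  linkage <- match.arg(linkage)
  stopifnot(is(cor, "CorrelationMatrix"))
  v <- corValues(cor)
  if (anyNA(v))
    stop("correlation matrix has missing entries; drop constant genes ",
         "upstream before clustering")
  stats::hclust(stats::as.dist(1 - v), method = linkage)
}

#' Export a dendrogram as Newick with branch lengths
#'
#' Branch lengths are the merge-height differences of the tree, so leaf
#' depths reproduce the merge heights.
#'
#' @param hc a [stats::hclust] tree.
#' @param path output file; when `NULL` the Newick string is returned.
#' @return The Newick string, invisibly when written to file.
#' @export
dendroToNewick <- function(hc, path = NULL) {
  stopifnot(inherits(hc, "hclust"))
  phy <- ape::as.phylo(hc)
  if (is.null(path)) return(ape::write.tree(phy))
  ape::write.tree(phy, file = path)
  invisible(ape::write.tree(phy))
}

#' Extract high-co-expression modules from a flat cut of the dendrogram
#'
#' Cuts the tree at a height (or into a fixed number of clusters), keeps
#' the clusters with at least `minSize` genes and mean off-diagonal
#' intra-cluster Spearman r of at least `minMeanIntraR`, and returns them
#' sorted by decreasing mean intra-module r with their min/mean/max
#' internal correlations. The thresholds replace the by-eye module
#' delineation often used on clustered heatmaps with explicit, recorded
#' parameters.
#'
#' @param hc a [stats::hclust] tree from [hierarchicalCluster()].
#' @param cor the \linkS4class{CorrelationMatrix} the tree was built from.
#' @param cutHeight numeric(1) cut height on the 1 - r scale (default
#'   0.7, i.e. clusters whose complete-linkage diameter keeps all pairwise
#'   r above 0.3). Give either this or `nClusters`, not both.
#' @param nClusters integer(1) number of flat clusters.
#' @param minSize integer(1) minimum module size, default 10.
#' @param minMeanIntraR numeric(1) minimum mean intra-module r, default 0.3.
#' @return A \linkS4class{ModuleSet}; empty (with a warning) when no
#'   cluster passes.
#' @export
extractModules <- function(hc, cor, cutHeight = 0.7, nClusters = NULL,
                           minSize = 10, minMeanIntraR = 0.3) {
  stopifnot(inherits(hc, "hclust"), is(cor, "CorrelationMatrix"))
  if (!missing(cutHeight) && !is.null(nClusters))
    stop("give exactly one of 'cutHeight' or 'nClusters'")
  if (!is.null(nClusters)) {
    cl <- stats::cutree(hc, k = nClusters)
  } else {
    cl <- stats::cutree(hc, h = cutHeight)
  }
  v <- corValues(cor)
  mods <- split(names(cl), cl)
  keep <- list(); st <- list()
  for (g in mods) {
    if (length(g) < minSize) next
    s <- moduleStats(g, cor)
    if (is.na(s$intra["mean"]) || s$intra["mean"] < minMeanIntraR) next
    keep[[length(keep) + 1L]] <- g
    st[[length(st) + 1L]] <- s$intra
  }
  if (!length(keep)) {
    warning("no cluster passes the size and intra-correlation thresholds")
    return(new("ModuleSet", modules = list(),
               stats = data.frame(module_id = character(), size = integer(),
                                  min_intra_r = numeric(),
                                  mean_intra_r = numeric(),
                                  max_intra_r = numeric()),
               parameters = list(cutHeight = if (is.null(nClusters)) cutHeight else NA,
                                 nClusters = nClusters, minSize = minSize,
                                 minMeanIntraR = minMeanIntraR)))
  }
  ord <- order(vapply(st, `[`, 0, "mean"), decreasing = TRUE)
  keep <- keep[ord]; st <- st[ord]
  names(keep) <- paste0("module_", seq_along(keep))
  stats_df <- data.frame(
    module_id = names(keep),
    size = lengths(keep),
    min_intra_r = vapply(st, `[`, 0, "min"),
    mean_intra_r = vapply(st, `[`, 0, "mean"),
    max_intra_r = vapply(st, `[`, 0, "max"),
    row.names = NULL)
  new("ModuleSet", modules = keep, stats = stats_df,
      parameters = list(cutHeight = if (is.null(nClusters)) cutHeight else NA,
                        nClusters = nClusters, minSize = minSize,
                        minMeanIntraR = minMeanIntraR))
}

#' Intra- and cross-set correlation summaries
#'
#' Minimum, mean and maximum of the off-diagonal Spearman r within a gene
#' set, and between the set and a second, disjoint set when given. A
#' singleton set with no partner set has an undefined intra range,
#' returned as `NA`.
#'
#' @param genes character vector of gene ids (subset of the matrix).
#' @param cor a \linkS4class{CorrelationMatrix}.
#' @param other optional second, disjoint gene set.
#' @return A list with components `intra` and (when `other` is given)
#'   `cross`, each a named numeric vector `min`, `mean`, `max`.
#' @export
moduleStats <- function(genes, cor, other = NULL) {
  stopifnot(is(cor, "CorrelationMatrix"))
  v <- corValues(cor)
  genes <- unique(as.character(genes))
  if (!all(genes %in% rownames(v)))
    stop("gene(s) not in the correlation matrix: ",
         paste(setdiff(genes, rownames(v)), collapse = ", "))
  out <- list()
  if (length(genes) >= 2L) {
    sub <- v[genes, genes]
    off <- sub[upper.tri(sub)]
    out$intra <- c(min = min(off), mean = mean(off), max = max(off))
  } else {
    out$intra <- c(min = NA_real_, mean = NA_real_, max = NA_real_)
  }
  if (!is.null(other)) {
    other <- unique(as.character(other))
    if (length(intersect(genes, other)))
      stop("'genes' and 'other' must be disjoint")
    if (!all(other %in% rownames(v)))
      stop("gene(s) not in the correlation matrix: ",
           paste(setdiff(other, rownames(v)), collapse = ", "))
    x <- v[genes, other, drop = FALSE]
    out$cross <- c(min = min(x), mean = mean(x), max = max(x))
  }
  out
}

#' Write a correlation matrix as labelled square TSV
#'
#' @param cor a \linkS4class{CorrelationMatrix}.
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
writeCorrelation <- function(cor, path) {
  stopifnot(is(cor, "CorrelationMatrix"))
  v <- corValues(cor)
  df <- data.frame(gene_id = rownames(v), v, check.names = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a labelled square correlation TSV
#'
#' @param path file written by [writeCorrelation()].
#' @return A \linkS4class{CorrelationMatrix}.
#' @export
readCorrelation <- function(path) {
  df <- utils::read.delim(path, check.names = FALSE,
                          stringsAsFactors = FALSE)
  m <- as.matrix(df[, -1L, drop = FALSE])
  rownames(m) <- df$gene_id
  new("CorrelationMatrix", values = m)
}
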