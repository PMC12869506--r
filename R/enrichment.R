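#' Upper-tail hypergeometric probability
#'
#' Probability of observing at least `k` successes in a draw of `n` from a
#' population of `N` containing `K` successes, i.e. `P(X >= k)` with the
#' observed count included — the over-representation convention. Evaluated
#' through the log-scale survival function for numerical stability at
#' extreme tails.
#'
#' @param k observed successes in the draw.
#' @param n draw size.
#' @param K successes in the population.
#' @param N population size.
#' @return The tail probability.
#' @examples
#' hypergeomUpperTail(k = 13, n = 26, K = 53, N = 320)  # 3.45e-05
#' @export
hypergeomUpperTail <- function(k, n, K, N) {
  for (v in list(k, n, K, N))
    if (!is.numeric(v) || length(v) != 1L || is.na(v) || v != round(v))
      stop("k, n, K, N must be single integers")
  if (K > N || n > N) stop("K and n must not exceed N")
  if (k < 0 || k > min(n, K)) stop("k must satisfy 0 <= k <= min(n, K)")
  if (k == 0) return(1)
  exp(stats::phyper(k - 1, K, N - K, n, lower.tail = FALSE, log.p = TRUE))
}

#' Disease-category enrichment of a module against a background
#'
#' Tests whether genes of the given categories are over-represented in a
#' module relative to a background network using the upper-tail
#' hypergeometric test, and reports the fold enrichment
#' `(k/n) / (K/N)` — the module's positive rate over the background rate.
#'
#' @param module character vector of gene ids, a subset of `background`.
#' @param background character vector of background gene ids.
#' @param categories a category table from [readCategoryTable()] (columns
#'   `gene`, `category`).
#' @param positive categories counted as positive; defaults to both
#'   disease categories.
#' @return A list: `k`, `n`, `K`, `N`, `fold`, `p`, `percent_module`,
#'   `percent_background` (percentages of positives, integer-rounded the
#'   way such figures are usually quoted). `fold` is `NA` when the
#'   background contains no positives.
#' @export
categoryEnrichment <- function(module, background, categories,
                               positive = c("epilepsy", "epilepsy_related")) {
  module <- unique(as.character(module))
  background <- unique(as.character(background))
  if (!all(module %in% background))
    stop("module must be a subset of the background")
  cat_map <- stats::setNames(categories$category, categories$gene)
  pos_genes <- names(cat_map)[cat_map %in% positive]
  k <- sum(module %in% pos_genes)
  K <- sum(background %in% pos_genes)
  n <- length(module)
  N <- length(background)
  fold <- if (K == 0) NA_real_ else (k / n) / (K / N)
  p <- if (K == 0) 1 else hypergeomUpperTail(k, n, K, N)
  list(k = k, n = n, K = K, N = N, fold = fold, p = p,
       percent_module = round(100 * k / n),
       percent_background = round(100 * K / N))
}

#' Over-representation analysis against a gene-set collection
#'
#' Per term: upper-tail hypergeometric p-value of the query/term overlap
#' in the background universe, fold enrichment `(k/n)/(K/N)`, and
#' Benjamini-Hochberg FDR adjusted across all terms of the collection
#' (one family per call; no cross-collection pooling). Query genes
#' outside the universe are dropped with a warning.
#'
#' @param query character vector of gene ids.
#' @param collection a \linkS4class{TermCollection}.
#' @param alpha FDR significance threshold, default 0.05.
#' @param background optional background universe overriding the
#'   collection's own.
#' @return data.frame sorted by raw p: term_id, description, k, n, K, N,
#'   fold, p, fdr, significant.
#' @export
ora <- function(query, collection, alpha = 0.05, background = NULL) {
  stopifnot(is(collection, "TermCollection"))
  universe <- if (is.null(background)) setUniverse(collection)
              else unique(as.character(background))
  query <- unique(as.character(query))
  outside <- setdiff(query, universe)
  if (length(outside)) {
    warning(length(outside), " query gene(s) outside the universe dropped")
    query <- setdiff(query, outside)
  }
  if (!length(query)) stop("empty query after universe restriction")
  n <- length(query); N <- length(universe)
  sets <- geneSets(collection)
  res <- data.frame(
    term_id = names(sets),
    description = collection@descriptions,
    k = vapply(sets, function(s) length(intersect(s, query)), 0L),
    n = n,
    K = vapply(sets, function(s) length(intersect(s, universe)), 0L),
    N = N, row.names = NULL)
  res$fold <- ifelse(res$K == 0, NA_real_, (res$k / n) / (res$K / N))
  res$p <- mapply(function(k, K) if (K == 0) 1 else
                    hypergeomUpperTail(k, n, K, N), res$k, res$K)
  res$fdr <- stats::p.adjust(res$p, method = "BH")
  res$significant <- res$fdr < alpha
  res[order(res$p, res$term_id), ]
}

#' Overlap test between two term lists
#'
#' Upper-tail hypergeometric probability of observing at least `overlap`
#' shared terms between two term lists drawn from a common universe of
#' candidate terms; symmetric in the two lists. Used to ask whether the
#' enriched-term lists of two analyses (e.g. for a module and its parent
#' network) share more terms than chance.
#'
#' @param nTermsA,nTermsB sizes of the two term lists.
#' @param overlap number of shared terms.
#' @param universeSize number of candidate terms.
#' @return The tail probability.
#' @export
termOverlapTest <- function(nTermsA, nTermsB, overlap, universeSize) {
  if (overlap > min(nTermsA, nTermsB))
    stop("overlap cannot exceed the smaller list")
  if (max(nTermsA, nTermsB) > universeSize)
    stop("list sizes cannot exceed the universe")
  hypergeomUpperTail(k = overlap, n = nTermsB, K = nTermsA,
                     N = universeSize)
}

#' Read a per-gene disease-category table
#'
#' TSV with columns `gene` and `category`; the category vocabulary is
#' closed (`epilepsy`, `epilepsy_related`, `none`) and case-sensitive.
#' Duplicate genes are allowed only when their categories agree.
#'
#' @param path file path.
#' @return data.frame with columns `gene`, `category` (one row per gene).
#' @export
readCategoryTable <- function(path) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE)
  if (!all(c("gene", "category") %in% colnames(df)))
    stop("category TSV must have columns gene, category")
  if (!nrow(df))
    return(data.frame(gene = character(), category = character()))
  vocab <- c("epilepsy", "epilepsy_related", "none")
  bad <- setdiff(unique(df$category), vocab)
  if (length(bad))
    stop("unknown category label(s): ", paste(bad, collapse = ", "),
         "; allowed: ", paste(vocab, collapse = ", "))
  agg <- tapply(df$category, df$gene, unique)
  if (any(lengths(agg) > 1L))
    stop("conflicting categories for gene(s): ",
         paste(names(agg)[lengths(agg) > 1L], collapse = ", "))
  out <- unique(df[, c("gene", "category")])
  rownames(out) <- NULL
  out
}

#' Construct a TermCollection
#'
#' @param sets named list of character gene-id vectors.
#' @param universe background gene ids; defaults to the union of the sets.
#' @param descriptions optional per-term descriptions.
#' @return A \linkS4class{TermCollection}.
#' @export
TermCollection <- function(sets, universe = NULL, descriptions = NULL) {
  sets <- lapply(sets, function(s) unique(as.character(s)))
  if (is.null(universe)) universe <- unique(unlist(sets, use.names = FALSE))
  if (is.null(descriptions)) descriptions <- rep("", length(sets))
  new("TermCollection", sets = sets,
      descriptions = as.character(descriptions),
      universe = unique(as.character(universe)))
}

#' Read / write gene-set collections in GMT format
#'
#' GMT: one term per line — term id, description, then tab-separated gene
#' ids. Reading is delegated to [fgsea::gmtPathways()] (descriptions are
#' not retained by that parser and come back empty).
#'
#' @param path file path.
#' @param universe optional background universe; defaults to the union of
#'   the sets read.
#' @return [readGMT()] returns a \linkS4class{TermCollection};
#'   [writeGMT()] returns `path` invisibly.
#' @export
readGMT <- function(path, universe = NULL) {
  sets <- fgsea::gmtPathways(path)
  TermCollection(sets, universe = universe)
}

#' @rdname readGMT
#' @param collection a \linkS4class{TermCollection}.
#' @export
writeGMT <- function(collection, path) {
  stopifnot(is(collection, "TermCollection"))
  sets <- geneSets(collection)
  desc <- collection@descriptions
  desc[!nzchar(desc)] <- "na"
  lines <- vapply(seq_along(sets), function(i)
    paste(c(names(sets)[i], desc[i], sets[[i]]), collapse = "\t"), "")
  writeLines(lines, path)
  invisible(path)
}
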