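#' @import methods
#' @importClassesFrom SummarizedExperiment SummarizedExperiment
#' @importFrom SummarizedExperiment SummarizedExperiment assay assay<- assayNames colData
#' @importFrom S4Vectors DataFrame metadata metadata<-
NULL

#' Container for a genes x cells count matrix with per-cell type labels
#'
#' `ExpressionCounts` extends \linkS4class{SummarizedExperiment} with the
#' constraints the co-expression pipeline relies on: a single `"counts"`
#' assay, unique non-empty gene and cell identifiers, and a `cell_type`
#' column in `colData()`. Raw objects hold non-negative counts; transformed
#' objects (see [log2Transform()]) keep the same shape and identifiers and
#' record the transformation in `metadata()`.
#'
#' @slot .    inherits all slots from `SummarizedExperiment`.
#' @seealso [ExpressionCounts()], [readExpression()], [simulateExpression()]
#' @export
setClass("ExpressionCounts", contains = "SummarizedExperiment")

setValidity("ExpressionCounts", function(object) {
  msg <- character()
  if (!"counts" %in% assayNames(object))
    msg <- c(msg, "assay 'counts' is required")
  else {
    m <- assay(object, "counts")
    if (anyNA(m)) msg <- c(msg, "counts must not contain NA")
  }
  rn <- rownames(object); cn <- colnames(object)
  if (is.null(rn) || anyDuplicated(rn) || any(!nzchar(rn)))
    msg <- c(msg, "gene ids must be present, unique and non-empty")
  if (is.null(cn) || anyDuplicated(cn) || any(!nzchar(cn)))
    msg <- c(msg, "cell ids must be present, unique and non-empty")
  if (!"cell_type" %in% colnames(colData(object)))
    msg <- c(msg, "colData must contain a 'cell_type' column")
  if (length(msg)) msg else TRUE
})

#' Scored human-to-fly ortholog pairs
#'
#' A validated table of `(human_gene, fly_gene, score)` records, the input
#' to score filtering and catalog expansion. Scores are integer orthology
#' support scores (DIOPT-style vote counts); duplicated
#' `(human_gene, fly_gene)` pairs are rejected.
#'
#' @slot records data.frame with columns `human_gene`, `fly_gene`, `score`.
#' @seealso [OrthologTable()], [filterByScore()], [classifyAndExpand()]
#' @export
setClass("OrthologTable", representation(records = "data.frame"))

setValidity("OrthologTable", function(object) {
  df <- object@records
  need <- c("human_gene", "fly_gene", "score")
  if (!all(need %in% colnames(df)))
    return(paste("records must have columns:", paste(need, collapse = ", ")))
  msg <- character()
  if (nrow(df)) {
    if (any(!nzchar(df$human_gene)) || any(!nzchar(df$fly_gene)) ||
        anyNA(df$human_gene) || anyNA(df$fly_gene))
      msg <- c(msg, "gene ids must be non-empty")
    if (anyNA(df$score) || any(df$score < 0))
      msg <- c(msg, "scores must be non-negative")
    if (anyDuplicated(df[, c("human_gene", "fly_gene")]))
      msg <- c(msg, "duplicate (human_gene, fly_gene) pairs")
  }
  if (length(msg)) msg else TRUE
})

#' Expanded fly-gene catalog with mapping provenance
#'
#' The result of [classifyAndExpand()]: an ordered, deduplicated list of
#' fly genes, each annotated with its mapping category (`one_to_one`,
#' `many_to_one` or `one_to_many`) and the human genes it represents.
#'
#' @slot flyGenes character, unique, in first-appearance order.
#' @slot category character, parallel to `flyGenes`.
#' @slot sources named list of character vectors of human source genes.
#' @export
setClass("MappingCatalog", representation(
  flyGenes = "character", category = "character", sources = "list"))

setValidity("MappingCatalog", function(object) {
  msg <- character()
  if (anyDuplicated(object@flyGenes)) msg <- c(msg, "fly genes must be unique")
  if (length(object@category) != length(object@flyGenes) ||
      length(object@sources) != length(object@flyGenes))
    msg <- c(msg, "category and sources must parallel flyGenes")
  ok <- c("one_to_one", "many_to_one", "one_to_many")
  if (!all(object@category %in% ok))
    msg <- c(msg, paste("categories must be one of:", paste(ok, collapse = ", ")))
  if (any(lengths(object@sources) < 1) && length(object@flyGenes))
    msg <- c(msg, "every fly gene needs at least one source human gene")
  if (length(msg)) msg else TRUE
})

#' Pairwise Spearman correlation matrix over genes
#'
#' A symmetric genes x genes matrix of Spearman rank correlations with a
#' unit diagonal. Entries for genes whose expression was constant across
#' cells are `NA` and must be resolved upstream before clustering.
#'
#' @slot values symmetric numeric matrix with dimnames = gene ids.
#' @seealso [spearmanMatrix()], [hierarchicalCluster()]
#' @export
setClass("CorrelationMatrix", representation(values = "matrix"))

setValidity("CorrelationMatrix", function(object) {
  v <- object@values
  msg <- character()
  if (nrow(v) != ncol(v)) return("matrix must be square")
  ids <- rownames(v)
  if (is.null(ids) || anyDuplicated(ids) || !identical(ids, colnames(v)))
    msg <- c(msg, "dimnames must be unique gene ids, identical on both axes")
  fin <- !is.na(v)
  if (any(abs(v[fin]) > 1 + 1e-12)) msg <- c(msg, "|r| must be <= 1")
  if (any(abs(v - t(v))[fin & t(fin)] > 1e-12))
    msg <- c(msg, "matrix must be symmetric within 1e-12")
  d <- diag(v)
  if (any(!is.na(d) & abs(d - 1) > 1e-12)) msg <- c(msg, "diagonal must be 1")
  if (length(msg)) msg else TRUE
})

#' A set of extracted co-expression modules with internal r statistics
#'
#' Disjoint gene modules cut from a dendrogram, each annotated with the
#' minimum, mean and maximum off-diagonal intra-module Spearman r, sorted
#' by decreasing mean intra-module r. The extraction parameters are stored
#' so every statistic is recomputable from the correlation matrix.
#'
#' @slot modules named list of character vectors (gene ids per module).
#' @slot stats data.frame: module_id, size, min_intra_r, mean_intra_r,
#'   max_intra_r.
#' @slot parameters list of the extraction parameters used.
#' @seealso [extractModules()], [moduleStats()]
#' @export
setClass("ModuleSet", representation(
  modules = "list", stats = "data.frame", parameters = "list"))

setValidity("ModuleSet", function(object) {
  msg <- character()
  genes <- unlist(object@modules, use.names = FALSE)
  if (anyDuplicated(genes)) msg <- c(msg, "modules must be disjoint")
  if (nrow(object@stats) != length(object@modules))
    msg <- c(msg, "stats must have one row per module")
  if (length(msg)) msg else TRUE
})

#' A collection of named gene sets over a fixed universe
#'
#' Gene sets (e.g. pathway or ontology terms) with free-text descriptions
#' and an explicit background universe; the substrate of
#' over-representation analysis. Serializable to/from GMT.
#'
#' @slot sets named list of character vectors, each a subset of `universe`.
#' @slot descriptions character, parallel to `sets`.
#' @slot universe character vector of background gene ids.
#' @seealso [ora()], [readGMT()], [simulateGeneSets()]
#' @export
setClass("TermCollection", representation(
  sets = "list", descriptions = "character", universe = "character"))

setValidity("TermCollection", function(object) {
  msg <- character()
  ids <- names(object@sets)
  if (length(object@sets) && (is.null(ids) || anyDuplicated(ids)))
    msg <- c(msg, "term ids must be unique and named")
  if (length(object@descriptions) != length(object@sets))
    msg <- c(msg, "descriptions must parallel sets")
  if (anyDuplicated(object@universe)) msg <- c(msg, "universe ids must be unique")
  stray <- setdiff(unlist(object@sets, use.names = FALSE), object@universe)
  if (length(stray))
    msg <- c(msg, paste0("sets must be subsets of the universe (",
                         length(stray), " stray ids)"))
  if (length(msg)) msg else TRUE
})

#' Cumulative seizure time courses per vial
#'
#' Long-format records of a heat-induced seizure assay: for each vial of a
#' genotype, the cumulative number of animals showing seizure-like
#' behaviour at each observation time. Cumulative counts must be
#' non-decreasing and bounded by the vial size.
#'
#' @slot data data.frame with columns vial_id, genotype, time_min,
#'   n_total, n_seized_cum.
#' @seealso [readSeizureCSV()], [simulateSeizureAssay()], [fitSigmoid()]
#' @export
setClass("SeizureTimeCourse", representation(data = "data.frame"))

setValidity("SeizureTimeCourse", function(object) {
  df <- object@data
  need <- c("vial_id", "genotype", "time_min", "n_total", "n_seized_cum")
  if (!all(need %in% colnames(df)))
    return(paste("data must have columns:", paste(need, collapse = ", ")))
  msg <- character()
  if (nrow(df)) {
    if (any(df$n_seized_cum < 0) || any(df$n_seized_cum > df$n_total))
      msg <- c(msg, "0 <= n_seized_cum <= n_total violated")
    for (v in split(df, df$vial_id)) {
      v <- v[order(v$time_min), ]
      if (any(diff(v$time_min) <= 0)) {
        msg <- c(msg, "timepoints must be strictly increasing per vial"); break
      }
      if (any(diff(v$n_seized_cum) < 0)) {
        msg <- c(msg, "cumulative counts must be non-decreasing per vial"); break
      }
    }
  }
  if (length(msg)) msg else TRUE
})

#' Result of a variable-slope sigmoid fit to seizure time courses
#'
#' Parameters of the Hill-form logistic in log10 time fitted by
#' [fitSigmoid()]: the half-response time T50 (and its log10, the
#' logEC50), the Hill slope, the lower and upper asymptotes, the residual
#' sum of squares, and convergence/extrapolation flags.
#'
#' @slot genotype character(1) label of the fitted group.
#' @slot t50 numeric(1), minutes.
#' @slot logT50 numeric(1), log10 minutes.
#' @slot hillSlope numeric(1).
#' @slot bottom,top numeric(1) fractions, bottom <= top.
#' @slot rss numeric(1), squared-fraction units.
#' @slot converged,extrapolated logical(1).
#' @slot nObs integer(1) number of fitted points.
#' @export
setClass("SigmoidFit", representation(
  genotype = "character", t50 = "numeric", logT50 = "numeric",
  hillSlope = "numeric", bottom = "numeric", top = "numeric",
  rss = "numeric", converged = "logical", extrapolated = "logical",
  nObs = "integer"))

setValidity("SigmoidFit", function(object) {
  msg <- character()
  if (object@bottom > object@top) msg <- c(msg, "bottom must be <= top")
  if (!is.na(object@t50) && object@t50 <= 0) msg <- c(msg, "t50 must be > 0")
  if (length(msg)) msg else TRUE
})
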