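#' Construct an ExpressionCounts object
#'
#' @param counts numeric genes x cells matrix of non-negative counts.
#'   Row and column names are used as gene and cell ids when `geneIds` /
#'   `cellIds` are not given.
#' @param cellTypes character vector of per-cell type labels.
#' @param geneIds,cellIds optional explicit identifiers.
#' @return An \linkS4class{ExpressionCounts} object.
#' @examples
#' m <- matrix(rpois(50, 5), 5, 10,
#'             dimnames = list(paste0("g", 1:5), paste0("c", 1:10)))
#' ec <- ExpressionCounts(m, rep(c("KC", "PN"), each = 5))
#' cellTypes(ec)
#' @export
ExpressionCounts <- function(counts, cellTypes,
                             geneIds = rownames(counts),
                             cellIds = colnames(counts)) {
  counts <- as.matrix(counts)
  if (anyNA(counts) || any(counts < 0))
    stop("counts must be non-negative and free of NA")
  if (is.null(geneIds) || is.null(cellIds))
    stop("gene and cell ids are required (dimnames or explicit arguments)")
  if (length(cellTypes) != ncol(counts))
    stop("cellTypes must have one label per cell")
  dimnames(counts) <- list(as.character(geneIds), as.character(cellIds))
  se <- SummarizedExperiment(
    assays = list(counts = counts),
    colData = DataFrame(cell_type = as.character(cellTypes),
                        row.names = colnames(counts)))
  new("ExpressionCounts", se)
}

#' @rdname ExpressionCounts-class
#' @export
setMethod("cellTypes", "ExpressionCounts",
          function(x) colData(x)$cell_type)

#' @rdname ExpressionCounts-class
#' @export
setMethod("geneIds", "ExpressionCounts", function(x) rownames(x))

#' Construct an OrthologTable
#'
#' @param records data.frame with columns `human_gene`, `fly_gene`,
#'   `score`, or a character vector of human gene ids when `fly_gene` and
#'   `score` are supplied separately.
#' @param fly_gene,score optional parallel vectors (vector interface).
#' @return An \linkS4class{OrthologTable}.
#' @export
OrthologTable <- function(records, fly_gene = NULL, score = NULL) {
  if (!is.data.frame(records)) {
    records <- data.frame(human_gene = as.character(records),
                          fly_gene = as.character(fly_gene),
                          score = as.numeric(score))
  }
  records <- as.data.frame(records)[, c("human_gene", "fly_gene", "score")]
  records$human_gene <- as.character(records$human_gene)
  records$fly_gene <- as.character(records$fly_gene)
  records$score <- as.numeric(records$score)
  rownames(records) <- NULL
  new("OrthologTable", records = records)
}

#' @rdname OrthologTable-class
#' @export
setMethod("orthologRecords", "OrthologTable", function(x) x@records)

#' @describeIn OrthologTable-class number of ortholog records.
#' @export
setMethod("length", "OrthologTable", function(x) nrow(x@records))

setMethod("show", "OrthologTable", function(object) {
  df <- object@records
  cat("OrthologTable with", nrow(df), "records:",
      length(unique(df$human_gene)), "human genes,",
      length(unique(df$fly_gene)), "fly genes\n")
  if (nrow(df)) {
    cat("  score range:", min(df$score), "-", max(df$score), "\n")
    print(utils::head(df, 4L))
    if (nrow(df) > 4L) cat("  ...\n")
  }
})

#' @rdname MappingCatalog-class
#' @export
setMethod("flyGenes", "MappingCatalog", function(x) x@flyGenes)

#' @rdname MappingCatalog-class
#' @export
setMethod("catalogTable", "MappingCatalog", function(x) {
  data.frame(fly_gene = x@flyGenes, category = x@category,
             source_genes = vapply(x@sources, paste, "", collapse = ";"),
             row.names = NULL)
})

#' @describeIn MappingCatalog-class number of catalog fly genes.
#' @export
setMethod("length", "MappingCatalog", function(x) length(x@flyGenes))

setMethod("show", "MappingCatalog", function(object) {
  cat("MappingCatalog with", length(object@flyGenes), "unique fly genes\n")
  if (length(object@flyGenes))
    print(table(factor(object@category, levels = c(
      "one_to_one", "many_to_one", "one_to_many"))))
})

#' @rdname CorrelationMatrix-class
#' @export
setMethod("corValues", "CorrelationMatrix", function(x) x@values)

#' @rdname CorrelationMatrix-class
#' @export
setMethod("geneIds", "CorrelationMatrix", function(x) rownames(x@values))

#' @describeIn CorrelationMatrix-class number of genes.
#' @export
setMethod("dim", "CorrelationMatrix", function(x) dim(x@values))

setMethod("show", "CorrelationMatrix", function(object) {
  v <- object@values
  off <- v[upper.tri(v)]
  cat("CorrelationMatrix over", nrow(v), "genes\n")
  if (length(off))
    cat(sprintf("  off-diagonal r: min %.3f, median %.3f, max %.3f, %d NA\n",
                min(off, na.rm = TRUE), stats::median(off, na.rm = TRUE),
                max(off, na.rm = TRUE), sum(is.na(off))))
})

#' @rdname ModuleSet-class
#' @export
setMethod("modules", "ModuleSet", function(x) x@modules)

#' @rdname ModuleSet-class
#' @export
setMethod("moduleTable", "ModuleSet", function(x) x@stats)

#' @describeIn ModuleSet-class number of modules.
#' @export
setMethod("length", "ModuleSet", function(x) length(x@modules))

setMethod("show", "ModuleSet", function(object) {
  cat("ModuleSet with", length(object@modules), "module(s)\n")
  if (nrow(object@stats)) print(object@stats)
})

#' @rdname TermCollection-class
#' @export
setMethod("geneSets", "TermCollection", function(x) x@sets)

#' @rdname TermCollection-class
#' @export
setMethod("setUniverse", "TermCollection", function(x) x@universe)

#' @describeIn TermCollection-class number of terms.
#' @export
setMethod("length", "TermCollection", function(x) length(x@sets))

setMethod("show", "TermCollection", function(object) {
  cat("TermCollection:", length(object@sets), "terms over a universe of",
      length(object@universe), "genes\n")
  if (length(object@sets)) {
    sz <- lengths(object@sets)
    cat("  set sizes:", min(sz), "-", max(sz), "\n")
  }
})

#' @rdname SeizureTimeCourse-class
#' @export
setMethod("timeCourseData", "SeizureTimeCourse", function(x) x@data)

setMethod("show", "SeizureTimeCourse", function(object) {
  df <- object@data
  cat("SeizureTimeCourse:", length(unique(df$vial_id)), "vials,",
      length(unique(df$genotype)), "genotype(s),",
      length(unique(df$time_min)), "timepoints\n")
})

#' @rdname SigmoidFit-class
#' @export
setMethod("t50", "SigmoidFit", function(x) x@t50)

setMethod("show", "SigmoidFit", function(object) {
  cat(sprintf(
    "SigmoidFit [%s]: T50 = %.3f min (logEC50 = %.4f), slope = %.3f\n",
    object@genotype, object@t50, object@logT50, object@hillSlope))
  cat(sprintf("  bottom = %.3f, top = %.3f, rss = %.4g, n = %d%s%s\n",
    object@bottom, object@top, object@rss, object@nObs,
    if (object@converged) ", converged" else ", NOT converged",
    if (object@extrapolated) ", extrapolated" else ""))
})
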