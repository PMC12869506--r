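#' Read a genes x cells count matrix with cell-type labels
#'
#' Two plain-text layouts are supported, both directory-based:
#' \describe{
#'   \item{mtx}{`matrix.mtx` (MatrixMarket, genes as rows) plus sidecars
#'     `genes.tsv` (one gene id per line, no header) and `cells.tsv`
#'     (header `cell_id`, `cell_type`).}
#'   \item{tsv}{`counts.tsv` (dense, genes as rows, first column
#'     `gene_id`, remaining columns named by cell id) plus the same
#'     `cells.tsv` sidecar.}
#' }
#' Dimension mismatches between the matrix and its sidecars, and
#' duplicated gene or cell ids, are format errors. A write/read round
#' trip preserves counts, ids and labels exactly.
#'
#' @param dir directory containing the files above.
#' @param format `"mtx"` or `"tsv"`.
#' @return An \linkS4class{ExpressionCounts}.
#' @seealso [writeExpression()]
#' @export
readExpression <- function(dir, format = c("mtx", "tsv")) {
  format <- match.arg(format)
  cells_path <- file.path(dir, "cells.tsv")
  if (!file.exists(cells_path)) stop("missing sidecar: ", cells_path)
  cells <- utils::read.delim(cells_path, stringsAsFactors = FALSE)
  if (!all(c("cell_id", "cell_type") %in% colnames(cells)))
    stop("cells.tsv must have columns cell_id, cell_type")
  if (anyDuplicated(cells$cell_id)) stop("duplicate cell ids in cells.tsv")

  if (format == "mtx") {
    genes_path <- file.path(dir, "genes.tsv")
    mtx_path <- file.path(dir, "matrix.mtx")
    if (!file.exists(genes_path)) stop("missing sidecar: ", genes_path)
    if (!file.exists(mtx_path)) stop("missing matrix: ", mtx_path)
    genes <- readLines(genes_path)
    genes <- genes[nzchar(genes)]
    if (anyDuplicated(genes)) stop("duplicate gene ids in genes.tsv")
    m <- as.matrix(Matrix::readMM(mtx_path))
    if (nrow(m) != length(genes))
      stop("matrix has ", nrow(m), " rows but genes.tsv lists ",
           length(genes), " genes")
    if (ncol(m) != nrow(cells))
      stop("matrix has ", ncol(m), " columns but cells.tsv lists ",
           nrow(cells), " cells")
    dimnames(m) <- list(genes, cells$cell_id)
  } else {
    tsv_path <- file.path(dir, "counts.tsv")
    if (!file.exists(tsv_path)) stop("missing matrix: ", tsv_path)
    df <- utils::read.delim(tsv_path, check.names = FALSE,
                            stringsAsFactors = FALSE)
    if (colnames(df)[1L] != "gene_id")
      stop("counts.tsv first column must be gene_id")
    if (anyDuplicated(df$gene_id)) stop("duplicate gene ids in counts.tsv")
    m <- as.matrix(df[, -1L, drop = FALSE])
    rownames(m) <- df$gene_id
    if (ncol(m) != nrow(cells))
      stop("counts.tsv has ", ncol(m), " cells but cells.tsv lists ",
           nrow(cells), " cells")
    if (!identical(colnames(m), cells$cell_id))
      stop("cell ids in counts.tsv and cells.tsv disagree")
  }
  ExpressionCounts(m, cells$cell_type)
}

#' Write an ExpressionCounts object to disk
#'
#' Inverse of [readExpression()]; emits the same directory layout.
#'
#' @param expr an \linkS4class{ExpressionCounts}.
#' @param dir output directory (created if needed).
#' @param format `"mtx"` or `"tsv"`.
#' @return `dir`, invisibly.
#' @export
writeExpression <- function(expr, dir, format = c("mtx", "tsv")) {
  format <- match.arg(format)
  stopifnot(is(expr, "ExpressionCounts"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  m <- assay(expr, "counts")
  utils::write.table(
    data.frame(cell_id = colnames(m), cell_type = cellTypes(expr)),
    file.path(dir, "cells.tsv"), sep = "\t", quote = FALSE,
    row.names = FALSE)
  if (format == "mtx") {
    writeLines(rownames(m), file.path(dir, "genes.tsv"))
    Matrix::writeMM(Matrix::Matrix(m, sparse = TRUE),
                    file.path(dir, "matrix.mtx"))
  } else {
    df <- data.frame(gene_id = rownames(m), m, check.names = FALSE)
    utils::write.table(df, file.path(dir, "counts.tsv"), sep = "\t",
                       quote = FALSE, row.names = FALSE)
  }
  invisible(dir)
}

#' Filter candidate genes by total count across cells
#'
#' Retains the candidates whose summed expression over all cells of the
#' matrix meets the threshold: `>= minTotalCounts` when `inclusive` (the
#' default), strictly `>` otherwise. Candidate order is preserved;
#' candidates absent from the matrix are dropped with a warning. Whether
#' the filter sees the full dataset or only pre-selected cells is decided
#' by what you pass as `expr` (the pipeline applies it before cell-type
#' selection by default).
#'
#' @param expr an \linkS4class{ExpressionCounts}.
#' @param candidates character vector of gene ids to consider.
#' @param minTotalCounts numeric(1) >= 0, default 5000.
#' @param inclusive logical(1); boundary handling as above.
#' @return Character vector of retained gene ids.
#' @export
filterGenesByTotalCounts <- function(expr, candidates,
                                     minTotalCounts = 5000,
                                     inclusive = TRUE) {
  stopifnot(is(expr, "ExpressionCounts"))
  if (!is.numeric(minTotalCounts) || length(minTotalCounts) != 1L ||
      minTotalCounts < 0)
    stop("minTotalCounts must be a single non-negative number")
  candidates <- as.character(candidates)
  missing <- setdiff(candidates, rownames(expr))
  if (length(missing))
    warning(length(missing), " candidate gene(s) absent from the matrix ",
            "and dropped: ", paste(utils::head(missing, 5L), collapse = ", "),
            if (length(missing) > 5L) ", ..." else "")
  candidates <- candidates[candidates %in% rownames(expr)]
  if (!length(candidates)) return(character())
  totals <- rowSums(assay(expr, "counts")[candidates, , drop = FALSE])
  pass <- if (inclusive) totals >= minTotalCounts else totals > minTotalCounts
  candidates[pass]
}

#' Subset cells by annotated type
#'
#' Exactly one of `include` / `exclude` must be given; labels are matched
#' case-sensitively. Listed labels absent from the data produce a warning,
#' not an error; a selection that leaves no cells is an error. The gene
#' axis is untouched.
#'
#' @param expr an \linkS4class{ExpressionCounts}.
#' @param include,exclude character vectors of cell-type labels.
#' @return An \linkS4class{ExpressionCounts} restricted to the selected
#'   cells.
#' @export
selectCellsByType <- function(expr, include = NULL, exclude = NULL) {
  stopifnot(is(expr, "ExpressionCounts"))
  if (is.null(include) == is.null(exclude))
    stop("give exactly one of 'include' or 'exclude'")
  types <- cellTypes(expr)
  wanted <- if (!is.null(include)) include else exclude
  absent <- setdiff(wanted, unique(types))
  if (length(absent))
    warning("cell type label(s) not present in the data: ",
            paste(absent, collapse = ", "))
  keep <- if (!is.null(include)) types %in% include else !(types %in% exclude)
  if (!any(keep)) stop("cell-type selection leaves no cells")
  expr[, keep]
}

#' Default neuronal cell-type include list
#'
#' Returns the 45 neuronal cell-type labels of the adult fly whole-brain
#' atlas used for co-expression analysis (projection-neuron, monoamine,
#' peptidergic, clock and lamina populations), shipped with the package as
#' a plain-text config asset. Cell types with strongly distinct
#' transcriptomic profiles (glia, optic lobe neurons, photoreceptors,
#' Kenyon cells) are deliberately not on the list.
#'
#' @return Character vector of labels.
#' @export
defaultNeuronalTypes <- function() {
  path <- system.file("extdata", "neuronal_celltypes.txt",
                      package = "CoModMap", mustWork = TRUE)
  x <- readLines(path)
  x[nzchar(x) & !startsWith(x, "#")]
}
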