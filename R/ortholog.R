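#' Read / write scored ortholog tables
#'
#' TSV with header `human_gene`, `fly_gene`, `score`.
#'
#' @param path file path.
#' @return [readOrthologTable()] returns an \linkS4class{OrthologTable};
#'   [writeOrthologTable()] returns `path` invisibly.
#' @export
readOrthologTable <- function(path) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE)
  need <- c("human_gene", "fly_gene", "score")
  if (!all(need %in% colnames(df)))
    stop("ortholog TSV must have columns: ", paste(need, collapse = ", "))
  OrthologTable(df)
}

#' @rdname readOrthologTable
#' @param table an \linkS4class{OrthologTable}.
#' @export
writeOrthologTable <- function(table, path) {
  stopifnot(is(table, "OrthologTable"))
  utils::write.table(orthologRecords(table), path, sep = "\t",
                     quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Filter ortholog records by minimum support score
#'
#' Retains exactly the records whose score is greater than or equal to
#' `minScore` (the boundary is inclusive), preserving input order. The
#' default of 3 is the conventional support threshold for DIOPT-style
#' integer scores.
#'
#' @param table an \linkS4class{OrthologTable}.
#' @param minScore numeric(1) >= 0.
#' @return A filtered \linkS4class{OrthologTable} (possibly empty).
#' @examples
#' ot <- OrthologTable(c("A", "B", "C"), c("a", "b", "c"), c(2, 3, 4))
#' length(filterByScore(ot, 3))  # 2
#' @export
filterByScore <- function(table, minScore = 3) {
  stopifnot(is(table, "OrthologTable"))
  if (!is.numeric(minScore) || length(minScore) != 1L || minScore < 0)
    stop("minScore must be a single non-negative number")
  df <- orthologRecords(table)
  OrthologTable(df[df$score >= minScore, , drop = FALSE])
}

#' Expand a score-filtered ortholog table into a fly-gene catalog
#'
#' Applies, per human gene, the three mapping categories used when
#' projecting a human gene network onto the fly genome:
#' \describe{
#'   \item{one_to_one}{the human gene has exactly one fly partner, and
#'     that fly gene serves no other human gene.}
#'   \item{many_to_one}{a single fly gene is the sole partner of two or
#'     more human genes (a conserved family collapsed in the fly).}
#'   \item{one_to_many}{a human gene has several fly partners with high
#'     and similar scores; all partners scoring within `tieWindow` of the
#'     best partner are kept.}
#' }
#' Fly genes are deduplicated across human genes; catalog order is the
#' first-appearance order of fly genes among the retained records. When a
#' fly gene is reachable through conflicting category paths (e.g. the sole
#' partner of one human gene and a tied partner of another), the category
#' of its first assignment in input order is kept and the conflict is
#' reported via `message()`.
#'
#' @param table a score-filtered \linkS4class{OrthologTable}.
#' @param tieWindow numeric(1) >= 0; partners with score >= max - tieWindow
#'   are considered "similar" and retained for one_to_many genes.
#' @return A \linkS4class{MappingCatalog}.
#' @examples
#' ot <- OrthologTable(c("H1", "H1", "H1"), c("f1", "f2", "f3"),
#'                     c(15, 14, 10))
#' flyGenes(classifyAndExpand(ot))  # f1 and f2 (within the tie window)
#' @export
classifyAndExpand <- function(table, tieWindow = 1) {
  stopifnot(is(table, "OrthologTable"))
  if (!is.numeric(tieWindow) || length(tieWindow) != 1L || tieWindow < 0)
    stop("tieWindow must be a single non-negative number")
  df <- orthologRecords(table)
  if (!nrow(df))
    return(new("MappingCatalog", flyGenes = character(),
               category = character(), sources = list()))

  # Per human gene decide which fly partners are kept and through which rule.
  n_partners <- table(df$human_gene)
  keep <- logical(nrow(df))
  via_multi <- logical(nrow(df))  # kept via the one_to_many tie rule
  for (h in unique(df$human_gene)) {
    idx <- which(df$human_gene == h)
    if (length(idx) == 1L) {
      keep[idx] <- TRUE
    } else {
      best <- max(df$score[idx])
      sel <- idx[df$score[idx] >= best - tieWindow]
      keep[sel] <- TRUE
      via_multi[sel] <- TRUE
    }
  }

  kept <- df[keep, , drop = FALSE]
  kept$via_multi <- via_multi[keep]

  # A fly gene is many_to_one when it is the sole kept partner of >1 human.
  sole <- kept[!kept$via_multi, , drop = FALSE]
  n_sole_sources <- table(sole$fly_gene)

  fly <- unique(kept$fly_gene)
  category <- character(length(fly))
  sources <- vector("list", length(fly))
  names(sources) <- fly
  for (i in seq_along(fly)) {
    f <- fly[i]
    rows <- kept[kept$fly_gene == f, , drop = FALSE]
    sources[[i]] <- unique(rows$human_gene)
    first_multi <- rows$via_multi[1L]
    n_sole <- if (f %in% names(n_sole_sources)) n_sole_sources[[f]] else 0L
    cat_first <- if (first_multi) "one_to_many"
                 else if (n_sole >= 2L) "many_to_one" else "one_to_one"
    # conflict: reachable both as a sole partner and through a tie set
    if (length(unique(rows$via_multi)) > 1L)
      message("fly gene '", f, "' reachable through conflicting mapping ",
              "paths; keeping category of first assignment (", cat_first, ")")
    category[i] <- cat_first
  }

  new("MappingCatalog", flyGenes = fly, category = category,
      sources = sources)
}

#' Write a mapping catalog as TSV
#'
#' Columns: `fly_gene`, `category`, `source_genes` (semicolon-joined).
#'
#' @param catalog a \linkS4class{MappingCatalog}.
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
writeCatalog <- function(catalog, path) {
  stopifnot(is(catalog, "MappingCatalog"))
  utils::write.table(catalogTable(catalog), path, sep = "\t",
                     quote = FALSE, row.names = FALSE)
  invisible(path)
}
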