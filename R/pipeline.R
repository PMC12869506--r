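.config_defaults <- list(
  min_score = 3, tie_window = 1,
  min_total_counts = 5000, inclusive = TRUE,
  filter_scope = "full_dataset",
  expression_format = "mtx",
  linkage = "complete",
  cut_height = 0.7, min_size = 10, min_mean_intra_r = 0.3,
  alpha = 0.05, enrichment_background = "retained",
  pseudocount = 1, seed = 1)

.config_required <- c("ortholog_table", "expression_dir", "out_dir")

.config_optional_paths <- c("ortholog_table", "expression_dir",
                            "category_table", "gmt", "cell_types_file")

.config_known <- unique(c(names(.config_defaults), .config_required,
                          "category_table", "gmt", "cell_types_file",
                          "cell_types_include", "cell_types_exclude"))

#' Validate and default-fill a pipeline configuration
#'
#' Reads a YAML (or JSON) configuration, rejects unknown keys by name,
#' checks that referenced files exist, validates parameter ranges, and
#' fills documented defaults: `min_score = 3`, `tie_window = 1`,
#' `min_total_counts = 5000` (inclusive), `filter_scope = "full_dataset"`,
#' `linkage = "complete"`, `cut_height = 0.7`, `min_size = 10`,
#' `min_mean_intra_r = 0.3`, `alpha = 0.05`, `pseudocount = 1`,
#' `seed = 1`.
#'
#' Required keys: `ortholog_table` (TSV), `expression_dir` (directory for
#' [readExpression()]), `out_dir`. Optional: `category_table`, `gmt`,
#' `cell_types_include` / `cell_types_exclude` (vectors) or
#' `cell_types_file` (newline-delimited include list),
#' `expression_format`, `enrichment_background` (`"retained"` or
#' `"catalog"`).
#'
#' @param path config file path (`.yaml`/`.yml` or `.json`).
#' @return A validated config list of class `"CoModMapConfig"`.
#' @export
validateConfig <- function(path) {
  if (!file.exists(path)) stop("config file does not exist: ", path)
  cfg <- if (grepl("\\.json$", path, ignore.case = TRUE))
    jsonlite::read_json(path, simplifyVector = TRUE)
  else yaml::read_yaml(path)
  if (!is.list(cfg)) stop("config must be a mapping of keys to values")

  unknown <- setdiff(names(cfg), .config_known)
  if (length(unknown))
    stop("unknown config key(s): ", paste(unknown, collapse = ", "))
  miss <- setdiff(.config_required, names(cfg))
  if (length(miss))
    stop("missing required config key(s): ", paste(miss, collapse = ", "))
  for (key in setdiff(names(.config_defaults), names(cfg)))
    cfg[[key]] <- .config_defaults[[key]]

  for (key in intersect(.config_optional_paths, names(cfg)))
    if (!file.exists(cfg[[key]]))
      stop("config key '", key, "' points to a missing path: ", cfg[[key]])

  if (!cfg$linkage %in% c("complete", "average", "single"))
    stop("config key 'linkage' must be one of: complete, average, single")
  if (!cfg$filter_scope %in% c("full_dataset", "selected_cells"))
    stop("config key 'filter_scope' must be one of: full_dataset, ",
         "selected_cells")
  if (!cfg$enrichment_background %in% c("retained", "catalog"))
    stop("config key 'enrichment_background' must be one of: retained, ",
         "catalog")
  if (!cfg$expression_format %in% c("mtx", "tsv"))
    stop("config key 'expression_format' must be one of: mtx, tsv")
  for (key in c("min_score", "tie_window", "min_total_counts",
                "cut_height", "min_size", "alpha", "pseudocount"))
    if (!is.numeric(cfg[[key]]) || cfg[[key]] < 0)
      stop("config key '", key, "' must be a non-negative number")
  if (cfg$alpha > 1) stop("config key 'alpha' must be in [0, 1]")
  if (!is.null(cfg$cell_types_include) && !is.null(cfg$cell_types_exclude))
    stop("give at most one of 'cell_types_include' / 'cell_types_exclude'")
  structure(cfg, class = "CoModMapConfig", path = normalizePath(path))
}

#' Run the full cross-species module-refinement pipeline
#'
#' Executes the stages in order — ortholog score filter and catalog
#' expansion, expression load, total-count gene filter, cell-type
#' selection, log2 transform, Spearman correlation, hierarchical
#' clustering, module extraction, and (when category tables / gene-set
#' collections are configured) enrichment — persisting every intermediate
#' under `out_dir`:
#' `catalog.tsv`, `retained_genes.txt`, `correlation.tsv`,
#' `dendrogram.nwk`, `modules.tsv`, `enrichment_category.tsv`,
#' `ora.tsv`, `report.json` and `run.log`. With `filter_scope =
#' "full_dataset"` (the default) the total-count filter sees all cells of
#' the dataset and is therefore invariant to the subsequent cell-type
#' selection.
#'
#' The run is a pure function of config plus inputs: rerunning with the
#' same config reproduces every output except the timestamps in the log
#' and the provenance block.
#'
#' @param config a `"CoModMapConfig"` from [validateConfig()].
#' @param verbose log stage progress to stderr, default `TRUE`.
#' @return The report, invisibly: a list with `catalog_size`,
#'   `category_counts`, `n_retained`, `n_cells_selected`, `modules`
#'   (module table plus memberships), `enrichment` (category test and/or
#'   ORA table) and a `provenance` block (config hash, package version,
#'   timestamp).
#' @export
runPipeline <- function(config, verbose = TRUE) {
  stopifnot(inherits(config, "CoModMapConfig"))
  out_dir <- config$out_dir
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  log_path <- file.path(out_dir, "run.log")
  log_con <- file(log_path, open = "wt")
  on.exit(close(log_con), add = TRUE)
  say <- function(...) {
    line <- paste0(format(Sys.time(), "%H:%M:%S"), " ", ...)
    writeLines(line, log_con)
    if (verbose) message(line)
  }
  stage <- function(name, expr) {
    t0 <- Sys.time()
    res <- tryCatch(expr, error = function(e)
      stop("pipeline stage '", name, "' failed: ", conditionMessage(e),
           call. = FALSE))
    say(sprintf("stage %-16s done in %.2fs", name,
                as.numeric(Sys.time() - t0, units = "secs")))
    res
  }

  catalog <- stage("orthologs", {
    tab <- readOrthologTable(config$ortholog_table)
    tab <- filterByScore(tab, minScore = config$min_score)
    cat_ <- classifyAndExpand(tab, tieWindow = config$tie_window)
    writeCatalog(cat_, file.path(out_dir, "catalog.tsv"))
    cat_
  })
  say("catalog: ", length(catalog), " unique fly genes")

  expr <- stage("read_expression", readExpression(
    config$expression_dir, format = config$expression_format))
  say("expression: ", nrow(expr), " genes x ", ncol(expr), " cells")

  include <- config$cell_types_include
  if (!is.null(config$cell_types_file))
    include <- {
      x <- readLines(config$cell_types_file)
      x[nzchar(x) & !startsWith(x, "#")]
    }
  select <- function(e) {
    if (!is.null(include)) selectCellsByType(e, include = include)
    else if (!is.null(config$cell_types_exclude))
      selectCellsByType(e, exclude = config$cell_types_exclude)
    else e
  }

  if (config$filter_scope == "full_dataset") {
    retained <- stage("filter_genes", filterGenesByTotalCounts(
      expr, flyGenes(catalog), minTotalCounts = config$min_total_counts,
      inclusive = config$inclusive))
    expr_sel <- stage("select_cells", select(expr))
  } else {
    expr_sel <- stage("select_cells", select(expr))
    retained <- stage("filter_genes", filterGenesByTotalCounts(
      expr_sel, flyGenes(catalog), minTotalCounts = config$min_total_counts,
      inclusive = config$inclusive))
  }
  writeLines(retained, file.path(out_dir, "retained_genes.txt"))
  say("retained ", length(retained), " of ", length(catalog),
      " catalog genes; ", ncol(expr_sel), " cells selected")
  if (length(retained) < 2L)
    stop("pipeline stage 'filter_genes' failed: fewer than 2 genes retained")

  cormat <- stage("correlate", {
    sub <- expr_sel[retained, ]
    cm <- spearmanMatrix(log2Transform(sub, pseudocount = config$pseudocount))
    writeCorrelation(cm, file.path(out_dir, "correlation.tsv"))
    cm
  })

  hc <- stage("cluster", {
    h <- hierarchicalCluster(cormat, linkage = config$linkage)
    dendroToNewick(h, file.path(out_dir, "dendrogram.nwk"))
    h
  })

  mods <- stage("extract_modules", {
    ms <- extractModules(hc, cormat, cutHeight = config$cut_height,
                         minSize = config$min_size,
                         minMeanIntraR = config$min_mean_intra_r)
    tab <- moduleTable(ms)
    long <- if (length(ms)) do.call(rbind, lapply(names(modules(ms)),
      function(id) data.frame(module_id = id, gene = modules(ms)[[id]],
                              mean_intra_r =
                                tab$mean_intra_r[tab$module_id == id])))
      else data.frame(module_id = character(), gene = character(),
                      mean_intra_r = numeric())
    utils::write.table(long, file.path(out_dir, "modules.tsv"), sep = "\t",
                       quote = FALSE, row.names = FALSE)
    ms
  })
  say(length(mods), " module(s) extracted")

  enrichment <- list()
  if (length(mods)) {
    top <- modules(mods)[[1L]]
    bg <- if (config$enrichment_background == "retained") retained
          else flyGenes(catalog)
    bg <- union(bg, top)
    if (!is.null(config$category_table)) {
      enrichment$category <- stage("enrich_category", {
        cats <- readCategoryTable(config$category_table)
        res <- categoryEnrichment(top, bg, cats)
        utils::write.table(as.data.frame(res),
                           file.path(out_dir, "enrichment_category.tsv"),
                           sep = "\t", quote = FALSE, row.names = FALSE)
        res
      })
    }
    if (!is.null(config$gmt)) {
      enrichment$ora <- stage("ora", {
        coll <- readGMT(config$gmt)
        res <- ora(top, coll, alpha = config$alpha)
        utils::write.table(res, file.path(out_dir, "ora.tsv"), sep = "\t",
                           quote = FALSE, row.names = FALSE)
        res
      })
    }
  }

  report <- list(
    catalog_size = length(catalog),
    category_counts = as.list(table(catalog@category)),
    n_retained = length(retained),
    n_cells_selected = ncol(expr_sel),
    modules = list(stats = moduleTable(mods), members = modules(mods)),
    enrichment = enrichment,
    provenance = list(
      config_md5 = unname(tools::md5sum(attr(config, "path") %||%
                                          config$ortholog_table)),
      package_version = as.character(utils::packageVersion("CoModMap")),
      timestamp = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z")))
  jsonlite::write_json(report, file.path(out_dir, "report.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE,
                       force = TRUE)
  say("report written to ", file.path(out_dir, "report.json"))
  invisible(report)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
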