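#' Read cumulative seizure time courses from CSV
#'
#' Expected columns: `vial_id`, `genotype`, `time_min`, `n_total`,
#' `n_seized_cum`. Validation (monotone cumulative counts, counts bounded
#' by vial size, strictly increasing timepoints per vial) happens at
#' construction.
#'
#' @param path CSV file path.
#' @return A \linkS4class{SeizureTimeCourse}.
#' @export
readSeizureCSV <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  new("SeizureTimeCourse", data = df)
}

#' Write a seizure time course as CSV
#'
#' @param tc a \linkS4class{SeizureTimeCourse}.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
writeSeizureCSV <- function(tc, path) {
  stopifnot(is(tc, "SeizureTimeCourse"))
  utils::write.csv(timeCourseData(tc), path, row.names = FALSE)
  invisible(path)
}

#' Fit a variable-slope sigmoid to cumulative seizure fractions
#'
#' Least-squares fit of the Hill-form logistic in log10 time,
#' `f(t) = bottom + (top - bottom) / (1 + 10^((logT50 - log10 t) * slope))`,
#' to the per-vial seized fractions of one genotype, all vials' points
#' jointly. The bottom asymptote is fixed at 0 (no animal seizes at
#' t = 0); the top is free in (0, 1] by default — not every animal seizes
#' within the observation window — or can be fixed at 1. `T50 = 10^logT50`
#' is the time at which the curve reaches half of `bottom + top`, the
#' quantity conventionally reported as logEC50.
#'
#' Initialization is deterministic: logT50 starts at the first crossing of
#' half the maximum pooled fraction (linear interpolation in time; the
#' last timepoint if never crossed), the slope at 1 and the top at the
#' maximum pooled fraction. Optimization uses Levenberg-Marquardt
#' bounded least squares ([minpack.lm::nlsLM()]); no randomness is
#' involved. A fit whose pooled response never reaches 0.5 is flagged
#' `extrapolated`.
#'
#' @param tc a \linkS4class{SeizureTimeCourse}.
#' @param genotype genotype to fit; may be omitted when the object holds
#'   a single genotype.
#' @param topFixed logical(1); fix the top asymptote at 1 instead of
#'   estimating it. Default `FALSE`.
#' @return A \linkS4class{SigmoidFit}.
#' @examples
#' tc <- simulateSeizureAssay(trueT50 = 40, hillSlope = 3, seed = 7)
#' fitSigmoid(tc)
#' @export
fitSigmoid <- function(tc, genotype = NULL, topFixed = FALSE) {
  stopifnot(is(tc, "SeizureTimeCourse"))
  df <- timeCourseData(tc)
  if (is.null(genotype)) {
    gts <- unique(df$genotype)
    if (length(gts) != 1L)
      stop("several genotypes present; name one via 'genotype'")
    genotype <- gts
  }
  df <- df[df$genotype == genotype, , drop = FALSE]
  if (!nrow(df)) stop("no records for genotype '", genotype, "'")
  df <- df[df$time_min > 0, , drop = FALSE]
  if (length(unique(df$time_min)) < 4L)
    stop("need at least 4 distinct positive timepoints")
  df$frac <- df$n_seized_cum / df$n_total

  pooled <- tapply(df$frac, df$time_min, mean)
  tp <- as.numeric(names(pooled))
  ord <- order(tp); tp <- tp[ord]; pooled <- as.numeric(pooled)[ord]
  maxF <- max(pooled)
  if (maxF == 0)
    stop("degenerate fit: no animal ever seizes; nothing to estimate")
  if (min(pooled) == maxF)
    stop("degenerate fit: response is flat at ", maxF,
         "; a sigmoid is not identifiable")
  extrapolated <- maxF < 0.5

  # deterministic init: first crossing of half-maximum, linearly interpolated
  half <- maxF / 2
  above <- which(pooled >= half)
  if (length(above)) {
    i <- above[1L]
    t_half <- if (i == 1L) tp[1L] else {
      tp[i - 1L] + (half - pooled[i - 1L]) /
        (pooled[i] - pooled[i - 1L]) * (tp[i] - tp[i - 1L])
    }
  } else t_half <- tp[length(tp)]
  start <- list(logT50 = log10(max(t_half, .Machine$double.eps)), slope = 1)

  fit <- if (topFixed) {
    minpack.lm::nlsLM(
      frac ~ 1 / (1 + 10^((logT50 - log10(time_min)) * slope)),
      data = df, start = start,
      lower = c(logT50 = -6, slope = 1e-3),
      upper = c(logT50 = 6, slope = 100),
      control = minpack.lm::nls.lm.control(maxiter = 200))
  } else {
    start$top <- min(max(maxF, 0.05), 1)
    minpack.lm::nlsLM(
      frac ~ top / (1 + 10^((logT50 - log10(time_min)) * slope)),
      data = df, start = start,
      lower = c(logT50 = -6, slope = 1e-3, top = 1e-6),
      upper = c(logT50 = 6, slope = 100, top = 1),
      control = minpack.lm::nls.lm.control(maxiter = 200))
  }
  est <- stats::coef(fit)
  top <- if (topFixed) 1 else unname(est["top"])
  rss <- sum(stats::resid(fit)^2)
  rss_flat <- sum((df$frac - mean(df$frac))^2)
  converged <- isTRUE(fit$convInfo$isConv) && rss <= rss_flat + 1e-12
  new("SigmoidFit", genotype = genotype,
      t50 = 10^unname(est["logT50"]), logT50 = unname(est["logT50"]),
      hillSlope = unname(est["slope"]), bottom = 0, top = top,
      rss = rss, converged = converged, extrapolated = extrapolated,
      nObs = nrow(df))
}

#' Normalize a fitted T50 against a same-day background control
#'
#' Returns `t50 / control_t50`. Ratios above 1 mean the genotype seizes
#' later than its control (protection); below 1, earlier (susceptibility).
#' Normalization against same-day controls absorbs day-to-day variation
#' in the assay.
#'
#' @param fit,controlFit converged \linkS4class{SigmoidFit} objects.
#' @return numeric(1) unitless ratio.
#' @export
normalizeT50 <- function(fit, controlFit) {
  stopifnot(is(fit, "SigmoidFit"), is(controlFit, "SigmoidFit"))
  if (!fit@converged || !controlFit@converged)
    stop("both fits must have converged before normalization")
  t50(fit) / t50(controlFit)
}

#' Summarize a mechanically induced seizure assay
#'
#' Converts per-vial seized/total counts into per-vial fractions, the
#' input of downstream rank-based group comparisons (which are left to
#' standard routines).
#'
#' @param table data.frame with columns `vial_id`, `genotype`, `n_total`,
#'   `n_seized`.
#' @return The table with an added `fraction` column, plus a
#'   `"by_genotype"` attribute holding the per-genotype fraction vectors.
#' @examples
#' summarizeBangAssay(data.frame(vial_id = "v1", genotype = "ctrl",
#'                               n_total = 5, n_seized = 3))$fraction  # 0.6
#' @export
summarizeBangAssay <- function(table) {
  need <- c("vial_id", "genotype", "n_total", "n_seized")
  if (!all(need %in% colnames(table)))
    stop("table must have columns: ", paste(need, collapse = ", "))
  if (any(table$n_seized < 0) || any(table$n_total < 0))
    stop("counts must be non-negative")
  if (any(table$n_seized > table$n_total))
    stop("n_seized cannot exceed n_total")
  out <- as.data.frame(table)
  out$fraction <- out$n_seized / out$n_total
  attr(out, "by_genotype") <- split(out$fraction, out$genotype)
  out
}
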