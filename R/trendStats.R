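## Sampling-bias diagnostics: data distribution per stage, Spearman rank
## correlations between per-stage series, and mean-centre / sigma-scaling
## for overlaying trends measured on different scales.

#' Number of data entries per stage
#'
#' The data distribution: one entry is one occurrence record; sentinel
#' (out-of-interval / unresolved) records are excluded. A per-bin proxy for
#' sampling effort.
#'
#' @param x an \linkS4class{OccurrenceRecordSet}.
#' @return named integer vector over the stages of the scale.
#' @export
entriesPerStage <- function(x) {
  sn <- stageNames(x@stageScale)
  b <- factor(x@records$stage, levels = sn)
  stats::setNames(as.integer(table(b)), sn)
}

#' Spearman rank correlation between two per-stage series
#'
#' Tests for a monotonic relationship using Spearman's \eqn{r_s} via
#' \code{stats::cor.test}: the exact two-sided permutation p-value for
#' \eqn{n \le 9} tie-free series, the t-approximation on average ranks
#' otherwise. A correlation is flagged strong when \eqn{|r_s| > 0.6} and
#' significant when \eqn{p < 0.05}; both flags are recomputed from the
#' values, never stored.
#'
#' @param x,y numeric series of equal length \eqn{\ge 3}, no missing values.
#' @return list of class \code{corr_result}: \code{r_s}, \code{p}, \code{n},
#'   \code{strong}, \code{significant}.
#' @export
spearmanTrend <- function(x, y) {
  if (length(x) != length(y)) stop("series must have equal length")
  if (length(x) < 3) stop("need at least 3 paired bins")
  if (anyNA(x) || anyNA(y)) stop("missing values are not allowed")
  if (stats::sd(x) == 0 || stats::sd(y) == 0)
    stop("Spearman correlation undefined for a constant series")
  ct <- suppressWarnings(stats::cor.test(x, y, method = "spearman"))
  r <- unname(ct$estimate)
  p <- min(1, unname(ct$p.value))
  structure(list(r_s = r, p = p, n = length(x),
                 strong = abs(r) > 0.6, significant = p < 0.05),
            class = "corr_result")
}

#' @export
print.corr_result <- function(x, ...) {
  cat(sprintf("Spearman r_s = %.3f (n = %d), p = %.4g%s%s\n",
              x$r_s, x$n, x$p,
              if (x$strong) ", strong" else "",
              if (x$significant) ", significant" else ""))
  invisible(x)
}

#' Mean-centre and scale a series to unit standard deviation
#'
#' Subtracts the mean and divides by the sample standard deviation
#' (\eqn{n - 1} denominator), so that series measured in different units
#' (e.g. richness counts and entry counts) can be overlaid. Invariant under
#' positive affine transforms of the input.
#'
#' @param x numeric series of length \eqn{\ge 2}, non-constant.
#' @param label optional source label, kept as an attribute.
#' @return numeric vector with mean 0 and sd 1, attribute
#'   \code{source_label}.
#' @export
centerScale <- function(x, label = deparse(substitute(x))) {
  if (length(x) < 2) stop("need at least 2 values")
  s <- stats::sd(x)
  if (s == 0) stop("constant series cannot be scaled")
  structure((x - mean(x)) / s, source_label = label)
}
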