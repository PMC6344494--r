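## Shareholder quorum subsampling (coverage-based rarefaction) by reference.
##
## References are drawn without replacement; each drawn reference contributes
## the occurrences of up to `sampleQuota` of its samples (chosen uniformly at
## random). With `mergeRepeats` a taxon occurring in several drawn samples of
## one reference is counted as a single occurrence, which prevents references
## that report few taxa repeatedly from inflating the coverage estimate.
## After every reference draw the coverage of the selection is estimated with
## Good's u = 1 - n1/N; whenever u reaches or overtakes the quorum the
## current distinct-taxon count is recorded. Recorded counts are pooled
## across trials and summarized by their median and 95% interval.

#' Good's coverage estimate of a selection of occurrences
#'
#' Estimates the fraction of the underlying taxon frequency distribution
#' represented by a selection, as \eqn{u = 1 - n_1/N} where \eqn{n_1} is the
#' number of taxa with exactly one occurrence in the selection and \eqn{N}
#' the total number of occurrences.
#'
#' @param occurrences character vector of taxon identities, one element per
#'   (merged) occurrence.
#' @return list with \code{N}, \code{n1} and \code{u} (\code{NA} for an
#'   empty selection, which callers treat as below any quorum).
#' @examples
#' goodsCoverage(c("A", "A", "B"))  # u = 2/3
#' @export
goodsCoverage <- function(occurrences) {
  N <- length(occurrences)
  if (N == 0) return(list(N = 0L, n1 = 0L, u = NA_real_))
  n1 <- sum(table(occurrences) == 1L)
  list(N = as.integer(N), n1 = as.integer(n1), u = 1 - n1 / N)
}

#' Subsampling configuration
#'
#' @param quorum target coverage fraction in (0, 1); default 0.4.
#' @param trials number of subsampling trials per bin; default 500.
#' @param sampleQuota maximum samples drawn per reference; default 5.
#' @param mergeRepeats merge a taxon's repeats across the drawn samples of
#'   one reference into a single occurrence; default \code{TRUE}.
#' @param record when to record the running richness: \code{"crossing"}
#'   (default) records at every upward crossing, i.e. whenever the coverage
#'   reaches or overtakes the quorum after having been below it, so recorded
#'   counts are taken at (approximately) the quorum coverage;
#'   \code{"continuous"} records after every reference draw whose coverage
#'   is at or above the quorum. Continuous recording pools counts from
#'   arbitrarily far beyond the quorum, which in well-sampled bins pulls the
#'   median toward the raw richness and removes the standardization the
#'   method exists for; it is kept as an option for comparison.
#' @param seed integer master seed for the subsampling RNG.
#' @return a validated list of class \code{sqs_config}.
#' @export
sqsConfig <- function(quorum = 0.4, trials = 500, sampleQuota = 5,
                      mergeRepeats = TRUE,
                      record = c("crossing", "continuous"), seed = 1L) {
  stopifnot(quorum > 0, quorum < 1, trials >= 1, sampleQuota >= 1)
  structure(list(quorum = quorum, trials = as.integer(trials),
                 sampleQuota = as.integer(sampleQuota),
                 mergeRepeats = isTRUE(mergeRepeats),
                 record = match.arg(record),
                 seed = as.integer(seed)),
            class = "sqs_config")
}

## One bin's incidence table -> recorded richness counts over all trials.
## `inc` has columns taxon_i (integer), ref (factor/int), sample (char).
.sqsBinTrials <- function(inc, nTaxaLevels, config) {
  refs <- unique(inc$ref)
  byRef <- split(inc[c("taxon_i", "sample")], inc$ref)
  recorded <- integer(0)
  failed <- 0L
  for (trial in seq_len(config$trials)) {
    order_r <- refs[sample.int(length(refs))]
    counts <- integer(nTaxaLevels)
    N <- 0L
    n1 <- 0L
    hit <- FALSE
    below <- TRUE  # coverage starts undefined, treated as below quorum
    for (r in order_r) {
      d <- byRef[[as.character(r)]]
      ss <- unique(d$sample)
      if (length(ss) > config$sampleQuota)
        ss <- ss[sample.int(length(ss), config$sampleQuota)]
      d <- d[d$sample %in% ss, , drop = FALSE]
      occ <- if (config$mergeRepeats) unique(d$taxon_i) else d$taxon_i
      for (t in occ) {
        counts[t] <- counts[t] + 1L
        if (counts[t] == 1L) n1 <- n1 + 1L
        else if (counts[t] == 2L) n1 <- n1 - 1L
      }
      N <- N + length(occ)
      at_quorum <- N > 0L && 1 - n1 / N >= config$quorum
      if (at_quorum && (config$record == "continuous" || below)) {
        recorded <- c(recorded, sum(counts > 0L))
        hit <- TRUE
      }
      below <- !at_quorum
    }
    if (!hit) failed <- failed + 1L
  }
  list(recorded = recorded, n_failed_trials = failed)
}

#' Subsample one bin's occurrences by reference
#'
#' Runs the reference-wise subsampling trials on the records of a single
#' bin and returns the pooled recorded richness counts. One occurrence is a
#' taxon's incidence in one sample (duplicate reports of a taxon within the
#' same sample are collapsed before subsampling).
#'
#' @param records data.frame with columns \code{taxon}, \code{reference_id},
#'   \code{sample_id} (occurrences of one bin).
#' @param config an \code{\link{sqsConfig}}.
#' @return list with \code{recorded} (integer vector, pooled over trials)
#'   and \code{n_failed_trials}.
#' @export
sqsByReference <- function(records, config = sqsConfig()) {
  if (nrow(records) == 0)
    return(list(recorded = integer(0), n_failed_trials = config$trials))
  inc <- unique(data.frame(taxon = records$taxon,
                           ref = records$reference_id,
                           sample = paste(records$reference_id,
                                          records$sample_id, sep = "\r"),
                           stringsAsFactors = FALSE))
  taxa <- unique(inc$taxon)
  inc$taxon_i <- match(inc$taxon, taxa)
  set.seed(config$seed)
  .sqsBinTrials(inc, length(taxa), config)
}

#' Summarize pooled subsampling trials
#'
#' Median and 95% interval (2.5th and 97.5th percentiles, linear
#' interpolation between order statistics, i.e. quantile type 7) of the
#' pooled recorded richness counts.
#'
#' @param recorded integer vector of pooled recorded richness counts.
#' @return list with \code{median_richness}, \code{ci_lower},
#'   \code{ci_upper}, \code{n_recorded}, and \code{no_estimate} flag
#'   (\code{TRUE} with all-\code{NA} values when nothing was recorded).
#' @export
summarizeTrials <- function(recorded) {
  if (length(recorded) == 0)
    return(list(median_richness = NA_real_, ci_lower = NA_real_,
                ci_upper = NA_real_, n_recorded = 0L, no_estimate = TRUE))
  q <- stats::quantile(recorded, c(0.025, 0.975), type = 7, names = FALSE)
  list(median_richness = stats::median(recorded),
       ci_lower = q[1], ci_upper = q[2],
       n_recorded = length(recorded), no_estimate = FALSE)
}

#' Shareholder quorum subsampling across all bins of a record set
#'
#' Applies \code{\link{sqsByReference}} to every stage of the scale and
#' summarizes each bin's pooled trials. Per-bin RNG substreams are derived
#' deterministically from the master seed, so results do not depend on the
#' order in which bins are computed.
#'
#' @param x a filtered \linkS4class{OccurrenceRecordSet}.
#' @param rankLevel taxon identity used for coverage and richness.
#' @param config an \code{\link{sqsConfig}}.
#' @return data.frame with one row per stage: \code{stage}, \code{quorum},
#'   \code{median_richness}, \code{ci_lower}, \code{ci_upper},
#'   \code{n_recorded}, \code{n_failed_trials}.
#' @export
sqs <- function(x, rankLevel = c("genus", "species", "family"),
                config = sqsConfig()) {
  rankLevel <- match.arg(rankLevel)
  sc <- x@stageScale
  rec <- x@records
  key <- .taxonKey(rec, rankLevel)
  binOf <- match(rec$stage, stageNames(sc))
  set.seed(config$seed)
  binSeeds <- sample.int(2^30, nStages(sc))
  rows <- lapply(seq_len(nStages(sc)), function(b) {
    in_b <- !is.na(binOf) & binOf == b & !is.na(key)
    cfg_b <- config
    cfg_b$seed <- binSeeds[b]
    res <- sqsByReference(data.frame(taxon = key[in_b],
                                     reference_id = rec$reference_id[in_b],
                                     sample_id = rec$sample_id[in_b],
                                     stringsAsFactors = FALSE), cfg_b)
    s <- summarizeTrials(res$recorded)
    data.frame(stage = stageNames(sc)[b], quorum = config$quorum,
               median_richness = s$median_richness, ci_lower = s$ci_lower,
               ci_upper = s$ci_upper, n_recorded = s$n_recorded,
               n_failed_trials = res$n_failed_trials,
               stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}
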