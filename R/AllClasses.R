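#' @import methods
NULL

## Sentinel stage labels: records outside the analysed interval or without a
## single-bin assignment. Pre-/post-interval records are kept for range
## extension; unresolved records are dropped by the selection filters.
.sentinelStages <- c("pre-interval", "post-interval", "unresolved")

.qualifierVocab <- c("sp", "spp", "cf", "aff", "question", "ex_gr",
                     "other-open-nomenclature")

.recordColumns <- c("record_id", "genus_name", "species_epithet",
                    "qualifiers", "qualifier_position", "rank",
                    "higher_group", "fossil_class", "stage",
                    "reference_id", "sample_id", "reworked", "family")

#' StageScale: ordered chronostratigraphic bins
#'
#' An ordered sequence of stages (oldest first), each with a base and top age
#' in Ma. Durations (Myr) are derived as \code{base - top} and are used to
#' normalize turnover counts to per-Myr rates.
#'
#' @slot stageName character vector of stage names, oldest first.
#' @slot baseAge numeric, age of each stage's lower boundary (Ma).
#' @slot topAge numeric, age of each stage's upper boundary (Ma).
#' @exportClass StageScale
setClass("StageScale",
         representation(stageName = "character",
                        baseAge = "numeric",
                        topAge = "numeric"))

setValidity("StageScale", function(object) {
  n <- length(object@stageName)
  msg <- character(0)
  if (length(object@baseAge) != n || length(object@topAge) != n)
    msg <- c(msg, "stageName, baseAge and topAge must have equal length")
  if (n == 0)
    msg <- c(msg, "a StageScale needs at least one stage")
  if (anyDuplicated(object@stageName))
    msg <- c(msg, "stage names must be unique")
  if (any(object@stageName %in% .sentinelStages))
    msg <- c(msg, "stage names must not collide with sentinel labels")
  if (n > 0 && length(msg) == 0) {
    if (any(object@baseAge - object@topAge <= 0))
      msg <- c(msg, "every stage must have positive duration (base > top)")
    if (n > 1 && any(abs(object@topAge[-n] - object@baseAge[-1]) > 1e-9))
      msg <- c(msg, "adjacent stages must share a boundary age (oldest first)")
  }
  if (length(msg)) msg else TRUE
})

#' OccurrenceRecordSet: a validated set of fossil occurrence records
#'
#' Long-format occurrence records (one row per taxon occurrence) bound to a
#' \linkS4class{StageScale}, with a provenance log of every transformation
#' applied since ingestion. Record counts are auditable: the initial count
#' minus all logged removals equals the current count.
#'
#' @slot records data.frame in the canonical column layout (see
#'   \code{\link{readOccurrenceTable}}).
#' @slot stageScale the \linkS4class{StageScale} the records are binned on.
#' @slot provenance data.frame with columns \code{step}, \code{removed},
#'   \code{n_after}, \code{detail}.
#' @exportClass OccurrenceRecordSet
setClass("OccurrenceRecordSet",
         representation(records = "data.frame",
                        stageScale = "StageScale",
                        provenance = "data.frame"))

setValidity("OccurrenceRecordSet", function(object) {
  msg <- character(0)
  rec <- object@records
  missing_cols <- setdiff(.recordColumns, names(rec))
  if (length(missing_cols))
    return(paste("records lack canonical columns:",
                 paste(missing_cols, collapse = ", ")))
  if (anyDuplicated(rec$record_id))
    msg <- c(msg, "record_id must be unique")
  ok_stage <- rec$stage %in% c(object@stageScale@stageName, .sentinelStages)
  if (!all(ok_stage))
    msg <- c(msg, paste("unknown stage label(s):",
                        paste(unique(rec$stage[!ok_stage]), collapse = ", ")))
  bad_sp <- rec$rank == "species" & rec$species_epithet == ""
  if (any(bad_sp))
    msg <- c(msg, "species-rank records must carry a species epithet")
  prov <- object@provenance
  if (nrow(prov) > 0) {
    n0 <- prov$n_after[1] + prov$removed[1]
    if (n0 - sum(prov$removed) != nrow(rec))
      msg <- c(msg, "provenance removal counts do not sum to the record deficit")
  }
  if (length(msg)) msg else TRUE
})

#' TaxonRangeSet: stratigraphic ranges at one taxonomic rank
#'
#' One range per taxon: the first and last sampled bin, the per-bin sampled
#' pattern, and flags for occurrences pre- or post-dating the analysed
#' interval (used to extend ranges to the outer boundaries of the scale when
#' \code{extend} is \code{TRUE}).
#'
#' @slot taxon character, taxon names at the analysis rank.
#' @slot firstBin,lastBin integer bin indices of first/last sampled presence.
#' @slot sampled logical matrix (taxa x bins) of in-bin sampled presence.
#' @slot extendedBefore,extendedAfter logical, out-of-interval occurrences.
#' @slot extend logical, whether out-of-interval occurrences extend inferred
#'   presence to the scale boundaries.
#' @slot rankLevel one of "species", "genus", "family".
#' @slot stageScale the \linkS4class{StageScale} used for binning.
#' @slot nDropped integer, records or taxa dropped while building ranges.
#' @exportClass TaxonRangeSet
setClass("TaxonRangeSet",
         representation(taxon = "character",
                        firstBin = "integer",
                        lastBin = "integer",
                        sampled = "matrix",
                        extendedBefore = "logical",
                        extendedAfter = "logical",
                        extend = "logical",
                        rankLevel = "character",
                        stageScale = "StageScale",
                        nDropped = "integer"))

setValidity("TaxonRangeSet", function(object) {
  msg <- character(0)
  k <- length(object@taxon)
  if (length(object@firstBin) != k || length(object@lastBin) != k ||
      nrow(object@sampled) != k)
    msg <- c(msg, "per-taxon slots must have one entry per taxon")
  if (k > 0) {
    if (any(object@firstBin > object@lastBin))
      msg <- c(msg, "firstBin must be <= lastBin")
    n <- length(object@stageScale@stageName)
    if (ncol(object@sampled) != n)
      msg <- c(msg, "sampled matrix must have one column per stage")
    idx <- cbind(seq_len(k), object@firstBin)
    if (!all(object@sampled[idx] | object@extendedBefore))
      msg <- c(msg, "firstBin must be sampled unless the range extends before")
    idx <- cbind(seq_len(k), object@lastBin)
    if (!all(object@sampled[idx] | object@extendedAfter))
      msg <- c(msg, "lastBin must be sampled unless the range extends after")
  }
  if (length(msg)) msg else TRUE
})

#' TrueHistory: known taxon histories for a synthetic fossil record
#'
#' The ground truth behind a simulated occurrence table: each taxon's true
#' first and last bin (contiguous range) and its relative abundance weight.
#'
#' @slot taxa data.frame with columns \code{taxon}, \code{first_bin},
#'   \code{last_bin}, \code{weight}.
#' @slot stageScale the \linkS4class{StageScale} the history lives on.
#' @exportClass TrueHistory
setClass("TrueHistory",
         representation(taxa = "data.frame",
                        stageScale = "StageScale"))

setValidity("TrueHistory", function(object) {
  tx <- object@taxa
  need <- c("taxon", "first_bin", "last_bin", "weight")
  if (!all(need %in% names(tx)))
    return("taxa must have columns taxon, first_bin, last_bin, weight")
  n <- length(object@stageScale@stageName)
  msg <- character(0)
  if (any(tx$first_bin < 1 | tx$last_bin > n | tx$first_bin > tx$last_bin))
    msg <- c(msg, "taxon ranges must be contiguous and inside the scale")
  if (any(tx$weight <= 0))
    msg <- c(msg, "abundance weights must be positive")
  if (anyDuplicated(tx$taxon))
    msg <- c(msg, "taxon names must be unique")
  if (length(msg)) msg else TRUE
})
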