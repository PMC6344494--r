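## Stratigraphic ranges and per-stage diversity / turnover indices.
##
## All indices derive from the "four types" of taxa present in a bin:
## single-interval taxa, bottom-boundary crossers (going extinct), top-
## boundary crossers (originating) and range-through taxa. Sampled-in-bin
## (SIB) richness counts documented occurrences only; total (range-through)
## richness adds inferred presences between a taxon's first and last
## occurrence, whose in-bin absences are the Lazarus taxa.

.taxonKey <- function(rec, rankLevel) {
  switch(rankLevel,
         species = ifelse(rec$rank == "species",
                          paste(rec$genus_name, rec$species_epithet), NA),
         genus = ifelse(rec$genus_name != "", rec$genus_name, NA),
         family = ifelse(rec$family != "", rec$family, NA))
}

#' Build stratigraphic ranges for every taxon at a rank
#'
#' Collapses an occurrence record set to one range per taxon: the first and
#' last bin with a documented occurrence, the per-bin sampled pattern, and
#' flags for occurrences pre- or post-dating the interval. With
#' \code{extend = TRUE} (the default) out-of-interval occurrences extend the
#' inferred presence to the corresponding outer boundary of the scale.
#' Records that carry no identity at the requested rank (e.g. family-only
#' records at genus rank, records with an empty family at family rank) are
#' dropped and counted, as are taxa known only from out-of-interval
#' occurrences (never present in the studied interval).
#'
#' @param x a filtered \linkS4class{OccurrenceRecordSet}.
#' @param rankLevel \code{"species"}, \code{"genus"} or \code{"family"}.
#' @param extend logical; use pre-/post-interval occurrences to extend
#'   ranges to the scale boundaries.
#' @return a \linkS4class{TaxonRangeSet}.
#' @export
buildTaxonRanges <- function(x, rankLevel = c("species", "genus", "family"),
                             extend = TRUE) {
  rankLevel <- match.arg(rankLevel)
  sc <- x@stageScale
  nb <- nStages(sc)
  rec <- x@records
  key <- .taxonKey(rec, rankLevel)
  dropped_rec <- sum(is.na(key))
  rec <- rec[!is.na(key), , drop = FALSE]
  key <- key[!is.na(key)]

  taxa <- sort(unique(key))
  k <- length(taxa)
  bin <- match(rec$stage, stageNames(sc))
  ti <- match(key, taxa)
  sampled <- matrix(FALSE, k, nb, dimnames = list(taxa, stageNames(sc)))
  in_int <- !is.na(bin)
  sampled[cbind(ti[in_int], bin[in_int])] <- TRUE
  extB <- as.logical(tabulate(ti[rec$stage == "pre-interval"], k) > 0)
  extA <- as.logical(tabulate(ti[rec$stage == "post-interval"], k) > 0)

  has_in <- rowSums(sampled) > 0
  dropped_taxa <- sum(!has_in)
  taxa <- taxa[has_in]
  sampled <- sampled[has_in, , drop = FALSE]
  extB <- extB[has_in]
  extA <- extA[has_in]
  firstBin <- apply(sampled, 1, function(v) which(v)[1])
  lastBin <- apply(sampled, 1, function(v) max(which(v)))
  if (length(taxa) == 0) { firstBin <- integer(0); lastBin <- integer(0) }

  new("TaxonRangeSet", taxon = taxa,
      firstBin = as.integer(firstBin), lastBin = as.integer(lastBin),
      sampled = sampled, extendedBefore = extB, extendedAfter = extA,
      extend = extend, rankLevel = rankLevel, stageScale = sc,
      nDropped = as.integer(dropped_rec + dropped_taxa))
}

#' @describeIn buildTaxonRanges taxon names of a range set.
#' @param ranges a \linkS4class{TaxonRangeSet}.
#' @export
rangeTaxa <- function(ranges) ranges@taxon

#' Inferred (range-through) presence matrix
#'
#' \code{TRUE} for every bin between a taxon's first and last occurrence
#' (extended to the scale boundaries when out-of-interval occurrences exist
#' and \code{extend} was requested). Bins where a taxon is inferred present
#' but not sampled are its Lazarus bins.
#'
#' @param ranges a \linkS4class{TaxonRangeSet}.
#' @return logical matrix (taxa x bins).
#' @export
presenceMatrix <- function(ranges) {
  nb <- nStages(ranges@stageScale)
  k <- length(ranges@taxon)
  lo <- ranges@firstBin
  hi <- ranges@lastBin
  if (ranges@extend) {
    lo[ranges@extendedBefore] <- 1L
    hi[ranges@extendedAfter] <- nb
  }
  m <- matrix(FALSE, k, nb,
              dimnames = list(ranges@taxon, stageNames(ranges@stageScale)))
  for (i in seq_len(k)) m[i, lo[i]:hi[i]] <- TRUE
  m
}

.effectiveBounds <- function(ranges) {
  nb <- nStages(ranges@stageScale)
  lo <- ranges@firstBin
  hi <- ranges@lastBin
  if (ranges@extend) {
    ## an out-of-interval occurrence counts as crossing the scale's outer
    ## boundary, so the effective bound lies outside the scale
    lo[ranges@extendedBefore] <- 0L
    hi[ranges@extendedAfter] <- nb + 1L
  }
  list(lo = lo, hi = hi)
}

#' Classify the taxa present in one bin into the four basic types
#'
#' Every taxon whose (range-through) presence includes the bin falls into
#' exactly one class: present only in this bin (\code{n_single}); crossing
#' the bottom boundary but not the top, i.e. going extinct
#' (\code{n_bottom_only}); first appearing here and crossing the top, i.e.
#' originating (\code{n_top_only}); or crossing both boundaries
#' (\code{n_through}).
#'
#' @param ranges a \linkS4class{TaxonRangeSet}.
#' @param bin stage name or bin index.
#' @return named integer vector \code{n_single}, \code{n_bottom_only},
#'   \code{n_top_only}, \code{n_through}.
#' @export
classifyStageTaxa <- function(ranges, bin) {
  nb <- nStages(ranges@stageScale)
  if (is.character(bin)) bin <- match(bin, stageNames(ranges@stageScale))
  if (is.na(bin) || bin < 1 || bin > nb)
    stop("bin outside the stage scale")
  b <- .effectiveBounds(ranges)
  present <- pmax(b$lo, 1L) <= bin & pmin(b$hi, nb) >= bin
  cb <- b$lo < bin & present
  ct <- b$hi > bin & present
  c(n_single = sum(present & !cb & !ct),
    n_bottom_only = sum(cb & !ct),
    n_top_only = sum(ct & !cb),
    n_through = sum(cb & ct))
}

#' Per-stage diversity, turnover and bias-diagnostic table
#'
#' Computes for every bin: sampled-in-bin richness (\code{sib}), total
#' (range-through) richness, normalized diversity (an estimate of mean
#' standing diversity: range-through taxa plus half weight for taxa whose
#' range starts and/or ends in the bin), the four type counts, Lazarus
#' counts and proportions, origination/extinction/turnover counts (boundary
#' crossers only, single-bin taxa excluded) and their per-Myr rates, the
#' number of data entries per bin, and Good's coverage estimate \eqn{u} for
#' the bin.
#'
#' The single-bin weight \code{wSingle} controls how a taxon confined to one
#' bin enters normalized diversity: it both originates and goes extinct
#' there, so with \code{wSingle = 1} (default) it contributes two half-events
#' (weight 0.5 total); \code{wSingle = 0} omits single-bin taxa.
#'
#' Coverage is estimated on the same occurrence definition the subsampling
#' uses: one occurrence per taxon per reference within the bin (repeats of a
#' taxon across samples of one reference merged).
#'
#' @param x the filtered \linkS4class{OccurrenceRecordSet} the ranges were
#'   built from.
#' @param ranges the matching \linkS4class{TaxonRangeSet}.
#' @param wSingle 0 or 1; see Details.
#' @return data.frame, one row per stage.
#' @export
computeStageTable <- function(x, ranges, wSingle = 1) {
  stopifnot(wSingle %in% c(0, 1))
  sc <- ranges@stageScale
  nb <- nStages(sc)
  dur <- stageDurations(sc)
  rec <- x@records
  key <- .taxonKey(rec, ranges@rankLevel)
  binOf <- match(rec$stage, stageNames(sc))

  out <- data.frame(stage = stageNames(sc), duration = as.numeric(dur),
                    stringsAsFactors = FALSE)
  four <- t(vapply(seq_len(nb), function(b) classifyStageTaxa(ranges, b),
                   integer(4)))
  sib <- if (length(ranges@taxon)) as.integer(colSums(ranges@sampled))
         else integer(nb)
  total <- as.integer(rowSums(four))
  out$sib <- sib
  out$total <- total
  out$normalized <- four[, "n_through"] +
    0.5 * (four[, "n_bottom_only"] + four[, "n_top_only"] +
             wSingle * four[, "n_single"])
  out$lazarus_count <- total - sib
  out$lazarus_proportion <- ifelse(total > 0, (total - sib) / total, 0)
  out <- cbind(out, four)
  out$originations <- four[, "n_top_only"]
  out$extinctions <- four[, "n_bottom_only"]
  out$turnover <- out$originations + out$extinctions
  out$origination_rate <- out$originations / out$duration
  out$extinction_rate <- out$extinctions / out$duration
  out$turnover_rate <- out$turnover / out$duration
  out$n_entries <- vapply(seq_len(nb), function(b)
    sum(binOf == b, na.rm = TRUE), integer(1))
  out$coverage_u <- vapply(seq_len(nb), function(b) {
    in_b <- !is.na(binOf) & binOf == b & !is.na(key)
    occ <- unique(data.frame(taxon = key[in_b],
                             ref = rec$reference_id[in_b]))$taxon
    goodsCoverage(occ)$u
  }, numeric(1))
  rownames(out) <- NULL
  out
}

#' Extinction as a percentage of bin diversity
#'
#' Returns \eqn{100 \cdot extinctions(bin) / total(bin)} (unrounded). The
#' denominator is the bin's range-through diversity by default;
#' \code{denominator = "sib"} uses sampled-in-bin richness instead.
#'
#' @param table a stage table from \code{\link{computeStageTable}}.
#' @param bin stage name or index.
#' @param denominator \code{"total"} (default) or \code{"sib"}.
#' @return numeric percentage.
#' @export
extinctionFraction <- function(table, bin, denominator = c("total", "sib")) {
  denominator <- match.arg(denominator)
  if (is.character(bin)) bin <- match(bin, table$stage)
  if (is.na(bin) || bin < 1 || bin > nrow(table))
    stop("bin outside the stage table")
  denom <- table[[denominator]][bin]
  if (denom == 0)
    stop("undefined extinction fraction: ", denominator, " is zero in bin ",
         table$stage[bin])
  100 * table$extinctions[bin] / denom
}

#' Species diversity with and without the one-species-per-genus floor
#'
#' Species-level total diversity can undercount when genera are recorded
#' without any named species in a bin (or are only inferred present there):
#' logically at least one species per genus must have existed. Mode
#' \code{"named-only"} returns the species range-through diversity; mode
#' \code{"min-one-per-genus"} adds, per bin, one species for every genus
#' present (range-through) that contributes no named species to that bin.
#'
#' @param rangesSpecies species-level \linkS4class{TaxonRangeSet}.
#' @param rangesGenus genus-level \linkS4class{TaxonRangeSet} from the same
#'   record set.
#' @param mode \code{"named-only"} or \code{"min-one-per-genus"}.
#' @return named integer vector of per-bin counts.
#' @export
speciesDiversityVariants <- function(rangesSpecies, rangesGenus,
                                     mode = c("named-only",
                                              "min-one-per-genus")) {
  mode <- match.arg(mode)
  spPres <- presenceMatrix(rangesSpecies)
  named <- colSums(spPres)
  if (mode == "named-only")
    return(stats::setNames(as.integer(named), colnames(spPres)))
  genPres <- presenceMatrix(rangesGenus)
  spGenus <- vapply(strsplit(rangeTaxa(rangesSpecies), " ", fixed = TRUE),
                    `[`, character(1), 1)
  nb <- ncol(genPres)
  extra <- integer(nb)
  for (b in seq_len(nb)) {
    covered <- unique(spGenus[spPres[, b]])
    present <- rownames(genPres)[genPres[, b]]
    extra[b] <- sum(!present %in% covered)
  }
  stats::setNames(as.integer(named + extra), colnames(genPres))
}

setMethod("show", "TaxonRangeSet", function(object) {
  cat(sprintf("TaxonRangeSet: %d %s-level taxa on %d stages (%d records/taxa dropped)\n",
              length(object@taxon), object@rankLevel,
              nStages(object@stageScale), object@nDropped))
  if (length(object@taxon)) {
    span <- object@lastBin - object@firstBin + 1L
    cat(sprintf("  range span: median %.0f bins; %d taxa extend before, %d after\n",
                stats::median(span), sum(object@extendedBefore),
                sum(object@extendedAfter)))
  }
})
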