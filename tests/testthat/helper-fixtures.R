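# Fixture builders and independent oracles shared across the suite.

# Four equal-duration toy bins for cases where stage durations are irrelevant.
toyScale <- function(n = 4) {
  stageScale(paste0("Bin", seq_len(n)), baseAge = seq(n, 1), topAge = seq(n - 1, 0))
}

# Compact record-set builder: one row per occurrence, defaults filled in.
makeRecords <- function(taxon, stage, ref = "r1", sample = "s1",
                        class = "macrofossil", group = "plant",
                        reworked = "no", family = "",
                        scale = defaultStageScale()) {
  n <- length(taxon)
  occurrenceRecordSet(data.frame(
    taxon = taxon, stage = stage,
    reference_id = rep_len(ref, n), sample_id = rep_len(sample, n),
    class = rep_len(class, n), group = rep_len(group, n),
    reworked = rep_len(reworked, n), family = rep_len(family, n),
    stringsAsFactors = FALSE), stageScale = scale)
}

# Build a TaxonRangeSet directly from first/last bins (sampled everywhere in
# range), bypassing the record path, for classification unit tests.
makeRanges <- function(first, last, scale = toyScale(),
                       extB = rep(FALSE, length(first)),
                       extA = rep(FALSE, length(first)), extend = TRUE) {
  k <- length(first)
  nb <- nStages(scale)
  taxa <- sprintf("Rangetaxon%02d", seq_len(k))
  sampled <- matrix(FALSE, k, nb, dimnames = list(taxa, stageNames(scale)))
  for (i in seq_len(k)) sampled[i, first[i]:last[i]] <- TRUE
  new("TaxonRangeSet", taxon = taxa, firstBin = as.integer(first),
      lastBin = as.integer(last), sampled = sampled,
      extendedBefore = extB, extendedAfter = extA, extend = extend,
      rankLevel = "genus", stageScale = scale, nDropped = 0L)
}

# Independent brute-force oracle: classify the taxa of one bin by testing
# boundary crossing taxon-by-taxon from effective first/last bins.
oracleFourTypes <- function(first, last, bin, nb, extB = NULL, extA = NULL) {
  k <- length(first)
  if (is.null(extB)) extB <- rep(FALSE, k)
  if (is.null(extA)) extA <- rep(FALSE, k)
  counts <- c(n_single = 0L, n_bottom_only = 0L, n_top_only = 0L,
              n_through = 0L)
  for (i in seq_len(k)) {
    lo <- if (extB[i]) 0L else first[i]
    hi <- if (extA[i]) nb + 1L else last[i]
    if (max(lo, 1L) > bin || min(hi, nb) < bin) next
    cb <- lo < bin
    ct <- hi > bin
    cls <- if (cb && ct) "n_through" else if (cb) "n_bottom_only"
           else if (ct) "n_top_only" else "n_single"
    counts[cls] <- counts[cls] + 1L
  }
  counts
}

# Independent Spearman oracle: rank correlation from first principles and a
# two-sided p-value by exhaustive enumeration of all permutations of y.
oracleSpearman <- function(x, y) {
  rs <- function(a, b) {
    ra <- rank(a); rb <- rank(b)
    sum((ra - mean(ra)) * (rb - mean(rb))) /
      sqrt(sum((ra - mean(ra))^2) * sum((rb - mean(rb))^2))
  }
  perms <- function(v) {
    if (length(v) == 1) return(list(v))
    out <- list()
    for (i in seq_along(v))
      for (p in perms(v[-i])) out[[length(out) + 1L]] <- c(v[i], p)
    out
  }
  r_obs <- rs(x, y)
  all_r <- vapply(perms(y), function(p) rs(x, p), numeric(1))
  list(r_s = r_obs,
       p = mean(abs(all_r) >= abs(r_obs) - 1e-12))
}
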