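test_that("ranges infer presence between first and last occurrence (Lazarus gaps)", {
  x <- makeRecords(rep("Glossopteris gl", 2),
                   stage = c("Wuchiapingian", "Induan"))
  rg <- buildTaxonRanges(x, "genus")
  pres <- presenceMatrix(rg)
  expect_true(pres["Glossopteris", "Changhsingian"])
  expect_false(rg@sampled["Glossopteris", "Changhsingian"])
  expect_equal(rg@firstBin, 1L)
  expect_equal(rg@lastBin, 3L)
})

test_that("out-of-interval occurrences extend ranges to the scale boundary", {
  x <- makeRecords(rep("Peltaspermum pe", 2),
                   stage = c("pre-interval", "Olenekian"))
  rg <- buildTaxonRanges(x, "genus", extend = TRUE)
  pres <- presenceMatrix(rg)
  expect_equal(unname(pres[1, ]), c(TRUE, TRUE, TRUE, TRUE, FALSE, FALSE))
  # without extension only the sampled bin is inferred
  rg0 <- buildTaxonRanges(x, "genus", extend = FALSE)
  expect_equal(unname(presenceMatrix(rg0)[1, ]),
               c(FALSE, FALSE, FALSE, TRUE, FALSE, FALSE))
})

test_that("a single-bin taxon has equal first and last bin, no extensions", {
  rg <- buildTaxonRanges(makeRecords("Voltzia vo", "Anisian"), "genus")
  expect_equal(rg@firstBin, rg@lastBin)
  expect_false(rg@extendedBefore)
  expect_equal(classifyStageTaxa(rg, "Anisian"),
               c(n_single = 1L, n_bottom_only = 0L, n_top_only = 0L,
                 n_through = 0L))
})

test_that("taxa known only from out-of-interval occurrences emit no range", {
  x <- makeRecords(c("Outsider ou", "Insider in"),
                   stage = c("pre-interval", "Induan"))
  rg <- buildTaxonRanges(x, "genus")
  expect_equal(rangeTaxa(rg), "Insider")
  expect_equal(rg@nDropped, 1L)
})

test_that("four-type classification matches the enumeration oracle on the worked case", {
  rg <- makeRanges(first = c(1, 1, 2, 2), last = c(4, 2, 3, 2))
  got <- classifyStageTaxa(rg, 2)
  expect_equal(got, c(n_single = 1L, n_bottom_only = 1L, n_top_only = 1L,
                      n_through = 1L))
  expect_equal(got, oracleFourTypes(c(1, 1, 2, 2), c(4, 2, 3, 2), 2, 4))
  expect_error(classifyStageTaxa(rg, 9), "outside")
})

test_that("four-type classification matches brute force on random range sets", {
  set.seed(42)
  for (rep in 1:60) {
    k <- sample(0:50, 1)
    first <- sample(1:6, k, replace = TRUE)
    last <- pmin(6L, first + sample(0:5, k, replace = TRUE))
    extB <- stats::runif(k) < 0.15
    extA <- stats::runif(k) < 0.15
    rg <- makeRanges(first, last, scale = toyScale(6), extB = extB,
                     extA = extA)
    for (b in 1:6)
      expect_equal(classifyStageTaxa(rg, b),
                   oracleFourTypes(first, last, b, 6, extB, extA))
  }
})

test_that("stage table arithmetic follows the four-type conventions", {
  # 2 through, 1 going extinct, 1 originating, 1 single in the Induan
  rg <- makeRanges(first = c(1, 1, 1, 3, 3), last = c(6, 6, 3, 6, 3),
                   scale = defaultStageScale())
  x <- makeRecords("Dummy du", "Induan")  # entries only; not used for types
  tab <- computeStageTable(x, rg, wSingle = 1)
  i <- which(tab$stage == "Induan")
  expect_equal(tab$total[i], 5)
  expect_equal(tab$normalized[i], 3.5)
  expect_equal(tab$extinctions[i], 1)
  expect_equal(tab$originations[i], 1)
  expect_equal(tab$turnover[i], 2)
  expect_equal(tab$extinction_rate[i], 1 / 0.702, tolerance = 1e-12)
  # with wSingle = 0 the single-bin taxon is omitted from normalized
  tab0 <- computeStageTable(x, rg, wSingle = 0)
  expect_equal(tab0$normalized[i], 3)
})

test_that("stage table invariants hold on random synthetic sets", {
  set.seed(99)
  for (rep in 1:20) {
    h <- simulateTrueHistory(30, pOrig = 0.2, pExt = 0.2, seed = rep)
    rec <- simulatePreservation(h, samplingConfig(rep(6L, 6), 2, 3,
                                                  seed = rep + 100))
    rg <- buildTaxonRanges(rec, "genus")
    if (length(rangeTaxa(rg)) == 0) next
    tab <- computeStageTable(rec, rg)
    expect_true(all(tab$sib <= tab$total))
    expect_equal(tab$total,
                 tab$n_single + tab$n_bottom_only + tab$n_top_only +
                   tab$n_through)
    expect_equal(tab$lazarus_count, tab$total - tab$sib)
    expect_true(all(tab$lazarus_count >= 0))
    expect_true(all(tab$normalized <= tab$total))
    expect_equal(tab$turnover, tab$originations + tab$extinctions)
    expect_equal(tab$turnover_rate, tab$turnover / tab$duration)
  }
})

test_that("normalized diversity limits: all-through equals total, all-single halves it", {
  through <- makeRanges(first = rep(1, 4), last = rep(4, 4))
  x <- makeRecords("Dummy du", "Bin2", scale = toyScale())
  tabT <- computeStageTable(x, through)
  expect_equal(tabT$normalized[2:3], tabT$total[2:3])
  singles <- makeRanges(first = rep(2, 6), last = rep(2, 6))
  tabS <- computeStageTable(x, singles, wSingle = 1)
  expect_equal(tabS$normalized[2], tabS$total[2] * 0.5)
})

test_that("adding an occurrence never decreases sib or total (monotonicity)", {
  set.seed(13)
  stages <- stageNames(defaultStageScale())
  taxa <- sprintf("Montax%02d %s", 1:8, letters[1:8])
  base_t <- sample(taxa, 25, replace = TRUE)
  base_s <- sample(stages, 25, replace = TRUE)
  x <- makeRecords(base_t, base_s)
  rgx <- buildTaxonRanges(x, "genus")
  tabx <- computeStageTable(x, rgx)
  for (i in 1:10) {
    y <- makeRecords(c(base_t, sample(taxa, 1)), c(base_s, sample(stages, 1)))
    rgy <- buildTaxonRanges(y, "genus")
    taby <- computeStageTable(y, rgy)
    expect_true(all(taby$sib >= tabx$sib))
    expect_true(all(taby$total >= tabx$total))
  }
})

test_that("removing a bin's occurrences creates Lazarus taxa but keeps total (Jaanusson effect)", {
  taxa <- sprintf("Jaantax%02d ja", 1:6)
  x <- makeRecords(rep(taxa, each = 6),
                   stage = rep(stageNames(defaultStageScale()), 6))
  tab <- computeStageTable(x, buildTaxonRanges(x, "genus"))
  keep <- occurrenceRecords(x)$stage != "Olenekian"
  y <- x
  y@records <- occurrenceRecords(x)[keep, , drop = FALSE]
  taby <- computeStageTable(y, buildTaxonRanges(y, "genus"))
  i <- which(taby$stage == "Olenekian")
  expect_equal(taby$sib[i], 0)
  expect_equal(taby$total[i], tab$total[i])
  expect_equal(taby$lazarus_proportion[i], 1)
})

test_that("extinction fraction uses the requested denominator and guards zero", {
  rg <- makeRanges(first = c(1, 1, 1, 3, 3), last = c(6, 6, 3, 6, 3),
                   scale = defaultStageScale())
  x <- makeRecords("Dummy du", "Induan")
  tab <- computeStageTable(x, rg)
  expect_equal(extinctionFraction(tab, "Induan"), 100 * 1 / 5)
  expect_equal(extinctionFraction(tab, "Wuchiapingian"), 0)
  empty <- makeRanges(first = 2, last = 2, scale = defaultStageScale())
  tab0 <- computeStageTable(x, empty)
  expect_error(extinctionFraction(tab0, "Ladinian"), "zero")
})

test_that("species diversity variants add one species per uncovered genus", {
  # G1 has a named species everywhere it occurs; G2 is genus-only records
  x <- makeRecords(c("Gone alpha", "Gtwo sp."), stage = "Anisian")
  gen <- buildTaxonRanges(applySelectionFilters(x, "genus"), "genus")
  spp <- buildTaxonRanges(applySelectionFilters(x, "species"), "species")
  named <- speciesDiversityVariants(spp, gen, "named-only")
  floor <- speciesDiversityVariants(spp, gen, "min-one-per-genus")
  expect_equal(unname(named[["Anisian"]]), 1)
  expect_equal(unname(floor[["Anisian"]]), 2)
  expect_true(all(floor >= named))

  # when every genus has a named species in every occupied bin, modes agree
  y <- makeRecords(c("Gone alpha", "Gtwo beta"), stage = "Anisian")
  gy <- buildTaxonRanges(applySelectionFilters(y, "genus"), "genus")
  sy <- buildTaxonRanges(applySelectionFilters(y, "species"), "species")
  expect_equal(speciesDiversityVariants(sy, gy, "named-only"),
               speciesDiversityVariants(sy, gy, "min-one-per-genus"))
})
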