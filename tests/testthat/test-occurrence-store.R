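test_that("taxon-name parsing separates genus, epithet and qualifiers", {
  p <- parseTaxonName(c("Lepidopteris sp.",
                        "Lepidopteris martinsii",
                        "?Lepidopteris martinsii",
                        "Lepidopteris cf. martinsii",
                        "cf. Lepidopteris martinsii",
                        "Aratrisporites spp.",
                        "Pleuromeia indet."))
  expect_equal(p$genus, c(rep("Lepidopteris", 5), "Aratrisporites",
                          "Pleuromeia"))
  expect_equal(p$epithet[1], "")
  expect_equal(p$qualifiers[1], "sp")
  expect_equal(p$qualifier_position[1], "species-level")
  expect_equal(p$epithet[2], "martinsii")
  expect_equal(p$qualifiers[2], "")
  expect_equal(p$qualifier_position[2], "none")
  expect_equal(p$qualifiers[3], "question")
  expect_equal(p$qualifier_position[3], "genus-level")
  expect_equal(p$qualifier_position[4], "species-level")
  expect_equal(p$qualifier_position[5], "genus-level")
  expect_equal(p$qualifiers[6], "spp")
  expect_equal(p$qualifiers[7], "other-open-nomenclature")
})

test_that("reading a delimited table ingests rows identically and validates", {
  path <- withr::local_tempfile(fileext = ".csv")
  writeLines(c("taxon,stage,reference_id,sample_id,class,group",
               "Lepidopteris martinsii,Induan,r1,s1,macrofossil,pteridosperm",
               "Lepidopteris sp.,Anisian,r1,s2,macrofossil,pteridosperm",
               "Pleuromeia sternbergii,pre-interval,r2,s1,macrofossil,lycophyte"),
             path)
  x <- readOccurrenceTable(path)
  expect_s4_class(x, "OccurrenceRecordSet")
  expect_equal(nrow(occurrenceRecords(x)), 3)
  expect_equal(sum(provenanceLog(x)$removed), 0)
  expect_equal(occurrenceRecords(x)$rank, c("species", "genus", "species"))

  # tab-delimited dialect and case-insensitive headers
  tsv <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c("Taxon\tSTAGE\treference_id\tsample_id\tClass\tGroup",
               "Voltzia heterophylla\tAnisian\tr9\ts1\tmacrofossil\tconifer"),
             tsv)
  expect_equal(nrow(occurrenceRecords(readOccurrenceTable(tsv))), 1)
})

test_that("schema and validation errors name the offending column or rows", {
  path <- withr::local_tempfile(fileext = ".csv")
  writeLines(c("taxon,stage,reference_id,class,group",
               "Lepidopteris sp.,Induan,r1,macrofossil,pteridosperm"), path)
  expect_error(readOccurrenceTable(path), "sample_id")

  bad <- withr::local_tempfile(fileext = ".csv")
  writeLines(c("taxon,stage,reference_id,sample_id,class,group",
               "Lepidopteris sp.,Cretaceous,r1,s1,macrofossil,pteridosperm"),
             bad)
  expect_error(readOccurrenceTable(bad), "Cretaceous")

  dup <- data.frame(taxon = c("A a", "B b"), stage = "Induan",
                    reference_id = "r1", sample_id = "s1",
                    class = "macrofossil", group = "g",
                    record_id = c("x", "x"))
  expect_error(occurrenceRecordSet(dup), "duplicate record_id")
})

test_that("synonymy mapping merges genera and lowers sampled-in-bin diversity by one", {
  x <- makeRecords(c("GenusA alpha", "GenusB beta"),
                   stage = c("Induan", "Induan"))
  # before: two genera in the Induan
  rg0 <- buildTaxonRanges(applySelectionFilters(x, "genus"), "genus")
  expect_equal(sum(rg0@sampled[, "Induan"]), 2)
  y <- normalizeTaxonomy(x, synonymyMap = data.frame(from = "GenusA",
                                                     to = "GenusB"))
  rg1 <- buildTaxonRanges(applySelectionFilters(y, "genus"), "genus")
  expect_equal(sum(rg1@sampled[, "Induan"]), 1)
  expect_equal(rangeTaxa(rg1), "GenusB")

  # unchanged under empty maps
  z <- normalizeTaxonomy(x)
  expect_equal(occurrenceRecords(z)[names(occurrenceRecords(x))],
               occurrenceRecords(x))

  # chained maps are a configuration error
  expect_error(normalizeTaxonomy(x, data.frame(from = c("A", "B"),
                                               to = c("B", "C"))),
               "pre-resolve")
})

test_that("family mapping fills empty families and logs unmapped genera", {
  x <- makeRecords(c("GenusA alpha", "GenusC gamma"), stage = "Anisian")
  y <- normalizeTaxonomy(x, familyMap = data.frame(genus = "GenusA",
                                                   family = "Famone"))
  expect_equal(occurrenceRecords(y)$family, c("Famone", ""))
  expect_match(provenanceLog(y)$detail[nrow(provenanceLog(y))],
               "1 records without family")
  # unmapped genus is excluded from family-level counts downstream
  rf <- buildTaxonRanges(applySelectionFilters(y, "family"), "family")
  expect_equal(rangeTaxa(rf), "Famone")
  expect_equal(rf@nDropped, 1L)
})

test_that("selection filters enforce rank-specific open-nomenclature rules", {
  x <- makeRecords(c("Lepidopteris sp.", "?Lepidopteris martinsii",
                     "Lepidopteris martinsii"),
                   stage = "Changhsingian")
  sp <- applySelectionFilters(x, "species")
  expect_equal(occurrenceRecords(sp)$record_id, "rec000003")
  gen <- applySelectionFilters(x, "genus")
  # "Lepidopteris sp." kept at genus rank, "?Lepidopteris" dropped
  expect_setequal(occurrenceRecords(gen)$record_id,
                  c("rec000001", "rec000003"))
})

test_that("reworked sporomorphs are excluded at every rank; macrofossils kept", {
  x <- makeRecords(c("Lundbladispora spA", "Densoisporites spB", "Voltzia spC"),
                   stage = "Induan",
                   class = c("sporomorph", "sporomorph", "macrofossil"),
                   reworked = c("possibly-reworked", "no", "reworked"))
  for (rk in c("species", "genus", "family")) {
    f <- applySelectionFilters(x, rk)
    expect_false("rec000001" %in% occurrenceRecords(f)$record_id)
    expect_true("rec000003" %in% occurrenceRecords(f)$record_id)
  }
})

test_that("unresolved stages are dropped while sentinel stages are retained", {
  x <- makeRecords(paste("Genus", letters[1:3]),
                   stage = c("unresolved", "pre-interval", "Ladinian"))
  f <- applySelectionFilters(x, "genus")
  expect_setequal(occurrenceRecords(f)$stage, c("pre-interval", "Ladinian"))
  log <- provenanceLog(f)
  expect_equal(log$removed[log$step == "drop_unresolved_stage"], 1L)
})

test_that("filtering is idempotent and provenance counts reconcile", {
  set.seed(7)
  pool <- c("Alpha sp.", "Beta bea", "?Gamma gam", "Delta dea")
  x <- makeRecords(sample(pool, 30, replace = TRUE),
                   stage = sample(c(stageNames(defaultStageScale()),
                                    "unresolved"), 30, replace = TRUE),
                   reworked = sample(c("no", "reworked"), 30, replace = TRUE),
                   class = sample(c("macrofossil", "sporomorph"), 30,
                                  replace = TRUE))
  f1 <- applySelectionFilters(x, "species")
  f2 <- applySelectionFilters(f1, "species")
  expect_equal(occurrenceRecords(f2), occurrenceRecords(f1))
  log <- provenanceLog(f2)
  expect_equal(log$n_after[1] - sum(log$removed), nrow(occurrenceRecords(f2)))
  expect_equal(sum(provenanceLog(f2)$removed[-seq_len(nrow(provenanceLog(f1)))]), 0)
})

test_that("round-tripping a record set through disk preserves the records", {
  x <- makeRecords(c("Alpha aa", "Beta sp."), stage = c("Induan", "Anisian"))
  path <- withr::local_tempfile(fileext = ".csv")
  writeOccurrenceTable(x, path)
  y <- readOccurrenceTable(path, schemaConfig = list(
    taxon = "__absent__", genus = "genus_name", species = "species_epithet",
    group = "higher_group", class = "fossil_class"))
  expect_equal(occurrenceRecords(y)$genus_name,
               occurrenceRecords(x)$genus_name)
  expect_equal(occurrenceRecords(y)$stage, occurrenceRecords(x)$stage)
})
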