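## End-to-end orchestration: read -> normalize -> filter -> ranges ->
## stage table -> subsampling -> correlations, per rank x group slice,
## with deterministic seeding and auditable exports.

#' Assemble and validate an analysis configuration
#'
#' @param occurrences path to a delimited occurrence table, or an
#'   \linkS4class{OccurrenceRecordSet}.
#' @param stageScale a \linkS4class{StageScale}.
#' @param synonymy,families optional paths to two-column mapping tables
#'   (from,to) and (genus,family), or data.frames.
#' @param ranks rank levels to analyse, subset of
#'   \code{c("species", "genus", "family")}.
#' @param groupBy optional record column to slice by (e.g.
#'   \code{"fossil_class"} or \code{"higher_group"}); every slice is
#'   analysed separately, in addition to the pooled \code{"all"} slice.
#' @param schemaConfig column mapping for \code{\link{readOccurrenceTable}}.
#' @param reworkedClasses fossil classes subject to the reworked filter.
#' @param wSingle single-bin taxon weight for normalized diversity (0 or 1).
#' @param sqsSettings an \code{\link{sqsConfig}} (its seed is overridden by
#'   the master seed), or \code{NULL} to skip subsampling.
#' @param seed master seed; every random substream derives from it.
#' @return list of class \code{analysis_config}.
#' @export
analysisConfig <- function(occurrences, stageScale = defaultStageScale(),
                           synonymy = NULL, families = NULL,
                           ranks = "genus", groupBy = NULL,
                           schemaConfig = list(),
                           reworkedClasses = "sporomorph",
                           wSingle = 1, sqsSettings = sqsConfig(),
                           seed = 1L) {
  bad <- setdiff(ranks, c("species", "genus", "family"))
  if (length(bad))
    stop("config error in field 'ranks': unknown rank ", paste(bad, collapse = ", "))
  if (!wSingle %in% c(0, 1))
    stop("config error in field 'wSingle': must be 0 or 1")
  readMap <- function(p) {
    if (is.null(p) || is.data.frame(p)) return(p)
    if (!file.exists(p)) stop("config error: mapping file not found: ", p)
    utils::read.csv(p, stringsAsFactors = FALSE)
  }
  structure(list(occurrences = occurrences, stageScale = stageScale,
                 synonymy = readMap(synonymy), families = readMap(families),
                 ranks = ranks, groupBy = groupBy,
                 schemaConfig = schemaConfig,
                 reworkedClasses = reworkedClasses, wSingle = wSingle,
                 sqsSettings = sqsSettings, seed = as.integer(seed)),
            class = "analysis_config")
}

.configHash <- function(config) {
  f <- tempfile()
  on.exit(unlink(f))
  ## hash the deparsed configuration (paths, parameters, seed), not object
  ## addresses, so identical configurations hash identically
  writeLines(deparse(config[setdiff(names(config), "occurrences")]), f)
  unname(tools::md5sum(f))
}

#' Run the full diversity analysis
#'
#' Reads (if needed), normalizes and then, for every requested rank and
#' group slice: applies the selection filters, builds ranges, computes the
#' stage diversity table, runs shareholder quorum subsampling, and tests
#' the Spearman correlation of the per-stage entry counts against the
#' sampled-in-bin richness. Empty slices are logged and skipped, never
#' fatal. Deterministic under a fixed seed.
#'
#' @param config an \code{\link{analysisConfig}}.
#' @return list of class \code{result_bundle}: \code{stageTables},
#'   \code{sqsResults} (named \code{"<rank>.<group>"}),
#'   \code{correlations} (data.frame), \code{provenance}, \code{skipped},
#'   \code{seed}, \code{configHash}.
#' @export
runAnalysis <- function(config) {
  stopifnot(inherits(config, "analysis_config"))
  base <- if (is(config$occurrences, "OccurrenceRecordSet")) config$occurrences
          else readOccurrenceTable(config$occurrences, config$schemaConfig,
                                   config$stageScale)
  base <- normalizeTaxonomy(base, config$synonymy, config$families)
  if ("family" %in% config$ranks && all(base@records$family == ""))
    stop("config error in field 'families': family rank requested but no ",
         "family column or family map supplies family assignments")

  groups <- "all"
  if (!is.null(config$groupBy)) {
    if (!config$groupBy %in% names(base@records))
      stop("config error in field 'groupBy': no record column ",
           config$groupBy)
    groups <- c("all", sort(unique(base@records[[config$groupBy]])))
  }

  stageTables <- list()
  sqsResults <- list()
  corr <- list()
  skipped <- character(0)
  set.seed(config$seed)
  sliceSeeds <- sample.int(2^30, length(config$ranks) * length(groups))
  i <- 0L
  for (rank in config$ranks) {
    for (g in groups) {
      i <- i + 1L
      label <- paste(rank, g, sep = ".")
      slice <- base
      if (g != "all") {
        keep <- slice@records[[config$groupBy]] == g
        slice@records <- slice@records[keep, , drop = FALSE]
        slice <- .logStep(slice, "slice_group", sum(!keep),
                          sprintf("%s == %s", config$groupBy, g))
      }
      slice <- applySelectionFilters(slice, rank, config$reworkedClasses)
      ranges <- buildTaxonRanges(slice, rank)
      if (length(rangeTaxa(ranges)) == 0) {
        warning("slice ", label, " is empty after filtering; skipped")
        skipped <- c(skipped, label)
        next
      }
      tab <- computeStageTable(slice, ranges, config$wSingle)
      stageTables[[label]] <- tab
      if (!is.null(config$sqsSettings)) {
        cfg <- config$sqsSettings
        cfg$seed <- sliceSeeds[i]
        sqsResults[[label]] <- sqs(slice, rank, cfg)
      }
      ent <- entriesPerStage(slice)
      ct <- tryCatch(spearmanTrend(as.numeric(ent), tab$sib),
                     error = function(e) NULL)
      if (!is.null(ct))
        corr[[label]] <- data.frame(slice = label,
                                    pair = "entries_vs_sib",
                                    r_s = ct$r_s, p = ct$p, n = ct$n,
                                    strong = ct$strong,
                                    significant = ct$significant,
                                    stringsAsFactors = FALSE)
    }
  }
  structure(list(stageTables = stageTables, sqsResults = sqsResults,
                 correlations = if (length(corr)) do.call(rbind, corr)
                                else NULL,
                 provenance = provenanceLog(base), skipped = skipped,
                 seed = config$seed, configHash = .configHash(config)),
            class = "result_bundle")
}

#' Export a result bundle as delimited tables plus a manifest
#'
#' Writes one CSV per stage table, subsampling table and the correlation
#' table, each headed by a comment line carrying the seed and configuration
#' hash, plus a JSON manifest (files, seed, hash, package version, input
#' hashes). Refuses to overwrite a non-empty directory unless
#' \code{force = TRUE}; partial writes are cleaned up on failure.
#'
#' @param bundle a \code{result_bundle} from \code{\link{runAnalysis}}.
#' @param dir output directory (created if absent).
#' @param force overwrite existing files.
#' @param inputPaths optional character vector of input files to hash into
#'   the manifest.
#' @return invisibly, the written file paths.
#' @export
exportBundle <- function(bundle, dir, force = FALSE, inputPaths = NULL) {
  stopifnot(inherits(bundle, "result_bundle"))
  if (dir.exists(dir) && length(list.files(dir)) > 0 && !force)
    stop("output directory ", dir, " is not empty; use force = TRUE")
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  written <- character(0)
  ok <- FALSE
  on.exit(if (!ok) unlink(written))
  stamp <- sprintf("# strataDiv seed=%d config=%s", bundle$seed,
                   bundle$configHash)
  writeOne <- function(tab, name) {
    path <- file.path(dir, paste0(name, ".csv"))
    con <- file(path, "w")
    writeLines(stamp, con)
    utils::write.csv(tab, con, row.names = FALSE)
    close(con)
    written <<- c(written, path)
    path
  }
  for (nm in names(bundle$stageTables))
    writeOne(bundle$stageTables[[nm]], paste0("diversity_", nm))
  for (nm in names(bundle$sqsResults))
    writeOne(bundle$sqsResults[[nm]], paste0("sqs_", nm))
  if (!is.null(bundle$correlations))
    writeOne(bundle$correlations, "correlations")
  writeOne(bundle$provenance, "provenance")
  manifest <- list(
    package = "strataDiv",
    version = as.character(utils::packageVersion("strataDiv")),
    seed = bundle$seed, config_hash = bundle$configHash,
    skipped_slices = bundle$skipped,
    files = basename(written),
    input_hashes = if (!is.null(inputPaths))
      as.list(tools::md5sum(inputPaths)) else NULL)
  mpath <- file.path(dir, "manifest.json")
  jsonlite::write_json(manifest, mpath, auto_unbox = TRUE, pretty = TRUE,
                       null = "null")
  written <- c(written, mpath)
  ok <- TRUE
  invisible(written)
}

#' @export
print.result_bundle <- function(x, ...) {
  cat(sprintf("strataDiv result bundle: %d stage tables, %d SQS tables (seed %d, config %s)\n",
              length(x$stageTables), length(x$sqsResults), x$seed,
              substr(x$configHash, 1, 8)))
  if (length(x$skipped))
    cat("  skipped slices:", paste(x$skipped, collapse = ", "), "\n")
  invisible(x)
}
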