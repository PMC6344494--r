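## Ingestion, taxonomic normalization and selection filtering of long-format
## occurrence tables. The pipeline order is fixed: read -> normalize ->
## filter (recorded in the provenance log).

.emptyProvenance <- function() {
  data.frame(step = character(0), removed = integer(0),
             n_after = integer(0), detail = character(0),
             stringsAsFactors = FALSE)
}

.logStep <- function(x, step, removed, detail = "") {
  x@provenance <- rbind(x@provenance, data.frame(
    step = step, removed = as.integer(removed),
    n_after = nrow(x@records), detail = detail, stringsAsFactors = FALSE))
  x
}

#' Access the records, provenance log or stage scale of a record set
#'
#' @param x an \linkS4class{OccurrenceRecordSet}.
#' @return \code{occurrenceRecords}: the canonical records data.frame;
#'   \code{provenanceLog}: the log of applied transformations;
#'   \code{recordStageScale}: the bound \linkS4class{StageScale}.
#' @export
occurrenceRecords <- function(x) x@records

#' @rdname occurrenceRecords
#' @export
provenanceLog <- function(x) x@provenance

#' @rdname occurrenceRecords
#' @export
recordStageScale <- function(x) x@stageScale

setMethod("show", "OccurrenceRecordSet", function(object) {
  rec <- object@records
  in_int <- sum(rec$stage %in% stageNames(object@stageScale))
  cat(sprintf(paste0("OccurrenceRecordSet: %d records ",
                     "(%d in-interval, %d sentinel) on %d stages\n"),
              nrow(rec), in_int, nrow(rec) - in_int,
              nStages(object@stageScale)))
  cat(sprintf("  provenance: %s\n",
              paste(object@provenance$step, collapse = " -> ")))
})

#' Parse a taxon-name string into genus, epithet and qualifiers
#'
#' Splits strings such as \code{"Lepidopteris sp."},
#' \code{"?Lepidopteris martinsii"} or \code{"Lepidopteris cf. martinsii"}
#' into a genus name, a species epithet and open-nomenclature qualifiers.
#' Recognized qualifier tokens are \code{sp.}, \code{spp.}, \code{cf.},
#' \code{aff.}, \code{?} and \code{ex gr.}; any other abbreviated
#' (period-terminated) lowercase token is treated as
#' \code{other-open-nomenclature}. A qualifier placed before the genus name
#' (e.g. a leading \code{?} or \code{cf.}) marks a tentative generic
#' assignment (\code{qualifier_position = "genus-level"}); a qualifier after
#' the genus applies at species level.
#'
#' @param x character vector of taxon-name strings.
#' @return data.frame with columns \code{genus}, \code{epithet},
#'   \code{qualifiers} (semicolon-joined tokens, \code{""} if none) and
#'   \code{qualifier_position} (\code{"genus-level"}, \code{"species-level"}
#'   or \code{"none"}).
#' @examples
#' parseTaxonName(c("Lepidopteris sp.", "?Lepidopteris martinsii"))
#' @export
parseTaxonName <- function(x) {
  if (length(x) == 0)
    return(data.frame(genus = character(0), epithet = character(0),
                      qualifiers = character(0),
                      qualifier_position = character(0),
                      stringsAsFactors = FALSE))
  do.call(rbind, lapply(as.character(x), .parseOneTaxonName))
}

.parseOneTaxonName <- function(s) {
  s <- gsub("\\s+", " ", trimws(s))
  genus <- ""
  epithet <- ""
  quals <- character(0)
  pos <- "none"
  seen_genus <- FALSE
  toks <- if (nzchar(s)) strsplit(s, " ", fixed = TRUE)[[1]] else character(0)
  ## split a glued leading "?" into its own token
  expand <- function(tok) {
    if (nchar(tok) > 1 && startsWith(tok, "?")) c("?", substring(tok, 2))
    else tok
  }
  toks <- unlist(lapply(toks, expand))
  i <- 1
  while (i <= length(toks)) {
    tok <- toks[i]
    bare <- tolower(sub("\\.+$", "", tok))
    qual <- NA_character_
    if (bare == "?") qual <- "question"
    else if (bare %in% c("sp", "spp", "cf", "aff")) qual <- bare
    else if (bare == "ex" && i < length(toks) &&
             tolower(sub("\\.+$", "", toks[i + 1])) == "gr") {
      qual <- "ex_gr"
      i <- i + 1
    } else if (grepl("\\.$", tok) && !grepl("^[A-Z]", tok)) {
      ## unknown abbreviated token: open nomenclature of unknown kind
      qual <- "other-open-nomenclature"
    }
    if (!is.na(qual)) {
      quals <- c(quals, qual)
      new_pos <- if (seen_genus) "species-level" else "genus-level"
      ## genus-level dominates: a tentative genus makes the whole name tentative
      if (pos != "genus-level") pos <- new_pos
    } else if (!seen_genus && grepl("^[A-Z]", tok)) {
      genus <- tok
      seen_genus <- TRUE
    } else if (seen_genus && epithet == "" && grepl("^[a-z]", tok)) {
      epithet <- sub("\\.+$", "", tok)
    }
    i <- i + 1
  }
  data.frame(genus = genus, epithet = epithet,
             qualifiers = paste(unique(quals), collapse = ";"),
             qualifier_position = if (length(quals)) pos else "none",
             stringsAsFactors = FALSE)
}

.normalizeReworked <- function(v) {
  v <- tolower(trimws(as.character(v)))
  out <- rep(NA_character_, length(v))
  out[v %in% c("", "no", "n", "false", "0", "none", "na")] <- "no"
  out[v %in% c("reworked", "yes", "y", "true", "1")] <- "reworked"
  out[v %in% c("possibly-reworked", "possibly reworked", "possible",
               "possibly", "?reworked", "reworked?")] <- "possibly-reworked"
  if (anyNA(out))
    stop("unrecognized 'reworked' values: ",
         paste(unique(v[is.na(out)]), collapse = ", "))
  out
}

#' Default logical-to-physical column mapping for occurrence tables
#'
#' @return named list mapping logical field names to expected column headers
#'   (matched case-insensitively).
#' @export
defaultSchemaConfig <- function() {
  list(record_id = "record_id", taxon = "taxon", genus = "genus",
       species = "species", rank = "rank", group = "group",
       class = "class", stage = "stage", reference_id = "reference_id",
       sample_id = "sample_id", reworked = "reworked", family = "family",
       qualifiers = "qualifiers", qualifier_position = "qualifier_position")
}

#' Read a delimited occurrence table into a validated record set
#'
#' Reads a CSV or TSV file (delimiter sniffed from the header line, headers
#' matched case-insensitively), parses taxon-name strings into genus, epithet
#' and open-nomenclature qualifiers, validates stage labels against the
#' stage scale plus the sentinel labels, and initializes the provenance log.
#'
#' Required logical columns: \code{taxon} (or \code{genus} and optionally
#' \code{species}), \code{group}, \code{class}, \code{stage},
#' \code{reference_id}, \code{sample_id}. Optional: \code{record_id},
#' \code{rank} (derived from the parsed name when absent), \code{reworked}
#' (defaults to \code{"no"}), \code{family}, pre-parsed \code{qualifiers} and
#' \code{qualifier_position}.
#'
#' @param path path to a delimited text file with a header row.
#' @param schemaConfig named list mapping logical fields to column headers;
#'   see \code{\link{defaultSchemaConfig}}. Partial lists override defaults.
#' @param stageScale a \linkS4class{StageScale}; defaults to
#'   \code{\link{defaultStageScale}()}.
#' @return an \linkS4class{OccurrenceRecordSet}.
#' @export
readOccurrenceTable <- function(path, schemaConfig = list(),
                                stageScale = defaultStageScale()) {
  if (!file.exists(path)) stop("file not found: ", path)
  schema <- utils::modifyList(defaultSchemaConfig(), schemaConfig)
  header <- readLines(path, n = 1L)
  sep <- if (grepl("\t", header, fixed = TRUE)) "\t" else ","
  tab <- utils::read.table(path, header = TRUE, sep = sep, quote = "\"",
                           stringsAsFactors = FALSE, check.names = FALSE,
                           comment.char = "", colClasses = "character")
  occurrenceRecordSet(tab, schemaConfig = schema, stageScale = stageScale)
}

#' Build a record set from an in-memory data.frame
#'
#' Same semantics as \code{\link{readOccurrenceTable}} but starting from a
#' data.frame (used by the synthetic-record generator and tests).
#'
#' @param tab data.frame of raw occurrence rows.
#' @inheritParams readOccurrenceTable
#' @return an \linkS4class{OccurrenceRecordSet}.
#' @export
occurrenceRecordSet <- function(tab, schemaConfig = list(),
                                stageScale = defaultStageScale()) {
  schema <- utils::modifyList(defaultSchemaConfig(), schemaConfig)
  lower <- tolower(trimws(names(tab)))
  ## the package's own output dialect is readable without a schema config
  canonical <- c(group = "higher_group", class = "fossil_class",
                 genus = "genus_name", species = "species_epithet")
  col <- function(field) {
    i <- match(tolower(schema[[field]]), lower)
    if (is.na(i) && field %in% names(canonical))
      i <- match(canonical[[field]], lower)
    if (is.na(i)) NULL else trimws(tab[[i]])
  }
  required <- c("group", "class", "stage", "reference_id", "sample_id")
  for (f in required)
    if (is.null(col(f)))
      stop("schema error: required column '", schema[[f]],
           "' (field ", f, ") not found")

  n <- nrow(tab)
  if (!is.null(col("taxon"))) {
    parsed <- parseTaxonName(col("taxon"))
  } else if (!is.null(col("genus"))) {
    gname <- col("genus")
    ep <- if (!is.null(col("species"))) col("species") else rep("", n)
    parsed <- data.frame(genus = gname, epithet = ep,
                         qualifiers = rep("", n),
                         qualifier_position = rep("none", n),
                         stringsAsFactors = FALSE)
  } else {
    stop("schema error: required column '", schema$taxon,
         "' (field taxon; or '", schema$genus, "') not found")
  }
  if (!is.null(col("qualifiers"))) {
    parsed$qualifiers <- col("qualifiers")
    qp <- col("qualifier_position")
    parsed$qualifier_position <-
      if (!is.null(qp)) qp
      else ifelse(nzchar(parsed$qualifiers), "species-level", "none")
  }

  rank <- if (!is.null(col("rank"))) {
    r <- tolower(col("rank"))
    r[r %in% c("family", "family-only")] <- "family-only"
    r
  } else {
    ifelse(parsed$epithet != "", "species",
           ifelse(parsed$genus != "", "genus", "family-only"))
  }
  bad_rank <- !rank %in% c("species", "genus", "family-only")
  if (any(bad_rank))
    stop("validation error: unknown rank value(s): ",
         paste(unique(rank[bad_rank]), collapse = ", "))

  rid <- if (!is.null(col("record_id"))) col("record_id")
         else sprintf("rec%06d", seq_len(n))
  if (anyDuplicated(rid))
    stop("validation error: duplicate record_id: ",
         paste(utils::head(unique(rid[duplicated(rid)]), 5), collapse = ", "))

  stage <- col("stage")
  ok <- stage %in% c(stageNames(stageScale), .sentinelStages)
  if (!all(ok))
    stop("validation error: unknown stage label(s) in rows ",
         paste(utils::head(which(!ok), 10), collapse = ", "), ": ",
         paste(utils::head(unique(stage[!ok]), 5), collapse = ", "))

  rec <- data.frame(
    record_id = rid,
    genus_name = parsed$genus,
    species_epithet = parsed$epithet,
    qualifiers = parsed$qualifiers,
    qualifier_position = parsed$qualifier_position,
    rank = rank,
    higher_group = col("group"),
    fossil_class = tolower(col("class")),
    stage = stage,
    reference_id = col("reference_id"),
    sample_id = col("sample_id"),
    reworked = if (!is.null(col("reworked"))) .normalizeReworked(col("reworked"))
               else rep("no", n),
    family = if (!is.null(col("family"))) col("family") else rep("", n),
    stringsAsFactors = FALSE)

  x <- new("OccurrenceRecordSet", records = rec, stageScale = stageScale,
           provenance = .emptyProvenance())
  .logStep(x, "read", 0L, sprintf("%d records ingested", n))
}

#' Apply synonymy and family mapping tables
#'
#' Replaces genus names and full binomials by their accepted names using a
#' user-supplied two-column synonymy table, and fills empty \code{family}
#' fields from a genus-to-family table. Whole-plant merging of biologically
#' connected organ genera is expressed through the same synonymy table
#' (several organ genera mapping to one accepted genus). Unmapped names pass
#' through unchanged. Maps must be pre-resolved: an accepted name may not
#' itself appear as a key (chained a->b, b->c mappings are rejected).
#'
#' @param x an \linkS4class{OccurrenceRecordSet}.
#' @param synonymyMap data.frame with columns \code{from}, \code{to}
#'   (old name -> accepted name; either bare genus names or binomials), or
#'   \code{NULL}.
#' @param familyMap data.frame with columns \code{genus}, \code{family}, or
#'   \code{NULL}.
#' @return the record set with names normalized and the step logged.
#' @export
normalizeTaxonomy <- function(x, synonymyMap = NULL, familyMap = NULL) {
  rec <- x@records
  n_syn <- 0L
  if (!is.null(synonymyMap) && nrow(synonymyMap) > 0) {
    from <- trimws(as.character(synonymyMap[[1]]))
    to <- trimws(as.character(synonymyMap[[2]]))
    if (anyDuplicated(from))
      stop("configuration error: duplicate keys in synonymy map")
    chained <- to %in% from
    if (any(chained))
      stop("configuration error: chained/cyclic synonymy mapping (",
           paste(unique(to[chained]), collapse = ", "),
           " is both an accepted name and a key); pre-resolve the map")
    full <- ifelse(rec$species_epithet != "",
                   paste(rec$genus_name, rec$species_epithet), rec$genus_name)
    i_full <- match(full, from)
    i_gen <- match(rec$genus_name, from)
    hit_full <- !is.na(i_full)
    if (any(hit_full)) {
      acc <- parseTaxonName(to[i_full[hit_full]])
      rec$genus_name[hit_full] <- acc$genus
      rec$species_epithet[hit_full] <-
        ifelse(acc$epithet != "", acc$epithet,
               rec$species_epithet[hit_full])
    }
    hit_gen <- !hit_full & !is.na(i_gen)
    if (any(hit_gen)) {
      acc <- parseTaxonName(to[i_gen[hit_gen]])
      rec$genus_name[hit_gen] <- acc$genus
    }
    n_syn <- sum(hit_full | hit_gen)
  }
  n_fam <- 0L
  if (!is.null(familyMap) && nrow(familyMap) > 0) {
    fg <- trimws(as.character(familyMap[[1]]))
    ff <- trimws(as.character(familyMap[[2]]))
    need <- rec$family == "" & rec$genus_name != ""
    i <- match(rec$genus_name, fg)
    fill <- need & !is.na(i)
    rec$family[fill] <- ff[i[fill]]
    n_fam <- sum(fill)
  }
  n_unmapped <- sum(rec$family == "")
  x@records <- rec
  .logStep(x, "normalize_taxonomy", 0L,
           sprintf("%d synonym replacements; %d families filled; %d records without family",
                   n_syn, n_fam, n_unmapped))
}

#' Apply the selection filters for a given analysis rank
#'
#' Removes, in order and with logged counts: (1) records with
#' \code{stage = "unresolved"} (insufficiently constrained dating; pre- and
#' post-interval records are retained, they only extend ranges); (2) records
#' of the configured fossil classes flagged reworked or possibly reworked
#' (by default sporomorphs only); (3) at species rank, every record carrying
#' any open-nomenclature qualifier; (4) at genus rank, records whose
#' qualifier sits at genus level (tentative generic assignment) --- species-
#' level qualifiers such as \code{sp.} or \code{cf.} before the epithet are
#' retained at genus rank. Filtering is idempotent.
#'
#' @param x an \linkS4class{OccurrenceRecordSet} (normalize first).
#' @param rankLevel one of \code{"species"}, \code{"genus"},
#'   \code{"family"}.
#' @param reworkedClasses fossil classes to which the reworked filter
#'   applies; default \code{"sporomorph"}.
#' @return the filtered record set with every removal logged.
#' @export
applySelectionFilters <- function(x,
                                  rankLevel = c("species", "genus", "family"),
                                  reworkedClasses = "sporomorph") {
  rankLevel <- match.arg(rankLevel)
  drop <- function(x, keep, step) {
    removed <- sum(!keep)
    x@records <- x@records[keep, , drop = FALSE]
    .logStep(x, step, removed, sprintf("rank=%s", rankLevel))
  }
  x <- drop(x, x@records$stage != "unresolved", "drop_unresolved_stage")
  keep <- !(x@records$fossil_class %in% reworkedClasses &
              x@records$reworked %in% c("reworked", "possibly-reworked"))
  x <- drop(x, keep, "drop_reworked")
  if (rankLevel == "species") {
    x <- drop(x, x@records$qualifiers == "", "drop_open_nomenclature")
  } else if (rankLevel == "genus") {
    x <- drop(x, x@records$qualifier_position != "genus-level",
              "drop_genus_level_qualifiers")
  }
  x
}

#' Write a record set back to delimited text
#'
#' @param x an \linkS4class{OccurrenceRecordSet}.
#' @param path output file path; \code{.tsv} extension selects tab delimiting.
#' @return invisibly, the path.
#' @export
writeOccurrenceTable <- function(x, path) {
  sep <- if (grepl("\\.tsv$", path)) "\t" else ","
  utils::write.table(x@records, path, sep = sep, row.names = FALSE,
                     quote = TRUE)
  invisible(path)
}
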