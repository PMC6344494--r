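#' Construct a stage scale
#'
#' @param stageName character, stage names oldest first.
#' @param baseAge,topAge numeric boundary ages in Ma; adjacent stages must
#'   share a boundary (\code{topAge[i] == baseAge[i+1]}).
#' @return a \linkS4class{StageScale}.
#' @examples
#' sc <- stageScale(c("A", "B"), baseAge = c(10, 8), topAge = c(8, 5))
#' stageDurations(sc)
#' @export
stageScale <- function(stageName, baseAge, topAge) {
  new("StageScale", stageName = as.character(stageName),
      baseAge = as.numeric(baseAge), topAge = as.numeric(topAge))
}

#' Default Wuchiapingian--Ladinian stage scale
#'
#' The six stages of the late Permian to Middle Triassic with boundary ages
#' from the 2018/08 International Chronostratigraphic Chart. The Induan is by
#' far the shortest bin (ca. 0.7 Myr versus 2.2--5.2 Myr for the others),
#' which is central to the sampling-bias diagnostics this package supports.
#'
#' @return a \linkS4class{StageScale} with six bins.
#' @export
defaultStageScale <- function() {
  stageScale(
    stageName = c("Wuchiapingian", "Changhsingian", "Induan",
                  "Olenekian", "Anisian", "Ladinian"),
    baseAge = c(259.1, 254.14, 251.902, 251.2, 247.2, 242.0),
    topAge  = c(254.14, 251.902, 251.2, 247.2, 242.0, 237.0))
}

#' @describeIn stageScale stage names, oldest first.
#' @param x a \linkS4class{StageScale}.
#' @export
stageNames <- function(x) x@stageName

#' @describeIn stageScale stage durations in Myr.
#' @export
stageDurations <- function(x) {
  d <- x@baseAge - x@topAge
  names(d) <- x@stageName
  d
}

#' @describeIn stageScale number of stages.
#' @export
nStages <- function(x) length(x@stageName)

setMethod("show", "StageScale", function(object) {
  cat(sprintf("StageScale with %d stages (%.2f-%.2f Ma)\n",
              nStages(object), object@baseAge[1],
              object@topAge[nStages(object)]))
  print(data.frame(stage = object@stageName, base_Ma = object@baseAge,
                   top_Ma = object@topAge,
                   duration_Myr = object@baseAge - object@topAge))
})

#' Sentinel stage labels
#'
#' Labels accepted in the \code{stage} field besides the scale's own bins:
#' \code{"pre-interval"} and \code{"post-interval"} mark occurrences outside
#' the analysed interval (retained to extend taxon ranges), and
#' \code{"unresolved"} marks records without a single-bin assignment
#' (removed by the selection filters).
#'
#' @return character vector of the three sentinel labels.
#' @export
sentinelStages <- function() .sentinelStages
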