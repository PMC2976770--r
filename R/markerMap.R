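#' @include AllGenerics.R
NULL

#' Construct a MarkerMap
#'
#' @param markers character vector of marker names in chromosomal order.
#' @param centromere name (or index) of the centromere-linked marker.
#' @param intervals named list of length-2 character vectors giving the
#'   scored intervals; defaults to all adjacent marker pairs.
#' @param trpAllele parental allele (\code{"P1"} or \code{"P2"}) at the
#'   centromere marker that confers tryptophan prototrophy.
#' @param matingMarker name of the mating-type locus, or \code{NA}.
#' @return a [MarkerMap-class].
#' @examples
#' markerMap(c("A", "B", "C"), centromere = "B")
#' @export
markerMap <- function(markers, centromere,
                      intervals = NULL, trpAllele = "P1",
                      matingMarker = NA) {
  cen <- if (is.character(centromere)) match(centromere, markers)
         else as.integer(centromere)
  if (is.null(intervals)) {
    intervals <- lapply(seq_len(length(markers) - 1L),
                        function(i) markers[c(i, i + 1L)])
    names(intervals) <- vapply(intervals, paste, "", collapse = "-")
  }
  iv <- do.call(rbind, intervals)
  colnames(iv) <- c("left", "right")
  mm <- if (is.na(matingMarker)) NA_integer_
        else if (is.character(matingMarker)) match(matingMarker, markers)
        else as.integer(matingMarker)
  new("MarkerMap", markers = markers, centromere = as.integer(cen),
      intervals = iv, trpAllele = trpAllele, matingMarker = mm)
}

#' Default chromosome III marker map
#'
#' The standard layout used throughout: HML:ADE1 - HIS4 - LEU2 -
#' CEN3:TRP1 - MAT, scoring the three classical intervals HML:ADE1-HIS4,
#' HIS4-LEU2 and LEU2-MAT (the last spans the centromere). TRP1 is
#' centromere-linked and carried on the P1 homolog; MAT is the mating-type
#' locus.
#'
#' @return a [MarkerMap-class].
#' @examples
#' yeastChrIIIMap()
#' @export
yeastChrIIIMap <- function() {
  markerMap(
    markers = c("HML_ADE1", "HIS4", "LEU2", "CEN3_TRP1", "MAT"),
    centromere = "CEN3_TRP1",
    intervals = list(
      `HML_ADE1-HIS4` = c("HML_ADE1", "HIS4"),
      `HIS4-LEU2`     = c("HIS4", "LEU2"),
      `LEU2-MAT`      = c("LEU2", "MAT")),
    trpAllele = "P1",
    matingMarker = "MAT")
}

#' @describeIn markerMap marker names, in order.
#' @param x a MarkerMap (or object carrying one).
#' @export
setMethod("markers", "MarkerMap", function(x) x@markers)

#' @describeIn markerMap the scored intervals (two-column matrix).
#' @export
setMethod("intervals", "MarkerMap", function(x) x@intervals)

#' @describeIn markerMap name of the centromere-linked marker.
#' @export
setMethod("centromereMarker", "MarkerMap", function(x)
  x@markers[x@centromere])

## adjacent-marker (simulation) intervals and their labels
.simIntervals <- function(map) {
  m <- map@markers
  lab <- paste(m[-length(m)], m[-1L], sep = "-")
  structure(cbind(left = m[-length(m)], right = m[-1L]),
            dimnames = list(lab, c("left", "right")))
}

## resolve an interval argument (label or c(left, right)) to marker names
.resolveInterval <- function(map, interval) {
  if (length(interval) == 1L) {
    iv <- map@intervals
    if (!interval %in% rownames(iv))
      stop("unknown interval '", interval, "'; known: ",
           paste(rownames(iv), collapse = ", "))
    interval <- iv[interval, ]
  }
  if (!all(interval %in% map@markers))
    stop("interval endpoints must be markers of the map")
  unname(interval)
}
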