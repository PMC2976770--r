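#' @include tetrad-model.R
NULL

SPORE_COLS <- c("mating", "trp", "hyg", "cyh", "karyotype", "southern")

#' Construct a TetradSet
#'
#' @param spores a spore-level data.frame (four rows per tetrad; see
#'   [TetradSet-class]) or a list of [Tetrad-class] objects.
#' @param map a [MarkerMap-class].
#' @param params list of simulation provenance (optional).
#' @param groundTruth data.frame of simulator labels (optional).
#' @return a [TetradSet-class].
#' @export
tetradSet <- function(spores, map = yeastChrIIIMap(), params = list(),
                      groundTruth = NULL) {
  if (is.list(spores) && !is.data.frame(spores)) {
    spores <- do.call(rbind, lapply(spores, function(tt) {
      data.frame(tetrad_id = tt@id, strain_id = tt@strain,
                 spore_index = 1:4, viable = tt@viable,
                 as.data.frame(tt@alleles),
                 mating = tt@mating, trp = tt@trp, hyg = tt@hyg,
                 cyh = tt@cyh, karyotype = tt@karyotype,
                 southern = tt@southern,
                 stringsAsFactors = FALSE, check.names = FALSE)
    }))
  }
  rownames(spores) <- NULL
  ## keep the four spores of each tetrad contiguous and ordered
  spores <- spores[order(match(spores$tetrad_id, unique(spores$tetrad_id)),
                         spores$spore_index), , drop = FALSE]
  rownames(spores) <- NULL
  new("TetradSet", spores = spores, markerMap = map, params = params,
      groundTruth = if (is.null(groundTruth))
        data.frame() else groundTruth)
}

#' @describeIn tetradSet number of tetrads.
#' @param x a TetradSet.
#' @export
setMethod("length", "TetradSet", function(x)
  length(unique(x@spores$tetrad_id)))

#' @describeIn tetradSet the spore-level data.frame.
#' @export
setMethod("sporeData", "TetradSet", function(x) x@spores)

#' @describeIn tetradSet the simulator ground-truth labels.
#' @export
setMethod("groundTruth", "TetradSet", function(x) x@groundTruth)

#' @describeIn tetradSet the simulation parameter provenance.
#' @export
setMethod("simProvenance", "TetradSet", function(x) x@params)

#' @describeIn tetradSet the marker map.
#' @export
setMethod("markers", "TetradSet", function(x) x@markerMap@markers)

#' @describeIn tetradSet the scored intervals.
#' @export
setMethod("intervals", "TetradSet", function(x) x@markerMap@intervals)

#' @describeIn tetradSet extract one tetrad by id or position.
#' @param i tetrad id (character) or position (numeric).
#' @export
setMethod("[[", "TetradSet", function(x, i) {
  ids <- unique(x@spores$tetrad_id)
  id <- if (is.character(i)) i else ids[i]
  sp <- x@spores[x@spores$tetrad_id == id, , drop = FALSE]
  if (nrow(sp) != 4L) stop("no tetrad '", id, "'")
  sp <- sp[order(sp$spore_index), ]
  tetrad(id = id, strain = sp$strain_id[1L], viable = sp$viable,
         alleles = as.matrix(sp[, x@markerMap@markers, drop = FALSE]),
         mating = sp$mating, trp = sp$trp, hyg = sp$hyg, cyh = sp$cyh,
         karyotype = sp$karyotype, southern = sp$southern,
         map = x@markerMap)
})

#' @describeIn tetradSet subset to selected tetrads (by ids, positions or
#'   a per-tetrad logical).
#' @param j,drop,... ignored.
#' @export
setMethod("[", "TetradSet", function(x, i, j, ..., drop = FALSE) {
  ids <- unique(x@spores$tetrad_id)
  keep <- if (is.character(i)) i else ids[i]
  sp <- x@spores[x@spores$tetrad_id %in% keep, , drop = FALSE]
  gt <- x@groundTruth
  if (nrow(gt)) gt <- gt[gt$tetrad_id %in% keep, , drop = FALSE]
  tetradSet(sp, map = x@markerMap, params = x@params, groundTruth = gt)
})

#' @describeIn tetradSet per-tetrad viable-spore counts (named integer
#'   vector, in sheet order).
#' @export
setMethod("viability", "TetradSet", function(x) {
  v <- matrix(x@spores$viable, nrow = 4L)
  structure(colSums(v), names = unique(x@spores$tetrad_id))
})

## per-tetrad 4 x n matrix of one spore column
.sporeMatrix <- function(x, col) matrix(x@spores[[col]], nrow = 4L)

#' Classify every tetrad of a set for one interval
#'
#' Vectorized equivalent of calling [classifyTetrad()] tetrad by tetrad:
#' four-viable tetrads are scored directly; three-viable tetrads are first
#' completed by Mendelian dead-spore inference (when \code{inferDead});
#' everything else, and any tetrad with missing calls or non-2:2
#' segregation at either flanking marker, is \code{unscorable} with a
#' reason.
#'
#' @param x a [TetradSet-class].
#' @param interval interval label or \code{c(left, right)} marker names.
#' @param inferDead complete three-viable tetrads.
#' @return data.frame with \code{tetrad_id}, \code{strain_id},
#'   \code{nViable}, \code{class} and \code{reason}.
#' @export
classifyTetrads <- function(x, interval, inferDead = TRUE) {
  stopifnot(is(x, "TetradSet"))
  pair <- .resolveInterval(x@markerMap, interval)
  ids <- unique(x@spores$tetrad_id)
  strain <- x@spores$strain_id[match(ids, x@spores$tetrad_id)]
  V <- .sporeMatrix(x, "viable")
  nV <- colSums(V)
  a1 <- .sporeMatrix(x, pair[1L])
  a2 <- .sporeMatrix(x, pair[2L])

  complete <- function(a) {
    ## fill the dead spore of 3-viable tetrads where survivors are 2:1
    idx <- which(nV == 3L)
    for (i in idx) {
      live <- a[V[, i], i]
      if (anyNA(live)) next
      c1 <- sum(live == "P1")
      fill <- if (c1 == 1L) "P1" else if (c1 == 2L) "P2" else NA_character_
      a[!V[, i], i] <- fill
    }
    a
  }
  if (inferDead) { a1 <- complete(a1); a2 <- complete(a2) }

  cls <- rep("unscorable", length(ids))
  reason <- rep(NA_character_, length(ids))
  eligible <- nV == 4L | (inferDead & nV == 3L)
  reason[!eligible] <- sprintf("%d viable spores", nV[!eligible])

  hasNA <- colSums(is.na(a1)) > 0L | colSums(is.na(a2)) > 0L
  reason[eligible & hasNA] <- "missing or non-inferable allele call"
  ok <- eligible & !hasNA

  two1 <- colSums(a1 == "P1", na.rm = TRUE) == 2L
  two2 <- colSums(a2 == "P1", na.rm = TRUE) == 2L
  reason[ok & !(two1 & two2)] <- "non-2:2 segregation"
  ok <- ok & two1 & two2

  nRec <- colSums(a1 != a2, na.rm = TRUE)
  cls[ok & nRec == 0L] <- "PD"
  cls[ok & nRec == 4L] <- "NPD"
  cls[ok & nRec == 2L] <- "TT"
  data.frame(tetrad_id = ids, strain_id = strain, nViable = nV,
             class = cls, reason = reason, stringsAsFactors = FALSE)
}

#' Tally PD/NPD/TT counts for one interval
#'
#' @param x a [TetradSet-class].
#' @param interval interval label or marker pair.
#' @param nViable restrict to tetrads with this many viable spores
#'   (e.g. \code{4} or \code{3}); \code{NULL} counts both four-viable and
#'   inferred three-viable tetrads together.
#' @param inferDead complete three-viable tetrads by Mendelian inference.
#' @return an [IntervalCounts-class].
#' @export
countTetradClasses <- function(x, interval, nViable = NULL,
                               inferDead = TRUE) {
  cl <- classifyTetrads(x, interval, inferDead = inferDead)
  if (!is.null(nViable)) cl <- cl[cl$nViable %in% nViable, , drop = FALSE]
  intervalCounts(sum(cl$class == "PD"), sum(cl$class == "NPD"),
                 sum(cl$class == "TT"))
}

#' @describeIn detectMINondisjunction vectorized over a set: named
#'   logical per tetrad (\code{NA} = undetermined).
#' @export
setMethod("detectMINondisjunction", "TetradSet", function(x) {
  V <- .sporeMatrix(x, "viable")
  m <- .sporeMatrix(x, "mating")
  nV <- colSums(V)
  nonm <- colSums(V & !is.na(m) & m == "nonmater")
  known <- colSums(V & !is.na(m))
  out <- rep(FALSE, ncol(V))
  two <- nV == 2L
  out[two & known < 2L] <- NA
  out[two & known == 2L & nonm == 2L] <- TRUE
  structure(out, names = unique(x@spores$tetrad_id))
})

#' @describeIn classifySisterhood vectorized over a set: named character
#'   per tetrad (\code{NA} for tetrads without exactly two viable spores).
#' @export
setMethod("classifySisterhood", "TetradSet", function(x) {
  V <- .sporeMatrix(x, "viable")
  t <- .sporeMatrix(x, "trp")
  nV <- colSums(V)
  out <- rep(NA_character_, ncol(V))
  for (i in which(nV == 2L)) {
    tv <- t[V[, i], i]
    out[i] <- if (anyNA(tv)) "undetermined"
              else if (tv[1L] == tv[2L]) "sister" else "non-sister"
  }
  structure(out, names = unique(x@spores$tetrad_id))
})
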