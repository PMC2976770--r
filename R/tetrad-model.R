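#' @include markerMap.R
NULL

.unscorable <- function(...) {
  stop(errorCondition(paste0(...),
                      class = c("tetradkit_unscorable", "error")))
}

.precondition <- function(...) {
  stop(errorCondition(paste0(...),
                      class = c("tetradkit_precondition", "error")))
}

#' Construct a Tetrad
#'
#' Builds one tetrad from per-spore calls. Dead spores are scrubbed to
#' all-\code{NA} (a dead spore carries no scorable information). When the
#' tryptophan phenotype is not supplied it is derived from the allele call
#' at the centromere-linked marker (carriers of the map's \code{trpAllele}
#' are prototrophs).
#'
#' @param id,strain identifiers.
#' @param viable logical(4).
#' @param alleles 4 x M matrix (or vector recycled per marker) of
#'   \code{"P1"}/\code{"P2"}/\code{NA} calls; columns in map order.
#' @param mating,trp,hyg,cyh,karyotype,southern character(4) phenotype
#'   calls (tokens: mating \code{a}/\code{alpha}/\code{nonmater}; trp
#'   \code{prototroph}/\code{auxotroph}; drugs \code{R}/\code{S};
#'   karyotype \code{normal}/\code{faster}/\code{slower}; southern
#'   \code{present}/\code{absent}); \code{NA} = unknown.
#' @param map a [MarkerMap-class].
#' @return a [Tetrad-class].
#' @examples
#' m <- yeastChrIIIMap()
#' a <- matrix(rep(c("P1", "P1", "P2", "P2"), 5), 4,
#'             dimnames = list(NULL, markers(m)))
#' tetrad("t1", "WT", rep(TRUE, 4), a, map = m)
#' @export
tetrad <- function(id, strain, viable, alleles,
                   mating = NA, trp = NA, hyg = NA, cyh = NA,
                   karyotype = NA, southern = NA,
                   map = yeastChrIIIMap()) {
  M <- length(map@markers)
  alleles <- matrix(as.character(alleles), nrow = 4L, ncol = M,
                    dimnames = list(NULL, map@markers))
  fix4 <- function(x) rep(as.character(x), length.out = 4L)
  trp <- fix4(trp)
  cenCall <- alleles[, map@centromere]
  derive <- is.na(trp) & !is.na(cenCall)
  trp[derive] <- ifelse(cenCall[derive] == map@trpAllele,
                        "prototroph", "auxotroph")
  viable <- as.logical(viable)
  ## dead spores carry no information
  phen <- list(mating = fix4(mating), trp = trp, hyg = fix4(hyg),
               cyh = fix4(cyh), karyotype = fix4(karyotype),
               southern = fix4(southern))
  if (any(!viable)) {
    alleles[!viable, ] <- NA_character_
    phen <- lapply(phen, function(v) { v[!viable] <- NA_character_; v })
  }
  new("Tetrad", id = as.character(id), strain = as.character(strain),
      viable = viable, alleles = alleles,
      mating = phen$mating, trp = phen$trp, hyg = phen$hyg,
      cyh = phen$cyh, karyotype = phen$karyotype,
      southern = phen$southern, markerMap = map)
}

#' @describeIn tetrad number of viable spores.
#' @param x a Tetrad.
#' @export
setMethod("viability", "Tetrad", function(x) sum(x@viable))

#' Check Mendelian 2:2 segregation at one marker
#'
#' Counts parental alleles among the four spores of a fully viable tetrad
#' and reports whether the marker segregated 2:2. A 3:1 or 4:0 pattern
#' flags non-Mendelian segregation (gene conversion).
#'
#' @param x a [Tetrad-class] with four viable spores.
#' @param marker marker name.
#' @return list with \code{countP1}, \code{countP2} and \code{is2to2}.
#' @examples
#' m <- yeastChrIIIMap()
#' a <- matrix(rep(c("P1", "P1", "P2", "P2"), 5), 4,
#'             dimnames = list(NULL, markers(m)))
#' checkMendelian(tetrad("t1", "WT", rep(TRUE, 4), a, map = m), "HIS4")
#' @export
setMethod("checkMendelian", "Tetrad", function(x, marker) {
  if (!marker %in% x@markerMap@markers)
    stop("unknown marker '", marker, "'")
  if (sum(x@viable) != 4L)
    .precondition("checkMendelian requires four viable spores")
  calls <- x@alleles[, marker]
  if (anyNA(calls))
    .unscorable("missing allele call at ", marker)
  c1 <- sum(calls == "P1")
  list(countP1 = c1, countP2 = 4L - c1, is2to2 = c1 == 2L)
})

#' Infer the dead spore's genotype in a three-viable tetrad
#'
#' Assuming Mendelian 2:2 segregation, the dead spore carries, at each
#' marker, the allele observed only once among the three viable spores.
#' Markers at which the viable spores are 3:0 (or any viable call is
#' missing) cannot be completed and are returned as \code{NA} with a
#' non-inferable flag (3:0 among survivors implies gene conversion).
#'
#' @param x a [Tetrad-class] with exactly three viable spores.
#' @return named character vector of inferred alleles for the dead spore
#'   (\code{NA} where non-inferable), with attribute \code{nonInferable}
#'   (named logical).
#' @export
setMethod("inferDeadSpore", "Tetrad", function(x) {
  if (sum(x@viable) != 3L)
    .precondition("inferDeadSpore requires exactly three viable spores")
  live <- x@alleles[x@viable, , drop = FALSE]
  inferred <- apply(live, 2L, function(a) {
    if (anyNA(a)) return(NA_character_)
    c1 <- sum(a == "P1")
    if (c1 == 1L) "P1" else if (c1 == 2L) "P2" else NA_character_
  })
  nonInf <- is.na(inferred) & !apply(live, 2L, anyNA)
  structure(inferred, nonInferable = nonInf)
})

## internal: completed 4 x M allele matrix, or NULL with a reason
.completedAlleles <- function(x, inferDead = TRUE) {
  nv <- sum(x@viable)
  if (nv == 4L) return(list(alleles = x@alleles, reason = NULL))
  if (nv == 3L && inferDead) {
    a <- x@alleles
    a[!x@viable, ] <- inferDeadSpore(x)
    return(list(alleles = a, reason = NULL))
  }
  list(alleles = NULL,
       reason = sprintf("%d viable spores", nv))
}

#' Classify a tetrad for one interval as PD, NPD or TT
#'
#' For a marker pair segregating 2:2 at both ends, each spore is parental
#' (same parental origin at both markers) or recombinant; four parental
#' spores make a parental ditype (PD), four recombinant a non-parental
#' ditype (NPD), and two of each a tetratype (TT). Three-viable tetrads
#' are completed by [inferDeadSpore()] first. Anything else (missing
#' calls, non-2:2 segregation, fewer than three viable spores) is
#' \code{unscorable}, with the reason attached.
#'
#' @param x a [Tetrad-class].
#' @param interval an interval label of the map, or \code{c(left, right)}
#'   marker names.
#' @param inferDead complete three-viable tetrads by Mendelian inference.
#' @return one of \code{"PD"}, \code{"NPD"}, \code{"TT"},
#'   \code{"unscorable"}; unscorable results carry a \code{reason}
#'   attribute.
#' @export
setMethod("classifyTetrad", "Tetrad",
          function(x, interval, inferDead = TRUE) {
  pair <- .resolveInterval(x@markerMap, interval)
  comp <- .completedAlleles(x, inferDead)
  if (is.null(comp$alleles))
    return(structure("unscorable", reason = comp$reason))
  a1 <- comp$alleles[, pair[1L]]
  a2 <- comp$alleles[, pair[2L]]
  if (anyNA(a1) || anyNA(a2))
    return(structure("unscorable", reason = "missing allele call"))
  if (sum(a1 == "P1") != 2L || sum(a2 == "P1") != 2L)
    return(structure("unscorable", reason = "non-2:2 segregation"))
  nRec <- sum(a1 != a2)
  switch(as.character(nRec),
         "0" = "PD", "4" = "NPD", "2" = "TT",
         structure("unscorable", reason = "inconsistent configuration"))
})

#' Detect meiosis I non-disjunction from mating phenotypes
#'
#' A meiosis in which both chromosome III homologs segregate to the same
#' pole yields two dead nullisomic spores and two viable disomic spores;
#' the disomes carry both MATa and MATalpha and are therefore non-maters
#' (they are also Trp prototrophs, carrying both centromere alleles —
#' reported as corroborating metadata, not required for the call).
#'
#' @param x a [Tetrad-class].
#' @return \code{TRUE} if exactly two spores are viable and both are
#'   non-maters; \code{NA} (undetermined) when a viable spore's mating
#'   phenotype is unknown in a two-viable tetrad; \code{FALSE} otherwise.
#' @export
setMethod("detectMINondisjunction", "Tetrad", function(x) {
  if (sum(x@viable) != 2L) return(FALSE)
  m <- x@mating[x@viable]
  if (anyNA(m)) return(NA)
  all(m == "nonmater")
})

#' Classify the two surviving spores as sisters or non-sisters
#'
#' Sister spores carry the same centromere-linked TRP1 allele: both
#' tryptophan prototrophs or both auxotrophs. Non-sisters differ.
#'
#' @param x a [Tetrad-class] with exactly two viable spores.
#' @return \code{"sister"}, \code{"non-sister"}, or \code{"undetermined"}
#'   when either Trp phenotype is unknown.
#' @export
setMethod("classifySisterhood", "Tetrad", function(x) {
  if (sum(x@viable) != 2L)
    .precondition("classifySisterhood requires exactly two viable spores")
  t <- x@trp[x@viable]
  if (anyNA(t)) return("undetermined")
  if (t[1L] == t[2L]) "sister" else "non-sister"
})
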