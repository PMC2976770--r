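#' @include recomb-stats.R
NULL

#' Construct a ReporterConfig
#'
#' Default coordinates place the HYG-CYH2 cassette upstream of HIS4 and
#' the single HYG cassette downstream of LEU2 on chromosome III.
#'
#' @param cassettePositions numeric(2): coordinates of the upstream
#'   (HYG-CYH2) and downstream (HYG) cassettes.
#' @param cyh2Dominant logical; CYH2 is dominant to cyh2-r.
#' @return a [ReporterConfig-class].
#' @export
reporterConfig <- function(cassettePositions = c(65822, 92654),
                           cyh2Dominant = TRUE) {
  new("ReporterConfig", cassettePositions = as.numeric(cassettePositions),
      cyh2Dominant = cyh2Dominant)
}

#' Drug-resistance segregation pattern of a reporter tetrad
#'
#' @param x a [Tetrad-class] with four viable spores and known Hyg and
#'   Cyh phenotypes.
#' @return list with \code{hyg = c(R, S)} and \code{cyh = c(S, R)}
#'   integer counts.
#' @export
setMethod("segregationPattern", "Tetrad", function(x) {
  if (sum(x@viable) != 4L)
    .precondition("segregationPattern requires four viable spores")
  bad <- which(is.na(x@hyg) | is.na(x@cyh))
  if (length(bad))
    stop("unknown drug phenotype for spore(s) ",
         paste(bad, collapse = ", "), " of tetrad ", x@id)
  list(hyg = c(R = sum(x@hyg == "R"), S = sum(x@hyg == "S")),
       cyh = c(S = sum(x@cyh == "S"), R = sum(x@cyh == "R")))
})

.eventCall <- function(call, hyg, cyh, note = "") {
  new("EventCall", call = call,
      hygRatio = paste(hyg, collapse = ":"),
      cyhRatio = paste(cyh, collapse = ":"),
      note = note)
}

#' Diagnose an unequal-recombination reporter tetrad
#'
#' Decision table over the drug-segregation gate and the physical
#' evidence:
#' \itemize{
#'   \item 3 HygR : 1 HygS with 2 CyhS : 2 CyhR — a reciprocal crossover
#'     between the two cassettes.
#'   \item 2:2 Hyg with 1 CyhS : 3 CyhR — a loss event, disambiguated by
#'     CHEF karyotype and Southern blot: exactly one faster-migrating
#'     chromosome III that has lost the CYH2 insert (and no slower band)
#'     is an intra-chromatid \emph{deletion}; one faster plus one slower
#'     band (deletion + triplication products) is an unequal
#'     sister-chromatid exchange (\emph{usce}); an all-normal karyotype
#'     with the CYH2 insert lost from one chromatid by Southern is a
#'     \emph{gene conversion}.
#'   \item 2:2 Hyg with 2:2 Cyh and a normal karyotype — no event.
#' }
#' Missing or contradictory physical evidence yields \code{ambiguous}
#' with a diagnostic note, never a definite call and never an error.
#'
#' @param x a [Tetrad-class] with four viable spores and scored drug
#'   phenotypes.
#' @param config a [ReporterConfig-class] (layout bookkeeping).
#' @return an [EventCall-class].
#' @export
setMethod("callEvent", "Tetrad", function(x, config = reporterConfig()) {
  pat <- segregationPattern(x)
  hyg <- pat$hyg
  cyh <- pat$cyh
  kar <- x@karyotype
  sou <- x@southern
  nFast <- sum(kar == "faster", na.rm = TRUE)
  nSlow <- sum(kar == "slower", na.rm = TRUE)
  karKnown <- !anyNA(kar)

  if (hyg[["R"]] == 3L && cyh[["S"]] == 2L) {
    if (nFast + nSlow > 0L)
      return(.eventCall("ambiguous", hyg, cyh,
        "aberrant karyotype contradicts a 3:1 Hyg crossover pattern"))
    return(.eventCall("reciprocal_crossover", hyg, cyh,
      "3:1 Hyg with 2:2 Cyh: crossover between the cassettes"))
  }

  if (hyg[["R"]] == 2L && cyh[["S"]] == 2L) {
    if (nFast + nSlow > 0L)
      return(.eventCall("ambiguous", hyg, cyh,
        "size-variant chromosome III without a 1:3 Cyh pattern"))
    return(.eventCall("none", hyg, cyh, "parental segregation"))
  }

  if (hyg[["R"]] == 2L && cyh[["S"]] == 1L) {
    if (!karKnown)
      return(.eventCall("ambiguous", hyg, cyh,
        "karyotype evidence incomplete"))
    if (nFast == 1L && nSlow == 1L)
      return(.eventCall("usce", hyg, cyh,
        "faster (deletion) and slower (triplication) products recovered"))
    if (nFast == 1L && nSlow == 0L) {
      sf <- sou[which(kar == "faster")]
      if (is.na(sf))
        return(.eventCall("ambiguous", hyg, cyh,
          "Southern evidence missing for the faster chromosome III"))
      if (sf == "absent")
        return(.eventCall("deletion", hyg, cyh,
          "single faster chromosome III lacking the CYH2 insert"))
      return(.eventCall("ambiguous", hyg, cyh,
        "faster chromosome III still carries CYH2: contradictory"))
    }
    if (nFast == 0L && nSlow == 0L) {
      if (anyNA(sou))
        return(.eventCall("ambiguous", hyg, cyh,
          "normal karyotype but Southern evidence incomplete"))
      if (sum(sou == "present") == 1L)
        return(.eventCall("gene_conversion", hyg, cyh,
          "normal karyotype; CYH2 insert replaced on one chromatid"))
      return(.eventCall("ambiguous", hyg, cyh,
        "Southern pattern inconsistent with a single-copy loss"))
    }
    return(.eventCall("ambiguous", hyg, cyh,
      sprintf("unexpected karyotype multiset (%d faster, %d slower)",
              nFast, nSlow)))
  }

  .eventCall("ambiguous", hyg, cyh,
    sprintf("segregation pattern %s Hyg / %s Cyh matches no event class",
            paste(hyg, collapse = ":"), paste(cyh, collapse = ":")))
})

#' Tally event calls into a summary row
#'
#' Counts each diagnosis and computes the unequal-recombination
#' percentage, 100 (USCE + deletions) / total, and the gene-conversion
#' percentage, 100 conversions / total. Reciprocal crossovers between
#' the cassettes are tallied but excluded from the unequal-recombination
#' percentage.
#'
#' @param calls list of [EventCall-class] objects (or a character vector
#'   of calls).
#' @param total total number of tetrads dissected (the denominator;
#'   must be at least the number of calls).
#' @return list with \code{counts} (named integer vector over the event
#'   classes), \code{pctUnequal} and \code{pctConversion}.
#' @export
tallyEvents <- function(calls, total) {
  cls <- if (is.character(calls)) calls
         else vapply(calls, function(e) e@call, "")
  if (total < length(cls))
    stop("total must be at least the number of calls")
  bad <- setdiff(unique(cls), EVENT_LEVELS)
  if (length(bad)) stop("unknown event call(s): ", paste(bad, collapse = ", "))
  cnt <- vapply(EVENT_LEVELS, function(l) sum(cls == l), 0L)
  list(counts = cnt,
       total = total,
       pctUnequal = if (total >= 1L)
         eventRate(cnt[["usce"]] + cnt[["deletion"]], total) else 0,
       pctConversion = if (total >= 1L)
         eventRate(cnt[["gene_conversion"]], total) else 0)
}
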