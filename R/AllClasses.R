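#' @import methods
NULL

ALLELE_LEVELS    <- c("P1", "P2")
MATING_LEVELS    <- c("a", "alpha", "nonmater")
TRP_LEVELS       <- c("prototroph", "auxotroph")
DRUG_LEVELS      <- c("R", "S")
KARYOTYPE_LEVELS <- c("normal", "faster", "slower")
SOUTHERN_LEVELS  <- c("present", "absent")
EVENT_LEVELS     <- c("none", "reciprocal_crossover", "deletion", "usce",
                      "gene_conversion", "ambiguous")
DEATH_LEVELS     <- c("none", "random", "ndj", "half_crossover", "entanglement")

.okEnum <- function(x, levels) all(is.na(x) | x %in% levels)

#' MarkerMap: ordered markers along one chromosome
#'
#' Describes the marker layout used to score a cross: marker names in
#' chromosomal order, the index of the centromere-linked marker, the named
#' genetic intervals that are scored (pairs of markers, not necessarily
#' adjacent), which parental allele confers tryptophan prototrophy at the
#' centromere marker, and (optionally) which marker is the mating-type locus.
#'
#' @slot markers character vector of marker names, in chromosomal order.
#' @slot centromere integer index into \code{markers} of the
#'   centromere-linked marker.
#' @slot intervals character matrix with two columns (\code{left},
#'   \code{right}); row names are interval labels.
#' @slot trpAllele \code{"P1"} or \code{"P2"}: the parental allele at the
#'   centromere marker whose carriers are tryptophan prototrophs.
#' @slot matingMarker integer index of the mating-type locus, or
#'   \code{NA} when the cross carries none.
#'
#' @seealso [yeastChrIIIMap()] for the default chromosome III layout.
#' @export
setClass("MarkerMap",
  representation(markers = "character", centromere = "integer",
                 intervals = "matrix", trpAllele = "character",
                 matingMarker = "integer"))

setValidity("MarkerMap", function(object) {
  msg <- character()
  m <- object@markers
  if (length(m) < 2L) msg <- c(msg, "need at least two markers")
  if (anyDuplicated(m)) msg <- c(msg, "marker names must be unique")
  if (length(object@centromere) != 1L || is.na(object@centromere) ||
      object@centromere < 1L || object@centromere > length(m))
    msg <- c(msg, "centromere index out of range")
  iv <- object@intervals
  if (!is.character(iv) || ncol(iv) != 2L)
    msg <- c(msg, "intervals must be a two-column character matrix")
  else {
    if (!all(iv %in% m)) msg <- c(msg, "interval endpoints must be markers")
    if (any(iv[, 1L] == iv[, 2L]))
      msg <- c(msg, "interval endpoints must be distinct")
    if (is.null(rownames(iv))) msg <- c(msg, "intervals must be named")
  }
  if (!object@trpAllele %in% ALLELE_LEVELS)
    msg <- c(msg, "trpAllele must be 'P1' or 'P2'")
  if (!is.na(object@matingMarker) &&
      (object@matingMarker < 1L || object@matingMarker > length(m)))
    msg <- c(msg, "matingMarker index out of range")
  if (length(msg)) msg else TRUE
})

#' Tetrad: the four spores of one meiosis
#'
#' Holds per-spore viability, allele calls at every marker of the
#' associated [MarkerMap-class], and the scored phenotypes (mating type,
#' tryptophan growth, hygromycin and cycloheximide resistance, CHEF-gel
#' karyotype, Southern-blot presence of the CYH2 insert on chromosome III).
#' Dead spores carry no information: all their calls are \code{NA}.
#'
#' @slot id tetrad identifier.
#' @slot strain diploid strain identifier.
#' @slot viable logical(4).
#' @slot alleles 4 x M character matrix of \code{"P1"}/\code{"P2"}/\code{NA}
#'   calls, columns named by marker.
#' @slot mating,trp,hyg,cyh,karyotype,southern character(4) phenotype calls
#'   (see the tetrad sheet dialect in [readTetradSheet()] for the tokens).
#' @slot markerMap the [MarkerMap-class] the allele columns refer to.
#' @export
setClass("Tetrad",
  representation(id = "character", strain = "character", viable = "logical",
                 alleles = "matrix", mating = "character", trp = "character",
                 hyg = "character", cyh = "character",
                 karyotype = "character", southern = "character",
                 markerMap = "MarkerMap"))

setValidity("Tetrad", function(object) {
  msg <- character()
  if (length(object@viable) != 4L || anyNA(object@viable))
    msg <- c(msg, "viable must be logical(4) without NA")
  a <- object@alleles
  if (!is.character(a) || nrow(a) != 4L ||
      !identical(colnames(a), object@markerMap@markers))
    msg <- c(msg, "alleles must be a 4-row matrix with marker columns")
  else if (!.okEnum(a, ALLELE_LEVELS))
    msg <- c(msg, "allele calls restricted to P1/P2/NA")
  for (s in c("mating", "trp", "hyg", "cyh", "karyotype", "southern"))
    if (length(slot(object, s)) != 4L)
      msg <- c(msg, sprintf("%s must have length 4", s))
  if (!.okEnum(object@mating, MATING_LEVELS)) msg <- c(msg, "bad mating call")
  if (!.okEnum(object@trp, TRP_LEVELS)) msg <- c(msg, "bad trp call")
  if (!.okEnum(object@hyg, DRUG_LEVELS)) msg <- c(msg, "bad hyg call")
  if (!.okEnum(object@cyh, DRUG_LEVELS)) msg <- c(msg, "bad cyh call")
  if (!.okEnum(object@karyotype, KARYOTYPE_LEVELS))
    msg <- c(msg, "bad karyotype call")
  if (!.okEnum(object@southern, SOUTHERN_LEVELS))
    msg <- c(msg, "bad southern call")
  if (is.character(a) && nrow(a) == 4L) {
    deadHasData <- !object@viable &
      (rowSums(!is.na(a)) > 0L | !is.na(object@mating) | !is.na(object@trp) |
       !is.na(object@hyg) | !is.na(object@cyh) |
       !is.na(object@karyotype) | !is.na(object@southern))
    if (any(deadHasData))
      msg <- c(msg, "dead spores must have all calls NA")
  }
  if (length(msg)) msg else TRUE
})

#' TetradSet: a sheet of tetrads with its marker map
#'
#' Column-oriented container for a whole dissection experiment (or a
#' simulated dataset): one row per spore, four rows per tetrad, plus the
#' [MarkerMap-class], the simulation parameters that produced it (if any)
#' and the simulator's ground-truth labels (if any).
#'
#' @slot spores data.frame with columns \code{tetrad_id}, \code{strain_id},
#'   \code{spore_index}, \code{viable}, one column per marker, and
#'   \code{mating}, \code{trp}, \code{hyg}, \code{cyh}, \code{karyotype},
#'   \code{southern}.
#' @slot markerMap the [MarkerMap-class].
#' @slot params list of simulation provenance (empty for field data).
#' @slot groundTruth data.frame of per-tetrad simulator labels (zero rows
#'   for field data).
#' @export
setClass("TetradSet",
  representation(spores = "data.frame", markerMap = "MarkerMap",
                 params = "list", groundTruth = "data.frame"))

setValidity("TetradSet", function(object) {
  msg <- character()
  sp <- object@spores
  need <- c("tetrad_id", "strain_id", "spore_index", "viable",
            object@markerMap@markers,
            "mating", "trp", "hyg", "cyh", "karyotype", "southern")
  miss <- setdiff(need, names(sp))
  if (length(miss))
    msg <- c(msg, paste("missing spore columns:", paste(miss, collapse = ", ")))
  else {
    tab <- table(sp$tetrad_id)
    if (length(tab) && any(tab != 4L))
      msg <- c(msg, paste("tetrads without exactly 4 spore rows:",
                          paste(utils::head(names(tab)[tab != 4L], 5L),
                                collapse = ", ")))
    if (nrow(sp) && !all(sp$spore_index %in% 1:4))
      msg <- c(msg, "spore_index must be in 1..4")
  }
  if (length(msg)) msg else TRUE
})

#' IntervalCounts: PD/NPD/TT tallies for one interval
#'
#' @slot PD,NPD,TT non-negative integer counts of parental ditypes,
#'   non-parental ditypes and tetratypes.
#' @export
setClass("IntervalCounts",
  representation(PD = "integer", NPD = "integer", TT = "integer"))

setValidity("IntervalCounts", function(object) {
  v <- c(object@PD, object@NPD, object@TT)
  if (length(v) != 3L || anyNA(v) || any(v < 0L))
    "PD, NPD and TT must be single non-negative integers" else TRUE
})

#' MapDistance: a Perkins map-distance estimate
#'
#' @slot cM point estimate in centimorgans.
#' @slot se multinomial delta-method standard error in centimorgans
#'   (\code{NA} when not computed).
#' @slot n total number of scorable tetrads.
#' @export
setClass("MapDistance",
  representation(cM = "numeric", se = "numeric", n = "integer"))

setValidity("MapDistance", function(object) {
  if (length(object@cM) != 1L || object@cM < 0)
    return("cM must be a single non-negative number")
  if (length(object@se) != 1L || (!is.na(object@se) && object@se < 0))
    return("se must be a single non-negative number or NA")
  if (length(object@n) != 1L || is.na(object@n) || object@n < 1L)
    return("n must be a positive integer")
  TRUE
})

#' TestResult: a G or chi-square test
#'
#' @slot statistic test statistic (G or chi-square).
#' @slot df degrees of freedom.
#' @slot p p-value.
#' @slot p.adjusted Benjamini-Hochberg adjusted p-value, or \code{NA} when
#'   no family-wise adjustment has been applied.
#' @slot method label of the test performed.
#' @export
setClass("TestResult",
  representation(statistic = "numeric", df = "integer", p = "numeric",
                 p.adjusted = "numeric", method = "character"))

setValidity("TestResult", function(object) {
  msg <- character()
  if (object@p < 0 || object@p > 1) msg <- c(msg, "p must be in [0, 1]")
  if (!is.na(object@p.adjusted) &&
      object@p.adjusted < object@p - 1e-12)
    msg <- c(msg, "p.adjusted must be >= p")
  if (object@df < 1L) msg <- c(msg, "df must be >= 1")
  if (length(msg)) msg else TRUE
})

#' EventCall: diagnosis of one reporter tetrad
#'
#' @slot call one of \code{none}, \code{reciprocal_crossover},
#'   \code{deletion}, \code{usce}, \code{gene_conversion}, \code{ambiguous}.
#' @slot hygRatio,cyhRatio the observed segregation ratios, as
#'   \code{"R:S"} and \code{"S:R"} strings.
#' @slot note diagnostic message (why a call is ambiguous, what evidence
#'   supported a definite call).
#' @export
setClass("EventCall",
  representation(call = "character", hygRatio = "character",
                 cyhRatio = "character", note = "character"))

setValidity("EventCall", function(object) {
  if (!object@call %in% EVENT_LEVELS) "unknown event call" else TRUE
})

#' ReporterConfig: layout of the unequal-recombination reporter
#'
#' Two hygromycin-resistance cassettes flank one genetic interval on the
#' reporter parent's chromosome III; the upstream cassette also carries a
#' dominant CYH2 gene (cycloheximide sensitivity) that reports loss events
#' against a resistant cyh2-r background.
#'
#' @slot cassettePositions numeric(2), chromosomal coordinates of the
#'   upstream (HYG-CYH2) and downstream (HYG) cassettes; must be ordered.
#' @slot cyh2Dominant logical; CYH2 is dominant to cyh2-r.
#' @export
setClass("ReporterConfig",
  representation(cassettePositions = "numeric", cyh2Dominant = "logical"))

setValidity("ReporterConfig", function(object) {
  p <- object@cassettePositions
  if (length(p) != 2L || anyNA(p) || p[1L] >= p[2L])
    return("cassettePositions must be two ordered distinct coordinates")
  TRUE
})

#' SimParams: parameterization of the forward meiosis simulator
#'
#' @slot distances numeric vector of true map distances (cM) for each
#'   adjacent-marker interval of the map (length = markers - 1).
#' @slot suppression homeologous suppression factor in (0, 1] multiplying
#'   the effective distances.
#' @slot pNdj0 probability of meiosis I non-disjunction given zero
#'   crossovers on the chromosome.
#' @slot qHalf probability an initiated crossover resolves as a lethal
#'   half-crossover.
#' @slot pEnt probability a meiosis carries an unresolved sister
#'   entanglement distal to the last marker.
#' @slot pDeath per-spore random death probability.
#' @slot rCo,rDel,rUsce,rGc per-meiosis rates of the four reporter event
#'   classes (reciprocal crossover between the cassettes, intra-chromatid
#'   deletion, unequal sister-chromatid exchange, gene conversion).
#' @slot reporter logical; whether the cross carries the reporter construct
#'   (drug phenotypes are emitted only when it does).
#' @slot n number of meioses to simulate.
#' @slot seed RNG seed recorded in the output header (\code{NA} = use the
#'   current RNG state).
#' @slot strain strain label written on every tetrad.
#' @export
setClass("SimParams",
  representation(distances = "numeric", suppression = "numeric",
                 pNdj0 = "numeric", qHalf = "numeric", pEnt = "numeric",
                 pDeath = "numeric", rCo = "numeric", rDel = "numeric",
                 rUsce = "numeric", rGc = "numeric", reporter = "logical",
                 n = "integer", seed = "integer", strain = "character"))

setValidity("SimParams", function(object) {
  msg <- character()
  if (any(object@distances < 0) || anyNA(object@distances))
    msg <- c(msg, "distances must be non-negative")
  if (object@suppression <= 0 || object@suppression > 1)
    msg <- c(msg, "suppression must be in (0, 1]")
  pr <- c(pNdj0 = object@pNdj0, qHalf = object@qHalf, pEnt = object@pEnt,
          pDeath = object@pDeath, rCo = object@rCo, rDel = object@rDel,
          rUsce = object@rUsce, rGc = object@rGc)
  bad <- names(pr)[is.na(pr) | pr < 0 | pr > 1]
  if (length(bad))
    msg <- c(msg, paste("probabilities outside [0, 1]:",
                        paste(bad, collapse = ", ")))
  if (object@rCo + object@rDel + object@rUsce + object@rGc > 1)
    msg <- c(msg, "reporter event rates must sum to at most 1")
  if (is.na(object@n) || object@n < 1L) msg <- c(msg, "n must be >= 1")
  if (length(msg)) msg else TRUE
})

## ---- show methods -------------------------------------------------------

setMethod("show", "MarkerMap", function(object) {
  cat("MarkerMap with", length(object@markers), "markers:",
      paste(object@markers, collapse = " - "), "\n")
  cat("  centromere at", object@markers[object@centromere],
      "(Trp+ allele:", paste0(object@trpAllele, ")"), "\n")
  cat("  scored intervals:", paste(rownames(object@intervals),
                                   collapse = ", "), "\n")
})

setMethod("show", "Tetrad", function(object) {
  cat("Tetrad", object@id, "from strain", object@strain, "-",
      sum(object@viable), "viable spores\n")
  df <- data.frame(viable = object@viable, object@alleles,
                   mating = object@mating, trp = object@trp,
                   hyg = object@hyg, cyh = object@cyh,
                   karyotype = object@karyotype, southern = object@southern,
                   check.names = FALSE)
  print(df)
})

setMethod("show", "TetradSet", function(object) {
  n <- length(unique(object@spores$tetrad_id))
  cat("TetradSet with", n, "tetrads (",
    paste(unique(object@spores$strain_id), collapse = ", "), ")\n")
  if (length(object@params))
    cat("  simulated (seed ", object@params$seed %||% "NA", ")\n", sep = "")
  if (nrow(object@groundTruth)) cat("  ground-truth labels attached\n")
})

setMethod("show", "IntervalCounts", function(object) {
  cat("IntervalCounts: PD =", object@PD, " NPD =", object@NPD,
      " TT =", object@TT, " (total", object@PD + object@NPD + object@TT,
      ")\n")
})

setMethod("show", "MapDistance", function(object) {
  cat(sprintf("Map distance: %.3f cM (SE %s, n = %d tetrads)\n",
              object@cM,
              if (is.na(object@se)) "NA" else sprintf("%.3f", object@se),
              object@n))
})

setMethod("show", "TestResult", function(object) {
  cat(sprintf("%s: statistic = %.4g, df = %d, p = %.4g",
              object@method, object@statistic, object@df, object@p))
  if (!is.na(object@p.adjusted))
    cat(sprintf(", BH-adjusted p = %.4g", object@p.adjusted))
  cat("\n")
})

setMethod("show", "EventCall", function(object) {
  cat("EventCall:", object@call,
      sprintf("[Hyg %s, Cyh %s]", object@hygRatio, object@cyhRatio), "\n")
  if (nzchar(object@note)) cat("  ", object@note, "\n")
})

setMethod("show", "SimParams", function(object) {
  cat("SimParams for", object@n, "meioses (strain", object@strain, ")\n")
  cat("  distances (cM):",
      paste(sprintf("%s=%g", names(object@distances), object@distances),
            collapse = ", "), "\n")
  cat(sprintf("  suppression=%g pNdj0=%g qHalf=%g pEnt=%g pDeath=%g\n",
              object@suppression, object@pNdj0, object@qHalf, object@pEnt,
              object@pDeath))
  if (object@reporter)
    cat(sprintf("  reporter rates: co=%g del=%g usce=%g gc=%g\n",
                object@rCo, object@rDel, object@rUsce, object@rGc))
  cat("  seed:", object@seed, "\n")
})

`%||%` <- function(a, b) if (is.null(a)) b else a
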