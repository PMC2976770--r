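#' @include tetrad-set.R
NULL

#' Construct IntervalCounts
#'
#' @param PD,NPD,TT non-negative integer counts.
#' @return an [IntervalCounts-class].
#' @examples
#' intervalCounts(626, 0, 4)
#' @export
intervalCounts <- function(PD, NPD, TT) {
  v <- c(PD, NPD, TT)
  if (any(v != round(v))) stop("counts must be integers")
  new("IntervalCounts", PD = as.integer(PD), NPD = as.integer(NPD),
      TT = as.integer(TT))
}

#' @describeIn intervalCounts the counts as a named integer vector.
#' @param x an IntervalCounts.
#' @export
setMethod("counts", "IntervalCounts", function(x)
  c(PD = x@PD, NPD = x@NPD, TT = x@TT))

.total <- function(x) x@PD + x@NPD + x@TT

#' Perkins map distance
#'
#' The tetrad-based map-distance estimator
#' \deqn{cM = 100 (TT/2 + 3\,NPD) / (PD + NPD + TT),}
#' which corrects for the double-crossover origin of non-parental ditypes.
#' The value is stored unrounded; round only for display.
#'
#' @param x an [IntervalCounts-class] (or a length-3 numeric
#'   \code{c(PD, NPD, TT)}).
#' @param se also compute the multinomial delta-method standard error
#'   (needs at least two tetrads; see [mapDistanceSE()]).
#' @return a [MapDistance-class].
#' @examples
#' perkinsMapDistance(intervalCounts(611, 1, 19))
#' @export
setMethod("perkinsMapDistance", "IntervalCounts", function(x, se = TRUE) {
  n <- .total(x)
  if (n < 1L) stop("no scorable tetrads")
  cM <- 100 * (x@TT / 2 + 3 * x@NPD) / n
  new("MapDistance", cM = cM,
      se = if (se && n >= 2L) mapDistanceSE(x) else NA_real_,
      n = n)
})

#' @rdname perkinsMapDistance-IntervalCounts-method
#' @export
setMethod("perkinsMapDistance", "numeric", function(x, se = TRUE)
  perkinsMapDistance(intervalCounts(x[1L], x[2L], x[3L]), se = se))

#' Standard error of the Perkins map distance
#'
#' Delta-method standard error under the multinomial sampling model for
#' (PD, NPD, TT). With \eqn{n} tetrads, \eqn{t = TT/n} and
#' \eqn{d = NPD/n},
#' \deqn{se = 100 \sqrt{ \left( t(1-t)/4 + 9 d(1-d) - 3 t d \right) / n }.}
#'
#' @param x an [IntervalCounts-class] with at least two tetrads.
#' @return standard error in centimorgans.
#' @export
setMethod("mapDistanceSE", "IntervalCounts", function(x) {
  n <- .total(x)
  if (n < 2L) stop("standard error needs at least two tetrads")
  t <- x@TT / n
  d <- x@NPD / n
  100 * sqrt((t * (1 - t) / 4 + 9 * d * (1 - d) - 3 * t * d) / n)
})

#' @rdname mapDistanceSE-IntervalCounts-method
#' @export
setMethod("mapDistanceSE", "numeric", function(x)
  mapDistanceSE(intervalCounts(x[1L], x[2L], x[3L])))

.testResult <- function(statistic, df, p, method) {
  new("TestResult", statistic = statistic, df = as.integer(df),
      p = min(1, p), p.adjusted = NA_real_, method = method)
}

#' Likelihood-ratio (G) test of a count table
#'
#' \eqn{G = 2 \sum O \ln(O/E)} over cells with positive observed counts,
#' with expected counts from the row and column margins. Degrees of
#' freedom are \eqn{(r-1)(c-1)} computed on the table as supplied —
#' all-zero columns are retained, so comparing e.g. two (PD, NPD, TT)
#' rows that both lack NPDs still uses df = 2. No Williams or Yates
#' correction is applied.
#'
#' @param x a matrix (or rbind-able rows) of non-negative integer counts
#'   with at least one positive entry in some row and column.
#' @return a [TestResult-class].
#' @examples
#' gTest(rbind(c(626, 0, 4), c(147, 0, 13)))
#' @export
gTest <- function(x) {
  x <- as.matrix(x)
  if (anyNA(x) || any(x < 0) || any(x != round(x)))
    stop("counts must be non-negative integers")
  if (all(rowSums(x) == 0) || all(colSums(x) == 0))
    stop("need at least one positive row and column")
  E <- outer(rowSums(x), colSums(x)) / sum(x)
  G <- 2 * sum(ifelse(x > 0, x * log(x / E), 0))
  df <- (nrow(x) - 1L) * (ncol(x) - 1L)
  .testResult(G, df, stats::pchisq(G, df, lower.tail = FALSE), "G-test")
}

#' Chi-square test of a 50:50 sister : non-sister ratio
#'
#' One-degree-of-freedom goodness-of-fit test of the observed
#' sister/non-sister split against equal frequencies, without continuity
#' correction. A significant deviation toward sisters is the hallmark of
#' meiosis I non-disjunction; toward non-sisters, of the destruction of
#' recombined entangled chromatids.
#'
#' @param sisters,nonsisters observed counts (not both zero).
#' @return a [TestResult-class].
#' @examples
#' chiSquare5050(110, 191)
#' @export
chiSquare5050 <- function(sisters, nonsisters) {
  n <- sisters + nonsisters
  if (n < 1L) stop("need at least one observation")
  e <- n / 2
  x2 <- (sisters - e)^2 / e + (nonsisters - e)^2 / e
  .testResult(x2, 1L, stats::pchisq(x2, 1L, lower.tail = FALSE),
              "chi-square 50:50")
}

#' Benjamini-Hochberg adjustment
#'
#' Standard step-up false-discovery-rate adjustment with monotonicity
#' enforcement, returned in input order.
#'
#' @param p numeric vector of p-values in [0, 1].
#' @return adjusted p-values, same length and order.
#' @export
bhAdjust <- function(p) {
  if (anyNA(p) || any(p < 0 | p > 1))
    stop("p-values must lie in [0, 1]")
  stats::p.adjust(p, method = "BH")
}

#' Pool interval counts after a homogeneity G-test
#'
#' Sums two or more (PD, NPD, TT) count sets and tests their homogeneity
#' with an r x 3 G-test. Pooling is flagged inadmissible (but the pooled
#' counts are still returned) when the homogeneity p-value falls below
#' \code{alpha}.
#'
#' @param countSets list of [IntervalCounts-class] objects (>= 2).
#' @param alpha homogeneity threshold (default 0.05).
#' @return list with \code{pooled} ([IntervalCounts-class]),
#'   \code{homogeneity} ([TestResult-class]) and \code{admissible}
#'   (logical).
#' @export
poolCounts <- function(countSets, alpha = 0.05) {
  if (length(countSets) < 2L) stop("need at least two count sets")
  m <- do.call(rbind, lapply(countSets, counts))
  hom <- gTest(m)
  tot <- colSums(m)
  list(pooled = intervalCounts(tot[1L], tot[2L], tot[3L]),
       homogeneity = hom,
       admissible = hom@p >= alpha)
}

#' Event rate as a percentage
#'
#' @param events,total counts with \code{0 <= events <= total},
#'   \code{total >= 1}.
#' @return \code{100 * events / total}, unrounded.
#' @export
eventRate <- function(events, total) {
  if (total < 1L) stop("total must be at least 1")
  if (events < 0 || events > total)
    stop("events must lie between 0 and total")
  100 * events / total
}

#' Fold change between two map distances
#'
#' @param reference_cM,test_cM map distances in cM; \code{test_cM} must
#'   be positive (a zero divisor means no recombinants were recovered and
#'   the fold reduction is unbounded, returned as \code{Inf} with a
#'   warning).
#' @return \code{reference_cM / test_cM}.
#' @export
foldChange <- function(reference_cM, test_cM) {
  if (test_cM == 0) {
    warning("no recombinants in the test cross; fold change is unbounded")
    return(Inf)
  }
  reference_cM / test_cM
}
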