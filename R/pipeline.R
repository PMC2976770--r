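#' @include io.R
NULL

#' Call reporter events for every four-viable tetrad of a set
#'
#' @param x a [TetradSet-class] whose spores carry Hyg/Cyh phenotypes.
#' @param config a [ReporterConfig-class].
#' @return data.frame with \code{tetrad_id}, \code{strain_id},
#'   \code{call} and \code{note}; tetrads that are not four-viable or
#'   lack drug phenotypes are omitted.
#' @export
callEvents <- function(x, config = reporterConfig()) {
  stopifnot(is(x, "TetradSet"))
  sp <- x@spores
  ids <- unique(sp$tetrad_id)
  V <- .sporeMatrix(x, "viable")
  hygKnown <- colSums(!is.na(.sporeMatrix(x, "hyg"))) == 4L
  cyhKnown <- colSums(!is.na(.sporeMatrix(x, "cyh"))) == 4L
  use <- which(colSums(V) == 4L & hygKnown & cyhKnown)
  out <- vector("list", length(use))
  map <- x@markerMap
  for (k in seq_along(use)) {
    i <- use[k]
    rows <- (4L * (i - 1L) + 1L):(4L * i)
    tt <- tetrad(id = ids[i], strain = sp$strain_id[rows[1L]],
                 viable = sp$viable[rows],
                 alleles = as.matrix(sp[rows, map@markers, drop = FALSE]),
                 mating = sp$mating[rows], trp = sp$trp[rows],
                 hyg = sp$hyg[rows], cyh = sp$cyh[rows],
                 karyotype = sp$karyotype[rows],
                 southern = sp$southern[rows], map = map)
    ec <- callEvent(tt, config)
    out[[k]] <- data.frame(tetrad_id = ids[i],
                           strain_id = sp$strain_id[rows[1L]],
                           call = ec@call, note = ec@note,
                           stringsAsFactors = FALSE)
  }
  if (!length(out))
    return(data.frame(tetrad_id = character(), strain_id = character(),
                      call = character(), note = character()))
  do.call(rbind, out)
}

.mapDistRow <- function(cnt) {
  n <- .total(cnt)
  if (n == 0L)
    return(data.frame(PD = 0L, NPD = 0L, TT = 0L, n = 0L,
                      cM = NA_real_, se = NA_real_))
  md <- perkinsMapDistance(cnt)
  data.frame(PD = cnt@PD, NPD = cnt@NPD, TT = cnt@TT, n = n,
             cM = md@cM, se = md@se)
}

#' Run the full tetrad-analysis pipeline
#'
#' Orchestrates the whole analysis on a tetrad sheet: per strain and
#' interval, PD/NPD/TT counts for the four-viable and (Mendelian
#' dead-spore-inferred) three-viable classes with Perkins distances and
#' standard errors; G-tests of the three- versus four-viable class
#' distributions; cross-strain G-tests against a reference strain;
#' homogeneity-gated pooling of the non-reference strains; meiosis I
#' non-disjunction frequencies; sister/non-sister tallies with the 50:50
#' chi-square; and reporter event tallies. Benjamini-Hochberg correction
#' is applied within each comparison family (one family per result
#' table). Every excluded tetrad is logged with its reason so
#' denominators are auditable.
#'
#' @param x a [TetradSet-class] or the path of a tetrad sheet.
#' @param referenceStrain strain the others are compared against
#'   (default: the first in the sheet).
#' @param homogeneityAlpha G-test threshold below which pooling is
#'   flagged inadmissible.
#' @param inferDead complete three-viable tetrads by Mendelian
#'   inference.
#' @param events run the reporter event classifier (skipped
#'   automatically when no drug phenotypes are present).
#' @return list of data.frames (class \code{tetradReport}):
#'   \code{viability}, \code{mapDistances}, \code{threeVsFour},
#'   \code{strainComparisons}, \code{pooling}, \code{ndj},
#'   \code{sisterhood}, \code{events}, \code{exclusions}.
#' @export
runPipeline <- function(x, referenceStrain = NULL,
                        homogeneityAlpha = 0.05, inferDead = TRUE,
                        events = TRUE) {
  if (is.character(x)) x <- readTetradSheet(x)
  stopifnot(is(x, "TetradSet"))
  sp <- x@spores
  strains <- unique(sp$strain_id)
  if (is.null(referenceStrain)) referenceStrain <- strains[1L]
  ivs <- rownames(x@markerMap@intervals)
  bySt <- lapply(strains, function(s)
    x[unique(sp$tetrad_id[sp$strain_id == s])])
  names(bySt) <- strains

  ## viability spectrum -----------------------------------------------
  viab <- do.call(rbind, lapply(strains, function(s) {
    nv <- viability(bySt[[s]])
    data.frame(strain = s, total = length(nv),
               v0 = sum(nv == 0), v1 = sum(nv == 1), v2 = sum(nv == 2),
               v3 = sum(nv == 3), v4 = sum(nv == 4),
               pctTwoViable = 100 * mean(nv == 2))
  }))

  ## map distances and 3- vs 4-viable comparison ----------------------
  md <- list(); tvf <- list(); excl <- list()
  for (s in strains) for (iv in ivs) {
    cl <- classifyTetrads(bySt[[s]], iv, inferDead = inferDead)
    bad <- cl[cl$class == "unscorable" & cl$nViable >= 3L, ]
    if (nrow(bad))
      excl[[length(excl) + 1L]] <-
        data.frame(strain = s, interval = iv, tetrad_id = bad$tetrad_id,
                   reason = bad$reason)
    cnt <- function(nv) {
      k <- cl[cl$nViable == nv & cl$class != "unscorable", ]
      intervalCounts(sum(k$class == "PD"), sum(k$class == "NPD"),
                     sum(k$class == "TT"))
    }
    c4 <- cnt(4L); c3 <- cnt(3L)
    md[[length(md) + 1L]] <- cbind(
      data.frame(strain = s, interval = iv, class = c("4-viable", "3-viable")),
      rbind(.mapDistRow(c4), .mapDistRow(c3)))
    if (.total(c4) > 0L && .total(c3) > 0L) {
      g <- gTest(rbind(counts(c4), counts(c3)))
      tvf[[length(tvf) + 1L]] <-
        data.frame(strain = s, interval = iv, G = g@statistic,
                   df = g@df, p = g@p)
    }
  }
  md <- do.call(rbind, md)
  tvf <- if (length(tvf)) do.call(rbind, tvf) else NULL
  if (!is.null(tvf)) tvf$p.adjusted <- bhAdjust(tvf$p)

  ## cross-strain comparisons (both viability classes combined) -------
  combined <- function(s, iv)
    countTetradClasses(bySt[[s]], iv, nViable = 3:4, inferDead = inferDead)
  cmp <- list()
  for (s in setdiff(strains, referenceStrain)) for (iv in ivs) {
    cr <- combined(referenceStrain, iv); ct <- combined(s, iv)
    if (.total(cr) == 0L || .total(ct) == 0L) next
    g <- gTest(rbind(counts(cr), counts(ct)))
    cmp[[length(cmp) + 1L]] <-
      data.frame(strain = s, reference = referenceStrain, interval = iv,
                 G = g@statistic, df = g@df, p = g@p)
  }
  cmp <- if (length(cmp)) do.call(rbind, cmp) else NULL
  if (!is.null(cmp)) cmp$p.adjusted <- bhAdjust(cmp$p)

  ## homogeneity-gated pooling of the non-reference strains -----------
  others <- setdiff(strains, referenceStrain)
  pool <- NULL
  if (length(others) >= 2L) {
    pool <- do.call(rbind, lapply(ivs, function(iv) {
      sets <- lapply(others, combined, iv = iv)
      keep <- vapply(sets, function(k) .total(k) > 0L, TRUE)
      if (sum(keep) < 2L) return(NULL)
      pl <- poolCounts(sets[keep], alpha = homogeneityAlpha)
      r <- .mapDistRow(pl$pooled)
      data.frame(interval = iv, strains = paste(others[keep], collapse = "+"),
                 r, homogeneityP = pl$homogeneity@p,
                 admissible = pl$admissible)
    }))
  }

  ## meiosis I non-disjunction ----------------------------------------
  ndj <- do.call(rbind, lapply(strains, function(s) {
    calls <- detectMINondisjunction(bySt[[s]])
    data.frame(strain = s, total = length(calls),
               ndj = sum(calls, na.rm = TRUE),
               undetermined = sum(is.na(calls)),
               pct = eventRate(sum(calls, na.rm = TRUE), length(calls)))
  }))
  ndjCmp <- NULL
  if (length(strains) > 1L) {
    ref <- ndj[ndj$strain == referenceStrain, ]
    ndjCmp <- do.call(rbind, lapply(setdiff(strains, referenceStrain),
      function(s) {
        row <- ndj[ndj$strain == s, ]
        g <- gTest(rbind(c(ref$ndj, ref$total - ref$ndj),
                         c(row$ndj, row$total - row$ndj)))
        data.frame(strain = s, reference = referenceStrain,
                   G = g@statistic, df = g@df, p = g@p)
      }))
    ndjCmp$p.adjusted <- bhAdjust(ndjCmp$p)
  }

  ## sister / non-sister ----------------------------------------------
  sis <- do.call(rbind, lapply(strains, function(s) {
    cl <- classifySisterhood(bySt[[s]])
    ns <- sum(cl == "non-sister", na.rm = TRUE)
    ss <- sum(cl == "sister", na.rm = TRUE)
    p <- if (ss + ns >= 1L) chiSquare5050(ss, ns)@p else NA_real_
    data.frame(strain = s, sisters = ss, nonsisters = ns,
               undetermined = sum(cl == "undetermined", na.rm = TRUE),
               p = p)
  }))
  okp <- !is.na(sis$p)
  sis$p.adjusted <- NA_real_
  if (any(okp)) sis$p.adjusted[okp] <- bhAdjust(sis$p[okp])

  ## reporter events ----------------------------------------------------
  evTab <- NULL
  if (events && any(!is.na(sp$hyg))) {
    evTab <- do.call(rbind, lapply(strains, function(s) {
      ec <- callEvents(bySt[[s]])
      tl <- tallyEvents(ec$call, total = length(bySt[[s]]))
      data.frame(strain = s, t(tl$counts), total = tl$total,
                 pctUnequal = tl$pctUnequal,
                 pctConversion = tl$pctConversion)
    }))
  }

  structure(list(viability = viab, mapDistances = md, threeVsFour = tvf,
                 strainComparisons = cmp, pooling = pool,
                 ndj = ndj, ndjComparisons = ndjCmp, sisterhood = sis,
                 events = evTab,
                 exclusions = if (length(excl)) do.call(rbind, excl)
                              else data.frame(strain = character(),
                                              interval = character(),
                                              tetrad_id = character(),
                                              reason = character()),
                 referenceStrain = referenceStrain),
            class = "tetradReport")
}

#' @export
print.tetradReport <- function(x, ...) {
  cat("Tetrad analysis report (reference strain:", x$referenceStrain,
      ")\n\n")
  for (nm in c("viability", "mapDistances", "threeVsFour",
               "strainComparisons", "pooling", "ndj", "sisterhood",
               "events")) {
    if (is.null(x[[nm]])) next
    cat("==", nm, "==\n")
    print(x[[nm]], digits = 4)
    cat("\n")
  }
  if (nrow(x$exclusions))
    cat(nrow(x$exclusions), "tetrad/interval exclusions logged\n")
  invisible(x)
}

#' Write a pipeline report to disk
#'
#' Numbers are computed unrounded by [runPipeline()]; TSV output applies
#' the given display precision while JSON keeps full precision.
#'
#' @param report a \code{tetradReport} from [runPipeline()].
#' @param dir output directory (created if needed).
#' @param format \code{"tsv"}, \code{"json"} or both.
#' @param digits display rounding for the TSV tables.
#' @return the output paths, invisibly.
#' @export
writeReport <- function(report, dir, format = c("tsv", "json"),
                        digits = 3) {
  stopifnot(inherits(report, "tetradReport"))
  format <- match.arg(format, several.ok = TRUE)
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  paths <- character()
  tables <- Filter(is.data.frame, report)
  if ("tsv" %in% format) {
    for (nm in names(tables)) {
      p <- file.path(dir, paste0(nm, ".tsv"))
      tab <- tables[[nm]]
      num <- vapply(tab, is.numeric, TRUE)
      tab[num] <- lapply(tab[num], function(v) signif(v, digits))
      utils::write.table(tab, p, sep = "\t", quote = FALSE,
                         row.names = FALSE)
      paths <- c(paths, p)
    }
  }
  if ("json" %in% format) {
    p <- file.path(dir, "report.json")
    jsonlite::write_json(tables, p, dataframe = "rows", na = "null",
                         auto_unbox = TRUE, digits = NA)
    paths <- c(paths, p)
  }
  invisible(paths)
}
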