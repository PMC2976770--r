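#' @include meiosis-sim.R
NULL

## The tetrad sheet dialect: UTF-8, tab-separated, NA for missing values.
## Header lines are prefixed "#! "; they carry the format version, the
## marker map and (for simulated data) the full parameterization, so a
## sheet round-trips losslessly and is auditable by eye.

SHEET_VERSION <- "tetradsheet 1"

#' Write a tetrad sheet
#'
#' @param x a [TetradSet-class].
#' @param path output file.
#' @return \code{path}, invisibly.
#' @seealso [readTetradSheet()] for the dialect.
#' @export
writeTetradSheet <- function(x, path) {
  stopifnot(is(x, "TetradSet"))
  map <- x@markerMap
  hdr <- c(
    paste("#!", SHEET_VERSION),
    paste0("#! markers: ", paste(map@markers, collapse = ",")),
    paste0("#! centromere: ", map@markers[map@centromere]),
    paste0("#! intervals: ",
           paste(sprintf("%s=%s:%s", rownames(map@intervals),
                         map@intervals[, 1L], map@intervals[, 2L]),
                 collapse = ";")),
    paste0("#! trpAllele: ", map@trpAllele),
    paste0("#! matingMarker: ",
           if (is.na(map@matingMarker)) "NA"
           else map@markers[map@matingMarker]))
  if (length(x@params))
    hdr <- c(hdr, vapply(names(x@params), function(k)
      sprintf("#! param %s=%s", k, format(x@params[[k]])), ""))
  ok <- tryCatch({
    con <- file(path, "w", encoding = "UTF-8")
    on.exit(close(con))
    writeLines(hdr, con)
    utils::write.table(x@spores, con, sep = "\t", quote = FALSE,
                       row.names = FALSE, na = "NA")
    TRUE
  }, error = function(e)
    stop("failed writing tetrad sheet to '", path, "': ",
         conditionMessage(e)))
  invisible(path)
}

.parseHeader <- function(lines) {
  get1 <- function(key) {
    hit <- grep(paste0("^#! ", key, ": "), lines, value = TRUE)
    if (!length(hit)) return(NA_character_)
    sub(paste0("^#! ", key, ": "), "", hit[1L])
  }
  markers <- strsplit(get1("markers"), ",", fixed = TRUE)[[1L]]
  ivSpec <- get1("intervals")
  intervals <- NULL
  if (!is.na(ivSpec)) {
    parts <- strsplit(ivSpec, ";", fixed = TRUE)[[1L]]
    kv <- strsplit(parts, "[=:]")
    intervals <- lapply(kv, function(p) p[2:3])
    names(intervals) <- vapply(kv, `[`, "", 1L)
  }
  mm <- get1("matingMarker")
  map <- markerMap(markers, centromere = get1("centromere"),
                   intervals = intervals,
                   trpAllele = get1("trpAllele"),
                   matingMarker = if (is.na(mm) || mm == "NA") NA else mm)
  pLines <- grep("^#! param ", lines, value = TRUE)
  params <- list()
  if (length(pLines)) {
    kv <- strsplit(sub("^#! param ", "", pLines), "=", fixed = TRUE)
    params <- lapply(kv, function(p) {
      v <- suppressWarnings(as.numeric(p[2L]))
      if (is.na(v) && !p[2L] %in% c("NA", "NaN")) p[2L] else v
    })
    names(params) <- vapply(kv, `[`, "", 1L)
  }
  list(map = map, params = params)
}

#' Read a tetrad sheet
#'
#' Reads the package's tab-separated tetrad sheet dialect: \code{#!}
#' header lines carrying the format version, marker map and simulation
#' provenance, then one row per spore (four per tetrad) with columns
#' \code{tetrad_id}, \code{strain_id}, \code{spore_index}, \code{viable},
#' one allele column per marker (\code{P1}/\code{P2}/\code{NA}) and the
#' phenotype columns \code{mating}, \code{trp}, \code{hyg}, \code{cyh},
#' \code{karyotype}, \code{southern}. \code{NA} marks missing calls.
#'
#' In strict mode any malformed content (unknown enum token, tetrad
#' without exactly four rows) aborts with the offending tetrad ids and
#' sheet line numbers; in lenient mode offending tetrads are dropped
#' with a warning.
#'
#' @param path input file.
#' @param strict abort on malformed rows (default) instead of skipping
#'   them.
#' @return a [TetradSet-class].
#' @export
readTetradSheet <- function(path, strict = TRUE) {
  if (!file.exists(path)) stop("no such file: '", path, "'")
  lines <- readLines(path, encoding = "UTF-8")
  hdrIdx <- grep("^#", lines)
  if (!length(hdrIdx) || !grepl(SHEET_VERSION, lines[1L], fixed = TRUE))
    stop("'", path, "' is not a ", SHEET_VERSION, " sheet")
  hdr <- .parseHeader(lines[hdrIdx])
  body <- lines[-hdrIdx]
  sp <- utils::read.delim(text = body, stringsAsFactors = FALSE,
                          na.strings = "NA")
  need <- c("tetrad_id", "strain_id", "spore_index", "viable",
            hdr$map@markers, SPORE_COLS)
  miss <- setdiff(need, names(sp))
  if (length(miss))
    stop("sheet is missing column(s): ", paste(miss, collapse = ", "))
  sp$tetrad_id <- as.character(sp$tetrad_id)
  sp$strain_id <- as.character(sp$strain_id)
  sp$viable <- as.logical(sp$viable)
  for (cc in c(hdr$map@markers, SPORE_COLS))
    sp[[cc]] <- as.character(sp[[cc]])

  lineOf <- hdrIdx[length(hdrIdx)] + 1L + seq_len(nrow(sp))

  ## enum validation
  enums <- c(stats::setNames(rep(list(ALLELE_LEVELS), length(hdr$map@markers)),
                             hdr$map@markers),
             list(mating = MATING_LEVELS, trp = TRP_LEVELS,
                  hyg = DRUG_LEVELS, cyh = DRUG_LEVELS,
                  karyotype = KARYOTYPE_LEVELS, southern = SOUTHERN_LEVELS))
  badRows <- integer()
  for (cc in names(enums)) {
    bad <- which(!(is.na(sp[[cc]]) | sp[[cc]] %in% enums[[cc]]))
    if (length(bad)) {
      msg <- sprintf("line %d: unknown %s token '%s'",
                     lineOf[bad[1L]], cc, sp[[cc]][bad[1L]])
      if (strict) stop(msg)
      warning(msg, " (row skipped)")
      badRows <- c(badRows, bad)
    }
  }
  if (length(badRows)) sp <- sp[-unique(badRows), , drop = FALSE]

  tab <- table(sp$tetrad_id)
  wrong <- names(tab)[tab != 4L]
  if (length(wrong)) {
    msg <- paste0("tetrad(s) without exactly four spore rows: ",
                  paste(utils::head(wrong, 10L), collapse = ", "))
    if (strict) stop(msg)
    warning(msg, " (dropped)")
    sp <- sp[!sp$tetrad_id %in% wrong, , drop = FALSE]
  }
  tetradSet(sp, map = hdr$map, params = hdr$params)
}
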