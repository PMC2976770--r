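#' @include event-classifier.R
NULL

#' Construct SimParams
#'
#' Parameterizes the forward meiosis simulator: true per-interval map
#' distances (for every adjacent-marker interval of the map), a global
#' homeologous suppression factor, the spore-death branches
#' (non-disjunction conditioned on a crossover-less chromosome, lethal
#' half-crossovers, sister-chromatid entanglement, random death) and the
#' reporter-event rates.
#'
#' @param distances numeric vector of true distances in cM, one per
#'   adjacent-marker interval (named or in map order).
#' @param suppression homeologous suppression factor in (0, 1].
#' @param pNdj0 P(meiosis I non-disjunction | zero crossovers).
#' @param qHalf P(an initiated crossover resolves as a lethal
#'   half-crossover).
#' @param pEnt P(the meiosis carries an unresolved sister entanglement
#'   distal to the last marker).
#' @param pDeath per-spore random death probability.
#' @param rCo,rDel,rUsce,rGc per-meiosis reporter event rates (must sum
#'   to at most 1).
#' @param reporter whether the cross carries the reporter construct;
#'   defaults to \code{TRUE} when any event rate is positive.
#' @param n number of meioses.
#' @param seed RNG seed (\code{NA}: use the current RNG state).
#' @param strain strain label.
#' @param map the [MarkerMap-class] the distances refer to.
#' @return a [SimParams-class].
#' @export
simParams <- function(distances, suppression = 1,
                      pNdj0 = 0, qHalf = 0, pEnt = 0, pDeath = 0,
                      rCo = 0, rDel = 0, rUsce = 0, rGc = 0,
                      reporter = (rCo + rDel + rUsce + rGc) > 0,
                      n = 1000, seed = NA, strain = "sim",
                      map = yeastChrIIIMap()) {
  lab <- rownames(.simIntervals(map))
  if (length(distances) != length(lab))
    stop("need one distance per adjacent-marker interval (",
         length(lab), ")")
  if (is.null(names(distances))) names(distances) <- lab
  distances <- distances[lab]
  if (anyNA(distances)) stop("distance names must match the map intervals")
  new("SimParams", distances = distances, suppression = suppression,
      pNdj0 = pNdj0, qHalf = qHalf, pEnt = pEnt, pDeath = pDeath,
      rCo = rCo, rDel = rDel, rUsce = rUsce, rGc = rGc,
      reporter = reporter, n = as.integer(n),
      seed = if (is.na(seed)) NA_integer_ else as.integer(seed),
      strain = strain)
}

#' Preset parameters: homologous Y55 diploid with the reporter
#'
#' Study conditions of a wild-type homologous cross carrying the
#' HYG-CYH2/HYG reporter: interval distances from the homologous map
#' (41.8, 15.5 and 27.7 cM for the three scored intervals, the last
#' split 0.5/1.48-proportionally across the centromere by physical
#' position), ~90% four-viable tetrads via random death, and reporter
#' event rates matching the wild-type tallies (6/255 USCE, 0 deletions,
#' 11/255 conversions, plus a nominal inter-cassette crossover rate).
#'
#' @param n number of meioses.
#' @param seed RNG seed.
#' @param strain strain label.
#' @return a [SimParams-class].
#' @export
simParamsHomologous <- function(n = 1000, seed = NA,
                                strain = "WT_homologous") {
  simParams(distances = c(41.8, 15.5, 7.0, 20.7),
            pDeath = 0.026,
            rCo = 0.01, rDel = 0, rUsce = 6 / 255, rGc = 11 / 255,
            n = n, seed = seed, strain = strain)
}

#' Preset parameters: homeologous partial-hybrid diploid
#'
#' Study conditions of the wild-type partial hybrid in which chromosome
#' III comes from a diverged sister species: effective interval
#' distances equal to the observed four-viable map (0.317, 0.079 and
#' 1.981 cM, the last split across the centromere), non-disjunction at
#' rate 0.12 conditional on a crossover-less chromosome (so that the
#' marginal non-disjunction frequency is ~11.5%), and a high lethal
#' half-crossover probability producing the recombination-enriched
#' three-viable class.
#'
#' @inheritParams simParamsHomologous
#' @return a [SimParams-class].
#' @export
simParamsHomeologous <- function(n = 1000, seed = NA,
                                 strain = "WT_homeologous") {
  simParams(distances = c(0.317, 0.079, 0.5, 1.481),
            pNdj0 = 0.12, qHalf = 0.8, pDeath = 0.05,
            n = n, seed = seed, strain = strain)
}

## reporter phenotype templates, spore rows 1:2 = reporter (P1) chromatids
.reporterBase <- function() list(
  hyg = c("R", "R", "S", "S"),
  cyh = c("S", "S", "R", "R"),
  kar = rep("normal", 4L),
  sou = c("present", "present", "absent", "absent"))

#' Expected tetrad-class frequencies under the no-interference model
#'
#' Marginal PD/NPD/TT probabilities for an interval of true length
#' \code{d} cM, from the Poisson-Markov chain over crossover-chromatid
#' choices: each crossover moves PD to TT; TT to PD, NPD or TT with
#' probabilities 1/4, 1/4, 1/2; NPD to TT. The tetratype marginal has
#' the closed form \eqn{T(d) = (2/3)(1 - e^{-3d/100})}.
#'
#' @param d true distance in cM.
#' @return named numeric: \code{PD}, \code{NPD}, \code{TT}.
#' @export
expectedClassFreqs <- function(d) {
  Tt <- 2 / 3 * (1 - exp(-3 * d / 100))
  ## PD - NPD decays by a factor e^{-d/50} per unit of map length
  diffPN <- exp(-2 * d / 100)
  PD <- (1 - Tt + diffPN) / 2
  c(PD = PD, NPD = 1 - Tt - PD, TT = Tt)
}

#' Simulate one diploid meiosis
#'
#' @param params a [SimParams-class] (its \code{n} is ignored; one
#'   meiosis is drawn using the current RNG state unless \code{seed} is
#'   set).
#' @param map a [MarkerMap-class].
#' @return list with \code{tetrad} (a [Tetrad-class]) and \code{truth}
#'   (one-row data.frame of ground-truth labels).
#' @export
simulateMeiosis <- function(params, map = yeastChrIIIMap()) {
  params@n <- 1L
  set <- simulateTetrads(params, map)
  list(tetrad = set[[1L]], truth = groundTruth(set))
}

#' Forward-simulate a set of meioses
#'
#' Mechanistic generator of tetrad sheets. For each meiosis: (1) the
#' crossover count in each adjacent-marker interval is Poisson with mean
#' \code{suppression * d / 50} (one expected exchange per bivalent per
#' 50 cM); each crossover picks one chromatid from each homolog
#' uniformly and exchanges the segment on the centromere-distal side of
#' the interval, so centromere alleles stay with their spindle poles and
#' spores 1/2 and 3/4 are sister pairs. (2) A crossover-less chromosome
#' suffers meiosis I non-disjunction with probability \code{pNdj0}: two
#' dead nullisomic spores and two viable disomic non-mater,
#' Trp-prototrophic spores. (3) Each crossover independently resolves as
#' a lethal half-crossover with probability \code{qHalf}, killing the
#' spore that inherits the unrepaired reciprocal chromatid. (4) With
#' probability \code{pEnt} the meiosis carries an unresolved sister
#' entanglement distal to the last marker; if any crossover falls in an
#' interval between the centromere and that end, the two spores
#' receiving the recombined/entangled chromatids die, leaving non-sister
#' survivors. (5) Each remaining spore dies with probability
#' \code{pDeath}. (6) In reporter crosses one of the four reporter event
#' classes (or none) is drawn per meiosis and consistent
#' Hyg/Cyh/karyotype/Southern evidence is emitted.
#'
#' @param params a [SimParams-class].
#' @param map a [MarkerMap-class].
#' @return a [TetradSet-class] with ground-truth labels: per-interval
#'   crossover counts (\code{xo_*}), per-spore death causes
#'   (\code{cause_1..4}), viable-spore count, non-disjunction flag,
#'   reporter event class and true sisterhood of two-viable survivors.
#' @export
setMethod("simulateTetrads", "SimParams", function(params,
                                                   map = yeastChrIIIMap()) {
  validObject(params)
  validObject(map)
  if (!is.na(params@seed)) set.seed(params@seed)
  n <- params@n
  M <- length(map@markers)
  nI <- M - 1L
  cen <- map@centromere
  ivLab <- rownames(.simIntervals(map))
  lam <- params@suppression * params@distances / 50

  K <- matrix(stats::rpois(n * nI, rep(lam, each = n)), nrow = n)
  total <- rowSums(K)

  ## chromatid genotypes: rows 1:2 carry the P1 centromere, 3:4 the P2
  G <- array(rep(c(1L, 1L, 2L, 2L), M * n), dim = c(4L, M, n))
  dead <- matrix(FALSE, 4L, n)
  cause <- matrix("none", 4L, n)

  isNdj <- logical(n)
  idx0 <- which(total == 0L)
  if (length(idx0) && params@pNdj0 > 0)
    isNdj[idx0] <- stats::runif(length(idx0)) < params@pNdj0

  entangled <- if (params@pEnt > 0) stats::runif(n) < params@pEnt
               else logical(n)

  for (i in which(total > 0L)) {
    g <- G[, , i]
    entPair <- NULL
    for (j in seq_len(nI)) {
      kj <- K[i, j]
      if (kj == 0L) next
      leftOfCen <- (j + 1L) <= cen
      cols <- if (leftOfCen) seq_len(j) else (j + 1L):M
      for (z in seq_len(kj)) {
        a <- sample(2L, 1L)
        b <- 2L + sample(2L, 1L)
        tmp <- g[a, cols]
        g[a, cols] <- g[b, cols]
        g[b, cols] <- tmp
        if (params@qHalf > 0 && stats::runif(1L) < params@qHalf) {
          v <- if (stats::runif(1L) < 0.5) a else b
          if (cause[v, i] == "none") {
            dead[v, i] <- TRUE
            cause[v, i] <- "half_crossover"
          }
        }
        if (is.null(entPair) && !leftOfCen) entPair <- c(a, b)
      }
    }
    G[, , i] <- g
    if (entangled[i] && !is.null(entPair)) {
      for (v in entPair) if (cause[v, i] == "none") {
        dead[v, i] <- TRUE
        cause[v, i] <- "entanglement"
      }
    }
  }

  ## non-disjunction: spores 1,2 become viable disomes; 3,4 die nullisomic
  if (any(isNdj)) {
    dead[3:4, isNdj] <- TRUE
    cause[3:4, isNdj][cause[3:4, isNdj] == "none"] <- "ndj"
  }

  if (params@pDeath > 0) {
    rd <- matrix(stats::runif(4L * n) < params@pDeath, 4L, n)
    sel <- rd & !dead
    dead[sel] <- TRUE
    cause[sel] <- "random"
  }

  ## reporter events
  ev <- rep("none", n)
  hyg <- cyh <- kar <- sou <- matrix(NA_character_, 4L, n)
  if (params@reporter) {
    base <- .reporterBase()
    hyg[] <- base$hyg
    cyh[] <- base$cyh
    kar[] <- base$kar
    sou[] <- base$sou
    cum <- cumsum(c(params@rCo, params@rDel, params@rUsce, params@rGc))
    u <- stats::runif(n)
    cls <- c("reciprocal_crossover", "deletion", "usce",
             "gene_conversion", "none")
    ev <- cls[findInterval(u, c(0, cum))]
    for (i in which(ev != "none")) {
      a <- sample(2L, 1L)             # affected reporter chromatid
      switch(ev[i],
        reciprocal_crossover = {
          b <- 2L + sample(2L, 1L)    # recipient non-reporter chromatid
          hyg[b, i] <- "R"
        },
        deletion = {
          cyh[a, i] <- "R"
          kar[a, i] <- "faster"
          sou[a, i] <- "absent"
        },
        usce = {
          t <- 3L - a                 # the other sister: triplication
          cyh[a, i] <- "R"
          kar[a, i] <- "faster"
          sou[a, i] <- "absent"
          kar[t, i] <- "slower"
        },
        gene_conversion = {
          cyh[a, i] <- "R"
          sou[a, i] <- "absent"
        })
    }
  }

  ## phenotypes from genotype
  trpNum <- if (map@trpAllele == "P1") 1L else 2L
  trp <- matrix(ifelse(matrix(G[, cen, ], 4L, n) == trpNum,
                       "prototroph", "auxotroph"), 4L, n)
  mating <- matrix(NA_character_, 4L, n)
  if (!is.na(map@matingMarker))
    mating[] <- ifelse(matrix(G[, map@matingMarker, ], 4L, n) == 1L,
                       "a", "alpha")

  ## disomic spores: allele calls inexpressible, non-mater, Trp+
  alleles <- matrix(ifelse(G == 1L, "P1", "P2"), nrow = 4L)  # (4, M*n)
  dim(alleles) <- c(4L, M, n)
  if (any(isNdj)) {
    alleles[1:2, , isNdj] <- NA_character_
    mating[1:2, isNdj] <- "nonmater"
    trp[1:2, isNdj] <- "prototroph"
    hyg[1:2, isNdj] <- NA_character_
    cyh[1:2, isNdj] <- NA_character_
    kar[1:2, isNdj] <- NA_character_
    sou[1:2, isNdj] <- NA_character_
  }

  ## dead spores carry no information
  for (m in seq_len(M)) {
    am <- matrix(alleles[, m, ], 4L, n)
    am[dead] <- NA_character_
    alleles[, m, ] <- am
  }
  mating[dead] <- NA_character_
  trp[dead] <- NA_character_
  hyg[dead] <- NA_character_
  cyh[dead] <- NA_character_
  kar[dead] <- NA_character_
  sou[dead] <- NA_character_

  ids <- sprintf("%s_t%06d", params@strain, seq_len(n))
  sp <- data.frame(tetrad_id = rep(ids, each = 4L),
                   strain_id = params@strain,
                   spore_index = rep(1:4, n),
                   viable = as.vector(!dead),
                   stringsAsFactors = FALSE)
  for (m in seq_len(M)) sp[[map@markers[m]]] <- as.vector(alleles[, m, ])
  sp$mating <- as.vector(mating)
  sp$trp <- as.vector(trp)
  sp$hyg <- as.vector(hyg)
  sp$cyh <- as.vector(cyh)
  sp$karyotype <- as.vector(kar)
  sp$southern <- as.vector(sou)

  nViable <- colSums(!dead)
  sis <- rep(NA_character_, n)
  for (i in which(nViable == 2L)) {
    surv <- which(!dead[, i])
    sis[i] <- if (all(surv <= 2L) || all(surv >= 3L)) "sister"
              else "non-sister"
  }
  gt <- data.frame(tetrad_id = ids, stringsAsFactors = FALSE)
  for (j in seq_len(nI)) gt[[paste0("xo_", ivLab[j])]] <- K[, j]
  gt$totalCrossovers <- total
  for (s in 1:4) gt[[paste0("cause_", s)]] <- cause[s, ]
  gt$nViable <- nViable
  gt$ndj <- isNdj
  gt$event <- ev
  gt$sisterhood <- sis

  tetradSet(sp, map = map,
            params = c(list(seed = params@seed, strain = params@strain,
                            n = n, suppression = params@suppression,
                            pNdj0 = params@pNdj0, qHalf = params@qHalf,
                            pEnt = params@pEnt, pDeath = params@pDeath,
                            rCo = params@rCo, rDel = params@rDel,
                            rUsce = params@rUsce, rGc = params@rGc,
                            reporter = params@reporter),
                      as.list(params@distances)),
            groundTruth = gt)
})

#' Simulate a dataset and write it to disk
#'
#' Runs [simulateTetrads()] and writes the tetrad sheet plus a parallel
#' ground-truth sheet keyed by tetrad id. Output is deterministic given
#' the seed: the same parameters produce byte-identical files.
#'
#' @param params a [SimParams-class].
#' @param prefix output path prefix; writes \code{<prefix>.tsv} and
#'   \code{<prefix>.truth.tsv}.
#' @param map a [MarkerMap-class].
#' @return the simulated [TetradSet-class], invisibly.
#' @export
simulateDataset <- function(params, prefix, map = yeastChrIIIMap()) {
  set <- simulateTetrads(params, map)
  writeTetradSheet(set, paste0(prefix, ".tsv"))
  truthPath <- paste0(prefix, ".truth.tsv")
  ok <- tryCatch({
    utils::write.table(groundTruth(set), truthPath, sep = "\t",
                       quote = FALSE, row.names = FALSE)
    TRUE
  }, error = function(e)
    stop("failed writing ground truth to '", truthPath, "': ",
         conditionMessage(e)))
  invisible(set)
}
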