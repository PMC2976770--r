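mapIII <- yeastChrIIIMap()

fullTetrad <- function(callsByMarker, ...) {
  a <- do.call(cbind, callsByMarker)
  colnames(a) <- markers(mapIII)
  tetrad("t", "s", rep(TRUE, 4), a, ..., map = mapIII)
}

test_that("Mendelian check counts alleles and flags non-2:2 patterns", {
  mk <- function(v) fullTetrad(rep(list(v), 5))
  expect_equal(checkMendelian(mk(c("P1", "P1", "P2", "P2")), "HIS4"),
               list(countP1 = 2L, countP2 = 2L, is2to2 = TRUE))
  expect_equal(checkMendelian(mk(c("P1", "P1", "P1", "P2")), "HIS4"),
               list(countP1 = 3L, countP2 = 1L, is2to2 = FALSE))
  # exhaustive: of the 16 possible call vectors exactly choose(4,2) = 6
  # segregate 2:2
  grid <- expand.grid(rep(list(c("P1", "P2")), 4), stringsAsFactors = FALSE)
  res <- apply(grid, 1, function(v)
    checkMendelian(mk(unname(v)), "HIS4")$is2to2)
  expect_equal(sum(res), 6L)
  # missing call is unscorable
  expect_error(checkMendelian(mk(c("P1", NA, "P2", "P2")), "HIS4"),
               class = "tetradkit_unscorable")
})

test_that("interval classification partitions 2:2 x 2:2 tetrads 1:1:4", {
  twoTwo <- utils::combn(4, 2, function(i) {
    v <- rep("P2", 4); v[i] <- "P1"; v
  })
  cls <- character()
  for (i in 1:6) for (j in 1:6) {
    tt <- fullTetrad(list(twoTwo[, i], twoTwo[, j],
                          rep(NA, 4), rep(NA, 4), rep(NA, 4)))
    cls <- c(cls, classifyTetrad(tt, "HML_ADE1-HIS4"))
  }
  # exhaustive and mutually exclusive over all 36 joint configurations,
  # with the classical independent-assortment ratio PD:NPD:TT = 6:6:24
  expect_equal(as.vector(table(factor(cls, c("PD", "NPD", "TT")))),
               c(6L, 6L, 24L))
  expect_false(any(cls == "unscorable"))
})

test_that("canonical patterns classify as PD, NPD, TT", {
  expect_equal(classifyTetrad(makeIntervalTetrad("PD"),
                              "HML_ADE1-HIS4"), "PD")
  expect_equal(classifyTetrad(makeIntervalTetrad("NPD"),
                              "HML_ADE1-HIS4"), "NPD")
  expect_equal(classifyTetrad(makeIntervalTetrad("TT"),
                              "HML_ADE1-HIS4"), "TT")
  # a 3:1 (conversion) marker makes the interval unscorable, with reason
  tt <- fullTetrad(list(c("P1", "P1", "P1", "P2"),
                        c("P1", "P1", "P2", "P2"),
                        rep(NA, 4), rep(NA, 4), rep(NA, 4)))
  cl <- classifyTetrad(tt, "HML_ADE1-HIS4")
  expect_equal(as.character(cl), "unscorable")
  expect_match(attr(cl, "reason"), "non-2:2")
})

test_that("dead-spore inference completes 2:2 and flags 3:0 conversion", {
  a <- matrix(NA_character_, 4, 5, dimnames = list(NULL, markers(mapIII)))
  a[, "HIS4"] <- c("P1", "P1", "P2", NA)
  a[, "LEU2"] <- c("P2", "P2", "P2", NA)
  tt <- tetrad("t", "s", c(TRUE, TRUE, TRUE, FALSE), a, map = mapIII)
  inf <- inferDeadSpore(tt)
  expect_equal(unname(inf["HIS4"]), "P2")
  expect_true(is.na(inf["LEU2"]))
  expect_true(attr(inf, "nonInferable")["LEU2"])
  expect_false(attr(inf, "nonInferable")["HIS4"])
  # precondition: exactly three viable spores
  expect_error(inferDeadSpore(makeIntervalTetrad("PD")),
               class = "tetradkit_precondition")
})

test_that("masking one spore of a conversion-free tetrad is lossless", {
  # simulator round trip: no death branches, so every tetrad is
  # four-viable and conversion-free; mask one random spore and check
  # inference recovers both the genotype and the interval class
  p <- simParams(distances = c(30, 10, 5, 20), n = 400, seed = 20260901)
  s <- simulateTetrads(p)
  sp <- sporeData(s)
  set.seed(1)
  ids <- unique(sp$tetrad_id)
  masked <- sp
  mk <- markers(s)
  drop <- sample(4, length(ids), replace = TRUE)
  rows <- 4 * (seq_along(ids) - 1) + drop
  masked$viable[rows] <- FALSE
  masked[rows, c(mk, "mating", "trp", "hyg", "cyh", "karyotype",
                 "southern")] <- NA_character_
  ms <- tetradSet(masked, map = s@markerMap)
  nRecov <- 0L
  for (i in seq_along(ids)) {
    inf <- inferDeadSpore(ms[[i]])
    truth <- sp[rows[i], mk]
    nRecov <- nRecov + all(inf == unlist(truth))
  }
  expect_equal(nRecov, length(ids))
  for (iv in rownames(intervals(s))) {
    expect_equal(classifyTetrads(ms, iv)$class,
                 classifyTetrads(s, iv)$class)
  }
})

test_that("MI non-disjunction calls need two viable non-maters", {
  mk2v <- function(mating) {
    a <- matrix(NA_character_, 4, 5, dimnames = list(NULL, markers(mapIII)))
    tetrad("t", "s", c(TRUE, TRUE, FALSE, FALSE), a,
           mating = c(mating, NA, NA), map = mapIII)
  }
  expect_true(detectMINondisjunction(mk2v(c("nonmater", "nonmater"))))
  expect_false(detectMINondisjunction(mk2v(c("a", "alpha"))))
  expect_true(is.na(detectMINondisjunction(mk2v(c("nonmater", NA)))))
  expect_false(detectMINondisjunction(makeIntervalTetrad("PD")))
})

test_that("sisterhood follows the centromere-linked Trp phenotype", {
  mk2v <- function(trp) {
    a <- matrix(NA_character_, 4, 5, dimnames = list(NULL, markers(mapIII)))
    tetrad("t", "s", c(TRUE, TRUE, FALSE, FALSE), a,
           trp = c(trp, NA, NA), map = mapIII)
  }
  expect_equal(classifySisterhood(mk2v(c("prototroph", "prototroph"))),
               "sister")
  expect_equal(classifySisterhood(mk2v(c("auxotroph", "auxotroph"))),
               "sister")
  expect_equal(classifySisterhood(mk2v(c("prototroph", "auxotroph"))),
               "non-sister")
  expect_equal(classifySisterhood(mk2v(c("prototroph", NA))),
               "undetermined")
  expect_error(classifySisterhood(makeIntervalTetrad("PD")),
               class = "tetradkit_precondition")
})

test_that("dead spores are scrubbed and Trp derives from the centromere", {
  a <- matrix("P1", 4, 5, dimnames = list(NULL, markers(mapIII)))
  a[3:4, ] <- "P2"
  tt <- tetrad("t", "s", c(TRUE, TRUE, TRUE, FALSE), a, hyg = "R",
               map = mapIII)
  expect_true(all(is.na(tt@alleles[4, ])))
  expect_true(is.na(tt@hyg[4]))
  expect_equal(tt@trp[1:3], c("prototroph", "prototroph", "auxotroph"))
})
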