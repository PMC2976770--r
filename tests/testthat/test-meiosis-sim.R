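test_that("a crossover-free, death-free meiosis yields four PD spores", {
  p <- simParams(distances = rep(0, 4), n = 50, seed = 1)
  s <- simulateTetrads(p)
  expect_true(all(viability(s) == 4L))
  for (iv in rownames(intervals(s)))
    expect_true(all(classifyTetrads(s, iv)$class == "PD"))
})

test_that("identical parameters and seed give byte-identical output", {
  p <- simParams(distances = c(10, 5, 2, 8), pDeath = 0.1, pNdj0 = 0.2,
                 qHalf = 0.1, pEnt = 0.05, rUsce = 0.02, rGc = 0.02,
                 n = 300, seed = 77)
  d <- withr::local_tempdir()
  simulateDataset(p, file.path(d, "a"))
  simulateDataset(p, file.path(d, "b"))
  expect_identical(readLines(file.path(d, "a.tsv")),
                   readLines(file.path(d, "b.tsv")))
  expect_identical(readLines(file.path(d, "a.truth.tsv")),
                   readLines(file.path(d, "b.truth.tsv")))
})

test_that("random death alone thins viability binomially", {
  p <- simParams(distances = rep(0, 4), pDeath = 0.1, n = 1000, seed = 3)
  s <- simulateTetrads(p)
  frac4 <- mean(viability(s) == 4L)
  expected <- 0.9^4
  se <- sqrt(expected * (1 - expected) / 1000)
  expect_lt(abs(frac4 - expected), 3 * se)
  expect_true(all(groundTruth(s)$cause_1 %in% c("none", "random")))
})

test_that("non-disjunction tetrads are exactly the detected non-maters", {
  p <- simParams(distances = rep(0, 4), pNdj0 = 0.3, n = 800, seed = 4)
  s <- simulateTetrads(p)
  truth <- groundTruth(s)
  calls <- detectMINondisjunction(s)
  expect_equal(unname(calls), truth$ndj)
  # the surviving disomes are Trp prototrophs and sisters by construction
  sis <- classifySisterhood(s)
  expect_true(all(sis[truth$ndj] == "sister"))
  # random two-spore death with observable maters never looks like NDJ
  p2 <- simParams(distances = rep(0, 4), pDeath = 0.35, n = 800, seed = 5)
  s2 <- simulateTetrads(p2)
  two <- viability(s2) == 2L
  expect_gt(sum(two), 50)
  expect_false(any(detectMINondisjunction(s2)[two], na.rm = TRUE))
})

test_that("entangled meioses kill the recombined pair, leaving non-sisters", {
  p <- simParams(distances = c(0, 0, 30, 30), pEnt = 1, n = 600, seed = 6)
  s <- simulateTetrads(p)
  truth <- groundTruth(s)
  ent <- truth$cause_1 == "entanglement" | truth$cause_2 == "entanglement" |
         truth$cause_3 == "entanglement" | truth$cause_4 == "entanglement"
  # entanglement fires only when a crossover links centromere and distal end
  expect_true(all(truth$totalCrossovers[ent] >= 1))
  expect_gt(sum(ent), 100)
  sis <- classifySisterhood(s)
  expect_true(all(sis[ent & truth$nViable == 2] == "non-sister"))
  # crossovers left of the centromere never trigger the branch
  pL <- simParams(distances = c(30, 30, 0, 0), pEnt = 1, n = 300, seed = 7)
  truthL <- groundTruth(simulateTetrads(pL))
  expect_true(all(truthL$nViable == 4L))
})

test_that("ground-truth sisterhood matches the phenotype-based call", {
  p <- simParams(distances = c(20, 10, 5, 15), pDeath = 0.3, n = 1500,
                 seed = 8)
  s <- simulateTetrads(p)
  truth <- groundTruth(s)
  two <- truth$nViable == 2L
  expect_gt(sum(two), 200)
  expect_equal(unname(classifySisterhood(s)[two]), truth$sisterhood[two])
  # of the six survivor pairs under random death, two are sister pairs
  frac <- mean(truth$sisterhood[two] == "sister")
  se <- sqrt(1 / 3 * 2 / 3 / sum(two))
  expect_lt(abs(frac - 1 / 3), 3 * se)
})

test_that("lethal half-crossovers enrich recombinants among 3-viable tetrads", {
  p <- simParams(distances = c(2, 0, 0, 0), qHalf = 0.8, n = 30000,
                 seed = 9)
  s <- simulateTetrads(p)
  c4 <- countTetradClasses(s, "HML_ADE1-HIS4", nViable = 4)
  c3 <- countTetradClasses(s, "HML_ADE1-HIS4", nViable = 3)
  expect_gt(perkinsMapDistance(c3, se = FALSE)@cM,
            perkinsMapDistance(c4, se = FALSE)@cM)
  # the dead spore of a half-crossover tetrad carries a recombinant
  truth <- groundTruth(s)
  expect_gt(sum(truth$cause_1 == "half_crossover" |
                truth$cause_2 == "half_crossover" |
                truth$cause_3 == "half_crossover" |
                truth$cause_4 == "half_crossover"), 100)
})

test_that("the Perkins estimator recovers the configured distance", {
  p <- simParams(distances = c(5, 0, 0, 0), n = 20000, seed = 10)
  s <- simulateTetrads(p)
  md <- perkinsMapDistance(countTetradClasses(s, "HML_ADE1-HIS4"))
  expect_lt(abs(md@cM - 5), 3 * md@se)
})

test_that("very long intervals assort independently (PD:NPD:TT = 1:1:4)", {
  p <- simParams(distances = c(500, 0, 0, 0), n = 20000, seed = 12)
  s <- simulateTetrads(p)
  cnt <- counts(countTetradClasses(s, "HML_ADE1-HIS4"))
  n <- sum(cnt)
  expected <- c(PD = 1 / 6, NPD = 1 / 6, TT = 2 / 3)
  for (k in names(expected)) {
    se <- sqrt(expected[k] * (1 - expected[k]) / n)
    expect_lt(abs(cnt[k] / n - expected[k]), 4 * se)
  }
})

test_that("suppression rescales the effective map", {
  p <- simParams(distances = c(40, 0, 0, 0), suppression = 0.1,
                 n = 20000, seed = 13)
  s <- simulateTetrads(p)
  md <- perkinsMapDistance(countTetradClasses(s, "HML_ADE1-HIS4"))
  expect_lt(abs(md@cM - 4), 3 * md@se)
})

test_that("invalid parameters are rejected before simulation", {
  expect_error(simParams(distances = rep(0, 4), pDeath = 1.2),
               "probabilities outside")
  expect_error(simParams(distances = c(-1, 0, 0, 0)), "non-negative")
  expect_error(simParams(distances = rep(0, 3)), "one distance per")
  expect_error(simParams(distances = rep(0, 4), rUsce = 0.6, rGc = 0.6),
               "sum to at most 1")
})
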