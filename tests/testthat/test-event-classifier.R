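RR <- c("R", "R", "S", "S")            # parental Hyg
SSRR <- c("S", "S", "R", "R")          # parental Cyh (S = carries CYH2)

test_that("segregation patterns count resistant and sensitive spores", {
  par <- makeReporterTetrad(RR, SSRR)
  expect_equal(segregationPattern(par),
               list(hyg = c(R = 2L, S = 2L), cyh = c(S = 2L, R = 2L)))
  figA <- makeReporterTetrad(c("R", "R", "R", "S"), SSRR)
  expect_equal(segregationPattern(figA)$hyg, c(R = 3L, S = 1L))
  figB <- makeReporterTetrad(RR, c("S", "R", "R", "R"))
  expect_equal(segregationPattern(figB)$cyh, c(S = 1L, R = 3L))
  expect_error(segregationPattern(
    makeReporterTetrad(c("R", NA, "S", "S"), SSRR)), "spore")
})

test_that("the decision table reproduces the reporter event classes", {
  # reciprocal crossover between the cassettes: 3:1 Hyg, 2:2 Cyh
  expect_equal(callEvent(makeReporterTetrad(
    c("R", "R", "R", "S"), SSRR))@call, "reciprocal_crossover")
  # deletion: one faster chromosome III that lost the CYH2 insert
  expect_equal(callEvent(makeReporterTetrad(
    RR, c("S", "R", "R", "R"),
    karyotype = c("normal", "faster", "normal", "normal"),
    southern = c("present", "absent", "absent", "absent")))@call,
    "deletion")
  # unequal sister-chromatid exchange: faster + slower products
  expect_equal(callEvent(makeReporterTetrad(
    RR, c("S", "R", "R", "R"),
    karyotype = c("slower", "faster", "normal", "normal")))@call,
    "usce")
  # gene conversion: normal karyotype, CYH2 replaced on one chromatid
  expect_equal(callEvent(makeReporterTetrad(
    RR, c("S", "R", "R", "R"),
    southern = c("present", "absent", "absent", "absent")))@call,
    "gene_conversion")
  # no event
  expect_equal(callEvent(makeReporterTetrad(RR, SSRR))@call, "none")
})

test_that("missing or contradictory evidence yields ambiguous calls", {
  # 1:3 Cyh gate with unknown karyotype
  amb <- callEvent(makeReporterTetrad(RR, c("S", "R", "R", "R")))
  expect_equal(amb@call, "ambiguous")
  expect_match(amb@note, "karyotype")
  # faster band that still carries CYH2
  expect_equal(callEvent(makeReporterTetrad(
    RR, c("S", "R", "R", "R"),
    karyotype = c("normal", "faster", "normal", "normal"),
    southern = c("present", "present", "absent", "absent")))@call,
    "ambiguous")
  # slower band without the 1:3 Cyh pattern contradicts every class
  expect_equal(callEvent(makeReporterTetrad(
    RR, SSRR,
    karyotype = c("slower", "normal", "normal", "normal")))@call,
    "ambiguous")
})

test_that("every evidence combination maps to exactly one valid call", {
  drugs <- c("R", "S")
  kar <- c("normal", "faster", "slower", NA)
  sou <- c("present", "absent", NA)
  set.seed(99)
  for (rep in 1:400) {
    tt <- makeReporterTetrad(sample(drugs, 4, TRUE),
                             sample(drugs, 4, TRUE),
                             karyotype = sample(kar, 4, TRUE),
                             southern = sample(sou, 4, TRUE))
    ec <- callEvent(tt)
    expect_s4_class(ec, "EventCall")
    expect_length(ec@call, 1)
  }
  # systematic sweep of all 16 x 16 drug patterns with clean physical
  # evidence: the gate decides, and definite calls appear only behind
  # the documented gates
  pats <- expand.grid(rep(list(drugs), 4), stringsAsFactors = FALSE)
  for (i in seq_len(nrow(pats))) for (j in seq_len(nrow(pats))) {
    tt <- makeReporterTetrad(unlist(pats[i, ]), unlist(pats[j, ]),
                             southern = c("present", "absent",
                                          "absent", "absent"))
    ec <- callEvent(tt)
    hygR <- sum(pats[i, ] == "R")
    cyhS <- sum(pats[j, ] == "S")
    if (!((hygR == 3 && cyhS == 2) || (hygR == 2 && cyhS %in% c(1, 2))))
      expect_equal(ec@call, "ambiguous")
  }
})

test_that("classifier recovers simulator ground truth, degrading safely", {
  p <- simParamsHomologous(n = 4000, seed = 5)
  s <- simulateTetrads(p)
  calls <- callEvents(s)
  truth <- groundTruth(s)
  m <- merge(calls, truth[, c("tetrad_id", "event")])
  # full evidence: every four-viable tetrad recovers its generating class
  expect_gt(nrow(m), 3000)
  expect_equal(m$call, m$event)
  # karyotype withheld: loss events collapse to ambiguous, never to a
  # wrong definite class
  sp <- sporeData(s)
  sp$karyotype <- NA_character_
  sp$southern <- NA_character_
  blind <- tetradSet(sp, map = s@markerMap, groundTruth = truth)
  bm <- merge(callEvents(blind), truth[, c("tetrad_id", "event")])
  loss <- bm[bm$event %in% c("deletion", "usce", "gene_conversion"), ]
  expect_true(all(loss$call == "ambiguous"))
  keep <- bm[bm$event %in% c("none", "reciprocal_crossover"), ]
  expect_equal(keep$call, keep$event)
})

test_that("event tallies reproduce the printed percentages", {
  for (i in seq_len(nrow(table23))) {
    r <- table23[i, ]
    calls <- rep(c("usce", "deletion", "gene_conversion"),
                 c(r$usce, r$del, r$gc))
    tl <- tallyEvents(calls, total = r$total)
    dec <- if (r$strain == "top3id") 2 else 1
    expect_equal(round(tl$pctUnequal, dec), r$pctUnequal)
    if (r$gcOK) expect_equal(round(tl$pctConversion, 1), r$pctGC)
  }
  empty <- tallyEvents(character(), total = 120)
  expect_true(all(empty$counts == 0))
  expect_equal(empty$pctUnequal, 0)
  expect_equal(empty$pctConversion, 0)
})
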