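# Fixtures built in code: printed count tables used as inputs, and
# constructors for hand-made tetrads and count-encoded sheets.

# Map distances in the four- and three-viable tetrad classes of the
# homeologous diploids (counts and printed values).
table1 <- local({
  df <- read.table(header = TRUE, text = "
strain  interval       class PD NPD TT    cM   decimals
WT      HML_ADE1-HIS4  4    626 0   4   0.317  3
WT      HML_ADE1-HIS4  3    147 0   13  4.06   2
WT      HIS4-LEU2      4    630 0   1   0.079  3
WT      HIS4-LEU2      3    158 0   2   0.625  3
WT      LEU2-MAT       4    611 1   19  1.981  3
WT      LEU2-MAT       3    126 2   24  11.84  2
pCLB2   HML_ADE1-HIS4  4    194 0   11  2.7    1
pCLB2   HML_ADE1-HIS4  3    151 0   12  3.7    1
pCLB2   HIS4-LEU2      4    202 0   3   0.7    1
pCLB2   HIS4-LEU2      3    156 0   7   2.1    1
pCLB2   LEU2-MAT       4    179 2   24  8.8    1
pCLB2   LEU2-MAT       3    140 2   22  10.4   1
mlh1id  HML_ADE1-HIS4  4    744 0   13  0.9    1
mlh1id  HML_ADE1-HIS4  3    143 0   14  4.5    1
mlh1id  HIS4-LEU2      4    756 0   2   0.1    1
mlh1id  HIS4-LEU2      3    153 0   5   1.6    1
mlh1id  LEU2-MAT       4    728 1   31  2.4    1
mlh1id  LEU2-MAT       3    129 0   29  9.2    1
")
  df
})

# Printed three- vs four-viable G-test p-values for the same nine
# strain x interval pairs, with the number of significant digits printed.
table1P <- read.table(header = TRUE, text = "
strain  interval       p        sig
WT      HML_ADE1-HIS4  2.87e-6  3
WT      HIS4-LEU2      0.218    3
WT      LEU2-MAT       4.97e-8  3
pCLB2   HML_ADE1-HIS4  0.736    3
pCLB2   HIS4-LEU2      0.25     2
pCLB2   LEU2-MAT       0.86     2
mlh1id  HML_ADE1-HIS4  2e-4     1
mlh1id  HIS4-LEU2      0.0065   2
mlh1id  LEU2-MAT       4.27e-8  3
")

# Gene conversion and unequal recombination tallies for the homologous
# diploids (reporter assay), with printed percentages. The conversion
# percentage printed for sgs1-dC795 (2.6) disagrees with its own counts
# (4/177 = 2.26) and is excluded from assertions.
table23 <- read.table(header = TRUE, text = "
strain   gc  usce del total pctGC  pctUnequal gcOK
WT       11  6    0   255   4.3    2.4        TRUE
sgs1d    5   13   5   178   2.8    10.1       TRUE
dC795    4   4    8   177   2.6    6.8        FALSE
mlh1id   8   8    10  421   1.9    4.3        TRUE
top3id   4   9    4   225   1.8    5.78       TRUE
")

# Sister / non-sister tallies in the two-viable class with printed
# chi-square p-values.
table4 <- read.table(header = TRUE, text = "
strain  sisters nonsisters p      sig
sgs1d   110     191        3e-6   1
dC795   56      89         0.006  1
pCLB2   3       18         0.001  1
top3id  47      61         0.178  3
")

# |computed - printed| tolerance: agreement at the printed precision
# (half a unit in the last printed significant digit).
printedTol <- function(printed, sig) {
  10^(floor(log10(abs(printed))) - sig + 1) / 2 + 1e-12
}

# ---- hand-made tetrads --------------------------------------------------

# Allele patterns per (marker1, marker2) for the canonical classes.
classPatterns <- list(
  PD  = cbind(c("P1", "P1", "P2", "P2"), c("P1", "P1", "P2", "P2")),
  NPD = cbind(c("P1", "P1", "P2", "P2"), c("P2", "P2", "P1", "P1")),
  TT  = cbind(c("P1", "P1", "P2", "P2"), c("P1", "P2", "P1", "P2")))

# A four-viable tetrad with the given patterns at the two markers of an
# interval and NA elsewhere.
makeIntervalTetrad <- function(class, interval = c("HML_ADE1", "HIS4"),
                               id = "t1", strain = "s",
                               viable = rep(TRUE, 4),
                               map = yeastChrIIIMap()) {
  a <- matrix(NA_character_, 4, length(markers(map)),
              dimnames = list(NULL, markers(map)))
  pat <- classPatterns[[class]]
  a[, interval[1]] <- pat[, 1]
  a[, interval[2]] <- pat[, 2]
  tetrad(id, strain, viable, a, map = map)
}

# A reporter tetrad: four viable spores with drug/karyotype/Southern
# evidence and no allele calls.
makeReporterTetrad <- function(hyg, cyh, karyotype = rep("normal", 4),
                               southern = rep(NA, 4), id = "r1",
                               strain = "s", map = yeastChrIIIMap()) {
  a <- matrix(NA_character_, 4, length(markers(map)),
              dimnames = list(NULL, markers(map)))
  tetrad(id, strain, rep(TRUE, 4), a, hyg = hyg, cyh = cyh,
         karyotype = karyotype, southern = southern, map = map)
}

# Spore-level rows encoding given PD/NPD/TT counts for one interval
# (other markers NA). viableClass 4 emits four-viable tetrads;
# viableClass 3 masks the fourth spore (its genotype is then recovered
# by Mendelian inference).
sheetFromCounts <- function(strain, interval, PD, NPD, TT,
                            viableClass = 4, idPrefix = strain,
                            map = yeastChrIIIMap()) {
  mk <- markers(map)
  cls <- rep(c("PD", "NPD", "TT"), c(PD, NPD, TT))
  n <- length(cls)
  if (!n) return(NULL)
  rows <- lapply(seq_len(n), function(i) {
    a <- matrix(NA_character_, 4, length(mk), dimnames = list(NULL, mk))
    pat <- classPatterns[[cls[i]]]
    a[, interval[1]] <- pat[, 1]
    a[, interval[2]] <- pat[, 2]
    viable <- rep(TRUE, 4)
    if (viableClass == 3) {
      viable[4] <- FALSE
      a[4, ] <- NA_character_
    }
    data.frame(tetrad_id = sprintf("%s_%s_v%d_%04d", idPrefix,
                                   paste(interval, collapse = "."),
                                   viableClass, i),
               strain_id = strain, spore_index = 1:4, viable = viable,
               as.data.frame(a), mating = NA_character_,
               trp = NA_character_, hyg = NA_character_,
               cyh = NA_character_, karyotype = NA_character_,
               southern = NA_character_,
               stringsAsFactors = FALSE, check.names = FALSE)
  })
  do.call(rbind, rows)
}
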