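Package: tetradkit
Title: Tetrad Analysis, Recombination Statistics and Forward Meiosis
    Simulation for Yeast Crosses
Version: 0.99.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "maintainer@example.org")
Description: Classification and statistical analysis of meiotic tetrads
    from Saccharomyces crosses. Provides parental-ditype /
    non-parental-ditype / tetratype typing of four-viable and
    (via Mendelian dead-spore inference) three-viable tetrads, Perkins
    map distances with multinomial delta-method standard errors, G-tests
    of class distributions with Benjamini-Hochberg correction,
    homogeneity-gated pooling, detection of meiosis I non-disjunction
    from mating phenotypes, sister/non-sister calling from a
    centromere-linked marker, and a decision-table classifier for
    unequal sister-chromatid exchange, deletion and gene-conversion
    events scored with a two-cassette drug-resistance reporter. A
    mechanistic forward simulator of diploid meiosis (Poisson crossover
    placement, homeologous suppression, non-disjunction, half-crossover
    and sister-entanglement spore-death branches, reporter events)
    generates fully labelled synthetic tetrad sheets for validation.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports: methods, stats, utils, jsonlite
Suggests: testthat (>= 3.0.0), withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
Collate:
    'AllClasses.R'
    'AllGenerics.R'
    'markerMap.R'
    'tetrad-model.R'
    'tetrad-set.R'
    'recomb-stats.R'
    'event-classifier.R'
    'meiosis-sim.R'
    'io.R'
    'pipeline.R'
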