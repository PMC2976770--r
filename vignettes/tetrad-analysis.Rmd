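---
title: "Tetrad analysis and forward meiosis simulation with tetradkit"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Tetrad analysis and forward meiosis simulation with tetradkit}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(tetradkit)
```

# The analysis model

A yeast tetrad is the four haploid products of one meiosis. For a pair
of linked markers, a tetrad with 2:2 segregation at both ends falls
into exactly one of three classes: parental ditype (PD, no recombinant
spores), non-parental ditype (NPD, four recombinants, requiring a
four-strand double crossover) or tetratype (TT, two recombinants, one
crossover). The Perkins estimator

$$\mathrm{cM} = 100\,\frac{TT/2 + 3\,NPD}{PD + NPD + TT}$$

weights NPDs by three because, under no chromatid interference, each
observed four-strand double stands in for two two-strand and one
three-strand double that went uncounted. The estimator is unbiased for
short intervals, corrects for double but not higher-order exchanges,
and therefore saturates as the true distance grows: its expectation
falls below the truth from roughly 25 cM and approaches 66.7 cM
asymptotically. The package stores the estimate unrounded and leaves
display rounding to report rendering.

## Standard error

The published analyses cite an online calculator without formulas, so
the package states its own: treating the class counts as one
multinomial draw with proportions $(p, d, t)$ for (PD, NPD, TT) and
applying the delta method to the Perkins statistic gives

$$\mathrm{se} = 100\sqrt{\frac{t(1-t)/4 + 9\,d(1-d) - 3\,t\,d}{n}}.$$

The test suite cross-validates this closed form against a 100,000-
replicate multinomial bootstrap at several published count vectors
(agreement required within 5% relative error).

## Hypothesis tests

Class distributions are compared with the likelihood-ratio G-test,
$G = 2\sum O \ln(O/E)$, with expected counts from the margins. Two
conventions matter and both are deliberate:

* **Degrees of freedom retain all-zero columns.** Comparing two
  (PD, NPD, TT) rows that both have zero NPDs still uses
  $df = (2-1)(3-1) = 2$. Dropping the empty column leaves $G$
  unchanged but halves the df and changes the p-value; the retained-df
  convention is the one that reproduces the published three- versus
  four-viable p-values from their printed counts, and both behaviours
  are pinned by tests.
* **No Williams or Yates corrections.** The uncorrected statistics
  reproduce the published values; corrections would not.

The sister:non-sister 50:50 test is the ordinary 1-df goodness-of-fit
chi-square without continuity correction, again validated against the
published p-values. Families of comparisons are adjusted with
Benjamini–Hochberg (`bhAdjust()` delegates to the standard step-up
implementation and is checked against a brute-force oracle); family
membership is explicit — one family per report table — never inferred.

Pooling strains (e.g. several mutant alleles of one gene) is gated on
an r x 3 homogeneity G-test: the pooled counts are always returned,
but pooling is flagged inadmissible below the threshold
(`homogeneityAlpha`, default 0.05).

## Dead-spore inference and exclusions

Three-viable tetrads are completed by Mendel's first law: at a marker
where the survivors are 2:1, the dead spore must carry the allele seen
once. A 3:0 marker among survivors cannot be completed — it implies a
gene conversion — and the affected interval (only) is excluded as
unscorable rather than imputed; conversions are tallied separately.
The same rule applies to four-viable tetrads with non-2:2 markers.
This per-interval (not per-tetrad) exclusion is a documented choice:
the source analyses do not state their handling, and excluding only
the affected interval preserves information at the clean interval.
Every exclusion is logged with tetrad id and reason so report
denominators are auditable.

## Segregation-defect calls

* **Meiosis I non-disjunction** (chromosome III): two viable spores,
  both non-maters (disomes carry both MATa and MATalpha). Disomes are
  also Trp prototrophs via the centromere marker; this corroborates
  but is not required for the call. An unknown mating phenotype in a
  two-viable tetrad yields "undetermined", never FALSE.
* **Sister / non-sister**: in two-viable tetrads, matching TRP1
  phenotypes mean sister spores, differing phenotypes non-sisters.
  Under purely random death 1/3 of survivor pairs are sisters (two of
  the six spore pairs); excess sisters indicate non-disjunction,
  excess non-sisters indicate destruction of recombined, entangled
  chromatids.

## The reporter event classifier

The unequal-recombination reporter places HYG-CYH2 upstream of HIS4
and a second HYG downstream of LEU2 on one parent's chromosome III
(CYH2 dominant over the resistant cyh2-r background). The decision
table is gated by drug segregation among four-viable tetrads:

| Hyg R:S | Cyh S:R | karyotype / Southern | call |
|---|---|---|---|
| 3:1 | 2:2 | all normal | reciprocal crossover between cassettes |
| 2:2 | 1:3 | one faster band, CYH2 lost from it | deletion |
| 2:2 | 1:3 | one faster + one slower band | unequal sister-chromatid exchange |
| 2:2 | 1:3 | all normal, one CYH2 copy lost | gene conversion |
| 2:2 | 2:2 | all normal | none |

Physical evidence disambiguates only within a gate; anything missing
or contradictory (a slower band without the 1:3 Cyh pattern, a faster
band still carrying CYH2) is "ambiguous" with a diagnostic note —
the classifier degrades to ambiguity, never to a wrong definite call,
and never errors on odd evidence. Reciprocal crossovers are tallied
separately and excluded from the unequal-recombination percentage,
which counts USCE + deletions over all dissected tetrads. Event
calling is restricted to four-viable tetrads while all dissected
tetrads form the denominator, matching the published tallies; both
choices are configurable at the tally level.

# The simulator

`simulateTetrads()` is a mechanistic forward model, not a resampler.
Per meiosis, in a fixed documented order (so a seed fully determines
the output):

1. **Crossovers.** Each adjacent-marker interval receives a Poisson
   number of exchanges with mean $s\,d_i/50$ — 50 cM corresponds to
   one expected exchange per bivalent, the standard tetrad
   calibration; $s \in (0,1]$ is a global homeologous suppression
   factor. Each exchange picks one chromatid per homolog uniformly and
   swaps the segment on the centromere-distal side, so centromere
   alleles stay attached to their spindle poles and spores 1/2 and
   3/4 are sister pairs by construction. There is no crossover
   interference: the class marginal is the Poisson mixture of the
   chain PD -> TT; TT -> PD, NPD, TT with probabilities 1/4, 1/4,
   1/2; NPD -> TT, whose tetratype marginal is the closed form
   $T(d) = \tfrac{2}{3}(1 - e^{-3d/100})$. The suite verifies the
   simulator against both the closed form and a transition-matrix
   oracle at d = 1, 10, 50 and 200 cM with 100,000 meioses each.
2. **Non-disjunction.** A meiosis with zero crossovers anywhere on the
   chromosome suffers MI non-disjunction with probability `pNdj0`:
   both homologs travel to one pole, meiosis II gives two viable
   disomic spores (non-maters, Trp prototrophs, allele calls emitted
   NA because a P1/P2 call cannot express disomy) and two dead
   nullisomic spores.
3. **Half-crossovers.** Each exchange independently fails at second-end
   capture with probability `qHalf`; the spore inheriting the
   unrepaired reciprocal chromatid dies. This is what enriches
   recombinants among three-viable tetrads in diverged crosses.
4. **Entanglement.** With probability `pEnt` the meiosis carries an
   unresolved sister entanglement, modelled distal to the last marker
   on the centromere-right arm; if any exchange links the centromere
   to that end (i.e. falls in an interval right of the centromere),
   the two spores receiving the recombined chromatids die and the
   survivors are non-sisters. This is a deliberate geometric
   simplification of the entanglement-plus-crossover mechanism.
5. **Random death** at `pDeath` per remaining spore.
6. **Reporter events.** One event class (or none) is drawn per meiosis
   from the rates (`rCo`, `rDel`, `rUsce`, `rGc`) and consistent
   Hyg/Cyh/karyotype/Southern evidence is written onto the reporter
   parent's chromatids. Reporter evidence is generated from the event
   class independently of the marker-interval crossovers — a crossover
   between the cassettes *is* the reciprocal-crossover class — which
   keeps evidence and ground truth consistent by construction.

Every tetrad carries ground-truth labels (per-interval crossover
counts, per-spore death causes, event class, true sisterhood), making
the callers testable at 100% recovery.

## Default parameter sets

`simParamsHomeologous()` encodes the partial-hybrid wild-type
conditions: effective distances 0.317, 0.079 and 1.981 cM for the
three scored intervals (the third split 0.5 + 1.481 across the
centromere in proportion to physical position: LEU2 at ~85 kb, CEN3 at
~114 kb, MAT at ~200 kb), `pNdj0 = 0.12` so the marginal
non-disjunction frequency is ~11.5%, `qHalf = 0.8` and
`pDeath = 0.05`. The half-crossover and entanglement probabilities are
not published quantities; these defaults are illustrative magnitudes
chosen to reproduce the qualitative viability spectrum (a substantial
recombination-enriched three-viable class), and validation asserts
recovery of whatever values are configured, not of any published rate.
`simParamsHomologous()` encodes a homologous wild-type reporter cross:
distances 41.8, 15.5 and 27.7 cM (the homeologous values times the
published 132/196/14-fold reductions), `pDeath = 0.026` (~90%
four-viable tetrads), USCE and conversion rates 6/255 and 11/255, and
a nominal 1% inter-cassette crossover rate. Divergence can be modelled
either through the `suppression` factor or by setting effective
distances directly; the presets do the latter and leave
`suppression = 1`.

## What the simulator does and does not emulate

It reproduces: linkage with the correct no-interference class
distribution; the viability spectrum generated by the four death
mechanisms; non-mater disomes; the sister/non-sister bookkeeping; and
reporter evidence faithful to each event class. It does **not** model:
crossover interference (a counting-model hook is out of scope), gene
conversion tracts at the linkage markers (so the dead-spore inference
round-trip is exact on simulated data — real data contain conversions
that the analysis excludes as unscorable rather than recovers),
aneuploidy beyond the non-mater criterion, slow-growth phenotypes of
disomes, chromosome-scale sequence, or multi-event reporter tetrads.
Passing tests therefore demonstrate correctness of the estimators and
callers under the stated stochastic model, not robustness to every
artefact of real dissection data.

# Numerical and design choices

* All statistics are computed unrounded; report rendering rounds at
  display time (TSV) while JSON retains full precision.
* `gTest()` sums $O\ln(O/E)$ over positive cells only; zero observed
  cells contribute zero (their limit), and zero-margin cells produce
  no NaNs.
* Perkins recovery in validation is asserted within 3 delta-method
  standard errors at distances up to 10 cM and by class frequencies
  (4 Monte-Carlo SDs) elsewhere, reflecting the estimator's known
  bias range rather than a tolerance on the simulator.
* Validation problem sizes: 100,000 meioses per distance for the
  class-frequency checks, 10,000 tetrads for the dead-spore round
  trip and event-classifier recovery, 100,000 bootstrap replicates
  for the SE oracle. These sizes make the Monte-Carlo bands a few
  times tighter than the effects being checked.
* Missing data propagate as explicit "undetermined"/"unscorable"
  categories with reasons; nothing is silently coerced.
* The tetrad sheet is UTF-8, tab-separated, `NA` for missing, with
  `#!` header lines carrying the marker map and full simulation
  provenance, so a sheet is self-describing and byte-reproducible
  from its seed.
* Strict parsing aborts on the first malformed construct with tetrad
  ids and line numbers; lenient parsing drops offending tetrads with
  warnings.

# Known limitations

The Perkins estimator's bias beyond ~25 cM is inherent to the method,
not corrected here (no Stahl-style map functions, no NPD-ratio
interference test, no confidence intervals beyond the delta-method
SE). The entanglement geometry is a single-distal-region
simplification. Event classification assumes one event per tetrad.
The G-test df convention is a modelling commitment: users comparing
against software that drops empty columns will see different p-values
on tables with empty classes.
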