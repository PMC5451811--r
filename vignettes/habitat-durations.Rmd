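---
title: "Habitat type and species duration in the fossil record: methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Habitat type and species duration in the fossil record: methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
library(paleodur)
```

## The question and the data model

Living amphibians that breed in flowing water are, today, more
threatened than those breeding in ponds and lakes. `paleodur` implements
the machinery to ask the mirror-image question of the fossil record: did
species associated with high-flow-energy habitats persist for shorter or
longer spans of geological time than their still-water relatives?

The unit of observation is a fossil *occurrence*: a species name tied to
a geological stage (or a two-stage interval), a lithology string, palaeo
coordinates, a publication reference, and optional lagerstätte and
specimen-condition annotations. Occurrence tables arrive in
Paleobiology-Database or similar flavours; readers normalise the column
names, drop open-nomenclature records (names containing `aff.`, `cf.`
or `?`, matched literally and case-insensitively — the markers are
well-defined but their context is not, so we do not attempt name
parsing), collapse exact duplicates, and log every removal so that
`rows_in = rows_out + sum(removed)` holds by construction. Extant
species are removed against a user-supplied list, after the
proportion-of-living-taxa-with-a-fossil-record metric has been taken.

A *timescale* is an ordered set of non-overlapping stages with base and
top boundary ages in Ma. Stage midpoints `(base + top)/2` are the
temporal anchor for all durations.

## Habitat from lithology

Lithology is a first-order proxy for the energy of the depositional
environment, and hence for the water body the organism lived (and
fossilised) in. The classification has three levels:

* **Level 1** — four categories ordered by flow energy: *stagnant*,
  *low-velocity*, *medium-velocity*, *high-velocity*. Assignment walks
  an ordered rule table of case-insensitive substring patterns; the
  first match wins. The default table follows the grain-size gradient
  (clay/mud/shale and still-water chemical or organic sediments →
  stagnant; siltstone → low; sandstone → medium; conglomerate, breccia,
  gravel → high), with cross-stratified variants bumped one class up
  because bedforms indicate traction transport. Lithologies carrying no
  energy information ("cave infill", blanks) are excluded and counted.
  The table ships as data but is config-replaceable
  (`read_habitat_map()`), because any fixed vocabulary is a judgement
  call: the default is documented, not canonical.
* **Level 2** — *lentic* (stagnant) vs *lotic* (all flowing
  categories).
* **Level 3** — *low* energy (stagnant + low-velocity) vs *high*
  energy (medium + high-velocity).

Levels 2 and 3 are fixed total functions of level 1, so a species' sets
on the higher levels can never be larger than its level-1 set — a
property the test suite checks on randomised inputs. A species is
counted **once per category per level** no matter how many of its
occurrences support that category; this prevents heavily sampled
species from dominating the comparisons. The map format would permit
rules targeting level 2 or 3 directly (for lithologies diagnostic of,
say, lentic conditions without resolving flow velocity), but the default
map defines none.

Occurrences record a primary and sometimes a secondary lithology; only
the primary is used, as the depositional signal of record.

## Durations, ranges and their conventions

* `duration_stages` = inclusive index span from first to last occupied
  stage. Occurrences spanning two stages resolve to the older stage for
  first-occurrence purposes and the younger for last-occurrence — the
  conservative outer bound.
* `duration_ma` = |midpoint(first) − midpoint(last)|, rounded to integer
  My. "Rounded to the next million years" is read as round-half-away-
  from-zero; a `ceiling` switch implements the alternative reading.
  Singletons have duration 0 My by construction.
* Geographic range = number of distinct cells of a 2°×2° grid anchored
  at 0°, cells half-open `[2k, 2k+2)`, on the palaeocoordinates as
  given (no reprojection; occurrences without coordinates are skipped
  and logged). The default small/large stratification is 1 cell vs ≥2
  cells, with a median-split alternative.

## Record-quality metrics

**FreqRat** estimates per-stage preservation probability as
`f2²/(f1·f3)` from the counts of taxa with 1-, 2- and 3-stage ranges.
For geometric true durations with per-stage Bernoulli sampling at
probability *p*, the expected frequencies satisfy
E[f1] ∝ p·q/(1−a)², E[f2] ∝ p²q(1−q)/(1−a)², E[f3] ∝ p²q(1−q)²/(1−a)²
with `a = (1−p)(1−q)`, so the ratio of expectations is exactly *p* for
any extinction rate *q*. The package treats the equation's typography as
the Foote–Raup form; a `denominator_factor` switch provides the
`f2²/(2·f1·f3)` reading. Note the *estimator* (a ratio of noisy counts)
is consistent but not unbiased: at a few thousand taxa its sampling
standard deviation is of order 0.05–0.1, which is why the validation
checks the mean over replicate simulations and a large-n run rather
than demanding per-replicate precision.

**SCM** = known/assumed record within each taxon's range; 1 means
gapless. Ranks above species merge the occupied-stage sets of their
members (genus = first token of the binomial; family via a user
lookup). Two aggregation modes are provided because the choice is
genuinely open: *pooled* (Σknown/Σassumed, weighting long-ranged taxa
more) and *mean* (unweighted per-taxon average). Since singletons are
gapless by definition and inflate the metric, the endpoint-excluded
variant drops the first and last stage from both counts; taxa spanning
fewer than three stages then carry no information and are flagged
undefined rather than counted.

**Specimen completeness** (ordinal 1–5, isolated bones → multiple
skeletons) is compared between habitats and taxon groups with the same
trimmed-mean/Kruskal–Wallis/Wilcoxon machinery as durations. Scores are
expected only on a subset of occurrences.

## Singleton reliability diagnostics

A record dominated by single-stage species is only usable if those
singletons are biology, not artefact. Four checks:

1. **Stage-length correlations** — Spearman's rank correlation of stage
   length with per-stage richness, singleton count and singleton
   proportion. Richness uses range-through membership by default (a
   species counts in every stage of its range) with an occurrences-only
   alternative, since the right basis is not obvious. Constant inputs
   yield flagged, not crashing, results.
2. **Lagerstätte test** — 2×2 chi-square of lagerstätte membership
   (any flagged occurrence) against singleton status.
3. **Monographic effect** — singleton share among species appearing in
   references with more than 20 occurrences vs the whole dataset. The
   threshold is a parameter; 20 is the conventional default.
4. **Singletons by habitat** — chi-square of habitat category ×
   singleton status on levels 1 and 3, with standardised residuals to
   localise the deviation.

## Statistical engine

* **Trimmed mean**, trim = 0.1: drops `floor(n·trim)` values per tail,
  matching the convention of the describe-style summaries this field
  uses; the duration distribution is strongly right-skewed, so a robust
  location estimate is essential.
* **Kruskal–Wallis** with tie correction for the omnibus; degenerate
  all-equal input returns H = 0, p = 1, flagged.
* **Pairwise Wilcoxon**, two-sided: exact enumeration when both sides
  have ≤8 tie-free values, otherwise the normal approximation with tie
  and continuity correction. Exhaustive enumeration at n₁ = n₂ = 8
  shows the approximation within 0.011 of exact; at very small n
  (2–4) the gap grows to ~0.09, which is one reason the exact branch
  exists.
* **Benjamini–Hochberg** adjustment, applied jointly over the pairwise
  family of one comparison call — not across analyses, which is the
  convention of pairwise-test reports.
* **Chi-square**: Yates continuity correction on 2×2 tables only (the
  default of the field's toolchain), never on larger tables; a flag
  disables it.
* Taxon-scheme comparisons run at one hierarchical level per call —
  lissamphibian orders, or the higher groups
  Temnospondyli/No-Temnospondyli/Lepospondyli/No-Lepospondyli — so
  groups of different rank are never tested against each other. The
  complement groups overlap by construction; for the habitat-preference
  contingency table the disjoint partition
  (Temnospondyli/Lepospondyli/other) is used instead, since a
  contingency table must not double-count species.

## The synthetic-data generator

`simulate_record()` is a first-class module, not a fixture: it encodes
the study conditions the analyses are validated against.

* **Timescale**: 53 stages, lengths from a normal(5.7, 2.5) truncated
  below at 1 My — the stage-count and length scale of the
  Carboniferous-to-Holocene amphibian record.
* **Species**: four level-1 habitats with 214/130/56/18 species, true
  durations exponential with means 4/5/7/7 My. The exponential
  (memoryless extinction) is the simplest survivorship law consistent
  with the FreqRat derivation. Species originate uniformly in time.
* **Preservation**: per overlapped stage, an occurrence appears with
  habitat-specific probability 0.6/0.5/0.4/0.35 — calmer water
  preserves better, the gradient the specimen-completeness comparison
  expects. 5% of stages are lagerstätten with a 2× multiplier (capped
  at 1): lagerstätten are stage-scoped, the simplest model of
  "occurrences tagged as coming from a lagerstätte".
* **Observables**: lithology strings drawn from a vocabulary inverted
  from the default habitat map (guaranteeing round-trip assignability),
  with a 10% noise fraction of non-informative lithologies to exercise
  the exclusion path; coordinates scatter (sd 5°) around a per-species
  range centre; ordinal specimen scores on 25% of occurrences, with
  higher scores in calmer habitats; reference ids grouped within
  stages; taxon groups drawn from habitat-specific mixtures (e.g.
  Lepospondyli weighted toward stagnant).

Species with no preserved occurrence exist in the ground truth but not
in the occurrence table, so recovery, truncation and estimator bias can
all be measured (`truth_report()`).

What the generator deliberately does **not** emulate: temporal
clustering of congeners (genus identities are assigned serially, so
genus-rank completeness metrics on simulated data are pessimistic),
plate motion or any spatial structure beyond the range centre,
speciation/phylogeny, database-specific taxonomic noise, and secular
trends in preservation. Passing tests on simulated data therefore
validate the *machinery* — filters, arithmetic, estimators, test
calibration, direction recovery — not the realism of any particular
parameter value for the real record.

Two emergent properties are worth knowing. First, because high-energy
habitats combine longer true durations with worse preservation, the
simulated singleton share can end up *higher* in high-energy settings —
the net of two opposing forces, either of which can dominate for other
parameter choices. Second, with these study conditions the observed
lotic−lentic trimmed-mean contrast is small (the 1–3 My true gaps are
roughly halved by range truncation), so single runs at the default sizes
are not expected to reach significance; the direction-recovery
validation instead uses a dedicated two-habitat configuration (5 vs
8 My, 500 species per side, p = 0.5) where the per-replicate success
rate is high.

## Validation problem sizes

The test suite checks, among others: exact equivalence of SCM with a
brute-force gap enumeration on 1,000 random occupancy sets; exhaustive
duration arithmetic over all stage pairs of a 20-stage timescale;
Wilcoxon normal-vs-exact agreement exhaustively at n₁ = n₂ = 8; BH and
chi-square against direct formulas; FreqRat consistency (mean over 10
replicates of 2,000 taxa at p ∈ {0.3, 0.5, 0.7}, plus one 200,000-taxon
run); type-I calibration of the singleton-habitat test (200 null
datasets) and of the level-2 duration comparison (200 null pipeline
runs); and direction recovery over 20 replicates. These sizes keep the
whole suite in the minutes range while leaving the Monte-Carlo error
well below the tolerances tested.

## Known limitations

* Habitat assignment inherits every weakness of free-text lithology:
  the default rule table cannot adjudicate genuinely ambiguous entries,
  and out-of-habitat transport is invisible to it.
* FreqRat point estimates on datasets of a few hundred taxa carry
  sampling error comparable to the differences one might want to
  interpret; treat them as order-of-magnitude summaries.
* Range-through richness and the midpoint duration convention both
  discretise time at stage resolution; durations shorter than a stage
  are indistinguishable from zero.
* The complement taxon groups (No-X) share members with every other
  group, so their pairwise tests are not independent; they are reported
  because the field reports them, and should be read accordingly.
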