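# paleodur

Habitat-dependent species durations in the fossil record.

`paleodur` is an R package for asking whether the habitat a species lived
in — inferred from the lithology its fossils are embedded in — predicts
how long that species persisted in the geological record. It was built
around the amphibian fossil record, where living species breeding in
flowing water (lotic habitats) are more threatened than pond and lake
breeders (lentic habitats), and the question is whether the same
extinction-risk gradient held in deep time. The package covers the whole
workflow: reading Paleobiology-Database-flavoured occurrence tables,
vetting the record with standard completeness metrics, classifying
occurrences into flow-energy habitat categories, computing stratigraphic
durations and palaeogeographic range sizes, and comparing durations
between habitats and taxonomic groups with robust statistics. A forward
simulator with known ground truth makes every step testable without any
database download.

## The metrics and models at the core

**Durations.** A species' duration is measured two ways: the number of
geological stages from first to last occurrence (used by the
completeness metrics), and the distance in millions of years between the
midpoints of the first and last stage, rounded to integer My (used by
the habitat comparisons). Species known from a single stage
("singletons") have duration 0 My.

**FreqRat.** The Foote–Raup frequency-ratio estimator of per-stage
preservation probability,

    FreqRat = f2^2 / (f1 * f3),

where `f1`, `f2`, `f3` count taxa with stratigraphic ranges of exactly
one, two and three stages. Under geometric true durations and
independent per-stage sampling, the ratio of expected frequencies equals
the per-stage preservation probability exactly.

**SCM.** The simple completeness metric is the share of stages inside a
taxon's range that actually contain fossils: `SCM = known / assumed`,
with 1 meaning a gapless record. Because range endpoints are occupied by
definition, the package also offers the endpoint-excluded variant, which
removes the contribution of the singleton-heavy part of the record.

**Habitat classification.** Lithologies map to four level-1 flow-energy
categories (*stagnant*, *low-velocity*, *medium-velocity*,
*high-velocity*) through an ordered, config-replaceable rule table;
fixed rollups collapse these to *lentic*/*lotic* (level 2) and
*low*/*high* energy (level 3). Each species enters a category at most
once per level, however many lithologies it occurs in.

**Comparisons.** Durations (and grid-cell range sizes) are compared
between groups with 10%-trimmed means, a Kruskal–Wallis omnibus test,
and pairwise two-sided Wilcoxon rank-sum tests with Benjamini–Hochberg
adjustment; habitat-preference and singleton-distribution questions use
Pearson chi-square tests (Yates-corrected on 2×2 tables). Bias
diagnostics cover stage-length correlations, lagerstätte
over-representation and the monographic effect.

## Worked example

Using the small synthetic example dataset shipped with the package:

```r
library(paleodur)
occ <- read_occurrences(system.file("extdata", "example_occurrences.csv",
                                    package = "paleodur"), dialect = "pbdb")
filter_log(occ)
#>            rows_in  qualifier_removed duplicates_removed           rows_out
#>                 25                  1                  1                 23
```

One row carried an open-nomenclature name (`cf.`) and one was an exact
duplicate; both were removed and logged. Durations and the quality
metrics:

```r
stages <- read_timescale(system.file("extdata", "example_timescale.csv",
                                     package = "paleodur"))
s <- species_summaries(occ, stages)
fr <- freqrat(s$duration_stages)
#> FreqRat: f = (5, 3, 3), value = 0.600
aggregate_scm(s, "species", "pooled")$value
#> [1] 0.7428571
```

Five species span one stage, three span two and three span three, so the
estimated per-stage preservation probability is `3^2/(5*3) = 0.6`; the
pooled SCM says 74% of the stages inside species ranges contain fossils.
The headline comparison, durations by lentic vs lotic habitat:

```r
hs <- species_habitat_sets(occ)
compare_durations(s, hs, grouping = "level2")
#> Group comparison: duration_by_level2
#>   group n median trimmed_mean
#>  lentic 7      0     10.14286
#>   lotic 5     14     12.20000
#> Kruskal-Wallis: H = 1.349, df = 1, p = 0.2455
#> BH-adjusted pairwise Wilcoxon p-values:
#>        lentic  lotic
#> lentic     NA 0.2808
#> lotic  0.2808     NA
```

Lotic species have the larger trimmed mean duration here (12.2 vs
10.1 My), but at 12 species the difference is, unsurprisingly, not
significant. On realistically sized data the same call powers the full
analysis; `run_all()` executes the complete battery (quality gates,
diagnostics, all grouping levels, taxonomic schemes, range-size and
singleton controls) and writes one TSV per analysis plus a JSON summary.

## The analysis workflow

The `analysis/` scripts run the whole study on the reference synthetic
conditions and leave their outputs under `results/`:

```sh
Rscript analysis/01_simulate.R          # generate the reference record
Rscript analysis/02_quality.R           # FreqRat, SCM, specimen scores
Rscript analysis/03_diagnostics.R       # singleton reliability checks
Rscript analysis/04_habitat_durations.R # habitat/duration comparisons
```

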