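## Fossil-record quality metrics: FreqRat preservation probability,
## simple completeness metric (SCM), proportion of living taxa with a
## fossil record, and specimen-completeness comparisons.

#' FreqRat preservation probability
#'
#' Foote-Raup frequency-ratio estimator of the per-stage preservation
#' probability, `f2^2 / (f1 * f3)`, where `f1`, `f2`, `f3` are the numbers
#' of taxa with stratigraphic ranges of exactly one, two and three
#' geological stages. Lower values indicate more short-ranged taxa and a
#' lower preservation probability. The ratio is invariant to using counts
#' or proportions; counts are reported.
#'
#' @param durations_stages Integer vector (>= 1) of per-taxon range lengths
#'   in stages.
#' @param denominator_factor Constant multiplying `f1 * f3` (default 1;
#'   set 2 for the alternative reading of the ratio).
#' @return List with `f1`, `f2`, `f3`, `value` and `undefined` (`TRUE`
#'   when any of the three frequencies is zero, in which case `value` is
#'   `NA`).
#' @export
freqrat <- function(durations_stages, denominator_factor = 1) {
  stopifnot(length(durations_stages) > 0, all(durations_stages >= 1))
  f <- tabulate(as.integer(durations_stages), nbins = 3)
  undefined <- any(f == 0)
  value <- if (undefined) NA_real_
           else f[2]^2 / (denominator_factor * f[1] * f[3])
  list(f1 = f[1], f2 = f[2], f3 = f[3], value = value, undefined = undefined)
}

#' Simple completeness metric (SCM)
#'
#' Ratio of the known record (stages within a taxon's range that actually
#' contain an occurrence) to the assumed record (all stages spanned from
#' first to last occurrence, inclusive). 1 means a gapless record. With
#' `exclude_endpoints` the first and last stage — occupied by definition —
#' are dropped from both counts, which removes the contribution of
#' single-interval taxa; taxa spanning fewer than three stages then have
#' no interior and yield an undefined result.
#'
#' @param occupied_stage_indices Integer set of occupied stage indices.
#' @param exclude_endpoints Drop the range endpoints from both counts.
#' @return List with `known`, `assumed`, `value`, `endpoints_excluded`,
#'   `undefined`.
#' @export
scm <- function(occupied_stage_indices, exclude_endpoints = FALSE) {
  stopifnot(length(occupied_stage_indices) > 0)
  s <- sort(unique(as.integer(occupied_stage_indices)))
  lo <- min(s); hi <- max(s)
  if (exclude_endpoints) {
    assumed <- max(hi - lo + 1L - 2L, 0L)
    known <- sum(s > lo & s < hi)
  } else {
    assumed <- hi - lo + 1L
    known <- length(s)
  }
  undefined <- assumed == 0L
  list(known = known, assumed = assumed,
       value = if (undefined) NA_real_ else known / assumed,
       endpoints_excluded = exclude_endpoints, undefined = undefined)
}

## genus = first whitespace-separated token of the binomial
.genus_of <- function(species_name) {
  vapply(strsplit(species_name, "\\s+"), `[`, character(1), 1)
}

#' Aggregate SCM over taxa at a taxonomic level
#'
#' Computes the SCM at species, genus or family level. Higher-rank
#' occupancy sets are the unions of their species' occupied stages (genus
#' = first word of the binomial; family from a user-supplied lookup).
#' Pooled mode divides summed known by summed assumed records; mean mode
#' averages per-taxon ratios.
#'
#' @param summaries Species summary table ([species_summaries()]).
#' @param level `"species"`, `"genus"` or `"family"`.
#' @param mode `"pooled"` or `"mean"`.
#' @param family_lookup Data frame (`species_name`, `family`), required
#'   for family level.
#' @param exclude_endpoints Passed to [scm()].
#' @return List with `value`, `n_taxa`, `level`, `mode`.
#' @export
aggregate_scm <- function(summaries, level = c("species", "genus", "family"),
                          mode = c("pooled", "mean"), family_lookup = NULL,
                          exclude_endpoints = FALSE) {
  level <- match.arg(level)
  mode <- match.arg(mode)
  taxon <- switch(level,
    species = summaries$species_name,
    genus = .genus_of(summaries$species_name),
    family = {
      if (is.null(family_lookup)) {
        stop("family-level SCM requires a family_lookup table")
      }
      fam <- family_lookup$family[match(summaries$species_name,
                                        family_lookup$species_name)]
      if (anyNA(fam)) {
        stop("species missing from family lookup: ",
             paste(utils::head(summaries$species_name[is.na(fam)], 5),
                   collapse = ", "))
      }
      fam
    })
  sets <- lapply(split(summaries$occupied_stages, taxon),
                 function(l) sort(unique(unlist(l))))
  per <- lapply(sets, scm, exclude_endpoints = exclude_endpoints)
  per <- per[!vapply(per, `[[`, logical(1), "undefined")]
  if (length(per) == 0) {
    return(list(value = NA_real_, n_taxa = 0L, level = level, mode = mode))
  }
  value <- if (mode == "pooled") {
    sum(vapply(per, `[[`, numeric(1), "known")) /
      sum(vapply(per, `[[`, numeric(1), "assumed"))
  } else {
    mean(vapply(per, `[[`, numeric(1), "value"))
  }
  list(value = value, n_taxa = length(per), level = level, mode = mode)
}

#' Proportion of living taxa with a fossil record
#'
#' The share of an extant taxon list already known as fossils — a basic
#' measure of a group's preservation potential.
#'
#' @param extant_taxa Character set of extant taxon names (non-empty).
#' @param fossil_taxa Character set of taxa with a fossil record.
#' @return Proportion in `[0, 1]`.
#' @export
proportion_with_fossil <- function(extant_taxa, fossil_taxa) {
  extant_taxa <- unique(extant_taxa)
  if (length(extant_taxa) == 0) stop("extant taxon set is empty")
  length(intersect(extant_taxa, fossil_taxa)) / length(extant_taxa)
}

#' Compare specimen completeness between groups
#'
#' Compares ordinal 1-5 specimen-condition scores (isolated bones up to
#' multiple skeletons) between habitat categories or taxonomic groups:
#' per-group trimmed means, a Kruskal-Wallis omnibus test and BH-adjusted
#' pairwise Wilcoxon tests. Occurrences without a score are dropped.
#'
#' @param tab An `occurrence_table` with `specimen_score` on the included
#'   occurrences.
#' @param by `"habitat"` (level-1 category of each occurrence's lithology)
#'   or `"taxon_group"`.
#' @param map Habitat map used when `by = "habitat"`.
#' @param groups Optional restriction: keep only these group labels.
#' @param trim Trim fraction for the trimmed means.
#' @return A `group_comparison` object ([compare_groups()]).
#' @export
specimen_completeness_compare <- function(tab, by = c("habitat", "taxon_group"),
                                          map = default_habitat_map(),
                                          groups = NULL, trim = 0.1) {
  by <- match.arg(by)
  keep <- !is.na(tab$specimen_score)
  tab <- tab[keep, , drop = FALSE]
  label <- if (by == "habitat") assign_level1(tab$lithology, map)
           else tab$taxon_group
  ok <- label != "excluded"
  label <- label[ok]
  score <- tab$specimen_score[ok]
  if (!is.null(groups)) {
    keep <- label %in% groups
    label <- label[keep]; score <- score[keep]
  }
  g <- split(as.numeric(score), label)
  g <- g[vapply(g, length, integer(1)) > 0]
  if (length(g) < 2) stop("specimen comparison needs >= 2 non-empty groups")
  compare_groups(g, trim = trim, grouping = paste0("specimen_score_by_", by))
}
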