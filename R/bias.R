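## Reliability checks for single-interval taxa: stage-length correlations,
## lagerstaetten effect, monographic effect, singleton-by-habitat tests.
## A high share of single-interval species is only trustworthy if it is
## not manufactured by the structure of the rock/sampling record.

#' Spearman correlations of stage length with richness and singletons
#'
#' Builds the per-stage table (stage length in My, species richness,
#' number and proportion of single-interval species) and correlates stage
#' length with each of the three quantities using Spearman's rank
#' correlation. A correlation would indicate that single-interval species
#' are an artefact of the temporal resolution of the rock record rather
#' than genuinely short-lived. Richness counts species ranging through a
#' stage (every stage from first to last occurrence) by default;
#' `membership = "occurrences"` counts only stages with an actual
#' occurrence. Singletons are counted in their unique stage.
#'
#' @param stages Stage table.
#' @param summaries Species summary table.
#' @param membership `"range_through"` or `"occurrences"`.
#' @return List with `per_stage` (data frame) and `correlations` (data
#'   frame: variable, rho, p_value, undefined). A constant variable yields
#'   an undefined flagged row.
#' @export
stage_singleton_correlations <- function(stages, summaries,
                                         membership = c("range_through",
                                                        "occurrences")) {
  membership <- match.arg(membership)
  if (nrow(stages) < 3) stop("need >= 3 stages")
  present <- function(s) {
    if (membership == "range_through") {
      summaries$first_stage_index <= s & summaries$last_stage_index >= s
    } else {
      vapply(summaries$occupied_stages, function(o) s %in% o, logical(1))
    }
  }
  richness <- vapply(stages$index, function(s) sum(present(s)), integer(1))
  singly <- vapply(stages$index, function(s) {
    sum(summaries$is_single_interval & summaries$first_stage_index == s)
  }, integer(1))
  per_stage <- data.frame(
    stage_index = stages$index, stage_name = stages$name,
    length_ma = stages$length_ma, richness = richness,
    n_singletons = singly,
    prop_singletons = ifelse(richness > 0, singly / richness, NA_real_)
  )
  cors <- lapply(c(richness = "richness", n_singletons = "n_singletons",
                   prop_singletons = "prop_singletons"), function(v) {
    y <- per_stage[[v]]
    ok <- !is.na(y)
    if (length(unique(per_stage$length_ma[ok])) < 2 ||
        length(unique(y[ok])) < 2) {
      return(data.frame(variable = v, rho = NA_real_, p_value = NA_real_,
                        undefined = TRUE))
    }
    ct <- suppressWarnings(
      stats::cor.test(per_stage$length_ma[ok], y[ok], method = "spearman",
                      exact = FALSE))
    data.frame(variable = v, rho = unname(ct$estimate),
               p_value = ct$p.value, undefined = FALSE)
  })
  list(per_stage = per_stage,
       correlations = do.call(rbind, c(cors, make.row.names = FALSE)))
}

#' Lagerstaetten effect on single-interval species
#'
#' Compares the proportion of single-interval species between species with
#' at least one lagerstaette occurrence and all remaining species, via
#' Pearson's chi-square on the 2x2 count table (Yates continuity
#' correction by default).
#'
#' @param summaries Species summary table (`in_lagerstatte`,
#'   `is_single_interval`).
#' @param yates Apply continuity correction.
#' @return List with `table` (2x2 counts), `proportions` (singleton share
#'   per stratum), `statistic`, `df`, `p_value`.
#' @export
lagerstatten_test <- function(summaries, yates = TRUE) {
  if (length(unique(summaries$in_lagerstatte)) < 2) {
    stop("need both lagerstaette and non-lagerstaette species")
  }
  tab <- table(
    lagerstatte = factor(summaries$in_lagerstatte, c(TRUE, FALSE),
                         c("lagerstatte", "other")),
    singleton = factor(summaries$is_single_interval, c(TRUE, FALSE),
                       c("singleton", "multi"))
  )
  ct <- .chisq_counts(tab, yates = yates)
  list(table = tab,
       proportions = prop.table(tab, margin = 1)[, "singleton"],
       statistic = unname(ct$statistic), df = unname(ct$parameter),
       p_value = ct$p.value)
}

#' Monographic effect on single-interval species
#'
#' Large publications (references covering more than `min_occurrences`
#' occurrences) concentrate sampling effort and can inflate apparent
#' singletons. Reports the proportion of single-interval species among
#' species appearing in such references versus among all species; similar
#' proportions argue against a monographic effect.
#'
#' @param tab Occurrence table with `reference_id`.
#' @param summaries Species summary table.
#' @param min_occurrences Threshold above which a reference counts as a
#'   large publication (default 20).
#' @return List with `proportion_large_pubs` (`NA` + `undefined` flag when
#'   no reference qualifies), `proportion_overall`, `n_large_refs`,
#'   `n_species_large`.
#' @export
monographic_effect <- function(tab, summaries, min_occurrences = 20) {
  singleton <- summaries$is_single_interval[
    match(tab$species_name, summaries$species_name)]
  ref_n <- table(tab$reference_id)
  large <- names(ref_n)[ref_n > min_occurrences]
  sp_large <- unique(tab$species_name[tab$reference_id %in% large])
  overall <- mean(summaries$is_single_interval)
  if (length(sp_large) == 0) {
    return(list(proportion_large_pubs = NA_real_, undefined = TRUE,
                proportion_overall = overall, n_large_refs = 0L,
                n_species_large = 0L))
  }
  prop_large <- mean(summaries$is_single_interval[
    summaries$species_name %in% sp_large])
  list(proportion_large_pubs = prop_large, undefined = FALSE,
       proportion_overall = overall, n_large_refs = length(large),
       n_species_large = length(sp_large))
}

#' Are single-interval species distributed evenly across habitats?
#'
#' Chi-square test of the habitat category x singleton (yes/no)
#' contingency table, species counted once per category on the requested
#' level. Reports expected counts and standardised residuals so the
#' over/under-represented categories can be identified.
#'
#' @param summaries Species summary table.
#' @param habitat_sets Long habitat table.
#' @param level Habitat level: 1, 2 or 3 (or `"level1"` etc.).
#' @param yates Continuity correction for 2x2 tables.
#' @return List with `observed`, `expected`, `residuals`, `statistic`,
#'   `df`, `p_value`, `proportions` (singleton share per category).
#' @export
singleton_habitat_test <- function(summaries, habitat_sets, level = 1,
                                   yates = TRUE) {
  lev <- if (is.numeric(level)) paste0("level", level) else level
  hs <- habitat_sets[habitat_sets$level == lev, , drop = FALSE]
  m <- merge(hs, summaries[c("species_name", "is_single_interval")],
             by = "species_name")
  empty <- setdiff(unique(hs$category), unique(m$category))
  if (length(empty) > 0) {
    warning("dropping empty habitat categor(ies): ",
            paste(empty, collapse = ", "))
  }
  if (length(unique(m$category)) < 2) {
    stop("singleton-by-habitat test needs >= 2 populated categories")
  }
  tab <- table(category = m$category,
               singleton = factor(m$is_single_interval, c(TRUE, FALSE),
                                  c("singleton", "multi")))
  ct <- .chisq_counts(tab, yates = yates)
  list(observed = tab, expected = ct$expected, residuals = ct$stdres,
       statistic = unname(ct$statistic), df = unname(ct$parameter),
       p_value = ct$p.value,
       proportions = prop.table(tab, margin = 1)[, "singleton"])
}
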