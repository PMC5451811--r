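## End-to-end orchestration: ingest -> quality metrics -> bias
## diagnostics -> habitat assignment -> durations/ranges -> comparisons.
## Quality gates run before any inference, mirroring the analysis order
## of the workflow scripts; every number in the run summary is assembled
## from exactly one module call, never recomputed.

## rank-level range lengths (stages) for FreqRat above the species level
.rank_durations <- function(summaries, level, family_lookup = NULL) {
  taxon <- switch(level,
    species = summaries$species_name,
    genus = .genus_of(summaries$species_name),
    family = {
      if (is.null(family_lookup)) return(NULL)
      family_lookup$family[match(summaries$species_name,
                                 family_lookup$species_name)]
    })
  if (is.null(taxon) || anyNA(taxon)) return(NULL)
  vapply(split(summaries$occupied_stages, taxon), function(l) {
    s <- unlist(l); max(s) - min(s) + 1L
  }, integer(1))
}

#' Run the full analysis pipeline
#'
#' Executes, in order: ingest and filtering; fossil-record quality metrics
#' (FreqRat at species/genus/family rank, SCM pooled and mean, with and
#' without range endpoints, proportion of living taxa with a fossil
#' record, specimen completeness by habitat and taxon); single-interval
#' bias diagnostics (stage-length correlations, lagerstaetten,
#' monographic effect, singletons by habitat); habitat assignment;
#' durations and palaeo-grid range sizes; and the comparison battery
#' (habitat levels 1-3, taxon schemes, within-taxon, range strata,
#' singleton-excluded). If no occurrence has an assignable lithology the
#' habitat-dependent stages are skipped with an explicit notice while the
#' quality metrics are still produced.
#'
#' @param occurrences An `occurrence_table` or a file path readable by
#'   [read_occurrences()].
#' @param timescale A stage table or a file path for [read_timescale()].
#' @param habitat_map A `habitat_map` (default [default_habitat_map()]).
#' @param dialect Dialect for reading `occurrences` from a path.
#' @param extant_names Optional extant species names, removed after the
#'   preservation-potential metric is computed.
#' @param synonyms Optional synonym map applied at read time.
#' @param family_lookup Optional (`species_name`, `family`) table enabling
#'   family-rank metrics.
#' @param rounding Duration rounding mode ([species_duration()]).
#' @param yates Continuity correction on 2x2 chi-square tables.
#' @param freqrat_denominator Denominator factor for [freqrat()].
#' @param range_rule Rule for [stratify_by_range()].
#' @param trim Trim fraction for all trimmed means.
#' @param out_dir Optional directory: write every result table as TSV
#'   plus a machine-readable `summary.json`.
#' @return A `paleodur_run` list: `tables` (named data frames), `results`
#'   (the underlying result objects), `summary` (nested list) and `log`
#'   (named counts).
#' @export
run_all <- function(occurrences, timescale,
                    habitat_map = default_habitat_map(),
                    dialect = "generic", extant_names = NULL,
                    synonyms = NULL, family_lookup = NULL,
                    rounding = "nearest", yates = TRUE,
                    freqrat_denominator = 1, range_rule = "one_cell",
                    trim = 0.1, out_dir = NULL) {
  ## ---- ingest ----
  tab <- if (is.character(occurrences)) {
    read_occurrences(occurrences, dialect = dialect, synonyms = synonyms)
  } else occurrences
  stages <- if (is.character(timescale)) read_timescale(timescale)
            else timescale
  prop_fossil <- if (!is.null(extant_names)) {
    proportion_with_fossil(extant_names, unique(tab$species_name))
  } else NA_real_
  if (!is.null(extant_names)) tab <- drop_extant(tab, extant_names)
  if (nrow(tab) == 0) stop("ingest: no occurrences left after filtering")
  log <- filter_log(tab)

  ## ---- durations, ranges ----
  summaries <- species_summaries(tab, stages, rounding = rounding)
  summaries <- stratify_by_range(summaries, rule = range_rule)

  ## ---- quality metrics ----
  qrows <- list()
  addq <- function(metric, rank, value, n) {
    qrows[[length(qrows) + 1L]] <<- data.frame(
      metric = metric, rank = rank, value = value, n = n,
      stringsAsFactors = FALSE)
  }
  for (lev in c("species", "genus", "family")) {
    dur <- .rank_durations(summaries, lev, family_lookup)
    if (is.null(dur)) next
    fr <- freqrat(dur, denominator_factor = freqrat_denominator)
    addq("freqrat", lev, fr$value, length(dur))
    for (mode in c("pooled", "mean")) {
      sc <- aggregate_scm(summaries, level = lev, mode = mode,
                          family_lookup = family_lookup)
      addq(paste0("scm_", mode), lev, sc$value, sc$n_taxa)
      sce <- aggregate_scm(summaries, level = lev, mode = mode,
                           family_lookup = family_lookup,
                           exclude_endpoints = TRUE)
      addq(paste0("scm_", mode, "_no_endpoints"), lev, sce$value, sce$n_taxa)
    }
  }
  if (!is.na(prop_fossil)) {
    addq("proportion_living_with_fossil", "species", prop_fossil,
         length(unique(extant_names)))
  }
  addq("median_stage_length_ma", "stage", stats::median(stages$length_ma),
       nrow(stages))
  quality <- do.call(rbind, c(qrows, make.row.names = FALSE))

  specimen_cmp <- tryCatch(
    specimen_completeness_compare(tab, by = "habitat", map = habitat_map,
                                  trim = trim),
    error = function(e) NULL)

  ## ---- bias diagnostics ----
  corrs <- stage_singleton_correlations(stages, summaries)
  lager <- tryCatch(lagerstatten_test(summaries, yates = yates),
                    error = function(e) NULL)
  mono <- monographic_effect(tab, summaries)

  ## ---- habitat assignment ----
  habitat_sets <- species_habitat_sets(tab, habitat_map)
  hlog <- attr(habitat_sets, "habitat_log")
  comparisons <- list()
  singleton_tests <- list()
  notices <- character(0)
  if (hlog[["species_assigned"]] < 2 || nrow(habitat_sets) == 0) {
    notices <- c(notices,
                 "no assignable lithologies: habitat comparisons skipped")
  } else {
    addcmp <- function(name, expr) {
      out <- tryCatch(expr, error = function(e) {
        notices <<- c(notices, paste0(name, " skipped: ",
                                      conditionMessage(e)))
        NULL
      })
      if (!is.null(out)) comparisons[[name]] <<- out
    }
    for (lev in c("level1", "level2", "level3")) {
      addcmp(paste0("duration_", lev),
             compare_durations(summaries, habitat_sets, grouping = lev,
                               trim = trim))
      addcmp(paste0("duration_", lev, "_no_singletons"),
             compare_durations(summaries, habitat_sets, grouping = lev,
                               exclude_singletons = TRUE, trim = trim))
    }
    for (sch in c("lissamphibia", "higher")) {
      addcmp(paste0("duration_", sch),
             compare_durations(summaries, habitat_sets, grouping = sch,
                               trim = trim))
    }
    for (tx in unique(summaries$taxon_group)) {
      addcmp(paste0("duration_level1_within_", tx),
             compare_durations(summaries, habitat_sets, grouping = "level1",
                               taxon = tx, trim = trim))
    }
    for (lev in c("level1", "level3")) {
      addcmp(paste0("range_", lev),
             compare_ranges(summaries, habitat_sets, grouping = lev,
                            trim = trim))
    }
    for (stratum in c("small", "large")) {
      addcmp(paste0("duration_level3_", stratum, "_range"),
             compare_durations(summaries, habitat_sets, grouping = "level3",
                               range_stratum = stratum, trim = trim))
    }
    if (!is.null(specimen_cmp)) comparisons$specimen_by_habitat <- specimen_cmp
    for (lev in c(1, 3)) {
      singleton_tests[[paste0("level", lev)]] <- tryCatch(
        singleton_habitat_test(summaries, habitat_sets, level = lev,
                               yates = yates),
        error = function(e) NULL)
    }
  }
  pref <- lapply(c(lissamphibia = "lissamphibia", higher = "higher"),
                 function(sch) tryCatch(
                   habitat_preference_test(summaries, habitat_sets,
                                           scheme = sch, yates = yates),
                   error = function(e) NULL))

  ## ---- assemble ----
  comparison_tbl <- if (length(comparisons) > 0) {
    do.call(rbind, c(unname(lapply(names(comparisons), function(nm) {
      cbind(analysis = nm, comparison_report(comparisons[[nm]]))
    })), make.row.names = FALSE))
  } else NULL
  group_tbl <- if (length(comparisons) > 0) {
    do.call(rbind, c(unname(lapply(names(comparisons), function(nm) {
      cbind(analysis = nm, comparisons[[nm]]$summary)
    })), make.row.names = FALSE))
  } else NULL

  summary <- list(
    counts = c(as.list(log), as.list(hlog),
               n_species = nrow(summaries),
               n_singletons = sum(summaries$is_single_interval)),
    quality = quality,
    diagnostics = list(
      stage_correlations = corrs$correlations,
      lagerstatten = if (!is.null(lager)) {
        list(statistic = lager$statistic, df = lager$df,
             p_value = lager$p_value,
             proportions = as.list(lager$proportions))
      },
      monographic = mono[c("proportion_large_pubs", "proportion_overall")],
      singleton_by_habitat = lapply(singleton_tests, function(x) {
        if (is.null(x)) NULL
        else list(statistic = x$statistic, df = x$df, p_value = x$p_value,
                  proportions = as.list(x$proportions))
      }),
      habitat_preference = lapply(pref, function(x) {
        if (is.null(x)) NULL
        else list(statistic = x$statistic, df = x$df, p_value = x$p_value)
      })
    ),
    notices = notices
  )

  tables <- list(
    species_summaries = summaries[setdiff(names(summaries),
                                          "occupied_stages")],
    habitat_sets = habitat_sets,
    quality_metrics = quality,
    stage_diagnostics = corrs$per_stage,
    stage_correlations = corrs$correlations,
    comparisons = comparison_tbl,
    comparison_groups = group_tbl
  )
  tables <- tables[!vapply(tables, is.null, logical(1))]

  run <- list(tables = tables,
              results = list(comparisons = comparisons,
                             singleton_tests = singleton_tests,
                             habitat_preference = pref,
                             lagerstatten = lager, monographic = mono,
                             specimen = specimen_cmp),
              summary = summary, log = log)
  class(run) <- "paleodur_run"

  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    for (nm in names(tables)) {
      write_table(tables[[nm]], file.path(out_dir, paste0(nm, ".tsv")))
    }
    jsonlite::write_json(summary, file.path(out_dir, "summary.json"),
                         auto_unbox = TRUE, digits = NA, pretty = TRUE,
                         na = "null", dataframe = "rows", force = TRUE)
  }
  run
}

#' @export
print.paleodur_run <- function(x, ...) {
  cat("paleodur pipeline run\n")
  cat("  occurrences in/out:", x$log[["rows_in"]], "/",
      x$log[["rows_out"]], "\n")
  cat("  species:", x$summary$counts$n_species,
      "(singletons:", x$summary$counts$n_singletons, ")\n")
  cat("  analyses:", length(x$results$comparisons), "comparisons,",
      sum(!vapply(x$results$singleton_tests, is.null, logical(1))),
      "singleton tests\n")
  if (length(x$summary$notices) > 0) {
    cat("  notices:\n")
    for (n in x$summary$notices) cat("   -", n, "\n")
  }
  invisible(x)
}
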