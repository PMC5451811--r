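## Comparative statistics: trimmed means, Kruskal-Wallis, pairwise
## Wilcoxon with Benjamini-Hochberg correction, chi-square preference
## tests, and the duration/range comparison drivers.

#' Trimmed mean
#'
#' Mean after discarding `floor(n * trim)` values from each tail — a
#' robust location estimate for strongly right-skewed duration
#' distributions.
#'
#' @param values Non-empty numeric vector.
#' @param trim Trim fraction in `[0, 0.5)`.
#' @return Numeric scalar.
#' @export
trimmed_mean <- function(values, trim = 0.1) {
  stopifnot(length(values) > 0)
  if (trim < 0 || trim >= 0.5) stop("trim must be in [0, 0.5)")
  mean(values, trim = trim)
}

#' Kruskal-Wallis rank sum test over a list of groups
#'
#' Tie-corrected H statistic with a chi-square upper-tail p-value
#' (delegates to [stats::kruskal.test()]). When every value is identical
#' the statistic is 0, p is 1 and the result is flagged degenerate.
#'
#' @param groups List of >= 2 non-empty numeric vectors, total n >= 3.
#' @return List with `statistic`, `df`, `p_value`, `degenerate`.
#' @export
kruskal_wallis <- function(groups) {
  if (length(groups) < 2 || any(vapply(groups, length, integer(1)) == 0)) {
    stop("kruskal_wallis needs >= 2 non-empty groups")
  }
  x <- unlist(groups, use.names = FALSE)
  if (length(x) < 3) stop("kruskal_wallis needs total n >= 3")
  if (length(unique(x)) == 1) {
    return(list(statistic = 0, df = length(groups) - 1L, p_value = 1,
                degenerate = TRUE))
  }
  g <- factor(rep(seq_along(groups), vapply(groups, length, integer(1))))
  kt <- stats::kruskal.test(x, g)
  list(statistic = unname(kt$statistic), df = unname(kt$parameter),
       p_value = kt$p.value, degenerate = FALSE)
}

## Two-sided two-sample Wilcoxon rank-sum p-value. Exact enumeration when
## both samples are small and tie-free, otherwise normal approximation
## with tie correction and (optional) continuity correction.
.wilcox_p <- function(x, y, exact_max_n = 8, correct = TRUE, exact = NULL) {
  if (is.null(exact)) {
    exact <- length(x) <= exact_max_n && length(y) <= exact_max_n &&
      !anyDuplicated(c(x, y))
  }
  if (length(unique(c(x, y))) == 1) return(1)
  suppressWarnings(
    stats::wilcox.test(x, y, exact = exact, correct = correct)$p.value
  )
}

#' Pairwise Wilcoxon tests with Benjamini-Hochberg adjustment
#'
#' Two-sided rank-sum tests for every pair of groups (exact when both
#' sides have at most `exact_max_n` tie-free values, otherwise the normal
#' approximation with tie and continuity correction), with BH ("fdr")
#' adjustment applied jointly over all pairs of the call.
#'
#' @param groups Named list of >= 2 numeric vectors.
#' @param exact_max_n Upper sample size for exact enumeration.
#' @param correct Continuity correction in the normal approximation.
#' @return List with symmetric matrices `p_raw` and `p_adjusted`.
#' @export
pairwise_wilcoxon_bh <- function(groups, exact_max_n = 8, correct = TRUE) {
  k <- length(groups)
  if (k < 2) stop("pairwise comparison needs >= 2 groups")
  nm <- names(groups)
  if (is.null(nm)) nm <- paste0("group", seq_len(k))
  praw <- matrix(NA_real_, k, k, dimnames = list(nm, nm))
  pairs <- utils::combn(k, 2)
  pvec <- apply(pairs, 2, function(ij) {
    .wilcox_p(groups[[ij[1]]], groups[[ij[2]]],
              exact_max_n = exact_max_n, correct = correct)
  })
  padj <- stats::p.adjust(pvec, method = "BH")
  for (j in seq_len(ncol(pairs))) {
    i1 <- pairs[1, j]; i2 <- pairs[2, j]
    praw[i1, i2] <- praw[i2, i1] <- pvec[j]
  }
  pm <- praw
  for (j in seq_len(ncol(pairs))) {
    i1 <- pairs[1, j]; i2 <- pairs[2, j]
    pm[i1, i2] <- pm[i2, i1] <- padj[j]
  }
  list(p_raw = praw, p_adjusted = pm)
}

#' Full group comparison (trimmed means + omnibus + pairwise)
#'
#' The statistical core shared by the duration, range-size and
#' specimen-completeness comparisons: per-group n, median and trimmed
#' mean; Kruskal-Wallis omnibus; BH-adjusted pairwise Wilcoxon matrix; and
#' pairwise trimmed-mean differences.
#'
#' @param groups Named list of >= 2 non-empty numeric vectors.
#' @param trim Trim fraction.
#' @param grouping Label describing what is being compared.
#' @return A `group_comparison` list with elements `grouping`, `summary`
#'   (data frame: group, n, median, trimmed_mean), `omnibus`, `pairwise`
#'   (p-value matrices), `trimmed_mean_diff` (matrix), `trim`.
#' @export
compare_groups <- function(groups, trim = 0.1, grouping = "groups") {
  groups <- groups[vapply(groups, length, integer(1)) > 0]
  if (length(groups) < 2) stop("compare_groups needs >= 2 non-empty groups")
  nm <- names(groups)
  tm <- vapply(groups, trimmed_mean, numeric(1), trim = trim)
  summary <- data.frame(
    group = nm,
    n = vapply(groups, length, integer(1)),
    median = vapply(groups, stats::median, numeric(1)),
    trimmed_mean = tm,
    row.names = NULL, stringsAsFactors = FALSE
  )
  res <- list(
    grouping = grouping,
    summary = summary,
    omnibus = kruskal_wallis(groups),
    pairwise = pairwise_wilcoxon_bh(groups),
    trimmed_mean_diff = outer(tm, tm, `-`),
    trim = trim
  )
  class(res) <- "group_comparison"
  res
}

#' @export
print.group_comparison <- function(x, ...) {
  cat("Group comparison:", x$grouping, "\n")
  print(x$summary, row.names = FALSE)
  cat(sprintf("Kruskal-Wallis: H = %.4g, df = %d, p = %.4g\n",
              x$omnibus$statistic, as.integer(x$omnibus$df),
              x$omnibus$p_value))
  cat("BH-adjusted pairwise Wilcoxon p-values:\n")
  print(round(x$pairwise$p_adjusted, 4))
  invisible(x)
}

## ---- duration comparison drivers -------------------------------------

.lissamphibia_groups <- c("Allocaudata", "Urodela", "Parabatrachia",
                          "Salientia", "Gymnophiona")

## Build the named duration groups for one grouping scheme. A species
## contributes its duration once per category it belongs to (habitat
## levels), or once per taxon group / complement group (taxon schemes).
.duration_groups <- function(summaries, habitat_sets, grouping) {
  if (grouping %in% c("level1", "level2", "level3")) {
    hs <- habitat_sets[habitat_sets$level == grouping, , drop = FALSE]
    m <- merge(hs, summaries[c("species_name", "duration_ma")],
               by = "species_name")
    split(as.numeric(m$duration_ma), m$category)
  } else if (grouping == "lissamphibia") {
    s <- summaries[summaries$taxon_group %in% .lissamphibia_groups, ,
                   drop = FALSE]
    split(as.numeric(s$duration_ma), s$taxon_group)
  } else if (grouping == "higher") {
    out <- list(
      Temnospondyli = summaries$duration_ma[
        summaries$taxon_group == "Temnospondyli"],
      `No-Temnospondyli` = summaries$duration_ma[
        summaries$taxon_group != "Temnospondyli"],
      Lepospondyli = summaries$duration_ma[
        summaries$taxon_group == "Lepospondyli"],
      `No-Lepospondyli` = summaries$duration_ma[
        summaries$taxon_group != "Lepospondyli"]
    )
    lapply(out, as.numeric)
  } else {
    stop("unknown grouping: ", grouping)
  }
}

#' Compare species durations between habitats or taxonomic groups
#'
#' Runs the full comparison (trimmed means, Kruskal-Wallis, BH-adjusted
#' pairwise Wilcoxon) on species durations in Ma for one grouping scheme.
#' Habitat groupings count each species once per category it belongs to on
#' that level; taxon schemes are either the lissamphibian orders or the
#' higher groups (Temnospondyli / No-Temnospondyli, Lepospondyli /
#' No-Lepospondyli) — the two hierarchical levels are never mixed in one
#' call. Optional filters restrict to one taxon group, drop
#' single-interval species, or keep one geographic range stratum.
#'
#' @param summaries Species summary table.
#' @param habitat_sets Long habitat table ([species_habitat_sets()]);
#'   required for habitat groupings.
#' @param grouping One of `"level1"`, `"level2"`, `"level3"`,
#'   `"lissamphibia"`, `"higher"`.
#' @param taxon Optional taxon group name: restrict to its species first.
#' @param exclude_singletons Drop single-interval species.
#' @param range_stratum `"all"`, `"small"` or `"large"` (requires a
#'   `range_stratum` column from [stratify_by_range()]).
#' @param trim Trim fraction.
#' @return A `group_comparison`.
#' @export
compare_durations <- function(summaries, habitat_sets = NULL,
                              grouping = c("level1", "level2", "level3",
                                           "lissamphibia", "higher"),
                              taxon = NULL, exclude_singletons = FALSE,
                              range_stratum = c("all", "small", "large"),
                              trim = 0.1) {
  grouping <- match.arg(grouping)
  range_stratum <- match.arg(range_stratum)
  filters <- character(0)
  if (!is.null(taxon)) {
    summaries <- summaries[summaries$taxon_group == taxon, , drop = FALSE]
    filters <- c(filters, paste0("taxon=", taxon))
  }
  if (exclude_singletons) {
    summaries <- summaries[!summaries$is_single_interval, , drop = FALSE]
    filters <- c(filters, "exclude_singletons")
  }
  if (range_stratum != "all") {
    if (is.null(summaries$range_stratum)) {
      stop("range_stratum filter requires stratify_by_range() first")
    }
    summaries <- summaries[summaries$range_stratum == range_stratum, ,
                           drop = FALSE]
    filters <- c(filters, paste0("range=", range_stratum))
  }
  if (grouping %in% c("level1", "level2", "level3") &&
      is.null(habitat_sets)) {
    stop("habitat groupings require habitat_sets")
  }
  g <- .duration_groups(summaries, habitat_sets, grouping)
  g <- g[vapply(g, length, integer(1)) > 0]
  if (length(g) < 2) {
    stop("fewer than 2 populated groups for grouping '", grouping, "'",
         if (length(filters) > 0)
           paste0(" after filter(s): ", paste(filters, collapse = ", "))
         else "")
  }
  label <- paste0("duration_by_", grouping,
                  if (length(filters) > 0)
                    paste0(" [", paste(filters, collapse = ", "), "]")
                  else "")
  compare_groups(g, trim = trim, grouping = label)
}

#' Compare geographic range sizes between habitat groups
#'
#' Same engine as [compare_durations()], applied to occupied-grid-cell
#' counts.
#'
#' @inheritParams compare_durations
#' @return A `group_comparison`.
#' @export
compare_ranges <- function(summaries, habitat_sets,
                           grouping = c("level1", "level2", "level3"),
                           trim = 0.1) {
  grouping <- match.arg(grouping)
  hs <- habitat_sets[habitat_sets$level == grouping, , drop = FALSE]
  m <- merge(hs, summaries[c("species_name", "grid_cell_count")],
             by = "species_name")
  g <- split(as.numeric(m$grid_cell_count), m$category)
  g <- g[vapply(g, length, integer(1)) > 0]
  if (length(g) < 2) stop("fewer than 2 populated habitat groups")
  compare_groups(g, trim = trim, grouping = paste0("range_by_", grouping))
}

## chi-square on a contingency table; Yates correction only ever applies
## to 2x2 tables (R's convention, which the analysis follows)
.chisq_counts <- function(tab, yates = TRUE) {
  correct <- yates && all(dim(tab) == c(2, 2))
  suppressWarnings(stats::chisq.test(tab, correct = correct))
}

#' Habitat-preference test: taxa x habitat categories
#'
#' Tests whether habitat-category frequencies (each species counted once
#' per category) differ between taxonomic groups, via Pearson's chi-square
#' on the species-count contingency table. Degrees of freedom are
#' `(r-1)(c-1)`; a 2x2 table falls back to the Yates-corrected statistic.
#'
#' @param summaries Species summary table.
#' @param habitat_sets Long habitat table.
#' @param scheme `"lissamphibia"` or `"higher"` (higher scheme uses the
#'   disjoint groups Temnospondyli / Lepospondyli / other, since
#'   complement groups would double-count species in one table).
#' @param level Habitat level for the columns (default `"level1"`).
#' @param yates Apply continuity correction on 2x2 tables.
#' @return List with `observed`, `expected`, `residuals` (standardised),
#'   `statistic`, `df`, `p_value`, and `dropped` (empty rows/columns).
#' @export
habitat_preference_test <- function(summaries, habitat_sets,
                                    scheme = c("lissamphibia", "higher"),
                                    level = "level1", yates = TRUE) {
  scheme <- match.arg(scheme)
  hs <- habitat_sets[habitat_sets$level == level, , drop = FALSE]
  m <- merge(hs, summaries[c("species_name", "taxon_group")],
             by = "species_name")
  taxon <- if (scheme == "lissamphibia") {
    ifelse(m$taxon_group %in% .lissamphibia_groups, m$taxon_group, NA)
  } else {
    ifelse(m$taxon_group %in% c("Temnospondyli", "Lepospondyli"),
           m$taxon_group, "other")
  }
  keep <- !is.na(taxon)
  tab <- table(taxon = taxon[keep], category = m$category[keep])
  dropped <- c(rownames(tab)[rowSums(tab) == 0],
               colnames(tab)[colSums(tab) == 0])
  if (length(dropped) > 0) {
    warning("dropping empty row/column(s): ", paste(dropped, collapse = ", "))
    tab <- tab[rowSums(tab) > 0, colSums(tab) > 0, drop = FALSE]
  }
  if (any(dim(tab) < 2)) stop("habitat preference test needs >= 2 taxa and >= 2 categories")
  ct <- .chisq_counts(tab, yates = yates)
  list(observed = ct$observed, expected = ct$expected,
       residuals = ct$stdres, statistic = unname(ct$statistic),
       df = unname(ct$parameter), p_value = ct$p.value, dropped = dropped)
}

#' Tidy one group comparison into a long report table
#'
#' @param x A `group_comparison`.
#' @return Data frame in long format: one row per group (summary block)
#'   and one per pair (pairwise block), with significance stars at
#'   0.05/0.01/0.001.
#' @export
comparison_report <- function(x) {
  stopifnot(inherits(x, "group_comparison"))
  pairs <- which(upper.tri(x$pairwise$p_adjusted), arr.ind = TRUE)
  nm <- rownames(x$pairwise$p_adjusted)
  stars <- function(p) ifelse(p < 0.001, "***",
                       ifelse(p < 0.01, "**", ifelse(p < 0.05, "*", "")))
  data.frame(
    grouping = x$grouping,
    group_a = nm[pairs[, 1]], group_b = nm[pairs[, 2]],
    n_a = x$summary$n[pairs[, 1]], n_b = x$summary$n[pairs[, 2]],
    trimmed_mean_a = x$summary$trimmed_mean[pairs[, 1]],
    trimmed_mean_b = x$summary$trimmed_mean[pairs[, 2]],
    trimmed_mean_diff = x$trimmed_mean_diff[pairs],
    omnibus_H = x$omnibus$statistic, omnibus_p = x$omnibus$p_value,
    p_raw = x$pairwise$p_raw[pairs],
    p_adjusted = x$pairwise$p_adjusted[pairs],
    signif = stars(x$pairwise$p_adjusted[pairs]),
    row.names = NULL, stringsAsFactors = FALSE
  )
}
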