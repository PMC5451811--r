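## Stratigraphic durations and palaeogeographic range sizes.

#' Midpoint age of a geological stage
#'
#' @param stage One or more rows of a stage table (or any data frame with
#'   `base_ma` and `top_ma`).
#' @return Numeric midpoint age(s) in Ma, `(base_ma + top_ma) / 2`.
#' @export
stage_midpoint <- function(stage) (stage$base_ma + stage$top_ma) / 2

## Resolve occurrence stage names to stage-table indices. Occurrences may
## span two stages; the early (older) name bounds the first occurrence,
## the late (younger) name the last.
.resolve_stages <- function(tab, stages) {
  early_idx <- stages$index[match(tab$early_stage, stages$name)]
  late_idx <- stages$index[match(tab$late_stage, stages$name)]
  bad <- which(is.na(early_idx) | is.na(late_idx))
  if (length(bad) > 0) {
    stop("unresolvable stage name(s) in occurrence(s): ",
         paste(utils::head(tab$occurrence_id[bad], 5), collapse = ", "))
  }
  if (any(late_idx < early_idx)) {
    stop("early_stage younger than late_stage in occurrence(s): ",
         paste(tab$occurrence_id[late_idx < early_idx], collapse = ", "))
  }
  data.frame(early_idx = early_idx, late_idx = late_idx)
}

## round half away from zero (base round() is banker's rounding)
.round_half_up <- function(x) sign(x) * floor(abs(x) + 0.5)

#' Duration of one species from its occurrences
#'
#' First occurrence = oldest resolved stage, last = youngest. The duration
#' in stages is the inclusive index span; the duration in Ma is the
#' distance between the midpoints of the first and last stage, rounded to
#' integer millions of years. A single-interval species has duration 1
#' stage and 0 Ma.
#'
#' @param occs Occurrence rows of one species.
#' @param stages Stage table ([read_timescale()] / [make_stage_table()]).
#' @param rounding `"nearest"` (round half away from zero, default) or
#'   `"ceiling"`.
#' @return List with `first_index`, `last_index`, `duration_stages`,
#'   `duration_ma`.
#' @export
species_duration <- function(occs, stages, rounding = c("nearest", "ceiling")) {
  rounding <- match.arg(rounding)
  idx <- .resolve_stages(occs, stages)
  first <- min(idx$early_idx)
  last <- max(idx$late_idx)
  gap <- abs(stages$mid_ma[match(first, stages$index)] -
               stages$mid_ma[match(last, stages$index)])
  dur_ma <- if (rounding == "nearest") .round_half_up(gap) else ceiling(gap)
  list(first_index = first, last_index = last,
       duration_stages = last - first + 1L,
       duration_ma = as.integer(dur_ma))
}

#' Palaeo-grid cell identifiers
#'
#' Projects a 2 x 2 decimal-degree grid anchored at 0 deg onto
#' palaeocoordinates; each cell is the half-open square
#' `[2k, 2k+2) x [2l, 2l+2)`. Points with missing coordinates yield `NA`.
#'
#' @param paleo_lng,paleo_lat Numeric vectors of palaeocoordinates.
#' @return Character cell ids `"lngbin:latbin"` (floor(lng/2), floor(lat/2)).
#' @export
grid_cell_ids <- function(paleo_lng, paleo_lat) {
  ifelse(is.na(paleo_lng) | is.na(paleo_lat), NA_character_,
         paste0(floor(paleo_lng / 2), ":", floor(paleo_lat / 2)))
}

#' Per-species summary table
#'
#' Collapses an occurrence table to one row per species: stratigraphic
#' range (first/last stage index, duration in stages and Ma), the
#' single-interval flag, occurrence and occupied-grid-cell counts, the
#' occupied stage set (list column, used by the completeness metrics) and
#' whether any occurrence is flagged as coming from a lagerstaette.
#'
#' @param tab An `occurrence_table`.
#' @param stages Stage table.
#' @param rounding Passed to [species_duration()].
#' @return Data frame with columns `species_name`, `taxon_group`,
#'   `first_stage_index`, `last_stage_index`, `duration_stages`,
#'   `duration_ma`, `is_single_interval`, `n_occurrences`,
#'   `grid_cell_count`, `in_lagerstatte` and list column `occupied_stages`.
#' @export
species_summaries <- function(tab, stages, rounding = "nearest") {
  if (nrow(tab) == 0) stop("empty occurrence table")
  idx <- .resolve_stages(tab, stages)
  split_rows <- split(seq_len(nrow(tab)), tab$species_name)
  rows <- lapply(split_rows, function(i) {
    first <- min(idx$early_idx[i]); last <- max(idx$late_idx[i])
    occupied <- sort(unique(unlist(
      Map(seq, idx$early_idx[i], idx$late_idx[i]))))
    gap <- abs(stages$mid_ma[stages$index == first] -
                 stages$mid_ma[stages$index == last])
    dur_ma <- if (rounding == "nearest") .round_half_up(gap) else ceiling(gap)
    cells <- unique(stats::na.omit(grid_cell_ids(tab$paleo_lng[i],
                                                 tab$paleo_lat[i])))
    data.frame(
      species_name = tab$species_name[i[1]],
      taxon_group = tab$taxon_group[i[1]],
      first_stage_index = first, last_stage_index = last,
      duration_stages = last - first + 1L,
      duration_ma = as.integer(dur_ma),
      is_single_interval = (last == first),
      n_occurrences = length(i),
      grid_cell_count = length(cells),
      in_lagerstatte = any(tab$is_lagerstatte[i]),
      stringsAsFactors = FALSE
    )
  })
  out <- do.call(rbind, rows)
  out$occupied_stages <- lapply(split_rows, function(i) {
    sort(unique(unlist(Map(seq, idx$early_idx[i], idx$late_idx[i]))))
  })
  rownames(out) <- NULL
  out
}

#' Split species into small- and large-range strata
#'
#' @param summaries Species summary table with `grid_cell_count`.
#' @param rule `"one_cell"` (default: small = exactly 1 occupied cell,
#'   large = 2 or more) or `"median"` (small = at or below the median
#'   count).
#' @return The summary table with an added `range_stratum` column
#'   (`"small"`/`"large"`).
#' @export
stratify_by_range <- function(summaries, rule = c("one_cell", "median")) {
  rule <- match.arg(rule)
  cc <- summaries$grid_cell_count
  small <- if (rule == "one_cell") cc <= 1 else cc <= stats::median(cc)
  summaries$range_stratum <- ifelse(small, "small", "large")
  if (all(small)) warning("large range stratum is empty")
  summaries
}
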