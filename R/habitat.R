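## Three-level habitat classification from lithology.
##
## Level 1 orders depositional settings by water flow energy:
##   stagnant < low-velocity < medium-velocity < high-velocity
## (grain size increases along the same gradient). Level 2 collapses this
## to lentic (standing water) vs lotic (flowing water); level 3 to low vs
## high energy. Levels 2 and 3 are fixed rollups of level 1.

.level1_categories <- c("stagnant", "low-velocity", "medium-velocity",
                        "high-velocity")
.level2_map <- c("stagnant" = "lentic", "low-velocity" = "lotic",
                 "medium-velocity" = "lotic", "high-velocity" = "lotic")
.level3_map <- c("stagnant" = "low", "low-velocity" = "low",
                 "medium-velocity" = "high", "high-velocity" = "high")

#' Default lithology-to-habitat rule table
#'
#' An ordered rule list mapping lithology substrings to level-1 flow-energy
#' categories; the first matching rule wins, so more specific patterns
#' (e.g. cross-stratified variants, which indicate higher flow energy and
#' are bumped one class up) precede bare rock names. Fine-grained rocks
#' and chemical/organic sediments that form in still water map to
#' *stagnant*; grain size then tracks increasing flow velocity
#' (siltstone, sandstone, conglomerate/gravel/breccia). Entries that carry
#' no information about the original energetic setting (e.g. "cave
#' infill") map to *excluded*. The table is config-replaceable
#' ([read_habitat_map()]); this default is documented, not canonical.
#'
#' @return A data frame with columns `pattern`, `category`, `note`,
#'   of class `habitat_map`.
#' @export
default_habitat_map <- function() {
  rules <- rbind(
    ## non-informative settings first: never assignable
    c("cave",            "excluded",       "karst/cave infill, no energy signal"),
    c("fissure",         "excluded",       "fissure fill, no energy signal"),
    c("amber",           "excluded",       "no depositional energy signal"),
    ## cross-stratification indicates traction transport: bump one class up
    c("cross-stratified siltstone", "medium-velocity", "bedform transport"),
    c("cross-stratified sandstone", "high-velocity",   "bedform transport"),
    c("cross-bedded sandstone",     "high-velocity",   "bedform transport"),
    ## coarse clastics: high flow energy
    c("conglomerate",    "high-velocity",  "coarse clastic"),
    c("breccia",         "high-velocity",  "coarse clastic"),
    c("gravel",          "high-velocity",  "coarse clastic"),
    ## medium grain
    c("sandstone",       "medium-velocity", "medium grain"),
    c("sand",            "medium-velocity", "medium grain"),
    ## fine grain, weak flow
    c("siltstone",       "low-velocity",   "fine grain, weak current"),
    c("silt",            "low-velocity",   "fine grain, weak current"),
    ## finest clastics and still-water chemical/organic sediments
    c("claystone",       "stagnant", "suspension settling"),
    c("clay",            "stagnant", "suspension settling"),
    c("mudstone",        "stagnant", "suspension settling"),
    c("mud",             "stagnant", "suspension settling"),
    c("shale",           "stagnant", "suspension settling"),
    c("lignite",         "stagnant", "still-water organic"),
    c("coal",            "stagnant", "still-water organic"),
    c("peat",            "stagnant", "still-water organic"),
    c("peal",            "stagnant", "alias of peat"),
    c("diatomite",       "stagnant", "still-water biogenic"),
    c("dolomite",        "stagnant", "still-water chemical"),
    c("gyps",            "stagnant", "gypsum, evaporitic still water"),
    c("marl",            "stagnant", "still-water chemical"),
    c("phosphorite",     "stagnant", "still-water chemical"),
    c("tuff",            "stagnant", "airfall into standing water"),
    c("limestone",       "stagnant", "carbonate, low energy")
  )
  map <- data.frame(pattern = rules[, 1], category = rules[, 2],
                    note = rules[, 3], stringsAsFactors = FALSE)
  class(map) <- c("habitat_map", "data.frame")
  map
}

#' Read a habitat rule table from YAML or JSON
#'
#' The file holds an ordered list of `{pattern, category, note}` entries;
#' categories must be one of the four level-1 categories or `excluded`.
#'
#' @param path `.yaml`/`.yml` or `.json` file.
#' @return A `habitat_map` data frame.
#' @export
read_habitat_map <- function(path) {
  ext <- tolower(tools::file_ext(path))
  raw <- if (ext %in% c("yaml", "yml")) yaml::read_yaml(path)
         else jsonlite::fromJSON(path, simplifyDataFrame = FALSE)
  map <- do.call(rbind, lapply(raw, function(r) {
    data.frame(pattern = r$pattern, category = r$category,
               note = if (is.null(r$note)) "" else r$note,
               stringsAsFactors = FALSE)
  }))
  bad <- setdiff(unique(map$category), c(.level1_categories, "excluded"))
  if (length(bad) > 0) {
    stop("unknown habitat category in map: ", paste(bad, collapse = ", "))
  }
  class(map) <- c("habitat_map", "data.frame")
  map
}

#' Assign lithologies to level-1 habitat categories
#'
#' Case-insensitive substring match of each rule's pattern against the
#' normalised lithology string (trimmed, whitespace collapsed); the first
#' matching rule wins. Missing/blank lithologies and lithologies matched
#' by no rule return `"excluded"`.
#'
#' @param lithology Character vector of lithology descriptions.
#' @param map A `habitat_map` (default [default_habitat_map()]).
#' @return Character vector over
#'   `c("stagnant", "low-velocity", "medium-velocity", "high-velocity",
#'   "excluded")`.
#' @export
assign_level1 <- function(lithology, map = default_habitat_map()) {
  stopifnot(nrow(map) > 0)
  x <- tolower(trimws(gsub("\\s+", " ", as.character(lithology))))
  out <- rep("excluded", length(x))
  undecided <- !is.na(x) & nzchar(x)
  for (i in seq_len(nrow(map))) {
    if (!any(undecided)) break
    hit <- undecided & grepl(map$pattern[i], x, fixed = TRUE)
    out[hit] <- map$category[i]
    undecided <- undecided & !hit
  }
  out
}

#' Roll level-1 categories up to level 2 (lentic/lotic)
#'
#' `stagnant` water is lentic; any flowing-water category is lotic.
#'
#' @param level1_category Character vector of level-1 categories.
#' @return Character vector over `c("lentic", "lotic")`.
#' @export
rollup_level2 <- function(level1_category) {
  .rollup(level1_category, .level2_map)
}

#' Roll level-1 categories up to level 3 (low/high energy)
#'
#' `stagnant` and `low-velocity` are low-energy settings; `medium-` and
#' `high-velocity` are high-energy.
#'
#' @inheritParams rollup_level2
#' @return Character vector over `c("low", "high")`.
#' @export
rollup_level3 <- function(level1_category) {
  .rollup(level1_category, .level3_map)
}

.rollup <- function(x, map) {
  bad <- setdiff(unique(x), names(map))
  if (length(bad) > 0) {
    stop("not a level-1 habitat category: ", paste(bad, collapse = ", "),
         " (excluded occurrences must be filtered upstream)")
  }
  unname(map[x])
}

#' Per-species deduplicated habitat sets
#'
#' Assigns every occurrence's lithology to a level-1 category and collects,
#' per species, the set of distinct categories on each of the three levels.
#' A species occurring in several lithologies of the same category enters
#' that category once; species with no assignable occurrence are omitted
#' (their count is recorded in the `"habitat_log"` attribute).
#'
#' @param tab An `occurrence_table`.
#' @param map A `habitat_map`.
#' @return A long data frame with columns `species_name`, `level`
#'   (`"level1"`, `"level2"`, `"level3"`) and `category`, one row per
#'   distinct species x level x category.
#' @export
species_habitat_sets <- function(tab, map = default_habitat_map()) {
  cat1 <- assign_level1(tab$lithology, map)
  keep <- cat1 != "excluded"
  n_occ_excluded <- sum(!keep)
  sp_all <- unique(tab$species_name)
  df <- unique(data.frame(species_name = tab$species_name[keep],
                          category = cat1[keep], stringsAsFactors = FALSE))
  lvl <- function(name, category) {
    unique(data.frame(species_name = df$species_name,
                      level = rep(name, nrow(df)), category = category,
                      stringsAsFactors = FALSE))
  }
  out <- if (nrow(df) == 0) {
    data.frame(species_name = character(0), level = character(0),
               category = character(0), stringsAsFactors = FALSE)
  } else {
    rbind(lvl("level1", df$category),
          lvl("level2", rollup_level2(df$category)),
          lvl("level3", rollup_level3(df$category)))
  }
  rownames(out) <- NULL
  attr(out, "habitat_log") <- c(
    occurrences_excluded = n_occ_excluded,
    species_in = length(sp_all),
    species_assigned = length(unique(df$species_name)),
    species_omitted = length(sp_all) - length(unique(df$species_name))
  )
  out
}
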