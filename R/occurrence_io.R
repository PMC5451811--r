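#' @keywords internal
"_PACKAGE"

## Canonical occurrence-table columns. All readers map dialect-specific
## headers onto these; downstream code only ever sees this layout.
.occ_columns <- c(
  "occurrence_id", "species_name", "taxon_group", "early_stage",
  "late_stage", "lithology", "paleo_lng", "paleo_lat", "reference_id",
  "is_lagerstatte", "specimen_score", "source_db"
)

.taxon_groups <- c(
  "Allocaudata", "Urodela", "Parabatrachia", "Salientia", "Gymnophiona",
  "Lepospondyli", "Temnospondyli", "other"
)

## Column-name aliases per input dialect. Only the names differ between
## dialects; unknown extra columns are carried through untouched.
.dialect_aliases <- list(
  pbdb = c(
    accepted_name = "species_name",
    early_interval = "early_stage",
    late_interval = "late_stage",
    lithology1 = "lithology",
    lithology2 = "lithology_secondary",
    paleolng = "paleo_lng",
    paleolat = "paleo_lat",
    reference_no = "reference_id",
    occurrence_no = "occurrence_id"
  ),
  fosfar = c(
    species = "species_name",
    genus_species = "species_name",
    stage_from = "early_stage",
    stage_to = "late_stage",
    rock_type = "lithology",
    paleolongitude = "paleo_lng",
    paleolatitude = "paleo_lat",
    source = "reference_id",
    id = "occurrence_id"
  ),
  generic = character(0)
)

#' Read a fossil occurrence table
#'
#' Reads a CSV or TSV occurrence table (delimiter chosen from the file
#' extension), maps dialect-specific column names onto the canonical
#' layout, applies the standard row filters — removal of open-nomenclature
#' records (names carrying `aff.`, `cf.` or `?`), collapse of exact
#' duplicates — and validates coordinates and specimen scores. Counts of
#' rows removed per rule are recorded in the table's filter log
#' (see [filter_log()]).
#'
#' @param path Path to a `.csv` or `.tsv`/`.txt` file.
#' @param dialect Column-name dialect: `"generic"` (canonical names),
#'   `"pbdb"` (Paleobiology Database download headers) or `"fosfar"`.
#' @param synonyms Optional synonym map, a data frame with columns
#'   `old_name`, `new_name`, applied to `species_name` before filtering
#'   (used to harmonise taxonomies between databases).
#' @param source_db Value recorded in the `source_db` column when the file
#'   does not provide one.
#' @return A `data.frame` of class `occurrence_table` with the canonical
#'   columns, a `"filter_log"` attribute (named integer vector) and a
#'   `"provenance"` attribute.
#' @export
read_occurrences <- function(path,
                             dialect = c("generic", "pbdb", "fosfar"),
                             synonyms = NULL,
                             source_db = dialect) {
  dialect <- match.arg(dialect)
  if (!file.exists(path)) stop("file not found: ", path)
  df <- .read_delim_auto(path)
  aliases <- .dialect_aliases[[dialect]]
  hit <- names(df) %in% names(aliases)
  names(df)[hit] <- unname(aliases[names(df)[hit]])

  required <- c("species_name", "early_stage")
  missing_cols <- setdiff(required, names(df))
  if (length(missing_cols) > 0) {
    stop("missing required column(s) for dialect '", dialect, "': ",
         paste(missing_cols, collapse = ", "))
  }
  if (is.null(df$source_db)) {
    df$source_db <- rep(if (identical(source_db, "generic")) "synthetic"
                        else source_db, nrow(df))
  }
  tab <- as_occurrence_table(df, synonyms = synonyms)
  attr(tab, "provenance") <- list(path = path, dialect = dialect,
                                  read_at = "run time")
  tab
}

.read_delim_auto <- function(path) {
  ext <- tolower(tools::file_ext(path))
  sep <- if (ext %in% c("tsv", "txt", "tab")) "\t" else ","
  utils::read.table(path, header = TRUE, sep = sep, quote = "\"",
                    stringsAsFactors = FALSE, comment.char = "",
                    na.strings = c("NA", ""), check.names = FALSE,
                    colClasses = NA)
}

#' Coerce a data frame to a validated occurrence table
#'
#' Normalises columns to the canonical layout, applies the qualifier and
#' duplicate filters and validates field ranges. This is the constructor
#' behind both [read_occurrences()] and [simulate_record()].
#'
#' @param df A data frame with at least `species_name` and `early_stage`.
#' @param synonyms Optional synonym map (`old_name`, `new_name`).
#' @param filter Apply the qualifier/duplicate filters (default `TRUE`).
#' @return An `occurrence_table` (see [read_occurrences()]).
#' @export
as_occurrence_table <- function(df, synonyms = NULL, filter = TRUE) {
  n_in <- nrow(df)
  log <- c(rows_in = n_in)

  if (is.null(df$late_stage)) df$late_stage <- df$early_stage
  df$late_stage <- ifelse(is.na(df$late_stage), df$early_stage, df$late_stage)
  for (col in c("occurrence_id", "taxon_group", "lithology", "reference_id")) {
    if (is.null(df[[col]])) df[[col]] <- rep(NA_character_, nrow(df))
    df[[col]] <- as.character(df[[col]])
  }
  if (is.null(df$occurrence_id) || all(is.na(df$occurrence_id))) {
    df$occurrence_id <- as.character(seq_len(nrow(df)))
  }
  df$taxon_group <- ifelse(
    is.na(df$taxon_group) | !(df$taxon_group %in% .taxon_groups),
    "other", df$taxon_group)
  for (col in c("paleo_lng", "paleo_lat")) {
    if (is.null(df[[col]])) df[[col]] <- rep(NA_real_, nrow(df))
    val <- suppressWarnings(as.numeric(df[[col]]))
    bad <- which(!is.na(df[[col]]) & is.na(val) & df[[col]] != "")
    if (length(bad) > 0) {
      stop("unparseable ", col, " in row(s): ", paste(bad, collapse = ", "))
    }
    df[[col]] <- val
  }
  if (is.null(df$is_lagerstatte)) df$is_lagerstatte <- rep(FALSE, nrow(df))
  df$is_lagerstatte <- .as_flag(df$is_lagerstatte)
  if (is.null(df$specimen_score)) df$specimen_score <- rep(NA_integer_,
                                                           nrow(df))
  score <- suppressWarnings(as.integer(df$specimen_score))
  bad <- which(!is.na(df$specimen_score) &
                 (is.na(score) | score < 1L | score > 5L))
  if (length(bad) > 0) {
    stop("specimen_score outside 1..5 in row(s): ", paste(bad, collapse = ", "))
  }
  df$specimen_score <- score
  if (is.null(df$source_db)) df$source_db <- rep("synthetic", nrow(df))

  bad_lat <- which(!is.na(df$paleo_lat) & abs(df$paleo_lat) > 90)
  bad_lng <- which(!is.na(df$paleo_lng) & abs(df$paleo_lng) > 180)
  if (length(c(bad_lat, bad_lng)) > 0) {
    stop("coordinates out of range in row(s): ",
         paste(sort(unique(c(bad_lat, bad_lng))), collapse = ", "))
  }

  if (!is.null(synonyms)) {
    stopifnot(all(c("old_name", "new_name") %in% names(synonyms)))
    idx <- match(df$species_name, synonyms$old_name)
    n_syn <- sum(!is.na(idx))
    df$species_name[!is.na(idx)] <- synonyms$new_name[idx[!is.na(idx)]]
    log <- c(log, synonyms_applied = n_syn)
  }

  if (filter && nrow(df) > 0) {
    qual <- grepl("aff\\.|cf\\.|\\?", df$species_name, ignore.case = TRUE)
    log <- c(log, qualifier_removed = sum(qual))
    df <- df[!qual, , drop = FALSE]
    key <- do.call(paste, c(df[c("species_name", "early_stage", "late_stage",
                                 "lithology", "reference_id",
                                 "paleo_lng", "paleo_lat")], sep = "\r"))
    dup <- duplicated(key)
    log <- c(log, duplicates_removed = sum(dup))
    df <- df[!dup, , drop = FALSE]
  } else {
    log <- c(log, qualifier_removed = 0L, duplicates_removed = 0L)
  }
  log <- c(log, rows_out = nrow(df))

  extra <- setdiff(names(df), .occ_columns)
  df <- df[c(.occ_columns, extra)]
  rownames(df) <- NULL
  class(df) <- c("occurrence_table", "data.frame")
  attr(df, "filter_log") <- log
  df
}

.as_flag <- function(x) {
  if (is.logical(x)) return(ifelse(is.na(x), FALSE, x))
  x <- tolower(as.character(x))
  !is.na(x) & x %in% c("true", "t", "1", "yes", "y")
}

#' Filter log of an occurrence table
#'
#' @param x An `occurrence_table`.
#' @return Named integer vector of row counts: `rows_in`, rows removed per
#'   filter rule, `rows_out`. The counts satisfy
#'   `rows_in == rows_out + sum(removed per rule)`.
#' @export
filter_log <- function(x) attr(x, "filter_log")

#' Remove extant species from an occurrence table
#'
#' Species present in a user-supplied extant-taxon list are dropped so the
#' analysis runs on extinct species only; the removal count is appended to
#' the filter log.
#'
#' @param tab An `occurrence_table`.
#' @param extant_names Character vector of extant species names.
#' @return The filtered `occurrence_table`.
#' @export
drop_extant <- function(tab, extant_names) {
  hit <- tab$species_name %in% extant_names
  out <- tab[!hit, , drop = FALSE]
  rownames(out) <- NULL
  log <- attr(tab, "filter_log")
  log <- c(log[names(log) != "rows_out"], extant_removed = sum(hit),
           rows_out = nrow(out))
  if (nrow(out) == 0 && nrow(tab) > 0) {
    warning("all species were extant; table is empty")
  }
  class(out) <- class(tab)
  attr(out, "filter_log") <- log
  attr(out, "provenance") <- attr(tab, "provenance")
  out
}

#' Read a geological timescale table
#'
#' Expects columns `name`, `base_ma`, `top_ma` (ages of the older and
#' younger stage boundary, in Ma). Stages are sorted from oldest to
#' youngest and indexed from 0; overlapping stages are rejected, gaps are
#' reported as warnings.
#'
#' @param path CSV or TSV file path.
#' @return A `data.frame` with columns `name`, `index`, `base_ma`,
#'   `top_ma`, `mid_ma`, `length_ma`, oldest first.
#' @export
read_timescale <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  df <- .read_delim_auto(path)
  missing_cols <- setdiff(c("name", "base_ma", "top_ma"), names(df))
  if (length(missing_cols) > 0) {
    stop("timescale file missing column(s): ",
         paste(missing_cols, collapse = ", "))
  }
  make_stage_table(df$name, as.numeric(df$base_ma), as.numeric(df$top_ma))
}

#' Build a validated stage table from boundary ages
#'
#' @param name Stage names.
#' @param base_ma,top_ma Older/younger boundary ages in Ma.
#' @return Stage table as in [read_timescale()].
#' @export
make_stage_table <- function(name, base_ma, top_ma) {
  if (any(is.na(base_ma)) || any(is.na(top_ma))) {
    stop("timescale boundary ages must not be missing")
  }
  bad <- which(base_ma <= top_ma)
  if (length(bad) > 0) {
    stop("base_ma <= top_ma for stage(s): ", paste(name[bad], collapse = ", "))
  }
  ord <- order(base_ma, decreasing = TRUE)
  name <- as.character(name)[ord]; base_ma <- base_ma[ord]; top_ma <- top_ma[ord]
  if (anyDuplicated(name)) stop("duplicated stage name(s)")
  n <- length(name)
  if (n > 1) {
    over <- which(base_ma[-1] > top_ma[-n] + 1e-9)
    if (length(over) > 0) {
      stop("overlapping stages: ", paste(name[over + 1], collapse = ", "))
    }
    gaps <- which(base_ma[-1] < top_ma[-n] - 1e-9)
    if (length(gaps) > 0) {
      warning("timescale has gap(s) below stage(s): ",
              paste(name[gaps], collapse = ", "))
    }
  }
  data.frame(
    name = name, index = seq_len(n) - 1L, base_ma = base_ma, top_ma = top_ma,
    mid_ma = (base_ma + top_ma) / 2, length_ma = base_ma - top_ma,
    stringsAsFactors = FALSE
  )
}

#' Read a species synonym map
#'
#' @param path CSV/TSV with columns `old_name`, `new_name`.
#' @return Data frame with those two character columns.
#' @export
read_synonyms <- function(path) {
  df <- .read_delim_auto(path)
  stopifnot(all(c("old_name", "new_name") %in% names(df)))
  df[c("old_name", "new_name")]
}

#' Write a result table as TSV
#'
#' UTF-8, tab-separated, header row, missing values as empty fields. The
#' output round-trips through [read_result_table()].
#'
#' @param rows A data frame.
#' @param path Output path.
#' @export
write_table <- function(rows, path) {
  rows <- as.data.frame(rows)
  ## list-columns (e.g. occupied stage sets) serialised as comma lists
  for (col in names(rows)) {
    if (is.list(rows[[col]])) {
      rows[[col]] <- vapply(rows[[col]], function(v) paste(v, collapse = ","),
                            character(1))
    }
  }
  con <- file(path, open = "w", encoding = "UTF-8")
  on.exit(close(con))
  utils::write.table(rows, con, sep = "\t", quote = FALSE, na = "",
                     row.names = FALSE)
  invisible(path)
}

#' Read a TSV written by [write_table()]
#'
#' @param path File path.
#' @return Data frame.
#' @export
read_result_table <- function(path) {
  utils::read.table(path, header = TRUE, sep = "\t", quote = "",
                    stringsAsFactors = FALSE, comment.char = "",
                    na.strings = "", check.names = FALSE)
}
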