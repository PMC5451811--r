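## Forward simulation of a fossil record with known ground truth.
##
## Species get a true habitat, an exponential true duration and a uniform
## placement in time; each geological stage overlapped by the true range
## yields an occurrence with a habitat-specific per-stage preservation
## probability (boosted in lagerstaette stages). Lithologies are drawn
## from a vocabulary consistent with the species' habitat so the habitat
## assignment step can recover the truth; coordinates scatter around a
## per-species range centre. Everything is reproducible from the seed.

.default_habitats <- function() {
  data.frame(
    category = c("stagnant", "low-velocity", "medium-velocity",
                 "high-velocity"),
    n_species = c(214L, 130L, 56L, 18L),
    mean_duration_ma = c(4, 5, 7, 7),
    preservation_prob = c(0.6, 0.5, 0.4, 0.35),
    stringsAsFactors = FALSE
  )
}

.lithology_vocab <- list(
  "stagnant" = c("claystone", "mudstone", "gray shale", "coal", "marl"),
  "low-velocity" = c("siltstone", "laminated siltstone"),
  "medium-velocity" = c("sandstone", "fine sandstone"),
  "high-velocity" = c("conglomerate", "breccia", "coarse gravel")
)

.score_probs <- list(
  "stagnant" = c(0.10, 0.15, 0.20, 0.25, 0.30),
  "low-velocity" = c(0.15, 0.20, 0.25, 0.20, 0.20),
  "medium-velocity" = c(0.30, 0.25, 0.20, 0.15, 0.10),
  "high-velocity" = c(0.40, 0.25, 0.20, 0.10, 0.05)
)

.taxon_weights <- list(
  "stagnant" = c(Temnospondyli = 0.35, Lepospondyli = 0.20, Urodela = 0.12,
                 Salientia = 0.18, Allocaudata = 0.05, Gymnophiona = 0.02,
                 Parabatrachia = 0.01, other = 0.07),
  "low-velocity" = c(Temnospondyli = 0.40, Lepospondyli = 0.05,
                     Urodela = 0.10, Salientia = 0.28, Allocaudata = 0.03,
                     Gymnophiona = 0.02, Parabatrachia = 0.01, other = 0.11),
  "medium-velocity" = c(Temnospondyli = 0.45, Lepospondyli = 0.03,
                        Urodela = 0.08, Salientia = 0.30,
                        Allocaudata = 0.02, Gymnophiona = 0.02,
                        Parabatrachia = 0.00, other = 0.10),
  "high-velocity" = c(Temnospondyli = 0.50, Lepospondyli = 0.02,
                      Urodela = 0.05, Salientia = 0.30, Allocaudata = 0.02,
                      Gymnophiona = 0.01, Parabatrachia = 0.00, other = 0.10)
)

#' Simulation configuration
#'
#' Assembles and validates the generator configuration. The defaults are
#' the package's reference study conditions: a 53-stage timescale with
#' stage lengths of mean 5.7 and sd 2.5 My; four level-1 habitats with
#' species counts 214/130/56/18, true mean durations 4/5/7/7 My
#' (high-energy habitats longer-lived) and per-stage preservation
#' probabilities 0.6/0.5/0.4/0.35 (calmer water preserves better); 5% of
#' stages flagged as lagerstaetten with a 2x preservation boost.
#'
#' @param seed Integer seed; drives every random draw of the run.
#' @param n_stages Number of stages (>= 3).
#' @param stage_length_mean,stage_length_sd Stage-length distribution (My,
#'   truncated normal, minimum 1 My).
#' @param habitats Data frame with columns `category`, `n_species`,
#'   `mean_duration_ma`, `preservation_prob`.
#' @param taxon_weights Named list per habitat: taxon-group mixture weights.
#' @param lagerstatten_fraction Fraction of stages flagged as lagerstaetten.
#' @param lagerstatten_multiplier Preservation multiplier (>= 1) in flagged
#'   stages (capped at probability 1).
#' @param dispersal_sd Coordinate scatter (degrees) around each species'
#'   range centre.
#' @param noise_lithology_fraction Fraction of occurrences given a
#'   non-informative lithology ("cave infill" or missing), exercising the
#'   exclusion path.
#' @param score_fraction Fraction of occurrences carrying a specimen
#'   completeness score.
#' @param singleton_free Force preservation of each species' true first
#'   and last overlapped stage (no observed range truncation at the
#'   endpoints).
#' @param species_per_genus Genus structure of generated names.
#' @return A validated `sim_config` list.
#' @export
sim_config <- function(seed = 1L, n_stages = 53L, stage_length_mean = 5.7,
                       stage_length_sd = 2.5, habitats = .default_habitats(),
                       taxon_weights = .taxon_weights,
                       lagerstatten_fraction = 0.05,
                       lagerstatten_multiplier = 2,
                       dispersal_sd = 5,
                       noise_lithology_fraction = 0.1,
                       score_fraction = 0.25,
                       singleton_free = FALSE,
                       species_per_genus = 3L) {
  stopifnot(n_stages >= 3, stage_length_sd > 0,
            all(habitats$preservation_prob > 0),
            all(habitats$preservation_prob <= 1),
            all(habitats$n_species >= 1),
            lagerstatten_multiplier >= 1,
            lagerstatten_fraction >= 0, lagerstatten_fraction < 1,
            score_fraction >= 0, score_fraction <= 1)
  cfg <- list(seed = as.integer(seed), n_stages = as.integer(n_stages),
              stage_length_mean = stage_length_mean,
              stage_length_sd = stage_length_sd, habitats = habitats,
              taxon_weights = taxon_weights,
              lagerstatten_fraction = lagerstatten_fraction,
              lagerstatten_multiplier = lagerstatten_multiplier,
              dispersal_sd = dispersal_sd,
              noise_lithology_fraction = noise_lithology_fraction,
              score_fraction = score_fraction,
              singleton_free = isTRUE(singleton_free),
              species_per_genus = as.integer(species_per_genus))
  class(cfg) <- "sim_config"
  cfg
}

## truncated-normal draws (lower bound `lo`) by rejection, exactness
## matters for the Monte-Carlo checks against the closed-form median
.rtnorm <- function(n, mean, sd, lo = 1) {
  out <- numeric(0)
  while (length(out) < n) {
    x <- stats::rnorm(n, mean, sd)
    out <- c(out, x[x >= lo])
  }
  out[seq_len(n)]
}

#' Simulate a geological timescale
#'
#' Contiguous stages with lengths drawn from a normal distribution
#' truncated below at 1 My; the youngest stage tops out at 0 Ma.
#'
#' @param n_stages Number of stages (>= 3).
#' @param mean,sd Stage-length mean and sd in My (sd > 0).
#' @param seed Optional seed (omit when called inside [simulate_record()],
#'   which seeds the whole run).
#' @return Stage table as from [make_stage_table()].
#' @export
make_timescale <- function(n_stages = 53L, mean = 5.7, sd = 2.5,
                           seed = NULL) {
  stopifnot(n_stages >= 3)
  if (sd <= 0) stop("stage length sd must be > 0")
  if (!is.null(seed)) set.seed(seed)
  len <- .rtnorm(n_stages, mean, sd)
  base <- rev(cumsum(rev(len)))
  top <- base - len
  top[n_stages] <- 0
  make_stage_table(sprintf("S%02d", seq_len(n_stages)), base, top)
}

#' Simulate a fossil occurrence record with ground truth
#'
#' Runs the generative model described in [sim_config()] and returns the
#' observable occurrence table (validated through the standard
#' constructor), the timescale it lives on, and the ground truth:
#' per-species true habitat, origination/extinction times and true
#' duration. Species whose every potential occurrence fails preservation
#' are absent from the table but present in the truth.
#'
#' @param config A `sim_config`.
#' @return List with `occurrences` (an `occurrence_table`), `timescale`,
#'   `truth` (data frame) and `lagerstatte_stages` (indices).
#' @export
simulate_record <- function(config = sim_config()) {
  stopifnot(inherits(config, "sim_config"))
  set.seed(config$seed)
  stages <- make_timescale(config$n_stages, config$stage_length_mean,
                           config$stage_length_sd)
  n_lager <- round(config$lagerstatten_fraction * nrow(stages))
  lager_idx <- if (n_lager > 0) sort(sample(stages$index, n_lager))
               else integer(0)

  hb <- config$habitats
  truth_rows <- list(); occ_rows <- list()
  serial <- 0L
  for (h in seq_len(nrow(hb))) {
    cat1 <- hb$category[h]
    n_sp <- hb$n_species[h]
    p <- hb$preservation_prob[h]
    w <- config$taxon_weights[[cat1]]
    vocab <- .lithology_vocab[[cat1]]
    sprob <- .score_probs[[cat1]]
    for (s in seq_len(n_sp)) {
      serial <- serial + 1L
      genus <- sprintf("%s%03d", c("stagnant" = "Stagnops",
                                   "low-velocity" = "Lenirana",
                                   "medium-velocity" = "Fluvites",
                                   "high-velocity" = "Torrentor")[cat1],
                       ceiling(s / config$species_per_genus))
      species <- sprintf("%s sp%04d", genus, serial)
      taxon <- sample(names(w), 1, prob = w)
      repeat {
        dur <- stats::rexp(1, rate = 1 / hb$mean_duration_ma[h])
        orig <- stats::runif(1, min = 0, max = max(stages$base_ma))
        ext <- max(orig - dur, 0)
        overlap <- which(stages$top_ma < orig & stages$base_ma > ext)
        if (length(overlap) == 0) next      # range fell into no stage
        if (!config$singleton_free || length(overlap) >= 2) break
      }
      centre_lng <- stats::runif(1, -180, 180)
      centre_lat <- stats::runif(1, -60, 70)
      p_eff <- pmin(1, p * ifelse(stages$index[overlap] %in% lager_idx,
                                  config$lagerstatten_multiplier, 1))
      hit <- stats::runif(length(overlap)) < p_eff
      if (config$singleton_free) {
        hit[c(1, length(hit))] <- TRUE      # endpoints always preserved
      }
      truth_rows[[serial]] <- data.frame(
        species_name = species, taxon_group = taxon, habitat = cat1,
        origination_ma = orig, extinction_ma = ext,
        true_duration_ma = orig - ext,
        n_stages_overlapped = length(overlap),
        recovered = any(hit), stringsAsFactors = FALSE)
      if (!any(hit)) next
      st <- overlap[hit]
      n_occ <- length(st)
      noise <- stats::runif(n_occ) < config$noise_lithology_fraction
      litho <- sample(vocab, n_occ, replace = TRUE)
      litho[noise] <- sample(c("cave infill", NA_character_), sum(noise),
                             replace = TRUE)
      lng <- ((centre_lng + stats::rnorm(n_occ, 0, config$dispersal_sd) +
                 180) %% 360) - 180
      lat <- pmax(-89.9, pmin(89.9,
                              centre_lat + stats::rnorm(n_occ, 0,
                                                        config$dispersal_sd)))
      score <- ifelse(stats::runif(n_occ) < config$score_fraction,
                      vapply(seq_len(n_occ), function(i)
                        sample(1:5, 1, prob = sprob), integer(1)),
                      NA_integer_)
      occ_rows[[length(occ_rows) + 1L]] <- data.frame(
        species_name = species, taxon_group = taxon,
        early_stage = stages$name[st], late_stage = stages$name[st],
        lithology = litho, paleo_lng = lng, paleo_lat = lat,
        reference_id = sprintf("ref_%s_%d", stages$name[st],
                               1L + (stages$index[st] %% 3L)),
        is_lagerstatte = stages$index[st] %in% lager_idx,
        specimen_score = score, source_db = "synthetic",
        stringsAsFactors = FALSE)
    }
  }
  occurrences <- do.call(rbind, occ_rows)
  if (is.null(occurrences)) {
    occurrences <- data.frame(species_name = character(0),
                              early_stage = character(0))
  }
  occurrences$occurrence_id <- as.character(seq_len(nrow(occurrences)))
  tab <- as_occurrence_table(occurrences)
  truth <- do.call(rbind, truth_rows)
  rownames(truth) <- NULL
  list(occurrences = tab, timescale = stages, truth = truth,
       lagerstatte_stages = lager_idx)
}

#' Simulate observed range-length frequencies under per-stage sampling
#'
#' The idealised sampling model behind the FreqRat estimator: taxa with
#' geometric true durations (in stages), each stage of a taxon's true
#' range preserved independently with probability `p`; the observed range
#' is the span from first to last preserved stage. Taxa with no preserved
#' stage are dropped.
#'
#' @param n_taxa Number of taxa.
#' @param p Per-stage preservation probability.
#' @param mean_duration_stages Mean of the geometric true duration
#'   (stages, >= 1).
#' @param seed Optional seed.
#' @return Integer vector of observed range lengths (stages).
#' @export
simulate_range_frequencies <- function(n_taxa, p,
                                       mean_duration_stages = 3,
                                       seed = NULL) {
  stopifnot(n_taxa >= 1, p > 0, p <= 1, mean_duration_stages >= 1)
  if (!is.null(seed)) set.seed(seed)
  Tdur <- stats::rgeom(n_taxa, prob = 1 / mean_duration_stages) + 1L
  obs <- vapply(Tdur, function(T) {
    s <- which(stats::runif(T) < p)
    if (length(s) == 0) NA_integer_ else max(s) - min(s) + 1L
  }, integer(1))
  obs[!is.na(obs)]
}

#' Recovery report: observed pipeline output vs simulated truth
#'
#' Joins the per-species summaries computed from a simulated record back
#' onto the ground truth and reports, per species, the true and observed
#' duration and the truncation (true minus observed); per habitat, the
#' recovered vs configured mean duration; and the FreqRat estimate over
#' observed range lengths next to the configured preservation
#' probabilities.
#'
#' @param truth Ground-truth table from [simulate_record()].
#' @param summaries Species summary table computed from the simulated
#'   occurrences.
#' @param config The `sim_config` used (for the configured parameters).
#' @return List with `per_species`, `per_habitat`, `freqrat`,
#'   `non_recovery` (TRUE when no species was recovered).
#' @export
truth_report <- function(truth, summaries, config = NULL) {
  unknown <- setdiff(summaries$species_name, truth$species_name)
  if (length(unknown) > 0) {
    stop("summaries contain species absent from truth: ",
         paste(utils::head(unknown, 5), collapse = ", "))
  }
  if (nrow(summaries) == 0) {
    return(list(per_species = NULL, per_habitat = NULL, freqrat = NULL,
                non_recovery = TRUE))
  }
  m <- merge(truth, summaries[c("species_name", "duration_ma",
                                "duration_stages")], by = "species_name")
  per_species <- data.frame(
    species_name = m$species_name, habitat = m$habitat,
    true_duration_ma = m$true_duration_ma,
    observed_duration_ma = m$duration_ma,
    truncation_ma = m$true_duration_ma - m$duration_ma,
    stringsAsFactors = FALSE)
  agg <- lapply(split(m, m$habitat), function(d) {
    data.frame(habitat = d$habitat[1], n_recovered = nrow(d),
               true_mean_ma = mean(d$true_duration_ma),
               observed_mean_ma = mean(d$duration_ma),
               stringsAsFactors = FALSE)
  })
  per_habitat <- do.call(rbind, c(agg, make.row.names = FALSE))
  if (!is.null(config)) {
    per_habitat$configured_mean_ma <- config$habitats$mean_duration_ma[
      match(per_habitat$habitat, config$habitats$category)]
    per_habitat$configured_preservation <- config$habitats$preservation_prob[
      match(per_habitat$habitat, config$habitats$category)]
  }
  list(per_species = per_species, per_habitat = per_habitat,
       freqrat = freqrat(summaries$duration_stages), non_recovery = FALSE)
}
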