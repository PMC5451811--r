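test_that("make_timescale is contiguous, reproducible, and respects limits", {
  st <- make_timescale(10, 5.7, 2.5, seed = 1)
  expect_equal(nrow(st), 10)
  expect_equal(st$base_ma[-1], st$top_ma[-10])      # contiguous
  expect_true(all(st$length_ma >= 1))               # truncation floor
  expect_equal(st$top_ma[10], 0)
  expect_identical(st, make_timescale(10, 5.7, 2.5, seed = 1))
  expect_error(make_timescale(10, 5.7, 0), "sd")
  # sd -> 0+ collapses lengths onto the mean
  tight <- make_timescale(10, 5.7, 1e-6, seed = 2)
  expect_equal(tight$length_ma, rep(5.7, 10), tolerance = 1e-4)
})

test_that("simulated stage lengths match the truncated-normal median", {
  set.seed(3)
  lens <- make_timescale(10000, 5.7, 2.5)$length_ma
  ## closed-form median of a normal truncated below at 1
  p1 <- pnorm(1, 5.7, 2.5)
  med <- qnorm(p1 + 0.5 * (1 - p1), 5.7, 2.5)
  expect_lt(abs(median(lens) - med), 0.2)
})

test_that("the generator is byte-identical under a fixed config and seed", {
  cfg <- sim_config(seed = 42)
  a <- simulate_record(cfg)
  b <- simulate_record(cfg)
  expect_identical(a$occurrences, b$occurrences)
  expect_identical(a$truth, b$truth)
  expect_identical(a$timescale, b$timescale)
  # truth holds every species, including unrecovered ones
  expect_equal(nrow(a$truth), sum(cfg$habitats$n_species))
  expect_true(all(unique(a$occurrences$species_name) %in%
                    a$truth$species_name))
  expect_gt(sum(!a$truth$recovered), 0)
  expect_true(all(a$truth$true_duration_ma >= 0))
})

test_that("perfect preservation recovers the exact true stage span", {
  hb <- data.frame(category = c("stagnant", "medium-velocity"),
                   n_species = c(40L, 40L), mean_duration_ma = c(5, 8),
                   preservation_prob = c(1, 1))
  cfg <- sim_config(seed = 7, habitats = hb, noise_lithology_fraction = 0,
                    lagerstatten_fraction = 0)
  rec <- simulate_record(cfg)
  s <- species_summaries(rec$occurrences, rec$timescale)
  m <- merge(s, rec$truth, by = "species_name")
  expect_equal(nrow(m), 80)                 # every species recovered
  expect_equal(m$duration_stages, m$n_stages_overlapped)
  rep_ <- truth_report(rec$truth, s, cfg)
  expect_false(rep_$non_recovery)
  # truncation bounded by the half-stage rounding slack at both endpoints
  slack <- max(rec$timescale$length_ma) + 1
  expect_true(all(rep_$per_species$truncation_ma < slack))
})

test_that("observed durations are truncated one-sidedly under sampling loss", {
  hb <- data.frame(category = "stagnant", n_species = 150L,
                   mean_duration_ma = 6, preservation_prob = 0.3)
  cfg <- sim_config(seed = 8, habitats = hb)
  rec <- simulate_record(cfg)
  s <- species_summaries(rec$occurrences, rec$timescale)
  m <- merge(s, rec$truth, by = "species_name")
  # observed stage span never exceeds the true overlapped span
  expect_true(all(m$duration_stages <= m$n_stages_overlapped))
})

test_that("richness rises and singleton share falls with preservation", {
  probe <- function(p, seed = 13) {
    hb <- data.frame(category = "stagnant", n_species = 150L,
                     mean_duration_ma = 5, preservation_prob = p)
    rec <- simulate_record(sim_config(seed = seed, habitats = hb))
    s <- species_summaries(rec$occurrences, rec$timescale)
    c(rich = nrow(s), sing = mean(s$is_single_interval))
  }
  res <- vapply(c(0.1, 0.3, 0.5, 0.7, 0.9), probe, numeric(2))
  expect_true(all(diff(res["rich", ]) >= 0))
  expect_true(all(diff(res["sing", ]) <= 0))
})

test_that("singleton-free mode preserves both range endpoints", {
  hb <- data.frame(category = "stagnant", n_species = 60L,
                   mean_duration_ma = 8, preservation_prob = 0.4)
  cfg <- sim_config(seed = 9, habitats = hb, singleton_free = TRUE)
  rec <- simulate_record(cfg)
  s <- species_summaries(rec$occurrences, rec$timescale)
  m <- merge(s, rec$truth, by = "species_name")
  expect_equal(nrow(m), 60)                 # endpoints forced: all recovered
  expect_equal(m$duration_stages, m$n_stages_overlapped)
  expect_false(any(m$is_single_interval))
})

test_that("truth_report flags identifier mismatches and empty recovery", {
  cfg <- sim_config(seed = 10)
  rec <- simulate_record(cfg)
  s <- species_summaries(rec$occurrences, rec$timescale)
  bad <- s
  bad$species_name[1] <- "Imposter maximus"
  expect_error(truth_report(rec$truth, bad), "absent")
  empty <- truth_report(rec$truth, s[0, ], cfg)
  expect_true(empty$non_recovery)
  ok <- truth_report(rec$truth, s, cfg)
  expect_equal(sort(unique(ok$per_habitat$habitat)),
               sort(cfg$habitats$category))
  expect_equal(ok$per_habitat$configured_preservation,
               cfg$habitats$preservation_prob[
                 match(ok$per_habitat$habitat, cfg$habitats$category)])
})

test_that("a simulated lotic duration advantage is recovered by the pipeline", {
  ## lentic 5 My vs lotic 8 My true mean duration, per-stage preservation
  ## 0.5, 500 species per side: the level-2 comparison should find the
  ## lotic group longer-lived in at least 18 of 20 replicates
  hits <- vapply(1:20, function(seed) {
    hb <- data.frame(category = c("stagnant", "medium-velocity"),
                     n_species = c(500L, 500L), mean_duration_ma = c(5, 8),
                     preservation_prob = c(0.5, 0.5))
    rec <- simulate_record(sim_config(seed = seed, habitats = hb))
    s <- species_summaries(rec$occurrences, rec$timescale)
    hs <- species_habitat_sets(rec$occurrences)
    cmp <- compare_durations(s, hs, grouping = "level2")
    tm <- setNames(cmp$summary$trimmed_mean, cmp$summary$group)
    (tm[["lotic"]] > tm[["lentic"]]) &&
      cmp$pairwise$p_adjusted["lotic", "lentic"] < 0.05
  }, logical(1))
  expect_gte(sum(hits), 18)
})
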