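test_that("stage-length correlations recover perfect monotone structure", {
  # richness rises deterministically with stage length
  st <- make_stage_table(LETTERS[1:6], c(330, 320, 311, 303, 296, 290),
                         c(320, 311, 303, 296, 290, 285))
  # stage lengths 10, 9, 8, 7, 6, 5: put more range-through species in
  # longer (older) stages
  rows <- list()
  for (i in 1:6) {
    k <- 14 - 2 * i
    rows[[i]] <- occ_df(sprintf("S%d_%d", i, seq_len(k)), LETTERS[i])
  }
  tab <- as_occurrence_table(do.call(rbind, rows), filter = FALSE)
  s <- species_summaries(tab, st)
  res <- stage_singleton_correlations(st, s)
  rich <- res$correlations[res$correlations$variable == "richness", ]
  expect_equal(rich$rho, 1, tolerance = 1e-12)
  # equal stage lengths: correlation undefined, flagged not crashed
  st2 <- toy_stages(5)
  tab2 <- as_occurrence_table(occ_df(paste("X", 1:10),
                                     sample(LETTERS[1:5], 10, replace = TRUE)),
                              filter = FALSE)
  res2 <- stage_singleton_correlations(st2, species_summaries(tab2, st2))
  expect_true(all(res2$correlations$undefined))
})

test_that("shuffled stage lengths show no spurious correlation", {
  set.seed(61)
  st <- make_timescale(53, 5.7, 2.5)
  n <- 300
  first <- sample(0:49, n, replace = TRUE)
  s <- data.frame(
    species_name = paste0("sp", 1:n),
    first_stage_index = first,
    last_stage_index = pmin(first + rgeom(n, 0.6), 52L))
  s$is_single_interval <- s$first_stage_index == s$last_stage_index
  s$occupied_stages <- Map(seq, s$first_stage_index, s$last_stage_index)
  rhos <- replicate(100, {
    st_perm <- st
    st_perm$length_ma <- sample(st$length_ma)
    res <- stage_singleton_correlations(st_perm, s)
    mean(abs(res$correlations$rho), na.rm = TRUE)
  })
  expect_lt(mean(rhos), 0.2)
})

test_that("lagerstatten 2x2 test matches hand arithmetic", {
  mk <- function(counts) {
    data.frame(
      in_lagerstatte = rep(c(TRUE, TRUE, FALSE, FALSE), counts),
      is_single_interval = rep(c(TRUE, FALSE, TRUE, FALSE), counts))
  }
  # balanced table: statistic exactly zero whatever the correction
  bal <- lagerstatten_test(mk(c(10, 10, 10, 10)))
  expect_equal(bal$statistic, 0)
  # [[20,10],[10,20]] without Yates: sum (O-E)^2/E with E = 15 -> 20/3
  raw <- lagerstatten_test(mk(c(20, 10, 10, 20)), yates = FALSE)
  expect_equal(raw$statistic, 20 / 3, tolerance = 1e-12)
  expect_equal(raw$df, 1)
  expect_equal(unname(raw$proportions), c(2 / 3, 1 / 3))
  # Yates default matches the corrected oracle
  cor_ <- lagerstatten_test(mk(c(20, 10, 10, 20)))
  expect_equal(cor_$statistic,
               chisq_oracle(matrix(c(20, 10, 10, 20), 2), yates = TRUE),
               tolerance = 1e-9)
  expect_error(lagerstatten_test(mk(c(0, 0, 10, 20))), "both")
})

test_that("monographic effect compares large publications with the whole set", {
  # one reference with 25 occurrences over 4 species, 1 of them a singleton
  st <- toy_stages(4)
  big <- occ_df(rep(c("A a", "B b", "C c", "D d"), c(7, 6, 6, 6)),
                c(rep(c("A", "B"), c(4, 3)), rep(c("A", "B"), 3),
                  rep(c("B", "C"), 3), rep("D", 6)),
                ref = "mono1")
  small <- occ_df(c("E e", "F f"), c("A", "C"), ref = c("s1", "s2"))
  tab <- as_occurrence_table(rbind(big, small), filter = FALSE)
  s <- species_summaries(tab, st)
  res <- monographic_effect(tab, s, min_occurrences = 20)
  expect_equal(res$proportion_large_pubs, 0.25)   # only 'D d' is a singleton
  expect_equal(res$proportion_overall, 3 / 6)
  # no reference is large enough: flagged undefined, overall still computed
  res2 <- monographic_effect(tab, s, min_occurrences = 100)
  expect_true(res2$undefined)
  expect_equal(res2$proportion_overall, 3 / 6)
  # zero threshold: every species is in a 'large' publication
  res3 <- monographic_effect(tab, s, min_occurrences = 0)
  expect_equal(res3$proportion_large_pubs, res3$proportion_overall)
})

test_that("singleton-by-habitat chi-square matches the arithmetic oracle", {
  ## counts patterned on a strongly uneven level-3 split
  mk_tab <- function(n_sing, n_multi, lith, taxon = "other") {
    sp <- sprintf("%s %d", lith, seq_len(n_sing + n_multi))
    early <- c(rep("A", n_sing), rep("A", n_multi))
    late <- c(rep("A", n_sing), rep("B", n_multi))
    occ_df(sp, early, late = late, lithology = lith, taxon = taxon)
  }
  df <- rbind(mk_tab(87, 13, "claystone"), mk_tab(66, 34, "sandstone"))
  tab <- as_occurrence_table(df, filter = FALSE)
  s <- species_summaries(tab, toy_stages(3))
  hs <- species_habitat_sets(tab)
  res <- singleton_habitat_test(s, hs, level = 3, yates = FALSE)
  counts <- matrix(c(66, 34, 87, 13), 2, byrow = TRUE)  # high, low rows
  expect_equal(res$statistic, chisq_oracle(counts), tolerance = 1e-9)
  expect_equal(res$df, 1)
  resy <- singleton_habitat_test(s, hs, level = 3)
  expect_equal(resy$statistic, chisq_oracle(counts, yates = TRUE),
               tolerance = 1e-9)
  expect_equal(unname(res$proportions[c("low", "high")]), c(0.87, 0.66))
  # identical proportions: statistic approximately zero
  df0 <- rbind(mk_tab(50, 50, "claystone"), mk_tab(50, 50, "sandstone"))
  tab0 <- as_occurrence_table(df0, filter = FALSE)
  res0 <- singleton_habitat_test(species_summaries(tab0, toy_stages(3)),
                                 species_habitat_sets(tab0), level = 3,
                                 yates = FALSE)
  expect_lt(res0$statistic, 1e-9)
  # a single populated category is an error
  only <- as_occurrence_table(mk_tab(5, 5, "claystone"), filter = FALSE)
  expect_error(singleton_habitat_test(species_summaries(only, toy_stages(3)),
                                      species_habitat_sets(only), level = 3),
               "2 populated")
})

test_that("singleton-habitat test is calibrated under the null", {
  ## habitat-independent singleton probability: rejection rate at alpha=0.05
  ## stays within Monte-Carlo range of nominal over 200 datasets
  set.seed(71)
  lith <- c("claystone", "siltstone", "sandstone", "conglomerate")
  rejections <- replicate(200, {
    n <- 300
    sp_lith <- sample(lith, n, replace = TRUE, prob = c(0.45, 0.3, 0.15, 0.1))
    sing <- runif(n) < 0.6
    df <- occ_df(sprintf("Sp %d", 1:n), ifelse(sing, "A", "A"),
                 late = ifelse(sing, "A", "B"), lithology = sp_lith)
    tab <- as_occurrence_table(df, filter = FALSE)
    res <- singleton_habitat_test(species_summaries(tab, toy_stages(3)),
                                  species_habitat_sets(tab), level = 1,
                                  yates = FALSE)
    res$p_value < 0.05
  })
  expect_lte(mean(rejections), 0.08)
})
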