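test_that("trimmed mean drops floor(n*trim) per tail", {
  expect_equal(trimmed_mean(1:10, 0.1), 5.5)       # mean of 2..9
  expect_equal(trimmed_mean(rep(3.2, 7), 0.4), 3.2)
  expect_equal(trimmed_mean(1:3, 0.1), 2)          # floor(0.3) = 0 trimmed
  expect_error(trimmed_mean(1:5, 0.5), "trim")
})

test_that("kruskal_wallis handles identical, separated and degenerate groups", {
  same <- kruskal_wallis(list(c(1, 2, 3), c(1, 2, 3)))
  expect_equal(same$statistic, 0, tolerance = 1e-12)
  expect_equal(same$p_value, 1, tolerance = 1e-6)
  # frozen from exact rank arithmetic: ranks 1..6, H = 12/42*(36/3+225/3)-21
  sep <- kruskal_wallis(list(c(1, 2, 3), c(10, 11, 12)))
  expect_equal(sep$statistic, 27 / 7, tolerance = 1e-12)
  expect_equal(sep$df, 1)
  deg <- kruskal_wallis(list(c(2, 2), c(2, 2)))
  expect_true(deg$degenerate)
  expect_equal(deg$p_value, 1)
  expect_error(kruskal_wallis(list(1:3, numeric(0))), "non-empty")
})

test_that("pairwise Wilcoxon p-values use exact enumeration on small tie-free data", {
  g <- list(a = c(1, 2, 3, 4), b = c(5, 6, 7, 8))
  res <- pairwise_wilcoxon_bh(g)
  expect_equal(res$p_raw["a", "b"], 2 / 70)        # full C(8,4) enumeration
  expect_equal(res$p_adjusted["a", "b"], 2 / 70)   # single pair: BH identity
  expect_true(isSymmetric(res$p_adjusted))
  same <- pairwise_wilcoxon_bh(list(x = 1:5, y = 1:5))
  expect_equal(same$p_adjusted["x", "y"], 1)
})

test_that("BH adjustment matches the p*m/rank cumulative-minimum formula", {
  bh_oracle <- function(p) {
    m <- length(p); o <- order(p, decreasing = TRUE)
    ro <- order(o)
    pmin(1, cummin(p[o] * m / (m - seq_along(p) + 1)))[ro]
  }
  expect_equal(stats::p.adjust(c(0.01, 0.02, 0.03), "BH"),
               c(0.03, 0.03, 0.03))
  set.seed(31)
  for (rep in 1:20) {
    p <- runif(sample(2:12, 1))
    expect_equal(stats::p.adjust(p, "BH"), bh_oracle(p), tolerance = 1e-12)
  }
  # monotone: permuting inputs permutes outputs; adjusted >= raw
  p <- runif(8)
  perm <- sample(8)
  expect_equal(stats::p.adjust(p, "BH")[perm], stats::p.adjust(p[perm], "BH"))
  g <- list(a = rnorm(10), b = rnorm(10) + 1, c = rnorm(10) + 2)
  res <- pairwise_wilcoxon_bh(g)
  up <- upper.tri(res$p_raw)
  expect_true(all(res$p_adjusted[up] >= res$p_raw[up]))
  expect_true(all(res$p_adjusted[up] <= 1 & res$p_raw[up] >= 0))
})

test_that("normal-approximation Wilcoxon p tracks exact enumeration at n=8", {
  x <- 1:8
  combs <- combn(16, 8)
  worst <- 0
  for (j in seq_len(ncol(combs))) {
    a <- combs[, j]; b <- setdiff(1:16, a)
    pex <- wilcox_exact_oracle(a, b)
    pnorm_ <- suppressWarnings(
      stats::wilcox.test(a, b, exact = FALSE, correct = TRUE)$p.value)
    worst <- max(worst, abs(pex - pnorm_))
  }
  expect_lt(worst, 0.02)
})

test_that("chi-square statistics agree with the direct formula", {
  set.seed(17)
  for (rep in 1:30) {
    tab <- matrix(rpois(4, 20) + 1, 2, 2)
    got_y <- paleodur:::.chisq_counts(as.table(tab), yates = TRUE)
    got_n <- paleodur:::.chisq_counts(as.table(tab), yates = FALSE)
    expect_equal(unname(got_y$statistic), chisq_oracle(tab, yates = TRUE),
                 tolerance = 1e-9)
    expect_equal(unname(got_n$statistic), chisq_oracle(tab, yates = FALSE),
                 tolerance = 1e-9)
    big <- matrix(rpois(12, 15) + 1, 3, 4)
    got_b <- paleodur:::.chisq_counts(as.table(big), yates = TRUE)
    expect_equal(unname(got_b$statistic), chisq_oracle(big),
                 tolerance = 1e-9)   # larger tables never corrected
  }
})

test_that("compare_durations respects grouping schemes and filters", {
  st <- toy_stages(6)
  df <- rbind(
    occ_df(paste("Lent", 1:6), rep(LETTERS[1:3], 2), lithology = "claystone",
           taxon = rep(c("Salientia", "Urodela"), 3)),
    occ_df(paste("Lent", 1:6), rep(LETTERS[3:5], 2), lithology = "claystone",
           taxon = rep(c("Salientia", "Urodela"), 3)),
    occ_df(paste("Lot", 1:6), rep(LETTERS[1:3], 2), lithology = "sandstone",
           taxon = "Temnospondyli"),
    occ_df(paste("Lot", 1:6), rep(LETTERS[4:6], 2), lithology = "sandstone",
           taxon = "Temnospondyli"))
  tab <- as_occurrence_table(df, filter = FALSE)
  s <- species_summaries(tab, st)
  hs <- species_habitat_sets(tab)
  lvl2 <- compare_durations(s, hs, grouping = "level2")
  expect_setequal(lvl2$summary$group, c("lentic", "lotic"))
  # all durations identical within groups -> meaningful output shape
  expect_true(all(lvl2$pairwise$p_adjusted >= 0, na.rm = TRUE))
  # taxon schemes never mix hierarchical levels in one call
  hi <- compare_durations(s, hs, grouping = "higher")
  expect_setequal(hi$summary$group,
                  c("Temnospondyli", "No-Temnospondyli", "Lepospondyli",
                    "No-Lepospondyli")[c(1, 2, 4)])  # no lepospondyl species
  expect_false(any(c("Salientia", "Urodela") %in% hi$summary$group))
  liss <- compare_durations(s, hs, grouping = "lissamphibia")
  expect_false(any(grepl("Temnospondyli", liss$summary$group)))
  # identical values across groups: adjusted p = 1
  sc <- s; sc$duration_ma <- 5L
  cmp <- compare_durations(sc, hs, grouping = "level2")
  expect_equal(unname(cmp$pairwise$p_adjusted["lentic", "lotic"]), 1)
  # filters that empty the groups raise a named error
  expect_error(compare_durations(s, hs, grouping = "level1",
                                 taxon = "Gymnophiona"), "Gymnophiona")
})

test_that("habitat preference test reports df = (r-1)(c-1) and residuals", {
  set.seed(23)
  n <- 160
  taxa <- sample(c("Temnospondyli", "Lepospondyli", "Salientia", "Urodela"),
                 n, replace = TRUE)
  lith <- sample(c("claystone", "siltstone", "sandstone", "conglomerate"),
                 n, replace = TRUE)
  df <- occ_df(paste("Sp", 1:n), "A", lithology = lith, taxon = taxa)
  tab <- as_occurrence_table(df, filter = FALSE)
  s <- species_summaries(tab, toy_stages(3))
  hs <- species_habitat_sets(tab)
  pref <- habitat_preference_test(s, hs, scheme = "lissamphibia")
  expect_equal(pref$df, (nrow(pref$observed) - 1) * (ncol(pref$observed) - 1))
  expect_equal(dim(pref$residuals), dim(pref$observed))
  # uniform 4x4 table: statistic near zero, df 9
  hi <- habitat_preference_test(s, hs, scheme = "higher")
  expect_equal(hi$df, (nrow(hi$observed) - 1) * (ncol(hi$observed) - 1))
  expect_equal(unname(hi$statistic),
               chisq_oracle(unclass(hi$observed)), tolerance = 1e-9)
})
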