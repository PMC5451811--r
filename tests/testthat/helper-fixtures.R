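extdata <- function(f) system.file("extdata", f, package = "paleodur")

## tiny in-code occurrence table builder; every column beyond species and
## stage is optional and defaulted
occ_df <- function(species, early, late = early, lithology = NA,
                   lng = NA_real_, lat = NA_real_, ref = "r1",
                   lager = FALSE, score = NA_integer_,
                   taxon = "other") {
  data.frame(species_name = species, taxon_group = taxon,
             early_stage = early, late_stage = late, lithology = lithology,
             paleo_lng = lng, paleo_lat = lat, reference_id = ref,
             is_lagerstatte = lager, specimen_score = score,
             source_db = "synthetic", stringsAsFactors = FALSE)
}

## contiguous 10-My stages, oldest base at `base`; names A, B, C, ...
toy_stages <- function(n = 5, base = 330, len = 10) {
  make_stage_table(LETTERS[seq_len(n)],
                   base - len * (seq_len(n) - 1),
                   base - len * seq_len(n))
}

## brute-force SCM oracle: enumerate every stage in the range and count
scm_oracle <- function(occupied, exclude_endpoints = FALSE) {
  rng <- seq(min(occupied), max(occupied))
  if (exclude_endpoints) rng <- setdiff(rng, range(occupied))
  if (length(rng) == 0) return(NA_real_)
  sum(rng %in% occupied) / length(rng)
}

## exact two-sided Wilcoxon rank-sum p by full enumeration of rank splits
wilcox_exact_oracle <- function(x, y) {
  N <- length(x) + length(y)
  stopifnot(!anyDuplicated(c(x, y)))
  r <- rank(c(x, y))
  w_obs <- sum(r[seq_along(x)]) - length(x) * (length(x) + 1) / 2
  all_w <- combn(N, length(x), function(i) sum(i)) -
    length(x) * (length(x) + 1) / 2
  min(1, 2 * min(mean(all_w <= w_obs), mean(all_w >= w_obs)))
}

## chi-square oracle: direct sum((O-E)^2/E), optional Yates on 2x2
chisq_oracle <- function(tab, yates = FALSE) {
  E <- outer(rowSums(tab), colSums(tab)) / sum(tab)
  d <- abs(tab - E)
  if (yates) d <- pmax(d - 0.5, 0)
  sum(d^2 / E)
}
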