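#!/usr/bin/env Rscript
## Step 3: single-interval-taxon reliability diagnostics.
##
## Before trusting duration comparisons that lean on a singleton-heavy
## record: do stage lengths drive apparent singletons? are singletons
## concentrated in lagerstaetten or big monographs? are they spread
## evenly across habitats?

suppressPackageStartupMessages(library(paleodur))

occ <- read_occurrences("results/simulated/occurrences.tsv")
stages <- read_timescale("results/simulated/timescale.tsv")
summaries <- species_summaries(occ, stages)
habitat_sets <- species_habitat_sets(occ)

corr <- stage_singleton_correlations(stages, summaries)
write_table(corr$per_stage, "results/per_stage_diagnostics.tsv")
write_table(corr$correlations, "results/stage_correlations.tsv")
message("stage-length Spearman correlations:")
print(corr$correlations, row.names = FALSE)

lag <- tryCatch(lagerstatten_test(summaries), error = function(e) NULL)
if (!is.null(lag)) {
  message(sprintf("lagerstaetten: chisq = %.3f (df %d, p = %.3g); singleton share %0.2f vs %0.2f",
                  lag$statistic, lag$df, lag$p_value,
                  lag$proportions[["lagerstatte"]],
                  lag$proportions[["other"]]))
}

mono <- monographic_effect(occ, summaries)
message(sprintf("monographic effect: singleton share %s in large pubs vs %.2f overall",
                ifelse(mono$undefined, "n/a",
                       sprintf("%.2f", mono$proportion_large_pubs)),
                mono$proportion_overall))

for (lev in c(1, 3)) {
  st <- singleton_habitat_test(summaries, habitat_sets, level = lev)
  message(sprintf("singletons by habitat (level %d): chisq = %.3f, df = %d, p = %.3g",
                  lev, st$statistic, st$df, st$p_value))
  write_table(as.data.frame(st$observed),
              sprintf("results/singletons_level%d.tsv", lev))
}
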