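#!/usr/bin/env Rscript
# Stage 3: per-species prioritisation — top-ranked EDGE2 species, the
# capture curve (how much avertable loss the top fractions hold), and the
# EDGE-species flags. Reads the tables written by 02_run_pipeline.R.

library(phylorisk)

agg <- read.csv("results/pipeline/species_aggregate.csv")
capture <- read.csv("results/pipeline/capture_curve.csv")

cat("Top 10 species by median EDGE2:\n")
print(head(agg[order(agg$rank),
               c("species", "clade", "category", "TBL_median",
                 "EDGE2_median", "edge_species")], 10), row.names = FALSE)

top1 <- capture$captured[which.min(abs(capture$top_fraction - 1))]
cat(sprintf("\nTop 1%% of species capture %.1f%% of summed median EDGE2\n",
            top1))
cat(sprintf("%d of %d species (%.1f%%) meet the EDGE-species criteria\n",
            sum(agg$edge_species), nrow(agg),
            100 * mean(agg$edge_species)))
by_clade <- tapply(agg$edge_species, agg$clade, function(x)
  sprintf("%d/%d", sum(x), length(x)))
cat("EDGE species per clade:\n")
print(by_clade)
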