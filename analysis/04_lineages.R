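#!/usr/bin/env Rscript
# Stage 4: family-level assessment — fully-threatened and monotypic family
# counts, EDGE Lineages, stem ages, the population-trend null for monotypic
# families, and the taxonomy-only candidate proportions.

library(phylorisk)

fam <- read.csv("results/pipeline/family_summary.csv")
trend <- read.csv("results/pipeline/trend_tests.csv")
cand <- read.csv("results/pipeline/candidate_edge_species.csv")

cat(sprintf("%d families, %d monotypic (%.0f%%)\n", nrow(fam),
            sum(fam$monotypic), 100 * mean(fam$monotypic)))
cat(sprintf("All species threatened:            %d families\n",
            sum(fam$fully_threatened_all)))
cat(sprintf("All data sufficient threatened:    %d families\n",
            sum(fam$fully_threatened_ds)))
cat(sprintf("EDGE Lineages (3-part criterion):  %d families\n",
            sum(fam$edge_lineage, na.rm = TRUE)))
cat(sprintf("Median family stem age: %.1f MY\n\n",
            median(fam$stem_age_median, na.rm = TRUE)))

cat("Monotypic-family population trends vs matched null:\n")
print(trend, row.names = FALSE)

cat("\nTaxonomy-only candidate EDGE species (proportion flagged):\n")
print(cand, row.names = FALSE)
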