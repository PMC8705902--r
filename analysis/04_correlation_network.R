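#!/usr/bin/env Rscript
# Stage 4: metabolite-clinical correlation screen and the tri-partite
# network.
#
# Spearman correlations between every metabolite's net-secretion series
# and every clinical parameter (plus the derived leptin/adiponectin
# ratio), FDR-adjusted across the full pair family; edges kept at
# |rho| > 0.7 and adjusted p < 0.1, then joined with the producing
# strains into the clinical-metabolite-strain network.

suppressMessages(library(fluxcomm))
suppressMessages(library(igraph))

ed <- read_table_tsv("results/pipeline/correlations.tsv")
cat("tested", nrow(ed), "metabolite x clinical pairs;",
    sum(ed$kept == "TRUE" | ed$kept == TRUE), "pass |rho| > 0.7, FDR p < 0.1\n\n")
kept <- ed[ed$kept == "TRUE" | ed$kept == TRUE, ]
print(kept[order(kept$p_fdr), ])

g <- read_graph("results/pipeline/network.graphml", format = "graphml")
cat("\nnetwork:", vcount(g), "nodes,", ecount(g), "edges\n")
cat("node types:\n")
print(table(V(g)$type))

cat("\nproduction links (metabolite -- producing strain):\n")
ends_m <- ends(g, E(g))
prod <- which(E(g)$etype == "production")
for (e in prod)
  cat("  ", ends_m[e, 1], "--", ends_m[e, 2],
      sprintf("(share %.2f)\n", E(g)$share[e]))
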