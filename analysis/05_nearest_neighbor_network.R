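#!/usr/bin/env Rscript

## Weighted coexpression network over all studied molecules, reduced to
## nearest-neighbour edges: vertices that are the top correlate of many
## molecules end up with high degree (drawn large in network figures).

library(balcornet)

expr <- read_expression_tsv("results/cohort/expression.tsv")
meta <- read_metadata_tsv("results/cohort/metadata.tsv")
dir.create("results/network", showWarnings = FALSE)

for (g in c("sarcoidosis", "progressing", "regressing", "control")) {
  graph <- prune_nearest_neighbors(
    full_weighted_graph(expr, meta, group = g), k = 1)
  write_coexpression_graph(graph, sprintf("results/network/nn_%s", g))
  hubs <- sort(graph$vertex_size, decreasing = TRUE)[1:5]
  kept <- graph$edges[graph$edges$retained, ]
  strongest <- kept[which.max(kept$weight), ]
  cat(sprintf("%-12s retained %3d of %d edges; hubs: %s\n", g, nrow(kept),
              nrow(graph$edges),
              paste(sprintf("%s(%d)", names(hubs), hubs), collapse = " ")))
  cat(sprintf("    strongest retained pair: %s-%s (|rho| = %.2f)\n",
              strongest$source, strongest$target, strongest$weight))
}
cat("graphs -> results/network/ (GraphML + edge/vertex tables)\n")
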