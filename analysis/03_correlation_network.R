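#!/usr/bin/env Rscript

## Spearman miRNA-mRNA-T-bet correlation analysis per study group:
## coefficient and P matrices, significance-filtered chord edges with the
## w = 1 + 10 (|rho| - t)^2 transform, Circos tableviewer exports, and the
## clustered correlation heatmap for the pooled patient group.

library(balcornet)

expr <- read_expression_tsv("results/cohort/expression.tsv")
meta <- read_metadata_tsv("results/cohort/metadata.tsv")
design <- default_study_design()
dir.create("results/corr", showWarnings = FALSE)

rows <- c(design$mirna, design$tf)
cols <- setdiff(design$mrna, design$tf)
alpha <- 0.05

for (g in c("sarcoidosis", "progressing", "regressing", "control")) {
  cr <- correlation_result(expr, rows, cols, meta = meta, group = g)
  t_g <- critical_rho(cr$n, alpha)
  edges <- chord_edges(cr, alpha = alpha)
  cat(sprintf("%-12s n = %2d  t = %.3f  significant pairs = %d\n",
              g, cr$n, t_g, nrow(edges)))
  if (nrow(edges)) {
    top <- edges[order(edges$p)[1:min(3, nrow(edges))], ]
    cat(sprintf("    strongest: %s\n",
                paste(sprintf("%s-%s (rho %.2f, w %.2f)", top$source,
                              top$target, top$rho, top$w), collapse = "; ")))
  }
  utils::write.table(edges, sprintf("results/corr/chord_edges_%s.tsv", g),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  write_circos_table(cr, sprintf("results/corr/circos_%s.tsv", g),
                     alpha = alpha)
  if (g == "sarcoidosis") {
    hm <- cluster_heatmap(cr)
    write_heatmap(hm, "results/corr/heatmap_sarcoidosis.tsv")
  }
}
## with 26 x 28 pairs tested per group, a null group still shows ~alpha
## of them significant by chance; only fractions well above alpha indicate
## real coexpression structure
cat(sprintf("chance expectation per group: ~%.0f pairs (alpha x %d)\n",
            alpha * length(rows) * length(cols), length(rows) * length(cols)))
cat("tables -> results/corr/\n")
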