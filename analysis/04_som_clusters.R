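#!/usr/bin/env Rscript

## Kohonen self-organizing map over the joint miRNA+mRNA profiles of the
## sarcoidosis patients: does the unsupervised 2-D map separate progressing
## from regressing disease?

library(balcornet)

expr <- read_expression_tsv("results/cohort/expression.tsv")
meta <- read_metadata_tsv("results/cohort/metadata.tsv")
dir.create("results/som", showWarnings = FALSE)

pat <- meta$group %in% c("regressing", "progressing")
model <- train_som(expr[meta$sample_id[pat], ], grid = c(4, 3),
                   epochs = 100, seed = 1)
report <- assign_and_report(model, expr[meta$sample_id[pat], ], meta[pat, ])

utils::write.table(report, "results/som/som_neurons.tsv", sep = "\t",
                   quote = FALSE, row.names = FALSE)

sm <- attr(report, "summary")
cat(sprintf("occupied neurons: %d of %d (grid 4 x 3)\n",
            nrow(report), nrow(model$codebook)))
cat(sprintf("pure: %d, majority: %d, mixed: %d\n",
            sm["pure"], sm["majority"], sm["mixed"]))
for (i in seq_len(nrow(report))) {
  r <- report[i, ]
  cat(sprintf("  neuron (%d,%d): %2d patients (%4.1f%% of cohort), top %s (purity %.2f)\n",
              r$row, r$col, r$n_samples, r$percent_of_cohort,
              r$top_class, r$purity))
}
cat(sprintf("final quantization error: %.3f\n", tail(model$qe, 1)))
cat("report -> results/som/som_neurons.tsv\n")
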