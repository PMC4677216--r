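#!/usr/bin/env Rscript

## Simulate a BAL cohort with the study design (14 controls, 28 regressing,
## 20 progressing; 25 miRNAs, 28 cytokine/chemokine/receptor mRNAs + T-bet)
## and a known planted structure that mimics the kind of signal the real
## cohort shows: a few miRNAs and Th1-axis genes shifted in patients, two
## miRNAs shifted specifically in progression, and a handful of
## miRNA-mRNA / T-bet-mRNA rank correlations.

library(balcornet)

seed <- 1L
out <- "results/cohort"
dir.create(out, recursive = TRUE, showWarnings = FALSE)

design <- default_study_design()

up_in_patients <- function(feature, lfs) {
  list(planted_effect(feature, "regressing", lfs),
       planted_effect(feature, "progressing", lfs))
}
effects <- c(
  up_in_patients("miR-150", log(3)),
  up_in_patients("miR-146a", log(1.6)),
  up_in_patients("CCL5", log(2)),
  up_in_patients("CXCL9", log(2.5)),
  up_in_patients("IFNG", log(2.5)),
  up_in_patients("T-bet", log(1.8)),
  list(planted_effect("miR-155", "progressing", log(2)),
       planted_effect("let-7c", "progressing", log(1.8)))
)
correlations <- list(
  ## Th1 axis: T-bet hub plus mutual links among its targets (a pure star
  ## of strong correlations would not be a valid correlation structure)
  planted_correlation("T-bet", "IFNG", 0.7),
  planted_correlation("T-bet", "CXCR3", 0.7),
  planted_correlation("T-bet", "IL2RB", 0.6),
  planted_correlation("IFNG", "CXCR3", 0.5),
  planted_correlation("IFNG", "IL2RB", 0.45),
  planted_correlation("CXCR3", "IL2RB", 0.45),
  planted_correlation("miR-212", "CXCL10", 0.6,
                      groups = c("regressing", "progressing")),
  planted_correlation("miR-146a", "CCL19", 0.6, groups = "regressing"),
  planted_correlation("miR-25", "CCL2", 0.55,
                      groups = c("regressing", "progressing"))
)

cohort <- generate_cohort(design, effects = effects,
                          correlations = correlations, seed = seed)

write_expression_tsv(cohort$expression, file.path(out, "expression.tsv"),
                     comments = sprintf("synthetic cohort, seed %d", seed))
write_metadata_tsv(cohort$metadata, file.path(out, "metadata.tsv"))

cat(sprintf("simulated %d samples x %d features -> %s\n",
            nrow(cohort$expression), ncol(cohort$expression), out))
cat(sprintf("planted: %d group shifts, %d rank correlations\n",
            length(effects), length(correlations)))
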