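#' Cohort design for the BAL expression study
#'
#' A cohort design records the group sizes and the feature panel (miRNAs and
#' mRNAs, one of which is flagged as the transcription-factor feature) used by
#' the synthetic-cohort generator and by the downstream bookkeeping.
#'
#' @param n_control,n_regressing,n_progressing group sizes; each must be >= 2.
#' @param mirna character vector of miRNA feature names.
#' @param mrna character vector of mRNA feature names; must contain `tf`.
#' @param tf name of the transcription-factor feature (an mRNA).
#' @return An object of class `cohort_design`.
#' @seealso [default_study_design()] for the study panel this package models.
#' @export
cohort_design <- function(n_control, n_regressing, n_progressing,
                          mirna, mrna, tf = mrna[length(mrna)]) {
  assert_that(all(c(n_control, n_regressing, n_progressing) >= 2),
              "all group sizes must be >= 2")
  assert_that(length(mirna) >= 1 && length(mrna) >= 1,
              "feature name lists must be non-empty")
  assert_that(!anyDuplicated(c(mirna, mrna)),
              "miRNA and mRNA feature names must be disjoint and unique")
  assert_that(tf %in% mrna, "the transcription-factor feature must be an mRNA")
  structure(
    list(n_control = as.integer(n_control),
         n_regressing = as.integer(n_regressing),
         n_progressing = as.integer(n_progressing),
         mirna = as.character(mirna),
         mrna = as.character(mrna),
         tf = as.character(tf)),
    class = "cohort_design")
}

#' @export
print.cohort_design <- function(x, ...) {
  cat("BAL cohort design\n")
  cat(sprintf("  groups: control n=%d, regressing n=%d, progressing n=%d\n",
              x$n_control, x$n_regressing, x$n_progressing))
  cat(sprintf("  features: %d miRNA, %d mRNA (TF: %s)\n",
              length(x$mirna), length(x$mrna), x$tf))
  invisible(x)
}

#' The default BAL study design
#'
#' Group sizes and the feature panel of the sarcoidosis BAL study this package
#' models: 14 control subjects, 28 patients with regressing and 20 with
#' progressing disease; 25 inflammation-related miRNAs; 28
#' cytokine/chemokine/receptor mRNAs plus the Th1 transcription factor T-bet.
#'
#' @return A [cohort_design()].
#' @export
default_study_design <- function() {
  mirna <- c("let-7c", "let-7d", "miR-21", "miR-24", "miR-25", "miR-92a",
             "miR-125a", "miR-126", "miR-133a", "miR-146a", "miR-148a",
             "miR-150", "miR-155", "miR-181a", "miR-199a", "miR-202",
             "miR-204", "miR-206", "miR-212", "miR-214", "miR-222",
             "miR-223", "miR-302c", "miR-424", "miR-503")
  mrna <- c("CCL2", "CCL3", "CCL4", "CCL5", "CCL7", "CCL8", "CCL13", "CCL19",
            "CXCL2", "CXCL3", "CXCL9", "CXCL10", "CXCL11", "CXCL12", "CXCL16",
            "CCR1", "CCR2A", "CCR2B", "CCR5", "CXCR3", "CXCR4", "CXCR6",
            "CXCR7", "IL2", "IL2RA", "IL2RB", "IL15RA", "IFNG", "T-bet")
  cohort_design(n_control = 14, n_regressing = 28, n_progressing = 20,
                mirna = mirna, mrna = mrna, tf = "T-bet")
}

#' Planted group mean-shift for the synthetic generator
#'
#' @param feature feature name (must exist in the design it is used with).
#' @param group group whose log-scale location is shifted.
#' @param log_fold_shift shift of the log-mean (natural-log scale); `log(2)`
#'   doubles the group geometric mean.
#' @return An object of class `planted_effect`.
#' @export
planted_effect <- function(feature, group, log_fold_shift) {
  assert_that(group %in% GROUP_LEVELS,
              sprintf("unknown group '%s' in planted effect", group))
  assert_that(is.finite(log_fold_shift), "log_fold_shift must be finite")
  structure(list(feature = feature, group = group,
                 log_fold_shift = log_fold_shift),
            class = "planted_effect")
}

#' Planted Spearman correlation for the synthetic generator
#'
#' The generator plants the rank correlation on the latent Gaussian scale via
#' the copula identity `rho_pearson = 2 sin(pi rho_s / 6)`, so the population
#' Spearman correlation of the generated pair equals `rho_s`.
#'
#' @param feature_a,feature_b the correlated pair (distinct features).
#' @param rho_s target population Spearman correlation, in \[-1, 1\].
#' @param groups groups in which the correlation holds; the latent correlation
#'   is zero in the remaining groups.
#' @return An object of class `planted_correlation`.
#' @export
planted_correlation <- function(feature_a, feature_b, rho_s,
                                groups = GROUP_LEVELS) {
  assert_that(feature_a != feature_b,
              "planted correlation needs two distinct features")
  assert_that(abs(rho_s) <= 1, "|rho_s| must be <= 1")
  assert_that(all(groups %in% GROUP_LEVELS), "unknown group label")
  structure(list(feature_a = feature_a, feature_b = feature_b,
                 rho_s = rho_s, groups = groups),
            class = "planted_correlation")
}
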