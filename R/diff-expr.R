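#' Per-group means with confidence intervals
#'
#' Arithmetic mean and t-distribution confidence interval
#' (`mean +/- t_{n-1, 1-alpha/2} * sd / sqrt(n)`) per feature and group,
#' the reporting shape used for relative-expression tables. The pooled
#' patient group (`sarcoidosis` = regressing + progressing) is included by
#' default alongside the three design groups.
#'
#' @param expr samples x features expression matrix.
#' @param meta metadata with `sample_id`, `group`.
#' @param ci_level confidence level in \[0, 1); 0 degenerates to the mean.
#' @param pool_sarcoidosis include the pooled patient group.
#' @return data.frame: `feature`, `group`, `n`, `mean`, `ci_low`, `ci_high`,
#'   `degenerate` (TRUE when n < 2 and the interval is undefined; the
#'   interval then collapses to the mean).
#' @export
summarize_groups <- function(expr, meta, ci_level = 0.95,
                             pool_sarcoidosis = TRUE) {
  check_expr_meta(expr, meta)
  assert_that(ci_level >= 0 && ci_level < 1, "ci_level must be in [0, 1)")
  groups <- intersect(GROUP_LEVELS, unique(meta$group))
  if (pool_sarcoidosis &&
      any(meta$group %in% c("regressing", "progressing"))) {
    groups <- c("sarcoidosis", groups)
  }
  rows <- list()
  for (g in groups) {
    ids <- group_samples(meta, g)
    sub <- expr[ids, , drop = FALSE]
    n <- nrow(sub)
    mu <- colMeans(sub)
    if (n >= 2 && ci_level > 0) {
      se <- apply(sub, 2L, stats::sd) / sqrt(n)
      tq <- stats::qt(1 - (1 - ci_level) / 2, df = n - 1)
      lo <- mu - tq * se; hi <- mu + tq * se
      degen <- FALSE
    } else {
      lo <- hi <- mu
      degen <- n < 2
    }
    rows[[g]] <- data.frame(feature = colnames(expr), group = g, n = n,
                            mean = unname(mu), ci_low = unname(lo),
                            ci_high = unname(hi), degenerate = degen,
                            stringsAsFactors = FALSE)
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Differential-expression table across study groups
#'
#' One row per feature with the three comparisons used for group
#' differences in this design: Kruskal-Wallis across control / regressing /
#' progressing, Mann-Whitney sarcoidosis (pooled) versus control, and
#' Mann-Whitney regressing versus progressing. Significance is the
#' unadjusted `p < alpha` criterion; Benjamini-Hochberg adjusted columns are
#' reported alongside for reference but do not drive the `sig_*` flags.
#'
#' @param expr samples x features matrix.
#' @param meta metadata with `sample_id`, `group` covering all three groups.
#' @param alpha significance level for the `sig_*` flags.
#' @param mode test mode passed to [mann_whitney()].
#' @param ci_level confidence level for the group summaries.
#' @return data.frame with group summary columns (`mean_<group>`,
#'   `lo_<group>`, `hi_<group>`) and test columns (`p_kw`, `p_s_vs_c`,
#'   `p_reg_vs_prog`, BH-adjusted versions, `sig_*` flags).
#' @export
de_table <- function(expr, meta, alpha = 0.05, mode = "auto",
                     ci_level = 0.95) {
  check_expr_meta(expr, meta)
  assert_that(all(GROUP_LEVELS %in% meta$group),
              "de_table needs samples in all three groups")
  feats <- colnames(expr)
  idx <- lapply(c("control", "regressing", "progressing", "sarcoidosis"),
                function(g) group_samples(meta, g))
  names(idx) <- c("control", "regressing", "progressing", "sarcoidosis")

  p_kw <- p_sc <- p_rp <- numeric(length(feats))
  for (i in seq_along(feats)) {
    x <- expr[, i]
    p_kw[i] <- kruskal_wallis(list(x[idx$control], x[idx$regressing],
                                   x[idx$progressing]))$p_value
    p_sc[i] <- mann_whitney(x[idx$sarcoidosis], x[idx$control],
                            mode = mode)$p_value
    p_rp[i] <- mann_whitney(x[idx$regressing], x[idx$progressing],
                            mode = mode)$p_value
  }

  smry <- summarize_groups(expr, meta, ci_level = ci_level)
  wide <- data.frame(feature = feats, stringsAsFactors = FALSE)
  for (g in unique(smry$group)) {
    sub <- smry[smry$group == g, ]
    sub <- sub[match(feats, sub$feature), ]
    wide[[paste0("mean_", g)]] <- sub$mean
    wide[[paste0("lo_", g)]] <- sub$ci_low
    wide[[paste0("hi_", g)]] <- sub$ci_high
  }
  wide$p_kw <- p_kw
  wide$p_s_vs_c <- p_sc
  wide$p_reg_vs_prog <- p_rp
  wide$padj_kw <- stats::p.adjust(p_kw, "BH")
  wide$padj_s_vs_c <- stats::p.adjust(p_sc, "BH")
  wide$padj_reg_vs_prog <- stats::p.adjust(p_rp, "BH")
  wide$sig_kw <- p_kw < alpha
  wide$sig_s_vs_c <- p_sc < alpha
  wide$sig_reg_vs_prog <- p_rp < alpha
  wide
}

#' Write a differential-expression table in the publication layout
#'
#' Emits a TSV with one `mean (low-high)` column per group followed by the
#' three P-value columns, mirroring the layout of per-gene qPCR summary
#' tables.
#'
#' @param de result of [de_table()].
#' @param path output path.
#' @param digits significant digits for means and CI bounds.
#' @param comments provenance comment lines.
#' @export
write_de_table <- function(de, path, digits = 3, comments = character()) {
  fmt <- function(m, lo, hi)
    sprintf("%s (%s-%s)", signif(m, digits), signif(lo, digits), signif(hi, digits))
  grp_cols <- sub("^mean_", "", grep("^mean_", names(de), value = TRUE))
  out <- data.frame(feature = de$feature, stringsAsFactors = FALSE)
  for (g in grp_cols) {
    out[[g]] <- fmt(de[[paste0("mean_", g)]], de[[paste0("lo_", g)]],
                    de[[paste0("hi_", g)]])
  }
  out$p_kruskal_wallis <- signif(de$p_kw, 3)
  out$p_s_vs_c <- signif(de$p_s_vs_c, 3)
  out$p_reg_vs_prog <- signif(de$p_reg_vs_prog, 3)
  write_tsv(out, path, comments)
}
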