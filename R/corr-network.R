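#' Spearman correlation result for a row x column feature panel
#'
#' All pairwise Spearman coefficients and two-sided P values between a set of
#' row features (typically the miRNAs plus the transcription factor) and a
#' set of column features (the mRNAs), computed on the samples of one study
#' group. Numeric sample covariates (e.g. % lymphocytes) can be appended as
#' extra rows.
#'
#' @param expr samples x features matrix.
#' @param row_features,col_features feature names selecting the two panels.
#' @param meta metadata (required when `group` or `covariates` is used).
#' @param group `NULL`/"all", one of control/regressing/progressing, or
#'   "sarcoidosis" for the pooled patient group.
#' @param covariates names of numeric metadata columns appended as rows.
#' @param p_mode mode passed to [spearman_p()].
#' @return An object of class `correlation_result`: list with `rho`, `p`
#'   (matrices rows x cols), `n`, `row_features`, `col_features`, `group`,
#'   `undefined` (pairs involving a constant feature, reported and set `NA`).
#' @export
correlation_result <- function(expr, row_features, col_features,
                               meta = NULL, group = NULL,
                               covariates = NULL, p_mode = "auto") {
  if (!is.null(meta)) check_expr_meta(expr, meta)
  ids <- if (is.null(meta)) rownames(expr) else group_samples(meta, group)
  assert_that(length(ids) >= 3, "need at least 3 samples in the group",
              class = "balcornet_too_few_samples")
  assert_that(all(row_features %in% colnames(expr)) &&
                all(col_features %in% colnames(expr)),
              "row/col features must be columns of the expression matrix")
  sub <- expr[ids, , drop = FALSE]
  rows <- sub[, row_features, drop = FALSE]
  if (!is.null(covariates)) {
    assert_that(!is.null(meta), "covariates require metadata")
    assert_that(all(covariates %in% names(meta)),
                "unknown covariate column(s)")
    cv <- as.matrix(meta[match(ids, meta$sample_id), covariates, drop = FALSE])
    storage.mode(cv) <- "double"
    rows <- cbind(rows, cv)
  }
  cols <- sub[, col_features, drop = FALSE]

  const_r <- apply(rows, 2L, function(v) stats::sd(v) == 0)
  const_c <- apply(cols, 2L, function(v) stats::sd(v) == 0)
  rho <- suppressWarnings(
    stats::cor(rows, cols, method = "spearman"))
  undefined <- character()
  if (any(const_r) || any(const_c)) {
    rho[const_r, ] <- NA_real_
    rho[, const_c] <- NA_real_
    undefined <- c(colnames(rows)[const_r], colnames(cols)[const_c])
  }
  n <- length(ids)
  p <- rho
  ok <- !is.na(rho)
  p[ok] <- spearman_p(rho[ok], n, mode = p_mode)
  structure(
    list(rho = rho, p = p, n = n,
         row_features = colnames(rows), col_features = colnames(cols),
         group = group %||% "all", undefined = undefined),
    class = "correlation_result")
}

#' @export
print.correlation_result <- function(x, ...) {
  cat(sprintf("Spearman correlation result: %d x %d features, n = %d (%s)\n",
              length(x$row_features), length(x$col_features), x$n, x$group))
  if (length(x$undefined)) {
    cat("  undefined (constant) features:",
        paste(x$undefined, collapse = ", "), "\n")
  }
  invisible(x)
}

#' Chord-diagram weight transform
#'
#' Maps a significant Spearman coefficient to the band weight used in chord
#' diagrams: `w = 1 + 10 (|rho| - t)^2`, where `t` is the significance
#' threshold on `|rho|` (the critical coefficient at the chosen alpha, see
#' [critical_rho()]). The transform is 1 at the threshold, symmetric in the
#' sign of `rho`, and accentuates differences between strong correlations.
#'
#' @param rho Spearman coefficient(s).
#' @param t threshold in \[0, 1\].
#' @return Weight(s) `>= 1`.
#' @export
chord_weight <- function(rho, t) {
  assert_that(all(abs(rho) <= 1), "|rho| must be <= 1")
  assert_that(length(t) == 1 && t >= 0 && t <= 1, "t must be in [0, 1]")
  1 + 10 * (abs(rho) - t)^2
}

#' Significant chord edges from a correlation result
#'
#' Pairs with `p < alpha`, weighted by [chord_weight()] with the threshold
#' `t` computed from the group's sample size (unless overridden). An empty
#' edge set is a legitimate outcome - small null groups typically yield none.
#'
#' @param cr a [correlation_result()].
#' @param alpha significance level.
#' @param t threshold override; default `critical_rho(cr$n, alpha)`.
#' @return data.frame: `source`, `target`, `rho`, `p`, `w`, ordered by
#'   feature names.
#' @export
chord_edges <- function(cr, alpha = 0.05, t = NULL) {
  assert_that(inherits(cr, "correlation_result"), "cr must be a correlation_result")
  t <- t %||% critical_rho(cr$n, alpha)
  if (is.na(t)) t <- 1       # unreachable alpha: no pair can be significant
  sig <- which(!is.na(cr$p) & cr$p < alpha, arr.ind = TRUE)
  out <- data.frame(
    source = cr$row_features[sig[, 1]],
    target = cr$col_features[sig[, 2]],
    rho = cr$rho[sig], p = cr$p[sig],
    stringsAsFactors = FALSE)
  out$w <- if (nrow(out)) chord_weight(out$rho, t) else numeric(0)
  out <- out[order(out$source, out$target, method = "radix"), , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "t") <- t
  attr(out, "alpha") <- alpha
  attr(out, "n") <- cr$n
  out
}

#' Circos tableviewer export of chord weights
#'
#' Tab-delimited matrix (row/column feature labels, integer cell values) in
#' the tableviewer input layout: cell = `round(100 w)` for significant pairs,
#' 0 otherwise.
#'
#' @param cr a [correlation_result()].
#' @param path output path.
#' @param alpha,t as in [chord_edges()].
#' @export
write_circos_table <- function(cr, path, alpha = 0.05, t = NULL) {
  edges <- chord_edges(cr, alpha = alpha, t = t)
  M <- matrix(0L, length(cr$row_features), length(cr$col_features),
              dimnames = list(cr$row_features, cr$col_features))
  if (nrow(edges)) {
    M[cbind(edges$source, edges$target)] <- as.integer(round(100 * edges$w))
  }
  con <- file(path, "wt"); on.exit(close(con))
  writeLines(paste(c("labels", colnames(M)), collapse = "\t"), con)
  utils::write.table(M, con, sep = "\t", quote = FALSE, col.names = FALSE)
  invisible(path)
}

#' Hierarchically clustered ordering of a correlation matrix
#'
#' Reorders rows and columns of the Spearman correlation matrix by
#' agglomerative clustering for heatmap display. Each row feature is
#' characterised by its correlation profile (its row of `rho`); the
#' dissimilarity between two profiles is `1 - cor(profiles)` (sign-aware:
#' anti-correlated profiles are maximally distant), and likewise for
#' columns. Features are pre-sorted lexicographically so the leaf order is
#' deterministic and invariant to the input ordering.
#'
#' @param cr a [correlation_result()] with no undefined correlations.
#' @param linkage `"average"`, `"complete"` or `"single"`.
#' @return list: `rho` (reordered matrix), `row_order`, `col_order`,
#'   `row_newick`, `col_newick` (dendrograms; `NA` for single-leaf sides).
#' @export
cluster_heatmap <- function(cr, linkage = c("average", "complete", "single")) {
  linkage <- match.arg(linkage)
  assert_that(inherits(cr, "correlation_result"), "cr must be a correlation_result")
  assert_that(!anyNA(cr$rho),
              "undefined correlations present; drop constant features first",
              class = "balcornet_undefined_correlation")
  rho <- cr$rho
  rho <- rho[lex_order(rownames(rho)), lex_order(colnames(rho)), drop = FALSE]

  side <- function(m) {            # rows of m are the profiles to cluster
    if (nrow(m) < 2) return(list(order = rownames(m), newick = NA_character_))
    if (ncol(m) < 2) {
      d <- stats::dist(m)          # scalar profiles: plain distance
    } else {
      cm <- suppressWarnings(stats::cor(t(m)))
      cm[is.na(cm)] <- 0           # constant profile rows: treat as unrelated
      d <- stats::as.dist(1 - cm)
    }
    hc <- stats::hclust(d, method = linkage)
    list(order = rownames(m)[hc$order],
         newick = ape::write.tree(ape::as.phylo(hc)))
  }
  rs <- side(rho)
  cs <- side(t(rho))
  list(rho = rho[rs$order, cs$order, drop = FALSE],
       row_order = rs$order, col_order = cs$order,
       row_newick = rs$newick, col_newick = cs$newick)
}

#' Write a clustered correlation heatmap as TSV (+ newick dendrograms)
#'
#' @param hm result of [cluster_heatmap()].
#' @param path TSV path for the reordered matrix; dendrograms are written to
#'   `<path>.rows.nwk` / `<path>.cols.nwk` when present.
#' @param comments provenance comment lines.
#' @export
write_heatmap <- function(hm, path, comments = character()) {
  df <- data.frame(feature = rownames(hm$rho), hm$rho,
                   check.names = FALSE, stringsAsFactors = FALSE)
  write_tsv(df, path, comments)
  if (!is.na(hm$row_newick)) writeLines(hm$row_newick, paste0(path, ".rows.nwk"))
  if (!is.na(hm$col_newick)) writeLines(hm$col_newick, paste0(path, ".cols.nwk"))
  invisible(path)
}
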