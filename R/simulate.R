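#' Spearman-to-Pearson conversion for the Gaussian copula
#'
#' For a bivariate Gaussian copula the population Spearman correlation
#' `rho_s` and the latent Pearson correlation `rho_p` are linked exactly by
#' `rho_p = 2 sin(pi rho_s / 6)`. Planting `rho_p` on the latent scale
#' therefore yields marginals whose Spearman correlation is `rho_s`,
#' whatever strictly monotone marginal transform (here `exp`) is applied.
#'
#' @param rho_s Spearman correlation(s) in \[-1, 1\].
#' @return Latent Pearson correlation(s).
#' @export
spearman_to_pearson <- function(rho_s) {
  assert_that(all(abs(rho_s) <= 1), "|rho_s| must be <= 1")
  2 * sin(pi * rho_s / 6)
}

## Latent correlation matrix for one group: identity plus the planted pairs
## active in that group, converted to the Pearson scale.
latent_corr_matrix <- function(features, correlations, group) {
  p <- length(features)
  R <- diag(p)
  dimnames(R) <- list(features, features)
  for (pc in correlations) {
    if (!(group %in% pc$groups)) next
    i <- match(pc$feature_a, features)
    j <- match(pc$feature_b, features)
    R[i, j] <- R[j, i] <- spearman_to_pearson(pc$rho_s)
  }
  R
}

#' Generate a synthetic BAL expression cohort
#'
#' Draws calibrator-relative expression values with log-normal marginals from
#' a Gaussian copula. Group-specific location shifts (`effects`) act on the
#' log-mean, so a shift of `log(2)` doubles the group geometric mean. Planted
#' Spearman correlations (`correlations`) are imposed on the latent Gaussian
#' scale via [spearman_to_pearson()] and may be restricted to a subset of
#' groups, in which case each group uses its own latent correlation matrix.
#'
#' The per-group latent correlation matrix must be positive semi-definite;
#' otherwise generation is rejected with an error naming the planted pairs.
#'
#' @param design a [cohort_design()].
#' @param effects list of [planted_effect()] objects.
#' @param correlations list of [planted_correlation()] objects.
#' @param base_log_mean baseline log-scale location; recycled over features.
#'   The default `log(0.1)` matches the typical magnitude of
#'   calibrator-relative qPCR expression in BAL cells.
#' @param base_log_sd log-scale standard deviation (default 0.5).
#' @param seed integer seed; generation is bit-reproducible for a fixed seed.
#' @return A list with `expression` (samples x features matrix, all values
#'   positive) and `metadata` (data.frame with `sample_id`, `group`).
#' @export
generate_cohort <- function(design, effects = list(), correlations = list(),
                            base_log_mean = log(0.1), base_log_sd = 0.5,
                            seed = 1L) {
  assert_that(inherits(design, "cohort_design"), "design must be a cohort_design")
  features <- c(design$mirna, design$mrna)
  assert_that(base_log_sd > 0, "base_log_sd must be positive")
  mu0 <- rep_len(base_log_mean, length(features))
  names(mu0) <- features

  for (ef in effects) {
    assert_that(inherits(ef, "planted_effect"), "effects must be planted_effect objects")
    assert_that(ef$feature %in% features,
                sprintf("planted effect on unknown feature '%s'", ef$feature))
  }
  for (pc in correlations) {
    assert_that(inherits(pc, "planted_correlation"),
                "correlations must be planted_correlation objects")
    ok <- all(c(pc$feature_a, pc$feature_b) %in% features)
    assert_that(ok, sprintf("planted correlation on unknown feature(s): %s-%s",
                            pc$feature_a, pc$feature_b))
  }

  sizes <- c(control = design$n_control,
             regressing = design$n_regressing,
             progressing = design$n_progressing)
  prefix <- c(control = "C", regressing = "R", progressing = "P")

  ## Pre-compute one latent square root per group; reject non-PSD structures.
  roots <- lapply(GROUP_LEVELS, function(g) {
    R <- latent_corr_matrix(features, correlations, g)
    ev <- eigen(R, symmetric = TRUE)
    if (min(ev$values) < -1e-8) {
      bad <- vapply(correlations, function(pc)
        if (g %in% pc$groups) paste0(pc$feature_a, "-", pc$feature_b) else NA_character_,
        character(1))
      stop_balcornet(
        sprintf(paste0("planted correlations do not form a positive ",
                       "semi-definite latent structure in group '%s' ",
                       "(pairs involved: %s)"),
                g, paste(stats::na.omit(bad), collapse = ", ")),
        class = "balcornet_non_psd")
    }
    ev$vectors %*% (sqrt(pmax(ev$values, 0)) * t(ev$vectors))
  })
  names(roots) <- GROUP_LEVELS

  set.seed(as.integer(seed))
  blocks <- list(); ids <- character(); grp <- character()
  for (g in GROUP_LEVELS) {
    n <- sizes[[g]]
    mu <- mu0
    for (ef in effects) if (ef$group == g) {
      mu[ef$feature] <- mu[ef$feature] + ef$log_fold_shift
    }
    Z <- matrix(stats::rnorm(n * length(features)), nrow = n) %*% roots[[g]]
    X <- exp(sweep(base_log_sd * Z, 2L, mu, "+"))
    blocks[[g]] <- X
    ids <- c(ids, sprintf("%s%02d", prefix[[g]], seq_len(n)))
    grp <- c(grp, rep(g, n))
  }
  expr <- do.call(rbind, blocks)
  dimnames(expr) <- list(ids, features)
  meta <- data.frame(sample_id = ids, group = grp, stringsAsFactors = FALSE)
  list(expression = expr, metadata = meta)
}

#' Write / read an expression matrix as TSV
#'
#' First column `sample_id`, one column per feature.
#' @param expr samples x features matrix.
#' @param path file path.
#' @param comments optional provenance comment lines.
#' @export
write_expression_tsv <- function(expr, path, comments = character()) {
  df <- data.frame(sample_id = rownames(expr), expr,
                   check.names = FALSE, stringsAsFactors = FALSE)
  write_tsv(df, path, comments)
}

#' @rdname write_expression_tsv
#' @export
read_expression_tsv <- function(path) {
  df <- read_tsv(path)
  m <- as.matrix(df[, -1, drop = FALSE])
  rownames(m) <- df$sample_id
  storage.mode(m) <- "double"
  m
}

#' Write / read sample metadata as TSV
#' @param meta data.frame with `sample_id` and `group` (plus covariates).
#' @inheritParams write_expression_tsv
#' @export
write_metadata_tsv <- function(meta, path, comments = character()) {
  write_tsv(meta, path, comments)
}

#' @rdname write_metadata_tsv
#' @export
read_metadata_tsv <- function(path) {
  read_tsv(path)
}
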