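#' Pipeline run configuration
#'
#' Collects every tunable of the end-to-end analysis. Either paths to an
#' expression matrix and metadata TSV, or `design = "default"` (or a
#' [cohort_design()]) to simulate a synthetic cohort.
#'
#' @param out_dir output directory for all artifacts.
#' @param expression_tsv,metadata_tsv input paths (optional).
#' @param design cohort design for synthetic input; `"default"` uses
#'   [default_study_design()].
#' @param effects,correlations planted structure for the synthetic cohort.
#' @param alpha significance level used throughout.
#' @param ci_level confidence level of group summaries.
#' @param som_grid,som_epochs SOM geometry and training length.
#' @param k_nn neighbours kept by the nearest-neighbour pruning.
#' @param critical_t optional fixed chord threshold overriding the per-group
#'   critical coefficient.
#' @param seed integer seed recorded in every output.
#' @return A list of class `run_config`.
#' @export
run_config <- function(out_dir, expression_tsv = NULL, metadata_tsv = NULL,
                       design = "default", effects = list(),
                       correlations = list(), alpha = 0.05, ci_level = 0.95,
                       som_grid = c(4, 3), som_epochs = 100, k_nn = 1L,
                       critical_t = NULL, seed = 1L) {
  assert_that(alpha > 0 && alpha < 1, "alpha must be in (0, 1)")
  structure(list(out_dir = out_dir, expression_tsv = expression_tsv,
                 metadata_tsv = metadata_tsv, design = design,
                 effects = effects, correlations = correlations,
                 alpha = alpha, ci_level = ci_level, som_grid = som_grid,
                 som_epochs = som_epochs, k_nn = as.integer(k_nn),
                 critical_t = critical_t, seed = as.integer(seed)),
            class = "run_config")
}

#' Read a pipeline configuration from YAML
#'
#' Scalar fields of [run_config()] in a flat YAML mapping; planted effects
#' and correlations as lists of mappings (`feature`/`group`/`log_fold_shift`
#' and `feature_a`/`feature_b`/`rho_s`/`groups`).
#'
#' @param path YAML file.
#' @return A [run_config()].
#' @export
read_run_config <- function(path) {
  y <- yaml::read_yaml(path)
  effects <- lapply(y$effects %||% list(), function(e)
    planted_effect(e$feature, e$group, e$log_fold_shift))
  correlations <- lapply(y$correlations %||% list(), function(e)
    planted_correlation(e$feature_a, e$feature_b, e$rho_s,
                        e$groups %||% GROUP_LEVELS))
  run_config(
    out_dir = y$out_dir %||% "results",
    expression_tsv = y$expression_tsv, metadata_tsv = y$metadata_tsv,
    design = y$design %||% "default",
    effects = effects, correlations = correlations,
    alpha = y$alpha %||% 0.05, ci_level = y$ci_level %||% 0.95,
    som_grid = unlist(y$som_grid %||% c(4, 3)),
    som_epochs = y$som_epochs %||% 100,
    k_nn = y$k_nn %||% 1L, critical_t = y$critical_t,
    seed = y$seed %||% 1L)
}

with_stage <- function(stage, expr) {
  tryCatch(expr, error = function(e) {
    stop_balcornet(sprintf("stage '%s' failed: %s", stage, conditionMessage(e)),
                   class = "balcornet_stage_error")
  })
}

#' Run the full analysis pipeline
#'
#' Sequences every stage on one cohort: input (or synthetic generation),
#' differential-expression table, per-group Spearman correlation results,
#' chord-edge and Circos exports, clustered correlation heatmap, SOM
#' clustering of patients, and nearest-neighbour coexpression graphs per
#' group. All artifacts are TSV/GraphML/newick text files under
#' `config$out_dir`; a manifest with MD5 checksums and a log recording
#' alpha, the chord threshold t, and the sample size per group are written
#' alongside.
#'
#' @param config a [run_config()].
#' @return Invisibly, the manifest data.frame (`file`, `md5`, `bytes`).
#' @export
run_all <- function(config) {
  assert_that(inherits(config, "run_config"), "config must be a run_config")
  dir.create(config$out_dir, recursive = TRUE, showWarnings = FALSE)
  logf <- file.path(config$out_dir, "run.log")
  loglines <- character()
  say <- function(...) {
    line <- sprintf(...)
    loglines <<- c(loglines, line)
    message(line)
  }
  prov <- c(sprintf("balcornet %s", as.character(utils::packageVersion("balcornet"))),
            sprintf("seed %d alpha %g", config$seed, config$alpha))
  say("run_all: seed %d, alpha %g", config$seed, config$alpha)

  ## ---- input ---------------------------------------------------------------
  if (!is.null(config$expression_tsv)) {
    cohort <- with_stage("input", list(
      expression = read_expression_tsv(config$expression_tsv),
      metadata = read_metadata_tsv(config$metadata_tsv)))
    say("input: read %d samples x %d features from %s",
        nrow(cohort$expression), ncol(cohort$expression), config$expression_tsv)
    design <- NULL
  } else {
    design <- if (identical(config$design, "default")) {
      default_study_design()
    } else config$design
    cohort <- with_stage("simulate", generate_cohort(
      design, effects = config$effects, correlations = config$correlations,
      seed = config$seed))
    say("simulate: %d samples x %d features",
        nrow(cohort$expression), ncol(cohort$expression))
  }
  expr <- cohort$expression; meta <- cohort$metadata
  write_expression_tsv(expr, file.path(config$out_dir, "expression.tsv"), prov)
  write_metadata_tsv(meta, file.path(config$out_dir, "metadata.tsv"), prov)

  mirna <- if (!is.null(design)) design$mirna else {
    grep("^(miR|let)", colnames(expr), value = TRUE)
  }
  tf <- if (!is.null(design)) design$tf else "T-bet"
  mrna <- setdiff(colnames(expr), mirna)
  row_feats <- unique(c(mirna, tf))
  col_feats <- setdiff(mrna, tf)

  ## ---- differential expression --------------------------------------------
  de <- with_stage("diff_expr", de_table(expr, meta, alpha = config$alpha,
                                         ci_level = config$ci_level))
  write_tsv(de, file.path(config$out_dir, "de_table.tsv"), prov)
  write_de_table(de, file.path(config$out_dir, "de_table_formatted.tsv"),
                 comments = prov)
  say("diff_expr: %d features, %d significant S-vs-C at alpha %g",
      nrow(de), sum(de$sig_s_vs_c), config$alpha)

  ## ---- correlation networks per group --------------------------------------
  groups <- c("sarcoidosis", "progressing", "regressing", "control")
  for (g in groups) {
    n_g <- length(group_samples(meta, g))
    if (n_g < 4) { say("corr[%s]: skipped (n = %d)", g, n_g); next }
    cr <- with_stage(paste0("corr_", g), correlation_result(
      expr, row_feats, col_feats, meta = meta, group = g))
    t_g <- config$critical_t %||% critical_rho(cr$n, config$alpha)
    edges <- chord_edges(cr, alpha = config$alpha, t = t_g)
    say("corr[%s]: n = %d, t = %.4f, %d significant edges",
        g, cr$n, t_g, nrow(edges))
    write_tsv(data.frame(feature = rownames(cr$rho), cr$rho, check.names = FALSE),
              file.path(config$out_dir, sprintf("corr_%s_rho.tsv", g)), prov)
    write_tsv(data.frame(feature = rownames(cr$p), cr$p, check.names = FALSE),
              file.path(config$out_dir, sprintf("corr_%s_p.tsv", g)), prov)
    write_tsv(edges, file.path(config$out_dir, sprintf("chord_edges_%s.tsv", g)),
              c(prov, sprintf("t %.6f n %d", t_g, cr$n)))
    write_circos_table(cr, file.path(config$out_dir, sprintf("circos_%s.tsv", g)),
                       alpha = config$alpha, t = t_g)
    if (g == "sarcoidosis") {
      hm <- with_stage("heatmap", cluster_heatmap(cr))
      write_heatmap(hm, file.path(config$out_dir, "heatmap_sarcoidosis.tsv"), prov)
    }
    gr <- with_stage(paste0("nn_", g), prune_nearest_neighbors(
      full_weighted_graph(expr, meta, group = g), k = config$k_nn))
    write_coexpression_graph(gr, file.path(config$out_dir, sprintf("nn_%s", g)),
                             prov)
  }

  ## ---- SOM over patients ---------------------------------------------------
  pat <- group_samples(meta, "sarcoidosis")
  som <- with_stage("som", train_som(expr[pat, , drop = FALSE],
                                     grid = config$som_grid,
                                     epochs = config$som_epochs,
                                     seed = config$seed))
  rep_df <- assign_and_report(som, expr[pat, , drop = FALSE],
                              meta[meta$sample_id %in% pat, ])
  write_tsv(rep_df, file.path(config$out_dir, "som_neurons.tsv"), prov)
  sm <- attr(rep_df, "summary")
  say("som: %d occupied neurons (%d pure, %d majority, %d mixed)",
      nrow(rep_df), sm["pure"], sm["majority"], sm["mixed"])

  ## ---- manifest ------------------------------------------------------------
  writeLines(loglines, logf)
  files <- sort(setdiff(list.files(config$out_dir, full.names = TRUE),
                        file.path(config$out_dir, "manifest.tsv")),
                method = "radix")
  manifest <- data.frame(
    file = basename(files),
    md5 = unname(tools::md5sum(files)),
    bytes = file.size(files),
    stringsAsFactors = FALSE)
  write_tsv(manifest, file.path(config$out_dir, "manifest.tsv"))
  invisible(manifest)
}
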