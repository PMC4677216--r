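#' Complete weighted coexpression graph over all features
#'
#' Vertices are all measured molecules (miRNAs, mRNAs, transcription
#' factor); the weight of edge (a, b) is `|spearman rho|` between the two
#' features across the selected group's samples. Pairs involving a constant
#' feature get weight 0 and are flagged.
#'
#' @param expr samples x features matrix.
#' @param meta optional metadata (required with `group`).
#' @param group study group to restrict to (see [correlation_result()]).
#' @return An object of class `coexpression_graph`: list with `weights`
#'   (symmetric |rho| matrix, zero diagonal), `rho` (signed), `features`,
#'   `n`, `group`, `undefined` (constant features), `k` (NA until pruned),
#'   `vertex_size` (NA until pruned).
#' @export
full_weighted_graph <- function(expr, meta = NULL, group = NULL) {
  if (!is.null(meta)) check_expr_meta(expr, meta)
  ids <- if (is.null(meta)) rownames(expr) else group_samples(meta, group)
  assert_that(length(ids) >= 3, "need at least 3 samples",
              class = "balcornet_too_few_samples")
  sub <- expr[ids, , drop = FALSE]
  rho <- suppressWarnings(stats::cor(sub, method = "spearman"))
  undefined <- colnames(sub)[apply(sub, 2L, function(v) stats::sd(v) == 0)]
  rho[is.na(rho)] <- 0
  diag(rho) <- 0
  structure(
    list(weights = abs(rho), rho = rho, features = colnames(sub),
         n = length(ids), group = group %||% "all",
         undefined = undefined, k = NA_integer_, vertex_size = NULL),
    class = "coexpression_graph")
}

#' Nearest-neighbour pruning of a weighted coexpression graph
#'
#' Retains edge (a, b) iff b is among a's `k` highest-weight neighbours OR a
#' is among b's (the mutual-OR rule), so every vertex keeps at least its own
#' top neighbour. Vertex size is the degree in the pruned graph - vertices
#' that are the nearest neighbour of many molecules grow large. Weight ties
#' are broken lexicographically on the neighbour's feature name, making the
#' result deterministic.
#'
#' @param graph a [full_weighted_graph()].
#' @param k neighbours retained per vertex (default 1, the nearest
#'   neighbour). `k >=` vertex count returns the complete graph with a
#'   warning.
#' @return The graph with `edges` (data.frame `source`, `target`, `rho`,
#'   `weight`, `retained` over all pairs), `vertex_size` (named degree
#'   vector) and `k` filled in.
#' @export
prune_nearest_neighbors <- function(graph, k = 1L) {
  assert_that(inherits(graph, "coexpression_graph"),
              "graph must be a coexpression_graph")
  assert_that(k >= 1, "k must be >= 1")
  W <- graph$weights
  feats <- graph$features
  nv <- length(feats)
  if (k >= nv) {
    warning("k >= vertex count: no pruning applied")
    k <- nv - 1L
  }
  ## top-k neighbour sets, ties broken by feature name
  keep <- matrix(FALSE, nv, nv, dimnames = dimnames(W))
  for (i in seq_len(nv)) {
    nb <- setdiff(seq_len(nv), i)
    ord <- nb[order(-W[i, nb], feats[nb], method = "radix")]
    keep[i, ord[seq_len(k)]] <- TRUE
  }
  retained <- keep | t(keep)                  # mutual-OR rule

  pairs <- which(upper.tri(W), arr.ind = TRUE)
  edges <- data.frame(
    source = feats[pairs[, 1]], target = feats[pairs[, 2]],
    rho = graph$rho[pairs], weight = W[pairs],
    retained = retained[pairs], stringsAsFactors = FALSE)
  edges <- edges[order(edges$source, edges$target, method = "radix"), ]
  rownames(edges) <- NULL

  deg <- rowSums(retained)
  graph$edges <- edges
  graph$vertex_size <- deg
  graph$k <- as.integer(k)
  graph
}

#' Convert a pruned coexpression graph to igraph
#'
#' Retained edges only; vertex attribute `size` is the nearest-neighbour
#' degree, edge attributes carry `rho` and `weight`.
#'
#' @param graph a pruned [prune_nearest_neighbors()] result.
#' @return An [igraph::graph] object.
#' @export
as_igraph <- function(graph) {
  assert_that(!is.null(graph$edges), "prune the graph first")
  el <- graph$edges[graph$edges$retained, c("source", "target", "rho", "weight")]
  g <- igraph::graph_from_data_frame(
    el, directed = FALSE,
    vertices = data.frame(name = graph$features,
                          size = unname(graph$vertex_size)))
  g
}

#' Write a pruned coexpression graph (GraphML + TSV tables)
#'
#' @param graph pruned graph.
#' @param path_prefix output prefix; writes `<prefix>.graphml`,
#'   `<prefix>_edges.tsv`, `<prefix>_vertices.tsv`.
#' @param comments provenance comment lines for the TSV tables.
#' @export
write_coexpression_graph <- function(graph, path_prefix, comments = character()) {
  igraph::write_graph(as_igraph(graph), paste0(path_prefix, ".graphml"),
                      format = "graphml")
  write_tsv(graph$edges, paste0(path_prefix, "_edges.tsv"), comments)
  write_tsv(data.frame(feature = graph$features,
                       vertex_size = unname(graph$vertex_size),
                       stringsAsFactors = FALSE),
            paste0(path_prefix, "_vertices.tsv"), comments)
  invisible(path_prefix)
}
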