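make_graph <- function(W, n = 20, group = "all") {
  structure(list(weights = W, rho = W, features = rownames(W),
                 n = n, group = group, undefined = character(),
                 k = NA_integer_, vertex_size = NULL),
            class = "coexpression_graph")
}

test_that("the 3-vertex worked example prunes to {AB, AC}", {
  W <- matrix(0, 3, 3, dimnames = list(c("A", "B", "C"), c("A", "B", "C")))
  W["A", "B"] <- W["B", "A"] <- 0.9
  W["A", "C"] <- W["C", "A"] <- 0.2
  W["B", "C"] <- W["C", "B"] <- 0.1
  g <- prune_nearest_neighbors(make_graph(W), k = 1)
  kept <- g$edges[g$edges$retained, ]
  expect_setequal(paste(kept$source, kept$target), c("A B", "A C"))
  expect_equal(g$vertex_size, c(A = 2, B = 1, C = 1))
})

test_that("pruning matches a brute-force oracle on random graphs", {
  for (s in 1:40) {
    set.seed(s)
    nv <- 10
    W <- matrix(0, nv, nv)
    W[upper.tri(W)] <- runif(choose(nv, 2))
    W <- W + t(W)
    dimnames(W) <- list(sprintf("v%02d", 1:nv), sprintf("v%02d", 1:nv))
    k <- sample(1:3, 1)
    g <- prune_nearest_neighbors(make_graph(W), k = k)
    got <- matrix(FALSE, nv, nv, dimnames = dimnames(W))
    kept <- g$edges[g$edges$retained, ]
    got[cbind(kept$source, kept$target)] <- TRUE
    got <- got | t(got)
    expect_identical(got, oracle_prune(W, k), label = sprintf("seed %d", s))
    expect_equal(g$vertex_size, rowSums(got))
    expect_true(all(g$vertex_size >= 1))   # OR rule keeps every top neighbour
  }
})

test_that("pruning is monotone in k and k = n-1 keeps everything", {
  set.seed(99)
  nv <- 8
  W <- matrix(0, nv, nv)
  W[upper.tri(W)] <- runif(choose(nv, 2))
  W <- W + t(W)
  dimnames(W) <- list(letters[1:nv], letters[1:nv])
  kept_k <- lapply(1:(nv - 1), function(k) {
    e <- prune_nearest_neighbors(make_graph(W), k)$edges
    paste(e$source, e$target)[e$retained]
  })
  for (k in 2:(nv - 1)) {
    expect_true(all(kept_k[[k - 1]] %in% kept_k[[k]]))
  }
  expect_length(kept_k[[nv - 1]], choose(nv, 2))
  expect_warning(full <- prune_nearest_neighbors(make_graph(W), nv + 2),
                 "no pruning")
  expect_equal(sum(full$edges$retained), choose(nv, 2))
})

test_that("weight ties break deterministically by feature name", {
  W <- matrix(0.5, 4, 4, dimnames = list(c("d", "b", "a", "c"),
                                         c("d", "b", "a", "c")))
  diag(W) <- 0
  g1 <- prune_nearest_neighbors(make_graph(W), 1)
  ## everyone's nearest neighbour under ties is the alphabetically first other
  kept <- g1$edges[g1$edges$retained, ]
  expect_true(all(kept$source == "a" | kept$target == "a"))
  g2 <- prune_nearest_neighbors(make_graph(W[c(3, 2, 4, 1), c(3, 2, 4, 1)]), 1)
  canon <- function(e) sort(paste(pmin(e$source, e$target),
                                  pmax(e$source, e$target)))
  expect_equal(canon(g2$edges[g2$edges$retained, ]), canon(kept))
})

test_that("the full graph is the complete |rho| graph over features", {
  d <- tiny_design(8, 10, 12)
  ch <- generate_cohort(
    d, correlations = list(planted_correlation("miR-1", "GENE1", 0.9)),
    seed = 71)
  g <- full_weighted_graph(ch$expression, ch$metadata, group = "sarcoidosis")
  expect_equal(g$n, 22)
  expect_equal(dim(g$weights), c(5, 5))
  expect_equal(g$weights, t(g$weights))
  expect_equal(unname(diag(g$weights)), rep(0, 5))
  ## planted strong pair carries its vertex's maximal weight
  expect_equal(names(which.max(g$weights["miR-1", ])), "GENE1")
  ## constant feature: flagged, weight zero
  expr2 <- ch$expression; expr2[, "GENE2"] <- 1
  g2 <- full_weighted_graph(expr2, ch$metadata, group = "sarcoidosis")
  expect_equal(g2$undefined, "GENE2")
  expect_equal(unname(g2$weights["GENE2", ]), rep(0, 5))
  expect_error(full_weighted_graph(ch$expression[1:2, ]),
               class = "balcornet_too_few_samples")
})

test_that("graph export writes GraphML and degree tables", {
  d <- tiny_design(8, 10, 12)
  ch <- generate_cohort(d, seed = 72)
  g <- prune_nearest_neighbors(full_weighted_graph(ch$expression), 1)
  prefix <- file.path(withr::local_tempdir(), "net")
  write_coexpression_graph(g, prefix)
  ig <- igraph::read_graph(paste0(prefix, ".graphml"), format = "graphml")
  expect_equal(igraph::gorder(ig), 5)
  expect_equal(igraph::gsize(ig), sum(g$edges$retained))
  expect_equal(sort(igraph::V(ig)$size), sort(unname(g$vertex_size)))
  verts <- read.delim(paste0(prefix, "_vertices.tsv"), comment.char = "#")
  expect_equal(verts$vertex_size, unname(g$vertex_size))
})
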