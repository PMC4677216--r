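test_that("chord weights follow w = 1 + 10 (|rho| - t)^2", {
  expect_equal(chord_weight(0.8, 0.3), 3.5)
  for (t in seq(0, 1, by = 0.1)) {
    expect_equal(chord_weight(t, t), 1)
    expect_equal(chord_weight(-0.7, t), chord_weight(0.7, t))
    rhos <- seq(t, 1, length.out = 25)
    w <- chord_weight(rhos, t)
    expect_true(all(w >= 1))
    expect_true(all(diff(w) > 0) || t == 1)   # strictly increasing on [t, 1]
  }
  expect_error(chord_weight(1.2, 0.3), "rho")
  expect_error(chord_weight(0.5, 1.3), "t must be")
})

test_that("correlation results carry the group's n and flag constant features", {
  ch <- generate_cohort(tiny_design(8, 10, 12), seed = 51)
  cr_all <- correlation_result(ch$expression, c("miR-1", "miR-2", "TF1"),
                               c("GENE1", "GENE2"), meta = ch$metadata)
  expect_equal(cr_all$n, 30)
  cr_p <- correlation_result(ch$expression, c("miR-1", "miR-2", "TF1"),
                             c("GENE1", "GENE2"), meta = ch$metadata,
                             group = "progressing")
  expect_equal(cr_p$n, 12)
  expect_equal(dim(cr_p$rho), c(3, 2))
  expect_true(all(abs(cr_p$rho) <= 1))
  expect_true(all(cr_p$p >= 0 & cr_p$p <= 1))
  ## constant feature -> NA + flag, not silent NaN
  expr2 <- ch$expression; expr2[, "GENE2"] <- 4
  cr_c <- correlation_result(expr2, c("miR-1", "TF1"), c("GENE1", "GENE2"),
                             meta = ch$metadata)
  expect_true(all(is.na(cr_c$rho[, "GENE2"])))
  expect_equal(cr_c$undefined, "GENE2")
  expect_error(correlation_result(ch$expression[1:2, ], "miR-1", "GENE1"),
               class = "balcornet_too_few_samples")
})

test_that("metadata covariates can enter as correlation rows", {
  ch <- generate_cohort(tiny_design(8, 10, 12), seed = 52)
  meta <- ch$metadata
  set.seed(1)
  meta$pct_ly <- rank(ch$expression[, "GENE1"]) + rnorm(30, 0, 2)
  cr <- correlation_result(ch$expression, c("miR-1", "miR-2"), c("GENE1"),
                           meta = meta, covariates = "pct_ly")
  expect_true("pct_ly" %in% cr$row_features)
  expect_gt(cr$rho["pct_ly", "GENE1"], 0.5)
})

test_that("chord edges are the significant pairs, planted pairs on top", {
  d <- default_study_design()
  ch <- generate_cohort(
    d, correlations = list(planted_correlation("miR-146a", "CCL19", 0.85)),
    seed = 53)
  cr <- correlation_result(ch$expression, c(d$mirna, d$tf),
                           setdiff(d$mrna, d$tf),
                           meta = ch$metadata, group = "sarcoidosis")
  edges <- chord_edges(cr, alpha = 0.05)
  expect_true(all(edges$p < 0.05))
  expect_true(all(edges$w >= 1))
  top <- edges[which.max(edges$w), ]
  expect_equal(paste(top$source, top$target), "miR-146a CCL19")
  ## monotone in alpha: stricter level keeps a subset of edges
  e01 <- chord_edges(cr, alpha = 0.01)
  key <- function(e) paste(e$source, e$target)
  expect_true(all(key(e01) %in% key(edges)))
  ## threshold equals the critical coefficient for this n
  expect_equal(attr(edges, "t"), critical_rho(cr$n, 0.05))
})

test_that("the Circos tableviewer export is an integer-weight matrix", {
  d <- tiny_design(8, 10, 12)
  ch <- generate_cohort(
    d, correlations = list(planted_correlation("miR-1", "GENE1", 0.9)),
    seed = 54)
  cr <- correlation_result(ch$expression, c("miR-1", "miR-2", "TF1"),
                           c("GENE1", "GENE2"), meta = ch$metadata)
  path <- withr::local_tempfile(fileext = ".tsv")
  write_circos_table(cr, path)
  tab <- read.delim(path, row.names = 1, check.names = FALSE)
  expect_equal(dim(tab), c(3, 2))
  expect_true(all(tab == floor(tab)))            # integer-scaled weights
  edges <- chord_edges(cr)
  expect_equal(tab["miR-1", "GENE1"],
               as.integer(round(100 * edges$w[edges$source == "miR-1" &
                                                edges$target == "GENE1"])))
  expect_equal(sum(tab > 0), nrow(edges))
})

test_that("clustered heatmap ordering groups block-structured features", {
  feats_r <- sprintf("r%02d", 1:6); feats_c <- sprintf("c%02d", 1:4)
  rho <- matrix(0, 6, 4, dimnames = list(feats_r, feats_c))
  rho[1:3, 1:2] <- 0.9; rho[4:6, 3:4] <- 0.9
  rho[1:3, 3:4] <- -0.5; rho[4:6, 1:2] <- -0.5
  rho <- rho + outer(seq(0, 0.01, length.out = 6), seq(0, 0.01, length.out = 4))
  cr <- fake_correlation_result(rho)
  hm <- cluster_heatmap(cr)
  blocks <- ifelse(hm$row_order %in% feats_r[1:3], 1, 2)
  expect_equal(length(rle(blocks)$lengths), 2)   # block members contiguous
  cblocks <- ifelse(hm$col_order %in% feats_c[1:2], 1, 2)
  expect_equal(length(rle(cblocks)$lengths), 2)
  expect_match(hm$row_newick, "^\\(")            # parseable dendrogram
  expect_s3_class(ape::read.tree(text = hm$row_newick), "phylo")
})

test_that("heatmap ordering is invariant to input permutation; 1x1 is identity", {
  ch <- generate_cohort(tiny_design(8, 10, 12), seed = 55)
  cr <- correlation_result(ch$expression, c("miR-1", "miR-2", "TF1"),
                           c("GENE1", "GENE2"), meta = ch$metadata)
  hm1 <- cluster_heatmap(cr)
  perm <- cr
  perm$rho <- cr$rho[c(3, 1, 2), c(2, 1)]
  perm$p <- cr$p[c(3, 1, 2), c(2, 1)]
  perm$row_features <- rownames(perm$rho); perm$col_features <- colnames(perm$rho)
  hm2 <- cluster_heatmap(perm)
  expect_equal(hm1$row_order, hm2$row_order)
  expect_equal(hm1$col_order, hm2$col_order)
  one <- fake_correlation_result(matrix(0.4, 1, 1, dimnames = list("r", "c")))
  hm3 <- cluster_heatmap(one)
  expect_equal(hm3$rho, one$rho)
  cr_na <- fake_correlation_result(matrix(c(0.1, NA), 1, 2,
                                          dimnames = list("r", c("a", "b"))))
  expect_error(cluster_heatmap(cr_na),
               class = "balcornet_undefined_correlation")
})
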