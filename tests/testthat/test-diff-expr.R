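test_that("exact Mann-Whitney matches the labeling-enumeration oracle", {
  expect_equal(mann_whitney(c(1, 2, 3), c(4, 5, 6), "exact")$p_value, 0.1)
  expect_equal(mann_whitney(c(1, 2, 3), c(4, 5, 6), "exact")$statistic, 0)
  set.seed(101)
  for (na in 2:6) for (nb in 2:(12 - na)) {
    a <- rnorm(na); b <- rnorm(nb)
    expect_equal(mann_whitney(a, b, "exact")$p_value, oracle_mw_p(a, b),
                 info = sprintf("na=%d nb=%d", na, nb))
  }
  ## tied data enumerate over midranks
  a <- c(1, 2, 2, 5); b <- c(2, 3, 3)
  expect_equal(mann_whitney(a, b, "exact")$p_value, oracle_mw_p(a, b))
})

test_that("exact Mann-Whitney agrees with the reference distribution", {
  set.seed(5)
  for (i in 1:10) {
    a <- rnorm(6); b <- rnorm(7)
    expect_equal(mann_whitney(a, b, "exact")$p_value,
                 wilcox.test(a, b, exact = TRUE)$p.value)
  }
})

test_that("normal approximation tracks the exact Mann-Whitney P", {
  expect_equal(mann_whitney(c(3, 1, 2), c(2, 1, 3), "exact")$p_value, 1)
  set.seed(7)
  for (i in 1:20) {
    a <- rnorm(8); b <- rnorm(8)
    pe <- mann_whitney(a, b, "exact")$p_value
    pn <- mann_whitney(a, b, "normal")$p_value
    expect_lt(abs(pe - pn), 0.03)
  }
})

test_that("Kruskal-Wallis follows the rank formula and is exchangeable", {
  r <- kruskal_wallis(list(c(1, 2), c(3, 4), c(5, 6)))
  ## hand calculation: H = 12/(N(N+1)) * sum n_i (Rbar_i - Rbar)^2
  expect_equal(r$statistic, 12 / (6 * 7) * 2 * ((1.5 - 3.5)^2 + (5.5 - 3.5)^2))
  expect_equal(r$df, 2)
  same <- kruskal_wallis(list(c(5, 6), c(1, 2), c(3, 4)))
  expect_equal(same$statistic, r$statistic)
  ident <- kruskal_wallis(list(c(2, 2), c(2, 2), c(2, 2)))
  expect_equal(ident$statistic, 0)
  expect_equal(ident$p_value, 1)
  expect_error(kruskal_wallis(list(1:3)), "at least 2 groups")
  expect_error(mann_whitney(1, 1:4), "at least 2 observations")
})

test_that("two-group Kruskal-Wallis ranks datasets like Mann-Whitney", {
  set.seed(9)
  datasets <- replicate(12, list(a = rnorm(6), b = rnorm(6, sample(0:2, 1))),
                        simplify = FALSE)
  p_mw <- sapply(datasets, function(d) mann_whitney(d$a, d$b, "normal")$p_value)
  p_kw <- sapply(datasets, function(d) kruskal_wallis(list(d$a, d$b))$p_value)
  expect_equal(order(p_mw), order(p_kw))
})

test_that("group summaries use the t interval", {
  ## hand-checked case: values 1,2,3 -> 2 +/- 4.303/sqrt(3)
  sub <- cohort_design(3, 2, 2, "miR-1", "GENE1")
  ch2 <- generate_cohort(sub, seed = 1)
  ch2$expression[ch2$metadata$group == "control", "miR-1"] <- c(1, 2, 3)
  s <- summarize_groups(ch2$expression, ch2$metadata)
  row <- s[s$feature == "miR-1" & s$group == "control", ]
  expect_equal(row$mean, 2)
  expect_equal(row$ci_low, 2 - qt(0.975, 2) / sqrt(3), tolerance = 1e-10)
  expect_equal(row$ci_high, 2 + qt(0.975, 2) / sqrt(3), tolerance = 1e-10)
  ## constant feature: zero-width interval
  ch2$expression[ch2$metadata$group == "control", "GENE1"] <- 7
  s2 <- summarize_groups(ch2$expression, ch2$metadata)
  r2 <- s2[s2$feature == "GENE1" & s2$group == "control", ]
  expect_equal(c(r2$mean, r2$ci_low, r2$ci_high), c(7, 7, 7))
  ## ci_level 0 degenerates to the mean
  s0 <- summarize_groups(ch2$expression, ch2$metadata, ci_level = 0)
  expect_equal(s0$ci_low, s0$mean)
  expect_equal(s0$ci_high, s0$mean)
})

test_that("the DE table has one row per feature and coherent flags", {
  d <- cohort_design(5, 6, 7, mirna = "miR-1", mrna = "GENE1")
  ch <- generate_cohort(d, seed = 31)
  de <- de_table(ch$expression, ch$metadata)
  expect_equal(nrow(de), 2)
  expect_equal(de$sig_s_vs_c, de$p_s_vs_c < 0.05)
  expect_equal(de$sig_reg_vs_prog, de$p_reg_vs_prog < 0.05)
  expect_true(all(de$padj_kw >= de$p_kw))
  ## single-feature matrix
  d1 <- cohort_design(5, 6, 7, mirna = "miR-1", mrna = "GENE1")
  ch1 <- generate_cohort(d1, seed = 32)
  de1 <- de_table(ch1$expression[, "miR-1", drop = FALSE], ch1$metadata)
  expect_equal(nrow(de1), 1)
  ## metadata mismatch
  bad_meta <- ch$metadata[-1, ]
  expect_error(de_table(ch$expression, bad_meta),
               class = "balcornet_sample_mismatch")
  ## formatted writer emits the table layout
  path <- withr::local_tempfile(fileext = ".tsv")
  write_de_table(de, path)
  out <- read.delim(path, comment.char = "#", check.names = FALSE)
  expect_true(all(c("feature", "sarcoidosis", "control",
                    "p_kruskal_wallis") %in% names(out)))
  expect_match(out$control[1], "^[0-9.eE+-]+ \\([0-9.eE+-]+-[0-9.eE+-]+\\)$")
})

test_that("a planted shift is detected and null features are calibrated", {
  d <- cohort_design(14, 28, 20, mirna = "m1", mrna = "g1")
  hits_shift <- 0; hits_null <- 0; B <- 60
  for (i in seq_len(B)) {
    ch <- generate_cohort(
      d, effects = list(planted_effect("m1", "progressing", log(2))),
      seed = 4000 + i)
    de <- de_table(ch$expression, ch$metadata)
    hits_shift <- hits_shift + de$sig_reg_vs_prog[de$feature == "m1"]
    hits_null <- hits_null + de$sig_reg_vs_prog[de$feature == "g1"]
  }
  expect_gt(hits_shift / B, 0.5)       # majority of runs detect ln-2 shift
  expect_lt(hits_null / B, 0.2)        # null feature near nominal alpha
})
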