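#' Mann-Whitney U test (two-sided)
#'
#' Rank-sum comparison of two groups with midranks for ties. The exact mode
#' uses the null distribution of U over all `choose(n_a + n_b, n_a)` group
#' labelings: for tie-free data this is the classical Wilcoxon distribution;
#' with ties the labelings are enumerated directly (feasible for small
#' groups). The normal approximation uses the tie-corrected variance and a
#' continuity correction. Mode `"auto"` selects exact for
#' `n_a + n_b <= 20` without ties.
#'
#' @param a,b numeric vectors, each with >= 2 observations.
#' @param mode `"auto"`, `"exact"` or `"normal"`.
#' @return A list with `statistic` (U for group `a`), `p_value`, `method`,
#'   `n_a`, `n_b`.
#' @export
mann_whitney <- function(a, b, mode = c("auto", "exact", "normal")) {
  mode <- match.arg(mode)
  assert_that(length(a) >= 2 && length(b) >= 2,
              "each group needs at least 2 observations")
  assert_that(all(is.finite(a)) && all(is.finite(b)), "inputs must be finite")
  na <- length(a); nb <- length(b); n <- na + nb
  pooled <- c(a, b)
  r <- rank(pooled)
  ties <- anyDuplicated(pooled) > 0
  U <- sum(r[seq_len(na)]) - na * (na + 1) / 2

  if (mode == "auto") mode <- if (n <= 20 && !ties) "exact" else "normal"

  if (mode == "exact") {
    if (!ties) {
      ## Wilcoxon count distribution == enumeration of all labelings.
      lo <- stats::pwilcox(U, na, nb)
      hi <- stats::pwilcox(U - 1, na, nb, lower.tail = FALSE)
      p <- min(1, 2 * min(lo, hi))
    } else {
      nlab <- choose(n, na)
      assert_that(nlab <= 2e6,
                  "exact Mann-Whitney with ties is limited to small samples; use mode = 'normal'")
      idx <- utils::combn(n, na)
      Us <- colSums(matrix(r[idx], nrow = na)) - na * (na + 1) / 2
      p <- min(1, 2 * min(mean(Us <= U), mean(Us >= U)))
    }
    method <- "exact"
  } else {
    mu <- na * nb / 2
    tie_tab <- table(pooled)
    sig2 <- na * nb / 12 * ((n + 1) - sum(tie_tab^3 - tie_tab) / (n * (n - 1)))
    if (sig2 <= 0) {
      p <- 1          # all observations identical
    } else {
      z <- (U - mu - sign(U - mu) * 0.5) / sqrt(sig2)
      p <- min(1, 2 * stats::pnorm(-abs(z)))
    }
    method <- "normal-approx"
  }
  list(statistic = U, p_value = p, method = method, n_a = na, n_b = nb)
}

#' Kruskal-Wallis rank test across groups
#'
#' Tie-corrected H statistic referred to a chi-square null with `k - 1`
#' degrees of freedom (delegates to [stats::kruskal.test()]).
#'
#' @param groups list of >= 2 numeric vectors, each with >= 2 observations.
#' @return A list with `statistic` (H), `df`, `p_value`.
#' @export
kruskal_wallis <- function(groups) {
  assert_that(is.list(groups) && length(groups) >= 2,
              "need at least 2 groups")
  assert_that(all(vapply(groups, length, integer(1)) >= 2),
              "each group needs at least 2 observations")
  if (length(unique(unlist(groups))) == 1L) {
    ## degenerate: every observation identical, no rank separation
    return(list(statistic = 0, df = length(groups) - 1, p_value = 1))
  }
  kt <- stats::kruskal.test(groups)
  list(statistic = unname(kt$statistic), df = unname(kt$parameter),
       p_value = kt$p.value)
}
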