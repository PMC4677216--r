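#' Spearman rank correlation
#'
#' Pearson correlation of midranks; for tie-free data this equals the
#' classical `1 - 6 sum(d^2) / (n (n^2 - 1))`.
#'
#' @param x,y numeric vectors of equal length >= 3.
#' @return The Spearman correlation coefficient.
#' @export
spearman_rho <- function(x, y) {
  assert_that(length(x) == length(y), "x and y must have equal length")
  assert_that(length(x) >= 3, "need at least 3 observations")
  assert_that(all(is.finite(x)) && all(is.finite(y)), "inputs must be finite")
  if (stats::sd(x) == 0 || stats::sd(y) == 0) {
    stop_balcornet("Spearman correlation undefined for constant input",
                   class = "balcornet_undefined_correlation")
  }
  stats::cor(rank(x), rank(y))
}

## ---- exact permutation null -------------------------------------------------
## The exact null distribution of the Spearman coefficient for tie-free data
## of size n: all n! permutations of the ranks, enumerated once per n and
## cached. Feasible for the n <= 9 regime the exact mode targets.

.spearman_cache <- new.env(parent = emptyenv())

## All permutations of 1..n, built by inserting n into every position of the
## permutations of 1..(n-1); returns an (n! x n) matrix.
enumerate_permutations <- function(n) {
  P <- matrix(1L, 1L, 1L)
  if (n == 1L) return(P)
  for (k in 2L:n) {
    m <- nrow(P)
    out <- matrix(0L, m * k, k)
    for (pos in seq_len(k)) {
      rows <- (pos - 1L) * m + seq_len(m)
      if (pos > 1L) out[rows, seq_len(pos - 1L)] <- P[, seq_len(pos - 1L), drop = FALSE]
      out[rows, pos] <- k
      if (pos < k) out[rows, pos + seq_len(k - pos)] <-
          P[, (pos - 1L) + seq_len(k - pos), drop = FALSE]
    }
    P <- out
  }
  P
}

## Sorted attainable rho values and their null probabilities for sample size n.
spearman_exact_null <- function(n) {
  key <- as.character(n)
  if (!is.null(.spearman_cache[[key]])) return(.spearman_cache[[key]])
  assert_that(n >= 3 && n <= 9, "exact Spearman null supported for 3 <= n <= 9")
  P <- enumerate_permutations(n)
  r <- seq_len(n)
  S <- colSums((t(P) - r)^2)               # sum of squared rank differences
  rho <- 1 - 6 * S / (n * (n^2 - 1))
  tab <- table(rho)
  null <- list(rho = as.numeric(names(tab)),
               prob = as.vector(tab) / nrow(P))
  .spearman_cache[[key]] <- null
  null
}

#' Two-sided P value for a Spearman correlation
#'
#' Exact mode enumerates the full rank-permutation null (tie-free ranks) and
#' reports `P(|R| >= |rho|)`; the t approximation uses
#' `t = rho sqrt((n - 2) / (1 - rho^2))` on `n - 2` degrees of freedom. Mode
#' `"auto"` selects exact for `n <= 9`.
#'
#' @param rho observed Spearman coefficient, in \[-1, 1\].
#' @param n sample size (>= 3).
#' @param mode `"auto"`, `"exact"` or `"t"`.
#' @return Two-sided P value.
#' @export
spearman_p <- function(rho, n, mode = c("auto", "exact", "t")) {
  mode <- match.arg(mode)
  assert_that(all(abs(rho) <= 1 + 1e-12), "|rho| must be <= 1")
  assert_that(n >= 3, "need n >= 3")
  rho <- pmin(1, pmax(-1, rho))
  if (mode == "auto") mode <- if (n <= 9) "exact" else "t"
  if (mode == "exact") {
    null <- spearman_exact_null(n)
    vapply(rho, function(r) {
      sum(null$prob[abs(null$rho) >= abs(r) - 1e-12])
    }, numeric(1))
  } else {
    tstat <- abs(rho) * sqrt((n - 2) / pmax(1 - rho^2, .Machine$double.eps))
    tstat[abs(rho) >= 1] <- Inf
    pmin(1, 2 * stats::pt(tstat, df = n - 2, lower.tail = FALSE))
  }
}

#' Critical Spearman coefficient at a significance level
#'
#' The smallest attainable `|rho|` whose two-sided P value is below `alpha`
#' at sample size `n`. This is the threshold `t` entering the chord-diagram
#' weight transform [chord_weight()]: every significant pair satisfies
#' `|rho| >= t`. In exact mode the attainable values come from the
#' permutation null; in t mode the closed-form inversion
#' `rho = q / sqrt(n - 2 + q^2)` with `q = qt(1 - alpha/2, n - 2)` is used.
#'
#' @param n sample size (>= 4).
#' @param alpha two-sided significance level in (0, 1).
#' @param mode `"auto"`, `"exact"` or `"t"`.
#' @return The critical `|rho|`, or `NA` with a warning when no attainable
#'   coefficient reaches significance at this `n`.
#' @export
critical_rho <- function(n, alpha = 0.05, mode = c("auto", "exact", "t")) {
  mode <- match.arg(mode)
  assert_that(n >= 4, "need n >= 4")
  assert_that(alpha > 0 && alpha < 1, "alpha must be in (0, 1)")
  if (mode == "auto") mode <- if (n <= 9) "exact" else "t"
  if (mode == "exact") {
    null <- spearman_exact_null(n)
    vals <- sort(unique(abs(null$rho)))
    sf <- vapply(vals, function(r) sum(null$prob[abs(null$rho) >= r - 1e-12]),
                 numeric(1))
    ok <- which(sf < alpha)
    if (!length(ok)) {
      warning(sprintf("no attainable |rho| reaches two-sided P < %g at n = %d",
                      alpha, n))
      return(NA_real_)
    }
    vals[min(ok)]
  } else {
    q <- stats::qt(1 - alpha / 2, df = n - 2)
    q / sqrt(n - 2 + q^2)
  }
}
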