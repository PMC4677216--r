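# Independent brute-force oracles used across the suite. These deliberately
# share no code with the package implementation.

## All permutations of 1..n by straightforward recursion.
oracle_perms <- function(n) {
  if (n == 1) return(matrix(1L, 1, 1))
  sub <- oracle_perms(n - 1)
  do.call(rbind, lapply(seq_len(n), function(first) {
    rest <- sub
    rest[rest >= first] <- rest[rest >= first] + 1L
    cbind(first, rest, deparse.level = 0)
  }))
}

## Exact two-sided Spearman P by full enumeration of rank permutations.
oracle_spearman_p <- function(rho_obs, n) {
  P <- oracle_perms(n)
  S <- apply(P, 1, function(p) sum((p - seq_len(n))^2))
  rho_all <- 1 - 6 * S / (n * (n^2 - 1))
  mean(abs(rho_all) >= abs(rho_obs) - 1e-12)
}

## Exact two-sided Mann-Whitney P by full enumeration of group labelings.
oracle_mw_p <- function(a, b) {
  na <- length(a); n <- na + length(b)
  r <- rank(c(a, b))
  U_obs <- sum(r[seq_len(na)]) - na * (na + 1) / 2
  labelings <- combn(n, na)
  Us <- apply(labelings, 2, function(idx) sum(r[idx]) - na * (na + 1) / 2)
  min(1, 2 * min(mean(Us <= U_obs), mean(Us >= U_obs)))
}

## Brute-force nearest-neighbour pruning: keep (i, j) iff j is in i's top-k
## by weight (ties by name) or vice versa.
oracle_prune <- function(W, k) {
  nv <- nrow(W); feats <- rownames(W)
  topk <- function(i) {
    others <- setdiff(seq_len(nv), i)
    df <- data.frame(j = others, w = W[i, others], nm = feats[others])
    df <- df[order(-df$w, df$nm), ]
    df$j[seq_len(min(k, nrow(df)))]
  }
  keep <- matrix(FALSE, nv, nv)
  for (i in seq_len(nv)) keep[i, topk(i)] <- TRUE
  ret <- keep | t(keep)
  dimnames(ret) <- dimnames(W)
  ret
}

## Noiseless logistic amplification curve.
logistic_curve <- function(c0 = 25, k = 1, cycles = 1:40, id = "lc") {
  amplification_curve(cycles, 1 / (1 + exp(-k * (cycles - c0))), id = id)
}

## Small synthetic design used by many tests.
tiny_design <- function(n_c = 6, n_r = 6, n_p = 6) {
  cohort_design(n_c, n_r, n_p,
                mirna = c("miR-1", "miR-2"),
                mrna = c("GENE1", "GENE2", "TF1"), tf = "TF1")
}

## Build a correlation_result object directly (for ordering/weight units).
fake_correlation_result <- function(rho, n = 20, p = NULL) {
  structure(list(rho = rho,
                 p = p %||% matrix(0, nrow(rho), ncol(rho),
                                   dimnames = dimnames(rho)),
                 n = n,
                 row_features = rownames(rho), col_features = colnames(rho),
                 group = "all", undefined = character()),
            class = "correlation_result")
}

`%||%` <- function(x, y) if (is.null(x)) y else x
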