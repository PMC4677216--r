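#' Train a Kohonen self-organizing map on sample expression profiles
#'
#' Classic online SOM on a rectangular 2-D grid: each presented sample pulls
#' its best-matching unit (BMU, Euclidean distance) and the BMU's grid
#' neighbours toward itself, with a Gaussian neighbourhood
#' `h = exp(-d_grid^2 / (2 sigma(t)^2))` and linearly decaying learning rate
#' and radius. Features are z-scored before training so miRNA and mRNA
#' panels with very different magnitudes contribute comparably to the
#' distance; the scaling is stored in the model and reapplied on assignment.
#'
#' @param expr samples x features matrix (>= 1 sample).
#' @param grid `c(rows, cols)` of the neuron grid (default 4 x 3).
#' @param epochs passes over the data (samples shuffled each epoch).
#' @param eta `c(initial, final)` learning rate, decayed linearly.
#' @param radius `c(initial, final)` neighbourhood radius in grid units;
#'   radius 0 updates the BMU only. Default starts at half the larger grid
#'   dimension.
#' @param seed seed for codebook initialisation (random data rows) and
#'   presentation order; training is deterministic given the seed.
#' @param scale z-score features before training.
#' @return An object of class `som_model`: `codebook` (neurons x features),
#'   `grid_coords`, `grid`, `center`, `scale`, `qe` (mean quantization error
#'   per epoch), `params`.
#' @export
train_som <- function(expr, grid = c(4, 3), epochs = 100,
                      eta = c(0.5, 0.02), radius = c(max(grid) / 2, 0.5),
                      seed = 1L, scale = TRUE) {
  assert_that(is.matrix(expr) && nrow(expr) >= 1, "need a non-empty matrix")
  assert_that(length(grid) == 2 && all(grid >= 1), "grid must be c(rows, cols)")
  n <- nrow(expr); p <- ncol(expr)
  if (scale) {
    ctr <- colMeans(expr)
    scl <- apply(expr, 2L, stats::sd)
    scl[scl == 0] <- 1                    # constant features carry no signal
  } else {
    ctr <- rep(0, p); scl <- rep(1, p)
  }
  X <- sweep(sweep(expr, 2L, ctr), 2L, scl, "/")

  nr <- grid[1]; nc <- grid[2]; k <- nr * nc
  coords <- cbind(row = rep(seq_len(nr), times = nc),
                  col = rep(seq_len(nc), each = nr))
  gd2 <- as.matrix(stats::dist(coords))^2   # squared grid distances

  set.seed(as.integer(seed))
  codebook <- X[sample.int(n, k, replace = n < k), , drop = FALSE]
  rownames(codebook) <- NULL

  total <- epochs * n
  step <- 0L
  qe <- numeric(epochs)
  for (ep in seq_len(epochs)) {
    ord <- sample.int(n)
    err <- 0
    for (i in ord) {
      frac <- step / max(total - 1, 1)
      eta_t <- eta[1] + (eta[2] - eta[1]) * frac
      sig_t <- radius[1] + (radius[2] - radius[1]) * frac
      x <- X[i, ]
      d2 <- rowSums(sweep(codebook, 2L, x)^2)
      bmu <- which.min(d2)
      err <- err + sqrt(d2[bmu])
      if (sig_t <= 0) {
        codebook[bmu, ] <- codebook[bmu, ] + eta_t * (x - codebook[bmu, ])
      } else {
        h <- exp(-gd2[bmu, ] / (2 * sig_t^2))
        codebook <- codebook + (eta_t * h) * sweep(-codebook, 2L, x, "+")
      }
      step <- step + 1L
    }
    qe[ep] <- err / n
  }
  structure(
    list(codebook = codebook, grid_coords = coords, grid = grid,
         center = ctr, scale = scl, qe = qe,
         params = list(epochs = epochs, eta = eta, radius = radius,
                       seed = seed, scaled = scale)),
    class = "som_model")
}

#' Assign samples to their best-matching neurons
#'
#' @param model a trained [train_som()] model.
#' @param expr samples x features matrix on the model's feature set.
#' @return Integer vector of neuron indices (row-major into the grid).
#' @export
som_assign <- function(model, expr) {
  assert_that(inherits(model, "som_model"), "model must be a som_model")
  assert_that(ncol(expr) == ncol(model$codebook),
              "feature set does not match the trained model",
              class = "balcornet_feature_mismatch")
  X <- sweep(sweep(expr, 2L, model$center), 2L, model$scale, "/")
  apply(X, 1L, function(x) {
    which.min(colSums((t(model$codebook) - x)^2))
  })
}

#' Per-neuron class composition report
#'
#' Nearest-codebook assignment of every sample, then per occupied neuron the
#' class fractions, the share of the cohort it captures, and a purity
#' summary (pure / majority / mixed neuron counts).
#'
#' @param model a [train_som()] model.
#' @param expr samples x features matrix.
#' @param meta metadata with `sample_id` and `group`.
#' @return data.frame with one row per occupied neuron: `neuron`, `row`,
#'   `col`, `n_samples`, `percent_of_cohort`, one `frac_<group>` column per
#'   group present, `top_class`, `purity`. The attribute `summary` holds
#'   counts of pure (purity = 1), majority (0.5 < purity < 1) and mixed
#'   neurons.
#' @export
assign_and_report <- function(model, expr, meta) {
  check_expr_meta(expr, meta)
  bmu <- som_assign(model, expr[meta$sample_id, , drop = FALSE])
  groups <- sort(unique(meta$group), method = "radix")
  occupied <- sort(unique(bmu))
  n_total <- length(bmu)
  rows <- lapply(occupied, function(nu) {
    in_nu <- bmu == nu
    cnt <- vapply(groups, function(g) sum(meta$group[in_nu] == g), numeric(1))
    fr <- cnt / sum(cnt)
    df <- data.frame(neuron = nu,
                     row = model$grid_coords[nu, "row"],
                     col = model$grid_coords[nu, "col"],
                     n_samples = sum(in_nu),
                     percent_of_cohort = 100 * sum(in_nu) / n_total)
    for (g in groups) df[[paste0("frac_", g)]] <- unname(fr[g])
    df$top_class <- groups[which.max(fr)]
    df$purity <- max(fr)
    df
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  attr(out, "summary") <- c(
    pure = sum(out$purity == 1),
    majority = sum(out$purity > 0.5 & out$purity < 1),
    mixed = sum(out$purity <= 0.5))
  out
}
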