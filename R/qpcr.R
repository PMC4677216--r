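#' Amplification curve container
#'
#' @param cycles strictly increasing integer cycle index (>= 10 cycles).
#' @param fluorescence finite fluorescence readings, one per cycle.
#' @param id optional curve identifier.
#' @return An object of class `amplification_curve`.
#' @export
amplification_curve <- function(cycles, fluorescence, id = NA_character_) {
  assert_that(length(cycles) == length(fluorescence),
              "cycles and fluorescence must have equal length")
  assert_that(length(cycles) >= 10, "need at least 10 cycles")
  assert_that(all(diff(cycles) > 0),
              "cycle index must be strictly increasing",
              class = "balcornet_bad_cycles")
  assert_that(all(is.finite(fluorescence)), "fluorescence must be finite")
  structure(list(cycles = as.numeric(cycles),
                 fluorescence = as.numeric(fluorescence),
                 id = id),
            class = "amplification_curve")
}

## Band-limited (spectral) reconstruction of the curve's first and second
## derivatives from the first-difference sequence. The first differences of a
## complete amplification curve decay to ~0 at both ends (flat baseline and
## plateau), so the sequence can be treated as one period of a band-limited
## signal; the difference operator is deconvolved exactly in the frequency
## domain and a raised-cosine taper above `cutoff` suppresses out-of-band
## noise. Returns the dense grid and both derivative estimates.
spectral_derivatives <- function(fl, cyc, upsample = 32, cutoff = 0.75 * pi) {
  N <- length(fl) - 1L
  d1 <- diff(fl)
  Y <- stats::fft(d1)
  w <- 2 * pi * (0:(N - 1)) / N
  w[w > pi] <- w[w > pi] - 2 * pi
  shift <- exp(1i * w)                     # symbol of f(c + 1) - f(c)
  H2 <- ifelse(abs(w) < 1e-12, 0, -w^2 / (shift - 1))
  H1 <- ifelse(abs(w) < 1e-12, 0, (1i * w) / (shift - 1))
  taper <- ifelse(abs(w) <= cutoff, 1,
                  0.5 * (1 + cos(pi * (abs(w) - cutoff) / (pi - cutoff))))
  M <- N * upsample
  pad <- function(Z) {
    Zp <- complex(M)
    pos <- which(w >= 0); neg <- which(w < 0)
    Zp[pos] <- Z[pos]
    Zp[M - (N - neg)] <- Z[neg]
    Re(stats::fft(Zp, inverse = TRUE)) / N
  }
  list(grid = cyc[1] + (0:(M - 1)) / upsample,
       d1 = pad(Y * H1 * taper),
       d2 = pad(Y * H2 * taper),
       upsample = upsample)
}

#' Call the quantification cycle by the second-derivative-maximum method
#'
#' The Cq is the fractional cycle at which the second derivative of the
#' amplification curve attains its maximum on the rising phase. The curve is
#' optionally smoothed with a Savitzky-Golay filter (`smoothing_window`),
#' its second derivative is reconstructed by band-limited spectral
#' differentiation of the cycle-to-cycle differences, and the peak is located
#' on an upsampled grid with a final quadratic refinement. The search is
#' restricted to the growth phase (at most a few cycles before the maximum
#' slope), which keeps baseline noise from being picked as a peak.
#'
#' A curve is reported as no-amplification when it never rises, or when its
#' total rise is below `min_rise_frac` of `reference_rise` (typically the
#' largest rise observed across a run; see [call_cq_run()]).
#'
#' @param curve an [amplification_curve()].
#' @param smoothing_window odd Savitzky-Golay window length in cycles; 1
#'   disables smoothing (the default: symmetric smoothing shifts the skewed
#'   second-derivative peak and trades bias for variance).
#' @param min_rise_frac no-amplification threshold as a fraction of
#'   `reference_rise`.
#' @param reference_rise dynamic range of the run; `NULL` disables the
#'   relative-rise check (flat curves are still flagged).
#' @param upsample grid refinement factor for peak localisation.
#' @return A list with `cq` (fractional cycle, `NA` for no-amplification),
#'   `status` (`"ok"` or `"no_amplification"`), `rise`, `curve_id`.
#' @export
call_cq <- function(curve, smoothing_window = 1, min_rise_frac = 0.1,
                    reference_rise = NULL, upsample = 32) {
  assert_that(inherits(curve, "amplification_curve"),
              "curve must be an amplification_curve")
  cyc <- curve$cycles; fl <- curve$fluorescence
  assert_that(smoothing_window %% 2 == 1, "smoothing_window must be odd")
  assert_that(smoothing_window < length(cyc),
              "smoothing_window must be smaller than the number of cycles")
  assert_that(all(abs(diff(cyc) - 1) < 1e-8),
              "cycles must be consecutive (unit spacing)")
  if (smoothing_window > 1) {
    fl <- signal::sgolayfilt(fl, p = 2, n = smoothing_window)
  }
  no_amp <- function() list(cq = NA_real_, status = "no_amplification",
                            rise = max(fl) - min(fl), curve_id = curve$id)

  rise <- max(fl) - min(fl)
  scale0 <- max(abs(fl), 1e-300)
  if (rise <= 1e-10 * scale0) return(no_amp())          # flat curve
  d1 <- diff(fl)
  if (max(d1) <= 0) return(no_amp())                    # never rises
  if (!is.null(reference_rise) && rise < min_rise_frac * reference_rise) {
    return(no_amp())
  }

  sp <- spectral_derivatives(fl, cyc, upsample = upsample)
  ## growth phase: second-derivative maximum precedes the slope maximum
  cg <- cyc[which.max(d1)] + 0.5
  win <- which(sp$grid >= cg - 4 & sp$grid <= cg + 0.5)
  j <- win[which.max(sp$d2[win])]
  cq <- sp$grid[j]
  if (j > 1 && j < length(sp$grid)) {
    num <- sp$d2[j - 1] - sp$d2[j + 1]
    den <- sp$d2[j - 1] - 2 * sp$d2[j] + sp$d2[j + 1]
    if (is.finite(num / den)) cq <- cq + 0.5 * num / den / sp$upsample
  }
  cq <- min(max(cq, min(cyc)), max(cyc))
  list(cq = cq, status = "ok", rise = rise, curve_id = curve$id)
}

#' Call Cq for a run of amplification curves
#'
#' The run's dynamic range (largest rise across all curves) sets the
#' no-amplification threshold for each curve.
#'
#' @param curves list of [amplification_curve()] objects.
#' @param ... passed to [call_cq()].
#' @return data.frame: `curve_id`, `cq`, `status`, `rise`.
#' @export
call_cq_run <- function(curves, ...) {
  rises <- vapply(curves, function(cv) {
    max(cv$fluorescence) - min(cv$fluorescence)
  }, numeric(1))
  ref <- max(rises)
  res <- lapply(curves, call_cq, reference_rise = ref, ...)
  data.frame(curve_id = vapply(res, `[[`, character(1), "curve_id"),
             cq = vapply(res, `[[`, numeric(1), "cq"),
             status = vapply(res, `[[`, character(1), "status"),
             rise = vapply(res, `[[`, numeric(1), "rise"),
             stringsAsFactors = FALSE)
}

#' Calibrator-relative, reference-normalised expression
#'
#' Relative expression of a target in a sample, normalised to a reference
#' assay and expressed relative to a common calibrator sample:
#' `E_t^(Cq_t,cal - Cq_t,sample) / E_r^(Cq_r,cal - Cq_r,sample)`,
#' with amplification efficiencies `E` in (1, 2\] (2 = perfect doubling).
#'
#' @param cq_target_sample,cq_target_cal Cq of the target assay in the sample
#'   and in the calibrator.
#' @param cq_ref_sample,cq_ref_cal Cq of the reference assay.
#' @param eff_target,eff_ref amplification efficiencies in (1, 2\].
#' @return Relative expression value (> 0).
#' @export
relative_expression <- function(cq_target_sample, cq_target_cal,
                                cq_ref_sample, cq_ref_cal,
                                eff_target = 2, eff_ref = 2) {
  cqs <- c(cq_target_sample, cq_target_cal, cq_ref_sample, cq_ref_cal)
  assert_that(all(is.finite(cqs)), "all Cq values must be finite",
              class = "balcornet_bad_cq")
  assert_that(eff_target > 1 && eff_target <= 2 && eff_ref > 1 && eff_ref <= 2,
              "efficiencies must be in (1, 2]")
  eff_target^(cq_target_cal - cq_target_sample) /
    eff_ref^(cq_ref_cal - cq_ref_sample)
}

#' Read amplification curves from long-format CSV
#'
#' Expected columns: `curve_id`, `cycle`, `fluorescence`.
#'
#' @param path CSV path.
#' @return Named list of [amplification_curve()] objects.
#' @examples
#' run <- read_amplification_curves(
#'   system.file("extdata", "synthetic_amplification_curves.csv",
#'               package = "balcornet"))
#' call_cq_run(run)
#' @export
read_amplification_curves <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  assert_that(all(c("curve_id", "cycle", "fluorescence") %in% names(df)),
              "expected columns curve_id, cycle, fluorescence")
  out <- lapply(split(df, df$curve_id), function(d) {
    d <- d[order(d$cycle), ]
    amplification_curve(d$cycle, d$fluorescence, id = d$curve_id[1])
  })
  out[order(names(out), method = "radix")]
}
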