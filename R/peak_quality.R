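# Peak-level quality metrics for detected chromatographic peaks.
#
# All metrics operate on the intensity slice I_1..I_N between a peak's
# left and right boundaries, with p the apex index inside the slice.
# Good peaks have high sharpness, Gaussian similarity, SNR and peak
# significance, and low TPASR and local zigzag index.

#' Sharpness of a peak slice
#'
#' Sum of relative point-to-point rises from the left boundary to the
#' apex plus relative falls from the apex to the right boundary:
#' \deqn{\sum_{i=2}^{p} (I_i - I_{i-1})/I_{i-1} +
#'       \sum_{i=p}^{N-1} (I_i - I_{i+1})/I_{i+1}}
#' When any denominator point is zero (common after local-minimum
#' boundary placement) the whole slice is offset by `eps` first.
#'
#' @param I Intensity slice between the peak boundaries.
#' @param p Apex index within the slice.
#' @param eps Offset applied when a zero denominator would occur
#'   (intensity units).
#' @return Sharpness (unitless); 0 for a flat slice.
#' @export
#' @examples
#' sharpness(c(1, 2, 4, 2, 1), p = 3)  # 4
sharpness <- function(I, p, eps = 1) {
  n <- length(I)
  if (n < 3L) stop("sharpness requires at least 3 points")
  stopifnot(p >= 1L, p <= n)
  denominators <- I[setdiff(seq_len(n), p)]
  if (any(denominators == 0)) I <- I + eps
  up <- if (p >= 2L) sum((I[2:p] - I[1:(p - 1L)]) / I[1:(p - 1L)]) else 0
  down <- if (p <= n - 1L) {
    sum((I[p:(n - 1L)] - I[(p + 1L):n]) / I[(p + 1L):n])
  } else 0
  up + down
}

#' Gaussian similarity of a peak slice
#'
#' Fits a Gaussian (height, center, sigma) to the baseline-subtracted
#' slice by nonlinear least squares (baseline fixed at the slice minimum;
#' start values from the apex and the full width at half maximum) and
#' returns the cosine between the baseline-subtracted slice and the
#' fitted curve, clamped to \[0, 1\]. Symmetric peaks score near 1;
#' tailing lowers the score.
#'
#' @inheritParams sharpness
#' @return Similarity in \[0, 1\].
#' @export
gaussian_similarity <- function(I, p) {
  n <- length(I)
  if (n < 4L) stop("Gaussian similarity requires at least 4 points")
  stopifnot(p >= 1L, p <= n)
  y <- I - min(I)
  if (all(y == 0)) {
    stop2("chromqc_fit_failure", "flat slice: Gaussian fit undefined")
  }
  x <- seq_len(n)
  h0 <- y[p]
  if (h0 <= 0) h0 <- max(y)
  above <- which(y >= h0 / 2)
  fwhm <- max(diff(range(above)) + 1, 2)
  s0 <- fwhm / 2.355
  fit <- tryCatch(
    minpack.lm::nlsLM(
      y ~ h * exp(-(x - c)^2 / (2 * s^2)),
      start = list(h = h0, c = p, s = s0),
      lower = c(h = 0, c = 1, s = 0.3),
      upper = c(h = Inf, c = n, s = 5 * n),
      control = minpack.lm::nls.lm.control(maxiter = 100)),
    error = function(e) NULL)
  if (is.null(fit)) {
    stop2("chromqc_fit_failure", "Gaussian fit did not converge")
  }
  g <- stats::fitted(fit)
  if (!all(is.finite(g)) || all(g == 0)) {
    stop2("chromqc_fit_failure", "degenerate Gaussian fit")
  }
  min(max(cosine_similarity(y, g), 0), 1)
}

#' CWT signal-to-noise ratio of a detected peak
#'
#' Ratio of the absolute CWT coefficient at the apex at the ridge's best
#' scale to the 95% quantile of absolute scale-1 coefficients within a
#' local window around the apex.
#'
#' @param eic The `EIC` the peak was detected in.
#' @param peak One-row peak data frame from [detect_peaks()] (fields `p`
#'   and, if available, `ridge_scale`; otherwise the best scale is taken
#'   as the per-scale coefficient argmax at the apex).
#' @param scales CWT scale grid.
#' @param window Half-width (scans) of the scale-1 noise window.
#' @return SNR (unitless, >= 0).
#' @export
peak_snr <- function(eic, peak, scales = 1:16, window = 50L) {
  stopifnot(inherits(eic, "EIC"))
  coeffs <- cwt_transform(eic$intensities, scales)
  apex <- peak$p
  sc <- peak$ridge_scale
  if (is.null(sc) || is.na(sc)) {
    sc <- scales[which.max(abs(coeffs[, apex]))]
  }
  cwt_snr(coeffs, apex, sc, window = window)
}

#' Peak significance level
#'
#' Ratio between the mean intensity of points near the apex
#' (`apex_halfwin` on each side) and the mean intensity of points near
#' the two boundaries (`edge_count` from each end of the slice).
#'
#' @inheritParams sharpness
#' @param apex_halfwin Points on each side of the apex in the numerator.
#' @param edge_count Points taken from each boundary in the denominator.
#' @return Significance ratio (> 0); `Inf` when the boundary mean is 0
#'   (treated as a pass by [filter_peaks()]).
#' @export
#' @examples
#' peak_significance(c(1, 1, 5, 1, 1), p = 3, apex_halfwin = 1, edge_count = 1)
peak_significance <- function(I, p, apex_halfwin = 1L, edge_count = 2L) {
  n <- length(I)
  stopifnot(p >= 1L, p <= n)
  if (n < 2L * edge_count + 1L) {
    stop("slice too short for the requested edge windows")
  }
  apex_idx <- max(1L, p - apex_halfwin):min(n, p + apex_halfwin)
  edge_idx <- c(seq_len(edge_count), n - edge_count + seq_len(edge_count))
  apex_mean <- mean(I[apex_idx])
  edge_mean <- mean(I[edge_idx])
  if (edge_mean == 0) return(Inf)
  apex_mean / edge_mean
}

#' Triangle peak area similarity ratio (TPASR)
#'
#' Relative discrepancy between the triangle area spanned by the apex and
#' the two boundaries, `TPA = 0.5 * (N - 1) * I[apex]`, and the raw peak
#' area `RPA = sum(I)`: `TPASR = |TPA - RPA| / TPA`. Values near 0
#' indicate a well-formed peak.
#'
#' @inheritParams sharpness
#' @param p Apex index within the slice (defaults to the maximum).
#' @return TPASR (unitless, >= 0).
#' @export
#' @examples
#' tpasr(c(0, 2, 4, 2, 0))  # 0
#' tpasr(c(0, 0, 4, 0, 0))  # 0.5
tpasr <- function(I, p = which.max(I)) {
  n <- length(I)
  if (n < 2L) stop("TPASR requires at least 2 points")
  apex <- I[p]
  if (apex <= 0) stop("TPASR undefined for a zero apex")
  tpa <- 0.5 * (n - 1L) * apex
  rpa <- sum(I)
  abs(tpa - rpa) / tpa
}

#' Local zigzag index of a peak slice
#'
#' Identical computation to the EIC-level [global_zigzag_index()],
#' applied to the slice between the peak boundaries (EPI taken from the
#' slice itself).
#'
#' @inheritParams sharpness
#' @return Zigzag index in \[0, 4).
#' @export
local_zigzag_index <- function(I) global_zigzag_index(I)

#' Score one detected peak with all six quality metrics
#'
#' Metrics that fail on a degenerate slice (flat, failed Gaussian fit)
#' are recorded as `NA` and fail their clause in [filter_peaks()].
#'
#' @param eic The `EIC` the peak belongs to.
#' @param peak One-row peak data frame from [detect_peaks()].
#' @param config A [pipeline_config()] (scales, SNR window defaults).
#' @return One-row data frame: `eic_id`, `scan_apex`, `sharpness`,
#'   `gaussian_similarity`, `snr`, `peak_significance`, `tpasr`,
#'   `local_zigzag`.
#' @export
score_peak <- function(eic, peak, config = pipeline_config()) {
  sl <- peak_slice(eic, peak)
  I <- sl$I; p <- sl$p
  safe <- function(expr) {
    tryCatch(expr,
             chromqc_degenerate_series = function(c) NA_real_,
             chromqc_fit_failure = function(c) NA_real_,
             error = function(c) NA_real_)
  }
  snr_val <- if (!is.null(peak$snr) && !is.na(peak$snr)) {
    peak$snr
  } else {
    safe(peak_snr(eic, peak, scales = config$scales))
  }
  data.frame(
    eic_id = peak$eic_id,
    scan_apex = peak$scan_apex,
    sharpness = safe(sharpness(I, p)),
    gaussian_similarity = safe(gaussian_similarity(I, p)),
    snr = snr_val,
    peak_significance = safe(peak_significance(I, p)),
    tpasr = safe(tpasr(I, p)),
    local_zigzag = safe(local_zigzag_index(I))
  )
}

#' Score every peak of a detected peak table
#'
#' @param eics List of `EIC` objects (must contain every `eic_id`
#'   referenced by `peaks`).
#' @param peaks Peak data frame from [detect_peaks()] (rows over any
#'   number of EICs).
#' @inheritParams score_peak
#' @return Data frame with one row per peak (see [score_peak()]).
#' @export
score_peaks <- function(eics, peaks, config = pipeline_config()) {
  ids <- vapply(eics, function(e) e$eic_id, numeric(1))
  rows <- lapply(seq_len(nrow(peaks)), function(i) {
    pk <- peaks[i, , drop = FALSE]
    e <- eics[[match(pk$eic_id, ids)]]
    score_peak(e, pk, config)
  })
  if (!length(rows)) {
    return(data.frame(eic_id = integer(0), scan_apex = integer(0),
                      sharpness = numeric(0), gaussian_similarity = numeric(0),
                      snr = numeric(0), peak_significance = numeric(0),
                      tpasr = numeric(0), local_zigzag = numeric(0)))
  }
  do.call(rbind, c(rows, list(make.row.names = FALSE)))
}

#' Combined threshold filter over the six peak quality metrics
#'
#' A peak is kept iff sharpness >= `sharpness_min`, Gaussian similarity
#' >= `gauss_min`, SNR >= `snr_min`, peak significance >= `signif_min`,
#' TPASR <= `tpasr_max` and local zigzag <= `zigzag_max`. Any threshold
#' set to `NA` disables its clause (single-metric mode for sweeps). A
#' missing (`NA`) metric value fails its clause, except `Inf` peak
#' significance which passes.
#'
#' @param reports Data frame from [score_peaks()].
#' @param sharpness_min,gauss_min,snr_min,signif_min,tpasr_max,zigzag_max
#'   Thresholds (`NA` = disabled).
#' @return Logical keep vector, one element per report row.
#' @export
filter_peaks <- function(reports, sharpness_min = 2.0, gauss_min = 0.6,
                         snr_min = 1.3, signif_min = 1.2, tpasr_max = 0.8,
                         zigzag_max = 0.9) {
  ge <- function(x, th) {
    if (is.na(th)) rep(TRUE, length(x)) else (!is.na(x) & x >= th)
  }
  le <- function(x, th) {
    if (is.na(th)) rep(TRUE, length(x)) else (!is.na(x) & x <= th)
  }
  ge(reports$sharpness, sharpness_min) &
    ge(reports$gaussian_similarity, gauss_min) &
    ge(reports$snr, snr_min) &
    ge(reports$peak_significance, signif_min) &
    le(reports$tpasr, tpasr_max) &
    le(reports$local_zigzag, zigzag_max)
}

#' Normalize metric vectors for clustering
#'
#' Each metric column is mean-subtracted and divided by its maximum
#' absolute deviation, mapping it into \[-1, 1\]. Infinite values are
#' replaced by the column's finite maximum first.
#'
#' @param reports Data frame from [score_peaks()].
#' @return Numeric matrix (rows = peaks, columns = the six metrics).
#' @export
normalize_metrics <- function(reports) {
  cols <- c("sharpness", "gaussian_similarity", "snr",
            "peak_significance", "tpasr", "local_zigzag")
  m <- as.matrix(reports[cols])
  for (j in seq_len(ncol(m))) {
    v <- m[, j]
    fin <- v[is.finite(v)]
    v[is.infinite(v)] <- max(fin)
    v <- v - mean(v, na.rm = TRUE)
    mx <- max(abs(v), na.rm = TRUE)
    if (mx > 0) v <- v / mx
    m[, j] <- v
  }
  m
}
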