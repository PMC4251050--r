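# EIC-level quality metrics: the MCQ (mass chromatographic quality) index
# family and the global zigzag index, plus threshold filtering of EICs.
#
# An EIC is scored on its dense intensity series I_1..I_N.  The MCQ index
# is the CODA-style similarity between the unit-norm smoothed series and
# the unit-norm mean-subtracted original; it decomposes into a spike
# detection index (original vs smoothed) and a background detection index
# (original vs mean-subtracted).  The global zigzag index is the mean
# squared second difference of the series normalized by the squared
# effective peak intensity (EPI): low values mean a smooth trace, and the
# index is bounded by 4 (N-2)/N < 4.

#' Smooth an intensity series with a centered moving average
#'
#' Boundary points use a truncated (shorter) window so the output has the
#' same length as the input and a constant series is returned unchanged.
#'
#' @param intensities Numeric vector of non-negative intensities.
#' @param window Odd integer window width (scans), at least 3 and at most
#'   `length(intensities)`.
#' @return Numeric vector of the same length.
#' @export
#' @examples
#' smooth_chromatogram(c(0, 3, 0), window = 3)
smooth_chromatogram <- function(intensities, window = 5L) {
  stopifnot(is.numeric(intensities))
  window <- as.integer(window)
  if (window %% 2L == 0L || window < 3L) {
    stop("`window` must be an odd integer >= 3")
  }
  if (window > length(intensities)) {
    stop("`window` must not exceed the series length")
  }
  moving_average(intensities, window)
}

#' Spike detection index
#'
#' Cosine similarity between an intensity series and its moving-average
#' smoothed version. Smooth traces score close to 1; spiky traces lower.
#'
#' @inheritParams smooth_chromatogram
#' @return Similarity in \[-1, 1\] (in practice \[0, 1\] for non-negative
#'   series).
#' @export
spike_index <- function(intensities, window = 5L) {
  if (all(intensities == 0)) {
    stop2("chromqc_degenerate_series",
          "spike index undefined for an all-zero series")
  }
  cosine_similarity(intensities, smooth_chromatogram(intensities, window))
}

#' Background detection index
#'
#' Cosine similarity between an intensity series and its mean-subtracted
#' version; equals sd/sqrt(sd^2 + mean^2) (population sd) in closed form.
#' High flat background drives the index towards 0.
#'
#' @inheritParams smooth_chromatogram
#' @return Similarity in \[0, 1\].
#' @export
background_index <- function(intensities) {
  centered <- intensities - mean(intensities)
  if (all(centered == 0)) {
    stop2("chromqc_degenerate_series",
          "background index undefined for a constant series")
  }
  cosine_similarity(intensities, centered)
}

#' MCQ (mass chromatographic quality) index
#'
#' CODA-style quality score: the inner product of the unit-norm smoothed
#' series with the unit-norm mean-subtracted original, clamped to
#' \[0, 1\]. It penalizes both spikes (via smoothing) and flat background
#' (via mean subtraction), and is bounded above by approximately
#' `min(spike_index, background_index)`.
#'
#' @inheritParams smooth_chromatogram
#' @return Quality score in \[0, 1\].
#' @export
mcq_index <- function(intensities, window = 5L) {
  if (all(intensities == 0)) {
    stop2("chromqc_degenerate_series",
          "MCQ index undefined for an all-zero series")
  }
  centered <- intensities - mean(intensities)
  if (all(centered == 0)) {
    stop2("chromqc_degenerate_series",
          "MCQ index undefined for a constant series")
  }
  smoothed <- smooth_chromatogram(intensities, window)
  val <- cosine_similarity(smoothed, centered)
  min(max(val, 0), 1)
}

#' Effective peak intensity (EPI)
#'
#' Apex intensity minus the baseline estimate at the apex. The baseline is
#' estimated as the series minimum, which is exact on zero-baseline series,
#' shifts one-for-one under a constant offset (leaving EPI unchanged), and
#' keeps the zigzag index within its nominal \[0, 4\] range.
#'
#' @inheritParams smooth_chromatogram
#' @return Non-negative intensity.
#' @export
effective_peak_intensity <- function(intensities) {
  stopifnot(is.numeric(intensities), length(intensities) >= 3L)
  max(intensities) - min(intensities)
}

#' Global zigzag index of an intensity series
#'
#' Second-difference energy of the series normalized by its length and
#' squared effective peak intensity:
#' \deqn{Z = \sum_{n=2}^{N-1} (2 I_n - I_{n-1} - I_{n+1})^2 / (N \cdot EPI^2)}
#' A linear ramp scores 0; an alternating zero/EPI series approaches the
#' supremum 4 as N grows. Lower is smoother.
#'
#' @inheritParams smooth_chromatogram
#' @return Non-negative value, strictly below 4.
#' @export
#' @examples
#' global_zigzag_index(c(0, 1, 2, 1, 0))   # 0.2
#' global_zigzag_index(c(0, 4, 0, 4, 0))   # 2.4
global_zigzag_index <- function(intensities) {
  n <- length(intensities)
  if (n < 3L) stop("zigzag index requires at least 3 points")
  epi <- effective_peak_intensity(intensities)
  if (epi == 0) {
    stop2("chromqc_degenerate_series",
          "zigzag index undefined when EPI is 0 (flat series)")
  }
  d2 <- 2 * intensities[2:(n - 1L)] -
    intensities[1:(n - 2L)] - intensities[3:n]
  sum(d2^2) / (n * epi^2)
}

#' Score a collection of EICs with the EIC-level quality metrics
#'
#' @param eics List of `EIC` objects (see [extract_eics()]).
#' @param window Smoothing window (odd scans) for the spike/MCQ indices.
#' @return A data frame with one row per EIC: `eic_id`, `spike_index`,
#'   `background_index`, `mcq_index`, `epi`, `zigzag_index`. Metrics that
#'   are undefined for a degenerate EIC (constant or all-zero series) are
#'   reported as `NA` and such EICs are rejected by [filter_eics()].
#' @export
score_eics <- function(eics, window = 5L) {
  rows <- lapply(eics, function(e) {
    I <- e$intensities
    safe <- function(expr) tryCatch(expr, chromqc_degenerate_series = function(c) NA_real_)
    data.frame(
      eic_id = e$eic_id,
      spike_index = safe(spike_index(I, window)),
      background_index = safe(background_index(I)),
      mcq_index = safe(mcq_index(I, window)),
      epi = effective_peak_intensity(I),
      zigzag_index = safe(global_zigzag_index(I))
    )
  })
  do.call(rbind, c(rows, list(make.row.names = FALSE)))
}

#' Filter EICs on MCQ and/or zigzag thresholds
#'
#' An EIC is kept in mode `"mcq"` when its MCQ index is at least
#' `mcq_min`; in mode `"zigzag"` when its global zigzag index is below
#' `zigzag_max`; and in mode `"either"` when either condition holds. EICs
#' whose metric is `NA` (degenerate series) fail that condition.
#'
#' @param eics List of `EIC` objects.
#' @param reports Data frame from [score_eics()] covering every EIC.
#' @param mcq_min,zigzag_max Thresholds.
#' @param mode One of `"mcq"`, `"zigzag"`, `"either"`.
#' @return The kept subset of `eics` (same order).
#' @export
filter_eics <- function(eics, reports, mcq_min = 0.6, zigzag_max = 0.9,
                        mode = c("zigzag", "mcq", "either")) {
  mode <- match.arg(mode)
  ids <- vapply(eics, function(e) e$eic_id, numeric(1))
  idx <- match(ids, reports$eic_id)
  if (anyNA(idx)) stop("missing quality report for some EICs")
  pass_mcq <- !is.na(reports$mcq_index[idx]) & reports$mcq_index[idx] >= mcq_min
  pass_zz <- !is.na(reports$zigzag_index[idx]) & reports$zigzag_index[idx] < zigzag_max
  keep <- switch(mode,
    mcq = pass_mcq,
    zigzag = pass_zz,
    either = pass_mcq | pass_zz
  )
  eics[keep]
}
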