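# Chromatographic peak detection by continuous wavelet transform (CWT)
# ridge analysis, in the centWave tradition: Mexican-hat (Ricker) CWT
# over a grid of scales, local maxima linked across adjacent scales into
# ridge lines, one peak per accepted ridge. The best ridge scale tracks
# the peak's characteristic width; boundaries come from a local-minimum
# walk on the smoothed series capped at twice the best scale.

# Ricker (Mexican hat) wavelet sampled at integer offsets for scale a.
ricker_kernel <- function(a) {
  half <- ceiling(5 * a)
  t <- (-half):half
  A <- 2 / (sqrt(3 * a) * pi^0.25)
  A * (1 - (t / a)^2) * exp(-t^2 / (2 * a^2))
}

#' Continuous wavelet transform with the Ricker wavelet
#'
#' Coefficients are computed by convolution against reflectively padded
#' data, so edges see a mirror image of the series rather than zeros.
#'
#' @param intensities Numeric series.
#' @param scales Positive, sorted scale grid (scans).
#' @return A `length(scales) x length(intensities)` coefficient matrix
#'   (rows = scales), with `scales` attached as an attribute.
#' @export
cwt_transform <- function(intensities, scales = 1:16) {
  if (length(scales) == 0L) stop("empty scale set")
  stopifnot(all(scales > 0), !is.unsorted(scales))
  n <- length(intensities)
  out <- matrix(0, nrow = length(scales), ncol = n)
  for (k in seq_along(scales)) {
    kern <- ricker_kernel(scales[k])
    half <- (length(kern) - 1L) %/% 2L
    # reflective padding
    pre <- intensities[pmin(pmax(half:1, 1L), n)]
    post <- intensities[pmin(pmax(n - seq_len(half) + 1L, 1L), n)]
    padded <- c(pre, intensities, post)
    conv <- stats::filter(padded, rev(kern), method = "convolution",
                          sides = 2L)
    out[k, ] <- conv[(half + 1L):(half + n)]
  }
  attr(out, "scales") <- scales
  out
}

# Indices of strict-ish local maxima of x (plateaus take their first
# index); endpoints qualify when they exceed their single neighbor.
local_maxima <- function(x) {
  n <- length(x)
  if (n < 2L) return(integer(0))
  left <- c(-Inf, x[-n])
  right <- c(x[-1], -Inf)
  which(x > left & x >= right)
}

local_minima <- function(x) local_maxima(-x)

#' Link CWT local maxima across scales into ridge lines
#'
#' Starting from the largest scale, each ridge is continued at the next
#' smaller scale by the nearest coefficient local maximum within a
#' position tolerance equal to the current scale; up to `gap_max`
#' consecutive scales may fail to contribute before the ridge stops.
#' Ridges spanning fewer than `min_length` scales are dropped.
#'
#' @param coeffs Coefficient matrix from [cwt_transform()].
#' @param gap_max Maximum consecutive missing scales inside a ridge.
#' @param min_length Minimum ridge length (scales).
#' @return A list of ridges; each has `positions`, `scales` (values, not
#'   indices), `coeffs`, `best_scale`, `best_position`, `best_coeff`.
#' @export
find_ridge_lines <- function(coeffs, gap_max = 2L, min_length = 3L) {
  scales <- attr(coeffs, "scales")
  stopifnot(!is.null(scales))
  ns <- length(scales)
  maxima <- lapply(seq_len(ns), function(k) local_maxima(coeffs[k, ]))
  used <- lapply(maxima, function(m) rep(FALSE, length(m)))
  ridges <- list()
  for (k0 in rev(seq_len(ns))) {
    for (j0 in seq_along(maxima[[k0]])) {
      if (used[[k0]][j0]) next
      pos <- maxima[[k0]][j0]
      used[[k0]][j0] <- TRUE
      r_pos <- pos; r_sc <- scales[k0]
      r_cf <- coeffs[k0, pos]
      gap <- 0L
      cur <- pos
      if (k0 > 1L) {
        for (k in (k0 - 1L):1L) {
          cand <- maxima[[k]]
          free <- which(!used[[k]])
          cand <- cand[free]
          if (length(cand)) {
            d <- abs(cand - cur)
            jmin <- which.min(d)
            if (d[jmin] <= max(scales[k], 2)) {
              cur <- cand[jmin]
              used[[k]][free[jmin]] <- TRUE
              r_pos <- c(r_pos, cur); r_sc <- c(r_sc, scales[k])
              r_cf <- c(r_cf, coeffs[k, cur])
              gap <- 0L
              next
            }
          }
          gap <- gap + 1L
          if (gap > gap_max) break
        }
      }
      if (length(r_pos) >= min_length) {
        # best scale: strongest interior local maximum of the
        # coefficient-vs-scale profile. A real peak's response peaks at
        # its characteristic scale; a 1-scan spike's response decays
        # monotonically from scale 1, so endpoint maxima are only used
        # as a fallback (peak wider than the scale grid).
        ord <- order(r_sc)
        sc_sorted <- r_sc[ord]; cf_sorted <- r_cf[ord]; pos_sorted <- r_pos[ord]
        m <- length(cf_sorted)
        b <- if (m >= 3L) {
          interior <- which(cf_sorted[2:(m - 1L)] >= cf_sorted[1:(m - 2L)] &
                              cf_sorted[2:(m - 1L)] >= cf_sorted[3:m]) + 1L
          if (length(interior)) interior[which.max(cf_sorted[interior])]
          else which.max(abs(cf_sorted))
        } else {
          which.max(abs(cf_sorted))
        }
        ridges[[length(ridges) + 1L]] <- list(
          positions = pos_sorted, scales = sc_sorted, coeffs = cf_sorted,
          best_scale = sc_sorted[b], best_position = pos_sorted[b],
          best_coeff = cf_sorted[b])
      }
    }
  }
  ridges
}

# CWT signal-to-noise ratio: |coefficient| at the apex at `scale` over
# the 95% quantile of |scale-1 coefficients| within +/- `window` scans.
cwt_snr <- function(coeffs, apex, scale, window = 50L, eps = 1e-6) {
  scales <- attr(coeffs, "scales")
  krow <- which.min(abs(scales - scale))
  k1 <- which.min(abs(scales - 1))
  n <- ncol(coeffs)
  lo <- max(1L, apex - window); hi <- min(n, apex + window)
  if (hi < lo) stop("empty SNR window")
  noise <- stats::quantile(abs(coeffs[k1, lo:hi]), 0.95, names = FALSE)
  abs(coeffs[krow, apex]) / max(noise, eps)
}

#' Detect chromatographic peaks in one EIC
#'
#' One candidate peak per accepted CWT ridge: the apex is the ridge's
#' best-coefficient position snapped to the nearest local maximum of the
#' smoothed series within one best-scale, then to the raw-intensity
#' maximum of the final slice; boundaries are the nearest local minima of
#' the smoothed series on either side, capped at twice the best scale
#' from the apex and truncated at zero-intensity gaps. Candidates with
#' width outside `[min_width, max_width]` scans or CWT SNR below
#' `snr_floor` are rejected; overlapping slices are trimmed at the
#' between-apex minimum so boundary intervals never overlap.
#'
#' @param eic An `EIC`.
#' @param scales CWT scale grid (scans).
#' @param snr_floor Minimum CWT signal-to-noise ratio.
#' @param min_width,max_width Accepted slice widths (points, inclusive).
#' @param smooth_window Smoothing window for apex/boundary placement.
#' @return A data frame of peaks sorted by `scan_apex`: columns `eic_id`,
#'   `p` (apex index within the EIC series), `scan_apex`, `scan_left`,
#'   `scan_right`, `mz_apex`, `rt_apex_s`, `ridge_scale`, `cwt_coeff`,
#'   `snr`.
#' @export
detect_peaks <- function(eic, scales = 1:16, snr_floor = 1,
                         min_width = 5L, max_width = 50L,
                         smooth_window = 5L) {
  stopifnot(inherits(eic, "EIC"))
  I <- eic$intensities
  n <- length(I)
  empty <- data.frame(eic_id = integer(0), p = integer(0),
                      scan_apex = integer(0), scan_left = integer(0),
                      scan_right = integer(0), mz_apex = numeric(0),
                      rt_apex_s = numeric(0), ridge_scale = numeric(0),
                      cwt_coeff = numeric(0), snr = numeric(0))
  if (n < min_width || all(I == 0)) return(empty)
  # detection geometry runs on a despiked series: a centered binomial
  # (1,2,1)/4 average first (it cancels alternating zigzag noise without
  # any phase shift; a running median alone turns such noise into
  # spurious plateaus), then a width-9 running median (accepted peaks
  # are at least `min_width` >= 5 scans wide while centroiding spikes
  # span 1-3, at most 5 after the binomial average, so a width-11
  # median removes them without erasing any admissible peak). Quality
  # metrics and the SNR are always taken from the raw series.
  D <- (c(I[1L], I[-n]) + 2 * I + c(I[-1L], I[n])) / 4
  if (n >= 11L) D <- stats::runmed(D, 11L, endrule = "median")
  win <- min(smooth_window, if (n %% 2L == 1L) n else n - 1L)
  S <- smooth_chromatogram(D, max(win, 3L))
  coeffs <- cwt_transform(D, scales)
  coeffs_raw <- cwt_transform(I, scales)
  ridges <- find_ridge_lines(coeffs)
  if (!length(ridges)) return(empty)
  rows <- list()
  scale_rows <- attr(coeffs, "scales")
  for (r in ridges) {
    if (r$best_coeff <= 0) next
    sc <- r$best_scale
    # snap the apex on the best-scale coefficient row (not the smoothed
    # series: residual spikes still dominate a window-5 average, while
    # the best-scale CWT response is insensitive to them)
    krow <- which.min(abs(scale_rows - sc))
    halfw <- ceiling(sc)
    lo <- max(1L, r$best_position - halfw)
    hi <- min(n, r$best_position + halfw)
    apex <- lo - 1L + which.max(coeffs[krow, lo:hi])
    # boundary walk on the smoothed series: stop at the first local
    # minimum, at a zero-intensity gap, when the signal has decayed to
    # 1% of the apex amplitude above baseline, or at 2 * best scale;
    # the cap also keeps the slice within max_width, so broad peaks get
    # a truncated slice rather than no detection
    cap <- min(ceiling(2 * sc), (max_width - 1L) %/% 2L)
    smin <- min(S)
    floor_level <- smin + 0.01 * (S[apex] - smin)
    left <- apex
    while (left > 1L && apex - left < cap) {
      if (I[left - 1L] == 0 && I[left] == 0) break
      if (S[left - 1L] > S[left] && left < apex) break
      if (S[left - 1L] < floor_level && left < apex) break
      left <- left - 1L
    }
    right <- apex
    while (right < n && right - apex < cap) {
      if (I[right + 1L] == 0 && I[right] == 0) break
      if (S[right + 1L] > S[right] && right > apex) break
      if (S[right + 1L] < floor_level && right > apex) break
      right <- right + 1L
    }
    width <- right - left + 1L
    if (width < min_width || width > max_width) next
    # final apex: maximum of the despiked slice, so a residual spike
    # inside the slice cannot displace the apex; the running median
    # flattens a smooth apex into a plateau, so take the plateau middle
    dmax <- which(D[left:right] == max(D[left:right]))
    apex <- left - 1L + dmax[ceiling(length(dmax) / 2)]
    # coherence check: the smoothed despiked slice must itself rise at
    # the apex. Slices that owe their prominence to a 1-3-scan spike or
    # to flat alternating noise have no such rise and are not
    # chromatographic peaks
    ssl <- S[left:right]
    pp <- apex - left + 1L
    apex_level <- mean(ssl[max(1L, pp - 1L):min(width, pp + 1L)])
    edge_level <- mean(ssl[c(1L, 2L, width - 1L, width)])
    if (apex_level < 1.15 * edge_level) next
    snr_val <- cwt_snr(coeffs_raw, apex, sc)
    if (snr_val < snr_floor) next
    rows[[length(rows) + 1L]] <- data.frame(
      eic_id = eic$eic_id, p = apex,
      scan_apex = eic$scan_first + apex - 1L,
      scan_left = eic$scan_first + left - 1L,
      scan_right = eic$scan_first + right - 1L,
      mz_apex = if (!is.na(eic$mz_trace[apex])) eic$mz_trace[apex] else eic$mz_center,
      rt_apex_s = eic$rt[apex],
      ridge_scale = sc, cwt_coeff = r$best_coeff, snr = snr_val)
  }
  if (!length(rows)) return(empty)
  pks <- do.call(rbind, rows)
  pks <- pks[order(pks$scan_apex, -pks$cwt_coeff), , drop = FALSE]
  # collapse ridges that resolved to the same apex; keep strongest
  pks <- pks[!duplicated(pks$scan_apex), , drop = FALSE]
  pks <- pks[order(pks$scan_apex), , drop = FALSE]
  # enforce non-overlapping slices: trim at the between-apex minimum
  if (nrow(pks) > 1L) {
    for (i in seq_len(nrow(pks) - 1L)) {
      if (pks$scan_right[i] >= pks$scan_left[i + 1L]) {
        a <- pks$p[i]; b <- pks$p[i + 1L]
        cut <- if (b - a >= 2L) a + which.min(S[(a + 1L):(b - 1L)]) else a
        pks$scan_right[i] <- eic$scan_first + cut - 1L
        pks$scan_left[i + 1L] <- eic$scan_first + cut
      }
    }
    w <- pks$scan_right - pks$scan_left + 1L
    keep <- w >= min_width & w <= max_width &
      pks$scan_apex >= pks$scan_left & pks$scan_apex <= pks$scan_right
    pks <- pks[keep, , drop = FALSE]
  }
  rownames(pks) <- NULL
  pks
}

# Intensity slice of a detected peak within its EIC.
peak_slice <- function(eic, peak_row) {
  i1 <- peak_row$scan_left - eic$scan_first + 1L
  i2 <- peak_row$scan_right - eic$scan_first + 1L
  list(I = eic$intensities[i1:i2], p = peak_row$p - i1 + 1L)
}
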