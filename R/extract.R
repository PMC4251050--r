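# Acute EIC extraction by region-of-interest (mass trace) tracking in
# (scan, m/z) space. An open ROI is extended scan by scan with the point
# whose m/z lies within the ppm tolerance of the ROI's running
# intensity-weighted mean; traces not extended for more than `max_gap`
# consecutive scans are closed, and closed traces with too few nonzero
# points are discarded. The running-mean rule follows drifting m/z
# without the signal splitting that fixed bins suffer from.

#' EIC container
#'
#' A dense intensity series over a contiguous scan range for one mass
#' trace. Gap scans (no centroid assigned) hold intensity 0 and an `NA`
#' m/z so downstream index arithmetic can treat the series as regularly
#' sampled.
#'
#' @param eic_id Integer id.
#' @param mz_center Intensity-weighted mean m/z of the trace.
#' @param scan_first,scan_last Absolute scan range (inclusive).
#' @param intensities Dense intensity series (length
#'   `scan_last - scan_first + 1`).
#' @param mz_trace Per-scan m/z values (`NA` at gaps).
#' @param rt Per-scan retention times (seconds).
#' @return An object of class `EIC`.
#' @export
new_eic <- function(eic_id, mz_center, scan_first, scan_last,
                    intensities, mz_trace, rt) {
  n <- scan_last - scan_first + 1L
  stopifnot(length(intensities) == n, length(mz_trace) == n,
            length(rt) == n, all(intensities >= 0))
  structure(list(eic_id = as.integer(eic_id), mz_center = mz_center,
                 scan_first = as.integer(scan_first),
                 scan_last = as.integer(scan_last),
                 intensities = intensities, mz_trace = mz_trace, rt = rt,
                 n = n),
            class = "EIC")
}

#' @export
print.EIC <- function(x, ...) {
  cat(sprintf("<EIC %d> m/z %.4f, scans %d-%d (%d pts, %d nonzero), max %.4g\n",
              x$eic_id, x$mz_center, x$scan_first, x$scan_last, x$n,
              sum(x$intensities > 0), max(x$intensities)))
  invisible(x)
}

#' Extract EICs from a centroided run by ROI tracking
#'
#' @param run An `LCMSRun`.
#' @param ppm_tolerance Mass tolerance (ppm) for extending a trace from
#'   its running intensity-weighted mean m/z.
#' @param min_trace_points Minimum number of nonzero points a closed
#'   trace needs to be kept.
#' @param max_gap Maximum consecutive scans a trace may go without a
#'   point before it is closed.
#' @return A list of `EIC` objects, ids assigned in order of
#'   (`scan_first`, `mz_center`). The list carries an attribute
#'   `point_counts` with the per-run accounting (`assigned`,
#'   `discarded`): every centroid point lands in exactly one of the two.
#' @export
extract_eics <- function(run, ppm_tolerance = 40, min_trace_points = 5L,
                         max_gap = 2L) {
  stopifnot(inherits(run, "LCMSRun"), ppm_tolerance > 0)
  pts <- run$points
  n_scans <- length(run$rt)
  by_scan <- split(seq_len(nrow(pts)), factor(pts$scan, levels = seq_len(n_scans)))

  open <- list()    # each: mz_mean, wt, last_scan, scans, mzs, ints
  closed <- list()

  close_roi <- function(roi) {
    closed[[length(closed) + 1L]] <<- roi
  }

  for (s in seq_len(n_scans)) {
    idx <- by_scan[[s]]
    # close stale ROIs first
    if (length(open)) {
      stale <- vapply(open, function(r) s - r$last_scan > max_gap + 1L, logical(1))
      for (r in open[stale]) close_roi(r)
      open <- open[!stale]
    }
    if (length(idx)) {
      mzs <- pts$mz[idx]
      ints <- pts$intensity[idx]
      taken_pt <- rep(FALSE, length(idx))
      if (length(open)) {
        centers <- vapply(open, function(r) r$mz_mean, numeric(1))
        # all (roi, point) pairs inside tolerance, best (smallest ppm
        # deviation) first; each ROI takes one point, each point one ROI
        dev <- abs(outer(mzs, centers, "-")) /
          rep(centers, each = length(mzs)) * 1e6
        cand <- which(dev <= ppm_tolerance, arr.ind = TRUE)
        if (nrow(cand)) {
          cand <- cand[order(dev[cand]), , drop = FALSE]
          taken_roi <- rep(FALSE, length(open))
          for (k in seq_len(nrow(cand))) {
            pi <- cand[k, 1]; ri <- cand[k, 2]
            if (taken_pt[pi] || taken_roi[ri]) next
            taken_pt[pi] <- TRUE; taken_roi[ri] <- TRUE
            r <- open[[ri]]
            w <- r$wt + ints[pi]
            r$mz_mean <- (r$mz_mean * r$wt + mzs[pi] * ints[pi]) / w
            r$wt <- w
            r$last_scan <- s
            r$scans <- c(r$scans, s)
            r$mzs <- c(r$mzs, mzs[pi])
            r$ints <- c(r$ints, ints[pi])
            open[[ri]] <- r
          }
        }
      }
      # unassigned points seed new ROIs
      for (pi in which(!taken_pt)) {
        open[[length(open) + 1L]] <- list(
          mz_mean = mzs[pi], wt = ints[pi], last_scan = s,
          scans = s, mzs = mzs[pi], ints = ints[pi])
      }
    }
  }
  for (r in open) close_roi(r)

  keep <- vapply(closed, function(r) length(r$scans) >= min_trace_points,
                 logical(1))
  discarded_points <- sum(vapply(closed[!keep], function(r) length(r$scans),
                                 integer(1)))
  closed <- closed[keep]
  if (length(closed)) {
    ord <- order(vapply(closed, function(r) r$scans[1], numeric(1)),
                 vapply(closed, function(r) r$mz_mean, numeric(1)))
    closed <- closed[ord]
  }
  eics <- vector("list", length(closed))
  for (i in seq_along(closed)) {
    r <- closed[[i]]
    first <- r$scans[1]; last <- r$scans[length(r$scans)]
    dense_i <- numeric(last - first + 1L)
    dense_m <- rep(NA_real_, last - first + 1L)
    pos <- r$scans - first + 1L
    dense_i[pos] <- r$ints
    dense_m[pos] <- r$mzs
    eics[[i]] <- new_eic(i, r$mz_mean, first, last, dense_i, dense_m,
                         run$rt[first:last])
  }
  attr(eics, "point_counts") <- c(
    assigned = sum(vapply(closed, function(r) length(r$scans), integer(1))),
    discarded = discarded_points
  )
  eics
}
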