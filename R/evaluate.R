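# Benchmarking against a consensus ground truth: tolerance matching of
# peak lists, "detected by at least two of three tools" truth
# construction (with the inclusion-exclusion identity as a cross-check),
# Recall/Precision/F-Score, and single-metric threshold sweeps.
#
# Note on Precision: the source formulation of Recall and Precision uses
# TP/NP for both, which cannot be right for Precision (and is
# inconsistent with the benchmark numbers it accompanies); Precision here
# is TP divided by the number of peaks the evaluated program detected.

#' Match two peak lists under m/z and RT tolerances
#'
#' Candidate pairs satisfy |dmz| <= `mz_tol` and |drt| <= `rt_tol`; they
#' are accepted greedily in order of increasing combined normalized
#' distance `|dmz|/mz_tol + |drt|/rt_tol`, each peak matching at most
#' once (one-to-one matching).
#'
#' @param A,B Peak-record data frames (columns `mz_apex`, `rt_apex_s`).
#' @param mz_tol m/z tolerance (Daltons).
#' @param rt_tol RT tolerance (seconds).
#' @return Data frame of matched pairs: `i` (row in A), `j` (row in B),
#'   `dist` (combined normalized distance), ordered by `dist`.
#' @export
match_peaks <- function(A, B, mz_tol = 0.05, rt_tol = 5) {
  stopifnot(mz_tol > 0, rt_tol > 0)
  na <- nrow(A); nb <- nrow(B)
  if (na == 0L || nb == 0L) {
    return(data.frame(i = integer(0), j = integer(0), dist = numeric(0)))
  }
  dmz <- abs(outer(A$mz_apex, B$mz_apex, "-"))
  drt <- abs(outer(A$rt_apex_s, B$rt_apex_s, "-"))
  ok <- dmz <= mz_tol & drt <= rt_tol
  cand <- which(ok, arr.ind = TRUE)
  if (!nrow(cand)) {
    return(data.frame(i = integer(0), j = integer(0), dist = numeric(0)))
  }
  d <- dmz[cand] / mz_tol + drt[cand] / rt_tol
  ord <- order(d, cand[, 1], cand[, 2])
  cand <- cand[ord, , drop = FALSE]
  d <- d[ord]
  used_a <- rep(FALSE, na); used_b <- rep(FALSE, nb)
  keep <- logical(nrow(cand))
  for (k in seq_len(nrow(cand))) {
    i <- cand[k, 1]; j <- cand[k, 2]
    if (!used_a[i] && !used_b[j]) {
      used_a[i] <- TRUE; used_b[j] <- TRUE; keep[k] <- TRUE
    }
  }
  data.frame(i = cand[keep, 1], j = cand[keep, 2], dist = d[keep])
}

#' Consensus ground truth from three tools' peak lists
#'
#' A ground-truth peak is one detected by at least two of the three
#' tools: pairwise one-to-one matchings are merged into co-location
#' groups, and every group containing two or more distinct tools
#' contributes one truth peak (a peak matched by all three counts once),
#' represented by its medoid member (minimal summed m/z+RT normalized
#' distance to the rest of the group).
#'
#' The returned `np` (direct >= 2-vote count) should equal the
#' inclusion-exclusion count [np_inclusion_exclusion()]
#' `N12 + N13 + N23 - 2 * N123` whenever matching is unambiguous.
#'
#' @param L1,L2,L3 Peak-record data frames.
#' @inheritParams match_peaks
#' @return List with `truth` (peak-record data frame of medoids), `np`
#'   (number of truth peaks), and `n_all_three` (groups seen by all
#'   three tools).
#' @export
ground_truth_peaks <- function(L1, L2, L3, mz_tol = 0.05, rt_tol = 5) {
  lists <- list(L1, L2, L3)
  sizes <- vapply(lists, nrow, integer(1))
  offset <- c(0L, cumsum(sizes))[1:3]
  ntot <- sum(sizes)
  parent <- seq_len(max(ntot, 1L))
  find <- function(x) {
    while (parent[x] != x) {
      parent[x] <<- parent[parent[x]]
      x <- parent[x]
    }
    x
  }
  union_ <- function(a, b) {
    ra <- find(a); rb <- find(b)
    if (ra != rb) parent[rb] <<- ra
  }
  for (pair in list(c(1L, 2L), c(1L, 3L), c(2L, 3L))) {
    a <- pair[1]; b <- pair[2]
    m <- match_peaks(lists[[a]], lists[[b]], mz_tol, rt_tol)
    for (k in seq_len(nrow(m))) {
      union_(offset[a] + m$i[k], offset[b] + m$j[k])
    }
  }
  if (ntot == 0L) {
    return(list(truth = peak_records(numeric(0), numeric(0)), np = 0L,
                n_all_three = 0L))
  }
  tool_of <- rep(1:3, sizes)
  row_of <- unlist(lapply(sizes, seq_len), use.names = FALSE)
  root <- vapply(seq_len(ntot), find, integer(1))
  groups <- split(seq_len(ntot), root)
  medoids <- list()
  n_all_three <- 0L
  for (g in groups) {
    tools <- unique(tool_of[g])
    if (length(tools) < 2L) next
    if (length(tools) == 3L) n_all_three <- n_all_three + 1L
    mz <- mapply(function(t, r) lists[[t]]$mz_apex[r], tool_of[g], row_of[g])
    rt <- mapply(function(t, r) lists[[t]]$rt_apex_s[r], tool_of[g], row_of[g])
    dist_sum <- vapply(seq_along(g), function(k) {
      sum(abs(mz - mz[k]) / mz_tol + abs(rt - rt[k]) / rt_tol)
    }, numeric(1))
    best <- which.min(dist_sum)
    medoids[[length(medoids) + 1L]] <- c(mz[best], rt[best])
  }
  np <- length(medoids)
  truth <- if (np) {
    m <- do.call(rbind, medoids)
    ord <- order(m[, 2], m[, 1])
    peak_records(mz_apex = m[ord, 1], rt_apex_s = m[ord, 2],
                 source = "consensus")
  } else {
    peak_records(numeric(0), numeric(0))
  }
  list(truth = truth, np = np, n_all_three = n_all_three)
}

#' Inclusion-exclusion count of consensus peaks
#'
#' `N12 + N13 + N23 - 2 * N123`, where the pairwise counts are the sizes
#' of the one-to-one matchings and `N123` is the number of co-location
#' groups seen by all three tools.
#'
#' @inheritParams ground_truth_peaks
#' @return Integer count.
#' @export
np_inclusion_exclusion <- function(L1, L2, L3, mz_tol = 0.05, rt_tol = 5) {
  n12 <- nrow(match_peaks(L1, L2, mz_tol, rt_tol))
  n13 <- nrow(match_peaks(L1, L3, mz_tol, rt_tol))
  n23 <- nrow(match_peaks(L2, L3, mz_tol, rt_tol))
  n123 <- ground_truth_peaks(L1, L2, L3, mz_tol, rt_tol)$n_all_three
  n12 + n13 + n23 - 2L * n123
}

#' F-Score (harmonic mean of recall and precision)
#'
#' @param recall,precision Fractions in \[0, 1\].
#' @return `2 * R * P / (R + P)`, or 0 when `R + P == 0`.
#' @export
fscore <- function(recall, precision) {
  ifelse(recall + precision > 0,
         2 * recall * precision / (recall + precision), 0)
}

#' Recall, Precision and F-Score of a detected peak list
#'
#' True positives are detected peaks matched one-to-one to the truth list
#' within tolerance. Recall = TP/NP, Precision = TP/n_detected (see the
#' module note on the Precision denominator), F-Score their harmonic
#' mean; all are 0 when their denominator is 0.
#'
#' @param detected Peak-record data frame to evaluate.
#' @param truth Truth peak-record data frame.
#' @param np Ground-truth count (defaults to `nrow(truth)`).
#' @inheritParams match_peaks
#' @return A one-row data frame of class `prf_result`: `np`, `tp`,
#'   `n_detected`, `recall`, `precision`, `fscore`.
#' @export
prf <- function(detected, truth, np = nrow(truth), mz_tol = 0.05, rt_tol = 5) {
  tp <- nrow(match_peaks(detected, truth, mz_tol, rt_tol))
  n_det <- nrow(detected)
  r <- if (np > 0) tp / np else 0
  p <- if (n_det > 0) tp / n_det else 0
  structure(data.frame(np = np, tp = tp, n_detected = n_det,
                       recall = r, precision = p, fscore = fscore(r, p)),
            class = c("prf_result", "data.frame"))
}

#' @export
print.prf_result <- function(x, ...) {
  cat(sprintf("NP = %d, TP = %d, detected = %d | Recall %.4f, Precision %.4f, F-Score %.4f\n",
              x$np, x$tp, x$n_detected, x$recall, x$precision, x$fscore))
  invisible(x)
}

# metric -> (report column, keep direction). "ge": keep metric >= th,
# loosening = decreasing threshold; "le": keep metric <= th (strict <
# for the EIC zigzag filter), loosening = increasing threshold.
sweep_metric_table <- function() {
  data.frame(
    metric = c("mcq", "eic_zigzag", "sharpness", "gaussian", "snr",
               "significance", "tpasr", "zigzag"),
    level = c("eic", "eic", "peak", "peak", "peak", "peak", "peak", "peak"),
    column = c("mcq_index", "zigzag_index", "sharpness",
               "gaussian_similarity", "snr", "peak_significance",
               "tpasr", "local_zigzag"),
    direction = c("ge", "le", "ge", "ge", "ge", "ge", "le", "le"),
    stringsAsFactors = FALSE
  )
}

#' Single-metric threshold sweep of final peak detection performance
#'
#' Holds a pipeline state (extracted EICs, their quality reports,
#' detected peaks and peak quality reports) fixed, varies one metric's
#' cutoff over a grid with every other filter disabled, and computes
#' Recall/Precision/F-Score against the truth list at each cutoff. For
#' EIC-level metrics (`"mcq"`, `"eic_zigzag"`) filtering removes whole
#' EICs and all their peaks; for peak-level metrics (`"sharpness"`,
#' `"gaussian"`, `"snr"`, `"significance"`, `"tpasr"`, `"zigzag"`) it
#' removes individual peaks.
#'
#' @param state Pipeline state from [run_pipeline()] (`keep_state =
#'   TRUE`) or a list with `eic_reports`, `peak_reports`, and `records`
#'   (the unfiltered detected peak records, row-aligned with
#'   `peak_reports`).
#' @param metric Metric name (see above).
#' @param grid Numeric threshold grid.
#' @param truth Truth peak-record data frame.
#' @param np Ground-truth count.
#' @inheritParams match_peaks
#' @return Data frame of class `sweep_result`: one row per threshold with
#'   the PRF columns.
#' @export
sweep_threshold <- function(state, metric, grid, truth, np = nrow(truth),
                            mz_tol = 0.05, rt_tol = 5) {
  tab <- sweep_metric_table()
  row <- tab[tab$metric == metric, ]
  if (nrow(row) != 1L) {
    stop("unknown metric '", metric, "'; one of: ",
         paste(tab$metric, collapse = ", "))
  }
  grid <- sort(grid)
  records <- state$records
  if (row$level == "eic") {
    vals <- state$eic_reports[[row$column]][
      match(records$eic_id, state$eic_reports$eic_id)]
  } else {
    vals <- state$peak_reports[[row$column]]
  }
  res <- lapply(grid, function(th) {
    keep <- if (row$direction == "ge") {
      !is.na(vals) & vals >= th
    } else {
      !is.na(vals) & vals < th
    }
    keep[is.infinite(vals) & vals > 0 & row$direction == "ge"] <- TRUE
    cbind(threshold = th,
          prf(records[keep, , drop = FALSE], truth, np, mz_tol, rt_tol))
  })
  out <- do.call(rbind, c(res, list(make.row.names = FALSE)))
  attr(out, "metric") <- metric
  attr(out, "direction") <- row$direction
  class(out) <- c("sweep_result", "data.frame")
  out
}
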