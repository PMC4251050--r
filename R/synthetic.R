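# Synthetic centroided LC/MS data with planted, fully known peaks.
#
# The generator emulates the failure modes that motivate EIC / peak
# quality scoring in electrospray LC/MS metabolomics: Gaussian and
# tail-convolved chromatographic peaks 5-50 scans wide, additive baseline
# with drift, point-to-point multiplicative zigzag noise, 1-3-scan
# spikes at 5-20x the local level, per-scan m/z drift inside a ppm
# envelope, and background channels carrying noisy low-quality bumps.
# Every planted peak is exported in a truth table so downstream stages
# can be benchmarked without external data.

#' Construct a truth table of planted chromatographic peaks
#'
#' @param mz Peak m/z (Thomson).
#' @param rt_apex Apex retention time (seconds).
#' @param height Apex intensity above baseline (> 0).
#' @param sigma Gaussian width (seconds, > 0).
#' @param tail_tau Exponential tail time constant (seconds); 0 gives a
#'   symmetric Gaussian, > 0 convolves it with an exponential decay
#'   (chromatographic tailing).
#' @return A `data.frame` with one row per peak.
#' @export
truth_peaks <- function(mz, rt_apex, height, sigma, tail_tau = 0) {
  df <- data.frame(mz = mz, rt_apex = rt_apex, height = height,
                   sigma = sigma,
                   tail_tau = rep_len(tail_tau, length(mz)))
  stopifnot(all(df$mz > 0), all(df$height > 0), all(df$sigma > 0),
            all(df$tail_tau >= 0))
  df
}

#' Specification of a synthetic centroided run
#'
#' @param truth Truth table from [truth_peaks()] (may have zero rows).
#' @param n_scans Number of scans (>= 10).
#' @param scan_rate Seconds per scan.
#' @param baseline_level Constant additive baseline intensity.
#' @param baseline_drift Baseline slope (intensity per scan).
#' @param zigzag_amplitude Relative magnitude of the per-scan
#'   alternating-sign multiplicative noise (fraction of the local level).
#' @param spike_rate Expected spikes per 100 scans.
#' @param spike_width Maximum spike width (1--3 scans).
#' @param ppm_jitter Per-scan m/z jitter envelope (ppm).
#' @param noise_floor Minimum local level used to scale noise.
#' @param background_channels Number of extra truth-free m/z channels
#'   carrying heavy zigzag noise and low-quality bumps (decoys for
#'   filtering benchmarks).
#' @param background_zigzag Relative zigzag amplitude of those channels.
#' @param seed Integer seed; all randomness flows from it.
#' @return A list of class `synthetic_spec`.
#' @export
synthetic_spec <- function(truth = truth_peaks(numeric(0), numeric(0),
                                               numeric(0), numeric(0)),
                           n_scans = 600L,
                           scan_rate = 1.2,
                           baseline_level = 20,
                           baseline_drift = 0,
                           zigzag_amplitude = 0.05,
                           spike_rate = 0.3,
                           spike_width = 3L,
                           ppm_jitter = 10,
                           noise_floor = 5,
                           background_channels = 0L,
                           background_zigzag = 0.12,
                           seed = 1L) {
  stopifnot(n_scans >= 10L, scan_rate > 0, zigzag_amplitude >= 0,
            spike_rate >= 0, spike_width >= 1L, spike_width <= 3L,
            ppm_jitter >= 0, noise_floor >= 0, background_channels >= 0L)
  span <- c(0, (n_scans - 1L) * scan_rate)
  if (nrow(truth) && (any(truth$rt_apex < span[1]) || any(truth$rt_apex > span[2]))) {
    stop("truth peak rt_apex outside the run span [",
         span[1], ", ", span[2], "] s")
  }
  structure(list(
    truth = truth, n_scans = as.integer(n_scans), scan_rate = scan_rate,
    baseline_level = baseline_level, baseline_drift = baseline_drift,
    zigzag_amplitude = zigzag_amplitude, spike_rate = spike_rate,
    spike_width = as.integer(spike_width), ppm_jitter = ppm_jitter,
    noise_floor = noise_floor,
    background_channels = as.integer(background_channels),
    background_zigzag = background_zigzag,
    seed = as.integer(seed)
  ), class = "synthetic_spec")
}

# Noiseless peak profile sampled on the run's rt grid, scaled to apex
# height. Tailing is a discrete convolution of the Gaussian with a
# normalized exponential-decay kernel, then rescaled to the same height.
peak_profile <- function(rt, rt_apex, height, sigma, tail_tau, scan_rate) {
  g <- exp(-(rt - rt_apex)^2 / (2 * sigma^2))
  if (tail_tau > 0) {
    j <- 0:ceiling(6 * tail_tau / scan_rate)
    kern <- exp(-j * scan_rate / tail_tau)
    kern <- kern / sum(kern)
    n <- length(g)
    out <- numeric(n)
    for (k in seq_along(kern)) {
      shift <- j[k]
      idx <- seq_len(n - shift)
      out[idx + shift] <- out[idx + shift] + kern[k] * g[idx]
    }
    g <- out
  }
  if (max(g) > 0) g <- g / max(g)
  height * g
}

# Apply zigzag noise and spikes to a noiseless expectation. The zigzag
# model is a zero-mean multiplicative perturbation with strictly
# alternating sign (random phase) and per-scan U(0.5, 1) magnitude,
# scaled by `amplitude` and the local level: alternation is what makes
# the noise "zigzag" rather than white, injecting second-difference
# energy the way detector oscillation does in real chromatograms.
# Spikes are rectangular bursts of 1..spike_width scans at 5-20x the
# local level. Caller owns the RNG state.
apply_channel_noise <- function(expected, amplitude, spike_rate, spike_width,
                                noise_floor, n_scans) {
  level <- pmax(expected, noise_floor)
  out <- expected
  if (amplitude > 0) {
    s <- (-1)^(seq_len(n_scans) + sample(0:1, 1L))
    u <- stats::runif(n_scans, 0.5, 1)
    out <- out + amplitude * level * s * u
  }
  if (spike_rate > 0) {
    n_spikes <- stats::rpois(1L, spike_rate * n_scans / 100)
    if (n_spikes > 0) {
      pos <- sample.int(n_scans, n_spikes, replace = TRUE)
      for (p in pos) {
        w <- sample.int(spike_width, 1L)
        idx <- p:min(p + w - 1L, n_scans)
        out[idx] <- out[idx] + stats::runif(1, 5, 20) * level[idx]
      }
    }
  }
  pmax(out, 0)
}

#' Generate one synthetic EIC (a single m/z channel)
#'
#' The expected value at scan t is
#' `baseline_level + baseline_drift * (t - 1) + sum of peak profiles`;
#' the realized series adds zigzag noise and spikes. Deterministic given
#' `spec$seed`.
#'
#' @param spec A [synthetic_spec()].
#' @return A list with `intensities` (length `n_scans`), `rt` (seconds
#'   per scan), and `truth` (the spec's truth table).
#' @export
generate_eic <- function(spec) {
  stopifnot(inherits(spec, "synthetic_spec"))
  local_rng(spec$seed)
  rt <- (seq_len(spec$n_scans) - 1L) * spec$scan_rate
  expected <- spec$baseline_level +
    spec$baseline_drift * (seq_len(spec$n_scans) - 1L)
  if (nrow(spec$truth)) {
    for (i in seq_len(nrow(spec$truth))) {
      p <- spec$truth[i, ]
      expected <- expected + peak_profile(rt, p$rt_apex, p$height, p$sigma,
                                          p$tail_tau, spec$scan_rate)
    }
  }
  intensities <- apply_channel_noise(expected, spec$zigzag_amplitude,
                                     spec$spike_rate, spec$spike_width,
                                     spec$noise_floor, spec$n_scans)
  list(intensities = intensities, rt = rt, truth = spec$truth)
}

#' Generate a synthetic centroided LC/MS run
#'
#' Each truth peak contributes one centroid point per scan within +/- 4
#' sigma (plus tail) of its apex, with per-scan m/z jittered uniformly
#' inside the ppm envelope. Truth peaks sharing an m/z channel (isomers)
#' are merged into one channel. Background channels emulate
#' solvent/contaminant traces: a high background level carrying shallow
#' bumps under level-scaled zigzag noise and spikes, which peak
#' detection will flag but quality filtering should reject.
#' Deterministic given `spec$seed`.
#'
#' @param spec A [synthetic_spec()].
#' @return A list with `run` (an `LCMSRun`) and `truth` (truth table with
#'   added `scan_apex` column).
#' @export
generate_run <- function(spec) {
  stopifnot(inherits(spec, "synthetic_spec"))
  truth <- spec$truth
  if (nrow(truth) == 0L && spec$background_channels == 0L) {
    stop("empty truth set with zero background channels: nothing to emit")
  }
  # distinct-m/z precondition: channels either identical m/z (isomers) or
  # separated by > 3x the ppm envelope
  if (nrow(truth) > 1L) {
    mzs <- sort(unique(truth$mz))
    if (length(mzs) > 1L) {
      gap_ppm <- diff(mzs) / mzs[-length(mzs)] * 1e6
      if (any(gap_ppm <= 3 * max(spec$ppm_jitter, 1))) {
        stop("truth peak m/z values closer than 3x the ppm envelope ",
             "(flag isomers by giving them identical m/z)")
      }
    }
  }
  local_rng(spec$seed)
  n <- spec$n_scans
  rt <- (seq_len(n) - 1L) * spec$scan_rate
  pts <- list()

  emit_channel <- function(mz, expected, amplitude, support) {
    intens <- apply_channel_noise(expected, amplitude, spec$spike_rate,
                                  spec$spike_width, spec$noise_floor, n)
    keep <- support & intens > 0
    if (!any(keep)) return(NULL)
    scan <- which(keep)
    jit <- if (spec$ppm_jitter > 0) {
      stats::runif(length(scan), -spec$ppm_jitter, spec$ppm_jitter) * 1e-6
    } else 0
    data.frame(scan = scan, mz = mz * (1 + jit), intensity = intens[keep])
  }

  # the truth table reports the apex of the planted profile: for tailed
  # peaks the profile maximum sits later than the nominal Gaussian
  # center, and downstream benchmarking must match against what was
  # actually planted
  truth$rt_center <- truth$rt_apex
  truth$scan_apex <- NA_integer_
  if (nrow(truth)) {
    for (mz in unique(truth$mz)) {
      idx <- which(truth$mz == mz)
      expected <- rep(spec$baseline_level, n) +
        spec$baseline_drift * (seq_len(n) - 1L)
      support <- rep(FALSE, n)
      for (i in idx) {
        p <- truth[i, ]
        prof <- peak_profile(rt, p$rt_center, p$height, p$sigma,
                             p$tail_tau, spec$scan_rate)
        truth$scan_apex[i] <- which.max(prof)
        truth$rt_apex[i] <- rt[truth$scan_apex[i]]
        expected <- expected + prof
        half <- 4 * p$sigma + 4 * p$tail_tau
        support <- support | (rt >= p$rt_center - half & rt <= p$rt_center + half)
      }
      if (length(idx) > 1L) {
        # isomer channels (several peaks at one m/z) keep contiguous
        # baseline support between their peaks, as a real solvent
        # background would, so extraction sees one trace with several
        # apexes rather than disconnected fragments
        covered <- range(which(support))
        support[covered[1]:covered[2]] <- TRUE
      }
      pts[[length(pts) + 1L]] <-
        emit_channel(mz, expected, spec$zigzag_amplitude, support)
    }
  }

  if (spec$background_channels > 0L) {
    mz_lo <- if (nrow(truth)) max(truth$mz) + 20 else 100
    bg_mz <- mz_lo + (seq_len(spec$background_channels) - 1L) * 15 +
      stats::runif(spec$background_channels, 0, 5)
    for (ch in seq_along(bg_mz)) {
      mz <- bg_mz[ch]
      level <- spec$baseline_level * stats::runif(1, 8, 15)
      expected <- rep(level, n)
      alpha <- spec$background_zigzag
      if (ch %% 3L == 0L) {
        # every third background channel is pure zigzag noise with no
        # underlying feature: its global zigzag index sits above 1, the
        # regime the EIC-level filter exists to remove
        alpha <- max(alpha, 0.45)
      } else {
        # the rest are high-background channels with shallow bumps:
        # solvent/contaminant traces whose undulations a ridge picker
        # flags but whose relative amplitude is too small for good
        # sharpness/significance - the "bad peak" taxonomy of
        # high-background chromatograms
        n_bumps <- sample(1:3, 1L)
        for (b in seq_len(n_bumps)) {
          apex <- stats::runif(1, rt[20], rt[n - 20L])
          sg <- stats::runif(1, 4, 9) * spec$scan_rate
          f <- stats::runif(1, 0.2, 0.4)
          expected <- expected + level * f *
            exp(-(rt - apex)^2 / (2 * sg^2))
        }
      }
      pts[[length(pts) + 1L]] <-
        emit_channel(mz, expected, alpha, rep(TRUE, n))
    }
  }

  pts <- do.call(rbind, pts)
  if (is.null(pts) || nrow(pts) == 0L) stop("generated run contains no points")
  pts <- pts[order(pts$scan, pts$mz), , drop = FALSE]
  rownames(pts) <- NULL
  run <- new_lcms_run(pts, rt, spec$scan_rate)
  list(run = run, truth = truth)
}

#' Simulate three tools' peak lists from a shared truth table
#'
#' Each simulated tool reports a seeded random subset of the truth
#' (fraction = its recall), with m/z and RT perturbed uniformly within
#' the stated jitter, plus a number of false peaks. False peaks are
#' placed on a jittered grid in an m/z region above all truth peaks with
#' mutual spacing far beyond typical matching tolerances, so consensus
#' counting over the three lists is unambiguous.
#'
#' @param truth Truth table ([truth_peaks()]).
#' @param per_tool_recall Numeric length 3, recalls in \[0, 1\].
#' @param per_tool_fp Integer length 3, false peaks per tool.
#' @param mz_jitter,rt_jitter Half-width of the uniform perturbation
#'   applied to reported apexes (Daltons, seconds).
#' @param seed Integer seed.
#' @return A list of three peak-record data frames (see [peak_records()]).
#' @export
generate_toolset_peaklists <- function(truth, per_tool_recall, per_tool_fp,
                                       mz_jitter = 0.01, rt_jitter = 1,
                                       seed = 1L) {
  stopifnot(length(per_tool_recall) == 3L, length(per_tool_fp) == 3L,
            all(per_tool_recall >= 0), all(per_tool_recall <= 1))
  local_rng(seed)
  n <- nrow(truth)
  fp_base <- (if (n) max(truth$mz) else 400) + 50
  # one shared pool of well-separated false-peak sites; each tool draws
  # disjoint sites so false peaks never corroborate each other
  total_fp <- sum(per_tool_fp)
  fp_sites <- if (total_fp > 0) {
    site <- sample.int(max(4L * total_fp, 16L), total_fp)
    data.frame(mz = fp_base + site * 1.0 + stats::runif(total_fp, -0.2, 0.2),
               rt = stats::runif(total_fp, 0, 1000))
  } else data.frame(mz = numeric(0), rt = numeric(0))
  fp_at <- 0L
  out <- vector("list", 3L)
  for (t in 1:3) {
    n_keep <- round(per_tool_recall[t] * n)
    keep <- if (n_keep > 0) sort(sample.int(n, n_keep)) else integer(0)
    mz <- truth$mz[keep] + stats::runif(n_keep, -mz_jitter, mz_jitter)
    rt <- truth$rt_apex[keep] + stats::runif(n_keep, -rt_jitter, rt_jitter)
    nf <- per_tool_fp[t]
    if (nf > 0) {
      idx <- fp_at + seq_len(nf)
      mz <- c(mz, fp_sites$mz[idx])
      rt <- c(rt, fp_sites$rt[idx])
      fp_at <- fp_at + nf
    }
    out[[t]] <- peak_records(mz_apex = mz, rt_apex_s = rt,
                             source = paste0("tool", t))
  }
  out
}

#' Default synthetic benchmark: a run with 20 planted peaks plus decoys
#'
#' The standing study conditions used throughout the package's tests and
#' documentation: a 600-scan run at 1.2 s/scan carrying 20 Gaussian or
#' mildly tailed peaks (heights 500--5000, widths 3--8 scans, a quarter
#' tailed), moderate zigzag noise (5% of the local level), occasional
#' 1--3-scan spikes, 10 ppm m/z jitter, and 12 heavy-noise background
#' channels whose bumps act as plantable false positives for the quality
#' filters.
#'
#' @param seed Integer seed.
#' @return The [synthetic_spec()] describing the benchmark.
#' @export
benchmark_spec <- function(seed = 1L) {
  local_rng(seed)
  n_peaks <- 20L
  mz <- 85 + 25 * (seq_len(n_peaks) - 1L) + stats::runif(n_peaks, 0, 8)
  rt_apex <- sort(stats::runif(n_peaks, 60, 660))
  height <- stats::runif(n_peaks, 500, 5000)
  sigma <- stats::runif(n_peaks, 3, 8) * 1.2
  tail_tau <- ifelse(seq_len(n_peaks) %% 4L == 0L, 0.6 * sigma, 0)
  synthetic_spec(
    truth = truth_peaks(mz, rt_apex, height, sigma, tail_tau),
    n_scans = 600L, scan_rate = 1.2,
    baseline_level = 20, baseline_drift = 0,
    zigzag_amplitude = 0.05, spike_rate = 0.3, spike_width = 3L,
    ppm_jitter = 10, noise_floor = 5,
    background_channels = 12L, background_zigzag = 0.12,
    seed = seed + 1000L
  )
}

#' Twelve representative good and bad chromatographic peak cases
#'
#' Deterministic fixture mirroring the case taxonomy used for peak-metric
#' validation: six "good" peaks (ideal, tailed, high-baseline, apex dip,
#' mildly zigzagging, broad) and six "bad" twins (shallow high-background
#' bump, noise blob, shallow noisy dip, shallow noisy tail, heavy zigzag
#' broad bump, weak fluctuation), each as a 101-scan EIC plus a
#' hand-specified peak. Every bad case is designed to violate at least
#' one clause of the default combined filter, and the normalized
#' six-metric vectors of the two groups separate under 2-cluster
#' agglomerative clustering.
#'
#' @return A list with elements `eics` (list of 12 `EIC`s), `peaks`
#'   (12-row peak data frame, row-aligned), `label` (`"good"`/`"bad"`),
#'   and `case` (short archetype names).
#' @export
peak_case_fixtures <- function() {
  make_case <- function(id, baseline, h, sigma, tau = 0, alpha = 0,
                        dip = FALSE, seed = 0) {
    local_rng(seed)
    n <- 101L; ctr <- 51L
    x <- seq_len(n)
    g <- exp(-(x - ctr)^2 / (2 * sigma^2))
    if (tau > 0) {
      j <- 0:ceiling(6 * tau)
      kern <- exp(-j / tau); kern <- kern / sum(kern)
      out <- numeric(n)
      for (k in seq_along(kern)) {
        idx <- seq_len(n - j[k])
        out[idx + j[k]] <- out[idx + j[k]] + kern[k] * g[idx]
      }
      g <- out / max(out)
    }
    I <- baseline + h * g
    if (dip) I[(ctr - 1L):(ctr + 1L)] <- I[(ctr - 1L):(ctr + 1L)] * 0.78
    if (alpha > 0) {
      s <- (-1)^x
      u <- stats::runif(n, 0.5, 1)
      I <- pmax(I + alpha * I * s * u, 0)
    }
    e <- new_eic(id, 100 + id, 1L, n, I, rep(100 + id, n), x * 1.2)
    half <- min(ceiling(2.5 * sigma + 2 * tau), 24L)
    lo <- ctr - half; hi <- ctr + half
    p <- lo - 1L + which.max(I[lo:hi])
    list(eic = e,
         peak = data.frame(eic_id = id, p = p, scan_apex = p,
                           scan_left = lo, scan_right = hi))
  }
  specs <- list(
    ideal          = list(baseline = 10,  h = 1000, sigma = 5),
    tailed         = list(baseline = 10,  h = 800,  sigma = 4, tau = 6),
    high_baseline  = list(baseline = 500, h = 900,  sigma = 5),
    apex_dip       = list(baseline = 10,  h = 1000, sigma = 6, dip = TRUE),
    mild_zigzag    = list(baseline = 20,  h = 1200, sigma = 6, alpha = 0.06, seed = 5),
    broad          = list(baseline = 20,  h = 700,  sigma = 9),
    shallow_bg     = list(baseline = 400, h = 100,  sigma = 5, alpha = 0.10, seed = 11),
    noise_blob     = list(baseline = 50,  h = 30,   sigma = 4, alpha = 0.50, seed = 12),
    noisy_dip      = list(baseline = 120, h = 50,   sigma = 6, dip = TRUE, alpha = 0.18, seed = 13),
    noisy_tail     = list(baseline = 150, h = 60,   sigma = 3, tau = 8, alpha = 0.12, seed = 14),
    heavy_zigzag   = list(baseline = 80,  h = 100,  sigma = 8, alpha = 0.50, seed = 15),
    weak_flutter   = list(baseline = 200, h = 50,   sigma = 6, alpha = 0.15, seed = 16)
  )
  eics <- vector("list", length(specs))
  peaks <- vector("list", length(specs))
  for (i in seq_along(specs)) {
    a <- specs[[i]]
    cs <- make_case(i, a$baseline, a$h, a$sigma,
                    tau = if (is.null(a$tau)) 0 else a$tau,
                    alpha = if (is.null(a$alpha)) 0 else a$alpha,
                    dip = isTRUE(a$dip),
                    seed = if (is.null(a$seed)) 0 else a$seed)
    eics[[i]] <- cs$eic
    peaks[[i]] <- cs$peak
  }
  list(eics = eics,
       peaks = do.call(rbind, c(peaks, list(make.row.names = FALSE))),
       label = rep(c("good", "bad"), each = 6L),
       case = names(specs))
}
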