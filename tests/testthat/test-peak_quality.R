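# The six peak-level quality metrics, the combined filter, and the
# good/bad case taxonomy.

test_that("sharpness evaluates its defining sum exactly", {
  expect_equal(sharpness(c(1, 2, 4, 2, 1), p = 3), 4)
  expect_equal(sharpness(rep(7, 5), p = 3), 0)
  # a taller apex at equal width strictly increases sharpness
  lo <- gauss_series(21, ctr = 11, sigma = 3, h = 100, baseline = 10)
  hi <- gauss_series(21, ctr = 11, sigma = 3, h = 300, baseline = 10)
  expect_gt(sharpness(hi, 11), sharpness(lo, 11))
  # zero denominators are handled by the eps offset, not NaN/Inf
  expect_true(is.finite(sharpness(c(0, 2, 4, 2, 0), p = 3)))
  expect_error(sharpness(c(1, 2), p = 1), "3 points")
})

test_that("Gaussian similarity is ~1 for a pure Gaussian, lower for tails", {
  g <- gauss_series(41, ctr = 21, sigma = 5, h = 1000, baseline = 20)
  expect_gte(gaussian_similarity(g, 21), 0.999)
  # tailed twin scores strictly lower
  x <- seq_len(41)
  tail_kern <- exp(-(0:24) / 5) / sum(exp(-(0:24) / 5))
  tailed <- numeric(41)
  for (k in seq_along(tail_kern)) {
    idx <- seq_len(41 - k + 1)
    tailed[idx + k - 1] <- tailed[idx + k - 1] + tail_kern[k] * (g[idx] - 20)
  }
  tailed <- tailed / max(tailed) * 1000 + 20
  expect_lt(gaussian_similarity(tailed, which.max(tailed)),
            gaussian_similarity(g, 21))
  expect_error(gaussian_similarity(rep(5, 10), 5),
               class = "chromqc_fit_failure")
})

test_that("CWT SNR is high for clean peaks and falls with scale-1 noise", {
  base <- gauss_series(121, ctr = 61, sigma = 5, h = 1000, baseline = 10)
  pk <- data.frame(eic_id = 1L, p = 61L, scan_apex = 61L,
                   scan_left = 45L, scan_right = 77L,
                   ridge_scale = NA_real_)
  expect_gte(peak_snr(series_eic(base), pk), 20)
  snrs <- vapply(c(0.05, 0.2, 0.5), function(a) {
    I <- pmax(base + alt_noise(121, a, 200, seed = 23), 0)
    peak_snr(series_eic(I), pk)
  }, numeric(1))
  expect_true(all(diff(snrs) < 0))
})

test_that("peak significance follows its window definition", {
  expect_equal(peak_significance(c(1, 1, 5, 1, 1), p = 3,
                                 apex_halfwin = 1, edge_count = 1),
               (7 / 3) / 1)
  expect_equal(peak_significance(rep(4, 9), p = 5), 1)
  expect_identical(peak_significance(c(0, 0, 5, 0, 0), p = 3,
                                     apex_halfwin = 1, edge_count = 2), Inf)
  expect_error(peak_significance(c(1, 2, 1), p = 2, edge_count = 2), "short")
})

test_that("TPASR matches the triangle-area identity", {
  expect_equal(tpasr(c(0, 2, 4, 2, 0)), 0)
  expect_equal(tpasr(c(0, 0, 4, 0, 0)), 0.5)
  expect_error(tpasr(rep(0, 5)), "zero apex")
})

test_that("local zigzag matches the global computation on slices", {
  expect_equal(local_zigzag_index(c(0, 1, 2, 1, 0)), 0.2)
  g <- gauss_series(31, ctr = 16, sigma = 5, h = 1000)
  expect_lt(local_zigzag_index(g), 0.05)
})

test_that("score_peak assembles regimes for archetypal fixtures", {
  cfg <- pipeline_config()
  # noiseless Gaussian: every metric in its good regime
  g <- gauss_series(61, ctr = 31, sigma = 5, h = 1000, baseline = 10)
  e <- series_eic(g)
  pk <- data.frame(eic_id = 1L, p = 31L, scan_apex = 31L,
                   scan_left = 18L, scan_right = 44L)
  r <- score_peak(e, pk, cfg)
  expect_gt(r$sharpness, 2)
  expect_gt(r$gaussian_similarity, 0.95)
  expect_gt(r$snr, 1.3)
  expect_gt(r$peak_significance, 1.2)
  expect_lt(r$tpasr, 0.8)
  expect_lt(r$local_zigzag, 0.9)
  # pure zigzag noise blob: zigzag flags it
  I <- pmax(rep(100, 61) + alt_noise(61, 0.6, 100, seed = 31), 0)
  rz <- score_peak(series_eic(I), pk, cfg)
  expect_gt(rz$local_zigzag, 0.9)
  # tailed peak: gaussian similarity drops, zigzag stays low
  sp <- synthetic_spec(truth_peaks(200, 36, 1000, 4.8, tail_tau = 7),
                       n_scans = 80, zigzag_amplitude = 0, spike_rate = 0,
                       baseline_level = 10, noise_floor = 0, seed = 2)
  It <- generate_eic(sp)$intensities
  et <- series_eic(It)
  pt <- detect_peaks(et)
  expect_equal(nrow(pt), 1)
  rt_ <- score_peak(et, pt, cfg)
  expect_lt(rt_$gaussian_similarity, r$gaussian_similarity)
  expect_lt(rt_$local_zigzag, 0.1)
})

test_that("the combined filter keeps the 6 good and drops the 6 bad cases", {
  fx <- peak_case_fixtures()
  rep <- do.call(rbind, lapply(1:12, function(i) {
    score_peak(fx$eics[[i]], fx$peaks[i, ])
  }))
  kept <- filter_peaks(rep)
  expect_identical(kept, fx$label == "good")
})

test_that("disabling thresholds keeps everything; tightening never grows the keep-set", {
  fx <- peak_case_fixtures()
  rep <- do.call(rbind, lapply(1:12, function(i) {
    score_peak(fx$eics[[i]], fx$peaks[i, ])
  }))
  all_na <- filter_peaks(rep, NA, NA, NA, NA, NA, NA)
  expect_true(all(all_na))
  loose <- filter_peaks(rep, sharpness_min = 1)
  tight <- filter_peaks(rep, sharpness_min = 5)
  expect_true(all(which(tight) %in% which(loose)))
})

test_that("normalized six-metric vectors cluster good apart from bad", {
  fx <- peak_case_fixtures()
  rep <- do.call(rbind, lapply(1:12, function(i) {
    score_peak(fx$eics[[i]], fx$peaks[i, ])
  }))
  m <- normalize_metrics(rep)
  expect_true(all(abs(m) <= 1 + 1e-12))
  cl <- stats::cutree(stats::hclust(stats::dist(m), method = "complete"),
                      k = 2)
  expect_length(unique(cl[fx$label == "good"]), 1)
  expect_length(unique(cl[fx$label == "bad"]), 1)
  expect_false(cl[1] == cl[12])
})

test_that("good peaks outrank bad on sharpness/significance/zigzag", {
  good <- lapply(1:40, function(s) draw_case_report("good", seed = s))
  bad <- lapply(1:40, function(s) draw_case_report("bad", seed = 1000 + s))
  good <- do.call(rbind, good)
  bad <- do.call(rbind, bad)
  grid <- expand.grid(g = seq_len(nrow(good)), b = seq_len(nrow(bad)))
  frac <- function(x) mean(x)
  expect_gte(frac(good$sharpness[grid$g] > bad$sharpness[grid$b]), 0.95)
  expect_gte(frac(good$peak_significance[grid$g] >
                    bad$peak_significance[grid$b]), 0.95)
  expect_gte(frac(good$local_zigzag[grid$g] < bad$local_zigzag[grid$b]), 0.95)
})

test_that("sharpness, significance and SNR are positively rank-correlated", {
  reports <- do.call(rbind, c(
    lapply(1:60, function(s) draw_case_report("good", seed = 2000 + s)),
    lapply(1:60, function(s) draw_case_report("bad", seed = 3000 + s))
  ))
  expect_gt(stats::cor(reports$sharpness, reports$peak_significance,
                       method = "spearman"), 0)
  expect_gt(stats::cor(reports$sharpness, reports$snr,
                       method = "spearman"), 0)
  expect_gt(stats::cor(reports$peak_significance, reports$snr,
                       method = "spearman"), 0)
})
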