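# CWT transform, ridge linking, and peak detection.

test_that("CWT coefficient matrix peaks at the right scale and position", {
  I <- gauss_series(121, ctr = 61, sigma = 4, h = 1000)
  co <- cwt_transform(I, 1:16)
  # brute-force argmax over the whole matrix
  idx <- which(co == max(co), arr.ind = TRUE)
  expect_equal(unname(idx[1, 2]), 61, tolerance = 1)
  best_scale <- attr(co, "scales")[idx[1, 1]]
  # response maximum tracks the peak width (between sigma and 3 sigma)
  expect_gte(best_scale, 4)
  expect_lte(best_scale, 12)
})

test_that("CWT of degenerate series behaves as expected", {
  expect_true(all(cwt_transform(rep(0, 50), 1:8) == 0))
  # Ricker has two vanishing moments: a linear ramp gives ~zero response
  # away from the padded edges (compare: a peak of the same magnitude
  # responds with coefficients in the hundreds)
  ramp <- seq(0, 100, length.out = 80)
  co <- cwt_transform(ramp, c(2, 4))
  interior <- co[, 25:55]
  expect_lt(max(abs(interior)), 0.01)
  expect_error(cwt_transform(1:10, numeric(0)), "empty")
})

test_that("ridge lines track peaks and ignore seeded noise", {
  one <- gauss_series(121, ctr = 61, sigma = 5, h = 1000)
  r1 <- find_ridge_lines(cwt_transform(one, 1:16))
  pos_ok <- vapply(r1, function(r) abs(r$best_position - 61) <= 3 &&
                     r$best_coeff > 0, logical(1))
  expect_equal(sum(pos_ok), 1)
  two <- gauss_series(121, ctr = 41, sigma = 5, h = 1000) +
    gauss_series(121, ctr = 81, sigma = 5, h = 800)
  r2 <- find_ridge_lines(cwt_transform(two, 1:16))
  pos <- vapply(r2[vapply(r2, function(r) r$best_coeff > 0, logical(1))],
                function(r) r$best_position, numeric(1))
  expect_true(any(abs(pos - 41) <= 3))
  expect_true(any(abs(pos - 81) <= 3))
  # pure iid noise: the detector accepts at most stray candidates,
  # while a real peak of the same span is always found
  noise_peaks <- vapply(1:50, function(s) {
    I <- withr::with_seed(s, stats::runif(100, 5, 15))
    nrow(detect_peaks(series_eic(I)))
  }, numeric(1))
  expect_gte(mean(noise_peaks == 0), 0.5)
  expect_lte(max(noise_peaks), 3)
})

test_that("a single synthetic Gaussian peak is detected at its apex", {
  sp <- synthetic_spec(truth_peaks(200, 60, 1000, 5), n_scans = 100,
                       zigzag_amplitude = 0, spike_rate = 0,
                       baseline_level = 5, noise_floor = 0, seed = 1)
  I <- generate_eic(sp)$intensities
  e <- series_eic(I)
  pk <- detect_peaks(e)
  expect_equal(nrow(pk), 1)
  truth_scan <- which.max(I)   # noiseless: the argmax is the apex
  expect_lte(abs(pk$scan_apex - truth_scan), 1)
  expect_equal(pk$p, pk$scan_apex - e$scan_first + 1)
})

test_that("isomer pair in one EIC yields two peaks with disjoint slices", {
  sp <- synthetic_spec(truth_peaks(c(300, 300), c(120, 220), c(1000, 1500),
                                   c(5, 6)),
                       n_scans = 300, zigzag_amplitude = 0.03,
                       spike_rate = 0, seed = 8)
  out <- generate_run(sp)
  eics <- extract_eics(out$run, 40, 5, 2)
  expect_length(eics, 1)
  pk <- detect_peaks(eics[[1]])
  expect_equal(nrow(pk), 2)
  expect_lt(pk$scan_right[1], pk$scan_left[2])
  for (i in seq_len(nrow(pk))) {
    expect_lte(abs(out$run$rt[pk$scan_apex[i]] - out$truth$rt_apex[i]), 5)
  }
})

test_that("short spikes are not reported as peaks", {
  I <- rep(10, 60)
  I[30] <- 800
  expect_equal(nrow(detect_peaks(series_eic(I))), 0)
  I2 <- rep(10, 60)
  I2[30:32] <- c(700, 900, 650)
  expect_equal(nrow(detect_peaks(series_eic(I2))), 0)
})

test_that("detection is invariant under intensity scaling", {
  sp <- synthetic_spec(truth_peaks(200, 60, 1200, 5), n_scans = 100,
                       zigzag_amplitude = 0.05, spike_rate = 0, seed = 13)
  I <- generate_eic(sp)$intensities
  a <- detect_peaks(series_eic(I))
  b <- detect_peaks(series_eic(I * 37.5))
  expect_equal(a[c("p", "scan_apex", "scan_left", "scan_right")],
               b[c("p", "scan_apex", "scan_left", "scan_right")])
})

test_that("noiseless in-range peaks are always recovered", {
  withr::with_seed(17, {
    for (k in 1:8) {
      sigma_scans <- stats::runif(1, 2.2, 7)
      ctr_s <- stats::runif(1, 50, 90)
      sp <- synthetic_spec(truth_peaks(250, ctr_s, 2000, sigma_scans * 1.2),
                           n_scans = 120, zigzag_amplitude = 0,
                           spike_rate = 0, baseline_level = 5,
                           noise_floor = 0, seed = k)
      I <- generate_eic(sp)$intensities
      pk <- detect_peaks(series_eic(I))
      expect_gte(nrow(pk), 1)
      truth_scan <- which.max(I)   # noiseless: the argmax is the apex
      expect_lte(min(abs(pk$scan_apex - truth_scan)), 1)
    }
  })
})

test_that("detected slices within an EIC never overlap", {
  for (seed in 1:5) {
    sp <- synthetic_spec(truth_peaks(c(300, 300, 300), c(80, 180, 280),
                                     c(900, 1400, 700), c(5, 6, 4)),
                         n_scans = 320, zigzag_amplitude = 0.08,
                         spike_rate = 1, seed = seed)
    I <- generate_eic(sp)$intensities
    pk <- detect_peaks(series_eic(I))
    if (nrow(pk) > 1) {
      expect_true(all(diff(pk$scan_apex) > 0))
      expect_true(all(pk$scan_left[-1] > pk$scan_right[-nrow(pk)]))
    }
    expect_true(all(pk$scan_left <= pk$scan_apex))
    expect_true(all(pk$scan_apex <= pk$scan_right))
    w <- pk$scan_right - pk$scan_left + 1
    expect_true(all(w >= 5 & w <= 50))
  }
})
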