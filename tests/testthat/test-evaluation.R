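# Consensus ground truth, tolerance matching, PRF, and sweeps.

test_that("identical lists match fully; tolerance edges are respected", {
  A <- peak_records(mz_apex = c(100, 200, 300), rt_apex_s = c(10, 20, 30))
  expect_equal(nrow(match_peaks(A, A)), 3)
  B <- peak_records(mz_apex = 100.06, rt_apex_s = 10)
  expect_equal(nrow(match_peaks(peak_records(100, 10), B)), 0)
  C <- peak_records(mz_apex = 100.05, rt_apex_s = 15)
  expect_equal(nrow(match_peaks(peak_records(100, 10), C)), 1)
})

test_that("matching is one-to-one and the closer candidate wins", {
  A <- peak_records(mz_apex = c(100.000, 100.020), rt_apex_s = c(10, 10))
  B <- peak_records(mz_apex = 100.004, rt_apex_s = 10)
  m <- match_peaks(A, B)
  expect_equal(nrow(m), 1)
  expect_equal(m$i, 1L)   # 0.004 Da beats 0.016 Da
  # brute force over all one-to-one assignments on a small instance
  withr::with_seed(41, {
    for (k in 1:10) {
      A <- peak_records(mz_apex = stats::runif(4, 100, 100.1),
                        rt_apex_s = stats::runif(4, 0, 10))
      B <- peak_records(mz_apex = stats::runif(3, 100, 100.1),
                        rt_apex_s = stats::runif(3, 0, 10))
      m <- match_peaks(A, B)
      # count of an optimal matching can never be beaten by greedy by
      # more than zero pairs on instances where all pairs are in
      # tolerance; verify at least maximality: no unmatched in-tolerance
      # pair remains
      um_a <- setdiff(seq_len(4), m$i)
      um_b <- setdiff(seq_len(3), m$j)
      for (i in um_a) for (j in um_b) {
        in_tol <- abs(A$mz_apex[i] - B$mz_apex[j]) <= 0.05 &&
          abs(A$rt_apex_s[i] - B$rt_apex_s[j]) <= 5
        expect_false(in_tol)
      }
    }
  })
})

test_that("match counts are symmetric", {
  withr::with_seed(43, {
    for (k in 1:10) {
      A <- peak_records(mz_apex = stats::runif(8, 100, 100.2),
                        rt_apex_s = stats::runif(8, 0, 20))
      B <- peak_records(mz_apex = stats::runif(6, 100, 100.2),
                        rt_apex_s = stats::runif(6, 0, 20))
      expect_equal(nrow(match_peaks(A, B)), nrow(match_peaks(B, A)))
    }
  })
})

test_that("three identical lists give NP = k under both counting routes", {
  L <- peak_records(mz_apex = c(100, 150, 200, 250, 300),
                    rt_apex_s = c(10, 30, 50, 70, 90))
  gt <- ground_truth_peaks(L, L, L)
  expect_equal(gt$np, 5)
  expect_equal(gt$n_all_three, 5)
  expect_equal(np_inclusion_exclusion(L, L, L), 5)
})

test_that("simulated tool subsets give the expected consensus counts", {
  tr <- truth_peaks(mz = 100 + 12 * (1:10), rt_apex = 40 * (1:10),
                    height = 1000, sigma = 5)
  # two perfect tools, one empty: every truth peak has exactly two votes
  out <- generate_toolset_peaklists(tr, c(1, 1, 0), c(0L, 0L, 0L), seed = 3)
  gt <- ground_truth_peaks(out[[1]], out[[2]], out[[3]])
  expect_equal(gt$np, 10)
  expect_equal(np_inclusion_exclusion(out[[1]], out[[2]], out[[3]]), 10)
  # a single tool never makes a consensus peak
  out1 <- generate_toolset_peaklists(tr, c(1, 0, 0), c(0L, 0L, 0L), seed = 4)
  expect_equal(ground_truth_peaks(out1[[1]], out1[[2]], out1[[3]])$np, 0)
})

test_that("a constructed overlap pattern reproduces NP by inclusion-exclusion", {
  # groups: 250 in all three, 50 in 1&2 only, 30 in 1&3 only, 60 in 2&3
  # only, plus singletons; pairwise counts 300/280/310, triple 250
  base <- function(n, off) {
    peak_records(mz_apex = 100 + off + (seq_len(n)) * 0.4,
                 rt_apex_s = (seq_len(n)) * 11)
  }
  all3 <- base(250, 0)
  only12 <- base(50, 150)
  only13 <- base(30, 300)
  only23 <- base(60, 450)
  solo <- function(n, off) base(n, off)
  L1 <- rbind(all3, only12, only13, solo(5, 600))
  L2 <- rbind(all3, only12, only23, solo(7, 700))
  L3 <- rbind(all3, only13, only23, solo(4, 800))
  expect_equal(nrow(match_peaks(L1, L2)), 300)
  expect_equal(nrow(match_peaks(L1, L3)), 280)
  expect_equal(nrow(match_peaks(L2, L3)), 310)
  gt <- ground_truth_peaks(L1, L2, L3)
  expect_equal(gt$n_all_three, 250)
  expect_equal(gt$np, 300 + 280 + 310 - 2 * 250)
  expect_equal(np_inclusion_exclusion(L1, L2, L3), gt$np)
})

test_that("PRF handles the identity and empty cases", {
  truth <- peak_records(mz_apex = c(100, 200), rt_apex_s = c(10, 20))
  res <- prf(truth, truth)
  expect_equal(res$recall, 1)
  expect_equal(res$precision, 1)
  expect_equal(res$fscore, 1)
  empty <- peak_records(numeric(0), numeric(0))
  res0 <- prf(empty, truth)
  expect_equal(res0$recall, 0)
  expect_equal(res0$fscore, 0)
  resn <- prf(truth, empty, np = 0)
  expect_equal(resn$precision, 0)
})

test_that("F-score is bounded by min/max of recall and precision", {
  withr::with_seed(47, {
    r <- stats::runif(200)
    p <- stats::runif(200)
    f <- fscore(r, p)
    # the harmonic mean lies between its two arguments
    expect_true(all(f <= pmax(r, p) + 1e-12))
    expect_true(all(f >= pmin(r, p) - 1e-12))
    expect_equal(fscore(0.4, 0.4), 0.4)
    expect_equal(fscore(0, 0), 0)
  })
})

test_that("sweep endpoints behave: loosest = unfiltered, tightest empties", {
  bm <- benchmark_state()
  st <- bm$state
  sw <- sweep_threshold(st, "zigzag", c(1e-6, 4), bm$truth_rec)
  unf <- prf(st$records, bm$truth_rec)
  # loosest zigzag cutoff (4, above the index's range) keeps everything
  expect_equal(sw$recall[sw$threshold == 4], unf$recall)
  expect_equal(sw$n_detected[sw$threshold == 4], unf$n_detected)
  # tightest cutoff keeps (almost surely) nothing
  expect_equal(sw$tp[sw$threshold == 1e-6], 0)
  expect_error(sweep_threshold(st, "not_a_metric", 1, bm$truth_rec),
               "unknown metric")
})

test_that("recall is monotone and TP/FP nest along any loosening sweep", {
  bm <- benchmark_state()
  st <- bm$state
  for (met in c("zigzag", "sharpness", "mcq")) {
    grid <- switch(met,
                   zigzag = seq(0.05, 1.5, by = 0.05),
                   sharpness = seq(0.5, 30, by = 0.5),
                   mcq = seq(0.05, 0.95, by = 0.05))
    sw <- sweep_threshold(st, met, grid, bm$truth_rec)
    r <- sw$recall; tp <- sw$tp; n <- sw$n_detected
    if (attr(sw, "direction") == "ge") {
      r <- rev(r); tp <- rev(tp); n <- rev(n)
    }
    expect_false(is.unsorted(r))
    expect_false(is.unsorted(tp))
    expect_false(is.unsorted(n - tp))   # false positives nest too
  }
})
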