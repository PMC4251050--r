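# Fixture builders shared across test files. Everything is generated in
# code; no binary fixtures.

# Gaussian peak series on an integer scan grid.
gauss_series <- function(n = 61, ctr = (n + 1) / 2, sigma = 5, h = 1000,
                         baseline = 0) {
  x <- seq_len(n)
  baseline + h * exp(-(x - ctr)^2 / (2 * sigma^2))
}

# A standalone EIC wrapping a series (scan_rate 1.2 s).
series_eic <- function(I, eic_id = 1L, mz = 200) {
  n <- length(I)
  new_eic(eic_id, mz, 1L, n, I, rep(mz, n), seq_len(n) * 1.2)
}

# Strictly alternating zigzag noise, reproducible.
alt_noise <- function(n, amplitude, level, seed) {
  withr::with_seed(seed, {
    s <- (-1)^(seq_len(n) + sample(0:1, 1))
    u <- stats::runif(n, 0.5, 1)
    amplitude * level * s * u
  })
}

# One "good" (clean Gaussian) or "bad" (shallow noisy bump) peak case;
# returns its six-metric report.
draw_case_report <- function(kind = c("good", "bad"), seed) {
  kind <- match.arg(kind)
  withr::with_seed(seed, {
    n <- 81L; ctr <- 41L
    sigma <- stats::runif(1, 4, 7)
    if (kind == "good") {
      baseline <- stats::runif(1, 5, 30)
      h <- stats::runif(1, 500, 3000)
      alpha <- stats::runif(1, 0.02, 0.08)
    } else {
      baseline <- stats::runif(1, 150, 400)
      h <- baseline * stats::runif(1, 0.2, 0.45)
      alpha <- stats::runif(1, 0.10, 0.20)
    }
    I <- gauss_series(n, ctr, sigma, h, baseline)
    s <- (-1)^(seq_len(n) + sample(0:1, 1))
    u <- stats::runif(n, 0.5, 1)
    I <- pmax(I + alpha * I * s * u, 0)
    e <- series_eic(I, eic_id = 1L)
    half <- min(ceiling(2.5 * sigma), 24L)
    lo <- ctr - half; hi <- ctr + half
    p <- lo - 1L + which.max(I[lo:hi])
    pk <- data.frame(eic_id = 1L, p = p, scan_apex = p,
                     scan_left = lo, scan_right = hi)
    score_peak(e, pk)
  })
}

# Rewrite an mzML file's scan start times from seconds to minutes
# (declared unit included), producing a unit-conversion fixture.
mzml_in_minutes <- function(path_in, path_out) {
  doc <- xml2::read_xml(path_in)
  ns <- xml2::xml_ns_rename(xml2::xml_ns(doc), d1 = "m")
  nodes <- xml2::xml_find_all(doc, "//m:cvParam[@accession='MS:1000016']", ns)
  vals <- as.numeric(xml2::xml_attr(nodes, "value"))
  xml2::xml_attr(nodes, "value") <- format(vals / 60, digits = 12)
  xml2::xml_attr(nodes, "unitAccession") <- "UO:0000031"
  xml2::xml_attr(nodes, "unitName") <- "minute"
  xml2::write_xml(doc, path_out)
  path_out
}

# Pipeline state + truth for the default synthetic benchmark (cached per
# session; building it costs a couple of seconds).
benchmark_state <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) {
      spec <- benchmark_spec(seed = 1)
      sim <- generate_run(spec)
      res <- run_pipeline(sim$run, pipeline_config(),
                          eic_filter = FALSE, peak_filter = FALSE,
                          keep_state = TRUE)
      cache <<- list(spec = spec, run = sim$run, truth = sim$truth,
                     state = res$state,
                     truth_rec = peak_records(sim$truth$mz,
                                              sim$truth$rt_apex,
                                              source = "truth"))
    }
    cache
  }
})
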