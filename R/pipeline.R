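# Four-stage pipeline orchestration: acute EIC extraction -> EIC quality
# evaluation and filtering -> CWT peak detection -> peak quality
# evaluation and filtering.

#' Run the full EIC/peak quality pipeline
#'
#' @param input An `LCMSRun`, a `synthetic_spec` (simulated on the fly),
#'   or a path to a centroided mzML file.
#' @param config A [pipeline_config()].
#' @param eic_filter,peak_filter Logical switches for the two filtering
#'   stages (both on by default; disabling one passes everything
#'   through).
#' @param keep_state Also return the full intermediate state (EICs,
#'   reports, unfiltered peaks) for sweeps and diagnostics.
#' @param verbose Print one structured line per stage.
#' @return A list of class `chromqc_pipeline`:
#'   \describe{
#'     \item{peaks}{kept peak records with their six metric columns}
#'     \item{record}{per-stage counts, config snapshot, seed}
#'     \item{state}{(if `keep_state`) `run`, `eics`, `eic_reports`,
#'       `kept_eics`, `peaks_all`, `peak_reports`, `records` (unfiltered
#'       detected peak records, row-aligned with `peak_reports`)}
#'   }
#' @export
run_pipeline <- function(input, config = pipeline_config(),
                         eic_filter = TRUE, peak_filter = TRUE,
                         keep_state = FALSE, verbose = FALSE) {
  say <- function(...) if (verbose) message(sprintf(...))
  run <- if (inherits(input, "LCMSRun")) {
    input
  } else if (inherits(input, "synthetic_spec")) {
    generate_run(input)$run
  } else if (is.character(input) && length(input) == 1L) {
    read_mzml_centroid(input)
  } else {
    stop("input must be an LCMSRun, a synthetic_spec, or an mzML path")
  }
  n_points <- nrow(run$points)
  say("stage=input points=%d scans=%d", n_points, length(run$rt))

  eics <- extract_eics(run, config$ppm_tolerance, config$min_trace_points,
                       config$max_gap)
  say("stage=extract eics=%d", length(eics))

  eic_reports <- score_eics(eics, config$smooth_window)
  kept_eics <- if (eic_filter) {
    filter_eics(eics, eic_reports, config$eic_mcq_min,
                config$eic_zigzag_max, config$eic_filter_mode)
  } else {
    eics
  }
  say("stage=qc-eic kept=%d of %d", length(kept_eics), length(eics))

  peaks_all <- do.call(rbind, c(
    lapply(kept_eics, function(e) {
      detect_peaks(e, config$scales, config$snr_floor, config$min_width,
                   config$max_width, config$smooth_window)
    }),
    list(make.row.names = FALSE)))
  if (is.null(peaks_all)) {
    peaks_all <- detect_peaks(new_eic(0L, 1, 1L, 5L, c(0, 1, 0, 1, 0),
                                      rep(NA_real_, 5), 1:5))[0, ]
  }
  say("stage=detect peaks=%d", nrow(peaks_all))

  peak_reports <- score_peaks(kept_eics, peaks_all, config)
  keep <- if (peak_filter && nrow(peak_reports)) {
    filter_peaks(peak_reports, config$sharpness_min, config$gauss_min,
                 config$snr_min, config$signif_min, config$tpasr_max,
                 config$zigzag_max)
  } else {
    rep(TRUE, nrow(peak_reports))
  }
  say("stage=qc-peaks kept=%d of %d", sum(keep), nrow(peak_reports))

  records <- peak_table_to_records(peaks_all, source = "chromqc")
  kept_records <- records[keep, , drop = FALSE]
  kept_metrics <- peak_reports[keep, setdiff(names(peak_reports),
                                             c("eic_id", "scan_apex")),
                               drop = FALSE]
  peaks_out <- cbind(kept_records, kept_metrics)
  rownames(peaks_out) <- NULL

  record <- list(
    config = config,
    seed = config$seed,
    counts = c(points = n_points,
               eics_extracted = length(eics),
               eics_kept = length(kept_eics),
               peaks_detected = nrow(peaks_all),
               peaks_kept = sum(keep)),
    timestamp = Sys.time()
  )
  out <- list(peaks = peaks_out, record = record)
  if (keep_state) {
    out$state <- list(run = run, eics = eics, eic_reports = eic_reports,
                      kept_eics = kept_eics, peaks_all = peaks_all,
                      peak_reports = peak_reports, records = records)
  }
  class(out) <- "chromqc_pipeline"
  out
}

#' Convert a detected peak table to peak records
#'
#' @param peaks Data frame from [detect_peaks()].
#' @param source Source label.
#' @return A peak-record data frame ([peak_records()]).
#' @export
peak_table_to_records <- function(peaks, source = "chromqc") {
  peak_records(
    mz_apex = peaks$mz_apex, rt_apex_s = peaks$rt_apex_s,
    eic_id = peaks$eic_id, scan_apex = peaks$scan_apex,
    scan_left = peaks$scan_left, scan_right = peaks$scan_right,
    source = source
  )
}

#' @export
print.chromqc_pipeline <- function(x, ...) {
  cat("<chromqc pipeline run>\n")
  cnt <- x$record$counts
  cat(sprintf("  points          %d\n", cnt[["points"]]))
  cat(sprintf("  EICs extracted  %d (kept %d)\n",
              cnt[["eics_extracted"]], cnt[["eics_kept"]]))
  cat(sprintf("  peaks detected  %d (kept %d)\n",
              cnt[["peaks_detected"]], cnt[["peaks_kept"]]))
  invisible(x)
}
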