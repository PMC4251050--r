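# Pipeline configuration: one flat list of tunables shared by all stages.

#' Pipeline configuration
#'
#' Collects every tunable of the four-stage pipeline (extraction, EIC
#' filtering, peak detection, peak filtering) plus benchmark matching
#' tolerances. Defaults follow common practice for UPLC/Q-TOF centroid
#' data: 40 ppm mass-trace tolerance, peak widths of 5--50 scans, 0.05 Da
#' / 5 s peak-matching tolerances, and the combined peak-filter thresholds
#' sharpness >= 2.0, Gaussian similarity >= 0.6, SNR >= 1.3, peak
#' significance >= 1.2, TPASR <= 0.8, local zigzag <= 0.9 (EIC zigzag
#' < 0.9).
#'
#' @param ppm_tolerance Mass-trace extension tolerance (parts per million).
#' @param min_trace_points Minimum nonzero points for a mass trace to
#'   become an EIC.
#' @param max_gap Maximum consecutive empty scans before a trace is closed.
#' @param smooth_window Odd moving-average window (scans) used by the
#'   spike/MCQ indices and by peak boundary placement.
#' @param eic_mcq_min,eic_zigzag_max,eic_filter_mode EIC filter settings
#'   (see [filter_eics()]).
#' @param scales Integer CWT scale grid (scans).
#' @param min_width,max_width Accepted peak widths (scans, inclusive).
#' @param snr_floor Detection-stage CWT signal-to-noise floor.
#' @param sharpness_min,gauss_min,snr_min,signif_min,tpasr_max,zigzag_max
#'   Combined peak-filter thresholds (see [filter_peaks()]); set to `NA`
#'   to disable a clause.
#' @param mz_tol,rt_tol Peak matching tolerances (Daltons, seconds).
#' @param seed Integer seed for any stochastic stage.
#' @return A list of class `chromqc_config`.
#' @export
pipeline_config <- function(ppm_tolerance = 40,
                            min_trace_points = 5L,
                            max_gap = 2L,
                            smooth_window = 5L,
                            eic_mcq_min = 0.6,
                            eic_zigzag_max = 0.9,
                            eic_filter_mode = "zigzag",
                            scales = 1:16,
                            min_width = 5L,
                            max_width = 50L,
                            snr_floor = 1,
                            sharpness_min = 2.0,
                            gauss_min = 0.6,
                            snr_min = 1.3,
                            signif_min = 1.2,
                            tpasr_max = 0.8,
                            zigzag_max = 0.9,
                            mz_tol = 0.05,
                            rt_tol = 5,
                            seed = 1L) {
  stopifnot(ppm_tolerance > 0, mz_tol > 0, rt_tol > 0,
            min_trace_points >= 1, max_gap >= 0,
            min_width >= 2, max_width >= min_width,
            length(scales) >= 1, all(scales > 0))
  structure(list(
    ppm_tolerance = ppm_tolerance,
    min_trace_points = as.integer(min_trace_points),
    max_gap = as.integer(max_gap),
    smooth_window = as.integer(smooth_window),
    eic_mcq_min = eic_mcq_min,
    eic_zigzag_max = eic_zigzag_max,
    eic_filter_mode = eic_filter_mode,
    scales = as.integer(scales),
    min_width = as.integer(min_width),
    max_width = as.integer(max_width),
    snr_floor = snr_floor,
    sharpness_min = sharpness_min,
    gauss_min = gauss_min,
    snr_min = snr_min,
    signif_min = signif_min,
    tpasr_max = tpasr_max,
    zigzag_max = zigzag_max,
    mz_tol = mz_tol,
    rt_tol = rt_tol,
    seed = as.integer(seed)
  ), class = "chromqc_config")
}

#' Read a pipeline configuration from a flat key = value file
#'
#' Lines of the form `key = value` (or `key: value`); `#` starts a
#' comment. Keys mirror the arguments of [pipeline_config()]; `scales`
#' may be given as `1:16` or a comma-separated list.
#'
#' @param path File path.
#' @return A `chromqc_config` list.
#' @export
read_config <- function(path) {
  if (!file.exists(path)) stop("config file not found: ", path)
  lines <- readLines(path, warn = FALSE)
  lines <- sub("#.*$", "", lines)
  lines <- trimws(lines)
  lines <- lines[nzchar(lines)]
  kv <- regmatches(lines, regexec("^([A-Za-z_][A-Za-z0-9_]*)\\s*[=:]\\s*(.+)$", lines))
  bad <- lengths(kv) != 3L
  if (any(bad)) stop("unparseable config line(s): ", paste(lines[bad], collapse = "; "))
  keys <- vapply(kv, `[`, "", 2L)
  vals <- vapply(kv, `[`, "", 3L)
  args <- list()
  for (i in seq_along(keys)) {
    v <- trimws(vals[i])
    args[[keys[i]]] <-
      if (grepl("^-?[0-9.]+:[0-9.]+$", v)) {
        rng <- as.numeric(strsplit(v, ":", fixed = TRUE)[[1]])
        seq(rng[1], rng[2])
      } else if (grepl(",", v, fixed = TRUE)) {
        as.numeric(strsplit(v, ",", fixed = TRUE)[[1]])
      } else if (v %in% c("zigzag", "mcq", "either")) {
        v
      } else {
        num <- suppressWarnings(as.numeric(v))
        if (is.na(num)) stop("non-numeric value for config key ", keys[i])
        num
      }
  }
  unknown <- setdiff(names(args), names(formals(pipeline_config)))
  if (length(unknown)) stop("unknown config key(s): ", paste(unknown, collapse = ", "))
  do.call(pipeline_config, args)
}

#' @export
print.chromqc_config <- function(x, ...) {
  cat("<chromqc pipeline configuration>\n")
  for (k in names(x)) {
    v <- x[[k]]
    if (k == "scales") v <- paste0(min(v), ":", max(v))
    cat(sprintf("  %-18s %s\n", k, paste(format(v), collapse = " ")))
  }
  invisible(x)
}
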