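# Reading and writing the pipeline's external formats: centroided mzML
# runs (via mzR), CSV peak lists, and CSV EIC tables.

#' LCMSRun container
#'
#' An ordered collection of centroided MS1 scans. `points` is one data
#' frame over all scans (`scan` 1-based, `mz`, `intensity`); `rt` maps
#' scan index to retention time in seconds and is strictly increasing.
#'
#' @param points Data frame with columns `scan`, `mz`, `intensity`.
#' @param rt Numeric vector, seconds, one entry per scan.
#' @param scan_rate Seconds per scan (median RT step if not given).
#' @return An object of class `LCMSRun`.
#' @export
new_lcms_run <- function(points, rt, scan_rate = NULL) {
  stopifnot(is.data.frame(points),
            all(c("scan", "mz", "intensity") %in% names(points)),
            all(points$intensity >= 0), all(points$mz > 0),
            all(points$scan >= 1L), all(points$scan <= length(rt)))
  if (length(rt) > 1L && any(diff(rt) <= 0)) {
    stop("retention times must be strictly increasing with scan index")
  }
  if (is.null(scan_rate)) {
    scan_rate <- if (length(rt) > 1L) stats::median(diff(rt)) else NA_real_
  }
  structure(list(points = points, rt = rt, scan_rate = scan_rate),
            class = "LCMSRun")
}

#' @export
print.LCMSRun <- function(x, ...) {
  cat(sprintf("<LCMSRun> %d scans, %d centroid points, RT %.1f-%.1f s (%.3g s/scan)\n",
              length(x$rt), nrow(x$points), min(x$rt), max(x$rt), x$scan_rate))
  invisible(x)
}

#' Read a centroided mzML file into an LCMSRun
#'
#' Loads all MS1 spectra in acquisition order. Retention times are
#' normalized to seconds whatever unit the file declares (mzR performs
#' the conversion). Files whose MS1 spectra are flagged profile-mode are
#' rejected: this pipeline operates on centroid data only.
#'
#' @param path Path to an mzML file.
#' @return An `LCMSRun`.
#' @export
read_mzml_centroid <- function(path) {
  if (!file.exists(path)) stop("mzML file not found: ", path)
  handle <- mzR::openMSfile(path)
  on.exit(mzR::close(handle), add = TRUE)
  hdr <- mzR::header(handle)
  ms1 <- which(hdr$msLevel == 1L)
  if (length(ms1) == 0L) stop("no MS1 spectra in ", path)
  cent <- hdr$centroided[ms1]
  if (any(!is.na(cent) & !cent)) {
    stop("profile-mode MS1 spectra detected in ", path,
         "; centroid the data before analysis")
  }
  ms1 <- ms1[order(hdr$retentionTime[ms1])]
  rt <- hdr$retentionTime[ms1]
  pk <- mzR::peaks(handle, ms1)
  if (is.matrix(pk)) pk <- list(pk)
  pts <- do.call(rbind, lapply(seq_along(pk), function(i) {
    m <- pk[[i]]
    if (is.null(m) || nrow(m) == 0L) return(NULL)
    data.frame(scan = i, mz = m[, 1], intensity = m[, 2])
  }))
  if (is.null(pts)) pts <- data.frame(scan = integer(0), mz = numeric(0),
                                      intensity = numeric(0))
  pts <- pts[pts$intensity > 0, , drop = FALSE]
  pts <- pts[order(pts$scan, pts$mz), , drop = FALSE]
  rownames(pts) <- NULL
  new_lcms_run(pts, rt)
}

#' Write an LCMSRun to mzML
#'
#' Emits one centroided MS1 spectrum per scan (scans without points are
#' written empty) so synthetic runs round-trip through the same reader as
#' real data.
#'
#' @param run An `LCMSRun`.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_mzml <- function(run, path) {
  stopifnot(inherits(run, "LCMSRun"))
  n <- length(run$rt)
  pk <- lapply(seq_len(n), function(i) {
    p <- run$points[run$points$scan == i, , drop = FALSE]
    cbind(mz = p$mz, intensity = p$intensity)
  })
  counts <- vapply(pk, nrow, integer(1))
  hdr <- data.frame(
    seqNum = seq_len(n), acquisitionNum = seq_len(n), msLevel = 1L,
    polarity = 1L, peaksCount = counts,
    totIonCurrent = vapply(pk, function(m) sum(m[, 2]), numeric(1)),
    retentionTime = run$rt,
    basePeakMZ = vapply(pk, function(m) if (nrow(m)) m[which.max(m[, 2]), 1] else 0, numeric(1)),
    basePeakIntensity = vapply(pk, function(m) if (nrow(m)) max(m[, 2]) else 0, numeric(1)),
    collisionEnergy = 0, ionisationEnergy = 0,
    lowMZ = vapply(pk, function(m) if (nrow(m)) min(m[, 1]) else 0, numeric(1)),
    highMZ = vapply(pk, function(m) if (nrow(m)) max(m[, 1]) else 0, numeric(1)),
    precursorScanNum = 0L, precursorMZ = 0, precursorCharge = 0L,
    precursorIntensity = 0,
    mergedScan = 0L, mergedResultScanNum = 0L,
    mergedResultStartScanNum = 0L, mergedResultEndScanNum = 0L,
    injectionTime = 0, filterString = NA_character_,
    spectrumId = paste0("scan=", seq_len(n)), centroided = TRUE,
    ionMobilityDriftTime = NA_real_,
    isolationWindowTargetMZ = NA_real_, isolationWindowLowerOffset = NA_real_,
    isolationWindowUpperOffset = NA_real_,
    scanWindowLowerLimit = NA_real_, scanWindowUpperLimit = NA_real_,
    stringsAsFactors = FALSE
  )
  mzR::writeMSData(pk, path, header = hdr, outformat = "mzml")
  invisible(path)
}

#' Construct a peak-record data frame
#'
#' The exchange format for detected/reported peaks: one row per peak with
#' apex m/z, apex retention time in seconds, and optional scan-indexed
#' apex/boundaries (boundaries default to the apex scan when a tool does
#' not report them).
#'
#' @param mz_apex,rt_apex_s Numeric vectors (required).
#' @param eic_id,scan_apex,scan_left,scan_right Optional integer vectors.
#' @param source Free-text label of the producing tool.
#' @return A `data.frame` with the canonical peak-record columns.
#' @export
peak_records <- function(mz_apex, rt_apex_s, eic_id = NA_integer_,
                         scan_apex = NA_integer_, scan_left = NA_integer_,
                         scan_right = NA_integer_, source = "unknown") {
  n <- length(mz_apex)
  stopifnot(length(rt_apex_s) == n)
  df <- data.frame(
    eic_id = rep_len(as.integer(eic_id), n),
    mz_apex = mz_apex, rt_apex_s = rt_apex_s,
    scan_apex = rep_len(as.integer(scan_apex), n),
    scan_left = rep_len(as.integer(scan_left), n),
    scan_right = rep_len(as.integer(scan_right), n),
    source = rep_len(source, n),
    stringsAsFactors = FALSE
  )
  fix <- !is.na(df$scan_apex) & is.na(df$scan_left)
  df$scan_left[fix] <- df$scan_apex[fix]
  fix <- !is.na(df$scan_apex) & is.na(df$scan_right)
  df$scan_right[fix] <- df$scan_apex[fix]
  ok <- is.na(df$scan_left) | (df$scan_left <= df$scan_apex &
                                 df$scan_apex <= df$scan_right)
  if (!all(ok)) stop("scan_left <= scan_apex <= scan_right violated")
  df
}

#' Write a peak list (with optional metric columns) to CSV
#'
#' Rows are ordered by `eic_id` then `scan_apex` (ties broken by
#' `rt_apex_s`, then `mz_apex`) so output is deterministic. An empty
#' record set writes the header only.
#'
#' @param records Peak-record data frame ([peak_records()]).
#' @param path Output CSV path.
#' @param metrics Optional data frame of per-peak metric columns,
#'   row-aligned with `records`.
#' @return `path`, invisibly.
#' @export
write_peaklist <- function(records, path, metrics = NULL) {
  cols <- c("eic_id", "mz_apex", "rt_apex_s", "scan_apex",
            "scan_left", "scan_right", "source")
  stopifnot(all(cols %in% names(records)))
  df <- records[cols]
  if (!is.null(metrics)) {
    stopifnot(nrow(metrics) == nrow(df))
    df <- cbind(df, metrics)
  }
  ord <- order(df$eic_id, df$scan_apex, df$rt_apex_s, df$mz_apex)
  df <- df[ord, , drop = FALSE]
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE, na = "")
  invisible(path)
}

#' Read a peak list from delimited text
#'
#' Requires at least apex m/z and apex RT columns; other canonical
#' columns are filled with defaults when absent (missing boundaries are
#' set to the apex scan). Non-canonical headers are handled with
#' `column_map`, e.g. `c(mz_apex = "mz", rt_apex_s = "rt")` for
#' XCMS-style exports. RT given in minutes (declare with
#' `rt_unit = "min"`) is converted to seconds.
#'
#' @param path CSV/TSV path (delimiter sniffed from the header line).
#' @param column_map Named character vector mapping canonical names to
#'   file column names.
#' @param source Label recorded in the `source` column (default: file
#'   name).
#' @param rt_unit `"s"` (default) or `"min"`.
#' @return A peak-record data frame.
#' @export
read_peaklist <- function(path, column_map = NULL, source = NULL,
                          rt_unit = c("s", "min")) {
  rt_unit <- match.arg(rt_unit)
  if (!file.exists(path)) stop("peak list not found: ", path)
  first <- readLines(path, n = 1L)
  sep <- if (grepl("\t", first)) "\t" else ","
  df <- utils::read.table(path, header = TRUE, sep = sep,
                          stringsAsFactors = FALSE)
  if (!is.null(column_map)) {
    for (canon in names(column_map)) {
      have <- column_map[[canon]]
      if (!have %in% names(df)) stop("column_map names absent column: ", have)
      names(df)[names(df) == have] <- canon
    }
  }
  need <- c("mz_apex", "rt_apex_s")
  if (!all(need %in% names(df))) {
    stop("peak list must provide columns ", paste(need, collapse = ", "),
         " (use column_map to rename)")
  }
  for (col in need) {
    v <- df[[col]]
    if (!is.numeric(v)) {
      v2 <- suppressWarnings(as.numeric(v))
      if (anyNA(v2) && !anyNA(v)) stop("non-numeric values in column ", col)
      df[[col]] <- v2
    }
  }
  rt <- df$rt_apex_s * if (rt_unit == "min") 60 else 1
  grab <- function(col) if (col %in% names(df)) df[[col]] else NA_integer_
  peak_records(
    mz_apex = df$mz_apex, rt_apex_s = rt,
    eic_id = grab("eic_id"), scan_apex = grab("scan_apex"),
    scan_left = grab("scan_left"), scan_right = grab("scan_right"),
    source = if (!is.null(source)) source
             else if ("source" %in% names(df)) df$source
             else basename(path)
  )
}

#' Write extracted EICs to a long-format CSV table
#'
#' One row per (EIC, scan): `eic_id, scan, rt_s, mz, intensity`. Gap
#' scans inside an EIC appear with intensity 0 and an empty m/z.
#'
#' @param eics List of `EIC` objects.
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_eic_table <- function(eics, path) {
  rows <- lapply(eics, function(e) {
    data.frame(eic_id = e$eic_id,
               scan = e$scan_first:e$scan_last,
               rt_s = e$rt,
               mz = e$mz_trace,
               intensity = e$intensities)
  })
  df <- do.call(rbind, c(rows, list(make.row.names = FALSE)))
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE, na = "")
  invisible(path)
}

#' Read an EIC table written by [write_eic_table()]
#'
#' @param path CSV path.
#' @return A list of `EIC` objects.
#' @export
read_eic_table <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("eic_id", "scan", "rt_s", "mz", "intensity")
  if (!all(need %in% names(df))) {
    stop("EIC table must have columns ", paste(need, collapse = ", "))
  }
  lapply(split(df, df$eic_id), function(d) {
    d <- d[order(d$scan), , drop = FALSE]
    nz <- d$intensity > 0 & !is.na(d$mz)
    mzc <- if (any(nz)) {
      stats::weighted.mean(d$mz[nz], d$intensity[nz])
    } else NA_real_
    new_eic(eic_id = d$eic_id[1], mz_center = mzc,
            scan_first = d$scan[1], scan_last = d$scan[nrow(d)],
            intensities = d$intensity, mz_trace = d$mz, rt = d$rt_s)
  })
}
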