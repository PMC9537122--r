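#' Read a PPG record from CSV or WFDB
#'
#' Two dialects are supported: a headered CSV with a named pleth column
#' (time column optional), and a minimal WFDB record pair (`.hea` header +
#' 16-bit `.dat`).  Samples are returned as stored; no resampling is
#' performed.  Non-finite samples are counted and reported via
#' `meta$n_nonfinite`.
#'
#' @param path file path; for WFDB either the header path or the record
#'   name without extension.
#' @param format `"csv"` or `"wfdb"`.
#' @param pleth_column CSV column holding the pleth signal.
#' @param fs sampling frequency in Hz; required for CSV, read from the
#'   header for WFDB.
#' @param subject_id,label record metadata.
#' @return a `ppg_record`.
#' @export
read_record <- function(path, format = c("csv", "wfdb"),
                        pleth_column = "pleth", fs = NULL,
                        subject_id = "unknown", label = "non_anesthesia") {
  format <- match.arg(format)
  rec <- switch(format,
    csv = .read_record_csv(path, pleth_column, fs, subject_id, label),
    wfdb = .read_record_wfdb(path, subject_id, label)
  )
  rec$meta$n_nonfinite <- sum(!is.finite(rec$samples))
  rec
}

.read_record_csv <- function(path, pleth_column, fs, subject_id, label) {
  if (!file.exists(path)) stop("file not found: ", path)
  df <- read.csv(path, check.names = FALSE)
  if (nrow(df) == 0) stop("empty input: ", path)
  if (!pleth_column %in% names(df)) {
    stop("format error: column '", pleth_column, "' not found in ", path)
  }
  if (is.null(fs)) {
    if (!"time_s" %in% names(df)) {
      stop("fs not supplied and no time_s column to derive it from")
    }
    fs <- 1 / median(diff(df$time_s))
  }
  rec <- ppg_record(df[[pleth_column]], fs, subject_id, label, source = "csv")
  rec
}

#' Write a record as CSV (columns `time_s`, `pleth`)
#'
#' @param record a `ppg_record`.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_record_csv <- function(record, path) {
  stopifnot(inherits(record, "ppg_record"))
  n <- length(record$samples)
  df <- data.frame(time_s = (seq_len(n) - 1) / record$fs,
                   pleth = record$samples)
  write.csv(df, path, row.names = FALSE)
  invisible(path)
}

# Minimal WFDB writer: single-signal format-16 record (little-endian
# 16-bit integers) with a plain-text .hea header.  The gain is chosen so
# the signal spans most of the 16-bit range; round-trip error is bounded
# by 0.5 / gain.
#' Write a record as a WFDB pair (`.hea` + 16-bit `.dat`)
#'
#' @param record a `ppg_record`.
#' @param record_name path without extension.
#' @return the header path, invisibly.
#' @export
write_record_wfdb <- function(record, record_name) {
  stopifnot(inherits(record, "ppg_record"))
  x <- record$samples
  span <- max(abs(x), 1e-12)
  gain <- 30000 / span
  dig <- as.integer(round(x * gain))
  dig <- pmin(pmax(dig, -32768L), 32767L)
  base <- basename(record_name)
  hea <- c(
    sprintf("%s 1 %.10g %d", base, record$fs, length(x)),
    sprintf("%s.dat 16 %.10g(0)/au 16 0 %d 0 0 pleth", base, gain, dig[1]),
    sprintf("# subject_id: %s", record$subject_id),
    sprintf("# label: %s", as.character(record$label))
  )
  writeLines(hea, paste0(record_name, ".hea"))
  con <- file(paste0(record_name, ".dat"), "wb")
  on.exit(close(con))
  writeBin(dig, con, size = 2L, endian = "little")
  invisible(paste0(record_name, ".hea"))
}

.read_record_wfdb <- function(path, subject_id, label) {
  hea_path <- if (grepl("\\.hea$", path)) path else paste0(path, ".hea")
  if (!file.exists(hea_path)) stop("file not found: ", hea_path)
  lines <- readLines(hea_path)
  if (length(lines) < 2) stop("format error: truncated WFDB header")
  rec_fields <- strsplit(trimws(lines[1]), "\\s+")[[1]]
  if (length(rec_fields) < 4) stop("format error: bad WFDB record line")
  fs <- as.numeric(rec_fields[3])
  n <- as.integer(rec_fields[4])
  sig_fields <- strsplit(trimws(lines[2]), "\\s+")[[1]]
  if (length(sig_fields) < 3 || sig_fields[2] != "16") {
    stop("format error: only single-signal format-16 records are supported")
  }
  gain_str <- sig_fields[3]
  gain <- as.numeric(sub("\\(.*$", "", sub("/.*$", "", gain_str)))
  baseline <- 0
  if (grepl("\\(", gain_str)) {
    baseline <- as.numeric(sub("^.*\\(([^)]*)\\).*$", "\\1", gain_str))
  }
  # metadata comments written by write_record_wfdb()
  meta_line <- function(key) {
    m <- grep(paste0("^# ", key, ": "), lines, value = TRUE)
    if (length(m)) sub(paste0("^# ", key, ": "), "", m[1]) else NULL
  }
  sid <- meta_line("subject_id"); if (!is.null(sid)) subject_id <- sid
  lab <- meta_line("label"); if (!is.null(lab)) label <- lab
  dat_path <- file.path(dirname(hea_path), sub("\\s.*$", "", sig_fields[1]))
  con <- file(dat_path, "rb")
  on.exit(close(con))
  dig <- readBin(con, "integer", n = n, size = 2L, signed = TRUE,
                 endian = "little")
  if (length(dig) < n) stop("format error: .dat shorter than header claims")
  ppg_record((dig - baseline) / gain, fs, subject_id, label, source = "wfdb")
}

#' Write every record of a cohort as per-subject CSV files
#'
#' @param cohort a `ppg_cohort` (or list of `ppg_record`).
#' @param dir output directory (created if missing).
#' @return data.frame manifest with columns `subject_id`, `label`, `path`.
#' @export
write_cohort_csv <- function(cohort, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  rows <- lapply(cohort, function(rec) {
    path <- file.path(dir, paste0(rec$subject_id, ".csv"))
    write_record_csv(rec, path)
    data.frame(subject_id = rec$subject_id,
               label = as.character(rec$label), path = path)
  })
  do.call(rbind, rows)
}

#' Cut a record into consecutive non-overlapping 5-s segments
#'
#' Windows start at the record start; a trailing remainder shorter than
#' `window_s` is dropped.  A record shorter than one window yields an
#' empty list (with a message), not an error.
#'
#' @param record a `ppg_record`.
#' @param window_s window length in seconds (default 5).
#' @return list of `ppg_segment` objects.
#' @export
segment_record <- function(record, window_s = 5) {
  stopifnot(inherits(record, "ppg_record"), window_s > 0)
  n_win <- round(window_s * record$fs)
  n_seg <- length(record$samples) %/% n_win
  if (n_seg == 0) {
    message("record ", record$subject_id, " shorter than one window; ",
            "no segments")
    return(list())
  }
  lapply(seq_len(n_seg), function(i) {
    idx <- ((i - 1) * n_win + 1):(i * n_win)
    structure(
      list(samples = record$samples[idx], fs = record$fs,
           subject_id = record$subject_id, label = record$label,
           start_time = (i - 1) * n_win / record$fs,
           quality_ok = NA, quality_reason = "unscreened"),
      class = "ppg_segment"
    )
  })
}

#' Quality-screening rules
#'
#' Automatic stand-in for manual signal-quality review.  A segment fails
#' when any rule fires; the first firing rule is recorded.
#'
#' @param flatline_var_frac flatline when the sample variance is below this
#'   fraction of the squared signal range (a zero range is always flat).
#' @param clipping_run_s clipping when the signal stays within
#'   `clipping_tol_frac` of the segment minimum or maximum for at least
#'   this long (sustained rail contact, as produced by sensor
#'   saturation); brief contact at pulse peaks or the diastolic floor
#'   does not fire the rule.
#' @param clipping_tol_frac tolerance band as a fraction of the range.
#' @param slope_change_factor broadband noise when first-difference sign
#'   changes (counted on the smoothed segment, ignoring differences below
#'   `slope_eps_frac` of the range) exceed this multiple of the expected
#'   beat count.
#' @param slope_eps_frac hysteresis for the sign-change count.
#' @param expected_beats_per_s expected beat rate used by the sign-change
#'   rule (1.25 beats/s ~ 75 bpm).
#' @param min_beats minimum delineated beats per segment.
#' @return an object of class `ppg_quality_rules`.
#' @export
quality_rules <- function(flatline_var_frac = 1e-6, clipping_run_s = 0.15,
                          clipping_tol_frac = 0.001,
                          slope_change_factor = 20, slope_eps_frac = 0.005,
                          expected_beats_per_s = 1.25, min_beats = 3) {
  structure(as.list(environment()), class = "ppg_quality_rules")
}

#' Screen one segment's quality
#'
#' Deterministic and segment-local: flags flatline, clipping, broadband
#' (out-of-band) noise, and too few delineated beats, in that order.
#'
#' @param segment a `ppg_segment`.
#' @param rules a [quality_rules()] object.
#' @param preprocess_params parameters passed to the internal delineation
#'   check (see [preprocess_params()]).
#' @return the segment with `quality_ok` and `quality_reason` set.
#' @export
screen_quality <- function(segment, rules = quality_rules(),
                           preprocess_params = NULL) {
  stopifnot(inherits(segment, "ppg_segment"))
  x <- segment$samples
  rng <- diff(range(x))
  fail <- function(reason) {
    segment$quality_ok <- FALSE
    segment$quality_reason <- reason
    segment
  }
  if (rng == 0 || var(x) < rules$flatline_var_frac * rng^2) {
    return(fail("flatline"))
  }
  tol <- rules$clipping_tol_frac * rng
  near_edge <- (x >= max(x) - tol) | (x <= min(x) + tol)
  runs <- rle(near_edge)
  longest <- if (any(runs$values)) max(runs$lengths[runs$values]) else 0L
  if (longest >= round(rules$clipping_run_s * segment$fs)) {
    return(fail("clipping"))
  }
  if (is.null(preprocess_params)) preprocess_params <- preprocess_params()
  sm <- tryCatch(
    savgol_smooth(x, preprocess_params$sg_order, preprocess_params$sg_frame),
    error = function(e) x
  )
  d <- diff(sm)
  d <- d[abs(d) > rules$slope_eps_frac * rng]
  n_changes <- sum(diff(sign(d)) != 0)
  window_s <- length(x) / segment$fs
  if (n_changes > rules$slope_change_factor *
        rules$expected_beats_per_s * window_s) {
    return(fail("out_of_band"))
  }
  lm <- tryCatch({
    bl <- remove_baseline(sm, segment$fs, preprocess_params)
    delineate_beats(bl, segment$fs, preprocess_params)
  }, error = function(e) NULL)
  if (is.null(lm) || nrow(lm) < rules$min_beats) return(fail("too_few_beats"))
  segment$quality_ok <- TRUE
  segment$quality_reason <- "ok"
  segment
}
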