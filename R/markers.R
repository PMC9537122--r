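#' Names of the 13 temporal markers
#'
#' Rising time, total pulse area, and pulse widths at eleven fractional
#' amplitudes (10-90 % of the onset-to-peak amplitude).
#'
#' @return character vector of length 13.
#' @export
marker_names <- function() {
  c("rising_time", "total_area",
    paste0("width_", c(10, 20, 25, 30, 40, 50, 60, 70, 75, 80, 90)))
}

.width_fracs <- c(10, 20, 25, 30, 40, 50, 60, 70, 75, 80, 90) / 100

#' Rising time of a normalized beat
#'
#' Time from the beat onset to the systolic peak, as a fraction of the
#' beat duration (both axes are already normalized).
#'
#' @param beat a `ppg_beat`.
#' @return fraction in (0, 1).
#' @export
rising_time <- function(beat) {
  stopifnot(inherits(beat, "ppg_beat"))
  y <- beat$normalized
  (which.max(y) - 1) / (length(y) - 1)
}

#' Total area under a normalized beat
#'
#' Composite trapezoid rule over the unit-square normalized beat; a
#' constant pulse at the peak level would give exactly 1.
#'
#' @param beat a `ppg_beat`.
#' @return dimensionless area in (0, 1].
#' @export
total_area <- function(beat) {
  stopifnot(inherits(beat, "ppg_beat"))
  y <- beat$normalized
  x <- seq(0, 1, length.out = length(y))
  pracma::trapz(x, y)
}

#' Pulse width at a fractional amplitude
#'
#' Width of the pulse at level `f` of the onset-to-peak amplitude: time of
#' the last down-crossing of `f` after the peak minus time of the first
#' up-crossing before the peak, with linear interpolation between samples.
#' The first-rise/last-fall convention makes level sets nested, so widths
#' are non-increasing in `f` for every beat.  `NA` is returned when the
#' level is never crossed on one side.
#'
#' @param beat a `ppg_beat`.
#' @param f level as a fraction of the normalized amplitude, in (0, 1).
#' @return width as a fraction of the beat duration, or `NA`.
#' @export
width_at <- function(beat, f) {
  stopifnot(inherits(beat, "ppg_beat"), f > 0, f < 1)
  y <- beat$normalized
  L <- length(y)
  x <- seq(0, 1, length.out = L)
  p <- which.max(y)
  # first up-crossing at or before the peak
  left <- NA_real_
  if (y[1] >= f) {
    left <- x[1]
  } else {
    for (i in 2:p) {
      if (y[i - 1] < f && y[i] >= f) {
        left <- x[i - 1] + (x[i] - x[i - 1]) * (f - y[i - 1]) / (y[i] - y[i - 1])
        break
      }
    }
  }
  # last down-crossing at or after the peak
  right <- NA_real_
  if (y[L] >= f) {
    right <- NA_real_  # never falls below the level again
  } else {
    for (j in L:(p + 1)) {
      if (y[j - 1] >= f && y[j] < f) {
        right <- x[j - 1] + (x[j] - x[j - 1]) * (f - y[j - 1]) / (y[j] - y[j - 1])
        break
      }
    }
  }
  if (is.na(left) || is.na(right)) return(NA_real_)
  right - left
}

#' All 13 markers for one beat
#'
#' @param beat a `ppg_beat`.
#' @return named numeric vector (see [marker_names()]); widths that never
#'   cross their level are `NA`.
#' @export
beat_markers <- function(beat) {
  widths <- vapply(.width_fracs, function(f) width_at(beat, f), numeric(1))
  setNames(c(rising_time(beat), total_area(beat), widths), marker_names())
}

#' Average beat markers over one segment
#'
#' Beats with any missing marker are excluded wholesale so the per-segment
#' marker vector stays jointly consistent; segments with fewer than
#' `min_beats` usable beats are rejected.
#'
#' @param segment a `ppg_segment`.
#' @param beats list of `ppg_beat` for the segment.
#' @param min_beats minimum usable beats (default 3).
#' @return one-row data.frame with `subject_id`, `label`, `segment_start`,
#'   `n_beats` and the 13 marker means, or `NULL` when the segment is
#'   rejected.
#' @export
extract_segment_features <- function(segment, beats, min_beats = 3) {
  stopifnot(inherits(segment, "ppg_segment"))
  if (length(beats) == 0) return(NULL)
  m <- t(vapply(beats, beat_markers, numeric(length(marker_names()))))
  # a marker outside its physiological range (areas and fractions live in
  # the unit interval) marks the whole beat as unusable, exactly like a
  # width whose level is never crossed
  valid_range <- m > 0 & m <= 1
  m[!valid_range] <- NA_real_
  complete <- stats::complete.cases(m)
  if (sum(complete) < min_beats) return(NULL)
  means <- colMeans(m[complete, , drop = FALSE])
  out <- data.frame(subject_id = segment$subject_id,
                    label = as.character(segment$label),
                    segment_start = segment$start_time,
                    n_beats = sum(complete))
  cbind(out, as.data.frame(as.list(means)))
}

#' Extract the per-segment feature table for a set of records
#'
#' Runs segmentation, quality screening, preprocessing, and marker
#' averaging for every record and stacks the results.
#'
#' @param records a `ppg_cohort` or list of `ppg_record`.
#' @param window_s segment length in seconds.
#' @param rules a [quality_rules()] object.
#' @param params a [preprocess_params()] object.
#' @return data.frame (class `ppg_feature_table`) with one row per kept
#'   segment; attribute `screening` holds per-record segment yields.
#' @export
extract_features <- function(records, window_s = 5,
                             rules = quality_rules(),
                             params = preprocess_params()) {
  per_record <- lapply(records, function(rec) {
    segs <- segment_record(rec, window_s)
    segs <- lapply(segs, screen_quality, rules = rules,
                   preprocess_params = params)
    kept <- Filter(function(s) isTRUE(s$quality_ok), segs)
    rows <- lapply(kept, function(s) {
      pp <- preprocess_segment(s, params)
      extract_segment_features(s, pp$beats, min_beats = rules$min_beats)
    })
    rows <- Filter(Negate(is.null), rows)
    yield <- data.frame(subject_id = rec$subject_id,
                        n_segments = length(segs),
                        n_quality_ok = length(kept),
                        n_features = length(rows))
    list(rows = rows, yield = yield)
  })
  tab <- do.call(rbind, unlist(lapply(per_record, `[[`, "rows"),
                               recursive = FALSE))
  screening <- do.call(rbind, lapply(per_record, `[[`, "yield"))
  if (is.null(tab)) {
    tab <- data.frame()
  }
  attr(tab, "screening") <- screening
  class(tab) <- c("ppg_feature_table", class(tab))
  tab
}
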