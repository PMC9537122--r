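#' Preprocessing parameters
#'
#' @param sg_order Savitzky-Golay polynomial order (default 4).
#' @param sg_frame Savitzky-Golay frame length; must be odd and larger
#'   than `sg_order` (default 21, the odd frame closest to 20 samples).
#' @param peak_prominence_frac minimum peak prominence as a fraction of
#'   the median peak-to-onset amplitude (default 0.3).
#' @param refractory_s minimum spacing between accepted systolic peaks in
#'   seconds; the smaller of two closer peaks (typically the dicrotic
#'   bump) is discarded (default 0.3).
#' @param beat_length number of samples per normalized beat (default 100).
#' @return an object of class `ppg_preprocess_params`.
#' @export
preprocess_params <- function(sg_order = 4, sg_frame = 21,
                              peak_prominence_frac = 0.3,
                              refractory_s = 0.3, beat_length = 100) {
  stopifnot(sg_frame %% 2 == 1, sg_frame > sg_order, beat_length >= 10)
  structure(as.list(environment()), class = "ppg_preprocess_params")
}

#' Savitzky-Golay smoothing
#'
#' Least-squares local polynomial smoothing via [signal::sgolayfilt()];
#' edges are handled by polynomial fits on the truncated startup/ending
#' windows.  Reproduces polynomials up to the fit order exactly.
#'
#' @param x numeric signal.
#' @param order polynomial order.
#' @param frame frame length (odd, > order, <= length(x)).
#' @return smoothed signal, same length as `x`.
#' @export
savgol_smooth <- function(x, order = 4, frame = 21) {
  if (frame <= order) stop("frame must exceed the polynomial order")
  if (frame %% 2 == 0) stop("frame must be odd")
  if (frame > length(x)) stop("frame longer than the signal")
  signal::sgolayfilt(x, p = order, n = frame)
}

#' Remove respiratory baseline wander
#'
#' Anchors a cubic spline (natural boundary, linear extrapolation) at the
#' detected beat-onset samples and subtracts it, so beat onsets sit near
#' zero while the pulse shape between onsets is preserved.  With fewer
#' than two detectable onsets the segment mean is subtracted instead and
#' the result carries `attr(, "fallback") = TRUE`.
#'
#' @param x smoothed segment samples.
#' @param fs sampling frequency in Hz.
#' @param params a [preprocess_params()] object.
#' @return baseline-corrected signal.
#' @export
remove_baseline <- function(x, fs, params = preprocess_params()) {
  onsets <- tryCatch(.detect_onsets(x, fs, params), error = function(e) integer(0))
  if (length(onsets) < 2) {
    out <- x - mean(x)
    attr(out, "fallback") <- TRUE
    return(out)
  }
  base <- spline(onsets, x[onsets], xout = seq_along(x),
                 method = "natural")$y
  x - base
}

# Onset candidates: global minimum between consecutive accepted peaks,
# plus the pre-first-peak minimum when the segment genuinely starts at an
# onset.  Shared by baseline removal and delineation.
.detect_onsets <- function(x, fs, params) {
  peaks <- .accepted_peaks(x, fs, params)
  if (length(peaks) < 2) return(integer(0))
  onsets <- vapply(seq_len(length(peaks) - 1), function(i) {
    span <- peaks[i]:peaks[i + 1]
    span[which.min(x[span])]
  }, integer(1))
  lead_span <- 1:peaks[1]
  m0 <- lead_span[which.min(x[lead_span])]
  minima <- find_extrema(x)$minima
  if (m0 %in% minima || m0 <= 2) onsets <- c(m0, onsets)
  onsets
}

#' Locate extrema by slope sign change
#'
#' A sample is a maximum when the first difference changes from positive
#' to negative there (negative to positive for minima); plateaus are
#' assigned to the first plateau sample.  Monotone signals yield empty
#' index vectors.
#'
#' @param x numeric signal (length >= 3).
#' @return list with integer vectors `maxima` and `minima`.
#' @export
find_extrema <- function(x) {
  stopifnot(length(x) >= 3)
  d <- diff(x)
  s <- sign(d)
  # plateau rule: a zero difference takes the sign of the next nonzero
  # difference, so the extremum lands on the first plateau sample
  nz <- s != 0
  if (!any(nz)) return(list(maxima = integer(0), minima = integer(0)))
  idx <- rev(seq_along(s))
  filled <- s
  carry <- 0
  for (i in idx) {
    if (filled[i] == 0) filled[i] <- carry else carry <- filled[i]
  }
  # trailing zeros (carry never set beyond them) keep 0 -> no extremum
  ch <- which(filled[-length(filled)] > 0 & filled[-1] < 0)
  mins <- which(filled[-length(filled)] < 0 & filled[-1] > 0)
  list(maxima = ch + 1L, minima = mins + 1L)
}

# Systolic peak candidates: slope-based maxima filtered by a refractory
# rule (drop the smaller of two peaks closer than refractory_s) and a
# prominence rule (drop peaks whose rise above the larger flanking
# minimum is under peak_prominence_frac of the median peak amplitude).
.accepted_peaks <- function(x, fs, params) {
  ext <- find_extrema(x)
  peaks <- ext$maxima
  if (length(peaks) == 0) return(integer(0))
  refr <- round(params$refractory_s * fs)
  repeat {
    if (length(peaks) < 2) break
    gaps <- diff(peaks)
    close_i <- which(gaps < refr)
    if (length(close_i) == 0) break
    i <- close_i[1]
    drop <- if (x[peaks[i]] >= x[peaks[i + 1]]) i + 1L else i
    peaks <- peaks[-drop]
  }
  if (length(peaks) == 0) return(integer(0))
  mins <- ext$minima
  amp <- vapply(peaks, function(p) {
    left <- mins[mins < p]
    right <- mins[mins > p]
    lv <- if (length(left)) x[max(left)] else min(x[1:p])
    rv <- if (length(right)) x[min(right)] else min(x[p:length(x)])
    x[p] - max(lv, rv)
  }, numeric(1))
  med <- median(amp[amp > 0])
  if (!is.finite(med) || med <= 0) return(integer(0))
  peaks[amp >= params$peak_prominence_frac * med]
}

#' Delineate beats in a baseline-corrected segment
#'
#' Peaks are slope-based maxima surviving the prominence and refractory
#' rules; each onset is the global minimum between consecutive peaks; a
#' beat spans onset to next onset.  Partial beats at the segment edges are
#' dropped.
#'
#' @param x baseline-corrected samples.
#' @param fs sampling frequency in Hz.
#' @param params a [preprocess_params()] object.
#' @return data.frame with columns `onset`, `peak`, `end` (sample
#'   indices); zero rows when no complete beat is found.
#' @export
delineate_beats <- function(x, fs, params = preprocess_params()) {
  empty <- data.frame(onset = integer(0), peak = integer(0),
                      end = integer(0))
  if (length(x) < 3) return(empty)
  peaks <- .accepted_peaks(x, fs, params)
  if (length(peaks) < 2) return(empty)
  onsets <- .detect_onsets(x, fs, params)
  if (length(onsets) < 2) return(empty)
  beats <- lapply(seq_len(length(onsets) - 1), function(j) {
    o <- onsets[j]; e <- onsets[j + 1]
    p <- peaks[peaks > o & peaks < e]
    if (length(p) == 0) return(NULL)
    p <- p[which.max(x[p])]
    data.frame(onset = o, peak = p, end = e)
  })
  beats <- do.call(rbind, beats)
  if (is.null(beats)) empty else beats
}

#' Two-dimensional beat normalization
#'
#' Rescales one beat so the onset value maps to 0 and the peak value to 1,
#' and resamples the onset-to-end span to exactly `L` samples by linear
#' interpolation.  This removes amplitude (gain) and sampling-rate
#' differences between recordings, which is what makes the temporal
#' markers comparable across monitor databases.
#'
#' @param x segment samples.
#' @param onset,peak,end landmark sample indices (onset < peak < end).
#' @param fs sampling frequency in Hz.
#' @param L normalized beat length (default 100 samples).
#' @return an object of class `ppg_beat` with fields `normalized`
#'   (length-`L` series), `period_s`, `source_fs`, `peak_frac`.
#' @export
normalize_beat <- function(x, onset, peak, end, fs, L = 100) {
  stopifnot(onset < peak, peak < end, end <= length(x), onset >= 1)
  v <- x[onset:end]
  v0 <- x[onset]; vp <- x[peak]
  if (!(vp > v0)) stop("degenerate beat: peak value does not exceed onset")
  norm <- (v - v0) / (vp - v0)
  xs <- seq(0, 1, length.out = length(v))
  out <- approx(xs, norm, xout = seq(0, 1, length.out = L))$y
  # linear resampling can place the peak between grid points; rescale so
  # the resampled maximum is exactly 1 (the onset stays at 0)
  out <- out / max(out)
  structure(
    list(normalized = out, period_s = (end - onset) / fs, source_fs = fs,
         peak_frac = (peak - onset) / (end - onset)),
    class = "ppg_beat"
  )
}

#' Preprocess one segment into normalized beats
#'
#' Applies Savitzky-Golay smoothing, baseline removal, delineation, and
#' beat normalization in one call.
#'
#' @param segment a `ppg_segment`.
#' @param params a [preprocess_params()] object.
#' @return list with `beats` (list of `ppg_beat`), `landmarks`
#'   (data.frame), and `clean` (smoothed, baseline-corrected samples).
#' @export
preprocess_segment <- function(segment, params = preprocess_params()) {
  stopifnot(inherits(segment, "ppg_segment"))
  sm <- savgol_smooth(segment$samples, params$sg_order, params$sg_frame)
  bl <- remove_baseline(sm, segment$fs, params)
  lm <- delineate_beats(bl, segment$fs, params)
  beats <- if (nrow(lm)) {
    lapply(seq_len(nrow(lm)), function(i) {
      tryCatch(
        normalize_beat(bl, lm$onset[i], lm$peak[i], lm$end[i],
                       segment$fs, params$beat_length),
        error = function(e) NULL
      )
    })
  } else list()
  beats <- Filter(Negate(is.null), beats)
  list(beats = beats, landmarks = lm, clean = bl)
}
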