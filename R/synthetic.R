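#' Pulse shape parameters
#'
#' Parametric model of a single PPG pulse on one beat period: a systolic
#' Gaussian component plus a smaller dicrotic Gaussian component on a zero
#' baseline.  All timing parameters are expressed as fractions of the beat
#' period, so the same shape can be rendered at any heart rate and sampling
#' frequency.
#'
#' @param systolic_center center of the systolic wave, fraction of the beat
#'   period in (0, 1).
#' @param systolic_sigma width (standard deviation) of the systolic wave's
#'   falling flank, fraction of the beat period.
#' @param systolic_sigma_left width of the rising flank (default equal to
#'   `systolic_sigma`, a symmetric wave); a slow-rising pulse has a larger
#'   left width together with a later peak.
#' @param dicrotic_center center of the dicrotic wave; must exceed
#'   `systolic_center`.
#' @param dicrotic_sigma width of the dicrotic wave.
#' @param dicrotic_rel_amp dicrotic amplitude relative to the systolic
#'   amplitude, in `[0, 1)` so the systolic peak stays the global maximum.
#' @param amplitude systolic amplitude in arbitrary units.
#' @param runoff_amp amplitude of the diastolic runoff: a smooth
#'   bi-exponential decay launched at the systolic peak (rise constant
#'   `runoff_tau / 4`, fall constant `runoff_tau`) that fills the
#'   diastolic valley and carries the waveform down toward the next beat
#'   onset, so the end-diastolic minimum sits at the beat boundary
#'   instead of on a flat floor.  0 (the default) gives the plain
#'   two-Gaussian pulse.
#' @param runoff_tau runoff fall time constant as a fraction of the beat
#'   period.
#' @return an object of class `ppg_pulse_shape`.
#' @examples
#' sh <- pulse_shape(0.3, 0.1, 0.6, 0.11, 0.3)
#' beat <- generate_beat(sh, period_s = 0.8, fs = 100)
#' @export
pulse_shape <- function(systolic_center, systolic_sigma,
                        dicrotic_center, dicrotic_sigma,
                        dicrotic_rel_amp, amplitude = 1,
                        runoff_amp = 0, runoff_tau = 0.25,
                        systolic_sigma_left = systolic_sigma) {
  stopifnot(
    systolic_center > 0, systolic_center < 1,
    dicrotic_center > systolic_center, dicrotic_center < 1,
    systolic_sigma > 0, dicrotic_sigma > 0,
    dicrotic_rel_amp >= 0, dicrotic_rel_amp < 1,
    amplitude > 0, runoff_amp >= 0, runoff_tau > 0,
    systolic_sigma_left > 0
  )
  structure(
    list(
      systolic_center = systolic_center, systolic_sigma = systolic_sigma,
      systolic_sigma_left = systolic_sigma_left,
      dicrotic_center = dicrotic_center, dicrotic_sigma = dicrotic_sigma,
      dicrotic_rel_amp = dicrotic_rel_amp, amplitude = amplitude,
      runoff_amp = runoff_amp, runoff_tau = runoff_tau
    ),
    class = "ppg_pulse_shape"
  )
}

#' Mixture of pulse-shape archetypes for one class
#'
#' A class in a synthetic cohort may contain morphological sub-phenotypes;
#' subjects are assigned to archetypes in (deterministic) proportion to the
#' weights, then jittered individually.
#'
#' @param shapes list of [pulse_shape()] objects.
#' @param weights archetype proportions (normalized internally).
#' @param names optional archetype names.
#' @return an object of class `ppg_shape_mixture`.
#' @export
shape_mixture <- function(shapes, weights = rep(1, length(shapes)),
                          names = NULL) {
  stopifnot(length(shapes) >= 1L, length(weights) == length(shapes),
            all(weights > 0))
  stopifnot(all(vapply(shapes, inherits, logical(1), "ppg_pulse_shape")))
  if (is.null(names)) names <- paste0("archetype", seq_along(shapes))
  structure(list(shapes = shapes, weights = weights / sum(weights),
                 names = names),
            class = "ppg_shape_mixture")
}

#' Noise parameters for synthetic PPG records
#'
#' @param baseline_amp amplitude of the respiratory baseline-wander
#'   sinusoid (same arbitrary units as the pulse amplitude).
#' @param baseline_freq respiratory frequency in Hz (typically 0.1-0.5 Hz).
#' @param powerline_amp amplitude of the powerline sinusoid.
#' @param powerline_freq powerline frequency in Hz.
#' @param white_sd standard deviation of additive white (sensor) noise.
#' @param motion_burst_rate expected motion artefacts per minute; each
#'   artefact saturates the sensor at a rail level for 0.3 s with 0.1-s
#'   ramps on either side.
#' @param motion_burst_amp rail excursion above the clean-signal maximum.
#' @return an object of class `ppg_noise_params`.
#' @export
noise_params <- function(baseline_amp = 0.25, baseline_freq = 0.25,
                         powerline_amp = 0.02, powerline_freq = 50,
                         white_sd = 0.01, motion_burst_rate = 1,
                         motion_burst_amp = 1) {
  stopifnot(baseline_amp >= 0, powerline_amp >= 0, white_sd >= 0,
            motion_burst_rate >= 0, motion_burst_amp >= 0,
            baseline_freq > 0, powerline_freq > 0)
  structure(
    list(baseline_amp = baseline_amp, baseline_freq = baseline_freq,
         powerline_amp = powerline_amp, powerline_freq = powerline_freq,
         white_sd = white_sd, motion_burst_rate = motion_burst_rate,
         motion_burst_amp = motion_burst_amp),
    class = "ppg_noise_params"
  )
}

#' Silent noise (no baseline wander, powerline, white noise or artefacts)
#' @return a `ppg_noise_params` object with all amplitudes zero.
#' @export
noise_none <- function() {
  noise_params(baseline_amp = 0, powerline_amp = 0, white_sd = 0,
               motion_burst_rate = 0, motion_burst_amp = 0)
}

#' Synthetic cohort configuration
#'
#' @param n_subjects_per_class subjects per class (>= 1).
#' @param record_seconds record duration per subject; must be at least 5 s
#'   (one analysis window).
#' @param fs sampling frequency in Hz: either a single value used for both
#'   classes or a length-2 vector `c(non_anesthesia, anesthesia)`.  The
#'   default preset samples the two classes at different rates to emulate
#'   recordings pooled from two monitor databases.
#' @param heart_rate_mean,heart_rate_sd between-subject heart-rate
#'   distribution (bpm).
#' @param period_jitter_sd per-beat period jitter as a fraction of the
#'   subject's mean period; periods are truncated at +/- 30 %.
#' @param class0_shape,class1_shape a [pulse_shape()] or [shape_mixture()]
#'   for the non-anesthesia (0) and anesthesia (1) class.
#' @param noise a [noise_params()] object.
#' @param subject_jitter list of between-subject morphology jitters:
#'   `center_sd` (absolute, beat fraction), `sigma_rel_sd` (log scale),
#'   `dicrotic_center_sd`, and `area_rel_sd` (log-scale spread of the
#'   per-subject pulse-area target).
#' @param pulse_area_target if non-`NULL`, the dicrotic relative amplitude
#'   of every subject is re-solved so the normalized pulse area equals this
#'   value, enforcing the equal-area contrast between classes.
#' @param dicrotic_bounds bounds for the per-subject dicrotic-amplitude
#'   solve; the upper bound keeps the dicrotic bump small enough that
#'   delineation never mistakes it for a systolic peak.
#' @param seed integer seed; the whole cohort is reproducible from it.
#' @return an object of class `ppg_cohort_config`.
#' @export
cohort_config <- function(n_subjects_per_class = 32,
                          record_seconds = 60,
                          fs = c(non_anesthesia = 125, anesthesia = 100),
                          heart_rate_mean = 75, heart_rate_sd = 6,
                          period_jitter_sd = 0.02,
                          class0_shape, class1_shape,
                          noise = noise_params(),
                          subject_jitter = list(center_sd = 0.012,
                                                sigma_rel_sd = 0.06,
                                                dicrotic_center_sd = 0.008,
                                                area_rel_sd = 0.02),
                          pulse_area_target = NULL,
                          dicrotic_bounds = c(0.02, 0.60),
                          seed = 1L) {
  stopifnot(n_subjects_per_class >= 1, record_seconds >= 5,
            all(fs > 0), length(fs) %in% c(1L, 2L),
            heart_rate_mean > 0, heart_rate_sd >= 0, period_jitter_sd >= 0)
  as_mix <- function(x) {
    if (inherits(x, "ppg_pulse_shape")) shape_mixture(list(x)) else x
  }
  class0_shape <- as_mix(class0_shape)
  class1_shape <- as_mix(class1_shape)
  stopifnot(inherits(class0_shape, "ppg_shape_mixture"),
            inherits(class1_shape, "ppg_shape_mixture"),
            inherits(noise, "ppg_noise_params"))
  if (length(fs) == 1L) fs <- c(non_anesthesia = fs, anesthesia = fs)
  names(fs) <- .anes_levels
  structure(
    list(n_subjects_per_class = as.integer(n_subjects_per_class),
         record_seconds = record_seconds, fs = fs,
         heart_rate_mean = heart_rate_mean, heart_rate_sd = heart_rate_sd,
         period_jitter_sd = period_jitter_sd,
         class0_shape = class0_shape, class1_shape = class1_shape,
         noise = noise, subject_jitter = subject_jitter,
         pulse_area_target = pulse_area_target,
         dicrotic_bounds = dicrotic_bounds,
         seed = as.integer(seed)),
    class = "ppg_cohort_config"
  )
}

#' Render one noiseless PPG beat
#'
#' Evaluates the two-Gaussian pulse model on one beat period.  A linear
#' ramp through the period-boundary values is subtracted so the first
#' sample is exactly the beat onset (value 0) and consecutive beats
#' concatenate without step discontinuities.
#'
#' @param shape a [pulse_shape()].
#' @param period_s beat period in seconds.
#' @param fs sampling frequency in Hz; `fs * period_s` must be >= 10.
#' @return numeric vector of `round(fs * period_s)` samples; the global
#'   maximum lies at the systolic component and the first sample is the
#'   onset minimum.
#' @export
generate_beat <- function(shape, period_s, fs) {
  stopifnot(inherits(shape, "ppg_pulse_shape"))
  if (!is.finite(period_s) || period_s <= 0 || !is.finite(fs) || fs <= 0) {
    stop("period_s and fs must be positive")
  }
  n <- round(period_s * fs)
  if (n < 10) stop("fs * period_s must be at least 10 samples")
  t <- (seq_len(n) - 1) / n
  y <- .pulse_eval(shape, t)
  # endpoint correction: anchor phase 0 and phase 1 at zero
  y0 <- .pulse_eval(shape, 0)
  y1 <- .pulse_eval(shape, 1)
  y - (y0 * (1 - t) + y1 * t)
}

.pulse_eval <- function(shape, t) {
  with(shape, {
    sig <- ifelse(t < systolic_center, systolic_sigma_left, systolic_sigma)
    y <- exp(-(t - systolic_center)^2 / (2 * sig^2)) +
      dicrotic_rel_amp *
        exp(-(t - dicrotic_center)^2 / (2 * dicrotic_sigma^2))
    if (runoff_amp > 0) {
      # reservoir decay switched on smoothly just past the systolic peak
      # (logistic onset at center + 2.5 sigma), so it fills the diastolic
      # valley and sets the end-diastolic minimum without touching the
      # upper part of the systolic wave
      t0 <- systolic_center + 2.5 * systolic_sigma
      s_on <- 1 / (1 + exp(-(t - t0) / (0.3 * systolic_sigma)))
      y <- y + runoff_amp * s_on * exp(-pmax(t - t0, 0) / runoff_tau)
    }
    amplitude * y
  })
}

#' Normalized pulse area of a shape
#'
#' Renders the beat at high resolution, rescales it to unit amplitude, and
#' integrates over the beat fraction: the same dimensionless quantity as
#' the `total_area` marker computed by the analysis pipeline.
#'
#' @param shape a [pulse_shape()].
#' @param n_render samples used for the quadrature.
#' @return dimensionless area in (0, 1].
#' @export
pulse_shape_area <- function(shape, n_render = 2000) {
  y <- generate_beat(shape, period_s = 1, fs = n_render)
  # onset value (first sample) is zero by construction; scale the peak to
  # one, matching the marker pipeline's beat normalization
  y <- y / max(y)
  t <- (seq_along(y) - 1) / length(y)
  pracma::trapz(t, y)
}

#' Pulse area as the analysis pipeline measures it
#'
#' Renders three noiseless beats at the given sampling rate and heart
#' rate, applies the standard smoothing and delineation, and computes the
#' `total_area` marker of the middle beat.  Unlike [pulse_shape_area()]
#' this includes the smoothing attenuation and onset-detection behavior
#' of the measurement chain, so shapes calibrated against it are matched
#' on the marker actually reported downstream.
#'
#' @param shape a [pulse_shape()].
#' @param fs sampling frequency in Hz.
#' @param period_s beat period in seconds.
#' @param params a [preprocess_params()] object.
#' @return dimensionless area, or `NA` when delineation fails.
#' @export
measured_pulse_area <- function(shape, fs = 100, period_s = 0.8,
                                params = preprocess_params()) {
  beat <- generate_beat(shape, period_s, fs)
  x <- rep(beat, 3)
  sm <- tryCatch(savgol_smooth(x, params$sg_order, params$sg_frame),
                 error = function(e) x)
  lm <- delineate_beats(sm, fs, params)
  if (nrow(lm) < 1) return(NA_real_)
  mid <- which.min(abs(lm$onset - length(beat)))
  b <- tryCatch(
    normalize_beat(sm, lm$onset[mid], lm$peak[mid], lm$end[mid], fs,
                   params$beat_length),
    error = function(e) NULL
  )
  if (is.null(b)) return(NA_real_)
  total_area(b)
}

# Solve the dicrotic relative amplitude so the pulse area hits `target`.
# With `fs` and `period_s` given, the objective is the measured area
# (see measured_pulse_area); otherwise the analytic one.  Returns the
# input shape with the amplitude clamped to the nearest bound when no
# root exists inside the bounds.
calibrate_dicrotic_amp <- function(shape, target, bounds = c(0.02, 0.60),
                                   fs = NULL, period_s = 0.8) {
  f <- function(a) {
    s <- shape
    s$dicrotic_rel_amp <- a
    area <- if (is.null(fs)) pulse_shape_area(s) else {
      ma <- measured_pulse_area(s, fs, period_s)
      if (is.na(ma)) pulse_shape_area(s) else ma
    }
    area - target
  }
  lo <- f(bounds[1]); hi <- f(bounds[2])
  if (is.na(lo) || is.na(hi) || lo * hi > 0) {
    shape$dicrotic_rel_amp <- if (abs(lo) < abs(hi)) bounds[1] else bounds[2]
    return(shape)
  }
  root <- stats::uniroot(f, interval = bounds, tol = 1e-6)$root
  shape$dicrotic_rel_amp <- root
  shape
}

# Deterministic archetype counts for n subjects given mixture weights.
.archetype_counts <- function(weights, n) {
  diff(c(0L, round(cumsum(weights) * n)))
}

# Draw one subject's individual morphology and heart rate from a class
# mixture.  Uses the current RNG stream.  The equal-area solve targets
# the measured (pipeline) area at the subject's own sampling rate and
# heart rate.
.draw_subject <- function(config, class_label, archetype_id) {
  mix <- if (class_label == "anesthesia") config$class1_shape else
    config$class0_shape
  base <- mix$shapes[[archetype_id]]
  jit <- config$subject_jitter
  sh <- base
  sh$systolic_center <- base$systolic_center + rnorm(1, 0, jit$center_sd)
  sig_fac <- exp(rnorm(1, 0, jit$sigma_rel_sd))
  sh$systolic_sigma <- base$systolic_sigma * sig_fac
  sh$systolic_sigma_left <- base$systolic_sigma_left * sig_fac
  sh$dicrotic_center <- sh$systolic_center +
    (base$dicrotic_center - base$systolic_center) +
    rnorm(1, 0, jit$dicrotic_center_sd)
  sh$dicrotic_sigma <- base$dicrotic_sigma * exp(rnorm(1, 0, jit$sigma_rel_sd))
  hr <- max(40, rnorm(1, config$heart_rate_mean, config$heart_rate_sd))
  if (!is.null(config$pulse_area_target)) {
    target <- config$pulse_area_target
    if (!is.null(jit$area_rel_sd) && jit$area_rel_sd > 0) {
      target <- target * exp(rnorm(1, 0, jit$area_rel_sd))
    }
    fs <- unname(config$fs[class_label])
    sh <- calibrate_dicrotic_amp(sh, target,
                                 bounds = config$dicrotic_bounds,
                                 fs = fs, period_s = 60 / hr)
  }
  list(shape = sh, hr_bpm = hr, archetype = mix$names[archetype_id])
}

#' Generate one subject's synthetic PPG record
#'
#' Concatenates beats whose periods are drawn from the subject's heart-rate
#' distribution (junctions blended by a 2-sample linear crossfade), then
#' adds respiratory baseline wander, a powerline sinusoid, white noise, and
#' Poisson-timed motion (saturation) artefacts.  Fully reproducible from
#' the config seed, subject index and class.
#'
#' @param config a [cohort_config()].
#' @param subject_index subject number within the class (1-based).
#' @param class_label `"anesthesia"` or `"non_anesthesia"` (or 0/1).
#' @return an object of class `ppg_record` with fields `samples`, `fs`,
#'   `subject_id`, `label`, `source`, and generator ground truth in `meta`.
#' @export
generate_record <- function(config, subject_index, class_label) {
  stopifnot(inherits(config, "ppg_cohort_config"), subject_index >= 1)
  label <- as_anes_label(class_label)
  if (config$record_seconds < 5) {
    stop("record_seconds must be at least 5 (one analysis window)")
  }
  cls <- as.integer(label) - 1L  # 0 = non_anesthesia, 1 = anesthesia
  mix <- if (cls == 1L) config$class1_shape else config$class0_shape
  counts <- .archetype_counts(mix$weights, config$n_subjects_per_class)
  archetype_id <- findInterval(subject_index, cumsum(counts),
                               left.open = TRUE) + 1L
  archetype_id <- min(archetype_id, length(mix$shapes))
  seed <- derive_seed(config$seed, paste0("record/", cls, "/", subject_index))
  withr::with_seed(seed, {
    subj <- .draw_subject(config, as.character(label), archetype_id)
    fs <- unname(config$fs[as.character(label)])
    n_total <- round(config$record_seconds * fs)
    mean_period <- 60 / subj$hr_bpm
    samples <- numeric(0)
    periods <- numeric(0)
    while (length(samples) < n_total + round(mean_period * fs)) {
      p <- rnorm(1, mean_period, config$period_jitter_sd * mean_period)
      p <- min(max(p, 0.7 * mean_period), 1.3 * mean_period)
      beat <- generate_beat(subj$shape, p, fs)
      if (length(samples) >= 2 && length(beat) >= 2) {
        # 2-sample linear crossfade across the junction
        j <- length(samples)
        a <- samples[j - 1]; b <- beat[2]
        samples[j] <- (2 * a + b) / 3
        beat[1] <- (a + 2 * b) / 3
      }
      samples <- c(samples, beat)
      periods <- c(periods, p)
    }
    samples <- samples[seq_len(n_total)]
    tt <- (seq_len(n_total) - 1) / fs
    nz <- config$noise
    clean_max <- max(samples)
    if (nz$baseline_amp > 0) {
      samples <- samples +
        nz$baseline_amp * sin(2 * pi * nz$baseline_freq * tt + runif(1, 0, 2 * pi))
    }
    if (nz$powerline_amp > 0) {
      samples <- samples +
        nz$powerline_amp * sin(2 * pi * nz$powerline_freq * tt + runif(1, 0, 2 * pi))
    }
    if (nz$white_sd > 0) samples <- samples + rnorm(n_total, 0, nz$white_sd)
    n_bursts <- if (nz$motion_burst_rate > 0) {
      rpois(1, nz$motion_burst_rate * config$record_seconds / 60)
    } else 0L
    if (n_bursts > 0) {
      rail <- clean_max + nz$motion_burst_amp
      ramp <- round(0.1 * fs); hold <- round(0.3 * fs)
      for (b in seq_len(n_bursts)) {
        start <- 1L + floor(runif(1, 0, max(1, n_total - (2 * ramp + hold))))
        w <- c(seq(0, 1, length.out = ramp), rep(1, hold),
               seq(1, 0, length.out = ramp))
        idx <- start + seq_along(w) - 1L
        keep <- idx <= n_total
        samples[idx[keep]] <- (1 - w[keep]) * samples[idx[keep]] +
          w[keep] * rail
      }
    }
    prefix <- if (cls == 1L) "A" else "N"
    structure(
      list(samples = samples, fs = fs,
           subject_id = sprintf("%s%02d", prefix, subject_index),
           label = label, source = "synthetic",
           meta = list(shape = subj$shape, hr_bpm = subj$hr_bpm,
                       archetype = subj$archetype,
                       beat_periods = periods, n_bursts = n_bursts)),
      class = "ppg_record"
    )
  })
}

#' Construct a PPG record from raw samples
#'
#' @param samples numeric amplitude series.
#' @param fs sampling frequency in Hz.
#' @param subject_id subject identifier.
#' @param label class label (see [as_anes_label()]).
#' @param source provenance tag (`"synthetic"`, `"csv"`, `"wfdb"`).
#' @return a `ppg_record` object.
#' @export
ppg_record <- function(samples, fs, subject_id, label, source = "csv") {
  stopifnot(is.numeric(samples), length(samples) > 0, fs > 0)
  structure(list(samples = as.numeric(samples), fs = fs,
                 subject_id = as.character(subject_id),
                 label = as_anes_label(label), source = source,
                 meta = list()),
            class = "ppg_record")
}

#' @export
print.ppg_record <- function(x, ...) {
  cat(sprintf("<ppg_record> %s [%s] %.1f s @ %g Hz (%s)\n",
              x$subject_id, as.character(x$label),
              length(x$samples) / x$fs, x$fs, x$source))
  invisible(x)
}

#' Generate a full two-class synthetic cohort
#'
#' @param config a [cohort_config()].
#' @return list of `ppg_record` objects (class `ppg_cohort`), non-anesthesia
#'   subjects first; subject ids are unique.
#' @export
generate_cohort <- function(config) {
  stopifnot(inherits(config, "ppg_cohort_config"))
  records <- c(
    lapply(seq_len(config$n_subjects_per_class), function(i)
      generate_record(config, i, "non_anesthesia")),
    lapply(seq_len(config$n_subjects_per_class), function(i)
      generate_record(config, i, "anesthesia"))
  )
  ids <- vapply(records, `[[`, character(1), "subject_id")
  if (anyDuplicated(ids)) stop("internal error: duplicate subject ids")
  structure(records, class = "ppg_cohort")
}

#' @export
print.ppg_cohort <- function(x, ...) {
  labs <- vapply(x, function(r) as.character(r$label), character(1))
  cat(sprintf("<ppg_cohort> %d records (%d anesthesia, %d non-anesthesia)\n",
              length(x), sum(labs == "anesthesia"),
              sum(labs == "non_anesthesia")))
  invisible(x)
}
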