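# Shared fixture builders.  All synthetic inputs are generated in code;
# no stored data files.

# Wrap a normalized amplitude series as a beat object (markers only read
# $normalized).
as_beat <- function(y, period_s = 0.8, fs = 100) {
  structure(list(normalized = y, period_s = period_s, source_fs = fs,
                 peak_frac = (which.max(y) - 1) / (length(y) - 1)),
            class = "ppg_beat")
}

# Symmetric triangle pulse: 0 at both ends, 1 at the midpoint sample.
# Use odd L so the peak lies exactly on a grid point.
triangle_beat <- function(L = 101) {
  x <- seq(0, 1, length.out = L)
  as_beat(1 - 2 * abs(x - 0.5))
}

# Half-sine pulse over the full beat.
halfsine_beat <- function(L = 100) {
  x <- seq(0, 1, length.out = L)
  as_beat(sin(pi * x))
}

# Gaussian pulse of known sigma (in beat-fraction units), renormalized so
# min = 0 and max = 1.
gaussian_beat <- function(sigma = 0.08, center = 0.5, L = 100) {
  x <- seq(0, 1, length.out = L)
  y <- exp(-(x - center)^2 / (2 * sigma^2))
  y <- (y - min(y)) / (max(y) - min(y))
  as_beat(y)
}

# A segment object from raw samples.
make_segment <- function(samples, fs = 100, subject_id = "T01",
                         label = "non_anesthesia", start_time = 0) {
  structure(list(samples = samples, fs = fs, subject_id = subject_id,
                 label = as_anes_label(label), start_time = start_time,
                 quality_ok = NA, quality_reason = "unscreened"),
            class = "ppg_segment")
}

# Small noiseless cohort config around a single shape.
quiet_config <- function(shape, n = 2, seconds = 20, fs = 100, seed = 7,
                         hr = 60, hr_sd = 0, jitter = 0) {
  cohort_config(
    n_subjects_per_class = n, record_seconds = seconds, fs = fs,
    heart_rate_mean = hr, heart_rate_sd = hr_sd, period_jitter_sd = jitter,
    class0_shape = shape, class1_shape = shape, noise = noise_none(),
    subject_jitter = list(center_sd = 0, sigma_rel_sd = 0,
                          dicrotic_center_sd = 0),
    seed = seed
  )
}

# A reference analytic pulse with dicrotic wave and diastolic runoff,
# matching the default preset's typical non-anesthesia morphology.
reference_shape <- function() {
  pulse_shape(0.25, 0.088, 0.50, 0.11, 0.40,
              runoff_amp = 0.30, runoff_tau = 0.25)
}

# Feature table with grouped subjects for split/CV tests: `spread`
# controls class separation of the single feature.
toy_feature_table <- function(n_subjects = 20, segments_each = 10,
                              spread = 3, seed = 1) {
  withr::with_seed(seed, {
    subs <- sprintf("S%02d", seq_len(n_subjects))
    label <- rep(c("non_anesthesia", "anesthesia"),
                 length.out = n_subjects)
    rows <- do.call(rbind, lapply(seq_len(n_subjects), function(i) {
      center <- if (label[i] == "anesthesia") spread else 0
      data.frame(subject_id = subs[i], label = label[i],
                 segment_start = seq_len(segments_each) - 1,
                 n_beats = 4,
                 f1 = rnorm(segments_each, center),
                 f2 = rnorm(segments_each, center / 2))
    }))
    rows
  })
}
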