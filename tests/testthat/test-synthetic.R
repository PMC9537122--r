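test_that("generate_beat places the systolic peak and the onset correctly", {
  sh <- pulse_shape(0.3, 0.05, 0.6, 0.1, 0)
  beat <- generate_beat(sh, period_s = 1, fs = 200)
  expect_length(beat, 200)
  # single-Gaussian pulse: argmax at systolic_center within one sample
  expect_lte(abs((which.max(beat) - 1) / 200 - 0.3), 1 / 200)
  expect_equal(beat[1], 0)
  expect_equal(which.min(beat[1:which.max(beat)]), 1)
})

test_that("generate_beat matches the analytic Gaussian half-amplitude width", {
  sigma <- 0.04
  sh <- pulse_shape(0.5, sigma, 0.9, 0.05, 0)
  fs <- 1000; period <- 1
  beat <- generate_beat(sh, period, fs)
  half <- max(beat) / 2
  above <- which(beat >= half)
  width_s <- (max(above) - min(above)) / fs
  expect_equal(width_s, 2 * sigma * sqrt(2 * log(2)) * period,
               tolerance = 2e-2)
})

test_that("generate_beat is deterministic and validates its inputs", {
  sh <- pulse_shape(0.3, 0.1, 0.6, 0.11, 0.3)
  expect_identical(generate_beat(sh, 0.8, 100), generate_beat(sh, 0.8, 100))
  expect_error(generate_beat(sh, -1, 100), "positive")
  expect_error(generate_beat(sh, 0.8, 0), "positive")
  expect_error(generate_beat(sh, 0.05, 100), "10 samples")
})

test_that("noiseless records contain the expected number of beats", {
  cfg <- quiet_config(reference_shape(), seconds = 20, hr = 60)
  rec <- generate_record(cfg, 1, "non_anesthesia")
  expect_equal(length(rec$samples), 20 * 100)
  lm <- delineate_beats(rec$samples, rec$fs)
  expect_gte(nrow(lm), 19)
  expect_lte(nrow(lm), 21)
})

test_that("powerline noise shows up at the configured frequency", {
  sh <- reference_shape()
  cfg <- cohort_config(
    n_subjects_per_class = 1, record_seconds = 20, fs = 125,
    heart_rate_mean = 72, heart_rate_sd = 0, period_jitter_sd = 0,
    class0_shape = sh, class1_shape = sh,
    noise = noise_params(baseline_amp = 0, powerline_amp = 0.05,
                         powerline_freq = 50, white_sd = 0,
                         motion_burst_rate = 0, motion_burst_amp = 0),
    seed = 11
  )
  rec <- generate_record(cfg, 1, "anesthesia")
  spec <- stats::spec.pgram(stats::ts(rec$samples, frequency = 125),
                            plot = FALSE, taper = 0, detrend = TRUE)
  band <- which(abs(spec$freq - 50) < 2)
  peak_f <- spec$freq[band[which.max(spec$spec[band])]]
  # local periodogram maximum within one bin of 50 Hz
  expect_lt(abs(peak_f - 50), 0.1)
})

test_that("records are bitwise reproducible from the seed", {
  cfg <- default_cohort_config(seed = 5, n_subjects_per_class = 2,
                               record_seconds = 10)
  r1 <- generate_record(cfg, 2, "anesthesia")
  r2 <- generate_record(cfg, 2, "anesthesia")
  expect_identical(r1$samples, r2$samples)
  r3 <- generate_record(cfg, 1, "anesthesia")
  expect_false(identical(r1$samples, r3$samples))
})

test_that("generate_record refuses records shorter than one window", {
  cfg <- quiet_config(reference_shape())
  cfg$record_seconds <- 3
  expect_error(generate_record(cfg, 1, "anesthesia"), "at least 5")
})

test_that("generate_cohort honors counts, labels and unique ids", {
  cfg <- default_cohort_config(seed = 3, n_subjects_per_class = 2,
                               record_seconds = 10)
  co <- generate_cohort(cfg)
  expect_length(co, 4)
  labs <- vapply(co, function(r) as.character(r$label), character(1))
  expect_equal(sum(labs == "anesthesia"), 2)
  ids <- vapply(co, `[[`, character(1), "subject_id")
  expect_equal(anyDuplicated(ids), 0L)
  co2 <- generate_cohort(cfg)
  expect_identical(lapply(co, `[[`, "samples"), lapply(co2, `[[`, "samples"))
})

test_that("identical class shapes yield no marker association", {
  # null cohort: both classes share one morphology; every point-biserial
  # correlation should be negligible at >= 200 segments
  sh <- reference_shape()
  cfg <- cohort_config(
    n_subjects_per_class = 9, record_seconds = 60,
    fs = c(non_anesthesia = 125, anesthesia = 100),
    heart_rate_mean = 75, heart_rate_sd = 6, period_jitter_sd = 0.02,
    class0_shape = sh, class1_shape = sh, noise = noise_params(),
    subject_jitter = list(center_sd = 0.009, sigma_rel_sd = 0.03,
                          dicrotic_center_sd = 0.008),
    pulse_area_target = pulse_shape_area(sh),
    seed = 202
  )
  tab <- extract_features(generate_cohort(cfg))
  expect_gte(nrow(tab), 200)
  y <- as.integer(as_anes_label(tab$label)) - 1L
  r <- vapply(marker_names(), function(m) point_biserial(tab[[m]], y),
              numeric(1))
  expect_lt(max(abs(r)), 0.2)
})

test_that("the default preset shifts rising time but not pulse area", {
  cfg <- default_cohort_config(seed = 17, n_subjects_per_class = 8,
                               record_seconds = 30)
  tab <- extract_features(generate_cohort(cfg))
  y <- as_anes_label(tab$label)
  rt0 <- mean(tab$rising_time[y == "non_anesthesia"])
  rt1 <- mean(tab$rising_time[y == "anesthesia"])
  expect_gt(rt1 - rt0, 0.05)
  a0 <- mean(tab$total_area[y == "non_anesthesia"])
  a1 <- mean(tab$total_area[y == "anesthesia"])
  expect_lt(abs(a1 - a0) / a0, 0.02)
})

test_that("the equal-area calibration hits its target", {
  sh <- pulse_shape(0.3, 0.09, 0.58, 0.11, 0.25,
                    runoff_amp = 0.3, runoff_tau = 0.25)
  out <- anespulse:::calibrate_dicrotic_amp(sh, 0.40)
  expect_equal(pulse_shape_area(out), 0.40, tolerance = 1e-4)
})
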