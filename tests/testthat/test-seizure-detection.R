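# Build a recording with one hand-planted discharge train on channel 1.
planted_recording <- function(seed, event_class = "spike_wave", f = 2.8,
                              amp = 80, onset = 200, dur = 30, fs = 250,
                              session = 480, channels = 1L, delays = NULL) {
  marks <- quick_marks(session)
  x <- generate_baseline(session, fs = fs, n_channels = 4, seed = seed)
  if (is.null(delays)) delays <- rep(0, length(channels))
  for (k in seq_along(channels)) {
    seg <- generate_ictal_segment(event_class, dur - delays[k], fs, f, amp,
                                  seed = seed + k)
    i0 <- round((onset + delays[k]) * fs) + 1
    x[i0:(i0 + length(seg) - 1), channels[k]] <-
      x[i0:(i0 + length(seg) - 1), channels[k]] + seg
  }
  as_recording(x, fs, marks)
}

test_that("baseline statistics use only the pre-injection control window", {
  rec <- baseline_recording(seed = 4)
  bs <- compute_baseline_stats(rec)
  expect_length(bs$mad, 4L)
  # generator noise scale: median 2-s p-p calibrated to 15 uV
  expect_true(all(bs$p2p_ref > 15 * 0.8 & bs$p2p_ref < 15 * 1.2))
  # causality: perturbing post-injection data does not change the stats
  rec2 <- rec
  post <- (90 * rec$fs + 1):nrow(rec$samples)
  rec2$samples[post, ] <- rec2$samples[post, ] + 100
  bs2 <- compute_baseline_stats(rec2)
  expect_identical(bs$mad, bs2$mad)
  expect_identical(bs$p2p_ref, bs2$p2p_ref)
})

test_that("degenerate or too-short control windows are rejected", {
  zero <- as_recording(matrix(0, 250 * 200, 4), fs = 250, quick_marks(200))
  expect_error(compute_baseline_stats(zero), "degenerate|zero")
  short <- as_recording(matrix(rnorm(250 * 200), ncol = 4), fs = 250,
                        marks = timeline_marks(0, 30, 60, 200))
  expect_error(compute_baseline_stats(short), "control window")
})

test_that("a planted fast spike-wave train is detected with high overlap", {
  rec <- bandpass(planted_recording(seed = 11, f = 2.8, onset = 200, dur = 30))
  ev <- detect_seizures(rec)
  expect_identical(nrow(ev), 1L)
  expect_gte(interval_jaccard(200, 230, ev$onset_s, ev$offset_s), 0.8)
})

test_that("slow (1 Hz) spike trains do not satisfy the >2.5 Hz repetition rule", {
  fs <- 250
  marks <- quick_marks()
  x <- generate_baseline(480, fs = fs, n_channels = 4, seed = 12)
  # 1 Hz monophasic spike train, 30 s, well above amplitude threshold
  t_idx <- round(seq(200, 230, by = 1) * fs)
  spike <- 60 * sin(pi * seq_len(round(0.04 * fs)) / round(0.04 * fs))
  for (i0 in t_idx) x[i0:(i0 + length(spike) - 1), 1] <-
    x[i0:(i0 + length(spike) - 1), 1] + spike
  ev <- detect_seizures(bandpass(as_recording(x, fs, marks)))
  expect_identical(nrow(ev), 0L)
})

test_that("pure baseline produces no detections at default thresholds", {
  for (seed in c(5, 6, 7)) {
    ev <- detect_seizures(bandpass(baseline_recording(seed)))
    expect_identical(nrow(ev), 0L)
  }
})

test_that("detection is invariant to a global sign flip", {
  rec <- bandpass(planted_recording(seed = 13, event_class = "theta", f = 6,
                                    amp = 120))
  flipped <- rec
  flipped$samples <- -flipped$samples
  ev1 <- detect_seizures(rec)
  ev2 <- detect_seizures(flipped)
  expect_equal(ev1[c("onset_s", "offset_s")], ev2[c("onset_s", "offset_s")])
})

test_that("candidates never start before the stabilization window ends", {
  # plant a discharge straddling the injection: only the post-stabilization
  # part may be reported
  rec <- bandpass(planted_recording(seed = 14, onset = 80, dur = 80, f = 2.9))
  ev <- detect_seizures(rec)
  expect_true(all(ev$onset_s >= rec$marks$stabilization_end))
})

test_that("segment_events merges within the gap and drops short events", {
  cand <- list(
    data.frame(onset_s = c(100, 105), offset_s = c(104, 109)),  # 1 s apart
    data.frame(onset_s = numeric(0), offset_s = numeric(0)),
    data.frame(onset_s = 200, offset_s = 204),                  # isolated 4 s
    data.frame(onset_s = numeric(0), offset_s = numeric(0)))
  out <- segment_events(cand, merge_gap = 2, min_duration = 5)
  expect_identical(nrow(out), 1L)
  expect_equal(out$onset_s, 100)
  expect_equal(out$offset_s, 109)
  expect_equal(out$duration_s, 9)
  expect_true(is.na(out$onset_ch3_s))
  expect_error(segment_events(cand, merge_gap = -1), "merge_gap")
})

test_that("overlapping multichannel candidates unify into one event", {
  cand <- list(
    data.frame(onset_s = 100.0, offset_s = 130),
    data.frame(onset_s = 100.8, offset_s = 131),
    data.frame(onset_s = 101.5, offset_s = 129),
    data.frame(onset_s = 102.0, offset_s = 132))
  out <- segment_events(cand)
  expect_identical(nrow(out), 1L)
  expect_equal(out$onset_s, 100)
  expect_equal(out$offset_s, 132)
  expect_equal(as.numeric(out[paste0("onset_ch", 1:4, "_s")]),
               c(100, 100.8, 101.5, 102))
})

test_that("events are classified by dominant frequency into the two patterns", {
  cases <- list(list(f = 6, class = "theta", ec = "theta"),
                list(f = 2.5, class = "spike_wave", ec = "spike_wave"))
  for (cs in cases) {
    rec <- bandpass(planted_recording(seed = 15, event_class = cs$ec,
                                      f = cs$f, amp = 100))
    ev <- detect_seizures(rec)
    expect_identical(nrow(ev), 1L)
    expect_identical(ev$class, cs$class)
    expect_equal(ev$dominant_freq_hz, cs$f, tolerance = 0.5 / cs$f)
  }
})

test_that("oscillations outside both class bands are classified as other", {
  fs <- 250
  marks <- quick_marks()
  x <- generate_baseline(480, fs = fs, n_channels = 4, seed = 16)
  t <- seq(1 / fs, 30, by = 1 / fs)
  x[(200 * fs + 1):(230 * fs), 1] <- x[(200 * fs + 1):(230 * fs), 1] +
    50 * sin(2 * pi * 10 * t)
  ev <- detect_seizures(bandpass(as_recording(x, fs, marks)))
  expect_identical(nrow(ev), 1L)
  expect_identical(ev$class, "other")
})

test_that("the status-epilepticus flag uses a strict 300 s boundary", {
  ev <- data.frame(duration_s = c(301, 300, 299))
  out <- flag_se(ev)
  expect_identical(out$is_se, c(TRUE, FALSE, FALSE))
})

test_that("a long planted discharge is flagged SE-like and can stay focal", {
  rec <- bandpass(planted_recording(seed = 17, f = 2.6, onset = 130,
                                    dur = 310, session = 600))
  ev <- detect_seizures(rec)
  expect_identical(nrow(ev), 1L)
  expect_true(ev$is_se)
  expect_identical(ev$spread, "focal")
})

test_that("generalized planted events unify with four per-channel onsets", {
  rec <- bandpass(planted_recording(seed = 18, event_class = "theta", f = 6,
                                    amp = 120, channels = 1:4,
                                    delays = c(0.8, 0, 1.4, 1.9)))
  ev <- detect_seizures(rec)
  expect_identical(nrow(ev), 1L)
  expect_identical(ev$spread, "generalized")
  ons <- as.numeric(ev[paste0("onset_ch", 1:4, "_s")])
  expect_true(all(!is.na(ons)))
  expect_identical(ev$onset_channel, 2L)
})

test_that("invalid detector parameters are rejected", {
  expect_error(detector_params(k = 0), "k")
  expect_error(detector_params(k = -2), "k")
  expect_error(detector_params(merge_gap = -1), "merge_gap")
})
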