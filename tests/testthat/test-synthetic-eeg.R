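test_that("baseline stays under the 20 uV peak-to-peak ceiling and is band-limited", {
  x <- generate_baseline(60, fs = 500, n_channels = 4, seed = 1)
  expect_equal(dim(x), c(30000L, 4L))
  for (ch in 1:4) {
    expect_lte(median(sliding_p2p(x[, ch], 500)), 20)
  }
  # spectral content: under 1% of power above 45 Hz (periodogram oracle)
  expect_lt(oracle_highband_fraction(x[, 1], 500, 45), 0.01)
  expect_lt(oracle_highband_fraction(x[, 3], 500, 45), 0.01)
})

test_that("baseline generation is reproducible and rejects bad arguments", {
  a <- generate_baseline(5, fs = 250, seed = 99)
  b <- generate_baseline(5, fs = 250, seed = 99)
  expect_identical(a, b)
  c <- generate_baseline(5, fs = 250, seed = 100)
  expect_false(identical(a, c))
  expect_error(generate_baseline(0, fs = 250), "duration")
  expect_error(generate_baseline(-3, fs = 250), "duration")
  expect_error(generate_baseline(5, fs = 0), "fs")
  expect_error(generate_baseline(5, fs = 100), "200")
})

test_that("ictal segments have their spectral peak at the requested frequency", {
  cases <- list(list(class = "spike_wave", dur = 30, f = 2.5, amp = 80),
                list(class = "theta", dur = 10, f = 6, amp = 100),
                list(class = "theta", dur = 20, f = 5.5, amp = 150),
                list(class = "spike_wave", dur = 40, f = 2.0, amp = 60))
  for (cs in cases) {
    seg <- generate_ictal_segment(cs$class, cs$dur, fs = 500,
                                  dominant_freq = cs$f, amplitude_pp = cs$amp,
                                  seed = 5)
    expect_equal(oracle_peak_freq(seg, 500), cs$f, tolerance = 0.5 / cs$f)
    expect_equal(max(seg) - min(seg), cs$amp, tolerance = 0.05)
  }
})

test_that("ictal segments reject out-of-band frequencies and weak amplitudes", {
  expect_error(generate_ictal_segment("theta", 10, 500, 2, 100), "band")
  expect_error(generate_ictal_segment("spike_wave", 10, 500, 6, 100), "band")
  expect_error(generate_ictal_segment("theta", 10, 500, 6, 15), "20")
})

test_that("non-responders yield baseline-only recordings", {
  prof <- quick_profile(responder = FALSE)
  out <- generate_recording(prof, quick_marks(), fs = 250, seed = 3)
  expect_identical(nrow(out$truth), 0L)
  # baseline only: whole-session amplitudes stay near baseline scale
  expect_lt(max(abs(out$recording$samples)), 40)
})

test_that("ground-truth events respect the timeline and duration rules", {
  marks <- quick_marks()
  for (seed in 1:60) {
    tr <- draw_events(quick_profile(count_mean = 3), marks, seed = seed)
    if (!nrow(tr)) next
    expect_true(all(tr$onset_s >= marks$stabilization_end))
    expect_true(all(tr$duration_s >= 5))
    expect_true(all(tr$onset_s + tr$duration_s <= marks$session_end))
    # non-overlapping
    if (nrow(tr) > 1) {
      expect_true(all(diff(tr$onset_s) >= tr$duration_s[-nrow(tr)]))
    }
  }
})

test_that("planted event counts follow the profile distribution", {
  # truncated-Poisson mean should be recovered within 2 SE over many draws
  marks <- timeline_marks(0, 600, 690, 3600)
  for (sex in c("male", "female")) {
    prof <- animal_profile(sex)
    counts <- vapply(1:120, function(s) {
      nrow(draw_events(prof, marks, seed = s))
    }, numeric(1))
    se <- sd(counts) / sqrt(length(counts))
    expect_lt(abs(mean(counts) - prof$count_mean), 2 * se + 0.02)
    expect_true(all(counts >= 1))
  }
})

test_that("planted durations and latencies match the profile means", {
  marks <- timeline_marks(0, 600, 690, 3600)
  prof <- animal_profile("male")
  trs <- lapply(1:80, function(s) draw_events(prof, marks, seed = s))
  durs <- unlist(lapply(trs, `[[`, "duration_s"))
  lats <- vapply(trs, function(tr) min(tr$onset_s) - marks$injection_time,
                 numeric(1))
  expect_lt(abs(mean(durs) - prof$duration_mean),
            2 * sd(durs) / sqrt(length(durs)) + 1)
  expect_lt(abs(mean(lats) - prof$latency_mean),
            2 * sd(lats) / sqrt(length(lats)) + 10)
})

test_that("a degenerate count distribution plants the exact count", {
  # count_mean barely above 1 makes the truncated Poisson essentially
  # deterministic at 1
  prof <- quick_profile(count_mean = 1.0001)
  for (seed in 1:5) {
    tr <- draw_events(prof, quick_marks(), seed = seed)
    expect_identical(nrow(tr), 1L)
  }
})

test_that("the 17-animal preset cohort has the documented structure", {
  coh <- generate_cohort(cohort_preset("ptz17"), seed = 42, truth_only = TRUE)
  expect_length(coh, 17L)
  sexes <- vapply(coh, function(a) a$profile$sex, "")
  expect_identical(sum(sexes == "male"), 8L)
  expect_identical(sum(sexes == "female"), 9L)
  n_events <- vapply(coh, function(a) nrow(a$truth), numeric(1))
  expect_identical(sum(n_events == 0), 3L)
  nr_sex <- sexes[n_events == 0]
  expect_identical(sum(nr_sex == "male"), 1L)
  expect_identical(sum(nr_sex == "female"), 2L)
})

test_that("cohort generation is deterministic and validates its config", {
  a <- generate_cohort(cohort_preset("ptz14"), seed = 7, truth_only = TRUE)
  b <- generate_cohort(cohort_preset("ptz14"), seed = 7, truth_only = TRUE)
  expect_identical(lapply(a, `[[`, "truth"), lapply(b, `[[`, "truth"))
  expect_identical(generate_cohort(cohort_config(0, 0), seed = 1), list())
  expect_error(cohort_config(-1, 5), "non-negative")
  expect_error(cohort_config(2, 2, n_nonresponder_male = 3), "exceed")
})

test_that("recordings superimpose events at the planted locations", {
  prof <- quick_profile(count_mean = 1.0001, p_focal = 1)
  out <- generate_recording(prof, quick_marks(), fs = 250, seed = 21)
  tr <- out$truth
  expect_identical(nrow(tr), 1L)
  ch <- tr$onset_channel
  fs <- 250
  i0 <- round(tr$onset_s * fs); i1 <- round((tr$onset_s + tr$duration_s) * fs)
  inside <- out$recording$samples[i0:i1, ch]
  outside <- out$recording$samples[1:(120 * fs), ch]
  expect_gt(max(abs(inside)), 3 * max(abs(outside)))
  # uninvolved channels stay at baseline amplitude inside the event window
  for (other in setdiff(1:4, ch)) {
    expect_lt(max(abs(out$recording$samples[i0:i1, other])), 40)
  }
})
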