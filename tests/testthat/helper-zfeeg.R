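# Shared fixtures: short sessions and modest profiles keep unit tests fast;
# full-hour sessions are exercised in the acceptance suite.

quick_marks <- function(session = 480) {
  timeline_marks(control_start = 0, injection_time = 90,
                 stabilization_end = 120, session_end = session)
}

quick_profile <- function(sex = "male", ...) {
  defaults <- list(sex = sex, count_mean = 2, duration_mean = 20,
                   duration_cv = 0.3, latency_mean = 120, latency_cv = 0.3,
                   id = "T01")
  args <- utils::modifyList(defaults, list(...))
  do.call(animal_profile, args)
}

# Independent periodogram oracle (stats::spec.pgram, not the package's own
# FFT helper): frequency of the largest spectral peak.
oracle_peak_freq <- function(x, fs) {
  sp <- stats::spec.pgram(stats::ts(x, frequency = fs), taper = 0,
                          detrend = TRUE, plot = FALSE)
  sp$freq[which.max(sp$spec)]
}

# Fraction of periodogram power above `f0` Hz.
oracle_highband_fraction <- function(x, fs, f0) {
  sp <- stats::spec.pgram(stats::ts(x, frequency = fs), taper = 0,
                          detrend = TRUE, plot = FALSE)
  sum(sp$spec[sp$freq > f0]) / sum(sp$spec)
}

interval_jaccard <- function(a0, a1, b0, b1) {
  inter <- max(0, min(a1, b1) - max(a0, b0))
  union <- max(a1, b1) - min(a0, b0)
  inter / union
}

# Greedy one-to-one matching of detected against planted events at a Jaccard
# threshold; returns c(tp, n_truth, n_detected).
match_events <- function(truth, detected, jaccard = 0.5) {
  if (!nrow(truth) || !nrow(detected)) {
    return(c(tp = 0, n_truth = nrow(truth), n_detected = nrow(detected)))
  }
  used <- rep(FALSE, nrow(detected))
  tp <- 0L
  for (i in seq_len(nrow(truth))) {
    for (j in seq_len(nrow(detected))) {
      if (used[j]) next
      if (interval_jaccard(truth$onset_s[i],
                           truth$onset_s[i] + truth$duration_s[i],
                           detected$onset_s[j], detected$offset_s[j]) >= jaccard) {
        tp <- tp + 1L; used[j] <- TRUE; break
      }
    }
  }
  c(tp = tp, n_truth = nrow(truth), n_detected = nrow(detected))
}

# Baseline-only recording (no events) with the standard short timeline.
baseline_recording <- function(seed, fs = 250, session = 480) {
  marks <- if (session >= 150) quick_marks(session) else
    timeline_marks(0, session / 2, session * 0.6, session)
  x <- generate_baseline(session, fs = fs, n_channels = 4, seed = seed)
  as_recording(x, fs, marks)
}
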