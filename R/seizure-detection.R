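#' Detector parameters
#'
#' @param k amplitude threshold multiplier: a sample is "high-voltage" when
#'   the local rectified peak envelope (sliding maximum of the absolute
#'   signal) exceeds `k` times the per-channel baseline MAD.
#' @param rate_threshold minimum discharge repetition rate, Hz; the seizure
#'   definition in this model requires repetitive discharges faster than
#'   2.5 Hz.
#' @param rate_window sliding window used for the rate estimate, seconds.
#' @param envelope_smooth rectified-envelope smoothing length, seconds.
#' @param merge_gap per-channel candidates closer than this are merged,
#'   seconds.
#' @param min_duration events shorter than this are discarded, seconds
#'   (events under 5 s are excluded by definition).
#' @return an object of class `zf_detector_params`.
#' @export
detector_params <- function(k = 4, rate_threshold = 2.5, rate_window = 2,
                            envelope_smooth = 0.25, merge_gap = 2,
                            min_duration = 5) {
  if (!is.numeric(k) || length(k) != 1L || is.na(k) || k <= 0) {
    stop("`k` must be a single positive number", call. = FALSE)
  }
  if (merge_gap < 0) stop("`merge_gap` must be non-negative", call. = FALSE)
  structure(list(k = k, rate_threshold = rate_threshold,
                 rate_window = rate_window,
                 envelope_smooth = envelope_smooth,
                 merge_gap = merge_gap, min_duration = min_duration),
            class = "zf_detector_params")
}

#' Baseline amplitude statistics from the control window
#'
#' Robust per-channel amplitude scales computed strictly from the
#' pre-injection control window, so that post-injection activity can never
#' contaminate the reference the detector thresholds against.
#'
#' @param recording a `zf_recording` whose marks provide at least 60 s of
#'   control data before the injection.
#' @return an object of class `zf_baseline_stats` with per-channel `mad`
#'   (median absolute deviation, uV) and `p2p_ref` (median 2-s window
#'   peak-to-peak, uV).
#' @export
compute_baseline_stats <- function(recording) {
  stopifnot(inherits(recording, "zf_recording"))
  m <- recording$marks
  fs <- recording$fs
  if (m$injection_time - m$control_start < 60) {
    stop("control window shorter than 60 s; cannot estimate baseline",
         call. = FALSE)
  }
  i0 <- round(m$control_start * fs) + 1L
  i1 <- round(m$injection_time * fs)
  seg <- recording$samples[i0:i1, , drop = FALSE]
  mads <- apply(seg, 2, stats::mad)
  if (any(mads <= 0)) {
    stop("degenerate (zero-variance) control window on channel(s): ",
         paste(which(mads <= 0), collapse = ", "), call. = FALSE)
  }
  p2p <- apply(seg, 2, function(x) stats::median(sliding_p2p(x, fs)))
  structure(list(mad = mads, p2p_ref = p2p, n_channels = ncol(seg)),
            class = "zf_baseline_stats")
}

#' Detect per-channel discharge candidates
#'
#' Implements the operational seizure definition used for adult-zebrafish
#' scalp EEG: a sample belongs to a candidate epileptiform discharge when
#' (i) the local rectified peak envelope (sliding maximum of `|x|` over
#' `envelope_smooth` seconds, which tracks spiky discharges that a moving
#' average would dilute) exceeds `k` times the baseline MAD (the
#' "high-voltage" clause) and (ii) the local discharge repetition rate
#' — peaks of the rectified signal above threshold, counted in a sliding
#' window — exceeds 2.5 per second (the "faster than 2.5 Hz" clause).
#' Candidates are restricted to times at or after the end of the 90-s
#' post-injection stabilization window, which is excluded from analysis.
#'
#' @param recording a (band-passed) `zf_recording`.
#' @param baseline a [compute_baseline_stats()] result.
#' @param params a [detector_params()].
#' @return list (one element per channel) of data.frames with columns
#'   `onset_s`, `offset_s`.
#' @export
detect_discharges <- function(recording, baseline = NULL,
                              params = detector_params()) {
  stopifnot(inherits(recording, "zf_recording"),
            inherits(params, "zf_detector_params"))
  if (is.null(baseline)) baseline <- compute_baseline_stats(recording)
  fs <- recording$fs
  m <- recording$marks
  t_min <- m$stabilization_end
  lapply(seq_len(ncol(recording$samples)), function(ch) {
    x <- recording$samples[, ch]
    thr <- params$k * baseline$mad[ch]
    env <- slide_max(abs(x), round(params$envelope_smooth * fs))
    amp_ok <- env > thr
    # discharge repetition rate: peaks of |x| above thr per sliding window
    pk <- find_peaks(abs(x), threshold = thr)
    pk_ind <- integer(length(x)); pk_ind[pk] <- 1L
    w <- round(params$rate_window * fs)
    cs <- c(0L, cumsum(pk_ind))
    half <- w %/% 2L
    lo <- pmax(seq_along(x) - half, 1L)
    hi <- pmin(seq_along(x) + half, length(x))
    rate <- (cs[hi + 1L] - cs[lo]) / ((hi - lo + 1L) / fs)
    ok <- amp_ok & rate > params$rate_threshold
    # analysis window only
    ok[seq_len(min(length(ok), round(t_min * fs)))] <- FALSE
    r <- rle(ok)
    ends <- cumsum(r$lengths)
    starts <- ends - r$lengths + 1L
    keep <- r$values
    if (!any(keep)) {
      return(data.frame(onset_s = numeric(0), offset_s = numeric(0)))
    }
    data.frame(onset_s = (starts[keep] - 1L) / fs,
               offset_s = ends[keep] / fs)
  })
}

#' Segment candidates into multichannel events
#'
#' Per-channel candidates separated by less than `merge_gap` are merged;
#' candidates that overlap in time across channels are unified into a single
#' event carrying each involved channel's own onset (a propagating discharge
#' is one seizure). Unified events shorter than `min_duration` (default 5 s)
#' are discarded, matching the event-counting convention that excludes
#' sub-5-s discharges.
#'
#' @param candidates per-channel candidate list from [detect_discharges()].
#' @param merge_gap per-channel merge gap, seconds.
#' @param min_duration minimum unified event duration, seconds.
#' @return data.frame with columns onset_s, offset_s, duration_s,
#'   onset_ch1_s..onset_ch4_s (NA when a channel is not involved).
#' @export
segment_events <- function(candidates, merge_gap = 2, min_duration = 5) {
  if (merge_gap < 0) stop("`merge_gap` must be non-negative", call. = FALSE)
  n_ch <- length(candidates)
  merged <- lapply(candidates, merge_intervals, gap = merge_gap)
  all_iv <- do.call(rbind, lapply(seq_len(n_ch), function(ch) {
    iv <- merged[[ch]]
    if (!nrow(iv)) return(NULL)
    cbind(iv, channel = ch)
  }))
  empty <- data.frame(onset_s = numeric(0), offset_s = numeric(0),
                      duration_s = numeric(0),
                      onset_ch1_s = numeric(0), onset_ch2_s = numeric(0),
                      onset_ch3_s = numeric(0), onset_ch4_s = numeric(0))
  if (is.null(all_iv) || !nrow(all_iv)) return(empty)
  all_iv <- all_iv[order(all_iv$onset_s), , drop = FALSE]
  # cluster intervals that overlap across channels (>=1 sample in common)
  grp <- integer(nrow(all_iv))
  g <- 1L; grp[1] <- 1L; cur_end <- all_iv$offset_s[1]
  for (i in seq_len(nrow(all_iv))[-1]) {
    if (all_iv$onset_s[i] < cur_end) {
      grp[i] <- g
      cur_end <- max(cur_end, all_iv$offset_s[i])
    } else {
      g <- g + 1L; grp[i] <- g; cur_end <- all_iv$offset_s[i]
    }
  }
  rows <- lapply(split(all_iv, grp), function(d) {
    ons <- rep(NA_real_, 4)
    for (ch in unique(d$channel)) ons[ch] <- min(d$onset_s[d$channel == ch])
    data.frame(onset_s = min(d$onset_s), offset_s = max(d$offset_s),
               duration_s = max(d$offset_s) - min(d$onset_s),
               onset_ch1_s = ons[1], onset_ch2_s = ons[2],
               onset_ch3_s = ons[3], onset_ch4_s = ons[4])
  })
  out <- do.call(rbind, rows)
  out <- out[out$duration_s >= min_duration, , drop = FALSE]
  rownames(out) <- NULL
  if (!nrow(out)) return(empty)
  out[order(out$onset_s), , drop = FALSE]
}

merge_intervals <- function(iv, gap) {
  if (!nrow(iv)) return(iv)
  iv <- iv[order(iv$onset_s), , drop = FALSE]
  on <- iv$onset_s; off <- iv$offset_s
  keep_on <- on[1]; keep_off <- off[1]
  for (i in seq_along(on)[-1]) {
    j <- length(keep_on)
    if (on[i] - keep_off[j] <= gap) {
      keep_off[j] <- max(keep_off[j], off[i])
    } else {
      keep_on <- c(keep_on, on[i]); keep_off <- c(keep_off, off[i])
    }
  }
  data.frame(onset_s = keep_on, offset_s = keep_off)
}

#' Classify an event by its dominant frequency
#'
#' Dominant frequency is the periodogram argmax in 1-40 Hz of the event's
#' samples on its onset channel. Events with a dominant frequency in
#' 4.5-7.5 Hz are high-amplitude theta discharges; 1.5-3.5 Hz are
#' absence-like spike-wave complexes; anything else is `"other"`.
#'
#' @param event one-row event data.frame (from [segment_events()]).
#' @param recording the `zf_recording` the event was detected in.
#' @return the event row with `class` and `dominant_freq_hz` columns filled.
#' @export
classify_event <- function(event, recording) {
  stopifnot(inherits(recording, "zf_recording"))
  fs <- recording$fs
  ons <- as.numeric(event[paste0("onset_ch", 1:4, "_s")])
  ch <- if (all(is.na(ons))) 1L else which.min(ons)
  i0 <- max(1L, round(event$onset_s * fs) + 1L)
  i1 <- min(nrow(recording$samples), round(event$offset_s * fs))
  pg <- periodogram(recording$samples[i0:i1, ch], fs)
  in_band <- pg$freq >= 1 & pg$freq <= 40
  f_dom <- pg$freq[in_band][which.max(pg$power[in_band])]
  event$dominant_freq_hz <- f_dom
  event$class <- if (f_dom >= 4.5 && f_dom <= 7.5) "theta"
    else if (f_dom >= 1.5 && f_dom <= 3.5) "spike_wave"
    else "other"
  event
}

#' Flag status-epilepticus-like events
#'
#' An event persisting strictly longer than 5 minutes (300 s) is flagged as
#' a status-epilepticus (SE)-like event. SE status is independent of spread:
#' focal SE-like events occur.
#'
#' @param events event data.frame with `duration_s`.
#' @return the events with a logical `is_se` column.
#' @export
flag_se <- function(events) {
  events$is_se <- events$duration_s > 300
  events
}

#' Full per-recording detection pipeline
#'
#' Baseline statistics, candidate detection, segmentation, classification,
#' SE flagging and onset-channel localization in one call.
#'
#' @param recording a `zf_recording` (apply [bandpass()] first if the data
#'   are unfiltered).
#' @param params a [detector_params()].
#' @param baseline optional precomputed [compute_baseline_stats()].
#' @return event data.frame with columns onset_s, offset_s, duration_s,
#'   class, dominant_freq_hz, is_se, spread, onset_channel,
#'   onset_ch1_s..onset_ch4_s.
#' @export
#' @examples
#' prof <- animal_profile("male", count_mean = 2, latency_mean = 60,
#'                        duration_mean = 15)
#' marks <- timeline_marks(0, 90, 120, 420)
#' sim <- generate_recording(prof, marks, fs = 250, seed = 7)
#' ev <- detect_seizures(bandpass(sim$recording))
#' ev[, c("onset_s", "duration_s", "class", "onset_channel")]
detect_seizures <- function(recording, params = detector_params(),
                            baseline = NULL) {
  if (is.null(baseline)) baseline <- compute_baseline_stats(recording)
  cand <- detect_discharges(recording, baseline, params)
  ev <- segment_events(cand, merge_gap = params$merge_gap,
                       min_duration = params$min_duration)
  if (!nrow(ev)) {
    ev$class <- character(0); ev$dominant_freq_hz <- numeric(0)
    ev$is_se <- logical(0); ev$spread <- character(0)
    ev$onset_channel <- integer(0)
    return(ev[event_csv_cols])
  }
  ev <- do.call(rbind, lapply(seq_len(nrow(ev)), function(i) {
    classify_event(ev[i, , drop = FALSE], recording)
  }))
  ev <- flag_se(ev)
  loc <- t(vapply(seq_len(nrow(ev)), function(i) {
    oc <- onset_channel(ev[i, , drop = FALSE])
    c(oc$channel, NA)
  }, numeric(2)))
  ev$onset_channel <- as.integer(loc[, 1])
  ev$spread <- vapply(seq_len(nrow(ev)), function(i) {
    classify_spread(ev[i, , drop = FALSE])
  }, "")
  rownames(ev) <- NULL
  ev[event_csv_cols]
}
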