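#' Default four-channel montage
#'
#' Channel-to-region map for the non-invasive four-electrode array: channels
#' 1 and 2 sit over the right and left telencephalon, channels 3 and 4 over
#' the left and right posterior brain (midbrain/cerebellar area; the
#' anatomical naming of the posterior pair is reported inconsistently in the
#' field, so the labels are configurable).
#'
#' @param labels channel labels (used as EDF signal labels).
#' @param regions per-channel anatomical region names.
#' @param lobes per-channel coarse grouping, `"telencephalon"` or
#'   `"posterior"`.
#' @return data.frame with columns channel, label, region, lobe.
#' @export
default_montage <- function(labels = c("RT_TEL", "LT_TEL", "L_MID", "R_MID"),
                            regions = c("right telencephalon",
                                        "left telencephalon",
                                        "posterior left", "posterior right"),
                            lobes = c("telencephalon", "telencephalon",
                                      "posterior", "posterior")) {
  stopifnot(length(labels) == 4L, length(regions) == 4L, length(lobes) == 4L)
  data.frame(channel = 1:4, label = labels, region = regions, lobe = lobes,
             stringsAsFactors = FALSE)
}

new_recording <- function(samples, fs, marks, montage = default_montage(),
                          subject = list(id = NA_character_, sex = NA_character_)) {
  colnames(samples) <- montage$label[seq_len(ncol(samples))]
  structure(list(samples = samples, fs = fs, marks = marks,
                 montage = montage, subject = subject),
            class = "zf_recording")
}

#' @export
print.zf_recording <- function(x, ...) {
  cat(sprintf("<zf_recording> %d ch x %.0f s @ %g Hz (%s%s)\n",
              ncol(x$samples), nrow(x$samples) / x$fs, x$fs,
              if (is.na(x$subject$id)) "unnamed" else x$subject$id,
              if (is.na(x$subject$sex)) "" else paste0(", ", x$subject$sex)))
  invisible(x)
}

# Pink (1/f-weighted) Gaussian noise, soft low-passed at `f_cut`, built in
# the frequency domain. Synthesizes up to two independent channels from one
# inverse FFT (two real signals packed into one complex transform).
pink_noise <- function(n, fs, f_cut = 40, n_channels = 1L) {
  nf <- stats::nextn(n, c(2, 3, 5))
  freqs <- seq(0, fs / 2, length.out = nf %/% 2 + 1L)
  amp <- 1 / sqrt(pmax(freqs, freqs[2]))          # 1/f power weighting
  amp <- amp / sqrt(1 + (freqs / f_cut)^8)        # soft low-pass roll-off
  amp[1] <- 0                                     # no DC
  hermitian <- function() {
    ph <- stats::runif(length(freqs), 0, 2 * pi)
    half <- amp * exp(1i * ph)
    c(half, Conj(rev(half[2:(length(half) - 1L)])))
  }
  out <- matrix(0, n, n_channels)
  ch <- 1L
  while (ch <= n_channels) {
    if (ch < n_channels) {
      z <- stats::fft(hermitian() + 1i * hermitian(), inverse = TRUE)
      out[, ch] <- Re(z)[seq_len(n)]
      out[, ch + 1L] <- Im(z)[seq_len(n)]
      ch <- ch + 2L
    } else {
      out[, ch] <- Re(stats::fft(hermitian(), inverse = TRUE))[seq_len(n)]
      ch <- ch + 1L
    }
  }
  out
}

#' Generate baseline (non-ictal) EEG
#'
#' Produces multichannel baseline activity matching the quiet, low-amplitude
#' character of non-invasive adult-zebrafish scalp EEG: 1/f-weighted noise
#' band-limited below 40 Hz, scaled so the median 2-s sliding-window
#' peak-to-peak amplitude sits near `target_p2p` microvolts — comfortably
#' under the 20 uV baseline ceiling.
#'
#' @param duration length in seconds (> 0).
#' @param fs sampling rate in Hz (>= 200).
#' @param n_channels number of channels (default 4).
#' @param seed RNG seed; identical arguments and seed reproduce the signal
#'   exactly.
#' @param target_p2p target median 2-s-window peak-to-peak amplitude, uV.
#' @return numeric matrix, time (rows) by channels (columns), microvolts.
#' @export
#' @examples
#' x <- generate_baseline(10, fs = 500, seed = 1)
#' stats::median(sliding_p2p(x[, 1], 500))
generate_baseline <- function(duration, fs = 500, n_channels = 4, seed = NULL,
                              target_p2p = 15) {
  stopifnot_scalar_pos(duration, "duration")
  stopifnot_scalar_pos(fs, "fs")
  if (fs < 200) stop("`fs` must be at least 200 Hz", call. = FALSE)
  n <- round(duration * fs)
  with_seed(seed, {
    out <- pink_noise(n, fs, n_channels = n_channels)
    for (ch in seq_len(n_channels)) {
      x <- out[, ch]
      ref <- if (duration >= 2) stats::median(sliding_p2p(x, fs)) else diff(range(x))
      out[, ch] <- x * (target_p2p / ref)
    }
    out
  })
}

#' Generate one ictal (seizure) signal segment
#'
#' Synthesizes a single-channel epileptiform discharge of one of the two
#' patterns seen in this seizure model: `"theta"` — a high-amplitude,
#' amplitude-modulated 5-7 Hz oscillation typical of generalized seizures —
#' or `"spike_wave"` — a repeating 2-3 Hz complex of a brief biphasic spike
#' (40 ms) followed by a slow half-sine wave, typical of longer
#' absence-like/status runs. Edges are cosine-tapered so the discharge rises
#' out of and sinks back into baseline.
#'
#' @param event_class `"theta"` or `"spike_wave"`.
#' @param duration segment length, seconds.
#' @param fs sampling rate, Hz.
#' @param dominant_freq fundamental frequency, Hz; must lie in 5-7 for
#'   theta, 2-3 for spike_wave.
#' @param amplitude_pp peak-to-peak amplitude, microvolts (> 20).
#' @param seed RNG seed for the amplitude-modulation phase/jitter.
#' @return numeric vector of length `round(duration * fs)`, microvolts.
#' @export
generate_ictal_segment <- function(event_class = c("theta", "spike_wave"),
                                   duration, fs = 500, dominant_freq,
                                   amplitude_pp, seed = NULL) {
  event_class <- match.arg(event_class)
  stopifnot_scalar_pos(duration, "duration")
  stopifnot_scalar_pos(fs, "fs")
  band <- if (event_class == "theta") c(5, 7) else c(2, 3)
  if (dominant_freq < band[1] || dominant_freq > band[2]) {
    stop(sprintf("dominant_freq %.2f Hz outside the %s band [%g, %g] Hz",
                 dominant_freq, event_class, band[1], band[2]), call. = FALSE)
  }
  if (amplitude_pp <= 20) {
    stop("`amplitude_pp` must exceed the 20 uV baseline ceiling", call. = FALSE)
  }
  n <- round(duration * fs)
  t <- seq_len(n) / fs
  with_seed(seed, {
    x <- if (event_class == "theta") {
      # waxing-and-waning tonic-clonic-like oscillation
      ph <- stats::runif(1, 0, 2 * pi)
      mod_f <- stats::runif(1, 0.2, 0.5)
      mod <- 1 - 0.25 * (1 + sin(2 * pi * mod_f * t + stats::runif(1, 0, 2 * pi))) / 2
      (amplitude_pp / 2) * mod * sin(2 * pi * dominant_freq * t + ph)
    } else {
      period <- 1 / dominant_freq
      kernel <- spike_wave_kernel(period, fs)
      n_cyc <- ceiling(n / length(kernel)) + 1L
      gains <- 1 + stats::runif(n_cyc, -0.1, 0.1)  # mild cycle-to-cycle variation
      train <- unlist(lapply(seq_len(n_cyc), function(i) gains[i] * kernel),
                      use.names = FALSE)[seq_len(n)]
      train * (amplitude_pp / (max(train) - min(train)))
    }
    x * tukey_window(n, alpha = min(1, 2 / duration))
  })
}

# One spike-and-slow-wave cycle: biphasic 40 ms spike then a slow half-sine
# of opposite polarity filling the remainder of the period.
spike_wave_kernel <- function(period, fs) {
  n <- max(8L, round(period * fs))
  spike_n <- max(4L, round(0.040 * fs))
  spike_n <- min(spike_n, n %/% 2L)
  half <- spike_n %/% 2L
  spike <- c(sin(pi * seq_len(half) / half),
             -0.6 * sin(pi * seq_len(spike_n - half) / (spike_n - half)))
  wave_n <- n - spike_n
  wave <- -0.5 * sin(pi * seq_len(wave_n) / wave_n)
  c(1.6 * spike, wave)
}

#' Draw ground-truth events for one animal
#'
#' Samples the event-level ground truth (count, onsets, durations, classes,
#' onset channels, spread) implied by an [animal_profile()], without
#' synthesizing any signal. The first event's onset is the animal's latency
#' draw; remaining events are placed uniformly later in the session,
#' non-overlapping with a minimum inter-event gap. Used by
#' [generate_recording()] and convenient for fast cohort-level statistics.
#'
#' @param profile an [animal_profile()].
#' @param marks a [timeline_marks()].
#' @param seed RNG seed.
#' @param min_gap minimum spacing between consecutive events, seconds.
#' @param min_delay,max_delay range of per-channel propagation delays for
#'   generalized events, seconds.
#' @param max_tries placement retries before giving up.
#' @return data.frame of ground-truth events (possibly 0 rows) with columns
#'   onset_s, duration_s, class, dominant_freq_hz, amplitude_pp,
#'   onset_channel, generalized and a list column channel_delays (seconds,
#'   NA for uninvolved channels).
#' @export
draw_events <- function(profile, marks = timeline_marks(), seed = NULL,
                        min_gap = 5, min_delay = 0.1, max_delay = 2.0,
                        max_tries = 200) {
  stopifnot(inherits(profile, "zf_profile"), inherits(marks, "zf_marks"))
  empty <- data.frame(onset_s = numeric(0), duration_s = numeric(0),
                      class = character(0), dominant_freq_hz = numeric(0),
                      amplitude_pp = numeric(0), onset_channel = integer(0),
                      generalized = integer(0), stringsAsFactors = FALSE)
  empty$channel_delays <- list()
  if (!profile$responder) return(empty)
  with_seed(seed, {
    lambda <- trunc_pois_lambda(profile$count_mean)
    n_ev <- rtrunc_pois(1, lambda)
    t0 <- marks$stabilization_end
    t_end <- marks$session_end
    avail <- t_end - t0
    lat_par <- lnorm_pars(profile$latency_mean, profile$latency_cv)
    dur_par <- lnorm_pars(profile$duration_mean, profile$duration_cv)
    min_lat <- t0 - marks$injection_time  # first event cannot precede stabilization
    for (try in seq_len(max_tries)) {
      durs <- pmax(5, stats::rlnorm(n_ev, dur_par[1], dur_par[2]))
      if (profile$se_prob > 0 && stats::runif(1) < profile$se_prob) {
        durs[which.max(durs)] <- stats::runif(1, 310, 500)
      }
      lat <- stats::rlnorm(1, lat_par[1], lat_par[2])
      if (lat < min_lat) next
      onset1 <- marks$injection_time + lat
      if (onset1 + durs[1] > t_end) next
      if (sum(durs) + (n_ev - 1) * min_gap > avail) {
        if (try == max_tries) break
        next
      }
      if (n_ev == 1L) { onsets <- onset1; break }
      # place the remaining events after the first, uniformly, non-overlapping
      rest_lo <- onset1 + durs[1] + min_gap
      slack <- t_end - rest_lo - sum(durs[-1]) - (n_ev - 2) * min_gap
      if (slack < 0) next
      k <- n_ev - 1L
      rest_durs <- durs[-1L]
      u <- sort(stats::runif(k, 0, slack))
      offs <- c(0, cumsum(rest_durs[-k] + min_gap))
      onsets <- c(onset1, rest_lo + u + offs)
      if (all(onsets + durs <= t_end)) break
      if (try == max_tries) {
        stop("could not place events within the session; ",
             "shorten durations or lengthen the session", call. = FALSE)
      }
    }
    if (!exists("onsets", inherits = FALSE)) {
      stop("could not place events within the session; ",
           "shorten durations or lengthen the session", call. = FALSE)
    }
    cls <- ifelse(stats::runif(n_ev) < profile$p_theta, "theta", "spike_wave")
    freq <- ifelse(cls == "theta", stats::runif(n_ev, 5, 7),
                   stats::runif(n_ev, 2, 3))
    amp <- stats::runif(n_ev, 60, 200)
    onset_ch <- apply(stats::rmultinom(n_ev, 1, profile$onset_probs), 2, which.max)
    focal <- stats::runif(n_ev) < profile$p_focal
    delays <- lapply(seq_len(n_ev), function(i) {
      d <- rep(NA_real_, 4)
      d[onset_ch[i]] <- 0
      if (!focal[i]) {
        others <- setdiff(1:4, onset_ch[i])
        d[others] <- stats::runif(3, min_delay, max_delay)
      }
      d
    })
    out <- data.frame(onset_s = onsets, duration_s = durs, class = cls,
                      dominant_freq_hz = freq, amplitude_pp = amp,
                      onset_channel = as.integer(onset_ch),
                      generalized = as.integer(!focal),
                      stringsAsFactors = FALSE)
    out$channel_delays <- delays
    out[order(out$onset_s), , drop = FALSE]
  })
}

# lambda of a zero-truncated Poisson with mean m (m > 1), by bisection on
# lambda / (1 - exp(-lambda)) = m.
trunc_pois_lambda <- function(m) {
  if (m <= 1) stop("truncated-Poisson mean must exceed 1", call. = FALSE)
  stats::uniroot(function(l) l / (1 - exp(-l)) - m,
                 lower = 1e-8, upper = m, tol = 1e-10)$root
}

rtrunc_pois <- function(n, lambda) {
  out <- stats::rpois(n, lambda)
  while (any(out == 0L)) {
    k <- out == 0L
    out[k] <- stats::rpois(sum(k), lambda)
  }
  out
}

# mean/cv -> (meanlog, sdlog)
lnorm_pars <- function(m, cv) {
  s2 <- log(1 + cv^2)
  c(log(m) - s2 / 2, sqrt(s2))
}

#' Generate a full labelled recording
#'
#' Builds a complete session for one animal: baseline activity across the
#' whole session with ictal events superimposed on the involved channels at
#' their per-channel onsets (ground truth is returned exactly as planted).
#' Events only occur at or after the end of the post-injection stabilization
#' window.
#'
#' @inheritParams draw_events
#' @param fs sampling rate, Hz.
#' @param events optional pre-drawn ground-truth table (as from
#'   [draw_events()]); drawn from `profile` when `NULL`.
#' @return list with elements `recording` (a `zf_recording`) and `truth`
#'   (the ground-truth event data.frame).
#' @export
#' @examples
#' prof <- animal_profile("male", count_mean = 2, latency_mean = 100,
#'                        duration_mean = 20)
#' marks <- timeline_marks(0, 120, 210, 600)
#' out <- generate_recording(prof, marks, fs = 250, seed = 42)
#' nrow(out$truth)
generate_recording <- function(profile, marks = timeline_marks(), fs = 500,
                               seed = NULL, events = NULL,
                               min_gap = 5, min_delay = 0.1, max_delay = 2.0) {
  stopifnot(inherits(profile, "zf_profile"), inherits(marks, "zf_marks"))
  seeds <- derive_seeds(seed, 3L)
  if (is.null(events)) {
    events <- draw_events(profile, marks, seed = seeds[1],
                          min_gap = min_gap, min_delay = min_delay,
                          max_delay = max_delay)
  }
  dur_total <- marks$session_end - marks$control_start
  samples <- generate_baseline(dur_total, fs = fs, n_channels = 4,
                               seed = seeds[2])
  if (nrow(events)) {
    seg_seeds <- derive_seeds(seeds[3], nrow(events) * 4L)
    for (i in seq_len(nrow(events))) {
      d <- events$channel_delays[[i]]
      for (ch in which(!is.na(d))) {
        ch_on <- events$onset_s[i] + d[ch]
        ch_dur <- events$duration_s[i] - d[ch]
        if (ch_dur < 1) next
        seg <- generate_ictal_segment(events$class[i], ch_dur, fs,
                                      events$dominant_freq_hz[i],
                                      events$amplitude_pp[i],
                                      seed = seg_seeds[(i - 1L) * 4L + ch])
        i0 <- round((ch_on - marks$control_start) * fs) + 1L
        idx <- i0:(i0 + length(seg) - 1L)
        keep <- idx <= nrow(samples)
        samples[idx[keep], ch] <- samples[idx[keep], ch] + seg[keep]
      }
    }
  }
  rec <- new_recording(samples, fs, marks,
                       subject = list(id = profile$id, sex = profile$sex))
  list(recording = rec, truth = events)
}

#' Generate a labelled cohort
#'
#' Simulates every animal of a [cohort_config()] (or named preset),
#' deterministic in `(config, seed)`. Per-animal seeds are derived from the
#' cohort seed, so each animal is independently reproducible.
#'
#' @param config a [cohort_config()] or a preset name accepted by
#'   [cohort_preset()].
#' @param seed cohort RNG seed.
#' @param truth_only if `TRUE`, skip signal synthesis and return ground
#'   truth only (fast cohort-level statistics).
#' @param ... additional arguments passed to [generate_recording()] /
#'   [draw_events()] (`min_gap`, `min_delay`, `max_delay`).
#' @return list of per-animal lists with elements `profile`, `truth` and
#'   (unless `truth_only`) `recording`.
#' @export
generate_cohort <- function(config = cohort_preset("ptz17"), seed = NULL,
                            truth_only = FALSE, ...) {
  if (is.character(config)) config <- cohort_preset(config)
  stopifnot(inherits(config, "zf_cohort_config"))
  profiles <- cohort_profiles(config)
  if (!length(profiles)) return(list())
  seeds <- derive_seeds(seed, length(profiles))
  lapply(seq_along(profiles), function(i) {
    p <- profiles[[i]]
    if (truth_only) {
      tr <- draw_events(p, config$marks, seed = seeds[i], ...)
      list(profile = p, truth = tr)
    } else {
      out <- generate_recording(p, config$marks, fs = config$fs,
                                seed = seeds[i], ...)
      list(profile = p, truth = out$truth, recording = out$recording)
    }
  })
}

cohort_profiles <- function(config) {
  mk <- function(sex, n, n_nr, args) {
    if (n == 0L) return(list())
    lapply(seq_len(n), function(i) {
      do.call(animal_profile, c(
        list(sex = sex, responder = i > n_nr,
             id = sprintf("%s%02d", if (sex == "male") "M" else "F", i)),
        args))
    })
  }
  c(mk("male", config$n_male, config$n_nonresponder_male, config$male_args),
    mk("female", config$n_female, config$n_nonresponder_female,
       config$female_args))
}
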