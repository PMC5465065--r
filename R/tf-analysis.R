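#' Morlet continuous wavelet transform
#'
#' Time-frequency decomposition with the complex Morlet wavelet (centre
#' frequency `omega0 = 6` by default), computed per analysis frequency by
#' FFT convolution. Scales follow the standard Fourier-wavelength relation
#' so each row of the map is labelled by its equivalent Fourier frequency.
#' Power inside the cone of influence (within `sqrt(2) * scale` of either
#' edge) is zeroed, since those estimates are contaminated by edge effects.
#'
#' @param x numeric signal vector (one channel), microvolts.
#' @param fs sampling rate, Hz.
#' @param freqs analysis frequencies, Hz; default 100 log-spaced points over
#'   0.5-50 Hz. Must lie strictly inside (0, fs/2).
#' @param omega0 Morlet centre frequency (dimensionless), default 6.
#' @param mask_coi zero the cone of influence (default TRUE).
#' @return an object of class `zf_tfmap`: list with `times` (s), `freqs`
#'   (Hz) and `power` (time x frequency matrix, uV^2).
#' @export
#' @examples
#' t <- seq(0, 4, by = 1 / 250)
#' tf <- morlet_cwt(sin(2 * pi * 6 * t), fs = 250)
#' tf$freqs[which.max(global_wavelet_spectrum(tf)$power)]
morlet_cwt <- function(x, fs, freqs = default_tf_freqs(), omega0 = 6,
                       mask_coi = TRUE) {
  if (!length(freqs)) stop("`freqs` must not be empty", call. = FALSE)
  if (any(freqs <= 0 | freqs >= fs / 2)) {
    stop("analysis frequencies must lie strictly inside (0, fs/2)",
         call. = FALSE)
  }
  n <- length(x)
  dt <- 1 / fs
  nf <- stats::nextn(2L * n, 2)           # pad to suppress wrap-around
  xh <- stats::fft(c(x - mean(x), rep(0, nf - n)))
  w_k <- 2 * pi * fs * c(seq(0, nf / 2), seq(-nf / 2 + 1, -1)) / nf
  # scale for Fourier wavelength 1/f (Morlet): lambda = 4*pi*s/(w0+sqrt(2+w0^2))
  fourier_factor <- 4 * pi / (omega0 + sqrt(2 + omega0^2))
  scales <- (1 / freqs) / fourier_factor
  power <- matrix(0, nrow = n, ncol = length(freqs))
  norm0 <- pi^(-0.25)
  for (j in seq_along(scales)) {
    s <- scales[j]
    psi <- numeric(nf)
    pos <- w_k > 0
    psi[pos] <- norm0 * sqrt(2 * pi * s / dt) * exp(-(s * w_k[pos] - omega0)^2 / 2)
    w <- stats::fft(xh * psi, inverse = TRUE) / nf
    power[, j] <- Mod(w[seq_len(n)])^2
  }
  if (mask_coi) {
    for (j in seq_along(scales)) {
      e <- ceiling(sqrt(2) * scales[j] * fs)
      if (e >= 1 && e < n) {
        power[c(seq_len(e), (n - e + 1L):n), j] <- 0
      } else if (e >= n) power[, j] <- 0
    }
  }
  structure(list(times = (seq_len(n) - 1L) * dt, freqs = freqs,
                 power = power), class = "zf_tfmap")
}

#' Default time-frequency analysis grid
#'
#' @param n number of grid points.
#' @param range frequency range, Hz.
#' @return log-spaced frequency vector.
#' @export
default_tf_freqs <- function(n = 100, range = c(0.5, 50)) {
  exp(seq(log(range[1]), log(range[2]), length.out = n))
}

#' @export
print.zf_tfmap <- function(x, ...) {
  cat(sprintf("<zf_tfmap> %d samples x %d freqs (%.2g-%.3g Hz)\n",
              length(x$times), length(x$freqs), min(x$freqs), max(x$freqs)))
  invisible(x)
}

#' Global wavelet spectrum
#'
#' Time-average of scalogram power at each analysis frequency — the
#' wavelet analogue of a power spectrum, used to confirm that recorded
#' activity stays below 40-50 Hz.
#'
#' @param tfmap a [morlet_cwt()] result.
#' @return data.frame with columns `freq_hz`, `power`.
#' @export
global_wavelet_spectrum <- function(tfmap) {
  stopifnot(inherits(tfmap, "zf_tfmap"))
  data.frame(freq_hz = tfmap$freqs, power = colMeans(tfmap$power))
}

#' Confirm an event's onset channel from time-frequency power
#'
#' Independent cross-check of onset-channel localization: for each channel,
#' the band-limited scalogram power (in the event's class band) is compared
#' with its pre-event median; the channel whose power first exceeds
#' `ratio` times that median is the confirmed onset channel. Simultaneous
#' first crossings are broken toward the lowest channel index and flagged.
#'
#' @param tfmaps list of per-channel [morlet_cwt()] maps covering a common
#'   interval that extends before the event onset.
#' @param event one-row event data.frame with `onset_s` and `class`.
#' @param band frequency band, Hz; defaults to the event's class band
#'   (5-7 Hz theta, 2-3 Hz spike-wave, else 1-40 Hz).
#' @param ratio threshold over the pre-event median power (default 10).
#' @return list with `channel` (NA when no channel crosses), `time_s`, and
#'   `tie`.
#' @export
onset_confirmation <- function(tfmaps, event, band = NULL, ratio = 10) {
  times <- tfmaps[[1]]$times
  for (m in tfmaps) {
    if (!inherits(m, "zf_tfmap") || length(m$times) != length(times) ||
        max(abs(m$times - times)) > 1e-9) {
      stop("per-channel maps must cover the same time interval",
           call. = FALSE)
    }
  }
  if (is.null(band)) {
    band <- switch(as.character(event$class),
                   theta = c(5, 7), spike_wave = c(2, 3), c(1, 40))
  }
  pre <- times < event$onset_s
  if (!any(pre)) stop("maps must extend before the event onset", call. = FALSE)
  cross <- vapply(tfmaps, function(m) {
    sel <- m$freqs >= band[1] & m$freqs <= band[2]
    bp <- rowMeans(m$power[, sel, drop = FALSE])
    ref <- stats::median(bp[pre])
    if (ref <= 0) ref <- max(bp[pre], .Machine$double.eps)
    idx <- which(!pre & bp > ratio * ref)
    if (!length(idx)) NA_real_ else times[idx[1]]
  }, numeric(1))
  if (all(is.na(cross))) {
    return(list(channel = NA_integer_, time_s = NA_real_, tie = FALSE))
  }
  tmin <- min(cross, na.rm = TRUE)
  at_min <- which(!is.na(cross) & cross == tmin)
  list(channel = at_min[1], time_s = tmin, tie = length(at_min) > 1L)
}

#' Save a time-frequency map as CSV
#'
#' Writes the power matrix with times as rows (first column `time_s`) and
#' one column per analysis frequency.
#'
#' @param tfmap a [morlet_cwt()] result.
#' @param path CSV path.
#' @export
write_tfmap_csv <- function(tfmap, path) {
  stopifnot(inherits(tfmap, "zf_tfmap"))
  df <- data.frame(time_s = tfmap$times)
  p <- tfmap$power
  colnames(p) <- sprintf("f_%0.3f_hz", tfmap$freqs)
  utils::write.csv(cbind(df, p), path, row.names = FALSE)
  invisible(path)
}
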