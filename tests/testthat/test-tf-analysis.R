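test_that("scalogram peak matches pure-tone frequency within one grid step", {
  fs <- 250
  t <- seq(0, 20 - 1 / fs, by = 1 / fs)
  freqs <- default_tf_freqs()
  for (f in c(2, 6, 10, 30)) {
    tf <- morlet_cwt(sin(2 * pi * f * t), fs, freqs)
    gws <- global_wavelet_spectrum(tf)
    j <- which.max(gws$power)
    nearest <- which.min(abs(freqs - f))
    expect_lte(abs(j - nearest), 1L)
  }
})

test_that("zero input gives an all-zero power map and bad grids error", {
  tf <- morlet_cwt(rep(0, 500), fs = 250)
  expect_true(all(tf$power == 0))
  expect_true(all(tf$power >= 0))
  expect_error(morlet_cwt(rnorm(100), 250, freqs = numeric(0)), "empty")
  expect_error(morlet_cwt(rnorm(100), 250, freqs = c(10, 200)), "fs/2")
})

test_that("a two-tone signal produces local maxima at both frequencies", {
  fs <- 250
  t <- seq(0, 30 - 1 / fs, by = 1 / fs)
  x <- sin(2 * pi * 3 * t) + sin(2 * pi * 20 * t)
  gws <- global_wavelet_spectrum(morlet_cwt(x, fs))
  freqs <- gws$freq_hz
  # local maxima of the spectrum
  p <- gws$power
  locmax <- which(diff(sign(diff(p))) == -2) + 1
  peak_freqs <- freqs[locmax[order(p[locmax], decreasing = TRUE)][1:2]]
  expect_lte(min(abs(peak_freqs - 3)) / 3, 0.08)
  expect_lte(min(abs(peak_freqs - 20)) / 20, 0.08)
})

test_that("the global spectrum is the time-mean and is additive over halves", {
  fs <- 250
  x <- generate_baseline(16, fs = fs, n_channels = 1, seed = 31)[, 1]
  tf <- morlet_cwt(x, fs, mask_coi = FALSE)
  gws <- global_wavelet_spectrum(tf)
  expect_equal(gws$power, colMeans(tf$power))
  # mean of the two half-interval spectra equals the full spectrum
  half <- seq_len(length(x) / 2)
  s1 <- colMeans(tf$power[half, ])
  s2 <- colMeans(tf$power[-half, ])
  expect_lt(max(abs((s1 + s2) / 2 - gws$power)), 1e-9 * max(gws$power))
})

test_that("time-shifting the input shifts the power map (edges excluded)", {
  fs <- 250
  n <- 16 * fs
  x <- generate_baseline(16, fs = fs, n_channels = 1, seed = 32)[, 1]
  shift <- fs  # 1 s
  xs <- c(rep(0, shift), x[1:(n - shift)])
  freqs <- default_tf_freqs(30, c(2, 40))  # away from long-scale edges
  p0 <- morlet_cwt(x, fs, freqs, mask_coi = FALSE)$power
  p1 <- morlet_cwt(xs, fs, freqs, mask_coi = FALSE)$power
  mid <- (4 * fs):(10 * fs)
  rel <- abs(p1[mid + shift, ] - p0[mid, ]) / max(p0[mid, ])
  expect_lt(max(rel), 0.02)
})

test_that("time-frequency onset confirmation recovers the planted channel", {
  fs <- 250
  dur <- 60
  marks <- timeline_marks(0, 20, 25, dur)
  x <- generate_baseline(dur, fs = fs, n_channels = 4, seed = 33)
  delays <- c(1, 0, 2, 1.5)   # channel 2 leads
  t_on <- 30
  for (ch in 1:4) {
    seg <- generate_ictal_segment("theta", 20 - delays[ch], fs, 6, 100,
                                  seed = 40 + ch)
    i0 <- round((t_on + delays[ch]) * fs) + 1
    x[i0:(i0 + length(seg) - 1), ch] <- x[i0:(i0 + length(seg) - 1), ch] + seg
  }
  freqs <- default_tf_freqs(40, c(2, 20))
  maps <- lapply(1:4, function(ch) morlet_cwt(x[, ch], fs, freqs))
  event <- data.frame(onset_s = t_on, class = "theta")
  conf <- onset_confirmation(maps, event)
  expect_identical(conf$channel, 2L)
  expect_false(conf$tie)
})

test_that("onset confirmation signals when no channel crosses threshold", {
  fs <- 250
  x <- generate_baseline(30, fs = fs, n_channels = 2, seed = 34)
  maps <- lapply(1:2, function(ch) morlet_cwt(x[, ch], fs,
                                              default_tf_freqs(20, c(2, 20))))
  conf <- onset_confirmation(maps, data.frame(onset_s = 15, class = "theta"))
  expect_true(is.na(conf$channel))
  # mismatched intervals are rejected
  short <- morlet_cwt(x[1:1000, 1], fs, default_tf_freqs(20, c(2, 20)))
  expect_error(onset_confirmation(list(maps[[1]], short),
                                  data.frame(onset_s = 15, class = "theta")),
               "same time interval")
})

test_that("tf maps serialize to CSV with matching grids", {
  fs <- 250
  tf <- morlet_cwt(sin(2 * pi * 6 * seq(0, 4, by = 1 / fs)), fs,
                   default_tf_freqs(10, c(2, 20)))
  path <- withr::local_tempfile(fileext = ".csv")
  write_tfmap_csv(tf, path)
  back <- utils::read.csv(path)
  expect_identical(nrow(back), length(tf$times))
  expect_identical(ncol(back), length(tf$freqs) + 1L)
})
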