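#' Band-pass filter specification
#'
#' The acquisition band used throughout: 0.1-55 Hz, chosen to exclude 60 Hz
#' line noise while keeping the full EEG band. Realized as a zero-phase
#' Butterworth band-pass: the squared analytic Butterworth magnitude
#' response (the amplitude response a forward-backward pass would have) is
#' applied in the frequency domain, so the filter is exactly linear phase
#' (zero phase) with no startup transients.
#'
#' @param low_cut,high_cut band edges, Hz.
#' @param order Butterworth order of each (low- and high-pass) prototype;
#'   the zero-phase realization squares the magnitude. The default order 5
#'   attenuates 60 Hz by more than 20 dB while staying flat within 1 dB at
#'   10 Hz.
#' @param zero_phase kept for interface completeness; only zero-phase
#'   application is supported.
#' @return an object of class `zf_filter_spec`.
#' @export
filter_spec <- function(low_cut = 0.1, high_cut = 55, order = 5,
                        zero_phase = TRUE) {
  if (!(low_cut > 0 && low_cut < high_cut)) {
    stop("need 0 < low_cut < high_cut", call. = FALSE)
  }
  structure(list(low_cut = low_cut, high_cut = high_cut, order = order,
                 zero_phase = zero_phase), class = "zf_filter_spec")
}

# Squared Butterworth band-pass magnitude (zero-phase gain) at frequency f.
butter_gain2 <- function(f, spec) {
  lp <- 1 / (1 + (f / spec$high_cut)^(2 * spec$order))
  hp <- 1 / (1 + ifelse(f > 0, (spec$low_cut / f)^(2 * spec$order), Inf))
  (lp * hp)^2
}

#' Apply the acquisition band-pass to a recording
#'
#' Zero-phase Butterworth band-pass, all channels at once. At the defaults
#' the passband is flat within 1 dB at 10 Hz and 60 Hz line noise is
#' attenuated by more than 20 dB (in amplitude).
#'
#' @param recording a `zf_recording`.
#' @param spec a [filter_spec()].
#' @return the recording with filtered samples.
#' @export
bandpass <- function(recording, spec = filter_spec()) {
  stopifnot(inherits(recording, "zf_recording"),
            inherits(spec, "zf_filter_spec"))
  fs <- recording$fs
  if (spec$high_cut >= fs / 2) {
    stop(sprintf("high_cut (%g Hz) must be below the Nyquist frequency (%g Hz)",
                 spec$high_cut, fs / 2), call. = FALSE)
  }
  x <- recording$samples
  n <- nrow(x)
  n_ch <- ncol(x)
  # pad past the high-pass settling time to avoid circular wrap-around
  pad <- round(10 / spec$low_cut * fs)
  nf <- stats::nextn(n + pad, c(2, 3, 5))
  half <- seq(0, floor(nf / 2))
  freqs_abs <- c(half, rev(half[seq(2, length(half) - (nf %% 2 == 0))])) * fs / nf
  gain <- butter_gain2(freqs_abs, spec)
  y <- matrix(0, n, n_ch)
  zpad <- rep(0, nf - n)
  ch <- 1L
  # real gain keeps filtered channels real, so two channels share one
  # complex FFT round-trip
  while (ch <= n_ch) {
    if (ch < n_ch) {
      z <- stats::fft(c(x[, ch], zpad) + 1i * c(x[, ch + 1L], zpad))
      z <- stats::fft(z * gain, inverse = TRUE) / nf
      y[, ch] <- Re(z)[seq_len(n)]
      y[, ch + 1L] <- Im(z)[seq_len(n)]
      ch <- ch + 2L
    } else {
      z <- stats::fft(c(x[, ch], zpad))
      y[, ch] <- Re(stats::fft(z * gain, inverse = TRUE) / nf)[seq_len(n)]
      ch <- ch + 1L
    }
  }
  colnames(y) <- colnames(x)
  recording$samples <- y
  recording
}

#' Construct a recording from a sample matrix
#'
#' Wraps a time-by-channel numeric matrix (microvolts) as a `zf_recording`
#' so externally acquired data can enter the pipeline.
#'
#' @param samples numeric matrix or vector, time (rows) by channels.
#' @param fs sampling rate, Hz.
#' @param marks a [timeline_marks()]; defaults to marks spanning the data
#'   with a control window over the first fifth of the session.
#' @param montage a [default_montage()]-style data.frame.
#' @param subject list with `id` and `sex`.
#' @return a `zf_recording`.
#' @export
as_recording <- function(samples, fs, marks = NULL,
                         montage = default_montage(),
                         subject = list(id = NA_character_,
                                        sex = NA_character_)) {
  if (is.vector(samples)) samples <- matrix(samples, ncol = 1)
  if (!is.matrix(samples) || !is.numeric(samples)) {
    stop("`samples` must be a numeric matrix (time x channels)", call. = FALSE)
  }
  if (any(!is.finite(samples))) {
    stop("`samples` must be finite", call. = FALSE)
  }
  dur <- nrow(samples) / fs
  if (is.null(marks)) {
    marks <- timeline_marks(0, dur / 5, dur / 5 + min(90, dur / 20), dur)
  }
  new_recording(samples, fs, marks, montage = montage, subject = subject)
}

# ---- EDF (European Data Format, 16-bit) ------------------------------------
# Minimal EDF support sufficient for these recordings: one fixed physical
# range, integer sampling rates, 1-s data records, no annotations.

edf_pad <- function(x, width) {
  s <- substr(as.character(x), 1L, width)
  formatC(s, width = width, flag = "-")
}

#' Write a recording as EDF
#'
#' 16-bit EDF with 1-second data records, physical dimension uV and a
#' symmetric physical range. Samples outside the physical range are an
#' error rather than being silently clipped.
#'
#' @param recording a `zf_recording`; `fs` must be an integer and the
#'   duration a whole number of seconds.
#' @param path output file path.
#' @param physical_range symmetric physical full scale, uV (default 500).
#' @return `path`, invisibly.
#' @export
write_edf <- function(recording, path, physical_range = 500) {
  stopifnot(inherits(recording, "zf_recording"))
  fs <- recording$fs
  if (fs != round(fs)) stop("EDF export needs an integer sampling rate",
                            call. = FALSE)
  x <- recording$samples
  if (max(abs(x)) > physical_range) {
    stop(sprintf("samples exceed the +/-%g uV physical range; not clipping",
                 physical_range), call. = FALSE)
  }
  n <- nrow(x)
  ns <- ncol(x)
  n_rec <- n %/% fs
  if (n_rec * fs != n) stop("EDF export needs a whole number of seconds",
                            call. = FALSE)
  dig_max <- 32767L; dig_min <- -32768L
  scale <- (dig_max - dig_min) / (2 * physical_range)
  con <- file(path, "wb")
  on.exit(close(con))
  hdr <- paste0(
    edf_pad("0", 8),
    edf_pad(paste0("subject ", recording$subject$id), 80),
    edf_pad("zfeeg synthetic recording", 80),
    edf_pad("01.01.00", 8), edf_pad("00.00.00", 8),
    edf_pad(256 + 256 * ns, 8),
    edf_pad("", 44),
    edf_pad(n_rec, 8), edf_pad(1, 8), edf_pad(ns, 4))
  writeChar(hdr, con, eos = NULL)
  labels <- colnames(x)
  if (is.null(labels)) labels <- paste0("ch", seq_len(ns))
  field <- function(vals, width) {
    writeChar(paste0(vapply(vals, edf_pad, "", width = width),
                     collapse = ""), con, eos = NULL)
  }
  field(labels, 16)
  field(rep("", ns), 80)                       # transducer
  field(rep("uV", ns), 8)                      # physical dimension
  field(rep(-physical_range, ns), 8)
  field(rep(physical_range, ns), 8)
  field(rep(dig_min, ns), 8)
  field(rep(dig_max, ns), 8)
  field(rep("BP:0.1-55Hz", ns), 80)            # prefilter note
  field(rep(fs, ns), 32)                       # samples per record
  field(rep("", ns), 32)                       # reserved
  dig <- round((x + physical_range) * scale) + dig_min
  dig <- matrix(as.integer(dig), nrow = n)
  # interleave per 1-s record: all samples of signal 1, then signal 2, ...
  for (r in seq_len(n_rec)) {
    rows <- ((r - 1L) * fs + 1L):(r * fs)
    writeBin(as.integer(as.vector(dig[rows, ])), con, size = 2L,
             endian = "little")
  }
  invisible(path)
}

#' Read an EDF recording
#'
#' @param path EDF file path.
#' @return a `zf_recording` (timeline marks default to [timeline_marks()]
#'   clipped to the file duration; adjust afterwards if needed).
#' @param marks optional [timeline_marks()] to attach.
#' @export
read_edf <- function(path, marks = NULL) {
  con <- file(path, "rb")
  on.exit(close(con))
  getf <- function(w) trimws(readChar(con, w, useBytes = TRUE))
  ver <- getf(8)
  if (!identical(ver, "0")) stop("not an EDF file (bad version field): ", path,
                                 call. = FALSE)
  getf(80); getf(80); getf(8); getf(8)
  getf(8)  # header bytes
  getf(44)
  n_rec <- as.integer(getf(8))
  rec_dur <- as.numeric(getf(8))
  ns <- as.integer(getf(4))
  if (is.na(ns) || ns < 1L) stop("EDF header: invalid signal count",
                                 call. = FALSE)
  fieldv <- function(w) vapply(seq_len(ns), function(i) getf(w), "")
  labels <- fieldv(16)
  fieldv(80)
  dims <- fieldv(8)
  if (!all(dims %in% c("uV", "mV"))) {
    stop("EDF physical dimension must be uV or mV, got: ",
         paste(unique(dims), collapse = ", "), call. = FALSE)
  }
  pmin_ <- as.numeric(fieldv(8)); pmax_ <- as.numeric(fieldv(8))
  dmin_ <- as.numeric(fieldv(8)); dmax_ <- as.numeric(fieldv(8))
  fieldv(80)
  spr <- as.integer(fieldv(32))
  fieldv(32)
  if (length(unique(spr)) != 1L) {
    stop("mixed per-signal sampling rates are not supported", call. = FALSE)
  }
  fs <- spr[1] / rec_dur
  raw <- readBin(con, integer(), n = n_rec * sum(spr), size = 2L,
                 endian = "little")
  x <- matrix(0, nrow = n_rec * spr[1], ncol = ns)
  pos <- 0L
  for (r in seq_len(n_rec)) {
    for (s in seq_len(ns)) {
      vals <- raw[(pos + 1L):(pos + spr[s])]
      pos <- pos + spr[s]
      g <- (pmax_[s] - pmin_[s]) / (dmax_[s] - dmin_[s])
      phys <- pmin_[s] + (vals - dmin_[s]) * g
      if (dims[s] == "mV") phys <- phys * 1000
      x[((r - 1L) * spr[s] + 1L):(r * spr[s]), s] <- phys
    }
  }
  colnames(x) <- labels
  dur <- nrow(x) / fs
  if (is.null(marks)) {
    marks <- if (dur >= 3600) timeline_marks() else
      timeline_marks(0, dur * 0.2, dur * 0.2 + min(90, dur * 0.05), dur)
  }
  mont <- default_montage()
  if (ns == 4L && all(nzchar(labels))) mont$label <- labels
  rec <- new_recording(x, fs, marks, montage = mont)
  rec
}

# ---- CSV -------------------------------------------------------------------

#' Write a recording as long-form CSV
#'
#' Columns `time_s, ch1..chN` (seconds / microvolts).
#' @param recording a `zf_recording`.
#' @param path output path.
#' @export
write_recording_csv <- function(recording, path) {
  stopifnot(inherits(recording, "zf_recording"))
  x <- recording$samples
  df <- data.frame(time_s = (seq_len(nrow(x)) - 1L) / recording$fs)
  for (ch in seq_len(ncol(x))) df[[paste0("ch", ch)]] <- x[, ch]
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}

#' Read a recording
#'
#' Loads EDF or the package's long-form CSV dialect (`time_s, ch1..chN`
#' header required; values in microvolts).
#'
#' @param path file path.
#' @param format `"edf"` or `"csv"`; guessed from the extension by default.
#' @param marks optional [timeline_marks()] to attach.
#' @return a `zf_recording`.
#' @export
read_recording <- function(path, format = c("auto", "edf", "csv"),
                           marks = NULL) {
  format <- match.arg(format)
  if (format == "auto") {
    format <- if (grepl("\\.edf$", path, ignore.case = TRUE)) "edf" else "csv"
  }
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  if (format == "edf") return(read_edf(path, marks = marks))
  df <- utils::read.csv(path, check.names = FALSE)
  if (!"time_s" %in% names(df)) {
    stop("CSV recording must have a `time_s` column; header was: ",
         paste(names(df), collapse = ", "), call. = FALSE)
  }
  ch_cols <- grep("^ch[0-9]+$", names(df), value = TRUE)
  if (length(ch_cols) < 1L) {
    stop("CSV recording has no channel columns (expected ch1, ch2, ...)",
         call. = FALSE)
  }
  expected <- paste0("ch", seq_along(ch_cols))
  if (!all(expected %in% ch_cols)) {
    stop("CSV channel columns must be consecutive from ch1; missing: ",
         paste(setdiff(expected, ch_cols), collapse = ", "), call. = FALSE)
  }
  fs <- 1 / stats::median(diff(df$time_s))
  x <- as.matrix(df[expected])
  dur <- nrow(x) / fs
  if (is.null(marks)) {
    marks <- if (dur >= 3600) timeline_marks() else
      timeline_marks(0, dur * 0.2, dur * 0.2 + min(90, dur * 0.05), dur)
  }
  new_recording(x, round(fs), marks)
}

# ---- event tables ----------------------------------------------------------

event_csv_cols <- c("onset_s", "offset_s", "duration_s", "class",
                    "dominant_freq_hz", "is_se", "spread", "onset_channel",
                    "onset_ch1_s", "onset_ch2_s", "onset_ch3_s", "onset_ch4_s")

#' Write / read detected-event tables
#'
#' Lossless CSV round-trip of a detected-event table (as produced by
#' [detect_seizures()]), including per-channel onsets.
#'
#' @param events detected-event data.frame.
#' @param path CSV path.
#' @return `write_events()` returns `path` invisibly; `read_events()`
#'   returns the event data.frame (zero rows for a header-only file).
#' @export
write_events <- function(events, path) {
  df <- events
  if (!nrow(df)) {
    df <- as.data.frame(stats::setNames(rep(list(logical(0)), length(event_csv_cols)),
                                 event_csv_cols))
  } else {
    missing_cols <- setdiff(event_csv_cols, names(df))
    if (length(missing_cols)) {
      stop("event table is missing columns: ",
           paste(missing_cols, collapse = ", "), call. = FALSE)
    }
    df <- df[event_csv_cols]
  }
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_events
#' @export
read_events <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  missing_cols <- setdiff(event_csv_cols, names(df))
  if (length(missing_cols)) {
    stop("event CSV schema mismatch; missing: ",
         paste(missing_cols, collapse = ", "), call. = FALSE)
  }
  if (!nrow(df)) {
    df <- as.data.frame(stats::setNames(list(numeric(0), numeric(0), numeric(0),
                                      character(0), numeric(0), logical(0),
                                      character(0), integer(0), numeric(0),
                                      numeric(0), numeric(0), numeric(0)),
                                 event_csv_cols))
    return(df)
  }
  df$is_se <- as.logical(df$is_se)
  df$onset_channel <- as.integer(df$onset_channel)
  df[order(df$onset_s), event_csv_cols, drop = FALSE]
}

#' Write ground-truth event tables
#'
#' Cohort-level ground truth as tidy CSV: one row per planted event with
#' animal id, sex, onset, duration, class, dominant frequency, onset channel
#' and whether the event generalized.
#'
#' @param cohort list as returned by [generate_cohort()].
#' @param path CSV path.
#' @export
write_ground_truth <- function(cohort, path) {
  rows <- lapply(cohort, function(a) {
    tr <- a$truth
    if (!nrow(tr)) return(NULL)
    data.frame(animal_id = a$profile$id, sex = a$profile$sex,
               onset_s = tr$onset_s, duration_s = tr$duration_s,
               class = tr$class, dominant_freq_hz = tr$dominant_freq_hz,
               onset_channel = tr$onset_channel,
               generalized = tr$generalized, stringsAsFactors = FALSE)
  })
  df <- do.call(rbind, c(rows, list(
    data.frame(animal_id = character(0), sex = character(0),
               onset_s = numeric(0), duration_s = numeric(0),
               class = character(0), dominant_freq_hz = numeric(0),
               onset_channel = integer(0), generalized = integer(0)))))
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}
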