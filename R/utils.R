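#' @keywords internal
"_PACKAGE"

# Run expr with a private RNG stream seeded by `seed`, restoring the caller's
# RNG state afterwards. All generator functions route randomness through this
# so that identical (arguments, seed) give bitwise-identical output.
with_seed <- function(seed, expr) {
  if (!is.null(seed)) {
    if (!is.numeric(seed) || length(seed) != 1L || is.na(seed)) {
      stop("`seed` must be a single integer", call. = FALSE)
    }
    old <- if (exists(".Random.seed", globalenv(), inherits = FALSE)) {
      get(".Random.seed", globalenv())
    } else NULL
    on.exit({
      if (is.null(old)) {
        if (exists(".Random.seed", globalenv(), inherits = FALSE)) {
          rm(".Random.seed", envir = globalenv())
        }
      } else {
        assign(".Random.seed", old, envir = globalenv())
      }
    })
    set.seed(as.integer(seed))
  }
  force(expr)
}

# Derive n child seeds (< 2^31) from one parent seed.
derive_seeds <- function(seed, n) {
  with_seed(seed, sample.int(.Machine$integer.max, n))
}

stopifnot_scalar_pos <- function(x, name) {
  if (!is.numeric(x) || length(x) != 1L || is.na(x) || x <= 0) {
    stop(sprintf("`%s` must be a single positive number", name), call. = FALSE)
  }
  invisible(x)
}

#' Sliding-window peak-to-peak amplitude
#'
#' Computes the peak-to-peak (max minus min) amplitude of a signal in sliding
#' windows, the summary used to verify that baseline activity stays under the
#' 20 microvolt ceiling characteristic of non-invasive adult-zebrafish scalp
#' recordings.
#'
#' @param x numeric signal vector (microvolts).
#' @param fs sampling rate in Hz.
#' @param window window length in seconds (default 2).
#' @param step hop between window starts in seconds (default 1).
#' @return numeric vector of per-window peak-to-peak amplitudes.
#' @export
sliding_p2p <- function(x, fs, window = 2, step = 1) {
  stopifnot_scalar_pos(fs, "fs")
  w <- round(window * fs)
  h <- max(1L, round(step * fs))
  n <- length(x)
  if (n < w) return(diff(range(x)))
  starts <- seq(1L, n - w + 1L, by = h)
  vapply(starts, function(s) {
    seg <- x[s:(s + w - 1L)]
    max(seg) - min(seg)
  }, numeric(1))
}

# One-sided periodogram: list(freq, power). Zero-pads to a power of two
# (fast FFT, finer frequency grid). Used internally for dominant-frequency
# estimation; tests cross-check peak locations against stats::spec.pgram.
periodogram <- function(x, fs) {
  n <- length(x)
  x <- x - mean(x)
  nf <- stats::nextn(n, c(2, 3, 5))
  X <- stats::fft(c(x, rep(0, nf - n)))
  half <- seq_len(nf %/% 2 + 1L)
  list(freq = (half - 1L) * fs / nf,
       power = (Mod(X[half])^2) / n)
}

# Sliding-window maximum (centered, window w samples) in O(n) via the
# block prefix/suffix-max decomposition.
slide_max <- function(x, w) {
  w <- as.integer(w)
  n <- length(x)
  if (w <= 1L || n == 0L) return(x)
  half <- w %/% 2L
  # trailing-window max on x padded left so window t covers [t-half, t+half]
  xp <- c(rep(x[1L], half), x, rep(x[n], w - half - 1L))
  np <- length(xp)
  nb <- ceiling(np / w)
  xb <- c(xp, rep(-Inf, nb * w - np))
  m <- matrix(xb, nrow = w)
  pre <- m; suf <- m
  for (i in 2:w) pre[i, ] <- pmax(pre[i - 1L, ], m[i, ])
  for (i in (w - 1L):1L) suf[i, ] <- pmax(suf[i + 1L, ], m[i, ])
  P <- as.vector(pre); S <- as.vector(suf)
  idx_end <- seq_len(n) + (w - 1L)          # trailing window end in xp
  out <- pmax(S[idx_end - w + 1L], P[idx_end])
  out
}

# Indices of strict local maxima of x exceeding `threshold`.
find_peaks <- function(x, threshold = -Inf) {
  n <- length(x)
  if (n < 3L) return(integer(0))
  d <- diff(x)
  idx <- which(d[-(n - 1L)] > 0 & d[-1L] <= 0) + 1L
  idx[x[idx] > threshold]
}

# Centered moving average with edge padding (replicates first/last value).
moving_average <- function(x, k) {
  k <- max(1L, as.integer(k))
  if (k == 1L) return(x)
  n <- length(x)
  pad_l <- rep(x[1L], k)
  pad_r <- rep(x[n], k)
  cs <- cumsum(c(pad_l, x, pad_r))
  half <- k %/% 2L
  lo <- seq_len(n) + k - half
  hi <- lo + k - 1L
  (cs[hi] - cs[lo - 1L]) / k
}

# Tukey (tapered cosine) window of length n with taper fraction alpha.
tukey_window <- function(n, alpha = 0.1) {
  if (n <= 1L) return(rep(1, n))
  t <- seq(0, 1, length.out = n)
  w <- rep(1, n)
  edge <- alpha / 2
  lo <- t < edge
  hi <- t > 1 - edge
  w[lo] <- 0.5 * (1 + cos(pi * (2 * t[lo] / alpha - 1)))
  w[hi] <- 0.5 * (1 + cos(pi * (2 * (t[hi] - 1) / alpha + 1)))
  w
}
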