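#' Skin-electrode equivalent-circuit parameters
#'
#' Parameters of the series equivalent circuit for a dry electrode on fish
#' skin: a series (solution/access) resistance `R_s`, an optional
#' subcutaneous block — resistance `R_sub` in parallel with capacitance
#' `C_sub` (skull, epidermis, scales) — and the electrode interface block, a
#' charge-transfer resistance `R_ct` in parallel with a constant phase
#' element (CPE). The CPE has impedance `1 / (Q * (j*w)^n)` and captures the
#' non-ideal double-layer capacitance of the mucous skin surface; `n = 1`
#' recovers an ideal capacitor, `n = 0` a resistor.
#'
#' @param R_s series resistance, ohm.
#' @param R_ct charge-transfer resistance, ohm.
#' @param Q CPE coefficient, S * s^n.
#' @param n CPE exponent in `[0, 1]`.
#' @param R_sub,C_sub optional subcutaneous parallel RC block (ohm, farad);
#'   both `NULL` for the reduced circuit.
#' @return an object of class `zf_circuit_params`.
#' @export
circuit_params <- function(R_s, R_ct, Q, n, R_sub = NULL, C_sub = NULL) {
  for (nm in c("R_s", "R_ct", "Q")) stopifnot_scalar_pos(get(nm), nm)
  if (!is.numeric(n) || length(n) != 1L || is.na(n) || n < 0 || n > 1) {
    stop("`n` must lie in [0, 1]", call. = FALSE)
  }
  if (xor(is.null(R_sub), is.null(C_sub))) {
    stop("supply both `R_sub` and `C_sub`, or neither", call. = FALSE)
  }
  if (!is.null(R_sub)) {
    stopifnot_scalar_pos(R_sub, "R_sub"); stopifnot_scalar_pos(C_sub, "C_sub")
  }
  structure(list(R_s = R_s, R_ct = R_ct, Q = Q, n = n,
                 R_sub = R_sub, C_sub = C_sub),
            class = "zf_circuit_params")
}

#' @export
print.zf_circuit_params <- function(x, ...) {
  cat(sprintf("<zf_circuit_params> R_s=%.4g ohm, R_ct=%.4g ohm, Q=%.4g S*s^n, n=%.3f",
              x$R_s, x$R_ct, x$Q, x$n))
  if (!is.null(x$R_sub)) {
    cat(sprintf(", R_sub=%.4g ohm, C_sub=%.4g F", x$R_sub, x$C_sub))
  }
  cat("\n")
  invisible(x)
}

#' Complex impedance of the equivalent circuit
#'
#' `Z(w) = R_s + (R_sub || 1/(j*w*C_sub)) + (R_ct || Z_CPE)` with
#' `Z_CPE = 1 / (Q * (j*w)^n)` and `w = 2*pi*f`; the subcutaneous term is
#' omitted for the reduced circuit.
#'
#' @param params a [circuit_params()].
#' @param freq frequencies, Hz (all > 0); vectorized.
#' @return complex impedance vector, ohm.
#' @export
#' @examples
#' p <- circuit_params(R_s = 1e3, R_ct = 1e7, Q = 5e-7, n = 0.9)
#' Mod(circuit_impedance(p, c(1, 50)))
circuit_impedance <- function(params, freq) {
  stopifnot(inherits(params, "zf_circuit_params"))
  if (any(!is.finite(freq)) || any(freq <= 0)) {
    stop("frequencies must be positive and finite", call. = FALSE)
  }
  w <- 2 * pi * freq
  jw <- complex(real = 0, imaginary = 1) * w
  z_cpe <- 1 / (params$Q * jw^params$n)
  z <- params$R_s + (params$R_ct * z_cpe) / (params$R_ct + z_cpe)
  if (!is.null(params$R_sub)) {
    z_c <- 1 / (jw * params$C_sub)
    z <- z + (params$R_sub * z_c) / (params$R_sub + z_c)
  }
  z
}

#' Impedance spectrum container
#'
#' @param freqs frequencies, Hz, strictly increasing.
#' @param magnitude impedance magnitudes, ohm, positive.
#' @param phase optional phase, degrees.
#' @return an object of class `zf_eis_spectrum` (a data.frame).
#' @export
eis_spectrum <- function(freqs, magnitude, phase = NULL) {
  if (any(diff(freqs) <= 0)) {
    stop("frequencies must be strictly increasing", call. = FALSE)
  }
  if (any(magnitude <= 0)) stop("magnitudes must be positive", call. = FALSE)
  df <- data.frame(freq_hz = freqs, z_mag_ohm = magnitude)
  if (!is.null(phase)) df$phase_deg <- phase
  class(df) <- c("zf_eis_spectrum", "data.frame")
  df
}

#' Read an impedance spectrum CSV
#'
#' Expects columns `freq_hz`, `z_mag_ohm` and optionally `phase_deg`. Rows
#' are sorted by frequency.
#'
#' @param path CSV path.
#' @return a [eis_spectrum()].
#' @export
read_spectrum <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  df <- utils::read.csv(path)
  need <- c("freq_hz", "z_mag_ohm")
  if (!all(need %in% names(df))) {
    stop("spectrum CSV needs columns freq_hz, z_mag_ohm", call. = FALSE)
  }
  df <- df[order(df$freq_hz), ]
  eis_spectrum(df$freq_hz, df$z_mag_ohm,
               phase = if ("phase_deg" %in% names(df)) df$phase_deg)
}

#' Reference five-point skin-electrode spectrum
#'
#' The bundled five-point impedance-magnitude spectrum of the dry
#' skin-electrode interface measured at one representative frequency per
#' EEG band (delta 1 Hz, theta 5 Hz, alpha 10 Hz, beta 30 Hz, gamma 50 Hz):
#' 2.7 Mohm, 585.4 kohm, 306.9 kohm, 106.7 kohm, 72.8 kohm.
#'
#' @return a [eis_spectrum()].
#' @export
reference_impedance <- function() {
  read_spectrum(system.file("extdata", "skin_electrode_impedance.csv",
                            package = "zfeeg", mustWork = TRUE))
}

#' Fit the equivalent circuit to a measured spectrum
#'
#' Least-squares fit of `log10 |Z_model|` to `log10 |Z_data|` (log space
#' balances the Mohm-to-kohm dynamic range across the EEG band), with phase
#' residuals (degrees, scaled) added when the spectrum carries phase. Sparse
#' spectra (< 7 points) default to the reduced circuit (no subcutaneous RC)
#' to stay identifiable. Fitting uses Levenberg-Marquardt on box-bounded
#' parameters, `R_s`, `R_ct` and `Q` in log10 space.
#'
#' @param spectrum a [eis_spectrum()].
#' @param model `"auto"`, `"reduced"` or `"full"`.
#' @param init optional [circuit_params()] starting point.
#' @param phase_weight weight of one degree of phase residual relative to
#'   one dex of log-magnitude residual.
#' @return list of class `zf_circuit_fit`: `params` ([circuit_params()]),
#'   `residuals` (log10 magnitude, dex), `fitted` (ohm), `ssq`, `chisq`,
#'   `df`, `p_value` (chi-square goodness of fit on relative residuals),
#'   and the `spectrum`.
#' @export
#' @examples
#' fit <- fit_circuit(reference_impedance())
#' evaluate_band_frequencies(fit$params)
fit_circuit <- function(spectrum, model = c("auto", "reduced", "full"),
                        init = NULL, phase_weight = 0.02) {
  stopifnot(inherits(spectrum, "zf_eis_spectrum"))
  model <- match.arg(model)
  n_pts <- nrow(spectrum)
  if (model == "auto") model <- if (n_pts < 7) "reduced" else "full"
  n_par <- if (model == "reduced") 4L else 6L
  if (n_pts < n_par) {
    stop(sprintf("need at least %d points to fit the %s circuit",
                 n_par, model), call. = FALSE)
  }
  f <- spectrum$freq_hz
  logz <- log10(spectrum$z_mag_ohm)
  has_phase <- "phase_deg" %in% names(spectrum)

  if (is.null(init)) {
    # slope of log|Z| vs log f approximates -n for a CPE-dominated spectrum
    sl <- -stats::coef(stats::lm(logz ~ log10(f)))[2]
    n0 <- min(max(sl, 0.05), 0.98)
    zmax <- max(spectrum$z_mag_ohm); zmin <- min(spectrum$z_mag_ohm)
    q0 <- 1 / (zmax * (2 * pi * f[which.max(spectrum$z_mag_ohm)])^n0)
    init <- list(R_s = 0.05 * zmin, R_ct = 50 * zmax, Q = q0, n = n0,
                 R_sub = 0.5 * zmin, C_sub = 1e-7)
  } else {
    init <- unclass(init)
    if (is.null(init$R_sub)) { init$R_sub <- 0.5 * min(spectrum$z_mag_ohm)
                               init$C_sub <- 1e-7 }
  }
  to_params <- function(th) {
    if (model == "reduced") {
      circuit_params(R_s = 10^th[1], R_ct = 10^th[2], Q = 10^th[3], n = th[4])
    } else {
      circuit_params(R_s = 10^th[1], R_ct = 10^th[2], Q = 10^th[3], n = th[4],
                     R_sub = 10^th[5], C_sub = 10^th[6])
    }
  }
  th0 <- c(log10(init$R_s), log10(init$R_ct), log10(init$Q), init$n)
  lower <- c(-2, 0, -15, 0); upper <- c(12, 14, 0, 1)
  if (model == "full") {
    th0 <- c(th0, log10(init$R_sub), log10(init$C_sub))
    lower <- c(lower, -2, -12); upper <- c(upper, 12, 0)
  }
  resid_fn <- function(th) {
    z <- circuit_impedance(to_params(th), f)
    r <- log10(Mod(z)) - logz
    if (has_phase) {
      r <- c(r, phase_weight * (Arg(z) * 180 / pi - spectrum$phase_deg))
    }
    r
  }
  fit <- minpack.lm::nls.lm(par = th0, lower = lower, upper = upper,
                            fn = resid_fn,
                            control = minpack.lm::nls.lm.control(
                              maxiter = 500, ftol = 1e-12, ptol = 1e-12))
  if (fit$info == 0 || fit$info == 9) {
    stop(sprintf("circuit fit failed to converge (final ssq %.3g)",
                 fit$deviance), call. = FALSE)
  }
  params <- to_params(fit$par)
  fitted <- Mod(circuit_impedance(params, f))
  res <- log10(fitted) - logz
  # chi-square goodness of fit on relative magnitude residuals, assuming a
  # 10% measurement coefficient of variation per point
  rel <- (fitted - spectrum$z_mag_ohm) / spectrum$z_mag_ohm
  chisq <- sum((rel / 0.10)^2)
  dof <- max(1L, n_pts - n_par)
  structure(list(params = params, residuals = res, fitted = fitted,
                 ssq = sum(resid_fn(fit$par)^2), chisq = chisq, df = dof,
                 p_value = stats::pchisq(chisq, dof, lower.tail = FALSE),
                 model = model, spectrum = spectrum),
            class = "zf_circuit_fit")
}

#' @export
print.zf_circuit_fit <- function(x, ...) {
  cat(sprintf("<zf_circuit_fit> %s circuit, %d points\n", x$model,
              nrow(x$spectrum)))
  print(x$params)
  cat(sprintf("  max |log10 residual| = %.4g dex; chisq(%d) = %.3g (p = %.3g)\n",
              max(abs(x$residuals)), x$df, x$chisq, x$p_value))
  invisible(x)
}

#' Evaluate the circuit at one frequency per EEG band
#'
#' Impedance magnitudes at 1, 5, 10, 30 and 50 Hz — a representative point
#' in each of the delta, theta, alpha, beta and gamma bands.
#'
#' @param params a [circuit_params()] (or a `zf_circuit_fit`).
#' @return named numeric vector (ohm) with names delta, theta, alpha, beta,
#'   gamma.
#' @export
evaluate_band_frequencies <- function(params) {
  if (inherits(params, "zf_circuit_fit")) params <- params$params
  f <- c(delta = 1, theta = 5, alpha = 10, beta = 30, gamma = 50)
  stats::setNames(Mod(circuit_impedance(params, unname(f))), names(f))
}
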