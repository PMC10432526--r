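#' Swept-source laser and digitizer configuration
#'
#' Describes the wavelength-swept laser and acquisition electronics of a
#' swept-source OCT interferometer. The defaults reproduce a
#' polygon-scanner system: 1307 nm center wavelength, 43.2 kHz A-line rate,
#' 2048 samples per A-line digitized at 108 MS/s, and a Gaussian sweep power
#' envelope. The wavenumber tuning rate `k1` is chosen so that one depth
#' pixel spans 21.5 um, equivalently one fringe-frequency pixel spans
#' `f_s / n_samples` = 52.73 kHz.
#'
#' Derived quantities stored in the object:
#' * `k0 = 2*pi/lambda0`, the center wavenumber (rad/m);
#' * `T = 1/f_A`, the sweep (A-line) period (s);
#' * `df_pixel = f_s / n_samples`, fringe-frequency pixel spacing (Hz);
#' * `dz_pixel = pi * f_s / (k1 * n_samples)`, depth pixel spacing (m);
#' * `z_nyquist = dz_pixel * n_samples / 2`, unambiguous depth range (m);
#' * `sigma_z = 4*log(2) / (sigma_env * k1 * T)`, FWHM axial resolution (m).
#'
#' @param lambda0 Center wavelength (m).
#' @param f_A A-line (sweep) rate (Hz).
#' @param n_samples Digitized samples per A-line.
#' @param f_s Digitizer sampling rate (samples/s).
#' @param sigma_env Fractional FWHM of the Gaussian sweep power envelope,
#'   relative to the sweep period (dimensionless, 0 < sigma_env < 1).
#' @param sigma_T Standard deviation of the per-sweep period jitter (s).
#' @param k1 Wavenumber tuning rate (rad m^-1 s^-1). The default ties the
#'   depth pixel to 21.5 um at the default digitizer settings.
#' @param dz_pixel Depth pixel spacing (m) used to derive `k1` when `k1` is
#'   not given explicitly.
#'
#' @return An object of class `sweep_config`.
#' @examples
#' sw <- sweep_config()
#' sw$dz_pixel   # 2.15e-5 m
#' sw$df_pixel   # 52734.375 Hz
#' @export
sweep_config <- function(lambda0 = 1307e-9,
                         f_A = 43.2e3,
                         n_samples = 2048,
                         f_s = 108e6,
                         sigma_env = 0.8,
                         sigma_T = 4.9e-9,
                         k1 = NULL,
                         dz_pixel = 21.5e-6) {
  stopifnot(lambda0 > 0, f_A > 0, n_samples >= 2, f_s > 0,
            sigma_env > 0, sigma_env < 1, sigma_T >= 0)
  if (n_samples * f_A > f_s * (1 + 1e-9)) {
    stop("acquisition window n_samples/f_s exceeds the sweep period 1/f_A")
  }
  df_pixel <- f_s / n_samples
  if (is.null(k1)) {
    stopifnot(dz_pixel > 0)
    k1 <- pi * df_pixel / dz_pixel
  } else {
    stopifnot(k1 > 0)
    dz_pixel <- pi * df_pixel / k1
  }
  T_sweep <- 1 / f_A
  obj <- list(
    lambda0 = lambda0, f_A = f_A, n_samples = as.integer(n_samples),
    f_s = f_s, sigma_env = sigma_env, sigma_T = sigma_T, k1 = k1,
    k0 = 2 * pi / lambda0,
    T = T_sweep,
    df_pixel = df_pixel,
    dz_pixel = dz_pixel,
    z_nyquist = dz_pixel * n_samples / 2,
    sigma_z = 4 * log(2) / (sigma_env * k1 * T_sweep)
  )
  class(obj) <- "sweep_config"
  obj
}

#' @export
print.sweep_config <- function(x, ...) {
  cat("<sweep_config>\n")
  cat(sprintf("  lambda0   : %.1f nm   (k0 = %.4g rad/m)\n",
              x$lambda0 * 1e9, x$k0))
  cat(sprintf("  f_A       : %.4g kHz  (T = %.4g us)\n",
              x$f_A / 1e3, x$T * 1e6))
  cat(sprintf("  sampling  : %d pts at %.4g MS/s\n", x$n_samples, x$f_s / 1e6))
  cat(sprintf("  k1        : %.6g rad/(m s)\n", x$k1))
  cat(sprintf("  pixel     : %.3g um depth / %.4g kHz fringe\n",
              x$dz_pixel * 1e6, x$df_pixel / 1e3))
  cat(sprintf("  envelope  : sigma = %.2f (axial FWHM %.3g um)\n",
              x$sigma_env, x$sigma_z * 1e6))
  cat(sprintf("  jitter    : sigma_T = %.3g ns\n", x$sigma_T * 1e9))
  invisible(x)
}

#' Sample times within one sweep
#'
#' Times `t_hat` of the digitized samples relative to the sweep center,
#' spanning approximately `[-n_samples/(2 f_s), +n_samples/(2 f_s)]`.
#' @param sweep A [sweep_config()].
#' @return Numeric vector of length `n_samples` (s).
#' @keywords internal
sweep_sample_times <- function(sweep) {
  s <- seq_len(sweep$n_samples) - 1
  (s - sweep$n_samples / 2) / sweep$f_s
}

#' Gaussian sweep power envelope
#'
#' `P(t) = exp(-4 log(2) t^2 / (sigma_env * T)^2)`, evaluated at the sample
#' times of the sweep.
#' @param sweep A [sweep_config()].
#' @param t_hat Times relative to sweep center (s); defaults to the sample grid.
#' @return Numeric vector of envelope values in (0, 1].
#' @export
sweep_envelope <- function(sweep, t_hat = sweep_sample_times(sweep)) {
  exp(-4 * log(2) * t_hat^2 / (sweep$sigma_env * sweep$T)^2)
}
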