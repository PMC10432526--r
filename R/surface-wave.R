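#' Analytic near-field surface-wave displacement
#'
#' Surface displacement produced by a harmonically vibrating cylindrical
#' probe of radius `a` on an incompressible half-space, as the sum of the
#' Rayleigh and supershear pole contributions:
#' `u(x) = i*pi*(a p0 K^4)/(rho omega^2) * [ J1(K_R a) K_R / F'(K_R) * H0^(1)(-K_R x)
#'        + J1(K_SS a) K_SS / F'(K_SS) * H0^(1)(-K_SS x) ]`
#' where `K` is the complex bulk shear wavenumber (`k_r - i k_i` for a wave
#' `exp(i(omega t - k x))` decaying with distance), `K_R` and `K_SS` the
#' secular-equation roots, `J1` the Bessel function and `H0^(1)` the Hankel
#' function of the first kind on the principal branch. The Hankel argument
#' `-K x` then has a non-negative imaginary part for `x > 0`, giving
#' outward-decaying waves.
#'
#' @param x Lateral distances from the probe axis (m), `|x| >= a`.
#' @param K Complex bulk shear wavenumber (rad/m), `Re(K) > 0`,
#'   `Im(K) <= 0`.
#' @param a Probe radius (m).
#' @param rho Density (kg/m^3).
#' @param omega_m Angular vibration frequency (rad/s).
#' @param p0 Pressure amplitude (arbitrary complex scale; only relative
#'   displacement shapes matter downstream).
#' @return Complex displacement at each `x`.
#' @export
surface_wave_displacement <- function(x, K, a, rho, omega_m, p0 = 1) {
  stopifnot(all(abs(x) >= a), Re(K) > 0)
  roots <- secular_roots_cached()
  K <- as.complex(K)
  K_R <- roots$rayleigh * K
  K_SS <- roots$supershear * K
  pref <- 1i * pi * a * p0 * K^4 / (rho * omega_m^2)
  term <- function(Kr) {
    besselJ1c(Kr * a) * Kr / secular_deriv(Kr, K) * hankel1_0(-Kr * x)
  }
  as.vector(pref * (term(K_R) + term(K_SS)))
}

# secular roots are constants of the model; compute once per session
secular_roots_cached <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) cache <<- secular_roots()
    cache
  }
})

#' Fit the analytic surface-wave model to a measured profile
#'
#' Least-squares fit of [surface_wave_displacement()] to a complex surface
#' displacement profile, fitting the real and imaginary parts jointly with
#' Levenberg-Marquardt. Free parameters: the complex bulk shear wavenumber
#' `K = k_r - i k_i` and a complex amplitude scale (absorbing `p0` and any
#' instrumental phase).
#'
#' @param profile A [surface_profile()] (or list with `x`, `u`, `f`).
#' @param a Probe radius (m).
#' @param rho Density (kg/m^3).
#' @param K_init Initial guess for the complex wavenumber (rad/m). A real
#'   value gets a small default loss added; should be within about a factor
#'   of 3 of the truth (use [pick_mode()] to seed it).
#' @param omega_m Angular frequency (rad/s); defaults to `2*pi*profile$f`.
#' @return List with `K` (complex), `k_r`, `k_i`, `p0` (fitted complex
#'   scale), `residual` (RMS of the stacked real/imag residuals relative to
#'   RMS data), and the `nls.lm` convergence info.
#' @export
fit_surface_wave <- function(profile, a, rho, K_init, omega_m = NULL) {
  x <- profile$x
  u <- profile$u
  if (is.null(omega_m)) omega_m <- 2 * pi * profile$f
  stopifnot(length(x) >= 8, all(abs(x) >= a))
  K_init <- as.complex(K_init)
  if (Im(K_init) == 0) K_init <- K_init * (1 - 0.05i)

  # amplitude seed: match peak magnitudes with unit pressure
  u0 <- surface_wave_displacement(x, K_init, a, rho, omega_m, p0 = 1)
  p0_init <- sum(Conj(u0) * u) / sum(Mod(u0)^2)

  par0 <- c(Re(K_init), -Im(K_init), Re(p0_init), Im(p0_init))
  resid_fun <- function(p) {
    K <- complex(real = p[1], imaginary = -abs(p[2]))
    if (p[1] <= 0) return(rep(1e6, 2 * length(x)))
    p0 <- complex(real = p[3], imaginary = p[4])
    um <- surface_wave_displacement(x, K, a, rho, omega_m, p0 = p0)
    c(Re(um - u), Im(um - u))
  }
  fit <- minpack.lm::nls.lm(par = par0, fn = resid_fun,
                            control = minpack.lm::nls.lm.control(
                              maxiter = 200, ftol = 1e-14, ptol = 1e-14))
  p <- fit$par
  K <- complex(real = p[1], imaginary = -abs(p[2]))
  rms_res <- sqrt(mean(fit$fvec^2))
  rms_dat <- sqrt(mean(c(Re(u), Im(u))^2))
  list(K = K, k_r = Re(K), k_i = -Im(K),
       p0 = complex(real = p[3], imaginary = p[4]),
       residual = rms_res / rms_dat,
       info = fit$info, message = fit$message)
}
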