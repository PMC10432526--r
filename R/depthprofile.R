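#' Empirical skin dispersion model
#'
#' Parametric form for the Rayleigh-wave speed of layered skin versus
#' frequency (f in kHz):
#' `v(f) = v0 + a*f / sqrt(b^2 f^2 + 1) + c*f / (d*f + 1)` (m/s).
#' Presets: `"normal"` (v0 = 9.5, a = 0.44, b = 0.0032, c = 1.6, d = 0.02)
#' and `"hydrated"` (a = 1.25, b = 0.032, c = 0).
#'
#' @param preset "normal", "hydrated", or NULL to pass coefficients.
#' @param v0,a,b,c,d Model coefficients (v0 in m/s; f in kHz inside the
#'   formula).
#' @return Object of class `skin_velocity_model`.
#' @export
skin_velocity_model <- function(preset = c("normal", "hydrated", "custom"),
                                v0 = 9.5, a = 0.44, b = 0.0032,
                                c = 1.6, d = 0.02) {
  preset <- match.arg(preset)
  co <- switch(preset,
               normal = list(v0 = 9.5, a = 0.44, b = 0.0032, c = 1.6,
                             d = 0.02),
               hydrated = list(v0 = 9.5, a = 1.25, b = 0.032, c = 0,
                               d = 0.02),
               custom = list(v0 = v0, a = a, b = b, c = c, d = d))
  structure(co, class = "skin_velocity_model")
}

#' Evaluate (and differentiate) the skin dispersion model
#'
#' @param f_khz Frequency in kHz (non-negative).
#' @param model A [skin_velocity_model()].
#' @return `skin_velocity`: speed in m/s. `skin_velocity_deriv`: analytic
#'   derivative dv/df in (m/s) per kHz.
#' @examples
#' skin_velocity(0)                      # 9.5 m/s (normal preset)
#' skin_velocity(40, skin_velocity_model("hydrated"))
#' @export
skin_velocity <- function(f_khz, model = skin_velocity_model("normal")) {
  stopifnot(all(f_khz >= 0))
  with(model, v0 + a * f_khz / sqrt(b^2 * f_khz^2 + 1) +
         c * f_khz / (d * f_khz + 1))
}

#' @rdname skin_velocity
#' @export
skin_velocity_deriv <- function(f_khz, model = skin_velocity_model("normal")) {
  with(model, a * (b^2 * f_khz^2 + 1)^(-1.5) + c / (d * f_khz + 1)^2)
}

# single internal bulk-shear-to-Rayleigh factor (= K_R/K secular root)
shear_over_rayleigh <- function() secular_roots_cached()$rayleigh

#' Forward dispersion of a depth-varying shear modulus
#'
#' Rayleigh-wave dispersion of a half-space whose shear modulus varies with
#' depth, via the depth-averaged compliance approximation
#' `k^2 = (rho omega^2 / L_z) * integral_0^{L_z} dz / mu(z)`,
#' where `L_z = a_L * lambda = a_L * 2*pi/k` is the penetration depth of
#' the wave. The implicit relation is solved per frequency by fixed-point
#' iteration (relative tolerance 1e-10, at most 100 iterations).
#'
#' @param mu_fun Vectorized function `mu(z)` (Pa, z in m), positive.
#' @param f Frequencies (Hz).
#' @param rho Density (kg/m^3).
#' @param a_L Penetration-depth fraction of the wavelength (default 0.25).
#' @return data.frame with `f`, `k` (rad/m, bulk-shear-equivalent),
#'   `v` (m/s, = omega/k), `v_R` (Rayleigh speed, `v` divided by the
#'   secular-root factor ~1.047), `L_z` (m).
#' @export
forward_dispersion_from_profile <- function(mu_fun, f, rho = 1000,
                                            a_L = 0.25) {
  stopifnot(a_L > 0, rho > 0, all(f > 0))
  fac <- shear_over_rayleigh()
  res <- lapply(f, function(ff) {
    omega <- 2 * pi * ff
    k <- omega * sqrt(rho / mu_fun(0))
    for (it in 1:100) {
      L <- a_L * 2 * pi / k
      mean_inv_mu <- stats::integrate(function(z) 1 / mu_fun(z), 0, L,
                                      rel.tol = 1e-12)$value / L
      k_new <- omega * sqrt(rho * mean_inv_mu)
      if (abs(k_new - k) <= 1e-10 * k) { k <- k_new; break }
      if (it == 100) stop(sprintf(
        "penetration-depth iteration did not converge at f = %.4g Hz", ff))
      k <- 0.5 * (k + k_new)   # damped update for stability
    }
    c(k = k, L_z = a_L * 2 * pi / k)
  })
  k <- vapply(res, `[[`, numeric(1), "k")
  L_z <- vapply(res, `[[`, numeric(1), "L_z")
  data.frame(f = f, k = k, v = 2 * pi * f / k, v_R = 2 * pi * f / k / fac,
             L_z = L_z)
}

#' Depth-resolved shear modulus from a dispersion curve
#'
#' Inverts a measured Rayleigh-wave dispersion `v_R(f)` into a depth
#' profile of shear modulus using
#' `mu(z) = rho v^2 (v - f v') / (v + f v')` with `z = a_L v / f`, where
#' `v` is the bulk-shear-equivalent speed (the Rayleigh speed times the
#' secular-root factor ~1.047) and `v' = dv/df`. The derivative is the
#' dominant numerical hazard; it is taken from a smoother:
#' * `"model"`: least-squares fit of the [skin_velocity_model()] parametric
#'   form (analytic derivative);
#' * `"spline"`: smoothing spline `v(f)` differentiated analytically.
#'
#' Points where `v + f v' <= 0` (formula breakdown) are masked with a
#' warning.
#'
#' @param f Frequencies (Hz).
#' @param v_R Measured Rayleigh wave speeds (m/s).
#' @param rho Density (kg/m^3).
#' @param a_L Penetration-depth fraction (default 0.25).
#' @param smoother "spline" (default) or "model".
#' @param spar Optional smoothing parameter passed to
#'   [stats::smooth.spline()].
#' @return data.frame with `f`, `z` (m), `mu` (Pa), `v` (m/s), `v_prime`
#'   (m/s per Hz), `valid` (logical mask).
#' @export
invert_depth_profile <- function(f, v_R, rho = 1000, a_L = 0.25,
                                 smoother = c("spline", "model"),
                                 spar = NULL) {
  smoother <- match.arg(smoother)
  stopifnot(length(f) == length(v_R), length(f) >= 4, all(f > 0),
            all(v_R > 0))
  fac <- shear_over_rayleigh()
  v_meas <- v_R * fac
  if (smoother == "model") {
    fit <- fit_skin_velocity_model(f / 1e3, v_meas)
    v <- skin_velocity(f / 1e3, fit)
    v_prime <- skin_velocity_deriv(f / 1e3, fit) / 1e3  # per Hz
  } else {
    ss <- if (is.null(spar)) stats::smooth.spline(f, v_meas) else
      stats::smooth.spline(f, v_meas, spar = spar)
    v <- stats::predict(ss, f)$y
    v_prime <- stats::predict(ss, f, deriv = 1)$y
  }
  denom <- v + f * v_prime
  valid <- denom > 0
  if (any(!valid)) {
    warning(sprintf("%d point(s) masked where v + f v' <= 0", sum(!valid)))
  }
  mu <- rep(NA_real_, length(f))
  mu[valid] <- rho * v[valid]^2 * (v[valid] - f[valid] * v_prime[valid]) /
    denom[valid]
  data.frame(f = f, z = a_L * v / f, mu = mu, v = v, v_prime = v_prime,
             valid = valid)
}

#' Fit the parametric skin dispersion form to measured speeds
#'
#' Least-squares fit of the [skin_velocity_model()] functional form to
#' `(f, v)` samples (f in kHz, v in m/s), used as the default smoother for
#' depth inversion of skin-like dispersion data.
#'
#' @param f_khz Frequencies (kHz).
#' @param v Speeds (m/s).
#' @param start Optional named list of starting coefficients.
#' @return A fitted [skin_velocity_model()].
#' @export
fit_skin_velocity_model <- function(f_khz, v, start = NULL) {
  if (is.null(start)) {
    start <- list(v0 = max(min(v), 0.1), a = 1, b = 0.01,
                  c = 0.5, d = 0.02)
  }
  resid_fun <- function(p) {
    m <- skin_velocity_model("custom", v0 = p[1], a = p[2],
                             b = abs(p[3]), c = p[4], d = abs(p[5]))
    skin_velocity(f_khz, m) - v
  }
  fit <- minpack.lm::nls.lm(par = unlist(start), fn = resid_fun,
                            control = minpack.lm::nls.lm.control(
                              maxiter = 500))
  p <- fit$par
  skin_velocity_model("custom", v0 = p[1], a = p[2], b = abs(p[3]),
                      c = p[4], d = abs(p[5]))
}
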