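#' Discrete scatterer scene
#'
#' A set of point scatterers per lateral position. Depths are in meters,
#' reflectance amplitudes are dimensionless and non-negative. For a single
#' lateral position pass plain vectors; for an M-B scan pass lists with one
#' element per lateral position.
#'
#' @param z0 Scatterer depths (m): numeric vector, or list of numeric vectors
#'   (one per lateral position).
#' @param r Reflectance amplitudes, matching the shape of `z0`.
#' @param x Lateral positions (m), one per list element. Defaults to a
#'   uniform grid with spacing `dx`.
#' @param dx Lateral spacing (m) used when `x` is not supplied.
#' @return An object of class `scatterer_scene`: list with elements `x`
#'   (lateral positions) and `positions` (list of data.frames with columns
#'   `z0`, `r`).
#' @examples
#' scatterer_scene(z0 = c(1e-3, 2e-3), r = c(1, 0.5))
#' @export
scatterer_scene <- function(z0, r, x = NULL, dx = 10e-6) {
  if (!is.list(z0)) z0 <- list(z0)
  if (!is.list(r)) r <- list(r)
  if (length(r) == 1L && length(z0) > 1L) r <- rep(r, length(z0))
  stopifnot(length(z0) == length(r))
  positions <- mapply(function(z, rr) {
    stopifnot(length(z) == length(rr))
    if (length(z)) {
      stopifnot(all(is.finite(z)), all(is.finite(rr)), all(rr >= 0),
                all(z >= 0))
    }
    data.frame(z0 = as.numeric(z), r = as.numeric(rr))
  }, z0, r, SIMPLIFY = FALSE)
  if (is.null(x)) x <- (seq_along(positions) - 1) * dx
  stopifnot(length(x) == length(positions))
  structure(list(x = as.numeric(x), positions = positions),
            class = "scatterer_scene")
}

#' @export
print.scatterer_scene <- function(x, ...) {
  ns <- vapply(x$positions, nrow, integer(1))
  cat(sprintf("<scatterer_scene> %d lateral position(s), %s scatterer(s)\n",
              length(x$positions),
              if (length(unique(ns)) == 1) ns[1] else paste(range(ns),
                                                            collapse = "-")))
  invisible(x)
}

#' Harmonic vibration field
#'
#' Axial harmonic displacement of the scatterers,
#' `dz(x, z, t) = |delta(x, z)| * sin(omega_m t + phi + arg(delta(x, z)))`.
#' The complex amplitude `delta` encodes both the local vibration amplitude
#' (modulus, in meters) and the local phase of the traveling wave (argument),
#' so a propagating surface wave is written as
#' `delta(x) = delta0 * exp(-1i * k * x)`.
#'
#' @param delta Complex (or numeric) vibration amplitude (m). Either a single
#'   value, or a function `f(x, z)` returning the complex amplitude at lateral
#'   position `x` and depth `z`.
#' @param f_m Modulation frequency (Hz).
#' @param phi Global initial phase of the stimulus (rad).
#' @return Object of class `vibration_field`.
#' @examples
#' # 50 nm uniform vibration at 679.6 kHz
#' vibration_field(50e-9, f_m = 679.6e3)
#' @export
vibration_field <- function(delta, f_m, phi = 0) {
  stopifnot(f_m > 0)
  if (!is.function(delta)) {
    amp <- delta
    delta <- function(x, z) rep(amp, length(z))
  }
  structure(list(delta = delta, f_m = f_m, omega_m = 2 * pi * f_m, phi = phi),
            class = "vibration_field")
}

#' @export
print.vibration_field <- function(x, ...) {
  cat(sprintf("<vibration_field> f_m = %.4g kHz, phi = %.3g rad\n",
              x$f_m / 1e3, x$phi))
  invisible(x)
}

#' Three-scatterer demodulation demonstration scene
#'
#' The canonical scene used to exercise the anti-aliasing demodulator: three
#' scatterers separated in depth by exactly the sideband offset
#' `z_m = omega_m / (2 k1)`. The deepest scatterer (at `z0`) and the
#' shallowest (at `z0 - 2 z_m`) vibrate; the middle one (at `z0 - z_m`) is
#' static, so at the observation depth `z0 - z_m` the left sideband of the
#' deep scatterer, the static carrier of the middle one, and the right
#' sideband of the shallow one all coincide.
#'
#' @param sweep A [sweep_config()].
#' @param f_m Modulation frequency (Hz); the default 688.8 kHz equals
#'   `16 * f_A - 2.4 kHz` at the default A-line rate.
#' @param z0_pixel Depth pixel of the deepest scatterer.
#' @param delta Vibration amplitude of the two moving scatterers (m).
#' @param r Reflectance amplitudes of the three scatterers (deep, middle,
#'   shallow).
#' @param phi Initial stimulus phase (rad).
#' @return List with elements `scene` ([scatterer_scene()]), `vib`
#'   ([vibration_field()]), `z_m` (m), and the scatterer depths `z_scat`.
#' @export
three_scatterer_scene <- function(sweep = sweep_config(),
                                  f_m = 688.8e3,
                                  z0_pixel = 107,
                                  delta = 10e-9,
                                  r = c(1, 0.8, 0.9),
                                  phi = 0) {
  stopifnot(length(r) == 3)
  z_m <- 2 * pi * f_m / (2 * sweep$k1)
  z0 <- z0_pixel * sweep$dz_pixel
  z_scat <- c(z0, z0 - z_m, z0 - 2 * z_m)
  stopifnot(all(z_scat > 0), z0 < sweep$z_nyquist)
  vibrating <- c(TRUE, FALSE, TRUE)
  delta_fun <- function(x, z) {
    out <- complex(length(z))
    for (j in seq_along(z)) {
      i <- which.min(abs(z[j] - z_scat))
      out[j] <- if (vibrating[i]) complex(real = delta) else 0 + 0i
    }
    out
  }
  list(scene = scatterer_scene(z0 = z_scat, r = r),
       vib = vibration_field(delta_fun, f_m = f_m, phi = phi),
       z_m = z_m, z_scat = z_scat)
}
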