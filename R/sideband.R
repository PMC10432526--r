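#' Sideband demodulation plan
#'
#' Computes where the vibration sidebands of a scatterer land in depth and
#' how the modulation frequency folds into the sub-Nyquist band of the
#' A-line rate. Writing `f_m = fbar + 0.5 * n * f_A` with integer `n` and
#' `0 <= fbar < 0.5 f_A`, the sampled sideband phasor rotates at the
#' apparent frequency `fbar` when `n` is even and `fbar - 0.5 f_A`
#' (negative) when `n` is odd. The sideband depth offset is
#' `z_m = omega_m / (2 k1)`, i.e. `f_m / df_pixel` depth pixels.
#'
#' @param f_m Modulation frequency (Hz).
#' @param sweep A [sweep_config()].
#' @return Object of class `sideband_plan`: list with `f_m`, `n`, `fbar`,
#'   `apparent_f` (signed, Hz), `z_m` (m), `z_m_pixels`, `lobe`.
#' @examples
#' plan_sidebands(688.8e3, sweep_config())$apparent_f  # -2400 Hz
#' @export
plan_sidebands <- function(f_m, sweep) {
  stopifnot(f_m > 0)
  half <- 0.5 * sweep$f_A
  n <- floor(f_m / half)
  fbar <- f_m - n * half
  # guard against exact boundary falling on the wrong side numerically
  if (fbar >= half) { n <- n + 1; fbar <- f_m - n * half }
  apparent_f <- if (n %% 2 == 0) fbar else fbar - half
  z_m <- 2 * pi * f_m / (2 * sweep$k1)
  z_m_pixels <- z_m / sweep$dz_pixel
  if (z_m >= sweep$z_nyquist) {
    stop("sideband offset z_m exceeds the depth range; f_m too high")
  }
  structure(list(f_m = f_m, n = n, fbar = fbar, apparent_f = apparent_f,
                 z_m = z_m, z_m_pixels = z_m_pixels, lobe = "left"),
            class = "sideband_plan")
}

#' @export
print.sideband_plan <- function(x, ...) {
  cat(sprintf(paste0("<sideband_plan> f_m = %.4g kHz = %.4g kHz + %d * ",
                     "(f_A/2); apparent %.4g kHz; z_m = %.3f px\n"),
              x$f_m / 1e3, x$fbar / 1e3, x$n, x$apparent_f / 1e3,
              x$z_m_pixels))
  invisible(x)
}
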