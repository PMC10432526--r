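#' Surface displacement profile at one frequency
#'
#' Container for a complex surface displacement sampled on a uniform
#' lateral grid at a single vibration frequency.
#'
#' @param x Lateral positions (m), uniformly spaced, at least 8.
#' @param u Complex displacement at each position (m).
#' @param f Vibration frequency (Hz).
#' @return Object of class `surface_profile`.
#' @export
surface_profile <- function(x, u, f) {
  stopifnot(length(x) == length(u), length(x) >= 8, f > 0)
  dx <- diff(x)
  if (max(abs(dx - dx[1])) > 1e-9 * abs(dx[1])) {
    stop("surface profile requires a uniform lateral grid")
  }
  structure(list(x = as.numeric(x), u = as.complex(u), f = f,
                 dx = dx[1]),
            class = "surface_profile")
}

#' Spatial (x -> k) spectrum of a surface profile
#'
#' Fourier-transforms the complex displacement from lateral position to
#' wavenumber. A wave `u ~ exp(-i k x)` with `k > 0` (outward-propagating
#' under the `exp(i omega t)` convention) appears at positive `k` on the
#' returned axis. Zero padding refines the wavenumber grid for sub-bin peak
#' interpolation.
#'
#' @param profile A [surface_profile()].
#' @param pad_factor Zero-padding factor (>= 1).
#' @return List with `k` (rad/m, ascending, negative to positive) and
#'   `spectrum` (complex, same length), plus `dk`.
#' @export
spatial_spectrum <- function(profile, pad_factor = 8) {
  stopifnot(pad_factor >= 1)
  n <- length(profile$u)
  npad <- ceiling(n * pad_factor)
  u <- c(profile$u, rep(0 + 0i, npad - n))
  # inverse-transform convention sum u_j exp(+2*pi*i*j*q/npad) puts an
  # exp(-i k x) wave (k > 0, outward under exp(i omega t)) at bin
  # q = +k*dx*npad/(2*pi), i.e. at positive k on the returned axis.
  spec <- stats::fft(u, inverse = TRUE) / n
  k <- 2 * pi * (seq_len(npad) - 1) / (npad * profile$dx)
  # wrap to [-k_nyq, k_nyq)
  k_wrapped <- ifelse(k >= pi / profile$dx, k - 2 * pi / profile$dx, k)
  ord <- order(k_wrapped)
  list(k = k_wrapped[ord], spectrum = spec[ord],
       dk = 2 * pi / (npad * profile$dx))
}

#' Pick the dominant propagating mode from a spatial spectrum
#'
#' Finds the largest spectral peak within a wavenumber window (excluding
#' DC), refines its location with 3-point quadratic interpolation on the
#' log-magnitude, and converts it to phase velocity `v = 2*pi*f / k`.
#'
#' @param spec Output of [spatial_spectrum()].
#' @param f Vibration frequency (Hz).
#' @param k_range Wavenumber search window (rad/m), `c(kmin, kmax)` with
#'   `kmin > 0`.
#' @param snr_threshold Minimum ratio of the peak magnitude to the median
#'   in-window magnitude; below it no mode is declared.
#' @return List with `k_r` (rad/m), `v` (m/s), `peak_mag`, `threshold_ratio`.
#' @export
pick_mode <- function(spec, f, k_range = NULL, snr_threshold = 2.5) {
  k <- spec$k
  mag <- Mod(spec$spectrum)
  if (is.null(k_range)) k_range <- c(3 * spec$dk, max(k))
  stopifnot(k_range[1] > 0, k_range[2] > k_range[1])
  inw <- which(k >= k_range[1] & k <= k_range[2])
  if (length(inw) < 3) stop("wavenumber window too narrow for peak picking")
  i <- inw[which.max(mag[inw])]
  ratio <- mag[i] / stats::median(mag[inw])
  if (!is.finite(ratio) || ratio < snr_threshold) {
    stop(sprintf(paste0("no spectral peak above threshold in window ",
                        "[%.3g, %.3g] rad/m (peak/median = %.2f)"),
                 k_range[1], k_range[2], ratio))
  }
  if (i > 1 && i < length(k)) {
    y <- log(mag[(i - 1):(i + 1)] + .Machine$double.xmin)
    denom <- y[1] - 2 * y[2] + y[3]
    # tie-break toward lower k when the parabola degenerates
    shift <- if (abs(denom) < 1e-300) 0 else 0.5 * (y[1] - y[3]) / denom
    shift <- max(min(shift, 0.5), -0.5)
  } else {
    shift <- 0
  }
  k_r <- k[i] + shift * spec$dk
  list(k_r = k_r, v = 2 * pi * f / k_r, peak_mag = mag[i],
       threshold_ratio = ratio)
}

#' Band-pass filter a profile around a picked mode in the k domain
#'
#' Retains a configurable wavenumber band around a mode before velocity
#' extraction, removing higher-order modes and the counter-propagating
#' component.
#'
#' @param profile A [surface_profile()].
#' @param k_center Center of the retained band (rad/m).
#' @param rel_width Full width of the band relative to `k_center`.
#' @return A filtered [surface_profile()].
#' @export
filter_mode <- function(profile, k_center, rel_width = 0.6) {
  n <- length(profile$u)
  spec <- stats::fft(profile$u, inverse = TRUE) / n  # same axis as spatial_spectrum
  k <- 2 * pi * (seq_len(n) - 1) / (n * profile$dx)
  k <- ifelse(k >= pi / profile$dx, k - 2 * pi / profile$dx, k)
  keep <- abs(k - k_center) <= rel_width * abs(k_center) / 2
  spec[!keep] <- 0
  u <- stats::fft(spec)
  surface_profile(profile$x, u, profile$f)
}
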