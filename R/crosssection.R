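#' Cross-sectional complex displacement image
#'
#' Applies sideband demodulation at every lateral position of an M-B scan
#' cube and assembles the depth-resolved complex displacement field
#' `u(x, z)` at the modulation frequency. The real part is what a
#' wave-snapshot rendering displays.
#'
#' @param cube An [simulate_mscan()] cube with `B` lateral positions.
#' @param f_m Modulation frequency (Hz); defaults to the cube's stimulus
#'   frequency.
#' @param lobe,correct_jitter,window_m Passed to [demodulate()].
#' @return List with `u` (complex matrix `B x Z`, meters), `mask`
#'   (`B x Z` logical), `x` (m), `z` (m), `f_m`.
#' @export
cross_section_map <- function(cube, f_m = cube$meta$f_m,
                              lobe = "left", correct_jitter = FALSE,
                              window_m = "rect") {
  stopifnot(!is.na(f_m))
  sw <- cube$meta$sweep
  plan <- plan_sidebands(f_m, sw)
  B <- cube$meta$B
  Z <- sw$n_samples %/% 2
  u <- matrix(0 + 0i, B, Z)
  mask <- matrix(FALSE, B, Z)
  for (b in seq_len(B)) {
    tom <- aline_transform(cube, position = b)
    vm <- demodulate(tom, plan, lobe = lobe,
                     correct_jitter = correct_jitter, window_m = window_m)
    u[b, ] <- vm$k0delta / sw$k0
    mask[b, ] <- vm$mask
  }
  list(u = u, mask = mask, x = cube$meta$x,
       z = (seq_len(Z) - 1) * sw$dz_pixel, f_m = f_m)
}

#' Extract the surface displacement profile from a cross-section map
#'
#' Picks one depth pixel (by default the depth with the most unmasked
#' positions, i.e. the sample surface in a surface-scatterer scene) and
#' returns its complex displacement versus lateral position.
#'
#' @param xs A [cross_section_map()] result.
#' @param z_pixel Depth pixel (0-based); default: the row-wise most valid.
#' @return A [surface_profile()].
#' @export
surface_from_map <- function(xs, z_pixel = NULL) {
  if (is.null(z_pixel)) {
    counts <- colSums(xs$mask)
    z_pixel <- which.max(counts) - 1
  }
  surface_profile(xs$x, xs$u[, z_pixel + 1], xs$f_m)
}
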