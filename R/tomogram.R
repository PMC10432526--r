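#' Depth-domain complex tomogram of an M-scan
#'
#' Fourier-transforms each A-line from fringe time to depth, keeping the
#' one-sided spectrum (`Z = S/2` depth pixels with spacing
#' `sweep$dz_pixel`). The windowed raw samples are retained so that
#' downstream demodulation can evaluate the same transform at arbitrary
#' (sub-pixel) depth offsets via the Fourier shift theorem.
#'
#' @param cube An [simulate_mscan()] cube (single lateral position is
#'   extracted with `position`).
#' @param window Sample-domain window: "rect" (default) or "hann".
#' @param position Lateral position index (1-based).
#' @return Object of class `complex_tomogram`: list with `F` (complex
#'   matrix `N x Z`), `raw` (windowed samples, `N x S`), `dc` (complex
#'   length-Z carrier DC, the mean of `F` over A-lines), `sweep`, `meta`.
#' @export
aline_transform <- function(cube, window = c("rect", "hann"), position = 1) {
  window <- match.arg(window)
  sw <- cube$meta$sweep
  S <- sw$n_samples
  N <- cube$meta$N
  raw <- matrix(cube$data[position, , ], nrow = N)
  w <- switch(window,
              rect = rep(1, S),
              hann = 0.5 - 0.5 * cos(2 * pi * (seq_len(S) - 1) / (S - 1)))
  raw <- raw * matrix(w, N, S, byrow = TRUE)
  # FFT along samples; one-sided, normalized so a unit fringe gives ~1/2
  Ffull <- t(apply(raw, 1, stats::fft)) / S
  Z <- S %/% 2
  Fone <- Ffull[, seq_len(Z), drop = FALSE]
  structure(list(F = Fone,
                 raw = raw,
                 dc = colMeans(Fone),
                 window = window,
                 sweep = sw,
                 meta = c(cube$meta, list(position = position)),
                 stimulus_phase = cube$stimulus_phase[position, ],
                 t_m = cube$t_m[position, ]),
            class = "complex_tomogram")
}

#' @export
print.complex_tomogram <- function(x, ...) {
  cat(sprintf("<complex_tomogram> N=%d A-lines x Z=%d depth pixels (%s window)\n",
              nrow(x$F), ncol(x$F), x$window))
  invisible(x)
}

# Depth transform evaluated on the pixel grid shifted by a constant depth
# offset `z_off` (m): F(p*dz + z_off) for p = 0..Z-1, per A-line.
# Uses the modulation property: F(z + c) = FFT{ I(t) exp(-i 2 k1 c t) }.
shifted_transform <- function(tom, z_off) {
  sweep <- tom$sweep
  S <- sweep$n_samples
  Z <- S %/% 2
  if (abs(z_off) < .Machine$double.eps) return(tom$F)
  t_hat <- sweep_sample_times(sweep)
  mod <- exp(-2i * sweep$k1 * z_off * t_hat)
  shifted <- tom$raw * matrix(mod, nrow(tom$raw), S, byrow = TRUE)
  Fs <- t(apply(shifted, 1, stats::fft)) / S
  Fs[, seq_len(Z), drop = FALSE]
}
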