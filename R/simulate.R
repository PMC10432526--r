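#' Simulate one A-line interferogram
#'
#' Detector samples of the m-th wavelength sweep over a set of vibrating
#' point scatterers. The full interferometric phase is used (no small-
#' amplitude truncation): for each scatterer at depth `z0` with reflectance
#' `r`,
#' `I = r P(t) cos(2 k0 z0 + 2 k1 t z0 + (2 k0 + 2 k1 t) dz(t))`,
#' where `t` is time relative to the sweep center, `P` the Gaussian sweep
#' envelope and `dz(t)` the harmonic axial displacement of the scatterer
#' evaluated at absolute time `t + t_m`.
#'
#' @param scene_at_x A data.frame with columns `z0`, `r` (one lateral
#'   position of a [scatterer_scene()]), or a `scatterer_scene` whose first
#'   position is used.
#' @param sweep A [sweep_config()].
#' @param vib A [vibration_field()] or `NULL` for a static scene.
#' @param m A-line index (1-based), entering the vibration phase through the
#'   A-line start time.
#' @param t_m Absolute start time of the A-line (s); defaults to the nominal
#'   `m * T`.
#' @param x Lateral position (m) at which the vibration field is evaluated.
#' @return Numeric vector of `sweep$n_samples` detector samples.
#' @export
simulate_aline <- function(scene_at_x, sweep, vib = NULL, m = 1,
                           t_m = m * sweep$T, x = 0) {
  if (inherits(scene_at_x, "scatterer_scene")) {
    scene_at_x <- scene_at_x$positions[[1]]
  }
  drop(simulate_aline_block(scene_at_x, sweep, vib, t_m = t_m, x = x))
}

# Vectorized core: samples x A-lines matrix for one lateral position.
simulate_aline_block <- function(pos, sweep, vib, t_m, x = 0) {
  S <- sweep$n_samples
  N <- length(t_m)
  if (nrow(pos) == 0) return(matrix(0, S, N))
  if (any(pos$z0 >= sweep$z_nyquist)) {
    stop(sprintf("scatterer depth %.4g m beyond the unambiguous range %.4g m",
                 max(pos$z0), sweep$z_nyquist))
  }
  t_hat <- sweep_sample_times(sweep)
  P <- sweep_envelope(sweep, t_hat)
  out <- matrix(0, S, N)
  for (j in seq_len(nrow(pos))) {
    z0 <- pos$z0[j]
    static_phase <- 2 * sweep$k0 * z0 + 2 * sweep$k1 * t_hat * z0  # length S
    if (is.null(vib)) {
      out <- out + pos$r[j] * P * cos(static_phase)
      next
    }
    d <- vib$delta(x, z0)
    amp <- Mod(d)
    psi <- Arg(d)
    if (amp == 0) {
      out <- out + pos$r[j] * P * cos(static_phase)
      next
    }
    # g(t) at absolute times t_hat + t_m for every A-line: S x N
    tt <- outer(t_hat, t_m, "+")
    g <- sin(vib$omega_m * tt + vib$phi + psi)
    phase <- static_phase + (2 * sweep$k0 + 2 * sweep$k1 * t_hat) * amp * g
    out <- out + pos$r[j] * P * cos(phase)
  }
  out
}

#' Simulate an M-B scan cube
#'
#' Acquires `N` consecutive A-lines at each of the `B` lateral positions of
#' the scene, with a shared sweep-period jitter realization, additive white
#' Gaussian detector noise, and a simultaneously recorded stimulus phase
#' (carrying the identical jitter) for later correction.
#'
#' The detector noise is scaled so that the power SNR of the brightest
#' scatterer peak in a noise-free A-line, relative to the mean noise-floor
#' power per depth pixel, equals `10^(snr_db/10)`. `snr_db = Inf` disables
#' the noise. Jitter and detector noise are drawn from independent child
#' streams of `seed`, so disabling one does not shift the other.
#'
#' @param scene A [scatterer_scene()]; its lateral positions define `B`.
#' @param sweep A [sweep_config()].
#' @param vib A [vibration_field()] or `NULL`.
#' @param N Number of A-lines per M-scan.
#' @param snr_db A-line power SNR in dB (`Inf` = noise free).
#' @param seed Integer master seed.
#' @param jitter Optional [draw_jitter()] realization of length `N * B`
#'   overriding the internally drawn one (A-lines are consecutive across
#'   positions, position-major).
#' @return Object of class `mscan_cube`: list with
#'   `data` (array `B x N x S`), `stimulus_phase` (matrix `B x N`, the
#'   recorded stimulus phase `omega_m t_m + phi` of each A-line),
#'   `t_m` (matrix `B x N` of A-line times), and `meta` (sweep, protocol,
#'   vibration frequency, seed, total duration).
#' @examples
#' sc <- scatterer_scene(z0 = 2.3e-3, r = 1)
#' vib <- vibration_field(20e-9, f_m = 10.8e3)
#' cube <- simulate_mscan(sc, sweep_config(), vib, N = 8, snr_db = Inf)
#' dim(cube$data)
#' @export
simulate_mscan <- function(scene, sweep, vib = NULL, N = 108,
                           snr_db = Inf, seed = NULL, jitter = NULL) {
  stopifnot(inherits(scene, "scatterer_scene"), N >= 1)
  B <- length(scene$positions)
  S <- sweep$n_samples
  seeds <- child_seeds(seed, 2L)
  if (is.null(jitter)) {
    jitter <- draw_jitter(N * B, sweep$sigma_T, sweep$T,
                          seed = if (is.null(seed)) NULL else seeds[1])
  }
  stopifnot(length(jitter$t_m) >= N * B)
  t_m_all <- matrix(jitter$t_m[seq_len(N * B)], nrow = B, byrow = TRUE)

  data <- array(0, dim = c(B, N, S))
  for (b in seq_len(B)) {
    blk <- simulate_aline_block(scene$positions[[b]], sweep, vib,
                                t_m = t_m_all[b, ], x = scene$x[b])
    data[b, , ] <- t(blk)
  }

  if (is.finite(snr_db)) {
    # reference peak power from the brightest noise-free A-line
    pk <- 0
    for (b in seq_len(B)) {
      spec <- Mod(stats::fft(data[b, 1, ]) / S)^2
      pk <- max(pk, max(spec[2:(S / 2)]))
    }
    X <- 10^(snr_db / 10)
    sigma_n <- sqrt(S * pk / X)
    if (!is.null(seed)) {
      old <- if (exists(".Random.seed", globalenv())) get(".Random.seed",
                                                          globalenv()) else NULL
      set.seed(seeds[2])
      data <- data + array(stats::rnorm(length(data), 0, sigma_n), dim(data))
      if (!is.null(old)) assign(".Random.seed", old, globalenv())
    } else {
      data <- data + array(stats::rnorm(length(data), 0, sigma_n), dim(data))
    }
  }

  stimulus_phase <- if (!is.null(vib)) {
    vib$omega_m * t_m_all + vib$phi
  } else {
    matrix(0, B, N)
  }
  structure(list(
    data = data,
    stimulus_phase = stimulus_phase,
    t_m = t_m_all,
    meta = list(sweep = sweep, N = N, B = B, x = scene$x,
                f_m = if (!is.null(vib)) vib$f_m else NA_real_,
                phi = if (!is.null(vib)) vib$phi else NA_real_,
                snr_db = snr_db, seed = seed,
                duration = N * B / sweep$f_A)
  ), class = "mscan_cube")
}

#' @export
print.mscan_cube <- function(x, ...) {
  cat(sprintf("<mscan_cube> B=%d x N=%d x S=%d", x$meta$B, x$meta$N,
              x$meta$sweep$n_samples))
  if (!is.na(x$meta$f_m)) cat(sprintf(", f_m = %.4g kHz", x$meta$f_m / 1e3))
  cat(sprintf(", duration %.4g s\n", x$meta$duration))
  invisible(x)
}

# Deterministic child seeds below 2^31, derived from a master seed.
child_seeds <- function(seed, n) {
  if (is.null(seed)) return(rep(NA_integer_, n))
  s <- as.double(seed)
  out <- integer(n)
  for (i in seq_len(n)) {
    s <- (s * 48271 + 11) %% 2147483647
    out[i] <- as.integer(s)
  }
  out
}
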