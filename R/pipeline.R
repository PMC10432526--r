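#' Run the full simulate - demodulate - dispersion - modulus pipeline
#'
#' Executes the stages in acquisition order on a surface-scatterer scene
#' carrying a traveling surface wave:
#' 1. build the scene (one surface scatterer per lateral position) and the
#'    traveling-wave vibration field `delta(x) = delta0 exp(-i k x)`;
#' 2. simulate the M-B scan cube (jitter + detector noise);
#' 3. demodulate every lateral position at the stimulus frequency
#'    (anti-aliasing sideband demodulation, jitter-corrected);
#' 4. extract the surface displacement profile, transform x -> k, pick the
#'    propagating mode, convert to phase velocity;
#' 5. convert the velocity to shear modulus via the Rayleigh-speed ratio.
#'
#' The wave speed is taken from `config$vibration$wave_speed` (Rayleigh
#' speed, m/s) or derived from `material$mu` and `material$rho`.
#'
#' @param config A [load_config()] object (or path to a JSON config).
#' @param seed Overrides `config$seed` when given.
#' @return A result bundle: list with `dispersion` (one-row data.frame),
#'   `modulus` (Pa), `profile`, `map`, `config`, `provenance`.
#' @export
run_pipeline <- function(config, seed = NULL) {
  if (is.character(config) || !inherits(config, "run_config")) {
    config <- load_config(config)
  }
  if (is.null(seed)) seed <- config$seed
  sw <- config$sweep
  mat <- config$material
  f_m <- config$vibration$f_m

  cube <- simulate_from_config(config, seed = seed)
  xs <- cross_section_map(cube, f_m, correct_jitter = sw$sigma_T > 0)
  prof <- surface_from_map(xs, z_pixel = config$scene$z0_pixel)
  spec <- spatial_spectrum(prof, pad_factor = 16)
  pk <- pick_mode(spec, f_m)
  mu <- modulus_from_rayleigh(pk$v, nu = mat$nu, rho = mat$rho)

  dispersion <- data.frame(f = f_m, v = pk$v, k_r = pk$k_r,
                           k_i = config$vibration$k_i %||% NA_real_,
                           residual = NA_real_)
  list(dispersion = dispersion,
       modulus = mu,
       profile = prof,
       map = xs,
       config = config,
       provenance = list(seed = seed,
                         package_version =
                           as.character(utils::packageVersion("uwoce")),
                         duration_s = cube$meta$duration))
}

#' Simulate the M-B scan cube described by a run configuration
#'
#' Builds the surface-scatterer scene (one scatterer per lateral position)
#' and the traveling-wave vibration field
#' `delta(x) = delta0 * exp(-i k x)` from a [load_config()] object, then
#' runs [simulate_mscan()]. The wavenumber `k` comes from
#' `vibration$wave_speed` (Rayleigh speed) or from `material$mu` via the
#' secular-root speed ratio, with attenuation `vibration$k_i`.
#'
#' @param config A `run_config`.
#' @param seed Master seed; defaults to `config$seed`.
#' @return An [simulate_mscan()] cube.
#' @export
simulate_from_config <- function(config, seed = config$seed) {
  sw <- config$sweep
  prot <- config$protocol
  mat <- config$material
  vibc <- config$vibration

  f_m <- vibc$f_m
  c_R <- vibc$wave_speed
  if (is.null(c_R)) {
    if (is.null(mat$mu)) stop("config needs vibration$wave_speed or material$mu")
    c_R <- sqrt(mat$mu / mat$rho) / shear_over_rayleigh()
  }
  k_wave <- complex(real = 2 * pi * f_m / c_R,
                    imaginary = -(vibc$k_i %||% 0))

  dx <- prot$dx %||% (2 * pi / Re(k_wave) / 8)  # 8 samples per wavelength
  z0 <- config$scene$z0_pixel * sw$dz_pixel
  B <- prot$B
  scene <- scatterer_scene(z0 = rep(list(z0), B),
                           r = rep(list(config$scene$r), B), dx = dx)
  delta0 <- vibc$delta
  vib <- vibration_field(function(x, z) delta0 * exp(-1i * k_wave * x),
                         f_m = f_m, phi = vibc$phi %||% 0)
  simulate_mscan(scene, sw, vib, N = prot$N,
                 snr_db = prot$snr_db %||% Inf, seed = seed)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
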