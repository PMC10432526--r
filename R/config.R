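#' Load and validate a run configuration
#'
#' Reads a JSON configuration describing the sweep, scene, vibration and
#' acquisition protocol, applies instrument defaults, and rejects unknown
#' fields. All physical quantities in the file are SI (Hz, m, s) unless the
#' key name says otherwise (`snr_db`).
#'
#' Recognized sections and fields:
#' * `sweep`: `lambda0`, `f_A`, `n_samples`, `f_s`, `sigma_env`, `sigma_T`
#' * `scene`: `z0_pixel` (surface scatterer depth pixel), `r`
#' * `vibration`: `f_m`, `delta`, `phi`, and either `wave_speed` (Rayleigh
#'   speed, m/s) with optional `k_i` (rad/m), or nothing (uniform field)
#' * `material`: `rho`, `nu`, optional `mu` (used to derive the wave speed
#'   when `vibration.wave_speed` is absent)
#' * `protocol`: `N`, `B`, `dx`, `snr_db`
#' * `seed`
#'
#' @param path Path to a JSON file, or a list already parsed.
#' @return Object of class `run_config` (validated nested list).
#' @export
load_config <- function(path) {
  cfg <- if (is.character(path)) {
    jsonlite::fromJSON(path, simplifyVector = TRUE)
  } else {
    path
  }
  allowed <- list(
    sweep = c("lambda0", "f_A", "n_samples", "f_s", "sigma_env", "sigma_T"),
    scene = c("z0_pixel", "r"),
    vibration = c("f_m", "delta", "phi", "wave_speed", "k_i"),
    material = c("rho", "nu", "mu"),
    protocol = c("N", "B", "dx", "snr_db"),
    seed = NULL
  )
  bad_top <- setdiff(names(cfg), names(allowed))
  if (length(bad_top)) {
    stop("unknown configuration section(s): ", paste(bad_top, collapse = ", "))
  }
  for (sec in setdiff(names(cfg), "seed")) {
    bad <- setdiff(names(cfg[[sec]]), allowed[[sec]])
    if (length(bad)) {
      stop(sprintf("unknown field(s) in '%s': %s", sec,
                   paste(bad, collapse = ", ")))
    }
  }
  defaults <- list(
    sweep = list(),
    scene = list(z0_pixel = 107, r = 1),
    vibration = list(f_m = 40e3, delta = 20e-9, phi = 0),
    material = list(rho = 1000, nu = 0.5),
    protocol = list(N = 108, B = 96, dx = NULL, snr_db = Inf),
    seed = 1L
  )
  out <- defaults
  for (sec in names(cfg)) {
    if (sec == "seed") { out$seed <- cfg$seed; next }
    for (fld in names(cfg[[sec]])) out[[sec]][[fld]] <- cfg[[sec]][[fld]]
  }
  out$sweep <- do.call(sweep_config, out$sweep)
  structure(out, class = "run_config")
}

#' Save a run configuration to JSON
#'
#' Writes the user-settable fields of a [load_config()] object back to a
#' JSON file; `load_config(save_config(cfg, path))` round-trips.
#'
#' @param cfg A `run_config`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
save_config <- function(cfg, path) {
  sw <- cfg$sweep
  out <- list(
    sweep = list(lambda0 = sw$lambda0, f_A = sw$f_A,
                 n_samples = sw$n_samples, f_s = sw$f_s,
                 sigma_env = sw$sigma_env, sigma_T = sw$sigma_T),
    scene = cfg$scene,
    vibration = cfg$vibration,
    material = cfg$material,
    protocol = cfg$protocol,
    seed = cfg$seed
  )
  out$protocol <- out$protocol[!vapply(out$protocol, is.null, logical(1))]
  jsonlite::write_json(out, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(path)
}

#' Save / load an M-scan cube
#'
#' Serializes a cube (raw samples, stimulus record, metadata) to a single
#' file via RDS.
#'
#' @param cube An [simulate_mscan()] cube.
#' @param path File path.
#' @return `save_mscan`: `path` invisibly; `load_mscan`: the cube.
#' @export
save_mscan <- function(cube, path) {
  stopifnot(inherits(cube, "mscan_cube"))
  saveRDS(cube, path)
  invisible(path)
}

#' @rdname save_mscan
#' @export
load_mscan <- function(path) {
  cube <- readRDS(path)
  stopifnot(inherits(cube, "mscan_cube"))
  cube
}

#' Write a dispersion table to CSV
#'
#' Columns: `frequency_hz`, `v_m_per_s`, `k_r_rad_per_m`, `k_i_rad_per_m`,
#' `residual`. Missing quantities are written as NA.
#'
#' @param disp data.frame with at least `f` and `v` (or `k_r`).
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_dispersion_csv <- function(disp, path) {
  get0 <- function(nm) if (nm %in% names(disp)) disp[[nm]] else NA
  out <- data.frame(frequency_hz = disp$f,
                    v_m_per_s = get0("v"),
                    k_r_rad_per_m = get0("k_r"),
                    k_i_rad_per_m = get0("k_i"),
                    residual = get0("residual"))
  utils::write.csv(out, path, row.names = FALSE)
  invisible(path)
}
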