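# Shared fixtures: a jitter-free instrument and cached mirror cubes.

sw_clean <- sweep_config(sigma_T = 0)

# single mirror-like scatterer at an exact pixel depth
mirror_scene <- function(pixel = 107, r = 1, sw = sw_clean) {
  scatterer_scene(z0 = pixel * sw$dz_pixel, r = r)
}

# memoised mirror M-scan: repeated calls with identical arguments reuse
# the simulated cube (simulation dominates test time)
.cube_cache <- new.env(parent = emptyenv())
mirror_cube <- function(f_m, delta, N = 108, phi = 0, snr_db = Inf,
                        seed = NULL, sw = sw_clean, pixel = 107) {
  key <- paste(f_m, delta, N, phi, snr_db, seed %||% "x", sw$sigma_T, pixel,
               sep = "|")
  if (!is.null(.cube_cache[[key]])) return(.cube_cache[[key]])
  vib <- vibration_field(delta, f_m = f_m, phi = phi)
  cube <- simulate_mscan(mirror_scene(pixel, sw = sw), sw, vib, N = N,
                         snr_db = snr_db, seed = seed)
  .cube_cache[[key]] <- cube
  cube
}

`%||%` <- function(a, b) if (is.null(a)) b else a

shifted_transform_for_test <- function(tom, z_off) {
  uwoce:::shifted_transform(tom, z_off)
}

expect_rel_equal <- function(object, expected, tol) {
  expect_lt(max(abs(object / expected - 1)), tol)
}
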