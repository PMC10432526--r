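# uwoce — ultra-wideband optical coherence elastography

Optical coherence elastography (OCE) images shear and surface waves inside
tissue with phase-sensitive swept-source OCT and converts their dispersion
into mechanical properties. Because swept-source OCT acquires one depth
profile per wavelength sweep, the A-line rate `f_A` (tens of kHz) appears
to limit resolvable vibration frequencies to `f_A/2` — far below the
ultrasonic frequencies needed to probe stiff tissues and thin layers.

`uwoce` implements, in R, the computational stack that removes that limit,
for researchers in tissue biomechanics and OCT instrumentation:

* **Forward simulator** (`simulate_mscan()`): swept-source interferograms
  of vibrating point scatterers with the full interferometric phase,
  Gaussian sweep envelope, sweep-period timing jitter (`sigma_T`), a
  simultaneously recorded stimulus phase, and calibrated detector noise.
* **Anti-aliasing sideband demodulation** (`demodulate()`): recovers the
  depth-resolved complex vibration amplitude `k0*delta(z)` at *any*
  modulation frequency. A vibrating scatterer at depth `z0` carries
  sidebands at `z0 ± z_m`, `z_m = omega_m/(2 k1)`; after background
  subtraction and carrier normalization, an N-point DFT over A-lines reads
  the sideband phasor at its aliased apparent frequency
  (`f_m = fbar + 0.5 n f_A`; apparent `fbar` for even `n`,
  `fbar − 0.5 f_A` for odd `n`). Includes stimulus-phase jitter
  correction and the classical phase-oscillation method
  (`conventional_phase_demod()`) as an independent cross-check.
* **Noise budget** (`noise_budget()`): minimum detectable amplitude
  `k0 delta_min = X^(-1/2) N^(-1/2)`, jitter phase error
  `sigma_L = omega_m sigma_T sqrt((N+1)(2N+1)/(6N))`, total phase noise,
  and wave-velocity uncertainty `dv/v = (dphi/2pi)(lambda/L)`.
* **Wavefield analysis**: spatial spectra (`spatial_spectrum()`),
  Rayleigh-mode picking with sub-bin interpolation (`pick_mode()`), and
  least-squares fitting of the analytic near-field surface-wave model
  built on the secular equation
  `F(kappa) = (2kappa^2 − K^2)^2 − 4kappa^2 sqrt(kappa^2(kappa^2 − K^2))`
  with roots `K_R = 1.047 K` and `K_SS = (0.4696 − 0.1355i) K`
  (`secular_roots()`, `fit_surface_wave()`).
* **Elastodynamic inversion**: complex shear modulus
  `mu' + i mu'' = rho omega^2 / (k_r − i k_i)^2` (`complex_modulus()`),
  Rayleigh-ratio moduli for half-spaces (`modulus_from_rayleigh()`),
  fundamental Lamb modes (`lamb_dispersion()`), power-law rheology fits,
  and depth-resolved stiffness profiling
  `mu(z) = rho v^2 (v − f v')/(v + f v')` at `z = a_L v/f`
  (`invert_depth_profile()`, `forward_dispersion_from_profile()`).

## Worked example

Demodulate a 679.6 kHz vibration — nearly 16x the A-line rate — from a
simulated mirror M-scan at 40 dB SNR:

```r
library(uwoce)

sw <- sweep_config()        # 1307 nm, 43.2 kHz A-line rate, 2048 pts @ 108 MS/s
plan_sidebands(688.8e3, sw)
#> <sideband_plan> f_m = 688.8 kHz = 19.2 kHz + 31 * (f_A/2); apparent -2.4 kHz; z_m = 13.062 px

swq   <- sweep_config(sigma_T = 0)
scene <- scatterer_scene(z0 = 107 * swq$dz_pixel, r = 1)
vib   <- vibration_field(20.8e-9, f_m = 679.6e3)     # k0*delta = 0.1
cube  <- simulate_mscan(scene, swq, vib, N = 108, snr_db = 40, seed = 1)
vm    <- demodulate(aline_transform(cube), plan_sidebands(679.6e3, swq))
sprintf("recovered delta = %.2f nm at pixel 107", vm$delta[108] * 1e9)
#> "recovered delta = 20.96 nm at pixel 107"

secular_roots()[c("rayleigh", "supershear")]
#> $rayleigh   1.046778
#> $supershear 0.4695509-0.1354623i

modulus_from_rayleigh(1285, nu = 0.37, rho = 1200) / 1e9   # GPa
#> 2.256492

nb <- noise_budget(snr_db = 40, N = 108, f_m = 679.6e3)
sprintf("delta_min = %.0f pm, sigma_L = %.3f rad", nb$delta_min * 1e12, nb$sigma_L)
#> "delta_min = 200 pm, sigma_L = 0.126 rad"
```

Reading the numbers: the 688.8 kHz modulation folds to an apparent
2.4 kHz within the `±f_A/2` band, with sidebands 13.06 depth pixels from
the carrier; the demodulated amplitude (20.96 nm) recovers the simulated
20.8 nm to within the known `J1/J0` sideband bias plus noise; the secular
roots are the Rayleigh and leaky supershear wavenumber ratios used by the
surface-wave fit; 1285 m/s Rayleigh speed on an acrylate block
(`nu = 0.37`, `rho = 1.2 g/cm^3`) corresponds to a 2.26 GPa shear
modulus; and at 40 dB SNR with 108 A-lines the system resolves 200 pm
vibrations, with sweep-timing jitter contributing 0.126 rad of phase
noise at 679.6 kHz before stimulus-phase correction.

An end-to-end run — traveling surface wave on a soft half-space,
M-B scan, demodulation, k-domain mode picking, modulus — is one call:

```r
cfg <- load_config(list(material  = list(rho = 1000, mu = 9000, nu = 0.5),
                        vibration = list(f_m = 40e3, delta = 20e-9),
                        protocol  = list(N = 108, B = 96, snr_db = 40),
                        seed = 11))
res <- run_pipeline(cfg)
res$modulus      # 9012.6  (Pa; truth 9000, recovered within 0.2%)
```

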