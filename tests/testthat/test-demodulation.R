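test_that("sideband plans implement the folding parity rule", {
  sw <- sw_clean
  p <- plan_sidebands(688.8e3, sw)
  expect_equal(p$n, 31)
  expect_equal(p$fbar, 19.2e3, tolerance = 1e-9)
  expect_equal(abs(p$apparent_f), 2.4e3, tolerance = 1e-9)

  p2 <- plan_sidebands(10e3, sw)   # non-aliased
  expect_equal(p2$n, 0)
  expect_equal(p2$apparent_f, 10e3)

  p3 <- plan_sidebands(679.6e3, sw)
  expect_equal(p3$n, 31)
  expect_equal(p3$fbar, 10.0e3, tolerance = 1e-9)
  expect_equal(p3$apparent_f, -11.6e3, tolerance = 1e-9)
  expect_equal(p3$z_m_pixels, 679.6 / 52.734375, tolerance = 1e-9)
})

test_that("mirror vibration is recovered in amplitude and phase, both lobes", {
  sw <- sw_clean
  plan <- plan_sidebands(679.6e3, sw)
  cube <- mirror_cube(679.6e3, delta = 20.4e-9, phi = 0.7)
  tom <- aline_transform(cube)
  for (lobe in c("left", "right")) {
    vm <- demodulate(tom, plan, lobe = lobe)
    expect_rel_equal(vm$delta[108], 20.4e-9, 0.01)
    expect_lt(abs(vm$phase[108] - 0.7), 0.01)
    expect_true(vm$mask[108])
  }
})

test_that("a -20 dB sideband corresponds to 20.8 nm at 1307 nm", {
  # amplitude ratio 0.1 = k0 * delta  =>  delta = 0.1 / k0
  sw <- sw_clean
  delta <- 0.1 / sw$k0
  expect_equal(delta, 20.80e-9, tolerance = 1e-3)
  cube <- mirror_cube(679.6e3, delta = delta)
  vm <- demodulate(aline_transform(cube), plan_sidebands(679.6e3, sw))
  expect_rel_equal(vm$delta[108], delta, 0.01)
})

test_that("three-scatterer scene: only the vibrating scatterers demodulate", {
  sw <- sw_clean
  fx <- three_scatterer_scene(sw, f_m = 688.8e3, delta = 10e-9)
  cube <- simulate_mscan(fx$scene, sw, fx$vib, N = 108, snr_db = Inf)
  vm <- demodulate(aline_transform(cube), plan_sidebands(688.8e3, sw))
  px <- round(fx$z_scat / sw$dz_pixel) + 1
  expect_rel_equal(vm$delta[px[1]], 10e-9, 0.02)
  expect_rel_equal(vm$delta[px[3]], 10e-9, 0.02)
  expect_lt(vm$delta[px[2]], 0.02 * 10e-9 * 10)  # static: residual crosstalk
})

test_that("zero vibration leaves all pixels at the numerical noise floor", {
  cube <- simulate_mscan(mirror_scene(), sw_clean,
                         vibration_field(1e-18, 679.6e3), N = 108,
                         snr_db = Inf)
  vm <- demodulate(aline_transform(cube), plan_sidebands(679.6e3, sw_clean))
  expect_lt(max(vm$delta[vm$mask]), 1e-15)
})

test_that("demodulation is linear within 1% for k0*delta <= 0.05", {
  sw <- sw_clean
  plan <- plan_sidebands(679.6e3, sw)
  for (k0d in c(0.01, 0.05)) {
    cube <- mirror_cube(679.6e3, delta = k0d / sw$k0)
    vm <- demodulate(aline_transform(cube), plan)
    expect_rel_equal(vm$delta[108] * sw$k0, k0d, 0.01)
  }
})

test_that("recovery is invariant across aliased and non-aliased regimes", {
  sw <- sw_clean
  delta <- 10e-9
  # all with integer N * f_m / f_A at N = 108
  fms <- c(10.8e3, 40e3, 679.6e3, 688.8e3, 1363.2e3)
  deltas <- vapply(fms, function(fm) {
    cube <- mirror_cube(fm, delta = delta)
    demodulate(aline_transform(cube), plan_sidebands(fm, sw))$delta[108]
  }, numeric(1))
  expect_rel_equal(deltas, delta, 0.01)
  expect_lt(diff(range(deltas)) / delta, 0.005)
})

test_that("DC background of the sideband series cancels to machine precision", {
  sw <- sw_clean
  plan <- plan_sidebands(679.6e3, sw)
  cube <- mirror_cube(679.6e3, delta = 10e-9)
  tom <- aline_transform(cube)
  obs <- shifted_transform_for_test(tom, -plan$z_m)
  resid <- colMeans(obs - matrix(colMeans(obs), nrow(obs), ncol(obs),
                                 byrow = TRUE))
  expect_lt(max(Mod(resid)), 1e-12 * max(Mod(obs)))
})

test_that("non-integer cycle counts are refused unless windowed", {
  sw <- sw_clean
  cube <- mirror_cube(679.6e3, delta = 10e-9, N = 100)  # 100*679.6/43.2 not int
  tom <- aline_transform(cube)
  plan <- plan_sidebands(679.6e3, sw)
  expect_error(demodulate(tom, plan), "integer")
  vm <- demodulate(tom, plan, window_m = "hann")
  expect_rel_equal(vm$delta[108], 10e-9, 0.05)
})

test_that("anti-aliasing and conventional phase demodulation agree below Nyquist", {
  sw <- sw_clean
  for (fm in c(2e3, 10.8e3)) {
    cube <- mirror_cube(fm, delta = 20e-9, phi = 0.3)
    tom <- aline_transform(cube)
    vmA <- demodulate(tom, plan_sidebands(fm, sw))
    vmC <- conventional_phase_demod(tom, fm)
    expect_rel_equal(vmC$delta[108], 20e-9, 0.005)
    expect_rel_equal(vmA$delta[108] / vmC$delta[108], 1, 0.01)
    expect_lt(abs(vmA$phase[108] - vmC$phase[108]), 0.02)
  }
  expect_error(conventional_phase_demod(aline_transform(
    mirror_cube(679.6e3, 1e-9)), 679.6e3), "f_m < 0.5")
})

test_that("jitter correction is the identity without jitter and removes jitter noise", {
  sw <- sw_clean
  plan <- plan_sidebands(679.6e3, sw)
  cube <- mirror_cube(679.6e3, delta = 20e-9, phi = 0.3)
  tom <- aline_transform(cube)
  vm0 <- demodulate(tom, plan)
  vm1 <- demodulate(tom, plan, correct_jitter = TRUE)
  expect_lt(max(abs(vm1$delta - vm0$delta)), 1e-8 * vm0$delta[108])
  # phase convention: correction references phase to the stimulus
  expect_lt(abs(vm1$phase[108]), 1e-3)

  # with jitter and 40 dB SNR: corrected phase scatter collapses to the
  # SNR-limited floor and decouples from the accumulated jitter
  swj <- sweep_config()  # sigma_T = 4.9 ns
  scj <- scatterer_scene(z0 = 107 * swj$dz_pixel, r = 1)
  k0d <- 20e-9 * swj$k0
  vib <- vibration_field(20e-9, 679.6e3, phi = 0.3)
  ntr <- 40
  ph_un <- ph_co <- cumj <- numeric(ntr)
  for (i in seq_len(ntr)) {
    cu <- simulate_mscan(scj, swj, vib, N = 108, snr_db = 40, seed = i)
    to <- aline_transform(cu)
    ph_un[i] <- demodulate(to, plan)$phase[108]
    ph_co[i] <- demodulate(to, plan, correct_jitter = TRUE)$phase[108]
    cumj[i] <- mean(cu$t_m[1, ] - seq_len(108) * swj$T)
  }
  sigma_L <- jitter_phase_error(108, 679.6e3, 4.9e-9)
  snr_floor <- 1 / sqrt(2 * 108 * 1e4) / k0d  # phase noise at amplitude k0d
  expect_gt(sd(ph_un), 0.5 * sigma_L)   # uncorrected scatter at sigma_L scale
  expect_lt(sd(ph_co), 2 * snr_floor)   # corrected: SNR-limited
  expect_lt(abs(cor(ph_co, cumj)), 0.35)  # no residual jitter coupling (n=40)
  expect_gt(abs(cor(ph_un, cumj)), 0.8)   # uncorrected phase tracks jitter
})

test_that("missing stimulus record passes through with a warning", {
  sw <- sw_clean
  cube <- simulate_mscan(mirror_scene(), sw, NULL, N = 108, snr_db = Inf)
  tom <- aline_transform(cube)
  plan <- plan_sidebands(10.8e3, sw)
  expect_warning(demodulate(tom, plan, correct_jitter = TRUE),
                 "stimulus")
})

test_that("sensitivity: noise-floor SD follows X^-1/2 N^-1/2 / k0 scaling", {
  # quick version (acceptance runs the full 500-realization check)
  sw <- sw_clean
  plan <- plan_sidebands(679.6e3, sw)
  vals <- vapply(1:60, function(i) {
    cube <- simulate_mscan(mirror_scene(), sw,
                           vibration_field(1e-15, 679.6e3), N = 108,
                           snr_db = 40, seed = i)
    demodulate(aline_transform(cube), plan)$delta[108]
  }, numeric(1))
  pred <- min_detectable_amplitude(1e4, 108, sw$lambda0)
  expect_rel_equal(sqrt(mean(vals^2)), pred, 0.2)
})
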