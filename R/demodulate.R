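#' Demodulate depth-resolved vibration from an M-scan tomogram
#'
#' Recovers the complex vibration amplitude `k0 * delta(z)` at every depth
#' pixel from the sideband structure of the tomogram, at any modulation
#' frequency -- aliased or not. For each scatterer depth `z0` the algorithm
#' (left-lobe form):
#' 1. evaluates the depth transform at the sideband location `z0 - z_m`
#'    for every A-line (exactly, via the Fourier shift theorem);
#' 2. subtracts the static DC background (A-line average) at that depth;
#' 3. normalizes by the carrier DC background at `z0`;
#' 4. Fourier-transforms the resulting N-point series over A-lines and reads
#'    the bin at the (signed) apparent frequency of the plan. The
#'    counter-rotating bin carries the other scatterer
#'    (at `z0 - 2 z_m`) whose opposite sideband overlaps the same depth, so
#'    the two contributions separate cleanly in the temporal frequency
#'    domain.
#'
#' The A-line count must satisfy `N * f_m / f_A` integer (exact DC
#' cancellation and leakage-free bins); `window_m = "hann"` relaxes this
#' with the documented amplitude correction.
#'
#' @param tom A [aline_transform()] tomogram.
#' @param plan A [plan_sidebands()] plan.
#' @param lobe Which sidelobe to demodulate from: "left" (default) or
#'   "right".
#' @param correct_jitter Use the recorded stimulus phase to remove the
#'   accumulated sweep-timing jitter from the modulation phase.
#' @param window_m Temporal window over A-lines: "rect" (default; requires
#'   integer cycle count) or "hann".
#' @param dc_threshold_db Carrier-DC validity threshold above the median
#'   carrier magnitude (dB); pixels below it are masked.
#' @return Object of class `vibration_map`: list with `k0delta` (complex,
#'   per depth pixel: modulus is `k0*delta`, argument the vibration phase),
#'   `delta` (m), `phase` (rad), `mask` (logical), `z` (depth axis, m),
#'   `plan`, `lobe`, `jitter_corrected`.
#' @export
demodulate <- function(tom, plan, lobe = c("left", "right"),
                       correct_jitter = FALSE,
                       window_m = c("rect", "hann"),
                       dc_threshold_db = 6) {
  lobe <- match.arg(lobe)
  window_m <- match.arg(window_m)
  sw <- tom$sweep
  N <- nrow(tom$F)
  Z <- ncol(tom$F)
  k0 <- sw$k0

  cycles <- N * plan$f_m / sw$f_A
  if (window_m == "rect" && abs(cycles - round(cycles)) > 1e-6) {
    stop(sprintf(paste0("N * f_m / f_A = %.6g is not an integer; choose N ",
                        "accordingly or use window_m = 'hann'"), cycles))
  }
  qbin <- N * plan$apparent_f / sw$f_A      # signed fractional bin
  if (window_m == "rect" && abs(qbin - round(qbin)) > 0.25) {
    stop("apparent frequency falls more than 0.25 bin from a DFT bin")
  }
  qbin <- round(qbin)

  z_off <- if (lobe == "left") -plan$z_m else plan$z_m
  obs <- shifted_transform(tom, z_off)      # N x Z at z0 -/+ z_m
  dc_obs <- colMeans(obs)
  carrier <- tom$dc                          # DC at the scatterer depth z0
  y <- (obs - matrix(dc_obs, N, Z, byrow = TRUE)) /
    matrix(carrier, N, Z, byrow = TRUE)

  jitter_corrected <- FALSE
  if (correct_jitter) {
    sp <- tom$stimulus_phase
    if (is.null(sp) || all(sp == 0)) {
      warning("no stimulus record available; jitter correction skipped")
    } else {
      y <- jitter_correct(y, sp, plan$f_m, sw$T, lobe = lobe)
      jitter_corrected <- TRUE
    }
  }

  # With the one-sided transform (positive-frequency pixels capture
  # exp(+i Phi)), the left sideband of a scatterer carries
  # -k0*delta*exp(-i psi_m) and the right sideband +k0*delta*exp(+i psi_m),
  # psi_m = omega_m t_m + phi: the two lobes counter-rotate.
  m <- seq_len(N)
  q_read <- if (lobe == "left") -qbin else qbin
  w_m <- if (window_m == "hann") {
    0.5 - 0.5 * cos(2 * pi * (m - 1) / (N - 1))
  } else rep(1, N)
  e <- w_m * exp(-2i * pi * q_read * m / N) / sum(w_m)
  Y <- as.vector(matrix(e, 1, N) %*% y)

  k0delta <- if (lobe == "left") -Conj(Y) else Y
  noise_floor <- stats::median(Mod(carrier))
  mask <- Mod(carrier) >= noise_floor * 10^(dc_threshold_db / 20)

  structure(list(k0delta = k0delta,
                 delta = Mod(k0delta) / k0,
                 phase = Arg(k0delta),
                 mask = mask,
                 z = (seq_len(Z) - 1) * sw$dz_pixel,
                 plan = plan, lobe = lobe,
                 window_m = window_m,
                 jitter_corrected = jitter_corrected,
                 sweep = sw),
            class = "vibration_map")
}

#' @export
print.vibration_map <- function(x, ...) {
  act <- which(x$mask)
  cat(sprintf(paste0("<vibration_map> %d depth px, %d above carrier ",
                     "threshold; f_m = %.4g kHz (%s lobe%s)\n"),
              length(x$delta), length(act), x$plan$f_m / 1e3, x$lobe,
              if (x$jitter_corrected) ", jitter-corrected" else ""))
  if (length(act)) {
    i <- act[which.max(x$delta[act])]
    cat(sprintf("  max delta = %.3g nm at pixel %d\n",
                x$delta[i] * 1e9, i - 1))
  }
  invisible(x)
}

#' Remove sweep-timing jitter using the recorded stimulus phase
#'
#' The stimulus waveform is recorded with the same sweep clock as the
#' A-lines, so its per-A-line phase `psi_m = omega_m t_m + phi` carries the
#' identical accumulated timing jitter as the vibration sidebands. The
#' correction replaces the jittered modulation phase by the nominal one:
#' each A-line's demodulation series is rotated by
#' `-(psi_m - omega_m m T)` (left lobe; opposite sign for the right lobe).
#' With zero jitter and zero stimulus phase offset the correction is the
#' identity.
#'
#' @param y Complex matrix (`N x Z`) or vector of per-A-line demodulation
#'   series.
#' @param stimulus_phase Length-N recorded stimulus phase (rad).
#' @param f_m Modulation frequency (Hz).
#' @param T_sweep Nominal sweep period (s).
#' @param lobe "left" or "right".
#' @return `y` with the jitter (and global stimulus phase offset) removed.
#' @export
jitter_correct <- function(y, stimulus_phase, f_m, T_sweep,
                           lobe = c("left", "right")) {
  lobe <- match.arg(lobe)
  N <- if (is.matrix(y)) nrow(y) else length(y)
  stopifnot(length(stimulus_phase) == N)
  dpsi <- stimulus_phase - 2 * pi * f_m * seq_len(N) * T_sweep
  # the left-lobe series rotates as exp(-i psi_m), the right as exp(+i psi_m)
  rot <- exp((if (lobe == "left") 1i else -1i) * dpsi)
  if (is.matrix(y)) y * rot else y * rot
}

#' Conventional phase-based vibration demodulation
#'
#' The classical sub-Nyquist method (`f_m < 0.5 f_A`): the carrier and its
#' sidebands overlap in the same depth pixel, whose phase oscillates as
#' `2 k0 delta sin(omega_m t + phi)`; `delta` is read from the amplitude of
#' the per-pixel phase oscillation at `f_m` (DFT over A-lines of the
#' unwrapped pixel phase). Because the vibration advances during the sweep,
#' the pixel phase is the envelope-weighted average of the instantaneous
#' modulation; the resulting deterministic attenuation
#' `|sum(w P exp(i omega_m t)) / sum(w P)|` over the sample window is
#' divided out. Used as an independent oracle for [demodulate()].
#'
#' @param tom A [aline_transform()] tomogram.
#' @param f_m Modulation frequency (Hz), strictly below `0.5 f_A`.
#' @param dc_threshold_db Carrier validity threshold (dB over median).
#' @return A `vibration_map` (phase convention matches [demodulate()]).
#' @export
conventional_phase_demod <- function(tom, f_m, dc_threshold_db = 6) {
  sw <- tom$sweep
  if (f_m >= 0.5 * sw$f_A) {
    stop("conventional phase demodulation requires f_m < 0.5 * f_A")
  }
  N <- nrow(tom$F)
  Z <- ncol(tom$F)
  cycles <- N * f_m / sw$f_A
  if (abs(cycles - round(cycles)) > 1e-6) {
    stop("N * f_m / f_A must be an integer")
  }
  qbin <- round(cycles)
  theta <- Arg(tom$F)
  theta <- apply(theta, 2, unwrap_phase)
  m <- seq_len(N)
  e <- exp(-2i * pi * qbin * m / N) / N
  Y <- as.vector(matrix(e, 1, N) %*% theta)
  # theta ~ 2 k0 delta sin(omega_m t_m + phi') = k0 delta/i e^{i phi'} + cc
  k0delta <- 1i * Y
  # intra-sweep smearing: the pixel averages the modulation over the sweep
  t_hat <- sweep_sample_times(sw)
  wP <- sweep_envelope(sw, t_hat)   # rect window assumed for the oracle
  smear <- sum(wP * exp(2i * pi * f_m * t_hat)) / sum(wP)
  k0delta <- k0delta / Mod(smear)
  carrier <- tom$dc
  noise_floor <- stats::median(Mod(carrier))
  mask <- Mod(carrier) >= noise_floor * 10^(dc_threshold_db / 20)
  structure(list(k0delta = k0delta,
                 delta = Mod(k0delta) / sw$k0,
                 phase = Arg(k0delta),
                 mask = mask,
                 z = (seq_len(Z) - 1) * sw$dz_pixel,
                 plan = list(f_m = f_m, apparent_f = f_m),
                 lobe = "phase",
                 jitter_corrected = FALSE,
                 sweep = sw),
            class = "vibration_map")
}

unwrap_phase <- function(theta) {
  d <- diff(theta)
  theta + c(0, cumsum(-2 * pi * round(d / (2 * pi))))
}
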