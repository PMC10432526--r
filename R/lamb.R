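#' Lamb plate dispersion (fundamental A0 / S0 modes)
#'
#' Phase velocity of the fundamental antisymmetric (A0) or symmetric (S0)
#' Lamb mode of a free elastic plate, from the Rayleigh-Lamb
#' characteristic equations in pole-free product form:
#' * symmetric: `(q^2-k^2)^2 sin(qh/2)cos(ph/2) + 4k^2 p q cos(qh/2)sin(ph/2) = 0`
#' * antisymmetric: `(q^2-k^2)^2 cos(qh/2)sin(ph/2) + 4k^2 p q sin(qh/2)cos(ph/2) = 0`
#'
#' with `k = omega/v`, `p^2 = omega^2/c_L^2 - k^2`,
#' `q^2 = omega^2/c_s^2 - k^2` and
#' `c_L = c_s sqrt(2(1-nu)/(1-2nu))`. Below the bulk speeds the internal
#' wavenumber components turn imaginary; the trigonometric factors are
#' evaluated complex with exponential rescaling so the characteristic
#' function stays finite at large frequency-thickness. Roots are located by
#' sign-change bracketing on a velocity grid and refined with uniroot; the
#' smallest genuine root is the fundamental branch (spurious zeros where
#' both product terms vanish, e.g. at `v = c_s`, are rejected).
#'
#' Limits: S0 tends to the plate velocity `c_s sqrt(2/(1-nu))` as
#' `f h -> 0`; A0 tends to zero as `sqrt(f h)`; both tend to the Rayleigh
#' speed as `f h -> infinity`.
#'
#' @param f Frequency (Hz), vectorized.
#' @param h Plate thickness (m).
#' @param c_s Bulk shear speed (m/s).
#' @param nu Poisson's ratio, in `[0, 0.5)`.
#' @param mode "A0" or "S0".
#' @param n_grid Number of velocity grid points for bracketing.
#' @return Phase velocity (m/s), same length as `f`.
#' @examples
#' lamb_dispersion(787.6e3, h = 1e-3, c_s = 930, nu = 0.34, mode = "A0")
#' @export
lamb_dispersion <- function(f, h, c_s, nu, mode = c("A0", "S0"),
                            n_grid = 3000) {
  mode <- match.arg(mode)
  stopifnot(h > 0, c_s > 0, nu >= 0, nu < 0.5, all(f > 0))
  c_L <- c_s * sqrt(2 * (1 - nu) / (1 - 2 * nu))
  vapply(f, function(ff) {
    lamb_root_one(ff, h, c_s, c_L, mode, n_grid)
  }, numeric(1))
}

# scaled sin/cos: sin(z)*exp(-|Im z|), cos(z)*exp(-|Im z|) (bounded)
.scaled_trig <- function(z) {
  s <- exp(-abs(Im(z)))
  list(sin = sin(z) * s, cos = cos(z) * s)
}

lamb_char <- function(v, omega, h, c_s, c_L, mode) {
  k <- omega / v
  p <- sqrt(as.complex(omega^2 / c_L^2 - k^2))
  q <- sqrt(as.complex(omega^2 / c_s^2 - k^2))
  tq <- .scaled_trig(q * h / 2)
  tp <- .scaled_trig(p * h / 2)
  scale <- (omega / c_s)^4
  if (mode == "S0") {
    t1 <- (q^2 - k^2)^2 * tq$sin * tp$cos / scale
    t2 <- 4 * k^2 * p * q * tq$cos * tp$sin / scale
  } else {
    t1 <- (q^2 - k^2)^2 * tq$cos * tp$sin / scale
    t2 <- 4 * k^2 * p * q * tq$sin * tp$cos / scale
  }
  list(g = Re(t1 + t2) + Im(t1 + t2), t1 = t1, t2 = t2)
}

lamb_root_one <- function(f, h, c_s, c_L, mode, n_grid) {
  omega <- 2 * pi * f
  v_grid <- seq(0.002 * c_s, 0.9995 * c_L, length.out = n_grid)
  g <- vapply(v_grid, function(v) lamb_char(v, omega, h, c_s, c_L, mode)$g,
              numeric(1))
  sgn <- sign(g)
  idx <- which(sgn[-1] * sgn[-length(sgn)] < 0)
  for (i in idx) {
    root <- stats::uniroot(function(v) lamb_char(v, omega, h, c_s, c_L,
                                                 mode)$g,
                           c(v_grid[i], v_grid[i + 1]), tol = 1e-12)$root
    ch <- lamb_char(root, omega, h, c_s, c_L, mode)
    # reject spurious zeros where both product terms vanish together
    if (max(Mod(ch$t1), Mod(ch$t2)) < 1e-8) next
    if (abs(root - c_s) < 1e-5 * c_s) next
    return(root)
  }
  stop(sprintf(paste0("no %s root bracketed at f*h = %.4g m/s (searched ",
                      "v in [%.3g, %.3g] m/s, %d sign changes)"),
               mode, f * h, v_grid[1], v_grid[length(v_grid)], length(idx)))
}
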