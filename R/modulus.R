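#' Complex shear modulus from a complex wavenumber
#'
#' For a bulk shear wave `exp(i(omega t - k x))` with `k = k_r - i k_i`
#' (`k_i >= 0` in a passive medium), the storage and loss moduli are
#' `mu' = rho omega^2 (k_r^2 - k_i^2) / (k_r^2 + k_i^2)^2` and
#' `mu'' = 2 rho omega^2 k_r k_i / (k_r^2 + k_i^2)^2`, i.e. the real and
#' imaginary parts of `rho omega^2 / (k_r - i k_i)^2`.
#'
#' @param k_r Real wavenumber (rad/m).
#' @param k_i Attenuation coefficient (rad/m).
#' @param f Frequency (Hz).
#' @param rho Density (kg/m^3); soft-tissue default 1000.
#' @return data.frame with columns `f`, `mu_storage`, `mu_loss` (Pa),
#'   `v` (phase velocity, m/s), `k_r`, `k_i`.
#' @examples
#' complex_modulus(2000, 200, f = 40e3)
#' @export
complex_modulus <- function(k_r, k_i, f, rho = 1000) {
  stopifnot(all(k_r > 0), all(k_i >= 0), all(f > 0), rho > 0)
  omega <- 2 * pi * f
  s2 <- (k_r^2 + k_i^2)^2
  data.frame(f = f,
             mu_storage = rho * omega^2 * (k_r^2 - k_i^2) / s2,
             mu_loss = 2 * rho * omega^2 * k_r * k_i / s2,
             v = omega / k_r, k_r = k_r, k_i = k_i)
}

#' Complex wavenumber from a complex shear modulus
#'
#' Inverse of [complex_modulus()]: `k = omega * sqrt(rho / mu)` with
#' `mu = mu' + i mu''`, taking the branch with `Re(k) > 0, Im(k) <= 0`.
#'
#' @param mu_storage Storage modulus (Pa).
#' @param mu_loss Loss modulus (Pa).
#' @param f Frequency (Hz).
#' @param rho Density (kg/m^3).
#' @return data.frame with columns `f`, `k_r`, `k_i`.
#' @export
wavenumber_from_modulus <- function(mu_storage, mu_loss, f, rho = 1000) {
  omega <- 2 * pi * f
  k <- omega * sqrt(rho / complex(real = mu_storage, imaginary = mu_loss))
  k <- ifelse(Re(k) < 0, -k, k)
  data.frame(f = f, k_r = Re(k), k_i = -Im(k))
}

#' Rayleigh-to-shear speed ratio
#'
#' Approximate ratio `c_R / c_s = (0.862 + 1.14 nu) / (1 + nu)` for an
#' elastic half-space with Poisson's ratio `nu`.
#'
#' @param nu Poisson's ratio in `[0, 0.5]`.
#' @return Ratio `c_R / c_s` (dimensionless).
#' @examples
#' rayleigh_ratio(0.5)  # 0.9547
#' @export
rayleigh_ratio <- function(nu) {
  stopifnot(all(nu >= 0), all(nu <= 0.5))
  (0.862 + 1.14 * nu) / (1 + nu)
}

#' Shear modulus from a measured Rayleigh wave speed
#'
#' Converts a Rayleigh surface-wave speed to the bulk shear speed via
#' [rayleigh_ratio()] and then to the shear modulus `mu = rho c_s^2`.
#'
#' @param c_R Rayleigh wave speed (m/s).
#' @param nu Poisson's ratio.
#' @param rho Density (kg/m^3).
#' @return Shear modulus (Pa).
#' @examples
#' modulus_from_rayleigh(1285, nu = 0.37, rho = 1200) / 1e9  # ~2.26 GPa
#' @export
modulus_from_rayleigh <- function(c_R, nu, rho) {
  stopifnot(all(c_R > 0), rho > 0)
  c_s <- c_R / rayleigh_ratio(nu)
  rho * c_s^2
}
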