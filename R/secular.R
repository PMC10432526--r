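#' Surface-wave secular equation (incompressible half-space)
#'
#' `F(kappa) = (2 kappa^2 - K^2)^2
#'             - 4 kappa^2 sqrt(kappa^2 (kappa^2 - K^2)) * sign(Re(kappa^2 - K^2))`
#' with the square root on the principal branch. Its roots relative to the
#' bulk shear wavenumber `K` are the Rayleigh surface-wave wavenumber
#' (real, slightly above `K`) and the complex supershear (leaky) root below
#' `K`.
#'
#' Both the real Rayleigh root and the complex supershear root satisfy the
#' equation with the principal square root of `kappa^2 (kappa^2 - K^2)`;
#' the sign-of-real-part branch rule is exactly what the principal branch
#' realizes (for real kappa > K the factor is +1 and the root is the
#' classical Rayleigh condition).
#'
#' @param kappa Complex (or numeric) trial wavenumber.
#' @param K Bulk shear wavenumber (default 1: work in ratios).
#' @return Complex value of the secular function.
#' @export
secular_fun <- function(kappa, K = 1) {
  kappa <- as.complex(kappa)
  (2 * kappa^2 - K^2)^2 - 4 * kappa^2 * sqrt(kappa^2 * (kappa^2 - K^2))
}

# Analytic derivative dF/dkappa (principal branch).
secular_deriv <- function(kappa, K = 1) {
  kappa <- as.complex(kappa)
  r <- sqrt(kappa^2 * (kappa^2 - K^2))
  8 * kappa * (2 * kappa^2 - K^2) -
    (8 * kappa * r + 4 * kappa^2 * (2 * kappa^3 - kappa * K^2) / r)
}

#' Roots of the surface-wave secular equation
#'
#' Solves `F(kappa) = 0` for the incompressible (nu = 0.5) half-space in
#' units of the bulk shear wavenumber `K = 1`: the real Rayleigh root
#' (bracketed bisection + Newton polish) and the complex supershear root
#' (complex Newton iteration seeded near `0.5 - 0.1i`).
#'
#' @param tol Residual tolerance on `|F(kappa)|`.
#' @return List with `rayleigh` (real ratio `K_R/K`, about 1.047),
#'   `supershear` (complex ratio `K_SS/K`, about `0.4696 - 0.1355i`), and
#'   the residuals `residual_rayleigh`, `residual_supershear`.
#' @examples
#' secular_roots()$rayleigh
#' @export
secular_roots <- function(tol = 1e-12) {
  f_real <- function(x) Re(secular_fun(x + 0i))
  root <- stats::uniroot(f_real, c(1 + 1e-9, 2), tol = 1e-14)$root
  for (i in 1:8) {  # Newton polish to full precision
    root <- root - Re(secular_fun(root) / secular_deriv(root))
  }
  ss <- complex(real = 0.5, imaginary = -0.1)
  for (i in 1:60) {
    step <- secular_fun(ss) / secular_deriv(ss)
    ss <- ss - step
    if (Mod(step) < 1e-16) break
  }
  res_r <- Mod(secular_fun(root))
  res_s <- Mod(secular_fun(ss))
  if (res_r > tol || res_s > tol) {
    stop(sprintf("secular root refinement did not converge (residuals %.3g, %.3g)",
                 res_r, res_s))
  }
  list(rayleigh = root, supershear = ss,
       residual_rayleigh = res_r, residual_supershear = res_s)
}
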