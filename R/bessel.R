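# Complex-argument Bessel and Hankel functions needed by the near-field
# surface-wave source model. Power series for small |z|, Stokes asymptotic
# expansions for large |z|; principal branches throughout. Accuracy is at
# the 1e-10 level near the series/asymptotic crossover (|z| = 12) and
# better elsewhere; validated on the real axis against base besselJ/besselY.

bessel_series_J <- function(z, nu) {
  # nu = 0 or 1
  z2 <- (z / 2)^2
  term <- (z / 2)^nu / gamma(nu + 1)
  s <- term
  for (k in 1:60) {
    term <- -term * z2 / (k * (k + nu))
    s <- s + term
    if (all(Mod(term) < 1e-18 * (Mod(s) + 1e-300))) break
  }
  s
}

bessel_series_Y0 <- function(z) {
  # Y0(z) = (2/pi)[(log(z/2)+gamma) J0(z)] + (2/pi) sum (-1)^(k+1) H_k u^k/(k!)^2
  euler_gamma <- 0.57721566490153286
  z2 <- (z / 2)^2
  j0 <- bessel_series_J(z, 0)
  term <- z2          # u^k / (k!)^2, k = 1
  Hk <- 1
  s <- term * Hk
  sign <- 1
  for (k in 2:60) {
    term <- term * z2 / k^2
    Hk <- Hk + 1 / k
    sign <- -sign
    s <- s + sign * Hk * term
    if (all(Mod(Hk * term) < 1e-18 * (Mod(s) + 1e-300))) break
  }
  (2 / pi) * ((log(z / 2) + euler_gamma) * j0 + s)
}

# Stokes asymptotic expansion for H_nu^(1), valid for large |z|,
# -pi < arg z < 2*pi.
hankel1_asym <- function(z, nu) {
  mu <- 4 * nu^2
  # sum_k i^k a_k(nu) / (8z)^k with a_k = prod_{j=1..k}(mu-(2j-1)^2)/ (k! )
  s <- 1 + 0i
  term <- 1 + 0i
  for (k in 1:12) {
    term <- term * (mu - (2 * k - 1)^2) / (k * 8 * z) * 1i
    s <- s + term
  }
  sqrt(2 / (pi * z)) * exp(1i * (z - nu * pi / 2 - pi / 4)) * s
}

#' Bessel and Hankel functions of complex argument
#'
#' `besselJ0c`, `besselJ1c`, `besselY0c` and `hankel1_0` evaluate J0, J1,
#' Y0 and the Hankel function of the first kind H0^(1) on the principal
#' branch for complex arguments.
#'
#' @param z Complex (or numeric) vector.
#' @return Complex vector.
#' @name bessel-complex
#' @keywords internal
NULL

#' @rdname bessel-complex
besselJ0c <- function(z) {
  z <- as.complex(z)
  out <- z
  small <- Mod(z) <= 12
  if (any(small)) out[small] <- bessel_series_J(z[small], 0)
  if (any(!small)) {
    zb <- z[!small]
    # J = (H1 + H2)/2; compute H2 via H2_nu(z) = conj(H1_nu(conj(z)))
    out[!small] <- (hankel1_asym(zb, 0) +
                      Conj(hankel1_asym(Conj(zb), 0))) / 2
  }
  out
}

#' @rdname bessel-complex
besselJ1c <- function(z) {
  z <- as.complex(z)
  out <- z
  small <- Mod(z) <= 12
  if (any(small)) out[small] <- bessel_series_J(z[small], 1)
  if (any(!small)) {
    zb <- z[!small]
    out[!small] <- (hankel1_asym(zb, 1) +
                      Conj(hankel1_asym(Conj(zb), 1))) / 2
  }
  out
}

#' @rdname bessel-complex
besselY0c <- function(z) {
  z <- as.complex(z)
  out <- z
  small <- Mod(z) <= 12
  if (any(small)) out[small] <- bessel_series_Y0(z[small])
  if (any(!small)) {
    zb <- z[!small]
    out[!small] <- (hankel1_asym(zb, 0) -
                      Conj(hankel1_asym(Conj(zb), 0))) / (2i)
  }
  out
}

#' @rdname bessel-complex
hankel1_0 <- function(z) {
  z <- as.complex(z)
  out <- z
  small <- Mod(z) <= 12
  if (any(small)) {
    zs <- z[small]
    out[small] <- bessel_series_J(zs, 0) + 1i * bessel_series_Y0(zs)
  }
  if (any(!small)) out[!small] <- hankel1_asym(z[!small], 0)
  out
}
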