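#' Power-law fit of modulus versus frequency
#'
#' Fits `mu = A * f^alpha` by linear least squares in log-log space, either
#' as a single segment or as a bilinear (two-slope) fit with a fixed,
#' user-supplied breakpoint frequency.
#'
#' @param f Frequencies (Hz), positive.
#' @param mu Moduli (Pa), positive.
#' @param segments 1 (single power law) or 2 (bilinear).
#' @param breakpoint Breakpoint frequency (Hz), required when
#'   `segments = 2`; points at the breakpoint join the lower segment.
#' @return For `segments = 1`: list with `alpha`, `logA`, `fitted`.
#'   For `segments = 2`: list with `alpha` (length 2), `logA` (length 2),
#'   `breakpoint`, `fitted`.
#' @examples
#' f <- c(1e3, 2e3, 5e3, 1e4)
#' power_law_fit(f, 2 * f^0.5)$alpha  # 0.5
#' @export
power_law_fit <- function(f, mu, segments = 1, breakpoint = NULL) {
  stopifnot(length(f) == length(mu), segments %in% c(1, 2))
  if (any(f <= 0) || any(mu <= 0)) {
    stop("power-law fitting requires positive frequencies and moduli")
  }
  lf <- log(f); lm_ <- log(mu)
  one_fit <- function(sel) {
    if (sum(sel) < 3) stop("need at least 3 points per power-law segment")
    co <- stats::coef(stats::lm(lm_[sel] ~ lf[sel]))
    c(logA = unname(co[1]), alpha = unname(co[2]))
  }
  if (segments == 1) {
    co <- one_fit(rep(TRUE, length(f)))
    list(alpha = co["alpha"], logA = co["logA"],
         fitted = exp(co["logA"] + co["alpha"] * lf))
  } else {
    if (is.null(breakpoint)) stop("bilinear fit requires a breakpoint frequency")
    lo <- f <= breakpoint
    co1 <- one_fit(lo); co2 <- one_fit(!lo)
    list(alpha = c(low = unname(co1["alpha"]), high = unname(co2["alpha"])),
         logA = c(low = unname(co1["logA"]), high = unname(co2["logA"])),
         breakpoint = breakpoint,
         fitted = ifelse(lo, exp(co1["logA"] + co1["alpha"] * lf),
                         exp(co2["logA"] + co2["alpha"] * lf)))
  }
}
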