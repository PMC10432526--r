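#' Draw a sweep-period jitter realization
#'
#' The sweep period of the laser fluctuates: the i-th sweep is longer than
#' nominal by tau_i, with tau_i iid Gaussian of standard deviation `sigma_T`.
#' The deviations accumulate, so the m-th A-line starts at
#' `t_m = m*T + sum(tau_1..tau_m)`.
#'
#' @param N Number of A-lines.
#' @param sigma_T Period jitter standard deviation (s).
#' @param T_sweep Nominal sweep period (s).
#' @param seed Optional integer seed for reproducibility.
#' @return Object of class `jitter_realization`: list with `tau` (length-N
#'   period deviations, s) and `t_m` (length-N cumulative A-line times, s).
#' @examples
#' j <- draw_jitter(108, sigma_T = 4.9e-9, T_sweep = 1 / 43.2e3, seed = 1)
#' @export
draw_jitter <- function(N, sigma_T, T_sweep, seed = NULL) {
  stopifnot(N >= 1, sigma_T >= 0, T_sweep > 0)
  if (!is.null(seed)) {
    old <- if (exists(".Random.seed", globalenv())) get(".Random.seed",
                                                        globalenv()) else NULL
    on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
    set.seed(seed)
  }
  tau <- if (sigma_T > 0) stats::rnorm(N, 0, sigma_T) else numeric(N)
  t_m <- seq_len(N) * T_sweep + cumsum(tau)
  structure(list(tau = tau, t_m = t_m, sigma_T = sigma_T, T_sweep = T_sweep),
            class = "jitter_realization")
}
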