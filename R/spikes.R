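#' Inhomogeneous renewal spiking
#'
#' Spikes are drawn bin by bin: a spike occurs at `(m, n)` iff a uniform
#' variate falls below \eqn{\Delta t\,\exp(\mu_m + w_{mn} +
#' \lambda^G_{l(m,n)})}, with \eqn{\lambda^G} a user-supplied ground-truth
#' refractory log-modulation as a function of lag since the last spike
#' (`-Inf` entries give a hard refractory period; the term is 0 before a
#' trial's first spike and beyond the support of `lambda_G`). Probabilities
#' exceeding 1 are clipped with a warning reporting the maximum.
#'
#' @param osc an [gen_oscillation()] result, or an M x N drive matrix.
#' @param mu per-trial log-rate offsets (scalar recycled).
#' @param lambda_G numeric vector of refractory log-modulation by lag in
#'   bins (element k = lag of k bins), or NULL for none.
#' @param dt bin width, s (taken from `osc` when available).
#' @param seed optional seed.
#' @return a [spike_raster()].
#' @export
gen_spikes_renewal <- function(osc, mu, lambda_G = NULL, dt = NULL, seed = NULL) {
  w <- if (inherits(osc, "oscillation")) osc$w else as.matrix(osc)
  if (is.null(dt)) dt <- osc$dt
  M <- nrow(w)
  mu <- rep(mu, length.out = M)
  if (is.null(lambda_G)) lambda_G <- numeric(0)
  if (!is.null(seed)) set.seed(seed)
  res <- .sim_renewal(w, mu, as.numeric(lambda_G), dt)
  if (res$n_clipped > 0)
    warning(sprintf("%d bin probabilities clipped at 1 (max %.3g)",
                    res$n_clipped, res$max_p))
  spike_raster(res$y, dt)
}

#' Leaky integrate-and-fire spiking
#'
#' Euler integration of
#' \deqn{\Delta V = (-V/\tau + f_n + \mu_m + w_{mn})\,\Delta t +
#'       \sigma_b\sqrt{\Delta t}\,z,\quad z \sim N(0,1),}
#' with a spike emitted and `V` reset to 0 whenever `V >= 1`. The
#' \eqn{\sqrt{\Delta t}} noise scaling makes the background-fluctuation
#' strength independent of the bin width. Refractoriness arises naturally
#' from the reset, so the resulting rasters have an intrinsic
#' history-dependent intensity.
#'
#' @param osc an [gen_oscillation()] result or M x N drive matrix (set to a
#'   zero matrix for unmodulated cells).
#' @param mu per-trial DC drive (scalar recycled).
#' @param f length-N event-locked drive (scalar recycled), e.g. a
#'   stimulus-triggered rate change.
#' @param tau membrane time constant, s.
#' @param sigma_b2 background noise variance (per unit time).
#' @param dt bin width, s.
#' @param seed optional seed.
#' @return a [spike_raster()].
#' @export
gen_spikes_lif <- function(osc, mu, f = 0, tau = 0.2, sigma_b2 = 0.2,
                           dt = NULL, seed = NULL) {
  if (!(tau > 0)) stop("tau must be positive")
  w <- if (inherits(osc, "oscillation")) osc$w else as.matrix(osc)
  if (is.null(dt)) dt <- osc$dt
  M <- nrow(w); N <- ncol(w)
  mu <- rep(mu, length.out = M)
  f <- rep(f, length.out = N)
  if (!is.null(seed)) set.seed(seed)
  y <- .sim_lif(w, f, mu, tau, sqrt(sigma_b2), dt)
  spike_raster(y, dt)
}
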