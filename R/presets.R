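#' Simulation scenario presets
#'
#' Seedable generators for the package's benchmark scenarios. Each preset
#' reads its parameters from `inst/extdata/presets.yaml` (calibration
#' targets -- realised OCV, firing rate, phase locking -- are documented
#' there alongside the values that realise them):
#'
#' * `fig2`: LIF neuron, ~40 Hz firing with a stimulus-triggered rate bump,
#'   15 Hz irregular modulation (OCV ~0.13), 60 trials x 1 s.
#' * `fig3a`: renewal spiking at ~40 Hz with a refractory/rebound history,
#'   10 Hz modulation (OCV ~0.18).
#' * `fig6`: renewal at ~60 Hz, 20 Hz modulation (OCV ~0.14).
#' * `fig8`: renewal at ~22 Hz, 20 Hz modulation (OCV ~0.27) plus
#'   trial-specific square-wave slow offsets (50% duty), flat PSTH.
#' * `fig9`: renewal at ~36 Hz, 20 Hz modulation (OCV ~0.32), 80 trials x
#'   1.2 s with a fraction of weakly modulated trials (strength `s0 = 0.1`).
#'
#' @param name preset name.
#' @param seed integer seed.
#' @param M override the trial count.
#' @param weak_fraction (`fig9`) fraction of weakly modulated trials.
#' @return list with `raster`, `osc` (the ground-truth oscillation), `dt`,
#'   the resolved `params`, and scenario extras (`offsets`, `labels`).
#' @export
lost_preset <- function(name = c("fig2", "fig3a", "fig6", "fig8", "fig9"),
                        seed = 1L, M = NULL, weak_fraction = NULL) {
  name <- match.arg(name)
  pars <- preset_params()[[name]]
  if (!is.null(M)) pars$M <- M
  if (!is.null(weak_fraction)) pars$weak_fraction <- weak_fraction
  set.seed(seed)
  dt <- pars$dt
  N <- round(pars$duration / dt)
  osc <- gen_oscillation(nu = pars$nu, C_xi = pars$C_xi, C_A = pars$C_A,
                         depth = pars$depth,
                         ar1_timescales = pars$ar1_timescale,
                         M = pars$M, N = N, dt = dt)
  extras <- list()

  if (identical(pars$generator, "lif")) {
    f <- pars$f_amp * exp(-((seq_len(N) - 1) * dt - pars$f_center)^2 /
                            (2 * pars$f_sd^2))
    raster <- gen_spikes_lif(osc, mu = pars$mu, f = f, tau = pars$tau,
                             sigma_b2 = pars$sigma_b2, dt = dt)
    extras$f <- f
  } else {
    drive <- osc$w
    labels <- NULL
    if (!is.null(pars$weak_fraction) && pars$weak_fraction > 0) {
      nweak <- round(pars$weak_fraction * pars$M)
      weak <- seq_len(nweak)                       # first trials weak
      drive[weak, ] <- 1 + pars$s0 * (osc$w[weak, , drop = FALSE] - 1)
      labels <- ifelse(seq_len(pars$M) %in% weak, "weak", "strong")
      extras$labels <- labels
    }
    offs <- NULL
    if (isTRUE(pars$square_wave)) {
      offs <- gen_square_wave_offsets(
        duty = pars$duty, mean_state_duration = pars$mean_state_duration,
        min_duration = 0.1, levels = pars$levels, M = pars$M, N = N, dt = dt)
      drive <- drive + offs
      extras$offsets <- offs
    }
    lg <- if (is.null(pars$refractory)) NULL else ground_truth_history(pars, dt)
    raster <- gen_spikes_renewal(drive, mu = pars$mu, lambda_G = lg, dt = dt)
    raster$trial_labels <- labels
    extras$lambda_G <- lg
  }
  list(raster = raster, osc = osc, dt = dt, params = pars, extras = extras)
}

# refractory + rebound ground-truth history curve by lag bin
ground_truth_history <- function(pars, dt) {
  spec <- pars$refractory
  lags <- seq_len(round(spec$support / dt)) * dt
  lg <- spec$rebound * exp(-lags / spec$rebound_tau) -
    spec$inhibition * exp(-lags / spec$inhibition_tau)
  if (spec$hard > 0) lg[lags <= spec$hard] <- -Inf
  lg
}

preset_params <- function() {
  path <- system.file("extdata", "presets.yaml", package = "lost")
  yaml::read_yaml(path)
}
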