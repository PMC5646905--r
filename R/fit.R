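#' Fit the latent oscillatory spike train model
#'
#' Full Gibbs sampler for the point-process state-space model: per
#' iteration, in order, the Polya-Gamma field, the latent AR(p) paths
#' (forward-filter backward-sample per trial), the AR roots (component-wise
#' with the stationarity/structural prior), the innovation variance, the
#' trial offsets (sum-to-zero), the TAE weights, the spike-history weights
#' and, when enabled, the mixture strength / indicators / weights.
#'
#' The linear predictor of the spiking log-odds is
#' \eqn{s_m x_{mn} + f_n + \mu_m + \lambda^R_{l(m,n)} + I_{mn}}
#' with `s_m = 1` unless the mixture extension is on, `I` an optional known
#' signal (e.g. a slow modulation inferred by a first pass with
#' `ar1_mode = TRUE`), and the history contribution zero before a trial's
#' first spike.
#'
#' @param raster a [spike_raster()].
#' @param C,R numbers of complex pairs and real roots (ignored when
#'   `ar1_mode`).
#' @param iterations,burn_in,thin Gibbs schedule; posterior summaries are
#'   means over the post-burn-in draws.
#' @param seed optional integer seed.
#' @param history `"auto"` (knots from ISI features), a `spline_model`, or
#'   `"none"`.
#' @param tae `"auto"` (knots from the PSTH random search), a
#'   `spline_model`, or `"none"`.
#' @param known_signal optional M x N matrix added to the predictor.
#' @param mixture logical; enable the two-class modulation-strength
#'   mixture. Mixture updates start at `floor(2 * burn_in / 3)` (earlier
#'   iterations run with every trial at strength 1) so the class
#'   assignment is made against an established latent oscillation; starting
#'   the indicator/weight updates from scratch at iteration 1 lets the
#'   Dirichlet weight collapse onto the all-strong corner before the
#'   likelihood can speak.
#' @param ar1_mode single-real-root latent state (slow-fluctuation pass).
#' @param fixed_f,fixed_lamR,fixed_mu optionally fix the TAE curve (length
#'   N), the history curve (by lag bin) or the offsets instead of sampling
#'   them (used in recovery studies).
#' @param priors a [lost_priors()].
#' @param control a [lost_control()].
#' @return an object of class `lost_fit`; see [tidy.lost_fit()],
#'   [glance.lost_fit()], [assess_convergence()].
#' @export
lost_fit <- function(raster, C = 4, R = 1,
                     iterations = 5000, burn_in = 2000, thin = 1,
                     seed = NULL,
                     history = "auto", tae = "auto",
                     known_signal = NULL, mixture = FALSE, ar1_mode = FALSE,
                     fixed_f = NULL, fixed_lamR = NULL, fixed_mu = NULL,
                     priors = lost_priors(), control = lost_control()) {
  stopifnot(inherits(raster, "spike_raster"))
  if (!is.null(seed)) set.seed(seed)
  y <- raster$y
  M <- nrow(y); N <- ncol(y); dt <- raster$dt
  kappa <- y - 0.5
  lag <- raster$last_spike_lag

  I <- if (is.null(known_signal)) matrix(0, M, N) else as.matrix(known_signal)

  ## --- spike-history term ---------------------------------------------
  hist_on <- !identical(history, "none") && is.null(fixed_lamR)
  if (hist_on) {
    hsm <- if (inherits(history, "spline_model")) history
           else history_knots_from_isi(raster, prior_var = priors$v_var)
    Lmax <- ncol(hsm$basis)
  } else {
    hsm <- NULL
    Lmax <- if (is.null(fixed_lamR)) 0L else length(fixed_lamR)
  }
  lam_lookup <- function(hv) {
    # per-(m,n) history value from the by-lag curve hv (length Lmax)
    if (Lmax == 0L) return(matrix(0, M, N))
    idx <- pmin(pmax(lag, 1L), Lmax)
    val <- matrix(hv[idx], M, N)
    val[lag == 0L | lag > Lmax] <- 0
    val
  }
  sel_hist <- which(lag >= 1L & lag <= Lmax)   # cells with active history
  lag_sel <- lag[sel_hist]

  ## --- TAE term --------------------------------------------------------
  tae_on <- !identical(tae, "none") && is.null(fixed_f)
  if (tae_on) {
    tsm <- if (inherits(tae, "spline_model")) tae
           else tae_knots_from_psth(raster, smooth_sd = 0.010)
    tsm$prior_var <- rep(priors$alpha_var, nrow(tsm$basis))
    f <- spline_curve(tsm)           # initialised at the PSTH least squares
  } else {
    tsm <- NULL
    f <- if (is.null(fixed_f)) numeric(N) else as.numeric(fixed_f)
  }

  ## --- initial state ---------------------------------------------------
  rate <- mean(y) / dt
  if (ar1_mode) {
    comp <- ar_components(real_roots = 0.98, sigma2 = 1e-3)
  } else {
    f_lo <- 1 / (4 * dt * N)
    f_hi <- max(rate, 4 * f_lo)
    freqs <- exp(seq(log(f_lo), log(f_hi), length.out = C))
    # cap the slowest initial period at half a trial: a spectrally sharp
    # pair much slower than the window has a huge stationary variance that
    # takes thousands of sweeps to deflate
    periods <- pmin(1 / (freqs * dt), N / 2)
    moduli <- rep(0.9, C); moduli[which.max(periods)] <- 0.97
    comp <- ar_components(periods = periods, moduli = moduli,
                          real_roots = if (R > 0) rep(0.3, R) else numeric(0),
                          sigma2 = 1e-4)
  }
  p <- comp$p
  x <- matrix(0, M, N)
  mu <- if (is.null(fixed_mu)) numeric(M) else rep(fixed_mu, length.out = M)
  lamR <- if (hist_on) lam_lookup(spline_curve(hsm))
          else if (!is.null(fixed_lamR)) lam_lookup(as.numeric(fixed_lamR))
          else matrix(0, M, N)

  s0 <- priors$s0
  s1 <- 1
  strong <- rep(TRUE, M)
  pi_mix <- c(0.5, 0.5)
  s_m <- rep(1, M)
  mix_start <- if (mixture) max(1L, floor(2 * burn_in / 3)) else Inf

  keep <- which(seq_len(iterations) > burn_in &
                  (seq_len(iterations) - burn_in) %% thin == 0L)
  nkeep <- length(keep)

  trace <- data.frame(iteration = seq_len(iterations), freq_hz = NA_real_,
                      modulus = NA_real_, amplitude = NA_real_,
                      sigma2 = NA_real_, s1 = NA_real_, pi1 = NA_real_)
  x_sum <- matrix(0, M, N)
  f_sum <- numeric(N)
  mu_sum <- numeric(M)
  lam_curve_sum <- numeric(Lmax)
  Z1_sum <- numeric(M)
  pi1_draws <- rep(NA_real_, nkeep)
  s1_draws <- rep(NA_real_, nkeep)
  v_draws <- if (hist_on) matrix(NA_real_, nkeep, nrow(hsm$basis)) else NULL
  alpha_draws <- if (tae_on) matrix(NA_real_, nkeep, nrow(tsm$basis)) else NULL
  ik <- 0L
  clip_warned <- FALSE

  ## omega/X warm-up at fixed initial parameters (see lost_control)
  eta_no_x <- sweep(sweep(lamR + I, 2L, f, "+"), 1L, mu, "+")
  for (wu in seq_len(control$warmup)) {
    psi <- pmin(pmax(x * s_m + eta_no_x, -control$psi_clip), control$psi_clip)
    omega <- rpg(psi)
    pobs <- pseudo_observations(kappa, omega, eta_no_x, s = s_m)
    x <- ffbs_sample(pobs, comp, init_var = control$init_var,
                     method = control$backward)$x
  }

  for (it in seq_len(iterations)) {
    sx <- x * s_m
    eta_no_x <- sweep(sweep(lamR + I, 2L, f, "+"), 1L, mu, "+")

    ## 1. Polya-Gamma field
    psi <- sx + eta_no_x
    if (any(abs(psi) > control$psi_clip)) {
      if (!clip_warned) {
        warning("divergent predictor: |psi| clipped for the PG draw")
        clip_warned <- TRUE
      }
      psi <- pmin(pmax(psi, -control$psi_clip), control$psi_clip)
    }
    omega <- rpg(psi)

    ## 2. latent paths (FFBS)
    pobs <- pseudo_observations(kappa, omega, eta_no_x, s = s_m)
    draw <- ffbs_sample(pobs, comp, init_var = control$init_var,
                        method = control$backward)
    x <- draw$x
    x_ext <- extend_paths(x, draw$X0)

    ## 3. AR roots
    comp <- sweep_roots(x_ext, comp, modulus_prior = control$modulus_prior,
                        real_root_range = if (ar1_mode) c(0.9, 1) else c(-1, 1))

    ## 4. innovation variance
    eps <- component_residuals(x_ext, comp, NULL)
    comp$sigma2 <- sample_sigma2(sum(eps^2), length(eps),
                                 priors$a_sig, priors$b_sig)

    sx <- x * s_m
    base <- kappa / omega - sx - I

    ## 5. trial offsets
    if (is.null(fixed_mu)) {
      resid_mu <- sweep(base - lamR, 2L, f, "-")
      mu <- sample_offsets(omega, resid_mu, priors$mu_var)
    }

    ## 6. TAE weights
    if (tae_on) {
      resid_f <- sweep(base - lamR, 1L, mu, "-")
      wt <- colSums(omega)
      g <- colSums(omega * resid_f)
      tsm$weights <- sample_spline_weights(tsm, wt, g)
      f <- spline_curve(tsm)
    }

    ## 7. history weights
    if (hist_on && length(sel_hist)) {
      resid_v <- sweep(sweep(base, 2L, f, "-"), 1L, mu, "-")
      wt <- numeric(Lmax); g <- numeric(Lmax)
      acc <- rowsum(cbind(omega[sel_hist], (omega * resid_v)[sel_hist]), lag_sel)
      li <- as.integer(rownames(acc))
      wt[li] <- acc[, 1L]; g[li] <- acc[, 2L]
      hsm$weights <- sample_spline_weights(hsm, wt, g)
      lamR <- lam_lookup(spline_curve(hsm))
    }

    ## 8. mixture: strength, indicators, weights
    if (mixture && it >= mix_start) {
      eta_no_sx <- sweep(sweep(lamR + I, 2L, f, "+"), 1L, mu, "+")
      s1 <- sample_s1(omega, x, eta_no_sx, kappa, strong, s0, priors$s1_var)
      strong <- sample_Z(y, x, eta_no_sx, pi_mix, s0, s1)
      pi_mix <- sample_pi_mix(strong, priors$alpha_pi)
      s_m <- ifelse(strong, s1, s0)
    }

    ## trace + summaries
    sp <- slowest_pair(comp)
    trace$freq_hz[it] <- if (is.na(sp)) NA_real_ else 1 / (comp$periods[sp] * dt)
    trace$modulus[it] <- if (is.na(sp)) NA_real_ else comp$moduli[sp]
    trace$amplitude[it] <- sd(x)
    trace$sigma2[it] <- comp$sigma2
    if (mixture) { trace$s1[it] <- s1; trace$pi1[it] <- pi_mix[1L] }

    if (it %in% keep) {
      ik <- ik + 1L
      x_sum <- x_sum + x
      f_sum <- f_sum + f
      mu_sum <- mu_sum + mu
      if (hist_on) {
        lam_curve_sum <- lam_curve_sum + spline_curve(hsm)
        v_draws[ik, ] <- hsm$weights
      }
      if (tae_on) alpha_draws[ik, ] <- tsm$weights
      if (mixture) {
        Z1_sum <- Z1_sum + as.numeric(!strong)
        pi1_draws[ik] <- pi_mix[1L]
        s1_draws[ik] <- s1
      }
    }
    if (control$progress > 0 && it %% control$progress == 0L)
      message(sprintf("iteration %d / %d", it, iterations))
  }

  out <- list(
    raster = raster, dt = dt,
    config = list(C = C, R = R, iterations = iterations, burn_in = burn_in,
                  thin = thin, mixture = mixture, ar1_mode = ar1_mode,
                  priors = priors, control = control),
    trace = tibble::as_tibble(trace),
    components = comp,
    x_mean = x_sum / max(ik, 1L),
    f_mean = f_sum / max(ik, 1L),
    mu_mean = mu_sum / max(ik, 1L),
    history = if (hist_on) list(model = hsm, curve_mean = lam_curve_sum / max(ik, 1L),
                                draws = v_draws) else NULL,
    tae = if (tae_on) list(model = tsm, draws = alpha_draws) else NULL,
    mixture = if (mixture) list(Z1_mean = Z1_sum / max(ik, 1L),
                                pi1_draws = pi1_draws, s1_draws = s1_draws) else NULL,
    n_kept = ik)
  class(out) <- "lost_fit"
  out
}

#' Posterior mode of the weak-class mixture weight
#'
#' Kernel-density mode of the retained draws of `pi_1`; the mode is used
#' rather than the mean because the weight is bounded and its posterior can
#' pile up at 0.
#' @param fit a mixture-enabled [lost_fit()].
#' @export
pi1_mode <- function(fit) {
  d <- fit$mixture$pi1_draws
  d <- d[is.finite(d)]
  dd <- density(d, from = 0, to = 1)
  dd$x[which.max(dd$y)]
}

#' Classify trials as weakly or strongly modulated
#'
#' Applies the indicator-threshold rule: the `round(M * pi1_mode)` trials
#' with the largest posterior-mean weak indicator are labelled weak. (The
#' posterior mode of `pi_1` estimates the weak fraction, so `M * pi1*` is
#' the expected number of weak trials.)
#'
#' @param fit a mixture-enabled [lost_fit()].
#' @return tibble with `trial`, `Z1_mean`, `class` ("weak"/"strong").
#' @export
classify_trials <- function(fit) {
  if (is.null(fit$mixture)) stop("fit was run without the mixture extension")
  z <- fit$mixture$Z1_mean
  M <- length(z)
  k <- round(M * pi1_mode(fit))
  cls <- rep("strong", M)
  if (k > 0) cls[order(z, decreasing = TRUE)[seq_len(min(k, M))]] <- "weak"
  tibble::tibble(trial = seq_len(M), Z1_mean = z, class = cls)
}

#' @export
print.lost_fit <- function(x, ...) {
  cat(sprintf("<lost_fit> %d trials x %d bins, %d iterations (%d kept)\n",
              nrow(x$raster$y), ncol(x$raster$y),
              x$config$iterations, x$n_kept))
  tr <- x$trace[x$trace$iteration > x$config$burn_in, ]
  if (nrow(tr))
    cat(sprintf("  slowest pair: %.2f Hz (sd %.2f), modulus %.4f; latent amplitude %.3f\n",
                mean(tr$freq_hz), sd(tr$freq_hz), mean(tr$modulus),
                mean(tr$amplitude)))
  invisible(x)
}
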