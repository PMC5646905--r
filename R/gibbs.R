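#' Priors for the LOST sampler
#'
#' Gaussian priors for the trial offsets, spline weights and mixture
#' strength are broad and centred at zero (at `s0` for the mixture
#' strength); the innovation-variance prior is a conjugate inverse gamma
#' with small shape/scale so that small variances remain reachable.
#'
#' @param mu_var trial-offset prior variance (free components).
#' @param v_var,alpha_var history / TAE weight prior variances.
#' @param a_sig,b_sig inverse-gamma shape/scale hyperparameters for the
#'   innovation variance.
#' @param s0 fixed weak-trial modulation strength.
#' @param s1_var prior variance of the strong-trial strength (mean `s0`;
#'   the conditional is truncated below at `s0`, since the strongly
#'   modulated class is by definition at least as modulated as the weak
#'   one — without the truncation the sign and scale of `(s1, x)` are
#'   unidentified whenever one class empties, and the chain can freeze in
#'   a corner with a runaway latent amplitude).
#' @param alpha_pi Dirichlet hyperparameters for the mixture weights.
#' @export
lost_priors <- function(mu_var = 100, v_var = 25, alpha_var = 25,
                        a_sig = 0.001, b_sig = 1e-6,
                        s0 = 0.1, s1_var = 1, alpha_pi = c(1, 1)) {
  list(mu_var = mu_var, v_var = v_var, alpha_var = alpha_var,
       a_sig = a_sig, b_sig = b_sig, s0 = s0, s1_var = s1_var,
       alpha_pi = alpha_pi)
}

#' Sampler control settings
#'
#' @param init_var broad diagonal initial state covariance for the forward
#'   filter.
#' @param modulus_prior structural prior interval for the slowest complex
#'   pair's modulus.
#' @param psi_clip tilting arguments beyond this magnitude are clipped (for
#'   the Polya-Gamma draw only) with a warning.
#' @param backward `"rank1"` or `"dense"` backward sampling.
#' @param warmup Polya-Gamma/latent-path alternation cycles run before the
#'   main loop, with the AR components and every other parameter held at
#'   their initial values. The very first latent draw is made with
#'   Polya-Gamma weights computed at `x = 0`, which overshoots; letting the
#'   (omega, X) pair equilibrate first keeps that transient from being
#'   burned into the roots.
#' @param progress print progress every this many iterations (0 = quiet).
#' @export
lost_control <- function(init_var = 1.0, modulus_prior = c(0.97, 1),
                         psi_clip = 30, backward = "rank1", warmup = 25,
                         progress = 0) {
  list(init_var = init_var, modulus_prior = modulus_prior,
       psi_clip = psi_clip, backward = backward, warmup = warmup,
       progress = progress)
}

#' Conditional draw of the trial offsets
#'
#' The offsets are constrained to sum to zero; the M - 1 free components
#' (trials 2..M) have a Gaussian conditional whose precision couples every
#' pair of trials through trial 1's Polya-Gamma weights. With one trial the
#' offset is identically zero.
#'
#' @param omega M x N Polya-Gamma field.
#' @param resid M x N residual \eqn{\kappa/\omega} minus every predictor
#'   except the offsets.
#' @param prior_var prior variance of each free offset.
#' @return length-M offset vector summing to zero.
#' @export
sample_offsets <- function(omega, resid, prior_var = 100) {
  M <- nrow(omega)
  if (M == 1L) return(0)
  sw <- rowSums(omega)                 # sum_n omega_mn
  swr <- rowSums(omega * resid)        # sum_n omega_mn R_mn
  P <- matrix(sw[1L], M - 1L, M - 1L)
  diag(P) <- sw[1L] + sw[-1L]
  diag(P) <- diag(P) + 1 / prior_var
  b <- swr[-1L] - swr[1L]
  ch <- chol(P)
  mean_free <- backsolve(ch, forwardsolve(t(ch), b))
  free <- mean_free + backsolve(ch, rnorm(M - 1L))
  c(-sum(free), free)
}

#' Conditional draw of spline weights (shared quadratic form)
#'
#' Both the spike-history and TAE conditionals are Gaussian with precision
#' `basis %*% diag(wt) %*% t(basis) + prior precision` and right-hand side
#' `basis %*% g + prior`, where `wt` and `g` are Polya-Gamma-weighted
#' per-column accumulations of the residuals. Fixed components are held at
#' their values and moved to the right-hand side.
#'
#' @param sm a `spline_model` (its `weights` supply the fixed values).
#' @param wt per-column total Polya-Gamma weight.
#' @param g per-column total of `omega * residual`.
#' @return updated weight vector (fixed components untouched).
#' @export
sample_spline_weights <- function(sm, wt, g) {
  B <- sm$basis
  K <- nrow(B)
  Prec <- (B * rep(wt, each = K)) %*% t(B) + diag(1 / sm$prior_var, K)
  rhs <- as.numeric(B %*% g) + sm$prior_mean / sm$prior_var
  a <- sm$adjustable_idx
  if (!length(a)) return(sm$weights)
  f <- sm$fixed_idx
  rhs_a <- rhs[a]
  if (length(f)) rhs_a <- rhs_a - as.numeric(Prec[a, f, drop = FALSE] %*% sm$weights[f])
  Paa <- Prec[a, a, drop = FALSE]
  ch <- chol(Paa)
  mean_a <- backsolve(ch, forwardsolve(t(ch), rhs_a))
  w <- sm$weights
  w[a] <- mean_a + backsolve(ch, rnorm(length(a)))
  w
}

#' Conditional draw of the innovation variance
#'
#' Inverse-gamma draw with shape \eqn{(a + d + 2)/2} and scale
#' \eqn{b + \mathrm{SS}/2}, where `d` is the number of one-step AR residuals
#' and `SS` their sum of squares.
#'
#' @param ss residual sum of squares.
#' @param df residual count.
#' @param a_sig,b_sig prior shape/scale.
#' @export
sample_sigma2 <- function(ss, df, a_sig = 0.001, b_sig = 1e-6) {
  shape <- (a_sig + df + 2) / 2
  scale <- b_sig + ss / 2
  1 / rgamma(1L, shape = shape, rate = scale)
}

# log-likelihood of one trial under modulation strength s (mixture, Eq-42 form)
trial_loglik_scaled <- function(y_m, x_m, eta_m, s) {
  lp <- s * x_m + eta_m
  sum(ifelse(y_m == 1L, plogis(lp, log.p = TRUE), plogis(-lp, log.p = TRUE)))
}

#' Mixture conditionals: strength, indicators, weights
#'
#' `sample_s1` draws the strong-class modulation strength from its Gaussian
#' conditional (sums over strongly modulated trials) combined with the
#' N(`s0`, large) prior; `sample_Z` draws each trial's class from the
#' two-category multinomial whose weights are the class likelihoods times
#' the mixture weights; `sample_pi_mix` draws the weights from the
#' Dirichlet with prior counts `alpha_pi` plus class totals.
#'
#' @param omega,x,eta M x N matrices (`eta` = predictors except `s x`).
#' @param kappa M x N matrix `y - 1/2`.
#' @param strong logical vector: trials currently in the strong class.
#' @param s0,s1 weak / strong strengths.
#' @param s1_var prior variance of `s1` (prior mean `s0`).
#' @name mixture_conditionals
#' @export
sample_s1 <- function(omega, x, eta, kappa, strong, s0 = 0.1, s1_var = 1) {
  if (!any(strong)) {
    return(rtruncnorm1(s0, sqrt(s1_var), s0, Inf))
  }
  om <- omega[strong, , drop = FALSE]
  xs <- x[strong, , drop = FALSE]
  A <- 0.5 * sum(om * xs^2)
  B <- sum(om * xs * (kappa[strong, , drop = FALSE] / om - eta[strong, , drop = FALSE]))
  prec <- 2 * A + 1 / s1_var
  mean <- (B + s0 / s1_var) / prec
  rtruncnorm1(mean, sqrt(1 / prec), s0, Inf)
}

#' @rdname mixture_conditionals
#' @param y M x N binary matrix.
#' @param pi_mix length-2 mixture weights.
#' @export
sample_Z <- function(y, x, eta, pi_mix, s0, s1) {
  M <- nrow(y)
  strong <- logical(M)
  for (m in seq_len(M)) {
    l0 <- log(pi_mix[1L]) + trial_loglik_scaled(y[m, ], x[m, ], eta[m, ], s0)
    l1 <- log(pi_mix[2L]) + trial_loglik_scaled(y[m, ], x[m, ], eta[m, ], s1)
    p1 <- 1 / (1 + exp(l0 - l1))
    strong[m] <- runif(1L) < p1
  }
  strong
}

#' @rdname mixture_conditionals
#' @details `sample_Z_collapsed` draws the indicators with the latent paths
#'   integrated out: each trial's class weight is the mixture weight times
#'   the Kalman marginal likelihood of its Gaussian pseudo-observations
#'   under observation gain `s_j` (prediction-error decomposition). The
#'   conditioned-on-`x` form (`sample_Z`) cannot separate the classes in
#'   practice, because each trial's own path rescales to fit whatever class
#'   it currently carries; the collapsed form judges both classes against
#'   the shared latent prior.
#' @param pobs_t,pobs_r unscaled pseudo-observation pieces
#'   (`pobs_t = kappa/omega - eta`, `pobs_r = 1/omega`).
#' @param comp an [ar_components()].
#' @param init_var initial state variance of the filter.
#' @export
sample_Z_collapsed <- function(pobs_t, pobs_r, comp, pi_mix, s0, s1,
                               init_var = 1) {
  M <- nrow(pobs_t)
  strong <- logical(M)
  for (m in seq_len(M)) {
    l0 <- log(pi_mix[1L]) + .kalman_loglik(pobs_t[m, ], pobs_r[m, ],
                                           comp$coeffs, comp$sigma2,
                                           init_var, s0)
    l1 <- log(pi_mix[2L]) + .kalman_loglik(pobs_t[m, ], pobs_r[m, ],
                                           comp$coeffs, comp$sigma2,
                                           init_var, s1)
    strong[m] <- runif(1L) < 1 / (1 + exp(l0 - l1))
  }
  strong
}

#' @rdname mixture_conditionals
#' @param alpha_pi Dirichlet hyperparameters.
#' @param strong logical class indicator vector.
#' @export
sample_pi_mix <- function(strong, alpha_pi = c(1, 1)) {
  cnt <- c(sum(!strong), sum(strong))
  g <- rgamma(2L, shape = alpha_pi + cnt, rate = 1)
  g / sum(g)
}
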