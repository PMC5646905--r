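#' Gaussian pseudo-observations from Polya-Gamma augmentation
#'
#' Conditional on the Polya-Gamma field, each binary observation becomes a
#' continuous pseudo-observation of the latent state,
#' \eqn{t_{mn} = \kappa_{mn}/\omega_{mn} - \eta_{mn}} with noise variance
#' \eqn{r_{mn} = 1/\omega_{mn}}, where \eqn{\kappa = y - 1/2} and
#' \eqn{\eta} collects every predictor except the latent state (TAE, trial
#' offset, spike history, any known signal). The mixture variant rescales
#' both by the per-trial modulation strength `s` (observations are then of
#' `s x`): `t -> t / s`, `r -> 1/(omega s^2)`.
#'
#' @param kappa M x N matrix `y - 1/2`.
#' @param omega M x N positive Polya-Gamma draws.
#' @param eta M x N (or conformable) predictor excluding the latent state.
#' @param s per-trial modulation strengths (default 1).
#' @return list with matrices `t` and `r`.
#' @export
pseudo_observations <- function(kappa, omega, eta = 0, s = 1) {
  if (any(omega <= 0)) stop("omega must be positive everywhere")
  s <- rep(s, length.out = nrow(kappa))
  t <- (kappa / omega - eta) / s
  r <- 1 / (omega * s^2)
  if (any(!is.finite(t))) stop("non-finite pseudo-observation")
  list(t = t, r = r)
}

#' Forward-filter backward-sample of the latent AR(p) paths
#'
#' Draws whole latent paths from their joint conditional given the
#' pseudo-observations, independently per trial. The forward pass is a
#' Kalman filter on the companion form (scalar observation of the first
#' state component, rank-1 innovation covariance); the backward pass samples
#' the path from the smoothing distribution. By default the backward step
#' uses the rank-one form implied by the degenerate companion transition --
#' conditioning on the already-sampled `X_{n+1}` fixes all but the oldest
#' lag of `X_n`, leaving one scalar draw per bin -- which is algebraically
#' the Sherman-Morrison reduction of the dense step and costs O(p^2) per
#' bin. `method = "dense"` uses the textbook gain
#' \eqn{A = V F^T (F V F^T + Q)^{-1}} with explicit inversion, retained so
#' the reduction itself is testable.
#'
#' @param pobs list with `t`, `r` (M x N) from [pseudo_observations()].
#' @param comp an [ar_components()] (stationary).
#' @param init_var diagonal value of the broad initial state covariance.
#' @param method `"rank1"` (default) or `"dense"`.
#' @param deterministic if TRUE, propagate conditional means instead of
#'   sampling (the result is the fixed-interval smoother mean; used in
#'   tests).
#' @return list: `x` (M x N sampled paths), `X0` (M x p pre-trial states
#'   `(x_0, x_{-1}, ..., x_{1-p})`, drawn from the initial prior conditioned
#'   on the path so every innovation including the first bin's is defined),
#'   `filt_var1` (M x N forward filtered variance of the current-bin
#'   component).
#' @export
ffbs_sample <- function(pobs, comp, init_var = 1.0,
                        method = c("rank1", "dense"), deterministic = FALSE) {
  method <- match.arg(method)
  M <- nrow(pobs$t); N <- ncol(pobs$t); p <- comp$p
  x <- matrix(0, M, N)
  X0 <- matrix(0, M, p)
  fv <- matrix(0, M, N)
  for (m in seq_len(M)) {
    res <- .ffbs_trial(pobs$t[m, ], pobs$r[m, ], comp$coeffs, comp$sigma2,
                       init_var, method == "dense", deterministic)
    x[m, ] <- res$x
    X0[m, ] <- res$X0
    fv[m, ] <- res$filt_var1
  }
  list(x = x, X0 = X0, filt_var1 = fv)
}

# extended path: prepend the p pre-trial values (oldest first), so the AR
# innovation at every observed bin -- the first included -- is recomputable
extend_paths <- function(x, X0) {
  p <- ncol(X0)
  pre <- X0[, p:1, drop = FALSE]  # X0 = (x_0, x_{-1}, ..., x_{1-p}); oldest first
  cbind(pre, x)
}
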