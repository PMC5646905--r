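#' Stochastic irregular oscillation
#'
#' Generates per-trial modulation signals
#' \deqn{w_{mn} = 1 + d\,A_{mn}\sin(2\pi\nu t_{mn}),\qquad
#'       t_{m,n+1} = t_{mn} + \Delta t\,(1 + \xi_{mn} C_\xi),}
#' where the phase-rate perturbation \eqn{\xi} and the amplitude envelope
#' \eqn{A = 1 + C_A \eta} are driven by stationary unit-variance AR(1)
#' processes \eqn{\xi,\eta} with correlation times `ar1_timescales`
#' (coefficient \eqn{a = e^{-\Delta t/\tau}}). The phase-origin `t[m, 1]` is
#' uniform on \eqn{[0, 1]} so trials are not phase-aligned. With
#' `C_xi = C_A = 0` the signal is an exact unit-amplitude sinusoid offset by
#' one and its OCV (see [compute_ocv()]) is zero; `C_xi` makes the period
#' irregular and `C_A` makes the envelope wander.
#'
#' `depth` scales the whole oscillatory term and therefore sets the
#' modulation strength on the log-odds (renewal) or drive (LIF) scale.
#'
#' @param nu nominal frequency, Hz.
#' @param C_xi,C_A phase / amplitude perturbation scales (>= 0).
#' @param depth overall modulation depth multiplying the oscillatory term.
#' @param ar1_timescales length-2 correlation times (s) for \eqn{\xi} and
#'   \eqn{\eta}; a scalar is recycled. Defaults to one nominal period each.
#' @param M,N trials, bins.
#' @param dt bin width, s.
#' @param seed optional integer seed (applied with [set.seed()]).
#' @return An object of class `oscillation`: list with matrices `w`, `phase`
#'   (radians in \eqn{[0, 2\pi)}), `t`, `amp`, plus the parameters.
#' @export
gen_oscillation <- function(nu, C_xi = 0, C_A = 0, depth = 1,
                            ar1_timescales = NULL, M, N, dt, seed = NULL) {
  if (!(dt > 0) || !(nu > 0)) stop("dt and nu must be positive")
  if (C_xi < 0 || C_A < 0) stop("perturbation scales must be non-negative")
  if (!is.null(seed)) set.seed(seed)
  if (is.null(ar1_timescales)) ar1_timescales <- 1 / nu
  ts <- rep(ar1_timescales, length.out = 2L)

  xi  <- ar1_matrix(M, N, exp(-dt / ts[1L]))
  eta <- ar1_matrix(M, N, exp(-dt / ts[2L]))
  amp <- 1 + C_A * eta

  t <- matrix(0, M, N)
  t[, 1L] <- runif(M)
  step <- dt * (1 + xi * C_xi)
  for (n in seq_len(N - 1L)) t[, n + 1L] <- t[, n] + step[, n]

  w <- 1 + depth * amp * sin(2 * pi * nu * t)
  structure(
    list(w = w, phase = (2 * pi * nu * t) %% (2 * pi), t = t, amp = amp,
         nu = nu, C_xi = C_xi, C_A = C_A, depth = depth,
         ar1_timescales = ts, dt = dt),
    class = "oscillation")
}

# M x N matrix of independent stationary AR(1) rows with unit variance
ar1_matrix <- function(M, N, a) {
  innov_sd <- sqrt(1 - a^2)
  x <- matrix(0, M, N)
  x[, 1L] <- rnorm(M)
  for (n in seq_len(N - 1L)) x[, n + 1L] <- a * x[, n] + innov_sd * rnorm(M)
  x
}

#' @export
print.oscillation <- function(x, ...) {
  cat(sprintf(
    "<oscillation> %d trials x %d bins, nu = %g Hz, C_xi = %g, C_A = %g, depth = %g\n",
    nrow(x$w), ncol(x$w), x$nu, x$C_xi, x$C_A, x$depth))
  invisible(x)
}

#' @method as_tibble oscillation
#' @export
as_tibble.oscillation <- function(x, ...) {
  M <- nrow(x$w); N <- ncol(x$w)
  tibble::tibble(
    trial = rep(seq_len(M), times = N),
    time = rep((seq_len(N) - 1) * x$dt, each = M),
    w = as.numeric(x$w), phase = as.numeric(x$phase))
}

#' Trial-specific square-wave slow offsets
#'
#' Two-level signal per trial: state durations are exponential with the
#' stated means, truncated below at `min_duration` (default 100 ms), and the
#' duty cycle sets the occupancy of the high state (high/low mean durations
#' are `2 * duty * mean_state_duration` and `2 * (1 - duty) *
#' mean_state_duration`). Because the waves are independent across trials,
#' averaging many trials gives an approximately flat trial-average (flat
#' PSTH), so the slow structure is invisible to event-locked averaging.
#'
#' @param duty high-state occupancy, in (0, 1).
#' @param mean_state_duration overall mean state duration, s.
#' @param min_duration minimum state duration, s.
#' @param levels numeric length-2 `(low, high)` signal values.
#' @param M,N,dt trials, bins, bin width (s).
#' @param seed optional seed.
#' @return M x N matrix of offsets with attribute `"state"` (0/1 matrix).
#' @export
gen_square_wave_offsets <- function(duty = 0.5, mean_state_duration = 0.25,
                                    min_duration = 0.1, levels = c(-0.5, 0.5),
                                    M, N, dt, seed = NULL) {
  if (!(duty > 0 && duty < 1)) stop("duty must be in (0, 1)")
  if (min_duration < dt) stop("min_duration must be at least dt")
  if (!is.null(seed)) set.seed(seed)
  mean_hi <- 2 * duty * mean_state_duration
  mean_lo <- 2 * (1 - duty) * mean_state_duration
  state <- matrix(0L, M, N)
  for (m in seq_len(M)) {
    s <- as.integer(runif(1) < duty)
    n <- 1L
    while (n <= N) {
      mn <- if (s == 1L) mean_hi else mean_lo
      dur <- max(rexp(1, 1 / mn), min_duration)
      len <- max(1L, round(dur / dt))
      idx <- n:min(N, n + len - 1L)
      state[m, idx] <- s
      n <- n + len
      s <- 1L - s
    }
  }
  out <- matrix(levels[1L], M, N)
  out[state == 1L] <- levels[2L]
  attr(out, "state") <- state
  out
}
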