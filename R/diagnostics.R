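#' Oscillatory coefficient of variation
#'
#' Irregularity of an oscillation: the ratio of the standard deviation to
#' the mean of the time intervals between successive upward crossings of the
#' phase-0 level (the signal mean by default; 1 for modulation signals
#' generated around 1). Crossing times are linearly interpolated; intervals
#' are pooled across trials (rows).
#'
#' @param signal numeric vector or trials-by-bins matrix.
#' @param dt bin width, s.
#' @param level crossing level; default the signal mean.
#' @return OCV (scalar); attribute `"periods"` holds the intervals (s).
#' @export
compute_ocv <- function(signal, dt, level = NULL) {
  m <- if (is.matrix(signal)) signal else matrix(signal, 1L)
  if (is.null(level)) level <- mean(m)
  periods <- unlist(lapply(seq_len(nrow(m)), function(i) {
    s <- m[i, ] - level
    n <- length(s)
    up <- which(s[-n] < 0 & s[-1L] >= 0)
    if (length(up) < 3L) return(numeric(0))
    tc <- (up + (-s[up]) / (s[up + 1L] - s[up])) * dt
    diff(tc)
  }), use.names = FALSE)
  if (length(periods) < 2L)
    stop("signal crosses its phase-0 level fewer than 3 times")
  structure(sd(periods) / mean(periods), periods = periods)
}

#' Instantaneous phase by the analytic signal
#'
#' Mean-removes each trial, optionally zero-phase band-pass filters it
#' (forward-backward Butterworth), and takes the argument of the analytic
#' (Hilbert) signal. Phase 0 is at the upward crossing of the signal mean;
#' values lie in \eqn{[0, 2\pi)}.
#'
#' @param signal numeric vector or trials-by-bins matrix.
#' @param dt bin width, s.
#' @param band NULL or length-2 band edges in Hz.
#' @return matrix (or vector) of phases, same shape as `signal`.
#' @export
extract_phase <- function(signal, dt, band = NULL) {
  vec <- !is.matrix(signal)
  m <- if (vec) matrix(signal, 1L) else signal
  if (any(!is.finite(m))) stop("signal must be finite")
  out <- matrix(0, nrow(m), ncol(m))
  for (i in seq_len(nrow(m))) {
    s <- m[i, ] - mean(m[i, ])
    if (!is.null(band)) {
      bf <- signal::butter(2, pmin(pmax(band * 2 * dt, 1e-6), 0.999),
                           type = "pass")
      s <- signal::filtfilt(bf, s)
    }
    # analytic-signal phase: sin-convention, so shift the usual atan2 by pi/2
    out[i, ] <- (Arg(analytic_signal(s)) + pi / 2) %% (2 * pi)
  }
  if (vec) out[1L, ] else out
}

#' Resultant length of phase differences
#'
#' Circular concentration of the pointwise difference between an inferred
#' and a reference phase series:
#' \eqn{L e^{i\Phi} = \frac{1}{N}\sum_j e^{i(\phi_j - \psi_j)}}; `L = 1`
#' means perfect phase tracking, 0 no consistent relationship. Invariant to
#' a common constant phase shift of both series.
#'
#' @param phi,psi phase series (radians), equal shape; series are pooled
#'   over all elements (trials concatenated).
#' @return named vector `c(L, Phi)`.
#' @export
resultant_length <- function(phi, psi) {
  if (length(phi) != length(psi)) stop("phase series must have equal length")
  z <- mean(exp(1i * (as.numeric(phi) - as.numeric(psi))))
  c(L = Mod(z), Phi = Arg(z) %% (2 * pi))
}

#' Spike-phase histogram and circular statistic
#'
#' Concentration of the phases at which spikes occur,
#' \eqn{R e^{i\Phi} = \frac{1}{N_{spk}}\sum_n e^{i\phi(t_n)}}; measures
#' phase-locking strength (not phase-tracking accuracy).
#'
#' @param raster a [spike_raster()].
#' @param phase trials-by-bins phase matrix (radians) aligned with the
#'   raster.
#' @param nbins histogram bin count.
#' @return list with `R`, `Phi`, and `histogram` (tibble: bin centre,
#'   count, density).
#' @export
spike_phase_stat <- function(raster, phase, nbins = 16L) {
  idx <- raster$y == 1L
  if (!any(idx)) stop("raster contains no spikes")
  ph <- phase[idx] %% (2 * pi)
  z <- mean(exp(1i * ph))
  br <- seq(0, 2 * pi, length.out = nbins + 1L)
  cnt <- hist(ph, breaks = br, plot = FALSE)$counts
  list(R = Mod(z), Phi = Arg(z) %% (2 * pi),
       histogram = tibble::tibble(
         phase = (br[-1L] + br[-(nbins + 1L)]) / 2,
         count = cnt, density = cnt / sum(cnt) / diff(br)[1L]))
}

#' Convergence rules of thumb for a LOST chain
#'
#' Deterministic flags over a trace window: the frequency is considered
#' certain when its SD is at most 10% of its mean; the modulus when its SD
#' is below 0.005; and the latent state is considered practically flat when
#' its mean amplitude (SD of the path) is at or below 0.15 -- an amplitude
#' of 0.15 corresponds to a peak-to-peak firing-rate fluctuation of roughly
#' 30% of the mean at low rates, about the smallest modulation worth calling
#' an oscillation.
#'
#' @param trace a `lost_fit` trace (or the fit itself).
#' @param window iterations to use, counted from the end.
#' @return tibble with the summary statistics and logical flags.
#' @export
assess_convergence <- function(trace, window = NULL) {
  if (inherits(trace, "lost_fit")) {
    if (is.null(window))
      window <- trace$config$iterations - trace$config$burn_in
    trace <- trace$trace
  }
  if (is.null(window)) window <- nrow(trace)
  if (window > nrow(trace)) stop("window exceeds trace length")
  tr <- trace[(nrow(trace) - window + 1L):nrow(trace), ]
  freq_sd_over_mean <- sd(tr$freq_hz) / mean(tr$freq_hz)
  modulus_sd <- sd(tr$modulus)
  amplitude_mean <- mean(tr$amplitude)
  tibble::tibble(
    freq_mean = mean(tr$freq_hz), freq_sd_over_mean = freq_sd_over_mean,
    modulus_mean = mean(tr$modulus), modulus_sd = modulus_sd,
    amplitude_mean = amplitude_mean,
    frequency_certain = freq_sd_over_mean <= 0.10,
    modulus_certain = modulus_sd < 0.005,
    amplitude_nontrivial = amplitude_mean > 0.15)
}

#' Bootstrap standard error by trial resampling
#'
#' Recomputes a metric on `B` datasets formed by resampling trials with
#' replacement and reports the SD across replicates.
#'
#' @param metric function of a trial index vector returning a scalar (it
#'   should subset whatever per-trial objects it closes over).
#' @param M number of trials.
#' @param B replicates.
#' @param seed optional seed.
#' @export
bootstrap_error <- function(metric, M, B = 1000L, seed = NULL) {
  if (M < 2L) stop("need at least 2 trials")
  if (!is.null(seed)) set.seed(seed)
  reps <- vapply(seq_len(B), function(b) {
    metric(sample.int(M, M, replace = TRUE))
  }, numeric(1))
  sd(reps)
}

# analytic signal (Hilbert transform) via the FFT half-spectrum doubling
analytic_signal <- function(s) {
  n <- length(s)
  H <- fft(s)
  h <- numeric(n)
  h[1L] <- 1
  if (n %% 2 == 0) {
    h[n / 2 + 1L] <- 1
    h[2:(n / 2)] <- 2
  } else {
    h[2:((n + 1) / 2)] <- 2
  }
  fft(H * h, inverse = TRUE) / n
}

#' Welch-style power spectral density
#'
#' Averaged modified periodograms over Hann-windowed segments; used to
#' summarise the spectral content of latent paths.
#'
#' @param x numeric vector or trials-by-bins matrix (rows averaged).
#' @param dt bin width, s.
#' @param nseg segments per row.
#' @return tibble with `freq` (Hz) and `power`.
#' @export
spectrum_welch <- function(x, dt, nseg = 4L) {
  m <- if (is.matrix(x)) x else matrix(x, 1L)
  L <- floor(ncol(m) / nseg)
  win <- 0.5 * (1 - cos(2 * pi * seq_len(L) / (L + 1)))
  nf <- floor(L / 2)
  acc <- numeric(nf)
  cnt <- 0L
  for (i in seq_len(nrow(m))) for (s in seq_len(nseg)) {
    seg <- m[i, ((s - 1L) * L + 1L):(s * L)]
    seg <- (seg - mean(seg)) * win
    P <- Mod(fft(seg))^2
    acc <- acc + P[2:(nf + 1L)]
    cnt <- cnt + 1L
  }
  tibble::tibble(freq = (seq_len(nf)) / (L * dt), power = acc / cnt)
}
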