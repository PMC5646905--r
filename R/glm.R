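#' Spiking-history GLM baseline
#'
#' The comparison model: a point-process GLM whose conditional intensity is
#' \deqn{\lambda(m, n) = \exp\big(b_0 + \sum_{i=1}^{S} \bar a_i y_{m,n-i}
#'   + \sum_{j=1}^{O} \bar b_j C_{mj}\big),}
#' with `S` fine single-bin history lags and `O` coarse windows of
#' `coarse_width` bins tiling the lags beyond `S`. The fine coefficients
#' capture refractoriness; the coarse ones can encapsulate longer-term
#' oscillatory self-history. An intercept is included so the baseline rate
#' is matched. Fitting is by maximum likelihood (Poisson log link on the
#' binary counts).
#'
#' @param raster a [spike_raster()].
#' @param S fine history length, bins.
#' @param O number of coarse history bins.
#' @param coarse_width coarse bin width, bins (default 20 ms worth).
#' @return object of class `history_glm`: coefficients, the fitted CIF
#'   matrix (Hz; NA over the initial `S + O * coarse_width` bins), history
#'   span and fit diagnostics.
#' @export
fit_history_glm <- function(raster, S, O, coarse_width = NULL) {
  y <- raster$y; dt <- raster$dt
  if (is.null(coarse_width)) coarse_width <- max(1L, round(0.020 / dt))
  M <- nrow(y); N <- ncol(y)
  span <- S + O * coarse_width
  if (span >= N) stop("history span exceeds trial length")
  ns <- (span + 1L):N
  nobs <- length(ns) * M

  X <- matrix(0, nobs, 1L + S + O)
  X[, 1L] <- 1
  yy <- numeric(nobs)
  rowi <- 0L
  for (m in seq_len(M)) {
    ym <- y[m, ]
    idx <- rowi + seq_along(ns)
    yy[idx] <- ym[ns]
    for (i in seq_len(S)) X[idx, 1L + i] <- ym[ns - i]
    cs <- cumsum(ym)
    for (j in seq_len(O)) {
      hi <- ns - S - (j - 1L) * coarse_width   # window upper edge (inclusive)
      lo <- hi - coarse_width + 1L
      X[idx, 1L + S + j] <- cs[hi] - ifelse(lo > 1L, cs[lo - 1L], 0)
    }
    rowi <- rowi + length(ns)
  }

  fit <- glm.fit(X, yy, family = poisson(link = "log"))
  if (!fit$converged) stop("history GLM did not converge")
  beta <- fit$coefficients
  if (anyNA(beta)) stop("history GLM is rank deficient (separation?)")

  cif <- matrix(NA_real_, M, N)
  eta <- as.numeric(X %*% beta)
  rowi <- 0L
  for (m in seq_len(M)) {
    cif[m, ns] <- exp(eta[rowi + seq_along(ns)]) / dt
    rowi <- rowi + length(ns)
  }

  structure(
    list(intercept = beta[1L], a_bar = beta[1L + seq_len(S)],
         b_bar = beta[1L + S + seq_len(O)], S = S, O = O,
         coarse_width = coarse_width, span = span, cif = cif, dt = dt,
         deviance = fit$deviance,
         se = sqrt(diag(chol2inv(fit$qr$qr[seq_len(ncol(X)), , drop = FALSE])))),
    class = "history_glm")
}

#' @export
print.history_glm <- function(x, ...) {
  cat(sprintf("<history_glm> S = %d fine bins, O = %d coarse bins of %d (span %d bins), deviance %.1f\n",
              x$S, x$O, x$coarse_width, x$span, x$deviance))
  invisible(x)
}

#' Time-rescaling goodness of fit
#'
#' Rescales each interspike interval by the integrated conditional
#' intensity, \eqn{z_k = 1 - \exp(-\Lambda_k)}; under the true CIF the
#' `z_k` are Uniform(0, 1). Reports the KS statistic against uniformity and
#' whether it falls inside the standard 95% band \eqn{1.36/\sqrt{K}}.
#'
#' @param raster a [spike_raster()].
#' @param cif trials-by-bins intensity matrix, Hz (NA bins are skipped).
#' @return tibble: `ks`, `band95`, `within_band`, `n_intervals`.
#' @export
time_rescale_ks <- function(raster, cif) {
  y <- raster$y; dt <- raster$dt
  z <- unlist(lapply(seq_len(nrow(y)), function(m) {
    ok <- !is.na(cif[m, ])
    sp <- which(y[m, ] == 1L & ok)
    if (length(sp) < 2L) return(numeric(0))
    cum <- cumsum(ifelse(ok, cif[m, ], 0)) * dt
    Lam <- diff(cum[sp])
    1 - exp(-Lam)
  }), use.names = FALSE)
  if (length(z) < 5L) stop("too few rescaled intervals")
  ks <- suppressWarnings(ks.test(z, "punif"))$statistic
  band <- 1.36 / sqrt(length(z))
  tibble::tibble(ks = as.numeric(ks), band95 = band,
                 within_band = as.numeric(ks) <= band, n_intervals = length(z))
}

#' Oscillation phase from a GLM CIF
#'
#' Low-pass filters the fitted CIF (zero-phase Butterworth) to suppress the
#' fine refractory structure, then takes the analytic-signal phase. By
#' default the cutoff is 1.5 times the dominant spectral peak of the CIF.
#'
#' @param glm_fit a [fit_history_glm()] result (or a CIF matrix with `dt`
#'   given).
#' @param cutoff Hz; NULL for the automatic choice.
#' @param dt bin width when a bare matrix is supplied.
#' @return phase matrix over the bins where the CIF is defined (NA
#'   elsewhere).
#' @export
glm_phase <- function(glm_fit, cutoff = NULL, dt = NULL) {
  if (inherits(glm_fit, "history_glm")) {
    cif <- glm_fit$cif; dt <- glm_fit$dt
  } else cif <- glm_fit
  ok <- which(!is.na(cif[1L, ]))
  sub <- cif[, ok, drop = FALSE]
  if (is.null(cutoff)) {
    ps <- spectrum_welch(sub, dt)
    cutoff <- 1.5 * ps$freq[which.max(ps$power)]
  }
  bf <- signal::butter(2, min(cutoff * 2 * dt, 0.99), type = "low")
  out <- matrix(NA_real_, nrow(cif), ncol(cif))
  for (m in seq_len(nrow(sub))) {
    s <- signal::filtfilt(bf, sub[m, ] - mean(sub[m, ]))
    out[m, ok] <- (Arg(analytic_signal(s)) + pi / 2) %% (2 * pi)
  }
  out
}
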