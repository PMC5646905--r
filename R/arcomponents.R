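#' AR(p) latent process as characteristic roots
#'
#' The latent oscillation is an AR(p) process, parameterised not by its
#' coefficients but by the roots of its characteristic polynomial: `C`
#' complex-conjugate pairs (each an oscillatory AR(2) component with modulus
#' `r` in (0, 1] controlling spectral peakedness and period `lambda` in bins
#' controlling frequency) and `R` real roots in (-1, 1) (non-oscillatory
#' components), so `p = 2C + R`. A pair maps to AR(2) coefficients
#' \eqn{\phi_1 = 2 r \cos(2\pi/\lambda)}, \eqn{\phi_2 = -r^2}.
#'
#' @param periods complex-pair periods, bins.
#' @param moduli complex-pair moduli.
#' @param real_roots real roots.
#' @param sigma2 innovation variance.
#' @return object of class `ar_components` with derived `coeffs` (F_1:p)
#'   and the companion matrix `F`.
#' @export
ar_components <- function(periods = numeric(0), moduli = numeric(0),
                          real_roots = numeric(0), sigma2 = 1e-3) {
  stopifnot(length(periods) == length(moduli))
  comp <- list(periods = as.numeric(periods), moduli = as.numeric(moduli),
               real_roots = as.numeric(real_roots), sigma2 = sigma2)
  comp$p <- 2L * length(periods) + length(real_roots)
  class(comp) <- "ar_components"
  validate_components(comp)
  comp$coeffs <- coeffs_from_roots(comp)
  comp$F <- companion_matrix(comp$coeffs)
  comp
}

validate_components <- function(comp) {
  if (any(comp$moduli <= 0 | comp$moduli > 1))
    stop("complex moduli must lie in (0, 1]")
  if (any(abs(comp$real_roots) >= 1))
    stop("real roots must lie in (-1, 1)")
  if (any(comp$periods <= 2))
    stop("complex-pair periods must exceed 2 bins")
  invisible(comp)
}

#' @export
print.ar_components <- function(x, ...) {
  cat(sprintf("<ar_components> C = %d pairs, R = %d real, p = %d, sigma2 = %.3g\n",
              length(x$periods), length(x$real_roots), x$p, x$sigma2))
  if (length(x$periods))
    cat(sprintf("  pair %d: period %.1f bins, modulus %.4f\n",
                seq_along(x$periods), x$periods, x$moduli), sep = "")
  if (length(x$real_roots))
    cat("  real roots:", paste(signif(x$real_roots, 4), collapse = ", "), "\n")
  invisible(x)
}

# AR(2) coefficients of one complex pair
pair_phi <- function(r, lambda) c(2 * r * cos(2 * pi / lambda), -r^2)

# modulus/period implied by AR(2) coefficients in the complex region
phi_to_pair <- function(phi1, phi2) {
  r <- sqrt(-phi2)
  ang <- acos(pmin(pmax(phi1 / (2 * r), -1), 1))
  c(modulus = r, period = 2 * pi / ang)
}

#' Coefficients from roots (Vieta expansion)
#'
#' Expands the product of backshift factors
#' \eqn{\prod_r (1 - \alpha_r B) \prod_c (1 - \gamma_c B)(1 - \gamma_c^* B)}
#' and returns the AR coefficients `F_1:p` (the negated polynomial
#' coefficients of `B^i`).
#'
#' @param comp an [ar_components()] (or bare list with `periods`, `moduli`,
#'   `real_roots`).
#' @return numeric vector `F_1:p`.
#' @export
coeffs_from_roots <- function(comp) {
  poly <- 1
  for (j in seq_along(comp$periods)) {
    phi <- pair_phi(comp$moduli[j], comp$periods[j])
    poly <- poly_mult(poly, c(1, -phi[1L], -phi[2L]))
  }
  for (a in comp$real_roots) poly <- poly_mult(poly, c(1, -a))
  -poly[-1L]
}

poly_mult <- function(a, b) {
  out <- numeric(length(a) + length(b) - 1L)
  for (i in seq_along(a)) out[i:(i + length(b) - 1L)] <- out[i:(i + length(b) - 1L)] + a[i] * b
  out
}

#' @rdname coeffs_from_roots
#' @param coeffs AR coefficient vector `F_1:p`.
#' @return `roots_from_coeffs()`: complex vector of characteristic roots
#'   \eqn{\gamma} (eigenvalues of the companion matrix).
#' @export
roots_from_coeffs <- function(coeffs) {
  1 / polyroot(c(1, -coeffs))
}

#' @rdname coeffs_from_roots
#' @export
companion_matrix <- function(coeffs) {
  p <- length(coeffs)
  F <- matrix(0, p, p)
  F[1L, ] <- coeffs
  if (p > 1L) F[cbind(2:p, 1:(p - 1L))] <- 1
  F
}

# index of the slowest complex pair (largest period)
slowest_pair <- function(comp) {
  if (!length(comp$periods)) return(NA_integer_)
  which.max(comp$periods)
}

#' Correlated residuals with one component removed
#'
#' Applies the product of all retained roots' backshift filters to the
#' latent path, leaving the series that the removed component alone should
#' explain (an AR(2) for a removed complex pair, AR(1) for a removed real
#' root). `leave_out = NULL` applies every factor and returns the full AR
#' residuals.
#'
#' @param x_ext M x (N + p - 1) latent paths, each row prepended with its
#'   sampled pre-trial lags (oldest first... see [lost_fit()]); a bare M x N
#'   matrix also works, at the cost of `p - 1` lost bins.
#' @param comp an [ar_components()].
#' @param leave_out `list(type = "complex"|"real", index = j)` or NULL.
#' @return matrix of filtered series (trials in rows).
#' @export
component_residuals <- function(x_ext, comp, leave_out = NULL) {
  poly <- 1
  for (j in seq_along(comp$periods)) {
    if (!is.null(leave_out) && leave_out$type == "complex" && leave_out$index == j) next
    phi <- pair_phi(comp$moduli[j], comp$periods[j])
    poly <- poly_mult(poly, c(1, -phi[1L], -phi[2L]))
  }
  for (j in seq_along(comp$real_roots)) {
    if (!is.null(leave_out) && leave_out$type == "real" && leave_out$index == j) next
    poly <- poly_mult(poly, c(1, -comp$real_roots[j]))
  }
  if (length(poly) == 1L) return(x_ext * poly)
  .fir_filter(as.matrix(x_ext), poly)
}

# 1-D truncated normal by inverse CDF, numerically guarded
rtruncnorm1 <- function(mean, sd, lo, hi) {
  plo <- pnorm(lo, mean, sd)
  phi <- pnorm(hi, mean, sd)
  if (phi - plo < 1e-12) {
    # far tail: fall back to the nearer boundary region
    return(min(max(mean, lo + 1e-10), hi - 1e-10))
  }
  qnorm(runif(1, plo, phi), mean, sd)
}

#' Conditional draw of one complex pair
#'
#' Given the residual series with this pair removed, the pair's AR(2)
#' coefficients have a Gaussian conditional (lag-2 regression form) which is
#' truncated to the complex-root region \eqn{\{\phi_1^2/4 + \phi_2 < 0,\
#' \phi_2 > -1\}} and, when `modulus_range` is supplied (the slowest pair's
#' structural prior), to moduli in that interval. Sampling is by rejection
#' from the untruncated Gaussian with a Gibbs-within-Gibbs fallback of 1-D
#' truncated normals when the acceptance rate collapses.
#'
#' @param w residual matrix (trials in rows) from [component_residuals()].
#' @param sigma2 innovation variance.
#' @param modulus_range NULL or length-2 interval for the modulus.
#' @param current current `c(phi1, phi2)` (Gibbs fallback start).
#' @param max_tries rejection budget before falling back.
#' @return named vector `c(phi1, phi2, modulus, period)`.
#' @export
sample_complex_pair <- function(w, sigma2, modulus_range = NULL,
                                current = NULL, max_tries = 200L) {
  w <- as.matrix(w)
  K <- ncol(w)
  if (K < 4L) stop("residual series too short")
  st <- .lag2_stats(w)
  DtD <- matrix(c(st[1L], st[2L], st[2L], st[3L]), 2L, 2L)
  if (rcond(DtD) < 1e-12)
    stop("degenerate residual series: design is (numerically) singular")
  h <- solve(DtD, c(st[4L], st[5L]))
  S <- sigma2 * solve(DtD)
  ch <- chol(S)

  lo2 <- if (is.null(modulus_range)) 0 else modulus_range[1L]^2
  hi2 <- if (is.null(modulus_range)) 1 else modulus_range[2L]^2
  ok <- function(p1, p2) {
    p1^2 / 4 + p2 < 0 && p2 > -1 && -p2 >= lo2 && -p2 <= hi2
  }

  for (i in seq_len(max_tries)) {
    cand <- as.numeric(h + t(ch) %*% rnorm(2))
    if (ok(cand[1L], cand[2L])) {
      pr <- phi_to_pair(cand[1L], cand[2L])
      return(c(phi1 = cand[1L], phi2 = cand[2L], pr))
    }
  }

  # Gibbs-within-Gibbs on the two coordinates with 1-D truncations
  cur <- current
  if (is.null(cur) || !ok(cur[1L], cur[2L])) {
    r0 <- sqrt((lo2 + hi2) / 2)
    cur <- pair_phi(min(max(r0, 1e-3), 1 - 1e-6), 8)
    if (!ok(cur[1L], cur[2L])) cur <- c(0, -(lo2 + hi2) / 2)
  }
  P <- chol2inv(chol(S))  # precision
  for (sweep in 1:10) {
    # phi1 | phi2: |phi1| < 2 sqrt(-phi2)
    b <- 2 * sqrt(-cur[2L])
    m1 <- h[1L] - P[1L, 2L] / P[1L, 1L] * (cur[2L] - h[2L])
    s1 <- sqrt(1 / P[1L, 1L])
    cur[1L] <- rtruncnorm1(m1, s1, -b, b)
    # phi2 | phi1: max(-1, -hi2) < phi2 < min(-phi1^2/4, -lo2)
    lo <- max(-1, -hi2)
    hi <- min(-cur[1L]^2 / 4, -lo2)
    if (hi <= lo) { cur[1L] <- cur[1L] * 0.5; next }
    m2 <- h[2L] - P[1L, 2L] / P[2L, 2L] * (cur[1L] - h[1L])
    s2 <- sqrt(1 / P[2L, 2L])
    cur[2L] <- rtruncnorm1(m2, s2, lo, hi)
  }
  pr <- phi_to_pair(cur[1L], cur[2L])
  c(phi1 = cur[1L], phi2 = cur[2L], pr)
}

#' Conditional draw of one real root
#'
#' Lag-1 regression form: mean \eqn{\sum u_n u_{n-1} / \sum u_{n-1}^2},
#' variance \eqn{\sigma^2 / \sum u_{n-1}^2}, truncated to (-1, 1).
#'
#' @param u residual matrix (trials in rows) with this root removed.
#' @param sigma2 innovation variance.
#' @param range truncation interval (structural prior; default the full
#'   stationary range).
#' @return scalar draw inside `range`.
#' @export
sample_real_root <- function(u, sigma2, range = c(-1, 1)) {
  u <- as.matrix(u)
  st <- .lag1_stats(u)
  sxx <- st[1L]
  if (sxx <= 0) stop("all-zero residual series")
  m <- st[2L] / sxx
  s <- sqrt(sigma2 / sxx)
  rtruncnorm1(m, s, max(range[1L], -1 + 1e-10), min(range[2L], 1 - 1e-10))
}

#' One full root sweep
#'
#' Updates every complex pair and real root in turn from its conditional,
#' holding the others fixed, with the modulus prior applied to the slowest
#' pair (re-identified as the largest-period pair before each update so that
#' label switching cannot detach the prior from the slow component).
#'
#' @param x_ext latent paths with pre-trial lags prepended (see
#'   [component_residuals()]).
#' @param comp an [ar_components()].
#' @param modulus_prior interval for the slowest pair's modulus.
#' @param real_root_range truncation interval for real roots (the
#'   slow-fluctuation pass restricts its single root to [0.9, 1) so the
#'   latent state can only express slow structure).
#' @return updated `ar_components`.
#' @export
sweep_roots <- function(x_ext, comp, modulus_prior = c(0.97, 1),
                        real_root_range = c(-1, 1)) {
  for (j in seq_along(comp$periods)) {
    slow <- slowest_pair(comp)
    w <- component_residuals(x_ext, comp, list(type = "complex", index = j))
    cur <- pair_phi(comp$moduli[j], comp$periods[j])
    mr <- if (identical(j, slow)) modulus_prior else NULL
    draw <- sample_complex_pair(w, comp$sigma2, modulus_range = mr, current = cur)
    comp$moduli[j] <- draw[["modulus"]]
    comp$periods[j] <- draw[["period"]]
  }
  for (j in seq_along(comp$real_roots)) {
    u <- component_residuals(x_ext, comp, list(type = "real", index = j))
    comp$real_roots[j] <- sample_real_root(u, comp$sigma2, real_root_range)
  }
  # label switching can leave the prior on a pair that is no longer the
  # slowest; if so, redraw the now-slowest pair under the prior (one more
  # valid conditional update) so the structural support holds after every
  # sweep
  slow <- slowest_pair(comp)
  if (!is.na(slow) &&
      (comp$moduli[slow] < modulus_prior[1L] ||
         comp$moduli[slow] > modulus_prior[2L])) {
    w <- component_residuals(x_ext, comp, list(type = "complex", index = slow))
    draw <- sample_complex_pair(w, comp$sigma2, modulus_range = modulus_prior,
                                current = pair_phi(comp$moduli[slow],
                                                   comp$periods[slow]))
    comp$moduli[slow] <- draw[["modulus"]]
    comp$periods[slow] <- draw[["period"]]
  }
  comp$coeffs <- coeffs_from_roots(comp)
  comp$F <- companion_matrix(comp$coeffs)
  comp
}
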