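#' Polya-Gamma PG(1, z) draws
#'
#' Samples the Polya-Gamma variables used to augment the Bernoulli
#' likelihood. `rpg()` uses the alternating-series rejection sampler
#' (exponential tilting of PG(1, 0)); `rpg_gammasum()` is an independent
#' truncated sum-of-gammas construction,
#' \deqn{\omega = \frac{1}{2\pi^2}\sum_{k=1}^{K}
#'       \frac{g_k}{(k - 1/2)^2 + z^2/(4\pi^2)},\quad g_k \sim \mathrm{Exp}(1),}
#' kept for cross-validation of the rejection sampler.
#'
#' @param psi numeric vector/matrix of tilting arguments (the distribution
#'   depends only on `psi^2`).
#' @param terms truncation order of the gamma-sum construction.
#' @return draws with the shape of `psi`.
#' @export
rpg <- function(psi) {
  bad <- which(!is.finite(psi))
  if (length(bad))
    stop(sprintf("non-finite tilting argument at index %d", bad[1L]))
  out <- .rpg_devroye(as.numeric(psi))
  if (is.matrix(psi)) dim(out) <- dim(psi)
  out
}

#' @rdname rpg
#' @export
rpg_gammasum <- function(psi, terms = 200L) {
  n <- length(psi)
  k <- seq_len(terms) - 0.5
  denom <- outer(k^2, as.numeric(psi)^2 / (4 * pi^2), "+")
  g <- matrix(rexp(terms * n), terms, n)
  out <- colSums(g / denom) / (2 * pi^2)
  if (is.matrix(psi)) dim(out) <- dim(psi)
  out
}

#' @rdname rpg
#' @details `pg_mean()` is the closed-form mean
#'   \eqn{E[\omega] = \tanh(z/2)/(2z)} (limit 1/4 at z = 0).
#' @export
pg_mean <- function(psi) {
  z <- abs(psi)
  out <- ifelse(z < 1e-8, 0.25 - z^2 / 48, tanh(z / 2) / (2 * z))
  out
}
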