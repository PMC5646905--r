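# shared fixture builders (everything generated in code at test time)

# simulate latent AR(p) paths from known components, discarding a spin-up
sim_ar_paths <- function(comp, M, N, spin = 200L) {
  p <- comp$p
  x <- matrix(0, M, N + spin)
  sdev <- sqrt(comp$sigma2)
  for (m in seq_len(M)) {
    for (n in (p + 1L):(N + spin)) {
      x[m, n] <- sum(comp$coeffs * x[m, n - seq_len(p)]) + rnorm(1, 0, sdev)
    }
  }
  x[, (spin + 1L):(N + spin), drop = FALSE]
}

# Bernoulli raster from the model itself: logit rate = x + offset
sim_model_raster <- function(x, offset, dt = 0.001) {
  p <- plogis(x + offset)
  y <- matrix(rbinom(length(p), 1L, p), nrow(p), ncol(p))
  spike_raster(y, dt)
}

# raster whose single trial reproduces a prescribed ISI sequence (in bins)
raster_from_isis <- function(isis_bins, dt = 0.001) {
  sp <- cumsum(c(5L, isis_bins))
  y <- matrix(0L, 1L, max(sp) + 5L)
  y[1L, sp] <- 1L
  spike_raster(y, dt)
}

# homogeneous Bernoulli raster at a given rate (Hz)
flat_raster <- function(rate, M, N, dt = 0.001) {
  spike_raster(matrix(rbinom(M * N, 1L, rate * dt), M, N), dt)
}
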