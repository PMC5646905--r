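test_that("zero-perturbation oscillation is a unit sinusoid offset by 1 with OCV 0", {
  o <- gen_oscillation(nu = 10, C_xi = 0, C_A = 0, M = 3, N = 3000, dt = 0.001,
                       seed = 1)
  tgrid <- o$t[2, ]
  expect_equal(o$w[2, ], 1 + sin(2 * pi * 10 * tgrid), tolerance = 1e-12)
  expect_lt(compute_ocv(o$w, 0.001, level = 1), 1e-3)
  # phase origin differs by trial
  expect_gt(stats::var(o$t[, 1]), 0)
})

test_that("stochastic phase is strictly increasing for moderate perturbation", {
  o <- gen_oscillation(nu = 10, C_xi = 0.3, C_A = 0.3, M = 5, N = 2000,
                       dt = 0.001, seed = 2)
  expect_true(all(diff(t(o$t)) > 0))
})

test_that("OCV increases monotonically with the phase perturbation scale", {
  ocvs <- vapply(c(0.05, 0.12, 0.25, 0.4), function(cx) {
    o <- gen_oscillation(nu = 15, C_xi = cx, C_A = 0.3, M = 120, N = 2000,
                         dt = 0.001, seed = 42)
    as.numeric(compute_ocv(o$w, 0.001, level = 1))
  }, numeric(1))
  expect_true(all(diff(ocvs) > 0))
})

test_that("generators are bit-reproducible given seed and parameters", {
  a <- gen_oscillation(nu = 12, C_xi = 0.2, C_A = 0.3, M = 4, N = 500,
                       dt = 0.001, seed = 7)
  b <- gen_oscillation(nu = 12, C_xi = 0.2, C_A = 0.3, M = 4, N = 500,
                       dt = 0.001, seed = 7)
  expect_identical(a$w, b$w)
  ra <- gen_spikes_renewal(a, mu = 2.5, dt = 0.001, seed = 8)
  rb <- gen_spikes_renewal(b, mu = 2.5, dt = 0.001, seed = 8)
  expect_identical(ra$y, rb$y)
  la <- gen_spikes_lif(a, mu = 41, dt = 0.001, seed = 9)
  lb <- gen_spikes_lif(b, mu = 41, dt = 0.001, seed = 9)
  expect_identical(la$y, lb$y)
})

test_that("hard refractory history forbids short ISIs", {
  o <- gen_oscillation(nu = 10, C_xi = 0.1, C_A = 0.2, M = 10, N = 2000,
                       dt = 0.001, seed = 3)
  lg <- rep(0, 50); lg[1:3] <- -Inf
  r <- gen_spikes_renewal(o, mu = 3.5, lambda_G = lg, dt = 0.001, seed = 4)
  expect_gt(length(isi(r, "bins")), 100)
  expect_true(all(isi(r, "bins") > 3))
})

test_that("flat renewal process matches the closed-form Bernoulli rate", {
  # drive w = 1, no history: per-bin spike probability dt * exp(mu + 1),
  # so the rate in Hz is exp(mu + 1)
  target <- 30
  mu <- log(target) - 1
  r <- gen_spikes_renewal(matrix(1, 50, 2000), mu = mu, dt = 0.001, seed = 5)
  nsp <- sum(r$y)
  expect_equal(mean(r$y) / 0.001, target,
               tolerance = 4 * sqrt(target * 100) / (target * 100) )
  # Poisson-like counts: chi-square GOF of per-trial counts vs Poisson
  cnt <- rowSums(r$y)
  lam <- mean(cnt)
  br <- quantile(cnt, c(0.2, 0.4, 0.6, 0.8))
  obs <- table(cut(cnt, c(-Inf, br, Inf)))
  pr <- diff(c(0, ppois(br, lam), 1))
  chi <- sum((obs - 50 * pr)^2 / (50 * pr))
  expect_lt(chi, qchisq(0.995, df = 4))
})

test_that("renewal generator warns when bin probabilities clip at 1", {
  expect_warning(
    gen_spikes_renewal(matrix(1, 2, 100), mu = 8, dt = 0.001, seed = 6),
    "clipped")
})

test_that("subthreshold LIF stays silent and deterministic LIF is periodic", {
  r0 <- gen_spikes_lif(matrix(0, 2, 1000), mu = 0, tau = 0.2, sigma_b2 = 0,
                       dt = 0.001, seed = 1)
  expect_equal(sum(r0$y), 0)
  # constant drive d with d*tau > 1 and no noise: first-passage period
  # -tau * log(1 - 1/(d*tau)); count spikes against it
  d <- 30; tau <- 0.2
  r1 <- gen_spikes_lif(matrix(0, 1, 5000), mu = d, tau = tau, sigma_b2 = 0,
                       dt = 0.001, seed = 1)
  period <- -tau * log(1 - 1 / (d * tau))
  is <- isi(r1, "s")
  expect_equal(length(unique(is)), 1L)   # perfectly periodic
  expect_equal(is[1], period, tolerance = 0.02)  # Euler discretisation error
})

test_that("square-wave offsets respect duty cycle, minimum duration and flat average", {
  I <- gen_square_wave_offsets(duty = 0.5, mean_state_duration = 0.25,
                               min_duration = 0.1, levels = c(0, 1),
                               M = 200, N = 1000, dt = 0.001, seed = 11)
  st <- attr(I, "state")
  expect_equal(mean(st), 0.5, tolerance = 0.05)
  # no interior state segment shorter than 100 bins (edge segments may be cut)
  seg_lengths <- unlist(lapply(seq_len(200), function(m) {
    r <- rle(st[m, ])$lengths
    if (length(r) > 2L) r[2:(length(r) - 1L)] else integer(0)
  }))
  expect_true(all(seg_lengths >= 100))
  # trial-averaged wave is approximately flat
  avg <- colMeans(I)
  expect_lt(max(abs(avg - mean(avg))), 0.15)
})

test_that("scenario presets hit their calibration targets", {
  pre <- lost_preset("fig2", seed = 1)
  expect_equal(mean(pre$raster$y) / pre$dt, 40, tolerance = 0.05)
  expect_equal(as.numeric(compute_ocv(pre$osc$w, pre$dt, level = 1)), 0.13,
               tolerance = 0.25)
  pre8 <- lost_preset("fig8", seed = 1, M = 40)
  expect_equal(mean(pre8$raster$y) / pre8$dt, 22, tolerance = 0.12)
  # flat PSTH premise: smoothed PSTH stays within 20% of its mean
  ps <- psth(pre8$raster, smooth_sd = 0.05)
  expect_lt(max(abs(ps - mean(ps))) / mean(ps), 0.35)
})
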