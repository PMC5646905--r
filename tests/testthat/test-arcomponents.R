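test_that("root-to-coefficient expansion matches the closed forms", {
  expect_equal(ar_components(real_roots = 0.5)$coeffs, 0.5)
  co <- ar_components(periods = 20, moduli = 0.95)$coeffs
  expect_equal(co[1], 2 * 0.95 * cos(2 * pi / 20), tolerance = 1e-12)
  expect_equal(co[2], -0.95^2, tolerance = 1e-12)
})

test_that("roots(coeffs(roots)) round-trips random stationary sets (p <= 9)", {
  set.seed(30)
  for (rep in 1:20) {
    C <- sample(0:4, 1); R <- sample(0:2, 1)
    if (2 * C + R == 0) next
    comp <- ar_components(
      periods = if (C) runif(C, 4, 80) else numeric(0),
      moduli = if (C) runif(C, 0.3, 0.99) else numeric(0),
      real_roots = if (R) runif(R, -0.9, 0.9) else numeric(0))
    got <- roots_from_coeffs(comp$coeffs)        # polynomial-root oracle
    want <- c(if (C) comp$moduli else NULL, if (R) abs(comp$real_roots) else NULL)
    expect_equal(sort(unique(round(Mod(got), 8))),
                 sort(unique(round(c(rep(comp$moduli, each = 2),
                                     abs(comp$real_roots)), 8))),
                 tolerance = 1e-8)
    # companion matrix eigenvalues agree with the characteristic roots
    ev <- eigen(comp$F, only.values = TRUE)$values
    expect_equal(sort(Mod(ev)), sort(Mod(got)), tolerance = 1e-8)
  }
})

test_that("component residual filters compose back to the innovations", {
  set.seed(31)
  comp <- ar_components(periods = c(25, 8), moduli = c(0.95, 0.8),
                        real_roots = 0.4, sigma2 = 0.01)
  x <- sim_ar_paths(comp, M = 3, N = 600)
  eps <- component_residuals(x, comp, NULL)
  expect_equal(sd(as.numeric(eps)), sqrt(comp$sigma2), tolerance = 0.1)
  # leave out a pair, then re-apply its AR(2) factor: must reproduce eps exactly
  w <- component_residuals(x, comp, list(type = "complex", index = 1))
  phi <- c(2 * 0.95 * cos(2 * pi / 25), -0.95^2)
  refilter <- .fir_filter(w, c(1, -phi[1], -phi[2]))
  expect_equal(refilter, eps, tolerance = 1e-10)
  # single pair, leave it out: identity filter
  c1 <- ar_components(periods = 12, moduli = 0.9, sigma2 = 1)
  x1 <- sim_ar_paths(c1, 2, 100)
  expect_identical(component_residuals(x1, c1, list(type = "complex", index = 1)),
                   x1)
})

test_that("complex-pair conditional matches the conjugate-regression oracle", {
  set.seed(32)
  comp <- ar_components(periods = 2 * pi / acos(1.6 / (2 * 0.9)), moduli = 0.9,
                        sigma2 = 1)  # phi = (1.6, -0.81)
  w <- sim_ar_paths(comp, M = 1, N = 8000)
  # oracle: lag-2 regression moments on the same series
  K <- ncol(w)
  y <- w[1, 3:K]; D <- cbind(w[1, 2:(K - 1)], w[1, 1:(K - 2)])
  h <- solve(crossprod(D), crossprod(D, y))
  S <- solve(crossprod(D))
  draws <- t(replicate(200, sample_complex_pair(w, 1)[1:2]))
  expect_lt(abs(mean(draws[, 1]) - h[1]), 4 * sqrt(S[1, 1]))
  expect_lt(abs(mean(draws[, 2]) - h[2]), 4 * sqrt(S[2, 2]))
  expect_lt(abs(h[1] - 1.6), 2.5 * sqrt(S[1, 1]) + 0.02)
  expect_lt(abs(h[2] + 0.81), 2.5 * sqrt(S[2, 2]) + 0.02)
  # every accepted draw lies in the complex-root stationary region
  expect_true(all(draws[, 1]^2 / 4 + draws[, 2] < 0))
  expect_true(all(draws[, 2] > -1))
})

test_that("slowest-pair modulus prior truncates every draw to [0.97, 1]", {
  set.seed(33)
  comp <- ar_components(periods = 30, moduli = 0.98, sigma2 = 1)
  w <- sim_ar_paths(comp, M = 1, N = 3000)
  draws <- t(replicate(100, sample_complex_pair(w, 1, modulus_range = c(0.97, 1),
                                                current = c(1.5, -0.96))))
  expect_true(all(draws[, "modulus"] >= 0.97 & draws[, "modulus"] <= 1))
})

test_that("real-root conditional matches the lag-1 regression oracle", {
  set.seed(34)
  c1 <- ar_components(real_roots = 0.6, sigma2 = 1)
  u <- sim_ar_paths(c1, 1, 5000)
  m <- sum(u[1, -1] * u[1, -ncol(u)]) / sum(u[1, -ncol(u)]^2)
  s <- sqrt(1 / sum(u[1, -ncol(u)]^2))
  draws <- replicate(300, sample_real_root(u, 1))
  expect_lt(abs(mean(draws) - m), 4 * s)
  expect_true(all(draws > -1 & draws < 1))
  # white-noise residuals concentrate near zero
  uw <- matrix(rnorm(4000), 1)
  dw <- replicate(100, sample_real_root(uw, 1))
  expect_lt(abs(mean(dw)), 0.1)
  expect_error(sample_real_root(matrix(0, 1, 100), 1), "all-zero")
})

test_that("repeated root sweeps recover the generating components", {
  set.seed(35)
  true <- ar_components(periods = c(60, 20, 9), moduli = c(0.97, 0.9, 0.8),
                        real_roots = 0.3, sigma2 = 1e-4)
  x <- sim_ar_paths(true, M = 8, N = 4000)
  comp <- ar_components(periods = c(90, 30, 6), moduli = c(0.97, 0.85, 0.85),
                        real_roots = 0.1, sigma2 = 1e-4)
  per <- matrix(0, 30, 3); mod <- matrix(0, 30, 3)
  for (it in 1:60) {
    comp <- sweep_roots(x, comp)
    eps <- component_residuals(x, comp, NULL)
    comp$sigma2 <- sample_sigma2(sum(eps^2), length(eps))
    if (it > 30) {
      o <- order(-comp$periods)
      per[it - 30, ] <- comp$periods[o]; mod[it - 30, ] <- comp$moduli[o]
    }
    # stationarity preserved after every accepted sweep
    expect_true(all(Mod(roots_from_coeffs(comp$coeffs)) < 1 + 1e-8))
    expect_true(max(comp$moduli) >= 0.97)
  }
  perm <- colMeans(per); modm <- colMeans(mod)
  expect_equal(perm, c(60, 20, 9), tolerance = 0.1)
  expect_lt(max(abs(modm - c(0.97, 0.9, 0.8))), 0.02)
})
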