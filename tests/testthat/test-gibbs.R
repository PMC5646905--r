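test_that("offset conditional matches the quadratic-form oracle and sums to zero", {
  expect_identical(sample_offsets(matrix(1, 1, 5), matrix(0, 1, 5)), 0)

  set.seed(50)
  M <- 2; N <- 6
  omega <- matrix(runif(M * N, 0.1, 0.6), M, N)
  resid <- matrix(rnorm(M * N), M, N)
  pv <- 100
  # oracle: brute-force Newton on the exact negative log conditional in mu_2
  nll <- function(m2) {
    mu <- c(-m2, m2)
    0.5 * sum(omega * sweep(resid, 1, mu, "-")^2) + 0.5 * m2^2 / pv
  }
  g <- function(m2) (nll(m2 + 1e-6) - nll(m2 - 1e-6)) / 2e-6
  m2 <- 0
  for (i in 1:50) m2 <- m2 - g(m2) / ((g(m2 + 1e-4) - g(m2 - 1e-4)) / 2e-4)
  hess <- (g(m2 + 1e-4) - g(m2 - 1e-4)) / 2e-4
  draws <- t(replicate(4000, sample_offsets(omega, resid, pv)))
  expect_true(all(abs(rowSums(draws)) < 1e-12))
  expect_equal(mean(draws[, 2]), m2, tolerance = 5 / sqrt(4000 * hess))
  expect_equal(var(draws[, 2]), 1 / hess, tolerance = 0.1 / hess)
})

test_that("spline-weight conditional matches quadrature and no-ops when all fixed", {
  set.seed(51)
  # single adjustable weight: compare with 1-D numerical integration
  B <- matrix(runif(8, 0, 1), 1, 8)
  sm <- spline_model(knots = c(0, 1), basis = B, weights = 0,
                     prior_mean = 0.3, prior_var = 2)
  wt <- runif(8, 0.05, 0.5)
  g <- rnorm(8) * wt
  # exact conditional: exp(-0.5 (v^2 (B W B' + 1/pv) - 2 v (B g + pm/pv)))
  prec <- sum(B^2 * wt) + 1 / 2
  mean_th <- (sum(B * g) + 0.3 / 2) / prec
  grid <- seq(mean_th - 8 / sqrt(prec), mean_th + 8 / sqrt(prec), length.out = 4001)
  logd <- -0.5 * grid^2 * prec + grid * (sum(B * g) + 0.3 / 2)
  d <- exp(logd - max(logd)); d <- d / sum(d)
  mean_q <- sum(grid * d)
  var_q <- sum((grid - mean_q)^2 * d)
  draws <- replicate(4000, sample_spline_weights(sm, wt, g))
  expect_lt(abs(mean(draws) - mean_q), 5 * sqrt(var_q / 4000))
  expect_lt(abs(var(draws) - var_q), 0.15 * var_q)

  smf <- spline_model(knots = c(0, 1), basis = B, weights = 1.7,
                      fixed_idx = 1L)
  expect_identical(sample_spline_weights(smf, wt, g), 1.7)
})

test_that("TAE conditional equals the weighted normal-equations oracle", {
  set.seed(52)
  M <- 3; N <- 12; K <- 4
  B <- build_bspline_basis(seq(0, 1, length.out = 3), seq(0, 1, length.out = N))
  omega <- matrix(runif(M * N, 0.1, 0.4), M, N)
  resid <- matrix(rnorm(M * N), M, N)
  pv <- 25
  sm <- spline_model(knots = seq(0, 1, length.out = 3), basis = B,
                     weights = numeric(nrow(B)), prior_var = pv)
  wt <- colSums(omega)
  g <- colSums(omega * resid)
  Prec <- B %*% diag(wt) %*% t(B) + diag(1 / pv, nrow(B))
  mean_th <- solve(Prec, B %*% g)
  draws <- t(replicate(3000, sample_spline_weights(sm, wt, g)))
  S <- solve(Prec)
  expect_true(all(abs(colMeans(draws) - mean_th) < 5 * sqrt(diag(S) / 3000)))
  expect_equal(cov(draws), S, tolerance = 0.15)
})

test_that("innovation-variance conditional has the stated inverse-gamma moments", {
  # shape (a + d + 2)/2, scale b + SS/2; with a = 0.001, b = 1e-6, d = 100,
  # SS = 2 the posterior mean is scale/(shape - 1) ~ 0.0200
  set.seed(53)
  draws <- replicate(3000, sample_sigma2(2, 100, 0.001, 1e-6))
  shape <- (0.001 + 100 + 2) / 2
  scale <- 1e-6 + 1
  expect_equal(shape, 51.0005)
  expect_equal(scale, 1.000001)
  m_th <- scale / (shape - 1)
  expect_equal(m_th, 0.0200, tolerance = 1e-4)
  expect_lt(abs(mean(draws) - m_th), 4 * sqrt(m_th^2 / (shape - 2) / 3000))
  # zero residuals: draws collapse towards zero for large data
  expect_lt(mean(replicate(100, sample_sigma2(0, 1e4, 0.001, 1e-6))), 1e-6)
})

test_that("innovation variance is recovered from directly observed paths", {
  set.seed(54)
  comp <- ar_components(periods = 20, moduli = 0.9, sigma2 = 0.01)
  x <- sim_ar_paths(comp, M = 50, N = 2000)
  eps <- component_residuals(x, comp, NULL)
  draws <- replicate(200, sample_sigma2(sum(eps^2), length(eps)))
  expect_equal(mean(draws), 0.01, tolerance = 0.001)
})

test_that("mixture indicators reduce to the mixture weights when s0 = s1", {
  set.seed(55)
  M <- 400; N <- 20
  x <- matrix(rnorm(M * N), M, N)
  eta <- matrix(-2, M, N)
  y <- matrix(rbinom(M * N, 1, plogis(0.5 * x + eta)), M, N)
  strong <- sample_Z(y, x, eta, pi_mix = c(0.3, 0.7), s0 = 0.5, s1 = 0.5)
  expect_equal(mean(strong), 0.7, tolerance = 0.08)
})

test_that("mixture class probabilities equal hand-computed Bernoulli products", {
  # two-bin toy trial with pinned values
  x <- matrix(c(0.8, -0.4), 1, 2)
  eta <- matrix(c(-1, -2), 1, 2)
  y <- matrix(c(1L, 0L), 1, 2)
  s0 <- 0.1; s1 <- 1.2; pim <- c(0.4, 0.6)
  lik <- function(s) {
    p <- plogis(s * x + eta)
    prod(ifelse(y == 1, p, 1 - p))
  }
  p1 <- pim[2] * lik(s1) / (pim[1] * lik(s0) + pim[2] * lik(s1))
  set.seed(56)
  hits <- mean(replicate(4000, sample_Z(y, x, eta, pim, s0, s1)))
  expect_equal(hits, p1, tolerance = 4 * sqrt(p1 * (1 - p1) / 4000))
})

test_that("strength conditional combines likelihood and prior correctly", {
  set.seed(57)
  M <- 6; N <- 50
  omega <- matrix(runif(M * N, 0.1, 0.3), M, N)
  x <- matrix(rnorm(M * N), M, N)
  eta <- matrix(rnorm(M * N, -2), M, N)
  kappa <- matrix(rbinom(M * N, 1, 0.3), M, N) - 0.5
  strong <- rep(c(TRUE, FALSE), 3)
  A <- 0.5 * sum((omega * x^2)[strong, ])
  B <- sum((omega * x * (kappa / omega - eta))[strong, ])
  prec <- 2 * A + 1 / 100
  m_un <- (B + 0.1 / 100) / prec
  s_un <- sqrt(1 / prec)
  # oracle: moments of N(m_un, s_un) truncated below at s0 = 0.1
  a <- (0.1 - m_un) / s_un
  lam <- dnorm(a) / (1 - pnorm(a))
  m_tr <- m_un + s_un * lam
  v_tr <- s_un^2 * (1 + a * lam - lam^2)
  draws <- replicate(3000, sample_s1(omega, x, eta, kappa, strong, 0.1, 100))
  expect_true(all(draws >= 0.1))
  expect_lt(abs(mean(draws) - m_tr), 5 * sqrt(v_tr / 3000))
  expect_lt(abs(var(draws) - v_tr), 0.15 * v_tr)
  # Dirichlet weight update includes prior pseudocounts
  set.seed(58)
  pis <- t(replicate(2000, sample_pi_mix(strong, c(1, 1))))
  expect_equal(mean(pis[, 1]), 4 / 8, tolerance = 0.03)
  expect_true(all(abs(rowSums(pis) - 1) < 1e-12))
})

test_that("default weak-class strength is fixed at 0.1", {
  expect_equal(lost_priors()$s0, 0.1)
})
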