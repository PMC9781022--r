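test_that("EM recovers a single Gaussian from samples", {
  set.seed(4)
  x <- rnorm(10000)
  fit <- fit_mixture(x, n_components = 1, seed = 1)
  expect_equal(fit$n_components, 1L)
  expect_lt(abs(fit$means[1]), 0.05)
  expect_lt(abs(fit$variances[1] - 1), 0.1)
  expect_equal(sum(fit$weights), 1, tolerance = 1e-12)
})

test_that("EM separates two well-spaced clusters", {
  set.seed(8)
  x <- c(rnorm(3000, -5), rnorm(3000, 5))
  fit <- fit_mixture(x, n_components = 2, seed = 2)
  mns <- sort(fit$means)
  expect_lt(abs(mns[1] + 5), 0.1)
  expect_lt(abs(mns[2] - 5), 0.1)
  expect_true(all(abs(fit$weights - 0.5) < 0.05))
})

test_that("EM log-likelihood is non-decreasing and the fit is deterministic", {
  set.seed(12)
  x <- c(rnorm(400, -1, 0.7), rnorm(600, 2, 1.2))
  f1 <- fit_mixture(x, n_components = 2, seed = 5)
  f2 <- fit_mixture(x, n_components = 2, seed = 5)
  expect_identical(f1, f2)
  expect_true(all(diff(f1$loglik_trace) > -1e-8))
})

test_that("EM agrees with an independent mixture implementation", {
  skip_if_not_installed("mclust")
  withr::local_package("mclust")   # Mclust needs its namespace attached
  set.seed(19)
  x <- c(rnorm(1500, -2, 0.8), rnorm(1500, 1.5, 1.1))
  ours <- fit_mixture(x, n_components = 2, seed = 3)
  ref <- mclust::Mclust(x, G = 2, modelNames = "V", verbose = FALSE)
  expect_lt(abs(ours$loglik - ref$loglik) / abs(ref$loglik), 1e-4)
  grid <- seq(-5, 5, length.out = 101)
  ref_dens <- mclust::dens(modelName = "V", data = grid,
                           parameters = ref$parameters)
  expect_lt(max(abs(gmm_density(ours, grid) - ref_dens)), 0.01)
})

test_that("too few samples for the requested components is a data error", {
  expect_error(fit_mixture(rnorm(25), n_components = 3), "at least 10")
})

test_that("mixture density is normalized and matches direct summation", {
  m <- hand_mixture(c(0.3, 0.7), c(-1, 2), c(0.5, 2))
  expect_equal(stats::integrate(function(y) gmm_density(m, y), -Inf,
                                Inf)$value, 1, tolerance = 1e-6)
  y <- c(-1.3, 0, 2.4)
  direct <- 0.3 * dnorm(y, -1, sqrt(0.5)) + 0.7 * dnorm(y, 2, sqrt(2))
  expect_equal(gmm_density(m, y), direct)
})

test_that("mixture bias: zero at zero density, kT log 2 where P equals epsilon", {
  m <- hand_mixture(1, 0, 1)                 # standard normal density
  b <- gambes_bias(m, e_cut = 7, kT = 1)
  expect_equal(b$epsilon, dnorm(0) * exp(-7), tolerance = 1e-6)
  # P(y) = epsilon exactly at y = sqrt(2 * e_cut)
  expect_equal(bias_energy(b, sqrt(14)), log(2), tolerance = 1e-6)
  expect_lt(bias_energy(b, 50), 1e-12)       # vanishing density -> V = 0
})

test_that("mixture bias ceiling equals the energy cutoff at the density peak", {
  m <- hand_mixture(1, 0, 1)
  b <- gambes_bias(m, e_cut = 7, kT = 1)
  grid <- seq(-8, 8, length.out = 4001)
  vmax <- max(bias_energy(b, grid))
  expect_lt(abs(vmax - 7), 0.05)
  expect_equal(vmax, log1p(exp(7)), tolerance = 1e-6)  # exact ceiling value
  expect_true(all(bias_energy(b, grid) >= 0))
  expect_true(all(bias_energy(b, grid) <= 7 + log(2) + 1e-9))
})

test_that("mixture bias is monotone in the density and null far from the state", {
  m <- hand_mixture(c(0.4, 0.6), c(0, 1), c(0.4, 0.6))
  b <- gambes_bias(m, e_cut = 6, kT = 1)
  ys <- seq(0.5, 9, length.out = 60)       # density decreasing out here
  P <- gmm_density(m, ys)
  V <- bias_energy(b, ys)
  expect_true(all(diff(P) < 0))
  expect_true(all(diff(V) < 0))            # P(y1) < P(y2) => V(y1) < V(y2)
  # >= 8 standard deviations from all means: Grubmueller/Voter condition
  expect_lt(bias_energy(b, 1 + 8 * sqrt(0.6)), 1e-3)
})

test_that("mixture bias gradient matches a finite difference", {
  m <- hand_mixture(c(0.5, 0.5), c(-0.4, 0.9), c(0.3, 0.8))
  b <- gambes_bias(m, e_cut = 5, kT = 1)
  ys <- seq(-3, 3, length.out = 41)
  h <- 1e-6
  fd <- (bias_energy(b, ys + h) - bias_energy(b, ys - h)) / (2 * h)
  expect_equal(bias_gradient(b, ys), fd, tolerance = 1e-5)
})

test_that("mixture bias serializes to JSON and back", {
  set.seed(3)
  fit <- fit_mixture(rnorm(500, 1, 0.5), n_components = 1, seed = 1)
  b <- gambes_bias(fit, e_cut = 6)
  path <- withr::local_tempfile(fileext = ".json")
  write_gambes_bias(b, path)
  b2 <- read_gambes_bias(path)
  ys <- seq(-2, 4, length.out = 31)
  expect_equal(bias_energy(b2, ys), bias_energy(b, ys), tolerance = 1e-12)
})
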