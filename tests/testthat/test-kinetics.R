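test_that("time rescaling identities: zero, constant and stepped bias", {
  # zero bias: physical time equals apparent time
  ev0 <- rescale_time(hand_trajectory(rep(0, 10), dt = 0.1))
  expect_equal(ev0$acceleration, 1)
  expect_equal(ev0$physical_time, ev0$t_md)
  # constant bias V0 = 2 kT: tau = e^2 * t_MD
  ev2 <- rescale_time(hand_trajectory(rep(2, 4), dt = 0.25))
  expect_equal(ev2$acceleration, exp(2), tolerance = 1e-12)
  expect_equal(ev2$physical_time, exp(2) * 1, tolerance = 1e-12)
  # recorded series {0, 1, 2} kT over three unit steps: tau = e^0+e^1+e^2
  ev <- rescale_time(hand_trajectory(c(0, 1, 2), dt = 1))
  expect_equal(ev$physical_time, sum(exp(0:2)), tolerance = 1e-12)
})

test_that("rescaling refuses censored runs and negative bias", {
  tr <- hand_trajectory(rep(0, 5)); tr$escaped <- FALSE
  expect_error(rescale_time(tr), "censored")
  tr2 <- hand_trajectory(c(0, -0.5, 0))
  expect_error(rescale_time(tr2), "negative bias")
})

test_that("exit-time fit: moments, consistency and degenerate input", {
  f <- fit_exit_times(c(1, 2, 3))
  expect_equal(f$mu, 2)
  expect_equal(f$sigma, 1)
  set.seed(77)
  x <- rexp(5000, rate = 1 / 5)
  f2 <- fit_exit_times(x)
  expect_lt(abs(f2$tau_fit - 5), 3 * 5 / sqrt(5000))
  # all-equal times: sigma 0, finite positive tau from the ECDF fit
  f3 <- fit_exit_times(rep(2, 8))
  expect_equal(f3$sigma, 0)
  expect_true(is.finite(f3$tau_fit) && f3$tau_fit > 0)
  expect_error(fit_exit_times(3), "at least 2")
  expect_error(fit_exit_times(c(1, -2, 3)), "positive")
})

test_that("KS check accepts exact exponential quantiles, rejects a point mass", {
  n <- 25; tau <- 3
  q <- tau * log(n / (n - seq_len(n) + 0.5))
  ks <- ks_poisson_test(q, tau)
  expect_lt(ks$ks_statistic, 0.05)   # ECDF sits on the model CDF
  expect_gt(ks$p_value, 0.99)
  # 25 identical times: maximal ECDF/CDF gap, computed directly
  ident <- rep(2, 25)
  tau_star <- fit_exit_times(ident)$tau_fit
  ks2 <- ks_poisson_test(ident, tau_star)
  gap <- max(stats::pexp(2, 1 / tau_star), 1 - stats::pexp(2, 1 / tau_star))
  expect_equal(ks2$ks_statistic, gap, tolerance = 1e-9)
  expect_lt(ks2$p_value, 1e-4)
  expect_error(ks_poisson_test(c(1, 2, 3), 1), "more simulations")
})

test_that("release_kinetics object: coefficients, predictions, residuals, simulate", {
  set.seed(123)
  x <- rexp(200, 1 / 4)
  fit <- fit_release_kinetics(x)
  expect_s3_class(fit, "release_kinetics")
  expect_equal(unname(coef(fit)["k"] * coef(fit)["tau"]), 1,
               tolerance = 1e-12)
  expect_equal(predict(fit, 0), 0)
  expect_equal(predict(fit, Inf), 1)
  expect_equal(predict(fit, 2, type = "survival"),
               1 - predict(fit, 2, type = "cdf"))
  expect_lt(max(abs(residuals(fit))), 0.15)
  sims <- simulate(fit, nsim = 3, seed = 1)
  expect_length(sims, 3)
  expect_length(sims[[1]], fit$n_events)
  s <- summary(fit)
  expect_equal(s$tau, fit$tau_fit)
  expect_output(print(fit), "tau")
})

test_that("parametric bootstrap p-value is sane under the null", {
  set.seed(5)
  x <- rexp(30, 1 / 2)
  fit <- fit_release_kinetics(x, n_boot = 200)
  expect_true(fit$p_boot >= 0 && fit$p_boot <= 1)
  expect_gt(fit$p_boot, 0.01)   # null data should rarely be rejected
})

test_that("unbiased ensembles have unit acceleration and the rescaling is a no-op", {
  sc <- build_scenario("surface_desorption", ground_truth = FALSE)
  fit <- run_escape_ensemble(sc, "unbiased", n_runs = 10, base_seed = 3,
                             config = list(max_steps = 1e6L))
  expect_equal(fit$n_events, 10)
  expect_true(all(fit$events$acceleration == 1))
  expect_equal(fit$events$physical_time, fit$events$t_md)
  # identity: fitting raw apparent times gives the same tau exactly
  raw <- fit_exit_times(fit$events$t_md)
  expect_equal(fit$tau_fit, raw$tau_fit)
})

test_that("diffusion estimator: identity, worked example and ordering error", {
  set.seed(42)
  for (i in 1:25) {
    y <- sort(runif(2, -5, 5)); t <- sort(runif(2, 0, 10) + c(0, 1e-3))
    d <- estimate_diffusion(y[1], t[1], y[2], t[2])
    expect_equal(d$D * (t[2] - t[1]), (y[2] - y[1])^2, tolerance = 1e-12)
  }
  # 4.0 Angstrom separation, exit times 54.4 and 200.0 microseconds, cgs
  d <- estimate_diffusion(y1 = 0, t1 = 54.4e-6, y2 = 4.0e-8, t2 = 200.0e-6)
  expect_equal(d$D, 1.099e-11, tolerance = 1e-3)
  expect_equal(estimate_diffusion(3, 1, 3, 2)$D, 0)
  expect_error(estimate_diffusion(0, 2, 1, 2), "exceed")
})
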