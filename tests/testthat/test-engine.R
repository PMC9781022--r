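test_that("identical seeds give bit-identical trajectories", {
  sc <- scenario_double_well(4, ground_truth = FALSE)
  p <- sim_params(seed = 7, max_steps = 2e4)
  t1 <- simulate_langevin(sc, NULL, p)
  t2 <- simulate_langevin(sc, NULL, p)
  expect_identical(t1, t2)
  t3 <- simulate_langevin(sc, NULL, sim_params(seed = 8, max_steps = 2e4))
  expect_false(identical(t1$cv, t3$cv))
})

test_that("free diffusion satisfies the Einstein relation MSD = 2 D0 t", {
  sc <- scenario_spec(flat_surface(), 0, 49, label = "free")
  disp2 <- vapply(1:200, function(i) {
    tr <- simulate_langevin(sc, NULL,
                            sim_params(seed = 500 + i, max_steps = 1000L,
                                       record_stride = 1L))
    n <- length(tr$cv)
    (tr$cv[n] - tr$cv[1])^2 / (2 * tr$times[n])
  }, numeric(1))
  # (dy)^2/(2t) ~ D0 * chi^2_1, so sd of the mean is D0*sqrt(2/n)
  se <- sqrt(2 / length(disp2))
  expect_lt(abs(mean(disp2) - 1), 3 * se)
})

test_that("harmonic well equilibrates to the Boltzmann variance kT/kappa", {
  sc <- scenario_spec(harmonic_surface(kappa = 4), 0, 19, label = "ho")
  tr <- simulate_langevin(sc, NULL, sim_params(seed = 11, max_steps = 2e5))
  y <- tr$cv[-seq_len(2000)]    # discard equilibration
  v <- stats::var(y)
  # autocorrelation time ~ kT/(D0*kappa) = 250 steps -> ~400 independent
  # samples; 3 SE band on the variance
  expect_lt(abs(v - 0.25), 0.06)
  expect_false(tr$escaped)
})

test_that("zero-noise dynamics stays put at a minimum and descends otherwise", {
  sc <- scenario_double_well(5, ground_truth = FALSE)  # minimum at 0
  tr <- simulate_langevin(sc, NULL,
                          sim_params(seed = 1, max_steps = 100L),
                          noise = FALSE)
  expect_true(all(tr$cv == 0))
  sc2 <- scenario_spec(harmonic_surface(4), 2, 19, label = "slide")
  tr2 <- simulate_langevin(sc2, NULL,
                           sim_params(seed = 1, max_steps = 2000L),
                           noise = FALSE)
  expect_lt(abs(tr2$cv[length(tr2$cv)]), 1e-3)  # relaxed to the minimum
  expect_true(all(diff(tr2$cv) <= 0))           # monotone descent
})

test_that("escape is the first touch of |y| >= threshold and is recorded", {
  sc <- scenario_double_well(2, ground_truth = FALSE)
  tr <- simulate_langevin(sc, NULL, sim_params(seed = 3, max_steps = 1e5))
  expect_true(tr$escaped)
  expect_gte(abs(tr$escape_position), sc$absorbing_threshold)
  expect_true(all(abs(tr$cv) < sc$absorbing_threshold))
  expect_equal(tr$n_steps, tr$escape_step)
})

test_that("unbiased first-passage ensemble agrees with the quadrature oracle", {
  sc <- scenario_double_well(4)
  taus <- vapply(1:60, function(i) {
    tr <- simulate_langevin(sc, NULL,
      sim_params(seed = 9000 + i, max_steps = 5e5, record_stride = 1e5))
    if (!tr$escaped) return(NA_real_)
    tr$escape_step * tr$dt
  }, numeric(1))
  taus <- taus[!is.na(taus)]
  sem <- stats::sd(taus) / sqrt(length(taus))
  expect_lt(abs(mean(taus) - sc$ground_truth_mfpt), 3 * sem)
})

test_that("constant bias exerts no force but is recorded and nonnegative", {
  sc <- scenario_spec(harmonic_surface(4), 0, 19, label = "ho")
  p <- sim_params(seed = 21, max_steps = 5e3)
  tr0 <- simulate_langevin(sc, NULL, p)
  tr2 <- simulate_langevin(sc, constant_bias(2), p)
  expect_equal(tr0$cv, tr2$cv)            # same noise, same force
  expect_true(all(tr2$bias == 2))
  expect_true(all(tr0$bias == 0))
})
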