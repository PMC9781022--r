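test_that("kernel density estimate: empty, single-kernel and brute-force cases", {
  st <- opes_state(sigma = 1, e_cut = 5)
  expect_equal(opes_probability(st, c(-1, 0, 3)), c(0, 0, 0))
  expect_equal(bias_energy(st, c(-1, 0, 3)), c(0, 0, 0))
  st$centers <- 0; st$weights <- 1
  expect_equal(opes_probability(st, 0), 1 / sqrt(2 * pi))
  # three kernels, hand-chosen weights, independent brute-force sum
  st$centers <- c(-0.5, 0.2, 1.1)
  st$weights <- c(1, 2.5, 0.7)
  s <- 0.4
  brute <- sum(st$weights * exp(-(s - st$centers)^2 / 2) / sqrt(2 * pi)) /
    sum(st$weights)
  expect_equal(opes_probability(st, s), brute, tolerance = 1e-12)
})

test_that("first deposited kernel carries weight exp(0) = 1", {
  st <- opes_state(sigma = 0.3, e_cut = 4)
  opes_update(st, 0.1)
  expect_equal(st$centers, 0.1)
  expect_equal(st$weights, 1)
})

test_that("no deposition inside the excluded region", {
  st <- opes_state(sigma = 0.3, e_cut = 4, excluded = 8.5)
  opes_update(st, 9)       # |s| > 8.5: transition-state protection
  opes_update(st, -8.7)
  expect_length(st$centers, 0)
  opes_update(st, 8.4)
  expect_equal(st$centers, 8.4)
})

test_that("second deposition at the same point is weighted by the current bias", {
  kT <- 1; e_cut <- 2
  st <- opes_state(sigma = 0.5, e_cut = e_cut, gamma = 10, kT = kT)
  opes_update(st, 0)
  # hand computation of V_1(0): single kernel -> P(0) = G(0,0), Z_1 = P(0),
  # so P/Z = 1 and V = min(0.9 * log(1 + 1/eps), e_cut) = e_cut (ceiling)
  v1_hand <- min((1 - 1 / 10) * log1p(1 / st$epsilon), e_cut)
  expect_equal(bias_energy(st, 0), v1_hand)
  opes_update(st, 0)
  expect_equal(st$weights[2], exp(v1_hand / kT))
  expect_gt(st$weights[2], 1)
})

test_that("flooding bias formula: shift, substitution identity and ceiling", {
  st <- opes_state(sigma = 0.4, e_cut = 6, gamma = 10)
  pref <- (1 - 1 / 10)
  expect_equal(st$epsilon, exp(-6 / pref))
  st$centers <- c(-0.2, 0.3); st$weights <- c(1, 2); st$zn <- 0.5
  # at a point where P/Z_n = eps the bias is pref * kT * log 2
  # find it by inverting the density numerically
  f <- function(s) opes_probability(st, s) / st$zn - st$epsilon
  s_star <- stats::uniroot(f, c(0.3, 10), tol = 1e-12)$root
  expect_equal(bias_energy(st, s_star), pref * log(2), tolerance = 1e-6)
  # bounds: 0 <= V <= e_cut everywhere
  grid <- seq(-5, 5, length.out = 1001)
  V <- bias_energy(st, grid)
  expect_true(all(V >= 0))
  expect_true(all(V <= 6 + 1e-12))
})

test_that("gamma -> infinity recovers the static mixture functional form", {
  st <- opes_state(sigma = 0.5, e_cut = 6, gamma = 1e6)
  st$centers <- c(0, 0.4); st$weights <- c(1, 1.5); st$zn <- 0.8
  grid <- seq(-3, 3, length.out = 101)
  p_over_z <- opes_probability(st, grid) / st$zn
  gambes_form <- 1 * log((p_over_z + st$epsilon) / st$epsilon)
  expect_equal(bias_energy(st, grid), pmin(gambes_form, 6),
               tolerance = 1e-5)
})

test_that("flooding bias gradient matches a finite difference off the ceiling", {
  st <- opes_state(sigma = 0.3, e_cut = 8, gamma = 10)
  st$centers <- c(-0.5, 0.1, 0.6); st$weights <- c(1, 3, 9); st$zn <- 1.2
  ys <- seq(-2, 2, length.out = 61)
  below <- bias_energy(st, ys) < 8 - 1e-6
  h <- 1e-7
  fd <- (bias_energy(st, ys + h) - bias_energy(st, ys - h)) / (2 * h)
  expect_equal(bias_gradient(st, ys)[below], fd[below], tolerance = 1e-4)
})

test_that("driven by the engine, updates are deterministic and respect exclusion", {
  sc <- scenario_double_well(6)
  sig <- opes_bandwidth(sc, seed = 5)
  run <- function() {
    st <- opes_state(sigma = sig, e_cut = 4, excluded = 0.5, pace = 100L)
    tr <- simulate_langevin(sc, st, sim_params(seed = 31, max_steps = 3e5))
    list(tr = tr, st = st)
  }
  a <- run(); b <- run()
  expect_identical(a$tr, b$tr)
  expect_identical(a$st$centers, b$st$centers)
  expect_identical(a$st$weights, b$st$weights)
  # no kernel ever lands in the excluded region
  expect_true(all(abs(a$st$centers) <= 0.5))
  # recorded bias is nonnegative and bounded by the ceiling
  expect_true(all(a$tr$bias >= 0))
  expect_true(all(a$tr$bias <= 4 + 1e-9))
})

test_that("bias at the absorbing threshold stays negligible during flooding", {
  sc <- scenario_double_well(7)
  sig <- opes_bandwidth(sc, seed = 5)
  st <- opes_state(sigma = sig, e_cut = 5, excluded = 0.5, pace = 100L)
  tr <- simulate_langevin(sc, st, sim_params(seed = 12, max_steps = 5e5))
  expect_true(tr$escaped)
  # flooding validity proxy: < 1% of the cutoff at the exit
  expect_lt(bias_energy(st, sc$absorbing_threshold), 0.01 * 5)
  # and at the barrier top (the transition state proper)
  expect_lt(bias_energy(st, 1), 0.01 * 5)
})

test_that("flooding state serializes to JSON and back", {
  st <- opes_state(sigma = 0.25, e_cut = 5, gamma = 8, excluded = 2,
                   pace = 50L)
  for (s in c(0.1, -0.2, 0.15)) opes_update(st, s)
  path <- withr::local_tempfile(fileext = ".json")
  write_opes_state(st, path)
  st2 <- read_opes_state(path)
  grid <- seq(-1, 1, length.out = 21)
  expect_equal(bias_energy(st2, grid), bias_energy(st, grid),
               tolerance = 1e-12)
  expect_equal(st2$zn, st$zn)
})
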