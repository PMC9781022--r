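#' Simulation parameters
#'
#' @param dt integration timestep (reduced time).
#' @param max_steps maximum number of steps before the run is declared
#'   censored (returned with `escaped = FALSE`).
#' @param kT thermal energy.
#' @param D0 diffusion coefficient.
#' @param seed integer seed; identical `(scenario, bias, params, seed)`
#'   give bit-identical trajectories.
#' @param record_stride record every this-many steps (>= 1). Biased runs
#'   meant for time rescaling should keep the default 1 so the mean
#'   exponentiated bias is exact.
#' @return A list of class `sim_params`.
#' @export
sim_params <- function(dt = 1e-3, max_steps = 1e6L, kT = 1, D0 = 1,
                       seed = 1L, record_stride = 1L) {
  check_positive(dt = dt, kT = kT, D0 = D0)
  max_steps <- as.integer(max_steps); record_stride <- as.integer(record_stride)
  stopifnot(max_steps >= 1L, record_stride >= 1L, is.finite(seed))
  structure(list(dt = dt, max_steps = max_steps, kT = kT, D0 = D0,
                 seed = as.integer(seed), record_stride = record_stride),
            class = "sim_params")
}

#' Propagate overdamped Langevin dynamics
#'
#' Euler--Maruyama integration of
#' `y_{n+1} = y_n - (D0/kT) * d(U+V)/dy * dt + sqrt(2 D0 dt) * xi_n`
#' with standard-normal increments from the seeded generator. The run ends
#' at the first step where `|y| >= absorbing_threshold` (escape) or at
#' `max_steps` (censored). Reflecting domain boundaries are enforced by
#' position mirroring. The recorded bias column holds the instantaneous
#' bias at the visited point at each step -- for an evolving flooding bias
#' this is the bias in force when the point was visited, which is the
#' convention the time-rescaling average uses.
#'
#' @param scenario a [scenario_spec()].
#' @param bias `NULL` for unbiased dynamics, a static bias (e.g.
#'   [gambes_bias()] or [constant_bias()]), or an [opes_state()] which is
#'   updated in place every `pace` steps with the current CV value.
#' @param params a [sim_params()]; its `kT` and `D0` override the
#'   scenario's for the integration.
#' @param noise logical; `FALSE` disables the stochastic term (deterministic
#'   gradient descent, used to test the zero-temperature limit).
#' @return An object of class `trajectory`: `times`, `cv`, `bias` (equal
#'   lengths, recorded every `record_stride` steps), `seed`, `escaped`,
#'   `escape_step`, `escape_position`, `dt`, `kT`, `method`.
#' @export
simulate_langevin <- function(scenario, bias = NULL, params = sim_params(),
                              noise = TRUE) {
  stopifnot(inherits(scenario, "scenario_spec"),
            inherits(params, "sim_params"))
  surf <- scenario$surface
  gradU <- surf$gradient
  lo <- surf$domain[1]; hi <- surf$domain[2]
  thr <- scenario$absorbing_threshold
  dt <- params$dt; kT <- params$kT; D0 <- params$D0
  mob <- D0 / kT * dt
  sig <- if (noise) sqrt(2 * D0 * dt) else 0
  n_max <- params$max_steps
  stride <- params$record_stride
  has_bias <- !is.null(bias)
  is_opes <- inherits(bias, "opes_state")
  pace <- if (is_opes) bias$pace else 0L

  n_rec_max <- n_max %/% stride + 1L
  rec_t <- numeric(n_rec_max); rec_y <- numeric(n_rec_max)
  rec_v <- numeric(n_rec_max)
  n_rec <- 0L

  set.seed(params$seed)
  chunk <- 65536L
  xi <- if (noise) stats::rnorm(chunk) else numeric(0)
  ix <- 0L

  y <- scenario$start_position
  escaped <- FALSE; escape_step <- NA_integer_
  step <- 0L
  repeat {
    if (is_opes && pace > 0L && step %% pace == 0L) opes_update(bias, y)
    if (has_bias) {
      v <- bias_energy(bias, y)
      if (v < -1e-9)
        stop("bias energy negative at y = ", y, " (contract violation)",
             call. = FALSE)
      gv <- bias_gradient(bias, y)
    } else {
      v <- 0; gv <- 0
    }
    if (step %% stride == 0L) {
      n_rec <- n_rec + 1L
      rec_t[n_rec] <- step * dt; rec_y[n_rec] <- y; rec_v[n_rec] <- v
    }
    g <- gradU(y) + gv
    if (!is.finite(g))
      stop("non-finite force at step ", step, " (y = ", y, ")",
           call. = FALSE)
    if (noise) {
      ix <- ix + 1L
      if (ix > chunk) { xi <- stats::rnorm(chunk); ix <- 1L }
      y <- y - g * mob + sig * xi[ix]
    } else {
      y <- y - g * mob
    }
    if (y < lo) y <- 2 * lo - y
    if (y > hi) y <- 2 * hi - y
    step <- step + 1L
    if (abs(y) >= thr) { escaped <- TRUE; escape_step <- step; break }
    if (step >= n_max) break
  }
  structure(list(times = rec_t[seq_len(n_rec)], cv = rec_y[seq_len(n_rec)],
                 bias = rec_v[seq_len(n_rec)], seed = params$seed,
                 escaped = escaped, escape_step = escape_step,
                 escape_position = if (escaped) y else NA_real_,
                 n_steps = step, dt = dt, kT = kT,
                 method = if (is_opes) "opes_f"
                          else if (has_bias) "biased" else "unbiased"),
            class = "trajectory")
}

#' @export
print.trajectory <- function(x, ...) {
  cat(sprintf("Trajectory (%s): %d steps, %d recorded, seed %d\n",
              x$method, x$n_steps, length(x$times), x$seed))
  if (x$escaped)
    cat(sprintf("  escaped at step %d (t_MD = %.6g, y = %.4g)\n",
                x$escape_step, x$escape_step * x$dt, x$escape_position))
  else cat("  censored: no escape within max_steps\n")
  invisible(x)
}

#' Constant bias
#'
#' A spatially uniform bias of height `V0`, exerting no force. Used in
#' fixtures and identity tests of the time-rescaling relation (constant
#' bias accelerates apparent time by exactly `exp(V0/kT)`).
#'
#' @param V0 bias height (kT units), nonnegative.
#' @return An object of class `constant_bias`.
#' @export
constant_bias <- function(V0) {
  stopifnot(is.numeric(V0), length(V0) == 1L, is.finite(V0), V0 >= 0)
  structure(list(V0 = V0), class = "constant_bias")
}

#' Evaluate a bias potential
#'
#' Generic over the package's bias types ([gambes_bias()], [opes_state()],
#' [constant_bias()]): `bias_energy` returns `V(s)` (always >= 0 by the
#' package-wide shift convention), `bias_gradient` returns `dV/ds`.
#'
#' @param bias a bias object.
#' @param s CV value(s).
#' @return Numeric vector.
#' @export
bias_energy <- function(bias, s) UseMethod("bias_energy")

#' @rdname bias_energy
#' @export
bias_gradient <- function(bias, s) UseMethod("bias_gradient")

#' @export
bias_energy.constant_bias <- function(bias, s) rep(bias$V0, length(s))

#' @export
bias_gradient.constant_bias <- function(bias, s) rep(0, length(s))
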