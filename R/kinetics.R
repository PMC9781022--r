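#' Rescale a biased trajectory to physical time
#'
#' Hyperdynamics-style rescaling: an escaped biased run with apparent
#' (simulation) time `t_MD` corresponds to the physical escape time
#' `tau_i = <exp(V/kT)> * t_MD`, where the average of the exponentiated
#' bias runs over the visited points of the biased run, each taken with the
#' bias in force at the step when the point was visited. For an unbiased
#' run the acceleration is exactly 1. The relation is valid when the bias
#' vanishes at the transition state, which both flooding biases in this
#' package enforce by construction.
#'
#' @param trajectory an escaped [simulate_langevin()] result (recorded at
#'   every step, i.e. `record_stride = 1`, for the average to be exact).
#' @param kT thermal energy; defaults to the trajectory's.
#' @return An object of class `escape_event`: `t_md`, `acceleration`,
#'   `physical_time`, `seed`, `method`.
#' @export
rescale_time <- function(trajectory, kT = trajectory$kT) {
  stopifnot(inherits(trajectory, "trajectory"))
  if (!isTRUE(trajectory$escaped))
    stop("trajectory did not escape; cannot rescale a censored run",
         call. = FALSE)
  b <- trajectory$bias
  if (any(b < -1e-9))
    stop("negative bias values violate the nonnegative-bias contract",
         call. = FALSE)
  t_md <- trajectory$escape_step * trajectory$dt
  acc <- mean(exp(b / kT))
  structure(list(t_md = t_md, acceleration = acc,
                 physical_time = acc * t_md,
                 seed = trajectory$seed, method = trajectory$method),
            class = "escape_event")
}

#' @export
print.escape_event <- function(x, ...) {
  cat(sprintf(paste0("Escape event (%s, seed %d): t_MD = %.6g, ",
                     "acceleration = %.6g, tau = %.6g\n"),
              x$method, x$seed, x$t_md, x$acceleration, x$physical_time))
  invisible(x)
}

#' Fit an exponential to exit times
#'
#' Least-squares fit of the empirical cumulative distribution (plotting
#' positions `i/n` at the sorted times) to `1 - exp(-t/tau)`, plus the
#' sample mean and standard deviation. For Poissonian escape statistics
#' `tau`, `mu` and `1/k` all estimate the same quantity; reporting the fit
#' and the moments side by side is the field's convention.
#'
#' @param times positive physical exit times, `n >= 2`.
#' @return List with `tau_fit`, `mu`, `sigma`.
#' @export
fit_exit_times <- function(times) {
  times <- as.numeric(times)
  if (length(times) < 2L)
    stop("need at least 2 exit times", call. = FALSE)
  if (any(!is.finite(times)) || any(times <= 0))
    stop("exit times must be positive and finite", call. = FALSE)
  n <- length(times)
  ts <- sort(times)
  Fi <- seq_len(n) / n
  mu <- mean(times)
  sse <- function(tau) sum((Fi - (1 - exp(-ts / tau)))^2)
  opt <- stats::optimize(sse, interval = mu * c(1e-3, 1e3))
  list(tau_fit = opt$minimum, mu = mu, sigma = stats::sd(times))
}

#' Kolmogorov-Smirnov check of Poissonian escape statistics
#'
#' One-sample KS test of the exit times against the exponential law
#' `1 - exp(-t/tau)`, with the p-value from the asymptotic Kolmogorov
#' distribution. A high p-value supports the memoryless (rare-event)
#' picture the time-rescaling relation presumes. When `tau` is estimated
#' from the same sample the p-value is mildly anti-conservative; see the
#' parametric bootstrap option of [fit_release_kinetics()].
#'
#' @param times positive exit times, `n >= 5`.
#' @param tau_fit exponential mean to test against.
#' @return List with `ks_statistic`, `p_value`.
#' @export
ks_poisson_test <- function(times, tau_fit) {
  times <- as.numeric(times)
  if (length(times) < 5L)
    stop("need at least 5 exit times for the KS check; run more simulations",
         call. = FALSE)
  check_positive(tau_fit = tau_fit)
  kt <- suppressWarnings(
    stats::ks.test(times, "pexp", rate = 1 / tau_fit, exact = FALSE))
  list(ks_statistic = unname(kt$statistic), p_value = kt$p.value)
}

#' Fit release kinetics to an ensemble of escape times
#'
#' The package's central estimator. Given physical escape times (or a table
#' of escape events from [run_escape_ensemble()]), fits the exponential
#' exit-time law, reports the release time `tau`, rate `k = 1/tau`, moments
#' `mu +- sigma`, and the Kolmogorov-Smirnov check of Poissonian
#' statistics.
#'
#' @param times positive escape times, or a data frame with a
#'   `physical_time` column (e.g. the `$events` table of an ensemble).
#' @param kT thermal energy (carried for reporting).
#' @param n_boot if > 0, also compute a parametric-bootstrap p-value: the
#'   KS statistic is recomputed on `n_boot` synthetic samples drawn from
#'   the fitted exponential with `tau` re-fit on each, and the p-value is
#'   the fraction of synthetic statistics at least as large as the
#'   observed one. This corrects the mild anti-conservatism of testing
#'   against a self-fitted `tau`.
#' @param censored number of censored (non-escaping) runs excluded
#'   upstream; carried into the summary.
#' @param method label of the sampling method that produced the times.
#' @return An object of class `release_kinetics` with fields `n_events`,
#'   `tau_fit`, `rate`, `mu`, `sigma`, `ks_statistic`, `p_value`,
#'   `p_boot` (if requested), `censored`, `times`, `method`.
#' @seealso [summary.release_kinetics()], [predict.release_kinetics()],
#'   [plot.release_kinetics()]
#' @export
fit_release_kinetics <- function(times, kT = 1, n_boot = 0L, censored = 0L,
                                 method = "unspecified") {
  if (is.data.frame(times)) {
    stopifnot("physical_time" %in% names(times))
    events <- times
    times <- events$physical_time
  } else events <- NULL
  fit <- fit_exit_times(times)
  ks <- ks_poisson_test(times, fit$tau_fit)
  p_boot <- NULL
  if (n_boot > 0L) {
    n <- length(times)
    stat_boot <- replicate(n_boot, {
      x <- stats::rexp(n, rate = 1 / fit$tau_fit)
      f <- fit_exit_times(x)
      ks_poisson_test(x, f$tau_fit)$ks_statistic
    })
    p_boot <- mean(stat_boot >= ks$ks_statistic)
  }
  structure(list(n_events = length(times), tau_fit = fit$tau_fit,
                 rate = 1 / fit$tau_fit, mu = fit$mu, sigma = fit$sigma,
                 ks_statistic = ks$ks_statistic, p_value = ks$p_value,
                 p_boot = p_boot, censored = as.integer(censored),
                 times = as.numeric(times), events = events,
                 kT = kT, method = method),
            class = "release_kinetics")
}

#' @export
print.release_kinetics <- function(x, digits = 4, ...) {
  cat(sprintf("Release kinetics (%s): n = %d event(s)", x$method,
              x$n_events))
  if (x$censored > 0L) cat(sprintf(" (+%d censored)", x$censored))
  cat("\n")
  cat(sprintf("  tau = %.*g   k = 1/tau = %.*g\n", digits, x$tau_fit,
              digits, x$rate))
  cat(sprintf("  mu +- sigma = %.*g +- %.*g\n", digits, x$mu, digits,
              x$sigma))
  cat(sprintf("  KS statistic %.*g, p = %.*g", digits, x$ks_statistic,
              digits, x$p_value))
  if (!is.null(x$p_boot))
    cat(sprintf(" (parametric bootstrap p = %.*g)", digits, x$p_boot))
  cat("\n")
  invisible(x)
}

#' @export
summary.release_kinetics <- function(object, ...) {
  out <- data.frame(n = object$n_events, tau = object$tau_fit,
                    k = object$rate, p_value = object$p_value,
                    mu = object$mu, sigma = object$sigma,
                    censored = object$censored, row.names = object$method)
  class(out) <- c("summary.release_kinetics", "data.frame")
  out
}

#' @export
coef.release_kinetics <- function(object, ...) {
  c(tau = object$tau_fit, k = object$rate)
}

#' @export
predict.release_kinetics <- function(object, times,
                                     type = c("cdf", "survival", "density"),
                                     ...) {
  type <- match.arg(type)
  switch(type,
         cdf = stats::pexp(times, rate = object$rate),
         survival = stats::pexp(times, rate = object$rate,
                                lower.tail = FALSE),
         density = stats::dexp(times, rate = object$rate))
}

#' @export
residuals.release_kinetics <- function(object, ...) {
  ts <- sort(object$times)
  seq_along(ts) / length(ts) - stats::pexp(ts, rate = object$rate)
}

#' @export
simulate.release_kinetics <- function(object, nsim = 1, seed = NULL, ...) {
  if (!is.null(seed)) set.seed(seed)
  replicate(nsim, stats::rexp(object$n_events, rate = object$rate),
            simplify = FALSE)
}

#' @export
plot.release_kinetics <- function(x, ...) {
  ts <- sort(x$times)
  graphics::plot(stats::ecdf(ts), verticals = TRUE, do.points = FALSE,
                 main = sprintf("Exit-time distribution (%s)", x$method),
                 xlab = "physical escape time", ylab = "cumulative fraction",
                 ...)
  tt <- seq(0, max(ts) * 1.05, length.out = 400)
  graphics::lines(tt, stats::pexp(tt, rate = x$rate), col = 2, lwd = 2)
  graphics::legend("bottomright", bty = "n", col = c(1, 2), lwd = c(1, 2),
                   legend = c("empirical",
                              sprintf("1 - exp(-t/%.3g)", x$tau_fit)))
  invisible(x)
}

#' Run an ensemble of escape simulations and fit the kinetics
#'
#' Runs `n_runs` independent seeded simulations of a scenario (seeds
#' `base_seed + 1 .. base_seed + n_runs`), rescales each escaped run to
#' physical time, and fits the exit-time distribution. For the static
#' mixture bias the bound state is sampled and fitted once and the same
#' bias drives every run; for the on-the-fly flooding bias a fresh state is
#' built per run. Censored runs (no escape within `max_steps`) are excluded
#' from the fit; their count is reported and a warning is raised when more
#' than 20 percent of the ensemble is censored.
#'
#' @param scenario a [scenario_spec()].
#' @param method `"unbiased"`, `"gambes"` (static mixture bias) or
#'   `"opes_f"` (on-the-fly flooding bias).
#' @param n_runs ensemble size, at least 5.
#' @param base_seed integer; run `i` uses seed `base_seed + i`.
#' @param config named list of method/engine settings; recognized entries
#'   (with defaults): `dt` (1e-3), `max_steps` (1e6), `e_cut` (6 kT),
#'   `gamma` (10), `pace` (100), `excluded` (half the distance to the
#'   nearest edge of the scenario's bound region, so the barrier approach
#'   stays bias-free and the bias growth is quasi-static before escape),
#'   `n_components` (3), `bound_steps` (2e5), `sigma` (bandwidth
#'   override), `n_boot` (0).
#' @return A [fit_release_kinetics()] object whose `$events` holds the
#'   per-run table (seed, t_md, acceleration, physical_time, method).
#' @export
run_escape_ensemble <- function(scenario,
                                method = c("unbiased", "gambes", "opes_f"),
                                n_runs = 25L, base_seed = 1L,
                                config = list()) {
  method <- match.arg(method)
  if (n_runs < 5L) stop("n_runs must be at least 5", call. = FALSE)
  cfg <- utils::modifyList(
    list(dt = 1e-3, max_steps = 1e6L, e_cut = 6, gamma = 10, pace = 100L,
         # deposit only within half the distance to the nearest edge of the
         # bound region: the barrier approach must stay bias-free
         excluded = 0.5 * min(abs(scenario$bound_region)),
         n_components = 3L, bound_steps = 2e5, sigma = NULL, n_boot = 0L),
    config)
  static_bias <- NULL
  sigma <- cfg$sigma
  if (method == "gambes") {
    samples <- sample_bound_state(scenario, n_steps = cfg$bound_steps,
                                  seed = base_seed, dt = cfg$dt)
    mix <- fit_mixture(samples, n_components = cfg$n_components,
                       seed = base_seed)
    static_bias <- gambes_bias(mix, e_cut = cfg$e_cut, kT = scenario$kT,
                               domain = scenario$surface$domain)
  } else if (method == "opes_f" && is.null(sigma)) {
    sigma <- opes_bandwidth(scenario, seed = base_seed, dt = cfg$dt)
  }
  rows <- vector("list", n_runs)
  censored <- 0L
  for (i in seq_len(n_runs)) {
    seed_i <- base_seed + i
    bias <- switch(method,
                   unbiased = NULL,
                   gambes = static_bias,
                   opes_f = opes_state(sigma = sigma, e_cut = cfg$e_cut,
                                       gamma = cfg$gamma, kT = scenario$kT,
                                       excluded = cfg$excluded,
                                       pace = cfg$pace))
    p <- sim_params(dt = cfg$dt, max_steps = cfg$max_steps,
                    kT = scenario$kT, D0 = scenario$D0, seed = seed_i)
    tr <- simulate_langevin(scenario, bias = bias, params = p)
    if (!tr$escaped) { censored <- censored + 1L; next }
    ev <- rescale_time(tr, kT = scenario$kT)
    rows[[i]] <- data.frame(seed = seed_i, t_md = ev$t_md,
                            acceleration = ev$acceleration,
                            physical_time = ev$physical_time,
                            method = method)
  }
  events <- do.call(rbind, rows[!vapply(rows, is.null, logical(1))])
  if (censored > 0.2 * n_runs)
    warning(sprintf("%d of %d runs censored (no escape within max_steps)",
                    censored, n_runs))
  if (is.null(events) || nrow(events) < 2L)
    stop("too few escaped runs to fit kinetics (", censored, " censored)",
         call. = FALSE)
  fit <- fit_release_kinetics(events, kT = scenario$kT,
                              n_boot = cfg$n_boot, censored = censored,
                              method = method)
  fit$scenario_label <- scenario$label
  fit
}

#' Flat summary of a kinetics fit
#'
#' The JSON-ready summary used by the command-line tools:
#' `{n, tau, k, mu, sigma, ks, p, censored}`.
#'
#' @param fit a [fit_release_kinetics()] object.
#' @return A named list of scalars.
#' @export
summary_list <- function(fit) {
  stopifnot(inherits(fit, "release_kinetics"))
  list(n = fit$n_events, tau = fit$tau_fit, k = fit$rate, mu = fit$mu,
       sigma = fit$sigma, ks = fit$ks_statistic, p = fit$p_value,
       censored = fit$censored)
}

#' Two-depth diffusion estimate
#'
#' Order-of-magnitude estimate of the in-host diffusion coefficient from
#' two release calculations started at different depths `y1`, `y2` with
#' exit times `t1`, `t2`: `D ~ (y2 - y1)^2 / (t2 - t1)`. Not rigorous, but
#' a useful scalar summary when in-host diffusion is the rate-limiting
#' step. Units propagate from the inputs (lengths squared over time).
#'
#' @param y1,y2 starting depths (any length unit).
#' @param t1,t2 exit times from those depths; `t2 > t1`.
#' @return An object of class `diffusion_estimate` with `y1, y2, t1, t2, D`.
#' @examples
#' # depths in cm, times in seconds -> D in cm^2/s
#' estimate_diffusion(y1 = 0, t1 = 54.4e-6, y2 = 4.0e-8, t2 = 200.0e-6)
#' @export
estimate_diffusion <- function(y1, t1, y2, t2) {
  stopifnot(is.finite(y1), is.finite(y2), is.finite(t1), is.finite(t2))
  if (t2 <= t1)
    stop("t2 must exceed t1 (deeper start, longer exit time)",
         call. = FALSE)
  structure(list(y1 = y1, y2 = y2, t1 = t1, t2 = t2,
                 D = (y2 - y1)^2 / (t2 - t1)),
            class = "diffusion_estimate")
}

#' @export
print.diffusion_estimate <- function(x, ...) {
  cat(sprintf("Two-depth diffusion estimate: D ~ (y2-y1)^2/(t2-t1) = %.4g\n",
              x$D))
  cat(sprintf("  y1 = %.4g (t1 = %.4g), y2 = %.4g (t2 = %.4g)\n",
              x$y1, x$t1, x$y2, x$t2))
  invisible(x)
}
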