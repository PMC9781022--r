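#' Fit a one-dimensional Gaussian mixture by EM
#'
#' Maximum-likelihood fit of `P(d) = sum_j w_j N(d; m_j, s2_j)` to bound-state
#' descriptor samples, by expectation-maximization. Runs `n_init` seeded
#' restarts (random-sample means, pooled variance, equal weights) and keeps
#' the best by log-likelihood; each run iterates until the log-likelihood
#' change falls below `tol` or `max_iter` iterations. Components whose
#' variance collapses below 1e-12 are pruned with a warning. The
#' log-likelihood trace of the winning run is kept in `$loglik_trace`
#' (non-decreasing, the EM guarantee).
#'
#' @param samples numeric vector of descriptor values; at least
#'   `10 * n_components`.
#' @param n_components number of Gaussian components (>= 1).
#' @param seed integer seed controlling the restarts (deterministic).
#' @param n_init number of restarts.
#' @param max_iter EM iteration cap per restart.
#' @param tol log-likelihood convergence threshold.
#' @return An object of class `gaussian_mixture`: `weights`, `means`,
#'   `variances`, `n_components`, `loglik`, `loglik_trace`.
#' @export
fit_mixture <- function(samples, n_components = 3L, seed = 1L,
                        n_init = 5L, max_iter = 500L, tol = 1e-8) {
  samples <- as.numeric(samples)
  n <- length(samples)
  n_components <- as.integer(n_components)
  if (n_components < 1L) stop("n_components must be >= 1", call. = FALSE)
  if (n < 10L * n_components)
    stop("need at least 10 * n_components samples (got ", n, ")",
         call. = FALSE)
  best <- NULL
  set.seed(as.integer(seed))
  for (init in seq_len(n_init)) {
    fit <- em_once(samples, n_components, max_iter, tol)
    if (is.null(best) || fit$loglik > best$loglik) best <- fit
  }
  pruned <- best$variances < 1e-12
  if (any(pruned)) {
    warning(sum(pruned), " degenerate component(s) pruned (variance < 1e-12)")
    keep <- !pruned
    best$weights <- best$weights[keep] / sum(best$weights[keep])
    best$means <- best$means[keep]
    best$variances <- best$variances[keep]
  }
  structure(list(n_components = length(best$weights),
                 weights = best$weights, means = best$means,
                 variances = best$variances, loglik = best$loglik,
                 loglik_trace = best$trace),
            class = "gaussian_mixture")
}

# one EM run from a random initialization (uses the current RNG stream)
em_once <- function(x, k, max_iter, tol) {
  n <- length(x)
  mu <- x[sample.int(n, k)]
  s2 <- rep(stats::var(x) + 1e-12, k)
  w <- rep(1 / k, k)
  ll_old <- -Inf
  trace <- numeric(0)
  for (it in seq_len(max_iter)) {
    # E step: responsibilities via log-sum-exp
    lp <- vapply(seq_len(k), function(j)
      log(w[j]) + stats::dnorm(x, mu[j], sqrt(s2[j]), log = TRUE),
      numeric(n))
    m <- lp[, 1L]
    if (k > 1L) for (j in 2:k) m <- pmax(m, lp[, j])
    lse <- m + log(rowSums(exp(lp - m)))
    ll <- sum(lse)
    trace <- c(trace, ll)
    r <- exp(lp - lse)
    # M step
    nk <- colSums(r)
    nk <- pmax(nk, 1e-300)
    w <- nk / n
    mu <- colSums(r * x) / nk
    s2 <- colSums(r * (outer(x, mu, "-")^2)) / nk
    s2 <- pmax(s2, 1e-300)
    if (is.finite(ll_old) && abs(ll - ll_old) < tol) break
    ll_old <- ll
  }
  list(weights = w, means = mu, variances = s2, loglik = ll, trace = trace)
}

#' Mixture density
#'
#' @param model a [fit_mixture()] result (or a list with `weights`, `means`,
#'   `variances`).
#' @param y evaluation points.
#' @return `P(y)`, the mixture probability density.
#' @export
gmm_density <- function(model, y) {
  out <- numeric(length(y))
  for (j in seq_along(model$weights))
    out <- out + model$weights[j] *
      stats::dnorm(y, model$means[j], sqrt(model$variances[j]))
  out
}

# d P / d y of the mixture
gmm_density_grad <- function(model, y) {
  out <- numeric(length(y))
  for (j in seq_along(model$weights))
    out <- out - model$weights[j] *
      stats::dnorm(y, model$means[j], sqrt(model$variances[j])) *
      (y - model$means[j]) / model$variances[j]
  out
}

#' @export
print.gaussian_mixture <- function(x, ...) {
  cat("Gaussian mixture,", x$n_components, "component(s)\n")
  print(data.frame(weight = x$weights, mean = x$means,
                   variance = x$variances))
  cat(sprintf("log-likelihood %.6g (%d EM iterations)\n",
              x$loglik, length(x$loglik_trace)))
  invisible(x)
}

#' Static Gaussian-mixture flooding bias
#'
#' Builds the static bias `V(d) = kT log((P(d) + eps) / eps)` from a fitted
#' bound-state mixture density `P`. This is the mixture-based bias
#' `(1/beta) log(P + eps)` shifted by `-kT log(eps)` so that `V = 0`
#' wherever the bound-state density vanishes -- in particular at the
#' transition state, which is the condition the time-rescaling relation
#' requires. The smoothing parameter is tied to the energy cutoff by
#' `eps = P_max exp(-E_cut/kT)` with `P_max` the density maximum (grid
#' search over the domain plus local refinement), so the bias ceiling is
#' `E_cut` at the density peak (and at most `E_cut + kT log 2` anywhere).
#'
#' @param mixture a [fit_mixture()] result.
#' @param e_cut energy cutoff (kT units); the bias never exceeds it by more
#'   than `kT log 2`.
#' @param kT thermal energy.
#' @param domain interval over which the density maximum is located;
#'   defaults to the mixture means +- 10 standard deviations.
#' @param grid_n grid points for the maximum search.
#' @return An object of class `gambes_bias`: `mixture`, `epsilon`, `e_cut`,
#'   `kT`, `p_max`, `shift` (`= -kT log(epsilon)`).
#' @export
gambes_bias <- function(mixture, e_cut, kT = 1, domain = NULL,
                        grid_n = 2001L) {
  check_positive(e_cut = e_cut, kT = kT)
  if (is.null(domain)) {
    sd_all <- sqrt(max(mixture$variances))
    domain <- range(mixture$means) + c(-10, 10) * sd_all
  }
  ys <- seq(domain[1], domain[2], length.out = grid_n)
  dens <- gmm_density(mixture, ys)
  i <- which.max(dens)
  lo <- ys[max(i - 1L, 1L)]; hi <- ys[min(i + 1L, length(ys))]
  opt <- stats::optimize(function(y) gmm_density(mixture, y),
                         c(lo, hi), maximum = TRUE)
  p_max <- max(opt$objective, dens[i])
  epsilon <- p_max * exp(-e_cut / kT)
  structure(list(mixture = mixture, epsilon = epsilon, e_cut = e_cut,
                 kT = kT, p_max = p_max, shift = -kT * log(epsilon)),
            class = "gambes_bias")
}

#' @export
bias_energy.gambes_bias <- function(bias, s) {
  P <- gmm_density(bias$mixture, s)
  bias$kT * log1p(P / bias$epsilon)
}

#' @export
bias_gradient.gambes_bias <- function(bias, s) {
  P <- gmm_density(bias$mixture, s)
  dP <- gmm_density_grad(bias$mixture, s)
  bias$kT * dP / (P + bias$epsilon)
}

#' @export
print.gambes_bias <- function(x, ...) {
  cat(sprintf(paste0("Gaussian-mixture flooding bias: E_cut = %.4g kT, ",
                     "epsilon = %.4g, P_max = %.4g\n"),
              x$e_cut, x$epsilon, x$p_max))
  print(x$mixture)
  invisible(x)
}

#' Serialize / restore a mixture bias
#'
#' JSON round-trip of the fitted mixture and bias parameters, for reuse of
#' one bound-state fit across many runs.
#'
#' @param bias a [gambes_bias()].
#' @param path file path.
#' @return `write_gambes_bias` returns `path` invisibly; `read_gambes_bias`
#'   returns the restored `gambes_bias`.
#' @export
write_gambes_bias <- function(bias, path) {
  obj <- list(weights = bias$mixture$weights, means = bias$mixture$means,
              variances = bias$mixture$variances, epsilon = bias$epsilon,
              e_cut = bias$e_cut, kT = bias$kT, p_max = bias$p_max,
              shift = bias$shift)
  jsonlite::write_json(obj, path, digits = NA, auto_unbox = TRUE)
  invisible(path)
}

#' @rdname write_gambes_bias
#' @export
read_gambes_bias <- function(path) {
  o <- jsonlite::read_json(path, simplifyVector = TRUE)
  mixture <- structure(list(n_components = length(o$weights),
                            weights = o$weights, means = o$means,
                            variances = o$variances,
                            loglik = NA_real_, loglik_trace = numeric(0)),
                       class = "gaussian_mixture")
  structure(list(mixture = mixture, epsilon = o$epsilon, e_cut = o$e_cut,
                 kT = o$kT, p_max = o$p_max, shift = o$shift),
            class = "gambes_bias")
}

#' Sample the bound state for a bias fit
#'
#' Runs a seeded unbiased trajectory confined to the scenario's
#' `bound_region` by reflecting walls (the absorbing threshold is disabled),
#' returning subsampled descriptor values for [fit_mixture()]. Default
#' length 2e5 steps subsampled every 10.
#'
#' @param scenario a [scenario_spec()].
#' @param n_steps unbiased steps.
#' @param subsample keep every this-many steps.
#' @param seed integer seed.
#' @param dt timestep.
#' @return Numeric vector of descriptor samples.
#' @export
sample_bound_state <- function(scenario, n_steps = 2e5, subsample = 10L,
                               seed = 1L, dt = 1e-3) {
  confined <- scenario
  confined$surface$domain <- scenario$bound_region
  confined$absorbing_threshold <- max(abs(scenario$bound_region)) + 1
  p <- sim_params(dt = dt, max_steps = n_steps, kT = scenario$kT,
                  D0 = scenario$D0, seed = seed,
                  record_stride = as.integer(subsample))
  tr <- simulate_langevin(confined, bias = NULL, params = p)
  tr$cv
}
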