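#' On-the-fly flooding bias state
#'
#' Mutable state of the on-the-fly probability-estimate flooding bias. The
#' CV distribution is estimated as a weighted Gaussian kernel density,
#' `P_n(s) = sum_k w_k G(s, s_k) / sum_k w_k`, with kernels deposited every
#' `pace` engine steps at the current CV value and weights
#' `w_k = exp(V_{k-1}(s_k)/kT)` computed from the bias in force just before
#' the deposition. The bias is
#' `V_n(s) = (1 - 1/gamma) kT log((P_n(s)/Z_n + eps)/eps)`,
#' the well-tempered flooding form shifted so `V = 0` wherever `P_n = 0`;
#' with `eps = exp(-E_cut/((1 - 1/gamma) kT))` the bias saturates near the
#' barrier parameter `E_cut`. `Z_n` is the mean of `P_n` over the deposited
#' kernel centres, recomputed at every update. No kernel is ever deposited
#' inside the excluded region `|s| > excluded` (which protects the
#' transition state), but the bias is evaluated -- and exerts force --
#' everywhere.
#'
#' The state is an environment (reference semantics): [opes_update()]
#' modifies it in place, which is what the engine relies on.
#'
#' @param sigma fixed kernel bandwidth (CV units); conventionally half the
#'   standard deviation of a short unbiased bound-state run.
#' @param e_cut barrier parameter / bias ceiling, kT units.
#' @param gamma well-tempered bias factor (> 1); controls how strongly the
#'   target distribution is broadened.
#' @param kT thermal energy.
#' @param excluded half-width of the excluded region: no deposition at
#'   `|s| > excluded`. Use `Inf` to disable.
#' @param pace deposit every `pace` engine steps. The default (100 steps at
#'   the default engine timestep, i.e. a few basin relaxation times) keeps
#'   the bias growth quasi-static so escapes happen after, not during, the
#'   filling transient; too slow a pace lets escapes occur mid-transient
#'   and systematically inflates the rescaled times.
#' @return An environment of class `opes_state`.
#' @export
opes_state <- function(sigma, e_cut, gamma = 10, kT = 1, excluded = Inf,
                       pace = 100L) {
  check_positive(sigma = sigma, e_cut = e_cut, kT = kT)
  if (!(gamma > 1)) stop("gamma must exceed 1", call. = FALSE)
  st <- new.env(parent = emptyenv())
  st$sigma <- sigma
  st$gamma <- gamma
  st$kT <- kT
  st$e_cut <- e_cut
  st$prefactor <- (1 - 1 / gamma) * kT
  st$epsilon <- exp(-e_cut / ((1 - 1 / gamma) * kT))
  st$excluded <- excluded
  st$pace <- as.integer(pace)
  st$centers <- numeric(0)
  st$weights <- numeric(0)
  st$zn <- 1
  class(st) <- "opes_state"
  st
}

#' @export
print.opes_state <- function(x, ...) {
  cat(sprintf(paste0("Flooding bias state: %d kernel(s), sigma = %.4g, ",
                     "gamma = %.3g, E_cut = %.4g kT\n"),
              length(x$centers), x$sigma, x$gamma, x$e_cut))
  cat(sprintf("  epsilon = %.4g, Z_n = %.6g, excluded |s| > %.4g, pace %d\n",
              x$epsilon, x$zn, x$excluded, x$pace))
  invisible(x)
}

#' Current on-the-fly probability estimate
#'
#' Weighted kernel density `P_n(s)`; returns 0 everywhere while no kernel
#' has been deposited.
#'
#' @param state an [opes_state()].
#' @param s CV value(s).
#' @return Density value(s).
#' @export
opes_probability <- function(state, s) {
  k <- length(state$centers)
  if (k == 0L) return(numeric(length(s)) * 0)
  w <- state$weights
  tot <- sum(w)
  vapply(s, function(si)
    sum(w * stats::dnorm(si, state$centers, state$sigma)) / tot,
    numeric(1))
}

#' Deposit a kernel (periodic bias update)
#'
#' Called every `pace` engine steps with the current CV value. If `s_now`
#' lies in the excluded region the state is returned unchanged (no
#' deposition). Otherwise a kernel is appended at `s_now` with weight
#' `exp(V_{k-1}(s_now)/kT)` -- the bias *before* this update -- and the
#' normalization `Z_n` is recomputed as the mean of the new `P_n` over all
#' kernel centres.
#'
#' @param state an [opes_state()]; modified in place.
#' @param s_now current CV value.
#' @return The state, invisibly.
#' @export
opes_update <- function(state, s_now) {
  if (abs(s_now) > state$excluded) return(invisible(state))
  w_new <- exp(bias_energy.opes_state(state, s_now) / state$kT)
  state$centers <- c(state$centers, s_now)
  state$weights <- c(state$weights, w_new)
  # Z_n: mean of P_n over the deposited kernel centres
  cs <- state$centers
  w <- state$weights
  tot <- sum(w)
  dens <- vapply(cs, function(ci)
    sum(w * stats::dnorm(ci, cs, state$sigma)) / tot, numeric(1))
  state$zn <- mean(dens)
  invisible(state)
}

#' @export
bias_energy.opes_state <- function(bias, s) {
  if (length(bias$centers) == 0L) return(numeric(length(s)) * 0)
  p <- opes_probability(bias, s)
  # e_cut is a hard ceiling (the "barrier" semantics): the raw form can
  # exceed it where P_n/Z_n > 1, which overfills the basin and breaks the
  # rare-event separation the rescaling relies on
  pmin(bias$prefactor * log1p(p / bias$zn / bias$epsilon), bias$e_cut)
}

#' @export
bias_gradient.opes_state <- function(bias, s) {
  k <- length(bias$centers)
  if (k == 0L) return(numeric(length(s)) * 0)
  w <- bias$weights; tot <- sum(w); sg <- bias$sigma
  vapply(s, function(si) {
    g <- stats::dnorm(si, bias$centers, sg)
    p <- sum(w * g) / tot
    raw <- bias$prefactor * log1p(p / bias$zn / bias$epsilon)
    if (raw >= bias$e_cut) return(0)   # capped region exerts no force
    dp <- -sum(w * g * (si - bias$centers)) / sg^2 / tot
    bias$prefactor * (dp / bias$zn) / (p / bias$zn + bias$epsilon)
  }, numeric(1))
}

#' Kernel bandwidth from a short bound-state run
#'
#' Fixed bandwidth rule: half the standard deviation of the CV in a short
#' seeded unbiased run confined to the bound region.
#'
#' @param scenario a [scenario_spec()].
#' @param n_steps length of the probe run.
#' @param seed integer seed.
#' @param dt timestep.
#' @return Bandwidth (CV units).
#' @export
opes_bandwidth <- function(scenario, n_steps = 2e4, seed = 1L, dt = 1e-3) {
  0.5 * stats::sd(sample_bound_state(scenario, n_steps = n_steps,
                                     subsample = 10L, seed = seed, dt = dt))
}

#' Serialize / restore a flooding-bias state
#'
#' @param state an [opes_state()].
#' @param path file path.
#' @return `write_opes_state` returns `path` invisibly; `read_opes_state`
#'   the restored state.
#' @export
write_opes_state <- function(state, path) {
  obj <- list(sigma = state$sigma, gamma = state$gamma, kT = state$kT,
              e_cut = state$e_cut, epsilon = state$epsilon,
              excluded = state$excluded, pace = state$pace,
              centers = state$centers, weights = state$weights,
              zn = state$zn)
  jsonlite::write_json(obj, path, digits = NA, auto_unbox = TRUE)
  invisible(path)
}

#' @rdname write_opes_state
#' @export
read_opes_state <- function(path) {
  o <- jsonlite::read_json(path, simplifyVector = TRUE)
  st <- opes_state(sigma = o$sigma, e_cut = o$e_cut, gamma = o$gamma,
                   kT = o$kT, excluded = as.numeric(o$excluded),
                   pace = o$pace)
  st$centers <- as.numeric(o$centers)
  st$weights <- as.numeric(o$weights)
  st$zn <- o$zn
  st
}
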