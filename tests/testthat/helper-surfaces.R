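# shared builders for test landscapes and hand-made objects

flat_surface <- function(half_width = 50) {
  potential_surface("flat", function(y) 0 * y, function(y) 0 * y,
                    c(-half_width, half_width))
}

harmonic_surface <- function(kappa = 4, half_width = 20) {
  potential_surface("harmonic",
                    function(y) 0.5 * kappa * y^2,
                    function(y) kappa * y,
                    c(-half_width, half_width),
                    params = list(kappa = kappa))
}

# a trajectory object assembled by hand (for rescaling identities)
hand_trajectory <- function(bias, dt = 1, kT = 1) {
  n <- length(bias)
  structure(list(times = (seq_len(n) - 1) * dt,
                 cv = seq(0, 1, length.out = n), bias = bias,
                 seed = 0L, escaped = TRUE, escape_step = n,
                 escape_position = 1, n_steps = n, dt = dt, kT = kT,
                 method = "biased"),
            class = "trajectory")
}

# a mixture assembled by hand (bypasses EM)
hand_mixture <- function(weights, means, variances) {
  structure(list(n_components = length(weights),
                 weights = weights / sum(weights), means = means,
                 variances = variances, loglik = NA_real_,
                 loglik_trace = numeric(0)),
            class = "gaussian_mixture")
}
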