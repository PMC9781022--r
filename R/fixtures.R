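#' Fixture specification for analysis-only tests
#'
#' Describes a synthetic set of COLVAR-dialect run files whose *rescaled*
#' exit times are, by construction, draws from an exponential with mean
#' `true_tau` -- the null hypothesis of the Poissonian escape picture. The
#' fixtures exercise the analysis pipeline (reader, rescaling, fit, KS
#' check) independently of the dynamics, so failures separate statistics
#' bugs from engine bugs.
#'
#' @param n_runs number of run files (>= 1).
#' @param true_tau mean physical exit time encoded in the files.
#' @param bias_profile `"zero"` (unbiased files), `"constant"` (flat bias
#'   `V0`, so every acceleration is exactly `exp(V0/kT)`), or `"ramp"` (a
#'   deposition-like rising bias saturating at `V0`).
#' @param V0 bias level for the constant and ramp profiles, kT.
#' @param seed base seed; file `i` is generated under `seed + i`.
#' @param dt nominal row spacing hint (rows are rescaled to the drawn
#'   apparent time).
#' @param n_rows rows per file.
#' @param kT thermal energy.
#' @return A list of class `fixture_spec`.
#' @export
fixture_spec <- function(n_runs, true_tau, bias_profile = c("zero",
                         "constant", "ramp"), V0 = 2, seed = 1L,
                         dt = 1e-3, n_rows = 100L, kT = 1) {
  bias_profile <- match.arg(bias_profile)
  stopifnot(n_runs >= 1L)
  check_positive(true_tau = true_tau, dt = dt, kT = kT)
  structure(list(n_runs = as.integer(n_runs), true_tau = true_tau,
                 bias_profile = bias_profile, V0 = V0,
                 seed = as.integer(seed), dt = dt,
                 n_rows = as.integer(n_rows), kT = kT),
            class = "fixture_spec")
}

#' Generate COLVAR fixture files
#'
#' Writes `n_runs` files `run_###.colvar` to `output_dir` plus a
#' `manifest.json` recording the seeds, the true mean exit time and the
#' per-file draws. For each file a physical exit time is drawn from
#' `Exp(true_tau)`; the bias rows follow the requested profile, the
#' acceleration is computed from those same rows, and the apparent run
#' time is set to `physical / acceleration` -- so the analysis pipeline
#' must recover `true_tau` up to Monte-Carlo error, exactly reversing the
#' construction. Byte-identical output for identical specs.
#'
#' @param spec a [fixture_spec()].
#' @param output_dir writable directory (created if missing).
#' @return The manifest, invisibly.
#' @export
generate_fixture <- function(spec, output_dir) {
  stopifnot(inherits(spec, "fixture_spec"))
  dir.create(output_dir, showWarnings = FALSE, recursive = TRUE)
  n <- spec$n_rows
  files <- sprintf("run_%03d.colvar", seq_len(spec$n_runs))
  seeds <- spec$seed + seq_len(spec$n_runs)
  draws <- numeric(spec$n_runs)
  for (i in seq_len(spec$n_runs)) {
    set.seed(seeds[i])
    t_phys <- stats::rexp(1, rate = 1 / spec$true_tau)
    draws[i] <- t_phys
    bias <- switch(spec$bias_profile,
                   zero = numeric(n),
                   constant = rep(spec$V0, n),
                   ramp = spec$V0 * pmin(1, seq_len(n) / (0.3 * n))^2)
    acc <- mean(exp(bias / spec$kT))
    t_app <- t_phys / acc
    dt_row <- t_app / n
    times <- (seq_len(n) - 1L) * dt_row
    # plausible outward drift of the CV toward the exit
    cv <- 2 * seq_len(n) / n + 0.05 * sin(seq_len(n))
    tr <- list(times = times, cv = cv, bias = bias)
    write_colvar(tr, file.path(output_dir, files[i]))
  }
  manifest <- list(true_tau = spec$true_tau,
                   bias_profile = spec$bias_profile, V0 = spec$V0,
                   base_seed = spec$seed, seeds = seeds, dt = spec$dt,
                   n_rows = spec$n_rows, kT = spec$kT, files = files,
                   physical_times = draws)
  jsonlite::write_json(manifest, file.path(output_dir, "manifest.json"),
                       digits = NA, auto_unbox = TRUE)
  invisible(manifest)
}
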