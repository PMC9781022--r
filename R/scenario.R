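#' Release scenario specification
#'
#' Bundles a potential surface with the escape problem posed on it: the
#' starting position, the absorbing threshold (escape is the first touch of
#' `|y| >= absorbing_threshold`; no persistence window), temperature and
#' diffusion coefficient. Reduced units throughout: kT = 1, D0 = 1 and
#' dimensionless lengths by default.
#'
#' @param surface a [potential_surface()].
#' @param start_position initial position, strictly inside the domain and
#'   with `|start_position| < absorbing_threshold`.
#' @param absorbing_threshold escape when `|y|` first reaches this value.
#' @param kT thermal energy (energy units of the surface).
#' @param D0 diffusion coefficient.
#' @param label scenario label.
#' @param two_exit logical; `TRUE` when the landscape is even in `y` and
#'   both exits are physical (used by the oracle geometry).
#' @param bound_region interval the bound-state sampler is confined to when
#'   fitting a flooding bias; defaults to
#'   `[-absorbing_threshold, absorbing_threshold]`.
#' @return An object of class `scenario_spec`.
#' @export
scenario_spec <- function(surface, start_position, absorbing_threshold,
                          kT = 1, D0 = 1, label = "custom",
                          two_exit = FALSE, bound_region = NULL) {
  stopifnot(inherits(surface, "potential_surface"))
  check_positive(absorbing_threshold = absorbing_threshold, kT = kT, D0 = D0)
  if (start_position <= surface$domain[1] ||
      start_position >= surface$domain[2])
    stop("start_position must lie strictly inside the surface domain",
         call. = FALSE)
  if (abs(start_position) >= absorbing_threshold)
    stop("|start_position| must be below absorbing_threshold", call. = FALSE)
  if (is.null(bound_region))
    bound_region <- c(-absorbing_threshold, absorbing_threshold)
  bound_region <- c(max(bound_region[1], surface$domain[1]),
                    min(bound_region[2], surface$domain[2]))
  structure(list(surface = surface, start_position = start_position,
                 absorbing_threshold = absorbing_threshold,
                 kT = kT, D0 = D0, label = label, two_exit = two_exit,
                 bound_region = bound_region),
            class = "scenario_spec")
}

#' @export
print.scenario_spec <- function(x, ...) {
  cat("Scenario:", x$label, "on", x$surface$name, "\n")
  cat(sprintf("  start %.3g, escape at |y| >= %.3g, kT = %.3g, D0 = %.3g\n",
              x$start_position, x$absorbing_threshold, x$kT, x$D0))
  if (!is.null(x$ground_truth_mfpt))
    cat(sprintf("  ground-truth MFPT %.6g\n", x$ground_truth_mfpt))
  invisible(x)
}

# shipped interlayer parameterization; start positions mirror a guest
# molecule at the gap centre, mid-way out, and at the edge
.shipped <- list(
  corrugation_depth = 4, corrugation_period = 1, edge_position = 6,
  solvation_drop = 2, edge_width = 0.5,
  absorbing_threshold = 8,
  starts = c(interlayer_center = 0, interlayer_mid = 3, interlayer_edge = 5.8),
  desorption_depth = 3, desorption_threshold = 4)

#' Build a shipped release scenario
#'
#' Returns one of the four canonical escape problems, with the exact oracle
#' mean first-passage time attached as `$ground_truth_mfpt`:
#' `interlayer_center`, `interlayer_mid` and `interlayer_edge` place the
#' guest molecule at the gap midpoint, mid-way out, and near the edge of the
#' interlayer surrogate (release slows sharply with penetration depth);
#' `surface_desorption` is fast escape from a single shallow binding well.
#'
#' @param label one of `"interlayer_center"`, `"interlayer_mid"`,
#'   `"interlayer_edge"`, `"surface_desorption"`.
#' @param overrides named list overriding surface or scenario parameters
#'   (e.g. `list(corrugation_depth = 3, start_position = 2)`).
#' @param ground_truth logical; attach the oracle MFPT (default `TRUE`).
#' @return A [scenario_spec()] with `$ground_truth_mfpt` (and the full
#'   oracle result in `$oracle`).
#' @export
build_scenario <- function(label = c("interlayer_center", "interlayer_mid",
                                     "interlayer_edge", "surface_desorption"),
                           overrides = list(), ground_truth = TRUE) {
  label <- match.arg(label)
  p <- utils::modifyList(.shipped, overrides)
  if (label == "surface_desorption") {
    surf <- make_single_well(depth = p$desorption_depth)
    start <- if (!is.null(overrides$start_position)) overrides$start_position
             else 0
    sc <- scenario_spec(surf, start_position = start,
                        absorbing_threshold = p$desorption_threshold,
                        label = label, two_exit = TRUE)
  } else {
    surf <- make_interlayer_surrogate(
      corrugation_depth = p$corrugation_depth,
      corrugation_period = p$corrugation_period,
      edge_position = p$edge_position,
      solvation_drop = p$solvation_drop,
      edge_width = p$edge_width)
    start <- if (!is.null(overrides$start_position)) overrides$start_position
             else unname(p$starts[[label]])
    sc <- scenario_spec(surf, start_position = start,
                        absorbing_threshold = p$absorbing_threshold,
                        label = label, two_exit = TRUE,
                        bound_region = c(-p$edge_position, p$edge_position))
  }
  if (ground_truth) {
    orc <- scenario_mfpt(sc)
    sc$oracle <- orc
    sc$ground_truth_mfpt <- orc$mfpt
  }
  sc
}

#' Double-well validation scenario
#'
#' A quartic double well translated so the bound minimum sits at `y = 0`,
#' the barrier at `y = a`, and the product minimum at `y = 2a`; escape is
#' `|y| >= 2a`. The translation keeps the package-wide symmetric escape
#' rule meaningful: the left outer wall (`64 B` at `y = -2a`) makes the
#' second exit unreachable, so the oracle geometry is reflect-at-domain-edge
#' / absorb-at-`2a`.
#'
#' @param barrier_height barrier in kT.
#' @param well_separation distance `2a` between minima.
#' @param ground_truth attach the oracle MFPT.
#' @return A [scenario_spec()] labelled `"double_well"`.
#' @export
scenario_double_well <- function(barrier_height, well_separation = 2,
                                 ground_truth = TRUE) {
  a <- well_separation / 2
  surf <- shift_surface(make_double_well(barrier_height, well_separation), a)
  sc <- scenario_spec(surf, start_position = 0, absorbing_threshold = 2 * a,
                      label = "double_well", two_exit = FALSE,
                      bound_region = c(surf$domain[1], a))
  if (ground_truth) {
    orc <- scenario_mfpt(sc)
    sc$oracle <- orc
    sc$ground_truth_mfpt <- orc$mfpt
  }
  sc
}
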