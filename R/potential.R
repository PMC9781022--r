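#' One-dimensional potential-energy surfaces
#'
#' A `potential_surface` is an evaluable one-dimensional energy landscape:
#' an energy function, its analytic gradient, a closed domain, and the kind
#' of boundary at each end. All energies are in units of kT (reduced units)
#' unless stated otherwise; lengths are dimensionless. Surfaces stand in for
#' the free-energy profile along the release coordinate of a drug-excipient
#' complex (here, the displacement of a guest molecule from the midpoint of
#' a layered host).
#'
#' @param name character label.
#' @param energy vectorized function of position returning energy (kT).
#' @param gradient vectorized function of position returning dU/dy (kT/length).
#' @param domain numeric length-2, closed interval `[y_min, y_max]`.
#' @param boundary character length-2, one of `"reflecting"`, `"absorbing"`,
#'   `"open"` for the lower and upper end.
#' @param params named list of the parameters the surface was built from.
#'
#' @return An object of class `potential_surface`.
#' @seealso [make_double_well()], [make_interlayer_surrogate()],
#'   [make_single_well()], [shift_surface()]
#' @export
potential_surface <- function(name, energy, gradient, domain,
                              boundary = c("reflecting", "reflecting"),
                              params = list()) {
  stopifnot(is.function(energy), is.function(gradient),
            is.numeric(domain), length(domain) == 2L, domain[1] < domain[2])
  boundary <- match.arg(boundary, c("reflecting", "absorbing", "open"),
                        several.ok = TRUE)
  if (length(boundary) == 1L) boundary <- rep(boundary, 2L)
  structure(list(name = name, energy = energy, gradient = gradient,
                 domain = as.numeric(domain), boundary = boundary,
                 params = params),
            class = "potential_surface")
}

#' @export
print.potential_surface <- function(x, ...) {
  cat("Potential surface:", x$name, "\n")
  cat("  domain: [", x$domain[1], ",", x$domain[2], "]  boundaries:",
      paste(x$boundary, collapse = " / "), "\n")
  if (length(x$params))
    cat("  params:", paste(names(x$params), unlist(x$params),
                           sep = " = ", collapse = ", "), "\n")
  invisible(x)
}

#' Evaluate a surface's energy or gradient
#'
#' @param surface a [potential_surface()].
#' @param y numeric vector of positions.
#' @return Numeric vector of energies (kT) or gradients (kT/length).
#' @export
pot_energy <- function(surface, y) surface$energy(y)

#' @rdname pot_energy
#' @export
pot_gradient <- function(surface, y) surface$gradient(y)

check_positive <- function(...) {
  vals <- list(...)
  bad <- names(vals)[!vapply(vals, function(v) is.numeric(v) && length(v) == 1L &&
                               is.finite(v) && v > 0, logical(1))]
  if (length(bad))
    stop("parameter(s) must be positive finite scalars: ",
         paste(bad, collapse = ", "), call. = FALSE)
  invisible(TRUE)
}

#' Symmetric quartic double well
#'
#' `U(y) = B (1 - (y/a)^2)^2` with `a = well_separation/2`: minima at
#' `y = -a, +a` where `U = 0`, and a barrier of height `B` at `y = 0`.
#' The standard validation landscape for rare-event machinery.
#'
#' @param barrier_height barrier `B` in kT, positive.
#' @param well_separation distance between the two minima (`= 2a`), positive.
#' @return A [potential_surface()] on `[-3a, 3a]` with reflecting boundaries.
#' @examples
#' dw <- make_double_well(7, 2)
#' pot_energy(dw, c(-1, 0, 1))   # 0, 7, 0
#' @export
make_double_well <- function(barrier_height, well_separation) {
  check_positive(barrier_height = barrier_height,
                 well_separation = well_separation)
  a <- well_separation / 2
  B <- barrier_height
  potential_surface(
    name = "double_well",
    energy = function(y) B * (1 - (y / a)^2)^2,
    gradient = function(y) -4 * B * y * (1 - (y / a)^2) / a^2,
    domain = c(-3 * a, 3 * a),
    boundary = c("reflecting", "reflecting"),
    params = list(barrier_height = B, well_separation = well_separation))
}

#' Interlayer release surrogate
#'
#' An even surrogate for the free-energy profile of a guest molecule moving
#' along the gap between two host layers toward either open edge. Inside the
#' gap (`|y| <= edge_position`) the profile is a periodic corrugation
#' `depth * sin^2(pi y / period)`, mimicking the succession of binding sites
#' the molecule hops between while it diffuses. Past the edge the energy
#' descends smoothly (logistically, over a few `edge_width`) by
#' `solvation_drop` to a flat solvent plateau at `-solvation_drop`, and the
#' corrugation switches off with the same smooth factor, so `U` is
#' continuous and differentiable everywhere.
#'
#' @param corrugation_depth barrier between adjacent binding sites, kT.
#' @param corrugation_period spacing of binding sites, length units.
#' @param edge_position half-length of the interlayer gap; must exceed
#'   `corrugation_period`.
#' @param solvation_drop free-energy gain on solvation, kT.
#' @param edge_width length scale of the edge crossover.
#' @return A [potential_surface()], even in `y`, with reflecting boundaries
#'   at `+- (edge_position + 12 * edge_width)`.
#' @export
make_interlayer_surrogate <- function(corrugation_depth = 4,
                                      corrugation_period = 1,
                                      edge_position = 6,
                                      solvation_drop = 2,
                                      edge_width = 0.5) {
  check_positive(corrugation_depth = corrugation_depth,
                 corrugation_period = corrugation_period,
                 edge_position = edge_position,
                 solvation_drop = solvation_drop,
                 edge_width = edge_width)
  if (edge_position <= corrugation_period)
    stop("edge_position must exceed corrugation_period", call. = FALSE)
  d <- corrugation_depth; p <- corrugation_period
  e <- edge_position; drop <- solvation_drop; w <- edge_width
  # Crossover centred 2w past the edge, scale w/4: the switch is < 4e-4 at
  # |y| = edge_position, so the corrugation form holds inside the gap, and
  # within 1e-6 of its plateau by |y| = edge_position + 6w.
  sw <- function(ay) stats::plogis((ay - e - 2 * w) / (w / 4))
  energy <- function(y) {
    ay <- abs(y)
    s <- sw(ay)
    d * sin(pi * y / p)^2 * (1 - s) - drop * s
  }
  gradient <- function(y) {
    ay <- abs(y)
    s <- sw(ay)
    ds <- s * (1 - s) / (w / 4) * sign(y)   # d s(|y|) / dy
    corr <- d * sin(pi * y / p)^2
    dcorr <- d * pi / p * sin(2 * pi * y / p)
    dcorr * (1 - s) - corr * ds - drop * ds
  }
  potential_surface(
    name = "interlayer_surrogate",
    energy = energy, gradient = gradient,
    domain = c(-(e + 12 * w), e + 12 * w),
    boundary = c("reflecting", "reflecting"),
    params = list(corrugation_depth = d, corrugation_period = p,
                  edge_position = e, solvation_drop = drop, edge_width = w))
}

#' Single-well surface-desorption surrogate
#'
#' A Gaussian binding well, `U(y) = depth * (1 - exp(-y^2 / (2 width^2)))`:
#' zero at the bound minimum, rising to a flat plateau of height `depth`.
#' Models fast desorption of a molecule physisorbed on an open surface,
#' where escape needs no enhanced sampling.
#'
#' @param depth well depth in kT.
#' @param width Gaussian width of the well, length units.
#' @return A [potential_surface()] on `[-6 width, 6 width]`.
#' @export
make_single_well <- function(depth = 3, width = 1) {
  check_positive(depth = depth, width = width)
  potential_surface(
    name = "single_well",
    energy = function(y) depth * (1 - exp(-y^2 / (2 * width^2))),
    gradient = function(y) depth * y / width^2 * exp(-y^2 / (2 * width^2)),
    domain = c(-6 * width, 6 * width),
    boundary = c("reflecting", "reflecting"),
    params = list(depth = depth, width = width))
}

#' Translate a surface along the coordinate
#'
#' Returns the surface with `U_new(y) = U(y - by)`; domain and boundaries
#' shift with it. Used to place a double-well's bound minimum at the origin
#' so the symmetric escape rule `|y| >= threshold` addresses the product
#' side only.
#'
#' @param surface a [potential_surface()].
#' @param by shift amount.
#' @return A shifted [potential_surface()].
#' @export
shift_surface <- function(surface, by) {
  stopifnot(is.numeric(by), length(by) == 1L, is.finite(by))
  e <- surface$energy; g <- surface$gradient
  potential_surface(
    name = paste0(surface$name, "_shifted"),
    energy = function(y) e(y - by),
    gradient = function(y) g(y - by),
    domain = surface$domain + by,
    boundary = surface$boundary,
    params = c(surface$params, list(shift = by)))
}

#' Check gradient-energy consistency of a surface
#'
#' Compares the analytic gradient with a central finite difference of the
#' energy on a grid of interior points. Used by the test suite for every
#' shipped surface.
#'
#' @param surface a [potential_surface()].
#' @param n number of interior grid points (at least 100).
#' @param h finite-difference step.
#' @return Maximum relative deviation (relative to `max(|grad|, 1)`),
#'   invisibly; the grid and deviations as attributes.
#' @export
check_gradient <- function(surface, n = 201, h = 1e-6) {
  dom <- surface$domain
  pad <- 2 * h + 1e-9 * diff(dom)
  ys <- seq(dom[1] + pad, dom[2] - pad, length.out = max(n, 100L))
  fd <- (pot_energy(surface, ys + h) - pot_energy(surface, ys - h)) / (2 * h)
  an <- pot_gradient(surface, ys)
  rel <- abs(an - fd) / pmax(abs(an), 1)
  structure(max(rel), grid = ys, rel = rel)
}
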