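#' Funnel-shaped restraint geometry
#'
#' Defines the cone-plus-cylinder restraint used to confine a dissociating
#' ligand: a cone of half-aperture `alpha` (measured from the axis) opens
#' around the binding pocket and merges into a cylinder of radius `r_cyl` at
#' axial distance `z_cc` from the funnel origin. Confining the unbound state
#' to a cylinder of known cross-section is what makes the standard-state
#' binding free energy recoverable from a one-dimensional potential of mean
#' force (see [binding_delta_g()]).
#'
#' The axis is user input: the package never infers it from a structure.
#' In a protein application it is placed along the ligand egress channel
#' (identified e.g. by random accelerated MD).
#'
#' @param origin Numeric 3-vector, nm. Anchor point of the axis inside the
#'   binding pocket.
#' @param axis Numeric 3-vector giving the egress direction; normalised on
#'   construction (must be non-zero).
#' @param z_cc Cone-to-cylinder switch distance, nm (> 0).
#' @param r_cyl Cylinder radius, nm (> 0).
#' @param alpha Cone half-aperture from the axis, rad (in (0, pi/2)).
#' @param k_wall One-sided harmonic wall stiffness, kJ mol^-1 nm^-2 (> 0).
#'   The default (10000) keeps toy particles inside the funnel for all but
#'   < 0.1\% of recorded frames at 300 K.
#'
#' @return An object of class `funnel_geometry`.
#' @examples
#' geom <- funnel_geometry(z_cc = 0.5, r_cyl = 0.1, alpha = 1.1)
#' funnel_radius(c(0.3, 0.5, 0.7), geom)
#' @export
funnel_geometry <- function(origin = c(0, 0, 0), axis = c(0, 0, 1),
                            z_cc = 0.5, r_cyl = 0.1, alpha = 1.1,
                            k_wall = 10000) {
  origin <- as.numeric(origin)
  axis <- as.numeric(axis)
  if (length(origin) != 3 || length(axis) != 3)
    abort("`origin` and `axis` must be numeric 3-vectors")
  nrm <- sqrt(sum(axis^2))
  if (!is.finite(nrm) || nrm < 1e-12) abort("`axis` must be non-zero")
  axis <- axis / nrm
  if (!is.finite(z_cc) || z_cc <= 0) abort("`z_cc` must be > 0")
  if (!is.finite(r_cyl) || r_cyl <= 0) abort("`r_cyl` must be > 0")
  if (!is.finite(alpha) || alpha <= 0 || alpha >= pi / 2)
    abort("`alpha` must lie in (0, pi/2)")
  if (!is.finite(k_wall) || k_wall <= 0) abort("`k_wall` must be > 0")
  structure(
    list(origin = origin, axis = axis, z_cc = z_cc, r_cyl = r_cyl,
         alpha = alpha, k_wall = k_wall),
    class = "funnel_geometry")
}

#' @export
print.funnel_geometry <- function(x, ...) {
  cat("<funnel_geometry>\n")
  cat(sprintf("  origin: (%.3f, %.3f, %.3f) nm  axis: (%.3f, %.3f, %.3f)\n",
              x$origin[1], x$origin[2], x$origin[3],
              x$axis[1], x$axis[2], x$axis[3]))
  cat(sprintf("  z_cc: %.3f nm  r_cyl: %.3f nm  alpha: %.3f rad  k_wall: %g kJ/mol/nm^2\n",
              x$z_cc, x$r_cyl, x$alpha, x$k_wall))
  invisible(x)
}

# coerce for the C++ layer
as_funnel_list <- function(geom) {
  if (is.null(geom)) return(list())
  stopifnot(inherits(geom, "funnel_geometry"))
  list(origin = geom$origin, axis = geom$axis, z_cc = geom$z_cc,
       r_cyl = geom$r_cyl, alpha = geom$alpha, k_wall = geom$k_wall)
}

#' Funnel radius profile along the axis
#'
#' Radius of the accessible region at axial coordinate `z`: constant `r_cyl`
#' in the cylinder section (`z >= z_cc`), opening linearly with slope
#' `tan(alpha)` toward the pocket (`z < z_cc`). Continuous at the switch and
#' never below `r_cyl`.
#'
#' @param z Axial coordinate(s), nm (vectorised).
#' @param geom A [funnel_geometry()].
#' @return Radius (radii), nm.
#' @export
funnel_radius <- function(z, geom) {
  stopifnot(inherits(geom, "funnel_geometry"))
  ifelse(z >= geom$z_cc, geom$r_cyl,
         geom$r_cyl + (geom$z_cc - z) * tan(geom$alpha))
}

#' Axial/radial decomposition of positions
#'
#' Splits positions into the axial coordinate `z` (projection onto the funnel
#' axis measured from the origin) and the radial distance `rho` from the
#' axis, so that `pos = origin + z * axis + rho * (unit radial)`.
#'
#' @param pos A numeric 3-vector or an n x 3 matrix of positions, nm.
#' @inheritParams funnel_radius
#' @return A tibble with columns `z` and `rho` (nm), one row per position.
#' @export
axial_decompose <- function(pos, geom) {
  stopifnot(inherits(geom, "funnel_geometry"))
  pos <- to_coord_matrix(pos)
  d <- sweep(pos, 2, geom$origin)
  z <- drop(d %*% geom$axis)
  radial <- d - outer(z, geom$axis)
  tibble(z = z, rho = sqrt(rowSums(radial^2)))
}

#' One-sided harmonic funnel wall energy
#'
#' Zero inside the funnel (radial distance `rho <= funnel_radius(z)`), and
#' `k_wall/2 * (rho - funnel_radius(z))^2` outside; continuous and once
#' differentiable across the wall.
#'
#' @inheritParams axial_decompose
#' @return Energy (energies), kJ mol^-1, one per position.
#' @examples
#' geom <- funnel_geometry(k_wall = 1000)
#' # 0.1 nm beyond the cylinder wall at z = 1: (1000/2) * 0.01 = 5 kJ/mol
#' wall_energy(c(0.2, 0, 1), geom)
#' @export
wall_energy <- function(pos, geom) {
  stopifnot(inherits(geom, "funnel_geometry"))
  dec <- axial_decompose(pos, geom)
  excess <- pmax(dec$rho - funnel_radius(dec$z, geom), 0)
  0.5 * geom$k_wall * excess^2
}

to_coord_matrix <- function(pos) {
  if (is.matrix(pos)) {
    if (ncol(pos) != 3) abort("position matrix must have 3 columns")
    return(pos)
  }
  if (length(pos) != 3) abort("a position must be a 3-vector or n x 3 matrix")
  matrix(as.numeric(pos), nrow = 1)
}
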