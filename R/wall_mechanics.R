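#' Lame hoop stress in a thick-walled cylinder
#'
#' Circumferential (hoop) stress at radius `r` of a linear-elastic
#' thick-walled cylinder under internal pressure `p_in` and external
#' pressure `p_out`:
#' `sigma(r) = (p_in a^2 - p_out b^2) / (b^2 - a^2) +
#'             (p_in - p_out) a^2 b^2 / ((b^2 - a^2) r^2)`
#' with `a`, `b` the inner and outer radii. `p_in` may be a vector (a
#' pressure series); `r` must be a scalar inside the wall.
#'
#' @param p_in Internal pressure(s) in Pa.
#' @param p_out External pressure in Pa.
#' @param geometry A [vessel_geometry()].
#' @param r Radius in m, `a <= r <= b`; defaults to the inner radius, where
#'   the hoop stress is largest.
#' @return Hoop stress(es) in Pa.
#' @examples
#' g <- vessel_geometry(0.008, 0.010)
#' lame_hoop_stress(1000, 0, g)          # ~4556 Pa at the inner wall
#' @export
lame_hoop_stress <- function(p_in, p_out = 0, geometry,
                             r = geometry$inner_diameter / 2) {
  stopifnot(inherits(geometry, "vessel_geometry"), is.numeric(p_in),
            is.numeric(p_out), length(p_out) == 1L, length(r) == 1L)
  a <- geometry$inner_diameter / 2
  b <- geometry$outer_diameter / 2
  if (r < a || r > b)
    stop(sprintf("radius %g m lies outside the wall [%g, %g] m", r, a, b))
  (p_in * a^2 - p_out * b^2) / (b^2 - a^2) +
    (p_in - p_out) * a^2 * b^2 / ((b^2 - a^2) * r^2)
}

#' Lame radial stress in a thick-walled cylinder
#'
#' Companion of [lame_hoop_stress()]; needed for the constitutive strain and
#' for the radial-equilibrium check `d(sigma_r)/dr + (sigma_r - sigma_t)/r = 0`.
#'
#' @inheritParams lame_hoop_stress
#' @return Radial stress(es) in Pa.
#' @export
lame_radial_stress <- function(p_in, p_out = 0, geometry,
                               r = geometry$inner_diameter / 2) {
  stopifnot(inherits(geometry, "vessel_geometry"))
  a <- geometry$inner_diameter / 2
  b <- geometry$outer_diameter / 2
  if (r < a || r > b)
    stop(sprintf("radius %g m lies outside the wall [%g, %g] m", r, a, b))
  (p_in * a^2 - p_out * b^2) / (b^2 - a^2) -
    (p_in - p_out) * a^2 * b^2 / ((b^2 - a^2) * r^2)
}

#' Constitutive hoop strain (generalized Hooke's law)
#'
#' `eps_t = (sigma_t - nu * (sigma_r + sigma_z)) / E`. When the axial
#' stress is not supplied it defaults to the plane-strain value
#' `sigma_z = nu * (sigma_t + sigma_r)`, appropriate for a long axially
#' constrained tube; pass `sigma_z = 0` for plane stress.
#'
#' @param sigma_theta Hoop stress(es) in Pa.
#' @param sigma_r Radial stress(es) in Pa.
#' @param sigma_z Axial stress(es) in Pa, or `NULL` for plane strain.
#' @param material A [wall_material()].
#' @return Dimensionless hoop strain(s).
#' @export
hoop_strain_constitutive <- function(sigma_theta, sigma_r = 0, sigma_z = NULL,
                                     material) {
  stopifnot(inherits(material, "wall_material"))
  nu <- material$poissons_ratio
  if (is.null(sigma_z)) sigma_z <- nu * (sigma_theta + sigma_r)
  (sigma_theta - nu * (sigma_r + sigma_z)) / material$youngs_modulus
}

#' Kinematic hoop strain from lumen distension
#'
#' Circumferential engineering strain implied by an area series:
#' `eps_t = (sqrt(A) - sqrt(A0)) / sqrt(A0) = dR / R0`. This is the route
#' used for probe-wise strain comparison in a 1D simulation: it inherits the
#' segment-wise stiffness through the tube law, which is exactly how the
#' location dependence of strain arises in a compliance-mismatch vessel.
#'
#' @param area_series Lumen area(s) in m^2 (> 0).
#' @param reference_area Unloaded reference area A0 in m^2.
#' @return Dimensionless hoop strain(s), one per input area.
#' @export
hoop_strain_kinematic <- function(area_series, reference_area) {
  stopifnot(all(area_series > 0), reference_area > 0)
  (sqrt(area_series) - sqrt(reference_area)) / sqrt(reference_area)
}
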