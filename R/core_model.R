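#' Blood rheology parameters
#'
#' Newtonian incompressible fluid model of blood. Defaults are the standard
#' whole-blood values used for large-artery haemodynamics.
#'
#' @param density Fluid density in kg/m^3. Must be strictly positive.
#' @param dynamic_viscosity Dynamic viscosity in Pa.s. Must be strictly
#'   positive.
#' @return An object of class `fluid_properties`.
#' @examples
#' blood <- fluid_properties()
#' blood$density / blood$dynamic_viscosity # 1/kinematic viscosity
#' @export
fluid_properties <- function(density = 1050, dynamic_viscosity = 0.0035) {
  stopifnot(is.numeric(density), length(density) == 1L, is.finite(density),
            is.numeric(dynamic_viscosity), length(dynamic_viscosity) == 1L,
            is.finite(dynamic_viscosity))
  if (density <= 0) stop("`density` must be strictly positive (kg/m^3)")
  if (dynamic_viscosity <= 0) stop("`dynamic_viscosity` must be strictly positive (Pa.s)")
  structure(list(density = density, dynamic_viscosity = dynamic_viscosity),
            class = "fluid_properties")
}

#' Linear elastic wall material
#'
#' Isotropic linear elastic description of an arterial wall segment,
#' parameterized by Young's modulus and Poisson's ratio. Nearly
#' incompressible walls use a ratio close to (but below) 0.5.
#'
#' @param youngs_modulus Young's modulus in Pa (> 0).
#' @param poissons_ratio Poisson's ratio, dimensionless, in [0, 0.5).
#' @return An object of class `wall_material`.
#' @export
wall_material <- function(youngs_modulus, poissons_ratio = 0.499) {
  stopifnot(is.numeric(youngs_modulus), length(youngs_modulus) == 1L,
            is.numeric(poissons_ratio), length(poissons_ratio) == 1L)
  if (!is.finite(youngs_modulus) || youngs_modulus <= 0)
    stop("`youngs_modulus` must be strictly positive (Pa)")
  if (!is.finite(poissons_ratio) || poissons_ratio < 0 || poissons_ratio >= 0.5)
    stop("`poissons_ratio` must lie in [0, 0.5)")
  structure(list(youngs_modulus = youngs_modulus,
                 poissons_ratio = poissons_ratio),
            class = "wall_material")
}

#' Vessel cross-section geometry
#'
#' Straight round vessel of uniform lumen. The wall thickness is derived as
#' half the diameter difference and stored for convenience.
#'
#' @param inner_diameter Lumen (inner) diameter in m.
#' @param outer_diameter Outer diameter in m; must exceed `inner_diameter`.
#' @return An object of class `vessel_geometry` with fields `inner_diameter`,
#'   `outer_diameter`, `wall_thickness` (m).
#' @export
vessel_geometry <- function(inner_diameter = 0.008, outer_diameter = 0.010) {
  stopifnot(is.numeric(inner_diameter), is.numeric(outer_diameter))
  if (!(outer_diameter > inner_diameter && inner_diameter > 0))
    stop("need outer_diameter > inner_diameter > 0")
  structure(list(inner_diameter = inner_diameter,
                 outer_diameter = outer_diameter,
                 wall_thickness = (outer_diameter - inner_diameter) / 2),
            class = "vessel_geometry")
}

#' Segmented vessel model
#'
#' A straight vessel made of consecutive axial segments, each with its own
#' wall material, preceded by an inlet extension. The lumen geometry is
#' uniform along the whole length; only wall stiffness varies, which is the
#' defining feature of a compliance-mismatch model.
#'
#' @param segments A list of segments, each a list with fields `length` (m)
#'   and `material` (a [wall_material()]).
#' @param inlet_extension_length Length in m of the inflow extension placed
#'   upstream of the first segment. The extension shares the material of the
#'   first segment.
#' @param geometry A [vessel_geometry()].
#' @param probe_positions Axial observation positions in m, measured from the
#'   inlet; all must lie within the vessel.
#' @return An object of class `segmented_vessel` with fields `segments`,
#'   `inlet_extension_length`, `geometry`, `probe_positions`, `total_length`.
#' @seealso [build_default_model()] for the stiff--compliant--stiff reference
#'   configuration, [material_at()] to query the wall at a position.
#' @export
segmented_vessel <- function(segments, inlet_extension_length, geometry,
                             probe_positions = numeric()) {
  stopifnot(is.list(segments), length(segments) >= 1L,
            inherits(geometry, "vessel_geometry"),
            is.numeric(inlet_extension_length), inlet_extension_length >= 0)
  for (seg in segments) {
    if (!is.list(seg) || is.null(seg$length) || is.null(seg$material))
      stop("each segment needs fields `length` and `material`")
    if (!(is.numeric(seg$length) && seg$length > 0))
      stop("segment lengths must be positive (m)")
    if (!inherits(seg$material, "wall_material"))
      stop("segment `material` must be a wall_material")
  }
  total <- inlet_extension_length + sum(vapply(segments, `[[`, numeric(1), "length"))
  if (any(probe_positions < 0 | probe_positions > total))
    stop("probe positions must lie in [0, total length]")
  structure(list(segments = segments,
                 inlet_extension_length = inlet_extension_length,
                 geometry = geometry,
                 probe_positions = probe_positions,
                 total_length = total),
            class = "segmented_vessel")
}

#' Default compliance-mismatch model
#'
#' Builds the reference configuration: a carotid-calibre straight vessel
#' (inner diameter 8 mm, outer diameter 10 mm) with a 30 mm inlet extension
#' followed by three 50 mm segments whose Young's moduli are 200, 5 and
#' 200 MPa -- a compliant segment sandwiched between two walls forty times
#' stiffer, as at the junctions of a stiff bypass conduit. Poisson's ratio is
#' 0.499 everywhere (nearly incompressible wall). Total length 180 mm; the
#' inlet extension carries the stiff end material. Default probes sit at 70,
#' 100 and 140 mm from the inlet: the middle of each segment, clear of the
#' entrance region.
#'
#' @return A [segmented_vessel()].
#' @examples
#' m <- build_default_model()
#' m$total_length                       # 0.18 m
#' material_at(m, 0.100)$youngs_modulus # 5e6 Pa: the compliant middle
#' @export
build_default_model <- function() {
  stiff <- wall_material(200e6, 0.499)
  compliant <- wall_material(5e6, 0.499)
  segmented_vessel(
    segments = list(
      list(length = 0.050, material = stiff),
      list(length = 0.050, material = compliant),
      list(length = 0.050, material = stiff)
    ),
    inlet_extension_length = 0.030,
    geometry = vessel_geometry(0.008, 0.010),
    probe_positions = c(0.070, 0.100, 0.140)
  )
}

#' Wall material at an axial position
#'
#' Returns the wall material of the segment containing axial position `x`
#' (m from the inlet). The inlet extension carries the first segment's
#' material. A point exactly on a junction belongs to the downstream
#' segment; the downstream convention is arbitrary but fixed, and never
#' matters for the default probes, which sit mid-segment.
#'
#' @param model A [segmented_vessel()].
#' @param x Axial position in m, `0 <= x <= model$total_length`.
#' @return A [wall_material()].
#' @export
material_at <- function(model, x) {
  stopifnot(inherits(model, "segmented_vessel"), is.numeric(x), length(x) == 1L)
  if (!is.finite(x) || x < 0 || x > model$total_length)
    stop(sprintf("position %g m outside vessel [0, %g m]", x, model$total_length))
  # upstream ends of each segment; extension belongs to segment 1
  starts <- model$inlet_extension_length +
    cumsum(c(0, vapply(model$segments, `[[`, numeric(1), "length")))
  idx <- findInterval(x, starts[-1]) + 1L   # boundary -> downstream segment
  idx <- min(idx, length(model$segments))   # x == total length -> last segment
  model$segments[[idx]]$material
}

#' @export
print.segmented_vessel <- function(x, ...) {
  cat(sprintf("Segmented vessel: %d segments + %.0f mm inlet extension, total %.0f mm\n",
              length(x$segments), 1000 * x$inlet_extension_length,
              1000 * x$total_length))
  cat(sprintf("  lumen %.1f mm / outer %.1f mm (wall %.2f mm)\n",
              1000 * x$geometry$inner_diameter, 1000 * x$geometry$outer_diameter,
              1000 * x$geometry$wall_thickness))
  pos <- x$inlet_extension_length
  for (i in seq_along(x$segments)) {
    seg <- x$segments[[i]]
    cat(sprintf("  segment %d: %.0f-%.0f mm, E = %g MPa, nu = %.3f\n",
                i, 1000 * pos, 1000 * (pos + seg$length),
                seg$material$youngs_modulus / 1e6, seg$material$poissons_ratio))
    pos <- pos + seg$length
  }
  if (length(x$probe_positions))
    cat("  probes at", paste(sprintf("%.0f", 1000 * x$probe_positions), collapse = ", "), "mm\n")
  invisible(x)
}
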