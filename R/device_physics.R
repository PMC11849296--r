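# Electrowetting and droplet-pressure models for a two-plate DMF device.
# All quantities are stored in SI internally; constructors accept the unit
# conventions of the lab (um, mm, mN/m, V_RMS) and convert at the boundary.

#' Dielectric stack of a DMF bottom plate
#'
#' Describes the insulating layer between the driving electrodes and the
#' droplet (here a parylene film under a hydrophobic topcoat), which sets the
#' areal capacitance that converts applied voltage into electrowetting force.
#'
#' @param thickness_um dielectric thickness in micrometres (default 6).
#' @param rel_permittivity relative permittivity (dimensionless, default 3.1).
#' @return an object of class `dielectric_stack` with SI fields `thickness`
#'   (m) and `rel_permittivity`.
#' @examples
#' dielectric_stack()               # 6 um parylene, eps_r = 3.1
#' dielectric_stack(12, 3.1)        # doubled thickness, half the capacitance
#' @export
dielectric_stack <- function(thickness_um = 6, rel_permittivity = 3.1) {
  if (!is.numeric(thickness_um) || length(thickness_um) != 1 || !is.finite(thickness_um) ||
      thickness_um <= 0)
    stop_invalid("invalid geometry: dielectric thickness must be a positive number")
  if (!is.numeric(rel_permittivity) || length(rel_permittivity) != 1 || rel_permittivity < 1)
    stop_invalid("invalid geometry: relative permittivity must be >= 1")
  structure(list(thickness = thickness_um * 1e-6,
                 rel_permittivity = rel_permittivity),
            class = "dielectric_stack")
}

#' Two-plate DMF device geometry
#'
#' Holds the inter-plate gap `h`, the destination (driving) electrode width
#' `w`, the shape and size of the densifying electrode (the small electrode
#' held active so a magnetically trapped bead pellet retains a droplet), and
#' the dielectric stack.
#'
#' @param gap_um inter-plate spacing in micrometres (default 190).
#' @param drive_width_mm destination electrode width `w` in mm (default 2.2).
#' @param densify_shape `"round"` or `"oval"`.
#' @param densify_minor_mm minor diameter of the densifying electrode in mm
#'   (default 1.0; this is `d` for a round electrode).
#' @param densify_major_mm major diameter in mm; defaults to the minor
#'   diameter (round).
#' @param stack a [dielectric_stack()].
#' @return an object of class `device_geometry` (SI fields).
#' @export
device_geometry <- function(gap_um = 190, drive_width_mm = 2.2,
                            densify_shape = c("round", "oval"),
                            densify_minor_mm = 1.0,
                            densify_major_mm = densify_minor_mm,
                            stack = dielectric_stack()) {
  densify_shape <- match.arg(densify_shape)
  lens <- c(gap_um = gap_um, drive_width_mm = drive_width_mm,
            densify_minor_mm = densify_minor_mm, densify_major_mm = densify_major_mm)
  if (!all(is.finite(lens)) || any(lens <= 0))
    stop_invalid("invalid geometry: all lengths must be positive")
  if (densify_minor_mm > densify_major_mm)
    stop_invalid("invalid geometry: densify_minor_mm must be <= densify_major_mm")
  if (densify_shape == "round" && densify_minor_mm != densify_major_mm)
    stop_invalid("invalid geometry: a round densifying electrode has equal axes")
  stopifnot(inherits(stack, "dielectric_stack"))
  structure(list(gap = gap_um * 1e-6,
                 drive_width = drive_width_mm * 1e-3,
                 densify_shape = densify_shape,
                 densify_minor = densify_minor_mm * 1e-3,
                 densify_major = densify_major_mm * 1e-3,
                 stack = stack),
            class = "device_geometry")
}

#' Working-fluid state
#'
#' @param sigma_mN_m liquid-filler interfacial tension in mN/m (default 42,
#'   an aqueous surfactant solution).
#' @param viscosity_mPa_s dynamic viscosity in mPa s (default 1, water-like).
#' @param k_factor dimensionless contact-angle-difference parameter in (0, 1):
#'   the fractional electrowetting reduction of the gap-curvature pressure
#'   term on actuated electrodes. Larger at higher voltage and lower
#'   surfactant concentration.
#' @param label free-text description (e.g. surfactant concentration).
#' @return an object of class `fluid_state` (SI fields `sigma` N/m,
#'   `viscosity` Pa s).
#' @export
fluid_state <- function(sigma_mN_m = 42, viscosity_mPa_s = 1,
                        k_factor = 0.6, label = "") {
  if (!is.finite(sigma_mN_m) || sigma_mN_m <= 0)
    stop_invalid("invalid fluid: sigma must be positive")
  if (!is.finite(viscosity_mPa_s) || viscosity_mPa_s <= 0)
    stop_invalid("invalid fluid: viscosity must be positive")
  if (!is.finite(k_factor) || k_factor <= 0 || k_factor >= 1)
    stop_invalid("invalid fluid: k_factor must lie strictly in (0, 1)")
  structure(list(sigma = sigma_mN_m * 1e-3,
                 viscosity = viscosity_mPa_s * 1e-3,
                 k_factor = k_factor, label = label),
            class = "fluid_state")
}

#' Electrode actuation state
#'
#' @param voltage_V RMS driving potential in volts (>= 0).
#' @param active logical; whether the electrode is energized.
#' @return an object of class `actuation_state`.
#' @export
actuation_state <- function(voltage_V, active = TRUE) {
  if (!is.finite(voltage_V) || voltage_V < 0)
    stop_invalid("invalid actuation: voltage must be >= 0")
  structure(list(voltage = voltage_V, active = isTRUE(active)),
            class = "actuation_state")
}

#' Areal capacitance of the dielectric stack
#'
#' `c = eps0 * eps_r / t`, the prerequisite quantity of the Young-Lippmann
#' relation between voltage and electrowetting force.
#'
#' @param stack a [dielectric_stack()].
#' @return areal capacitance in F/m^2.
#' @examples
#' capacitance_per_area(dielectric_stack(6, 3.1))  # ~4.57e-6 F/m^2
#' @export
capacitance_per_area <- function(stack) {
  stopifnot(inherits(stack, "dielectric_stack"))
  .EPS0 * stack$rel_permittivity / stack$thickness
}

#' Young-Lippmann electrowetting driving force
#'
#' The force per unit contact line exerted on a droplet edge by an energized
#' electrode is `c V^2 / 2`; multiplied by the actuated contact-line length
#' `L` it gives the net DMF driving force
#' \deqn{F = \tfrac12\, c\, V^2\, L, \qquad c = \varepsilon_0 \varepsilon_r / t.}
#' Quadratic in voltage, zero at V = 0 or when the electrode is inactive.
#'
#' @param actuation an [actuation_state()].
#' @param contact_line_length_mm actuated contact-line length in mm.
#' @param stack a [dielectric_stack()].
#' @return force in newtons.
#' @examples
#' # the device's upper operating corner: ~45 uN
#' young_lippmann_force(actuation_state(140), 1.0, dielectric_stack(6, 3.1))
#' @export
young_lippmann_force <- function(actuation, contact_line_length_mm, stack) {
  stopifnot(inherits(actuation, "actuation_state"))
  if (!is.finite(contact_line_length_mm) || contact_line_length_mm <= 0)
    stop_invalid("invalid geometry: contact line length must be positive")
  if (!actuation$active) return(0)
  0.5 * capacitance_per_area(stack) * actuation$voltage^2 *
    (contact_line_length_mm * 1e-3)
}

# Gap-curvature pressure coefficient -(cos theta_b + cos theta_t)/h for a
# pancake droplet between two plates with equal static contact angles.
# Positive for hydrophobic surfaces (theta > 90 deg).
gap_curvature_term <- function(gap, theta_deg) {
  -2 * cos(theta_deg * pi / 180) / gap
}

#' Pressure imbalance driving droplet retention on a densifying electrode
#'
#' During the splitting stroke, liquid over the active densifying electrode
#' (retained droplet, pressure `p1`) is connected through a necking region
#' (pressure `p2`) to the moving droplet on the destination electrode. A
#' positive imbalance `Delta p = p2 - p1` drains the neck and favours a clean
#' breakup that leaves a small droplet over the bead pellet.
#'
#' Both pressures follow the pancake-droplet Laplace decomposition
#' `p = sigma * (kappa_inplane - (cos theta_b + cos theta_t)/h)`:
#' \itemize{
#'   \item retained droplet: in-plane curvature `2/d` (footprint of the
#'     densifying electrode, minor axis for ovals); the gap term on this
#'     actuated electrode is reduced by the electrowetting factor `(1 - k)`;
#'   \item neck: a saddle whose in-plane radius is `neck_scale * (w - d)`
#'     (the separation between the densifying footprint and the destination
#'     electrode edge), contributing negative curvature; the neck sits over
#'     unactuated, fully hydrophobic surface.
#' }
#' This yields `Delta p = sigma * (k * g0 - 2/d - 1/(neck_scale * (w - d)))`
#' with `g0 = -2 cos(theta0)/h`: exactly linear in `sigma`, strictly
#' increasing in `k`, and increasing in `w` with diminishing increments.
#'
#' @param geom a [device_geometry()]; requires `densify_minor < drive_width`.
#' @param fluid a [fluid_state()] (supplies `sigma` and `k_factor`).
#' @param theta_deg static baseline contact angle on the hydrophobic coating,
#'   degrees (default 120).
#' @param neck_scale proportionality constant of the neck in-plane radius
#'   (default 1).
#' @return pressure imbalance in Pa; positive values are breakup-favourable.
#' @examples
#' # reference operating point: round d = 1.0 mm, w = 2.2 mm, k = 0.6,
#' # sigma = 42 mN/m -> Delta p > 0 (reliable breakup)
#' retention_pressure_imbalance(device_geometry(), fluid_state())
#' @export
retention_pressure_imbalance <- function(geom, fluid, theta_deg = 120,
                                         neck_scale = 1) {
  stopifnot(inherits(geom, "device_geometry"), inherits(fluid, "fluid_state"))
  d <- geom$densify_minor      # oval: curvature taken at the minor axis
  w <- geom$drive_width
  if (d >= w)
    stop_invalid("degenerate geometry: densifying electrode must be smaller ",
                 "than the destination electrode width")
  if (!is.finite(neck_scale) || neck_scale <= 0)
    stop_invalid("invalid input: neck_scale must be positive")
  g0 <- gap_curvature_term(geom$gap, theta_deg)
  fluid$sigma * (fluid$k_factor * g0 - 2 / d - 1 / (neck_scale * (w - d)))
}

#' Laplace pressure of the on-chip sample reservoir
#'
#' The reservoir is modelled as a pancake droplet squeezed between the
#' plates: footprint radius `r = sqrt(V / (pi h))`, pressure
#' `sigma * (1/r - (cos theta_b + cos theta_t)/h)`. As the sample is used up
#' the footprint shrinks and the pressure rises, which is what makes the
#' final splitting cycles of stepwise loading progressively harder.
#'
#' @param volume_ul reservoir volume in microlitres (> 0).
#' @param geom a [device_geometry()].
#' @param fluid a [fluid_state()].
#' @param theta_deg static contact angle, degrees (default 120).
#' @return pressure in Pa; strictly decreasing in `volume_ul`.
#' @export
reservoir_laplace_pressure <- function(volume_ul, geom, fluid, theta_deg = 120) {
  stopifnot(inherits(geom, "device_geometry"), inherits(fluid, "fluid_state"))
  if (!is.finite(volume_ul) || volume_ul <= 0)
    stop_invalid("invalid input: volume must be positive")
  v <- volume_ul * 1e-9                      # m^3
  r <- sqrt(v / (pi * geom$gap))             # pancake footprint radius
  fluid$sigma * (1 / r + gap_curvature_term(geom$gap, theta_deg))
}
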