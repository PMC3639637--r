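#' Fluid properties of the working fluid
#'
#' Bundles density and dynamic viscosity of the (Newtonian) fluid and derives
#' the kinematic viscosity. Defaults are whole blood treated as a Newtonian
#' fluid at body temperature, the standard choice for laminar flow in small
#' arteries.
#'
#' @param density_kg_m3 Fluid density in kg/m^3. Default 1060 (blood).
#' @param viscosity_pa_s Dynamic viscosity in Pa.s (kg/(m.s)). Default 0.004.
#' @return An object of class `fluid_properties` with fields `rho`, `mu` and
#'   the derived kinematic viscosity `nu` (m^2/s).
#' @examples
#' blood <- fluid_properties()
#' blood$nu # 0.004 / 1060
#' @export
fluid_properties <- function(density_kg_m3 = 1060, viscosity_pa_s = 0.004) {
  if (!is.numeric(density_kg_m3) || length(density_kg_m3) != 1L ||
      !is.finite(density_kg_m3) || density_kg_m3 <= 0) {
    stop("`density_kg_m3` must be a single positive number", call. = FALSE)
  }
  if (!is.numeric(viscosity_pa_s) || length(viscosity_pa_s) != 1L ||
      !is.finite(viscosity_pa_s) || viscosity_pa_s <= 0) {
    stop("`viscosity_pa_s` must be a single positive number", call. = FALSE)
  }
  structure(
    list(rho = density_kg_m3, mu = viscosity_pa_s,
         nu = viscosity_pa_s / density_kg_m3),
    class = "fluid_properties"
  )
}

#' Flow scenario: vessel calibre, inflow and fluid
#'
#' A scenario fixes the physical parametrization of a run: vessel width
#' (diameter), the peak of the parabolic inflow profile, the fluid, and the
#' spatial dimensionality. The default scenario is a 3 mm vessel with a
#' 50 mm/s peak parabolic inflow of blood, i.e. Reynolds number about 20.
#'
#' @param channel_width_m Vessel width / diameter D in meters. Default 3e-3.
#' @param u_max_m_s Peak inflow velocity in m/s. Default 0.05.
#' @param fluid A [fluid_properties()] object.
#' @param dimensionality 2 (planar channel) or 3 (circular tube).
#' @return An object of class `flow_scenario`.
#' @export
flow_scenario <- function(channel_width_m = 3e-3, u_max_m_s = 0.05,
                          fluid = fluid_properties(), dimensionality = 2L) {
  stopifnot(inherits(fluid, "fluid_properties"))
  if (!is.numeric(channel_width_m) || channel_width_m <= 0) {
    stop("`channel_width_m` must be positive", call. = FALSE)
  }
  if (!is.numeric(u_max_m_s) || u_max_m_s <= 0) {
    stop("`u_max_m_s` must be positive", call. = FALSE)
  }
  dimensionality <- as.integer(dimensionality)
  if (!dimensionality %in% c(2L, 3L)) {
    stop("`dimensionality` must be 2 or 3", call. = FALSE)
  }
  structure(
    list(D = channel_width_m, u_max = u_max_m_s, fluid = fluid,
         dimensionality = dimensionality),
    class = "flow_scenario"
  )
}

#' Lattice kinematic viscosity from the BGK relaxation time
#'
#' In the single-relaxation-time lattice Boltzmann method the kinematic
#' viscosity in lattice units is tied to the relaxation time tau by
#' nu = (1/3) (tau - 1/2). tau must exceed 1/2, otherwise the viscosity
#' is non-positive and the scheme is meaningless.
#'
#' @param tau Dimensionless relaxation time, > 0.5.
#' @return Kinematic viscosity in lattice units.
#' @examples
#' lattice_viscosity(1) # 1/6
#' @export
lattice_viscosity <- function(tau) {
  if (!is.numeric(tau) || any(!is.finite(tau))) {
    stop("`tau` must be numeric and finite", call. = FALSE)
  }
  if (any(tau <= 0.5)) {
    stop("`tau` must be > 0.5: tau <= 0.5 implies a non-positive viscosity",
         call. = FALSE)
  }
  (tau - 0.5) / 3
}

#' Build the physical <-> lattice unit system
#'
#' Diffusive-style scaling: the cell size dx is fixed by the number of cells
#' across the vessel width, the time step dt by pinning the peak inflow to a
#' prescribed lattice velocity (which controls the Mach number), and the
#' relaxation time tau then follows from matching the physical kinematic
#' viscosity.
#'
#' @param scenario A [flow_scenario()].
#' @param cells_across_width Number of lattice cells spanning the vessel
#'   width D (>= 8). Default 30.
#' @param u_lattice_max Peak inflow velocity in lattice units, in (0, 0.1).
#'   Default 0.05 (Mach about 0.087).
#' @param tau_max Upper bound on the admissible relaxation time. BGK is
#'   formally stable for any tau > 0.5 but accuracy degrades well before
#'   tau = 2; raise this only deliberately.
#' @return An object of class `unit_system` with fields `dx` (m), `dt` (s),
#'   `tau`, `u_lattice_max`, `nu_lattice`, and the originating `scenario`.
#' @examples
#' us <- build_unit_system(flow_scenario(), 30, 0.05)
#' us$dx # 1e-4 m
#' us$tau # about 0.6132
#' @export
build_unit_system <- function(scenario, cells_across_width = 30L,
                              u_lattice_max = 0.05, tau_max = 2) {
  stopifnot(inherits(scenario, "flow_scenario"))
  cells_across_width <- as.integer(cells_across_width)
  if (is.na(cells_across_width) || cells_across_width < 8L) {
    stop("`cells_across_width` must be >= 8", call. = FALSE)
  }
  if (!is.numeric(u_lattice_max) || u_lattice_max <= 0 || u_lattice_max >= 0.1) {
    stop("`u_lattice_max` must lie in (0, 0.1) to keep the Mach number low",
         call. = FALSE)
  }
  dx <- scenario$D / cells_across_width
  dt <- u_lattice_max * dx / scenario$u_max
  nu_lattice <- scenario$fluid$nu * dt / dx^2
  tau <- 3 * nu_lattice + 0.5
  if (tau <= 0.5 || tau > tau_max) {
    stop(sprintf(
      paste0("resulting relaxation time tau = %.4f is outside (0.5, %g]; ",
             "adjust `cells_across_width` (=%d) or `u_lattice_max` (=%g)"),
      tau, tau_max, cells_across_width, u_lattice_max), call. = FALSE)
  }
  structure(
    list(dx = dx, dt = dt, tau = tau, u_lattice_max = u_lattice_max,
         nu_lattice = nu_lattice, cells_across_width = cells_across_width,
         scenario = scenario),
    class = "unit_system"
  )
}

#' @export
print.unit_system <- function(x, ...) {
  cat("<unit_system>\n")
  cat(sprintf("  dx = %.4g m, dt = %.4g s\n", x$dx, x$dt))
  cat(sprintf("  tau = %.5f, nu_lattice = %.5f, u_lattice_max = %.3f\n",
              x$tau, x$nu_lattice, x$u_lattice_max))
  cat(sprintf("  Mach = %.4f, Re = %.3f\n",
              mach_number(x$u_lattice_max),
              reynolds_number(x$scenario$fluid,
                              characteristic_velocity(x$scenario),
                              x$scenario$D)))
  invisible(x)
}

#' Convert velocities between physical and lattice units
#'
#' @param u Velocity (m/s for `to_lattice`, lattice units for `to_physical`);
#'   any numeric array.
#' @param units A `unit_system`.
#' @return Velocity in the other unit system, same shape as `u`.
#' @export
to_lattice <- function(u, units) {
  stopifnot(inherits(units, "unit_system"))
  u * units$dt / units$dx
}

#' @rdname to_lattice
#' @export
to_physical <- function(u, units) {
  stopifnot(inherits(units, "unit_system"))
  u * units$dx / units$dt
}

#' Characteristic (mean) velocity of the parabolic inflow
#'
#' The Reynolds number of pipe/channel flow is conventionally formed with the
#' mean velocity of the profile. For a circular pipe the parabolic profile
#' averages to u_max/2; this convention is adopted for both dimensionalities
#' so that the default scenario yields Re = 19.875. (The planar-channel
#' cross-sectional mean would be 2/3 u_max.)
#'
#' @param scenario A [flow_scenario()].
#' @return Mean velocity in m/s.
#' @export
characteristic_velocity <- function(scenario) {
  stopifnot(inherits(scenario, "flow_scenario"))
  scenario$u_max / 2
}

#' Reynolds number
#'
#' Re = rho u D / mu, the ratio of inertial to viscous effects. With blood
#' (rho = 1060 kg/m^3, mu = 0.004 Pa.s), D = 3 mm and mean velocity 25 mm/s
#' this gives 19.875: firmly laminar.
#'
#' @param fluid A [fluid_properties()] object.
#' @param u_characteristic Characteristic velocity in m/s (> 0).
#' @param D Characteristic length (vessel width) in m (> 0).
#' @return Dimensionless Reynolds number.
#' @export
reynolds_number <- function(fluid, u_characteristic, D) {
  stopifnot(inherits(fluid, "fluid_properties"))
  if (!is.numeric(u_characteristic) || any(u_characteristic <= 0)) {
    stop("`u_characteristic` must be positive", call. = FALSE)
  }
  if (!is.numeric(D) || any(D <= 0)) {
    stop("`D` must be positive", call. = FALSE)
  }
  fluid$rho * u_characteristic * D / fluid$mu
}

#' Lattice Mach number
#'
#' The lattice sound speed of the D2Q9/D3Q19 models is c_s = 1/sqrt(3), so
#' the Mach number of a lattice velocity u is u * sqrt(3). The compressibility
#' error of the lattice Boltzmann method scales with M^2; the method
#' approximates incompressible flow only for M << 1. A warning is emitted
#' above M = 0.17 (u_lattice about 0.1).
#'
#' @param u_lattice_max Peak lattice velocity (dimensionless, >= 0).
#' @return Mach number.
#' @export
mach_number <- function(u_lattice_max) {
  if (!is.numeric(u_lattice_max) || any(u_lattice_max < 0)) {
    stop("`u_lattice_max` must be >= 0", call. = FALSE)
  }
  m <- u_lattice_max * sqrt(3)
  if (any(m > 0.17)) {
    warning("Mach number exceeds 0.17; compressibility error may be significant",
            call. = FALSE)
  }
  m
}
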