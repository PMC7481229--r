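#' Describe the two-phase fluid system at a T-junction
#'
#' Bundles the continuous-phase viscosity, the interfacial tension between
#' the immiscible phases, and the channel geometry of the droplet generator:
#' a rectangular main (continuous-phase) channel of width `W` and given depth
#' crossed by a cylindrical dispersed-phase channel.
#'
#' @param viscosity_mpas Dynamic viscosity of the continuous (oil) phase,
#'   mPa s. Default 13.3 (10:1 perfluorodecalin:perfluorooctanol).
#' @param tension_mn_m Interfacial tension between the phases, mN/m.
#'   Default 12.
#' @param width_um Width `W` of the continuous-phase channel, um. Default 100.
#' @param depth_um Depth of the continuous-phase channel, um. Default 75.
#' @param dispersed_diameter_um Diameter of the cylindrical dispersed-phase
#'   channel, um. Default 50.
#'
#' @return An object of class `fluid_system` with SI fields `eta` (Pa s),
#'   `sigma` (N/m), `width`, `depth`, `dispersed_diameter` (m) and `area`,
#'   the main-channel cross-section (m^2).
#' @examples
#' fs <- fluid_system()          # fluorinated-oil / mother-liquor defaults
#' capillary_number(fs, 9.02e-3) # ~1e-2
#' @export
fluid_system <- function(viscosity_mpas = 13.3, tension_mn_m = 12,
                         width_um = 100, depth_um = 75,
                         dispersed_diameter_um = 50) {
  stopifnot_positive(
    viscosity_mpas = viscosity_mpas, tension_mn_m = tension_mn_m,
    width_um = width_um, depth_um = depth_um,
    dispersed_diameter_um = dispersed_diameter_um
  )
  out <- list(
    eta = viscosity_mpas * 1e-3,
    sigma = tension_mn_m * 1e-3,
    width = um_to_m(width_um),
    depth = um_to_m(depth_um),
    dispersed_diameter = um_to_m(dispersed_diameter_um)
  )
  out$area <- out$width * out$depth
  structure(out, class = "fluid_system")
}

#' @export
print.fluid_system <- function(x, ...) {
  cat("<fluid_system>\n")
  cat(sprintf("  eta    = %.3g mPa s\n", x$eta * 1e3))
  cat(sprintf("  sigma  = %.3g mN/m\n", x$sigma * 1e3))
  cat(sprintf("  main channel %g x %g um, dispersed diameter %g um\n",
              x$width * 1e6, x$depth * 1e6, x$dispersed_diameter * 1e6))
  invisible(x)
}

#' Capillary number of the continuous phase
#'
#' `Ca = eta * v_c / sigma`: the ratio of viscous shear to interfacial
#' forces, the dimensionless group that controls the droplet break-up
#' regime at the junction.
#'
#' @param fluid A [fluid_system()].
#' @param v_c Continuous-phase velocity, m/s (non-negative).
#' @return Dimensionless capillary number (vectorised over `v_c`).
#' @export
capillary_number <- function(fluid, v_c) {
  stopifnot(inherits(fluid, "fluid_system"))
  stopifnot_positive(v_c = v_c, .allow_zero = TRUE)
  fluid$eta * v_c / fluid$sigma
}

#' Build a flow condition from the two volumetric flow rates
#'
#' Converts aqueous (dispersed) and oil (continuous) flow rates into
#' superficial velocities through the main-channel cross-section, the
#' capillary number, and the aqueous volume fraction
#' `p_aq = Q_aq / (Q_aq + Q_oil)`. Both phase velocities use the same
#' cross-section, so `v_d / v_tot` equals the flow-rate ratio exactly.
#'
#' `q_oil = 0` is accepted and flagged as continuous mode (pure aqueous
#' jetting, no droplet generation); frequency evaluation on such a
#' condition is an error.
#'
#' @param fluid A [fluid_system()].
#' @param q_aq_ul_min Aqueous flow rate, uL/min (>= 0).
#' @param q_oil_ul_min Oil flow rate, uL/min (>= 0). Not both zero.
#' @return An object of class `flow_condition` with SI fields `q_aq`,
#'   `q_oil`, `q_tot` (m^3/s), `v_d`, `v_c`, `v_tot` (m/s), `ca`, `p_aq`,
#'   and logical `continuous_mode`.
#' @examples
#' fs <- fluid_system()
#' fc <- flow_condition(fs, q_aq_ul_min = 4.5, q_oil_ul_min = 12)
#' fc$p_aq       # 0.2727...
#' fc$v_tot      # ~0.0367 m/s
#' @export
flow_condition <- function(fluid, q_aq_ul_min, q_oil_ul_min) {
  stopifnot(inherits(fluid, "fluid_system"))
  stopifnot_positive(q_aq_ul_min = q_aq_ul_min,
                     q_oil_ul_min = q_oil_ul_min, .allow_zero = TRUE)
  if (q_aq_ul_min + q_oil_ul_min <= 0) {
    stop("at least one of the aqueous and oil flow rates must be positive",
         call. = FALSE)
  }
  q_aq <- ul_min_to_m3s(q_aq_ul_min)
  q_oil <- ul_min_to_m3s(q_oil_ul_min)
  v_d <- q_aq / fluid$area
  v_c <- q_oil / fluid$area
  structure(list(
    q_aq = q_aq, q_oil = q_oil, q_tot = q_aq + q_oil,
    v_d = v_d, v_c = v_c, v_tot = v_d + v_c,
    ca = capillary_number(fluid, v_c),
    p_aq = q_aq / (q_aq + q_oil),
    continuous_mode = q_oil_ul_min == 0
  ), class = "flow_condition")
}

#' @export
print.flow_condition <- function(x, ...) {
  cat("<flow_condition>\n")
  cat(sprintf("  Q_aq = %.3g uL/min, Q_oil = %.3g uL/min (p_aq = %.3f)\n",
              m3s_to_ul_min(x$q_aq), m3s_to_ul_min(x$q_oil), x$p_aq))
  cat(sprintf("  v_d = %.3g mm/s, v_c = %.3g mm/s, Ca = %.3g\n",
              x$v_d * 1e3, x$v_c * 1e3, x$ca))
  if (x$continuous_mode) cat("  continuous mode (no oil)\n")
  invisible(x)
}
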