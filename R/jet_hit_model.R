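#' Jet geometry from flow rate and jet speed
#'
#' In a gas-focused liquid jet the speed is set by the sheath-gas pressure
#' drop, so mass conservation `pi r_j^2 v_j = Q_tot` fixes the radius:
#' `r_j = sqrt(Q_tot / (pi v_j))`.
#'
#' @param q_tot_ul_min Total liquid flow rate, uL/min (> 0).
#' @param jet_speed_m_s Jet speed `v_j`, m/s (> 0). Default 50, the speed
#'   needed to replenish the jet between MHz-spaced pulses.
#' @return `jet_params` object with SI fields `q_tot`, `v_j`, `r_j`.
#' @examples
#' jet_radius(16.5, 14) * 2e6  # jet diameter ~5 um
#' @export
jet_params <- function(q_tot_ul_min, jet_speed_m_s = 50) {
  stopifnot_positive(q_tot_ul_min = q_tot_ul_min,
                     jet_speed_m_s = jet_speed_m_s)
  q_tot <- ul_min_to_m3s(q_tot_ul_min)
  structure(list(
    q_tot = q_tot,
    v_j = jet_speed_m_s,
    r_j = sqrt(q_tot / (pi * jet_speed_m_s))
  ), class = "jet_params")
}

#' @rdname jet_params
#' @export
jet_radius <- function(q_tot_ul_min, jet_speed_m_s = 50) {
  jet_params(q_tot_ul_min, jet_speed_m_s)$r_j
}

#' Beam and crystal-suspension parameters
#'
#' @param beam_diameter_um X-ray beam diameter `D_b`, um. Default 20
#'   (a 15 x 20 um^2 focus collapsed to one scalar; use the width
#'   transverse to the jet for the ellipse refinement).
#' @param crystal_density_per_ml Crystal number density `n`, crystals/mL.
#'   Treated as a free calibration parameter of the model.
#' @return `beam_crystal` object with SI fields `d_b` (m), `n` (m^-3).
#' @export
beam_crystal <- function(beam_diameter_um = 20, crystal_density_per_ml) {
  stopifnot_positive(beam_diameter_um = beam_diameter_um,
                     crystal_density_per_ml = crystal_density_per_ml)
  structure(list(
    d_b = um_to_m(beam_diameter_um),
    n = crystal_density_per_ml * 1e6
  ), class = "beam_crystal")
}

#' Expected crystal hits per pulse under the plug-flow model
#'
#' With the beam wider than the jet and an unsynchronised alternating
#' plug stream, the expected number of crystals illuminated per pulse is
#'
#' \deqn{\langle N \rangle = \pi r_j^2 D_b n p_{aq}}
#'
#' Substituting `r_j^2 = Q_tot / (pi v_j)` and `p_aq = Q_aq / Q_tot` gives
#' the equivalent flow form `D_b n Q_aq / v_j`
#' ([hit_fraction_flow_form()]): the hit fraction is proportional to the
#' aqueous flow rate at fixed jet speed and beam.
#'
#' @param jet A [jet_params()].
#' @param beam A [beam_crystal()].
#' @param p_aq Aqueous volume fraction in [0, 1].
#' @return Expected hits per pulse (dimensionless).
#' @export
mean_hit_fraction <- function(jet, beam, p_aq) {
  stopifnot(inherits(jet, "jet_params"), inherits(beam, "beam_crystal"),
            p_aq >= 0, p_aq <= 1)
  pi * jet$r_j^2 * beam$d_b * beam$n * p_aq
}

#' @rdname mean_hit_fraction
#' @param q_aq_ul_min Aqueous flow rate, uL/min.
#' @param jet_speed_m_s Jet speed, m/s.
#' @export
hit_fraction_flow_form <- function(q_aq_ul_min, jet_speed_m_s, beam) {
  stopifnot(inherits(beam, "beam_crystal"))
  stopifnot_positive(jet_speed_m_s = jet_speed_m_s)
  stopifnot_positive(q_aq_ul_min = q_aq_ul_min, .allow_zero = TRUE)
  beam$d_b * beam$n * ul_min_to_m3s(q_aq_ul_min) / jet_speed_m_s
}

#' Plug timing in the jet
#'
#' A droplet of volume `V_d` stretched into the jet passes the interaction
#' point for `V_d / Q_tot` seconds; the oil slug that follows lasts
#' `(V_d Q_oil / Q_aq) / Q_tot`. One aqueous + oil pair spans exactly one
#' generation period `1/f_d`, and the aqueous share of the period is
#' `p_aq` exactly.
#'
#' @param volume_pl Droplet volume, pL (> 0).
#' @param q_aq_ul_min Aqueous flow rate, uL/min (> 0).
#' @param q_oil_ul_min Oil flow rate, uL/min (>= 0).
#' @param jet A [jet_params()] (for the plug length in the jet).
#' @return `plug_geometry` object: `aqueous_duration`, `oil_duration`,
#'   `period` (s), `aqueous_length` (m), `p_aq`.
#' @examples
#' jp <- jet_params(45, 50)
#' plug_geometry(375, 7.5, 37.5, jp)$aqueous_duration  # 500 us
#' @export
plug_geometry <- function(volume_pl, q_aq_ul_min, q_oil_ul_min, jet) {
  stopifnot(inherits(jet, "jet_params"))
  stopifnot_positive(volume_pl = volume_pl, q_aq_ul_min = q_aq_ul_min)
  stopifnot_positive(q_oil_ul_min = q_oil_ul_min, .allow_zero = TRUE)
  v_d <- pl_to_m3(volume_pl)
  q_aq <- ul_min_to_m3s(q_aq_ul_min)
  q_oil <- ul_min_to_m3s(q_oil_ul_min)
  q_tot <- q_aq + q_oil
  aq <- v_d / q_tot
  oil <- (v_d * q_oil / q_aq) / q_tot
  structure(list(
    aqueous_duration = aq,
    oil_duration = oil,
    period = aq + oil,
    aqueous_length = jet$v_j * aq,
    p_aq = q_aq / q_tot
  ), class = "plug_geometry")
}

#' Does the aqueous plug cover a full pulse train?
#'
#' TRUE iff the plug's dwell time at the interaction point is at least the
#' first-to-last-pulse span of a train, so a well-phased plug can supply
#' aqueous sample for every pulse of the train.
#'
#' @param plug A [plug_geometry()].
#' @param schedule A [pulse_schedule()].
#' @return Logical.
#' @export
spans_train <- function(plug, schedule) {
  stopifnot(inherits(plug, "plug_geometry"),
            inherits(schedule, "pulse_schedule"))
  plug$aqueous_duration >= train_span(schedule)
}
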