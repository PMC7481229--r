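# Shared fixtures: the fluorinated-oil system and the burst-mode schedule.
ref_fluid <- function() fluid_system(13.3, 12, 100, 75, 50)
euxfel <- function() facility_preset("euxfel")

# Condition built from target phase velocities (m/s) rather than flow rates.
cond_from_velocities <- function(fluid, v_d, v_c) {
  flow_condition(fluid,
                 m3s_to_ul_min(v_d * fluid$area),
                 m3s_to_ul_min(v_c * fluid$area))
}
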