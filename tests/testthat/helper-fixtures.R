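# Shared fixtures: the waxbill trait set and common physiologies.

waxbill_morph <- function(...) bird_morphology(...)

summer_night_phys <- function() night_physiology(bmr_W = 0.20)
autumn_phys <- function() bird_physiology(bmr_W = 0.17, rmr_W = 0.37)

# Mean curve from replicated respirometry observations (one row per setpoint),
# as the detection functions expect strictly increasing temperatures.
aggregate_curve <- function(obs) {
  agg <- stats::aggregate(metabolic_rate_W ~ air_temp_C, data = obs, FUN = mean)
  agg[order(agg$air_temp_C), ]
}

# Random-but-valid parameter draw for solver stress tests
random_solver_case <- function() {
  lhair <- runif(1, 8, 25)
  list(
    morph = bird_morphology(
      mass_g = runif(1, 6, 10),
      shape_ratio_max = runif(1, 1.2, 5),
      feather_depth_dorsal_mm = runif(1, 1.5, min(8, lhair)),
      feather_depth_ventral_mm = runif(1, 1.5, min(8, lhair)),
      feather_length_dorsal_mm = lhair,
      feather_length_ventral_mm = lhair,
      fiber_diameter_mm = runif(1, 0.02, 0.1),
      fiber_density_per_mm2 = runif(1, 10, 120)
    ),
    phys = bird_physiology(tb_core_C = runif(1, 39, 42),
                           bmr_W = runif(1, 0.15, 0.26),
                           rmr_W = 0.45),
    env = environment_state(runif(1, 5, 30), wind_m_s = runif(1, 0, 2),
                            rel_humidity_pct = runif(1, 0, 90)),
    scenario = sample(c("none", "p35", "p75", "p200", "full"), 1)
  )
}
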