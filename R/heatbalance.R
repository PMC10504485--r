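#' Effective thermal conductivity of the feather coat
#'
#' Mixing rule for the air/keratin composite: the fibre volume fraction is
#' \eqn{f_v = \rho_f (\pi d^2/4) L / z} (fibre areal density, fibre diameter,
#' fibre length, coat depth; consistent mm units), clipped to [0, 1], and
#' \eqn{k_{eff} = k_{air}(T) + (k_{fibre} - k_{air}(T)) f_v}. Erecting the
#' coat (larger depth at fixed fibre stock) therefore dilutes the fibres
#' toward pure trapped air.
#'
#' @param morph A \code{bird_morphology} (fibre diameter, density, conductivity).
#' @param effective_depth_mm Coat depth after any ptiloerection, mm.
#' @param mean_coat_temp_C Temperature at which the air conductivity is
#'   evaluated (mean coat temperature), C.
#' @param feather_length_mm Fibre length, mm; defaults to the dorsal value.
#' @return Effective conductivity, W/mK.
#' @export
effective_coat_conductivity <- function(morph, effective_depth_mm, mean_coat_temp_C,
                                        feather_length_mm = morph$feather_length_dorsal_mm) {
  if (!is.finite(effective_depth_mm) || effective_depth_mm <= 0) {
    stop("effective_coat_conductivity: coat depth must be positive")
  }
  k_air <- air_conductivity(mean_coat_temp_C)
  f_v <- morph$fiber_density_per_mm2 * (pi * morph$fiber_diameter_mm ^ 2 / 4) *
    feather_length_mm / effective_depth_mm
  f_v <- min(max(f_v, 0), 1)
  k_air + (morph$fiber_conductivity - k_air) * f_v
}

#' Convective heat-transfer coefficient
#'
#' Mixed free/forced convection on a sphere of the body's characteristic
#' length (equal-volume-sphere diameter), using the Ranz-Marshall correlation
#' \eqn{Nu = 2 + 0.6 Re^{1/2} Pr^{1/3}}. The stagnant-air limit \eqn{Nu = 2}
#' acts as the floor as wind goes to zero. Air properties are evaluated at
#' ambient temperature.
#'
#' @param geometry A \code{body_geometry}.
#' @param env An \code{environment_state}.
#' @return h in W m-2 K-1.
#' @export
convection_coefficient <- function(geometry, env) {
  l <- geometry$characteristic_length_m
  k <- air_conductivity(env$air_temp_C)
  nu_visc <- air_viscosity(env$air_temp_C) / air_density(env$air_temp_C)
  re <- env$wind_m_s * l / nu_visc
  nu <- 2 + 0.6 * sqrt(re) * air_prandtl(env$air_temp_C) ^ (1 / 3)
  nu * k / l
}

# --- internal exchange network -----------------------------------------------
#
# The exchange network is built on a sphere equivalent to the body: radial
# conduction through the coat shell and convection + longwave radiation at the
# coat surface, separately for the dorsal and ventral halves. Two equivalence
# strategies are provided:
#   "sphere-volume": inner radius from the equal-volume sphere (default),
#   "sphere-area":   inner radius from the equal-area sphere (makes body shape
#                    enter the network through the ellipsoid surface area).
exchange_radius <- function(geometry, strategy = c("sphere-volume", "sphere-area")) {
  strategy <- match.arg(strategy)
  switch(strategy,
    "sphere-volume" = (3 * geometry$volume_m3 / (4 * pi)) ^ (1 / 3),
    "sphere-area" = sqrt(geometry$surface_area_m2 / (4 * pi))
  )
}

# Solve the coat-surface temperature of one half-shell by Newton iteration:
#   G_cond (tb - Ts) = h A_out (Ts - Ta) + eps sigma A_rad (Ts^4 - Tr^4)
solve_surface_temp <- function(g_cond, h, a_out, eps_sigma_a_rad, tb, ta, tr) {
  tb_k <- tb + 273.15; ta_k <- ta + 273.15; tr_k <- tr + 273.15
  # linearised start
  hr <- 4 * eps_sigma_a_rad * ((tb_k + ta_k) / 2) ^ 3
  ts <- (g_cond * tb_k + h * a_out * ta_k + hr * tr_k) / (g_cond + h * a_out + hr)
  for (i in 1:50) {
    f <- g_cond * (tb_k - ts) - h * a_out * (ts - ta_k) -
      eps_sigma_a_rad * (ts ^ 4 - tr_k ^ 4)
    fp <- -g_cond - h * a_out - 4 * eps_sigma_a_rad * ts ^ 3
    step <- f / fp
    ts <- ts - step
    if (abs(step) < 1e-10) break
  }
  if (abs(step) >= 1e-8) {
    stop("solve_surface_temp: surface-temperature iteration failed to converge (",
         "G=", signif(g_cond, 4), ", tb=", tb, ", ta=", ta, ")")
  }
  ts - 273.15
}

# Per-half network pieces for a given effective depth (mm)
coat_half_network <- function(morph, geometry, env, depth_mm, length_mm, tb,
                              constants, strategy) {
  r1 <- exchange_radius(geometry, strategy)
  depth_m <- depth_mm / 1000
  r2 <- r1 + depth_m
  k_eff <- effective_coat_conductivity(morph, depth_mm, (tb + env$air_temp_C) / 2,
                                       feather_length_mm = length_mm)
  g_cond <- 2 * pi * k_eff * r1 * r2 / depth_m          # half shell
  a_out <- 2 * pi * r2 ^ 2
  r_rad <- r1 + constants$fractional_lw_depth * depth_m
  a_rad <- 2 * pi * r_rad ^ 2
  h <- convection_coefficient(geometry, env)
  ts <- solve_surface_temp(g_cond, h, a_out,
                           constants$emissivity_lw * constants$stefan_boltzmann * a_rad,
                           tb, env$air_temp_C, env$air_temp_C)
  list(q = g_cond * (tb - ts), ts = ts, g_cond = g_cond, a_out = a_out,
       k_eff = k_eff, h = h)
}

#' Dry heat loss through the feather coat
#'
#' Series resistance network from skin (held at core temperature: no flesh
#' resistance for a bird this small) through radial conduction across the
#' dorsal and ventral coat shells, with parallel convection and longwave
#' radiation at each coat surface. Longwave exchange acts at a surface located
#' at the fractional longwave depth of the coat (0.9 by default); in the
#' chamber the radiant temperature equals air temperature. Negative values
#' are a dry heat gain.
#'
#' @param morph A \code{bird_morphology}.
#' @param geometry A \code{body_geometry} (from \code{\link{ellipsoid_geometry}}).
#' @param env An \code{environment_state}.
#' @param effective_depth_mm Length-2 vector \code{c(dorsal, ventral)} of coat
#'   depths after ptiloerection, mm.
#' @param tb Skin/core temperature, C.
#' @param constants A \code{physical_constants}.
#' @param strategy Exchange-geometry strategy, see Details in the vignette.
#' @return List with \code{q_dry_W} and area-weighted
#'   \code{coat_surface_temp_C}, plus per-half diagnostics.
#' @export
dry_heat_loss <- function(morph, geometry, env, effective_depth_mm, tb,
                          constants = physical_constants(),
                          strategy = "sphere-volume") {
  stopifnot(length(effective_depth_mm) == 2)
  dor <- coat_half_network(morph, geometry, env, effective_depth_mm[[1]],
                           morph$feather_length_dorsal_mm, tb, constants, strategy)
  ven <- coat_half_network(morph, geometry, env, effective_depth_mm[[2]],
                           morph$feather_length_ventral_mm, tb, constants, strategy)
  ts_mean <- (dor$ts * dor$a_out + ven$ts * ven$a_out) / (dor$a_out + ven$a_out)
  list(q_dry_W = dor$q + ven$q, coat_surface_temp_C = ts_mean,
       dorsal = dor, ventral = ven)
}

#' Respiratory evaporative heat loss
#'
#' Ventilation is tied to oxygen demand: \eqn{\dot V O_2 = MR / 20.1} ml/s,
#' ventilation \eqn{= \dot VO_2 / (0.2094\, E_{O2})}, multiplied by the
#' panting level. Expired air is saturated at ambient + 5 C (capped at body
#' temperature); inspired vapour comes in at ambient humidity. The loss is
#' the latent heat of the net water flux, never negative.
#'
#' @param metabolic_rate_W Metabolic rate, W.
#' @param env An \code{environment_state}.
#' @param phys A \code{bird_physiology}.
#' @param pant_level Ventilation multiplier in \code{[1, pant_max]}.
#' @param tb_C Core temperature (cap for expired-air temperature), C.
#' @param constants A \code{physical_constants}.
#' @return q_resp in W.
#' @export
respiratory_evaporation <- function(metabolic_rate_W, env, phys, pant_level = 1,
                                    tb_C = phys$tb_core_C,
                                    constants = physical_constants()) {
  if (metabolic_rate_W < 0) stop("respiratory_evaporation: metabolic rate must be >= 0")
  metabolic_rate_W * resp_loss_slope(env, phys, tb_C, constants) * pant_level
}

# Respiratory loss per watt of metabolic rate (dimensionless); linear in MR.
resp_loss_slope <- function(env, phys, tb_C, constants) {
  te <- min(env$air_temp_C + phys$breath_offset_C, tb_C)
  rho_out <- vapor_density(te, 100)
  rho_in <- vapor_density(env$air_temp_C, env$rel_humidity_pct)
  vent_per_W <- 1e-6 / (constants$oxyjoule_J_per_mlO2 *
                          constants$o2_fraction_air * phys$o2_extraction)
  max(rho_out - rho_in, 0) * vent_per_W * latent_heat_vaporization(te)
}

#' Cutaneous evaporative heat loss
#'
#' Mass-transfer analogy to convection (\eqn{h_m = h / (\rho c_p Le^{2/3})})
#' applied over the wet fraction of the skin surface, with the water surface
#' saturated at the coat-surface temperature and the ambient vapour density
#' as the far field. Zero when the ambient air is the wetter side.
#'
#' @param geometry A \code{body_geometry}.
#' @param env An \code{environment_state}.
#' @param coat_surface_temp_C Coat surface temperature, C.
#' @param phys A \code{bird_physiology} (wet skin fraction).
#' @param constants A \code{physical_constants}.
#' @param strategy Exchange-geometry strategy (for the skin area).
#' @return q_cut in W.
#' @export
cutaneous_evaporation <- function(geometry, env, coat_surface_temp_C,
                                  phys = bird_physiology(),
                                  constants = physical_constants(),
                                  strategy = "sphere-volume") {
  if (phys$wet_skin_fraction == 0) return(0)
  h <- convection_coefficient(geometry, env)
  h_m <- h / (air_density(env$air_temp_C) * air_cp *
                constants$lewis_number ^ (2 / 3))
  a_skin <- 4 * pi * exchange_radius(geometry, strategy) ^ 2
  drho <- vapor_density(coat_surface_temp_C, 100) -
    vapor_density(env$air_temp_C, env$rel_humidity_pct)
  if (drho <= 0) return(0)
  phys$wet_skin_fraction * a_skin * h_m * drho *
    latent_heat_vaporization(coat_surface_temp_C)
}

# Effective depths (dorsal, ventral) for a scenario
scenario_depths <- function(morph, scenario) {
  c(apply_ptiloerection(morph$feather_depth_dorsal_mm,
                        morph$feather_length_dorsal_mm, scenario),
    apply_ptiloerection(morph$feather_depth_ventral_mm,
                        morph$feather_length_ventral_mm, scenario))
}

#' Metabolic rate required for homeothermy
#'
#' Solves the steady-state balance \eqn{MR = q_{dry} + q_{resp}(MR) + q_{cut}}
#' for the metabolic rate at a fixed body temperature and ptiloerection
#' scenario. The dry and cutaneous terms do not depend on MR and the
#' respiratory term is exactly linear in MR, so the fixed point has a closed
#' form; the balance residual of the returned root is zero to machine
#' precision. The returned rate is clamped below at \code{floor_W} (BMR at
#' night, RMR by day) and the solution is flagged \code{"thermoneutral"} when
#' the unclamped root falls below the floor.
#'
#' @param morph A \code{bird_morphology}.
#' @param phys A \code{bird_physiology}.
#' @param env An \code{environment_state}.
#' @param scenario Ptiloerection scenario label.
#' @param tb Body (= skin) temperature, C; defaults to the regulated core.
#' @param pant_level Ventilation multiplier in \code{[1, pant_max]}.
#' @param floor_W Resting floor for the returned rate; defaults to BMR.
#' @param constants A \code{physical_constants}.
#' @param strategy Exchange-geometry strategy.
#' @return A list of class \code{"metabolic_solution"}: \code{metabolic_rate_W}
#'   (clamped), \code{required_W} (unclamped root), loss terms, \code{tb_used_C},
#'   \code{scenario_used}, \code{pant_level}, \code{regulated_flag},
#'   \code{residual_W} (root balance residual) and \code{deficit_W} (unmet
#'   dissipation at the clamped rate; 0 on the cold side).
#' @export
solve_required_metabolic_rate <- function(morph, phys, env, scenario = "none",
                                          tb = phys$tb_core_C, pant_level = 1,
                                          floor_W = phys$bmr_W,
                                          constants = physical_constants(),
                                          strategy = "sphere-volume") {
  geometry <- ellipsoid_geometry(morph$mass_g, morph$body_density, morph$shape_ratio_max)
  depths <- scenario_depths(morph, scenario)
  dry <- dry_heat_loss(morph, geometry, env, depths, tb, constants, strategy)
  q_cut <- cutaneous_evaporation(geometry, env, dry$coat_surface_temp_C,
                                 phys, constants, strategy)
  slope <- resp_loss_slope(env, phys, tb, constants) * pant_level
  if (slope >= 1) {
    stop("solve_required_metabolic_rate: respiratory loss per watt >= 1; no finite root")
  }
  required <- (dry$q_dry_W + q_cut) / (1 - slope)
  if (required > 100 * phys$bmr_W) {
    stop("solve_required_metabolic_rate: no root below 100 x BMR (Ta = ",
         env$air_temp_C, " C, scenario = ", scenario, ")")
  }
  mr <- max(required, floor_W)
  q_resp_ret <- mr * slope
  sol <- list(
    metabolic_rate_W = mr,
    required_W = required,
    q_dry_W = dry$q_dry_W,
    q_conduction_W = dry$q_dry_W,   # conduction through the coat carries the dry flux
    q_convection_W = dry$dorsal$h * dry$dorsal$a_out * (dry$dorsal$ts - env$air_temp_C) +
      dry$ventral$h * dry$ventral$a_out * (dry$ventral$ts - env$air_temp_C),
    q_radiation_W = dry$q_dry_W -
      (dry$dorsal$h * dry$dorsal$a_out * (dry$dorsal$ts - env$air_temp_C) +
         dry$ventral$h * dry$ventral$a_out * (dry$ventral$ts - env$air_temp_C)),
    q_resp_evap_W = q_resp_ret,
    q_cut_evap_W = q_cut,
    coat_surface_temp_C = dry$coat_surface_temp_C,
    tb_used_C = tb,
    scenario_used = scenario,
    pant_level = pant_level,
    regulated_flag = if (required >= floor_W) "cold-stress" else "thermoneutral",
    residual_W = required - (dry$q_dry_W + required * slope + q_cut),
    deficit_W = max(floor_W - (dry$q_dry_W + floor_W * slope + q_cut), 0) *
      (required < floor_W)
  )
  class(sol) <- "metabolic_solution"
  sol
}

#' Thermoregulatory cascade
#'
#' Full thermoregulatory response at one set of conditions. Cold side: every
#' allowed ptiloerection level is evaluated and the minimum-metabolic-rate
#' solution returned. When even the best insulation needs no more than the
#' resting floor, the bird sits in its thermoneutral zone provided the least
#' insulated level can still dissipate the floor; the reported scenario is
#' then the most insulated level whose requirement stays at or below the
#' floor. Heat side (no level can dissipate the resting rate at the regulated
#' core temperature): body temperature rises in 0.25 C increments to its
#' maximum, then panting ramps ventilation up to \code{pant_max} (at the
#' printed BMR multiplier of 1 panting adds no metabolic heat). If the
#' balance still fails at maximum panting the solution is flagged
#' \code{"hyperthermic"} with the unmet deficit recorded.
#'
#' @inheritParams solve_required_metabolic_rate
#' @param scenario_set Character vector of allowed ptiloerection levels.
#' @return A \code{metabolic_solution}.
#' @export
thermoregulatory_cascade <- function(morph, phys, env,
                                     scenario_set = c("none", "p35", "p75", "p200", "full"),
                                     floor_W = phys$bmr_W,
                                     constants = physical_constants(),
                                     strategy = "sphere-volume") {
  if (length(scenario_set) == 0) stop("thermoregulatory_cascade: empty scenario set")
  sols <- lapply(scenario_set, function(s) {
    solve_required_metabolic_rate(morph, phys, env, s, floor_W = floor_W,
                                  constants = constants, strategy = strategy)
  })
  req <- vapply(sols, `[[`, numeric(1), "required_W")

  if (min(req) >= floor_W) {
    return(sols[[which.min(req)]])                       # cold side: argmin MR
  }
  if (max(req) >= floor_W) {
    # thermoneutral: some level needs less than the floor, another can still
    # dissipate it; the bird balances by intermediate coat adjustment and sits
    # at the resting floor. Report the most insulated level at or below it.
    below <- which(req < floor_W)
    sol <- sols[[below[which.max(req[below])]]]
    sol$regulated_flag <- "thermoneutral"
    return(sol)
  }

  # heat side at minimum insulation (largest dissipation); metabolic rate stays
  # at the resting floor while body temperature, then panting, raise dissipation
  idx <- which.max(req)
  scen <- scenario_set[[idx]]
  sol <- sols[[idx]]
  if (phys$pant_bmr_multiplier != 1) {
    return(heat_side_pant_costly(morph, phys, env, scen, floor_W, constants, strategy, sol))
  }
  tb <- phys$tb_core_C
  while (tb + phys$tb_increment_C <= phys$tb_max_C + 1e-9) {
    tb <- tb + phys$tb_increment_C
    cand <- solve_required_metabolic_rate(morph, phys, env, scen, tb = tb,
                                          floor_W = floor_W,
                                          constants = constants, strategy = strategy)
    sol <- cand
    if (cand$required_W >= floor_W) {
      # dissipation now covers the resting floor; the bird settles between
      # increments, so the reported rate stays at the floor
      sol$metabolic_rate_W <- floor_W
      sol$q_resp_evap_W <- floor_W * resp_loss_slope(env, phys, tb, constants)
      sol$regulated_flag <- "heat-stress"
      return(sol)
    }
  }
  # panting at the final tb: ventilation multiplier balancing the floor rate
  slope1 <- resp_loss_slope(env, phys, sol$tb_used_C, constants)
  q_fixed <- sol$q_dry_W + sol$q_cut_evap_W
  if (slope1 > 0) {
    pant_req <- (floor_W - q_fixed) / (slope1 * floor_W)
    if (pant_req <= phys$pant_max) {
      cand <- solve_required_metabolic_rate(morph, phys, env, scen,
                                            tb = sol$tb_used_C,
                                            pant_level = max(pant_req, 1),
                                            floor_W = floor_W,
                                            constants = constants, strategy = strategy)
      cand$regulated_flag <- "heat-stress"
      return(cand)
    }
  }
  sol <- solve_required_metabolic_rate(morph, phys, env, scen, tb = sol$tb_used_C,
                                       pant_level = phys$pant_max, floor_W = floor_W,
                                       constants = constants, strategy = strategy)
  sol$regulated_flag <- "hyperthermic"
  sol
}

# General heat-side search when panting carries a metabolic cost
# (pant_bmr_multiplier > 1): metabolic rate scales linearly with pant level up
# to floor_W * pant_bmr_multiplier at pant_max.
heat_side_pant_costly <- function(morph, phys, env, scen, floor_W, constants,
                                  strategy, fallback) {
  mr_at <- function(pant) {
    floor_W * (1 + (phys$pant_bmr_multiplier - 1) * (pant - 1) / (phys$pant_max - 1))
  }
  bal <- function(pant) {
    s <- solve_required_metabolic_rate(morph, phys, env, scen, tb = phys$tb_max_C,
                                       pant_level = pant, floor_W = 0,
                                       constants = constants, strategy = strategy)
    mr_at(pant) - s$required_W
  }
  if (bal(phys$pant_max) > 0) {
    sol <- solve_required_metabolic_rate(morph, phys, env, scen, tb = phys$tb_max_C,
                                         pant_level = phys$pant_max, floor_W = floor_W,
                                         constants = constants, strategy = strategy)
    sol$regulated_flag <- "hyperthermic"
    return(sol)
  }
  root <- stats::uniroot(bal, c(1, phys$pant_max), tol = 1e-8)$root
  sol <- solve_required_metabolic_rate(morph, phys, env, scen, tb = phys$tb_max_C,
                                       pant_level = root, floor_W = floor_W,
                                       constants = constants, strategy = strategy)
  sol$metabolic_rate_W <- mr_at(root)
  sol$regulated_flag <- "heat-stress"
  sol
}
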