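test_that("coat conductivity spans the air and keratin limits", {
  m <- waxbill_morph()
  # vanishing fibre stock -> pure trapped air
  m_air <- bird_morphology(fiber_density_per_mm2 = 1e-12)
  expect_equal(effective_coat_conductivity(m_air, 6, 20),
               air_conductivity(20), tolerance = 1e-6)
  expect_equal(air_conductivity(20), 0.02572, tolerance = 1e-3)
  # saturated fibre packing clips at the keratin conductivity
  m_solid <- bird_morphology(fiber_density_per_mm2 = 4000)
  expect_equal(effective_coat_conductivity(m_solid, 2, 20,
                                           feather_length_mm = 16.1), 0.209)
  # frozen hand evaluation: RHO 50/mm2, DHAIR 0.03 mm, LHAIR 16.1 mm, depth 6 mm
  expect_equal(effective_coat_conductivity(m, 6.0, 20), 0.04310275,
               tolerance = 1e-6)
  expect_error(effective_coat_conductivity(m, 0, 20), "positive")
})

test_that("convection has the stagnant-sphere floor and grows with wind", {
  g <- ellipsoid_geometry(8, 875, 3)
  still <- environment_state(20, wind_m_s = 0)
  expect_equal(convection_coefficient(g, still),
               2 * air_conductivity(20) / g$characteristic_length_m,
               tolerance = 1e-10)
  h <- vapply(c(0, 0.1, 0.5, 1, 5),
              function(w) convection_coefficient(g, environment_state(20, w)),
              numeric(1))
  expect_true(all(diff(h) > 0))
  # frozen hand evaluation on an 18 mm sphere, 0.1 m/s, 20 C
  g18 <- g; g18$characteristic_length_m <- 0.018
  expect_equal(convection_coefficient(g18, environment_state(20, 0.1)),
               11.21685, tolerance = 1e-4)
})

test_that("dry heat loss vanishes at zero gradient and falls with added depth", {
  m <- waxbill_morph()
  g <- ellipsoid_geometry(m$mass_g, m$body_density, m$shape_ratio_max)
  env <- chamber_environment(39.1)
  q0 <- dry_heat_loss(m, g, env, c(6, 7.5), tb = 39.1)
  expect_equal(q0$q_dry_W, 0, tolerance = 1e-9)
  env15 <- chamber_environment(15)
  q1 <- dry_heat_loss(m, g, env15, c(3, 3), tb = 39.1)$q_dry_W
  q2 <- dry_heat_loss(m, g, env15, c(6, 6), tb = 39.1)$q_dry_W
  expect_gt(q1, q2)
  expect_gt(q2, 0)
})

test_that("dry heat loss matches a term-by-term resistance-network oracle", {
  # independent solve: explicit conductances and a uniroot surface balance
  m <- waxbill_morph()
  g <- ellipsoid_geometry(m$mass_g, m$body_density, m$shape_ratio_max)
  env <- chamber_environment(15)
  cons <- physical_constants()
  tb <- 39.1
  depths <- c(6.0, 7.5)
  lens <- c(m$feather_length_dorsal_mm, m$feather_length_ventral_mm)
  r1 <- (3 * g$volume_m3 / (4 * pi)) ^ (1 / 3)
  h <- convection_coefficient(g, env)
  q_oracle <- 0
  for (i in 1:2) {
    k <- effective_coat_conductivity(m, depths[i], (tb + 15) / 2,
                                     feather_length_mm = lens[i])
    r2 <- r1 + depths[i] / 1000
    gc <- 2 * pi * k * r1 * r2 / (depths[i] / 1000)
    a_out <- 2 * pi * r2 ^ 2
    a_rad <- 2 * pi * (r1 + 0.9 * depths[i] / 1000) ^ 2
    bal <- function(ts) {
      gc * (tb - ts) - h * a_out * (ts - 15) -
        cons$emissivity_lw * cons$stefan_boltzmann * a_rad *
          ((ts + 273.15) ^ 4 - (15 + 273.15) ^ 4)
    }
    ts <- uniroot(bal, c(14, 39.1), tol = 1e-12)$root
    q_oracle <- q_oracle + gc * (tb - ts)
  }
  got <- dry_heat_loss(m, g, env, depths, tb)
  expect_equal(got$q_dry_W, q_oracle, tolerance = 1e-8)
  expect_gt(got$coat_surface_temp_C, 15)
  expect_lt(got$coat_surface_temp_C, 25)
})

test_that("respiratory evaporation follows ventilation and vanishes without a vapour gradient", {
  phys0 <- bird_physiology(breath_offset_C = 0)
  env_sat <- environment_state(20, rel_humidity_pct = 100)
  expect_equal(respiratory_evaporation(0.2, env_sat, phys0, tb_C = 39.1), 0)
  # frozen hand evaluation: MR 0.2 W, Ta 20 C, RH 5 %, extraction 25 %, offset 5 C
  phys <- bird_physiology()
  env <- environment_state(20, rel_humidity_pct = 5)
  expect_equal(respiratory_evaporation(0.2, env, phys, tb_C = 39.1),
               0.01026362, tolerance = 1e-6)
  q <- vapply(c(1, 2, 5, 15),
              function(p) respiratory_evaporation(0.2, env, phys, pant_level = p,
                                                  tb_C = 39.1),
              numeric(1))
  expect_true(all(diff(q) > 0))
  # expired air is capped at body temperature
  hot <- environment_state(41, rel_humidity_pct = 5)
  expect_equal(respiratory_evaporation(0.2, hot, phys, tb_C = 41.6),
               respiratory_evaporation(0.2, hot, bird_physiology(breath_offset_C = 10),
                                       tb_C = 41.6))
})

test_that("cutaneous evaporation is zero without wet skin or vapour gradient", {
  g <- ellipsoid_geometry(8, 875, 3)
  dry_phys <- bird_physiology(wet_skin_fraction = 0)
  env <- environment_state(20, rel_humidity_pct = 5)
  expect_identical(cutaneous_evaporation(g, env, 25, dry_phys), 0)
  env_sat <- environment_state(25, rel_humidity_pct = 100)
  expect_identical(cutaneous_evaporation(g, env_sat, 25, bird_physiology()), 0)
  q <- cutaneous_evaporation(g, env, 25, bird_physiology())
  expect_gt(q, 0)
  expect_lt(q, 0.1)
})

test_that("the solved metabolic rate balances the budget to machine precision", {
  set.seed(42)
  for (i in 1:20) {
    cs <- random_solver_case()
    sol <- solve_required_metabolic_rate(cs$morph, cs$phys, cs$env, cs$scenario)
    expect_lt(abs(sol$residual_W), 1e-6)
    expect_gte(sol$metabolic_rate_W, cs$phys$bmr_W)
    # budget re-check from the reported loss terms at the unclamped root
    losses <- sol$q_dry_W + sol$required_W *
      (sol$q_resp_evap_W / sol$metabolic_rate_W) + sol$q_cut_evap_W
    expect_lt(abs(sol$required_W - losses), 1e-6)
  }
})

test_that("root-finding agrees with a grid-search oracle on random draws", {
  set.seed(7)
  for (i in 1:20) {
    cs <- random_solver_case()
    sol <- solve_required_metabolic_rate(cs$morph, cs$phys, cs$env, cs$scenario)
    # independent oracle: scan MR at 1e-4 W resolution for the balance minimum
    g <- ellipsoid_geometry(cs$morph$mass_g, cs$morph$body_density,
                            cs$morph$shape_ratio_max)
    depths <- c(apply_ptiloerection(cs$morph$feather_depth_dorsal_mm,
                                    cs$morph$feather_length_dorsal_mm, cs$scenario),
                apply_ptiloerection(cs$morph$feather_depth_ventral_mm,
                                    cs$morph$feather_length_ventral_mm, cs$scenario))
    dry <- dry_heat_loss(cs$morph, g, cs$env, depths, cs$phys$tb_core_C)
    q_cut <- cutaneous_evaporation(g, cs$env, dry$coat_surface_temp_C, cs$phys)
    grid <- seq(cs$phys$bmr_W, 20 * cs$phys$bmr_W, by = 1e-4)
    resp <- vapply(grid, function(mr)
      respiratory_evaporation(mr, cs$env, cs$phys, tb_C = cs$phys$tb_core_C),
      numeric(1))
    resid <- abs(grid - (dry$q_dry_W + resp + q_cut))
    oracle_mr <- grid[which.min(resid)]
    expect_lt(abs(sol$metabolic_rate_W - oracle_mr), 1e-3)
  }
})

test_that("required metabolic rate falls with warmth, depth and fibre stock", {
  m <- waxbill_morph(); p <- summer_night_phys()
  mr <- function(ta, scen = "p200", morph = m) {
    solve_required_metabolic_rate(morph, p, chamber_environment(ta), scen)$required_W
  }
  expect_gt(mr(10), mr(20))
  expect_gt(mr(20), mr(28))
  # deeper coats cut the cold-side requirement
  expect_gt(mr(15, "none"), mr(15, "p35"))
  expect_gt(mr(15, "p35"), mr(15, "p200"))
  # under the air/keratin mixing rule, keratin conducts ~8x better than still
  # air, so a larger fibre volume fraction makes the coat more conductive and
  # raises the cold-side requirement
  m_dense <- bird_morphology(fiber_density_per_mm2 = 100)
  expect_lt(mr(15, "p200"), mr(15, "p200", m_dense))
})

test_that("the plateau clamps at the basal rate under chamber heat", {
  m <- waxbill_morph(); p <- summer_night_phys()
  sol32 <- thermoregulatory_cascade(m, p, chamber_environment(32), "p200")
  expect_equal(sol32$metabolic_rate_W, p$bmr_W)
  # air at body temperature and saturated: no dry or evaporative gradient
  sat <- environment_state(39.1, rel_humidity_pct = 100)
  sol <- solve_required_metabolic_rate(m, p, sat, "none")
  expect_lte(sol$required_W, 1e-6)
  expect_equal(sol$metabolic_rate_W, p$bmr_W)
  expect_equal(sol$regulated_flag, "thermoneutral")
})

test_that("the cascade selects the cheapest ptiloerection level in the cold", {
  m <- waxbill_morph(); p <- summer_night_phys()
  env <- chamber_environment(15)
  scen <- c("none", "p35", "p75", "p200")
  best <- thermoregulatory_cascade(m, p, env, scen)
  each <- vapply(scen, function(s)
    solve_required_metabolic_rate(m, p, env, s)$metabolic_rate_W, numeric(1))
  expect_equal(best$metabolic_rate_W, min(each))
  expect_identical(best$scenario_used, "p200")
  expect_lt(each[["p200"]], each[["p35"]])
})

test_that("heat stress raises body temperature before panting and flags hyperthermia", {
  m <- waxbill_morph()
  p <- bird_physiology(tb_core_C = 41.6, tb_max_C = 44, bmr_W = 0.2, rmr_W = 0.37)
  # forced maximal insulation at 40 C: cascade must shed heat
  sol <- thermoregulatory_cascade(m, p, chamber_environment(40), "p200",
                                  floor_W = p$bmr_W)
  expect_equal(sol$metabolic_rate_W, p$bmr_W)
  expect_gt(sol$tb_used_C, 41.6)
  expect_true(sol$regulated_flag %in% c("heat-stress", "hyperthermic"))
  # humid heat beyond panting capacity
  worst <- environment_state(44, wind_m_s = 0.1, rel_humidity_pct = 99)
  sol2 <- thermoregulatory_cascade(m, p, worst, "full", floor_W = p$bmr_W)
  expect_identical(sol2$regulated_flag, "hyperthermic")
  expect_equal(sol2$pant_level, p$pant_max)
  # cascade ordering: panting only engages once body temperature is maxed out
  for (ta in c(38, 40, 42)) {
    s <- thermoregulatory_cascade(m, p, chamber_environment(ta),
                                  c("none", "p35"), floor_W = p$bmr_W)
    # panting only after the body-temperature ladder is exhausted (increments
    # from 41.6 C stop at the last step at or below tb_max)
    expect_true(s$pant_level == 1 || s$tb_used_C + p$tb_increment_C > p$tb_max_C)
  }
})
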