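test_that("chamber ramp has the Scholander shape and a basal plateau", {
  m <- waxbill_morph(); p <- summer_night_phys()
  curve <- simulate_chamber(m, p, scenario_set = "p200")
  expect_s3_class(curve, "metabolic_curve")
  expect_equal(curve$air_temp_C, 10:40)
  # non-increasing down to the plateau, flat at BMR after
  expect_true(all(diff(curve$metabolic_rate_W) <= 1e-12))
  expect_equal(min(curve$metabolic_rate_W), p$bmr_W)
  expect_true(any(curve$metabolic_rate_W == p$bmr_W))
  # plateau sits at the measured basal range
  expect_gte(min(curve$metabolic_rate_W), 0.17)
  expect_lte(min(curve$metabolic_rate_W), 0.20)
})

test_that("ramp is deterministic and step-size consistent", {
  m <- waxbill_morph(); p <- summer_night_phys()
  c1 <- simulate_chamber(m, p, scenario_set = "p200", step = 1)
  c5 <- simulate_chamber(m, p, scenario_set = "p200", step = 5)
  shared <- intersect(c1$air_temp_C, c5$air_temp_C)
  expect_equal(c1$metabolic_rate_W[match(shared, c1$air_temp_C)],
               c5$metabolic_rate_W[match(shared, c5$air_temp_C)])
  expect_error(simulate_chamber(m, p, t_min = 30, t_max = 20), "below")
})

test_that("a ramp entirely above body temperature is flat at the basal rate", {
  m <- waxbill_morph(); p <- summer_night_phys()
  curve <- simulate_chamber(m, p, scenario_set = c("none", "p35"),
                            t_min = 40, t_max = 44, step = 1)
  expect_equal(curve$metabolic_rate_W, rep(p$bmr_W, nrow(curve)))
})

test_that("breakpoint detection finds a constructed kink and rejects degenerate curves", {
  ta <- 10:40
  mr <- 0.2 + 0.02 * pmax(0, 28 - ta)
  curve <- data.frame(air_temp_C = ta, metabolic_rate_W = mr)
  expect_equal(lower_critical_temperature(curve, bmr_W = 0.2), 28)
  expect_equal(lower_critical_temperature(curve, window = 1, bmr_W = 0.2), 28)
  flat <- data.frame(air_temp_C = ta, metabolic_rate_W = rep(0.2, length(ta)))
  expect_error(lower_critical_temperature(flat), "no breakpoint")
  mono <- data.frame(air_temp_C = ta, metabolic_rate_W = 1 - 0.02 * ta)
  expect_error(lower_critical_temperature(mono), "no breakpoint")
  expect_error(lower_critical_temperature(curve[1:4, ]), "too short")
})

test_that("breakpoint recovery stays within 1 C at the stated noise level", {
  # noise at 2 % of BMR, three replicate cycles per setpoint
  bird <- data.frame(id = "b1", bmr_W = 0.17)
  errs <- vapply(1:20, function(sd) {
    obs <- generate_respirometry(bird, temps = rep(10:40, each = 3), t_lc = 28,
                                 slope_W_per_C = 0.02,
                                 noise_sd = 0.02 * 0.17, seed = sd)
    est <- lower_critical_temperature(aggregate_curve(obs), bmr_W = 0.17)
    abs(est - 28)
  }, numeric(1))
  expect_true(all(errs <= 1))
})

test_that("detected lower critical temperature falls as insulation deepens", {
  m <- waxbill_morph(); p <- summer_night_phys()
  lct <- vapply(c("p35", "p200", "full"), function(s) {
    lower_critical_temperature(simulate_chamber(m, p, scenario_set = s),
                               bmr_W = p$bmr_W)
  }, numeric(1))
  expect_true(all(diff(lct) <= 0))
  expect_lt(lct[["full"]], lct[["p35"]])
})

test_that("curve RMSE matches hand arithmetic and rejects bad input", {
  pred <- data.frame(air_temp_C = c(10, 20, 30),
                     metabolic_rate_W = c(0.3, 0.25, 0.2))
  expect_equal(curve_rmse(pred, pred), 0)
  off <- pred; off$metabolic_rate_W <- pred$metabolic_rate_W + 0.05
  expect_equal(curve_rmse(pred, off), 0.05)
  obs <- data.frame(air_temp_C = c(10, 20, 30),
                    metabolic_rate_W = c(0.32, 0.24, 0.21))
  expect_equal(curve_rmse(pred, obs), 0.01414214, tolerance = 1e-6)
  expect_error(curve_rmse(pred, obs[0, ]), "no observations")
  bad <- data.frame(air_temp_C = 5, metabolic_rate_W = 0.3)
  expect_error(curve_rmse(pred, bad), "outside")
})

test_that("scenario ranking recovers the generating scenario", {
  m <- waxbill_morph(); p <- summer_night_phys()
  # self-consistency: observations equal to the p200 prediction
  pred <- simulate_chamber(m, p, scenario_set = "p200")
  obs <- data.frame(air_temp_C = pred$air_temp_C,
                    metabolic_rate_W = pred$metabolic_rate_W)
  rk <- rank_scenarios(m, p, obs)
  expect_equal(nrow(rk), 4)
  expect_identical(rk$scenario[1], "p200")
  expect_lt(rk$rmse_W[1], 1e-10)
  # synthetic observations generated under "full" with mild noise
  truth <- simulate_chamber(m, p, scenario_set = "full")
  set.seed(11)
  obs2 <- data.frame(air_temp_C = truth$air_temp_C,
                     metabolic_rate_W = truth$metabolic_rate_W +
                       rnorm(nrow(truth), 0, 0.002))
  rk2 <- rank_scenarios(m, p, obs2)
  expect_identical(rk2$scenario[1], "full")
  expect_error(rank_scenarios(m, p, obs, scenario_list = "p200"), "two scenarios")
})
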