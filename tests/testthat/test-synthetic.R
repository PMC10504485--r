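test_that("synthetic cohorts match the target distribution and scaling", {
  co <- generate_birds(1000, seed = 1)
  b <- co$birds
  expect_equal(mean(b$mass_g), 7.99, tolerance = 0.1)
  expect_true(all(b$mass_g > 4))
  expect_true(all(b$rmr_W >= b$bmr_W))
  # allometric structure: positive log-log mass scaling of both rates
  expect_gt(cor(log(b$mass_g), log(b$bmr_W)), 0.3)
  expect_gt(cor(log(b$mass_g), log(b$rmr_W)), 0.3)
  expect_equal(mean(b$bmr_W), 0.17, tolerance = 0.01)
})

test_that("cohort generation is deterministic and degenerates cleanly", {
  expect_identical(generate_birds(20, seed = 4)$birds, generate_birds(20, seed = 4)$birds)
  flat <- generate_birds(5, seed = 1, mass_sd = 0, log_noise_sd = 0)$birds
  expect_equal(length(unique(flat$mass_g)), 1)
  expect_equal(length(unique(flat$bmr_W)), 1)
  expect_equal(flat$bmr_W[1], 0.17)
  expect_error(generate_birds(0), ">= 1")
})

test_that("synthetic respirometry has the Scholander form and round-trips", {
  bird <- data.frame(id = "b1", bmr_W = 0.18)
  obs <- generate_respirometry(bird, temps = 10:40, t_lc = 28,
                               slope_W_per_C = 0.02, noise_sd = 0)
  expect_true(all(obs$metabolic_rate_W[obs$air_temp_C >= 28] == 0.18))
  expect_equal(obs$metabolic_rate_W[obs$air_temp_C == 23], 0.18 + 0.1)
  expect_equal(lower_critical_temperature(obs, bmr_W = 0.18), 28)
  expect_error(generate_respirometry(bird, temps = 10:20, t_lc = 28), "within")
})

test_that("synthetic feeding trials invert the intake bookkeeping", {
  bird <- data.frame(id = "b1", mass_g = 7.99)
  tr <- generate_feeding_trial(bird, true_EE_kJ = 109.43, mass_change_g = 0,
                               noise_cv = 0)
  expect_equal(net_energy_intake(tr), 109.43, tolerance = 1e-9)
  expect_equal(tr$energy_food_consumed_kJ / 15.66,
               50 - tr$food_leftover_g, tolerance = 1e-9)
  # mass change shifts intake by the fat-energy equivalent
  tr_loss <- generate_feeding_trial(bird, 109.43, mass_change_g = -0.5, noise_cv = 0)
  expect_equal(net_energy_intake(tr_loss), 109.43 - 19.75, tolerance = 1e-9)
  tr_gain <- generate_feeding_trial(bird, 109.43, mass_change_g = 0.19, noise_cv = 0)
  expect_equal(net_energy_intake(tr_gain), 109.43 + 8.78085, tolerance = 1e-9)
  expect_error(generate_feeding_trial(bird, 1e4), "50 g")
  # at the measured means, magnitudes sit at the observed scale
  expect_lt(abs(50 - tr$food_leftover_g - 9.7), 0.5)
})

test_that("food mass follows the millet energy density", {
  bird <- data.frame(id = "b1", mass_g = 8)
  tr <- generate_feeding_trial(bird, true_EE_kJ = 151.84 * 0.83 * 0.87,
                               noise_cv = 0)
  expect_equal(50 - tr$food_leftover_g, 9.696041, tolerance = 1e-4)
})

test_that("temperature logs stay in the recorded range with the 40/33 mask", {
  log <- generate_temperature_log(seed = 2)
  expect_equal(nrow(log), 73)
  expect_true(all(log$air_temp_C >= 19.6 & log$air_temp_C <= 22.3))
  expect_equal(sum(log$is_day), 40)
  expect_equal(sum(!log$is_day), 33)
  const <- generate_temperature_log(amplitude_C = 0, noise_sd = 0)
  expect_true(all(const$air_temp_C == 21))
  expect_identical(generate_temperature_log(seed = 8), generate_temperature_log(seed = 8))
})

test_that("cohort-to-detection pipeline recovers each bird's breakpoint", {
  co <- generate_birds(10, seed = 21)
  errs <- vapply(seq_len(10), function(i) {
    bird <- co$birds[i, ]
    obs <- generate_respirometry(bird, temps = rep(10:40, each = 3),
                                 t_lc = 27, slope_W_per_C = 0.02,
                                 noise_sd = 0.005, seed = 100 + i)
    abs(lower_critical_temperature(aggregate_curve(obs), bmr_W = bird$bmr_W) - 27)
  }, numeric(1))
  expect_true(all(errs <= 1))
})

test_that("cohort-to-regression pipeline recovers a unit slope", {
  co <- generate_birds(100, seed = 31)
  b <- co$birds
  true_ee <- time_energy_budget(b$bmr_W) * runif(100, 0.9, 1.1)
  mass_change <- rnorm(100, 0, 0.2)
  tab <- do.call(rbind, lapply(seq_len(100), function(i) {
    tr <- generate_feeding_trial(b[i, ], true_ee[i], mass_change_g = mass_change[i],
                                 noise_cv = 0.02, seed = 500 + i)
    data.frame(nei_kJ = net_energy_intake(tr),
               ee_nm_kJ = true_ee[i],
               ee_teb_kJ = time_energy_budget(b$bmr_W[i]),
               mass_change_g = mass_change[i],
               fat_energy_kJ = fat_energy_equivalent(mass_change[i])$signed_kJ)
  }))
  out <- compare_ee_models(tab)
  best <- out[out$prediction == "ee_nm_kJ" & out$covariate == "fat_energy_kJ", ]
  expect_lt(abs(best$slope - 1), 0.05)
  expect_identical(out$prediction[1], "ee_nm_kJ")
})
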