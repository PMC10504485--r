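#' Generate a synthetic bird cohort
#'
#' Masses are drawn from a truncated normal (> 4 g) around the measured
#' cohort mean; basal and daytime resting rates follow an allometric power
#' law \eqn{a\, m^{0.66} e^\varepsilon} with the coefficient calibrated so
#' the expected cohort mean matches the target, giving the positive log-log
#' mass scaling seen in the measurements. RMR is floored at BMR per
#' individual.
#'
#' @param n Number of individuals.
#' @param seed Integer seed.
#' @param mass_mean,mass_sd Body-mass distribution, g.
#' @param bmr_mean,rmr_mean Target mean rates, W.
#' @param allometric_exp Mass exponent of the rate scaling.
#' @param log_noise_sd SD of the lognormal rate noise.
#' @return List of class \code{"synthetic_cohort"}: \code{birds} (data frame
#'   with id, mass_g, bmr_W, rmr_W), \code{seed}, \code{params}.
#' @export
generate_birds <- function(n, seed = 1, mass_mean = 7.99, mass_sd = 0.93,
                           bmr_mean = 0.17, rmr_mean = 0.37,
                           allometric_exp = 0.66, log_noise_sd = 0.08) {
  if (n < 1) stop("generate_birds: n must be >= 1")
  set.seed(seed)
  mass <- stats::rnorm(n, mass_mean, mass_sd)
  while (any(mass <= 4)) {
    mass[mass <= 4] <- stats::rnorm(sum(mass <= 4), mass_mean, mass_sd)
  }
  scaled <- (mass / mass_mean) ^ allometric_exp
  noise <- function() exp(stats::rnorm(n, -log_noise_sd ^ 2 / 2, log_noise_sd))
  bmr <- bmr_mean * scaled * noise()
  rmr <- pmax(rmr_mean * scaled * noise(), bmr)
  out <- list(
    birds = data.frame(id = sprintf("bird%03d", seq_len(n)),
                       mass_g = mass, bmr_W = bmr, rmr_W = rmr,
                       stringsAsFactors = FALSE),
    seed = seed,
    params = list(mass_mean = mass_mean, mass_sd = mass_sd,
                  bmr_mean = bmr_mean, rmr_mean = rmr_mean,
                  allometric_exp = allometric_exp, log_noise_sd = log_noise_sd)
  )
  class(out) <- "synthetic_cohort"
  out
}

#' Generate synthetic respirometry observations
#'
#' Scholander-shaped metabolic response with a known breakpoint:
#' \eqn{MR(T) = BMR + s \max(0, T_{lc} - T) + \epsilon}. Temperatures may
#' repeat (replicate measurement cycles at the same setpoint).
#'
#' @param bird One row of a cohort's \code{birds} data frame (needs
#'   \code{bmr_W}; \code{id} if present is carried through).
#' @param temps Air temperatures of the observations, C.
#' @param t_lc True lower critical temperature, C (inside \code{temps} range).
#' @param slope_W_per_C Cold-side slope, W per C.
#' @param noise_sd Measurement noise SD, W.
#' @param seed Integer seed.
#' @return Data frame with \code{air_temp_C}, \code{metabolic_rate_W},
#'   \code{individual_id}, sorted by temperature.
#' @export
generate_respirometry <- function(bird, temps, t_lc, slope_W_per_C = 0.02,
                                  noise_sd = 0, seed = 1) {
  if (t_lc < min(temps) || t_lc > max(temps)) {
    stop("generate_respirometry: t_lc must lie within the temperature range")
  }
  set.seed(seed)
  temps <- sort(temps)
  mr <- bird$bmr_W + slope_W_per_C * pmax(0, t_lc - temps) +
    stats::rnorm(length(temps), 0, noise_sd)
  data.frame(air_temp_C = temps, metabolic_rate_W = mr,
             individual_id = if (!is.null(bird$id)) bird$id else "bird001",
             stringsAsFactors = FALSE)
}

#' Generate a synthetic feeding trial
#'
#' Inverts the net-energy-intake bookkeeping: given an assumed true energy
#' expenditure and a body-mass change, the required NEI is the expenditure
#' adjusted by the fat-energy equivalent of the mass change; food and excreta
#' energies are then chosen so that
#' \eqn{0.83 (E_{food} - E_{excreta})} equals that NEI (excreta a fixed
#' fraction of food energy), with optional multiplicative measurement noise
#' on the energies. Food mass follows from the energy density of hulled
#' millet (15.66 kJ/g).
#'
#' @param bird One cohort row (mass and id carried into the record).
#' @param true_EE_kJ Assumed true energy expenditure over the trial, kJ.
#' @param mass_change_g Body-mass change (post minus pre), g.
#' @param digestibility Net/metabolizable coefficient (0.83).
#' @param energy_density_kJ_per_g Food energy density, kJ/g.
#' @param excreta_fraction Excreta energy as a fraction of food energy.
#' @param noise_cv Coefficient of variation of the energy measurements.
#' @param seed Integer seed.
#' @param duration_h Trial length, h.
#' @return A \code{\link{feeding_trial}}.
#' @export
generate_feeding_trial <- function(bird, true_EE_kJ, mass_change_g = 0,
                                   digestibility = 0.83,
                                   energy_density_kJ_per_g = 15.66,
                                   excreta_fraction = 0.13,
                                   noise_cv = 0, seed = 1, duration_h = 73) {
  if (true_EE_kJ <= 0) stop("generate_feeding_trial: true_EE_kJ must be positive")
  set.seed(seed)
  nei <- true_EE_kJ + fat_energy_equivalent(mass_change_g)$signed_kJ
  e_food <- nei / (digestibility * (1 - excreta_fraction))
  e_exc <- excreta_fraction * e_food
  if (noise_cv > 0) {
    e_food <- e_food * exp(stats::rnorm(1, 0, noise_cv))
    e_exc <- e_exc * exp(stats::rnorm(1, 0, noise_cv))
  }
  food_g <- e_food / energy_density_kJ_per_g
  if (food_g > 50) {
    stop("generate_feeding_trial: required food (", round(food_g, 1),
         " g) exceeds the 50 g offered")
  }
  mass_post <- if (!is.null(bird$mass_g)) bird$mass_g else 7.99
  feeding_trial(
    individual_id = if (!is.null(bird$id)) bird$id else "bird001",
    food_offered_g = 50, food_leftover_g = 50 - food_g,
    excreta_g = e_exc / energy_density_kJ_per_g,  # nominal dry mass
    energy_food_consumed_kJ = e_food, energy_excreta_kJ = e_exc,
    mass_pre_g = mass_post - mass_change_g, mass_post_g = mass_post,
    duration_h = duration_h
  )
}

#' Generate a synthetic hourly temperature log
#'
#' Sinusoidal diel cycle around a base temperature with small Gaussian
#' noise, clipped to the recorded trial range (19.6-22.3 C by default), plus
#' the 40 day / 33 night hour mask.
#'
#' @param hours Number of hours.
#' @param base_C Mean temperature, C.
#' @param amplitude_C Diel half-amplitude, C.
#' @param noise_sd Hourly noise SD, C.
#' @param clip_range Two-element range the log is clipped to (NULL for none).
#' @param seed Integer seed.
#' @return Data frame with \code{hour_index}, \code{air_temp_C},
#'   \code{is_day}; attribute \code{"seed"}.
#' @export
generate_temperature_log <- function(hours = 73, base_C = 21, amplitude_C = 1.2,
                                     noise_sd = 0.15, clip_range = c(19.6, 22.3),
                                     seed = 1) {
  if (hours < 1) stop("generate_temperature_log: hours must be >= 1")
  set.seed(seed)
  h <- seq_len(hours)
  temp <- base_C + amplitude_C * sin(2 * pi * (h - 8) / 24) +
    stats::rnorm(hours, 0, noise_sd)
  if (!is.null(clip_range)) temp <- pmin(pmax(temp, clip_range[1]), clip_range[2])
  mask <- if (hours == 73) default_day_mask() else rep(c(rep(TRUE, 12), rep(FALSE, 12)), length.out = hours)
  out <- data.frame(hour_index = h, air_temp_C = temp, is_day = mask)
  attr(out, "seed") <- seed
  out
}
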