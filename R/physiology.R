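#' Bird physiology
#'
#' Physiological parameter set for the heat balance. Defaults are the
#' waxbill values: night core temperature 39.1 C, day 41.6 C, body-temperature
#' increments of 0.25 C up to a 44 C maximum, O2 extraction efficiency 25\%,
#' expired air 5 C above ambient, 1\% wet skin, maximum panting rate 15 with
#' a BMR multiplier of 1 at maximum panting, digestion-cost coefficient 0.83.
#'
#' @param tb_core_C Regulated core temperature, C (39.1 at night, 41.6 by day).
#' @param tb_max_C Maximum tolerated core temperature, C.
#' @param tb_increment_C Step size for heat-stress body-temperature elevation, C.
#' @param bmr_W Basal (night) metabolic rate, W (QBASAL).
#' @param rmr_W Daytime resting metabolic rate, W; floor for daytime solves.
#' @param o2_extraction Fraction of inspired O2 extracted per breath.
#' @param breath_offset_C Expired air temperature minus ambient, C.
#' @param wet_skin_fraction Fraction of skin surface acting as a free water
#'   surface for cutaneous evaporation.
#' @param pant_max Maximum panting level (ventilation multiplier).
#' @param pant_bmr_multiplier Multiplier on BMR at maximum panting (1 = panting
#'   costs no extra metabolic heat).
#' @param digestion_coefficient Net/metabolizable energy coefficient.
#' @return A list of class \code{"bird_physiology"}.
#' @export
bird_physiology <- function(tb_core_C = 39.1,
                            tb_max_C = 44,
                            tb_increment_C = 0.25,
                            bmr_W = 0.17,
                            rmr_W = 0.37,
                            o2_extraction = 0.25,
                            breath_offset_C = 5,
                            wet_skin_fraction = 0.01,
                            pant_max = 15,
                            pant_bmr_multiplier = 1,
                            digestion_coefficient = 0.83) {
  p <- list(
    tb_core_C = tb_core_C, tb_max_C = tb_max_C, tb_increment_C = tb_increment_C,
    bmr_W = bmr_W, rmr_W = rmr_W, o2_extraction = o2_extraction,
    breath_offset_C = breath_offset_C, wet_skin_fraction = wet_skin_fraction,
    pant_max = pant_max, pant_bmr_multiplier = pant_bmr_multiplier,
    digestion_coefficient = digestion_coefficient
  )
  if (p$tb_max_C < p$tb_core_C) stop("bird_physiology: tb_max_C must be >= tb_core_C")
  if (p$o2_extraction <= 0 || p$o2_extraction >= 1) stop("bird_physiology: o2_extraction must lie in (0,1)")
  if (p$bmr_W <= 0) stop("bird_physiology: bmr_W must be positive")
  if (p$rmr_W < p$bmr_W) stop("bird_physiology: rmr_W must be >= bmr_W")
  if (p$wet_skin_fraction < 0 || p$wet_skin_fraction > 1) stop("bird_physiology: wet_skin_fraction must lie in [0,1]")
  if (p$pant_max < 1) stop("bird_physiology: pant_max must be >= 1")
  class(p) <- "bird_physiology"
  p
}

#' Night and day physiology presets
#'
#' \code{night_physiology()} uses the night core temperature (39.1 C) with the
#' BMR as resting floor (the respirometry protocol measures basal rates at
#' night); \code{day_physiology()} uses 41.6 C with the daytime RMR floor.
#'
#' @param bmr_W Basal metabolic rate, W.
#' @param rmr_W Daytime resting metabolic rate, W.
#' @param ... Passed to \code{\link{bird_physiology}}.
#' @return A \code{bird_physiology}.
#' @export
night_physiology <- function(bmr_W = 0.17, ...) {
  bird_physiology(tb_core_C = 39.1, bmr_W = bmr_W, rmr_W = max(bmr_W, 0.37), ...)
}

#' @rdname night_physiology
#' @export
day_physiology <- function(bmr_W = 0.17, rmr_W = 0.37, ...) {
  bird_physiology(tb_core_C = 41.6, bmr_W = bmr_W, rmr_W = rmr_W, ...)
}

#' Environmental conditions for one time step
#'
#' @param air_temp_C Air temperature, C.
#' @param wind_m_s Wind speed, m/s.
#' @param rel_humidity_pct Relative humidity, \%.
#' @param solar_W_m2 Shortwave irradiance, W/m2 (zero in all chamber work).
#' @return A list of class \code{"environment_state"}.
#' @export
environment_state <- function(air_temp_C, wind_m_s = 0.1,
                              rel_humidity_pct = 5, solar_W_m2 = 0) {
  if (wind_m_s < 0) stop("environment_state: wind must be >= 0")
  if (rel_humidity_pct < 0 || rel_humidity_pct > 100) {
    stop("environment_state: relative humidity must lie in [0, 100]")
  }
  if (solar_W_m2 < 0) stop("environment_state: solar must be >= 0")
  e <- list(air_temp_C = air_temp_C, wind_m_s = wind_m_s,
            rel_humidity_pct = rel_humidity_pct, solar_W_m2 = solar_W_m2)
  class(e) <- "environment_state"
  e
}

#' Metabolic-chamber conditions
#'
#' The respirometry chamber is simulated with wind 0.1 m/s, relative humidity
#' 5\%, no solar radiation, and radiant temperature equal to air temperature.
#'
#' @param air_temp_C Chamber air temperature, C.
#' @return An \code{environment_state}.
#' @export
chamber_environment <- function(air_temp_C) {
  environment_state(air_temp_C, wind_m_s = 0.1, rel_humidity_pct = 5, solar_W_m2 = 0)
}
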