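#' Waxbill heat-balance model object
#'
#' Bundles a morphology, night/day physiology and physical constants into a
#' single model object with the usual methods: \code{print}, \code{summary}
#' (chamber ramp and lower critical temperature), \code{coef} (the trait
#' vector under its published mnemonics), \code{predict} (metabolic rate over
#' a data frame of environments) and \code{plot} (the chamber curve). The
#' model is a forward simulator — nothing is estimated from data — so there
#' are no \code{residuals} or \code{fitted} methods.
#'
#' @param morphology A \code{bird_morphology}.
#' @param physiology_night,physiology_day \code{bird_physiology} objects for
#'   the two circadian phases.
#' @param constants A \code{physical_constants}.
#' @param scenario_set Default ptiloerection levels for cascade solves.
#' @param strategy Exchange-geometry strategy.
#' @return An object of class \code{"waxbill_model"}.
#' @examples
#' m <- waxbill_model()
#' coef(m)
#' predict(m, data.frame(air_temp_C = c(10, 20, 30)))
#' @export
waxbill_model <- function(morphology = bird_morphology(),
                          physiology_night = night_physiology(),
                          physiology_day = day_physiology(),
                          constants = physical_constants(),
                          scenario_set = c("none", "p35", "p75", "p200", "full"),
                          strategy = "sphere-volume") {
  obj <- list(morphology = morphology, physiology_night = physiology_night,
              physiology_day = physiology_day, constants = constants,
              scenario_set = scenario_set, strategy = strategy)
  class(obj) <- "waxbill_model"
  obj
}

#' @export
print.waxbill_model <- function(x, ...) {
  m <- x$morphology
  cat("Biophysical heat-balance model\n")
  cat(sprintf("  body: %.2f g, density %.0f kg/m3, shape ratio <= %.1f\n",
              m$mass_g, m$body_density, m$shape_ratio_max))
  cat(sprintf("  coat: depth %.1f/%.1f mm, length %.1f/%.1f mm (dorsal/ventral),\n",
              m$feather_depth_dorsal_mm, m$feather_depth_ventral_mm,
              m$feather_length_dorsal_mm, m$feather_length_ventral_mm))
  cat(sprintf("        fibre %.3f mm, %.0f /mm2, k = %.3f W/mK\n",
              m$fiber_diameter_mm, m$fiber_density_per_mm2, m$fiber_conductivity))
  cat(sprintf("  physiology: Tb %.1f C night / %.1f C day, BMR %.2f W, RMR %.2f W\n",
              x$physiology_night$tb_core_C, x$physiology_day$tb_core_C,
              x$physiology_night$bmr_W, x$physiology_day$rmr_W))
  cat("  ptiloerection levels:", paste(x$scenario_set, collapse = ", "), "\n")
  invisible(x)
}

#' @export
coef.waxbill_model <- function(object, ...) {
  m <- object$morphology; p <- object$physiology_night
  c(AMASS = m$mass_g, TC = p$tb_core_C, TC_MAX = p$tb_max_C,
    SHAPE_B_MAX = m$shape_ratio_max, DHAIR = m$fiber_diameter_mm,
    LHAIR = mean(c(m$feather_length_dorsal_mm, m$feather_length_ventral_mm)),
    ZFUR = mean(c(m$feather_depth_dorsal_mm, m$feather_depth_ventral_mm)),
    RHO = m$fiber_density_per_mm2, QBASAL = p$bmr_W)
}

#' Predict metabolic rates over environments
#'
#' @param object A \code{waxbill_model}.
#' @param newdata Data frame with \code{air_temp_C} and optionally
#'   \code{wind_m_s}, \code{rel_humidity_pct}, \code{is_day} (default night).
#' @param ... Unused.
#' @return \code{newdata} with solution columns appended.
#' @export
predict.waxbill_model <- function(object, newdata, ...) {
  if (!"air_temp_C" %in% names(newdata)) stop("predict.waxbill_model: need air_temp_C")
  wind <- if ("wind_m_s" %in% names(newdata)) newdata$wind_m_s else rep(0.1, nrow(newdata))
  rh <- if ("rel_humidity_pct" %in% names(newdata)) newdata$rel_humidity_pct else rep(5, nrow(newdata))
  day <- if ("is_day" %in% names(newdata)) newdata$is_day else rep(FALSE, nrow(newdata))
  sols <- lapply(seq_len(nrow(newdata)), function(i) {
    phys <- if (day[i]) object$physiology_day else object$physiology_night
    floor_w <- if (day[i]) phys$rmr_W else phys$bmr_W
    thermoregulatory_cascade(object$morphology, phys,
                             environment_state(newdata$air_temp_C[i], wind[i], rh[i], 0),
                             object$scenario_set, floor_W = floor_w,
                             constants = object$constants,
                             strategy = object$strategy)
  })
  newdata$metabolic_rate_W <- vapply(sols, `[[`, numeric(1), "metabolic_rate_W")
  newdata$scenario_used <- vapply(sols, `[[`, character(1), "scenario_used")
  newdata$regulated_flag <- vapply(sols, `[[`, character(1), "regulated_flag")
  newdata
}

#' @export
summary.waxbill_model <- function(object, scenario_set = "p200", ...) {
  res <- tnz_result(object$morphology, object$physiology_night,
                    scenario_set = scenario_set,
                    constants = object$constants, strategy = object$strategy)
  out <- list(model = object, tnz = res)
  class(out) <- "summary.waxbill_model"
  out
}

#' @export
print.summary.waxbill_model <- function(x, ...) {
  print(x$model)
  cat(sprintf("\nChamber ramp (%s): lower critical temperature %.1f C; plateau %.3f W\n",
              x$tnz$scenario_label, x$tnz$lower_critical_temp_C,
              min(x$tnz$curve$metabolic_rate_W)))
  invisible(x)
}

#' @export
plot.waxbill_model <- function(x, scenario_set = x$scenario_set, ...) {
  curve <- simulate_chamber(x$morphology, x$physiology_night, scenario_set,
                            constants = x$constants, strategy = x$strategy)
  graphics::plot(curve$air_temp_C, curve$metabolic_rate_W, type = "b", pch = 16,
                 xlab = "Air temperature (°C)", ylab = "Metabolic rate (W)",
                 main = "Predicted metabolic-rate curve", ...)
  graphics::abline(h = x$physiology_night$bmr_W, lty = 3)
  invisible(curve)
}

#' @export
print.metabolic_solution <- function(x, ...) {
  cat(sprintf("Metabolic solution: %.4f W (%s)\n", x$metabolic_rate_W, x$regulated_flag))
  cat(sprintf("  required %.4f W | dry %.4f W, resp evap %.4f W, cut evap %.4f W\n",
              x$required_W, x$q_dry_W, x$q_resp_evap_W, x$q_cut_evap_W))
  cat(sprintf("  tb %.2f C, scenario %s, pant %.2f, coat surface %.2f C\n",
              x$tb_used_C, x$scenario_used, x$pant_level, x$coat_surface_temp_C))
  invisible(x)
}

#' @export
print.sensitivity_result <- function(x, ...) {
  cat(sprintf("Relative influence (%d samples, %d trees):\n", x$n_samples, x$n_trees))
  for (nm in names(x$influence_pct)) {
    cat(sprintf("  %-12s %5.1f%%\n", nm, x$influence_pct[[nm]]))
  }
  invisible(x)
}
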