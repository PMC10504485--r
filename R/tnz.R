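#' Simulate a metabolic chamber across a temperature ramp
#'
#' Runs one thermoregulatory-cascade solve per air temperature under chamber
#' conditions (wind 0.1 m/s, relative humidity 5\%, no solar radiation,
#' radiant temperature equal to air temperature). Night physiology (core
#' 39.1 C, BMR floor) is the default, matching the respirometry protocol.
#'
#' @param morph A \code{bird_morphology}.
#' @param phys A \code{bird_physiology}; floors at \code{phys$bmr_W}.
#' @param scenario_set Allowed ptiloerection levels. A single label forces
#'   that scenario at every temperature.
#' @param t_min,t_max,step Temperature ramp, C (default 10-40 in 1 C steps).
#' @param constants A \code{physical_constants}.
#' @param strategy Exchange-geometry strategy.
#' @return A data frame of class \code{"metabolic_curve"} with columns
#'   \code{air_temp_C}, \code{metabolic_rate_W}, \code{required_W},
#'   \code{scenario_used}, \code{tb_used_C}, \code{pant_level},
#'   \code{regulated_flag}.
#' @export
simulate_chamber <- function(morph, phys = night_physiology(),
                             scenario_set = c("none", "p35", "p75", "p200", "full"),
                             t_min = 10, t_max = 40, step = 1,
                             constants = physical_constants(),
                             strategy = "sphere-volume") {
  if (t_min >= t_max) stop("simulate_chamber: t_min must be below t_max")
  temps <- seq(t_min, t_max, by = step)
  rows <- lapply(temps, function(ta) {
    sol <- tryCatch(
      thermoregulatory_cascade(morph, phys, chamber_environment(ta),
                               scenario_set, floor_W = phys$bmr_W,
                               constants = constants, strategy = strategy),
      error = function(e) stop("simulate_chamber: solve failed at Ta = ", ta,
                               " C: ", conditionMessage(e), call. = FALSE)
    )
    data.frame(air_temp_C = ta, metabolic_rate_W = sol$metabolic_rate_W,
               required_W = sol$required_W, scenario_used = sol$scenario_used,
               tb_used_C = sol$tb_used_C, pant_level = sol$pant_level,
               regulated_flag = sol$regulated_flag, stringsAsFactors = FALSE)
  })
  curve <- do.call(rbind, rows)
  class(curve) <- c("metabolic_curve", "data.frame")
  curve
}

#' Lower critical temperature of the thermoneutral zone
#'
#' Locates the inflection where the metabolic-rate curve stops decreasing and
#' starts to plateau, via a second-difference operator on the curve: at every
#' interior temperature the local slope is fitted over \code{window} points on
#' each side and the breakpoint is the temperature maximising
#' (right slope - left slope). With \code{window = 1} this reduces to the
#' plain central second difference; the default window of 3 averages out
#' measurement noise. The candidate must sit between a genuinely decreasing
#' segment and a plateau (absolute plateau slope below
#' \code{plateau_tol_frac} of the basal rate per degree, or below half the
#' magnitude of the descending slope when noise dominates).
#'
#' @param curve A \code{metabolic_curve} or data frame with columns
#'   \code{air_temp_C} and \code{metabolic_rate_W} (ascending temperature).
#' @param window Half-window (number of points per side) for the local slopes.
#' @param plateau_tol_frac Plateau threshold as a fraction of the basal rate
#'   per degree C (default 0.005, i.e. 0.5\%).
#' @param bmr_W Basal rate used to scale the plateau threshold; defaults to
#'   the minimum of the curve.
#' @return Lower critical temperature, C.
#' @export
lower_critical_temperature <- function(curve, window = 3,
                                       plateau_tol_frac = 0.005, bmr_W = NULL) {
  ta <- curve$air_temp_C
  mr <- curve$metabolic_rate_W
  n <- length(ta)
  if (n < 2 * window + 1 || n < 4) stop("lower_critical_temperature: curve too short")
  if (any(diff(ta) <= 0)) stop("lower_critical_temperature: temperatures must be strictly increasing")
  if (is.null(bmr_W)) bmr_W <- min(mr)
  thr <- plateau_tol_frac * bmr_W

  fit_slope <- function(i, j) {
    x <- ta[i:j]; y <- mr[i:j]
    sum((x - mean(x)) * (y - mean(y))) / sum((x - mean(x)) ^ 2)
  }
  idx <- (window + 1):(n - window)
  s_left <- vapply(idx, function(i) fit_slope(i - window, i), numeric(1))
  s_right <- vapply(idx, function(i) fit_slope(i, i + window), numeric(1))
  curvature <- s_right - s_left
  best <- which.max(curvature)
  sl <- s_left[best]; sr <- s_right[best]
  plateau_ok <- abs(sr) < max(thr, 0.5 * abs(sl))
  if (curvature[best] <= thr || sl >= -thr || !plateau_ok) {
    stop("lower_critical_temperature: no breakpoint (curve monotone or flat)")
  }
  ta[idx[best]]
}

#' Root-mean-square error between a predicted curve and observations
#'
#' Predictions are linearly interpolated to the observed temperatures;
#' observations outside the predicted range are rejected rather than
#' extrapolated.
#'
#' @param predicted_curve Data frame with \code{air_temp_C},
#'   \code{metabolic_rate_W}.
#' @param observed_points Data frame with \code{air_temp_C},
#'   \code{metabolic_rate_W} (one row per observation; individuals may repeat
#'   temperatures).
#' @return RMSE in W.
#' @export
curve_rmse <- function(predicted_curve, observed_points) {
  if (is.null(observed_points) || nrow(observed_points) == 0) {
    stop("curve_rmse: no observations supplied")
  }
  rng <- range(predicted_curve$air_temp_C)
  if (any(observed_points$air_temp_C < rng[1] | observed_points$air_temp_C > rng[2])) {
    stop("curve_rmse: observed temperatures outside the predicted range")
  }
  pred <- stats::approx(predicted_curve$air_temp_C, predicted_curve$metabolic_rate_W,
                        xout = observed_points$air_temp_C)$y
  sqrt(mean((pred - observed_points$metabolic_rate_W) ^ 2))
}

#' Rank ptiloerection scenarios against observed metabolic rates
#'
#' Runs one fixed-scenario chamber simulation per entry (the scenario is
#' forced, not cascade-selected), scores each against the observations by
#' RMSE, and sorts ascending (best first).
#'
#' @inheritParams simulate_chamber
#' @param observed_points Observations as in \code{\link{curve_rmse}}.
#' @param scenario_list Character vector of scenarios to compare (>= 2).
#' @return Data frame with columns \code{scenario} and \code{rmse_W}, ordered
#'   by fit.
#' @export
rank_scenarios <- function(morph, phys, observed_points,
                           scenario_list = c("p35", "p75", "p200", "full"),
                           t_min = 10, t_max = 40, step = 1,
                           constants = physical_constants(),
                           strategy = "sphere-volume") {
  if (length(scenario_list) < 2) stop("rank_scenarios: need at least two scenarios")
  rmse <- vapply(scenario_list, function(s) {
    pred <- simulate_chamber(morph, phys, scenario_set = s,
                             t_min = t_min, t_max = t_max, step = step,
                             constants = constants, strategy = strategy)
    curve_rmse(pred, observed_points)
  }, numeric(1))
  out <- data.frame(scenario = scenario_list, rmse_W = rmse,
                    stringsAsFactors = FALSE)
  out[order(out$rmse_W), , drop = FALSE]
}

#' Thermoneutral-zone summary for a scenario
#'
#' Convenience wrapper: simulates the chamber ramp and detects the lower
#' critical temperature.
#'
#' @inheritParams simulate_chamber
#' @param ... Passed to \code{\link{lower_critical_temperature}}.
#' @return List of class \code{"tnz_result"}: \code{lower_critical_temp_C},
#'   \code{curve}, \code{scenario_label}.
#' @export
tnz_result <- function(morph, phys = night_physiology(), scenario_set = "p200",
                       t_min = 10, t_max = 40, step = 1,
                       constants = physical_constants(),
                       strategy = "sphere-volume", ...) {
  curve <- simulate_chamber(morph, phys, scenario_set, t_min, t_max, step,
                            constants, strategy)
  out <- list(
    lower_critical_temp_C = lower_critical_temperature(curve, bmr_W = phys$bmr_W, ...),
    curve = curve,
    scenario_label = paste(scenario_set, collapse = "+")
  )
  class(out) <- "tnz_result"
  out
}
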