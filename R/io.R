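# Parameter-file schema: key -> c(min, max) plausibility bounds used by the
# loader. Keys follow the published mnemonics where one exists.
param_schema <- function() {
  list(
    AMASS = c(1, 100),            # body mass, g
    TC = c(30, 45),               # night core temperature, C
    TC_DAY = c(30, 46),           # daytime core temperature, C
    TC_MAX = c(35, 48),           # maximum core temperature, C
    TB_INC = c(0.01, 2),          # body-temperature increment, C
    SHAPE_B_MAX = c(1, 10),       # max length:width ratio
    ANDENS = c(500, 1500),        # body density, kg/m3
    FAT_PCT = c(0, 50),           # body fat, %
    DHAIR = c(0.005, 0.5),        # fibre diameter, mm
    LHAIR_DORSAL = c(1, 100),     # feather length, mm
    LHAIR_VENTRAL = c(1, 100),
    ZFUR_DORSAL = c(0.1, 100),    # feather depth, mm
    ZFUR_VENTRAL = c(0.1, 100),
    RHO = c(0.1, 5000),           # fibre density, 1/mm2
    KHAIR = c(0.01, 2),           # fibre conductivity, W/mK
    QBASAL = c(0.01, 10),         # basal metabolic rate, W
    QBASAL_SUMMER = c(0.01, 10),  # summer BMR (thermoneutral-zone protocol), W
    RMR = c(0.01, 20),            # daytime resting metabolic rate, W
    O2_EXTRACTION_PCT = c(1, 99),
    BREATH_OFFSET_C = c(0, 20),
    WETSKIN_PCT = c(0, 100),
    PANT_MAX = c(1, 50),
    PANT_MULT = c(1, 10),
    DIGESTION_COEF = c(0.1, 1),
    LW_DEPTH_FRAC = c(0, 1),
    EMISSIVITY = c(0.5, 1)
  )
}

#' Load a model parameter file
#'
#' Reads a flat YAML (or JSON) key-value file using the published parameter
#' mnemonics, validates every value against plausibility bounds, rejects
#' unknown keys, and assembles the model inputs. All missing mandatory keys
#' are reported at once. The packaged default file carries the waxbill
#' trait set.
#'
#' @param path Path to the parameter file; default is the packaged waxbill
#'   file.
#' @return List with \code{morphology} (a \code{bird_morphology}),
#'   \code{physiology_night}, \code{physiology_day}, \code{bmr_summer_W},
#'   \code{constants} (a \code{physical_constants}) and \code{raw} (the
#'   validated key-value list).
#' @export
load_parameters <- function(path = system.file("extdata", "waxbill_params.yaml",
                                               package = "waxtherm")) {
  vals <- yaml::read_yaml(path)
  schema <- param_schema()
  unknown <- setdiff(names(vals), names(schema))
  if (length(unknown)) stop("load_parameters: unknown key(s): ", paste(unknown, collapse = ", "))
  missing <- setdiff(names(schema), names(vals))
  if (length(missing)) stop("load_parameters: missing key(s): ", paste(missing, collapse = ", "))
  for (k in names(vals)) {
    v <- vals[[k]]
    if (!is.numeric(v) || length(v) != 1L || !is.finite(v)) {
      stop("load_parameters: key ", k, " is not a single finite number")
    }
    b <- schema[[k]]
    if (v < b[1] || v > b[2]) {
      stop("load_parameters: key ", k, " = ", v, " outside plausible range [",
           b[1], ", ", b[2], "]")
    }
  }
  morph <- bird_morphology(
    mass_g = vals$AMASS, body_density = vals$ANDENS,
    shape_ratio_max = vals$SHAPE_B_MAX, fat_fraction = vals$FAT_PCT / 100,
    feather_depth_dorsal_mm = vals$ZFUR_DORSAL,
    feather_depth_ventral_mm = vals$ZFUR_VENTRAL,
    feather_length_dorsal_mm = vals$LHAIR_DORSAL,
    feather_length_ventral_mm = vals$LHAIR_VENTRAL,
    fiber_diameter_mm = vals$DHAIR, fiber_density_per_mm2 = vals$RHO,
    fiber_conductivity = vals$KHAIR
  )
  mk_phys <- function(tb, floor_rmr) bird_physiology(
    tb_core_C = tb, tb_max_C = vals$TC_MAX, tb_increment_C = vals$TB_INC,
    bmr_W = vals$QBASAL, rmr_W = max(vals$RMR, vals$QBASAL),
    o2_extraction = vals$O2_EXTRACTION_PCT / 100,
    breath_offset_C = vals$BREATH_OFFSET_C,
    wet_skin_fraction = vals$WETSKIN_PCT / 100,
    pant_max = vals$PANT_MAX, pant_bmr_multiplier = vals$PANT_MULT,
    digestion_coefficient = vals$DIGESTION_COEF
  )
  list(
    morphology = morph,
    physiology_night = mk_phys(vals$TC),
    physiology_day = mk_phys(vals$TC_DAY),
    bmr_summer_W = vals$QBASAL_SUMMER,
    constants = physical_constants(fractional_lw_depth = vals$LW_DEPTH_FRAC,
                                   emissivity_lw = vals$EMISSIVITY),
    raw = vals
  )
}

#' Write a parameter list back to YAML
#'
#' Round-trips with \code{\link{load_parameters}}: writing the \code{raw}
#' component and reloading reproduces the same validated values.
#'
#' @param vals Named list of parameter values (e.g. the \code{raw} component).
#' @param path Output path.
#' @return \code{path}, invisibly.
#' @export
write_parameters <- function(vals, path) {
  yaml::write_yaml(vals, path)
  invisible(path)
}

#' Read an observed metabolic-rate CSV
#'
#' Expected columns: \code{air_temp_C}, \code{metabolic_rate_W}, optionally
#' \code{individual_id}.
#'
#' @param path CSV path.
#' @return Data frame sorted by temperature.
#' @export
read_observed_curve <- function(path) {
  d <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("air_temp_C", "metabolic_rate_W")
  miss <- setdiff(need, names(d))
  if (length(miss)) stop("read_observed_curve: missing column(s): ", paste(miss, collapse = ", "))
  d[order(d$air_temp_C), , drop = FALSE]
}

#' Read an hourly temperature log CSV
#'
#' Expected columns: \code{hour_index}, \code{air_temp_C}, \code{is_day}.
#'
#' @param path CSV path.
#' @return Data frame ordered by hour.
#' @export
read_temperature_log <- function(path) {
  d <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("hour_index", "air_temp_C", "is_day")
  miss <- setdiff(need, names(d))
  if (length(miss)) stop("read_temperature_log: missing column(s): ", paste(miss, collapse = ", "))
  d$is_day <- as.logical(d$is_day)
  d[order(d$hour_index), , drop = FALSE]
}

#' Read a feeding-trial CSV
#'
#' One row per individual with the \code{\link{feeding_trial}} fields as
#' columns.
#'
#' @param path CSV path.
#' @return Data frame.
#' @export
read_feeding_trials <- function(path) {
  d <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("individual_id", "food_offered_g", "food_leftover_g", "excreta_g",
            "energy_food_consumed_kJ", "energy_excreta_kJ", "mass_pre_g",
            "mass_post_g")
  miss <- setdiff(need, names(d))
  if (length(miss)) stop("read_feeding_trials: missing column(s): ", paste(miss, collapse = ", "))
  d
}

#' Run the analysis pipeline
#'
#' Orchestrates the main stages over one parameter set and writes their
#' artifacts (curve and comparison CSVs, JSON summaries) plus a
#' machine-readable run manifest carrying the package version, seed and a
#' parameter-file hash, so a run can be reproduced exactly.
#'
#' @param stages Character subset of \code{c("synth", "tnz", "ee",
#'   "sensitivity")}.
#' @param out_dir Output directory (created if needed).
#' @param params_path Parameter file; default the packaged waxbill set.
#' @param seed Integer seed for every stochastic stage.
#' @param observed_csv Optional observed metabolic-rate CSV for scenario
#'   ranking; when absent, a synthetic curve is generated.
#' @param temps_csv Optional hourly temperature CSV for the EE stage; when
#'   absent, a synthetic log is generated.
#' @param n_sensitivity Latin-hypercube size for the sensitivity stage.
#' @return Invisibly, a list of the stage results.
#' @export
run_pipeline <- function(stages = c("tnz", "ee"), out_dir, params_path = NULL,
                         seed = 1, observed_csv = NULL, temps_csv = NULL,
                         n_sensitivity = 200) {
  stages <- match.arg(stages, c("synth", "tnz", "ee", "sensitivity"), several.ok = TRUE)
  if (missing(out_dir)) stop("run_pipeline: out_dir is required")
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  if (is.null(params_path)) {
    params_path <- system.file("extdata", "waxbill_params.yaml", package = "waxtherm")
  }
  pars <- load_parameters(params_path)
  results <- list()

  if ("synth" %in% stages) {
    cohort <- generate_birds(14, seed = seed)
    log <- generate_temperature_log(seed = seed)
    utils::write.csv(cohort$birds, file.path(out_dir, "synthetic_birds.csv"),
                     row.names = FALSE)
    utils::write.csv(log, file.path(out_dir, "synthetic_temperature_log.csv"),
                     row.names = FALSE)
    obs <- generate_respirometry(cohort$birds[1, ], temps = rep(10:32, each = 3),
                                 t_lc = 28, noise_sd = 0.002, seed = seed)
    utils::write.csv(obs, file.path(out_dir, "synthetic_respirometry.csv"),
                     row.names = FALSE)
    results$synth <- list(cohort = cohort, log = log, observed = obs)
  }

  if ("tnz" %in% stages) {
    phys <- pars$physiology_night
    phys$bmr_W <- pars$bmr_summer_W  # respirometry protocol used summer BMR
    res <- tnz_result(pars$morphology, phys, scenario_set = "p200",
                      constants = pars$constants)
    utils::write.csv(res$curve, file.path(out_dir, "tnz_curve.csv"), row.names = FALSE)
    observed <- if (!is.null(observed_csv)) read_observed_curve(observed_csv) else {
      generate_respirometry(data.frame(bmr_W = phys$bmr_W, id = "synthetic"),
                            temps = rep(seq(15, 32, 2), each = 3),
                            t_lc = res$lower_critical_temp_C,
                            noise_sd = 0.01, seed = seed)
    }
    ranking <- rank_scenarios(pars$morphology, phys, observed)
    jsonlite::write_json(
      list(lower_critical_temp_C = res$lower_critical_temp_C,
           scenario_ranking = ranking),
      file.path(out_dir, "tnz_summary.json"), auto_unbox = TRUE, digits = NA)
    results$tnz <- list(result = res, ranking = ranking)
  }

  if ("ee" %in% stages) {
    log <- if (!is.null(temps_csv)) read_temperature_log(temps_csv) else
      generate_temperature_log(seed = seed)
    ee <- simulate_ee(log$air_temp_C, pars$morphology, pars$physiology_night,
                      day_night_mask = log$is_day,
                      night_scenarios = "full",
                      constants = pars$constants)
    teb <- time_energy_budget(pars$physiology_night$bmr_W,
                              daylight_h = sum(log$is_day),
                              night_h = sum(!log$is_day))
    utils::write.csv(ee$hourly_W, file.path(out_dir, "ee_hourly.csv"), row.names = FALSE)
    jsonlite::write_json(list(ee_total_kJ = ee$total_kJ, ee_teb_kJ = teb),
                         file.path(out_dir, "ee_summary.json"),
                         auto_unbox = TRUE, digits = NA)
    results$ee <- list(ee = ee, teb = teb)
  }

  if ("sensitivity" %in% stages) {
    samples <- latin_hypercube(n = n_sensitivity, seed = seed)
    outs <- evaluate_variants(samples, outputs = "EE_73h_kJ")
    infl <- relative_influence(samples, outs$EE_73h_kJ, seed = seed)
    utils::write.csv(cbind(as.data.frame(samples), outs),
                     file.path(out_dir, "sensitivity_samples.csv"), row.names = FALSE)
    jsonlite::write_json(as.list(infl$influence_pct),
                         file.path(out_dir, "sensitivity_importance.json"),
                         auto_unbox = TRUE, digits = NA)
    results$sensitivity <- infl
  }

  manifest <- list(
    package = "waxtherm",
    version = as.character(utils::packageVersion("waxtherm")),
    seed = seed,
    stages = stages,
    parameter_file = basename(params_path),
    parameter_hash = unname(tools::md5sum(params_path))
  )
  jsonlite::write_json(manifest, file.path(out_dir, "run_manifest.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(results)
}
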