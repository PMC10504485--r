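#' Default parameter ranges for the sensitivity analysis
#'
#' The nine morphological and physiological parameters varied in the
#' sensitivity analysis, with their minimum/maximum bounds: core body
#' temperature TC (39-42 C), maximum body temperature TC_MAX (39-44 C), body
#' shape ratio SHAPE_B_MAX (1.2-5), feather fibre diameter DHAIR
#' (0.019-0.11 mm), feather length LHAIR (7.6-25 mm), feather depth ZFUR
#' (2.17-16.11 mm), feather density RHO (0.7-140 per mm2), basal metabolic
#' rate QBASAL (0.15-0.26 W) and body mass AMASS (6-10 g).
#'
#' The published RHO bounds are typeset ambiguously ("0.7...4140"); a density
#' of 4140 fibres/mm2 is physically implausible against the fixed working
#' value of 50/mm2, so the default upper bound is 140/mm2. Both bounds are
#' editable.
#'
#' @return Data frame with columns \code{mnemonic}, \code{min}, \code{max},
#'   \code{units}.
#' @export
parameter_ranges <- function() {
  data.frame(
    mnemonic = c("TC", "TC_MAX", "SHAPE_B_MAX", "DHAIR", "LHAIR", "ZFUR",
                 "RHO", "QBASAL", "AMASS"),
    min = c(39, 39, 1.2, 0.019, 7.6, 2.17, 0.7, 0.15, 6),
    max = c(42, 44, 5, 0.11, 25, 16.11, 140, 0.26, 10),
    units = c("C", "C", "-", "mm", "mm", "mm", "1/mm2", "W", "g"),
    stringsAsFactors = FALSE
  )
}

#' Latin-hypercube sample over parameter ranges
#'
#' Stratified design: for each parameter exactly one draw falls in each of
#' \code{n} equal-probability strata, uniform within stratum, with columns
#' permuted independently; values are rescaled to each parameter's
#' [min, max]. Reproducible under a fixed seed.
#'
#' @param ranges Data frame as from \code{\link{parameter_ranges}}.
#' @param n Number of model variants.
#' @param seed Integer RNG seed.
#' @return An n x p numeric matrix with the mnemonics as column names.
#' @export
latin_hypercube <- function(ranges = parameter_ranges(), n = 1000, seed = 1) {
  if (n < 2 * nrow(ranges)) stop("latin_hypercube: n must be at least twice the parameter count")
  bad <- which(!is.finite(ranges$min) | !is.finite(ranges$max) | ranges$min >= ranges$max)
  if (length(bad)) {
    stop("latin_hypercube: invalid range for ", paste(ranges$mnemonic[bad], collapse = ", "))
  }
  set.seed(seed)
  u <- lhs::randomLHS(n, nrow(ranges))
  s <- sweep(u, 2, ranges$max - ranges$min, `*`)
  s <- sweep(s, 2, ranges$min, `+`)
  colnames(s) <- ranges$mnemonic
  s
}

# Build morphology/physiology for one sampled variant. The sampled coat is a
# single layer (one ZFUR, one LHAIR applied to both halves); ZFUR above LHAIR
# is clamped to LHAIR to keep the design balanced. Table 1 carries no RMR row,
# so the daytime floor is tied to the sampled QBASAL by the measured
# RMR:BMR ratio 0.37/0.17.
variant_parameters <- function(row) {
  zfur <- min(row[["ZFUR"]], row[["LHAIR"]])
  morph <- bird_morphology(
    mass_g = row[["AMASS"]],
    shape_ratio_max = row[["SHAPE_B_MAX"]],
    feather_depth_dorsal_mm = zfur, feather_depth_ventral_mm = zfur,
    feather_length_dorsal_mm = row[["LHAIR"]], feather_length_ventral_mm = row[["LHAIR"]],
    fiber_diameter_mm = row[["DHAIR"]],
    fiber_density_per_mm2 = row[["RHO"]]
  )
  phys <- bird_physiology(
    tb_core_C = row[["TC"]], tb_max_C = max(row[["TC_MAX"]], row[["TC"]]),
    bmr_W = row[["QBASAL"]], rmr_W = row[["QBASAL"]] * 0.37 / 0.17
  )
  list(morph = morph, phys = phys, clamped = zfur < row[["ZFUR"]])
}

#' Evaluate model variants from a Latin-hypercube sample
#'
#' Runs, for each sampled parameter row, the chamber ramp (lower bound of the
#' thermoneutral zone) and/or the 73-h energy-expenditure simulation, using
#' the same model settings as the main analyses (TNZ: night physiology, 200\%
#' ptiloerection; EE: daytime 35\% / night full ptiloerection). Rows whose
#' TNZ detection fails (no breakpoint inside the ramp) carry \code{NA} and
#' are counted.
#'
#' @param samples Matrix from \code{\link{latin_hypercube}}.
#' @param outputs Which outputs to compute: \code{"EE_73h_kJ"},
#'   \code{"TNZ_lower_C"} or both.
#' @param hourly_temps_C Temperature trace for the EE runs (73 h); defaults
#'   to a constant 21 C.
#' @param day_night_mask Day mask for the EE runs.
#' @param max_failure_frac Abort when more than this fraction of TNZ
#'   detections fail.
#' @param strategy Exchange-geometry strategy.
#' @return Data frame with one row per variant and one column per requested
#'   output; attribute \code{"n_failed"} counts failed TNZ detections and
#'   \code{"n_clamped"} counts ZFUR > LHAIR clamps.
#' @export
evaluate_variants <- function(samples, outputs = c("EE_73h_kJ", "TNZ_lower_C"),
                              hourly_temps_C = rep(21, 73),
                              day_night_mask = NULL,
                              max_failure_frac = 0.2,
                              strategy = "sphere-volume") {
  outputs <- match.arg(outputs, c("EE_73h_kJ", "TNZ_lower_C"), several.ok = TRUE)
  n <- nrow(samples)
  ee <- rep(NA_real_, n); tnz <- rep(NA_real_, n)
  n_clamped <- 0L
  for (i in seq_len(n)) {
    vp <- variant_parameters(samples[i, ])
    if (vp$clamped) n_clamped <- n_clamped + 1L
    if ("EE_73h_kJ" %in% outputs) {
      ee[i] <- simulate_ee(hourly_temps_C, vp$morph, vp$phys,
                           day_night_mask = day_night_mask,
                           tb_day_C = vp$phys$tb_core_C + 2.5,
                           tb_night_C = vp$phys$tb_core_C,
                           night_scenarios = "full",
                           strategy = strategy)$total_kJ
    }
    if ("TNZ_lower_C" %in% outputs) {
      night <- vp$phys
      tnz[i] <- tryCatch({
        curve <- simulate_chamber(vp$morph, night, scenario_set = "p200",
                                  strategy = strategy)
        lower_critical_temperature(curve, bmr_W = night$bmr_W)
      }, error = function(e) NA_real_)
    }
  }
  if ("TNZ_lower_C" %in% outputs) {
    n_failed <- sum(is.na(tnz))
    if (n_failed > max_failure_frac * n) {
      stop("evaluate_variants: ", n_failed, "/", n, " TNZ detections failed")
    }
  } else {
    n_failed <- 0L
  }
  out <- data.frame(row.names = seq_len(n))
  if ("EE_73h_kJ" %in% outputs) out$EE_73h_kJ <- ee
  if ("TNZ_lower_C" %in% outputs) out$TNZ_lower_C <- tnz
  attr(out, "n_failed") <- n_failed
  attr(out, "n_clamped") <- n_clamped
  out
}

#' Relative influence of parameters via boosted regression trees
#'
#' Fits a gradient-boosted tree ensemble (squared-error loss, interaction
#' depth 3, shrinkage 0.1; number of trees chosen by held-out deviance on a
#' 20\% validation split) of the output on the sampled parameters and returns
#' the normalised split-gain importance in percent. A permutation-importance
#' alternative is provided for robustness checks.
#'
#' @param samples Parameter matrix (rows matching \code{outputs}).
#' @param outputs Numeric output vector; rows with \code{NA} are dropped.
#' @param seed Integer seed (validation split and tie-breaking).
#' @param method \code{"gain"} (default) or \code{"permutation"}.
#' @param max_rounds Upper limit on boosting rounds.
#' @return List of class \code{"sensitivity_result"}: \code{influence_pct}
#'   (named, sums to 100), \code{n_samples}, \code{output_name},
#'   \code{n_trees}, \code{seed}.
#' @export
relative_influence <- function(samples, outputs, seed = 1,
                               method = c("gain", "permutation"),
                               max_rounds = 600) {
  method <- match.arg(method)
  keep <- is.finite(outputs)
  x <- as.matrix(samples)[keep, , drop = FALSE]
  y <- outputs[keep]
  if (length(y) < 100) stop("relative_influence: need at least 100 complete rows")
  if (stats::sd(y) == 0) stop("relative_influence: output vector is constant")

  set.seed(seed)
  n <- nrow(x)
  val <- sample.int(n, max(1L, round(0.2 * n)))
  dtrain <- xgboost::xgb.DMatrix(x[-val, , drop = FALSE], label = y[-val])
  dval <- xgboost::xgb.DMatrix(x[val, , drop = FALSE], label = y[val])
  fit <- xgboost::xgb.train(
    params = list(objective = "reg:squarederror", max_depth = 3, eta = 0.1,
                  nthread = 1, seed = seed),
    data = dtrain, nrounds = max_rounds,
    evals = list(val = dval),
    early_stopping_rounds = 25, verbose = 0
  )
  infl <- stats::setNames(rep(0, ncol(x)), colnames(x))
  if (method == "gain") {
    imp <- xgboost::xgb.importance(model = fit)
    infl[imp$Feature] <- imp$Gain
  } else {
    base <- mean((stats::predict(fit, x) - y) ^ 2)
    for (j in seq_len(ncol(x))) {
      xp <- x
      xp[, j] <- xp[sample.int(n), j]
      infl[j] <- max(mean((stats::predict(fit, xp) - y) ^ 2) - base, 0)
    }
  }
  infl <- 100 * infl / sum(infl)
  n_trees <- as.integer(xgboost::xgb.attr(fit, "best_iteration"))
  out <- list(influence_pct = sort(infl, decreasing = TRUE),
              n_samples = n, output_name = deparse(substitute(outputs)),
              n_trees = if (length(n_trees)) n_trees else max_rounds, seed = seed)
  class(out) <- "sensitivity_result"
  out
}
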