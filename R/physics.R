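#' Physical constants used by the heat-balance model
#'
#' Returns the fixed physical constants of the exchange model. Values follow
#' standard physics tables except where a field convention applies (oxyjoule
#' equivalent, plumage longwave exchange depth).
#'
#' @param stefan_boltzmann Stefan-Boltzmann constant (W m-2 K-4).
#' @param emissivity_lw Longwave emissivity of the plumage surface.
#' @param oxyjoule_J_per_mlO2 Heat equivalent of oxygen consumption (J per ml O2).
#' @param fractional_lw_depth Fractional depth of the feather coat at which
#'   longwave radiation is exchanged (0 = skin, 1 = coat surface).
#' @param o2_fraction_air Mole fraction of O2 in dry air.
#' @param lewis_number Lewis number for water vapour in air, used in the
#'   heat/mass-transfer analogy.
#' @return A list of class \code{"physical_constants"}.
#' @export
physical_constants <- function(stefan_boltzmann = 5.670e-8,
                               emissivity_lw = 0.95,
                               oxyjoule_J_per_mlO2 = 20.1,
                               fractional_lw_depth = 0.9,
                               o2_fraction_air = 0.2094,
                               lewis_number = 0.86) {
  cons <- list(
    stefan_boltzmann = stefan_boltzmann,
    emissivity_lw = emissivity_lw,
    oxyjoule_J_per_mlO2 = oxyjoule_J_per_mlO2,
    fractional_lw_depth = fractional_lw_depth,
    o2_fraction_air = o2_fraction_air,
    lewis_number = lewis_number
  )
  bad <- names(cons)[!vapply(cons, function(x) is.numeric(x) && length(x) == 1L && is.finite(x) && x > 0, logical(1))]
  if (length(bad)) {
    stop("physical_constants: non-positive or non-finite: ", paste(bad, collapse = ", "))
  }
  class(cons) <- "physical_constants"
  cons
}

#' Thermal conductivity of air
#'
#' Power-law fit to tabulated dry-air conductivity, anchored at 0.02624 W/mK
#' at 300 K.
#'
#' @param temp_C Air temperature (degrees C).
#' @return Conductivity in W/mK.
#' @export
air_conductivity <- function(temp_C) {
  0.02624 * ((temp_C + 273.15) / 300) ^ 0.8646
}

# Sutherland's law for dynamic viscosity of air (kg m-1 s-1)
air_viscosity <- function(temp_C) {
  tk <- temp_C + 273.15
  1.458e-6 * tk ^ 1.5 / (tk + 110.4)
}

# Dry-air density at standard pressure (kg m-3)
air_density <- function(temp_C) {
  101325 * 0.028964 / (8.314462 * (temp_C + 273.15))
}

air_cp <- 1006  # J kg-1 K-1, effectively constant over 0-50 C

air_prandtl <- function(temp_C) {
  air_viscosity(temp_C) * air_cp / air_conductivity(temp_C)
}

#' Saturation vapour pressure of water
#'
#' Magnus-type closed form (Alduchov-Eskridge coefficients), valid over the
#' biologically relevant range.
#'
#' @param temp_C Temperature (degrees C).
#' @return Saturation vapour pressure in Pa.
#' @export
saturation_vapor_pressure <- function(temp_C) {
  610.94 * exp(17.625 * temp_C / (temp_C + 243.04))
}

# Water vapour density (kg m-3) at a given temperature and relative humidity (%)
vapor_density <- function(temp_C, rel_humidity_pct = 100) {
  e <- saturation_vapor_pressure(temp_C) * rel_humidity_pct / 100
  e * 0.018015 / (8.314462 * (temp_C + 273.15))
}

# Latent heat of vaporisation of water (J kg-1)
latent_heat_vaporization <- function(temp_C) {
  2.501e6 - 2369 * temp_C
}
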