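#' Bird morphology
#'
#' Container for the morphological traits that drive the heat balance: body
#' mass, density and shape, and the feather-coat descriptors (depth, length,
#' fibre diameter, fibre areal density, fibre conductivity). The coat is
#' carried as two halves, dorsal and ventral, each with its own depth and
#' length; \code{single_coat()} collapses them to their means for analyses
#' that treat the coat as one layer.
#'
#' Defaults are the common-waxbill trait set: 7.99 g body mass, density
#' 875 kg/m3, maximum length:width ratio 3, 4\% body fat, feather depth
#' 2.0 mm dorsal / 2.5 mm ventral, feather length 16.1 / 14.1 mm, fibre
#' diameter 0.03 mm, fibre density 50 /mm2, feather conductivity 0.209 W/mK.
#'
#' @param mass_g Body mass in grams (AMASS).
#' @param body_density Whole-body density, kg/m3.
#' @param shape_ratio_max Maximum ratio of body length to width (SHAPE_B_MAX).
#' @param fat_fraction Body fat fraction (carried for completeness; skin is
#'   modelled at core temperature so it does not enter the balance).
#' @param feather_depth_dorsal_mm,feather_depth_ventral_mm Coat depth (ZFUR), mm.
#' @param feather_length_dorsal_mm,feather_length_ventral_mm Feather length
#'   (LHAIR), mm.
#' @param fiber_diameter_mm Feather fibre diameter (DHAIR), mm.
#' @param fiber_density_per_mm2 Fibres per mm2 of skin (RHO).
#' @param fiber_conductivity Thermal conductivity of feather keratin, W/mK.
#' @return A list of class \code{"bird_morphology"}.
#' @export
bird_morphology <- function(mass_g = 7.99,
                            body_density = 875,
                            shape_ratio_max = 3,
                            fat_fraction = 0.04,
                            feather_depth_dorsal_mm = 2.0,
                            feather_depth_ventral_mm = 2.5,
                            feather_length_dorsal_mm = 16.1,
                            feather_length_ventral_mm = 14.1,
                            fiber_diameter_mm = 0.03,
                            fiber_density_per_mm2 = 50,
                            fiber_conductivity = 0.209) {
  m <- list(
    mass_g = mass_g, body_density = body_density,
    shape_ratio_max = shape_ratio_max, fat_fraction = fat_fraction,
    feather_depth_dorsal_mm = feather_depth_dorsal_mm,
    feather_depth_ventral_mm = feather_depth_ventral_mm,
    feather_length_dorsal_mm = feather_length_dorsal_mm,
    feather_length_ventral_mm = feather_length_ventral_mm,
    fiber_diameter_mm = fiber_diameter_mm,
    fiber_density_per_mm2 = fiber_density_per_mm2,
    fiber_conductivity = fiber_conductivity
  )
  num <- vapply(m, function(x) is.numeric(x) && length(x) == 1L && is.finite(x), logical(1))
  if (!all(num)) stop("bird_morphology: non-numeric field(s): ", paste(names(m)[!num], collapse = ", "))
  pos <- names(m)[vapply(m, function(x) x <= 0, logical(1))]
  pos <- setdiff(pos, "fat_fraction")  # fat may be zero
  if (length(pos)) stop("bird_morphology: non-positive field(s): ", paste(pos, collapse = ", "))
  if (m$shape_ratio_max < 1) stop("bird_morphology: shape_ratio_max must be >= 1")
  if (m$feather_depth_dorsal_mm > m$feather_length_dorsal_mm) {
    stop("bird_morphology: dorsal feather depth exceeds feather length")
  }
  if (m$feather_depth_ventral_mm > m$feather_length_ventral_mm) {
    stop("bird_morphology: ventral feather depth exceeds feather length")
  }
  class(m) <- "bird_morphology"
  m
}

#' Collapse the dorsal/ventral coat to a single layer
#'
#' Replaces both coat halves with the arithmetic mean of their depths and
#' lengths. Used by the sensitivity analysis, which samples one depth and one
#' length.
#'
#' @param morph A \code{bird_morphology}.
#' @return A \code{bird_morphology} with identical dorsal and ventral coats.
#' @export
single_coat <- function(morph) {
  stopifnot(inherits(morph, "bird_morphology"))
  d <- mean(c(morph$feather_depth_dorsal_mm, morph$feather_depth_ventral_mm))
  l <- mean(c(morph$feather_length_dorsal_mm, morph$feather_length_ventral_mm))
  morph$feather_depth_dorsal_mm <- morph$feather_depth_ventral_mm <- d
  morph$feather_length_dorsal_mm <- morph$feather_length_ventral_mm <- l
  morph
}

#' Ellipsoid body geometry
#'
#' Models the body as a prolate spheroid with semi-axes \eqn{a = k b} (b = c),
#' choosing b so that the volume equals mass/density. The surface area uses
#' the closed form for a prolate spheroid, and the characteristic length for
#' convection is the diameter of the equal-volume sphere,
#' \eqn{(6V/\pi)^{1/3}}.
#'
#' @param mass_g Body mass, g.
#' @param body_density Body density, kg/m3.
#' @param shape_ratio Ratio of long to short semi-axis (>= 1).
#' @return A list of class \code{"body_geometry"} with fields
#'   \code{semi_major_m}, \code{semi_minor_m}, \code{volume_m3},
#'   \code{surface_area_m2}, \code{characteristic_length_m}.
#' @export
ellipsoid_geometry <- function(mass_g, body_density, shape_ratio = 3) {
  if (!is.finite(mass_g) || mass_g <= 0) stop("ellipsoid_geometry: mass_g must be positive")
  if (!is.finite(body_density) || body_density <= 0) stop("ellipsoid_geometry: body_density must be positive")
  if (!is.finite(shape_ratio) || shape_ratio < 1) stop("ellipsoid_geometry: shape_ratio must be >= 1")
  volume <- mass_g / 1000 / body_density
  b <- (3 * volume / (4 * pi * shape_ratio)) ^ (1 / 3)
  a <- shape_ratio * b
  if (shape_ratio < 1 + 1e-9) {
    area <- 4 * pi * b ^ 2
  } else {
    e <- sqrt(1 - (b / a) ^ 2)
    area <- 2 * pi * b ^ 2 * (1 + a / (b * e) * asin(e))
  }
  out <- list(
    semi_major_m = a, semi_minor_m = b, volume_m3 = volume,
    surface_area_m2 = area,
    characteristic_length_m = (6 * volume / pi) ^ (1 / 3)
  )
  class(out) <- "body_geometry"
  out
}

#' Ptiloerection scenarios
#'
#' Scenario labels and their feather-depth multipliers: \code{none} (resting
#' depth), \code{p35}/\code{p75}/\code{p200} (depth increased by 35\%, 75\%
#' and 200\%), and \code{full} (depth raised to feather length, i.e. feathers
#' erected perpendicular to the skin). The transformed depth is always capped
#' at feather length.
#'
#' @return Named numeric vector of depth multipliers (\code{full} is
#'   \code{NA}: depth is set to length, not scaled).
#' @export
ptiloerection_levels <- function() {
  c(none = 1.00, p35 = 1.35, p75 = 1.75, p200 = 3.00, full = NA_real_)
}

#' Apply a ptiloerection scenario to a feather layer
#'
#' @param feather_depth_mm Resting coat depth, mm.
#' @param feather_length_mm Feather length, mm (upper limit of any erection).
#' @param scenario One of \code{"none"}, \code{"p35"}, \code{"p75"},
#'   \code{"p200"}, \code{"full"}.
#' @return Effective coat depth in mm.
#' @export
apply_ptiloerection <- function(feather_depth_mm, feather_length_mm, scenario) {
  scenario <- match.arg(scenario, names(ptiloerection_levels()))
  if (!is.finite(feather_depth_mm) || feather_depth_mm <= 0) {
    stop("apply_ptiloerection: feather depth must be positive")
  }
  if (feather_depth_mm > feather_length_mm) {
    stop("apply_ptiloerection: feather depth exceeds feather length")
  }
  if (scenario == "full") return(feather_length_mm)
  mult <- ptiloerection_levels()[[scenario]]
  min(feather_depth_mm * mult, feather_length_mm)
}
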