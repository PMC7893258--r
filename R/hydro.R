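#' Physical constants for the glide model
#'
#' Gravitational acceleration, surface air density and the
#' atmosphere-to-Pascal conversion used throughout the hydrodynamic model.
#' Air density is the standard sea-level value; it only enters the (small)
#' air-buoyancy term, where it is further compressed with depth.
#'
#' @param g gravitational acceleration, m s^-2.
#' @param rho_air density of air at the surface (1 atm), kg m^-3.
#' @param atmosphere_pa one atmosphere in Pascals.
#' @return a list of class `physical_constants`.
#' @export
physicalConstants <- function(g = 9.8, rho_air = 1.225, atmosphere_pa = 101325) {
  stopifnot(g > 0, rho_air > 0, atmosphere_pa > 0)
  structure(list(g = g, rho_air = rho_air, atmosphere_pa = atmosphere_pa),
            class = "physical_constants")
}

#' Hydrodynamic glide-model parameters
#'
#' The unknowns of the glide-acceleration model: tissue density at zero
#' pressure, the combined drag term \eqn{C_D A m^{-1}} (drag coefficient
#' times reference area over body mass, not separately identifiable), the
#' diving air volume per unit body mass, and the fixed tissue
#' compressibility.
#'
#' @param tissue_density tissue body density at the zero-pressure reference,
#'   kg m^-3 (must lie in 800--1200).
#' @param drag_term combined drag term \eqn{C_D A / m}, m^2 kg^-1, > 0.
#' @param air_per_mass diving air volume per unit mass \eqn{V_{air}/m},
#'   m^3 kg^-1, >= 0. 37.3 ml kg^-1 corresponds to 3.73e-5.
#' @param compressibility fractional tissue volume change per Pascal;
#'   default 0.38e-9 Pa^-1 (the value estimated for northern bottlenose
#'   whales and used here as a fixed constant).
#' @return a list of class `hydro_params`.
#' @export
hydroParams <- function(tissue_density, drag_term, air_per_mass = 0,
                        compressibility = 0.38e-9) {
  stopifnot(is.numeric(tissue_density), tissue_density >= 800, tissue_density <= 1200,
            drag_term > 0, air_per_mass >= 0, compressibility >= 0)
  structure(list(tissue_density = tissue_density, drag_term = drag_term,
                 air_per_mass = air_per_mass, compressibility = compressibility),
            class = "hydro_params")
}

#' Tissue density at depth
#'
#' Compresses the zero-pressure tissue density by the absolute pressure at
#' depth: \deqn{\rho_{tissue}(d) = \rho_{tissue}(0) / (1 - r (1 + 0.1 d) \cdot 101325)}
#' where \eqn{(1 + 0.1 d)} is the absolute pressure in atmospheres at depth
#' `d` metres and 101325 converts atmospheres to Pascals. Note the formula
#' applies the full 1 atm at the surface, so the reference density is a
#' zero-pressure (vacuum) value, marginally below the density at d = 0.
#'
#' @param rho0 zero-pressure tissue density, kg m^-3.
#' @param r compressibility, Pa^-1.
#' @param d depth, metres (>= 0). Vectorized over `d`.
#' @param atmosphere_pa Pascals per atmosphere.
#' @return tissue density at depth, kg m^-3.
#' @export
#' @examples
#' tissueDensityAtDepth(1036, 0.38e-9, 90) # 1036.399
tissueDensityAtDepth <- function(rho0, r, d, atmosphere_pa = 101325) {
  stopifnot(all(d >= 0), r >= 0)
  denom <- 1 - r * (1 + 0.1 * d) * atmosphere_pa
  if (any(denom <= 0)) {
    stop("non-physical compression: 1 - r*(1 + 0.1*d)*", atmosphere_pa, " <= 0")
  }
  rho0 / denom
}

#' Predicted along-path acceleration of a gliding whale
#'
#' Forward model of the net along-path acceleration of a gliding body as
#' the sum of three terms: drag, tissue buoyancy and air buoyancy,
#' \deqn{a = -\tfrac12 \frac{C_D A}{m} \rho_{sw} v^2
#'  + \left(\frac{\rho_{sw}}{\rho_{tissue}(d)} - 1\right) g \sin p
#'  + \frac{V_{air}}{m} g \sin p \,
#'    \frac{\rho_{sw} - \rho_{air}(1 + 0.1 d)}{1 + 0.1 d}}
#' with pitch `p` positive when ascending, so both buoyancy terms aid an
#' ascent (positive) for tissue less dense than seawater and oppose it
#' otherwise. Air is compressed with absolute pressure (Boyle's law), which
#' both shrinks the displaced volume (denominator) and raises the air
#' density (numerator correction).
#'
#' Vectorized over the observation arguments.
#'
#' @param params a [hydroParams()] object.
#' @param d depth, metres.
#' @param pitch pitch, radians (positive = ascending).
#' @param speed swim speed, m s^-1 (>= 0).
#' @param rho_sw seawater density at `d`, kg m^-3.
#' @param constants a [physicalConstants()] object.
#' @return net along-path acceleration, m s^-2, positive along the
#'   direction of motion.
#' @export
glideAcceleration <- function(params, d, pitch, speed, rho_sw,
                              constants = physicalConstants()) {
  stopifnot(inherits(params, "hydro_params"), all(speed >= 0), all(d >= 0))
  pr <- 1 + 0.1 * d                      # absolute pressure, atm
  rho_d <- tissueDensityAtDepth(params$tissue_density, params$compressibility,
                                d, constants$atmosphere_pa)
  drag <- -0.5 * params$drag_term * rho_sw * speed^2
  tissue <- (rho_sw / rho_d - 1) * constants$g * sin(pitch)
  air <- params$air_per_mass * constants$g * sin(pitch) *
    (rho_sw - constants$rho_air * pr) / pr
  drag + tissue + air
}

#' Default prior for the combined drag term
#'
#' A normal prior truncated to positive values, centred on
#' 11e-6 m^2 kg^-1 — the value expected when drag is partly induced by
#' lift on the flippers — with a weakly informative spread.
#'
#' @param mean prior mean, m^2 kg^-1.
#' @param sd prior standard deviation, m^2 kg^-1.
#' @return list with elements `mean`, `sd`, `lower` (0) and a `density`
#'   function (truncated-normal density, zero at non-positive drag).
#' @export
dragPriorDefault <- function(mean = 11e-6, sd = 5e-6) {
  stopifnot(mean > 0, sd > 0)
  norm_const <- 1 - stats::pnorm(0, mean, sd)
  list(
    mean = mean, sd = sd, lower = 0,
    density = function(x) {
      ifelse(x > 0, stats::dnorm(x, mean, sd) / norm_const, 0)
    }
  )
}
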