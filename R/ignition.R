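# Energy-balance ignition models for conifer needle beds struck by lightning.
#
# The criterion compares the heat delivered to the bed against the heat needed
# to dry and ignite it:
#
#   phi * E_imp * h + E_lcc * h  >=  E_ig
#   E_ig  = rho pi r^2 h { c_p (T_ig - T_0) + x [ c_pl (T_s - T_0) + h_lg ] }
#   E_imp = 0.2 Ip^2 rho^-0.05 (x+1)^0.006          [J/mm of bed thickness]
#   phi   = 69564 Ip^-1.83 rho^1.12 (x+1)^0.145     [percent]
#   E_lcc = 0.0447 t^1.1787                          [J/mm, t in ms]
#
# Units: Ip in kA, rho the bed bulk density in g/cm^3, x the dry-basis
# moisture fraction, h the bed thickness in mm. Only this combination puts
# the measured ~3 kJ critical energies and a 0-100% efficiency on the same
# scale. Inside E_ig, rho converts to kg/m^3 and h to m.

#' Thermophysical constants of the ignition energy balance
#'
#' @param specific_heat_fuel Specific heat of the needles, J/(kg C).
#'   Default 2000 (the value used for larch needles).
#' @param ignition_temperature Ignition temperature of the needles, C.
#' @param ambient_temperature Ambient temperature \eqn{T_0}, C.
#' @param boiling_point Boiling point of water \eqn{T_s}, C.
#' @param specific_heat_water Specific heat of liquid water, J/(kg C).
#' @param latent_heat_water Latent heat of vaporization, J/kg.
#' @param channel_radius Radius of the lightning channel, m. Default 1 cm.
#'
#' @return An object of class `thermo_params`.
#' @export
thermo_params <- function(specific_heat_fuel = 2000,
                          ignition_temperature = 400,
                          ambient_temperature = 20,
                          boiling_point = 100,
                          specific_heat_water = 4186,
                          latent_heat_water = 2.256e6,
                          channel_radius = 0.01) {
  p <- list(specific_heat_fuel = specific_heat_fuel,
            ignition_temperature = ignition_temperature,
            ambient_temperature = ambient_temperature,
            boiling_point = boiling_point,
            specific_heat_water = specific_heat_water,
            latent_heat_water = latent_heat_water,
            channel_radius = channel_radius)
  bad <- names(p)[!vapply(p, function(v) is.numeric(v) && length(v) == 1 && is.finite(v) && v > 0, logical(1))]
  if (length(bad)) stop("thermo parameters must be positive scalars: ",
                        paste(bad, collapse = ", "), call. = FALSE)
  if (p$ignition_temperature <= p$ambient_temperature)
    stop("`ignition_temperature` must exceed `ambient_temperature`", call. = FALSE)
  if (p$boiling_point <= p$ambient_temperature)
    stop("`boiling_point` must exceed `ambient_temperature`", call. = FALSE)
  structure(p, class = "thermo_params")
}

#' Coefficients of the fitted energy and efficiency models
#'
#' Every multiplier and exponent of the impulse-energy, heating-efficiency and
#' long-continuing-current models is overridable, so re-fitted models (from
#' [fit_power_law()]) can be plugged into [predict_ignition()].
#'
#' @param impulse_coefficient,impulse_exp_peak,impulse_exp_bulk,impulse_exp_moisture
#'   Impulse-energy model `E = c * Ip^a * rho^b * (x+1)^d` (J/mm).
#' @param efficiency_coefficient,efficiency_exp_peak,efficiency_exp_bulk,efficiency_exp_moisture
#'   Heating-efficiency model `phi = c * Ip^a * rho^b * (x+1)^d` (percent).
#' @param lcc_coefficient,lcc_exponent Continuing-current model
#'   `E = c * t^a` (J/mm, t in ms).
#'
#' @return An object of class `model_coefs`.
#' @export
model_coefs <- function(impulse_coefficient = 0.2,
                        impulse_exp_peak = 2,
                        impulse_exp_bulk = -0.05,
                        impulse_exp_moisture = 0.006,
                        efficiency_coefficient = 69564,
                        efficiency_exp_peak = -1.83,
                        efficiency_exp_bulk = 1.12,
                        efficiency_exp_moisture = 0.145,
                        lcc_coefficient = 0.0447,
                        lcc_exponent = 1.1787) {
  p <- list(impulse_coefficient = impulse_coefficient,
            impulse_exp_peak = impulse_exp_peak,
            impulse_exp_bulk = impulse_exp_bulk,
            impulse_exp_moisture = impulse_exp_moisture,
            efficiency_coefficient = efficiency_coefficient,
            efficiency_exp_peak = efficiency_exp_peak,
            efficiency_exp_bulk = efficiency_exp_bulk,
            efficiency_exp_moisture = efficiency_exp_moisture,
            lcc_coefficient = lcc_coefficient,
            lcc_exponent = lcc_exponent)
  bad <- names(p)[!vapply(p, function(v) is.numeric(v) && length(v) == 1 && is.finite(v), logical(1))]
  if (length(bad)) stop("model coefficients must be finite scalars: ",
                        paste(bad, collapse = ", "), call. = FALSE)
  if (p$impulse_coefficient <= 0 || p$efficiency_coefficient <= 0 || p$lcc_coefficient <= 0)
    stop("model multipliers must be positive", call. = FALSE)
  structure(p, class = "model_coefs")
}

#' Describe one or more needle-bed configurations
#'
#' @param species Species label(s).
#' @param bulk_gcm3 Bed bulk density \eqn{\rho}, g/cm^3.
#' @param solid_gcm3 Needle material (solid) density, g/cm^3. Must exceed the
#'   bulk density so the porosity is a proper fraction.
#' @param moisture Dry-basis moisture fraction \eqn{x} (0.107 means 10.7%).
#' @param thickness_mm Bed thickness \eqn{h}, mm.
#'
#' @return A tibble with one row per bed.
#' @examples
#' fuel_bed("Larix gmelinii", 0.1592, 0.350, 0, 3)
#' @export
fuel_bed <- function(species, bulk_gcm3, solid_gcm3, moisture, thickness_mm) {
  bed <- tibble::tibble(species = as.character(species),
                        bulk_gcm3 = bulk_gcm3, solid_gcm3 = solid_gcm3,
                        moisture = moisture, thickness_mm = thickness_mm)
  validate_fuel_bed(bed)
  bed
}

validate_fuel_bed <- function(bed) {
  need <- c("bulk_gcm3", "solid_gcm3", "moisture", "thickness_mm")
  miss <- setdiff(need, names(bed))
  if (length(miss)) stop("fuel bed is missing column(s): ",
                         paste(miss, collapse = ", "), call. = FALSE)
  if (any(bed$bulk_gcm3 <= 0)) stop("`bulk_gcm3` must be positive", call. = FALSE)
  if (any(bed$bulk_gcm3 >= bed$solid_gcm3))
    stop("`bulk_gcm3` must be below `solid_gcm3` (porosity must be in (0,1))",
         call. = FALSE)
  if (any(bed$moisture < 0)) stop("`moisture` must be non-negative", call. = FALSE)
  if (any(bed$thickness_mm <= 0)) stop("`thickness_mm` must be positive", call. = FALSE)
  invisible(bed)
}

#' Void fraction of a needle bed
#'
#' Porosity is one minus the ratio of bed bulk density to needle solid
#' density.
#'
#' @param bed A [fuel_bed()] tibble (columns `bulk_gcm3`, `solid_gcm3`).
#' @return Numeric vector of porosities in (0, 1).
#' @examples
#' porosity(fuel_bed("Pinus sylvestris", 0.1592, 0.510, 0, 3))  # 0.688
#' @export
porosity <- function(bed) {
  validate_fuel_bed(bed)
  1 - bed$bulk_gcm3 / bed$solid_gcm3
}

#' Heat required to ignite a needle bed within the lightning channel
#'
#' Evaluates the energy balance
#' \eqn{E_{ig} = \rho \pi r^2 h \{ c_p (T_{ig} - T_0) + x [ c_{pl} (T_s - T_0) + h_{lg} ] \}}:
#' the sensible heat to raise the channel's fuel mass to its ignition
#' temperature plus, per unit dry mass, the heat to warm and vaporize its
#' moisture. Bulk density is converted to kg/m^3 and thickness to m
#' internally.
#'
#' @inheritParams porosity
#' @param thermo A [thermo_params()] object.
#' @return Numeric vector, J.
#' @export
ignition_energy <- function(bed, thermo = thermo_params()) {
  validate_fuel_bed(bed)
  stopifnot(inherits(thermo, "thermo_params"))
  rho <- bed$bulk_gcm3 * 1000          # g/cm^3 -> kg/m^3
  h <- bed$thickness_mm / 1000         # mm -> m
  mass <- rho * pi * thermo$channel_radius^2 * h
  dT <- thermo$ignition_temperature - thermo$ambient_temperature
  wet <- thermo$specific_heat_water * (thermo$boiling_point - thermo$ambient_temperature) +
    thermo$latent_heat_water
  mass * (thermo$specific_heat_fuel * dT + bed$moisture * wet)
}

#' Impulse-current energy deposited per unit bed thickness
#'
#' The fitted power law `E = 0.2 Ip^2 rho^-0.05 (x+1)^0.006` in J/mm, with
#' `Ip` in kA, `rho` in g/cm^3 and `x` a dry-basis moisture fraction.
#'
#' @param peak_ka Peak impulse current, kA (positive).
#' @param bulk_gcm3 Bed bulk density, g/cm^3 (positive).
#' @param moisture Dry-basis moisture fraction (>= 0).
#' @param coefs A [model_coefs()] object.
#' @return Numeric vector, J/mm.
#' @examples
#' impulse_energy(69.83, 0.1062, 0.107)  # ~1091.5 J/mm
#' @export
impulse_energy <- function(peak_ka, bulk_gcm3, moisture, coefs = model_coefs()) {
  stopifnot(inherits(coefs, "model_coefs"))
  if (any(peak_ka <= 0)) stop("`peak_ka` must be positive", call. = FALSE)
  if (any(bulk_gcm3 <= 0)) stop("`bulk_gcm3` must be positive", call. = FALSE)
  if (any(moisture < 0)) stop("`moisture` must be non-negative", call. = FALSE)
  coefs$impulse_coefficient * peak_ka^coefs$impulse_exp_peak *
    bulk_gcm3^coefs$impulse_exp_bulk *
    (moisture + 1)^coefs$impulse_exp_moisture
}

#' Heating efficiency of the impulse current
#'
#' The fitted power law `phi = 69564 Ip^-1.83 rho^1.12 (x+1)^0.145`,
#' interpreted as a percent: the share of the total discharge energy
#' \eqn{\int U I dt} that heats the fuel rather than being lost to mechanical
#' work and air heating. The law can exceed 100% when extrapolated to peak
#' currents below the fitted range; such values are clamped to 100 with a
#' warning.
#'
#' @inheritParams impulse_energy
#' @return Numeric vector, percent in (0, 100].
#' @examples
#' heating_efficiency(33.67, 0.1592, 0)  # ~14.3 %
#' @export
heating_efficiency <- function(peak_ka, bulk_gcm3, moisture, coefs = model_coefs()) {
  stopifnot(inherits(coefs, "model_coefs"))
  if (any(peak_ka <= 0)) stop("`peak_ka` must be positive", call. = FALSE)
  if (any(bulk_gcm3 <= 0)) stop("`bulk_gcm3` must be positive", call. = FALSE)
  if (any(moisture < 0)) stop("`moisture` must be non-negative", call. = FALSE)
  phi <- coefs$efficiency_coefficient * peak_ka^coefs$efficiency_exp_peak *
    bulk_gcm3^coefs$efficiency_exp_bulk *
    (moisture + 1)^coefs$efficiency_exp_moisture
  over <- phi > 100
  if (any(over)) {
    warning(sum(over), " heating-efficiency value(s) above 100% clamped; ",
            "inputs lie outside the fitted range", call. = FALSE)
    phi[over] <- 100
  }
  phi
}

#' Long-continuing-current energy per unit bed thickness
#'
#' The channel model `1 V/mm x 44.7 t^0.1787 A` sustained for `t` ms gives
#' `E = 0.0447 t^1.1787` J/mm. A duration of zero means no continuing current
#' and returns zero energy.
#'
#' @param lcc_ms Continuing-current duration, ms (>= 0).
#' @param coefs A [model_coefs()] object.
#' @return Numeric vector, J/mm.
#' @examples
#' lcc_energy(1)  # 0.0447 J/mm
#' @export
lcc_energy <- function(lcc_ms, coefs = model_coefs()) {
  stopifnot(inherits(coefs, "model_coefs"))
  if (any(lcc_ms < 0)) stop("`lcc_ms` must be non-negative", call. = FALSE)
  ifelse(lcc_ms == 0, 0, coefs$lcc_coefficient * lcc_ms^coefs$lcc_exponent)
}

#' Full-waveform ignition criterion
#'
#' For each row, compares the heat delivered to the bed,
#' \eqn{(\phi/100) E_{imp} h + E_{lcc} h}, against the required ignition
#' energy from [ignition_energy()]. Ties count as ignition.
#'
#' @param data A data frame with columns `peak_ka`, `bulk_gcm3`, `moisture`
#'   and `thickness_mm`; an optional `lcc_ms` column (continuing-current
#'   duration, ms) defaults to 0. A `peak_ka` of 0 is allowed here and
#'   contributes no impulse heat.
#' @param thermo A [thermo_params()] object.
#' @param coefs A [model_coefs()] object.
#'
#' @return The input tibble with added columns `phi_pct`, `delivered_j`,
#'   `required_j`, `margin_ratio` (delivered/required) and `ignites`.
#' @examples
#' tibble::tibble(peak_ka = 33.67, bulk_gcm3 = 0.1592,
#'                moisture = 0, thickness_mm = 3) |>
#'   predict_ignition()
#' @export
predict_ignition <- function(data, thermo = thermo_params(), coefs = model_coefs()) {
  stopifnot(is.data.frame(data))
  need <- c("peak_ka", "bulk_gcm3", "moisture", "thickness_mm")
  miss <- setdiff(need, names(data))
  if (length(miss)) stop("`data` is missing column(s): ",
                         paste(miss, collapse = ", "), call. = FALSE)
  if (any(data$peak_ka < 0)) stop("`peak_ka` must be non-negative", call. = FALSE)
  lcc_ms <- if ("lcc_ms" %in% names(data)) data$lcc_ms else 0

  pos <- data$peak_ka > 0
  phi <- e_imp <- numeric(nrow(data))
  if (any(pos)) {
    phi[pos] <- heating_efficiency(data$peak_ka[pos], data$bulk_gcm3[pos],
                                   data$moisture[pos], coefs)
    e_imp[pos] <- impulse_energy(data$peak_ka[pos], data$bulk_gcm3[pos],
                                 data$moisture[pos], coefs)
  }
  bed <- tibble::tibble(species = NA_character_,
                        bulk_gcm3 = data$bulk_gcm3,
                        solid_gcm3 = Inf,   # porosity bound not needed here
                        moisture = data$moisture,
                        thickness_mm = data$thickness_mm)
  required <- ignition_energy(bed, thermo)
  delivered <- (phi / 100) * e_imp * data$thickness_mm +
    lcc_energy(rep_len(lcc_ms, nrow(data)), coefs) * data$thickness_mm

  out <- tibble::as_tibble(data)
  out$phi_pct <- phi
  out$delivered_j <- delivered
  out$required_j <- required
  out$margin_ratio <- delivered / required
  out$ignites <- delivered >= required
  out
}
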