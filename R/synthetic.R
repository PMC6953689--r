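# Synthetic experiment-record generation. Stands in for the physical
# discharge experiments: factorial energy measurements with multiplicative
# lognormal noise around the impulse-energy power law, Bernoulli ignition
# outcomes around the energy-balance criterion, and verbatim fixtures of the
# published summary tables.

#' Noise model for synthetic experiment records
#'
#' @param log_sd_energy Lognormal sigma on measured energies. The default 0.1
#'   gives a ~10% coefficient of variation, matching the relative SDs of the
#'   published replicate tables.
#' @param ignition_logistic_slope Slope of the ignition logistic on the log
#'   margin ratio: `P(ignite) = plogis(slope * ln(delivered/required))`, so a
#'   margin of 1 ignites with probability one half. `Inf` gives the
#'   deterministic criterion. The default 100 implies ~10% latent scatter in
#'   the critical peak current, again matching the published replicate SDs.
#' @param rng_seed Integer seed; generators are pure functions of their
#'   inputs and this seed, and leave the global RNG state untouched.
#'
#' @return An object of class `noise_model`.
#' @export
noise_model <- function(log_sd_energy = 0.1, ignition_logistic_slope = 100,
                        rng_seed = NULL) {
  if (log_sd_energy < 0) stop("`log_sd_energy` must be non-negative", call. = FALSE)
  if (ignition_logistic_slope <= 0) stop("`ignition_logistic_slope` must be positive",
                                         call. = FALSE)
  structure(list(log_sd_energy = log_sd_energy,
                 ignition_logistic_slope = ignition_logistic_slope,
                 rng_seed = rng_seed),
            class = "noise_model")
}

with_seed <- function(seed, code) {
  if (is.null(seed)) return(force(code))
  old <- get0(".Random.seed", envir = globalenv())
  on.exit(restore_rng(old))
  set.seed(seed)
  code
}

#' Generate factorial impulse-energy records
#'
#' For each grid row, draws a measured total discharge energy around the
#' impulse-energy power law: `energy_j = E(Ip, rho, x) * h * exp(N(0,
#' sigma))`, and attaches the action integral of the synthesized impulse
#' waveform at that peak current (the action integral scales exactly as
#' `Ip^2`, so one unit-peak synthesis is reused across rows).
#'
#' @param grid Design table with columns `peak_ka`, `bulk_gcm3`, `moisture`
#'   (e.g. [study_design_grid()]).
#' @param noise A [noise_model()]; `rng_seed` makes the table reproducible.
#' @param thickness_mm Bed thickness, mm.
#' @param species Species label for the records.
#' @param waveform Waveform label, `"front/half"` in microseconds.
#' @param polarity Current direction label.
#' @param coefs A [model_coefs()] object.
#'
#' @return An experiment-record tibble with columns `record_id`, `species`,
#'   `peak_ka`, `bulk_gcm3`, `moisture`, `thickness_mm`, `waveform`,
#'   `polarity`, `action_integral_a2s`, `energy_j`, `ignited` (NA until
#'   [generate_ignition_outcomes()]) and `is_critical`.
#' @export
generate_factorial_energies <- function(grid, noise = noise_model(),
                                        thickness_mm = 3,
                                        species = "Larix gmelinii",
                                        waveform = "8/20",
                                        polarity = "plate_to_electrode",
                                        coefs = model_coefs()) {
  stopifnot(is.data.frame(grid), inherits(noise, "noise_model"))
  need <- c("peak_ka", "bulk_gcm3", "moisture")
  miss <- setdiff(need, names(grid))
  if (length(miss)) stop("`grid` is missing column(s): ",
                         paste(miss, collapse = ", "), call. = FALSE)
  n <- nrow(grid)
  if (n == 0) stop("`grid` has no rows", call. = FALSE)

  shape <- as.numeric(strsplit(waveform, "/")[[1]])
  if (length(shape) != 2 || any(!is.finite(shape)))
    stop("`waveform` must look like \"8/20\" (front/half, us)", call. = FALSE)
  unit <- synthesize_impulse(impulse_spec(shape[1], shape[2], 1, polarity))
  unit_action <- extract_metrics(unit)$action_integral_a2s

  e_mm <- impulse_energy(grid$peak_ka, grid$bulk_gcm3, grid$moisture, coefs)
  noise_fac <- with_seed(noise$rng_seed,
                         exp(stats::rnorm(n, 0, noise$log_sd_energy)))
  tibble::tibble(
    record_id = sprintf("rec%04d", seq_len(n)),
    species = species,
    peak_ka = grid$peak_ka,
    bulk_gcm3 = grid$bulk_gcm3,
    moisture = grid$moisture,
    thickness_mm = thickness_mm,
    waveform = waveform,
    polarity = polarity,
    action_integral_a2s = unit_action * grid$peak_ka^2,
    energy_j = e_mm * thickness_mm * noise_fac,
    ignited = NA,
    is_critical = FALSE
  )
}

#' Draw Bernoulli ignition outcomes around the energy-balance criterion
#'
#' Each record ignites with probability
#' `plogis(slope * ln(margin_ratio))`, where the margin ratio
#' (delivered/required heat) comes from [predict_ignition()] on the record's
#' inputs. A margin of exactly 1 ignites with probability 0.5; an infinite
#' slope reproduces the deterministic criterion.
#'
#' @param records An experiment-record table (see
#'   [generate_factorial_energies()]); an optional `lcc_ms` column defaults
#'   to no continuing current.
#' @param thermo A [thermo_params()] object.
#' @param noise A [noise_model()].
#' @param coefs A [model_coefs()] object.
#' @return `records` with `margin_ratio` and filled `ignited` columns.
#' @export
generate_ignition_outcomes <- function(records, thermo = thermo_params(),
                                       noise = noise_model(),
                                       coefs = model_coefs()) {
  stopifnot(is.data.frame(records), inherits(noise, "noise_model"))
  pred <- predict_ignition(records[setdiff(names(records),
                                           c("phi_pct", "delivered_j", "required_j",
                                             "margin_ratio", "ignites"))],
                           thermo, coefs)
  s <- noise$ignition_logistic_slope
  p <- if (is.infinite(s)) as.numeric(pred$margin_ratio >= 1) else
    stats::plogis(s * log(pred$margin_ratio))
  p[pred$margin_ratio == 0] <- 0
  out <- tibble::as_tibble(records)
  out$margin_ratio <- pred$margin_ratio
  out$ignited <- with_seed(noise$rng_seed,
                           stats::runif(nrow(out)) < p)
  out
}

#' Published summary tables as packaged fixtures
#'
#' Verbatim transcriptions of the study's printed tables, stored as plain CSV
#' under `inst/extdata` so they are auditable: needle properties (diameter,
#' length, solid density, mean and SD per species), critical-ignition results
#' (peak current, action integral, energy, breakdown voltage per species) and
#' the waveform/polarity comparison (8/20 vs 10/350 us).
#'
#' @param which One of `"needle_properties"`, `"critical_ignition"`,
#'   `"waveform_comparison"`.
#' @return A tibble.
#' @examples
#' make_table_fixture("needle_properties")
#' @export
make_table_fixture <- function(which = c("needle_properties", "critical_ignition",
                                         "waveform_comparison")) {
  which <- match.arg(which)
  path <- system.file("extdata", paste0(which, ".csv"), package = "impulsefire",
                      mustWork = TRUE)
  readr::read_csv(path, show_col_types = FALSE)
}

#' Build a critical-ignition record pair
#'
#' A critical record is only meaningful next to its paired just-below-threshold
#' non-ignition trial; this helper builds both rows, with the sub-threshold
#' trial one step ratio below the critical level (its margin ratio is strictly
#' smaller since delivered heat increases with peak current).
#'
#' @param species Species label.
#' @param peak_ka Critical peak current, kA.
#' @param bulk_gcm3,moisture,thickness_mm Bed descriptors.
#' @param energy_j Measured total discharge energy at the critical level, J.
#' @param step_ratio Level ratio between the critical and sub-threshold trial.
#' @return A two-row experiment-record tibble; the critical row has
#'   `is_critical = TRUE` and `ignited = TRUE`.
#' @export
critical_pair <- function(species, peak_ka, bulk_gcm3, moisture, thickness_mm,
                          energy_j, step_ratio = 1.05) {
  stopifnot(peak_ka > 0, energy_j > 0, step_ratio > 1)
  below <- peak_ka / step_ratio
  tibble::tibble(
    record_id = c("crit-below", "crit"),
    species = species,
    peak_ka = c(below, peak_ka),
    bulk_gcm3 = bulk_gcm3, moisture = moisture, thickness_mm = thickness_mm,
    waveform = "8/20", polarity = "plate_to_electrode",
    action_integral_a2s = NA_real_,
    energy_j = c(energy_j / step_ratio^2, energy_j),
    ignited = c(FALSE, TRUE),
    is_critical = c(FALSE, TRUE)
  )
}
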