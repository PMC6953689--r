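# Synthetic experiment-record generation.

test_that("noise-free records reproduce the energy model and refit exactly", {
  grid <- study_design_grid()
  rec <- generate_factorial_energies(grid, noise_model(log_sd_energy = 0))
  expect_equal(rec$energy_j,
               impulse_energy(grid$peak_ka, grid$bulk_gcm3, grid$moisture) * 3)
  f <- fit_power_law(rec, "energy_j", c("peak_ka", "bulk_gcm3", "moisture"),
                     offsets = c(moisture = 1))
  expect_equal(f$coefficient, 0.2 * 3, tolerance = 1e-6)  # per-bed total, h = 3 mm
  expect_equal(unname(f$exponents), c(2, -0.05, 0.006), tolerance = 1e-6)
})

test_that("record generation is a pure function of grid and seed", {
  grid <- study_design_grid()
  noise <- noise_model(rng_seed = 7)
  r1 <- generate_factorial_energies(grid, noise)
  r2 <- generate_factorial_energies(grid, noise)
  expect_identical(r1, r2)
  # and leaves the ambient RNG stream untouched
  set.seed(123)
  before <- runif(3)
  set.seed(123)
  invisible(generate_factorial_energies(grid, noise))
  expect_identical(runif(3), before)
})

test_that("energy noise is multiplicative lognormal with the stated mean", {
  one <- study_design_grid()[rep(63, 1000), ]
  rec <- generate_factorial_energies(one, noise_model(log_sd_energy = 0.1,
                                                      rng_seed = 21))
  model <- impulse_energy(one$peak_ka[1], one$bulk_gcm3[1], one$moisture[1]) * 3
  expect_lt(abs(mean(rec$energy_j) - model * exp(0.1^2 / 2)) / model, 0.02)
})

test_that("action integrals scale as the squared peak of the synthesized shape", {
  grid <- study_design_grid()[c(1, 30, 125), ]
  rec <- generate_factorial_energies(grid, noise_model(log_sd_energy = 0))
  unit <- extract_metrics(synthesize_impulse(impulse_spec(8, 20, 1)))
  expect_equal(rec$action_integral_a2s,
               unit$action_integral_a2s * grid$peak_ka^2, tolerance = 1e-9)
})

test_that("an infinite logistic slope reproduces the deterministic verdict", {
  grid <- study_design_grid()
  rec <- generate_factorial_energies(grid, noise_model(log_sd_energy = 0))
  out <- generate_ignition_outcomes(rec, noise = noise_model(
    ignition_logistic_slope = Inf, rng_seed = 3))
  det <- predict_ignition(grid |> dplyr::mutate(thickness_mm = 3))
  expect_identical(out$ignited, det$ignites)
})

test_that("a unit margin ratio ignites about half the time", {
  # solve for the peak current whose delivered heat equals the requirement
  margin_at <- function(ip) predict_ignition(tibble::tibble(
    peak_ka = ip, bulk_gcm3 = 0.1592, moisture = 0, thickness_mm = 3))$margin_ratio
  ip_star <- uniroot(function(ip) margin_at(ip) - 1, c(20, 120), tol = 1e-10)$root
  rec <- generate_factorial_energies(
    tibble::tibble(peak_ka = ip_star, bulk_gcm3 = 0.1592, moisture = 0)[rep(1, 1000), ],
    noise_model(log_sd_energy = 0))
  out <- generate_ignition_outcomes(rec, noise = noise_model(rng_seed = 17))
  expect_equal(out$margin_ratio[1], 1, tolerance = 1e-9)
  expect_gt(mean(out$ignited), 0.45)
  expect_lt(mean(out$ignited), 0.55)
})

test_that("ignition frequency rises with the margin ratio", {
  grid <- study_design_grid()
  rec <- generate_factorial_energies(grid, noise_model(log_sd_energy = 0))
  reps <- rec[rep(seq_len(nrow(rec)), 50), ]
  out <- generate_ignition_outcomes(reps, noise = noise_model(
    ignition_logistic_slope = 5, rng_seed = 9))
  freq <- out |>
    dplyr::group_by(.data$record_id) |>
    dplyr::summarise(margin = .data$margin_ratio[1],
                     rate = mean(.data$ignited)) |>
    dplyr::arrange(.data$margin)
  # study-grid margins span roughly 0.17 to 1.1
  lo <- dplyr::filter(freq, .data$margin < 0.3)
  hi <- dplyr::filter(freq, .data$margin > 0.9)
  expect_gt(nrow(lo), 0)
  expect_gt(nrow(hi), 0)
  expect_gt(mean(hi$rate), mean(lo$rate))
  expect_gt(stats::cor(log(freq$margin), freq$rate, method = "spearman"), 0.8)
})

test_that("published table fixtures carry the printed values", {
  needles <- make_table_fixture("needle_properties")
  lg <- needles[needles$species == "Larix gmelinii", ]
  expect_equal(lg$diameter_mm_mean, 0.42)
  expect_equal(lg$density_gcm3_mean, 0.350)
  crit <- make_table_fixture("critical_ignition")
  lgc <- crit[crit$species == "Larix gmelinii", ]
  expect_equal(lgc$peak_ka_mean, 33.67)
  expect_equal(lgc$energy_j_mean, 803)
  expect_equal(lgc$breakdown_kv_mean, 7.52)
  wf <- make_table_fixture("waveform_comparison")
  expect_equal(wf$peak_ka_mean[wf$waveform == "10/350"], 11.05)
  expect_error(make_table_fixture("no_such_table"))
})

test_that("critical pairs keep the sub-threshold record strictly below", {
  pair <- critical_pair("Larix gmelinii", 33.67, 0.1592, 0, 3, energy_j = 803)
  expect_identical(pair$is_critical, c(FALSE, TRUE))
  m <- predict_ignition(pair)$margin_ratio
  expect_lt(m[1], m[2])
})
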