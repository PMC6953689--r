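# Shared fixtures and independent oracles for the test suite.

# Stochastic ignition oracle: success probability logistic in log level
# around `center`. Uses the ambient RNG stream (protocols seed it).
logistic_oracle <- function(center, slope) {
  function(level) stats::runif(1) < stats::plogis(slope * log(level / center))
}

# The ten printed bed porosities: five species at the critical-ignition bulk
# density (0.1592 g/cm3) and five at the breakdown bulk density (0.0955).
# Species order follows the published listing for each experiment.
POROSITY_CASES <- tibble::tibble(
  species = c("Pinus sylvestris", "Pinus massoniana", "Pinus pumila",
              "Picea jezoensis", "Larix gmelinii",
              "Pinus sylvestris", "Picea jezoensis", "Pinus massoniana",
              "Pinus pumila", "Larix gmelinii"),
  bulk_gcm3 = rep(c(0.1592, 0.0955), each = 5),
  printed_pct = c(68.8, 67.0, 49.5, 54.3, 54.5,
                  81.3, 72.6, 80.2, 69.7, 72.7)
)

solid_density_of <- function(species) {
  tab <- make_table_fixture("needle_properties")
  tab$density_gcm3_mean[match(species, tab$species)]
}

# Hand-evaluated energy-balance numbers (bed: L. gmelinii critical case,
# bulk 0.1592 g/cm3, dry, 3 mm; T0 = 20 C, r = 1 cm, cp = 2000, Tig = 400):
# E_ig = 159.2 * pi * 1e-4 * 0.003 * 2000 * 380
EIG_LGMELINII_DRY <- 114.032274
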