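# impulsefire

Can the impulse current of a lightning strike — tens of kiloamps lasting tens
of microseconds — ignite a conifer needle bed by itself, before any long
continuing current arrives? `impulsefire` is an R package for fire-ecology
and lightning-fire researchers that implements the full analysis chain behind
that question: standard surge-waveform synthesis, an energy-balance ignition
criterion for needle fuel beds, power-law model fitting, and simulation of
the staircase protocols used at an impulse-current generator bench.

## The model

A bed of bulk density ρ (g/cm³), thickness h (mm) and dry-basis moisture x
ignites when the heat delivered inside the lightning channel's footprint
(radius r) meets the requirement:

    φ/100 · E_imp · h + E_lcc · h  ≥  E_ig
    E_ig  = ρ π r² h { c_p (T_ig − T_0) + x [ c_pl (T_s − T_0) + h_lg ] }

with fitted power laws for the impulse energy per unit thickness and the
heating efficiency (the percentage of the discharge energy ∫UIdt that heats
fuel rather than air or mechanical work), and a channel model for the
long-continuing-current (LCC) energy:

    E_imp = 0.2 · Ip² · ρ^−0.05 · (x+1)^0.006      [J/mm],  Ip in kA
    φ     = 69564 · Ip^−1.83 · ρ^1.12 · (x+1)^0.145  [%]
    E_lcc = 0.0447 · t^1.1787                       [J/mm], t in ms

Waveforms are named front/half-wave (e.g. 8/20 µs): front time is 1.25× the
10–90 % rise interval, half-wave time runs from the virtual origin to the
50 % decay point. `synthesize_impulse()` calibrates a double exponential or a
Heidler function to the requested shape; `extract_metrics()` recovers Ip,
t_f, t_h, the action integral ∫I²dt and the energy ∫UIdt from any sampled
trace.

## Worked example

Synthesize the standard 8/20 µs shape at the measured critical current of a
*Larix gmelinii* bed, then ask the energy balance whether dry 3 mm beds
ignite at two peak currents:

```r
library(impulsefire)

extract_metrics(synthesize_impulse(impulse_spec(8, 20, peak_ka = 69.83)))
#> # A tibble: 1 × 4
#>   peak_ka front_us half_us action_integral_a2s
#>     <dbl>    <dbl>   <dbl>               <dbl>
#> 1    69.8     8.00    20.0              54660.

predict_ignition(tibble::tibble(
  peak_ka = c(33.67, 69.83), bulk_gcm3 = 0.1592,
  moisture = 0, thickness_mm = 3))
#> # A tibble: 2 × 6  (verdict columns)
#>   peak_ka phi_pct delivered_j required_j margin_ratio ignites
#> 1    33.7   14.2         106.       114.        0.932 FALSE
#> 2    69.8    3.75        120.       114.        1.05  TRUE
```

The verdict columns read: at 33.67 kA the bed receives 106 J against a 114 J
requirement (margin 0.93 — right at the observed ignition boundary, where
the balance closes within ~7 %); at 69.83 kA the efficiency has fallen to
3.8 % but the delivered heat still edges past the requirement. Re-deriving
the energy power law from a noisy synthetic factorial campaign:

```r
rec <- generate_factorial_energies(study_design_grid(),
                                   noise_model(log_sd_energy = 0.1,
                                               rng_seed = 42))
fit_power_law(rec, "energy_j", c("peak_ka", "bulk_gcm3", "moisture"),
              offsets = c(moisture = 1))
#> <power_law_fit>  energy_j = 0.6074 * peak_ka^1.986 * bulk_gcm3^-0.07129 * moisture^-0.01843
#>   n = 125, adj R^2 = 0.9913, residual log-SD = 0.1036
```

The recovered coefficient is the per-mm 0.2 times the 3 mm bed thickness,
and the exponents land on (2, −0.05, 0.006) up to the injected 10 % noise.
A thin CLI (`inst/cli/impulsefire`) exposes `simulate-waveform`,
`generate-data`, `fit`, `predict` and `protocol` subcommands over the same
functions.

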