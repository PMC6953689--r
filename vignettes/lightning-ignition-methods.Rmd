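---
title: "Modelling impulse-current ignition of conifer needle beds"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modelling impulse-current ignition of conifer needle beds}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(impulsefire)
```

## The problem

Most work on lightning-caused wildfire ignition has focused on the long
continuing current (LCC) — the 200–800 A tail that can persist for up to a
second after a stroke. The impulse component that precedes it (tens of kA for
tens of microseconds) carries a large share of the flash energy, and
laboratory surge generators show it can ignite dead conifer needle beds on
its own. `impulsefire` packages the analysis chain for that question: it
synthesizes standard surge-current waveforms, evaluates an energy-balance
ignition criterion for needle beds, re-derives the fitted power-law models
from (synthetic) experiment tables, and simulates the staircase measurement
protocols used at the generator bench.

## The energy balance

A bed ignites when the heat delivered into the lightning channel's footprint
reaches the heat needed to warm (and, if moist, dry) the fuel there:

$$\phi\, E_{imp}\, h + E_{lcc}\, h \;\ge\; E_{ig},$$

$$E_{ig} = \rho \pi r^2 h \left\{ c_p (T_{ig} - T_0)
  + x \left[ c_{pl} (T_s - T_0) + h_{lg} \right] \right\}.$$

Here $\rho$ is bed bulk density, $h$ bed thickness, $r$ the channel radius,
$x$ the dry-basis moisture fraction, and the braces hold the per-unit-mass
heat requirement (sensible heat to the ignition temperature $T_{ig}$, plus
warming and vaporizing the moisture). The typeset source equation is
ambiguous about whether the moisture bracket multiplies the channel fuel
mass; we place it inside the mass factor because the moisture term alone has
units of J/kg, so only that reading is dimensionally consistent
(`ignition_energy()`).

Two fitted power laws supply the delivered side. The impulse energy per unit
bed thickness and the heating efficiency (the percentage of total discharge
energy $\int U I\,dt$ that heats fuel rather than doing mechanical work or
heating air) are

$$E_{imp} = 0.2\, I_p^{2}\, \rho^{-0.05} (x+1)^{0.006} \;\mathrm{J/mm},
\qquad
\phi = 69564\, I_p^{-1.83}\, \rho^{1.12} (x+1)^{0.145} \;\%,$$

with $I_p$ in kA and $\rho$ in g/cm³. We adopted these units after checking
that only this combination reproduces the measured critical discharge
energies (~3 kJ for a 3 mm bed near 70 kA) while keeping $\phi$ inside a
physical 0–100 % range; treating $x$ as a percent would make $(x+1)$
meaningless at 120 % moisture. $\phi$ can exceed 100 % when extrapolated
below the fitted current range, so `heating_efficiency()` clamps at 100 with
a warning rather than failing. The continuing-current energy uses the
channel model $1\,\mathrm{V/mm} \times 44.7\, t^{0.1787}\,\mathrm{A}$ over
$t$ ms, i.e. $E_{lcc} = 0.0447\, t^{1.1787}$ J/mm, exactly equal to its
unit-converted product form.

Unprinted thermophysical constants default to standard values: $T_0 = 20$ °C,
$T_s = 100$ °C, $c_{pl} = 4186$ J/(kg·°C), $h_{lg} = 2.256 \times 10^6$ J/kg,
with $c_p = 2000$ J/(kg·°C), $T_{ig} = 400$ °C and $r = 1$ cm as used for
larch needle beds. All are configurable through `thermo_params()`, and every
power-law coefficient through `model_coefs()`, so re-fitted models plug
straight into `predict_ignition()`. Ties (delivered exactly equal to
required) count as ignition.

```{r}
predict_ignition(tibble::tibble(
  peak_ka = 33.67, bulk_gcm3 = 0.1592, moisture = 0, thickness_mm = 3))[
    , c("phi_pct", "delivered_j", "required_j", "margin_ratio", "ignites")]
```

At the measured critical current for *Larix gmelinii* beds the balance
closes to within about 7 % — the kind of internal consistency the model was
built to have.

## Waveform synthesis

Surge shapes are named front/half-wave: the front time $t_f$ is the virtual
rise time ($1.25\times$ the 10–90 % rise interval — the convention for
current impulses; the 30–90 % alternative exists but is not used here, which
we flag since generator reports rarely say which they apply), and the
half-wave time $t_h$ runs from the virtual origin to the 50 % point on the
tail.

The classic analytic idealization is the double exponential
$i(t) = k I_p (e^{-\alpha t} - e^{-\beta t})$. Calibrating it numerically
(the ratio $t_h/t_f$ is monotone in $\beta/\alpha$, so one root-find fixes
the shape and a time-scale fixes $t_f$) shows a hard floor: as
$\beta \to \alpha$ the ratio tends to about 3.905 under the conventions
above, so the double exponential cannot produce the 8/20 µs shape
(ratio 2.5) at all. This is a known limitation of the form, and it is why
`synthesize_impulse()` carries a second family: the Heidler function
$i(t) \propto \frac{(t/\tau_1)^{10}}{1 + (t/\tau_1)^{10}} e^{-t/\tau_2}$,
the standard lightning return-stroke model, which reaches ratios down to
about 1.9. With `model = "auto"` the double exponential is used where it is
realizable (ratio ≥ 4, e.g. 10/350 µs) and the Heidler function otherwise;
explicitly requesting the double exponential for an unreachable shape raises
an "unrealizable waveform shape" error. Circuit-level effects of real
generators (undershoot, load-dependent distortion) are not modelled.

Calibration solves the dimensionless shape parameter by `uniroot` on the
timing ratio (tolerance 1e-12, metrics of the continuous shape measured by
root-finding on interpolated 10/90/50 % crossings), then scales time and
amplitude; the requested peak is exact in the continuous form and the
timings land well inside the 1 % contract after sampling. The default grid
is 0.01 µs steps over ten half-wave times, which keeps the trapezoidal
action integral $\int I^2 dt$ converged to well under 0.1 %. A voltage
channel $u(t) = R_{\mathrm{eff}}\, i(t)$ can be attached so that
$\int U I\,dt$ fixtures exist; real dividers see a non-resistive channel,
so this is a deliberate simplification.

```{r}
extract_metrics(synthesize_impulse(impulse_spec(8, 20, peak_ka = 50)))
```

## Protocol simulation

The bench protocols are ascend-only staircases. `critical_current_search()`
raises the level geometrically (default step ratio 1.05 — the source never
states increments; geometric steps keep relative resolution constant across
20–120 kA) until an oracle reports ignition, once per replicate;
`breakdown_voltage_protocol()` accepts a level only when five trials out of
five succeed, six replicates by convention. Replicates draw sub-seeds
sequentially from the configured seed, so extending a run never perturbs
earlier replicates, and censored replicates (no success by `max_level`) are
reported rather than dropped. Replicates restart from `start_level`; whether
the laboratory refined near threshold instead is unknown, and the ascending
restart is the conservative reading of the written protocol.

## Synthetic data

`generate_factorial_energies()` emulates the 5×5×5 factorial campaign
(`study_design_grid()`: five peak currents, five bulk densities, five
moistures, 3 mm beds) with multiplicative lognormal noise on energies,
$\sigma_{\log} = 0.1$ by default so the coefficient of variation matches the
~10 % relative SDs of the published replicate tables.
`generate_ignition_outcomes()` draws Bernoulli outcomes with
$P = \mathrm{logistic}(s \ln(\text{margin ratio}))$; the default slope
$s = 100$ implies latent threshold scatter of about 10 % in peak current
(the delivered heat scales as $I_p^{2-1.83}$), consistent with the same
tables. Both are pure functions of their inputs and seed.

What the generator does *not* emulate: replicate-level correlation between
the action integral and measured energy beyond what the waveform model
implies, bed-packing heterogeneity, species differences other than through
the bed descriptors, and any mechanical (shock-wave) damage pathway. The
true replicate scatter model of the experiments is unknown; lognormal is an
assumption. Passing tests therefore demonstrate the internal consistency of
the analysis chain on data that *obey* the fitted models, not the models'
validity on new laboratory data.

## Numerical choices and problem sizes

Log-linear fits use natural logarithms (the base only moves the intercept
bookkeeping) and plain OLS — no heteroscedasticity weighting, since none is
described for the originals; whether the original efficiency fit used all
125 groups or only critical subsets is ambiguous, so `fit_power_law()` fits
whatever records it is given. Offsets implement shifted predictors such as
$(x+1)$, keeping zero moisture admissible. The test suite exercises the
stochastic properties at desk scale: 100 seeded staircase searches for
center recovery, 200 seeded noisy refits for exponent recovery, and
1000-draw Monte Carlo checks of the lognormal-mean and logistic-symmetry
identities — sizes chosen so the full suite runs in seconds while leaving
binomial sampling error far below the asserted margins.

Known limitations: the energy and efficiency laws are empirical fits for
*L. gmelinii* needle beds under one waveform and polarity, and extrapolation
outside 20–100 kA or the tested density/moisture ranges is exactly that; the
taxonomy windows in `classify_waveform_part()` complete partially specified
standard ranges with package conventions (documented there); and breakdown
physics is represented only through the caller-supplied oracle, never
modelled.
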