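# mosstherm

Photosynthetic temperature responses and summer carbon balance of polar
mosses, from raw measurements to scenario estimates.

Antarctic moss canopies spend most of the summer below the temperatures at
which their photosynthesis peaks, punctuated by brief midday radiative
warming. Whether a turf gains or loses carbon then hinges on three
quantities this package computes and combines:

1. **Microclimate** — the frequency of time, `Time(%) = 100·t/T`, that the
   canopy surface spends in each 2 °C temperature bin, from logger traces.
2. **Physiology** — pulse-modulated fluorescence parameters
   (`φPSII = (Fm′−Fs)/Fm′`, `NPQ = (Fm−Fm′)/Fm′`, `Fv/Fm`), electron
   transport `ETR = φPSII·PPFD·αβ`, light-curve fits (rational and
   waiting-in-line models → AQE, ETRmax), cubic temperature responses with
   optimum extraction (`dy/dT = 0`) and `Q10 = (g2/g1)^(10/(T2−T1))`, and
   variable-J mesophyll conductance adapted for astomatous bryophytes
   (ambient Ca replacing intercellular Ci):

   ```
   gm = Asat / ( Ca − Γ*·(ETR + 8(Asat+RL)) / (ETR − 4(Asat+RL)) ),
   Γ* = 0.5·O/S_C/O,   lm = (A/Cc)/(gm + A/Cc),   lb = 1 − lm
   ```

3. **Carbon balance** — each temperature bin contributes
   `Asat,T = Asat·f`; below a 4 °C threshold assimilation is a negative
   scenario fraction (50/33.3/25/5 %) of dark respiration at 5 °C; then
   `%C fixed = Σ(+) / (Σ(+) + |Σ(−)|) · 100`.

A synthetic-data module generates every input with recorded ground truth
(temperature traces with moisture-buffered diurnal cycles and radiative
spikes, light curves, internally consistent variable-J gas exchange,
cubic thermal series), so the entire chain is testable offline. It is
aimed at plant ecophysiologists working with PAM fluorometry, LI-6800-style
gas exchange, and microclimate loggers.

## Worked example

```r
library(mosstherm)

## variable-J mesophyll conductance (hand-checkable numbers)
est <- mesophyll_conductance(a_sat = 5, r_light = 1, ca = 300, etr = 42,
                             gamma_star = gamma_star(210000, 2625))
est
#> <mesophyll_estimate> gm = 0.05 mol m-2 s-1, Cc = 200 umol mol-1
#>   limitations: mesophyll 0.333 / biochemical 0.667
```

Here `Γ* = 0.5·210000/2625 = 40`, the Harley bracket gives
`Cc = 40·(42+48)/(42−24) = 200 µmol mol⁻¹`, so
`gm = 5/(300−200) = 0.05 mol m⁻² s⁻¹`; with the proxy slope
`A/Cc = 0.025`, mesophyll diffusion accounts for one third of the
limitation and biochemistry for two thirds.

```r
## a cold-dominated synthetic summer and its carbon balance
trace <- simulate_temperature_trace(seed = 1)     # 13 d, 30-min records
round(fraction_time_outside(trace), 1)
#> percent_below percent_above
#>          58.8           2.2

hist <- bin_temperature_frequency(trace, bin_width = 2)
ser  <- simulate_thermal_response(c(-4, 0.95, -0.021, -5e-5), seq(5, 35, 5))
fit  <- fit_cubic(ser)
fit
#> <cubic_thermal_fit> response vs temperature on [5, 35] degC
#>   coefficients: c0 = -4, c1 = 0.95, c2 = -0.021, c3 = -5e-05
#>   t_opt = 21 degC

resp <- assimilation_response(fit, r_dark_at_5 = 4)
run_scenarios(hist, resp, species = "synthetic")
#> <carbon_balance_result>
#>    species fraction_rd pct_lost pct_fixed
#>  synthetic       0.500    60.67     39.33
#>  synthetic       0.333    50.68     49.32
#>  synthetic       0.250    43.55     56.45
#>  synthetic       0.050    13.37     86.63
```

The canopy sits below 4 °C for 58.8% of the time while assimilation peaks
at 21 °C, so the turf only turns carbon-positive (`pct_fixed > 50`) when
cold respiration is strongly inhibited — here at the 25% and 5% scenarios,
not at 50%.

The full chain (trace → histogram; light curves → ETRmax(T) → Topt;
gas exchange → gm(T), Q10, limitations; Asat(T) → scenario balance) runs
from one validated YAML config via `run_pipeline()`; `simulate_study()`
writes a complete synthetic input bundle with a `truth.json` sidecar.

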