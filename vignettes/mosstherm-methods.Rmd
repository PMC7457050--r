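---
title: "Methods: from moss surface temperature to carbon balance"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: from moss surface temperature to carbon balance}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(mosstherm)
```

## The scientific problem

Polar mosses spend most of the summer well below the temperature at which
their photosynthetic machinery works best. Whether a moss turf gains or
loses carbon over a season therefore depends on the interplay of three
things: the *frequency distribution* of canopy-surface temperature (cold
most of the time, with brief radiative warming spikes around midday), the
*temperature response* of light-saturated net assimilation
($A_\mathrm{sat}$), and how strongly *respiration is inhibited* at
temperatures where assimilation is negative. `mosstherm` implements that
full chain as composable, tested pieces, plus the physiological
measurements that feed it: chlorophyll-fluorescence parameters, electron
transport light curves, and variable-J mesophyll conductance for
astomatous bryophyte canopies.

## Microclimate: frequency-of-time histograms

A logger trace is reduced to the fraction of records per temperature bin,

$$\mathrm{Time}(\%) = 100 \cdot t / T,$$

with uniform half-open bins $[\ell, u)$ of 2 °C by default, anchored at
integer multiples of the bin width so the conventional grid
$-4, -2, \dots, 28$ °C is reproduced exactly. Records outside a requested
range extend the histogram with additional bins rather than being dropped
(maritime canopies can exceed 30 °C). Two conventions are deliberate and
documented rather than incidental:

* a record exactly on a bin edge belongs to the *upper* bin (left-closed
  intervals); loggers quantise to fractions of a degree, so edge records
  are real and must land deterministically;
* `fraction_time_outside()` uses *strict* inequalities — a record at
  exactly 4 °C counts as neither "below 4" nor "above 14" — mirroring the
  below/exceeded phrasing such thresholds carry in field reports.

Rows that fail to parse are dropped and counted in a warning, never
interpolated; the diurnal summary reports hours with no records as absent
(`NA`), not zero.

## Fluorescence and electron transport

From pulse-modulated fluorescence channels the package computes

$$\phi_{PSII} = \frac{F_m' - F_s}{F_m'}, \qquad
  \mathrm{NPQ} = \frac{F_m - F_m'}{F_m'}, \qquad
  F_v/F_m = \frac{F_m - F_0}{F_m},$$

and the electron transport rate
$\mathrm{ETR} = \phi_{PSII} \cdot \mathrm{PPFD} \cdot \alpha\beta$, where
$\alpha\beta$ is the product of absorptance and the PSII partitioning of
absorbed quanta. Violated orderings ($F_s > F_m'$, $F_m < F_m'$,
$F_0 > F_m$) raise errors rather than being clipped: in practice they
indicate swapped or mislabelled columns, and silently "repairing" them
would corrupt every downstream quantity.

$\alpha\beta$ is a first-class value with provenance
(`absorptance_factor()`), not a bare constant, because two legitimate
sources coexist: the provisional literature value 0.42 (used when no
gas-exchange calibration exists, and assumed temperature-invariant), and a
per-species calibration from low-O2 light curves (below).

## Light-response curves

ETR light curves are fitted with one of two canonical two-parameter
models, both parameterised by the apparent quantum efficiency (AQE, the
initial slope) and ETR$_{max}$:

* **rational** (Smith-type saturating hyperbola), for curves that rise
  and saturate:
  $$\mathrm{ETR} = \frac{\mathrm{AQE}\cdot Q}
    {\sqrt{1 + \left(\mathrm{AQE}\cdot Q / \mathrm{ETR}_{max}\right)^2}}$$
* **waiting-in-line**, for photoinhibited curves that decline at high
  light, with its maximum of exactly ETR$_{max}$ at
  $Q^\* = \mathrm{ETR}_{max} e / \mathrm{AQE}$:
  $$\mathrm{ETR} = \mathrm{AQE}\cdot Q \cdot
    e^{-\mathrm{AQE}\, Q / (\mathrm{ETR}_{max} e)}$$

Printed renderings of these two models circulate in typographically
corrupted, dimensionally inconsistent variants; the package deliberately
implements the canonical forms the model names denote, parameterised so
that AQE is always the initial slope and ETR$_{max}$ the saturating or
peak rate — properties the tests verify analytically rather than assuming.

Model selection, when not forced, uses an operational photoinhibition
rule: a curve is photoinhibited when the mean ETR over the top quartile of
PPFD levels falls below 95% of the maximum observed ETR. The 95% cut is
our operationalisation of the rise-then-decline dichotomy; it is
deliberately insensitive to single-point noise because it averages the
top quartile.

Fitting is bounded Levenberg–Marquardt (`minpack.lm`) from a
*deterministic* multi-start grid: the base start takes AQE from the slope
of the two lowest-PPFD points and ETR$_{max}$ from the observed maximum,
and four further starts scale those by fixed factors (½×, 2× on AQE;
0.7×, 1.5× on ETR$_{max}$). No random jitter is used, so a fit is a pure
function of its curve. Curves with fewer than 4 points are rejected.

## Thermal responses, optima and Q10

Any response-versus-temperature series with at least four distinct
temperatures is fitted by an ordinary least-squares cubic
$y = c_0 + c_1 T + c_2 T^2 + c_3 T^3$. The optimum temperature is the real
root of $c_1 + 2 c_2 T + 3 c_3 T^2 = 0$ inside the data domain at which
the second derivative is negative; a cubic has at most one such interior
maximum, but near-degenerate fits are disambiguated by taking the
candidate with the highest fitted response. When no interior maximum
exists the domain endpoint with the higher fitted value is returned with
an explicit `boundary` flag — "$\geq T_{max}$"-style optima are
information, not missing data, so they are never silently converted to
`NA`.

The default workflow fits **one cubic per replicate** and summarises
optima as mean ± se across replicates (a pooled fit is available but not
default): per-replicate fitting is what makes between-species comparisons
of $T_{opt}$ statistically meaningful.

The temperature coefficient is
$Q_{10} = (g_2/g_1)^{10/(T_2 - T_1)}$; for mesophyll conductance the
pipeline evaluates it from mean $g_m$ at 15 °C and 25 °C (endpoint means,
not an interval regression — the published description is ambiguous
between the two; endpoint means are implemented and stated here).

## Variable-J mesophyll conductance for bryophytes

Because moss gametophytes lack stomata, the ambient CO2 concentration
$C_a$ replaces the intercellular $C_i$ of the original Harley
formulation:

$$g_m = \frac{A_\mathrm{sat}}
  {C_a - \dfrac{\Gamma^{*}\left(\mathrm{ETR} +
   8(A_\mathrm{sat} + R_L)\right)}
   {\mathrm{ETR} - 4(A_\mathrm{sat} + R_L)}}$$

The bracket is the chloroplastic CO2 concentration $C_c$; algebraically
$C_c = C_a - A_\mathrm{sat}/g_m$, and a test asserts the two agree. The
compensation point comes from the Rubisco specificity factor,
$\Gamma^{*} = 0.5\,O / S_{C/O}$. **$S_{C/O}$ has no default anywhere in
the package**: it is a measured, species-group-specific constant, and
supplying a silent default would amount to fabricating data. The oxygen
level is configurable (210000 µbar ambient; sub-1% for calibration runs);
unit consistency between $O$ and $S_{C/O}$ is the caller's declared
responsibility.

The denominator $\mathrm{ETR} - 4(A_\mathrm{sat} + R_L)$ is a genuine
pole: at low temperature, measured ETR routinely falls below the
carboxylation demand term and $g_m$ is undefined. The estimator raises a
singularity error exactly at and below the pole; `gas_exchange_table()`
converts that into a flagged, `NA`-valued record and counts it in the run
report, which is how cold-end observations drop out of $g_m$ temperature
curves without being silently lost.

Limitation partitioning follows the quantitative-limitation logic reduced
to the stomata-free case, with $A_\mathrm{sat}/C_c$ as the proxy for
$\partial A/\partial C_c$:

$$l_m = \frac{\partial A/\partial C_c}{g_m + \partial A/\partial C_c},
 \qquad l_b = \frac{g_m}{g_m + \partial A/\partial C_c},
 \qquad l_m + l_b = 1.$$

Two calibrations come from low-O2 (non-photorespiratory) light curves:

* **$\alpha\beta$**: with photorespiration suppressed, four electrons are
  needed per CO2, so $\alpha\beta = 4\,\phi_{CO2}/\phi_{PSII}$. Because
  the $\phi_{PSII}$:$\phi_{CO2}$ ratio drifts with PPFD, the default mode
  evaluates the ratio at the *highest* PPFD point (the light level at
  which $A_\mathrm{sat}$ itself is measured); the classical
  $4/\mathrm{slope}$ regression is retained as an explicit alternative,
  and both modes are reported when they disagree.
* **$R_L$** (respiration in the light): the negative intercept of the
  ordinary regression of $A_N$ on $\phi_{PSII}\cdot\mathrm{PPFD}/4$ over
  the light-limited points — by default the four lowest distinct PPFD
  levels, configurable via a PPFD cutoff.

Whether dark or light respiration enters the $g_m$ equation, and whether
$R_L$ is re-estimated per temperature, are left to the caller (both are
plain arguments); the package defaults to a single $R_L$ per species.

## Carbon balance under respiration-inhibition scenarios

Each histogram bin contributes $A_{\mathrm{sat},T} = A_\mathrm{sat}\cdot f$,
where $f$ is the bin's percent of time and $A_\mathrm{sat}$ is:

* for bin midpoints below the threshold (default 4 °C): a *negative*
  value equal to a scenario fraction of dark respiration at 5 °C,
  $-\,\mathrm{frac}\cdot R_D(5)$, with the canonical fraction set
  $\{0.50, 0.333, 0.25, 0.05\}$ — four scenarios of progressively
  stronger cold inhibition of respiration;
* otherwise: the fitted $A_\mathrm{sat}$ cubic evaluated at the bin
  *midpoint* (the least-biased single evaluation point for a 2 °C bin),
  clamped to the endpoints of the measured temperature range — cubics
  diverge outside their data and must never be extrapolated.

The midpoint rule decides the threshold-straddling bins: $[2,4)$ (midpoint
3) is negative, $[4,6)$ (midpoint 5) takes the cubic value. It also
settles the 4–5 °C gap between the threshold and the lowest measured
temperature: midpoints in that gap are clamped to the 5 °C endpoint value.
Both conventions are flagged in the per-bin output (`clamped`).

The balance is ratio-based and therefore invariant to rescaling all
frequencies:

$$\%C_\mathrm{fix} = \frac{\sum A_{\mathrm{sat},T}^{+}}
  {\sum A_{\mathrm{sat},T}^{+} + \left|\sum A_{\mathrm{sat},T}^{-}\right|}
  \cdot 100, \qquad \%C_\mathrm{lost} = 100 - \%C_\mathrm{fix}.$$

$\%C_\mathrm{fix}$ is monotone non-increasing in the respiration fraction
(tested as an invariant). The model inherits two explicit assumptions:
high temperatures are assumed to co-occur with high light (no
light-limitation correction), and canopy water content is assumed
non-limiting.

## The synthetic-data generators

Every input the pipeline consumes can be generated with known ground
truth; each generator is a pure function of (parameters, seed) — the
caller's RNG state is saved and restored, and one master seed fans out to
per-stream FNV-hashed sub-seeds so adding a generator never perturbs
existing fixtures. Truth parameters ride along as a `truth` attribute and
can be serialised as a JSON sidecar; recovery tests read truth only from
the sidecar.

The temperature generator is **phenomenological**, not an energy-balance
model: a sinusoidal diurnal cycle peaking at 12:30, Bernoulli per-day
clear-sky radiative spikes (Gaussian-shaped in time around the peak
hour), Gaussian noise, and a moisture `buffering` factor in $[0,1]$ that
scales down both amplitude and spikes (a saturated turf is thermally
damped). Only the frequency structure matters downstream, so this is the
right level of realism. The defaults — mean 3.1 °C, amplitude 4.5 °C,
spike probability 0.4/day with 8 °C magnitude and 1.2 h width, noise
1.2 °C, 13 days at 30-minute intervals — were chosen once to emulate a
coastal East Antarctic midsummer regime in which the canopy sits below
4 °C roughly 57% of the time and above 14 °C about 2–3% of the time; a
closed-form Gaussian-mixture expectation
(`expected_fraction_outside()`) gives the analytic fractions the
simulated ones are tested against. What the generator does *not* emulate:
weather autocorrelation across days, synoptic cold fronts, and the
coupling of moisture to radiation — so passing tests demonstrate the
*pipeline arithmetic* on realistic frequency structure, not predictive
skill on any particular field season.

The gas-exchange generator enforces the variable-J identities exactly
($A_\mathrm{sat} = g_m (C_a - C_c)$;
$\mathrm{ETR} = 4(A_\mathrm{sat}+R_L)(C_c + 2\Gamma^{*})/(C_c -
\Gamma^{*})$), making `mesophyll_conductance()` its exact inverse on
noiseless data — the round-trip identity that anchors the whole
gas-exchange module. In the bundled synthetic study, true $g_m$ rises
linearly from 0.005 mol m⁻² s⁻¹ at 5 °C by 0.002 per °C, and
$R_D(5\,°\mathrm{C})$ is set to 4 µmol m⁻² s⁻¹ — about two-thirds of the
peak $A_\mathrm{sat}$ (≈6.2) — because near the cold compensation point
respiration genuinely rivals assimilation; that ratio is what makes the
50%-inhibition scenario carbon-negative and the 5% scenario
carbon-positive, the qualitative crossing the scenario engine exists to
expose.

## Numerical choices and degenerate inputs

* Cubic fits use `stats::lm` on a raw polynomial design; rank deficiency
  (fewer than four distinct temperatures) is an error, not a warning.
* The light-curve optimiser treats a fit as converged on
  `minpack.lm` info codes 1–4; an unconverged best fit is returned with
  `converged = FALSE` rather than discarded, and total failure across all
  starts is an error naming the replicate.
* Histogram invariants (frequencies ≥ 0, summing to 100 within 1e-9) and
  the $l_m + l_b = 1$ and $\%C_\mathrm{fix} + \%C_\mathrm{lost} = 100$
  identities are enforced by construction and re-checked by
  property-style tests against brute-force oracles.
* Problem sizes in the test-suite simulations — a 20×20 $(g_m, C_c)$
  grid, 100-seed Monte-Carlo recovery runs, 1000 random instances for the
  counting oracles — were chosen so the full suite documents each claim
  in seconds while keeping Monte-Carlo error well below the asserted
  tolerances.

## Known limitations

* No Arrhenius or peaked-Arrhenius thermal models: cubics only, by
  design, including their boundary-optimum behaviour.
* No A–Ci curve machinery ($V_{cmax}$/$J_{max}$): $g_m$ comes only from
  variable-J at a single $C_a$.
* No quenching decomposition beyond NPQ; no photoinhibition kinetics.
* The carbon balance has no light-limitation or water-content
  modulation; its scenarios bracket, rather than resolve, cold-end
  respiration.
* The pipeline is an R API (`run_pipeline()` + YAML configs) rather than
  a shell tool; scripted use goes through `Rscript` as in
  `scripts/acceptance.R`.
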