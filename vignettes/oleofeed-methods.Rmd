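---
title: "Models and methods behind oleofeed"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods behind oleofeed}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(oleofeed)
```

`oleofeed` analyzes fed-batch lipid-production cultivations of oleaginous
yeasts and plans their carbon-source feeding. This vignette documents the
models, the accounting conventions, the numerical choices and the known
limitations — the decisions a maintainer or a careful user should know
about.

## The process being modelled

A two-phase fed-batch process: an initial batch phase in which the yeast
grows on dissolved sugar and consumes the medium's ammonium, followed by a
fed-batch phase in which nitrogen is exhausted but sugar keeps being
supplied. Under nitrogen limitation with carbon excess, oleaginous yeasts
divert carbon into intracellular triacylglycerols; lipid content is
measured indirectly as % FAME per cell dry weight. On glucose,
*S. podzolica* additionally oxidizes the C1 of the sugar to gluconic acid —
the more so the higher the dissolved sugar excess — and on xylose to small
amounts of xylonic acid. The feeding strategies compared are (i) daily
restock to a high target concentration, (ii) daily pulses sized from prior
runs' average consumption so the excess never falls below ~10 g/L, and
(iii) an automated continuous feed holding the same low excess.

## Chemical bookkeeping

Carbon fractions come from molecular formulas with IUPAC standard atomic
weights (C 12.011, H 1.008, O 15.999, N 14.007). Integer nucleon masses
would change the reported fractions by < 0.1 %, below every tolerance used
here. Glucose and xylose are both CH₂O multiples, so they share one carbon
mass fraction (0.40002) and equal sugar masses carry equal carbon — several
invariants rely on this.

Lipid-free cell mass uses the empirical composition C₆H₁₀O₃N for yeast
biomass (carbon fraction 0.4999). Cell dry weight includes the
intracellular lipid, so the balance always splits CDW into a lipid-free
part and a lipid part before weighting. Lipids have no single formula; the
default carbon mass fraction 0.77 corresponds to a C16/C18
triacylglycerol/FAME mixture (e.g. glyceryl trioleate is 0.774, methyl
palmitate 0.756). It is configurable via `speciesRegistry()` or a YAML
species file because this choice directly scales the lipid sink of the
carbon balance.

## The cultivation record and its conventions

* Time is hours from inoculation; the first sample defines t = 0.
* Events (pulse feeds, continuous segments, sample withdrawals) attribute
  to intervals closed on the left and open on the right: an event at a
  sample time happens *after* that sample is drawn. This matches bioreactor
  practice — the daily sample is taken, sugar is measured, then the feed is
  applied.
* Lipid titer (g/L) is always the derived product
  `cdw_gL * fame_pct_cdw / 100`, never an independent column, so the two
  measurements cannot drift apart.
* Missing measurements are `NA`, never zero. Ammonium below the detection
  limit is stored as 0 by the simulator (mirroring "not detected").
* Daily sample withdrawals default to 17 mL (15 mL for lipid analysis plus
  ~2 mL analytics); the value is a parameter, not a constant.

`metabolizedSugar()` is total applied sugar (initial dissolved mass plus
all feeds) minus the residual dissolved mass at the last sample minus
sugar removed in withdrawals. On noise-free simulated records it matches
the simulator's integrated consumption to well under 0.5 %.

## Yield and rate accounting: two bases

Published summary tables for such processes divide concentration
differences without correcting for the volume added by feeds or removed by
sampling. `phaseYields()` therefore offers two bases:

* `"concentration"` (default): concentration differences, feeds expressed
  on the initial volume. This basis reproduces published whole-process
  yields (e.g. final CDW divided by metabolized-mass/1.2 L gives 0.21–0.22
  g/g for the continuous processes, matching the printed totals within
  0.03).
* `"mass"`: every term volume-corrected via the tracked event log. Use
  this when feeds change the volume by more than a few percent.

Percent comparisons between strategies use an explicit base convention
(`percentChange(..., base = "reference")` or `"new"`) because published
headline numbers mix both: "48 % less gluconic acid" is on the reference
(high-excess) base, while "19 % more lipid titer" and "28 % more cell
mass" are on the new (continuous-feed) base.

The nitrogen-metabolization phase defaults to 0–72 h and the
nitrogen-limitation phase to 72 h–end, with window endpoints snapping to
the nearest sample within 2 h (sampling is daily, plus handling time).

## Feed planning

* `restockPulse()` is the high-excess strategy: `(target − current) × V`.
* `planCfs()` sizes daily pulses from a piecewise-constant daily mean
  consumption profile (day resolution matches how such processes are
  actually fed): each pulse replaces the consumption predicted until the
  next feed, topped up if the predicted pre-feed concentration would fall
  below the target floor. Reconstructing the published reduced-excess
  glucose schedule from the realized daily rates reproduces the printed
  pulses loosely (within ~25 % per pulse, ~12 % in total): the original
  plan came from unpublished multi-run averages and was fed in rounded-up
  portions, so exact agreement is not expected.
* Pulse volumes default to mass/500 g/L (feeding from a 500 g/L stock);
  configurable, since pulse volumes are rarely recorded.
* `continuousRates()` converts a daily sugar demand into a pump mass rate
  `demand/24/w` (w = sugar mass fraction of the feed, g/g) and a dilution
  rate `D = (rate/ρ)/V`. The published pump rates imply w ≈ 0.231 and feed
  density ρ ≈ 1081 g/L for a 250 g sugar/L glucose feed; the printed
  per-day D values additionally depend on the (unpublished) actual volume
  each day and are reproduced only within ~10 %. `D` uses the volume at
  segment start, constant per day.

## The bioreactor simulator

No kinetic model was published for this process, so the package ships its
own minimal one — a deliberately simple stand-in whose role is to generate
realistic, ground-truth-bearing records, not to be mechanistically
faithful:

* dual-Monod growth: μ = μ_max · S/(K_s+S) · N/(K_N+N);
* nitrogen use proportional to growth (Y_xn);
* a lipogenesis switch f_N = max(0, 1 − N/n_switch) that turns lipid
  synthesis on as ammonium is exhausted, with Monod dependence on sugar;
* organic-acid formation increasing with the dissolved sugar excess
  (Monod with K_acid = 15 g/L, so the rate roughly doubles between 10 and
  65 g/L excess);
* sugar consumption as the yield-weighted sum of growth, lipid and acid
  synthesis plus maintenance;
* CO2 emitted as exactly the consumed sugar carbon not fixed into cell
  mass, lipid or acid. Because the CO2-carbon derivative is a fixed linear
  combination of the other derivatives, Runge–Kutta integration preserves
  carbon closure to machine precision — the closure test measures ~1e-12
  relative error over a full 142 h horizon.

The two presets were tuned, against noise-free runs under the published
feed schedules, to the magnitudes typical of *S. podzolica* fed-batch
data: final CDW ~25–27 g/L; lipid fraction ~0.27–0.31 at 142 h; ammonium
detectable at 46 h but not at 70 h; batch-phase consumption ~46 g/L
(glucose) / ~34 g/L (xylose) by 48 h; gluconic acid ~9 g/L at 10 g/L
excess versus ~25 g/L under 90 g/L restock; xylonic acid below 1 g/L.
These are emulation targets, not asserted reproductions.

Numerical choices: fixed-step RK4 with dt = 0.01 h; event times rounded to
the grid; continuous feed applied as a per-step mass/volume chunk (first
order in dt — at dt = 0.01 h the error is far below every tolerance used);
sample observation, then withdrawal, then feeds when they coincide at one
grid point; concentrations clipped at zero after a step (the Monod forms
make undershoot negligible at this step size). Observation noise is
multiplicative Gaussian — relative sd 0.05 for concentrations, 0.03 for
CDW and lipid content, 0.02 for cumulative CO2 — from a single integer
seed; equal seeds give bit-identical records.

What the generator does *not* emulate: acid re-uptake late in
cultivation (xylonic acid slightly declines in real runs), substrate
inhibition at very high sugar, pH/temperature effects, oxygen transfer,
and day-to-day variability between replicate reactors. Tests passing on
simulated data therefore show the analysis pipeline is self-consistent
under these dynamics, not that the model predicts real cultivations.

## Logistic rate curves

Cumulative courses (consumed sugar, cell mass, lipid titer, acid) are
smoothed with the four-parameter logistic
y = (A₁−A₂)/(1+(x/x₀)ᵖ) + A₂ and differentiated analytically to volumetric
rates Q. Choices:

* Levenberg–Marquardt via `minpack.lm::nls.lm` on the residual function,
  max 500 iterations, ftol 1e-10; a fixed deterministic initializer
  (A₁ = first value, A₂ = last, x₀ at the half-range crossing, p = 4).
  Constant series short-circuit to a flagged degenerate fit.
* The model is undefined at t = 0 for non-integer p; evaluation shifts
  t ≤ 0 to 1e-6 h (daily-sampled data are never affected).
* Pulsed records are first transformed to cumulative consumption
  `applied(<t)/V̄ + S(0) − S(t)` — the feed sawtooth otherwise breaks the
  sigmoid shape. Whether published rate curves were fitted on
  concentrations or cumulative quantities is not stated; the cumulative
  choice is this package's interpretation and is exact for unfed series.
* The "peak interval" is the maximal contiguous span where the rate stays
  within `plateau_fraction` (default 0.99) of its maximum; no standard
  definition exists, so the fraction is a parameter.
* The sub-threshold time is the first grid point after the peak below the
  threshold (default 0.1 g/(L·h)), on a grid of step ≤ 0.1 h, and agrees
  with bisection on the closed form to the grid resolution.

**Limitation — peak smoothing.** A 4PL derivative is a smooth bell. Under
the simulator's sharp ammonium cutoff the true consumption rate collapses
abruptly, and the fitted peak underestimates the true instantaneous
maximum by a factor of ~2.4 regardless of sampling density. The tests
therefore assert what holds in the model class: exact recovery when the
truth is logistic, agreement between daily-sampled and densely-sampled
fits (within 10 % with 7 samples), and that the fitted peak never exceeds
the true maximum. Fitted peaks from daily fed-batch data should be read as
smoothed, conservative rates.

## Carbon balance

`carbonBalance()` distributes applied-sugar carbon over CO2, lipid-free
cell mass, lipid, organic acid, residual sugar, optionally the carbon
removed in daily samples, and an explicit unaccounted remainder, so the
fractions always sum to one exactly. Choices:

* Volume basis defaults to the initial volume (1.2 L in the bundled
  benchmarks): published biomass fractions are consistent with that basis
  and not with a feed-corrected volume. `"end"` and `"tracked"` bases are
  available; `"tracked"` also enables the sampled-out sink.
* The sampled-out sink defaults to off (published balances do not mention
  it); excluding it moves that carbon into the unaccounted remainder,
  typically a few percent.
* Only the CO2 fraction is volume-independent, which is why the
  reproduction tests pin the CO2 fractions (46.8 % on glucose, 54.08 % on
  xylose from the printed totals) but not the lipid/biomass fractions,
  which also depend on the unpublished lipid formula.
* A missing CO2 signal yields a partial balance with the CO2 sink marked
  absent and absorbed by the remainder.

## Problem sizes and test design

The test suite simulates full 142 h cultivations at dt = 0.01 h (14,200
steps, ~1–2 s each), uses 20 replicate fits for the noise-recovery
statistics, 100 random points for the finite-difference oracle of the
analytic derivative, and dense 0.5 h sampling where a near-continuous
truth is needed. Expected values in the tests were either hand-computed
from atomic weights and closed forms, taken from published totals that are
pure arithmetic on printed schedules, or generated by independent oracles
(finite differences, quadrature, bisection, simulator ground truth) —
never by running the code under test.
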