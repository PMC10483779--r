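---
title: "Models and methods for long-term repetitive-batch ALE simulation and estimation"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods for long-term repetitive-batch ALE simulation and estimation}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(rbale)
```

## The problem

Adaptive laboratory evolution (ALE) selects faster-growing mutants by serial
propagation. In the repetitive-batch variant (rbALE) a microbioreactor well
is cultivated until its scattered-light biomass signal (backscatter, BS)
crosses a preset threshold, at which point a small inoculum (50 uL into
800 uL of fresh medium, a ~17-fold dilution) starts the next batch in the
next well of the plate. The number of consecutive batches, and hence the
number of cell generations available for selection, is limited by the plate
— unless wells are emptied, washed, dried and reused. `rbale` simulates this
recycled workflow as a discrete-event system, generates realistic synthetic
backscatter and bioreactor datasets from it, and estimates the underlying
growth parameters back from those data, so that every stage of such an
analysis pipeline can be validated end to end without instrument access.

## Process models

### Piecewise-exponential repetitive-batch model

Within batch $i$ the biomass grows exponentially at a substrate-independent
specific rate $\mu_i$,
$$X(t) = X_{\mathrm{start},i}\, e^{\mu_i (t - t_i)},$$
and at each transfer timestamp the biomass drops instantaneously to
$X/f_{\mathrm{dil}}$. Substrate is intentionally absent from this model:
batch substrate concentrations stay orders of magnitude above the affinity
constants of the organism, so the growth rate is effectively constant within
a batch and depletion matters only through the trigger threshold. Allowing a
different $\mu_i$ per batch is what lets the same model describe an evolving
population whose rate ratchets upward. The analytic solution is exact; an
adaptive ODE integration (`deSolve::lsoda`, rtol = atol = 1e-8) with
multiplicative dilution events is kept in the package
(`rbale_trajectory_ode()`) purely as a numerical cross-check, and the two
agree to within 1e-6 relative error in the test suite.

A linear calibration $X = (BS - b)/a$ maps backscatter to biomass. Given
backscatter alone, $(a, b, X_0)$ are jointly unidentifiable — rescaling $a$
and $X_0$ together leaves the predicted signal unchanged — so estimation
fixes the identity calibration ($a = 1$, $b = 0$) by default and reports
biomass in backscatter units. Growth rates and the dilution factor are
invariant to this choice. Joint estimation of the calibration is possible
when an external calibration table pins down the scale, but it is an opt-in,
not a default.

### Generations accounting

Generations per batch equal $\log_2(BS_{\mathrm{end}}/BS_{\mathrm{start}})$
on blank-corrected signal. With the standard start signal of about 8 and
threshold 60 this is $\log_2 7.5 \approx 2.9$ — "about three generations per
batch", independent of growth rate and organism. A 48-well plate (6 groups
of 8 wells) without recycling therefore caps an experiment at
$48 \times 3 = 144$ generations; with recycling the capacity is unbounded.
Note a deliberate asymmetry the package preserves from practice: the
*first* batch starts at BS ~8 set by the inoculation density, while every
*continuing* batch starts at threshold/$f_{\mathrm{dil}}$ (~3.5 for 60/17),
because the pipetting volumes, not the first-batch inoculum, set the
dilution. The "3 generations per batch" figure is the standard planning
number and is what `plan_capacity()` uses by default.

### Competition model

A beneficial mutation initially lives in a vanishing fraction of the
population. The competition model tracks wild-type and mutant biomass as two
independent exponentials ($\mu_{wt} < \mu_{evo}$) sharing every dilution
event. Since dilution acts equally on both, the mutant-to-wild-type ratio
multiplies by $e^{(\mu_{evo}-\mu_{wt})\Delta t_i}$ per batch and the
*apparent* batch growth rate — log total fold-change over batch duration —
rises monotonically from $\mu_{wt}$ toward $\mu_{evo}$. This reproduces the
characteristic slow, steady takeover pattern seen in evolving ethanol
cultures and explains why long-term (many-generation) experiments are
needed for rates that differ moderately.

### Monod batch model

Lab-scale batch reactors are described by classical Monod kinetics,
$$\frac{dX}{dt} = \mu_{\max}\frac{S}{K_S+S}X,\qquad
  \frac{dS}{dt} = -\frac{1}{Y_{X/S}}\mu_{\max}\frac{S}{K_S+S}X,$$
integrated with `lsoda` at rtol = atol = 1e-8 and $S$ clipped at zero inside
the derivative. The system conserves $X + Y_{X/S} S$, which the tests verify
to 1e-6 relative; equivalently the final biomass gain is $Y_{X/S} S_0$ (8.87
g/L for 428 mM ethanol at a yield of 0.45 g/g).

At substrate levels far above $K_S$ the specific uptake rate implied by the
kinetic parameters is $q_S = \mu_{\max}/(Y_{X/S} M) \times 1000$
mmol g$^{-1}$ h$^{-1}$ ($M$ the molar mass). For $\mu_{\max} = 0.15$ 1/h and
$Y_{X/S} = 0.45$ g/g on ethanol this arithmetic gives 7.23 mmol/g/h.
Published uptake rates for comparable cultures are sometimes higher
(e.g. 8.45 mmol/g/h); such values cannot be reproduced from the two printed
parameters alone — they depend on how uptake was measured or which phase of
the culture was used — so `derived_rates()` reports the internally
consistent value and makes no attempt to force agreement.

## The discrete-event workflow simulator

`run_schedule()` advances each plate group through measure–trigger–
dispense–temper–harvest–inoculate–wash–dry cycles:

* All events snap to the measurement grid (15-min cycles by default); the
  trigger fires at the first grid point at or after the blank-corrected
  signal crosses the absolute threshold, so trigger quantization is at most
  one cycle.
* The threshold is supplied as an absolute number (in practice 60% of the
  expected final signal, fixed before the run); the simulator never infers
  it from data.
* Fresh medium tempers for one cycle before inoculation; the triggering
  culture keeps growing until it is harvested at the transfer timestamp,
  where dilution is instantaneous.
* Chain groups wrap to their first well under recycling; branch groups
  (fan-out layouts) are inoculated from the *concurrent* batch of their
  feeder group, never from a previous branch batch — the topology used to
  verify evolved strains on a second carbon source while keeping a glucose
  lineage running.
* Washing takes two 900-uL steps; a washed well should idle 40 h before
  reuse. Violations of the drying time are warnings by default (residual
  moisture is benign in practice: any survivors of washing would be
  overgrown by the ~50 uL-equivalent inoculum) and can be escalated to
  errors. Overlapping occupancy of a well is always a hard error.
* Residual-volume biomass carryover between batches is deliberately not
  modelled, for the same overgrowth reason.
* A technical failure of the liquid handler can be emulated with a `pause`:
  triggering halts, the affected culture saturates at a configurable
  stationary plateau, and the run resumes at the first cycle after the
  pause. Ties between groups triggering in the same cycle are processed in
  group-label order so logs are deterministic.

`validate_schedule()` re-derives the constraint checks from the event log
alone (occupancy, drying, dispense-before-inoculate), returning violations
as data rather than conditions.

## Synthetic data

`gen_rbale_dataset()` drives the simulator and adds measurement effects:
a per-well blank (default 2 backscatter units) is added to the calibrated
signal, and multiplicative Gaussian noise (default CV 2% for backscatter,
3% for offline bioreactor observables) perturbs every reading.
Multiplicative noise with a few-percent CV is the typical repeatability of
scattered-light and offline concentration measurements; no published noise
law exists for these instruments, so the CVs are package defaults chosen
once, and `cv = 0` yields data that the forward models reproduce exactly.
Three scenarios cover the study designs: `constant` (wild-type glucose
validation, $\mu = 0.41$ 1/h, 16 batches), `switching` (an evolving ethanol
culture whose per-batch rate follows `etoh_r3_schedule()`: 0.085 1/h for
batches 1–2, a linear ramp to 0.16 by batch 5 and 0.21 by batch 10, then
constant — linear interpolation between the three reported anchor rates is
the package's choice for the unreported intermediate batches), and
`competition` (explicit wild-type/mutant mixture). The anomalous-first-batch
artefact occasionally caused by insufficient washing between carbon sources
is not generated by default; fits handle it through the explicit
batch-exclusion mask instead.

`gen_bioreactor_dataset()` emulates four parallel 1-L batch reactors on
428 mM ethanol sampled every 2 h: global kinetics
($\mu_{\max} = 0.15$ 1/h, $K_S = 0.01$ g/L, $Y_{X/S} = 0.45$ g/g) shared
across reactors, local initial conditions jittered a few percent per
reactor to emulate separate inoculations (OD 3.5 converted to cell dry
weight at 0.25 g/L per OD unit — an instrument-specific factor users should
set explicitly when known; $K_S$ likewise is not reported for these
cultures and the default 0.01 g/L merely encodes "far below batch substrate
levels"). All generators are strictly seeded: one integer seed determines
every byte of the output, with no time-dependent state.

What the generator does *not* emulate — evaporation drift, plate-position
effects, optode channels, lag and death phases, non-linearity of
backscatter at high density — bounds what passing recovery tests show: they
demonstrate that the estimation stages invert the stated forward models at
realistic noise, not that those models capture every artefact of real
instruments.

## Estimation

`segment_and_normalize()` cuts the long-format series into one slice per
batch (from the event log, or by detecting >50% signal drops between
consecutive cycles when no log is available) and subtracts each destination
well's last pre-inoculation reading — the well blank. Slices with fewer
than 4 points are excluded with a warning.

`fit_rbale()` minimizes the sum of squared deviations between
blank-corrected backscatter and the piecewise model over one rate per
batch, a single shared dilution factor (one $f_{\mathrm{dil}}$ for the whole
run, as a pipetting property), and the initial biomass. The optimizer is
Levenberg–Marquardt (`minpack.lm::nls.lm`, ftol = ptol = 1e-10, at most 500
iterations per start) with 10 seeded starts by default: the first start uses
the log-linear per-batch slopes, the nominal dilution factor 17, and the
first observation; the rest jitter these multiplicatively. $f_{\mathrm{dil}}$
and $X_0$ are optimized on the log scale to enforce positivity, rates with
a zero lower bound. `loglinear_mu()` — the slope of $\ln BS$ against time
per slice — serves as a model-free oracle; on noiseless data the two routes
agree within 1%. Batch exclusion (for known artefacts) is explicit user
configuration; there is no automatic outlier rejection.

`fit_monod_hierarchical()` fits all reactors jointly: kinetic globals are
shared, initial-condition locals are free per reactor, every parameter on
the log scale. Residuals are weighted by the reciprocal of each
observable's per-reactor data range, so cell dry weight and substrate
contribute comparably despite an order-of-magnitude difference in scale
(whether real analyses weight these observables is usually unstated; range
weighting is this package's documented choice). Because a typical batch has
$S_0 \gg K_S$, the affinity constant shapes only the final sampling
interval before depletion: the fit computes approximate Wald intervals for
the log-parameters from the Levenberg–Marquardt Hessian and flags any
parameter whose 95% interval spans at least one order of magnitude as
weakly identified — $K_S$ invariably is, and reporting that is the correct
behaviour, not a failure.

`bootstrap_ci()` provides residual-bootstrap percentile intervals (default
100 replicates, 95% level, seeded). Residuals are resampled on the
*relative* scale by default — the fitted curve is multiplied by resampled
relative residuals — because measurement error is predominantly
multiplicative across the large dynamic range of a batch; absolute
resampling is available as an option. Refits start from the point estimate;
if fewer than half converge the intervals are flagged unreliable. The test
suite checks frequentist coverage of the true growth rate (≥ 80% observed
for nominal 95% intervals over 50 simulated 4-batch runs at 2% noise — the
reduced batch count and 60 bootstrap replicates keep the study quick while
preserving the calibration being tested). A full Bayesian treatment and
model selection between growth laws are out of scope.

## Reporting and reproducibility

`rbale_run()` ties the stages into commands (`capacity`, `simulate-rbale`,
`simulate-bioreactor`, `fit-rbale`, `fit-monod`, `report`) with
schema-validated YAML configuration (unknown keys are rejected), a resolved
`config.yaml` and a `run.log` (seed, configuration hash, package version)
written next to every output. A thin command-line wrapper is installed at
`system.file("cli", "rbale.R", package = "rbale")`; precedence is flag >
config file > default, and all randomness flows from the single seed.
`rbale_report()` aggregates whatever artifacts a run directory contains
into one summary CSV/JSON pair and is byte-idempotent.

## Numerical choices and limitations

* Time is in hours, biomass in g CDW/L (or backscatter units under the
  identity calibration), substrate in g/L internally with mM conversions by
  molar mass (ethanol 46.069, glucose 180.156 g/mol).
* Event times snap to the measurement grid; dilution is instantaneous at
  the inoculation timestamp; tempering is exactly one cycle by default.
* ODE tolerances 1e-8 throughout; optimizer tolerances 1e-10 with
  deterministic multi-start seeding; ties in trigger processing resolved by
  group label.
* The simulator's growth models are deterministic; all stochasticity lives
  in the measurement-noise layer. Biological batch-to-batch rate
  variability beyond the deterministic schedule (and mutation appearance
  itself) is not modelled.
* Backscatter is treated as linear in biomass over the working range;
  saturation at high density and the instrument gain mapping are hardware
  specific and outside scope, which is why synthetic backscatter is
  anchored only by the start ~8 / threshold 60 convention.
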