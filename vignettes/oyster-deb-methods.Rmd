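---
title: "Bioenergetics of flat and Pacific oysters: model, numerics and design choices"
author: "oysterDEB"
output: rmarkdown::html_vignette
---

# Scope

`oysterDEB` implements an individual-level Dynamic Energy Budget (DEB) model
for the European flat oyster (*Ostrea edulis*) and the Pacific cupped oyster
(*Crassostrea gigas*), of the 'asj' type: a standard DEB model extended with
metabolic acceleration between settlement (maturity `E_Hs`) and the end of
metamorphosis (`E_Hj`).  The package covers the full chain needed to work
with such a model offline: species parameter sets, environmental forcing
(temperature and chlorophyll-a), simulation with life-cycle events
(brooding, larval release, spawning, ageing, starvation death), observable
mappings (shell length, tissue weights, growth rate, fecundity, respiration
and clearance proxies), a parameter-estimation engine minimising a weighted
mean-relative-error loss with the Nelder--Mead simplex, and a seeded
synthetic-data generator so that every stage is testable without downloads.

# The model

## State variables and fluxes

Four energetic state variables describe the individual: reserve `E` (J),
structural volume `V` (cm^3), maturity `E_H` (J, cumulative investment into
development) and the reproduction buffer `E_R` (J).  Food intake at scaled
feeding level `f` drives assimilation

    p_A = s * {p_Am} * f * V^(2/3) * TC,

where `{p_Am}` is the maximum surface-specific assimilation rate, `s` the
acceleration factor and `TC` the temperature correction.  Reserve is
mobilised at

    p_C = E * (E_G * s * v * TC / L + p_S / V) / (kap * E / V + E_G),

with `L = V^(1/3)`.  A fixed fraction `kap` of mobilised energy goes to the
soma: somatic maintenance `p_S = [p_M]*V*TC + {p_T}*V^(2/3)*TC` has
priority, the rest `p_G = kap*p_C - p_S` builds structure at cost `E_G` per
cm^3.  The remaining `1 - kap` pays maturity maintenance
`p_J = k_J*E_H*TC` and accumulates as maturity before puberty
(`E_H < E_Hp`) or in the reproduction buffer after.  Before birth
(`E_H < E_Hb`) the embryo does not feed and runs down its initial reserve.

The kappa-rule balances `p_G + p_S = kap*p_C` and
`p_R + p_J = (1-kap)*p_C` hold identically in the implementation; the test
suite checks them to 1e-12 relative at random states, and checks the full
energy budget of simulated trajectories (assimilation = storage change +
structural growth cost + maintenance integrals + spawned energy) to 1e-6
relative.

## Metabolic acceleration

Between `E_Hs` and `E_Hj`, `{p_Am}` and `v` are both multiplied by
`s(t) = L/L_s`, where `L_s` is the structural length when maturity crossed
`E_Hs`; `s` is frozen at `s_M = L_j/L_s` afterwards and equals 1 before
settlement.  The simulator tracks `L_s` explicitly through its event
handling.  For states without a life-cycle history (e.g. a field adult
reconstructed from a weight) the packaged `s_M` (5.9 flat, 4.8 Pacific) is
used; the life-cycle solution at `f = 1` reproduces both values within a
few percent, essentially because maturity grows proportionally to structure
during the exponential metamorphic phase, so
`s_M ~ (E_Hj/E_Hs)^(1/3)`.

## Temperature and food

All rates share one five-parameter Arrhenius correction

    TC(T) = exp(T_A/T_ref - T_A/T) * s(T_ref)/s(T),
    s(T) = 1 + exp(T_AL/T - T_AL/T_L) + exp(T_AH/T_H - T_AH/T),

normalised so `TC(T_ref) = 1` exactly.  Decoupling ingestion from
respiration (a published refinement) is available: `compute_fluxes()`
accepts a separate correction for the feeding fluxes and
`deb_options(ingestion_temp = ...)` feeds a second Arrhenius block to the
simulator.  The coupled form remains the default because that is the model
the parameter values were estimated under.  Food enters as a Holling type-II scaled functional response
`f = X/(X + K_X)` on chlorophyll-a, with half-saturation constants
`K_X = 1.84` (flat) and `3.29` (Pacific) micrograms chl a per litre.
Temperatures are Kelvin internally and degrees Celsius at I/O boundaries
(offset 273.15); time is in days, energies in joules, lengths in cm.

## Weights and observables

Tissue dry weight is `d_V*V + w_E*(E + E_R)/mu_E` and wet weight divides by
the measured dry-to-total ratios (0.015 flat, 0.018 Pacific).  The
composition parameters `d_V = d_E = 0.09 g/cm^3`, `mu_E = 550 kJ/mol`,
`w_E = w_V = 23.9 g/mol` are not species-specific measurements but the
community defaults conventionally used with such parameter tables; they are
stored in the packaged parameter files and can be overridden there.
Physical (shell) length is `V^(1/3)/delta` with `del_Mb` before the end of
metamorphosis and `del_M` after; the change is a deliberate step at `E_Hj`
rather than an interpolation, since isomorphy visibly breaks at settlement
anyway.  Respiration is reported as a relative proxy (weighted dissipating
powers; absolute O2 calibration is out of scope), and clearance rate as
`F_m * s_M * V^(2/3) * TC` per gram dry weight.

# Life-cycle events

**Initial reserve.** The egg cost `E_0` solves the classical initial-value
problem: an embryo starting from `(E_0, V ~ 0, E_H = 0)` without feeding
must reach `E_Hb` with scaled reserve density `e_b` (default 1).  It is
found by bracketing and Brent root finding on `E_0` with the embryo ODE as
inner solver, started from `V_0 = 1e-12 cm^3` (small enough that the
implied age offset is ~1e-3 d).

**Brooding.** Flat oysters incubate larvae in the mantle cavity; during
brooding the feeding level is multiplied by 0.8.  The default brooding
duration is the time for a brooded embryo to develop from fertilisation to
the release threshold `E_Hr` at the ambient temperature; a fixed-duration
mode is available.

**Spawning.** The trigger is deliberately simple and fully configurable: on
a daily check, an adult spawns when the buffer density `E_R/V` exceeds 5%
of the maximum reserve capacity `E_m` and the temperature is at or above
15 degrees C, with a 30-day refractory period.  A spawning event releases
`kap_R * E_R` (0.45 for the flat oyster, the even egg/sperm split
convention for a sequential hermaphrodite), converts it to an egg count via
`E_0`, and for the flat oyster starts brooding.  The 5% threshold is about
half of the buffer density an adult accumulates over one growing season in
a typical seasonal forcing, which places spawning inside the warm season;
it is a stated default, not a fitted quantity.

**Starvation.** When `kap*p_C < p_S` the somatic shortfall is paid first
from the reproduction buffer, then by shrinking structure at `E_G` per
cm^3; an unpayable maturity-maintenance deficit (empty buffer) is likewise
paid from structure rather than by rejuvenation, which keeps the energy
budget closed under starvation.  The individual dies when the scaled
reserve density falls below 1e-4.  The rule is not printed in the source
material; this is standard DEB practice and is required for zero-food
scenarios.

**Ageing.** The Weibull--Gompertz pair (`h_a`, `s_g`) is integrated
alongside the energetics (one-way coupling), giving a survival probability
`S(t)`; the expected lifespan is `integral of S dt`.  Deterministic
survival bookkeeping is the default; no random death draws are used
anywhere in the package.

# Numerics

No ODE-solver package is available in the supported environment, so the
package carries its own integrator: an embedded Cash--Karp 4(5)
Runge--Kutta pair with proportional step control (rtol 1e-8, atol scaled
from the initial state), cubic-Hermite dense output on the requested grid,
and event localisation by bisection on the interpolant to 1e-6 d.
Maturity thresholds, starvation death and survival floors are events; the
simulator integrates phase-by-phase so the acceleration factor is exact
within each phase.  Under time-varying forcing the step is capped at 1 day
because the forcing is piecewise linear between daily records.  A
fixed-step Euler oracle (dt = 1e-3 d) is kept in the test suite as an
independent check; the two agree to better than 1e-3 relative over 30-day
windows, and long constant-condition runs match the von Bertalanffy closed
form to much better than 0.5% of the asymptotic length.

The hot inner loop uses a closure-compiled right-hand side with all
parameter lookups hoisted out; the documented `state_derivatives()` is the
reference implementation and the test suite asserts exact agreement
between the two on random states.

`init_from_weight()` inverts the (linear) weight model for structural
volume by safeguarded root finding under the field-initialisation
convention: fit animals (`e = 0.8`), empty buffer, full maturity.

# Estimation

The loss is the printed weighted root-mean-square relative error

    MRE = sqrt( sum_ij beta_ij ((Y_ij - Yhat_ij)/Y_ij)^2 / sum_ij beta_ij ),

with each zero-variate trait counting as one dataset; the default weights
are 1 per trait and `1/m` per point of an `m`-point series, so datasets
rather than points are the weighting unit.  An Add-my-Pet-style symmetric
variant is available behind a switch for cross-checking against parameter
sets estimated under that convention.

Minimisation uses a Nelder--Mead simplex written in the package (standard
coefficients 1, 2, 0.5, 0.5; convergence when the simplex value spread
drops below 1e-6; up to 3 restarts from the best vertex), with free
parameters in log10 space and fractions (`kap`, `kap_X`, ...) in logit
space so constraints hold by construction.  The engine is cross-checked
against `stats::optim`'s independent implementation on a standard test
function.  `calibrate_KX()` is a one-dimensional Brent minimisation of the
same loss over `K_X`, requiring chlorophyll-mode food in every dataset.

**Identifiability.** Growth (weight and length) series at two rations plus
size traits constrain `kap*p_Am/p_M` (asymptotic size), `p_M/E_G` (growth
rate) and `p_Am/v` (reserve capacity), but leave the `kap` direction weak
when `kap` is close to 1: with 5% multiplicative noise, recovered `kap`
can drift ~20% along a `kap`--`p_Am`--`p_M` ridge while the loss sits at
its noise floor.  Adding one reproduction-linked observable (ultimate
reproduction rate or fecundity-versus-length) breaks the ridge, because
reproductive output is proportional to `1 - kap`; the packaged recovery
experiments therefore include it, mirroring the role reproduction datasets
play in the original estimation.  This is the main non-identifiable
combination found; it is a property of the data design, not of the
optimiser.

# Synthetic data

The generator produces exactly the structures the estimation consumes:
constant or sinusoidal seasonal forcing; growth series simulated from a
known parameter set under a stated initial condition; trait tables from
the same dispatch used for prediction.  Observation noise is
multiplicative lognormal (`Y = true * exp(eps)`, `eps ~ N(0, sigma^2)`),
chosen because all observables are positive and the loss is relative, so
the noise is scale-free; all randomness flows from one integer seed and
the global RNG state is restored after generation.  The packaged "lab"
preset replicates the constant-condition experimental design (3, 8, 15,
20, 25, 30 degrees C crossed with 2 and 10 micrograms chl a per litre, 42
days, weekly observations, ~0.9 g spat); the "seasonal" preset is a
two-year sinusoidal aquaculture scenario.

A green closed-loop test (generate, perturb, re-estimate, recover)
establishes that the pipeline is self-consistent and that the stated
parameter subset is identifiable from the stated design at the stated
noise level.  It does not establish that field data of the same shape
would identify the parameters: real forcing is not sinusoidal, real noise
is not lognormal i.i.d., and food proxies confound chlorophyll with other
drivers of feeding.

# Design choices on genuinely open points

**Reference state of `{p_Am}`.** The printed parameter table is internally
inconsistent at the second decimal: the zoom factor, `{p_Am}`, `kap` and
`[p_M]` do not satisfy `z = kap*{p_Am}/[p_M]` under either the
pre-acceleration or post-acceleration reading of `{p_Am}`.  The package
stores `{p_Am}` as the pre-acceleration value and multiplies it by `s(t)`,
which is the reading consistent with the published flux convention for
accelerating models.  Under this reading the package reproduces the
reported early-life predictions essentially exactly (length at birth
0.0192 vs 0.0190 cm, at release 0.0200 vs 0.0200 cm, at settlement 0.0384
vs 0.0387 cm, emergent `s_M` 5.98 vs 5.9) and the lifespan within 18%,
while adult-scale predictions (weight at puberty, ultimate size and
reproduction) overshoot the reported values far beyond their printed
uncertainty -- consistent with those having been produced under a smaller
effective `{p_Am}`/zoom combination than the table prints.  The zoom
factor is therefore treated as derived, never asserted, and the
life-history comparison at adult scale is documented rather than gated.

**Other defaults.** Coupled Arrhenius correction across all fluxes
(decoupled variant available); step change of the shape coefficient at
`E_Hj`; spawning trigger and brooding duration as above; `kap_R` applied
as the emptied buffer fraction at spawning, exactly as stated, rather than
as a continuous conversion efficiency; observation-day matching to the
nearest simulated grid point within 0.5 d.

# Known limitations

* The standard-model Pacific oyster set (no maturity thresholds) supports
  post-metamorphic simulation only; embryo and larval operations refuse it.
* Respiration and clearance are relative proxies with configurable
  coefficients; no absolute metabolic calibration is attempted.
* Salinity, turbidity, current, fouling and air exposure do not enter the
  functional response; chlorophyll is the only food proxy.
* Adult-scale life-history traits inherit the printed-table inconsistency
  discussed above; simulations initialised from measured weights (the
  validation pathway) are unaffected by it over seasonal horizons.
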