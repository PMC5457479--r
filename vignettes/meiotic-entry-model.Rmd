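---
title: "A bistable switch model of meiotic entry in mouse oocytes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{A bistable switch model of meiotic entry in mouse oocytes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(meioswitch)
```

## The biological problem

Fully grown mouse oocytes rest for weeks to months in prophase I with an
intact nucleus (the germinal vesicle, GV). Resumption of meiosis — germinal
vesicle breakdown, GVBD — requires activation of the M-phase kinase, the
cyclin B:Cdk1 complex. Two brakes hold Cdk1 down during arrest:

* **APC/C^Cdh1^** (the anaphase-promoting complex loaded with its activator
  Cdh1) continuously degrades cyclin B, and also degrades the activating
  phosphatase Cdc25B;
* **inhibitory phosphorylation** of Cdk1 by the kinase Wee1B, reversed by
  Cdc25B.

Cdk1 in turn inhibits both brakes: it phosphorylates and inactivates Cdh1
and Wee1B, and it activates Cdc25B. These positive and double-negative
feedback loops make the network a classic bistable switch. `meioswitch`
implements the resulting deterministic ODE model and the analyses built on
it: time-course simulation, full steady-state enumeration with stability,
the two-dimensional phase-plane reduction, knockout scenarios, and a
synthetic kinase-assay pipeline with parameter recovery.

## The model

Six dynamic variables (all concentrations dimensionless, time in minutes):
total cyclin B `CycBT`, active cyclin B:Cdk1 `Cdk1`, active APC/C-Cdh1
`Cdh1`, total Cdc25B `Cdc25T`, active phosphorylated Cdc25B `Cdc25p`, and
active Wee1B `Wee1`. Four algebraic conservation relations define the
inactive pools: `Cdc25 = Cdc25T − Cdc25p`, `Wee1p = Wee1T − Wee1`,
`Cdk1p = CycBT − Cdk1`, `Cdh1p = Cdh1T − Cdh1`.

The right-hand sides (see `?modelDerivatives` for the full display)
combine mass-action synthesis/degradation for cyclin B and Cdc25B — with a
Cdh1-dependent degradation channel in both — with Michaelis–Menten
(in)activation cycles for Cdh1, Wee1B and Cdc25B and a two-channel
activation/inactivation flux for Cdk1 in which both the active and the
inactive forms of Cdc25B and Wee1B retain basal activity
(`Va1CDK`/`Vi1CDK` for the weak forms, `Va2CDK`/`Vi2CDK` for the strong
forms).

The default parameter set (`meioParams()`) describes wild-type GV arrest.
Two conventions matter:

* **Units.** All rate constants are per minute; Michaelis constants and
  totals are dimensionless concentrations (the totals `Cdh1T`, `Wee1T` are
  normalised to 1 in the wild type). Units are documented, not enforced by
  a unit system.
* **Immutability.** Parameter sets are value objects; `applyGvbdTrigger()`
  and `applyKnockout()` return modified copies, so scenario comparisons
  can never be contaminated by shared state.

### Triggering GVBD and knockouts

Meiotic resumption is modelled purely as a parameter switch: loss of PKA
activity weakens the phosphorylation brake, implemented as `VaWee` (Wee1B
activation) and `Vi25` (Cdc25B inactivation) dropping to 20% of their
resting values (both 0.375 → 0.075 per minute). The state is continuous
across the switch; the triggered run simply starts from the arrest state
under the new parameters.

Knockouts retain residual activity rather than vanishing, reflecting
incomplete depletion in conditional knockout oocytes. They are encoded as
fixed overrides, not a uniform percentage: total Cdh1 drops to `Cdh1T =
0.05` (5% of wild type) while the Cdc25B synthesis rate drops to `ksc25 =
0.0003` (2% of wild type). The double knockout composes both overrides
with no renormalisation. Knockout scenarios are always run *triggered*
(knockout oocytes are observed after release from arrest); use
`scenarioParams(name, triggered = FALSE)` for the resting variant.

A design choice worth flagging: knockout simulations do **not** start from
the wild-type arrest state. With `Cdh1T = 0.05` the wild-type value `Cdh1
= 0.9759` is not even an admissible state. Each scenario instead starts
from the arrest steady state of its own untriggered parameter set
(`arrestState()`), which is the state a pre-GVBD knockout oocyte would
actually occupy. All four untriggered scenario parameter sets possess such
a state: even the Cdh1 knockout arrests before triggering, because the
Wee1B/Cdc25B switch alone holds Cdk1 down while `VaWee` is high.

## The Goldbeter–Koshland switch and the 2-d reduction

The (in)activation cycles at steady state follow the zero-order
ultrasensitivity closed form: `goldbeterKoshland(Va, Vi, Ja, Ji)` returns
the unique root in [0, 1] of

$$V_a \frac{1-f}{J_a + 1 - f} = V_i \frac{f}{J_i + f}.$$

The quadratic is solved in product form, $f = 2 V_a J_i / (B + \sqrt{B^2 -
4 (V_i - V_a) V_a J_i})$ with $B = V_i - V_a + V_a J_i + V_i J_a$, which
avoids catastrophic cancellation for every sign of $V_i - V_a$ (the root
term always exceeds $-B$). The suite pins this against a plain bisection
oracle to 1e-10 across a six-decade log grid of rate ratios.

For phase-plane analysis the model is reduced to the two slow variables
(Cdk1, Cdh1) by placing the other four at pseudo-steady state
(`liftState()`): the totals follow synthesis/degradation balances
(`CycBT = ksCycB/(kd1CycB + kd2CycB·Cdh1)`, similarly `Cdc25T`), Wee1B is
a pure Goldbeter–Koshland balance, and Cdc25p is *not*: its balance
carries a degradation sink `(kd1c25 + kd2c25·Cdh1)·Cdc25p` on top of the
(in)activation cycle, so the closed form would be wrong. The lift solves
that scalar balance by bracketed root finding on [0, Cdc25T] (the residual
is strictly decreasing, so the root is unique); the closed form is used
only where it is exact.

* `cdh1Nullcline()` is single-valued and sigmoidal decreasing (a pure GK
  curve in Cdk1).
* `cdk1Nullcline()` is potentially S-shaped: for each Cdh1 the lifted Cdk1
  balance is scanned with 400 sign-change brackets over [0, CycBT(Cdh1)]
  and each bracket bisected; up to three roots per scan line, with branch
  labels assigned by nearest-neighbour continuity in Cdk1. Root
  enumeration per scan line was preferred over numerical continuation:
  at this dimension it is simpler, trivially parallel over the grid, and
  has no path-following failure modes. An even-multiplicity tangency
  (sign-preserving touch) would be missed by bracketing; in practice the
  fold points of this model are transversal on the default grids.
* `nullclineIntersections()` detects candidate crossings segment-pair-wise
  between the two polylines and polishes each with a damped 2-d Newton
  iteration on the reduced balance system, deduplicating at 1e-6.

Because the pseudo-steady-state assumptions are *exact* at equilibrium,
every intersection of the reduced model must coincide with a full-system
steady state. The suite enforces agreement to 1e-6 in (Cdk1, Cdh1) for
the wild-type, triggered and both knockout parameter sets — a strong
cross-validation between two independently implemented code paths.

## Steady states and stability

`findSteadyStates()` enumerates equilibria of the full six-variable system
by multi-start damped Newton iteration. Seeds are a 15×15 grid over Cdk1 ∈
[0, 1.2] × Cdh1 ∈ [0, Cdh1T], lifted to full states; the search region is
bounded because cyclin totals self-limit near `ksCycB/kd1CycB = 1`. The
Newton iterates are confined to a box that keeps the small Michaelis
denominators (`Jwee = J25 = 0.01`) away from their poles, with a halving
line search for global behaviour. Converged roots are kept if admissible
(within bounds at 1e-6 slack), deduplicated at 1e-6 per component, and
polished to residual infinity-norm < 1e-9. The steady-state count is
invariant to the grid density from 15×15 upward (tested at 21×21).

Stability comes from the eigenvalues of a central finite-difference
Jacobian (step `1e-7·max(1, |x|)`, checked in the suite against an
independent numerical differentiator): all real parts < −1e-8 is stable,
any real part > 1e-8 is unstable, and anything within ±1e-8 of the axis is
reported as `"marginal"` rather than silently classified — the honest
answer near a saddle-node.

Under wild-type parameters the system has exactly three steady states: a
stable high-Cdh1/low-Cdk1 arrest state (which reproduces the tabulated
resting values to four significant figures), a stable low-Cdh1/high-Cdk1
prometaphase state, and an intermediate saddle that acts as the barrier
between them. Applying the GVBD trigger removes the arrest state and the
saddle in a saddle-node bifurcation, leaving the prometaphase state as the
only attractor — arrest is lost irreversibly, not by being pushed over a
barrier. The package deliberately does not trace the bifurcation diagram
(no continuation); only the before/after steady-state structure is
computed.

## Simulation and scenario metrics

`simulateModel()` integrates with `deSolve`'s `lsoda` (adaptive,
stiff-capable) at `rtol = 1e-8`, `atol = 1e-10`; the output step (default
1 min over a 480-min horizon) is purely a reporting grid. Halving the
tolerances moves the triggered endpoint by < 1e-6 per component.
Round-off excursions outside the state bounds are clipped at the bound
when below 1e-6 and abort the run otherwise, protecting the
Michaelis denominators from spurious negative pools.

Scenario summaries (`runScenario()`) need event definitions, and the model
itself defines no numeric event for GVBD, so the package fixes two
conventions (both configurable):

* **commitment time** — first time Cdh1 falls below `0.5·Cdh1T`;
* **Cdk1 rise time** — time from 10% to 90% of the final Cdk1 value.

Both are computed with linear interpolation between output samples and are
stable to within the output step under step halving. With these
definitions the triggered wild type shows the model's signature two-phase
activation: a fast partial Cdk1 rise as the phosphorylation brake weakens,
then a long slow burn while Cdh1 is gradually worn down and cyclin B
accumulates, with commitment preceding 90% activation by a wide margin.
The Cdh1 knockout activates an order of magnitude faster (mitosis-like),
and adding the Cdc25B knockout on top delays commitment again — the
epistasis seen in the corresponding oocyte experiments.

## The synthetic kinase assay and parameter recovery

`sampleKinaseAssay()` emulates a sparse radiometric histone-H1 kinase
readout of Cdk1 activity. The default schedule is four samples — one
during arrest, one at the trigger, and 20 and 40 minutes after — encoded
as times `c(-30, 0, 20, 40)` relative to the trigger; negative times read
the arrested (stationary) value. Readouts are `scale·Cdk1(t)·(1 + ε)`
with ε zero-mean Gaussian of standard deviation `noiseSd`: multiplicative
noise is the natural first model for densitometry of autoradiographs,
whose errors scale with band intensity. An additive mode is available
behind a flag. All randomness flows from one explicit seed and the
caller's RNG state is restored afterwards.

What the generator does **not** emulate: film/phosphor saturation and
background subtraction, lysate-to-lysate loading variability, biological
asynchrony in GVBD timing between oocytes, and any uncertainty in mapping
assay time points onto model time. Passing recovery tests therefore show
that the *pipeline* is consistent and informative under the stated noise
model — not that real gel data would constrain the parameters equally
well.

`fitParameters()` recovers one or two free parameters by least squares.
The free set is restricted to `{Cdh1T, kd2CycB, ViCdh1, ksc25}`, chosen by
a sensitivity screen on the triggered Cdk1 time course: each of these
shifts the curve in a distinct, monotone way (plateau level and commitment
delay for `Cdh1T` and `kd2CycB`; commitment timing for `ViCdh1`; rise
sharpness for `ksc25`), whereas the switch Michaelis constants and the
paired (in)activation rates are practically unidentifiable from a single
Cdk1 readout. Joint fits of more than two parameters are refused. The
candidate-to-trajectory map is identical to the generator's (arrest of the
candidate set, then the triggered run), the objective is minimised over
log-parameters with `L-BFGS-B` inside positive bounds (default: two
decades around wild type), multi-started from seeded log-uniform draws.

The suite demonstrates: exact (≤ 1% error) recovery from dense noiseless
observations (every 5 min to 240 min); median error well inside 20% at 5%
multiplicative noise over 20 seeds; error decreasing monotonically with
noise over {0.2, 0.1, 0.05, 0} (paired seeds); and the four-point assay
design measurably weaker than the dense design at equal noise — a
pipeline finding about experimental design, not a claim about the assay
data themselves.

## Problem sizes and runtime choices

The analyses are sized so the whole test suite runs in a few minutes on
one core: steady-state searches use 15×15 seed grids (structure verified
unchanged at 21×21); nullclines use 161 Cdh1 scan lines × 400 brackets;
recovery studies use 20 seeds for the headline noise level and 7 paired
seeds for the monotonicity and design comparisons, with 2–3 optimizer
starts (the 1-d log-parameter loss surfaces are unimodal in practice;
extra starts guard against boundary stalls).

## Known limitations

* The model has no APC/C^Cdc20^ branch, so there is no exit from
  prometaphase, no anaphase, and no re-arrest: the prometaphase attractor
  is terminal.
* Deterministic only — no stochastic (Gillespie) variant; cell-to-cell
  variability enters solely through the synthetic measurement noise.
* No spatial compartments; "concentrations" are whole-oocyte activities.
* Knockout overrides are the fixed constants above; the package does not
  attempt to infer true residual activities.
* Saddle-node locations are not computed; only steady-state structure at
  the named parameter sets is reported.
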