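---
title: "Models and numerics behind pulmflow"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and numerics behind pulmflow}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

`pulmflow` simulates pulmonary arterial hemodynamics with a geometric
multiscale architecture: a closed-loop lumped-parameter (0D) circulation
model, three partitioned algorithms that couple an *open* variant of that
circuit to a distributed ("3D") model of the pulmonary arteries, an RLC
surrogate standing in for the 3D block, and an optional stabilized
finite-element solver on an idealized tube. This vignette records the
model equations, the parameter choices and their rationale, the numerical
decisions, and what the shipped verification does and does not establish.

## The closed-loop 0D circulation

Blood flow in the circuit analogy identifies pressure with voltage and
flow rate with current; resistances model viscous losses, capacitors wall
compliance, inductors blood inertia. Working units are mmHg, ml and s
throughout the 0D side (1 mmHg = 133.322 Pa at the finite-element bridge
only).

The loop is: right atrium → tricuspid valve → right ventricle → pulmonary
valve → proximal pulmonary-artery compartment (`R_IN, L_IN, C_IN`) →
pulmonary-artery block (`R_PA, L_PA, C_PA`; present in the closed loop
only — this is the block the distributed model replaces) →
microvasculature and lungs (`R_OUT, L_OUT, C_OUT`) → pulmonary veins →
left atrium → mitral valve → left ventricle → aortic valve → systemic
arteries → systemic veins → right atrium. Each chamber obeys the
elastance law `P = (E_a r(t) + E_b)(V − V_0)` with the piecewise-cosine
activation `r(t)` (contraction ramp up over `T_contr`, relaxation ramp
down over `T_relax`, zero afterwards); each valve is a smoothed diode
whose resistance interpolates between `R_min` and `R_max` on a log scale
via an arctangent of the pressure difference with slope `200π/2` per mmHg.
The state vector holds 4 chamber volumes, 6 capacitor pressures and 6
inductor flows (closed variant); the algebraic vector holds chamber
pressures, valve resistances and valve flows, all explicit functions of
`(t, y)`, so the system is a semi-explicit index-1 DAE integrated by
explicit schemes with the algebraic closure re-evaluated at every stage.

Total stored volume (chamber volumes plus `C·P` over all capacitors) is a
conserved quantity of the continuous closed loop — the per-equation sum
telescopes — and is the primary discretization diagnostic: the shipped
RK4 run at `dt = 1e-3` s drifts below 1e-6 relative over three beats.

### Parameters, gap-fills and one printed-value correction

The R/L/C/elastance values and the heartbeat period (0.8 s) are the
published calibration of this circulation model, shipped both as code
defaults and as `inst/extdata/params_healthy.yaml`. Three quantities the
publication leaves unstated are set here and are configurable:

* **Unstressed volumes** `V_0` = 10 (RA), 30 (RV), 10 (LA), 15 (LV) ml.
* **Activation timing**: ventricles activate at cycle time 0, atria at
  0.65 s (late diastole, the atrial kick).
* **Initial state** `y_0`: the shipped values are cycle-start states on
  the healthy and hypertensive limit cycles, frozen from long runs, so a
  three-beat simulation is periodic from the first beat and beat-3 metrics
  represent the regime state. Each scenario gets its own warm start
  because the inter-scenario blood-volume redistribution (systemic venous
  compliance 60 ml/mmHg) takes tens of beats — far longer than the
  three-beat reporting convention.

One printed parameter is corrected: the open-valve resistance. The quoted
table gives `R_min = 75e-3` mmHg·s/ml for all four valves, but with that
value the loop is valve-limited to a flow-to-pressure ratio of ~3.7
(ml/s)/mmHg at the pulmonary inlet, and no blood volume reaches the
published operating point (111 ml/s at 16.4 mmHg, ratio 6.8). With
`R_min = 7.5e-3` — the value used by the source circulation model this
parameter set descends from — the simulated ratio is 6.8 and the full
published healthy row lands on target under volume calibration alone. The
package therefore ships `R_min = 7.5e-3`, reading the printed value as a
misprint of the same kind as the quoted blood viscosity (3.5e3 Pa·s,
adopted here as the physiological 3.5e-3).

Calibration itself had a single free knob — total blood volume, applied
through the warm-start systemic venous pressure — chosen once so that the
beat-averaged healthy metrics sit inside the published physiological
windows, then frozen. Nothing else was tuned.

## Partitioned coupling

The open circuit exposes four interface quantities per step: it provides
the inlet flow `Q_IN` and outlet pressure `P_OUT`, and receives the inlet
pressure `P_IN` and outlet flow `Q_OUT` from the distributed model.

* **Splitting-explicit (SE)**: per step, the distributed model advances
  with the previous exchange `(Q_IN^n, P_OUT^n)`, then the 0D advances
  with the response `(P_IN^{n+1}, Q_OUT^{n+1})` as frozen forcings. One
  exchange per step makes the interface coupling explicit: first-order in
  `dt` (halving `dt` about halves the gap to the monolithic reference)
  and conditionally stable — the surrogate-coupled loop runs at
  `dt = 1e-3` s but blows up at `2e-3` s.
* **Splitting-implicit (SI)**: both subsystems restart from step-`n`
  checkpoints and iterate until the relative change of all four interface
  variables drops below `ε` (default 1e-3). The stopping norm is
  `max_i |x_i^{(k)} − x_i^{(k−1)}| / max(|x_i^{(k)}|, 1e-8)` — scale-free
  and robust at near-zero flows (the floor is in native units). With the
  surrogate the fixed-point map contracts with ratio ~0.8, so the
  converged iterate sits within a small multiple of `ε` of the step's
  fixed point (asserted at 5ε in the acceptance suite). No relaxation is
  applied by default; an under-relaxation factor is exposed.
* **One-way**: the closed loop is solved offline and its `Q_IN(t)`,
  `P_OUT(t)` drive the distributed model with no feedback.

The **bridging-region rule** explains the stability dichotomy: an
interface that receives a pressure needs an inductor as the adjacent 0D
element (so the exchanged flow is a state), and one that receives a flow
needs a capacitor (so the exchanged pressure is a state). "Setting 1"
(pulmonary valve coupled directly to the inlet) violates the rule at the
inlet — the valve flow is algebraic, and the explicit exchange through the
tiny surrogate capacitance has a per-step gain far above one — and the
run is flagged unstable within the first few steps; "setting 2" (proximal
compartment at the inlet) satisfies it and runs indefinitely.
`check_bridging()` performs the static check; the instability monitor
(caps 500 mmHg / 5000 ml/s, non-finite always fatal) provides the dynamic
verdict and halts runs gracefully with a partial record.

The RLC surrogate uses the closed loop's own PA block and the same RK4
integrator, so a partitioned run differs from the monolithic closed loop
by splitting error only — the basis of the convergence checks. Its
checkpoint/restore is an exact state snapshot, making subiterations
bitwise re-entrant.

## Time integration

RK4 is the default for all 0D production runs; explicit Euler is provided
and used in the SE-vs-SI comparison context. The PA block is the stiff
element (resonance `1/sqrt(L_PA C_PA) = 1000` rad/s): at `dt = 1e-3`
(`ω dt = 1`) RK4 is inside its stability region but outside its asymptotic
range, so the convergence-order tests run at `dt ≤ 2e-4`; explicit Euler
has no imaginary-axis stability and its order test runs on the open
circuit, where the fastest scale is ~50 rad/s. These are properties of
the steppers on this model, not tuning.

## The finite-element tube

The distributed model of record is an incompressible Navier–Stokes solver
on an idealized rigid straight tube (default radius 1.2 cm, roughly the
main pulmonary artery; the patient-specific anatomy is out of scope).
Discretization: Q1–Q1 hexahedra; implicit Euler in time with semi-implicit
(lagged) convection; SUPG/PSPG stabilization with the element-wise
parameter `τ = [(2ρ/Δt)² + (2ρ|u|/h_K)² + (12μ/h_K²)²]^{-1/2}`
(`h_K = V_K^{1/3}`; the second-derivative term of the residual is dropped,
as usual for trilinear elements); a backflow term
`β(ρ/2)|(uⁿ·n)_-| u^{n+1}·v` on the outlet (`β = 1`), exactly zero
wherever the lagged flow leaves the domain; do-nothing outlet traction
`T n = −P_OUT n`; strong parabolic inflow carrying `Q_IN` (the nodal
parabola is rescaled so its discrete flux equals `Q_IN` exactly); no-slip
walls. All unit conversions live in the adapter.

The mesh is a butterfly (O-grid) cross-section — a central square block
plus a structured ring whose outer nodes lie exactly on the circle —
extruded axially. A single-block square-to-disk map was tried first and
rejected: its four corner cells have three wall nodes each and misrepresent
the wall-normal gradient so badly that even the exact parabolic
interpolant evaluates ~20% low in mean wall shear stress. The O-grid gives
every wall cell a clean radial layering, which also enables wall-gradient
recovery: the wall traction uses `1.5 g_wall − 0.5 g_inner` (gradients in
the wall cell and its one-layer-inward neighbour), exact for a parabolic
profile; at `h = R/8` the recovered mean WSS sits within a fraction of a
percent of `4μQ/(πR³)`.

The linear system is solved exactly per step by a dense block-Thomas
sweep over axial node layers — the extruded mesh couples adjacent layers
only, so the matrix is block tridiagonal in that grouping. A direct solve
meets any iterative-residual requirement by construction and runs an
order of magnitude faster here than generic sparse LU.

Two numerical artifacts are worth knowing. First, the strong Dirichlet
inlet leaves a one-layer pressure plateau, so the inlet-to-outlet mean
pressure drop carries an error of roughly one axial layer's worth; the
quantitative Poiseuille check uses a tube of length 4R so this stays well
below the 5% band. Second, the Q1–Q1 pressure exhibits a mild even–odd
layer oscillation around the correct slope, a familiar trait of
PSPG-stabilized equal-order pairs.

## Verification scope and problem sizes

The shipped checks run at desk scale: 0D runs of three 0.8-s beats at
`dt = 1e-3` (2400 steps), coupling studies of one beat at
`dt ∈ [2.5e-4, 1e-3]`, and steady Poiseuille solves at `h = R/8` on a
radius-5-mm, length-20-mm tube (≈14k unknowns, three Picard iterations).
The quantitative targets are 0D-level: beat-averaged pressures, flows and
volumes of the healthy and hypertensive scenarios, where the closed-loop
model is itself an accurate surrogate of the full 3D–0D system's mean
quantities. The finite-element block is verified against analytic limits
(Poiseuille drop, WSS, mass balance, hydrostatic traction), not against
patient-specific 3D fields — passing these tests says the numerics are
right on the idealized geometry, not that the tube reproduces anatomical
flow patterns, secondary flows or WSS maps.

Known limitations, recorded deliberately:

* The hypertensive scenario's mean inlet pressure rise is
  `Q · ΔR_OUT ≈ 9` mmHg here versus ~11 mmHg published; the printed values
  imply a left-atrial pressure *rise* under distal resistance increase,
  which a fixed-volume closed loop of this topology cannot produce. The
  simulated value sits just inside the 10% band.
* Richardson extrapolation treats the printed formulas as normative. With
  rounded published inputs (mesh sizes 0.4/0.7/1.1 mm, nominal ratio 1.6,
  passed explicitly as `r`) the computed relative discrepancies are ~0.2,
  0.4 and 0.7% — not the published 4.9/2.9/1.8%, which are unreproducible
  from the rounded indices; none of those are asserted anywhere.
* The SE stability bound on `dt` is demonstrated empirically (stable at
  1e-3 s, unstable at 2e-3 s with the surrogate) but not derived.
* Rigid walls, a single downstream pressure for all outlets, no
  fluid-structure interaction, no patient geometry, straight tube only.
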