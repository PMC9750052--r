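# pulmflow

Geometric multiscale simulation of pulmonary arterial hemodynamics in R.

`pulmflow` couples a **closed-loop lumped-parameter (0D) model** of the
human circulation — four heart chambers with time-varying elastances, four
smoothed-diode valves, six RLC vascular compartments — to a pluggable
**distributed ("3D") model** of the pulmonary arteries through three
partitioned coupling algorithms: *splitting-explicit* (one exchange per
time step), *splitting-implicit* (fixed-point subiterations to interface
convergence) and *one-way* (the closed loop solved offline drives the
distributed model with no feedback). Two distributed models ship with the
package: an RLC pulmonary-artery surrogate (fast, and the basis of exact
consistency checks against the monolithic closed loop) and a stabilized
Q1–Q1 finite-element solver for incompressible flow in an idealized rigid
tube (SUPG/PSPG stabilization, outlet backflow dissipation, defective
boundary conditions, wall-shear-stress post-processing).

It is aimed at computational-hemodynamics practitioners who want a
desk-scale, fully scriptable testbed for 3D–0D coupling questions —
which circuit topologies destabilize explicit partitioning, how splitting
error decays with the time step, what a distal-resistance increase does to
right-heart loads — without an HPC finite-element stack.

## The model

Chamber pressure follows the time-varying elastance law
`P = E(t) (V − V₀)` with `E(t) = E_a r(t) + E_b`, where `r(t)` is a
piecewise-cosine activation ramp over the contraction and relaxation
phases of the heartbeat. Valves are non-ideal diodes whose resistance
interpolates between open (`R_min`) and closed (`R_max`) values on a log
scale, smoothly switched by the transvalvular pressure difference through
an arctangent:

    R = 10^c,  c = log₁₀R_min + (log₁₀R_max − log₁₀R_min) · [1/2 + arctan(100π (P₂−P₁))/π]

Each vascular compartment contributes a capacitor equation
`C dP/dt = Q_in − Q_out` and an inductor equation
`L dQ/dt = −R Q − ΔP`. The closed loop conserves total stored volume
exactly; the open variants expose an inlet (provides flow, receives
pressure) and an outlet (provides pressure, receives flow) for the
distributed model. The *bridging-region rule* — a pressure-receiving
interface needs an adjacent inductor, a flow-receiving interface an
adjacent capacitor — is checked statically by `check_bridging()` and
demonstrated dynamically: coupling the valve directly to the interface
("setting 1") blows up within the first heartbeat, while the proximal
RLC compartment ("setting 2") is stable.

## Worked example

```r
library(pulmflow)

run <- run_closed0d(scenario("healthy"), dt = 1e-3, beats = 3)
cycle_metrics(run, beat = 3)
#>   beat Q_IN_mean P_IN_mean P_RV_mean   EDV  ESV   SV P_IN_min P_IN_max ...
#> 1    3     109.2      16.1      14.5 162.9 75.5 87.4     13.1     20.5
```

Beat 3 of the healthy closed loop delivers a cardiac output of 109 ml/s
at a mean pulmonary-artery inlet pressure of 16.1 mmHg (pulse 13.1–20.5),
an end-diastolic right-ventricular volume of 163 ml and a stroke volume of
87 ml — a normal right heart. Quintupling the distal (microvasculature)
resistance produces the hypertensive case:

```r
pah <- run_closed0d(scenario("pah"), dt = 1e-3, beats = 3)
cycle_metrics(pah, beat = 3)
#>   beat Q_IN_mean P_IN_mean P_RV_mean   EDV  ESV   SV P_IN_min P_IN_max ...
#> 1    3     105.2      25.3      17.6 173.4 89.2 84.1     19.8     30.8
```

Mean inlet pressure rises from 16.1 to 25.3 mmHg (systolic peak
30.8 mmHg), the ventricle dilates (EDV 163 → 173 ml) and the stroke volume
falls slightly — the classic pressure-overload picture. The two
pressure-volume loops overlay with

```r
plot_pv_loops(healthy = pv_loop(run, 3), pah = pv_loop(pah, 3))
```

(the healthy loop encloses 1832 mmHg·ml of stroke work, the hypertensive
one 2367 mmHg·ml).

A partitioned 3D–0D run against the shipped surrogate, and the static
stability check:

```r
p  <- circulation_params()
dm <- pa_surrogate(p$compartments$pa)
cpl <- run_coupled(dm, p, setting = 2, algorithm = "si", dt = 1e-3, beats = 3)
cpl$mean_k                      # mean subiterations per step
check_bridging(circuit_topology("open_setting1", p))  # FAIL at the inlet
```

The finite-element tube stands in for the surrogate via
`fem_tube_model(tube_geometry(radius, length, h))`; the same
`run_coupled()` call drives it. A command-line wrapper over these
functions is installed at `system.file("cli", "pulmflow.R", package =
"pulmflow")` with subcommands `run0d`, `couple`, `richardson`, `metrics`,
`pvloop` and `femtube`.

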