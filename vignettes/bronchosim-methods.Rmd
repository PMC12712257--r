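---
title: "Modelling ventilation impairments during bronchoscopy"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modelling ventilation impairments during bronchoscopy}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(bronchosim)
```

## The problem

Inserting a flexible bronchoscope through an endotracheal tube (ETT) leaves
only an annular lumen for gas flow. Because tube resistance grows steeply as
the lumen narrows, bronchoscopy in a ventilated patient can produce two
distinct impairments: under volume-controlled (VC) ventilation the set tidal
volume is still delivered, but expiration becomes flow-limited and gas is
trapped breath after breath until the end-expiratory alveolar pressure —
intrinsic PEEP (iPEEP) — rises enough to drive the full volume back out;
under pressure-controlled (PC) ventilation inspiratory flow is limited too,
and the tidal volume falls instead. `bronchosim` quantifies both, and shows
how automatic tube compensation (ATC) removes them.

## Tube resistance model

The pressure drop across the tube is modelled by the Rohrer equation,
$\Delta p = k_1 \dot V + \mathrm{sign}(\dot V)\, k_2 (\dot V/\dot V_0)^2$,
with reference flow $\dot V_0 = 1$ L/s so that $k_1 + k_2$ is the secant
resistance at 1 L/s. Flow is positive toward the lung. $k_1$ is shared
between flow directions; $k_2$ may differ between inspiration and expiration
(`rohrer_model()` carries both), reflecting the compression–expansion
asymmetry where the tube tip meets the wider trachea. The diameter scaling
law (`scaling_law()`, `scaling_law_model()`) collapses all geometries to one
parameter, the effective diameter
$D_\mathrm{eff} = \sqrt{D_\mathrm{tube}^2 - D_\mathrm{scope}^2}$:

$$\Delta p = k_1 \left(\frac{D_\mathrm{eff}}{D_0}\right)^{\beta}
  \left(\dot V + \mathrm{sign}(\dot V)\, 4 \left(\frac{\dot V}{\dot V_0}\right)^2\right)$$

with defaults $k_1 = 0.72$ mbar, $D_0 = 10$ mm, and $\beta = -3.6$ for an
unobstructed tube versus $\beta = -5$ with a scope inserted. The $-3.6$
regime is shallower than the turbulent-flow expectation because the
unobstructed flow path includes diameter-insensitive losses (tracheal
transition, swivel connector) that are folded into the fitted exponent
rather than modelled separately; with a scope, wall friction in the
non-circular annulus dominates and the theoretical fifth-power scaling
reappears. The scaling law emits symmetric $k_2 = 4 k_1$ — the directional
difference does not vary systematically across geometries — while the
fitting path (`fit_rohrer()`) still estimates both, so bench asymmetry
remains measurable. One $k_1$ reference serves both regimes; the two differ
only in the exponent. Callers may override $\beta$ to study sensitivity.

## Ventilation simulator

The respiratory system is a passive single compartment: constant compliance
$C$ (default 50 ml/mbar), constant airway resistance $R_\mathrm{aw}$
(default 2 mbar·s/L) distal to the tube, muscular pressure fixed at zero
(sedated, non-triggering patient; the field exists for forward
compatibility but nothing varies it). Volume is tracked relative to the
elastic equilibrium at the set PEEP, so alveolar pressure is
$p_\mathrm{alv} = \mathrm{PEEP} + V/C$ and the instantaneous pressure
balance along the circuit is

$$p_\mathrm{vent} - \Delta p_\mathrm{ETT}(\dot V) - R_\mathrm{aw}\dot V
  - V/C - \mathrm{PEEP} = 0 .$$

Mode strategies supply the boundary condition per phase:

* **VC**: square inspiratory flow $V_T/T_\mathrm{in}$ (no end-inspiratory
  pause); the airway pressure is back-computed from the balance and not
  capped — a flow source — but samples exceeding `p_max` are counted and
  reported (`n_over_pmax`), since a real sensor or ventilator tops out
  (default 80 mbar). Expiration is passive into the PEEP source through the
  tube plus an optional linear valve resistance `r_valve` (default 0; no
  published value exists, so it is exposed as configuration — the reference
  PC result at a 7.5 mm lumen is insensitive to it).
* **PC**: constant $p_\mathrm{aw} = \mathrm{PEEP} + PS$ during inspiration
  (default $PS = 10$ mbar, ramp time 0; a linear ramp is available), passive
  expiration as in VC. No inspiratory demand-flow cap is applied.
* **ATC**: an ideal controller makes the *tracheal* pressure follow a
  triangular target — PEEP up to PEEP + 10 mbar over $T_\mathrm{in}$,
  linearly back down over $T_\mathrm{ex}$ — by delivering whatever airway
  pressure is required, including sub-atmospheric values during expiration
  (`allow_subatmospheric`, default on in ATC only). The only non-ideality
  retained is the delivery ceiling `p_max`: when the required pressure
  exceeds it, the airway pressure clamps and the flow is re-solved from the
  clamped balance. Controller dynamics, sensor noise and actuator lag are
  out of scope. ATC requires $R_\mathrm{aw} > 0$ (the ideal-controller flow
  $(p_\mathrm{target} - p_\mathrm{alv})/R_\mathrm{aw}$ is otherwise
  undefined).

Default timing is $T_\mathrm{in} = 1.8$ s, $T_\mathrm{ex} = 2.2$ s
(15 breaths/min), PEEP = 0, $V_T$ = 500 ml — the reference bench operating
point, so a bare `predict_ventilation()` call reproduces the headline
scenarios.

### Numerical scheme

The tube resistance is algebraic, so volume is the only state. Each phase is
integrated with a fixed step (`dt`, default 0.004 s, the 250 Hz hardware
update rate; each phase uses `round(duration/dt)` equal steps so arbitrary
rate and I:E grids stay exact). The step is an implicit trapezoid solved in
closed form: writing the new volume as
$V + 500\,\Delta t\,(\dot V_\mathrm{old} + \dot V_\mathrm{new})$ folds the
elastic term into an augmented series resistance
$r + 500\,\Delta t/C$, leaving the same sign-consistent quadratic that
`flow_from_driving_pressure()` solves exactly. Consequently the pressure
balance and the trapezoidal volume-continuity identity hold to machine
precision at every stored sample, and halving `dt` changes steady outcomes
by far less than 1 % (asserted in the suite at the narrowest bench lumen,
3.8 mm, under VC). Phase transitions are genuine flow discontinuities (no
inertance is modelled); the waveform stores a duplicated time sample at each
boundary — one sample per boundary condition — so integrals and continuity
checks never straddle the jump.

Runs start from the elastic equilibrium at PEEP with zero flow, first breath
inspiratory, giving a reproducible approach to steady state (iPEEP rises
monotonically from below). Steady state is declared when the end-expiratory
tracheal pressure changes by less than `steady_tol` (0.01 mbar) between
consecutive breaths, with a hard cap of 100 breaths and a `converged` flag.
iPEEP is reported primarily as the end-expiratory **tracheal** pressure —
the quantity a pressure line at the tube tip actually measures, and a close
proxy for alveolar pressure when end-expiratory flow and $R_\mathrm{aw}$
are small — with the alveolar value alongside.

## Synthetic bench data

`generate_sweep()` emulates the resistance bench: a blower ramps the driving
pressure 0 → +80 → 0 → −80 → 0 mbar (uniform in pressure, mirroring a
motor-speed ramp), the true flow follows the generating Rohrer model, and
both channels receive additive zero-mean Gaussian noise. 500 samples and a
pressure noise SD of 0.2 mbar are the default test conditions for noisy
fits. `generate_resistance_table()` perturbs scaling-law resistances over
the real tube–scope grid (`ett_scope_combinations()`) with multiplicative
log-normal noise; 10 % scatter matches the scoped regime's reported
describing error (≈10 %), and 2.4 % the unobstructed regime's. The noise
models are the simplest choices that exercise the fitters — the bench did
not publish a noise model. Generators are pure functions of their spec
(seeded via `withr::with_seed`, leaving the session RNG untouched).

What the generators deliberately do **not** emulate: sensor dynamics,
aliasing, the 25 Hz Bessel filtering of real recordings, secretions, or any
drift. Passing tests therefore demonstrate correctness of the fitting and
simulation machinery under the stated model class, not robustness to every
artefact of clinical signals.

## Fitting

`fit_rohrer()` is linear least squares in $(k_1, k_{2,insp}, k_{2,exp})$
with basis $\dot V$ and the direction-masked signed squares — closed-form
and deterministic. Non-negativity is enforced by clipping with a warning
rather than constrained optimisation; a clip signals data inconsistent with
the model class, not a silent fix. Rank deficiency (e.g. all flows equal)
is an error. `fit_power_law()` regresses $\log R$ on
$\log(D_\mathrm{eff}/D_0)$, matching the straight-line double-logarithmic
presentation of the bench data; whether the original fit was performed in
log space is not documented, but the log-space choice is reproducible and
scale-equivariant. Fits are unweighted; no subsampling of the ramp is
applied.

## Problem sizes

The test suite and acceptance script run the simulator at the default
0.004 s step; a breath is ~1000 samples, convergence takes 2 breaths at wide
lumens and ~30–40 breaths at 3.8 mm, so every scenario completes in well
under a minute on one core. Diameter sweeps use 8–9 grid points between 3.5
and 9 mm; Monte-Carlo checks of noisy fits use single fixed seeds with
tolerances frozen from 200-seed calibration runs.

## Known limitations

Single compartment, linear elastance, no airway closure or recruitment, no
secretions, no spontaneous effort or triggering, rigid trachea, clean tubes
(in-service tubes can be considerably more resistive). The scaling law is
validated for tube diameters 6.0–9.0 mm and scope shafts 3.8–5.9 mm;
extrapolation beyond that envelope (the CLI will happily compute a 1.1 mm
lumen) is exactly that. The ATC controller is ideal apart from its pressure
ceiling, so simulated ATC represents the best achievable compensation, not
a specific device.
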