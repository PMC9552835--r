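---
title: "Modelling coronary bypass graft haemodynamics with cabgflow"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modelling coronary bypass graft haemodynamics with cabgflow}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(cabgflow)
```

# The model

`cabgflow` simulates pulsatile blood flow in a network of one-dimensional
elastic vessel segments closed by zero-dimensional lumped-parameter outlets
— the multiscale description cardiovascular modellers call 1D-0D. The
purpose is surgical: given a patient-like coronary network with stenoses,
the solver predicts how alternative bypass-graft configurations perform, in
the same indices a surgeon reads off intraoperative transit-time flowmetry
(TTFM): mean graft flow (MGF), pulsatility index (PI), backflow percentage
(BF) and diastolic filling percentage (DF), plus the instantaneous wave-free
ratio (iFR) of each stenosis and regional myocardial perfusion.

## Governing equations

Each segment is a straight, thin-walled, elastic tube carrying an
incompressible Newtonian fluid (density $\rho = 1.06$ g/cm$^3$, viscosity
$\mu = 0.046$ dyn s/cm$^2$). Averaging the Navier–Stokes equations over the
cross-section gives, for area $A(x,t)$ and flow $Q(x,t)$,

$$\partial_t A + \partial_x Q = 0, \qquad
  \partial_t Q + \partial_x\!\left(\alpha \frac{Q^2}{A}\right)
  + \frac{A}{\rho}\,\partial_x P
  = -\frac{2\pi\nu\,\alpha}{\alpha - 1}\,\frac{Q}{A},$$

where $\alpha$ is the Coriolis (momentum-correction) coefficient fixing the
velocity-profile shape: 1.05 for the large systemic arteries (blunt
profiles) and 1.1 for coronary and small systemic vessels. The friction term
is the profile-consistent generalisation of Poiseuille drag; at
$\alpha = 4/3$ it reduces to the classical $8\mu L/\pi R^4$ resistance per
unit length.

The system is closed by an elastic tube law relating pressure to area,

$$P - P_{ext} = f\left(1 - \sqrt{A_0/A}\right) + P_0, \qquad
  f = \tfrac{4}{3}\left(k_1 e^{k_2 R_0} + k_3\right),$$

with empirical stiffness constants per wall class (coronary:
$k_1 = 20.0\times10^6$, $k_2 = -22.5$, $k_3 = 86.5\times10^4$; large
systemic: $3.0\times10^6$, $-9.0$, $33.7\times10^4$, CGS units). The
square-root form is the one consistent with both its closed-form inverse
(used at the Dirichlet inlet) and the Moens–Korteweg wave speed
$c_0 = \sqrt{f/2\rho}$; `wave_speed()` and `stiffness_f()` expose these.
Internal mammary and radial conduits use the coronary-like law — their
calibres and wall mechanics are closer to coronaries than to the aorta.

Radius is constant within a segment (step-wise taper): vessels narrow only
across junctions, which avoids the spurious reflections continuous tapers
can create and makes the pressure-gradient term expressible as an exact
conservative flux $\alpha Q^2/A + (f/\rho)\sqrt{A_0 A}$ with no geometric
source inside a segment.

## Discretisation

The interior of every segment is advanced with the Richtmyer two-step
Lax-Wendroff scheme, second-order in space and time: a half-step predictor
at staggered midpoints (friction source evaluated on averaged states)
followed by the full corrector, with the corrector's source taken as the
mean of the two adjacent half-step sources. The time step obeys the CFL
bound $\Delta t \le \Delta x / (|V| + c)$ with a safety factor of 0.9; the
bound is re-evaluated at every cycle boundary from the actual velocities and
distended wave speeds, and the step is shrunk if needed (a distended vessel
is stiffer than its unstressed state, so the rest-state bound alone is not
sufficient). Each segment receives at least 3 gridpoints; the target spacing
(default $\Delta x = 0.1$ cm) must be below half the shortest segment
length.

## Junctions

Segment endpoints couple through typed junctions: bifurcations (1 parent,
2 children), trifurcations (1–3), lumped stenoses (1–1), reverse
bifurcations for end-to-side grafts (2–1), cross-junctions for sequential
side-to-side grafts (2–2), and connectors for end-to-end extensions (1–1).
Every junction enforces conservation of mass and continuity of total
pressure $P + \tfrac{1}{2}\rho(Q/A)^2$ between its first parent and every
other port. The unknown end areas satisfy a small ($n \le 4$) nonlinear
system closed by the Keller-box boundary relations, which tie each end
state to the already-updated interior with the affine maps
$Q_M^{n+1} = -(\Delta x/\Delta t) A_M^{n+1} + b$ (parent ends) and
$Q_0^{n+1} = +(\Delta x/\Delta t) A_0^{n+1} + b$ (child starts). The system
is solved by Newton–Raphson with an analytic Jacobian: initial guess from
the previous step, residuals scaled by the local flow and stiffness
magnitudes, tolerance $10^{-10}$, at most 50 iterations, with step halving
whenever an area iterate would go nonpositive. In practice the solver
converges in 2–4 iterations; the test suite cross-checks it against a
derivative-free iterated grid search.

A stenosis junction adds the lumped pressure drop
$\Delta P = a_v Q + a_t Q|Q| + a_u\,\dot Q$ to its continuity equation, with
viscous, turbulent and inertial coefficients derived from the throat
geometry ($K_t = 1.52$, $K_u = 1.2$,
$K_v = \frac{4\alpha}{\alpha-1}\frac{L_a}{R_0}(A_0/A_s - 1)^2$,
$L_a = 0.83 L_s + 3.28 R_s$, $L_u = \rho L_s / \pi R_s^2$ for the
constant-radius throat). The throat flow's time derivative is a first-order
backward difference, and $A_0$, $R_0$ are the arithmetic means over the
proximal/distal host halves (the host is split symmetrically, so the mean is
exact). Percent stenosis follows the diameter convention
$A_0/A_s = 100/(100 - \%)$.

## Boundary conditions

The single network root (the aortic root) receives a Dirichlet pressure
waveform; its area follows from the tube-law inverse and its flow from the
left Keller relation. Every terminal segment ends in a three-element
Windkessel (RCR): proximal resistance $R_1$, compliance $C_t$, distal
resistance $R_2$, discharging against a class-specific external pressure
$P_{ext}(t)$ — the full LV contraction transient for left-ventricular beds,
0.2 of it for right-ventricular beds, 0.6 for septal beds, and a constant
1 mmHg venous pressure for systemic beds. The discretised RCR update,
the Keller relation and the tube law are reconciled each step by a
safeguarded Newton iteration on the scalar terminal pressure (tolerance
$10^{-10}$ mmHg). We chose Newton over relaxed successive substitution
deliberately: the substitution map's contraction factor scales with
$R_1 (\Delta x/\Delta t)(dA/dP)$ and exceeds 1 for large compliant outlets
such as the descending aorta, where plain iteration diverges; the residual
is strictly monotone in pressure, so safeguarded Newton always converges.

One modelling decision departs from placing the myocardial contraction
pressure inside the terminal 1D tube law: here $P_{ext}(t)$ acts only as the
back-pressure of the 0D outlet, and all 1D tube laws use $P_{ext} = 0$. This
keeps junction coupling well-posed where terminal and non-terminal segments
meet (no pressure step at equal areas), makes the rest state (inlet
pressure $\equiv P_0$, outlet back-pressure $\equiv P_0$) an exact fixed
point of the discrete scheme — which the test suite verifies to below
$10^{-6}$ ml/min — and preserves the physiological mechanism: systolic
compression of the myocardial bed still suppresses systolic coronary inflow
and produces the diastolic-dominant left coronary waveform.

## Outlet calibration

Outlet parameters are assigned once, on the disease-free network, and
carried unchanged into stenotic and grafted variants (conduits re-routed
into the coronary circulation simply lose their old outlet):

1. **Flow prescription.** Cardiac output (default 5 L/min) is split over
   outlets: systemic terminals by literature percentages carried on the
   segment table (e.g. 64.6% descending aorta, 2.2% LIMA), and 4.5% to the
   myocardium, divided between the LAD/CIRC/RCA territories and, within a
   territory, between outlets in proportion to $A_0^{2.6}$ (a Murray-law
   adaptation: larger terminals feed larger microvascular beds).
2. **Proximal resistance.** $R_1 = \rho c_0 / A_0$, the characteristic
   impedance, minimising wave reflection at the outlet (verified in the
   suite: a matched single vessel reflects under 5% of an incident pulse).
3. **Distal resistance.** $R_2 = (\bar P_{start} - \bar P_{ext})/\bar Q
   - R_{1D} - R_1$, where $\bar P_{start}$ is estimated by walking the tree
   from the root and subtracting each upstream segment's viscous resistance
   $R_{1D} = \frac{2\alpha}{\alpha-1}\frac{\mu L}{\pi R^4}$ times its mean
   flow (lumped stenoses on the path contribute their steady drop). The mean
   inlet pressure is the time average of the inlet waveform — the simplest
   estimate consistent with the Dirichlet inlet. Calibration fails loudly if
   a prescribed flow exceeds the available pressure head.
4. **Compliance.** $C_t = \tau/(R_1 + R_2)$ with $\tau = 1.25$ s by default;
   `fit_time_constant()` refits $\tau$ from any inlet waveform's diastolic
   decay.

This closure is self-consistent rather than exact — it linearises the
pulsatile run it is calibrating — but closes well: on the bundled fixture
the simulated cardiac output lands within a fraction of a percent of the
prescription and each territory's perfusion within a few percent (asserted
at 5% and 10% in the acceptance suite).

## Execution protocol and outputs

Runs start from rest ($Q = 0$, $A = A_0$, $P = P_0$ with $P_0$ the
diastolic inlet pressure, 76.41 mmHg for the default waveform) and advance
4 cardiac cycles of $T = 0.917$ s (about 65 bpm); the solution converges to
a periodic steady state and the 4th cycle is stored at 100 equally spaced
times for every gridpoint. Convergence is asserted, not assumed: the
cycle-to-cycle relative L2 drift is reported per segment and checked against
1%. Beds behind a near-occlusive (99%) stenosis drain towards a much lower
equilibrium pressure with time constant $\sim R_2 C_t$ and may still be
settling after 4 cycles; `check_convergence()` can warn instead of fail for
that case, and the residual drift is part of the reported output.

All metrics operate on the stored cycle. MGF is the plain mean of the 100
flow samples (reported in ml/min); PI is $(Q_{max}-Q_{min})/\bar Q$; BF is
the negative flow area as a percentage of total unsigned area (trapezoid
rule); DF is the diastolic share of the flow integral. Systole is taken
from the waveform foot to the dicrotic notch — generated waveforms carry
their notch time; measured waveforms need it supplied — and the diastolic
wave-free window is the last 75% of diastole, over which iFR is the
distal-to-proximal mean pressure ratio across the stenosis. Graft indices
are evaluated by default at the distal end of the graft, towards the
anastomosis, where TTFM readings are least confounded by the conduit's own
capacitance; the site is a parameter.

# The synthetic study conditions

Everything needed to run the pipeline is generated in code:

- `generate_inlet_pressure()` builds an aortic-root waveform from clinical
  summary parameters: period 0.917 s, diastolic minimum 76.41 mmHg, systolic
  peak 120 mmHg, dicrotic notch at 38% of the cycle, and an exponential
  diastolic decay whose time constant (1.25 s) round-trips through
  `fit_time_constant()`. The systolic segment is a ramp-plus-sine shape
  whose amplitude is solved so the maximum equals the systolic parameter
  exactly.
- `generate_lv_external_pressure()` gives a synchronised squared-sine LV
  contraction bump (peak 100 mmHg) over systole on a 1 mmHg venous plateau.
- `make_toy_network()` builds a 24-segment network: an aortic trunk with
  IMA take-offs and five systemic outlets, plus left and right coronary
  trees with eight outlets over the three territories (defaults LAD 42%,
  CIRC 27%, RCA 31% of myocardial flow). Three scenarios accompany it —
  stenotic (90% LAD, 99% OM2, 90% RCA lesions), separate grafting (in-situ
  LIMA and RIMA plus a free aortic radial graft) and composite grafting
  (LIMA with a Y limb extended end-to-end, sequentially through OM2 to the
  PDA) — and the composite scenario alone exercises all six junction types.
  Geometry is fixed by default; an optional seeded log-normal jitter
  perturbs radii and lengths reproducibly.

What the fixture does **not** emulate: patient-specific centreline geometry
(segment counts two orders below a segmented patient network), measured
rather than parametric pressure waveforms, vessel curvature, non-Newtonian
rheology, autoregulation, and hyperaemia. Passing tests on the fixture
therefore demonstrate correctness of the numerics and internal consistency
of the calibration, not clinical accuracy for any real patient.

# Numerical choices and edge cases

- Tolerances: junction Newton $10^{-10}$ (scaled), outlet Newton $10^{-10}$
  mmHg, both far below physiological signal; junction mass balance closes
  to $\sim10^{-14}$ relative in practice.
- Degenerate inputs are refused with named errors: nonpositive geometry,
  splits that would leave a zero-length half, percent stenosis outside
  $[0, 100)$, pressures at or beyond tube-law collapse, prescriptions that
  do not sum to 100% of cardiac output, dangling graft conduits at
  validation.
- A 0% stenosis junction has zero viscous and turbulent coefficients but
  retains the throat's inertance, and behaves as a plain connector at
  steady flow.
- Reverse flow needs no special casing: parent/child roles are topological,
  and negative flow simply appears as negative $Q$ (this is what the BF
  metric measures).
- Problem sizes in the tests and acceptance script: the 24-segment fixture
  (32–34 segments after editing) at $\Delta x = 0.1$ cm and
  $\Delta t \approx 6.6\times10^{-5}$ s over 4 cycles; a 40 cm, 401-point
  vessel for wave-speed measurements; grid-halving to $\Delta x = 0.05$ cm
  for the refinement check. Each network run takes on the order of a second
  with the compiled core. A pure-R reference engine implements the same
  algorithm from the exported step functions and is held to $10^{-10}$
  agreement with the compiled core on a small stenosed bifurcation.

# Known limitations

- The upstream mean-pressure estimate ignores pulsatile and kinetic
  contributions; the closure error lands inside the acceptance margins on
  the fixture but grows with stenosis severity, which is why calibration is
  staged on the disease-free network.
- A single Windkessel back-pressure class per outlet cannot reproduce
  intramyocardial pump dynamics in detail (a deliberate trade against
  RCRCR-class models); early-diastolic inertial effects in coronary flow
  are under-represented.
- The right coronary ostium is modelled without entrance head loss, which
  exaggerates its systolic peak; distal branches (where grafts land) are
  less affected.
- iFR is computed at rest; hyperaemic indices (FFR) would require
  re-parameterised outlets and a hyperaemic inlet waveform and are out of
  scope.

# Worked example

```{r example, eval = FALSE}
inlet <- generate_inlet_pressure()
lv <- generate_lv_external_pressure()
fx <- make_toy_network()
base <- calibrate_outlets(fx$topology, fx$prescription, inlet, lv)

grafted <- apply_scenario(fx$topology, fx$scenarios$separate)
grafted <- carry_outlets(base, grafted)
sol <- run_simulation(grafted, inlet, lv)
cabg_metrics(sol, inlet, grafts = fx$grafts$separate)
```

The README shows this example with the numbers it prints; the same pipeline
is what `scripts/acceptance.R` re-runs from scratch.
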