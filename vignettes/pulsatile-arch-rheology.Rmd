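---
title: "Methods: rheology-aware pulsatile flow in an idealized aortic arch"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: rheology-aware pulsatile flow in an idealized aortic arch}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(pulsarch)
```

## Purpose and scope

`pulsarch` isolates one question: holding geometry and cardiac input
fixed, how does blood rheology alone reshape the pressure–velocity–shear
environment of the aortic arch? The package deliberately replaces the 3D
arch by a reduced model that can be verified against closed-form
solutions. What is retained: shear-thinning constitutive behaviour,
pulsatile driving, radially resolved velocity profiles and wall shear
stress, lumped downstream vasculature. What is not modelled: curvature
and Dean-type secondary flows, branch junction geometry, turbulence,
wall compliance (fluid–structure interaction), and any patient-specific
anatomy. Cross-condition *differences* are therefore meaningful; absolute
3D quantities (e.g. WSS hot-spots at branch ostia) are not reproduced and
are not claimed.

## Constitutive model

Effective viscosity follows the Carreau form

$$\mu_{\mathrm{eff}}(\dot\gamma) = \mu_\infty + (\mu_0 - \mu_\infty)
  \bigl(1 + (\lambda\dot\gamma)^2\bigr)^{(k-1)/2},$$

a power-law transition between a zero-shear plateau $\mu_0$ and an
infinite-shear plateau $\mu_\infty$. (The family with a free transition
exponent is often called Carreau–Yasuda; here the Yasuda exponent is
fixed at 2 — the plain Carreau form — and no extra parameter is exposed.)
The four built-in parameter sets:

```{r}
blood_conditions()
```

Hematocrit is stored as metadata only; it does not enter the law. All
conditions share a density of 1060 kg/m³. Over the arterial shear range
$10^2$–$10^3\,\mathrm{s^{-1}}$ the sets order as diabetic > healthy2 >
healthy1 > anemic, which is the ordering every downstream WSS and
pressure-gradient comparison inherits.

Two numerical points. First, the transition factor is evaluated as
$\exp\!\bigl[\tfrac{k-1}{2}\,\mathrm{log1p}((\lambda\dot\gamma)^2)\bigr]$
with $\lambda\dot\gamma$ clamped above $10^{15}$: this preserves
$\mu(0) = \mu_0$ *exactly*, avoids overflow at any shear rate, and leaves
the high-shear plateau intact. Second, the rate at which
$\mu \to \mu_\infty$ depends on $k$: the anemic set ($k = 0.33$) is
within $10^{-6}$ relative of its plateau by $\dot\gamma = 10^{10}$, while
the healthy1 set ($k = 0.48$) needs roughly $10^{13}\,\mathrm{s^{-1}}$ —
the tests reflect this.

For 3D fields the scalar shear rate is
$\dot\gamma = \sqrt{2\,D\!:\!D}$ with $D$ the symmetric part of the
velocity gradient — the standard second invariant, normalized so that
simple shear $\partial u/\partial y = s$ gives $\dot\gamma = s$.

## Cardiac inflow

The inlet waveform is piecewise: a sinusoid
$A \sin[\omega(\tau + t_0)]$ on $\tau \in (0, t_s]$ and a plateau $d$ on
$(t_s, T]$, extended periodically (negative times included, since solvers
may evaluate at shifted times). Defaults: $T = 0.5$ s (120 beats/min),
$t_s = 0.218$ s, $A = 0.5$ m/s, $d = 0.1$ m/s, $t_0 = 0.016$ s,
$\omega = 4\pi$ rad/s. The phase offset makes the waveform nearly
continuous at both junctions (jumps of $1.5\times10^{-4}$ m/s). Boundary
convention: in-cycle time $\tau = 0$ belongs to the diastolic branch of
the previous cycle, matching continuity. The cycle mean (closed form,
$\approx 0.2123$ m/s with defaults) feeds the Windkessel resistance
estimates. `amplitude = 0` is accepted as the degenerate constant
waveform at the diastolic level — the steady-flow limit used by the
Poiseuille verification cases; a literal sinusoid of zero amplitude would
instead produce zero systolic flow, which is never the intended limit.

## Windkessel outlets

Each branch outlet carries a three-element RCR model:
$P = P_c + R_1 Q$, $C\,dP_c/dt = Q - P_c/R_2$. Parameters come from mean
haemodynamics: $R_{\mathrm{tot}} = \bar P / \bar Q$, split 5 % proximal /
95 % distal, $C = \tau / R_2$ with the diastolic decay constant
$\tau = 1.0$ s. The default mean pressure (13332 Pa ≈ 100 mmHg) and the
outlet flow fractions (brachiocephalic 0.15, left carotid 0.075, left
subclavian 0.075, descending aorta 0.70) are package defaults chosen at
physiological scale, not literature-fixed values; both are configurable.

The update is backward Euler with $\beta = R_2 C/\Delta t$:
$P_c^{n+1} = (\beta P_c^n + R_2 Q^{n+1})/(1+\beta)$. A dimensionally
inconsistent product form $\beta = R_2 C \Delta t$ circulates in print;
the quotient form used here is the one that makes the update the exact
backward-Euler discretization of the RCR ODE (we verified the algebra,
and the equivalent outlet-pressure form is implemented and tested to
agree to $10^{-12}$). The scheme is unconditionally stable — the
homogeneous map $\beta/(1+\beta)$ is a contraction for every
$\Delta t > 0$ — and first-order accurate, which the tests confirm
against an adaptive ODE integration.

## Reduced flow solver

The arch is modelled as fully developed axisymmetric flow in a rigid
circular tube, where the convective term vanishes identically and axial
momentum reduces to

$$\rho \frac{\partial u}{\partial t} = -\frac{dp}{dx}
  + \frac{1}{r}\frac{\partial}{\partial r}
    \Bigl(r\,\mu(|\partial u/\partial r|)\,\frac{\partial u}{\partial r}\Bigr),
  \qquad u(R) = 0.$$

Design choices, in the order they matter:

* **Driving.** The cross-section mean velocity is prescribed (the
  waveform is read as the instantaneous mean over the inlet face — the
  profile shape is left to the solver, since no profile shape is part of
  the problem statement), and the uniform $dp/dx$ is an extra unknown.
  The discrete system is tridiagonal plus one dense constraint row
  (trapezoidal $r$-weighted mean); it is solved by block elimination with
  two Thomas sweeps per iteration. A prescribed-$dp/dx$ mode exposes the
  configuration the analytic Womersley solution verifies.
* **Space.** Node-centred uniform radial grid; conservative
  finite-volume fluxes $r_{i+1/2}\,\mu_{i+1/2}(u_{i+1}-u_i)/h$. This
  stencil is *exact* for a parabolic profile, so the steady
  constant-viscosity solve reproduces Poiseuille flow to the accuracy of
  the quadrature weights (0.01 % at 101 nodes). At the axis the
  regularized limit $4\mu_{1/2}(u_1-u_0)/h^2$ (finite volume over
  $[0, h/2]$) removes the $1/r$ singularity.
* **Time.** Backward Euler; unconditionally stable, first-order,
  matching the implicit treatment of the outlet model. Nonlinearity is
  handled by Picard (lagged-viscosity) iteration with relative tolerance
  $10^{-8}$ and a 50-iteration cap; exceeding the cap raises a
  convergence error that carries branch/condition context. A
  constant-viscosity parameter set ($\mu_0 = \mu_\infty$) makes the
  operator linear and one solve per step suffices.
* **Initialization.** Runs start from the quasi-steady profile at the
  cycle-start waveform value, then integrate `n_cycles` cycles and
  report the last. Cycle-to-cycle periodicity is measured two ways: on
  the reported traces (pressure, flow, WSS — the quantities the pipeline
  summarizes; about 0.1–0.2 % at the defaults) and on the full radial
  profiles, whose viscous-core memory relaxes more slowly at aortic
  radii and low viscosity (up to ~0.7 % for the anemic set). Both appear
  in the report.
* **Wall shear stress.** One-sided second-order wall gradient,
  $\tau_w = \mu_{\mathrm{eff}}(\dot\gamma_w)\,|\partial u/\partial r|_R$,
  reported as a magnitude.

Defaults: `nr = 101` radial nodes, 1000 steps per cycle, 8 cycles, tube
radius 0.0125 m at the inlet (adult aorta scale; branch radii 0.006,
0.004, 0.004, 0.0105 m — all documented assumptions, since no vessel
dimensions are part of the problem statement).

## The arch pipeline

`run_condition()` splits the inlet flow by fixed fractions
($Q_i = f_i\,v_{\mathrm{inlet}}(t)\,\pi R_{\mathrm{in}}^2$), so mass is
conserved at the bifurcation *by construction* at every instant (the
report still asserts it). A pressure-equalizing junction would couple the
branches nonlinearly and is deliberately out of scope; fixed mean-flow
partitions are themselves part of the problem statement. Each branch runs
the tube solver at its scaled waveform, feeds its flow into its
Windkessel, and reports the final cycle. Branch *wall* pressure is the
Windkessel outlet pressure plus the axial-gradient contribution over a
nominal branch length (0.05 m default): without that term, outlet
pressures would be identical across blood conditions (flow is prescribed
and the Windkessel is linear), which would hide exactly the
rheology-driven contrast the pipeline exists to expose. The pipeline
contains no random numbers; identical configurations give
bitwise-identical outputs.

## Severity classification

Min/avg/max of WSS and wall pressure map to green/yellow/red bands. Only
one cutpoint is an established reference: average WSS between 0.4 and
1.5 Pa is the commonly quoted physiological band. Every other edge
(max-WSS yellow above 1.5 Pa and red above 4.5 Pa; min-WSS yellow below
0.05 Pa; the pressure bands at 60–90 / 70–105 / 90–140 mmHg for
min/avg/max) is an illustrative configuration default, flagged as such in
every serialized report. Band edges belong to the lower-severity side —
a value sitting exactly on a threshold is not escalated. Classification
of the max metric is monotone: raising a value never lowers its
severity.

## Synthetic references: what they do and do not show

All verification inputs are generated in closed form:

* **Womersley flow** (oscillatory pressure-gradient-driven pipe flow,
  complex Bessel solution) — the oracle for the unsteady solver. The
  complex-argument $J_0$ is evaluated by power series, adequate to near
  machine precision for $|z| \lesssim 40$, which covers aortic Womersley
  numbers ($\alpha \approx 24$ at defaults); it is itself tested against
  frozen arbitrary-precision values and the small-$\alpha$ Poiseuille
  limit.
* **Poiseuille flow** — the steady limit.
* **ABC (Arnold–Beltrami–Childress) flow** on a periodic grid — a
  Beltrami field whose curl equals itself, so helicity density must equal
  the squared speed; finite-difference helicity uses periodic wrapping
  there, one-sided second-order stencils on non-periodic fields.
* **Solid-body rotation and uniform fields** — helicity nulls.
* **The idealized arch network** with Windkessel parameters satisfying
  the estimation identities exactly.

Passing these tests shows the discretizations converge to the stated
analytic limits and the orchestration conserves mass and is
deterministic. It does *not* show that the reduced model reproduces 3D
arch features — secondary flows, junction hot-spots, helicity patterns of
a curved vessel — and no test claims that.

## Problem sizes used by the test suite

Accuracy-critical checks run at the resolutions the claims are stated at
(Womersley: 201 nodes, 2000 steps per cycle; Poiseuille: 201 nodes).
Orchestration checks (ordering, determinism, periodicity, conservation)
use reduced sizes — 41–51 nodes, 100–250 steps per cycle, 4–8 cycles —
chosen as the coarsest resolutions at which the solver's self-convergence
test (halving the step changes cycle-averaged WSS by under 0.5 %) still
passes with a wide margin.

## Known limitations

* The reduced geometry cannot produce curvature-driven secondary flows,
  so helicity diagnostics apply to supplied/synthetic 3D fields, not to
  the tube solution (which has none by symmetry).
* Fixed flow splits mean outlet pressures react to rheology only through
  the explicit axial-gradient term; a coupled junction model would be
  needed for pressure-mediated flow redistribution.
* Backward Euler is first-order in time; the defaults resolve the cycle
  well (the tests quantify this), but long-time accuracy studies should
  halve the step and compare.
* The Carreau law has no yield stress or thixotropy; viscoplastic or
  aggregation-dominated regimes (stasis, severe pathology) are outside
  its validity.
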