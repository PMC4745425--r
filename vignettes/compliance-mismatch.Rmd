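---
title: "Modelling compliance mismatch in a stiff-compliant-stiff artery"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modelling compliance mismatch in a stiff-compliant-stiff artery}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(pulsewave)
```

## The problem

When a diseased arterial segment is bypassed or replaced, the graft is
usually much stiffer than the native vessel it joins. The abutting segments
then differ in distensibility -- *compliance mismatch* -- and pulse waves
partially reflect at each stiffness junction. The local mechanical
environment (wall shear stress on the endothelium, transmural pressure,
circumferential stress and strain in the wall) changes segment by segment,
and those changes are implicated in intimal thickening and loss of graft
patency.

`pulsewave` models the canonical idealization of this situation: a straight
carotid-calibre vessel (inner diameter 8 mm, outer diameter 10 mm) made of
three 50 mm segments whose Young's moduli are 200, 5 and 200 MPa -- a
compliant artery sandwiched between walls forty times stiffer -- preceded by
a 30 mm inlet extension, with observation probes at 70, 100 and 140 mm from
the inlet (mid-segment, clear of the entrance region). Blood is treated as
incompressible and Newtonian (density 1050 kg/m^3, viscosity 0.0035 Pa s),
the wall as linear elastic and nearly incompressible (Poisson's ratio
0.499), and the inlet carries a periodic carotid-like mean-velocity waveform
of period 1 s.

## Model reduction: from 3D fluid-structure interaction to 1D pulse waves

Resolving this configuration with a full 3D arbitrary-Lagrangian-Eulerian
finite-element model is a cluster-scale exercise. The central design
decision of this package is to replace it with the standard one-dimensional
area-averaged system for flow in a compliant tube,

$$\partial_t A + \partial_x Q = 0, \qquad
  \partial_t Q + \partial_x\!\left(\frac{Q^2}{A}\right)
  = -\frac{A}{\rho}\,\partial_x p - 8\pi\nu\,\frac{Q}{A},$$

closed by the thin-wall elastic tube law

$$p(A) = p_{ext} + \beta\,(\sqrt{A} - \sqrt{A_0}), \qquad
  \beta = \frac{\sqrt{\pi}\,h\,E}{(1-\nu_w^2)\,A_0},$$

with $A$ the lumen area, $Q$ the volumetric flow, $h$ the wall thickness and
$E$ the segment-wise Young's modulus. The $(1-\nu_w^2)$ factor is the
plane-strain correction for a long, axially constrained tube, consistent
with a nearly incompressible wall. The rationale: the phenomenon under
study -- wave reflection at stiffness junctions and the segment-wise
redistribution of pressure and strain -- is governed by axial wave
mechanics, which the 1D system captures exactly in the small-amplitude
limit. What it deliberately gives up is the 3D velocity field (and with it
buckling-induced profile asymmetry and distension-driven local velocity
changes), wall inertia, and the detailed structural boundary conditions of
a tethered wall.

The characteristic speed of the system, $c = \sqrt{\beta\sqrt{A}/(2\rho)}$,
equals the Moens-Korteweg-type speed
$\sqrt{hE/(2\rho R_0 (1-\nu_w^2))}$ at the reference area: about 28 m/s in
the compliant segment and $\sqrt{40} \approx 6.3$ times that (178 m/s) in
the stiff ones. At a junction of equal lumen but different stiffness, a
pressure wave incident from tube 1 reflects with coefficient
$(Z_2 - Z_1)/(Z_1 + Z_2)$, $Z = \rho c / A_0$; for the 40-fold modulus drop
this is $-0.727$ -- a large, sign-inverting reflection, which is why the
compliant middle segment rings between its two stiff neighbours. (Continuity
of pressure and flow at the junction yields this sign convention: a wave
entering a more compliant tube reflects with negative pressure.)

## The inlet waveform generator

The measured carotid inlet waveform that motivates the model exists only as
a published plot, so the package generates a closed-form stand-in: a
diastolic plateau plus a single Gaussian systolic pulse, band-limited to
`harmonics_retained` Fourier harmonics. Two shapes were considered
(raised-cosine and Gaussian bump). The Gaussian was chosen because its
Fourier coefficients decay super-geometrically: truncation at the default 12
harmonics leaves no visible Gibbs ripple, so the sampled minimum and maximum
of the series sit on the configured diastolic and peak velocities to about
$10^{-5}$ relative, whereas a truncated raised cosine ripples at the 1%
level. `systolic_width_fraction` is the full width at half maximum of the
pulse as a fraction of the period.

Defaults (period 1 s, peak at 15% of the cycle, FWHM 25% of the cycle, 12
harmonics) give a waveform qualitatively matching published common-carotid
recordings: a systolic spike riding on a broad diastolic plateau. The
diastolic and peak velocities are not hard-coded: they are derived at load
time from the diastolic and peak-systolic Reynolds numbers (190 and 500,
$Re = \rho D_0 V / \mu$), so overriding the fluid or the geometry in a
configuration file keeps the Reynolds envelope intact. With the default
parameters this yields 0.079 and 0.208 m/s. The generator is deterministic;
an optional Gaussian perturbation for robustness studies demands an explicit
seed and restores the caller's RNG state.

What the synthetic waveform does *not* claim: any quantity tied to the
fine intra-cycle timing of the real measured waveform (e.g. the exact
instant of peak wall shear stress) is outside its remit, because only the
period and the Reynolds envelope of the measurement are honoured.

## The Womersley analytic engine

For a rigid straight tube the axisymmetric Navier-Stokes equations have an
exact harmonic solution. Driving it with the Fourier decomposition of the
inlet mean-velocity series gives, per mode $k$ with Womersley number
$\alpha_k = R\sqrt{k\omega/\nu}$ and $\Lambda_k = i^{3/2}\alpha_k$:

$$u_k(r) = c_k\,
  \frac{1 - J_0(\Lambda_k r/R)/J_0(\Lambda_k)}
       {1 - 2J_1(\Lambda_k)/(\Lambda_k J_0(\Lambda_k))},$$

normalized so that the cross-sectional average of mode $k$ equals the
velocity coefficient $c_k$; the steady mode is the Poiseuille parabola. The
package evaluates $J_0$, $J_1$ at complex argument with a guarded Maclaurin
series (safe for $|z| \lesssim 25$, which covers physiological $\alpha$ and
harmonic counts; below $\alpha = 10^{-3}$ the analytic quasi-steady limit is
substituted to avoid cancellation). The solution is flow-driven rather than
pressure-driven -- the tube is fed by a velocity inlet -- and the per-mode
pressure gradient $G_k = -\,i\,c_k\,\rho k\omega / D_k$ is back-computed
and reported; its $\alpha \to 0$ limit is the Poiseuille value
$-8\mu c_k/R^2$.

This module serves two roles: a scientific output in its own right
(velocity profiles, wall shear stress with its amplitude and phase lead
over the mean velocity), and the analytic oracle against which the 1D
solver is verified in its rigid limit. It also powers the optional
Womersley-corrected wall shear stress closure (below).

## Numerical scheme

The 1D system is advanced with a ghost-cell MacCormack scheme
(forward-difference predictor, backward-difference corrector): second-order
in space and time for smooth solutions, which is all this problem contains
at physiological amplitudes. Key numerical choices:

* **Conservation.** The continuity update is in exact flux form, including
  the boundary cells; the accumulated boundary fluxes therefore balance the
  stored volume to round-off, and every simulation carries a volume audit
  (relative closure error, typically $10^{-15}$, required $\le 10^{-8}$).
* **Junctions.** The stiffness $\beta(x)$ varies cell-by-cell; the pressure
  gradient term is discretized from the pointwise pressure
  $p_i = \beta_i(\sqrt{A_i}-\sqrt{A_0})$ with one-sided differences matched
  to each MacCormack sweep. Since $p \equiv 0$ at rest for any $\beta(x)$,
  resting states are preserved exactly and no special junction treatment is
  needed -- all three junctions are handled uniformly.
* **Boundaries.** The inlet prescribes the mean velocity $V(t)$ (evaluated
  exactly from the waveform's harmonic representation) together with the
  backward Riemann invariant $u - 4c$ extrapolated from the interior. The
  outlet holds the incoming invariant at its rest value -- a non-reflecting
  outflow, the 1D reading of a zero-normal-traction boundary. Ghost areas
  are reconstructed relative to the adjacent cell ($A_g = A_i (c_g/c_i)^4$),
  which is exact at rest, so a quiescent vessel stays identically at rest.
* **Stability.** The interior step is chosen from the CFL condition with a
  0.9 safety factor against the fastest segment (178 m/s) plus a velocity
  margin, then rounded so an integer number of steps lands on each 0.01 s
  output frame; the stepper re-checks the observed CFL number every step
  and aborts with a diagnostic rather than integrate an unstable state.
  With the default 0.5 mm cells this gives a ~2.5 microsecond interior step.
* **Initial conditions and cycles.** Runs start from zero (undeformed area,
  zero flow) and integrate 3 cycles; convergence is reported as the maximum
  relative change of the probe pressure waveforms between the last two
  cycles. Start-up transients ring between the junctions (reflection
  magnitude 0.727 per bounce) but decay within tens of milliseconds, so
  cycles 2 and 3 agree to ~$10^{-12}$; a single-cycle run is flagged as not
  demonstrating convergence.
* **Probes.** Probe series are linearly interpolated to the exact probe
  positions, making results comparable across grid resolutions; halving dx
  (and hence dt) moves the default-run probe pressures by under $10^{-5}$
  relative.

One behaviour of the non-reflecting outlet deserves emphasis: it presents
the tube's characteristic impedance $\rho c/A$ to *all* flow, including the
mean, so the absolute pressure level rides at roughly $\rho c \bar{u}$
above zero rather than at a physiological diastolic pressure. Waveform
shapes, probe-to-probe differences, and strains are the meaningful outputs;
the absolute pressure offset is a property of the chosen outflow model, not
of the vessel.

## Wall shear stress closures

A 1D model has no radial velocity profile, so wall shear stress at a probe
is reconstructed from the local flow and instantaneous radius. The default
closure is quasi-steady Poiseuille, $\tau_w = 4\mu Q/(\pi R^3)$ -- the
simplest consistent choice, matching the laminar friction term
($f = 8\pi\mu/\rho$, flat momentum-correction factor) used in the momentum
equation. At $\alpha = 5.5$ the true oscillatory wall shear leads the flow
and is amplified, so a Womersley-corrected closure is available
(`wss_method = "womersley"`): it applies the analytic per-harmonic amplitude
and phase factors to the harmonic content of the local flow series. In the
rigid limit this reproduces the analytic wall shear stress series to a
fraction of a percent; in compliant segments it remains an approximation,
since the local harmonics ride on a moving wall.

## Wall mechanics

Circumferential (hoop) stress at the inner wall is evaluated with the
classical Lame thick-cylinder solution driven by the probe pressure
(external pressure defaults to zero, as no perivascular pressure is part of
the model; a documented argument changes it). Hoop strain is available by
two routes:

* **kinematic** -- $(\sqrt{A}-\sqrt{A_0})/\sqrt{A_0} = \Delta R/R_0$ from
  the simulated distension; this inherits the segment-wise stiffness
  through the tube law and is the route used for probe-to-probe
  comparisons;
* **constitutive** -- generalized Hooke's law from the Lame stresses, with
  the axial stress defaulting to its plane-strain value (pass
  `sigma_z = 0` for plane stress).

The two are consistent linearizations of the same wall, with one caveat the
test-suite makes explicit: the tube law is a *wall-average* closure, so it
matches the constitutive strain evaluated at the mid-wall radius (within
10% for this geometry), while the inner-wall Lame strain is systematically
higher -- for this 25%-thick wall by roughly a third. At equal load, strain
scales exactly inversely with the modulus: the compliant segment strains
40 times more than the stiff ones, which is the mechanical signature of
compliance mismatch and is reproduced by the default run's strain ordering
(the 100 mm probe dominates both neighbours by more than an order of
magnitude).

## What the tests do and do not show

The verification suite is property-based: closed-form dimensionless numbers
(Womersley number 5.5 at the reference parameters), Poiseuille equivalence
of the steady solver, Womersley equivalence of the rigid limit, exact
volume conservation, pulse propagation at the tube-law wave speed (within
2%), junction reflection at the impedance-mismatch coefficient (within 5%),
cycle periodicity, grid convergence, and the qualitative strain ordering.
Problem sizes used by the default run and the tests: 360 cells of 0.5 mm
(720 of 0.25 mm for the grid-convergence pair), ~2.5 microsecond interior
steps, 3 cycles of 1 s, outputs at 10 ms cadence; the full default pipeline
completes in well under a minute on one CPU.

Passing these tests shows the reduced model is internally consistent and
faithful to its own governing equations -- not that it reproduces any
particular 3D fluid-structure computation or in vivo measurement. In
particular, the absolute magnitudes of wall stress and strain obtained by
3D models of this geometry depend on the full 3D stress state and the
structural boundary conditions, and are not recoverable from a 1D model;
this package reports its own orderings (e.g. where wall shear stress and
hoop stress attain their extrema) next to the strains without asserting
agreement with 3D results. Known further limitations: no wall inertia or
viscoelasticity, no axial tethering detail, no non-Newtonian rheology, no
curvature or taper, and axisymmetry by construction.

## A worked run

```{r, eval = FALSE}
model <- build_default_model()
blood <- fluid_properties()
waveform <- generate_waveform(waveform_params(), 256)

run <- simulate_pulse_wave(model, waveform, blood)
print(run)
summarize_run(run)

# analytic rigid-tube reference
ff <- solve_womersley(blood, model$geometry, decompose(waveform, 12),
                      times = waveform$times)
wss_series(ff)$max
```

The same pipeline, including all file outputs, is available as
`run_pipeline(config_from_list(list()), "out")` or through the thin command
line script `inst/scripts/pulsewave.R`.
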