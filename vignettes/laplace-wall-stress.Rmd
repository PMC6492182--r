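---
title: "Laplace wall-stress and power estimators against a semi-analytic ventricle"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Laplace wall-stress and power estimators against a semi-analytic ventricle}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(lvmech)
```

## The problem

Clinical assessment of left-ventricular (LV) wall stress and mechanical
power leans on variants of the law of Laplace: from a pressure `p`, a mean
inner radius `r`, a wall width `h` (or cavity and wall volumes), one scalar
"hoop stress" is computed and propagated into work, power and efficiency
indices. These formulas assume a thin-walled, isotropic, spherical shell —
assumptions the LV violates. `lvmech` quantifies what that costs. It builds
a setting in which the true stresses and powers are known exactly — the
inflation of an incompressible hyperelastic thick-walled sphere, solved
semi-analytically — and runs the clinical estimators against that ground
truth, both for quasi-static passive inflation and over a full synthetic
cardiac cycle.

## Ground truth: incompressible thick-sphere inflation

The wall material is hyperelastic. Two strain-energy functions are
implemented: the exponential isotropic (Demiray) form

$$\Psi = \frac{\kappa}{2}\log^2 J \;+\; \frac{a}{2b}\left(e^{b(\bar I_1-3)}-1\right),$$

and the transversely isotropic Guccione form
$\Psi = \frac{\kappa}{2}\log^2 J + \frac{a}{2}(e^{Q}-1)$ with $Q$ a
quadratic form in the modified isochoric Green–Lagrange strain expressed in
the local fiber/sheet/normal frame. Passive Cauchy stress follows from
$\sigma = J^{-1}\mathbf F\,(2\,\partial\Psi/\partial\mathbf C)\,\mathbf F^\top$,
implemented in closed form per material and verified in the test suite
against central finite differences of the energy. Active contraction is the
phenomenological transient
$S_a = S_\mathrm{peak}\,\phi(\lambda)\tanh^2(t_s/\tau_c)\tanh^2((t_\mathrm{dur}-t_s)/\tau_r)$
on $0 < t_s < t_\mathrm{dur}$; the length-dependence $\phi$ is injectable
and defaults to 1, since no specific functional form is assumed.

For a spherical shell the problem reduces to one dimension. With reference
radii $r_0 < \xi < R_0$ and an exactly incompressible wall, the deformed
radius of each shell layer is $\rho^3 = \xi^3 + (r^3 - r_0^3)$, the
in-plane stretch is $\lambda = \rho/\xi$ and the radial stretch
$\lambda^{-2}$. Radial equilibrium
$\mathrm d\sigma_{rr}/\mathrm d\rho = 2(\sigma_{\theta\theta}-\sigma_{rr})/\rho$
with a traction-free outer surface integrates to a single quadrature for
the luminal pressure,

$$p \;=\; \int_{r_0}^{R_0} \frac{2\,\Delta(\xi)\,\xi^2}{\rho^3}\,\mathrm d\xi,
\qquad
\Delta = a\,e^{b(I_1-3)}\left(\lambda^2-\lambda^{-4}\right) + S_a,$$

where an isotropic in-plane active tension $S_a$ adds equally to both
in-plane principal stresses. `pressure_from_inner_radius()` evaluates this
with Gauss–Legendre quadrature (200 nodes by default; the integrand is
analytic, so doubling the nodes moves `p` by less than $10^{-8}$
relative); `inflate()` root-finds the deformed radius for a target
pressure to $10^{-8}$ kPa. The full radial stress profile is accumulated
with 5-point Gauss panels on an 801-point wall grid, so the outer boundary
condition is met to near machine precision, and volume averages use the
fact that incompressibility makes the deformed volume element equal the
reference one.

Two exact identities anchor the solver and are asserted in the tests:

* energy conservation — internal work $\int\!\!\int \sigma:\dot\varepsilon$
  equals pressure–volume work $\int p\,\mathrm dV$ along any ramp (the
  discretized ramp agrees to well under 1%);
* the mean-stress (Signorini) identity — for any equilibrium state with
  traction only on the two surfaces,
  $\bar\sigma_{rr} + 2\bar\sigma_{\theta\theta} = 3\,p\,V_\mathrm{cav}/V_\mathrm{wall}$,
  independent of the constitutive law. This is a sharp check on the
  volume-averaged stresses: numerical schemes that recover stresses from
  displacement-based finite elements under near-incompressibility
  (penalty $\kappa$, linear tetrahedra) can violate it by several percent,
  with the volume-averaged *radial* stress affected most, while the
  semi-analytic reduction satisfies it to quadrature accuracy. We also
  solved the nearly incompressible radial boundary-value problem
  ($\kappa = 650$ kPa) by shooting; at 4 kPa it moves the averaged
  stresses by under 0.5%, so exact incompressibility is an excellent model
  of the penalty formulation at these pressures.

The three verification shells share $r_0 = 15$ mm with walls of 0.5, 2.5
and 15 mm ($h/r$ from 0.033 to 1, the last being LV-like), material
$a = 10$ kPa, $b = 8$, inflated to 4 kPa — diastolic-range loading for
which this stiffness is calibrated.

## The Laplace estimators

Three stress formulas are scored, all evaluated on deformed geometry:
thin-wall $\sigma_{L,h} = pr/2h$; thick-wall
$\sigma_{L,H} = \frac{pr}{2h}\big/\!\left(1+\frac{h}{2r}\right)$; and the
volume-based
$\sigma_{L,V} = p\,/\,[((V_\mathrm{cav}+V_\mathrm{myo})/V_\mathrm{cav})^{2/3}-1]$,
which is algebraically identical to $\sigma_{L,H}$ on an exact sphere (a
property-tested identity) but not on LV-like shapes. Laplace power uses the
wall-motion bracket

$$P_{\mathrm{int},\star}(t) = V_\mathrm{myo}(t)\,\sigma_{L,\star}(t)
\left(\frac{\dot r}{r_0} + \frac{\dot R}{R_0}\right),$$

with the bracket implemented literally as the sum over the two in-plane
directions (a `half_bracket` flag exposes the mean for sensitivity
analysis) and radii differentiated by central finite differences. Derived
indices: $\mathrm{IHW} = V_\mathrm{myo}\sigma_{L,\star}$ evaluated at the
stress-trace maximum (the evaluation instant is configurable, since the
definition leaves it open), $\mathrm{IHP} = \mathrm{IHW}/T_\mathrm{sct}$
with $T_\mathrm{sct}$ the time from end-diastole to peak stress;
hydrodynamic power $P_\mathrm{ext} = p\,\mathrm dV/\mathrm dt$; external
heart power $\mathrm{EHP}$ as the time average of $p_\mathrm{ao}q$ over
systole; and the efficiencies
$P_\mathrm{eff} = \mathrm{EHP}/\hat P_\mathrm{int}$ and
$P_\mathrm{eff,clin} = \mathrm{EHP}/\mathrm{IHP}$ as magnitude ratios.

One unit subtlety deserves note: because EHP averages over systole only,
the clinical shorthand "MAP × CO" matches it only when cardiac output is
taken per systolic second ($SV/T_\mathrm{sys}$). The conventional
per-minute product is smaller by roughly $T_\mathrm{sys}/T$ (a factor 3–5);
`ehp_map_co()` computes the conventional product and is documented as the
cycle-averaged quantity.

Sign convention: during ejection the wall contracts, so the literal
bracket makes generated power negative; user-facing summaries report
magnitudes, with the negative-generated convention available in the
summary's `paper_convention` field.

## The synthetic cycle generator

`simulate_cycle()` couples the active incompressible sphere to a
three-element Windkessel afterload (valve impedance $Z_v$, characteristic
impedance $Z_a$, peripheral resistance and compliance). One cycle runs
through isovolumetric contraction (fixed radius, rising $S_a$), ejection
(implicit per-step balance of shell pressure against
$p_\mathrm{ao} + Z_v q$ with backward-Euler compliance update), isovolumetric
relaxation, and a quasi-static filling ramp back to the end-diastolic
pressure, closing the loop at the ED state. The time step is 1 ms; each
ejection step solves a bracketed scalar root to $10^{-11}$ mm.

Default study conditions mirror a severe aortic-stenosis patient record
(EDV 112 ml, ESV 46 ml, EF 58.93%, HR 53/min, cuff pressures 74/126 mmHg,
transvalvular gradient 95 mmHg) and its fitted afterload
($Z_v = 35.82$, $Z_a = 26.00$, $R = 187.74$ kPa·ms/ml, $C = 15.23$
ml/kPa). Parameter choices made once, on physiological grounds:

* **Reference unloading.** EDV is a *loaded* volume. The mapping therefore
  fixes the ED radius from EDV and root-finds the stress-free reference
  radius so that passive inflation to EDP reproduces EDV exactly (wall
  volume conserved from the measured septal/lateral thickness). Treating
  EDV as the unloaded volume instead inflates the ED state 40–80% beyond
  the record, distorting stroke volume, flow and afterload pressures.
* **Passive wall for cycles**: Demiray $a = 1.5$ kPa, $b = 3$. The
  verification stiffness ($a=10$, $b=8$) is calibrated for diastolic
  loading ($p \le 4$ kPa, $\lambda \le 1.2$) and is unrealistically stiff
  in in-plane systolic compression (the $\lambda^{-4}$ term explodes),
  capping the achievable ejection fraction. The softer default gives an
  unloaded volume near 60% of EDV and systolic shortening at active
  tensions below 100 kPa, both physiological.
* **EDP** 1.5 kPa (≈11 mmHg, typical for pressure-overloaded LVs);
  **active transient** $\tau_c$ from the patient fit (80 ms),
  $t_\mathrm{dur} = 300$ ms, $\tau_r = 30$ ms (downstroke constants are
  rarely reported; 30 ms gives a physiological relaxation).
* **$S_\mathrm{peak}$** is never hand-picked: `config_from_patient()`
  bisects it until the simulated EF matches the record within 0.5
  percentage points. For the default record this converges to ≈42 kPa and
  EF 59.08%, with peak LV pressure 292 mmHg and peak transvalvular
  gradient 115 mmHg (the record's Bernoulli-estimated gradient is 95
  mmHg; the linear $Z_v q$ valve law concentrates the drop at peak flow).
* **Surface emission.** The mechanical model is spherical, but the emitted
  endo/epicardial meshes default to a volume-matched prolate ellipsoid
  (long/short axis 1.8, LV-like), with the epicardial offset solved so
  cavity *and* wall volumes match the shell at every frame. This keeps the
  surfaces consistent with the cavity-volume trace while giving the
  geometric analysis a realistically nonspherical anatomy — which is
  exactly what separates $\sigma_{L,V}$ from $\sigma_{L,h}$ and
  $\sigma_{L,H}$ and reproduces the characteristic ordering
  $|P_{\mathrm{int},V}| > |P_{\mathrm{int},h}| > |P_{\mathrm{int},H}|$; on
  an exact sphere the volume-based and thick-wall formulas are identical
  and the ordering cannot arise. A `shape = "sphere"` option retains exact
  icosphere emission for identity checks. Frames are emitted every 20 ms,
  comparable to short-axis cine imaging; optional Gaussian measurement
  noise on the radii traces is controlled by an explicit seed.

## Geometric slicing

`slice_and_sample()` reproduces an operator-free short-axis analysis: the
long axis from principal-component analysis of the endocardial vertices
(sign fixed by putting the wider, basal end at $+z$), decomposition into
8 mm slices anchored around the mean axial coordinate, and 40 rays per
slice (9° sampling) cast in-plane from the axis point; first intersections
with the endo- and epicardial surfaces give per-slice radii and wall
widths, averaged arithmetically per slice and across slices. Slices whose
rays miss a surface or strike it at grazing incidence (beyond 75° from the
facet normal) are dropped and reported. The azimuthal reference direction
is anchored to the endocardial vertex farthest from the axis with an
index-based tie-break, which makes the whole construction exactly
equivariant under rigid motions — including for symmetric meshes where the
farthest vertex is not unique.

Two properties of this construction are worth stating explicitly. First,
it measures *in-plane chord* radii: a slice of a sphere of radius 15 mm at
axial offset $z$ measures $\sqrt{15^2 - z^2}$, not 15, so multi-slice
means of a sphere are below the true radius; the tests assert the
per-slice closed form rather than pretending otherwise. Second,
comparisons between slice granularities (8 mm vs 1 mm) mostly measure
apex-coverage policy, not ray-casting accuracy; the accuracy oracle in the
tests therefore evaluates closed-form ellipsoid radii at the same slice
planes the method analyzed.

## What the tests do and do not show

The suite verifies: constitutive stresses against finite differences of
the energy; the shell solver against its boundary conditions, equilibrium
residual, incompressibility, the trace identity, thin-shell and
refined-quadrature limits; the Laplace identities and unit conventions;
valve logic, reproducibility and energy conservation of the simulator; and
mesh/slicing accuracy against closed forms. Passing them shows the
estimators are scored against a *correct* ground truth — within a model
world that is isotropic (for the truth), spherically symmetric in its
mechanics, activated simultaneously everywhere, and free of atria, valves
with inertia, pericardium, and regional heterogeneity. Conclusions about
the *size* of Laplace errors in real ventricles inherit those caveats: in
particular, the sphere is the Laplace law's own best case, so the errors
measured here (e.g. 58% overestimation by the thin-wall formula at
$h/r = 1$, radial stress at 48% of the in-plane mean) are lower bounds on
the geometric error, while fiber anisotropy and shape irregularity add
further terms that only full 3D models capture.

## Numerical choices, at a glance

| quantity | default | note |
|---|---|---|
| quadrature nodes (pressure integral) | 200 (64 in cycles) | analytic integrand; converged to 1e-8 |
| wall profile points | 801 | 5-point Gauss panels for cumulative stress |
| inflation root tolerance | 1e-12 mm / 1e-8 kPa | bracketed secant via `uniroot` |
| ramp steps (work integrals) | 40 | trapezoid in time/volume |
| cycle time step | 1 ms | backward-Euler Windkessel, implicit ejection |
| mesh frames | every 20 ms, icosphere subdiv 3 | subdiv 4 for accuracy tests |
| ray sampling | 40 rays / slice, 8 mm slices | grazing drop at 75° incidence |

Degenerate inputs are handled explicitly: zero-pressure inflation returns
the reference state; a perfectly spherical cloud has no preferred long
axis but slicing still succeeds; a zero-EF record maps to a quiescent
configuration with $S_\mathrm{peak} = 0$; compression of a passive shell
below its reference radius is a domain error unless explicitly allowed
(diastolic suction during relaxation).

## Known limitations

The ground truth is one-dimensional in space; regional stress variation,
fiber architecture and nonspherical mechanics are outside its reach, and
the Guccione law participates only pointwise (energies/stresses), not in
the shell solver. The filling phase is a quasi-static pressure ramp — no
atrial kick, no inertial effects. The valve is a linear impedance, so the
transvalvular drop scales with instantaneous flow rather than its square.
Published finite-element reference values for volume-averaged stresses in
thick shells carry discretization error of their own — the trace identity
above is the right tool for judging such tables — so agreement at the
few-percent level is the realistic target for cross-validation, and the
radial-stress average is the most fragile entry.
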