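---
title: "Multi-scale pulmonary perfusion: model, assumptions and numerics"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Multi-scale pulmonary perfusion: model, assumptions and numerics}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

pulmoperf simulates steady-state blood flow through the whole pulmonary
circulation at two coupled scales: a lumped pressure–flow model of the main,
left and right pulmonary arteries, and an anatomically based 1D network of
everything downstream, terminating in recruitable capillary beds. This
vignette records the model equations, the parameter choices and their
rationale, the numerical methods, and the limits of what the synthetic
geometry can and cannot demonstrate.

## The 1D network

Every extra-capillary vessel is a cylindrical element with centerline length
$L$ and unstrained diameter $D_0$. Flow $\dot Q$ and pressure drop obey a
Poiseuille law with a hydrostatic term,

$$\Delta P = \frac{128\,\mu L}{\pi D^4}\,\dot Q + \rho_b\, g\, L \cos\theta ,$$

with $\theta$ the angle between the element and the upward vertical, so a
vessel descending into dependent tissue gains pressure at zero flow (an
alternative convention measures $\theta$ from the gravity vector
instead; that sign cannot satisfy hydrostatic equilibrium, so the upward
convention is used and the magnitude is unchanged). Blood is Newtonian with
$\mu = 3.5\times10^{-3}$ Pa s and $\rho_b = 1050$ kg/m³; the capillary sheets
use a separate effective viscosity $\mu_c = 1.9\times10^{-3}$ Pa s.

Diameters respond linearly to transmural pressure, $D = D_0(1+\alpha
P_{tm})$ with $\alpha = 1.49\times10^{-4}$ Pa⁻¹. $P_{tm}$ is blood minus
extra-vascular pressure: alveolar pressure (default 0 Pa, a static
breath-hold) for vessels under 200 µm, and elastic recoil (tissue tethering)
for larger vessels. Recoil is linear in gravitational height, $P_e(h) =
P_{e,\mathrm{ref}} + s\,(h-h_\mathrm{mid})$ with $P_{e,\mathrm{ref}} = -500$
Pa and $s = -981$ Pa/m at 1 g (about $-1$ cmH₂O per cm of height), so
tethering is strongest — extra-vascular pressure most negative — in the
non-dependent lung; the gradient scales with $g$ and vanishes in zero
gravity. Neither the recoil reference, the slope, the alveolar pressure nor
the venous outlet pressure (666 Pa, a normal left-atrial value) is uniquely
fixed by measurement, so all four are configuration entries with these
defaults. The linear diameter law is clamped to $[0.1, 2]\times D_0$: the
floor keeps collapsing vessels numerically regular, the ceiling marks the
validity range of the linear law (converged states sit at $1.2$–$1.45\,D_0$,
far from either bound; the ceiling only matters during coupling transients
that briefly starve one lung).

## The capillary sheet and the ladder acinus

Capillary blood flows between two compliant membranes of height $H$
(sheet flow). With $P_{tm}$ the blood-minus-air pressure,

$$H(P_{tm}) = \begin{cases} 0 & P_{tm} < 0 \\ H_0 + \alpha_c P_{tm} & 0 \le
P_{tm} < P_{CU} \\ H_{max} & P_{tm} \ge P_{CU}, \end{cases}$$

with $H_0 = 3.5$ µm, $H_{max} = 7.7$ µm, $\alpha_c = 1.3\times10^{-9}$ m/Pa
and $P_{CU} = (H_{max}-H_0)/\alpha_c \approx 3231$ Pa. (One common write-up of
the middle branch, $H_0(1+\alpha_c P_{tm})$, is dimensionally inconsistent
with $\alpha_c$ in m/Pa; the form above is the one compatible with the
$H_{max}$ branch.) Sheet flow integrates the cubed height between the
venular and arteriolar transmural pressures,

$$\dot Q = \frac{SA}{\mu_c f l_c^2} \int_{P_{tm,v}}^{P_{tm,a}} H^3\,dP_{tm},$$

evaluated in closed form piece by piece: the collapsed region contributes
nothing, the compliant region a quartic, the saturated region a linear term.
This reproduces the three zonal regimes: both pressures below alveolar
pressure gives exactly zero flow (zone 1), a negative venular pressure clamps
the lower limit at zero (zone 2, waterfall), and both positive is zone 3.
$f = 21.6$ and $l_c = 1186$ µm. The whole-lung capillary surface area
$SA_{tot} = 65.4$ m² is split equally over all sheets — $N_{acini} \times 9$
of them — because no finer allocation is measured; the per-sheet area is a
configuration entry so sensitivity runs can vary it.

Each acinus is a nine-generation "ladder": symmetric arteriolar and venular
chains joined at every generation by one capillary sheet. Chain geometry is
not measured directly, so it is set once from anatomy: generation $i$ holds
$2^i$ parallel vessels (a dichotomously branching acinus), diameters shrink
by 0.8 per generation from the terminal vessel diameter, lengths by 0.8 from
$L_1 = 0.4$ mm. These choices make the sheet, not the chain, the dominant
and recruitable part of acinar resistance, which is the physiological role
the sheet model plays, and give a physiologic total vascular resistance.
The chain segments are themselves compliant against alveolar pressure with
the same $\alpha$; gravity is neglected inside the acinus where the
resistive term dominates.

## Macro model and coupling

The macro domain spans the MPA and its two branches. Each branch obeys
$P_{in}-P_i = a_i \dot Q_i + b_i \dot Q_i |\dot Q_i|$ — convex and
increasing, dominated at physiological flows by the flow-dependent term, as
3D simulations of these arteries are. $a_i$ comes from Poiseuille resistance
of cylinders with the measured branch areas (LPA $3.77\times10^{-4}$ m²,
RPA $3.54\times10^{-4}$ m², lengths 3 cm; MPA $7.72\times10^{-4}$ m², 5 cm)
and $b_i = K\rho_b/(2A_i^2)$. Because both families scale as $A_i^{-2}$, the
equal-pressure flow split depends only on the linear/quadratic mix while a
common rescaling sets the magnitude; calibration therefore root-finds the
mix so that 52.85% of flow enters the LPA at 4.8 L/min under equal outlet
pressures (the midpoint of the reference 52.5–53.2% band) and scales the whole
model so the junction-to-outlet drop is 300 Pa at that flow. The drop target
also sets the stiffness ratio between the two domains, which is what makes
the coupled iteration contract at the observed rate (about 25–30 iterations).

Coupling alternates the two domains: the macro model receives the cardiac
output and the current interface pressures and returns interface flows;
those flows (under-relaxed) become inlet boundary conditions of the 1D
network, whose solution returns interface pressures (under-relaxed back).
Under-relaxation is the standard $\lambda x_{new} + (1-\lambda) x_{old}$ —
the variant with $-\lambda$ on the old iterate has no fixed point for
$\lambda \ne 1$. Convergence is declared when the summed squared change of
interface pressures between iterations falls below $\epsilon = 0.1$ (the
criterion sums squares, in Pa², against a threshold quoted in Pa;
the sum-of-squares form is the default, with RMS and max-abs variants
available). A linearized analysis of the alternating map shows the iteration
matrix has determinant $(1-\lambda)^2$ and trace $2(1-\lambda) -
\lambda^2\gamma$, where $\gamma$ is the ratio of the 1D interface stiffness
to the macro stiffness; the spectral radius is $1-\lambda$ exactly when
$\lambda^2\gamma < 4(1-\lambda)$. $\gamma$ grows as the acinar count shrinks
(fewer parallel beds, stiffer lung), so $\lambda = 0.5$ converges only on
large networks; the default is $\lambda = 0.2$, stable from about 2,000
acini upward, and smaller values are advisable for toy networks. Converged
solutions are independent of $\lambda$ (tested).

Because the lumped macro domain has no spatial extent while the arteries it
represents transmit hydrostatic head losslessly, the hand-off gives the
macro model piezometric pressures ($P + \rho_b g h$ at each interface node,
common datum). Without this correction the hydrostatic elevation of the
dependent hilum in a lateral posture would masquerade as downstream
resistance and push flow away from the dependent lung — the opposite of the
physiological redistribution.

The same interface contract is serialized as a JSON exchange record
(iteration, inlet flow and pressure, per-outlet pressure and flow) written
once per coupling iteration when requested, so an external 3D solver can
replace the built-in surrogate without code changes.

## Synthetic geometry

The generator stands in for imaging-derived anatomy. Lungs are clipped
half-ellipsoids: total volume 4.0 L (the subject's seated FRC of 3.4 L
imaged at 50% of vital capacity implies roughly this), right lung 52.5% of
the total, dorsoventral depth 15 cm, cranio-caudal height 24 cm — textbook
adult dimensions. The right lung centre sits 8 mm dorsal and the left 8 mm
ventral of the midplane, so the volume of dependent tissue differs between
supine and prone; posture sensitivity of the left/right split arises from
this shape asymmetry about the hilum (placed at 60% of cranio-caudal height,
ventral of centre), not from any imposed split. Acinar seeds are a jittered
cubic grid (jitter ≤ 20% of spacing, seeded RNG), split between lungs in
proportion to volume.

Trees grow by recursive bisection of the seed cloud: each tip's subset is
split by the plane containing the parent direction and the subset centroid
(median split along the widest axis when degenerate), and branches extend
40% of the tip-to-centroid distance, at most 60° off the parent, never
shorter than 1.2 mm; single-seed subsets close with a terminal branch
straight to the seed. Diameters follow Strahler ordering with ratio 1.52
(arteries) and 1.56 (veins), anchored at the LPA/RPA equivalent diameters at
a common reference order for both lungs (the two stubs are the same
anatomical level; per-lung anchoring would make the shallower tree uniformly
fatter and bias the flow split). On top of the order formula the generator
applies seeded lognormal within-order scatter with CV 0.15 — vascular
casting shows broad within-order diameter distributions, and without any
scatter the synthetic tree is structurally far more uniform than a real one
— with children clamped to their parent so diameters never increase toward
the periphery. The venous tree mirrors the arterial topology at identical
node positions with reversed orientation, and both trees close through one
ladder acinus per terminal.

What the generator does *not* emulate: lobes and fissures, the imaged upper
vasculature (branch-by-branch lengths, curvature and diameters of real
segmental arteries), inter-subject shape variability, and the full depth of
the real tree — at 10,000 acini the generated tree reaches Strahler order
~11 against ~15 in a complete human arterial tree, so peripheral vessels
are systematically wider and the extra-acinar resistance (and with it part
of the gravitational contrast in perfusion) is under-represented relative
to a CT-based model. Results that depend on anatomic realism at the segment
level should be read as qualitative.

## Numerics

The steady network solution is a damped Picard (fixed-point) outer loop.
With diameters, ladder distension and sheet secant conductances frozen, flow
conservation at every node is a sparse symmetric positive-definite linear
system in nodal pressures — hydrostatic heads enter the right-hand side —
solved by sparse Cholesky (Matrix). Each acinus is then reduced exactly by
series–parallel elimination of its ladder (a nine-step scalar recursion,
vectorized across all acini), internal rung pressures are recovered by a
forward sweep, and sheet conductances are refreshed from the closed-form
flow as secants, $g = \dot Q / \Delta P$, falling back to the local
derivative $kH^3$ for vanishing drops. Updates are damped by 0.5; the loop
stops when nodal pressures move less than $10^{-4}$ Pa and relative diameter
changes are below $10^{-6}$ (at most 500 iterations; typical runs take
~20–30 cold and a handful warm-started). A final assembly at the converged
conductances guarantees flows that conserve mass to solver precision — the
acceptance suite asserts conservation to $10^{-8}$ relative. Each acinar
connector carries a floor conductance of $10^{-15}$ m³ s⁻¹ Pa⁻¹ so a fully
collapsed (zone 1) bed never disconnects the venous subtree; the standalone
ladder solver returns exactly zero flow in that regime. The ladder's
standalone solver uses the same secant iteration (tolerance $10^{-8}$ Pa,
damping 0.5, at most 200 iterations); a damped Newton on the rung pressures
would find the same fixed point but does not vectorize across $10^4$ acini.

Degenerate inputs are handled explicitly: empty seed subsets prune the
branch; colinear subsets fall back to a longest-axis median split; networks
without acini (resistor toys) skip the ladder machinery; nodes stranded by
excluding the central arteries in coupled mode are dropped from the system
and reported as NA.

## Problem sizes and what the tests show

The package's standard study conditions are 10,000 acini (right lung 52.5%
of volume), cardiac output 4.8 L/min, postures zero-gravity, supine, prone,
upright and right-lateral. The acceptance suite runs the coupled model at
exactly these conditions; unit tests use 40–150-acinus networks where the
property under test (conservation, closed forms, monotonicity, determinism)
is size-independent, and the conservation check also runs at 2,000 acini.
Passing tests demonstrate internal correctness of the numerics and the
qualitative physiology (dependent-lung dominance, posture redistribution
direction, recruitment flattening, COV falling with cardiac output); they do
not demonstrate subject-level anatomical fidelity, which would require the
imaged geometry the generator only approximates.

## Known limitations

Steady state only — no pulsatility, wave propagation or fluid–structure
interaction. One macro domain with two interfaces. The wall-shear analogue
is a Poiseuille tube estimate, deliberately not comparable to CFD
magnitudes. The half-ellipsoid lungs flatten the gravitational perfusion
gradient relative to imaged anatomy (see above), and the equal split of
capillary surface area over acini suppresses one real source of
heterogeneity. All defaults discussed here live in a single configuration
object (`default_run_config()`), and every randomized step is seeded.
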