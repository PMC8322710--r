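---
title: "Models and numerics behind oculotamp"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and numerics behind oculotamp}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(oculotamp)
```

# The problem

After vitrectomy for retinal detachment, silicone oil (SiO, a
polydimethylsiloxane of 1000 or 5000 mPa·s) is injected into the vitreous
chamber as a tamponade. Because the oil (980 kg/m³) floats on the residual
aqueous (1000 kg/m³), how much of the retina it actually presses against
depends on the fill fraction, the patient's posture and the interfacial
physics at the oil–aqueous–retina contact line. During saccades the oil drags
on the retina, producing wall shear stresses implicated in recurrent
detachment and oil emulsification. `oculotamp` provides a reduced-order,
fully testable model of both aspects: the static oil–aqueous equilibrium with
per-region contact fractions, and a per-vertex unsteady Stokes-layer model of
saccadic wall shear summarised by the five standard metrics (IMSS, PMSS,
VASS, ARSS, IMSR).

# Geometry and segmentation

The chamber is a sphere of radius 12 mm indented anteriorly by a lens sphere.
The lens-cap dimensions are not standardised; the defaults (`lens_radius =
5.5` mm centred `13` mm anterior of the eye centre, putting the indentation
rim at a polar angle of about 25°) give a phakic-looking anterior cap and are
fully configurable. The wall is an icosphere whose subdivision level is
chosen from a target edge length (`resolution`, default 0.75 mm, i.e. 10 242
vertices); vertices whose radial ray meets the lens sphere first are
projected onto it, so the mesh stays closed and watertight by construction.

Regions are polar-angle bands measured from the anterior axis: macula
(posterior cap, half-angle 20°), post-equatorial retina (to the equator),
pre-equatorial retina (to `ora_limit_angle`), ora serrata band (to the lens
rim) and the lens itself. The clinical "retina" aggregate is macula +
post- + pre-equatorial; the ora band and lens are reported separately and
excluded from retina denominators. The ora band's anterior limit is not a
published number; the default of 40° polar angle is configurable. The
superior/inferior split is anatomical (sign of the superior-axis coordinate)
and does not rotate with gravity.

Areas and wetted areas are computed on an exact decomposition: every triangle
is split along the region-boundary cones (with the exact quadratic
edge–cone intersection, not linear interpolation) and along the hemisphere
plane. This keeps region areas within a fraction of a percent of the
spherical-zone closed forms at the default resolution.

# Static equilibrium

## Interface family and energy

The equilibrium interface is chosen from the family of planes and spherical
caps whose centre lies on the gravity line through the chamber centroid. The
family is exact in both limits that bracket this system: at zero Bond number
the minimiser of interfacial + wetting energy in a spherical container is a
spherical cap meeting the wall at the contact angle, and at zero interfacial
tension it is the flat gravity-normal plane. The eye sits in between: with
Δρ = 20 kg/m³, L = 12 mm and σ = 0.044 N/m the Bond number is ≈ 0.64
(capillary length ≈ 15 mm, larger than the eye radius), so the
energy-minimising member interpolates, usually lying close to the
contact-angle cap.

For each candidate curvature the interface is positioned by root-finding so
the oil volume matches the requested fill (tolerance `tol`, default 1e-4 of
the chamber volume), and the total energy

E = σ (A_int + cos θ_aq · A_oilwet) + (ρ_oil − ρ_aq) g ∫ζ dV_oil

is minimised over curvature (grid of `n_kappa` values up to `kappa_max` =
0.4 mm⁻¹, refined by golden-section search). The wetting term follows from
Young's relation with the contact angle measured **through the aqueous
phase**: θ_aq = 16.2° means the aqueous wets the retina, which is what makes
aqueous rise along the wall (and, in the full physics, into the lens–ora
recess). The measuring phase is not stated with the published angle, so the
convention is a flag (`angle_convention` in `fluid_pair()`); the
through-aqueous default is the only choice consistent with the observed
aqueous capillary rise and with a 90% fill leaving well over a fifth of the
retina dry. Densities, tension and angles enter the statics; viscosity does
not, so SiO1000 and SiO5000 share each static solution.

## Numerics

All volumes, moments and wetted areas come from clipping the wall mesh
against the interface and applying the divergence theorem with fields chosen
to be well conditioned:

* Plane: fields vanish on the interface, so the clipped wall mesh suffices;
  volume integrands are linear per facet (centroid rule exact) and moment
  integrands quadratic (midedge rule exact).
* Sphere: smooth fields are gauged to the sphere pole nearest the chamber,
  and the flux through the open interface patch is added from semi-analytic
  patch integrals (area and polar moments of the patch, computed per azimuth
  against the analytic chamber with closed-form polar intervals). The gauge
  keeps every integrand of chamber size however large the cap radius is;
  curvatures below 1e-3 mm⁻¹ (cap radius beyond a metre) are snapped to the
  exact plane member. The analytic patch uses facet-effective radii (the
  icosphere's volume deficit) so the patch rim sits on the mean polyhedral
  surface.
* Sub-resolution films are excluded: an interface sphere hugging the wall
  closer than 1.5 edge lengths at the gravity-bottom pole describes an
  aqueous layer thinner than the mesh can represent, not a macroscopic
  meniscus, and is rejected during the energy scan. With strong aqueous
  wetting such members are nearly energy-degenerate with the true meniscus
  (the film penalty is only σ(1 − cos θ_aq) per unit area), so without the
  guard quadrature noise can select them on coarse meshes.

Wetting flags are per vertex; contact fractions use exact clipped triangle
areas by default (`method = "split"`), with the cheaper whole-triangle
majority vote available as `method = "majority"`. Regions with zero area
(e.g. the lens of a lens-free build) report `NA` fractions rather than
erroring, so lens-free test geometries remain usable.

## The axisymmetric oracle

In the supine posture the problem is axisymmetric and
`analytic_supine_coverage()` provides a closed-form (up to scalar
root-finding) covered-wall fraction: the interface is the spherical cap
meeting the wall exactly at the contact angle, with the rim colatitude fixed
by volume conservation; with the contact-angle term disabled it reduces to
the textbook flat-cap result x/2 with x²(3−x) = 4·fill. The oracle is the
zero-Bond limit; the mesh solver, which also feels gravity, sits between it
and the flat solution. The gap is therefore positive, shrinks with fill, and
stays within the few-percentage-point band expected at Bond ≈ 0.6 — the same
order as the analytic-vs-CFD differences reported for this configuration.

# Saccade kinematics

The saccade is a quintic polynomial θ(t) on [0, 0.137 s] with published
coefficients up to t⁴ (c2 = 2.01e4, c3 = −3.29e5, c4 = 2.30e6 in degree
units). The quintic coefficient is recovered from the end-of-saccade rest
condition θ'(T) = 0 — the alternative of fixing it by the 50° amplitude gives
an end angle differing by less than the reporting precision (50.01° vs 50°),
and the end-rest choice keeps velocity and acceleration continuous into the
post-saccade hold. The construction is cross-checked against the printed
landmarks: 50° amplitude (the constructor enforces agreement within 1%) and a
547°/s velocity peak 0.034 s after onset, found from the real roots of the
acceleration polynomial. After the rotation the eye is held fixed for a
further 0.137 s to capture the post-saccadic stress decay. The rotation axis
is not published; the default is the superior–inferior axis (a horizontal
saccade), configurable in `saccade_wave()`.

# Saccadic wall shear

The full two-phase Navier–Stokes problem is replaced by a local model: each
wall point drags a semi-infinite Newtonian half-space of the fluid assigned
to it by the static wetting map (oil where wet, aqueous where dry, frozen for
the saccade). The wall speed is U(x, t) = ω(t) d(x) with d the distance to
the rotation axis, and Duhamel superposition over the acceleration history
gives the wall shear

τ(t) = √(ρμ/π) ∫₀ᵗ U'(s) (t − s)^(−1/2) ds,

evaluated with a product-integration rule that integrates the endpoint
singularity exactly on each step of the uniform grid (default 1 ms over the
0.274 s window, 275 samples). The rule reproduces the impulsive-start
(Rayleigh) and oscillating-plate closed forms to well under 1% at the default
step, and halving the step changes peak tractions by less than 1%. The
half-space assumption is justified by the time scales: the viscous
penetration depth over one saccade, √(μT/ρ) ≈ 0.4 mm (SiO1000) to 0.8 mm
(SiO5000), is small compared with the 12 mm chamber.

Two structural consequences are worth knowing when interpreting results.
First, for fixed kinematics τ scales exactly as √(ρμ), so the SiO5000/SiO1000
traction ratio is √5 ≈ 2.24 everywhere — the full CFD shows "almost twice",
the same order. Second, the traction field is exactly separable,
τ(x, t) = d(x)·C(t), so region maxima inherit the bimodal time course of
|C(t)| (an acceleration peak and a deceleration peak), and the model cannot
produce features that require secondary flows, most notably the nonzero
vertical VASS pattern and the stress concentration along the oil–aqueous
meniscus line; both are documented out of scope.

# Shear metrics

From any traction series the five summary statistics are computed per region
and hemisphere: IMSS (per-instant regional maximum), PMSS (per-vertex
all-time maximum), VASS (per-vertex time mean of the vertical traction
component, signed, over the full 0.274 s window including the post-saccade
hold), ARSS (per-instant area-weighted regional mean, with one-third incident
triangle areas as vertex weights) and IMSR (per-instant regional maximum
shear rate). The shear rate divides traction by the local viscosity; the
default is the engineering convention γ̇ = τ/μ, with the
strain-rate-tensor-magnitude convention τ/(2μ) available as
`rate_convention_factor = 2` — it is never applied silently.

# Synthetic fixtures

`separable_traction_fixture()` generates traction series with exactly
separable structure A(x)·b(t): A is a seeded low-order spherical-harmonic
combination (smooth, so regional maxima are stable under meshing) and b a
two-Gaussian-bump profile emulating the accelerate/decelerate shape of
saccadic shear. The generator returns the closed forms of all five metrics
alongside the data, so the metric implementations are tested to round-off.
What the fixture does not emulate: tractions that change direction in time,
meniscus-line concentrations, or any coupling between space and time — so
passing metric tests certify the summary statistics, not the shear physics.
`analytic_cap_fixture()` tabulates the flat-interface coverage closed form,
and `posture_sweep_fixture()` enumerates the 30-run experimental grid
(2 oils × 5 fills from 80 to 100% in 5% steps × 3 postures; 15 unique
statics).

# Problem sizes and runtimes

The reference geometry uses a 0.75 mm target edge (10 242 vertices); a
capillary solve takes a few seconds there, so the full 15-configuration
static sweep completes in minutes. The test suite runs its property checks on
1.6 mm and 0.8 mm meshes, where solves take well under a second; area
convergence is checked between the 0.8 mm and 0.4 mm levels.

# Known limitations

* The single spherical-cap family spreads meniscus rise uniformly around the
  rim. In the standing posture the real interface concentrates the aqueous
  rise in the narrow lens–ora recess while the main meniscus at the retina
  stays lower; the model therefore understates standing and 45°-tilt retina
  contact (by roughly 10–15 percentage points at 80–90% fills) and can leave
  a small dry sliver at the macula edge where the full physics wets it
  completely. Supine (axisymmetric) solutions do not suffer from this and
  track the closed form closely.
* The interface is frozen at its static position during the saccade;
  meniscus-line stresses and interface deformation are out of scope.
* Advancing/receding contact angles are stored but unused: there is no
  moving-contact-line model.
* VASS from this model reflects only the geometry of the tangential
  direction field; the physical vertical-transport pattern arises from 3D
  effects the reduced model cannot produce.
* Tamponades with high-molecular-weight additives are viscoelastic and
  outside the Newtonian assumption.
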