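---
title: "Membrane wrapping of dumbbell colloids: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Membrane wrapping of dumbbell colloids: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(vesiwrap)
```

## The problem

When a micrometre-scale particle adheres to a lipid vesicle, the membrane
progressively covers it — the passive first stage of endocytosis. For a
*dumbbell* (two equal tangent spheres of diameter $d_s$), the neck between
the lobes concentrates negative curvature, and experiments on giant
unilamellar vesicles (GUVs) show two terminal outcomes: both lobes fully
wrapped, or a single lobe engulfed up to the waist. Which outcome occurs,
and how fast, is controlled by the adhesion energy per area $W$, the
membrane tension $\sigma$, the bending rigidity $\kappa$ and an effective
membrane microviscosity $\eta_\mathrm{eff}$.

`vesiwrap` implements four coupled pieces: (1) a coarse-grained Langevin
simulator of a vesicle wrapping an adhesive dumbbell, (2) trajectory
observables and a wrapping-state taxonomy, (3) flicker-spectroscopy
estimation of $(\sigma, \kappa)$ from equatorial contour fluctuations, and
(4) an analytical overdamped theory of the wrap time $T(\sigma)$ with
parameter fitting. Synthetic-data generators make every stage testable
without external data.

## Coarse-grained membrane model

The membrane is a one-particle-thick fluid surface of orientable beads.
A pair at distance $r$ with normals $\mathbf n_i,\mathbf n_j$ interacts via

$$u(r) = \begin{cases}
\varepsilon\left[\left(\frac{r_\min}{r}\right)^4
 - 2\left(\frac{r_\min}{r}\right)^2\right] + (1-\Phi)\,\varepsilon,
 & r < r_\min\\[4pt]
-\varepsilon\,\cos^{2\zeta}\!\left(\frac{\pi}{2}
 \frac{r-r_\min}{r_c-r_\min}\right)\Phi, & r_\min \le r < r_c
\end{cases}$$

with the orientation weight
$\Phi = 1 + \mu\left[(\mathbf n_i\times\hat r)\cdot(\mathbf n_j\times\hat r)
+ \sin\theta_0\,(\mathbf n_j-\mathbf n_i)\cdot\hat r - \sin^2\theta_0 - 1\right]$.
Defaults are $\varepsilon = 1$, $\mu = 3$, $\zeta = 4$, $\theta_0 = 0$,
$r_\min = 2^{1/6}\,\sigma_b$, $r_c = 2.6\,\sigma_b$, and a working
temperature $k_BT = 0.23\,\varepsilon$, a standard fluid-phase regime for
this model family. All parameters are exposed in
`membrane_potential_params()` and in the run configuration.

Two lattice-constant notions matter in practice. The zero-temperature flat
lattice minimises its energy at `equilibrium_bead_spacing()` (about
$0.86\,\sigma_b$ for the defaults — the soft $r^{-4}$ core lets the
attractive second and third shells densify the sheet), while at the working
temperature thermal pressure swells the sheet to about $1.0$–$1.05\,\sigma_b$.
`build_vesicle()` therefore places beads on a generalised spiral at the
*fluid* spacing (`fluid_bead_spacing()`, calibrated once from equilibrated
vesicle runs) and applies a short damped quench (600 steps). Longer quenches
would slowly densify the shell toward the $T=0$ optimum and shrink the
radius; the short quench keeps the relaxed radius within 5% of the target
and irons out the spiral's seam defects.

**Tension control.** Small solutes (diameter $0.5\,\sigma_b$, volume
exclusion only) are scattered inside and outside the vesicle, the outside
population held by a spherical wall. A concentration imbalance produces an
ideal-gas pressure difference $\Delta P = k_BT(c_\mathrm{in}-c_\mathrm{out})$
and hence, via Laplace's law, a tension $\sigma = \Delta P\,R/2$.
`set_tension_by_solutes()` converts a target tension into integer counts.
Concentrations refer to *accessible* volumes: the membrane's thermal
roughness excludes solute centres from a shell of about $0.35\,\sigma_b$
around the mean radius (measured from solute density profiles), and the
confining wall is penetrable by about $0.05\,\sigma_b$. With these margins
the measured mechanical pressure difference agrees with the ideal-gas
estimate to a few percent at the default concentrations.

**Dynamics.** A BAOAB-splitting Langevin integrator advances bead positions,
bead normals (rotational Langevin about the two in-plane axes, 2 degrees of
freedom per bead), solutes, and the rigid dumbbell. Because the dumbbell is
axisymmetric, its orientation is carried by the axis vector alone rather
than a full quaternion — the spin about the symmetry axis couples to
nothing and is not tracked; the lobe centres are derived as
$\mathbf c \pm a\,\hat{\mathbf u}$, so the lobe separation is exactly $2a$
by construction. With friction set to zero the scheme reduces to velocity
Verlet; energy drift is below $10^{-3}\,\varepsilon$ per bead per $10^4$
steps at $\delta t = 0.002\,\tau_0$, and the thermostat equipartitions
kinetic energy to within a few percent. The default production timestep is
$\delta t = 0.01\,\tau_0$ ($\tau_0 = \sigma_b\sqrt{m/\varepsilon}$, $m=1$).

**Adhesion.** Each membrane bead interacts with the *nearest* lobe surface
only (no double counting at the neck): a $\cos^2$ well of depth
$\varepsilon_\mathrm{ad}$ between the contact distance $0.5\,\sigma_b$ and
the cutoff `r_cut_ad`, with a capped harmonic core inside contact. The
adhesion energy per area maps as
$W \approx \varepsilon_\mathrm{ad}\times(\text{adhered bead surface density})$.

**Rupture.** A bead left with fewer than 3 neighbours within $r_c$ for more
than 100 steps flags the membrane as torn and ends the run. Strong binding
does tear the membrane — runs at
$\varepsilon_\mathrm{ad} \gtrsim 2.5\,\varepsilon$ (short adhesion range)
rupture reliably, which is why the default wrapping regime uses a moderate
well depth with a longer range ($\varepsilon_\mathrm{ad} = 1.6$,
`r_cut_ad = 1.8`), spreading the load over more beads.

**Scale mapping.** The default wrapping scenario uses a 1600-bead vesicle
(radius $\approx 11.6\,\sigma_b$) and lobe radius $a = 2$–$2.5\,\sigma_b$,
i.e. the vesicle radius is 2–3 dumbbell long axes. The experimental ratio
(a ~1 µm dumbbell in a 5–15 µm GUV) would need tens of thousands of beads;
the chosen size keeps a wrapping run at minutes of CPU while leaving the
lobe well resolved (~50 beads of membrane per lobe). Consequences of the
smaller ratio — a more strongly curved ambient membrane and a larger
area fraction consumed by wrapping (~7%) — are discussed under
*Limitations*.

## Wrapping observables and state taxonomy

For each snapshot the package reports the tilt angle
$\theta = \arccos|\hat{\mathbf u}\cdot\hat{\mathbf n}| \in [0^\circ,90^\circ]$
between the dumbbell axis and the *undistorted-sphere* radial direction at
the particle (the experimental definition against the GUV, not the local
deformed membrane normal), the insertion depth $d = R - |\mathbf x_\mathrm{com}
- \mathbf x_\mathrm{ves}|$ (positive inward, reported in units of $d_s$),
the height $z$ above the equator, and per-lobe wrapped fractions
$f_1 \ge f_2$ (the more-wrapped lobe is lobe 1 by convention). Tracking
retains frames with $-0.8R < z < 0.8R$, where both lobes can be located.

Wrapped fractions are estimated on a fixed 500-point quasi-uniform mesh per
lobe: a mesh point is covered when a membrane bead lies within the adhesion
cutoff, and the *neck-occluded cap* — where a bead adhering to the other
lobe would also register as contact — is excluded from the denominator,
making coverage attribution unambiguous.

Frames are classified into the state taxonomy: attachment states A1
(perpendicular, $\theta < 30^\circ$), A2 (oblique), A3 (parallel, both
lobes bound); B (first lobe partially wrapped, single-lobe contact); C
(both lobes shallowly bound); D (one lobe engulfed to the waist, other lobe
never bound — terminal); E1/E2 (asymmetric/symmetric consecutive wrapping);
F (fully wrapped — terminal). The fraction thresholds (0.05, 0.2, 0.45,
0.9) and the $30^\circ$ band are classifier conventions — the states are
defined pictorially in the experimental literature — and are configurable;
the classifier is validated against an independent re-implementation over
an exhaustive input grid. Transition times between states are measured
between run onsets after removing flickers shorter than a 5-frame debounce
window. Second-lobe contact is latched once seen: the biotin–NeutrAvidin
bonds it models are effectively irreversible, which is also why a
transition out of D into F is never observed on simulation timescales.

## Flicker spectroscopy

A quasi-spherical vesicle's equatorial contour $r(\varphi,t)$ is decomposed
into Fourier modes $c_n = \frac{1}{2\pi}\oint
[r(\varphi)/R - 1]e^{-in\varphi}\,d\varphi$. In the quasi-circular static
reduction the equilibrium mode powers are

$$\langle|c_n|^2\rangle = \frac{k_BT}{2\kappa}\,
\frac{1}{(n^2-1)\,(n^2 + \sigma R^2/\kappa)}, \qquad n \ge 2.$$

Mode powers of a thermally fluctuating contour are exponentially
distributed about these means, so `fit_fluctuation_spectrum()` maximises
the corresponding likelihood (per-mode mean powers over frames are
sufficient statistics), optionally with an additive white noise floor for
tracking error, and reports asymptotic standard errors. The default fit
range $n \in [3, 20]$ excludes the drift-contaminated lowest modes and the
noise-dominated high modes. The full video-microscopy treatment includes
integration-time and projection corrections; the static form suffices for
the synthetic data and the simulation-scale contours this package
produces. On synthetic contours at experimental scales
($\sigma = 100\,$nN/m, $\kappa = 20\,k_BT$, $R = 10\,\mu$m, 2000 frames)
the estimator recovers $\sigma$ within 10% and $\kappa$ within 20%.

## Analytical wrap-time theory

The dumbbell surface is modelled as two tangent spheres of radius
$a = d_s/2$ joined by a torus fillet of radius $\rho_n$ smoothing the
tangent-point singularity. The wrapping front is the axisymmetric contact
line at meridian arc length $s$ from the first-contact pole. The energy of
a partially wrapped state is

$$E(s) = -W A_w(s) + \sigma\,A_w(s)\frac{1-\cos\psi(s)}{2} +
\int_0^s 2\kappa H^2\,dA,$$

where $A_w$ is the wrapped area (closed form per zone), $\psi$ the
meridional tangent angle at the front (the $(1-\cos\psi)/2$ factor is the
standard far-field leading-order excess-area cost of tension) and $H$ the
mean curvature of the wrapped, neck-smoothed surface. The front advances
by an overdamped balance of thermodynamic drive against contact-line
friction,

$$v(s) = \frac{\max(0, -dE/ds)}{\alpha\,\eta_\mathrm{eff}\,L(s)},\qquad
T = \int \frac{ds}{v(s)},$$

with $L(s)$ the contact-line circumference (floored at $0.05a$ near the
poles, where the integration also starts/ends, representing the finite
initial contact patch) and $\alpha$ a dimensionless drag coefficient
(default 2). Where the drive is non-positive the front stalls and the
result is `STALLED` with the first stall location. In the single-sphere
limit every quantity reduces to the classical sphere-wrapping closed forms,
which the test suite checks to $10^{-8}$.

**The two neck radii.** With the purely geometric smoothing
$\rho_n = 0.15a$ (the default of `dumbbell_geometry()`), the bending-energy
density in the neck, $\sim\kappa/2\rho_n^2$, exceeds any experimentally
plausible adhesion: the landscape has a large barrier at the waist and the
front always stalls there — this is the regime behind the observed
metastable half-wrapped state, and it is the geometry used for the barrier
estimate below. A real membrane, however, does not conform to the tangent
junction: it detaches and bridges the neck with a wide, nearly minimal
(catenoid-like) surface. The wrap-time *kinetics* therefore use an
effective bridged-neck radius $\rho_n = 0.6a$, for which wrapping completes
below a tension threshold (about $2\text{–}3\times10^{-8}$ N/m at
$W = 0.76\,\mu$J/m², $\kappa = 20\,k_BT$) and $T(\sigma)$ grows
nonlinearly, diverging toward the stall threshold. Both radii are exposed
as parameters; the split is a modelling choice of this package, made once
and stated here.

With $\kappa = 20\,k_BT$ and $a = 0.49\,\mu$m, the spontaneous-wrapping
threshold for a sphere is $W_c = 2\kappa/a^2 \approx 0.69\,\mu$J/m² — the
experimentally inferred adhesion range ($0.69$–$0.79\,\mu$J/m²) sits just
above it, which is why wrap times are long (tens to hundreds of seconds)
and steeply tension dependent.

**Fitting.** `fit_wrap_time()` performs least squares on $\log T$ over
$(W, \eta_\mathrm{eff})$ with $\kappa$ fixed. The theory is exactly linear
in $\eta_\mathrm{eff}$, so $\log\eta_\mathrm{eff}$ is profiled out
analytically and the optimisation is one-dimensional in $\log W$ (coarse
log-grid scan, then golden-section refinement); stalled predictions are
excluded by a penalty. Confidence intervals come from the Jacobian at the
optimum. Log-space fitting matters because $T$ spans decades near the
stall threshold.

**Fluctuation barrier.** For the geometric neck, the barrier
$\Delta E$ between the half-wrapped minimum and the landscape maximum at
the waist is converted to a required membrane excursion $h^*$ by modelling
the excursion as a single mode of wavevector $q = \pi/a$ over the waist
annulus (area $\pi(a^2-\rho_n^2)$) with areal stiffness
$\sigma q^2 + \kappa q^4$:
$\Delta E = \tfrac12(\sigma + \kappa q^2)q^2 A\,h^{*2}$. This is an
order-of-magnitude estimator; at experimental parameters it gives
$h^* \sim 10^2$ nm, far beyond typical thermal roughness, consistent with
the half-wrapped state being terminal unless the second lobe binds first.

## Synthetic data

Three generators, all deterministic given a seed, feed the pipeline:

* `synth_contours()` draws mode amplitudes from the equilibrium spectrum
  (complex Gaussian, hence exponential powers), inverse-transforms to
  $r(\varphi)$ and adds white tracking noise.
* `synth_pathway()` produces observable series through the milestones of
  the four canonical pathways (initially parallel/perpendicular ending
  fully/half wrapped): cubic-spline milestone interpolants plus tracking
  noise (3° rms in $\theta$, 0.03 µm rms in $d$ — typical tracking
  precision), *not* mechanistic simulations. The fully-wrapped templates
  carry the overshoot–recoil signature (depth to $\approx1.5\,d_s$, then a
  $\approx0.7\,d_s$ plateau); the half-wrapped templates end near
  $0.5\,d_s$ at near-perpendicular tilt without overshoot; the waist
  crossing is the slowest segment.
* `synth_wraptime_dataset()` evaluates the theory on a tension grid and
  applies multiplicative lognormal noise.

What passing tests on these data do and do not show: recovery tests prove
the estimators are correct for data generated by their own forward models
(plus noise); pathway round-trips prove the observables/classifier machinery
resolves the documented phenomenology. They do not validate the spectral
model against real video microscopy (no integration-time/projection
corrections, no correlated tracking noise) nor the wrap-time theory against
real kinetics (adhesion-site disorder and membrane reservoir effects are
absent).

## Problem sizes and numerical choices

The packaged study conditions are chosen to keep every stage at desk scale:
tension-estimator checks use 128 angular samples and 2000 frames; theory
fits use 8 tensions and 20 noise replicates; wrapping-simulation checks use
a 1600-bead vesicle ($R \approx 11.6\,\sigma_b$), lobe radius
$2.2\,\sigma_b$, $\varepsilon_\mathrm{ad} = 1.6$, `r_cut_ad` $= 1.8$, and
runs of $4$–$12\times10^4$ steps at $\delta t = 0.01\,\tau_0$ (400–1200
$\tau_0$, bracketing the full-engulfment timescale of such simulations),
with small ensembles (a handful of seeds) rather than the tens of runs a
production study would use. Low tension is imposed as matched solute
concentrations ($\sigma \approx 0$, the vesicle keeps its excess area);
high tension as an inner-solute excess pressurising the vesicle, which
inflates it taut and suppresses wrapping of the second lobe — the same
mechanism by which tension selects the half-wrapped end state in
experiments.

Numerical conventions worth knowing: stall detection samples the drive on a
2001-point grid; the wrap-time quadrature is adaptive (`integrate`) on
$1/v$; the fillet bending integral is tabulated once per geometry on a
2001-point grid; tie-breaks in `wrapped_fraction` resolve equidistant
lobes to lobe 1; degenerate inputs (all-zero spectra, fewer than 3 fit
points, out-of-range front positions) raise errors rather than returning
silently.

## Limitations

* The simulation is solvent-free (no hydrodynamics): wrapping *rates* in
  reduced units map to real time only through an effective friction, so
  cross-checks against the theory are qualitative (ordering, stall
  behaviour), not quantitative rate comparisons.
* The scaled-down vesicle/colloid ratio makes membrane-area consumption
  during wrapping non-negligible (~7%), so tension rises during a run more
  than it would for a GUV; outcomes (F vs D fractions) are therefore
  ensemble targets, not per-seed predictions.
* At strong binding the membrane can tear (flagged, not prevented) — also
  observed in the experiments this package models.
* The flicker module implements the static quasi-circular spectrum; finite
  exposure and 3D-projection corrections are left as an explicit
  multiplicative hook.
* Flicker spectroscopy *of the simulated vesicles* can measure the bending
  rigidity but not the tension: at desk-scale radii
  ($R \approx 7$–$12\,\sigma_b$) the dimensionless combination
  $\sigma R^2/\kappa$ stays below ~2 for any sub-rupture tension, so every
  measurable mode is bending-dominated and $\sigma$ is unidentifiable from
  the contour spectrum. `equatorial_contour()` extracts the contours all the
  same; quantitative tension estimation requires the micrometre-scale radii
  of the synthetic-contour generator, where $\sigma R^2/\kappa \sim 10^2$.
* The wrap-time theory is axisymmetric: tilted wrapping pathways, which
  real dumbbells use to lower the barrier, are outside its scope — it
  describes the symmetric bound on the kinetics.
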