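# vesiwrap

Tools for studying how lipid vesicles wrap **anisotropic dumbbell
particles** — the passive first stage of endocytosis for a non-spherical
object. The package targets the model system of a giant unilamellar vesicle
(GUV) engulfing a colloidal dumbbell (two tangent spheres, sphere diameter
`d_s ≈ 1 µm`) bound by irreversible ligand–receptor adhesion, and provides:

* **`membrane_sim`** — a coarse-grained Langevin simulator: a
  one-particle-thick fluid membrane vesicle of orientable beads, membrane
  tension imposed by volume-exclusion solutes inside/outside the vesicle
  (ideal-gas Laplace pressure), and an adhesive rigid dumbbell, with
  rupture detection.
* **`trajectory_analysis`** — the wrapping observables: tilt angle `θ`
  between dumbbell axis and vesicle normal, insertion depth `d` relative to
  the undistorted sphere, the `−0.8R < z < 0.8R` tracking band, per-lobe
  wrapped fractions, a nine-state wrapping taxonomy
  (`A1 A2 A3 B C D E1 E2 F`) and debounced state-transition times.
* **`tension_spectroscopy`** — flicker spectroscopy: equatorial contour
  Fourier modes with equilibrium powers
  `⟨|c_n|²⟩ = (k_BT/2κ) / [(n²−1)(n² + σR²/κ)]`, and a maximum-likelihood
  fit of tension `σ` and bending rigidity `κ`.
* **`wrap_theory`** — an analytical overdamped contact-line theory of
  dumbbell engulfment: energy landscape
  `E(s) = −W A_w(s) + σ A_w (1−cos ψ)/2 + ∫2κH² dA` over the
  neck-smoothed two-sphere surface, front velocity
  `v = max(0, −dE/ds)/(α η_eff L)`, wrap time `T(σ)` with stall
  detection, `(W, η_eff)` fitting to wrap-time data, and the
  fluctuation-amplitude estimate of the waist barrier.
* **`synthetic_data`** — seeded generators for contour series with known
  `(σ, κ)`, canonical wrapping pathways (parallel/perpendicular ×
  full/half wrapped, with the overshoot–recoil signature), and noisy
  wrap-time datasets.

## Worked example

Estimate a vesicle's tension from synthetic contour data, then predict and
fit dumbbell wrap times:

```r
library(vesiwrap)
kT <- thermal_energy()                    # 4.11e-21 J at 298 K

## flicker spectroscopy on a synthetic GUV (sigma = 100 nN/m, kappa = 20 kT)
series <- synth_contours(sigma = 1e-7, kappa = 20 * kT, R = 1e-5,
                         n_frames = 2000, seed = 1)
fit_fluctuation_spectrum(series)
#> spectrum_estimate: sigma = 9.998e-08 +/- 1.2e-09 N/m, kappa = 19.74 kBT (8.12e-20 J)
#>   modes n in [3, 20], 2000 frames

## wrap-time theory at the experimentally inferred parameters
geom <- dumbbell_geometry(a = 0.49e-6, rho_n = 0.6 * 0.49e-6)
ep   <- energy_params(W = 0.76e-6, sigma = 0, kappa = 20 * kT)
kp   <- kinetic_params(eta_eff = 0.8)
wrap_time_curve(c(2e-9, 1e-8, 2e-8), ep, kp, geom)[, 1:2]
#>   sigma     time
#> 1 2e-09 48.94250
#> 2 1e-08 59.66840
#> 3 2e-08 95.24231

## recover (W, eta_eff) from a noisy dataset
ds <- synth_wraptime_dataset(W = 0.76e-6, eta_eff = 0.8, cv = 0.05, seed = 1,
                             geom = geom)
fit_wrap_time(ds$sigma, ds$time, geom, kappa = 20 * kT)
#> wrap_fit: W = 7.582e-07 J/m^2 [7.54e-07, 7.62e-07], eta_eff = 0.7754 Pa.s [0.708, 0.849]
#>   n = 8 points (0 dropped), RMS log-residual = 0.0378
```

The fitted tension is within a few percent of the generating 100 nN/m; the
wrap time grows nonlinearly with tension (diverging toward a stall
threshold near 2–3×10⁻⁸ N/m at these parameters); and the fit recovers the
generating adhesion energy (0.76 µJ/m²) and microviscosity (0.8 Pa·s)
within the noise.

A wrapping simulation and its observables:

```r
traj <- simulate_wrapping(n_beads = 1600, R0 = vesicle_radius_for(1600),
                          a = 2.2, orientation = "parallel",
                          target_sigma = 0,
                          sim = sim_params(dt = 0.01, n_steps = 80000,
                                           epsilon_ad = 1.6, r_cut_ad = 1.8,
                                           stride = 4000, seed = 1))
obs <- trajectory_observables(traj)
tail(obs[, c("time", "theta", "d_ds", "f1", "f2", "state")], 1)
```

A low-tension run typically passes `A3/C → E2/E1 → F` from a parallel
start, or `A1 → B → D → E1 → F` from a perpendicular one (fully wrapped,
`f1 ≈ f2 ≈ 1`), with the slow step at the dumbbell waist; pressurising the
vesicle (larger `target_sigma`) suppresses second-lobe wrapping.

There is also a thin command-line wrapper, `inst/cli/vesiwrap.R`:

```sh
Rscript inst/cli/vesiwrap.R synth contours --sigma 1e-7 --frames 500 --seed 1 --out out/
Rscript inst/cli/vesiwrap.R tension --in out/contours.csv --out out/
```

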