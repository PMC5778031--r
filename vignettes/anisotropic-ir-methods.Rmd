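---
title: "Methods: direction-resolved IR spectra of confined protonated water clusters"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: direction-resolved IR spectra of confined protonated water clusters}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

This vignette documents the models, conventions and numerical choices behind
`anisoIR`, in the spirit of a methods section: what is computed, under which
assumptions, which knobs matter, and what the synthetic data can and cannot
tell you about real systems.

## 1. Spectra from dipole fluctuations

The infrared absorption of a simulated system is obtained from the
autocorrelation of the dipole-moment derivative,

$$A_{\alpha\alpha}(\nu) \;\propto\; \int \langle \dot\mu_\alpha(0)\,
\dot\mu_\alpha(t)\rangle\, e^{-i\omega t}\, \mathrm{d}t,
\qquad \omega = 2\pi c \nu,$$

resolved per Cartesian direction $\alpha \in \{x, y, z\}$, which is what
makes the spectra *anisotropic*: for a cluster with a symmetry axis along
$z$, $A_{zz}$ and $A_{xy} = (A_{xx}+A_{yy})/2$ answer different physical
questions, and their ratio over a band quantifies its polarization.

**Estimator.** `spectrum_from_dipole()` computes the one-sided periodogram
of $\dot\mu_\alpha$ (Wiener–Khinchin route, equivalent to transforming the
*biased* autocovariance estimator). The biased estimator is chosen because
it never produces negative spectral densities and is the standard choice
for smooth vibrational spectra; its price is a $O(2\tau_c/T)$ downward bias
for features with correlation time $\tau_c$ on segments of length $T$,
which is why spectra are always averaged over many NVE segments rather than
estimated from one long trajectory.

**Normalization.** The proportionality constant is a convention. We fix it
so that the unsmoothed spectrum satisfies the discrete Parseval sum rule
$\sum_\nu A_{\alpha\alpha}(\nu)\,\Delta\nu = \overline{\dot\mu_\alpha^2}$
per component (units: (e Å fs⁻¹)² per cm⁻¹). This makes spectra computed
with the same convention mutually comparable to scale, which is all that
directional ratios, decompositions and difference spectra require. The
tests assert the sum rule to 1e-6 on noiseless fixtures (it holds to
machine precision).

**Differentiation.** $\dot\mu$ uses central differences in the interior and
one-sided differences at the two endpoints (`dipole_derivative()`), an
$O(\Delta t^2)$ scheme whose Taylor remainder is verified numerically in the
tests. The mean of $\dot\mu$ is removed by default (`detrend = TRUE`),
which zeroes the $\nu = 0$ bin; any check against a continuous reference
must therefore exclude the DC bin.

**Smoothing.** `smooth_gaussian()` convolves each component on the
wavenumber grid with a normalized Gaussian (default width
$\sigma_\nu = 50$ cm⁻¹, the conventional visualization width for AIMD water
spectra), truncated at six standard deviations with reflective edge
handling, which conserves band integrals and cannot create negative values.
$\sigma_\nu = 0$ is the exact identity. Smoothing is applied after segment
averaging, mirroring how such figures are prepared.

**Statistical errors.** Two routes are provided:

* segment scatter: `average_segments()` records the per-grid-point standard
  error over NVE segments;
* equivalent directions: for uniaxial clusters, $x$ and $y$ are
  statistically equivalent, so $|A_{xx}-A_{yy}|/2$ estimates the noise of
  the radial average (`radial_average()`).

A caution that we consider a genuine methods point: the per-point
half-difference is a *one-degree-of-freedom* variance estimate, so the
ratio $|A_{zz}-A_{xy}| / (|A_{xx}-A_{yy}|/2)$ is Cauchy-like — for
perfectly isotropic data only about two-thirds of grid points fall within
three times this "error". Isotropy tests in this package therefore use
`equivalent_direction_error()`, which pools the squared x/y half-differences
over segments (2M degrees of freedom for M segments) and propagates them to
the variance of $A_{zz} - A_{xy}$ of the segment average
($1.5\,\hat\sigma^2_{\mathrm{seg}}/M$). With this estimator a
$3\sigma$ criterion has its nominal coverage.

**Quantum corrections.** Harmonic quantum correction factors for classical
dipole autocorrelations are deliberately *not* applied; the estimator
operates on classical trajectories as given. (A multiplicative
post-processing hook is trivial to apply to the returned grid if desired.)

## 2. Dipole models and excess-proton bookkeeping

Two charge models (`charge_model()`):

* `wannier_full` — valence core charges (O +6 e, H +1 e) plus −2 e on each
  maximally localized Wannier center (four electron pairs per water). This
  is the "nuclei + electrons" dipole: electronic polarization is carried by
  the center displacements.
* `nuclear_effective` — nuclei only with $q_\mathrm{H} = -q_\mathrm{O}/2 =
  +1\,e$. This deliberately *overestimates* the water molecular dipole
  (an ideal monomer gives $|\mu| = 1.17$ e Å) but gives one excess proton
  exactly its +1 e charge, so it cleanly isolates the nuclear-motion
  contribution to a protonated cluster's spectrum.

Charge accounting (0 e neutral, +1 e protonated, per molecule and per
frame) is an invariant asserted across the test suite.

**Assignment and defect tracking.** `assign_molecules()` maps every H to
its geometrically nearest O, re-evaluated each frame with no topology
memory — the standard defect tracker under Grotthuss topology changes.
Ties (numerically equidistant H) break toward the lower atom index, a
documented determinism choice. Wannier centers attach to their nearest O
within 1.0 Å (bond and lone-pair centers in water lie within ~0.5 Å);
centers beyond the cutoff are flagged with a warning, not fatal, so a
single distorted frame cannot abort an analysis. The hydronium is the
unique O with three assigned H (`find_excess_proton()`); zero such O means
a neutral frame, and two or more (or any O with four H) raises a
defect-multiplicity error, which almost always indicates a wrong
protonation flag or an unphysical frame.

**Zundel vs Eigen.** Among the three hydronium hydrogens,
`classify_zundel()` selects the shared proton H\* minimizing the distance
asymmetry $\delta = |d(\mathrm{O_1H^*}) - d(\mathrm{O_2H^*})|$, with
$\mathrm{O_2}$ the nearest other oxygen; the state is Zundel when
$\delta < 0.25$ Å. The threshold is configurable: 0.25 Å is a common
geometric Zundel/Eigen discriminator, and since occupation probabilities
depend on it, they should be read as *relative* measures across geometries
at a fixed threshold, not absolute populations.

**Subgroup projection.** The Zundel-complex contribution is computed by
restricting the dipole sum to the O₂H₅⁺ sites (plus their assigned Wannier
centers in the full model). Because that selection carries +1 e, its dipole
is referenced to the selection's instantaneous geometric center, which
makes it translation invariant; the same rule applies to any charged
selection, including the full protonated cluster. This is a documented
stand-in for more elaborate projection formalisms: cross-correlation
(interference) terms between the subgroup and the remainder are excluded by
construction, so subgroup spectra decompose power, not amplitudes.

## 3. The synthetic-data stage

The generator replaces ab initio MD with a classical flexible-water toy
model so that the full pipeline runs at desk scale. It preserves the
*protocol* of the study conditions, not the electronic structure:

* **Geometries and confinement** (`confinement_spec()`): chains, discs and
  droplets of 15, 15 and 26 waters, stabilized by harmonic wall potentials
  acting on the oxygens only — $U^{\mathrm{chain}}_{xy} = K_{xy}(x^2+y^2)/2$
  with $K_{xy} = 2000$ (narrow) or 20 (wide) kJ mol⁻¹ nm⁻²,
  $U^{\mathrm{disc}} = K_z z^2/2 + K_{xy}(x^2+y^2)/2$ with $K_z = 2000$,
  $K_{xy} = 30$, and $U^{\mathrm{drop}} = K_r r^2/2$ with $K_r = 40$.
  Analytic forces are validated against finite differences.
* **Force field** (`run_toy_md()`): harmonic O–H bonds
  ($r_0 = 0.9572$ Å, $k_b = 4431.5$ kJ mol⁻¹ Å⁻²), harmonic H–O–H angle
  ($\theta_0 = 104.52°$, $k_a = 412.6$ kJ mol⁻¹ rad⁻²), SPC-like point
  charges ($q_\mathrm{H} = 0.41$ e) with Lennard-Jones on oxygen, all
  intermolecular pairs unscreened (no cutoff — the clusters are small and
  non-periodic). The angle constant was set so the model's *own* bend
  normal mode sits near the water bending band; `water_normal_modes()`
  exposes the model's three vibrational frequencies from a numeric
  mass-weighted Hessian, and the spectral tests compare simulated bands to
  those model frequencies, never to experimental ones. The excess proton is
  a third harmonic O–H bond on its oxygen (charges adjusted to keep the
  molecule at +1 e); the topology is fixed for the whole run.
* **Protocol** (`sim_params()`): Maxwell–Boltzmann initialization, BAOAB
  Langevin equilibration at $T = 300$ K (friction 2 ps⁻¹; a thermostat
  choice adequate for generating decorrelated NVE starting points), then
  velocity-Verlet NVE segments (default 5 ps, $\Delta t = 0.5$ fs,
  positions recorded every second step) separated by 0.5 ps thermostatted
  decorrelation stretches. Segment total energy is recorded; drift beyond
  1% of the thermal kinetic energy fails the test suite, and any velocity
  above 1 Å fs⁻¹ aborts with a stability error suggesting a smaller
  time step.
* **Proton-hop emulator** (`attach_proton_hopper()`): the physics of
  Grotthuss transport is *not* in the force field. Instead, a +1 e defect
  rides the time-averaged oxygen sites and performs Poisson-timed hops
  (default 20 ps⁻¹) to adjacent sites, interpolating linearly over a
  transit time drawn from 5–20 fs. The axis policy projects the defect
  dipole onto the direction of maximal extension — chain: $z$ only
  (hops along the z-ordered oxygen ladder, reflecting at the ends); disc:
  $xy$ only; droplet: isotropic nearest-neighbor hops. Using *static*
  time-averaged sites makes a rate-0 hopper exactly silent after
  detrending, and guarantees that the injected broadband power has the
  intended polarization by construction. The emulator models only the
  defect's translational dipole; it does not emulate electronic
  polarization amplification, so comparisons between the full and
  nuclear-effective routes exercise the two code paths structurally, not
  quantitatively.
* **Wannier synthesis** (`synthesize_wannier()`): four electron-pair
  centers per oxygen — two bond centers 0.5 Å from O along each O–H, two
  lone-pair centers 0.3 Å from O along ± the HOH-plane normal (for the
  hydronium: three bond centers and one lone pair along the negative
  pyramid direction) — plus optional seeded Gaussian jitter. The template
  admits a closed-form molecular dipole used as an exact oracle in the
  tests.
* **Analytic fixtures** (`generate_oscillator_dipole()`): sharp cosine
  modes at chosen wavenumbers, plus an optional Ornstein–Uhlenbeck
  component injected into the dipole *derivative* (the dipole is its
  cumulative sum), whose derivative PSD is exactly the Lorentzian
  $4\sigma^2\tau/(1+(2\pi f\tau)^2)$. The analytic reference is returned
  alongside the series.

**What passing tests do and do not show.** The synthetic stage reproduces
the qualitative polarization pattern — axial continuum band for chains,
in-plane for discs, isotropy for droplets — and the bookkeeping invariants
(charges, defect uniqueness, seeded reproducibility). It does not
reproduce, and is not intended to reproduce, ab initio band shapes,
electronic amplification of the continuum band, real Grotthuss chemistry,
nuclear quantum effects, or quantitative Zundel populations (the harmonic
fixed-topology model holds the defect in an Eigen-like geometry; Zundel
occupation on toy trajectories is near zero at the default threshold).

**Problem sizes.** The shipped tests run the simulator at reduced sizes
chosen as a deliberate compromise between statistical power and a test
suite that completes in minutes on one core: 2 ps equilibration with
2 × 2 ps NVE segments for chains and discs, 4 × 1.5 ps for the droplet,
a single 10 ps thermostatted run for the temperature check, and 26–256
analytic OU segments for estimator checks. All stochastic stages take a
single root seed and derive named substreams, and are bit-reproducible for
a fixed seed.

## 4. Polarized ATR resolution

For a uniaxial film on an internal reflection element, the two-phase
(Harrick thick-film) approximation gives squared effective field
amplitudes, with $n_{31} = n_3/n_1$, $s = \sin^2\alpha$:

$$E_y^2 = \frac{4\cos^2\alpha}{1-n_{31}^2},\qquad
E_x^2 = \frac{4\cos^2\alpha\,(s-n_{31}^2)}{D},\qquad
E_z^2 = \frac{4\cos^2\alpha\, s}{D},$$
$$D = (1-n_{31}^2)\left[(1+n_{31}^2)s - n_{31}^2\right].$$

Perpendicular polarization probes only the in-plane absorber
($A_\perp = E_y^2 a_{xy}$), parallel polarization a linear combination
($A_\parallel = E_x^2 a_{xy} + E_z^2 a_z$); `resolve_components()` inverts
these per grid point, normalized so an isotropic absorber yields
$A_{xy} = A_z$ exactly. The inversion is algebraically exact (round-trip
to 1e-10 in the tests). The isotropic dichroic ratio
$R = (E_x^2+E_z^2)/E_y^2$ is strictly decreasing in $\alpha$ above the
critical angle, so `angle_from_ratio()` can invert it by bracketed
root-finding (tolerance 1e-6 degrees) on
$(\theta_c, 90°)$, with the attainable range $(2-n_{31}^2,\, R(\theta_c^+))$
guarded explicitly. Shipped constants: $n_\mathrm{Si} = 3.42$ and
$n_\mathrm{water} = 1.32$ (standard mid-IR values, used for the
calibration computation) and $n = 1.6$ for rehydrated membrane-protein
films (the default sample index in `atr_geometry()`).

Design choices worth stating: the two-phase *thick*-film limit is used
throughout (no three-phase thin-film Fresnel treatment, no dispersion or
Kramers–Kronig correction, no multi-reflection accessories); the film is
assumed uniaxial ($a_x = a_y$), matching stacked membranes with the normal
along $z$; absorbances are treated per unit effective path, the global
constant being fixed by the isotropy normalization. `sensitivity_scan()`
re-resolves the input over a grid of $(\alpha, n_3)$ assumptions (default
37/39/41° × 1.5/1.6/1.7) and reports maximal deviations from the reference
geometry — the standard robustness check for the uncertainty in those two
parameters.

The diagnostic logic for oriented films falls out of the algebra: a
continuum band present in $A_\perp$ and $A_\parallel$ with
$A_\parallel/A_\perp = R_\mathrm{iso}$ resolves into equal $A_{xy}$ and
$A_z$; once $A_\parallel/A_\perp$ drops below $E_x^2/E_y^2$, $A_z$ changes
sign while $A_{xy}$ does not — so a band that appears strongly in the
lateral component and nearly vanishes in the normal one indicates an
absorber extended in the membrane plane.

## 5. Orchestration and reproducibility

A single YAML configuration drives all stages (`read_run_config()`,
`run_simulate()`, `run_spectra()`, `run_atr()`, with a thin shell wrapper
in `exec/anisoir`). Each stage writes a JSON manifest with the package
version, root seed, config hash and MD5 checksums of every output file;
identical config plus seed reproduces outputs byte-identically. File
formats are deliberately plain: multi-frame (extended) XYZ for
trajectories — Wannier centers either inline as `X` pseudo-atoms or as a
parallel XYZ-like file, both CP2K-style dialects — and CSV with a fixed
header contract for spectra and ATR tables. Units are Å, fs, elementary
charge, kJ mol⁻¹ and cm⁻¹ throughout; non-periodic systems only.

## 6. Known limitations

* The toy force field is a stand-in: band positions reflect its spring
  constants, and hydrogen-bond-induced shifts are only qualitatively
  water-like.
* Subgroup spectra omit subgroup–remainder interference terms.
* The Zundel/Eigen threshold is geometric and user-set; occupations are
  threshold-relative.
* The hop emulator is Markovian with a fixed rate; real defect dynamics
  are correlated with the hydrogen-bond network.
* The ATR model ignores optical dispersion across a band and thin-film
  interference; it is accurate in the thick-film, weak-absorption regime
  it targets.
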