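---
title: "Models and methods: mechanical cell competition in mechcompete"
author: "mechcompete authors"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods: mechanical cell competition in mechcompete}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
library(mechcompete)
```

# Scope

`mechcompete` studies how differences in adhesion decide mechanical
competition between two epithelial cell populations sharing a substrate.
It contains four scientific components:

1. a 3D multiphase-field simulator of an active cell monolayer with two
   cell types that differ in cell-cell and cell-substrate adhesion
   (`simConfig()`, `runSimulation()`);
2. the fluctuation and extrusion statistics that characterise the active
   interface (`susceptibility()`, `susceptibilityProfile()`,
   `spatialAutocorrelation()`, `detectExtrusions()`,
   `extrusionDistancePDF()`, `ensembleStressMap()`, ...);
3. an analytic energetics model of the work needed to eliminate a cell
   through a constant-volume cylinder-cone-sphere shape sequence
   (`eliminationWork()`, `phaseDiagram()`);
4. a force-inference chain from substrate displacements to tissue stress
   (`fttc()`, `bism()`) with exact forward models for validation.

Synthetic-data generators (`genGaussianField()`, `genStressTractionPair()`,
`genExtrusionCatalog()`, ...) provide ground truth with known parameters so
every stage is testable without experimental data.

# The multiphase-field model

Each cell $i$ is a smooth indicator field $\phi_i(\vec x, t) \in [0, 1]$ on
a grid that is periodic in $x$ and $y$ and bounded in $z$; a static field
$\phi_w$ represents the rigid substrate at the bottom.  The free energy is

$$
F = \sum_i \frac{\gamma^i}{\lambda}\int
    \left\{4\phi_i^2(1-\phi_i)^2 + \lambda^2 |\nabla\phi_i|^2\right\}
  + \sum_i \mu\left(1 - \frac{1}{V_0}\int\phi_i^2\right)^2
  + \sum_i\sum_{j\neq i}\frac{\kappa_{cc}}{\lambda^2}\int\phi_i^2\phi_j^2
  + \sum_i\sum_{j\neq i}\omega_{cc}^i\int\nabla\phi_i\cdot\nabla\phi_j
  + \text{substrate terms},
$$

with cortex tension $\gamma$, diffuse-interface width $\lambda$, a soft
volume constraint of strength $\mu$ around $V_0 = \tfrac43\pi R_0^3$, and
repulsion/adhesion couplings $\kappa$ and $\omega$.  The interface relaxes
by time-dependent Ginzburg-Landau dynamics with an advective term that
rigidly translates each cell with its overdamped velocity
$\vec v_i = (\alpha\hat p_i + \vec F_i^{int})/\xi$.  The interaction force
and the traction transmitted to the substrate are
$\vec T_i = \vec F_i^{int} = -\int \Pi^{int}\cdot\nabla\phi_i$, where the
interaction stress collects the isotropic part $-\sum_j \delta F/\delta\phi_j$
and the active stresses $-\zeta_S^i\phi_i \mathbf S_i$ (deviatoric cell-shape
stress) and $-\zeta_Q^i\phi_w \mathbf Q_w$ (substrate stress-fibre stress).
Polarity follows contact inhibition of locomotion: the angle relaxes toward
the traction direction with timescale $\tau_{pol}$ and diffuses with
rotational diffusivity $D_r$.  Extrusion is emergent: no rule removes a
cell; once out-of-plane forces overcome what keeps a cell on the substrate
it leaves the monolayer, and the analysis layer merely *detects* this
(`detectExtrusions()`, thresholds documented there).

## Discretization choices

* All gradient-square energy terms are discretized as sums over grid links
  (forward differences), so the 7-point laplacian used in the functional
  derivative is the **exact gradient** of the discrete energy.  This is what
  makes the passive energy-descent test sharp: with activity and noise off,
  $F$ never increases within per-step tolerance $10^{-6}|F|$.
* Advection uses first-order upwinding with the rigid per-cell velocity.  A
  CFL cap of $0.4\,a_0/dt$ per velocity component protects the explicit
  scheme against the large transient repulsion of overlapping initial
  droplets; after the first few steps typical speeds are two orders of
  magnitude below the cap.
* `simConfig()` refuses a time step above an explicit-Euler stability
  estimate based on the stiffest gradient-form terms,
  $dt < a_0^2 / (6\,\Gamma\,2\lambda(\gamma + 2\omega_{cc}))$.
* The polarity alignment is skipped when the in-plane traction is
  numerically zero ($|T_{xy}| < 10^{-10}$): the direction of a zero vector
  is undefined, and aligning to floating-point noise would (and in early
  versions did) break the exact translation equivariance of the dynamics.

## Composition of the interaction stress

Two terms of the free energy have functional derivatives that do not vanish
where the cell itself is absent: the cell-substrate adhesion cross-gradient
term, and the substrate active stress $\zeta_Q\phi_w\mathbf Q_w$.  Summing
such terms over all cells into one shared stress field makes the substrate
push on every cell with a force that grows linearly with the number of
cells — an unphysical artifact of composing per-cell functional derivatives
into a single field.  `mechcompete` therefore:

* models cell-substrate **adhesion** as a contact well
  $-(\omega_{cs}/\lambda^2)\int\phi_i^2 W(\phi_w)$ with
  $W = 16\phi_w^2(1-\phi_w)^2$ peaked on the substrate surface band.  This
  keeps the adhesive force proportional to the cell's own local presence
  (no spurious wetting layer far from the cell), has an exact discrete
  gradient, and represents the same short-range contact adhesion;
* applies the substrate active stress in each cell's force integral with
  that cell's **own** $\zeta_Q^i$, and only through its in-plane components:
  substrate stress fibres are an in-plane structure, and the $Q_{zz} = -1/2$
  component of the traceless nematic tensor would otherwise exert a uniform
  vertical push on the whole tissue.  For a single cell these choices
  coincide exactly with the literal formulas.

The exported `interactionStress()` field keeps the printed composition
(shared sums) so the tensor is well-defined per node; the per-cell force
corrections above are documented in `computeVelocityTraction()` and tested
against an independent quadrature oracle.

## Parameters

Reference constants (simulation units, grid spacing $a_0 = 1$):
$\gamma = 0.008$, $\mu = 45$, $\xi = 1$, $\zeta_S = 4\times 10^{-5}$,
$\zeta_Q = -0.01$, and reference speed $\bar v = 0.02$ defining the
characteristic time $\tau = 2R_0/\bar v$ for a cell to travel its own size
(one experimental "hour" maps to $\tau$ unless overridden).

The remaining constants are the package's own calibrated defaults, chosen
once so that (i) a single passive cell relaxes to a stable, resolved
sessile droplet that wets the substrate, (ii) the phase-field volume stays
within a few percent of $V_0$, and (iii) emergent speeds in a confluent
active layer are near $\bar v$: $\lambda = 2$, $\Gamma = 2$, $dt = 0.2$,
$\kappa_{cc} = 0.15$, $\kappa_{cs} = 0.02$, $\omega_{cc} = 0.004$,
$\omega_{cs} = 0.03$, $\alpha = 0.02$, $D_r = 0.01$, $\tau_{pol} = 20$.
Under crowding the soft volume constraint (stiff $\mu$, weak bulk slope
$8\gamma/\lambda$) pushes interior $\phi$ a few tenths above 1; the state
container accepts overshoot in $[-0.5, 1.5]$ and the dynamics aborts with a
numerical-instability error beyond $|\phi| > 2$.

## The competition scenario

`competitionScenario()` freezes the two-type collision assay used by the
validation suite: a $60\times30\times20$ grid with 36 cells of radius
$R_0 = 5$ (type A central band, two straight interfaces under periodic x).
Type A is the cohesive winner analog; type B has an 8-fold lower cell-cell
adhesion ($\omega_{cc}$: 0.004 vs 0.0005) and a higher substrate adhesion
($\omega_{cs}$: 0.01 vs 0.04) — the adhesion contrast under which the
low-cohesion type is eliminated at the interface.  Activity is raised to
$\alpha = 0.08$, $D_r = 0.1$, $\tau_{pol} = 10$ so that the emergent jostling
in the jammed layer reaches the reference speed scale.  At this scale
(1,500 steps, minutes of compute) every tested seed produces extrusions
exclusively of the low-cohesion type, all within $2R_0$ of the interface,
and the interface bin carries the maximum of the loser-type susceptibility
profile of the in-plane isotropic stress.  Runs with the cell-cell contrast
alone also eliminate only the low-cohesion type near the interface, but the
in-plane susceptibility peak then sits mid-band; the substrate-adhesion
contrast is what concentrates the stress tug-of-war at the interface.

The full-scale reference geometry (400 cells, $320\times320\times64$,
15,000 steps) is cluster-scale; the layout helper reproduces its
$20\times20$ lattice and is tested, but the package's routine validation
runs the scaled-down scenario above.  What the scaled runs do *not* probe:
long-time interface coarsening, large-sample extrusion-rate statistics, and
any quantitative match to experimental stresses.

# Stress statistics

The coarse-grained stress follows the nearest-neighbour moment formula
$\sigma(x) = a_0^{-3}\sum_{j\in N(x)} r^{xj}\otimes T^j$ over the
6-connected stencil, from per-cell tractions distributed onto nodes with
weight $\phi_i^2/\int\phi_i^2$ (`nodeTractionField()`); negative values are
compressive.  3D fields are reduced to monolayer maps by a mass-weighted
z-projection (`zProject()`).

Susceptibility is the sample-size-scaled population variance
$\chi = N(\langle A^2\rangle - \langle A\rangle^2)$; the `N` convention
(cells, or pixels as a proxy) is recorded in the output.  Profile values
are comparable *across* distance bins only when bin areas are comparable —
`susceptibilityProfile()` therefore reports the mean pixel count per bin
alongside $\chi$.  The spatial autocorrelation is masked and mean-subtracted
per frame, with pair counts from zero-padded FFTs; the correlation length is
the first zero crossing (linear interpolation), right-censored at the
largest lag when no crossing exists.  Because the generator's
squared-exponential covariance is strictly positive, the crossing exists
only through the finite-sample mean subtraction; its bias relative to the
e-folding length $\ell$ is characterised empirically (roughly
$2$-$3\times\ell$ at the benchmark geometry) rather than assumed, and the
estimator is validated by monotonicity in $\ell$ under common random
numbers.

Extrusion statistics normalise event counts by the "random probability" of
each interface distance (the pixel count of the type's region in the bin),
yielding $P(\text{extruded}\mid d)$; rates are counts per interval divided
by the occupied area of the type.  Ensemble stress maps cut square windows
around events, optionally rotated so the opposing type lies in the $+x$
half-plane, and aggregate with the median (mean optional).

Interface convexity is the hull-perimeter to region-perimeter ratio, so
convex islands score 1 and indented ones less; the literal
(region/hull $\geq 1$) ratio is attached as an attribute.  Masks are lightly
smoothed before contour extraction so pixel staircases do not inflate the
perimeter.

# Energetics of elimination

A cell leaving the monolayer is modelled as a constant-volume shape
sequence: cylinder (apical radius $r_a = 10\,\mu m$) $\to$ cone (basal
radius shrinks to zero) $\to$ sphere ($r_s = 10\,\mu m$), every shape with
volume $\tfrac43\pi r_s^3 \approx 4188.8\,\mu m^3$.  The work along the
path is

$$
dW^{I} = (\omega_s^{II} - \omega_s^{I})\,dA_s^{I}
       - f\,\omega_c^{I}\,dA_{cc}^{I} + k^{I}\,dA_{tot}^{I},
$$

with same-type contact fraction $f = 0.5$; the cross-type lateral term is
common to both types and drops from the difference, and the substrate term
uses the adhesion difference because the winner re-occupies the substrate
the loser vacates.  All areas are state functions of the shape, so the path
work equals the endpoint difference; `eliminationWork()` reports the two
legs and the term decomposition separately.  The normaliser $dW_0^k$ is the
magnitude of the pure-tension work with all adhesions zero (the sphere has
less surface than the cylinder, so that work is released; the magnitude
convention keeps normalised differences sign-interpretable).  The lateral
surface is the only cell-cell contact area and the apical disk is free
surface; the closed total surface enters the tension term.
`phaseDiagram()` varies $\Delta\omega_{cc}$ and $\Delta\omega_{cs}$ around a
baseline chosen so both signs of $\Delta W$ appear, and contains the
characteristic region where higher cell-cell adhesion wins despite lower
substrate adhesion.

# Traction and stress inference

`forwardDisplacement()` is the Boussinesq half-space convolution
$\hat u(k) = G(k)\hat t(k)$ with the standard Green tensor for Young modulus
$E$ and Poisson ratio $\nu$ (default 0.5, incompressible silicone; the
finite-thickness correction is omitted as substrates are much thicker than
the displacement scale).  `fttc()` inverts it mode-by-mode with Tikhonov
regularization $\hat t = (G^2 + \lambda I)^{-1} G \hat u$ after drift
correction, zeroing the rigid $k = 0$ mode (force balance over the field of
view); $\lambda$ defaults to $9\times10^{-9}$.  The noise benchmark that
validates the default (30 kPa substrate, 1 µm pixels, zero-mean traction
with 6 px correlation length and 50 Pa scale, 5% i.i.d. displacement noise)
recovers the truth with correlation above 0.9 on average.

`bism()` solves 2D force balance $\nabla\cdot\sigma = -t$ for the symmetric
tissue stress as a Tikhonov-regularized least-squares inversion
$\sigma = A^T(AA^T + \Lambda s I)^{-1}(-t)$, with $A$ the discrete
divergence operator (central differences, one-sided at the boundary,
*identical* to the forward operator `forwardTractionFromStress()`), and $s$
the largest diagonal entry of $AA^T$ so that $\Lambda$ (default $10^{-6}$)
is dimensionless.  Force balance leaves additive constants undetermined;
the gauge is fixed by zero mean normal (and shear) stress on the domain
boundary.  The problem is underdetermined (three stress components, two
balance equations), so only the row-space component of the stress is
identifiable; `genStressTractionPair()` draws its ground truth through the
adjoint $A^T$ applied to smooth random potentials — the identifiable class —
and applies the same boundary gauge, which is what makes a sub-10% recovery
benchmark meaningful for an inverse problem with a null space.

# Synthetic data

All generators are pure functions of their arguments including the seed and
attach their true parameters as attributes.  The Gaussian field generator
uses spectral synthesis with the squared-exponential spectrum and exact
expected-variance normalization ($\ell = 0$ degenerates to white noise).
Catalog generators place events in a type's region uniformly or with an
exponential interface bias.  Displacement benchmarks add i.i.d. Gaussian
noise only — no bleaching, drift or other microscopy artifacts are
emulated, so passing benchmarks demonstrate estimator correctness on clean
statistics, not robustness to instrument systematics.

# Problem sizes of the validation suite

The test suite and `scripts/acceptance.R` run: the passive conservation
control at $64\times64\times24$ with 16 cells for 2,000 steps; three seeds
of the competition scenario ($60\times30\times20$, 36 cells, 1,500 steps);
ten $128^2$ stress-inversion and traction-recovery benchmarks; twenty seeds
of the correlation-length and susceptibility calibrations; one hundred
uniform-null catalogs for the flatness test.  These sizes were chosen so a
full validation completes in tens of minutes on one CPU while each
statistic retains a clear margin; the vignette sections above state what
the scaled-down runs do and do not demonstrate.

# Known limitations

* No cell division or growth, nutrient fields, substrate deformability, or
  GPU kernels; cell identity is conserved.
* The simulator stores full-grid fields per cell, which bounds practical
  cell counts at workstation scale; the reference 400-cell geometry needs
  cluster resources.
* The interface-peaked susceptibility emerges robustly only in the
  two-contrast competition scenario; with the cell-cell contrast alone the
  fluctuation peak sits inside the loser band at this scale.
* The FTTC regularization constant is dimensionful against an unstated
  normalization in its original use; the default is exposed and validated
  on this package's benchmark, but equivalence to other pipelines cannot be
  asserted.
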