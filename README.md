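# mechcompete

Tools for studying **mechanical cell competition**: how two epithelial cell
populations that differ in cell–cell and cell–substrate adhesion compete at
a shared interface, eliminating cells by extrusion out of the monolayer
plane. The package is written for computational tissue-mechanics and
mechanobiology groups who want to simulate the competition, quantify the
stress fluctuations that drive it, and run the standard force-inference
chain on displacement data.

## What is inside

**3D multiphase-field simulator.** Each cell is a diffuse indicator field
φᵢ on a grid (periodic in x, y; rigid substrate at the bottom). The free
energy combines Cahn–Hilliard bulk/gradient terms (cortex tension γ,
interface width λ), a soft volume constraint μ(1 − V/V₀)², and per-type
repulsion (κ) and adhesion (ω) couplings between cells and with the
substrate. Dynamics: relaxational interface evolution plus rigid advection
with the overdamped velocity vᵢ = (α p̂ᵢ + Fᵢ^int)/ξ, where the interaction
force integrates the interaction stress (isotropic −Σ δF/δφ plus active
stresses −ζ_S φᵢ Sᵢ and −ζ_Q φ_w Q_w) against the cell's own gradient, and
contact-inhibition-of-locomotion polarity (alignment time τ_pol, rotational
noise D_r). Cell extrusion **emerges** from the force balance; no rule
removes cells.

**Stress & extrusion statistics.** Coarse-grained stress
σ(x) = a₀⁻³ Σⱼ r^{xj} ⊗ T^j, susceptibility χ = N·Var, distance-resolved
susceptibility profiles, masked spatial autocorrelation with zero-crossing
correlation length, interface-distance PDFs of extrusion events
(normalized by the random probability of each distance), extrusion rates,
ensemble stress maps around extrusions, and interface convexity.

**Elimination energetics.** Work to remove a cell through a
constant-volume cylinder → cone → sphere sequence (r = 10 µm, V ≈ 4188.8
µm³): dWᴵ = (ω_sᴵᴵ − ω_sᴵ)dA_s − ½ ω_cᴵ dA_cc + kᴵ dA_tot, and the win/lose
phase diagram over adhesion differences — including the regime where higher
cell–cell adhesion wins despite lower substrate adhesion.

**Force inference.** Fourier-transform traction cytometry (Boussinesq
half-space forward model, Tikhonov-regularized inversion, default
λ = 9×10⁻⁹) and Bayesian inversion stress microscopy (regularized inversion
of ∇·σ = −t, default Λ = 10⁻⁶, boundary-gauged), with exact forward models
and synthetic ground-truth generators for validation.

## Worked example

```r
library(mechcompete)

# elimination work of two types at an adhesion contrast
ae <- adhesionEnergetics(omegaS_I = 0.1, omegaS_II = 0.4,
                         omegaC_I = 0.8, omegaC_II = 0.1, k_I = 1)
wI  <- eliminationWork(ae, "I")
wII <- eliminationWork(ae, "II")
cat(sprintf("dW^I  = %.1f um^2 x energy/area (normalized %.3f)\n",
            wI$total, wI$normalized))
cat(sprintf("dW^II = %.1f um^2 x energy/area (normalized %.3f)\n",
            wII$total, wII$normalized))
cat(sprintf("Delta W / dW0 = %.3f -> type %s wins at the interface\n",
            (wII$total - wI$total) / wI$normalizer,
            if (wII$total > wI$total) "II" else "I"))

# stress inference round trip on synthetic ground truth
gt  <- genStressTractionPair(128, 128, smoothness = 8, seed = 1)
est <- bism(gt$traction, Lambda = 1e-6)
m   <- 3:126
err <- sqrt(sum((fieldValues(est)[m,m,] - fieldValues(gt$stress)[m,m,])^2)) /
       sqrt(sum(fieldValues(gt$stress)[m,m,]^2))
cat(sprintf("BISM stress recovery: %.2f%% relative L2 error\n", 100 * err))

# traction recovery at 5% displacement noise (30 kPa substrate)
sub <- elasticSubstrate(E = 3e4)
tr  <- genTractionField(128, ell = 6, sdT = 50, seed = 1)
u   <- genDisplacementFromTraction(tr, sub, noiseRel = 0.05, seed = 2)
rec <- fttc(u, sub)
cat(sprintf("FTTC traction correlation at 5%% noise: %.3f\n",
            cor(as.vector(fieldValues(rec)), as.vector(fieldValues(tr)))))
```

which prints:

```
dW^I  = 31.4 um^2 x energy/area (normalized 0.150)
dW^II = -73.3 um^2 x energy/area (normalized -0.350)
Delta W / dW0 = -0.500 -> type I wins at the interface
BISM stress recovery: 0.02% relative L2 error
FTTC traction correlation at 5% noise: 0.949
```

Type I (high cell–cell, low substrate adhesion) takes *more* work to
eliminate than type II even though type II grips the substrate harder — the
cohesion advantage. The inversion chain recovers synthetic ground truth
essentially exactly without noise and with correlation ≈ 0.95 at 5%
displacement noise.

To run a scaled-down two-type collision in which the low-cohesion type is
eliminated at the interface:

```r
res <- runSimulation(competitionScenario(seed = 1), saveEvery = 50)
res$events                                  # extrusion catalog (all type B)
susceptibilityProfile(res$frames$iso, res$frames$occ, binWidth = 5,
                      periodic = c(TRUE, TRUE))
```

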