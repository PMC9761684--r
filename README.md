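# gvpt2

Anharmonic vibrational spectroscopy from cubic–quartic force fields, with
automated, intensity-aware treatment of resonances.

Second-order vibrational perturbation theory (VPT2) corrects harmonic
energies and intensities using the cubic (k_ijk) and semidiagonal quartic
(K_ijkl) force constants expressed over dimensionless normal coordinates.
Its well-known failure mode is resonance: whenever a denominator such as
ω_i − ω_j − ω_k (Fermi) or ω_i − ω_j (1–1 Darling–Dennison) approaches
zero, perturbative terms blow up and both energies and band intensities
become unphysical. This package implements the full generalized scheme
(GVPT2):

1. **a priori resonance identification** — harmonic prefilter
   |Δ| < Δ^(A–B), then an energy-based index (Martin's κ = W⁴/Δ³, the CVPT
   divergence measure, or the Darling–Dennison coupling |⟨a|H̃|b⟩|)
   OR-combined with an intensity-aware index built on the perturbative
   wave-function coefficients (R12COEF = |W/Δ|, R11COEF = |K/Δ|), which is
   the quantity that actually enters the VPT2 transition moments;
2. **deperturbation (DVPT2)** — every χ-matrix and transition-moment term
   whose denominator belongs to an accepted resonance is removed and
   ledgered;
3. **variational correction (GVPT2)** — resonant states are clustered into
   polyads (connected components of the resonance graph over the
   N + N(N+1)/2 one- and two-quanta states); per-polyad matrices carry the
   DVPT2 energies on the diagonal and the Fermi/Darling–Dennison couplings
   off-diagonal, and the eigenvectors re-project the deperturbed
   transition moments onto the final states.

State energies follow the Dunham-type form
E(v) = ε₀ + Σᵢ ωᵢ(vᵢ+½) + Σ_{i≤j} χᵢⱼ(vᵢ+½)(vⱼ+½), with the χ matrix
including Coriolis (ζ) contributions and an optional smooth
degeneracy-corrected (HDCPT2-style) regularization that keeps every χ
element finite through exact degeneracies. Dipole and rotatory strengths
(IR/VCD) are assembled from electric- and magnetic-dipole transition
moments — the latter expanded over conjugate momenta with restricted index
permutation — and convolved with Lorentzian or Gaussian kernels.

Everything is validated against an in-package dense variational oracle
(product-basis diagonalization of the identical truncated Hamiltonian), so
oracle–VPT2 discrepancies measure perturbation error only. A synthetic
generator plants Fermi/Darling–Dennison resonances with exact gaps for
detection studies, and a Duschinsky consistency check (J, K) gates hybrid
force fields combining two electronic-structure levels.

## Worked example

A 9-mode synthetic system with one planted type-I Fermi resonance
(gap 2.6 cm⁻¹, cubic coupling 38 cm⁻¹ — the conditions of a strong
overtone–fundamental resonance in a neat liquid):

```r
library(gvpt2)
plan <- resonancePlan(9, planted = list(
  list(kind = "FERMI_I", delta = 2.6, coupling = 38)), seed = 7)
gen <- generateBundle(plan)
out <- runPipeline(list(bundle = gen$bundle, level = "GVPT2", seed = 1))
resonanceTable(out$resdb)
#>      kind i j k  l delta coupling indexEnergy indexIntensity         trigger
#> 1 FERMI_I 5 1 1 NA   2.6      9.5    463.4196       3.653846 R12MART+R12COEF
```

The planted triad (mode 5 against the first overtone of mode 1) is the
only accepted resonance: Martin's index is 463 cm⁻¹ (threshold 1) and the
first-order coefficient 3.65 (threshold 0.1), so both tests fire. The
2×2 polyad mixes the two deperturbed states (DVPT2 energies 797.3 and
792.1 cm⁻¹) into variational levels at 784.9 and 804.6 cm⁻¹:

```r
assignStates(out$gvpt2)
#>   level energy state overlap   tie
#> 1     1 784.88  2(1) 0.63088 FALSE
#> 2     2 804.56  1(5) 0.63088 FALSE
```

Each level keeps a 63/37 character — the hallmark of a strong Fermi dyad —
and the stick table carries the projected moments and strengths
(`D` in 10⁻⁴⁰ esu²cm², `R` in 10⁻⁴⁴ esu²cm²):

```r
subset(out$table, state %in% c("1(2)", "1(8)", "2(2)"))
#>    state   energy         D         mu1         mu2        mu3           R
#> 2   1(2)  462.791 335.69050 -0.03088555 -0.03981267 -0.0515471 -2854.91953
#> 8   1(8) 1661.020  26.79102 -0.00856799  0.01059281 -0.0151352  -607.15042
#> 19  2(2)  926.406   1.34499  0.00293668  0.00249438  0.0024439     4.58138
out$spectra$IR
#> BandShape (IR, lorentzian, hwhm 2.0): 15046 points on [377.0, 3386.0] cm-1
```

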