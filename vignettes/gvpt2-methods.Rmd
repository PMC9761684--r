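---
title: "Anharmonic vibrational spectra with automated resonance treatment: methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Anharmonic vibrational spectra with automated resonance treatment: methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(gvpt2)
```

## The model

The package works in the Watson vibrational Hamiltonian restricted to its
vibrational part, in wavenumbers over dimensionless normal coordinates
$q_i$ and conjugate momenta $p_i$:

$$H = \tfrac12\sum_i \omega_i (p_i^2 + q_i^2)
    + \tfrac16\sum_{ijk} k_{ijk}\, q_i q_j q_k
    + \tfrac1{24}\sum_{ijkl} K_{ijkl}\, q_i q_j q_k q_l
    + H_{\mathrm{Cor}},$$

where $k_{ijk}$ and $K_{ijkl}$ are the cubic and quartic force constants
(cm$^{-1}$) and $H_\mathrm{Cor}$ collects the Coriolis couplings
($B^{eq}_\tau$, $\zeta^\tau_{ij}$). The constant mass-dependent Watson
term is dropped: it cancels in every transition energy, so absolute
zero-point energies reported here exclude it. Only the semidiagonal
quartic patterns ($K_{iiii}$, $K_{iijj}$, $K_{iiij}$, $K_{iijk}$) are
assumed available, matching what two-step numerical differentiation of
analytic Hessians can deliver; off-semidiagonal elements are treated as
*unavailable*, never silently as zero, which is why 11–11
Darling–Dennison couplings (which need $K_{ijkl}$ with four distinct
indices) are excluded from the automatic treatment.

Second-order perturbation theory turns this into the Dunham-type form

$$E(\mathbf v) = \varepsilon_0 + \sum_i \omega_i\!\left(v_i+\tfrac12\right)
 + \sum_{i\le j} \chi_{ij}\left(v_i+\tfrac12\right)\left(v_j+\tfrac12\right).$$

The implemented $\chi$ elements, in the partial-fraction form that exposes
each resonance-capable denominator as a separate term, are

$$16\,\chi_{ii} = K_{iiii} - \sum_k k_{iik}^2\left[\frac{2}{\omega_k}
  - \frac{1/2}{2\omega_i-\omega_k} + \frac{1/2}{2\omega_i+\omega_k}\right],$$

$$4\,\chi_{ij} = K_{iijj} - \sum_k \frac{k_{iik}k_{jjk}}{\omega_k}
 - \frac{1}{2}\sum_k k_{ijk}^2\left[\frac{1}{\omega_i+\omega_j+\omega_k}
 + \frac{1}{\omega_i+\omega_k-\omega_j} + \frac{1}{\omega_j+\omega_k-\omega_i}
 - \frac{1}{\omega_i+\omega_j-\omega_k}\right]
 + 4\,\frac{\omega_i^2+\omega_j^2}{\omega_i\omega_j}\sum_\tau B^{eq}_\tau
   (\zeta^\tau_{ij})^2 .$$

The partial-fraction granularity is what deperturbation needs: the Fermi
triad $(a;b,c)$ with $\omega_a \approx \omega_b + \omega_c$ *owns* every
occurrence of the denominator $\pm(\omega_b+\omega_c-\omega_a)$ across all
$\chi$ elements, and DVPT2 removes exactly those occurrences. This keeps
the 2×2 consistency of the deperturbed picture: e.g. for a type-I triad
the removed pieces recombine to $W^2/\Delta$ with the deperturbed coupling
$W = k_{abb}/4$, which is what the variational step later restores
off-diagonally.

$\varepsilon_0$ is computed by direct second-order perturbation theory on
the ground state, so the reported total ZPE is
$\sum\omega_i/2 + \varepsilon_0$ (the full anharmonic ground-state shift,
e.g. $-11k^2/288\omega$ for a single cubic mode). It excludes the Coriolis
ZPE contribution along with the Watson term; both cancel in transition
energies, which are the package's subject.

State energies are reported relative to the ground state, where
$\varepsilon_0$ cancels exactly.

## Resonance identification

Selection is the classic two-step process: a cheap harmonic prefilter
(strict $|\Delta| < \Delta^{A\text{-}B}$) followed by index tests. The
deperturbed 2×2 couplings are $W = k_{abb}/4$ (type I, $\omega_a \approx
2\omega_b$) and $W = k_{abc}/(2\sqrt2)$ (type II, $\omega_a \approx
\omega_b + \omega_c$).

| scheme | quantity | units | default threshold |
|---|---|---|---|
| R12MART | $W^4/\Delta^3$ | cm$^{-1}$ | 1.0 |
| R12CVPT | $c\,|W/\Delta|$, $c=\sqrt2$ for overtones | – | 0.1–0.5 |
| R12WFRQ | $W^4/\Delta^5$ | cm$^{-3}$ | as configured |
| R12COEF | $|W/\Delta|$ (first-order coefficient) | – | 0.1 |
| R11HRS / R22HRS | $|\langle a|\tilde H|b\rangle|$ | cm$^{-1}$ | 10 / 20 |
| R11WFRQ | $|\langle a|\tilde H|b\rangle|/\Delta^2$ | cm | as configured |
| R11COEF | $|\langle a|\tilde H|b\rangle/\Delta|$ (second-order coefficient) | – | 0.3 |

Defaults (windows $\Delta^{1\text{-}2}=200$, $\Delta^{1\text{-}1}=
\Delta^{2\text{-}2}=100$ cm$^{-1}$) pair an energy test with an
intensity-aware coefficient test per kind — R12MART+R12COEF for Fermi,
R11HRS+R11COEF for 1–1, R22HRS for 2–2/2–11 — accepted by logical OR.
The coefficient tests matter because band intensities respond to weak
couplings between near-degenerate states that energy-based indices
underrate; perturbative consistency also requires those coefficients to
stay below 1, which bounds sensible thresholds. Exact degeneracies
($\Delta = 0$ with nonzero coupling) short-circuit to acceptance: every
denominator-based index exceeds any finite threshold in that limit. A
zero coupling is never accepted — a degenerate but uncoupled pair is not
a resonance, and accepting it would only pollute detection statistics.

R12WFRQ's gap weight is implemented as division by $\Delta^2$, by analogy
with the explicitly defined 1–1 rule; the power is exposed in the function
interface (`weight = "squared"|"linear"`) since conventions differ. The
R12CVPT overtone factor $\sqrt2$ is derived from the ratio of the type-I
and type-II matrix elements of the same cubic constant.

Darling–Dennison couplings are evaluated by an explicit Van Vleck
second-order sum over intermediate harmonic states,

$$\langle a|\tilde H|b\rangle = \langle a|V_4|b\rangle +
 \frac12\sum_{s\notin\{a,b\}} \langle a|V_3|s\rangle\langle s|V_3|b\rangle
 \left[\frac{1}{E_a-E_s}+\frac{1}{E_b-E_s}\right],$$

generated algorithmically with ladder-operator algebra rather than from
transcribed closed forms; internal Fermi-like denominators are smoothly
regularized (below) so the coupling is finite for any input. The same
engine serves 1–1, 2–2 and 2–11 patterns, and its correctness is pinned
by tests that extract mixing coefficients from $\lambda$-scaled dense
diagonalizations ($V_3 \to \lambda V_3$, $V_4 \to \lambda^2 V_4$) and
match them to 3–4 digits. Coriolis terms are currently *not* included in
these couplings (they are in $\chi$); synthetic fixtures set $\zeta = 0$,
and the omission is the main known limitation for real rovibrationally
coupled systems.

## Degeneracy-corrected regularization

The classic degeneracy-corrected replacement
$\mathrm{sign}(\Delta)\bigl(\sqrt{(\Delta/2)^2+W^2}-|\Delta|/2\bigr)$ is
bounded but jumps by $2W$ as $\Delta$ crosses zero — the repelled-level
identity swap. For an automated pipeline we prefer a regularizer that is
*continuous* through the crossing (the deperturbation + variational
machinery handles true degeneracies anyway), so resonant terms $W^2/\Delta$
are replaced by

$$f(\Delta, W) = \Lambda\,\frac{W^2}{\Delta}
 + (1-\Lambda)\,\frac{W^2\,\Delta}{\Delta^2+4W^2},\qquad
 \Lambda = 1-\exp\!\left[-\left(\frac{\Delta^2}{4W^2}\right)^{\!2}\right].$$

$f$ is odd in $\Delta$, vanishes at exact degeneracy, is bounded by
$\sim W/4$ near resonance, and collapses onto $W^2/\Delta$ with an error
that decays like $e^{-(\Delta/2W)^4}$ — already below $10^{-5}$ relative
at $|\Delta| \approx 4|W|$. The switching scale is the coupling itself, so
no tunable width parameter is introduced; the functional form is pinned in
`hdcptTerm()` with the crossover constant (4) visible in code.

## Variational step and transition moments

Polyads are connected components (internal union–find, cross-checked
against igraph in tests) of the accepted-resonance graph over the
$N + N(N+1)/2$ one- and two-quanta states. Per-polyad symmetric matrices
carry DVPT2 energies on the diagonal and couplings off-diagonal; LAPACK
`eigen(symmetric = TRUE)` diagonalizes them, eigenvalues ascending,
eigenvector phases fixed by making the largest-magnitude component
positive (otherwise the moment projection would be sign-ambiguous between
runs). Assignments label each level by its largest squared component; an
exact tie breaks toward the lower-energy basis state and is flagged. A
global-matrix mode is retained behind a flag purely for cross-validation —
it is memory-hungry and numerically noisier on large sparse problems.

Transition moments are built by explicit Rayleigh–Schrödinger expansion:
the ground and final wave functions to second order in the harmonic basis,
the property operator to matching order
($P^{(0)} = s_0P_0 + s_1\sum P_i\hat O_i$, $P^{(1)}$ the second
derivatives, $P^{(2)}$ the semidiagonal third derivatives), collecting the
bra–ket integral through $\lambda^2$ including the normalization term
$-\tfrac12(\|\psi^{(1)}_I\|^2+\|\psi^{(1)}_F\|^2) M^{(0)}$. Working with
the explicit sums has two payoffs: deperturbation is exact by construction
(the terms whose denominators belong to accepted resonances are simply
excluded, which *is* the resonance-consistent variant of the moment
formulas — the cancellations that motivate separate resonant closed forms
never arise because no term is double-counted), and the identical operator
expansion can be handed to the variational oracle, making 1%-level moment
comparisons meaningful. A denominator below $10^{-6}$ cm$^{-1}$ that is
*not* covered by an accepted resonance is a hard error pointing at the
resonance configuration; silent smoothing in a moment would hide exactly
the artifacts the deperturbation exists to fix.

For momentum-type properties ($S=-1$; magnetic dipole for VCD) the
operator factors are $\tilde p = (b^\dagger - b)/\sqrt2$ in a real
convention (the overall $i$ is carried into the rotatory-strength
assembly), derivatives are stored with restricted index permutation —
`P2[i, j]` is $\partial^2 P/\partial q_i\partial p_j$, third-derivative
keys carry the momentum index last — and unavailable patterns are dropped.
The $s_0,s_1,s_2,s_3$ prefactors default to 1 (a plain Taylor series in
dimensionless coordinates); properties with other conventions supply their
own values. Rotatory strengths use
$R = \mathrm{Im}(\boldsymbol\mu_{0f}\cdot\mathbf m_{f0})$, which in the
real convention becomes $-\boldsymbol\mu_{0f}\cdot\tilde{\mathbf m}_{0f}$;
the conversion constants ($6.46047\times10^4$ per a.u.² for $D$ in
$10^{-40}$ esu²cm², $4.71444\times10^6$ for $R$ in $10^{-44}$, and the
molar-absorptivity prefactor whose inverse is the textbook
$D = 91.86\times10^{-40}\int(\epsilon/\nu)\,d\nu$) live in one table with
unit tests.

Pseudoeigenvectors weight the Cartesian normal-mode columns with the
perturbative coefficients — unit weight plus the second-order 1–1
coefficients for fundamentals, the first-order Fermi-type coefficients for
2-quanta states — with resonant coefficients excluded; coefficients
computed during resonance analysis are cached and reused.

## Synthetic systems and the oracle

The generator emulates the fingerprint region of a mid-size organic
molecule: background wavenumbers uniform on 300–1700 cm$^{-1}$ with a
minimum spacing of 8 cm$^{-1}$ (to avoid accidental degeneracies the plan
did not ask for), sparse zero-mean cubic constants of 10 cm$^{-1}$ scale
and quartics of 5 cm$^{-1}$ (typical mid-IR magnitudes), dipole first
derivatives of 0.05 a.u. Planted features realize their gaps exactly by
construction. What it does *not* emulate: Coriolis coupling, symmetry
(selection rules and degenerate modes), large-amplitude motions, and the
dense CH-stretch manifolds of real molecules — so passing detection tests
demonstrates the identification logic, not robustness to every real-data
pathology. Active-mode masking (`maskActiveModes`) is the supported way to
excise hindered-rotor modes whose torsions a quartic field cannot
describe.

The oracle diagonalizes the *same* truncated polynomial Hamiltonian in a
product basis (≤ 3 modes, ≤ 20 quanta per mode, convergence guarded by a
0.01 cm$^{-1}$ ground-state shift test on basis increments), with
eigenvector phases fixed like the variational step. Because operator and
basis are shared, oracle-vs-VPT2 differences are pure perturbation error;
that is what makes the acceptance-grade assertions (fundamentals within
1 cm$^{-1}$ and moments within 1% at coupling-to-gap ratios below 0.05;
GVPT2 strictly closer than VPT2 on a 2.6 cm$^{-1}$/38 cm$^{-1}$ Fermi
dyad) sharp rather than tautological.

## Numerical choices and problem sizes

* Strict inequality in the prefilter windows; deterministic candidate
  ordering by mode indices.
* Amplitudes below $10^{-14}$ are pruned in the sparse wave-function
  algebra; eigenvalue/trace checks run at $10^{-8}$ cm$^{-1}$ and
  projection-norm conservation at $10^{-10}$ relative.
* Spectra default to a 0.2 cm$^{-1}$ grid (resolving the smallest HWHM in
  routine use, 2 cm$^{-1}$); kernels are unit-area, so rigid shifts
  commute with convolution and may be applied on either side.
* The Duschinsky gate computes $J = L_H^\top L_L$ after internal Eckart
  (Kabsch, mass-weighted) alignment; $K$ is reported but never gates —
  any non-rigid geometry change contaminates it — with a configurable
  warning on $\|K\|$.
* Test-suite problem sizes: 2–3-mode oracle fixtures (basis ≤ 17²), a
  50-seed detection suite on 6-mode bundles, and 72-mode combinatorial
  enumerations; the whole suite runs in well under a minute on one core.
* Linear molecules (3N−5) are supported by the containers but exercised
  only at unit level.

## Known limitations

3-quanta states (and hence second overtones, 1–3 Darling–Dennison
resonances and their tests) are out of scope; hot bands are ignored;
11–11 Darling–Dennison couplings are excluded for lack of off-semidiagonal
quartics; Coriolis contributions enter $\chi$ but not the
Darling–Dennison couplings; Raman/ROA invariant combinations are an
extension point of the generic-tensor stick pipeline, not a claimed
feature.
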