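---
title: "Anharmonic vibrational spectra of water clusters from diffusion Monte Carlo: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Anharmonic vibrational spectra of water clusters from diffusion Monte Carlo: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

This vignette explains the models and algorithms implemented in `dmcvib`,
the parameters that matter, the numerical choices made where the design was
genuinely open, and what the synthetic test systems do and do not probe.

## The physical problem

Small water clusters are dominated by nuclear quantum effects: the OH
stretch zero-point amplitude is about 0.07 Å, hydrogen bonds are floppy,
and vibrational fundamentals shift by tens to hundreds of cm⁻¹ relative to
harmonic estimates.  `dmcvib` predicts anharmonic fundamentals and IR
intensities of (H₂O)ₙ clusters in three stages:

1. **Sampling.**  Diffusion Monte Carlo (DMC) propagates an ensemble of
   configurations ("walkers") in imaginary time; the walker density
   converges to the nuclear ground state ψ₀.  Descendant weighting converts
   wave-function samples into probability-amplitude (|ψ₀|²) samples.
2. **Coordinates.**  Walkers are projected onto a redundant set of internal
   coordinates which is reduced to 3N−6 orthonormal combinations, either by
   plain SVD of the ensemble-averaged Wilson B matrix or by a chemically
   informed variant that pins the intramolecular coordinates exactly.
3. **Spectra.**  Mass-weighted PCA of the reduced coordinates yields
   vibrational modes; fundamentals follow from exciting the sampled ground
   state with a node-inserting linear polynomial along each mode, and
   intensities from the point-charge dipole.

## Potential energy surface

The flexible q-SPC/Fw point-charge surface is analytic and cheap: per
monomer a harmonic stretch/bend potential

$$V_\text{intra} = \tfrac{k_{OH}}{2}\left[(l_1-l_{eq})^2 + (l_2-l_{eq})^2\right] + \tfrac{k_A}{2}(\theta-\theta_{eq})^2,$$

plus O–O Lennard-Jones and intermolecular Coulomb terms from fixed charges
(no intramolecular nonbonded terms).  The bundled parameter file
(`inst/extdata/qspcfw.par`) uses the flexible-SPC intramolecular constants
k_OH = 1059.162 kcal mol⁻¹ Å⁻², k_A = 75.90 kcal mol⁻¹ rad⁻², l_eq = 1 Å,
θ_eq = 112°, charges ±0.84/0.42 e and the SPC O–O Lennard-Jones pair.
Under the (k/2)x² convention these give local-mode harmonics of
3630 cm⁻¹ (stretch) and 1389 cm⁻¹ (bend) with reduced masses
μ_OH = m_O m_H/(m_O+m_H) and μ_A = (l_eq²/2)/(1/m_H + (1−cosθ_eq)/m_O).
Masses are standard atomic weights; the energy zero is the isolated-monomer
equilibrium.  Interatomic distances below 0.1 Å are rejected (user-facing
calls) or clamped (inside the sampler) to keep the Coulomb term regular.

All internal computation uses atomic units (ħ = 1, mₑ, bohr, hartree), so
the conventional imaginary-time step Δτ = 1 is well defined; user-facing
I/O is in Å, amu, kcal/mol and cm⁻¹.

## Diffusion Monte Carlo

Each atom diffuses independently with diffusion constant D = ħ²/2m;
branching acts on whole walkers through exp[−(E−V_ref)Δτ].  Two weighting
schemes are implemented:

* **discrete** — integer birth/death branching (copy numbers capped at 3
  per step to suppress population spikes, which affects only transients);
* **continuous** — fixed population with per-walker weights; at every step
  walkers with w < 0.01 are removed and the same number of heaviest walkers
  are split at half weight, conserving the total weight of the split
  walkers.

V_ref is updated as the weighted mean energy minus a logarithmic
population-control feedback with gain α = 1/Δτ (discrete mode: a linear
feedback on the population).  Neither the feedback form nor its gain is
critical; the ZPE estimator is the mean of V_ref over the collection
window, and the tests verify it against closed forms.

**Importance sampling.**  The guiding function is the product over monomers
of Gaussians in the bond and angle displacements with widths
√(k_OH μ_OH)/ħ and √(k_A μ_A)/ħ — the exact ground state of the decoupled
intramolecular problem in the small-amplitude limit.  Guided walkers drift
along 2D∇lnψ_g Δτ and the combined drift-diffusion move is accepted by a
Metropolis test on ψ_g² with the drifted-Gaussian transition density.
Branching in guided mode uses the **local energy**
E_L = V − Σᵢ(ħ²/2mᵢ)(∇²ᵢψ_g)/ψ_g with closed-form bond/angle Laplacians
(validated against numeric Laplacians in the tests).  This is required for
the sampled density to be ψ₀ψ_g: branching guided walkers on the bare
potential provably converges to the wrong operator.  Because the Gaussians
live in curvilinear coordinates, E_L retains a small residual variance on
water (a few percent of the potential variance); on the rectilinear
harmonic test system the local energy is exactly constant.

**Protocol.**  The production defaults mirror the standard protocol:
τ = 50 000, Δτ = 1, τ_eq = 30 000 with the first 50 steps diffusion-only
(no drift, no branching — interpreted broadly: "only diffusion" — to reduce
early energetic bias), then 20 snapshots at even intervals over the final
20 000, with walker counts 5 000/10 000/50 000/100 000 for
n = 1/2/3/≥4.  Scaled-down versions of this protocol (smaller N_w, τ)
are used throughout the test-suite and the acceptance script; the sizes
actually used are stated where they are used (typically N_w = 2 000–5 000
and τ = 16 000–20 000 for the dimer, two concatenated repetitions).

**Descendant weighting.**  Each snapshot is propagated τ_DW further in
`N_DW` independent repetitions; a walker's descendant weight is the summed
final weight of its descendants divided by its weight at the snapshot.
Duplicates created by resampling credit their ancestor through an ancestor
index, which makes the weight-ratio definition well defined across
resampling events.  Amplitude-level expectations weight walkers by
W^DW·w; wave-function-level projections weight by w/ψ_g.  The fraction of
walkers with W^DW > 10⁻⁷ (the effective-sample fraction) decays with τ_DW
and faster for larger clusters; τ_DW = 1000 with N_DW = 3 is the default
compromise between amplitude convergence and statistical noise.

## Landscape exploration and classification

Isomer search combines a temperature-annealed Metropolis walk with
periodic BFGS minimization (analytic gradients, gradient-norm convergence
10⁻⁸ hartree/bohr).  Because the intramolecular force constants are stiff,
pure per-atom Cartesian moves have essentially zero acceptance at any
useful step size; the move set therefore mixes small per-atom jitter with
rigid-monomer translations/rotations, which is the standard practice for
cluster landscapes.  Stationary points reached from symmetric starting
structures can be saddles; candidates are admitted to the catalog only if
a finite-difference Hessian shows no negative curvature beyond the six
rigid-body zeros.  Minima are deduplicated by a permutation- and
rotation-invariant fingerprint (sorted element-pair distance spectra), so
the 2ⁿn! permutational copies of an isomer collapse onto one entry.

Walker classification minimizes the walker, matches the minimum to the
catalog by fingerprint, and identifies the atom labeling by Eckart-aligning
the minimized structure against every permutation variant (a mass-weighted
RMSD below 10⁻³ Å — "numerically zero" — picks the permutation; the
tolerance is far below inter-minimum distances and far above optimizer
noise).  Eckart alignment itself removes the center of mass and solves the
rotational Eckart condition by the Kabsch construction on mass-weighted
coordinates; degenerate-inertia cases would make the rotation non-unique
but do not arise for water-cluster minima.  The minimization-based
classifier can misassign walkers near basin boundaries; the
`oo_distances()` diagnostic exposes this by comparing O–O distance
distributions per class, and no numeric assertion is attached to it.

Not every relabeling is a chemical event.  Swapping the two acceptor
hydrogens of the achiral Cs dimer minimum maps the structure onto its
congruent mirror image through a planarization saddle well below the
zero-point energy, so the ground state delocalizes freely across that
"permutation" — it produces no chemically distinct configuration.  The
permutation-probability diagnostic therefore counts only non-trivial
permutations: variants whose permuted reference structure is *not*
superimposable on the reference under a (possibly improper) isometry.
What remains — hydrogen transfer between monomers, donor/acceptor
exchange — are the energetically costly events, and their probability in
dimer ensembles is numerically zero at the reported sampling.

## Internal coordinates and redundancy reduction

Two redundant bases are implemented: r_N2 (all OH bonds and HOH angles plus
every intermolecular atom-pair distance; quadratic growth) and r_N3 (r_N2
plus intermolecular angles; cubic growth).  "All intermolecular angles"
admits several readings; the default enumeration takes one angle per
sorted atom triple a < v < c that is not fully intramolecular, with the
vertex at the middle atom index — the set a plain combinations-of-three
loop generates, and the one whose standard-SVD imbalance diagnostics line
up with the reference values this package reproduces.  Four alternative
readings (all vertex choices per cross triple, both-arms-cross,
ends-span, and strictly three-monomer triples) are available behind the
`inter_angle_rule` flag.  Angle Jacobians are regularized at sinθ < 10⁻⁶; such
near-linear angles never occur at water-cluster equilibria but can for
distorted walkers.

The Wilson B matrix (analytic distance/angle Jacobians) is averaged over
Eckart-aligned walkers with amplitude weights, as is ⟨BΛBᵀ⟩ (Λ = diag 1/m),
giving the kinetic metric ⟨G⟩ = Uᵀ⟨BΛBᵀ⟩U for any reduction U.  The
element-wise double-sum definition of ⟨G⟩ is kept as a test oracle; the
vectorized accumulation must agree with it to 10⁻¹² on small ensembles.

* **Standard reduction**: SVD of ⟨B⟩, keep the 3N−6 leading left singular
  vectors.  Columns carry a deterministic sign (largest-magnitude entry
  positive, ties by lowest index) so U is reproducible across platforms;
  a degenerate singular-value gap at the cut triggers a warning and is
  broken by column order.
* **Chemically informed reduction**: the K = 3n intramolecular descriptors
  are pinned as exact coordinates (QR of ⟨B⟩_fixedᵀ spans their subspace),
  the intermolecular rows are projected into the orthogonal complement,
  and the remaining 3N−6−K directions come from the SVD of the projection;
  U is block diagonal with an identity in the intramolecular block.  A
  rank-deficient fixed block aborts with a diagnostic.

The transformation T = PᵀUᵀ from redundant descriptors to vibrational
modes supports the balance diagnostics: the total intramolecular character
χ (sum of squared T entries over intramolecular columns), the character
imbalance factors CIF = (χ−K)/K per descriptor class, the
intermolecular→intramolecular mixing fraction, and per-mode character
indices χ_l.  For the chemically informed scheme all CIFs are identically
zero for any ensemble and either basis; because Pᵀ is orthonormal the CIFs
are invariant under dropping it, which the tests assert.  For the standard
scheme CIF_intra is negative and grows more negative from r_N2 to r_N3 —
the quantified signature of intermolecular over-representation.

## GSPA spectra

With q = Uᵀr, the weighted covariance C of q (about its weighted mean) is
mass-weighted and diagonalized, A = ⟨G⟩^{-1/2} C ⟨G⟩^{-1/2} = PΛPᵀ.  The
mass-weighted mode coordinates are computed as v_MW = Pᵀ⟨G⟩^{-1/2}Uᵀ r.
One presentation of the transformation chain applies ⟨G⟩^{-1/2} *after*
Pᵀ; the two orders agree only if the matrices commute, and only the
order used here decorrelates the modes and makes the eigenvalue λ_l the
ground-state variance of mode l — properties the rest of the method
(effective-harmonic map, kinetic gap) relies on, so that order is used.
⟨G⟩^{-1/2} comes from a symmetric eigendecomposition with a relative
eigenvalue floor of 10⁻¹² (clamped values are warned about).

For each mode the excitation polynomial f = v_MW,l − ⟨v_MW,l⟩ inserts a
node; the fundamental is the sum of the potential gap
ΔV = ⟨Vf²⟩/⟨f²⟩ − ⟨V⟩ and the kinetic gap
ΔT = (ħ²/2)⟨f²⟩/(⟨f⁴⟩−⟨f²⟩²), all expectations amplitude-weighted.  The
kinetic gap is exact for a Gaussian amplitude and is used as stated, with
no correction for non-Gaussianity; a mode with ⟨f⁴⟩ ≤ ⟨f²⟩² (insufficient
sampling) is flagged and reports no frequency.  By construction
ν̃ = ΔV + ΔT holds identically.  The centering mean is taken over the
concatenated ensemble by default (consistent with concatenating
repetitions); per-snapshot recentering is available as an option and
suppresses slow population drift at a small variance cost.  Intensities
are I_l ∝ ν̃_l‖⟨μ⃗f⟩‖²/⟨f²⟩ from the point-charge dipole, reported
relative to the strongest band (the model provides no absolute scale).
Modes are indexed by descending covariance eigenvalue, which preserves
mode identity better than frequency ordering; mode labels combine the
χ-character class with the dominant descriptor, and a mode is called a
stretch or bend only if that class carries a strict majority (χ > 0.5) of
its character — heavily mixed modes stay "intermolecular".

The effective-harmonic estimate ν̃_eff = ħ/(2λ_l) (the PCA-only route) is
computed alongside for comparison; on a Morse oscillator with exact
ground-state sampling the GSPA fundamental is strictly closer to the exact
0→1 gap, which the tests verify against closed-form Morse levels.

## Optimization-based reverse mapping

The forward map x → v_MW(x) is many-to-one (rigid motions form a 6-D null
space).  Reverse mapping minimizes ‖v_MW(x) − v_target‖² by BFGS in the
full Cartesian space with the analytic Jacobian 2Bᵀ Aᵀ(v−v_target)
(A = Pᵀ⟨G⟩^{-1/2}Uᵀ), to an error below 10⁻⁸; the flat rigid-motion
directions are left free during optimization — the simplest well-posed
formulation, since the objective is rotation invariant — and the returned
geometry is gauge-fixed by Eckart alignment to the reference.
Mode animation solves the equilibrium geometry v_MW⁻¹(0, x_GM) first, then
walks ±kδ along one mode, warm-starting each solve from the previous
frame, and concatenates the frames into a multi-frame XYZ readable by
standard viewers.  The step defaults to δ = 0.25√λ_l (a quarter of the
mode's ground-state spread) with k_max = 8 — display choices, configurable.

## Synthetic systems and what the tests show

The package is self-contained: every reference geometry is produced by the
isomer-search fixture generator, and the validation systems are synthetic:

* separable harmonic oscillators (exact ZPE, moments, zero-variance guide);
* a Morse oscillator sampled exactly through its Gamma-distribution ground
  state (exact anharmonic levels as oracle);
* scaled-down water-cluster DMC runs (dimer/trimer at thousands of
  walkers, hexamer at hundreds).

These validate the estimators, the coordinate machinery and the scaled
reproduction of dimer spectroscopy, but not production-scale convergence
(hundreds of thousands of walkers), surfaces beyond the point-charge
model, overtones/combination bands, or comparison with experimental band
positions — all out of scope.  Statistical assertions use fixed seeds and
3σ-style tolerances; spectroscopic fundamentals at these ensemble sizes
carry seed-to-seed scatter of order 10 cm⁻¹ (bends, whose fourth-moment
estimator converges slowest, somewhat more), which is the scale to keep in
mind when comparing scaled-down runs against production values.

## Known limitations

* The kinetic-gap formula assumes a near-Gaussian amplitude along each
  mode; strongly anharmonic or double-well modes (e.g. across permutation
  barriers) would need explicit node placement, which is not implemented.
* Transition-state finding (NEB and barrier tables) is out of scope; the
  landscape module characterizes minima and permutations only.
* The permutation group is enumerated explicitly only up to n = 4 waters;
  larger clusters fall back to fingerprint-based isomer matching.
* Continuous-weighting resampling loses the (tiny) weight of removed
  walkers; total weight is conserved only through the duplicate-halving
  step, as specified for the threshold scheme.
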