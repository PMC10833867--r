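# memscore

An implicit-membrane electrostatic energy model for membrane-protein
scoring, orientation prediction and design evaluation, written for
structural bioinformaticians who need membrane energetics fast enough for
the inner loop of prediction and design rather than per-structure
Poisson–Boltzmann solves.

## The model

The lipid bilayer enters through three energy terms combined linearly
with an (injectable) soluble-protein baseline:

    E = E_baseline + w_wl * ΔG_wl + w_lipid * ΔG_lipid + w_dielec * Σ ΔE_elec

* **ΔG_lipid** — the interaction of protein partial charges with the
  electrostatic potential of the empty bilayer–water system,
  ΔG_lipid = Σ_r Σ_a ΔΨ(z_ra)·q_ra. ΔΨ(z) is obtained by solving
  Poisson's equation ∇²Ψ = −ρ/ε₀ on a periodic grid of lipid/water/salt
  charge densities with an FFT solver, laterally averaging, referencing
  to zero in bulk water (|z| ≈ 40 Å), and fitting a piecewise analytical
  profile per lipid type: a sigmoid tail A₁ + (A₁−A₂)/(1+exp((|z|−A₃)/A₄))
  for |z| ≥ z_c and a quartic core C₁|z|⁴+…+C₅ below it, with z_c the
  largest critical point of the quartic.
* **ΔE_elec** — a membrane-excess Coulomb term with a
  hydration-dependent dielectric: ε(r, f) mixes sigmoidal
  distance-dependent dielectrics for solution (6→80) and membrane (3→10)
  by the pair hydration fraction f_ij = √(f_i·f_j), and
  ΔE = C₀q_iq_j(1/r − 1/r_max)(1/ε(r,f) − 1/ε_sol(r)) with
  C₀ = 322 Å·kcal/mol·e⁻², r_max = 5.5 Å. It vanishes identically in
  water, strengthening electrostatics only inside the bilayer.
* **ΔG_wl** — water-to-bilayer transfer energy per atom,
  ΔG_atom·(1 − f_hyd), with atom-type energies solved by least squares
  from side-chain hydrophobicity scales via a stoichiometry matrix, and
  neutral-pH Asp/Glu (D⁻¹/E⁻¹) values extrapolated from the
  water-to-octanol scale through a linear fit — which renews the
  carboxylate atom types.

Default weights are (1, 0.128, 0.01); (0.5, 0, 0) recovers the
transfer-only predecessor model. A rigid-body scanner samples depth
(±60 Å), tilt (±180°) and axial rotation (0–360°) exhaustively to locate
the minimum-energy orientation, and ΔΔG protocols for insertion and
point mutation build on it. A design-metrics module computes sequence
recovery, KL divergence, confusion matrices and per-residue perplexity,
stratified by membrane region (lipid / interface / aqueous from
hydration thresholds).

All inputs can be generated synthetically (bilayer charge densities,
model peptides, design pairs, ΔΔG tables), so the package is fully
testable offline; shipped lipid profiles are fixture-fit placeholders,
replaceable by parameter tables fit from simulation densities.

## Worked example

```r
library(memscore)

prof <- default_lipid_profile("DMPC")     # fixture-fit placeholder profile
eval_profile(prof, 0)                     # bilayer-center potential
#> [1] 12.533                              # kcal mol^-1 e^-1

walp <- build_ideal_helix(fixture_sequence("walp", 8))  # WALP23
sc   <- membrane_scorer(prof)             # default weights (1, 0.128, 0.01)
land <- scan_orientations(walp, orientation_grid(), sc)
land
#> orientation landscape: 106872 grid points
#>   minimum E = -38.0122 at d = -2 A, theta = 40 deg, phi = 15 deg (tilt 40 deg)

best <- apply_orientation(walp, land$argmin$d, land$argmin$theta, land$argmin$phi)
total_score(best, weight_set(), prof)
#> energy breakdown (kcal/mol):
#>      transfer   lipid_field dielec_excess      baseline      combined
#>      -36.4335       -7.8653      -57.1930        0.0000      -38.0122

ddg_insertion(walp, sc)
#> ddG_ins = -37.949 kcal/mol (membrane minimum minus aqueous minimum)
```

The landscape minimum says the Trp-anchored WALP23 helix prefers a
membrane-spanning placement near the bilayer center (d = −2 Å) at a 40°
tilt under the default fixture profile; the breakdown shows the transfer
term dominating the combined score (the dielectric excess is large but
down-weighted by w_dielec = 0.01), and the insertion ΔΔG is the
energy gained over the fully aqueous placement.

Design evaluation on synthetic pairs:

```r
pairs <- fixture_design_pairs(n_pairs = 10, len = 80, recovery = 0.3, seed = 1)
m <- design_metrics(pairs)
m$recovery                      #> 0.3225
m$divergence$d_kl               #> 0.0174
round(m$perplexity[1:5], 2)     #> A 10.37  R 12.15  N 11.42  D 9.71  C 10.58
```

A command-line interface with the same operations (fit-profile,
eval-profile, score, scan, ddg-ins, ddg-mut, fit-weights,
design-metrics, make-fixture) is installed under
`system.file("cli", "memscore", package = "memscore")`.

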