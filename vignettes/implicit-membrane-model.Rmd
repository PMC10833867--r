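---
title: "An implicit-membrane electrostatic energy model"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{An implicit-membrane electrostatic energy model}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(memscore)
```

## The model

Membrane proteins sit in an environment that is electrostatically very
different from bulk water: lipid head groups carry large local charges
and dipoles, the hydrocarbon core has a dielectric constant an order of
magnitude below water's, and both effects vary strongly with depth.
Poisson–Boltzmann or generalized-Born treatments capture this but are too
expensive for the inner loop of structure prediction and design.
`memscore` implements a fast implicit alternative built from three
membrane energy terms that are combined linearly with a baseline
(soluble-protein) score:

$$E = E_\mathrm{baseline}
  + w_{w,l}\,\Delta G_{w,l}
  + w_\mathrm{lipid}\,\Delta G_\mathrm{lipid}
  + w_\mathrm{dielec}\,\sum_{ij}\Delta E^\mathrm{dielec}_{elec,ij}$$

with default weights $w_{w,l} = 1$, $w_\mathrm{lipid} = 0.128$,
$w_\mathrm{dielec} = 0.01$, fitted elsewhere against experimental
mutation ΔΔG data by bounded (L-BFGS-B, $[0,1]$) correlation
maximization; `fit_weights()` reproduces that procedure on any term/ΔΔG
table. Setting $(w_{w,l}, w_\mathrm{lipid}, w_\mathrm{dielec}) =
(0.5, 0, 0)$ recovers the predecessor transfer-energy-only model, a
property the test suite checks explicitly (the combined score then cannot
depend on the lipid profile at all).

### Lipid-field term

The electrostatic potential of the *empty* bilayer–water(–salt) system is
obtained by solving Poisson's equation
$\nabla^2 \Psi = -(\rho_l + \rho_w + \rho_s)/\varepsilon_0$ on a periodic
3D grid of charge densities with an FFT solver (`solve_poisson()`); the
dielectric constant is the vacuum value because all charges — lipid,
water, salt — enter explicitly. The solver inverts the *discrete*
7-point Laplacian in Fourier space, sets the zero-frequency mode to zero
(gauge), works in volts via the Coulomb prefactor
$e/4\pi\varepsilon_0 = 14.399645\ \mathrm{V\,\text{Å}}$, and converts
once to the package's potential unit with
$1\ \mathrm{V} = 23.061\ \mathrm{kcal\,mol^{-1}e^{-1}}$. The volume is
averaged laterally (`lateral_average()`) to a depth profile $\Psi(z)$ and
referenced to zero in bulk water at $|z| \approx 40$ Å.

Per lipid type the profile is summarized by a piecewise analytical form
(`fit_profile()` / `eval_profile()`):

$$\tilde\Psi_w(z) = \begin{cases}
 A_1 + \dfrac{A_1 - A_2}{1 + \exp\!\big((|z| - A_3)/A_4\big)} & |z| \ge z_c\\[6pt]
 C_1|z|^4 + C_2|z|^3 + C_3|z|^2 + C_4|z| + C_5 & |z| < z_c
\end{cases}$$

a function of $|z|$ only (profiles are symmetrized before fitting), with
$z_c$ the largest critical point of the quartic core. We evaluate the
*fitted* form by default (the raw averaged profile is also available via
`reference_profile()`), and clamp the potential to exactly zero beyond
the reference depth — bulk water — so that atoms outside the membrane
contribute nothing. The lipid-field energy is then
$\Delta G_\mathrm{lipid} = \sum_{r}\sum_{a} \Delta\Psi(z_{r,a})\,q_{r,a}$
over all atoms.

The printed sigmoid has the curiosity that its $|z|\to\infty$ asymptote
is $A_1$ while its value below $A_3$ approaches $2A_1 - A_2$; we
implement the expression exactly as written.

**Fitting strategy.** The two branches are coupled through $z_c$, which
is itself defined by the quartic being fitted. A naive alternation
(fit quartic on the current core window → recompute $z_c$ from its
critical points → fit sigmoid) is unstable on plateau-shaped profiles:
as the window shrinks the quartic flattens and its critical points
collapse toward zero, so the iteration walks $z_c$ monotonically inward.
`fit_profile()` instead scans candidate crossovers (quartic fit is linear
and cheap; the sigmoid is a Levenberg–Marquardt fit; a continuity
pseudo-observation at $z_c$ with 100× data weight ties the branches),
keeps the candidates whose joint residual is within 5% of the best, and
among those selects the most *self-consistent* one — minimizing the gap
between the crossover and the largest critical point of its own quartic —
before polishing with the fixed-point iteration
$z_c \leftarrow \max(\text{critical points})$ (tolerance 0.01 Å, cycle
detection, residual-band safeguard). On data genuinely generated from
the piecewise model the fixed point is recovered to well under 0.1 Å; on
flat-core profiles the critical points are degenerate and the
residual-optimal crossover is kept.

Degenerate input (an identically flat profile) returns the all-zero
amplitude parameter set rather than an error.

### Hydration and the membrane dielectric term

Membrane hydration $f_\mathrm{hyd} \in [0,1]$ is the model's proxy for
depth and water-cavity exposure: 0 for a lipid-exposed atom at the
bilayer center, 1 in bulk water. The depth dependence is a smooth
monotone logistic in normalized depth,
$f = u^n/(1+u^n)$ with $u = |z|/t$ (half-thickness $t = 15$ Å) and
$n = 10$; pore exposure enters as
$f_\mathrm{hyd} = \max(f, f_\mathrm{pore})$, with $f_\mathrm{pore} = 0$
by default (single helices have no pore). The functional form is this
package's own stand-in for hydration models that are derived from
solvent-accessibility calculations; it hits the stated limits (0 at the
center, 1 beyond ~4 half-thicknesses to within $10^{-6}$) and both
parameters are configurable through `membrane_geometry()`.

For an atom pair the hydration fraction is the geometric mean
$f_{ij} = \sqrt{f_i f_j}$. The pair dielectric mixes two sigmoidal
distance-dependent dielectrics linearly:
$\varepsilon(r, f) = f\,\varepsilon_\mathrm{sol}(r) +
(1-f)\,\varepsilon_\mathrm{memb}(r)$, where each sigmoid transitions
between a core and a surface value — 6→80 in solution, 3→10 in the
membrane. The sigmoid itself is the Hingerty–Lavery form
$\varepsilon(r) = \varepsilon_s - (\varepsilon_s - \varepsilon_c)
\big((\sigma r)^2 + 2\sigma r + 2\big)e^{-\sigma r}/2$ with steepness
$\sigma = 1.2\ \text{Å}^{-1}$; any monotone sigmoid satisfying the
endpoint contract would do, and this one is standard for
distance-dependent dielectrics. The membrane-excess Coulomb energy of a
pair is

$$\Delta E_{elec,ij} = C_0\, q_i q_j
 \Big(\tfrac{1}{r_{ij}} - \tfrac{1}{r_\mathrm{max}}\Big)
 \Big(\tfrac{1}{\varepsilon(r_{ij}, f_{ij})} -
      \tfrac{1}{\varepsilon_\mathrm{sol}(r_{ij})}\Big)$$

with $C_0 = 322\ \text{Å kcal/mol}\,e^{-2}$ and truncation
$r_\mathrm{max} = 5.5$ Å. Subtracting the solution-phase energy isolates
the membrane's excess effect and leaves the aqueous unfolded reference
untouched: the term vanishes identically at $f = 1$, is negative for
opposite charges and positive for like charges whenever $f < 1$
(because $\varepsilon(r,f) \le \varepsilon_\mathrm{sol}(r)$ pointwise).
We take the subtracted reference to be the same distance-dependent
$\varepsilon_\mathrm{sol}(r_{ij})$ rather than a constant 80; this is an
interpretation choice, made because it is the unique choice that makes
the term vanish exactly in water.

Pairs within the same residue are excluded from the pair list (they are
dominated by through-bond terms that belong to the baseline score); the
pair list and all distances are computed once per structure and reused
across rigid-body orientations, since rigid motion cannot change
internal distances — a property the tests verify to $10^{-9}$ Å.

### Transfer term and the neutral-pH Asp/Glu correction

The water-to-bilayer transfer energy uses per-atom-type energies scaled
by lipid exposure: $\Delta G_{w,l} = \sum_a \Delta G^{atom}_{w,l}(t_a)\,
(1 - f_{\mathrm{hyd},a})$. Atom-type energies are derived from
side-chain hydrophobicity scales by least squares on the stoichiometry
system $[A_{aa,atom}]\,\Delta G^{atom} = \Delta G^{aa}$
(`solve_atom_transfer()`), where the matrix counts each atom type per
side chain. The bilayer-context (MF-type) scale is measured in a
transmembrane host at pH 3.8, close to the Asp/Glu pK$_a$, so those two
measurements mix protonated and deprotonated forms. The correction:
fit the bilayer scale linearly on the water-to-octanol (WW) scale
excluding Asp/Glu, extrapolate the deprotonated D$^{-1}$/E$^{-1}$ values
from their WW counterparts (`extrapolate_charged()`), append the two
rows to the stoichiometry system, and re-solve — which renews the
carboxylate (COO/OOC) atom types.

Two practical notes. First, the side-chain data determine some type
pairs only in combination (a carboxylate always contributes one C and
two O; the amide O and N always co-occur), so the system is rank
deficient and the documented minimum-norm least-squares solution is
used, with a warning from `solve_atom_transfer()` (suppressed in the
prepackaged `default_atom_scale()`, where it is expected). Second,
backbone atom types carry zero transfer energy in the default scale:
the underlying scales are side-chain scales relative to an Ala host, so
they contain no backbone information. The shipped WW numbers are the
widely reproduced water-to-octanol values; the shipped MF-type column is
a placeholder constructed from the WW scale through a linear relation
with a higher slope (zeroed at the Ala host) and is labelled as such —
replace it via `read_aa_scale()` when absolute energies matter. All
quantitative tests use synthetic scales, so no result in the test suite
depends on transcription accuracy.

## Orientation sampling and ΔΔG protocols

`build_ideal_helix()` constructs ideal α-helices from sequence with
backbone dihedrals φ = −57°, ψ = −47°, standard bond geometry, and
side-chain heavy atoms from internal-coordinate templates at a single
extended default rotamer — a stated simplification relative to a packer;
there is no repacking anywhere in the package. Termini are charged by
default (protonated N-terminus; carboxylate C-terminus with OXT).
Partial charges are a simplified heavy-atom set (hydrogen charges
aggregated onto bonded heavy atoms, summing to the residue's formal
charge), shipped as an editable table.

`scan_orientations()` samples depth $d \in \pm60$ Å, tilt
$\theta \in \pm180°$, and axial rotation $\phi \in 0\!-\!360°$
exhaustively; the default steps (2 Å, 5°, 15°) keep the full scan of a
23-residue peptide around ten seconds on one CPU, and the grid object
accepts finer steps for refinement around a coarse minimum. The global
minimum is the predicted orientation; ties break deterministically
(smallest $|d|$, then smallest folded tilt, then smallest $\phi$). Tilt
is reported folded into $[0°, 90°]$ to match experimental conventions
(a surface-adsorbed peptide reports 90°).

Two free-energy protocols build on the scanner:

* `ddg_insertion()`: the difference between the lowest-energy
  membrane-embedded placement ($|d| < 40$ Å) and the lowest-energy
  aqueous placement ($|d| \ge 40$ Å). The unfolded-reference term
  cancels in the difference and is reported as zero for membrane-only
  scorers; the result is invariant to any additive constant in the
  scorer. The aqueous state is the *folded* helix at aqueous depth — for
  scorers whose membrane terms vanish in water this coincides with any
  aqueous reference up to a constant, which cancels.
* `ddg_mutation()`: fixed backbone, fixed orientation; both the native
  and the mutant side chain at the position are rebuilt from the same
  templates (so a self-mutation is exactly zero), and the water states
  are evaluated with every atom beyond the reference depth.

## Design metrics

`sequence_recovery()`, `aa_distribution()`, `kl_divergence()`,
`design_confusion()` and `perplexity()` evaluate designed sequences
against natives, overall or stratified by membrane region. Regions
follow the hydration thresholds: lipid at $f_\mathrm{hyd} < 0.25$,
interface at $f_\mathrm{hyd} \in [0.25, 0.75)$ (both with
$f_\mathrm{pore} < 0.5$), aqueous otherwise — the printed thresholds
leave gaps (e.g. exactly 0.75, or high pore exposure at low hydration),
which we close by sending everything else to aqueous, since pore-facing
residues are water-exposed. Perplexity uses base-2 logs as defined
($pp_r = 2^{-\sum p \log_2 p}$: 1 = fully confident, 20 = maximally
confused); the KL divergence uses natural logs by default with the base
configurable, since printed divergence values cannot disambiguate the
base. Zero-probability handling: $0\log 0 = 0$ inside $D_{KL}$; a
$D_s$ with zero probability on either side is reported as `NA` and
excluded from the sum $D$ with a warning (an optional pseudo-count is
available but off by default); design support where the native
distribution has none makes $D_{KL}$ infinite, with a warning, rather
than an error.

## Synthetic fixtures and what they do (and do not) show

Everything needed to exercise the pipeline ships as generated fixtures
(`fixture_*()`, `make_fixture()`), deterministic per seed:

* **Bilayer densities** are mirrored Gaussian slab systems: a
  zwitterionic head-group dipole (layers at 15 and 18 Å, surface density
  $10^{-3}\ e/\text{Å}^2$, width 1.5 Å), optionally an extra anionic
  head-group charge compensated by a uniform neutralizing background
  (the `neutralize` flag of `charge_density_grid()` exists exactly for
  such bare charged bilayers), and optionally an adsorbed counter-ion
  layer at 20.5 Å that cancels most of the anionic charge — emulating
  screening by a salt solution. With the counter-ion layer present the
  bilayer-center potential magnitude drops by an order of magnitude,
  which is the qualitative salt effect the acceptance suite checks. The
  layer positions and densities were chosen once to give potentials of
  realistic magnitude (order 10 kcal mol⁻¹e⁻¹ ≈ 0.5 V at the center)
  and are not tuned thereafter.
* **Default lipid profiles** for DLPC/DLPE/DLPG/DPPC/DOPC/POPC/DMPC are
  fit from these fixtures (head-group dipole strength and depth vary per
  lipid in the fixture settings) and are explicitly *placeholders* for
  parameters fit from all-atom simulation densities; load measured
  parameter tables with `read_profile_table()` for quantitative work.
* **Peptides**: polyalanine, Trp-anchored WALP (`GWW(LA)`~n~`LWWA`),
  and poly-Leu `GL`~x~`RL`~x~`G` generators.
* **Design pairs and ΔΔG tables** with controlled recovery/weights.

Because the fixtures are idealized (no water densities, no interface
deformation, single rotamer, synthetic charges), passing tests
demonstrate the *numerics* of the model — solver correctness against
independent oracles, fit recovery, term identities, rigid-body
invariants, metric definitions — not agreement with experimental tilt
angles, stabilities, or design recovery on real structures, which
additionally require a full all-atom baseline score and measured
profile/scale inputs.

## Numerical choices

* Poisson solver: discrete-Laplacian eigenvalues (not continuum $k^2$),
  so the FFT result matches a dense direct solve of the same operator to
  machine precision; neutrality enforced to $10^{-6}\,e$ unless the
  neutralizing background is requested.
* Problem sizes: the test suite uses ≤ $8^3$–$10^3$ grids for dense
  oracle comparisons, 320-point 1D quadrature oracles, and the full
  default orientation grid (106,872 points) only for the 23-residue WALP
  fixture; these sizes keep each check in seconds while leaving the
  discretization fine enough for sub-percent oracle agreement.
* Weight fitting maximizes a correlation, which is scale-free; the
  optimizer therefore reports *a* weight direction, and only the
  achieved correlation is contractual. Eight fixed-seed multi-starts
  guard against the flat directions.
* Tie-breaks, cycle detection and degenerate-input behavior are
  documented above where each arises.

## Limitations

The baseline (soluble-protein) score is an injected contract defaulting
to zero — scoring against a full all-atom energy requires supplying one.
No pK$_a$ shifts, no mixed or asymmetric bilayers, no membrane
deformation, no backbone flexibility, and no Monte-Carlo design: the
metrics module consumes sequences from any external designer.
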