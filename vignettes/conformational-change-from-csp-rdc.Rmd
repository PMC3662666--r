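---
title: "Detecting conformational change from amide CSPs and RDCs"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Detecting conformational change from amide CSPs and RDCs}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ringcsp)
```

## The problem

A fragment-sized ligand binding a protein perturbs the chemical shifts of
nearby backbone amide protons. Two mechanisms contribute: the direct
magnetic effect of the ligand — for aromatic fragments, overwhelmingly the
ring-current effect — and indirect effects of any structural rearrangement
of the protein itself (backbone movement, aromatic side-chain
reorientation). The direct part can be computed from docked poses of the
ligand in the apo structure. So if a residue's measured CSP is larger than
the ring-current prediction of *every* plausible pose, the excess must come
from the protein moving. That subtraction logic, plus an orthogonal check
using residual dipolar couplings, is what this package implements.

What it deliberately does not do: generate docking poses (they are
consumed as input), simulate hydrogen-bond or electric-field shift
contributions (unreliable for ligand complexes), predict nitrogen CSPs
(hard to interpret for ligand binding), or model alignment from molecular
shape.

## Ring-current model

We use the Haigh–Mallion semi-classical form. For a proton p and a ring
traversed in atom order, summing over ring bonds (j, k):

$$\delta = -\,i\,B \sum_{(j,k)} S_{jk}\left(\frac{1}{r_j^{3}} +
\frac{1}{r_k^{3}}\right)$$

* $S_{jk}$ — signed area of the triangle formed by the proton and the two
  bonded ring atoms **after projecting all three points onto the
  least-squares ring plane**; positive when the traversal
  $p' \to j' \to k'$ is counter-clockwise about the ring normal. The
  normal follows the right-hand rule over the atom ordering; reversing
  the ordering flips both the normal and the traversal, so the shift is
  invariant to that choice.
* $r_j, r_k$ — full three-dimensional (unprojected) distances from the
  ring atoms to the proton. Projecting only the areas is the literal
  reading of the model and is what the shoelace-closure identity below
  relies on.
* $i$ — ring-type intensity factor: 1.00 for a six-membered all-carbon
  ring (the reference value of the model); heteroaromatic
  six-rings (0.90) and five-rings (0.60) ship as editable defaults in
  `inst/extdata/ring_current_constants.csv`.
* $B$ — amide-proton target factor, default 5.4558 (ppm with coordinates
  in Å), the SHIFTX-lineage value. It is loaded from configuration and
  never hard-coded in a computation path; every structural property the
  tests rely on (symmetries, closure, scaling, recovery) is independent
  of $B$. With this $B$, the shielding cone 3 Å above a benzene centroid
  is about $-1.5$ ppm, the textbook magnitude.

The leading minus sign makes the axial shielding cone negative (upfield)
and the in-plane deshielding belt positive while keeping $B > 0$.

Per-residue **simulated CSP** is the magnitude of the signed sum over all
rings of a pose, because the experimental CSP (a difference of
magnitudes-insensitive peak positions) is reported as a magnitude. Signed
values remain available (`signed = TRUE`) and drive the iso-shielding
maps. When several rings overlap, signed contributions are summed first
and the magnitude taken last.

Protein-side aromatic rings (Phe/Tyr/Trp/His) are intentionally *not*
included in the simulation: their reorientation is one of the
conformational-change signals the method is designed to expose, not a
background to subtract.

Protons closer than 0.5 Å to a ring atom are flagged as steric artifacts
but their values are kept — docking programs do produce van-der-Waals
clashes, and those poses should be inspected, not silently dropped.

## Numerical checks the implementation must pass

Three identities pin the geometry down and are enforced in the test
suite:

1. **Shoelace closure** — for any proton position, $\sum_{(j,k)} S_{jk}$
   over the ring's bonds equals the signed projected area of the ring
   polygon itself (a fan triangulation from an arbitrary apex), exact to
   1e-10.
2. **Symmetries** — mirror symmetry across the ring plane; invariance of
   every simulated CSP under a joint rigid motion of protein and pose
   (≤ 1e-9 ppm); invariance under ring atom-order reversal (1e-12).
3. **Far field** — along the ring axis, $\delta \cdot z^3$ converges to a
   constant within 1% beyond 20 Å.

Independently of these, 100 random proton/ring configurations are checked
against a brute-force evaluator written with a different plane
construction (Newell polygon normal, explicit 2D shoelace areas) to 1e-12
relative agreement. The same dual-route check runs inside
`scripts/acceptance.R` at every seed.

## Experimental CSPs and the P factor

`compute_experimental_csp()` implements
$\mathrm{CSP}_H = |\delta_H^{bound} - \delta_H^{free}|$ per residue, the
nitrogen analogue, and the combined perturbation
$\sqrt{\mathrm{CSP}_H^2 + (0.14\,\mathrm{CSP}_N)^2}$. The 0.14 weight is
the standard amide nitrogen scaling; it is exposed as a parameter, and the
combined value is used only for binding-site mapping, never for pose
scoring. Saturation at the top titration point is assumed; no dissociation
constant extrapolation is attempted (unsaturated data only make simulated
values exceed experimental ones, which the tiering already tolerates).

The per-pose agreement factor defaults to a mean absolute deviation
normalised by a **caller-supplied** residue count N:

$$P_k = \frac{1}{N}\sum_{res} \left|\mathrm{CSP}_H^{exp} -
\mathrm{CSP}_H^{sim,k}\right|$$

Residues unobserved in experiment (overlap, exchange, absent from the
model) contribute nothing to the sum but still appear in N, keeping P
comparable across datasets with different coverage (e.g. N = 196 for
full-length Bcl-xL). An
RMSD-normalised mode is selectable and recorded in output metadata. A
useful sanity property, also tested: adding a constant $c$ to every
experimental CSP (with experiment ≥ simulation) raises mad-mode P by
exactly $c \cdot \mathrm{shared}/N$.

**Disagreement tiers.** Per residue,
$\Delta = \mathrm{CSP}_H^{exp} - \max_k \mathrm{CSP}_H^{sim,k}$ over the
in-scope poses (all poses, or one docking cluster). $\Delta > 0.2$ ppm is
`strong`, $\Delta > 0.06$ ppm `moderate`, $\Delta < 0$ `sim_exceeds_exp`,
else `none`. Boundaries are strict inequalities. The maximum is
idempotent, so the report is invariant to pose duplication and ordering.
Whether the comparison should run across the full ensemble or per cluster
is genuinely ambiguous in the method's description; both are supported via
`scope`, with the full ensemble as default (the more conservative choice —
a larger maximum flags fewer residues).

## RDC fitting

With partial alignment, the one-bond N–H coupling is
$D_i = u_i^\top S\, u_i$ for the unit bond vector $u_i$ and the symmetric
traceless Saupe matrix $S$. The dipolar prefactor is absorbed into $S$,
which is therefore fitted directly in Hz — every comparison the method
makes is in Hz, so no gyromagnetic constants are needed. Five independent
elements are solved by SVD least squares from ≥ 5 couplings; a design
matrix with relative singular value below 1e-8 (e.g. near-parallel
vectors) raises a rank-deficiency error rather than returning nonsense.
Plain least squares, no per-residue weights: the data carry no stated
uncertainties.

Fit quality: Pearson correlation r, and
$Q = \mathrm{rms}(D_{exp}-D_{calc}) / \mathrm{rms}(D_{exp})$ — the
simpler of the conventional normalisations; the axial-component-based Q
is out of scope. Outliers default to $|D_{exp}-D_{calc}| > 6.5$ Hz.
`compare_structures()` refits the tensor independently per candidate
structure (each row self-contained — the alternative, holding one tensor
fixed, penalises structures for alignment differences rather than
conformational ones) and ranks by r, optionally over a residue subset
such as the helices flanking a binding site.

`fit_alignment_tensor()` returns a classed model object with the familiar
verbs (`coef`, `predict`, `residuals`, `simulate`, `plot`, `summary`
reporting Da and rhombicity from the tensor eigenvalues).

## What the synthetic generators emulate — and what they do not

`fixture_spec()` drives four generators, each a pure function of the spec
(fixed seed ⟹ byte-identical output):

* `make_helix_protein()` — poly-alanine backbone from ideal internal
  coordinates (NeRF construction; bond lengths 1.458/1.525/1.329 Å,
  standard angles). We parameterise by dihedrals (φ = −57°, ψ = −47°)
  rather than rise/twist because dihedral construction guarantees
  chemically valid C(i−1)–N–CA geometry for amide-proton placement; the
  defaults realize the canonical ~1.5 Å rise and ~100° twist. Protons at
  1.02 Å in the peptide plane, the standard choice for back-calculation
  from crystal coordinates.
* `make_ring_pose()` — ideal benzene hexagons (C–C 1.39 Å), para-linked
  at 1.48 Å for the biphenyl chemotype, with a para fluorine and carboxyl
  carbon so perception runs on a realistic atom set. Target placement
  puts the first ring centroid at a set distance from a chosen residue's
  amide proton along the protein's outward radial direction, ring plane
  perpendicular — the geometry that maximises the shift at that proton
  and guarantees it receives the largest simulated CSP.
* `make_synthetic_peaklists()` — smooth fixed baselines plus the *signed*
  ring-current shift of one pose, optional Gaussian noise, and an
  injected perturbation on chosen residues added with the sign of the
  local ring shift, so the induced CSP magnitude is exactly ring
  contribution + injection. Nitrogen shifts pass through unchanged (the
  simulation is proton-only); combined-CSP code paths are tested with
  hand-set nitrogen deltas instead.
* `make_synthetic_rdcs()` — couplings from a supplied tensor plus seeded
  noise.

Noise defaults are zero because the generators' primary role is the exact
forward-model null: peak lists built from any single pose must give
P(that pose) = 0 and zero flagged residues, and injections of 0.3/0.1 ppm
must flag exactly the injected residues as strong/moderate. Those are the
package's principal end-to-end tests.

What passing them does **not** show about real data: the helix is not a
real fold (no tertiary contacts, no aromatic protein side chains, no
prolines); experimental peak lists carry assignment errors, exchange
broadening and incomplete saturation; real docking ensembles have
correlated, physically clustered poses rather than seeded jitter; and real
CSPs contain hydrogen-bond and electric-field terms the model excludes.
The synthetic system validates the machinery and its contracts, not the
biology.

## Problem sizes and defaults

The shipped analyses use a 60-residue helix, 20–50 pose ensembles, and
59-coupling RDC sets — comfortably representative of a small protein
domain while keeping the full suite and the acceptance script fast.
Tensor-recovery studies use 20 spread unit vectors (noise-free, 100
random tensors) and n ∈ {10, 20, 40} at 1 Hz noise for the
error-vs-data-size check. Binding energies in the jittered ensembles are
drawn from the fragment-typical −5.7 to −4.3 kcal/mol range.

Degenerate inputs are handled explicitly: poses without rings simulate to
all-zero with a warning; residues missing either an experimental or
simulated value drop out of sums by key intersection; prolines and the
N-terminus never carry amide protons; collinear ring atoms, < 5 RDCs and
parallel vector sets raise structured errors with dedicated condition
classes.

## Known limitations

* Ring perception is geometric (distance graph + planarity + element
  filter on 5/6-cycles); it cannot distinguish an aromatic ring from a
  planar aliphatic one, and macrocycles are ignored by design.
* The intensity table beyond benzene is a configurable convention, not a
  fitted quantity.
* Combined-CSP thresholds for binding-site mapping are configuration-only
  — no defaults are asserted.
* `pdbqt` is read-only; poses are written as multi-MODEL PDB.
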