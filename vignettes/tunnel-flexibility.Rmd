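---
title: "Methods: pH-series tunnel flexibility, substrate geometry and constant-pH Monte Carlo"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: pH-series tunnel flexibility, substrate geometry and constant-pH Monte Carlo}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(tunnelflex)
```

This vignette documents the models and numerical choices behind
`tunnelflex`. The package targets a recurring analysis pattern in the
structural enzymology of polysaccharide lyases (PLs): a single enzyme
crystallized at several pH values, in apo and substrate-bound forms,
interrogated for (i) where flexibility lives in the catalytic tunnel,
(ii) how an oligosaccharide is held subsite by subsite, (iii) which
ring face each sugar presents to the tunnel walls, and (iv) how
protonation states respond to pH.

## Structures and regions

Structures are plain fixed-column PDB models: atoms with coordinates,
isotropic B-factors and occupancies, plus the CRYST1 cell. Parsing and
writing delegate to `bio3d`, with the unit cell handled by the package
because `bio3d` discards CRYST1. Alternate locations other than blank
or `A` are dropped — the standard single-conformer convention — and
all geometry is heavy-atom based, because 2.2–2.6 Å models carry no
hydrogens. Author residue numbering is used throughout, since that is
how tunnel residues are referred to in practice (Y38, R312, ...).

The catalytic tunnel is described by a *region map*: named surfaces at
the entry face (roofs `R1`/`R2`, floors `F1`/`F2`, inner/outer left
and right walls) and two exit-face rings, plus three disjoint
substrate-interacting *site* sets — entry (6 residues), tunnel (7) and
exit (11), 24 residues in all — and the catalytic set (N167, H168,
Y222, with Q112 on the innermost surface). The map is data, not code
(`inst/extdata/tunnel_regions.yaml`), so any disagreement about a
residue's assignment is fixed by configuration. One known ambiguity is
recorded in the file itself: the interaction tables label R312 as
surface *F1* while the structural description places it in *F2*; the
default keeps *F2*, and `load_region_map()` overrides it in one line.
Overrides are re-validated: a residue claimed by two site sets is an
error, not a silent choice.

## B-factor flexibility profiling

The isotropic B-factor is used as a per-atom proxy for local
flexibility. Three statistics are computed:

* **Selection means** — the unweighted mean B over any atom selection.
  The whole-molecule mean (protein + ligands + waters) is the headline
  per-structure number; the backbone mean uses the `{N, CA, C, O}`
  set.
* **Scaled per-residue values** — each residue's all-atom mean divided
  by the *protein-only* mean of its structure. Scaling removes
  resolution and crystal-packing offsets so structures refined at
  different resolutions can be compared on one axis. "Divide by the
  average B of the molecule" is ambiguous when water counts differ
  between crystal forms; the protein-only denominator avoids that
  bias, and the whole-molecule mean is still reported separately. By
  construction the atom-count-weighted mean of scaled values over
  protein residues is exactly 1 (tested to 1e-9), and the profile is
  invariant under global rescaling of B.
* **Highest-fluctuation classification** — for a labeled series and a
  residue set, each residue is assigned to the structure where its
  scaled value is largest, and wins are tallied per structure. Scaled
  values are the default because raw B comparisons across crystal
  forms conflate flexibility with resolution; raw values remain
  available (`scaled = FALSE`). Residues unresolved in a structure
  are excluded from that structure's competition rather than imputed;
  residues resolved nowhere are skipped with a warning. Ties are
  broken by input order, which makes the result deterministic and
  documented. Occupancy weighting is not applied: the depositions this
  targets are essentially full-occupancy.

## Interactions and subsites

Noncovalent contacts are enumerated with distance-only criteria:

* **Hydrogen bond**: protein N/O to ligand N/O, heavy-atom distance ≤
  3.6 Å (default). The cutoff brackets the longest contact such
  interaction tables print; without hydrogens a donor–H–acceptor angle
  cannot be measured honestly.
* **Salt bridge**: Arg NH1/NH2/NE or Lys NZ to a carboxylate oxygen
  (uronic O6A/O6B, with O61/O62 aliases normalized; Asp/Glu-type
  oxygens for generality), ≤ 4.0 Å. Histidine contacts are typed as
  hydrogen bonds even though His is ionizable — that is the convention
  of the tables the output mirrors. The two record sets are disjoint
  by construction, bifurcated contacts appear as separate records, and
  the protein atom is always listed as the donor (the tables'
  convention, kept even for chemically ambiguous hydroxyl–hydroxyl
  pairs). Water-mediated bridges are out of scope.

Subsites are assigned from glycosidic connectivity: an exocyclic
oxygen within 1.8 Å of the anomeric C1 of another sugar is a linkage.
The chain must be linear; the unique sugar with a free anomeric C1 is
the reducing end, which by the biology of these tunnels exits first.
The scissile bond is the linkage whose glycosidic oxygen lies nearest
the catalytic-residue centroid (or an explicit `catalytic_point`, used
by fixtures); its reducing-side sugar is `+1`, its partner `-1`, and
numbering proceeds outward. A contact to a linkage oxygen itself is
labeled with both flanking subsites (e.g. `-1,+1`). Summary counts of
hydrogen bonds and salt bridges are restricted to the catalytic
`[-1, +1]` subsites, which is the comparison that matters for binding
strength at the cleavage site.

## Ring faces and rotamers

The ring plane is the least-squares plane through the six ring atoms
(SVD of centered coordinates); signed displacements along the normal
sum to zero by construction. A ring presents its **α face** to a
reference point when C1, C3 and C5 all lie on the reference side of
the plane, its **β face** when all lie opposite; mixed or flat
patterns are *indeterminate*, which is exactly what non-chair puckers
should return. "Above the plane" is meaningless without a frame, so
the package fixes the reference as the tunnel roof — the centroid of
the lid-loop residues Y38/Y39 — which makes face calls comparable
across superposed complexes; any explicit point can be supplied
instead. Reflecting the reference through the plane swaps α and β
(tested), and calls are invariant under rigid motion of ring and
reference together. A reference within 0.1 Å of the plane is rejected
rather than guessed. Cremer–Pople parameters are offered as auxiliary
output only; face calls deliberately use the simpler least-squares
plane, which is robust for the near-chair sugars seen in these
complexes.

Side-chain χ1 (N–CA–CB–γ, IUPAC sign) is binned g+ (0°, 120°], t
(120°, 180°] ∪ (−180°, −120°], g− (−120°, 0°]. Transitions across a
series are flagged against the first structure (by convention the
lowest pH); a residue missing its γ atom — glycine, alanine, or a
density gap — is `unresolved` and counts as changed, because an
unobservable rotamer is not evidence of conservation.

## Crystal packing

Cell volume uses the general triclinic formula (checked against the
metric-tensor determinant to 1e-6 relative). The Matthews coefficient
is V/(n·Z′·MW) with a built-in multiplicity table covering the space
groups of the crystal forms analyzed; solvent content is
(1 − 1.23/V~M~)·100 with Matthews' classic 1.23 Å³/Da constant.
Published tables computed with slightly different constants or
molecular weights can differ by up to about one percentage point of
solvent; the package documents a ±1% comparison tolerance rather than
reverse-engineering any particular table's constant. Z′ cannot be read
from a coordinate file and must be supplied.

## Constant-pH Monte Carlo

The titration engine samples binary protonation states with a
Metropolis criterion driven by

$$\Delta G = k_B T\,(\mathrm{pH} - pK_{a,\mathrm{ref}})\ln 10
  + \Delta G_{elec} - \Delta G_{elec,\mathrm{ref}}$$

with $k_B = 1.9872\times10^{-3}$ kcal/(mol·K) and T = 300 K by
default. The equation as printed carries no direction; the package
applies it to the **protonation** move (deprotonated → protonated) and
negates it for deprotonation. This is the orientation forced by the
physics: with pH above the reference pKa the pH term must *penalize*
protonation so that a null-model site titrates along the
Henderson–Hasselbalch curve $f_{prot} = 1/(1+10^{\mathrm{pH}-pK_a})$ —
the property the test suite verifies within binomial error, together
with the exact −1 pK~a~ shift produced by a constant electrostatic
offset of $k_BT\ln 10$.

The conformational-dynamics half of full constant-pH molecular
dynamics is deliberately absent: energies are fixed-geometry, and the
electrostatic hook (per-site offsets plus a symmetric pairwise
coupling matrix) is a Coulombic toy standing in for
conformation-dependent terms. Generalized-Born solvation is a
non-goal. A sweep is one attempted flip per site; the default burn-in
is 10% of sweeps; runs are bit-reproducible for a fixed seed. pK~a~ is
estimated by a Hill-form fit (`stats::nls`, started from the linear
interpolation of half-protonation), which also reports the Hill
coefficient; curves that never cross 0.5 are an error, not an
extrapolation. The suite uses 10^4^ sweeps per pH point, which
resolves a one-site pK~a~ to about ±0.01–0.03 and comfortably inside
the ±0.05 check; a two-site coupled system is verified against its
exact four-state Boltzmann distribution by a χ² test.

## What the synthetic generator does and does not emulate

Fixtures emulate the *statistical and geometric contracts* of real
structures: exact per-residue B profiles on a poly-alanine chain,
ideal alternating chairs (±0.25 Å displacements) with known face,
glycans with true 4←1 glycosidic connectivity and a free reducing-end
anomeric carbon, and donor–acceptor pairs at construction-exact
distances (PDB-format precision, 0.001 Å). All fixtures are
round-tripped through PDB text so every test exercises the real
parser. Contact fixtures guarantee clash-free geometry (no two atoms
under 1.0 Å) and produce exactly the requested interactions; jittered
B-factor chains make no clash guarantee, as they model B statistics,
not packing.

They do **not** emulate folded protein context: no realistic secondary
structure, no crystal contacts, no correlated B structure, no
solvent. Passing tests therefore demonstrate that the *computations*
are correct on inputs whose ground truth is known — not that any
biological conclusion holds for a particular deposited structure. The
suite's one network-dependent test applies the same functions to the
six deposited pH-series entries and checks the published whole-model
means, site means, the 9/12/3 flexibility split, interaction counts
and packing metrics; it requires fetching those entries from the
public archive at run time, since coordinate files are far too large
to ship with a source package.

## Known limitations

* Distance-only interaction criteria cannot distinguish a true
  hydrogen bond from a close polar contact with bad geometry; with
  hydrogen-free models this is irreducible.
* Face classification needs a reference frame; comparisons are only
  meaningful when structures share one (superposition or the roof
  convention).
* The titration engine is a property-checked toy: it implements the
  free-energy/Metropolis core exactly, but without conformational
  sampling or real electrostatics its absolute pK~a~ values for a
  protein are not predictions.
* Wilson-B estimation, TLS/anisotropy, automatic tunnel detection and
  π-stacking analysis are out of scope.
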