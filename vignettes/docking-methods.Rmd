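---
title: "Scoring, sampling and validation in moldock"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Scoring, sampling and validation in moldock}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

moldock places small-molecule ligands into protein or nucleic-acid binding
sites with an empirical composite scoring function and a staged stochastic
search. This vignette is the package's own account of the model, the
parameters that matter, the numerical choices behind the implementation,
and what the synthetic validation systems do and do not demonstrate.

## The composite score

Every pose is scored as a weighted sum of four components,

$$S_{total} = w_{inter} S_{inter} + w_{intra} S_{intra}
            + w_{site} S_{site} + w_{restraint} S_{restraint},$$

with all four weights defaulting to 1. $S_{inter}$ is the
ligand-receptor interaction score and the quantity of primary interest.
$S_{intra}$ is the ligand's internal energy *relative to the input
conformation* — it is exactly zero for the conformation read from file and
for every pose of a rigid ligand. $S_{site}$ is the analogous relative
energy of the flexible receptor region (the only flexible receptor bonds
are terminal hydroxyl and ammonium torsions). $S_{restraint}$ collects the
non-physical bias terms (pharmacophore spheres, cavity containment,
distance restraints).

The constituent potentials are:

* **van der Waals.** A soft-core $n$/$2n$ pair potential,
  $E = \varepsilon\,[(r_0/r)^n - 2 (r_0/r)^m]$ with $n = 2m$, in a hard
  "6-12" and a soft "4-8" form. The minimum is $-\varepsilon$ at
  $r = r_0$; the zero crossing sits at $r_0\,2^{-1/m}$. Per-element radii
  (Bondi-style) and well depths live in
  `inst/extdata/params/elements.csv`; pairs mix by
  Lorentz-Berthelot-style rules ($r_0$ = sum of radii, $\varepsilon$ =
  geometric mean). Pair energies are capped at +100 score units so that
  clashing poses remain finite for the optimiser. Polar (donor)
  hydrogens carry a reduced radius (0.5 Å) so that hydrogen-bond approach
  distances are not penalised sterically — the standard force-field
  convention.

* **Polar.** An empirical hydrogen-bond term,
  $E = \pm W f_d(d)\, f_\theta(\theta)\, f_\phi(\phi)$. $f_d$ is a
  trapezoidal ramp equal to 1 for donor-heavy-to-acceptor distances in
  [2.5, 3.1] Å, falling linearly to zero over a 0.6 Å tolerance band;
  $f_\theta$ ramps the donor angle (D–H···A, full weight above 150°) and
  $f_\phi$ the acceptor angle (root–A···H, full weight above 90°), each
  with a 30° tolerance. The well depth $W$ (default 4 score units) is the
  `polar` entry of the weight vector; pairs in which both partners are
  formally charged are doubled. Attractive contributions are aggregated
  by *exclusive best pairing*: a greedy matching in which every donor
  hydrogen forms at most one hydrogen bond and every acceptor accepts at
  most one. Without this saturation a single donor poking into a cluster
  of acceptors would be rewarded several times over, an exploit the
  search reliably finds. Under the default SF3 function, donor-donor and
  acceptor-acceptor contacts additionally incur a repulsive one-sided
  ramp (full weight below 3.1 Å); atoms that are simultaneously donor
  and acceptor (hydroxyl oxygens, amine nitrogens with H) are exempt,
  since their close approach to either polarity can be a genuine
  hydrogen bond.

* **Desolvation (SF5 only).** A weighted
  solvent-accessible-surface-area change,
  $\sum_i w_{class(i)} (A_i^{bound} - A_i^{free})$, over ligand and
  receptor atoms. Areas come from the pairwise probabilistic
  approximation
  $A_i = S_i \prod_j (1 - p_i\, p_{ij}\, b_{ij}/S_i)$ with
  $S_i = 4\pi (r_i + r_{solv})^2$ and $b_{ij}$ the sphere-overlap area of
  the solvent-inflated spheres. Both the per-element $p_i$ values
  and the connectivity-class constants $p_{ij}$ (1.0296 for 1-2 pairs,
  0 for 1-3 pairs, 0.2631 otherwise — the 1-3 contribution optimised to
  zero on the calibration set) were calibrated in-package against a
  numerical sphere-sampling (Shrake-Rupley-style) reference on toy
  molecules, with held-out molecules confirming the fit; the values are
  shipped in the element table. With the shipped class weights, burial of
  apolar surface is favourable (negative) and burial of polar surface
  unfavourable; the sign convention follows directly from the
  $A^{bound} - A^{free}$ difference.

* **Ligand dihedral strain.** A 3-fold cosine,
  $\tfrac{V}{2}(1 + \cos 3\phi)$ per rotatable bond, with the barrier $V$
  looked up by the central bond's element pair
  (`inst/extdata/params/torsions.csv`). Anti conformations are strain
  minima.

Two presets mirror the two shipped scoring functions: `SF3` (default)
uses the repulsive polar term and no desolvation; `SF5` the opposite. All
numeric parameters are this package's own calibration, documented in the
shipped tables — they are deliberately *not* claimed to reproduce any
external program's values.

### Interaction typing

Classes are a pure function of the molecular graph and formal charges:
polar hydrogens on N/O/S are donors, oxygen is always an acceptor,
nitrogen is an acceptor unless amide-like, aromatic N-H or positively
charged; carbon and halogens are apolar. Quaternary/protonated nitrogens
are positive centres (their hydrogens donate); carboxylate-type oxygens
are negatively flagged acceptors. The element-level defaults are a
shipped CSV so users can extend them.

## Cavity mapping

Two mappers define the docking volume on a cubic lattice (default
spacing 0.5 Å, a balance of fidelity and memory):

* **Reference ligand**: points within a given distance (6 Å by
  convention) of any reference heavy atom that are sterically accessible
  (no receptor heavy atom closer than its vdW radius plus a 1.4 Å probe
  allowance); connected components not overlapping the reference are
  discarded.
* **Two probe spheres** (defaults: large 6.0 Å, small 1.5 Å): the small
  probe defines reachable space; lattice points where the large probe can
  sit, flood-filled from the search-box boundary and dilated by the large
  radius, define open bulk solvent, which is excluded. The algorithm is
  re-derived from the two-probe principle; no claim is made that it
  reproduces any specific prior implementation point-for-point.

Distance queries against the cavity are exact brute-force
nearest-cavity-point distances (a point within half a lattice spacing of
a cavity point counts as inside); the lattice distance transform is
precomputed the same way.

## Pose search

The chromosome is the ligand centre of mass, the orientation as Euler
angles (heading, attitude, bank — Tait-Bryan z-y'-x'' intrinsic, applied
to the ligand principal axes with the largest principal moment first and
signs fixed by a largest-projection rule for reproducibility), the ligand
rotatable dihedrals, and the receptor rotatable dihedrals. Decoding
applies dihedrals to the input conformation, aligns the principal axes,
and translates; decode(encode(pose)) reproduces coordinates to 1e-6 Å
(exactly degenerate principal moments — perfectly symmetric ligands —
would make the axis convention ambiguous; the toy generators jitter
coordinates slightly to avoid this).

A docking run is GA1 → GA2 → GA3 → MC → MIN:

| stage | vdW form | polar tolerance scale | dihedral weight scale |
|-------|----------|----------------------|----------------------|
| GA1   | 4-8      | 2.0                  | 0.25                 |
| GA2   | 4-8      | 1.5                  | 0.50                 |
| GA3   | 6-12     | 1.2                  | 0.80                 |
| MC    | 6-12     | 1.0                  | 1.00                 |
| MIN   | 6-12     | 1.0                  | 1.00                 |

The soft early stages keep poor starting poses from being trapped; all
parameters are at their final values for MC/MIN, and reported scores are
always evaluated at the final parameters. The schedule invariants
(monotone tolerances, monotone dihedral weight, the form switch) are
asserted at run time.

The GA is steady-state with linear rank selection, per-gene uniform
crossover, single-DOF mutation from rectangular distributions (widths:
1 Å translation, 30° rotation/dihedral) and replace-worst insertion, so
the best individual is never lost and the best-score trace is
non-increasing. A generation has passed when a population's worth of new
individuals has been created. The run terminates when the best score has
improved by less than 0.1 score units over the last three generations
(tested from generation 3 on, so a converged or degenerate population
stops immediately), or at a hard cap of 100 generations. Population size
defaults to 50 plus 10 per rotatable dihedral. Where the population-best
versus population-mean reading of "scoring improvement" was open, the
population best was adopted: it is the quantity the elitist steady-state
design makes monotone.

Monte Carlo refinement runs 500 Metropolis steps at temperature 0.3
score units with small single-DOF moves (0.2 Å / 5°), returning the best
pose seen (never worse than the input). The final minimisation is
Nelder-Mead over the chromosome vector (via `stats::optim`), with a
1e-4 score-unit tolerance and a 2000-evaluation cap. A typical campaign
repeats the whole pipeline 50 times (the exhaustive-docking default) and
takes the overall best pose; the minimisation stage can also be entered
directly, or a pre-docked pose simply scored.

In tethered mode the first six genes become the substructure
centre-of-mass deviation (uniform in a ball of radius `transTol`,
default 0.1 Å) and a rotation vector with norm at most `rotTol` (default
1°); dihedrals whose rotation would move tethered atoms are frozen, and
the rotated side of every remaining dihedral is chosen away from the
tether. The bounds are therefore enforced *absolutely* by the
randomisation and mutation operators — `tetherViolation()` exists only to
verify emitted poses, not to penalise them.

Determinism: all stochastic steps draw from R's RNG; `dock()` derives a
per-run seed from the master seed (and `runHtvs()` a per-ligand stream
from the same scheme), so staged screening reproduces plain docking
run-for-run and two campaigns under one seed are bit-identical.

## Restraints

Pharmacophore restraints are tolerance spheres over eight feature types
(neutral acceptor/donor, hydrophobic, aliphatic, aromatic ring centroid,
negative, positive, any heavy atom). The penalty per restraint is
$W d^2$ with $d$ the distance from the nearest matching feature to the
sphere surface (zero inside); mandatory restraints always count, and the
$N_{opt}$ lowest-scoring optional restraints are added. Ligands lacking
the required feature inventory are screened out before docking. The
cavity penalty is $W \sum d^2$ over heavy atoms outside the docking
volume; distance restraints penalise the minimum selected-pair distance
beyond the bound. The wording of distance restraints ("a minimum
distance is fulfilled") is ambiguous between bound directions;
NOE-style *upper*-bound semantics is the default, with a `semantics =
"lower"` switch. All proportionality constants default to 1 and are
per-restraint overridable. The documented feature list enumerates eight
types; the engine implements exactly those eight.

Tether queries use a documented SMARTS subset (organic-subset elements,
aromatic lower case, bracket atoms with charges, `- = # : ~` bonds,
branches, ring closures); matching is non-induced subgraph isomorphism
with per-atom compatibility domains and a bond-order filter. Every
distinct correspondence is kept as its own library entry — for a
symmetric query each automorphic embedding defines a different whole-
molecule prealignment, and all of them deserve a docking run.

## The toy validation systems

The generators build what the engine needs for ground-truth testing, not
realistic chemistry:

* `makeToyLigand()` assembles an all-anti zig-zag carbon chain with one
  substituent per interior carbon — hydroxyl, carbonyl, ammonium,
  carboxylate, phenyl or methyl pads — giving exact control of the heavy
  atom count, rotor count and feature inventory. Emitted conformers are
  relaxed torsionally in vacuum (grid coordinate descent), mirroring
  pregenerated-conformer input.
* `makeToyCage()` surrounds the site with a shell of apolar carbon
  pseudo-atoms (with a small aperture, so a large probe cannot enter) and
  optional hydrogen-bonding wall groups. Pseudo-atoms carry real element
  labels so every typing rule applies unchanged.
* `makeRedockingSuite()` moulds the cage snugly around the ligand's
  designed pose (each shell atom pulled inward to vdW contact) and
  places donor/acceptor counter-sites exactly complementary to the
  ligand's polar groups, scanning nearby directions when the ideal
  placement would clash. Feature sets mix neutral and charged anchors so
  the designed pairing scores strictly better than any permuted
  engagement, and ligands never carry both a positive and a negative
  group (an internal salt bridge would otherwise compete with the
  designed pose). The stored optimum is the designed pose after Simplex
  refinement, cross-checked by a budgeted multi-start search (random
  initialisation + short MC + Simplex); if the search finds a better
  pose, that pose becomes the stored optimum. For flexible ligands this
  is a best-found-under-documented-budget claim, not a proof of global
  optimality.

What passing the suite shows: the engine reliably recovers deep,
engineered, funnel-shaped optima across 0-8 rotatable bonds, with all
components of the score and the restraint machinery behaving exactly as
specified. What it does not show: performance on real protein sites,
whose landscapes are flatter, noisier and full of competing minima, and
whose chemistry (tautomers, waters, metals, halogen bonds) the toys do
not emulate.

Problem sizes used throughout the validation workflow: 20 complexes,
50 runs each; 1000 random poses for the grid-fidelity comparison at
0.3 Å spacing; 20 molecules for the surface-area calibration check;
500 generated poses for tether compliance. These scales were chosen so a
complete validation pass runs on a single CPU in well under an hour while
keeping every estimate statistically meaningful.

## Numerical choices and limitations

* Exact brute-force distance queries (no approximate nearest-neighbour
  structures): cavity point sets are a few thousand points at toy scale.
* Trilinear interpolation for grid lookups; grids store capped energies,
  so interpolation is only faithful in the smooth attractive region —
  which is where grid-mode scoring is meant to operate. Grid error
  decreases quadratically with spacing.
* Automorphism enumeration for symmetry-aware RMSD uses VF2 with element
  and bond-order colours (Kekulé rings canonicalised to aromatic bonds)
  and a 1e5 mapping cap with a warning.
* The greedy hydrogen-bond matching can switch pairings discontinuously
  as geometries cross; the search tolerates this (the ramps already have
  slope discontinuities), but gradient-based optimisers would not.
* Automatic protonation/tautomer enumeration, ring-conformer generation,
  PDB input, receptor-ensemble docking and explicit-water sampling are
  out of scope; ligands are expected prepared, with correct topology,
  bond orders and ring geometries.
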