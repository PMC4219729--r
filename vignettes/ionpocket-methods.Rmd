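---
title: "Continuum electrostatics of cation and peptide binding to an acidic pocket"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Continuum electrostatics of cation and peptide binding to an acidic pocket}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

# The scientific problem

Some MHC class II molecules carry a cluster of glutamate side chains
(in HLA-DP2: beta-chain Glu26, Glu68 and Glu69) whose carboxylates
create a strongly negative pocket inside the peptide-binding groove. A
small divalent cation such as Be2+ can occupy that pocket, change the
electrostatics and geometry of the groove, and thereby change which
peptides bind and what conformational signal the bound complex
presents. `ionpocket` implements the computational machinery needed to
study this system: where on a structure a cation binds, how the binding
free energy of a peptide changes with the order of binding events
(cation first on the protein versus cation first on the peptide), how
the groove geometry evolves in a trajectory, and how the pocket
carboxylate pKa values shift when the cation is present.

All stages run on synthetic fixtures generated by the package itself;
every fixture ships machine-readable ground truth, so the predictions
are scored automatically. Real structures in PDB format can be
substituted at any stage through `readPDB()` / `readTrajectory()`.

# The continuum model

## Poisson solver

The electrostatic engine is a finite-difference Poisson solver in a
two-dielectric model: dielectric constant `epsIn` inside the
atom-sphere union (1 for binding-energy runs, 4 for pKa runs) and
`epsOut = 80` outside. The grid follows the *perfil* convention: the
molecule's largest dimension, including vdW radii, occupies a fixed
percentage (default 70) of the cubic grid edge; the default spacing is
1 Angstrom per grid unit, and node counts are odd so a centre node
exists. Charges spread trilinearly to the eight surrounding nodes;
boundary values are the screened Coulomb potentials of all charges;
the interior is solved by Gauss-Seidel successive over-relaxation with
automatically tuned relaxation factor, a convergence tolerance of
1e-6 kcal/(mol e) maximum node update per sweep, and a 20,000-sweep
cap. Face dielectrics use the exact fraction of each grid link inside
the (optionally probe-inflated) sphere union to weight a harmonic
average; this keeps the solvation energy smooth in the spacing, and on
the bundled Born fixture (radius 2 Angstrom, charge +2 e) the
reaction-field energy converges monotonically toward the analytic
value (about 2.6% error at 1.0 Angstrom spacing, 0.5% at 0.5, 0.1% at
0.25). No salt is modelled (pure Poisson, zero ionic strength) and the
dielectric boundary is the vdW-sphere union rather than a molecular
surface; both are deliberate desk-scale simplifications.

The polar solvation (reaction-field) energy of a solute is computed
from two runs on one identical grid - solvated (`epsOut = 80`) versus
a uniform `epsIn` reference - so the grid self-energy cancels exactly:
`dG = 1/2 sum_i q_i (phi_solv - phi_unif)`.

## Binding free energies

The binding score is the MM-PBSA-style decomposition
`G = E_Coul + E_solv(polar) + E_vdW`, and
`dG = G_AB - G_A - G_B` for a complex partitioned into A and B.
Nonpolar solvation, entropy and conformational reorganization are
excluded from the model by construction, so `dG` values are used for
ranking peptides and scenarios only, never as absolute affinities;
every result object carries a `ranking-only` note.

Two numerical choices matter here and are defaults of this package:

* **Common grid.** The three polar-solvation terms of `dG` are
  evaluated on a single grid derived from the complex. On per-part
  grids the per-atom grid self-energy artifacts of the reaction-field
  term do not cancel between `G_AB` and `G_A + G_B` and contribute
  tens of kcal/mol of seed-to-seed noise - larger than the class
  signal being measured. Per-part grids remain available
  (`commonGrid = FALSE`).
* **Minimize the complex, split rigidly.** The default `minimize =
  "complex"` energy-minimizes the assembled complex and takes the
  partner coordinates from a rigid split of the minimized structure,
  so partner energies correspond to one step of the complex
  minimization. Independently minimizing the partners (`"parts"`)
  injects differential strain-relief noise into `dG`; a pure rigid
  split (`"none"`) is the oracle mode used by the bookkeeping and
  limit tests.

The minimizer is steepest descent with backtracking on a heavy-atom
potential: 12-6 Lennard-Jones, Coulomb with the distance-dependent
dielectric eps(r) = 4r, and harmonic bond/1-3 restraints derived from
the input geometry. The first half of the step budget uses a soft-core
form of the nonbonded pair energy (repulsion damped by an r^2 shift)
so side chains can cross packing barriers; the second half uses the
full potential. Placed ions are tethered to their predicted site
(10 kcal/mol/A^2): the placement stage decides where the ion binds,
and minimization relaxes the contacts around it rather than
re-docking it. The step cap defaults to 5000; the pipeline uses 200
steps per structure, which is where the pocket contact energies of
the synthetic complexes stop changing materially.

## Ion-site prediction

Candidate positions are grid nodes whose distance off the vdW surface
lies in a shell (default one ion radius to one ion radius + 2
Angstrom). Only sign-compatible nodes are kept - a cation is never
placed at a positive-potential point, however large its magnitude -
then nodes are sorted by absolute potential and clustered greedily
with a 3 Angstrom radius; the cluster seed (its extremum) represents
the cluster, and the creation order is the Rank. The first ranked
position that does not overlap any atom (centre distance at least ion
radius + atom radius - 0.4 Angstrom) is the prediction.
`refineIonPosition()` optionally relaxes a placed ion to the nearest
local minimum of the host's force field; the scenario-comparison path
uses it so the cation starts from its coordination geometry between
the carboxylate oxygens rather than from a 1-Angstrom-resolution grid
node. Shell thickness and cluster radius are declared defaults, not
values inherited from any reference implementation.

## Binding-order scenarios

`compareScenarios()` builds and scores three cases with one shared
complex-assembly path: no ion; ion placed at its predicted site on
the free receptor, peptide binding the loaded receptor
(partition: receptor+ion vs peptide); and ion placed at its predicted
site on the free peptide, the loaded peptide binding the receptor
(partition: receptor vs peptide+ion). An ion attached to the peptide
moves rigidly with it during clash resolution. Free peptides with no
plausible cation site are recorded as "no stable Be-peptide complex"
rather than an error. Complex assembly resolves steric overlap
(interatomic distance below 0.7 of the vdW-radius sum) by rigidly
lifting the peptide along the local pocket exit axis in 0.2 Angstrom
steps with occasional small deterministic tilts, then settles back to
just-contact so clash resolution never strands the peptide above the
pocket.

## pKa and titration

The single-conformer continuum pKa machinery computes, per titratable
site (ASP, GLU, HIS, LYS, ARG, TYR), an intrinsic pKa from
desolvation and fixed-background terms:
`pKa_int = pKa_model ± ddG / 1.364` at 298 K, with the sign chosen so
that a desolvation penalty raises an acid's pKa and a nearby positive
fixed charge lowers it. The `ddG` terms come from Poisson runs of the
charged versus neutral site forms in the protein versus the isolated
model compound (site atoms alone in water); protonation adds +1 e on
the proton-bearing atom (e.g. OE2 for GLU). Site-site couplings form
a symmetric interaction matrix from the Poisson solution of each
site's ionization charge difference. Titration curves come from exact
enumeration of all 2^N ionization microstates (N <= 20) or Metropolis
single-flip Monte Carlo with a seeded generator; `pka50` is the
linearly interpolated half-protonation point, censored as
`"<min"`/`">max"` when the 0-14 grid (0.25 steps) is not crossed. MC
runs two independent chains and flags a split-half `pka50`
discrepancy above 0.2 units. Multi-conformer sampling (rotamer
ensembles coupled to ionization) is out of scope: absolute pKa values
of buried sites are therefore indicative, and the package's claims
about the pocket are claims about signs and orderings of shifts, not
about numeric equality with any particular reference calculation.
The cation is treated as a fixed, non-titratable +2 background charge
during titration; its stored reference energy is metadata only.

## Conformational sampling and trajectory analytics

Production explicit-solvent MD is deliberately replaced by an elastic
network model: one bead per residue (CA), springs (default
1 kcal/mol/A^2) between beads within 10 Angstrom, BAOAB Langevin
integration at 298 K with seeded, bitwise-reproducible noise.
Imported multi-model PDB trajectories are first-class citizens of
every analysis stage, so externally generated trajectories can be
used for fidelity. Time is measured in frames; the "trailing 40%"
window plays the role of the saturated tail of an equilibrating
observable.

Geometry analytics are Kabsch superposition (proper rotations
enforced), RMSD time series over a measurement selection after
fitting on a disjoint selection (default: everything except the
measured helix; an external reference structure can replace frame 1),
the five standard pocket-width CA-CA distances D1-D5
(`defaultPocketPairs()`), and trailing-window statistics with the
field's aggregation convention: median across the cases of a class
for RMSD observables, mean for distances, error bars as twice the
standard deviation. RMSD is unweighted and CA-based.

# The synthetic fixtures

`makeAcidicPocketReceptor()` builds a pseudo-protein, not a folded
domain: two backbone scaffolds form a groove roughly 13 Angstrom
wide; one wall and the groove floor carry three glutamate carboxylates
(numbered B:26, B:68, B:69, matching the residue numbering the
analyses select on) whose oxygen pairs cluster 3.5-7 Angstrom apart
around a cation seat, with neutral bulk closing the flanks, floor and
back of the cage so the seat keeps the strong negative potential of a
buried pocket while its mouth opens toward the groove centre line. An
aspartate (B:55) sits at the groove end, a two-residue basic decoy
patch (chain C) more than 15 Angstrom from the pocket, and a
compensating basic surface patch behind the acidic wall keeps the
scaffold net neutral so class contrasts reflect the local pocket
field rather than a global monopole. Wall residue numbers are chosen
so the five standard pocket pairs resolve. Every fixture is seeded
(0.15 Angstrom coordinate jitter) and ships its ground truth - the
carboxylate-oxygen centroid, the decoy centroid and the groove axis.

`makePeptide()` builds 10-mers on an extended backbone posed in the
groove frame: p4 and p7 side chains descend toward the pocket mouth,
the hydrophobic anchors p1/p6 slot against the opposite wall, p10
reaches the Asp-bearing wall, and the rest point out of the groove.
Class composition rules: `strong` = acidic (ASP/GLU) at both p4 and
p7; `weak` = acidic at exactly one of them; `natural` = hydrophobic
p1/p6, polar p10, neutral p4/p7; `DR` = p4/p7 drawn from
{LYS, ARG, GLN, LEU} - the template's own residues at those positions
plus the basic options that define the class. Template reproduction
mode emits FHYLPFLPST (natural) and YVKQNTLKLA (DR) verbatim.

`makeTrajectory()` emits trajectories with controlled geometry: the
chain-B residues of pairs D3-D5 are displaced across the groove with
a saturating ramp (static, opening, or closing modes) plus Gaussian
jitter, and the truth records the intended per-pair trend and
plateau.

What these fixtures do *not* emulate matters for interpretation: no
folded tertiary structure, no side-chain rotamer ensembles, no
explicit water, no peptide flexibility in the unbound state, and
class identity reduced to charge composition at key positions.
Passing tests therefore demonstrate that the machinery is correct and
that the paper-level orderings follow from pocket electrostatics
under these idealized conditions - not that the package reproduces
any particular experimental affinity.

# Design choices and known limitations

* Grid congruence: common-grid `dG` evaluation is the default (see
  above); this is the one place the package deviates from evaluating
  each part on its own perfil-derived grid, and it exists because the
  ranking signal would otherwise drown in grid noise.
* Heavy-atom parameterization is the default; the bundled TSV table
  is Amber-flavoured with Bondi-like radii, each residue's partial
  charges summing exactly to its formal charge. The Be2+ entry uses
  the 1.53 Angstrom Born radius for the dielectric cavity but a small
  Lennard-Jones half-rmin (0.75 Angstrom) so the ion can reach its
  ~1.7 Angstrom coordination distance to carboxylate oxygens; using
  the Born radius for both kept the ion artificially far from the
  oxygens it chelates.
* Residue numbering is used verbatim from input files;
  `renumberChain()` exists for reconciling author numbering. One
  published source for this system cites a PDB identifier (3LZM) for
  the native receptor that is inconsistent with the protein
  described; the package treats the structure the rest of the
  analyses use (3LQZ) as the reference and leaves any remapping to
  the user.
* Degenerate inputs fail loudly: empty structures, collinear point
  sets in superposition, atoms outside the grid, coincident charges,
  non-converged solver runs and mismatched trajectory rosters are
  all errors, not warnings.
* Problem sizes used by the bundled analyses: grids of roughly 40-55
  nodes per side, 200 minimization steps per structure, 20 seeded
  receptor fixtures for placement scoring, a 4 x 10 peptide panel for
  the scenario comparison, and 1e5 Monte Carlo sweeps per pH point.
  These are the package's standard study conditions; all are
  configurable.
* In the scenario comparison, the class ranking rests on local
  electrostatics of the key positions. Whole-structure shape
  complementarity - the reason control peptides optimized for a
  different receptor bind poorly in reality - is outside the
  generator's vocabulary, so ordering margins involving the control
  class are the least robust part of the qualitative reproduction
  and are reported with that caveat.
* The binding-order comparison is class-resolved in this model: for
  acid-carrying peptides, loading the receptor first is dramatically
  more favorable (tens of kcal/mol), because the seated cation is
  what their p4/p7 carboxylates coordinate. For peptides without
  acidic key positions the two orders differ by only a couple of
  kcal/mol, and the peptide-first order can come out slightly ahead:
  a cation riding on the peptide's solvent face keeps its hydration
  while still feeling a screened long-range attraction to the
  pocket, whereas a pocket-seated cation cancels part of the dipole
  attraction every peptide has to the bare pocket. In a full
  protein-peptide interface those pocket-centred terms are diluted
  by dozens of unchanged contacts; in the mini-receptor they are the
  whole interface. A pooled median over a mixed panel therefore
  understates the protein-first preference relative to what
  full-structure calculations report, and users should read the
  scenario comparison per class.

# A worked example

```{r example}
library(ionpocket)

rec <- makeAcidicPocketReceptor(seed = 1)
recP <- assignParameters(rec$structure)

# where does the cation bind?
site <- predictIonSite(recP)
site$position
sqrt(sum((site$position - rec$truth$pocketCentroid)^2))  # ~2.8 A

# does loading the receptor first beat loading the peptide first?
pep <- makePeptide("strong", seed = 101)$structure
res <- compareScenarios(rec$structure, pep, receptorSite = site)
vapply(res, function(r) r@dG, numeric(1))

# what happens to the pocket glutamates when the cation sits down?
sites <- identifySites(recP)
focus <- sites[sites$chainId == "B" & sites$resSeq %in% c(26, 68, 69), ]
free <- computeTitration(recP, sites = focus)
free
```
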