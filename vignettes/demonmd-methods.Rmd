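---
title: "Coarse-grained demon dynamics: model, design choices and limits"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Coarse-grained demon dynamics: model, design choices and limits}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
library(demonmd)
```

`demonmd` studies the conformational activation of Parkin-like proteins at
coarse grain: how phosphorylation of a single serine in the ubiquitin-like
(UBL) domain opens a cleft against the flexible linker and lets a biased
sampler walk the released N-terminal unit across the protein. This vignette
is the package's own account of its models and the choices behind them.
Every empirical number quoted here is computed by the test suite or the
acceptance script; nothing is asserted that the code does not measure.

## The bead model and its energy function

Each residue is one bead at the Calpha position (default mass 110 Da, radius
1.9 A); waters are single neutral beads (radius 1.4 A) and ions single
charged beads with hydrated radii (2.5/2.4 A, see below). Units are fixed
package-wide: Angstrom, kcal/mol, ps, K, elementary charge, with
1 kcal/mol = 418.4 Da A^2/ps^2.

The potential is native-structure-based. Bonds are harmonic,
`0.5 k (r - r0)^2`, about a global `bond_r0` (3.8 A, the Calpha-Calpha
virtual bond). Angles and torsions take their reference values from the
structure the evaluation context is built on, so a freshly built system sits
at the bonded minimum; torsion phases are set so each reference dihedral
minimizes its cosine term. This convention is what lets the rigidity of the
model live in the *reference geometry* rather than in residue-specific
chemistry, which is all a one-bead-per-residue model can support honestly.
One consequence matters for users: an evaluation context built on a deformed
structure treats that deformation as the new reference. Functions that must
relax toward a particular state (`equilibrate_zone()`, the minimizers inside
guidepost generation) therefore accept or construct an explicit reference
context.

Nonbonded terms are a 12-6 Lennard-Jones (well depth 0.2 kcal/mol; the pair
sigma scales with the bead radii, `sigma_ij = lj_sigma (r_i + r_j) / 3.8`,
so a mutation that shrinks a bead also loosens its packing) plus Coulomb
electrostatics with the distance-dependent dielectric `eps(r) = 4 r` and
Debye screening at the physiological 150 mM value (`lambda = 7.9 A`), both
truncated at 9 A with 1-2/1-3 exclusions and no 1-4 scaling. Two choices
deserve explanation:

* **Screened Coulomb instead of a full explicit ion bath.** Early designs
  carried the full ion count that 150 mM implies for the shell volume, with
  bare ionic radii. Two artifacts followed: occasional integration
  divergences when a counterion fell into the steep Coulomb-plus-LJ well of
  the doubly charged phosphoserine bead, and counterion condensation gluing
  the phospho-site to the acidic cleft wall, an effect that explicit-water
  all-atom systems screen away but a vacuum CG model overdoes. The package
  therefore carries bulk salt in the screened Coulomb term, keeps a token
  number of explicit ion pairs (default 4) for local ion sampling, and gives
  ions hydrated radii. This is the standard implicit-salt compromise for CG
  models without explicit water physics.
* **Rigid-core elastic network.** Beads tagged `rigid` (the Zn-coordinated
  core, residues 141-465 in the default plan) are connected by harmonic
  springs (k = 1 kcal/(mol A^2)) to every tagged neighbour within 10 A at
  the reference geometry. This is the CG analog of the semi-rigid
  zinc-cassette restraint scheme, which is also available explicitly via
  `zinc_restraints()` (all-pair relative restraints at 50 kcal/(mol A^2)
  plus soft adjacent-torsion restraints at 10, assigned relative to each
  other rather than to coordinate space).

Restraints (positional, relative, torsional), Gaussian native contacts and
an optional spherical containment wall (a half-harmonic beyond the system
extent, used to keep free-boundary solvent from evaporating, since the model
has no periodic box) complete the term list. Forces are analytic throughout
(the dihedral gradient is the exact Blondel-Karplus form) and are verified
against central finite differences to 1e-4 relative in the test suite.

## Integration, thermostats and equilibration

The integrator is velocity Verlet with a Verlet neighbour list (2.5 A skin,
rebuilt every 15 steps; the list is a superset filter, so results are
identical to full-pair evaluation). Temperature control is Berendsen weak
coupling (the production default, tau = 0.5-1 ps) or a Langevin
Ornstein-Uhlenbeck update drawing its noise from R's RNG so seeds reproduce
bit-for-bit. Centre-of-mass translation *and* rotation (inertia-tensor
angular-momentum subtraction) are removed on a fixed interval as the guard
against the flying ice-cube artifact. The default timestep is 0.002 ps in
the spirit of the constrained 2-fs all-atom step; the demo pipeline uses
0.004 ps, which the stiffest mode in the model (the k = 100 kcal/(mol A^2)
bond, period about 0.3 ps) tolerates with a wide margin. Microcanonical
energy conservation on a harmonic dimer (relative drift under 1e-4 over
10,000 steps at dt = 5e-4 ps) is the primary integrator oracle.

`staged_equilibration()` executes the equilibration ladder in its published
order - minimize; heat with positional restraints at k = 10 kcal/(mol A^2);
minimize; heat at k = 5; minimize with restraints reduced by 1 (k = 4);
unrestrained temperature ramp from 1 to 310 K - at configurable,
desk-scale stage lengths (demo: 300-step heating stages, 480-step ramp,
linear-in-T segments; the source protocol says only "slowly heated", so
linear is our choice).

## The synthetic Parkin-like system

No deposited structure exists for the full-length model the activation story
is built on, so the generator constructs a synthetic stand-in whose
*topology* carries the biology while making no claim about real Parkin
geometry:

* a UBL-like solenoid (residues 1-76) whose cleft face carries residues
  1-4 and 61-67;
* a serpentine linker wall (residues 95-128) packed against that face, with
  connector arcs for 77-94 and a tether (129-140) into the core;
* a rigid core solenoid (141-465) tagged for the elastic network;
* a Go-style contact network over non-local intra-UBL pairs (depth 2
  kcal/mol), because the UBL is a folded, internally stable unit even though
  it is *mobile* - without it the solenoid is spaghetti and the cleft metric
  measures fold collapse rather than domain motion;
* three loose tethers from the UBL underside to the core (depth 3) standing
  in for the UBL-core packing of the closed (auto-inhibited) state;
* the **Ser65 clamp**: three Gaussian wells from bead 65 to the wall triad
  110/111/115 (depth 7 kcal/mol each), tagged `kind = "site"`. The CoM1
  cleft metric is defined over exactly that triad, so the clamp pins the
  closed cleft;
* acidic decoration: unit negative charges at the aspartate/glutamate-like
  cleft positions 62, 115, 18, 60, 108 and 113, giving both walls the
  acidic character that makes the *unclamped* cleft repel open.

The mechanism encoded is deliberately simple. Unmodified serine keeps the
clamp; the cleft stays closed against the walls' mutual repulsion. Every
variant - phosphoserine and all substitutions alike - loses the serine
hydroxyl interaction and with it the clamp (`contact_scale = 0` in the
modification table; the intra-UBL fold network, `kind = "fold"`, is never
touched by a site modification). The walls then drift and repel apart, with
the site charge (-2 for pSer, -1 for the phosphomimetics D/E, 0 for A)
ordering how hard they are pushed. The phospho-dead variant opens on the
baseline repulsion alone, which is why its opening is slower - matching the
qualitative ordering the activation story reports. Phosphoserine is modelled
as -2, the dominant protonation state at pH 7.4 and the choice that gives
maximal contrast with the -1 mimetics.

Solvation places water beads uniformly in the shell between the clash
distance (2.8 A) and the shell depth (drawn from 15-18 A unless fixed),
rejection-sampled against overlap. The default density, 1 water per 1000
A^3, is a desk-scale surrogate: it provides positions for hydration counting
around the pocket, not bulk-water physics, and the vignette flags this as
the main respect in which passing tests say nothing about real solvent.

## Guideposts and the demon

`generate_guideposts()` builds an anisotropic-network-model basis on the
Calpha network, mixes the three lowest non-trivial modes with seeded
weights, and - because a literal linear displacement of tens of Angstroms
shears bonds and is promptly retracted by the minimizer - realizes the mode
direction as the finite hinge rotation of the flexible region that best
reproduces the mode field (least-squares angular velocity about the
flexible/rigid boundary). The rotation is walked in 1 A RMS sub-increments
with light relaxation and a fuller minimization at each post. The demo
amplitude of 40 A (RMS over the flexible region) gives five posts whose
consecutive all-Calpha RMSD spacing is about 4 A - deliberately larger than
the 3 A success radius, so every chained leg requires genuine demon-driven
descent rather than starting inside its target.

The demon itself accepts a sprint only if the RMSD collective variable did
not rise (`accept_tol = 0`, the strict ratchet; configurable because strict
descent can stall on rough landscapes). Rejection restores coordinates and
redraws isotropic Boltzmann velocities - the simplest demon consistent with
the method's description; a directional-draw option is declared but left
unimplemented. Sprint lengths are drawn uniformly from 80-240 steps: long
enough for coherent collective motion per lottery ticket, short enough that
the ratchet bites. The 3 A success radius is the reported per-guidepost
convergence bound, used here as the stopping criterion. Discard fractions on
the demo system run around 0.3-0.6, higher than the 8-16% the original
large-system runs report; the package records, and does not enforce, this
statistic. The collective variable targets the *next* guidepost by default
(RMSD to the final state is available by passing that structure instead).

## Zone-equilibrated ddG

`ddg_mutation()` follows the zone scheme: a five-residue flexibility zone
centred on the site, treated in torsion space with everything else frozen; a
physics zone of all residues within 12 A of the flexible ones, outside of
which nonbonded terms are dropped; equilibrate wild type, score, apply the
modification, re-equilibrate, score, and report `dG_wt - dG_mut`. The score
is the CG physics-zone energy - a stand-in for a knowledge-based unfolding
potential, so formula structure, zone mechanics and sign behaviour carry
over while absolute magnitudes do not (the published absolute values for the
Ser65 panel are explicitly not reproduction targets). The recorded
`inertia_scale = 11.0` is provenance only: it exists to tame fast-spinning
small groups in a dynamics-based equilibrator, and a torsion-space minimizer
has no dynamics, so it is intentionally inert. Zone clipping at chain
termini keeps at least three residues.

## Metrics

Cleft width is the distance between mass-weighted centroids of the CoM1
(110, 111, 115) and CoM2 (1, 2, 3, 4, 63) residue sets (geometric weighting
is available; the source does not state its atom set, so mass weighting is
the default). SASA is Shrake-Rupley on golden-spiral quadrature (default 960
points, which holds the isolated-bead closed form to under 2%; the demo
analysis uses 240 points for speed). Pocket waters are counted within 5 A of
any pocket-residue bead - the cavity criterion is not stated in the source,
so this cutoff rule is a declared surrogate. RMSF superposes frames on the
trajectory mean, iterated twice. Pseudo phi/psi angles are signed dihedrals
over consecutive Calpha quadruples. One reported metric mixes distance and
RMSD language for the core-to-active-site measure; the package exposes both
`pair_distance()` (Arg163-Cys431) and `rmsd_series()` and leaves the choice
to the analysis.

## Problem sizes and what the checks do (and do not) show

The bundled demo runs the 465-bead system: five guideposts at amplitude
40 A; demon legs capped at 400 sprints of 80-240 steps at dt = 0.004 ps;
four replicate chains; and 96,000-step (384 ps) solvated production runs per
Ser65 variant. These sizes were chosen so the full pipeline runs in minutes
on one CPU while leaving each convergence bound non-trivial. The directional
cleft check (every variant's mean cleft width over the final third of its
trajectory exceeds unmodified serine's) is a fixed-seed, sign-only claim on
this synthetic system: it demonstrates that the machinery resolves the
designed mechanism, not that real Parkin behaves this way. Likewise the
demon convergence bounds show the sampler works as specified at desk scale;
nothing here reproduces all-atom energetics, explicit-water hydration, or
the 100-1000 ns timescales of the original study.

## Known limitations

* No periodic boundaries or Ewald electrostatics: cutoff Coulomb with a
  containment wall instead; no barostat (constant volume only), so no
  ensemble equivalence is claimed with constant-pressure protocols.
* The minimizer implements Polak-Ribiere conjugate gradient (the variant the
  source names twice; it also once says "Powell-Reeves", a discrepancy noted
  and resolved in favour of Polak-Ribiere) plus steepest descent.
* SASA quadrature points live in the lab frame, so rotational invariance
  holds only to quadrature error.
* The synthetic system's fold, charges and contacts are a designed
  mechanism, not a prediction; only topology-level conclusions transfer.
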