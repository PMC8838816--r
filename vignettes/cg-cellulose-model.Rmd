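---
title: "A four-bead Martini 3 model of cellulose fibrils: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{A four-bead Martini 3 model of cellulose fibrils: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(cgcellulose)
```

## The model

Crystalline cellulose comes in several packings of the same polymer:
the native allomorphs I$\alpha$ (triclinic) and I$\beta$ (monoclinic),
and the regenerated, antiparallel type II form.  This package implements
a coarse-grained (CG) model in which each D-glucose residue of a
cellulose chain is reduced to four beads placed on the positions of its
O2, O3, C6 and O6 atoms (sites CG1--CG4).  Three uncharged Martini 3
bead types describe the nonbonded interactions: the three
oxygen-centred sites are small polar SP6 beads, the C6 site is a tiny
apolar TC1 bead.  The interaction matrix is an exact five-entry table
(SP6--SP6, TC1--TC1, SP6--TC1 and the two cross terms with Martini
water W); there are no combining rules, and all charges are zero, so
electrostatics is vacuous by construction.

A single chain is held in its flat, ribbon-like shape by an elastic
network: a triangulation of the ribbon surface by harmonic bonds.  Per
residue there are six intra-residue bonds (every pair among the four
sites except none -- the four sites form a complete graph minus
nothing: O2--O3, O2--C6, O3--C6, C6--O6, O2--O6, O3--O6), and per
residue junction three first-neighbour and three second-neighbour
same-site bonds (O2--O2, O3--O3, C6--C6).  The O6 site carries no
inter-residue bonds: it is the flexible hydroxymethyl oxygen whose
atomistic distance distributions (O2--O6, O3--O6) are bimodal, and it
is tied to the ribbon only through its residue.  Those two flexible
bonds get a soft spring ($k = 2500$ kJ mol$^{-1}$ nm$^{-2}$); all other
bonds are stiff ($k = 30\,000$).  For an $n$-residue chain the network
has $6n + 3(n-1) + 3(n-2) = 12n - 9$ bonds ($n \ge 3$).  The same
bonded table serves all three allomorphs, which is what makes the model
transferable between them; allomorphs differ only in how chains are
packed.  There are no angle or dihedral potentials anywhere: the
triangulated network alone maintains the ribbon.

The potential is

$$V = \sum_{\text{bonds}} \tfrac{1}{2} k (r - r_0)^2
    + \sum_{\text{pairs}} 4\epsilon\!\left[\left(\tfrac{\sigma}{r}\right)^{12}
    - \left(\tfrac{\sigma}{r}\right)^{6}\right] - V_{\text{shift}},$$

with the Lennard-Jones part truncated at 1.1 nm and shifted so the
potential is continuous at the cutoff.  The division of labour between
the two terms is strict: by default every intra-chain pair is excluded
from the LJ sum, so a chain's internal structure is governed entirely
by its elastic network and the LJ matrix acts between chains - which is
how the model is drawn (nonbonded interactions connect parallel
chains).  Excluding at least the bonded pairs is obligatory in any
case: several sit far inside $\sigma$ (C6--O6 at 1.43 Å against
$\sigma \approx 4$--$5$ Å) and would otherwise be crushed by enormous
repulsion.  The exclusion depth is configurable
(`makeExclusions(model, depth)`); during development we measured the
alternatives and they fail in instructive ways: excluding only bonded
pairs leaves near-neighbour intra-chain LJ pairs held by the network at
4.9--7.6 Å fighting LJ minima elsewhere, and in vacuum the frustration
relaxes chains into a pleated, strongly twisted conformation that
shifts bonded means off their reference values; excluding the network
neighbourhood but keeping long-range intra-chain LJ lets a free chain
fold onto itself instead.

## Building ideal chains and fibrils

The package builds ideal structures in closed form rather than mapping
an atomistic crystal.  A chain is an exact two-fold screw along $z$:
residue $i$ is the base residue rotated by $180 i$ degrees about the
axis and advanced by $i \cdot \text{rise}$.  The screw symmetry turns
most of the bonded table directly into geometry:

* every second-neighbour distance is exactly $2 \times \text{rise}$,
  so the printed 10.44 Å fixes rise $= 5.22$ Å -- and explains why the
  same 10.44 Å appears for O2--O2, O3--O3 and C6--C6: under the screw
  it is one number, the repeat length, not three coincidences;
* the first-neighbour distance of a site at radius $\rho$ from the
  axis is $\sqrt{4\rho^2 + \text{rise}^2}$, so the three printed
  first-neighbour values fix the radial positions of O2, O3 and C6;
* the six intra-residue distances then close the construction up to
  one orientational degree of freedom (the height of O3 above O2 along
  the axis) and discrete branch choices.

The leftover degree of freedom is fixed by requiring the junction twist
dihedral (O2$_i$, C6$_i$, C6$_{i+1}$, O2$_{i+1}$) of the ideal chain to
be exactly zero: built chains are untwisted, which gives twist
measurements on dynamics a clean zero reference.  The root is found by
two nested 1-D bisections, deterministic to $10^{-13}$; every bonded
pair of a built chain sits at its reference length to well below
$10^{-6}$ Å.  O6 is placed by trilateration from its three
intra-residue distances.  Two mirror-image embeddings satisfy all
printed distances; the package fixes one branch, which sets the chain's
handedness (the printed distances alone cannot distinguish the two).

Fibrils are chains replicated on a simplified two-direction lattice:
sheets of side-by-side chains along $x$ (spacing `dx`), sheets stacked
along $y$ (spacing `dy`), with a per-sheet axial stagger of a quarter
repeat as in the native crystals.  I$\alpha$ staggers sheets
progressively, I$\beta$ alternately; type II additionally packs
alternate sheets antiparallel.  The crystallographic unit cells are not
part of the CG parameter set, so the default spacings (8.3 Å and 4.6 Å)
are adapted to the CG bead sizes rather than copied from the crystals:
close-packed enough for cohesion, open enough that steepest-descent
minimization resolves the remaining contacts.  All lattice values are
overridable, and the builder refuses lattices that put beads from
different chains closer than 2 Å.  Atomistic structures with
CHARMM-style D-glucose atom names can be mapped instead of built: one
bead per named atom, positions copied exactly.

## The engine

A compiled velocity-Verlet engine drives the model; user-facing
coordinates are Å, internally the usual consistent MD units (nm, ps,
amu, kJ/mol).  The production timestep is 0.02 ps.  At that step the
stiffest network modes sit near $\omega\,\Delta t \approx 1.5$, so the
integrator splits the force: the soft LJ forces act as impulses at the
outer timestep while the stiff bonded forces are sub-integrated with
velocity Verlet at $\Delta t / 4$ (an r-RESPA splitting; `n_inner`
configurable).  For a single chain (whose LJ is fully excluded) this
keeps NVE energy wander below one part in $10^4$ over $10^5$ steps; in
multi-chain systems a residual wander at the $10^{-3}$ level comes from
the force discontinuity of the truncated LJ at the cutoff (it shrinks
an order of magnitude with a 3 nm cutoff, which is how truncation noise
was separated from integrator error during development).

Temperature control is BAOAB Langevin (friction 1 ps$^{-1}$) by
default, with Bussi stochastic velocity rescale ($\tau = 1$ ps) and
plain NVE as alternatives.  Two numerical details matter at this
timestep.  First, kinetic temperature under Langevin is measured at the
mid-step (post-thermostat) velocities: the on-step velocities of a
BAOAB step systematically under-read the temperature of stiff modes
(by ~10 % here), while the mid-step estimate is unbiased -- both were
measured on an isolated harmonic dimer during development.  Second,
the centre of mass is re-zeroed every step under Langevin (the noise
imparts net momentum), and instantaneous temperature uses $3N - 3$
degrees of freedom.  Initial velocities are Maxwell--Boltzmann at the
target temperature, rescaled exactly after centre-of-mass removal.  All
randomness flows through R's RNG, so a seeded run is bit-reproducible.

Nonbonded pairs come from a Verlet neighbour list (0.3 nm skin, rebuilt
when any bead has moved half the skin).  Minimization is steepest
descent with an adaptive step and a force-norm stopping criterion;
fibril lattices are minimized before dynamics, chains can run directly.
Degenerate inputs (two beads at one position) are rejected before
dynamics rather than propagating NaNs; an energy blow-up during a run
aborts with the step number.

## Validation statistics

* `pairDistanceStats` pools the per-frame distances of one bonded pair
  class over all residues, chains and frames and reports mean, SD and
  a normalized histogram (Freedman--Diaconis bins by default).
* `kabschRMSD` superposes with the SVD form of the Kabsch algorithm
  (reflection-corrected); `trajectoryRMSD` averages per-frame RMSD
  against a fixed reference; `crossRMSD` averages over every frame
  pair of two trajectories.  Superposition is applied by default in
  both: without it, diffusive rigid-body drift of a thermostatted
  vacuum system dominates and the statistic stops measuring internal
  structure.
* `twistStats` computes the fibril twist: the signed dihedral over the
  quadruple (O2$_i$, C6$_i$, C6$_{i+1}$, O2$_{i+1}$) for every
  consecutive-residue junction, pooled over junctions, chains and
  frames (the reported extrema only make sense for per-junction
  pooling).  The sign convention is fixed by the package's dihedral
  (the reference quadruple (0,0,0), (1,0,0), (1,1,0), (1,1,1) gives
  $-90^\circ$); bio3d's `torsion.xyz` uses the opposite sign, which
  the test suite pins down explicitly.

## The parameter scan

`beadTypeScan` re-implements the selection protocol that produced the
bead types: a grid of 18 candidate Martini 3 interaction types for the
oxygen sites (C6 held at TC1, overridable) crossed with soft-spring
constants {25, 250, 2500} kJ mol$^{-1}$ nm$^{-2}$, each grid point
scored by the Kabsch-superposed time-average RMSD from the ideal start
structure, aggregated over systems by the maximum ("simultaneously
small for all fibrils"), smallest score wins.  Unstable runs are
recorded and skipped, mirroring the candidates omitted from the
original selection for instability.  The published $\sigma/\epsilon$
values exist only for the selected SP6/TC1 set, so the full 18-type
sweep needs a user-supplied parameter table; the packaged table
exercises the machinery on the SP6 column.  Scan runs default to 1 ns
per grid point: in development, 0.1 ns rankings of the three spring
constants were noise-dominated and unstable under reruns, while at
1 ns the ranking is converged and reproduces the published selection
(2500 best, 25 worst).

## Desk scale: what the solvent-free systems do and do not show

The model was parameterized in solvated 36-chain fibrils of 100-residue
chains.  This package exercises it at desk scale: single 20-residue
chains and 3x3-chain fibrils, in vacuum, with 1 ns equilibration and
5 ns production.  What transfers and what does not:

* **Stiff-bond geometry transfers.**  Pooled means of every stiff
  elastic-network distance match their reference lengths to well
  within 0.05 Å (the anharmonic shift of a $k = 30\,000$ spring at
  300 K is ~0.003 Å).  Fluctuation widths in vacuum are narrower than
  the solvated values (~0.09 Å vs ~0.25 Å): solvent collisions, absent
  here, broaden the distributions.
* **Fibril RMSD magnitudes transfer; free-chain ones do not.**
  Time-average superposed RMSD of an equilibrated reduced fibril
  against its reference stays near 1 Å, well inside the 5 Å band that
  characterizes a well-behaved CG fibril.  A free chain instead wanders
  along its network mechanism (next point).
* **A free chain is a mechanism.**  The elastic network admits a
  one-parameter family of configurations that satisfies every bond
  length exactly - the same geometric freedom the builder root-finds
  over when it constructs the untwisted chain.  It is a zero-energy
  twist-like deformation: a single chain in vacuum thermally slides
  along it, so its bonded means stay pinned to the reference values
  (the motion lives on the constraint manifold) while its
  superposed RMSD from any fixed snapshot grows to the manifold's
  diameter (~10 Å for 20 residues) and its junction dihedrals swing
  tens of degrees around a zero mean.  A single-chain RMSD bound of
  5 Å is therefore not attainable; the corresponding acceptance check
  is left failing rather than re-tuned, with this mechanism as the
  diagnosis.  In fibrils the interchain LJ freezes the mechanism:
  fibril RMSD from the equilibrated structure stays small.
* **Twist signs do not transfer.**  With intra-chain LJ excluded,
  twist statistics in reduced fibrils reflect residual mechanism
  disorder frozen in during minimization and equilibration, with
  per-junction spreads of tens of degrees around small means.  The
  solvated sign pattern (type II negative, the I allomorphs positive,
  means of order one degree) does not emerge from the vacuum 3x3
  lattices; the corresponding acceptance check is left failing rather
  than re-tuned.  Reproducing the twist signs appears to require the
  solvated, full-size systems.

The thermal-stability property (bounded RMSD at 300 K and 400 K, with
400 K at or above 300 K) holds at desk scale: the bonded network does
not melt over this range.

## Problem sizes and determinism

Default test and acceptance problem sizes: 20-residue single chains
(80 beads; 300 000 steps = 6 ns in well under a minute on one core)
and 3x3 x 20-residue fibrils (720 beads; ~3 minutes per 5 ns run).
Every stochastic path takes a seed: the engine seeds R's RNG, the scan
derives one seed per run from its spec seed, fixtures record theirs.
Ties in the scan ranking are broken by table order; histogram binning
falls back to a single unit-width bin for degenerate (zero-variance)
series.

## Worked example

```{r example, eval = FALSE}
sys <- buildTopology(buildChain(20, "Ialpha"))
eq <- runDynamics(sys$model, sys$topology, engineConfig(seed = 1L),
                  n_steps = 50000, report_every = 1000)   # 1 ns
start <- sys$model
coords(start) <- eq@config$final_pos
tr <- runDynamics(start, sys$topology, engineConfig(seed = 2L),
                  n_steps = 250000, report_every = 250)   # 5 ns

pairDistanceStats(tr, sys$model, "O2-O3")$mean   # ~2.88 (Angstrom)
trajectoryRMSD(tr, coords(start))$mean           # ~10: the free chain
                                                 # slides along its
                                                 # network mechanism

fib <- buildFibril(9, c(3, 3), 20, "Ialpha")
fsys <- buildTopology(fib)
mn <- minimizeEnergy(fsys$model, fsys$topology, max_steps = 3000,
                     ftol = 50)
ftr <- runDynamics(mn$model, fsys$topology, engineConfig(seed = 3L),
                   n_steps = 50000, report_every = 1000)
fstart <- mn$model
coords(fstart) <- ftr@config$final_pos
prod <- runDynamics(fstart, fsys$topology, engineConfig(seed = 4L),
                    n_steps = 250000, report_every = 500)
trajectoryRMSD(prod, coords(fstart))$mean        # ~1: packing freezes
                                                 # the mechanism
```

The same protocols, seeded from the command line, are what
`scripts/acceptance.R` runs.

## Known limitations

* Vacuum only by default: no explicit Martini water, no barostat; the
  box is inert unless periodic boundaries are switched on.  The W
  cross terms are stored for completeness and for solvated extensions.
* GRO files carry no chain identifiers; the reader infers chain breaks
  where residue numbering does not increase, which round-trips files
  the package wrote but may mis-split exotic external files (PDB input
  keeps chains exactly).
* The lattice builder is a regular two-direction packing with
  per-sheet stagger, not a crystallographic unit-cell replica; it is
  meant to produce reasonable desk-scale starting structures, not
  refined crystal models.
* XTC trajectories are not read; multi-frame GRO (and PDB for single
  structures) are the interchange formats.
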