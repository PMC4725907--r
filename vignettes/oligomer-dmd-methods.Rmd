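---
title: "Event-driven DMD of peptide-polyphenol oligomers: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Event-driven DMD of peptide-polyphenol oligomers: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

This vignette is the package's own account of its science: the
coarse-grained model, the event-driven dynamics, the aggregation
statistics, the tunable parameters and their defaults, and the places
where the design was genuinely open. Every empirical statement here is one
the package's test suite or acceptance script computes itself.

## The problem

Human IAPP (amylin) is a 37-residue pancreatic peptide whose aggregation
into amyloid fibrils is implicated in type-2 diabetes. Small aromatic
molecules modulate this process in strikingly different ways: aspirin
barely interferes, while the polyphenols curcumin and resveratrol divert
the peptide into small, stable, off-pathway oligomers — nano-assemblies
with a hydrophobic small-molecule core and a peptide "corona". The package
provides a desk-scale simulation-plus-analysis pipeline for this system:
an event-driven discrete molecular dynamics (DMD) engine for
coarse-grained peptide/ligand mixtures, and the complete statistics stack
used to characterise the resulting assemblies (contacts, clustering,
cluster compositions, radial core/corona profiles, secondary structure,
replicate aggregation).

## The coarse-grained model

**Peptide.** IAPP is represented with two beads per residue: a backbone
bead (the peptide unit, 56 amu) and a sidechain centroid bead (residue
mass minus the peptide unit); glycines 24 and 33 have no sidechain bead,
giving 72 beads per chain. Sidechain classes follow residue identity
(hydrophobic L/F/I/V/A; aromatic flags on Phe15, His18, Phe23, Tyr37;
charged Lys1 and Arg11; polar otherwise). The pH 7 protonation state
carries +1 on Lys1, Arg11 and the free N-terminus; the C-terminus is
amidated and neutral. The Cys2-Cys7 disulfide is a permanent crosslink.
Chain connectivity uses hard-wall bond windows (backbone 3.45-4.15 A,
backbone-sidechain 2.7-3.7 A), a chain-stiffness window on second
neighbours (4.5-7.4 A) wide enough to accommodate both helical and
extended geometry, and 1-3 steric exclusions.

**Small molecules.** Aspirin, curcumin and resveratrol are 2-, 5- and
4-bead graphs carrying the interaction features that drive their
association: aromatic rings, aliphatic linkers, and hydroxyl/carboxyl
hydrogen-bond capacity (curcumin: one donor and one acceptor per ring plus
a carbonyl acceptor; resveratrol: three donors and three acceptors over
its two rings; aspirin: one donor and two acceptors on its polar-oxygen
bead).

**Initial conformation.** Chains start as a compact pseudo-helix (bend
angle 90 degrees, torsion 46 degrees) — helical intermediates are the
experimentally reported pre-aggregation state — with the Cys sidechains
tilted toward each other so the disulfide window is satisfied at `t = 0`.
The helix spans ~53 A and therefore fits the one-peptide 63.7 A box
without approaching its own periodic image.

## Interactions

All non-bonded interactions are discrete (multi-step) pair potentials: a
hard core at the sum of class radii, four equal-width shells obtained by
midpoint-averaging a Lennard-Jones-style profile over 3.2 A, and one wide
"dispersion tail" shell out to 6 A at a tenth of the contact depth.
Well depths are products of per-class hydrophobicity weights times a
global scale `eps0 = 1.5` kcal/mol; aromatic-aromatic pairs get a 1.25x
stacking bonus; mixed polar-hydrophobic pairs are damped to near zero (the
implicit-solvation penalty); charged pairs add a six-shell discretized
Debye-Hueckel tail (screening length 10 A, the 100 mM NaCl value, with
relative permittivity 78.4) out to 12 A.

The tail shell deserves a note: slow, heavy aggregates approach each other
with relative kinetic energies of only a few tenths of kcal/mol, so even a
weak long-range attraction acts as a capture funnel that a bare 3.2 A well
would not provide. Intra-molecular pairs use the same ladders without the
tail (long-range intra-chain dispersion is conventionally truncated in
coarse-grained chain models).

**Hydrogen bonds** use a reaction-like rule rather than a potential shape:
an unreacted donor-acceptor pair that crosses 5.0 A inward with spare
capacity on both beads forms a bond worth -1.5 kcal/mol; it must pay that
energy back to escape, and an inner wall at 3.0 A bounds the bond length.
Capacities are per-bead (backbone beads donate and accept once; sidechains
by residue chemistry) and are enforced greedily with ties broken by bead
index. Orientation criteria are deliberately out of scope for a
centroid-bead model.

**The ligand hydrophobicity ladder.** The three small molecules share bead
classes; a per-species multiplier sets their rungs (shipped: aspirin 0.60,
resveratrol 0.55, curcumin 1.22, from `scripts/calibrate_ladder.R`). The
ladder is a molecule-level property, not a bead-level one: resveratrol
sits at a lower per-bead rung than aspirin, yet its two rings and six
hydrogen-bonding sites make the whole molecule stickier — and, crucially,
its association stays *reversible* at 300 K, so a monomer pool survives in
pure-ligand simulations. Calibrating at the bead level alone (curcumin >
resveratrol > aspirin depths) made both polyphenols aggregate
irreversibly, erasing the monomer-probability ordering the solubility
ladder demands; the molecule-level calibration reproduces it with a clear
margin (monomer probabilities roughly 0.95 / 0.2-0.3 / 0.05 over seed
panels). The corresponding package-level ordering check is the
molecule-level pairwise virial sum `species_pair_virial()`.

## The engine

Between events every bead moves ballistically; events are hardcore
bounces, shell crossings (crossed when the radial kinetic energy exceeds
the step, else reflected), bond-wall reflections, hydrogen-bond
reactions/breaks, Anderson-thermostat reassignments, and bookkeeping
"refresh" events. Collisions exchange an impulse along the line of
centres, conserving linear momentum exactly and leaving the pair's angular
momentum about its centre of mass unchanged.

Scheduling is one-event-per-bead: each bead owns a single live queue entry
(its earliest pending pair event, or a refresh), invalidated lazily
through per-bead collision counters. Neighbourhoods are cached lists
rebuilt when the owner has travelled `delta = 1` A since the last rebuild;
the search radius of `cutoff + 2 delta` guarantees a pair cannot reach its
interaction cutoff before one participant's refresh has rediscovered it,
and list membership is kept mutual so that either bead's velocity change
rescans the pair. This plays the role a cell list plays in conventional
engines and is faster at the few-hundred-bead sizes used here.

Numerical choices: events are resolved at the exact boundary radius and
the pair is then parked 1e-8 A onto the side consistent with its outgoing
radial motion, so the piecewise-constant energy is unambiguous at emitted
frames; the "at a boundary" tolerance is 1e-9 A; simultaneous events are
ordered lexicographically by (time, bead ids). The engine's incremental
potential-energy bookkeeping is tested to agree with a direct O(N^2)
re-evaluation (`total_energy()`) to 1e-9, and NVE total energy is
conserved to ~1e-13 relative over 1e5 events. One defensive rule exists:
an outward crossing scheduled at the hardcore — geometrically possible
only for a pair already inside its core, which a rare scheduling race
(order one occurrence per 1e7 events in dense, hot systems) can produce —
is allowed to pass freely with zero energy step instead of trapping the
pair; occurrences are counted and reported in `event_counts["healed"]`.

The Anderson thermostat redraws single-bead velocities from the
Maxwell-Boltzmann distribution at exponentially distributed times. The
rate is a free parameter (the source protocol names the thermostat but not
its coupling): the default for plain runs is 0.002 per bead per reduced
time, weak enough to preserve the ballistic transport that event-driven
dynamics relies on for self-assembly; the ideal-gas tests use 0.1 for
rapid equilibration. Units are Angstrom / amu / kcal/mol, giving a reduced
time unit of ~48.9 fs.

## Study protocols at desk scale

Boxes follow the constant-peptide-density rule (`edge = 63.7 *
n_peptides^(1/3)` A, ~6.4 mM), molecules are placed with random positions
and orientations and rejection-sampled until no minimum-image hardcore
overlap remains (event-driven dynamics has no gradients, so overlap-free
placement replaces a steepest-descent minimization), and velocities start
Maxwell-Boltzmann with zero total momentum. Statistics are taken over the
last half of frames (`steady_state_window()`, floor split, with a
potential-energy trend test attached for inspection) and aggregated over
independent seeded replicates (`run_replicates()`, default ten).

Self-assembly of eight peptides at 6.4 mM is encounter-limited: with
physical bead masses, the mean time for the *final* cluster-cluster merge
is of order 1e4-3e4 reduced time units with a heavy tail, far beyond what
a fixed 300 K run samples in minutes of wall time. The package therefore
ships an annealed protocol (`run_dmd_annealed()`, and the adaptive
`run_until_assembled()`): a weakly coupled hot assembly stage (rate
3e-4; the released binding energy is allowed to heat the system to
~500-600 K, accelerating transport), run either for a fixed budget or in
chunks until the peptides form a single cluster, followed by a strongly
coupled quench (rate 0.01) whose steady-state window sits at ~300 K and
provides the analysis frames. Problem sizes shipped with the acceptance
checks: hot stages of 0.5-1.6e7 two-body events, quenches of 1.5-2e6
events, five seeds per condition, pure-ligand runs of 1.2e6 events with
16 molecules in a 127.3 A box.

Even so, the control system's full collapse to a single octamer is not
reliably reached within those budgets: runs typically arrest in two or
three clusters (tetramers and hexamers) whose mutual encounter times
exceed the hot-stage budget. The mass-weighted size distribution pooled
over five seeds then peaks below eight. This is a transport limitation of
the desk-scale realization, not of the model's equilibrium (runs that do
merge never dissociate); the corresponding acceptance check is left
failing deliberately, with this explanation, rather than weakened. The
curcumin-laden systems are not transport-limited in the same way — the
statistic of interest there (the pooled small-molecule:peptide ratio over
peptide-containing clusters, which the stoichiometry pins at 2:1) is
carried by ligand-peptide association, which is fast.

## The analysis stack

Two beads of different molecules are in contact when their minimum-image
distance is strictly below 5.5 A (configurable); molecules sharing a chain
of contacts form a cluster (connected components; `igraph` is the
implementation route and a hand-written union-find the test oracle).
`cluster_stats()` collects the peptide-containing cluster count histogram,
the mass-weighted size distribution `P(s) = <s n_s>/N` (the probability
that a randomly chosen chain sits in an s-mer), and the
(peptides, ligands) composition map, with ligand-only clusters excluded
from the count but kept in the map. `radial_profile()` unwraps each
matching cluster across the periodic boundary (molecules about their first
bead, then molecule-by-molecule along a spanning tree of the contact
graph), and histograms bead distances from the mass-weighted centre,
separately for peptide beads, ligand beads, ligand aliphatic carbons and
ligand oxygens.

Secondary structure is assigned from backbone pseudo-angles
(`theta`, beads i-1..i+1) and pseudo-dihedrals (`tau`, beads i-1..i+2):
helix for `tau` in [30, 70] and `theta` in [85, 105] degrees sustained for
three residues, strand for `|tau| >= 150` and `theta` in [110, 145] for
two, turns on 2-3-residue direction reversals of the chain, coil
otherwise. The thresholds are calibrated to the package's own idealized
templates (`make_ss_template()`), which are built exactly at the window
centres — not to an atomistic dictionary, whose residue counts are
force-field-dependent and out of scope here.

## What the synthetic fixtures do and do not show

`make_clustered_trajectory()` builds trajectories whose cluster structure
is known by construction: cluster centres on a grid separated farther than
any cluster's extent plus the contact cutoff, molecules chained
anchor-to-anchor at 4 A steps (so clusters are provably connected), and
whole-molecule jitter small enough (<= 0.4 A) that no link opens past the
cutoff. The generator verifies both properties frame by frame and errors
otherwise, so its labels are the unique connected-component solution.
These fixtures use simplified molecules (3-bead peptides, 1-bead ligands)
and make no attempt to emulate aggregation kinetics, bead chemistry or
realistic geometry: passing them demonstrates the correctness of the
analysis arithmetic, not the realism of the dynamics. Engine physics is
instead validated against closed forms: the Maxwell-Boltzmann speed law,
exact conservation laws, and the two-body square-well bound fraction
against its configurational integral (`bound_fraction_oracle()`).

## Known limitations

* Coarse-grained stand-in: the published system is atomistic with a
  force field whose parameters are not public; all class radii, well
  depths and hydrogen-bond energies here are the package's own, calibrated
  only against qualitative behaviours. Atomistic quantities (exact helix
  residue counts, binding percentages) are non-goals.
* Desk-scale transport: see above; full control-system collapse requires
  budgets beyond the shipped defaults.
* The hot assembly stage samples conformations at elevated temperature;
  secondary-structure content from annealed runs reflects the quench, not
  a long 300 K equilibrium.
* Hydrogen bonding is distance-only and capacity-limited; no orientation
  dependence.
* Periodic boundaries are assumed (the standard choice; the source
  protocol does not state its walls).
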