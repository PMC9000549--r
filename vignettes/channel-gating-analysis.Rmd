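---
title: "Methods: water wires, helix kinematics and pore profiling for Hv1 gating"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: water wires, helix kinematics and pore profiling for Hv1 gating}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(hvgate)
```

## Scope and model

Hv1 is a voltage-gated proton channel whose voltage-sensor domain — the
four transmembrane helices S1 (residues 97–120), S2 (133–157), S3
(166–188) and S4 (193–214) — itself conducts protons. Gating is read
from a molecular-dynamics trajectory through a small set of geometric
analyses: does the pore hold a membrane-spanning hydrogen-bonded water
chain (the proton conduit), how do the helices and gate sidechains move
along the membrane normal, how does the internal salt-bridge network
rearrange, and how wide is the pore. This package implements those
analyses; it does **not** run molecular dynamics, assign protonation
states, or model proton transfer itself (Grotthuss hopping is the
mechanism the water wire enables, not something we simulate).

All coordinates are in Å, with the pore axis along z and z increasing
toward the extracellular side. Trajectories are ordered frames over a
fixed topology (multi-model PDB with CHARMM-style naming, or the
package's long-format `frame_csv`); waters are recognized under the
residue names TIP3, TIP3P, HOH and WAT. Van der Waals radii come from a
bundled Bondi-type element table (C 1.70, O 1.52, N 1.55, H 1.20 Å, …);
unknown elements fall back to 1.70 Å with a warning, since trajectory
formats carry no radii.

## Water-wire classification

A frame is *continuous* when the graph whose vertices are the pore
water oxygens and whose edges join pairs with O–O distance **strictly
less than 3.4 Å** has a connected component containing at least one
oxygen at or above the extracellular membrane bound and one at or below
the intracellular bound. The occupancy of a trajectory is the fraction
of continuous frames after equilibration; run lengths of consecutive
continuous frames measure wire lifetime.

Two geometric choices here are ours, because "water in the channel" has
no unique definition:

- **Selection volume.** Pore waters are those inside a cylinder of
  radius 8 Å (default) about the axis through the four-helix centroid,
  with z within the membrane slab extended by a 2 Å margin. The margin
  lets boundary waters sit just outside the slab; spanning is still
  judged against the slab bounds themselves.
- **Cutoff strictness.** The O–O criterion is a strict `<` (the wire
  definition reads "less than"), whereas the hydrogen-bond criterion
  below is inclusive `≤` (a "cut-off of 3.4 Å"). The asymmetry is
  deliberate and tested at the boundary in both modules.

The reported spanning path is a fewest-hop route between boundary
waters; among ties we return the lexicographically smallest atom-index
sequence, so outputs are reproducible under water reordering.
Connectivity and shortest paths go through igraph.

## Hydrogen bonds and salt bridges

A donor–hydrogen–acceptor triple is a hydrogen bond when the
donor-heavy to acceptor-heavy distance is ≤ 3.4 Å **and** the D–H···A
angle deviates from linearity by ≤ 30°. The distance is heavy–heavy by
default for consistency with the water-wire O–O criterion (an H···A
mode is available); the hydrogen must lie within 1.2 Å of its donor, or
the triple is rejected as malformed. Counts between two residues
consider both donor directions. A *salt bridge* is the subset with an
Arg/Lys sidechain nitrogen donor (NE/NH1/NH2/NZ) and an Asp/Glu
carboxylate oxygen acceptor (OD1/OD2/OE1/OE2); partner occupancy is the
fraction of frames with at least one such bond, tabulated per
(basic, acidic) pair with a dominant-partner column. Residues without
hydrogens raise an error that points to the distance-only mode
(`angle_cutoff = Inf`) rather than silently counting nothing.

## Helix and sidechain kinematics

Helix displacement is the z of each helix's Cα centroid minus the z of
the **pooled** four-helix Cα centroid (the union of Cα atoms, not a
mean of helix means). With the pooled convention the atom-count-weighted
sum of the four series is exactly zero in every frame — a useful
invariant, and the reason a +2 Å shift of S4 alone appears as +1.5 Å
for S4 and −0.5 Å for the others when atom counts are equal. Centroids
are unweighted (geometric, not mass-weighted): the analyses are stated
in terms of "alpha carbons", with no mass weighting implied. Series can
be re-zeroed to the first analyzed frame (displacements) or left raw
(relative z); both are emitted because either convention is defensible
for plotting.

Sidechain tracks use the centroid of heavy atoms beyond Cα. When an
anchor residue is given (Asp108 by convention — the hydrophilic member
of the pore constriction), each frame is first rigidly superposed on the
anchor's heavy atoms in the reference frame, so net channel motion drops
out of the track. Superposition is the standard Kabsch SVD solution;
when the raw rotation would be a reflection the smallest singular
vector's sign is flipped, and collinear references are rejected rather
than silently fit.

Equilibration is detected from an RMSD-vs-frame series as the first
index whose forward window (default 10 frames) has a least-squares
slope below 1e-3 Å/frame in magnitude — the start of the plateau. The
plateau criterion is our operational choice; only "determined by RMSD"
is inherited.

## Pore radius profiling

For each slice of a z grid (default 0.5 Å steps across the membrane
slab), the pore radius is the clearance of the largest sphere centered
in the slice plane: r(c) = min over atoms of (|c − a| − r_vdw), using
all atoms of the four helix ranges. The center is seeded on the pore
axis and maximized by steepest-ascent steps (initial step 0.25 Å,
halved to 0.01 Å once no neighbor improves). Monotone ascent cannot
cross the channel wall — where the clearance is negative — so the
sphere stays in the pore basin; an unconstrained global maximization
over a 10 Å disc would instead "escape" to the open space outside the
protein, where clearances are larger than anywhere in the lumen. This
axis-seeded 2D search is a deliberate, fully deterministic
simplification of HOLE's 3D Monte-Carlo walk, adequate for near-axial
pores. Radii are clamped to [0, 10 Å]; 10 Å means "outside the pore",
and slices with no atoms in reach report the cap with a warning. A pore
is water-passable when its minimum radius reaches 1.15 Å (with 1e-9 Å
slack so threshold equality, as in the ideal 2.85 Å cylinder whose
clearance is exactly 2.85 − 1.70 = 1.15 Å, counts as passable).

Profiles are computed per frame; the drivers emit sampled frames plus
their mean, since averaging conventions differ between studies.

## Peptide charge and isoelectric points

Net charge at a pH is the Henderson–Hasselbalch sum
(+Σ 1/(1+10^(pH−pKa)) over N-terminus/Lys/Arg/His, −Σ 1/(1+10^(pKa−pH))
over C-terminus/Asp/Glu/Cys/Tyr), termini optional. The pI is the
bisection root on [0, 14]; the charge is strictly decreasing in pH so
the root is unique, and one-signed curves return the boundary with a
warning. Two standard pKa tables are bundled (EMBOSS and
Lehninger-style) because published pI values depend on the table used
and the tools behind reported values rarely disclose theirs; we
therefore treat helix pI comparisons as an *ordering* statement
(S3 < S1 < S2 < S4 — most acidic to Arg-rich) rather than as exact
values. The bundled helix segments are synthetic stand-ins matching the
helices' qualitative compositions; real sequences are user input, and a
FASTA reader is provided.

## The synthetic generator: what it emulates, and what it does not

The generator builds a four-quadrant cylindrical scaffold of carbon
beads (one residue per ring per helix, numbered inside the helix
ranges; every arc atom is named CA so Cα selections see equal atom
counts per helix) plus gate pseudo-residues — Asp108, Leu143, Phe146,
Phe178, Arg201, Arg204 — with explicit sidechain heavy atoms and, for
the arginines, hydrogens at ideal 1.0 Å bond lengths so angle criteria
are exactly computable. It plants:

- **wire frames**: exactly `round(fraction × n_frames)` frames sampled
  without replacement (the spec requires the product to be integral, so
  occupancy recovery is exact, not approximate); wire frames carry an
  axial water chain at 2.8 Å spacing spanning the slab, non-wire frames
  the same chain with one interior bond widened to 4.0 Å — an
  unambiguous super-cutoff break;
- **helix schedules**: rigid per-frame z offsets per helix;
- **contact schedules**: in "on" frames the arginine NH hydrogens and
  nitrogens are placed collinear with the aspartate carboxylate oxygens
  at 2.9 Å (an ideal bidentate contact, count = 2); in "off" frames the
  guanidinium rests ~6 Å away;
- **gate drift**: a linear sidechain z ramp for one residue;
- static off-cylinder decoy waters and one water beyond the z window,
  exercising the membership test.

Default conditions are one 200-frame trajectory per voltage with wire
fractions 0, 0.195, 0.285 and 0.49 for 0/50/150/250 mV — the observed
study proportions rounded to the nearest multiple of 1/200 — and helix
ramps a few Å in magnitude, matching the reported −3 to −4 Å relative
S2 displacement at high field.

What the generator does **not** emulate: thermal noise beyond optional
Gaussian jitter, force-field physics, sidechain rotamers, lipid or ion
atoms, periodic boundary images, or any coupling between voltage and
geometry (voltage is bookkeeping metadata; E = V/z is reported per
condition with the 36 Å default thickness as a user input, since how a
membrane thickness is measured varies between studies). Passing tests
therefore demonstrate that the analyses recover planted geometric facts
exactly under controlled conditions — not that they are robust to every
artifact of real MD data (imperfect water geometry, PBC wrapping,
tilted pores).

## Numerical choices and degenerate inputs

- Cutoff boundaries: strict `<` (water wire) vs inclusive `≤`
  (hydrogen bonds), each verified by bisection to ±0.01 Å / ±0.1°.
- Ties: spanning paths break ties by smallest atom-index sequence;
  `which.min`/`which.max` conventions (first minimum) fix the reported
  constriction slice and dominant partner under exact ties.
- Degenerate inputs raise errors naming the problem: empty selections,
  collinear superposition references, glycine sidechain requests,
  hydrogen-less residues under an angle criterion, inconsistent
  multi-model topologies, non-integral wire fractions, zero-radius
  scaffolds, non-positive membrane thickness.
- CSV outputs use fixed 6-decimal formatting and the report index uses
  paths relative to the output directory, so identical configurations
  reproduce byte-identical bundles.
- Problem sizes in the test-suite: 200-frame / ~660-atom trajectories
  for occupancy recovery, 6-point sets for the rotation-sampling
  superposition oracle, 20 jittered-wall instances at a 0.005 Å
  exhaustive grid for the pore oracle, and 500-atom frames for the
  Gaussian-jitter RMSD closed form. These sizes make every planted
  quantity exactly recoverable while keeping the suite quick.

## Known limitations

- The pore axis is fixed (z through the four-helix centroid); curved or
  strongly tilted pores would need HOLE's vector-following search.
- The water-wire definition considers water oxygens only; protein
  atoms cannot bridge a wire, consistent with the "chain of water
  molecules" definition, but this under-counts hybrid conduits.
- Hydrogen-bond detection requires explicit hydrogens (or the
  distance-only mode); no energetic scoring.
- `frame_csv` and the PDB dialect assume whole (un-imaged) systems; no
  periodic-boundary handling.
- Exact pI values depend on the pKa table; only orderings are
  meaningful across tools.
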