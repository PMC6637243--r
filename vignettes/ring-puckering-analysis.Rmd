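---
title: "Ring-puckering analysis of glycosidase enzyme:substrate dynamics"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Ring-puckering analysis of glycosidase enzyme:substrate dynamics}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(glycopucker)
```

## The problem

Retaining β-glycosidases distort the sugar ring held at the lytic
subsite −1 before cleaving the glycosidic bond between subsites −1 and
+1. The distorted conformers sampled by the Michaelis complex trace a
*conformational itinerary* — an ordered path on the sphere of
six-membered-ring shapes from a pre-transition-state skew-boat or boat,
through a half-chair or envelope transition state, down to the relaxed
⁴C₁ chair of the covalent intermediate. Which itinerary a GH family
follows is diagnostic of its stereoelectronic constraints (the
antiperiplanar lone pair hypothesis, ALPH, for β-glycosides) and can be
read off MD trajectories and docking ensembles. This package is the
analysis layer of that reading: puckering coordinates, conformer
classification, occupancy and excursion statistics, itinerary calls,
per-subsite flexibility, docking-pose triage and clan-level structure
trees. Engines that *produce* trajectories or poses are out of scope;
a synthetic generator stands in for them so every analytic is testable
end to end.

## The puckering model

For ring positions $\mathbf{R}_j$, $j = 1..6$ in the order O5, C1, C2,
C3, C4, C5, displacements are taken relative to the geometric centre.
The mean plane is fixed by $\sum_j z_j = 0$ together with the two
first-moment constraints
$\sum_j z_j \cos(2\pi(j-1)/6) = \sum_j z_j \sin(2\pi(j-1)/6) = 0$,
which resolve to a normal along the cross product of the two
first-moment lattice vectors. The displacement pattern then decomposes
into

$$q_2\cos\phi_2 = \sqrt{\tfrac13}\sum_j z_j \cos\tfrac{4\pi(j-1)}{6},
\qquad
q_2\sin\phi_2 = -\sqrt{\tfrac13}\sum_j z_j \sin\tfrac{4\pi(j-1)}{6},
\qquad
q_3 = \sqrt{\tfrac16}\sum_j (-1)^{j-1} z_j,$$

with $Q = \sqrt{q_2^2+q_3^2}$, $\cos\theta = q_3/Q$, $\phi = \phi_2$.
Two conventions are fixed here and asserted in tests, because the
coordinates are meaningless without them:

* **Atom order** O5, C1…C5 — the standard traversal for D-pyranoses.
* **Normal orientation** such that the alternating pattern with O5
  displaced upward is the north pole. Together these put ⁴C₁ at
  $\theta = 0$ and ¹C₄ at $\theta = 180°$, matching the usual Mercator
  charts where the three β-galactosidase itineraries run down the
  meridians $\phi = 210°$ (¹S₃/⁴H₃), $240°$ (¹,⁴B/⁴E) and $270°$
  (¹S₅/⁴H₅).

The decomposition is exactly invariant under rigid-body motion of the
ring (tested to $10^{-8}$ over random transforms) and was
cross-checked against an independent implementation during development.

## The conformer library and classification

The 38 canonical conformers — 2 chairs, 6 boats, 6 skew-boats, 12
half-chairs, 12 envelopes — are *derived*, not tabulated: each symbol
names the atoms displaced above (superscript) and below (subscript) the
reference plane; the corresponding ideal displacement pattern is built
and pushed through the forward decomposition to obtain
$(\theta_{ref}, \phi_{ref})$. This yields boats/skew-boats alternating
every 30° on the equator, half-chairs at $\theta = 50.77°$ and
envelopes at $\theta = 54.74°$ on the tropics (the two latitudes follow
from the ideal two-atom and one-atom patterns; charts that draw E and H
on one shared tropic are a visual simplification).

Classification is nearest-reference by great-circle distance on the
unit sphere, with ties (a probability-zero event on real data) broken
lexicographically. No basin boundaries are defined between adjacent
conformers: published inventories often report hybrid labels such as
⁴H₃/⁴E precisely because the regions blur, and nearest-reference
assignment plus occupancy aggregation preserves that information as two
adjacent canonical labels. Rings with $Q$ below **0.1 Å** are reported
`UNDEFINED`: near the planarity limit $\theta$ and $\phi$ degenerate,
and real pyranoses sit near $Q \approx 0.55$–0.6 Å.

## Trajectory statistics and the itinerary rule

Occupancy tables are plain frame percentages; conformers never observed
are omitted (rendered as a dash on wide export). Excursions are maximal
runs of non-⁴C₁ frames — intermediate envelope/half-chair frames count
inside the excursion, since reaching them is the prerequisite for an
equatorial visit — with a flag for whether the run touched a
boat/skew-boat.

The itinerary call needed a quantitative rule where the source analyses
argue from conformer inventories qualitatively. The rule adopted: an
itinerary is supported iff its equatorial anchor (¹S₃, ¹,⁴B or ¹S₅)
has nonzero occupancy; its support is the anchor's share of total
anchor occupancy; the call is the argmax, with all supported
itineraries reported; `NONE` (not ALPH-diagnostic) when no anchor was
ever seen. The rule is a pure function of the occupancy table, and
mixed-anchor runs — which do occur, e.g. inventories carrying ¹S₃ and
¹,⁴B at comparable weight — are deliberately reported with both
supports rather than forced into one call.

## Flexibility profiling

Each frame is superposed on the **protein heavy atoms** of frame 0 by
Kabsch least squares and the same transform is applied to the ligand;
the ligand is never re-fitted, so its RMSD measures motion relative to
the protein frame, which is the quantity that distinguishes a mobile
−1 residue from an anchored +1. Waters and hydrogens are excluded
upstream; a missing atom is an error, not a silent drop, because a
trajectory frame with missing atoms is corrupt. An independent
quaternion-method (Horn) superposition oracle pins the kernel to
$10^{-8}$ in tests.

## Docking-pose triage

Pose geometry is compared in the shared receptor frame (no
re-superposition — poses and reference complexes are defined against
the same receptor coordinates). Optimal fit is ring RMSD < 0.5 Å over
the six ring atoms of the −1 residue. The four MD-seed criteria are
operationalised as: (i) best dock score; (ii) whole matched-ligand RMSD
below 2.0 Å; (iii) the 0.5 Å ring fit; (iv) nucleophile carboxylate O
within 3.5 Å of the anomeric C1 and acid/base carboxylate O within
3.5 Å of the glycosidic O, plus an optional minimum count of
−1-subsite H-bond contacts at 3.4 Å. The numeric cutoffs in (ii) and
(iv) are this package's defaults — the protocol they implement states
none — and all are configurable and echoed in the JSON report. The
selected pose is the best score among poses passing (ii)–(iv); when
nothing passes the result says so explicitly, since a silently chosen
dislocated pose would poison everything downstream.

## MaxSub and the structure tree

MaxSub searches contiguous 4-residue seed windows, grows the matched
set over four iterations with the distance threshold ramping to its
final value (default 3.5 Å), and scores
$S = N^{-1}\sum_{i \in M} (1 + (d_i/d)^2)^{-1}$ with $N$ the **first**
structure's residue count — the normalisation choice that makes the
score asymmetric and is the reason the pairwise distance is defined on
the *average* of the two reciprocal scores, $1 - \mathrm{MaxSubAverage}$.
Normalising by the shorter chain instead is a one-line change; query
normalisation was chosen and is documented because the upstream tool's
choice is not recorded. The alignment search itself (sequence-independent
correspondence discovery) is out of scope: correspondences are inputs,
identity-by-index for equal-length structures. Neighbor-joining and
Newick export go through `ape`; NJ is exact on additive matrices
(verified over random 8–12-leaf trees) and occasional negative branch
lengths on non-additive input are clamped to zero with a warning.

## What the synthetic generator does and does not emulate

The generator encodes the study conditions: 1000 frames per
20 ns-equivalent run (one frame per 20 ps), ring amplitude 0.6 Å,
Gaussian angular noise of 3° applied in the tangent plane (isotropic on
the sphere, reflected at the poles, the azimuthal component scaled by
$1/\sin\theta$), amplitude noise 0.02 Å floored at 0.15 Å so
classification stays defined. Frames are allocated to waypoints by
dwell fraction in contiguous blocks — so programmed occupancies are
exact in expectation and excursion structure is controlled by the
waypoint sequence — with optional great-circle interpolation frames
between blocks. Mock complexes hold the protein scaffold rigid and
move only the −1 ring, which makes the −1 > +1 flexibility contrast a
construction guarantee rather than an emergent result.

What this validates: the analytics — decomposition, classification,
occupancy/excursion/itinerary arithmetic, superposition and RMSD
bookkeeping, file I/O — at known ground truth. What it does not:
force-field realism, solvent, protein breathing, correlated
ring/protein motion, kinetics of conformer interconversion. Passing
tests say the pipeline measures faithfully; they say nothing about what
real enzymes do.

## Numerical choices

* Planarity threshold $Q_{min} = 0.1$ Å; classification ties broken
  lexicographically; $\phi$ wrapped to $[0, 360)$; angles in degrees.
* The inverse ring construction shortens each in-plane polygon side to
  compensate its out-of-plane gap and re-closes the hexagon, keeping
  3-D bond lengths within ~5% of the 1.54 Å target up to $Q = 0.8$ Å;
  amplitudes above 1.5 Å are rejected as geometrically degenerate. The
  planar arrangement never enters the decomposition, so round-trip
  recovery of $(Q, \theta, \phi)$ stays exact to machine precision.
* Degenerate rings (collinear/coincident atoms) are errors, as are
  consecutive ring-atom distances outside (0.5, 3) Å.
* PDB output uses MODEL/ENDMDL blocks, occupancy 1.00, B-factor 0.00;
  coordinates survive the format's 3-decimal precision, which perturbs
  puckering angles far below the 30° conformer spacing.

## Problem sizes

The test suite and the acceptance script run at the sizes the analyses
themselves use: 1000-frame occupancy recoveries, 100-replicate
flexibility contrasts at 25 frames each, 100 random additive matrices
of 8–12 leaves, 60-residue synthetic Cα traces for MaxSub. The full
suite completes in well under a minute on one core.

## Known limitations

* Furanose (five-membered) puckering is not handled.
* The itinerary rule reads anchors only; it does not check that the
  transition-state tropic conformers of the called itinerary were also
  visited (inventories in practice always contain them when the anchor
  is hit, but a pathological table could be called on the anchor
  alone).
* MaxSub here scans contiguous seeds with single-pass extension; exotic
  correspondences whose best superimposable subset contains no 4
  contiguous matched pairs would be under-scored.
* Free-energy surfaces, Markov-state models and interconversion rates
  are out of scope by design.
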