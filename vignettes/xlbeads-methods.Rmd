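---
title: "Coarse-grained integrative modelling from cross-linking restraints: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Coarse-grained integrative modelling from cross-linking restraints: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

# The problem

Chemical cross-linking followed by mass spectrometry (XL-MS) reports pairs
of residues — typically lysines bridged by an amine-reactive reagent such
as DSS — that were close in space in the intact assembly.  A single
experiment can yield hundreds of such unique distance restraints (UDRs) at
a controlled false-discovery rate.  For complexes with no atomic structures
or homology models for any subunit, this is often the richest source of
spatial information available.  `xlbeads` turns a UDR table plus minimal
prior knowledge (copy number, approximate subunit localizations, known
subcomplexes) into a coarse-grained three-dimensional model of the
assembly, with ensemble-level measures of precision and robustness, and
supports restraint-guided docking of the modelled complex onto a
coarse-grained tubulin lattice.

# Representation

Each protein is a chain of spheres ("beads"), one bead per ten consecutive
residues by default.  The granularity is matched to the information
content of typical XL-MS data (about one cross-linked residue per 10–15
residues along a chain): finer beads would add degrees of freedom with no
data to restrain them, coarser beads would waste restraint information.
The final bead of a chain holds the sequence remainder and is simply
smaller; remainders are never redistributed, so the bead holding residue
$r$ is always $\lfloor (r-1)/g \rfloor$ — a pure function of $r$ that
cross-link bookkeeping relies on.

Bead volume comes from sequence mass: $V = c_\mathrm{vol}\, m_\mathrm{res}\, n_\mathrm{res}$
with $c_\mathrm{vol} = 1.21$ Å$^3$/Da (the conventional protein partial
specific volume) and $m_\mathrm{res} = 110$ Da per residue, giving a
radius of about 6.8 Å for a ten-residue bead.  Both constants are exposed
as arguments because they are conventions, not measurements.

Dimeric assemblies are represented as two copies with an exact two-fold
symmetry *constraint*: copy 1 has no independent degrees of freedom; every
accepted move maps copy 0 through the rigid transform.  The transform
(e.g. fitted from an EM map of the dimer) is part of the topology.

# The scoring function

All terms act on bead *surface* distances
$s_{ij} = \lVert c_i - c_j \rVert - r_i - r_j$ and are quadratic
penalties in dimensionless kT units:

* **Connectivity** — sequence-adjacent beads pay $k s^2$ for a positive
  gap.  The penalty is one-sided: overlap between neighbours is left to
  excluded volume, because a two-sided harmonic would doubly penalize the
  overlaps that excluded volume already handles.  (Published descriptions
  of this class of model often say only "harmonic with equilibrium 0 Å",
  leaving the sidedness open; the gap-only choice is deliberate here.)
* **Excluded volume** — every non-adjacent pair pays $k s^2$ when
  $s < 0$.  A soft quadratic is the simplest form parameterized by a
  single "intensity", and soft overlap matters: a bead must be able to
  pass through a crowded region on its way to satisfying a restraint.
* **Cross-links** — an upper-bound harmonic $k(s^* - b)^2$ for
  $s^* > b$ on the *minimum* surface distance $s^*$ over all endpoint
  assignments to the two copies (intra- and inter-copy).  The bound
  $b = 5$ Å is the bead-level analogue of the ≈30 Å Cα–Cα reach of a
  DSS-class reagent after accounting for bead radii; it is deliberately
  restrictive because an upper-bound harmonic can be marginally exceeded
  during sampling.  The ambiguity rule means the model is never forced to
  decide a priori whether a cross-link is intra- or inter-monomer.
* **Localization boxes** — beads of components with prior localization
  pay $k d^2$ on their Euclidean exit distance from an axis-aligned box.
  This is a restraint, not a constraint: a component may leave its box by
  any amount if enough cross-links pay for it.  Copy-1 beads are
  evaluated through the inverse symmetry transform, i.e. against the
  copy-0 box in the copy-0 frame; this keeps the energy identical whether
  the symmetry constraint is active or (during docking stage 2) released.
* **Subcomplex connectivity** — for each member of a declared subcomplex,
  the smallest surface distance $g$ to any other member contributes
  $k g^2$ when positive, encoding "each member touches at least one
  other" from biochemical dissociation data.

All spring constants default to 1.0.  The total is a pure function of
coordinates; with no boxes active it is invariant under global rigid
motion.  The C++ evaluator used by the sampler and the exported R term
functions implement the identical definitions and are cross-checked
against a brute-force enumeration oracle in the test suite at $10^{-9}$
relative tolerance.

# Sampling

Metropolis Monte Carlo with parallel tempering.  One randomly chosen
copy-0 bead is displaced per step, uniformly within a 1 Å ball; copy 1
follows by symmetry; acceptance is $\min(1, e^{-\Delta E/T})$.  Replicas
(34 at production scale) occupy a geometric temperature ladder between
1.0 and 3.0 kT — geometric spacing is the standard choice for roughly
uniform exchange acceptance, since the range and count alone do not fix
the ladder.  Neighbouring pairs are proposed for exchange every
`exchange_interval` steps with alternating even/odd pairing and the
standard acceptance $\min(1, e^{(\beta_i-\beta_j)(E_i-E_j)})$.

Energy changes are evaluated incrementally (only the terms touching the
moved bead and its mirror), and every cached replica energy is refreshed
from a full recomputation at each exchange sweep, so floating-point drift
cannot accumulate.  Each replica owns a counter-based RNG stream derived
from the master seed; the engine is single-threaded and bit-for-bit
reproducible given the seed.

Snapshots of the lowest-temperature replica are recorded at the exchange
cadence and the best `top_n_keep` (default 1000) are returned, sorted by
score.  Harvesting from the coldest replica only is a choice: it is the
replica whose stationary distribution is the target ensemble.

An optional well-tempered-ensemble bias on the total energy is available
(`wte_enabled`): deposited Gaussians of width 2 energy units decay with
bias factor $\gamma = 16$, broadening energy fluctuations to boost
exchange acceptance.  It is off by default; the desk-scale systems in
this package exchange at 30–80% without it.

Initialization places beads of box-restrained components uniformly inside
their box and all other beads uniformly inside the union of boxes — the
same prior the boxes themselves express.

# Ensemble analysis

* **Clustering** — greedy largest-neighbourhood (Daura) clustering at a
  1.7 nm cutoff.  The pairwise metric is bead-centre RMSD after optimal
  least-squares superposition over all beads, with no chain relabelling:
  the symmetric copy is a constraint, not a permutation freedom.  Ties
  are broken by score, then index, making the result deterministic.
* **Localization density** — every model is superposed onto the top
  cluster's centre; each bead's centre positions are histogrammed on a
  2 Å grid and normalized per bead, giving the probability that a region
  of space is occupied by that bead.  Maps can be written as MRC/CCP4
  volumes (summed over beads).
* **Bead variability** — the extent of each bead's density at half its
  maximum, measured as the largest distance between qualifying voxel
  centres (a diameter; for an isotropic Gaussian this equals the FWHM
  $2\sigma\sqrt{2\ln 2}$, which the tests verify).  The fraction of
  beads at or below 3 Å summarizes model precision.
* **Satisfaction** — a UDR fits a model when its minimum ambiguous
  surface distance is within 10 Å, twice the restraint bound; the looser
  reporting cutoff separates "essentially satisfied" from "violated"
  without rewarding the sampler for grinding the last Ångström out of
  soft restraints.
* **Contacts and macro-regions** — two beads are in contact at surface
  distance ≤ 5 Å, the cross-link restraint bound; "interaction" counts
  are defined by this cutoff.  Contacts aggregate per protein
  pair and per ~100-residue macro-region (N/M/C), split intra- vs
  inter-monomer, and two conditions can be compared region by region
  (shared / gained / lost).
* **Jackknife** — the assembly is re-modelled with random 95% subsets of
  the UDRs and the conserved fraction of the full model's bead-pair
  contacts is reported.  Subset runs reuse the full run's sampling seed
  (the subset draw has its own stream), so `fraction = 1` reproduces the
  full model exactly — a useful identity test — and differences at
  `fraction < 1` are attributable to the data, not to re-seeding.

# Docking onto the tubulin lattice

The lattice is a rigid 6 × 6 patch of alternating α/β-tubulin monomers
(α at the minus end), each a ten-residue-per-bead chain arranged
deterministically inside its subunit footprint; protofilaments run along
+z (plus end), lateral neighbours along x, at 52 Å lateral and 40 Å
axial spacing.  A flat patch (no cylindrical curvature) preserves the
restraint geometry at the contact face while keeping construction simple;
the 20 edge subunits are excluded from all restraint ambiguity, leaving
16 interior subunits.

Complex-to-tubulin cross-links are ambiguous over both complex copies
*and* over every interior subunit of the matching isoform (α records to α
subunits: residue numbering is isoform-specific, so spreading the
ambiguity across both isoforms would conflate different residues; a
config switch restores the permissive reading).

Docking is two-staged, with all free-complex restraints maintained:
stage 1 keeps the symmetry constraint, initializes the lattice at 100 nm
in a random orientation, and samples per-bead complex moves plus rigid
lattice moves; stage 2 continues from the best stage-1 state with the
symmetry constraint released.  Because the localization-box term
evaluates copy-1 beads through the inverse symmetry transform, the energy
is continuous across the stage boundary.  Rigid lattice proposals mix
translations and rotations about the lattice centroid; the default sizes
(2 Å, 2°) suit production-scale budgets, while the desk-scale analyses
in this package enlarge them (6 Å, 10°) and raise the lattice-move
fraction to 10% so that the long-range approach and the re-registration
of the lattice against the complex converge within hundreds of thousands
of steps instead of $10^8$.

Orientation is summarized as the angle between the complex's principal
axis (largest-variance direction of all bead centres) and the
protofilament axis, folded into [0°, 90°], with "perpendicular" (≥ 45°,
ring-compatible) vs "parallel" classes, plus a plus/minus-end-facing call
for labelled termini from the sign of their axial offset relative to the
complex centroid.

# Benchmarking cross-link data against known structures

For complexes with reference structures, `map_distances` computes
Cα–Cα distances per UDR (minimizing over equivalent chains of
homo-oligomers — the same conservatism as the modelling ambiguity rule;
model 1 of multi-model files), `fraction_within` reports the fraction
inside the reagent's span (30 Å for DSS), `enrichment_profile` compares
observed distances against the all-lysine-pair background as normalized
histograms with a cumulative-fraction ratio at 20 Å, and
`monolink_coverage` reports the fraction of lysines seen modified in
mono-link or cross-link records (either record type counts — coverage
measures reagent accessibility and detection, regardless of whether the
second end found a partner).

# The synthetic-data generator

Every quantitative claim in the test suite is made against data simulated
from a known ground truth:

* `generate_toy_assembly` builds each component as a self-avoiding chain
  of touching beads by a random walk, then relaxes it under connectivity
  + excluded volume (including against the symmetric image) with a
  centring pull until a radius-of-gyration target is met.  Construction
  is deterministic given the seed and errors out if the bead volume
  exceeds the packing limit of the target.
* `simulate_crosslinks` observes every lysine-like site pair (sites every
  8th residue, approximating lysine frequency without sequence realism)
  whose true minimum ambiguous surface distance is within 5 Å — the
  restraint bound, i.e. the bead-level analogue of the reagent span —
  with probability 0.7, then appends 1% uniformly random decoy pairs,
  mimicking the residual contamination of a 1% FDR dataset.  Decoys are
  drawn uniformly (not distance-weighted): worst-case contamination.
  The decoy flag is internal; written tables never expose it.
* `derive_bounding_boxes` inflates the true per-component bounding boxes
  by 20 Å, emulating localization priors that are purposefully larger
  than the underlying data.
* `simulate_tubulin_xls` rests the ground-truth complex on the lattice
  face (conjugating the symmetry transform into the planted frame so the
  dimer constraint still holds exactly) and records a tubulin cross-link
  for every reachable (site, tubulin bead) pair — one site can report
  against several tubulin residues, as real lysines do.

What the generator does *not* emulate: sequence-dependent reactivity,
peptide detectability, solvent accessibility (every site is reactive),
spectral miscleavage, or distance-correlated decoys.  Passing the
recovery tests therefore demonstrates that the modelling machinery
inverts its own forward model at realistic data quality — not that any
particular biological dataset would yield a model of comparable accuracy.

# Study problem sizes

The analyses shipped in the tests and the reproduction script use
reduced, fixed problem sizes chosen once so that the full battery runs
quickly on a single CPU while the recovery checks remain stable:

* End-to-end recovery: a three-protein dimer (160 + 140 + 100 residues,
  40 beads per copy), compactness target 25 Å, boxes padded 20 Å on two
  of the three components; sampling 2 × 10⁶ steps on 8 replicas; top
  1000 models analysed.  Three independent seeds.
* Jackknife: a two-protein dimer (120 + 80 residues) at 10⁵ steps on 4
  replicas; subset fractions 0.5/0.75/0.95 averaged over five seeds for
  the monotonicity check.
* Docking: the planted-pose study uses a looser dimer (compactness 35 Å,
  so the lattice-facing contact patch carries about a dozen planted
  restraints), 10 Å box padding on all components in the planted frame,
  and 2 × 10⁵ steps on 4 replicas per stage.  With only ~12 restraints
  concentrated in one contact patch the in-plane orientation of the
  lattice is much more weakly determined than with the hundreds of
  restraints of a real dataset — this is the main reason pose recovery
  is asserted across a set of seeds rather than per run.
* Boltzmann checks: single-bead 3D harmonic (a degenerate box at the
  origin), 10⁶ steps across 4 replicas, variance against T/2.

# Known limitations

* The bead representation has no shape anisotropy; elongated domains are
  spheres, which inflates apparent compaction.
* Upper-bound restraints make the score insensitive to everything closer
  than the bound; models are ensembles, and single-model distances below
  ~5 Å are not meaningful.
* The tubulin lattice is a flat rigid patch; curvature effects at ring
  scale and protofilament flexibility are out of scope.
* Orientation classification uses a single principal axis and is
  reported as undefined for nearly isotropic assemblies.
* The Daura clustering is $O(n^2)$ in ensemble size with an $O(n^2)$
  RMSD matrix; ensembles beyond ~5000 models should be thinned first.
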