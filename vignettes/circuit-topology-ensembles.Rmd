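---
title: "Circuit topology and ensemble analysis for disordered proteins: methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Circuit topology and ensemble analysis for disordered proteins: methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(cirtop)
```

## Scope and scientific setting

`cirtop` implements the analysis layer used to characterise conformational
ensembles of the androgen receptor's N-terminal transactivation domain
(AR-NTD), an intrinsically disordered region of 538 residues, and its
polyglutamine-expanded variant. The wild-type tract carries 23 glutamines;
the disease-associated expansion studied here carries 45, which lengthens
the chain by 22 residues and shifts the numbering of everything C-terminal
of the tract (the ANTS signature motif, wild-type/UniProt residues 233-246,
sits at 255-268 on the expanded chain). The domain is conventionally split
into an N-terminal region NR (residues 1-224) and a C-terminal region CR
(225-538).

The package covers five analysis families: residue-contact maps under
atom-pair criteria; circuit-topology (CT) profiling of the contact network;
per-residue fluctuation (RMSF) and helicity metrics; GROMOS-style
conformational clustering with coverage-based representative selection; and
interface fingerprinting of two-chain docking poses. It does not run
molecular dynamics or docking: it analyses conformers and pose sets given
to it, and ships a seeded synthetic-conformer generator so every stage is
testable with planted ground truth.

## Contact criteria

Two residues are in contact in a frame when at least 5 atom pairs (one
atom from each residue) lie within 4.5 angstrom and the residues are more
than 3 apart in sequence (the three nearest neighbours on each side are
excluded). All three numbers are parameters of `contact_criteria()`.

Two readings of the "at least five atoms" rule are possible; we count
qualifying *atom pairs* by default, and expose the stricter
five-distinct-atoms-per-side reading as `per_side = TRUE`. Distances are
Euclidean over all heavy atoms; hydrogens participate only if present.
Coarse-grained (CA-only) input cannot satisfy a multi-pair rule, so the
contact engine raises an explicit error rather than silently returning an
empty map; callers lower `min_pairs` for CG work. The same criteria engine
drives intra-chain contacts, contact-time fractions, CT, and cross-chain
interface detection (where sequence-neighbour exclusion is inapplicable);
a single configurable criterion serving all stages is a deliberate
simplification, recorded in every report's provenance block.

Replicate dispersion for contact-time fractions is the population standard
deviation: with three replicates, a sample SD would be a poor estimator
and the population form matches how small-n dispersion is conventionally
reported for such analyses.

## Circuit topology

Each contact is the closed sequence interval `[i, j]`. For any two
contacts the relation is:

* **series (S)** - intervals disjoint, or touching in at most one shared
  endpoint;
* **parallel (P)** - one interval nested in the other (the nested member
  is in the *inverse-parallel* relation); containment with a shared
  boundary counts as parallel;
* **cross (X)** - intervals interleave.

The shared-endpoint tie rules are a design choice: the relation taxonomy
is usually stated for generic (distinct-endpoint) contacts, and any
residue-resolved contact map will produce ties. Our rules are
deterministic and preserve the completeness identity
`n_S + n_P + n_X = choose(m, 2)` for every m-contact map, which the test
suite asserts against an independently formulated interval-overlap oracle
on a thousand random maps.

The per-residue *inverse-parallel profile* measures how sequestered each
residue is: for each sampled frame, every contact incident to a residue
contributes the number of other contacts enclosing it, and the per-frame
values are summed over the residue's incident contacts. Summation (rather
than averaging per incident contact) is the default because a residue
engaged in several deeply nested contacts is more sequestered than one in
a single nested contact; the mean-per-contact alternative is available via
`aggregate = "mean"`. Frames from all replicates are pooled before the
mean and SEM are taken - pooling first treats frames as the sampling unit,
which matches an error bar computed "over all extracted frames". The SEM
uses the population SD, which makes the frame-duplication invariance exact
(duplicating every frame leaves means unchanged and scales SEM by
1/sqrt(2)).

The *topology density* reduces each sampled frame to the point
`(n_S, n_P + n_X)` of its census and histograms the pooled points on
unit-width bins (configurable edges), normalised to total mass 1. Frames
are sampled on a 25 ns stride by default, the conventional coarse stride
for trajectory-level CT analysis; analyses of on-disk ensembles use their
time stamps, and frame-unit strides when stamps are absent.

No energy or contact-length filtering is applied and no circuit
decomposition is performed: published pipelines mention such filters
without stating parameters, so we provide none rather than guess;
`contact_criteria()` is the single filtering point.

## Ensemble metrics

**Superposition** is the Kabsch least-squares fit (SVD with the
determinant correction, proper rotations only, so mirror images are not
superposable). **RMSF** superposes all frames onto an iteratively refined
mean structure (converged when the mean moves < 1e-6 angstrom RMSD, at
most 10 iterations) and reports, per residue,
`sqrt(mean_f |x_rf - mean_r|^2)` over the selected atoms (CA by default),
in nm. For isotropic Gaussian displacements of per-axis SD sigma the
expected value is `sigma * sqrt(3)`, which the suite verifies to within 5%
on 2,000-frame synthetic ensembles.

**Secondary structure** is assigned by an explicit, self-contained
criterion rather than an external assigner: helical content is strongly
method-dependent (different force fields and assigners disagree on
absolute helicity), so a transparent criterion whose every parameter is
visible is preferable to wrapping a binary. All-atom path: a residue is
helical when it lies in a run of at least 4 consecutive residues with
phi in [-100, -30] and psi in [-80, -5] degrees (undefined terminal
dihedrals are not held against a residue). CA-only path: P-SEA-style
distances, `d(i, i+3)` in [4.8, 5.6] and `d(i, i+4)` in [5.9, 6.9]
angstrom, each qualifying i labelling the five-residue turn i..i+4.
Helicity content is the percentage of helical residue-frames over all
residues (termini included) and frames; per-replicate contents are
summarised as mean and population SD, and stable-helix residues are those
with helix probability above 0.30.

**GROMOS clustering** iterates: count each remaining frame's neighbours
within the RMSD cutoff (0.9 nm by default, over CA atoms after pairwise
Kabsch fits, unweighted); the frame with the most neighbours becomes a
center, its neighbourhood is removed, repeat. Neighbour-count ties break
toward the lowest frame index, making the solution deterministic.
**Representative selection** takes the smallest prefix of size-ordered
clusters whose cumulative membership reaches the coverage target (at
least 50% of frames by default) and returns their centers.

## Pose interface analysis

Interface residues are cross-chain residue contacts under the same
atom-pair criteria. Typed interactions use standard
interaction-fingerprinting windows (all configurable via
`interaction_params()`): hydrogen bond, donor-acceptor heavy atoms within
3.5 angstrom (plus a D-H...A angle of at least 120 degrees when hydrogens
are present); salt bridge, cationic N (Lys NZ, Arg NE/NH*, His ND1/NE2)
to anionic O (Asp OD*, Glu OE*, terminal OXT) within 4.0; pi-cation, ring
centroid to cationic N within 6.0 with the centroid-cation vector within
45 degrees of the ring normal; pi-stacking, centroids within 5.5 with
inter-plane angle below 30 (parallel) or above 60 degrees (T-shaped). A
close Lys-Glu pair may legitimately record both a salt bridge and a
hydrogen bond.

A pose's **region class** is NR (or CR) when at least 80% (the dominance
threshold) of its disordered-chain interface residues fall in that
region, else dual; fractions are over poses with non-empty interfaces.
The source analyses state no classification rule, so the rule and its
threshold are explicit parameters echoed into provenance. **Motif
status** per pose: blocked when at least half of the motif's residues are
interface residues (an `any_contact` mode exists for very short motifs
such as the 5-residue P-box); partially involved when at least one is;
exposed when none are and the motif's mean relative solvent accessibility
in the complex is at least 0.25. A motif with no interface involvement
*and* low accessibility falls outside this three-way rule; such poses are
reported as `buried` rather than silently mislabelled. The
SASA-thresholded "exposed" call is a stated operational proxy for what is
a visual judgement in the source analyses.

**SASA** is Shrake-Rupley sphere sampling with a deterministic
golden-spiral point set (960 points per atom by default, probe 1.4
angstrom), element-based van der Waals radii, and relative SASA
normalised by theoretical Gly-X-Gly maxima (Tien et al. 2013). No
installed R package computes SASA without delegating to external
binaries, so the implementation is part of the package and is tested
against the closed-form single-atom limit and the
complexation-never-increases-SASA invariant.

## Synthetic data: what it emulates, and what it does not

The generators produce the *measurable structure* of trajectory and pose
data with known ground truth: chains with planted contacts of known
topology (spring-relaxed bead chains, decorated with five pseudo-atoms per
residue so the 5-atom-pair rule is genuinely exercised; the planted set is
re-verified with the package's own contact engine before returning, with
bounded seed retries); ensembles with prescribed per-residue Gaussian
fluctuation amplitudes and deterministic contact on/off schedules; chains
with ideal helical segments built at canonical backbone geometry
(phi = -57, psi = -47; 1.5 angstrom rise, 3.8 angstrom CA-CA); and
two-chain poses with designed interfaces carrying exemplar interactions at
geometries inside the typing windows, everything else held beyond
geometric reach.

They are geometric, not thermodynamic: no excluded-volume realism beyond
the relaxation springs, no secondary-structure/contact coupling, no
solvent, no Boltzmann weighting, and residue displacements are rigid per
residue. Passing tests therefore demonstrate that the *analysis* layer
measures planted properties exactly under controlled conditions - they do
not validate force fields, sampling convergence, or any biological claim
about real trajectories. Headline ensemble statistics from
multi-microsecond simulations (helical contents, blockade percentages)
are not reproducible from scratch at desk scale; the analysis drivers
emulate their qualitative contrasts with planted compositions and the
acceptance machinery checks the measurement layer, not the physics.

## Numerical choices and degenerate inputs

* Intervals are 1-based and inclusive on both ends throughout.
* The polyglutamine tract's own coordinates are config-supplied (default
  58-80, the UniProt P10275 poly-Gln annotation); the printed record fixes
  only the lift images (233-246 to 255-268), and every construct and
  region map carries its frame label. Glutamine insertion is modelled at
  the tract C-terminus; since the tract is homopolymeric, any insertion
  point yields the same sequence and identical lifts outside the tract,
  so the choice is bookkeeping only (exposed as an argument).
* Indices strictly inside the expanded tract interior have no image under
  the contraction lift and raise an error rather than guessing.
* PDB I/O: models are frames; alternate locations resolve to the highest
  occupancy; insertion codes are rejected; topology must be identical
  across models; coordinates round-trip at the format's 3-decimal
  precision, and write-read-write is byte-identical. Configs and region
  maps are YAML.
* Empty contact maps yield zero censuses; residues with no contacts
  contribute zero to profiles in that frame; empty interfaces leave a
  pose unclassified (counted and flagged, excluded from fractions).
* All generators consume an explicit seed, restore the caller's RNG
  state, and are byte-deterministic given (spec, seed).
* Cluster ties break toward the lowest frame index; clusters are emitted
  in decreasing size with center order as the secondary key.

## Problem sizes

The bundled analysis drivers and test suite run at desk scale by choice:
100-residue chains, 12-frame replicate trajectories (three per variant),
8-20 pose sets, 2,000-frame ensembles where amplitude recovery is
measured, and 1,000 random maps for the census oracle. All sizes are
arguments, and the same code paths serve arbitrarily larger ensembles
read from multi-model PDB or per-frame CSV.

## Known limitations

* Single-chain circuit topology only; no multi-chain CT, no energy/length
  contact filtering, no circuit decomposition.
* The helix assigner covers the alpha basin only (no beta or 8-state
  taxonomy), and absolute helicity values are criterion-dependent.
* No periodic-boundary handling: molecules are analysed as given.
* Pose region classification counts interface residues; counting typed
  interactions instead would be a defensible alternative and would give
  slightly different fractions for sparse interfaces.
* The real receptor sequence is not bundled; sequence-level fixtures are
  synthetic stand-ins that are faithful in length, tract placement and
  numbering only.
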