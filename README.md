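# cirtop

Circuit-topology and conformational-ensemble analysis for intrinsically
disordered proteins, built around the androgen receptor N-terminal
transactivation domain (AR-NTD, 538 residues) and its polyglutamine-expanded
variant (23Q wild type vs 45Q expansion, the length range associated with
spinobulbar muscular atrophy). The package is for structural
bioinformaticians who have conformer ensembles (multi-model PDB) and
docking-pose sets and want the full measurement layer: contact maps,
contact-network topology, fluctuation and helicity profiles, conformational
clustering, and interface fingerprints.

## What it computes

**Residue contacts.** Residues i, j are in contact when ≥ 5 atom pairs lie
within 4.5 Å and |i − j| > 3 (all three parameters configurable). On top of
per-frame maps: per-pair contact frequencies and the fraction of frames in
which two residue groups (e.g. the NR region, residues 1–224, and the CR
region, 225–538) touch, with population-SD error bars over replicates.

**Circuit topology.** Every pair of contacts `[i1, j1]`, `[i2, j2]` is in
series (disjoint intervals), parallel (nested; the nested member is in the
inverse-parallel relation) or cross (interleaved), so an m-contact map has
a census with `n_S + n_P + n_X = C(m, 2)`. The package computes whole-chain
censuses, the per-residue mean inverse-parallel profile (± SEM over sampled
frames — a sequestration measure), and the density of visited `(n_S,
n_P + n_X)` configurations over a trajectory.

**Ensemble metrics.** Kabsch superposition; per-residue RMSF about the
iteratively refined mean structure; dihedral-window helix assignment (with
a P-SEA-style Cα fallback for coarse-grained input), helical content with
a 30% stable-helix threshold; GROMOS neighbour-count clustering at a 0.9 nm
RMSD cutoff, with representatives selected as the smallest set of largest
clusters covering ≥ 50% of frames.

**Pose analysis.** For two-chain docking poses: interface residues,
typed interactions (hydrogen bond, salt bridge, π-cation, π-stacking, with
standard geometric windows), NR/dual/CR region-binding fractions under a
dominance rule, motif blockade/exposure calls backed by Shrake–Rupley
solvent accessibility, and pose-set summaries such as the fraction of poses
blocking the P-box or the FQNLF motif.

**Synthetic generators.** Seeded, self-verifying generators plant ground
truth for every stage: contact scaffolds with exact planted contact sets,
Gaussian-fluctuation ensembles with contact schedules, ideal
helix/extended/segmented backbones, two-basin trajectories, and dimer poses
with designed interfaces. Sequence-level constructs (tract expansion,
numbering lifts such as ANTS 233–246 → 255–268) complete the toolkit.

## Worked example

The four drivers under `analysis/` run the whole workflow on synthetic
study fixtures (ensembles under `scratch/`, tables under `results/`):

```sh
Rscript analysis/01_constructs.R
Rscript analysis/02_simulate_ensembles.R
Rscript analysis/03_conformation_report.R
Rscript analysis/04_pose_report.R
```

`03_conformation_report.R` prints, per variant (wild-type-like vs
expansion-like fixtures):

```
wt:  RMSF 0.104 nm | NR-CR fraction 0.25 +/- 0.00 | mean census S/P/X 2.4/0.8/0.0  | tract inverse-parallel 0.00 (flank 0.02) | 1 clusters -> 1 representative(s)
pQe: RMSF 0.083 nm | NR-CR fraction 0.67 +/- 0.00 | mean census S/P/X 16.5/11.7/0.0 | tract inverse-parallel 1.06 (flank 0.05) | 1 clusters -> 1 representative(s)
wt backbone fixture: helical content 14.0% +/- 0.0, 14 stable-helix residues
pQe backbone fixture: helical content 22.0% +/- 0.0, 22 stable-helix residues
```

reading: the expansion-like fixture moves less (lower RMSF), keeps its two
regions in contact more of the time (0.67 vs 0.25), carries a denser,
more nested contact network (higher P counts), shows the inverse-parallel
peak inside the planted tract, and has higher helical content — each
number recomputed from the trajectory frames by the package, with the
planted design as ground truth. `04_pose_report.R` prints the pose-set
contrasts:

```
wt_partner (12 poses): NR/dual/CR = 0.00/0.00/1.00 | P-box blockade 0.67 | FQNLF blockade 0.00
pQe_partner (9 poses): NR/dual/CR = 0.89/0.00/0.11 | P-box blockade 0.11 | FQNLF blockade 0.00
pQe_dimer  (8 poses): NR/dual/CR = 0.62/0.00/0.38 | P-box blockade 0.00 | FQNLF blockade 0.62
```

In library code the same analyses are three calls:

```r
library(cirtop)
ens <- read_pdb("trajectory.pdb", time_ns = 25)
cm  <- residue_contacts(ens, frame = 1)          # 4.5 Å / ≥5 pairs / k = 3
topology_census(cm)                              # S / P / X counts
local_inverse_parallel_profile(ens)              # sequestration profile
```

See `vignettes/circuit-topology-ensembles.Rmd` for the methods: every
criterion, threshold and tie-break, what the synthetic generators emulate,
and the package's design decisions.

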