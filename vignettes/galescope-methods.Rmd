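---
title: "Methods: structural comparison and two-pocket specificity prediction for GalE homologs"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: structural comparison and two-pocket specificity prediction for GalE homologs}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(galescope)
```

This vignette documents the models, geometric criteria, numerical choices
and limitations behind each analysis stage. Statements about behaviour are
backed by the test suite and `scripts/acceptance.R`; nothing here reports a
number the shipped code does not itself compute.

## Scientific background and scope

UDP-glucose 4-epimerase (GalE) epimerizes the C4 position of UDP-linked
hexoses through an NAD⁺-mediated oxidation/rotation/reduction cycle. The
enzyme's substrate range — UDP-Glc/Gal only (group 1), both the hydroxy and
N-acetyl series (group 2), or preferentially the N-acetyl series (group 3)
— is strongly associated with two active-site subsites, named here for the
sugar atoms whose substituents they accommodate in the standard binding
conformation: the C2 pocket (position 200 in *B. longum* GalE numbering,
an Asn in groups 1b/2, His-like in 1a, Ala in 3) and the C5 pocket
(position 299, Cys/Ser in groups 2/3, Tyr/Leu in group 1). The package
implements the measurements that support this model and the categorical
classifier built on it. Out of scope by design: crystallographic data
processing and refinement, homology-model construction, solvation-energy
(ΔG) models of interfaces, quantitative activity prediction, and the
quantum chemistry of the hydride-transfer mechanism itself.

## Superposition

`kabsch_fit()` solves the least-squares rigid-body problem by SVD of the
3×3 covariance of the centered paired coordinates. When the optimal
orthogonal map is a reflection (negative determinant) the smallest
singular axis is sign-flipped, the standard correction that constrains the
result to a proper rotation. Degenerate inputs (fewer than three pairs, or
collinear points, detected by a second singular value below 1e-8 of the
largest) are errors, not silent results.

Residue pairing is alignment-driven (`pair_calpha_by_alignment()`):
one pair per aligned non-gap column in which both residues have a Cα.
Author numbering is never used for pairing because it differs across
homologs (the catalytic Tyr is 150 in the *B. longum* enzyme, 157 in the
human one, 149 in the *E. coli* one).

`trimmed_superpose()` implements the distance-cutoff variant used for
cross-homolog comparisons: fit, recompute per-pair deviations, drop all
pairs above the cutoff (default 2.0 Å), repeat until the retained set is
stable. Dropping all over-cutoff pairs per round (rather than one at a
time) was chosen because it converges in a handful of iterations and is
the common practice in structure-comparison software; only the cutoff
value itself is prescribed by the comparison convention. `max_iter`
defaults to 20; non-convergence is a warning carrying the last fit, not an
error. Results are reported as RMSD plus the retained-pair count (the
"0.69 Å (306 a.a.)" style), because the count depends mildly on the
pairing alignment and trimming schedule and should always be stated
alongside the RMSD.

Correctness is checked against two independent references: a brute-force
rotation-space search (random multi-start plus shrinking axis-angle
refinement, no SVD) that must agree within 0.1 Å, and dominance over 1,000
random proper rotations.

## Active-site geometry

All criteria operate on heavy atoms only; the crystal structures this
pipeline targets carry no hydrogens, and any hydrogens present are ignored.

- **Hydrogen bonds** (`detect_hbonds()`): donor–acceptor heavy-atom pairs
  (N/O/S) within `dmax` = 3.5 Å by default, with donor/acceptor capability
  assigned by residue chemistry (backbone N donates, backbone O accepts,
  side-chain tables for the polar residues; het-group N/O/S are treated as
  both, since protonation states of ligands are not modelled). No angular
  term is applied — without hydrogens an angle criterion would be guessed
  geometry, and the plain 3.5 Å heavy-atom cutoff is standard
  crystallographic practice.
- **Salt bridges** (`detect_salt_bridges()`): Lys NZ, Arg NE/NH1/NH2,
  His ND1/NE2 versus Asp OD1/OD2, Glu OE1/OE2, C-terminal OXT and
  phosphate-type het oxygens (O1A-style names), within 4.0 Å.
- **Catalytic C4–C4** (`catalytic_c4c4()`): distance between the sugar C4
  and the nicotinamide C4 — the hydride donor/acceptor pair. The
  productive-mode range defaults to [3.0, 3.7] Å with *inclusive* bounds:
  the literature convention writes the range without open/closed
  qualification, and a distance sitting exactly on a bound should not be
  called non-productive by a representation detail. Ligand identity is
  configured through a role map (`ligand_roles()`) rather than hard-coded
  het codes, because chemical-component dictionaries use different codes
  and atom-name conventions for UDP-glucose versus UDP-GlcNAc.
- **Ring face** (`ring_face()`): the nicotinamide plane normal is defined
  by the right-handed sum of consecutive cross-products of the ring atoms
  taken in dictionary order (N1, C2, C3, C4, C5, C6) about their centroid;
  the positive-normal side is declared the pro-S (B) face. A sugar C4 on
  the pro-S side is the "standard" conformation, the opposite side
  "flipped". This triple-product convention makes the call deterministic,
  invariant under proper rigid motion, and sign-inverting under
  reflection — all three properties are asserted in the tests.
- **Asn swing** (`classify_c2_swing()`): the C2-pocket Asn is called
  "swing in" when its carboxamide centroid (OD1/ND2 midpoint) lies within
  a threshold distance of the C2-substituent pocket center (by default the
  sugar's C2 substituent atom), "swing out" beyond it. χ1 and χ2 are
  reported for transparency but do not drive the call: the distance is the
  property of interest (is the pocket occupied by the side chain or
  vacated?) and is robust to backbone-numbering and rotamer-library
  differences across homologs. The published descriptions of the two
  conformers are figure-level, not geometric, so the threshold (default
  5.0 Å) is a reconstruction; it must be calibrated on reference complexes
  when deposited coordinates are available, and the package therefore
  exposes it as a parameter and records it in every result object.

Distances are carried at full precision and printed to one decimal, the
same precision as the comparative literature.

## Surface area and interface burial

`shrake_rupley_sasa()` is the classic sphere-point algorithm with one
deliberate change: the sample points come from a deterministic
golden-angle spiral, not an RNG, so areas are bit-reproducible and the
convergence study (96 → 960 → 9600 points) is meaningful. Defaults: probe
1.4 Å (water-sized), 960 points (single-sphere error < 1% against the
analytic 4π(r+probe)²; the relative change from 960 to 9600 points is
under 0.5% on cluster fixtures). Van der Waals radii are a single
element-keyed table (C 1.70, N 1.55, O 1.52, S 1.80, P 1.80, Mg 1.73, …),
config-overridable since interface-analysis servers do not publish their
exact tables.

`interface_report()` computes SASA for each isolated protomer and the
assembly. Because the "interface area" convention differs between tools —
total area lost over both protomers versus the half-sum — both
`buried_total` = SASA(A)+SASA(B)−SASA(AB) and `buried_half` =
`buried_total`/2 are always reported, and any comparison against published
numbers should state which convention reproduced them. Waters are always
excluded; other het groups are excluded by default (`include_het`).
Interface contacts reuse the geometric detectors above, restricted to
inter-chain pairs; contact counts carry their criteria with them and are
not expected to equal counts produced by other software's criteria.
The two-sphere case has a closed form (`two_sphere_sasa_exact()`, the
spherical-cap formula) which serves as the independent oracle.

## Sequences, maps, trees

Global alignment is Needleman–Wunsch with affine gaps via Biostrings,
defaults BLOSUM62 / gap open 10 / gap extend 0.5 — conventional protein
parameters, exposed because no alignment method is canonical for published
percent identities; results record their parameters. Percent identity
defaults to the non-gap aligned-column denominator (alternatives
selectable). Residue maps are derived only from non-gap columns, so a
functional position deleted in a homolog is reported absent rather than
silently shifted. Protein masses use average residue masses plus one
water. Distance matrices are 1 − fractional identity (matching a
"percent divergence" scale) with an optional Kimura correction
(−ln(1 − p − 0.2p²)) for multiple substitutions; trees are standard
neighbor joining (ape), exact on additive matrices, with negative branch
estimates clamped to zero under a warning. Sequences for deposited
structures should come from SEQRES/entity records, not ATOM records,
because unmodelled loops would corrupt identities.

## The two-pocket classifier

`classify_group()` is a transparent rule cascade on the C2/C5 residue
identities, with the C5 pocket primary:

1. C5 bulky (Tyr, Phe, Leu, Ile, Met, Trp, His) → group 1
   (Glc/Gal preferring); subgroup by C2: His-like large → 1a, Asn → 1b,
   otherwise unresolved. A phylogenetic clade assignment, when supplied,
   overrides the subgroup — the 1a/1b split is defined by tree separation,
   not pocket chemistry.
2. C5 small (Cys, Ser, Gly, Ala, Thr) and C2 = Asn → group 2 (dual).
3. C5 small and C2 small (Ala, Gly, Ser) → group 3 (GlcNAc/GalNAc
   preferring).
4. Anything else → unknown (a valid outcome, never an error).

The size classes extend the experimentally anchored residues (Cys/Ser
small; Tyr/Leu/His large) to the remaining amino acids by side-chain
volume; the tables are package constants and the profile source
(structure / sequence / model) is recorded in every profile. Known
ambiguity, stated rather than hidden: group 1b and group 2 both carry Asn
at C2, so an (Asn, small-C5) profile is reported as group 2 with an
explicit caveat in the rule trace — pocket identity alone cannot exclude a
hypothetical 1b-like enzyme with a small C5 residue. The classifier is
purely categorical; activity magnitudes are out of scope, and measured
activities serve only as ground-truth labels in the tests. Every
prediction carries its ordered rule trace, and the invariant that only a
C5 change can move a profile across the group-1 boundary is asserted over
all 20 amino acids at C2.

`mutate_and_reclassify()` applies an in-silico point swap at either pocket
and re-runs the cascade, reproducing the direction of the published
specificity-switching mutants (C5 Tyr→Cys gains the N-acetyl series,
C5 Cys→Tyr loses it).

## Synthetic data: what it emulates, and what it does not

The generators produce every fixture the tests need, with the ground truth
recorded in a manifest so oracles never peek at generator internals:

- `make_rotated_copy()` — known rotation/translation, optional Gaussian
  noise and planted fixed-magnitude outliers; the manifest stores the
  realized coordinates, making RMSD oracles exact for the realization,
  not just in expectation.
- `make_toy_complex()` — idealized planar "nicotinamide" and
  "pyranose" rings (1.4–1.5 Å bonds) with the C4–C4 distance, ring face,
  Tyr OH–O4 distance and Asn rotamer planted exactly. The geometry
  operations read only atom names and coordinates, so chemical idealization
  is harmless to what is being tested.
- `make_dimer_spheres()` — one-atom protomers reduce interface burial to
  the spherical-cap closed form; cluster protomers are cross-checked
  against an independent Monte-Carlo area estimator.
- `make_sequence_family()` — a root sequence evolved down a given tree
  under a Poisson process with uniform replacement over the 20 residues
  (a fraction 1/20 of events is silent), so branch lengths match expected
  divergence and realized event counts are recorded per edge.

Reproducibility contract: identical generator arguments and seed give
byte-identical fixtures. The generators use R's Mersenne–Twister through a
seed-scoped helper that restores the caller's RNG state; a
language-independent RNG was considered and rejected as needless
complexity for a single-language package — the testable invariant is
bit-reproducibility within R, which this provides.

What the synthetic fixtures deliberately do **not** emulate: real protein
folds and packing, rotamer libraries, crystallographic symmetry, missing
loops and alternate conformations beyond simple altloc records, or
BLOSUM-structured substitution preferences. Green synthetic tests
therefore demonstrate algorithmic correctness (against oracles and planted
truth), not agreement with any particular deposited structure; the
reproduction tests in `test-acceptance.R` cover the latter and require the
user to download the deposited entries listed in
`tests/testthat/deposited/README.md`.

## Pipeline and reporting

`run_report()` validates its configuration against the schema before any
computation, then runs alignment → mapping → profiling/classification →
superpositions → active-site geometry → interface → identity matrix →
tree, isolating failures per subject as error records. The JSON report
embeds a provenance block (package version, effective options, timestamp)
so every number in it can be traced to its parameters. Reports are
deterministic apart from the timestamp: all sampling in the pipeline is
either deterministic (golden-spiral SASA) or seeded.

Problem sizes used by the shipped tests and acceptance script — chosen as
comfortable desk-scale sizes for the synthetic study conditions — are:
20–50-point clouds for superposition oracles (20 seeded fixtures, 1,000
random-rotation dominance draws), 25 Cα pairs with 5 planted 5 Å outliers
for trimming recovery, 960-point SASA sampling (9,600 for the convergence
check), 4–6-taxon trees with 600-site simulated families, and a
2,000-site pair at 5% divergence for the identity expectation.

## Known limitations

- The swing-in/swing-out threshold is a geometric reconstruction of a
  figure-level description; calibrate on reference complexes before
  relying on calls for borderline conformers.
- Percent identities depend on alignment parameters; reproduction of
  published identity values to better than about one percentage point
  should not be expected without recording the original program's
  parameters.
- The pro-S face assignment is a fixed ring-ordering convention; it is
  self-consistent and reflection-sensitive, but mapping it onto the
  crystallographic A/B-face nomenclature for a particular cofactor model
  should be verified once against a known-annotation structure.
- `interface_report()` expects the biological dimer as an explicit
  two-chain file; symmetry expansion from crystallographic operators is
  intentionally outside the package.
- Group 1b versus group 2 cannot be separated from pocket identity alone
  when C2 is Asn; the rule trace says so explicitly, and a phylogenetic
  tree is the intended tie-breaker for the 1a/1b subgroup split.
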