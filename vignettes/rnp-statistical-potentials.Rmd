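---
title: "Coarse-grained statistical potentials for protein-RNA docking"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Coarse-grained statistical potentials for protein-RNA docking}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(rnpscore)
```

## The scoring problem

Rigid-body docking of a protein and an RNA produces thousands of
candidate poses (decoys), almost all of them wrong.  A scoring function
must rank near-native poses (ligand RMSD below ~10 Å after receptor
superposition) ahead of the rest.  `rnpscore` implements a
medium-resolution, knowledge-based answer: interaction statistics are
harvested from a training set of protein-RNA complexes in a
coarse-grained representation and inverted into energies by reverse
Boltzmann statistics,

$$\varepsilon(i, j, d) \;=\; -RT \,\ln
  \frac{N_{\mathrm{obs}}(i, j, d)}{N_{\mathrm{exp}}(i, j, d)},$$

where $N_{\mathrm{obs}}$ counts contacts between protein bead type $i$
and RNA bead type $j$ in bin $d$, and $N_{\mathrm{exp}}$ is the count
expected under a reference state with no specific interactions.
Enriched contacts score favourably (negative); depleted ones pay a
penalty.

## Representation

Amino acids are reduced to one to three united atoms: the alpha carbon
(CA), a proximal side-chain centroid (SC1, atoms out to the gamma
layer) and, for the thirteen largest residues, a distal centroid (SC2).
Glycine keeps only CA; alanine, serine, cysteine, threonine, valine and
proline keep CA + SC1.  Each (residue, role) pair is its own
interaction type — an alanine CA and a lysine CA are different types —
giving 52 protein types.  Nucleotides contribute a phosphate-group
centroid (P), a ribose centroid (RIB) and base-ring centroids: one for
pyrimidines (PYR), two for purines (PUR5, PUR6), giving 14 RNA types.
Post-transcriptionally modified nucleotides are mapped to their parent
base (a built-in lookup covering pseudouridine, methylated bases,
inosine and others; unknown codes fall back to a ring-atom census, and
MODRES annotations override that inference).  Hydrogens are ignored
throughout.

The exact atom membership of SC1/SC2 is this package's convention,
kept in a single editable table (`rnpscore:::.protein_bead_atoms`):
published descriptions of comparable reduced representations fix only
the bead *count* per residue, not the partition.

## The four energy terms

Scores sum four equally weighted terms over all protein-RNA bead pairs
within 9 Å (strictly below; half-open 1 Å bins):

* **Distance term** $E_d$ — $\varepsilon$ over nine 1 Å distance bins.
* **Angle term** $E_a$ — the angle between the RNA bead's reference
  axis and the direction to the protein bead, in nine 20° bins (the
  last bin closed so 180° is representable).  Base beads use the
  oriented base-plane normal as axis; backbone beads use virtual-bond
  directions (P to RIB, RIB to base).
* **Site (edge) term** $E_s$ — which face of the base the protein bead
  approaches: Watson-Crick, Hoogsteen or Sugar.  The protein bead is
  projected into the base plane and the signed angle $\varphi$ from the
  glycosidic direction assigns one of three 120° wedges (Sugar
  $[0°,120°)$, WC $[120°,240°)$, Hoogsteen $[240°,360°)$).  The wedge
  boundaries are module constants; published edge definitions are
  topological rather than metric, so an explicit angular convention is
  required, and only base-ring beads (PYR, PUR6) carry edges.
* **Clash penalty** $E_p$ — $+1\,RT$ per bead pair closer than 3 Å.
  Both constants are configurable; the defaults keep $E_p$ on the same
  scale as the statistical terms on the bundled fixtures.

Equal weights are deliberate: no weight optimisation is performed
anywhere in the package.

## Two reference states

**QUASI** (quasi-chemical): the expected count factorises over the
partners' mole fractions,
$N_{\mathrm{exp}}(i,j,d) = X_i X_j N_{\mathrm{obs}}(d)$, where $X_i$ is
the fraction of protein beads of type $i$ in the training set and
$N_{\mathrm{obs}}(d)$ the total count in bin $d$.  Because the mole
fractions each sum to one, expected counts are conserved per bin — a
property the test suite asserts to $10^{-9}$.  The same construction,
with per-bin totals of the corresponding table, supplies the angle and
edge references.

**DARS** (Decoys As the Reference State): expected counts are measured
on geometric docking decoys of the training complexes — poses that
touch the receptor and avoid bead overlap, generated with no energy
model — and scaled term-wise so grand totals match the native totals.
A pose sampler stands in for an external docking program: rotations
from a 10° Euler grid, translations uniform in a 15 Å shell around the
receptor, with rejection filters for touching and clashing (200 decoys
per complex at fixture scale).  The normalisation choice (one global
scale per term rather than per-bin scales) keeps the reference's
distance profile informative — per-bin scaling would erase exactly the
geometric signal DARS is meant to capture.

A pseudocount $\alpha = 1$ (configurable) is added to both numerator
and denominator so sparsely populated cells stay finite; at fixture
scale most of the $52 \times 14 \times 9$ cells are empty.  $RT = 1$
since only rankings and correlations matter.

## Training, cross-validation, evaluation

`rnp_potential()` is the fitting function; it returns an object with
`print`, `summary`, `coef`, `predict` and `plot` methods.
Leave-one-out tables (`loo_tables()`) retrain the potential for each
complex with that complex's contacts, beads and (for DARS) reference
decoys removed, so no structure is scored by a potential that saw it.

Evaluation follows docking practice: ligand RMSD (heavy atoms, or
beads for reduced models — the mode is recorded in the result's
attribute) after Kabsch superposition of the receptors; Pearson
correlation of score against RMSD below 5/10/20 Å thresholds with
$SE = \sqrt{(1-r^2)/(n-2)}$, thresholds with fewer than three decoys
reported as undefined; the native's rank by strict inequality; and
greedy clustering of the 100 best-scored decoys at a 5 Å cutoff (the
row of the RMSD matrix with most sub-cutoff entries seeds each
cluster), with a relaxed fallback (200 decoys, 10 Å) when the primary
pass finds nothing.  Tie-breaks are fixed for determinism: the
lowest-index row seeds, clusters order by size then representative
score.

## What the synthetic data emulates — and what it does not

All tests run without downloads, on two generators.

`make_toy_complex()` builds an idealised complex: an alpha-helical
protein (2.3 Å radius, 1.5 Å rise, 100°/residue) with templated
side-chain offsets, and a gently twisted RNA helix (8°/nt, 3.0 Å rise)
with exactly planar base rings, placed at a 4-6 Å interface gap.  Two
features mimic real recognition deliberately: interface-facing helix
positions draw from an RNA-binding residue set (ARG, LYS, SER, GLN) —
real binding sites are compositionally biased the same way — and the
decoy generator can mix in perturbative near-native poses, because
benchmark decoy sets span ligand RMSDs from fractions of an Ångström to
tens.  What the toys do *not* reproduce: real secondary-structure
diversity, grooves and induced fit, sequence-dependent base
geometries, crystallographic noise.  A green test suite therefore
demonstrates the correctness and internal consistency of the machinery
and its statistical behaviour under controlled conditions, not
performance on experimental complexes.

The native-discrimination study uses 20 toy complexes (24 residues +
16 nt), DARS leave-one-out tables and 200 test decoys per complex with
a 0.15 near-native fraction — sizes chosen to keep the full pipeline
in the minutes range on one core while leaving enough contacts
(30-60 per interface) for stable statistics.

`make_planted_training_set()` provides the sharper instrument: reduced
complexes assembled from isolated contact units on a coarse grid
(spacing above twice the cutoff, so each unit contributes exactly one
contact).  Background units draw distances from the volume-element
null density $p(r) \propto r^2$ — the same marginal random geometric
placement produces, so the background is genuinely null under the DARS
reference — while one (protein type, RNA type, distance bin) cell is
enriched by a known factor.  Recovering that cell as the global
minimum of $\varepsilon_d$ under both reference states is the
package's parameter-recovery check.  The planted-cell count is set
deterministically (the planted pair's background avoids the planted
bin), so the realised enrichment stays within a few percent of the
request.

## Numerical choices and degenerate inputs

* Boundary conventions: strict `<` at the 9 Å cutoff, half-open
  distance and angle bins with 180° closed into the last angle bin.
* Base-plane normals come from a least-squares (SVD) fit, sign-aligned
  with the Newell normal of the ring atoms in canonical order — a
  deterministic orientation that rotates with the molecule, which the
  signed edge angle requires.
* Degenerate geometry fails loudly: coincident beads, protein beads
  within 0.1 Å of a base centroid, or directions perpendicular to the
  base plane raise errors rather than returning arbitrary sectors.
* Kabsch superposition refuses fewer than three or collinear points;
  the proper-rotation branch guards against reflections.
* The decoy clash filter is adaptive by default: decoys may not pack
  any bead pair tighter than the native complex does (capped at 95% of
  the cutoff).  A fixed bead-centre threshold is physically
  meaningless across complexes — centroid beads hide atom-level
  interpenetration — and docking programs likewise need per-complex
  repulsion tuning to keep decoys realistic.  Pass an explicit
  `clash_distance` to override.
* Potential tables serialise to TSV with 17 significant digits plus a
  JSON header, and round-trip bit-exactly.

## Worked example

```{r example}
natives <- lapply(1:5, function(s) {
  s3 <- make_toy_complex(14, 10, seed = s)
  reduce_complex(s3, receptor_chains = "A", ligand_chains = "B")
})
names(natives) <- vapply(natives, `[[`, character(1), "id")

fit <- rnp_potential(natives, reference = "quasi")
fit

predict(fit, natives[[1]])

dec <- generate_decoys(natives[[1]], 50, seed = 9,
                       near_native_fraction = 0.2)
scores <- predict(fit, lapply(seq_len(dec$n), decoy_complex,
                              decoys = dec))$E
correlation_report(scores, dec$ligand_rmsds,
                   native_score = predict(fit, natives[[1]])$E)
```

## Known limitations

* Trained tables are only as good as their training set; the bundled
  generators are validation scaffolds, not substitutes for curated
  complexes.  To train on real structures, point the CLI `train`
  subcommand (or `read_pdb()` + `reduce_complex()`) at a directory of
  PDB files.
* Rigid-body throughout: no side-chain repacking, no RNA flexibility.
* The SC1/SC2 partition, the angle-axis definitions and the edge wedge
  boundaries are explicit package conventions (single tables/constants)
  and can be re-parameterised without touching the statistics code.
* One angle is counted per contact (RNA-side axis only), and all three
  statistical terms share the single 9 Å contact set.
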