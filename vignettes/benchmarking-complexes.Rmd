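---
title: "Benchmarking macromolecular complex predictions with qsbench"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Benchmarking macromolecular complex predictions with qsbench}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(qsbench)
```

## The problem

Comparing a predicted macromolecular complex against an experimental
reference requires, before any score can be computed, a one-to-one
correspondence between equivalent components: polymer chains must be
mapped within groups of chemically identical chains, and small-molecule
ligands must be identified by their chemistry rather than their names.
`qsbench` implements this pipeline end to end: structure input and
cleanup, sequence-based chain grouping, chain-mapping search (QSMap /
QSMapR), a reference LDDT implementation, quaternary-structure and
interface scores, and symmetry-corrected ligand scores. Everything is
deterministic: no step uses random numbers, so identical inputs give
byte-identical reports.

## Preprocessing

Structures are accepted in PDBx/mmCIF or legacy PDB format. Before
polymer scoring, a cleanup step (i) removes hydrogens, terminal OXT
atoms and atoms whose names are not part of the component dictionary,
(ii) replaces nonstandard residues by their parent residue (SEP becomes
SER, with atoms absent from the parent dropped), (iii) removes residues
without a dictionary entry, and (iv) drops chains shorter than 6
residues (peptides) or 4 residues (nucleotides), which are too short for
a reliable sequence-identity decision. Receptor structures used for
ligand scoring keep their nonstandard residues, because a phosphorylated
serine in a binding site is chemically meaningful there.

Decisions the file formats leave open are resolved deterministically:
for alternate conformations the highest-occupancy conformer is kept
(ties break alphabetically), only the first model of a multi-model PDB
file is used, residue identity is the (number, insertion code) pair, and
chains without entity records are typed nucleotide when at least half of
their classifiable residues are nucleotides. Zero-occupancy atoms are
kept: only the removals listed above are applied.

The bundled component dictionary is a curated plain-text subset
(standard amino acids, RNA/DNA nucleotides, SEP/TPO/MSE with parent
annotations, and a few small compounds used by the generator). A larger
dictionary with the same three tables can be supplied via
`ccd_dictionary(path)`.

## Chain grouping

Groups of chemically equivalent chains are established on the reference:
protein and nucleotide chains are separated, pairwise global alignments
(Needleman–Wunsch; BLOSUM62 for proteins with gap costs 11/1, an
embedded NUC44-style matrix for nucleotides with gap costs 5/2) give
sequence identities, and single-linkage clustering at 95% identity
defines the groups. Identity is counted over aligned (non-gap) column
pairs, which makes it insensitive to terminal gaps; both the linkage and
the denominator are implementation choices the identity criterion itself
does not fix, and both are deliberately the simplest deterministic ones.
When mmCIF entity records are available they define the groups directly,
and entities sharing one canonical sequence are merged — this rescues
references in which several chains cover nonoverlapping fragments of the
same target and sequence identity alone would split them.

Model chains are then assigned to the group of maximal identity against
the group representative, accepted at a relaxed 70% threshold so that
homologous models still map; the threshold can be changed or removed
(`identity_threshold = NULL`), at the cost of possibly assigning
unrelated chains. In CASP/CAMEO-style settings where models are numbered
according to the target sequence, `alignment_params(mode =
"residue_number")` pairs residues by author numbering and skips the
alignment entirely; this is the recommended mode whenever the numbering
convention is guaranteed.

## Chain mapping

QSMap optimises the QS-score; when nucleotides are involved it switches
to backbone LDDT (CA for peptides, C3' for nucleotides) with the
inclusion radius raised to 30 Å, because nucleotide backbones are too
widely spaced for the 15 Å default to capture the relevant distances.
QSMapR optimises the backbone RMSD over multiple-alignment columns
shared by every chain of a group, subsampled to 50 equidistant columns;
its per-group alignment is built by aligning each member to the group
representative, a choice that keeps the construction deterministic and
cheap.

Both scores are pairwise decomposable, so all per-chain and
per-chain-pair score contributions are cached once and shared between
the exhaustive and greedy searches. Problems whose group-respecting
mapping count does not exceed `8!` (QSMap) or `5!` (QSMapR, where the
N³ superpositions of the greedy search only beat `N!` enumeration above
N = 5) are enumerated exhaustively; larger ones use a greedy extension
seeded from every compatible reference/model chain pair. At each step
only "accessible" chains are considered: for the QS-score objective a
chain must bring a representative position (CB, CA for glycine) within
12 Å of a mapped chain and at least three inter-residue contacts at
8 Å; for the LDDT objective the reference threshold is the inclusion
radius and the model threshold the radius plus the maximal distance
deviation (4 Å). A stalled extension (disconnected complexes) is
re-seeded with every remaining pair and the best-scoring completion is
kept, so the final mapping is always complete. Score ties during
extension and between seeds break lexicographically on chain
identifiers, making the search deterministic. A swap-refinement step was
evaluated for this family of algorithms and found not to improve mapping
accuracy, so it is not part of the search.

Problem sizes in this package's own test panels run to 20-chain
homomers, which the greedy search completes in minutes on one CPU core;
the exhaustive branch is used up to the stated factorial limits.

## LDDT

The LDDT engine builds the contact table from the reference only: all
heavy-atom pairs within the inclusion radius (15 Å default), excluding
pairs within one residue. A contact is preserved when the model
reproduces its distance within a threshold; the score averages the
preserved fractions over the thresholds 0.5, 1, 2 and 4 Å. Contacts
whose model atoms are missing count as unpreserved, extra model atoms
are invisible to classical LDDT (the ligand score below differs here),
and an empty contact table yields a distinct not-computable result
rather than 0. The backbone variant keeps only CA/C3' representatives;
the interface variant keeps only cross-chain contacts, so the interface
LDDT of a monomer is not computable.

Residue naming ambiguities (ASP OD1/OD2, GLU OE1/OE2, ARG NH1/NH2,
PHE/TYR ring carbons, nucleotide OP1/OP2) are resolved per residue: each
permitted permutation is evaluated against that residue's contacts and
the best is kept, greedily in residue order. A global optimisation over
all residues simultaneously would be exponential; the greedy choice can
in principle be suboptimal when two symmetric residues share many
contacts, which is rare enough that the deterministic greedy pass is the
better trade.

Stereochemistry checks are available (`stereo_checks`): bonds and angles
deviating by more than 12 standard deviations from a bundled restraint
table (curated standard values for peptide and nucleotide backbones) are
flagged; side-chain violations remove the side chain, backbone
violations the whole residue, and steric clashes (non-bonded atoms from
different residues closer than the sum of covalent radii minus 0.4 Å)
remove the clashing atoms. Removed atoms make their reference contacts
score as unpreserved. The checks default to off in the programmatic API
and are opt-in per run.

## Quaternary-structure and interface scores

The QS-score compares interface contacts: residue pairs from different
chains whose representative positions lie within 12 Å. A contact found
in both structures contributes a weight that decays linearly with the
distance discrepancy, `w = max(0, 1 - |d_ref - d_mdl| / 12)`; the exact
weight shape is an implementation choice documented here and pinned by
the test suite. `qs_global` divides by the union of contacts in either
structure and is symmetric under swapping model and reference — an
incomplete reference therefore penalises it. `qs_best` restricts the
denominator to contacts among residues resolved in both structures and
is the variant to use when model and reference are assumed to share
stoichiometry and coverage; by the same token it does not penalise
incomplete models.

ICS is the F1 score of interface contact sets (any heavy-atom pair under
5 Å between residues of different chains, the CASP convention; the
criterion is configurable), with model contacts translated into
reference residue space; IPS is the Jaccard similarity of interface
residue sets. Trimmed variants remove model residues without a reference
counterpart before collecting contacts. Full-complex values pool all
contacts rather than averaging per-interface scores — per-interface
values are reported separately, and pooling is the deliberate choice
because any aggregation weighting would be arbitrary.

DockQ follows the published combination
`(fnat + 1/(1+(iRMSD/1.5)^2) + 1/(1+(LRMSD/8.5)^2))/3` with fnat
contacts at 5 Å, the interface at 10 Å, and backbone N/CA/C/O atoms; the
CAPRI peptide parameterisation (4 Å contacts, 8 Å interface measured on
CA positions) is enabled per run. In hetero interfaces the larger chain
acts as receptor, a convention the per-interface report records.
DockQ-ave and DockQ-wave aggregate per-interface values unweighted and
weighted by reference contact count respectively; the weighted variant
down-weights small interfaces, which can be exactly the wrong emphasis
when a small interface carries the topology, so both are reported.

GDT iterates superpose/extend cycles from sliding windows of sizes 7, 9,
12, 24 and 48 (up to 1000 equidistant placements each, floor-rounded
start indices) and reports, per threshold, the largest subset of
reference representative positions superposable within the threshold,
divided by all reference positions — incomplete models therefore lose
score. GDT_TS averages thresholds 1/2/4/8 Å, GDT_HA 0.5/1/2/4 Å, both on
a 0–1 scale. The backbone RMSD uses the Kabsch superposition over all
mapped representative positions. For oligomers both use the QSMapR
mapping.

## Ligand scores

Ligands are molecular graphs with element-labelled atoms; connectivity
comes from an SDF file when available, else from the component
dictionary, else from a van-der-Waals distance heuristic (bond when the
distance is below 0.6 times the sum of vdW radii — a last-resort rule).
Matching enumerates all graph isomorphisms, which captures chemical
symmetries such as the 12 automorphisms of a benzene ring. An incomplete
reference (missing density) may match as a subgraph of the model when
`substructure_match` is on — only in that direction, so incomplete
models never match complete references; coverage (reference atoms over
model atoms) is carried into the assignment step.

BiSyRMSD superposes the reference binding site (residues with any heavy
atom within 4 Å of the ligand, defined on the reference only) onto the
model — via CA/C3' atoms, or all backbone atoms when the site has two or
fewer residues — and reports the minimal ligand RMSD over all chain
mappings of the site (model chains collected with a lenient 25 Å rule
and grouped as for chain mapping) and all symmetry correspondences.
RMSD-LP is the site backbone RMSD of the reported mapping; LDDT-LP the
all-atom LDDT over the site residues (0 for a single-residue site by
definition). A ligand whose site is empty — an ion coordinated only by
another ligand, say — yields an explicit not-computable result with a
reason, never a sentinel number; raising the site radius is the
documented workaround.

LDDT-PLI scores polymer–ligand distances with a 6 Å inclusion radius and
the standard thresholds. Its distinctive feature is that model-side
contacts are added to the assessed set when both atoms can be mapped to
the reference, so contact overprediction is penalised; contacts from
model chains with no reference counterpart borrow the chemically
equivalent reference chain closest to the reference ligand (centre of
mass) — frames are never superposed in an LDDT, so "closest" is
measured in the reference frame. Chain mappings, ligand symmetries and
polymer residue symmetries are enumerated jointly (state count capped at
1e5 with a warning) and the best score is reported. No stereochemistry
checks apply here.

Assignments between reference and model ligands are greedy one-to-one:
iteratively take the best-scoring matching pair, restricted in each
iteration to pairs with coverage above the current maximum minus 0.2,
which discourages a solvent fragment in the reference from claiming a
large model ligand. Assignments are computed independently for BiSyRMSD
(lowest first) and LDDT-PLI (highest first) and may legitimately
disagree. Ties prefer higher coverage, then lexicographic ligand
identifiers.

## The synthetic generator, and what passing tests show

`make_complex()` builds helix-like chains on parametric curves, placed
on a ring so that adjacent chains form interfaces, with identical
sequences within each stoichiometry group; models derive from the
reference by per-chain rigid perturbations, per-atom Gaussian noise,
chain relabeling, an optional domain-hinge rotation and a global rigid
transform. `make_ideal_peptide()`/`make_ideal_nucleotide()` build chains
whose checked bonds and angles are exact, for stereochemistry tests;
`make_ligand()` provides ring, linear, ion and disconnected-fragment
templates. Identical seeds give identical structures, and the PDB and
mmCIF encodings decode to the same coordinates.

These fixtures exercise every code path with known ground truth, but
they are not real data: side chains beyond CB are absent from the
generated polymers (so full-atom LDDT on fixtures is effectively
backbone+CB), local geometry is only plausible rather than ideal outside
the dedicated stereo fixtures, and the noise model is isotropic Gaussian
rather than the correlated errors of real predictions. Passing tests
therefore demonstrate the correctness of the algorithms and their
invariants — oracle equality, symmetry absorption, definitional
orderings — not the scores' empirical behaviour on experimental
structures.

Test panel sizes (20 self-comparison fixtures, 100 mapping fixtures at
3–6 chains, 50 LDDT oracle fixtures, homomers to 20 chains) were chosen
as the smallest panels that cover every branch of the search and scoring
code; the acceptance script reruns the same computations at reduced
count.

## Known limitations

Peptide and oligosaccharide ligands are out of scope, as is any
biological-relevance filtering of ligands — every ligand present is
assessed. TM-score and CAD-score belong to external tools and are not
reimplemented. The greedy per-residue symmetry resolution and the capped
LDDT-PLI state enumeration are documented approximations; both report
deterministic results. Structure validation beyond the stereochemistry
filter is not included.
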