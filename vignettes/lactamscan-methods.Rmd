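---
title: "Methods: structure-guided screening for beta-lactam-forming thioesterase domains"
author: "lactamscan"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: structure-guided screening for beta-lactam-forming thioesterase domains}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(lactamscan)
```

## The screening problem

Most nonribosomal peptide synthetase (NRPS) assembly lines end in a
thioesterase (TE) domain that hydrolyses or macrocyclizes the finished
peptide.  In the sulfazecin synthetase SulM the terminal TE domain instead
closes a four-membered beta-lactam ring: the sulfonated beta-amine of the
C-terminal 2,3-diaminopropionate (DAP) residue attacks its own thioester.
Domains capable of this chemistry carry a recognizable constellation of
features:

1. a **cysteine** nucleophile housed in a **Gln-Cys-Asn** motif, with the
   catalytic-triad aspartate relocated to the loop *after strand beta-7*
   ("position II") rather than the loop after beta-6 ("position I") found
   in nearly all other NRPS TE domains;
2. a **cationic active-site wall** (reference residues Arg2849, Lys2854,
   Arg2858) that accommodates the sulfamate of the substrate;
3. a **DAP-specific specificity code** in the adenylation (A) domain of
   the last module, since DAP supplies the ring nitrogen;
4. a **sulfotransferase gene** in the same cluster, since N-sulfonation
   precedes ring closure.

`lactamscan` turns these four observations into a screening pipeline over
user-supplied proteins and gene clusters, plus the structural measurements
(superposition RMSD, buried interface area, helix angles, triad geometry)
used to establish the features in the first place.

## Anchoring model

Every sequence-level decision is made in the *reference coordinate frame*.
A candidate protein is locally aligned to the reference TE domain
(BLOSUM62, affine gaps costing `11 + L` for a gap of length `L`), and
reference author numbers (Cys2818, Asp2926, ...) are transferred onto the
query through the alignment columns (`mapPositions()`).  A reference
position aligned to a query gap is "unaligned" and counts against the
criterion that needs it.  The alternative - secondary-structure prediction
on the query to locate position I/II directly - was rejected: at sequence
level the alignment frame is far more robust, and it is how the
position-II assignment is argued structurally (by alignment to a solved
reference) in the first place.

The position-I/II call is therefore window-based: the acid is "position
II" when the residue aligned to reference 2926 (post-beta-7 loop,
2923-2946) is Asp/Glu, "position I" when an Asp/Glu instead anchors in the
window following strand beta-6 (reference frame 2838-2852), and
"undetermined" otherwise.

### Tunable parameters

| parameter | default | units | rationale |
|---|---|---|---|
| substitution matrix | BLOSUM62 | - | standard for 20-40% identity screening |
| `gapOpen` / `gapExtend` | 11 / 1 | score units | the conventional BLOSUM62 pairing |
| `teScoreMin`, `aScoreMin`, `sulfoScoreMin` | 200 | score units | a true 262-residue TE hit scores >1000 even at 5% mutation; unrelated 300-3000 residue proteins score < 100 locally |
| `similarityMin` | 70 | % columns | partition threshold separating close reference homologs from divergent candidates; similarity = fraction of local-alignment columns identical or scoring > 0 |
| `cationicMin` | 2 of 3 | residues | two basic residues suffice for a cationic pocket |
| `codeMatchMin` | 8 of 10 | residues | specificity codes of identical substrates typically differ at <= 2 positions |
| `criteriaMin` | 4 | criteria | a candidate must satisfy the full feature set |
| `strictCys` | TRUE | - | the beta-lactam chemistry is tied to a cysteine nucleophile; set FALSE to admit serine |

## The synthetic reference

The natural SulM sequence is not redistributable inside this package, so
the anchor frame is built on a **synthetic stand-in**
(`referenceSulM()`, and `inst/extdata/sulm_te_reference_synthetic.fasta`):
a deterministic pseudo-random 2984-residue protein carrying the documented
residues at the documented author positions (Gln2817-Cys2818-Asn2819,
Asp2926, His2956, Arg2849/Lys2854/Arg2858, lid loop 2844-2918, post-beta-7
loop 2923-2946, carrier serine Ser2688 inside a `GGDSL` motif), a module-3
A domain whose ten specificity-code positions follow the classic
GrsA-frame offsets, and a synthetic sulfotransferase.  The DAP entry of
the code table is self-extracted from this reference; the decoy substrate
codes are synthetic and differ from it at >= 5 positions.

This choice fixes what the test suite can and cannot show.  Everything
positional - anchoring, mapping, criterion logic, verdict aggregation,
tree building, every coordinate-level computation - is exercised exactly
as it would be on real data, because those computations never consult
anything but residue identities at anchored positions.  What the synthetic
frame cannot certify is performance on *natural* sequence divergence:
real TE families drift with biased substitution patterns and structural
constraints that a uniform mutation model does not emulate.  Classifier
sensitivity/specificity numbers reported by the acceptance script are
therefore statements about the planted-feature model, not field
performance.

## Synthetic data generation

Generators are seeded and bit-reproducible, and never disturb the global
RNG (`withSeed()`).  Two rules keep ground truth exact:

* planted edits are applied **before** random mutation and the edited
  positions are immune to it;
* indels are never placed within 2 residues of a protected position, so
  the recorded original-to-mutated position map stays valid at the
  anchors.

Default study conditions: point-mutation rate 0.05 and indel rate 0.005
for the "noisy" panels (a level at which local alignment is still
unambiguous but ~25 residues of a TE domain have changed), panel size 200
clusters with independently drawn feature flags (motif, DAP code and
sulfotransferase present with probability 1/2; acid position II with
probability 1/2, else I or none; cationic count uniform on 0-3; annotated
sulfotransferase half the time), one random decoy gene per cluster.
Cluster genes: one full-length NRPS (the 2984-residue reference variant),
an optional ~300-residue sulfotransferase, decoys of 250-350 residues.

## Phylogeny

Distances are `1 - identity` over global-alignment columns (a
Jukes-Cantor-style correction is available but off by default - with no
stated model, the uncorrected distance is the most transparent choice).
Trees are Saitou-Nei neighbor joining; negative branch lengths, which NJ
can produce on non-additive matrices, are clamped to zero with the deficit
moved onto the sibling branch so the path length between the joined pair
is preserved.  Newick output quotes labels containing metacharacters.

The bundled demo set (`demoTESet()`) contains four position-II variants
near the reference, four position-I variants descending from a common
strongly diverged ancestor (35% mutated, acid moved, motif ablated), and a
random outgroup; the two groups are monophyletic in the resulting tree,
which is the desk-scale analogue of the observation that
beta-lactam/lactone-forming TE domains cluster with type-II editing
thioesterases away from canonical NRPS TE domains.

## Structural metrics

* **Superposition** is the Kabsch least-squares rotation via SVD with the
  proper-rotation sign correction; collinear point sets (second singular
  value < 1e-10) are rejected.  The "refined" mode imitates
  outlier-trimming structure aligners: up to 5 cycles, each discarding
  pairs deviating more than 2x the current RMSD and refitting on the
  survivors.  The exact schedules of published aligners are not public;
  this simple schedule reproduces their qualitative behaviour (gross
  outliers rejected in one or two cycles).
* **SASA** is Shrake-Rupley with 960 deterministic golden-spiral test
  points per atom (4000 for convergence checks), probe 1.40 A, van der
  Waals radii C 1.70, N 1.55, O 1.52, S/P 1.80, Se 1.90 A; hydrogens are
  ignored (united-atom convention).  Buried interface area is
  `(SASA_A + SASA_B - SASA_AB) / 2`, protein (ATOM) records only, so
  cofactors such as the phosphopantetheine arm are excluded by default.
* **Helix axes** come from the second differences of the C-alpha trace:
  for a helix these vectors have no component along the axis, so cross
  products of successive second differences point along it; their
  (sign-aligned) average is the axis.  This is exact for an ideal helix of
  any length, whereas the principal component of the coordinate
  covariance - the more obvious choice - is biased by 2-3 degrees on
  15-18 residue helices because an incomplete final turn skews the
  covariance; that bias is larger than the 1-degree accuracy the package
  targets, which is why the covariance estimator is only the degenerate
  (straight-line) fallback.  Angles are reported in [0, 180] degrees with
  N-to-C orientation respected (no folding of obtuse angles).
* **Triad geometry** reports minimum distances from the His imidazole
  nitrogens (ND1/NE2) to the nucleophile (Cys SG / Ser OG) and to the acid
  carboxylate oxygens (Asp OD1/OD2 / Glu OE1/OE2); missing side-chain
  atoms are an error naming them.
* **Coordinates** are parsed from PDB or mmCIF; author residue numbering
  (with insertion codes) is used throughout, one altloc per atom is kept
  (highest occupancy, ties to the earlier letter), waters dropped by
  default.

### Deposited structures

`reproduceDepositedMetrics()` recomputes the full metric set (triad
distances, chain-chain and domain-domain RMSDs, lid-excluded
cross-protein RMSD via alignment-mediated C-alpha pairing, the carrier
alpha-2 inter-helix angle after TE-core superposition, both buried
PCP-TE interfaces) from locally provided copies of the deposited
coordinate files for the SulM TE domain (8W2C), the SulM PCP-TE didomain
(8W2D) and the EntF PCP-TE didomain (3TEJ).  The files are not bundled
and no download is attempted; place them under a directory and pass its
path.  On the EntF side, domain boundaries are derived from the structure
itself: the carrier serine is located through the `G-x-D-S-[LIV]` motif
of the structure-derived sequence and the TE portion is taken from 35
residues downstream of it, with the alpha-2 helix as the 15 residues from
the serine.  The corresponding acceptance test is expected to fail on a
machine where the files are absent - by design, rather than silently
skipping the check.

## Decisions on genuinely open points

* **The three cationic positions.**  The active-site basic residues are
  named but the criterion never enumerates its positions; 2849/2854/2858
  are the default and are configurable through the anchor object.
* **Specificity-code positions and the DAP entry.**  The GrsA-frame
  position convention is external community practice; the DAP code ships
  as configuration (self-derived from the reference A domain) and any
  reference A domain plus position list can be substituted.
* **"70% similarity".**  Operationalized as the fraction of
  local-alignment columns that are identical or positively scoring, in
  percent - a deliberate, documented stand-in for a database search
  engine's reported similarity, and exposed as a config threshold.
* **Nucleophile strictness.**  Criterion 1 demands Cys by default
  (`strictCys`), since the ring-forming chemistry is tied to a thioester
  on cysteine; serine can be admitted for exploratory screens.

## Problem sizes

The test suite and the acceptance script run entirely on synthetic data:
200-cluster panels at mutation rates 0 and 0.05, 100 random pairs
(<= 12-mers) for the alignment oracle, 100 random additive matrices
(<= 8 taxa) for NJ recovery, 20 seeded rigid transforms for Kabsch, 960-
and 4000-point SASA grids.  These sizes keep each stage's statistical
check meaningful (binomial noise on 200 clusters is ~3.5% at worst) while
the full suite completes in a couple of minutes on one CPU.

## Known limitations

* The classifier is validated against its own generative model; natural
  divergence, domain rearrangements and split genes are out of its scope.
* GenBank/antiSMASH ingestion is deliberately absent; the cluster JSON/TSV
  dialect is the only cluster input.
* NJ trees carry no bootstrap support; the phylogeny stage is descriptive.
* SASA treats all atoms with their heavy-atom radii and ignores
  hydrogens; absolute areas therefore differ by a few percent between
  SASA implementations, which is why interface-area comparisons should be
  read with a generous (~15%) tolerance.
* The reference is synthetic; any result that depends on the *actual*
  SulM residues outside the documented anchors (e.g. fine-grained
  similarity percentages) is illustrative only.
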