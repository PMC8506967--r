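---
title: "Methods: contact calling, pruned superposition and conservation tiering"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: contact calling, pruned superposition and conservation tiering}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(bromospec)
```

`bromospec` asks how a bromodomain achieves sequence-specific
recognition of an acetylated histone tail. Sequence identity of the
contacting residues rarely answers this on its own — many contact
residues are conserved across the whole domain family — so the package
combines three measurements: which residues touch the peptide, whether
homologous domains position those residues identically, and at which
phylogenetic depth each residue is conserved. This vignette documents
the models behind each stream, the tunable parameters, the numerical
choices, and what the synthetic benchmarks do and do not demonstrate.

## Structure model

Coordinate files (PDB or mmCIF, parsed via bio3d) are normalised into
a flat atom table. Author residue numbering is the single coordinate
system everywhere: published residue references (Asn1263, H3 G13–R17)
are author numbers, so profiles, classifications and alignments all
report in it. Only the first model of a multi-model file is used
(crystal structures are the intended input). Alternate conformations
are retained with their occupancies; hydrogens are parsed but flagged
and excluded from all distance logic, because the contact definition
is heavy-atom based. Modified residues (acetyl-lysine and friends) are
polymer residues that map to their parent one-letter code for
sequence work; the mapping table (`MODIFIED_RESIDUE_MAP`) is
user-extensible because chemical-component codes vary between
depositions.

## Contact calling

A domain residue contacts the peptide if

* **direct**: any heavy-atom pair across the interface is within
  `direct_cutoff` (default **3.0 Å**). All heavy atoms count, not just
  polar ones — hydrophobic packing contacts are real contacts and must
  be callable.
* **water bridge**: a single water oxygen lies within `hbond_cutoff`
  (default **3.5 Å**, the conventional heavy-atom hydrogen-bond limit)
  of at least one polar (N/O) domain atom *and* one polar peptide
  atom. The criterion is distance-only: no angular term and no
  explicit hydrogens, since crystallographic models at typical
  resolution do not place them reliably. Only single-water bridges are
  considered; two-water chains are out of scope. Sulfur can be added
  to the polar set via `contact_params(include_sulfur = TRUE)`.

Distances are minimised over all altloc combinations, so a contact
made by either conformer of a split side chain is reported — this
matters when, say, only the dominant rotamer of a glutamate reaches an
arginine. Symmetry mates are never generated: crystal-packing contacts
are artifacts for this analysis. The invariants are monotonicity
(larger cutoffs never shrink the contact set) and rigid-motion
invariance, both property-tested.

Sidechain chi-1 rotamers are computed directly from coordinates as the
N–CA–CB–γ torsion (IUPAC sign; γ is CG, CG1, OG, OG1 or SG by residue
type), per altloc. Rotamer-well matching in tests uses ±15°, matching
the precision with which such angles are usually quoted. Note that a
torsion is *invariant* under reversing the four-atom order — a
property the test suite pins down against an independent
projection-based formulation, alongside the closed-form cis/anti
cases.

## Pruned superposition

Two homologous domains are first paired residue-by-residue from a
global Needleman–Wunsch alignment (BLOSUM62, gap open 10, extend 0.5,
via Biostrings); every aligned non-gap column with C-alpha atoms on
both sides becomes a pair. The mobile domain is then fitted onto the
reference by the Kabsch algorithm — SVD of the weighted
cross-covariance with a determinant correction so reflections are
never returned — and pairs whose post-fit C-alpha deviation exceeds
`prune_cutoff` (default **2.0 Å**) are discarded, batch-wise, before
refitting. Pruning is monotone (a discarded pair never returns), which
guarantees a fixed point; `max_iterations` (50) is a safety cap that
is never reached in practice. Fewer than `min_retained_pairs` (3)
surviving pairs is a divergence error, not a silent answer.

The headline numbers are the rmsd over retained pairs and the retained
count ("rmsd 1.0 Å over 82 of 105 C-alpha pairs" style); the full
deviation profile is reported for *all* pairs under the final
transform, pruned or not, so flexible-loop excursions remain visible
in deviation-per-residue curves. `contact_deviation_summary()` then
extracts the contact residues from the profile, flags
identity substitutions (e.g. a glutamate replaced by arginine at the
position that forms a salt bridge), and reports unpaired contact
residues as missing rather than zero. Bound peptides are compared
separately by a direct, unpruned fit over a residue-number range
(`superpose_peptides()`).

Design choice: pairing is sequence-seeded rather than
structure-seeded. Iterating the fit to a fixed point makes the final
retained set insensitive to the seeding for genuinely superposable
cores, and the synthetic-family benchmark (below) confirms recovery;
a structure-seeded variant would add complexity without changing the
fixed point in these regimes. One consequence of monotone batch
pruning is that a strongly displaced segment can drag a few genuine
core pairs out of the retained set in the first iteration; the
transform still recovers to fractions of an Ångström, but retained
counts should be read as conservative.

## Conservation scoring and tiering

Ortholog alignments are first reduced to their *n* most diverse rows
by greedy maxmin selection on normalised mismatch distance
(mismatches over columns where neither row is gapped): seed with the
globally most distant pair, then repeatedly add the row maximising its
minimum distance to the selection, ties broken by input order. This is
a deterministic, reproducible stand-in for the "most diverse
sequences" reductions done by alignment tools, and it provably (and,
here, empirically against 1,000 random subsets) dominates random
subsampling in minimum pairwise distance.

Each column is scored by the Jensen–Shannon divergence (log base 2,
hence in [0, 1]) between the column's amino-acid distribution and the
BLOSUM62 background frequencies. Pseudocounts of `1/(20·rows)` per
residue regularise finite columns; the gap fraction multiplies the
score down, so a half-gapped column scores at most half its ungapped
equivalent; an all-gap column scores 0 and is flagged. Window
smoothing mixes each column with the mean of its
`window`-column neighbourhood (default 3, the center included):
`windowed = (1 − λ)·raw + λ·mean(window)` with λ = 0.5, so isolated
noisy columns are damped without erasing single-column signals.

A column is called **conserved** when its windowed score reaches
`similar_threshold` *and* fewer than `nonsyn_max_fraction` (default
**0.10**) of its residues are nonsynonymous. "Nonsynonymous" is
operationalised as a BLOSUM62 score ≤ 0 against the column consensus;
the consensus may be a pair of residues when two are each frequent
(≥ 30%) and mutually similar, rendered "X1/X2" in exports. The
10%-veto is assessed on the raw column, before smoothing. Published
analyses of this kind quote a similarity threshold of 2.2 on their
scoring tool's own output scale; that scale is not reconstructible
from the [0, 1] divergence used here, so the threshold is an explicit
calibration parameter. The default **0.4** was chosen against the
synthetic benchmark's design: invariant and 5%-conservative columns
score well above it, background-like columns well below, and the
decisive discrimination against drifted columns is carried by the
nonsynonymous veto, as in the published rule.

Tiering runs the same profile at up to three depths — the paralog's
orthologs, the domain family, all domains — and assigns each
reference-mapped residue the highest level at which it is conserved
(universal > family > paralog > none). Contact residues missing from
the profiles are reported as unscored, never dropped. Counts of
conserved residues are always derived from the supplied alignments at
run time: published tallies of this kind depend on the sequence
database snapshot behind the alignment and are not constants of the
method.

## Synthetic benchmarks: what they show

The generators produce inputs whose ground truth is recorded, not
re-derived:

* `make_complex()` builds a domain chain and peptide chain of sparse,
  correctly named residues, plants direct contacts and collinear
  water bridges at *exact* target distances, and places decoy waters
  outside a 4.5 Å exclusion shell. A post-generation audit re-measures
  every planted distance (≤ 0.05 Å tolerance) and scans for unplanned
  near-cutoff approaches, erroring rather than emitting an ambiguous
  fixture. These complexes exercise the distance logic exactly; they
  are not stereochemically realistic proteins, deliberately — contact
  calling is purely geometric.
* `make_family()` perturbs a compact four-helix-bundle base domain
  (globular, so rigid-body recovery is well conditioned; an elongated
  trace would leave a near-free screw degree of freedom) with
  per-coordinate Gaussian noise, an optional rigidly displaced
  segment, optional identity mutations, and a recorded random rigid
  transform per member.
* `make_msa()` plants invariant, conservative (BLOSUM62-positive
  neighbours at 5%) and randomly drifting (uniform at 20%) columns,
  with optional per-cell gaps, at the benchmark scale of 100 rows ×
  110 columns with 30 conserved columns — mirroring the size of a
  diversity-reduced ortholog set for a ~110-residue domain.

All generators are pure functions of their spec (seed included):
repeat calls are byte-identical, and they restore the caller's RNG
state. The benchmark suite demonstrates: Kabsch rmsd agreement with an
independent quaternion (Horn) oracle to 1e-8; exact precision and
recall of contact calling over 50 seeded complexes; displaced-segment
pruning and transform recovery (≥ 95% of 100 runs at noise σ ∈
[0.1, 0.5] Å with 30% of residues displaced 5 Å); conserved-column
sensitivity 1.0 at false-positive rate ≤ 0.05; and byte-deterministic
pipeline output. These sizes keep the full suite and the acceptance
script comfortably fast while leaving no stage untested.

What passing does **not** show: real crystal structures bring altloc
and insertion-code corner cases at scale, genuinely flexible loops,
and peptides that bind in shifted registers; real ortholog alignments
have phylogenetic correlation between rows, which JS-divergence
scoring ignores (no tree weighting — a stated non-goal). Anchors
against deposited structures (contact-set size, superposition rmsd
and retained counts, chi-1 rotamer pairs, model content counts) are
wired into the test suite and run whenever the coordinate files are
placed under `inst/extdata/deposited/`.

## Degenerate inputs and tie-breaks

Collinear point sets make superposition (rank-deficient covariance)
and torsions (undefined normal) errors, not numbers. Minimal-distance
ties break by atom-name order; maxmin ties break by input order;
duplicate alignment ids and ragged rows are rejected at parse.
`run_pipeline()` is staged: any failure removes partial outputs and
aborts with the stage name, and the run log records parameters and
input checksums (never timestamps), so identical inputs produce
byte-identical output trees.
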