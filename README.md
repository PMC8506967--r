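# bromospec

Structural and evolutionary specificity analysis of bromodomain–histone
peptide recognition, as an R package.

## The problem

Bromodomains (BDs) are ~110-residue four-helix reader modules that bind
acetylated lysines on histone tails. A recurring question for any
reader–mark pair is *what makes recognition sequence-specific*: the
residues that physically touch the peptide are often conserved across
the whole domain family, so identity alone cannot explain why one
paralog binds H3K14ac and another does not. `bromospec` implements the
three-stream analysis used to dissect this:

1. **Contact calling.** A BD residue is a *contact residue* if any of
   its heavy atoms lies within 3.0 Å of the peptide, or if it is linked
   to the peptide by a single water making hydrogen-bond-range
   (≤ 3.5 Å) approaches to polar (N/O) atoms on both sides. Alternate
   conformers all participate, so a contact made by a 60%-occupancy
   rotamer counts. Coordinate-level rotamer geometry (chi-1 =
   N–CA–CB–γ torsion) distinguishes such conformers.
2. **Positional comparison.** Homologous domains are paired by global
   sequence alignment (BLOSUM62, affine gaps), then superposed on
   C-alpha atoms by least squares (Kabsch, SVD with reflection
   exclusion), iteratively discarding residue pairs deviating by more
   than 2.0 Å and refitting to a fixed point. The result is an overall
   rmsd over the retained pairs plus a per-residue deviation profile —
   contact residues of true binders sit in near-identical positions
   (deviations ≤ 1.5 Å) even when their identities differ, while
   non-binders show multi-Å excursions exactly at contact positions.
3. **Conservation tiering.** Ortholog alignments are reduced to their
   most diverse rows (greedy maxmin on mismatch distance), scored
   per-column by Jensen–Shannon divergence against the BLOSUM62
   amino-acid background (log base 2, scores in [0, 1]; gap-fraction
   down-weighting; 3-column window smoothing), and a column is called
   conserved when its smoothed score passes a threshold *and* fewer
   than 10% of its residues are nonsynonymous (BLOSUM62 ≤ 0 versus the
   column consensus). Running this at three phylogenetic depths tiers
   each contact residue as conserved **universally**, within the
   **family**, only in the **paralog**, or not at all — the
   paralog-specific tier is where specificity determinants live.

Synthetic-data generators (`make_complex()`, `make_family()`,
`make_msa()`) produce fully ground-truthed inputs for every stage, so
the entire pipeline is testable without downloading structures or
sequences.

## Worked example

```r
library(bromospec)

# a synthetic domain-peptide complex with two planted direct contacts
# and one planted water bridge
cx <- make_complex(complex_spec(seed = 1))
direct  <- find_direct_contacts(cx$structure, cx$bd_sel, cx$pep_sel)
bridges <- find_water_bridges(cx$structure, cx$bd_sel, cx$pep_sel)
contact_residue_set(direct, bridges)
#>   bd_chain bd_resno bd_ins bd_resname        kinds  bd_sides
#> 1        A     1203               ALA       direct sidechain
#> 2        A     1208               VAL       direct sidechain
#> 3        A     1214               ILE water_bridge  backbone
```

The three rows are exactly the planted interactions: residues 1203 and
1208 touch the peptide directly (closest heavy-atom pairs at the
planted 2.8 Å and 2.6 Å), and residue 1214's backbone carbonyl reaches
the peptide through the planted bridging water.

```r
# superpose a noisy family member back onto its parent
fam <- make_family(family_spec(seed = 2))   # sigma 0.3 A, 20% displaced 5 A
res <- iterative_prune_superpose(
  select_residues(fam$base, selection("A")),
  select_residues(fam$members[[1]], selection("A")))
res
#> <bd_superposition> rmsd 0.517 A over 80 of 100 Ca pairs (2 iterations)
```

The displaced segment (residues 81–100) is pruned in full and the
recovered transform matches the generator's recorded ground truth to a
fraction of an Ångström; the rmsd over retained pairs reflects only
the planted coordinate noise.

```r
# score a 100-row ortholog alignment with 30 planted conserved columns
gen <- make_msa(msa_spec(seed = 3))
prof <- conservation_profile(gen$msa)
sum(prof$conserved)
#> [1] 30
```

All 30 planted columns (and nothing else, at this seed) pass the
conservation rule. `run_pipeline()` joins the three streams into a
per-contact-residue classification table (CSV) plus deviation profiles
and an annotated alignment.

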