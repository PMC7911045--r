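---
title: "Methods: mutable surface patches and degenerate library design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: mutable surface patches and degenerate library design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(scaffpatch)
```

## The problem

Directed evolution of a protein scaffold needs two decisions made before any
bench work: *which protein* to use as the framework, and *which of its
residues* to randomize. A good randomization site is a spatially contiguous
set of solvent-exposed residues that (a) the protein's evolutionary family
does not conserve, and (b) the fold tolerates energetically. scaffpatch
formalises both criteria, detects such **mutable surface patches**, and
turns the chosen patch into a degenerate-codon DNA library.

## Candidate filtering

A structure qualifies as a scaffold candidate when:

| rule | default | semantics |
|---|---|---|
| molecular weight | 10–25 kDa | inclusive bounds; average residue masses + one water |
| resolution | < 3.0 Å | strict; missing resolution is its own failure label |
| oligomeric state | 1 chain, ≥ 50 residues | chains in the coordinate file; assembly records are not expanded |
| cysteines | ≤ 2 | disulfides complicate display and folding |

Non-computable curation criteria (toxicity, immunogenicity, literature
solubility) are carried as free-text notes in the verdict and never scored.
Every evaluated rule appears in `metrics`, so a failed verdict is auditable.

## Per-residue evidence

**Conservation.** For each alignment column where the reference (scaffold)
record has a residue, conservation is the *identity-to-reference* fraction:
`100 × (records matching the reference symbol) / (all records)`. This
definition — rather than column entropy — is chosen because the selection
gate is phrased as an identity percentage; the denominator includes the
reference and gap-containing records (a gap counts as a mismatch), and `X`
matches nothing, itself included. Both choices are configurable in
`column_conservation()`'s documented alternatives, and the profile is
transferred to the structure through a global Needleman–Wunsch alignment
(BLOSUM62, gap open 10, extend 0.5); a transfer below 50 % identity aborts,
because that usually means the MSA belongs to a different protein.

**Mutability.** Saturation-mutagenesis position scans supply 20 folding
ΔΔG values per position (self-substitution = 0 by definition). The
mutability score is the percentage of the 20 with ΔΔG strictly below a
tolerance of 0.5 kcal/mol — the single inequality subsumes the stabilising
case ΔΔG < 0 — so scores live on the grid {0, 5, …, 100}. The denominator
deliberately includes the self substitution (the scan emits it and the
calculation includes it); with 19 instead, scores would not be comparable
across published thresholds. File input uses the position-scan TSV dialect
(`GA131 TAB W TAB 1.23`, or the two-column `GA131W TAB 1.23` variant).

When no force-field scan is available the pipeline can fall back to a
**surrogate**: ΔΔG(wt→a) = λ·(1 − min(rSASA, 1))·Grantham(wt, a)/100 with
λ = 1 kcal/mol. It encodes only two facts — buried positions tolerate less,
dissimilar substitutions cost more — and is tagged `source: "surrogate"`
end-to-end so it can never be mistaken for force-field output. It exists for
pipeline testing, not for ΔΔG prediction.

**Solvent accessibility.** Shrake–Rupley with van der Waals radii
(Bondi: C 1.70, N 1.55, O 1.52, S 1.80, H 1.20 Å; unknown → 1.70 Å with a
warning), probe 1.4 Å, 960 test points per atom placed on a deterministic
golden-spiral lattice — no RNG, so SASA is bit-stable across runs and
platforms. At 960 points the isolated-sphere error is well under 1 %.
Hydrogens are excluded by default (X-ray entries rarely have them).
Relative SASA divides by the residue type's theoretical maximum (Tien et
al. 2013, PLoS ONE 8:e80635); a residue is *surface* at rSASA ≥ 0.25. The
0.25 threshold is this package's choice — the workflow literature speaks of
"surface residues" without a number — and sits at the conventional
boundary between buried and exposed used in relative-accessibility scales.

## Selection and patch construction

A residue is **mutable** when conservation < 90 % *and* mutability > 50 %
(both strict, matching the printed thresholds) *and* it is a surface
residue. Residues missing either score are excluded and listed in a
diagnostics attribute — never silently dropped.

Patches are the **connected components** of the contact graph over the
mutable set: nodes are residues represented by Cβ (Cα for glycine), edges
join pairs within 8.0 Å. Components are the simplest faithful reading of
"continuous surface regions"; density-based clustering is an explicit
non-goal. The 8 Å Cβ–Cβ cutoff is a standard residue-contact definition and
is exposed as a parameter. Patches are ranked by size, then mean
mutability, then smallest author number — a full tie-break chain so output
is deterministic across platforms.

A patch smaller than the 10–12 window that ribosome-display complexity
favours is **completed** greedily: among surface residues within 8 Å of the
patch, add the highest-mutability one (ties: lower conservation, then lower
author number) until the window is reached or candidates run out
("undersized" flag). Seed and completion members are reported separately,
so the provenance of every randomized position is visible. Oversized
components are flagged, never truncated — shrinking a patch is a design
decision the user must make. Two patches are reported **independent** when
their member sets are disjoint and their minimum inter-residue distance
exceeds 8 Å; both facts appear in the report since either reading of
"independent" may be wanted.

## Library design

Each selected position gets an NNK codon (N = A/C/G/T, K = G/T): 32 codons
covering all 20 amino acids with a single stop (TAG). Diversity statistics
are exact: products are accumulated as decimal big integers (base-10⁴
limbs), so `protein_diversity_exact` for 10 NNK positions is the exact
string `"10240000000000"` (20¹⁰) and DNA diversity 32¹⁰ =
1 125 899 906 842 624; numeric doubles are returned alongside and are exact
below 2⁵³. Protein diversity counts **stop-free** sequences only — a
stop-containing variant is not a library member — and the stop-free
fraction (31/32)ⁿ quantifies the synthesis overhead stops impose.

The ribosome-display cassette is assembled in the fixed element order
T7 promoter, 5′ stem-loop, RBS, N-terminal Strep-tag, scaffold ORF,
c-Myc tag, TolA spacer, 3′ stem-loop, and validated: the tagged fusion must
translate without internal stops and the cassette must end without one
(ribosome display requires a stop-free ORF). The shipped element sequences
are representative published motifs plus synthetic linkers — *not* any
vendor's proprietary construct — and are overridable per element. Back
translation uses the most-frequent E. coli codon per amino acid,
also overridable. `sample_variants()` draws concrete library members
(seeded, optionally stop-excluding, optional per-base error rate).

## Fold verification

`superpose_models()` pairs residues by sequence alignment (default) rather
than author numbering, because evolved variants carry mutations and may be
renumbered; the alignment identity is reported so a suspicious pairing is
visible. The Kabsch solution uses the SVD of the cross-covariance with
reflection correction (the smallest singular direction is flipped when
det < 0), so the rotation is always proper — mirror-image inputs included.
No outlier trimming is applied: the RMSD is over the full common Cα set,
and `n_atoms` is reported so any discrepancy with a published value can be
traced to atom selection. Degenerate (collinear) inputs are rejected.

## What the synthetic data emulates — and what it does not

`synthetic_structure()` builds an ideal α-helical Cα/pseudo-Cβ trace (rise
1.5 Å, radius 2.3 Å, 100°/residue; consecutive Cα ≈ 3.83 Å). Every residue
is exposed (rSASA ≈ 0.29–0.72 at the default threshold), which is exactly
what the patch tests need: selection is then driven purely by conservation
and mutability, with geometry controlling only contiguity.
`synthetic_msa()` mutates each column independently at a chosen rate, so
measured conservation converges to 100(1 − p); `synthetic_ddg()` plants
positions with ≥ 14/20 tolerated substitutions (score > 50 %) against a
background of ≤ 8/20 (≤ 40 %), with the contract enforced after drawing.
Residue types avoid Gly and Cys so every residue has a Cβ and the cysteine
filter stays neutral.

Passing on these fixtures demonstrates the *machinery* — readers, scoring,
graph construction, completion, ranking, library arithmetic — under known
ground truth. It does not demonstrate that real proteins have such
cleanly separable patches: real surfaces have buried cores, correlated
columns in MSAs, and force-field ΔΔG landscapes far richer than the
surrogate. Position-scan files from a real force field and a real MSA are
the intended production inputs.

Default problem sizes (60-residue scaffolds, 20 pipeline seeds, 50–500
sequence alignments, 200 random graphs, 960 sphere points) were chosen so
the whole suite exercises every code path in well under a minute on a
laptop while keeping the statistical checks (binomial/convergence margins)
comfortably powered.

## Numerical and degenerate-input choices

- Alternate locations: highest occupancy wins, ties by file order.
- Missing resolution is a distinct filter failure (`resolution_unknown`),
  not a silent pass.
- Unknown elements get the carbon radius; unknown residue types get the
  mean max-ASA — both with warnings.
- Empty mutable sets yield an empty patch list, not an error; singleton
  patches are kept and flagged.
- All stochastic functions take an explicit seed and restore the caller's
  RNG state.

## Limitations

- No biological-assembly expansion: oligomeric state is judged from the
  coordinate file, as the curation step of the original workflow did
  manually.
- Conservation is reference-anchored; families with long insertions
  relative to the scaffold contribute no signal at those positions.
- The surrogate ΔΔG model is a monotone toy; its scores are only meaningful
  relative to its own threshold.
- Patch completion is greedy; with heavily tied scores multiple optimal
  completions exist and the tie-break chain picks one deterministically.
- No geodesic (surface-path) distances: patch contiguity is Euclidean.
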