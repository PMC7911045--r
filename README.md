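# scaffpatch

Small non-antibody protein scaffolds are engineered binders: a stable
single-domain framework whose solvent-exposed residues are randomized and
selected (e.g. by ribosome display) against a target. Picking a *good*
scaffold — and the right residues to randomize — is the part that can be done
computationally, and that is what this package implements:

1. **Candidate filtering** — screen structures for scaffold suitability:
   molecular weight within 10–25 kDa, X-ray resolution < 3.0 Å, a single
   polymer chain (monomer), few cysteines.
2. **Conservation** — per-position identity conservation from a multiple
   sequence alignment of homologs, mapped onto the structure by global
   alignment.
3. **Mutability** — per-position score from in-silico saturation mutagenesis:
   the percentage of the 20 substitutions (self included) with folding
   ΔΔG < 0.5 kcal/mol. ΔΔG tables are read from position-scan files; a
   clearly-labelled surrogate model (burial × Grantham distance) exists for
   testing without a force field.
4. **Patch detection** — residues with conservation < 90 %, mutability > 50 %
   and relative SASA ≥ 0.25 form the mutable set; connected components of the
   8 Å Cβ contact graph are the mutable surface patches, completed greedily
   up to 10–12 residues from neighbouring surface residues.
5. **Library design** — NNK degenerate codons over the patch positions, with
   exact DNA/protein diversity statistics and a ribosome-display cassette
   layout (T7 promoter → stem-loop → RBS → Strep-tag → ORF → c-Myc →
   TolA spacer, stop-free).
6. **Fold verification** — Kabsch superposition of an evolved variant onto
   the parent over the common Cα set, reporting RMSD.

Solvent accessibility is computed in-package (Shrake–Rupley on a
deterministic golden-spiral lattice); per-residue values are normalised by
theoretical maximum ASA (Tien et al. 2013).

## Worked example

Everything below runs offline on generated data with a planted ground truth:

```r
library(scaffpatch)

fb  <- fixture_bundle(tempdir(), n_residues = 60, planted = 20:29, seed = 1)
run <- run_pipeline(read_pipeline_config(fb$config))
run
#> Scaffold selection run: structure
#>   candidate filter: failed: molecular_weight
#>   60 residues | 60 surface | 10 mutable | 1 patch(es)
#>   top patch: 10 residues (mean mutability 82.5%)
#>   library: 10 x NNK, stop-free protein diversity 10240000000000
#>   outputs in /tmp/.../out
```

The 60-residue synthetic helix is below the 10 kDa floor, so the candidate
filter reports `molecular_weight` (a real scaffold would pass); the ten
planted residues (20–29) are the only ones that clear all three gates, they
form one patch, and the NNK library over those ten positions has exactly
20¹⁰ = 10 240 000 000 000 stop-free protein variants — above the 10¹²
diversity customary for ribosome display. Per-stage tables, the annotated
PDB (patch id in the B-factor column) and the library JSON are written to
`run$paths`.

Superposing a variant onto its parent:

```r
cmp <- compare_to_parent("parent.pdb", "variant.pdb")
cmp$rmsd     # C-alpha RMSD in Angstrom
cmp$n_atoms  # number of paired C-alpha atoms
```

A thin CLI wraps the same functions
(`inst/exec/scaffold-pipeline run config.yaml`).

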