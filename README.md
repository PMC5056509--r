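# vhhscreen

In silico screening of nanobody (VHH) variants for usable recombinant
yield, from molecular-dynamics conformational ensembles and
whole-molecule docking scores.

## The problem

Nanobodies — the isolated ~120–135-residue variable domains of camelid
heavy-chain antibodies — tolerate some engineering (humanizing point
mutations, CDR grafting) and fail badly on other, superficially similar
changes: the usable yield of correctly folded, soluble protein can drop
several-fold or to zero. Single-property predictors (folding ΔΔG,
intrinsic solubility) do not track these failures well, because yield is
dominated by *colloidal* behaviour: folded monomers sticking to each
other through surface hotspots and precipitating.

`vhhscreen` implements the post-processing side of a screening protocol
that attacks this directly. It consumes conformational ensembles (from
MD, as multi-model PDB) and docking score tables (from an external
docking engine), and produces:

1. **Representative conformations** — gromos clustering of the ensemble
   on an RMSF-gated backbone selection; the centre of the most populated
   cluster represents the molecule.
2. **Thermal-stability order parameters** — per-frame backbone RMSD of
   the two facing beta-sheet sets of the immunoglobulin sandwich and the
   distance between their centres of mass, the signature of "structural
   opening".
3. **Aggregation hotspots** — the union of (a) residues whose
   interactions changed most upon mutation, scored by the per-residue
   difference-contact statistic

   ΔC_i = Σ_{j : |j−i| > 1} | C̄_ij(variant) − C̄_ij(reference) |,

   where C̄_ij is the trajectory-averaged residue–residue contact area,
   thresholded at 20% above the profile mean; and (b) solvent-exposed
   hydrophobic residues (relative SASA ≥ 0.20 and Eisenberg consensus
   score ≥ 0). Candidates are merged into surface patches (connected
   components under an 8 Å closest-heavy-atom linkage) and the five
   largest patches are retained.
4. **A yield verdict** — all k(k−1)/2 unordered hotspot pairs define
   candidate dimers (10 for 5 hotspots). Per dimer combination, the
   docking cluster with the lowest score among those holding >10% of the
   docked structures is selected; the variant's five lowest scores are
   compared against the mean of the wild type's five lowest:
   all five strictly below → `reduced`, none below → `comparable`,
   otherwise `indeterminate`. The comparison is refused unless variant
   and reference have the same residue count (absolute docking scores
   scale with molecular size).

Every stage is also covered by seeded synthetic generators
(`make_toy_structure()`, `make_toy_trajectory()`, `make_mutant_pair()`,
`make_score_table()`), so the full pipeline runs and is testable without
any MD or docking run.

## Worked example

The bundled demonstration runs the complete protocol on a 60-residue
two-sheet toy scaffold with four variants: a wild type, one benign
variant (`HUM1`, 1 Å localized perturbation, high-yield score class) and
two disruptive variants (`MUT1`, `MUT2`, 3 Å block displacements,
low-yield score class):

```r
library(vhhscreen)
res <- run_pipeline(demo_config(outdir = "demo", seed = 1))
```

```
[WT] 36 frames -> representative frame 36 (1 clusters)
[HUM1] 36 frames -> representative frame 36 (1 clusters)
[MUT1] 36 frames -> representative frame 36 (1 clusters)
[MUT2] 36 frames -> representative frame 36 (1 clusters)
[WT] 9 candidate residues -> 5 hotspot(s), 10 dimer combination(s)
[HUM1] 22 candidate residues -> 4 hotspot(s), 6 dimer combination(s)
[MUT1] 20 candidate residues -> 5 hotspot(s), 10 dimer combination(s)
[MUT2] 18 candidate residues -> 5 hotspot(s), 10 dimer combination(s)
[HUM1] verdict: indeterminate (4/5 below wild-type mean -62.5)
[MUT1] verdict: reduced (5/5 below wild-type mean -62.5)
[MUT2] verdict: reduced (5/5 below wild-type mean -62.5)
```

Reading the output: each ensemble collapses to one dominant
conformational cluster whose centre becomes the representative; the wild
type's surface candidates resolve into 5 hotspots and hence 10 candidate
dimer orientations. Both disruptive variants have all five of their
lowest docking scores below the wild-type reference mean (−62.5) and are
flagged `reduced`; the benign variant is not.

```r
print(res$predictions$MUT1)
#> <yield_prediction> MUT1: reduced (5/5 lowest scores below the wild-type mean -62.5)
#>   five lowest: -95.7, -93.1, -92.8, -90.7, -90.5
```

Artifacts land under `demo/`: per-variant representative structures,
cluster reports, order-parameter series, difference-contact profiles,
hotspot tables and a PDB with patch ids in the B-factor column, plus the
docking table, `predictions.tsv` and a JSON manifest. Re-running with
the same seed reproduces every file byte for byte.

## Scope

The package post-processes ensembles and docking scores; it does not run
molecular dynamics or docking, build homology models, or predict
absolute yields in mg/L (classification against a same-length wild-type
reference only). See the methods vignette
(`vignettes/yield-screening.Rmd`) for the model details, parameter
defaults, and known limitations.
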