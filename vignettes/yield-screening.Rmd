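---
title: "Screening nanobody variants for usable yield: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Screening nanobody variants for usable yield: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

## The model

Usable recombinant yield of a nanobody (VHH) variant is treated as a
colloidal-stability problem: a variant whose folded monomers present
sticky surface patches binds itself into aggregation seeds, and its
yield falls relative to the wild type even when its fold is stable and
its intrinsic solubility looks fine. `vhhscreen` operationalizes this as
a four-stage post-processing chain over two externally produced inputs —
a conformational ensemble per molecule and a docking score table per
candidate dimer — and one internal comparison against a same-length
wild-type reference.

### Representative conformation

An ensemble is reduced to one structure by gromos clustering: frames are
compared by pairwise least-squares-fitted backbone RMSD over a gated
residue selection, the frame with the most neighbours within a cutoff
seeds a cluster, the cluster is removed and the rule repeats. The cutoff
defaults to the mean of the strict upper triangle of the RMSD matrix
(`cutoff = "auto"`); the diagonal is excluded because its zeros would
bias the mean low. The gate keeps residues whose C-alpha RMSF lies
strictly above the per-residue mean, minus `n_exclude_termini = 3`
residues per chain end — the mobile termini carry no conformational
signal. Clusters below `min_size` are discarded; the floor is 100 frames
for ensembles of at least 1000 frames and 10% of the frame count below
that, keeping the same proportional strictness on the small ensembles
the generators produce. The representative is the centre of the most
populated cluster. Ties in neighbour count and in cluster size are
broken toward the lower frame index; both tie-breaks are arbitrary but
fixed, so clustering is deterministic under frame relabeling.

The first 10% of each trajectory's time span is dropped before any
analysis (`discard_initial_fraction = 0.1`), the usual guard against
equilibration transients.

### Thermal-stability order parameters

The immunoglobulin sandwich is two facing beta-sheet sets. Per frame,
after a whole-molecule backbone fit to the representative,
`sheet_order_parameters()` reports the backbone RMSD of each sheet set
and the distance between their mass-weighted centres of mass. The fit is
deliberately global: sheets that stay internally intact while drifting
apart ("structural opening", the loss of tertiary contact that precedes
unfolding) then show up in the centre-of-mass series, which a per-sheet
re-fit would hide. A `refit_sheets` switch restores the per-sheet
convention when wanted. RMSD is unweighted; only the centre of mass uses
atomic masses. All lengths are Angstrom internally (the native PDB
unit); series are written as two-column `time_ps / value_A` text.

### The difference-contact statistic

For each conformation, C_ij collects the contact area between residues
i and j, summed over heavy-atom pairs. The contact area of one atom pair
is defined here as the area of the circle in which the two probe-expanded
spheres (van der Waals radius + 1.4 Å) intersect — a closed form that is
symmetric, rigid-motion invariant, zero beyond r_a + r_b + 2 r_p, and
directly testable against hand arithmetic. This is a stand-in definition
for "contact area" generally: it preserves the rank structure the
protocol needs (which residue pairs gained or lost contact, and by how
much) without claiming any particular reference algorithm, and it is
isolated behind `contact_map()` so another definition can be swapped in.
Maps are averaged over the trajectory first and subtracted second
(`mean_contact_map()`, then `difference_contact_map()`); per-frame
differencing is not the default because the comparison targets the mean
structural ensembles, not frame-by-frame noise.

The per-residue statistic is

ΔC_i = Σ over j with |j − i| > 1 of |ΔC̄_ij|,

the total absolute contact change of residue i against all non-self,
non-sequence-adjacent partners. Sequence neighbours are excluded because
their contacts are covalently enforced and carry no aggregation signal.
A strictly one-sided summation (j > i + 1 only) is available behind
`one_sided = TRUE`; it makes late residues sum fewer terms, so the
symmetric reading is the default.

`select_perturbed_residues()` flags residues with
ΔC_i ≥ 1.2 × mean(ΔC) — 20% above the profile average, with the mean
taken over all residues including zeros — AND ΔC_i ≥ 10 Å². The absolute
floor is about the overlap area of a single atomic contact: a residue
must have gained or lost at least one substantial atom–atom contact to
be flagged. Without the floor, the relative rule flags the peak of any
nonzero profile, including the numerically tiny (≲3 Å²) profiles that
centi-Angstrom coordinate differences produce; with it, near-identical
ensembles yield an empty selection, which is the behaviour a screening
protocol needs.

### Surface hotspots

The complementary candidate set is the solvent-exposed hydrophobic
surface: residues with relative SASA ≥ 0.20 and Eisenberg consensus
hydrophobicity ≥ 0. SASA is Shrake–Rupley with a deterministic
golden-spiral point set (default 960 points per atom), heavy atoms only;
for fixed `n_points` the result is bit-reproducible. Because the point
set is fixed in the laboratory frame, rotating a structure changes the
sampling: total SASA is rotation-invariant only to sampling accuracy
(measured ~0.5% at 960 points on the bundled scaffold), which the tests
assert at 1%. The relative-SASA denominator is the SASA of residue X in
an extended Gly-X-Gly tripeptide built with the package's own idealized
residue geometry — self-consistent with `sasa()` by construction rather
than copied from a literature table, and memoized per residue type.

Both candidate sets are merged (provenance kept) and grouped by
`group_hotspots()`: connected components over candidates with an edge
when the closest heavy-atom distance is within `link_distance` (default
8 Å, a side-chain-contact scale), ranked by residue count with ties
broken toward the lower minimum residue index, and trimmed to the five
largest patches. Five is the canonical hotspot count of the protocol;
with five hotspots the dimer enumeration below gives exactly ten
combinations.

### Docking aggregation and the yield verdict

Docking is consumed, never performed: each row of a score table is one
docking cluster of one dimer combination, with a score (more negative =
stronger predicted binding) and a population fraction.
`select_docking_cluster()` keeps the lowest-scoring cluster among those
holding more than 10% of the docked structures — small clusters are
conformationally heterogeneous and their scores unstable.
`enumerate_dimer_pairs()` enumerates the k(k−1)/2 unordered hotspot
pairs, excluding symmetric same-site dimers, since the molecules
screened are monomeric in solution and a same-site symmetric dimer is
not an available aggregation mode.

The verdict compares the variant's five lowest per-combination scores —
the most probable aggregation seeds — with the mean of the wild type's
five lowest (`reference_band()`; the population standard deviation is
reported alongside). All five strictly below the mean → `reduced`; none
below → `comparable`; otherwise `indeterminate` with the count reported.
The all-five/none/otherwise split is this package's operationalization
of "consistently falling below"; the counts are reported so users can
re-threshold. Ties count as not below, so degenerate equal-score tables
are deterministic. The comparison is refused outright when variant and
reference differ in residue count: absolute docking scores grow with
molecular size and no size normalization is attempted.

One operating characteristic is worth knowing: even a variant drawn from
the *same* score distribution as the wild type can land all five of its
lowest scores below the wild-type band by chance (the band is itself an
estimate from ten combinations), so the `reduced` verdict has a nonzero
false-positive rate on statistically identical molecules. The
class-recovery rate that `scripts/acceptance.R` computes quantifies
exactly this on the synthetic generator, and averages it over replicate
simulations because any single simulation's rate is dominated by its one
shared wild-type band draw.

## The synthetic generators

The generators exist to carry the statistical structure each stage
assumes, not to be physical VHH models:

* `make_toy_structure()` — two parallel slabs of idealized extended
  strands (3.8 Å C-alpha spacing, 4.8 Å strand spacing, configurable
  inter-slab separation, default 10–12 Å) with pleating CB placeholders
  and residue types drawn from hydrophobic and polar pools. It emulates
  the two facing beta-sheet sets of the framework and a surface with
  both sticky and benign residues.
* `make_toy_trajectory()` — seeded isotropic Gaussian jitter about the
  base (per-coordinate σ, so RMSF ≈ σ√3), optional larger σ on a residue
  subset and optional linear drift of one sheet to emulate structural
  opening.
* `make_mutant_pair()` — a mutation stand-in: the perturbed residues and
  their spatial neighbours within 6 Å are rigidly displaced radially
  away from the molecular centre of mass, and both trajectories share
  one jitter seed, so ensemble noise cancels exactly in the difference
  map and the ΔC_i signal concentrates at the displaced block.
* `make_score_table()` — per combination, a score drawn from a
  class-dependent normal (high-yield centred at −60, within the
  −40…−110 range docking scores of such dimers occupy; low-yield shifted
  by −30; between-combination spread 5) split into 2–4 clusters with the
  best cluster at the combination score and normalized population
  fractions.

What passing tests on these fixtures show is that the *machinery* is
correct: the statistics recover their closed forms, the clustering
matches a brute-force transcription, localized perturbations are
localized in ΔC_i, and class-separated scores produce class-separated
verdicts. What they cannot show is transferability to real VHHs —
real ensembles have correlated, anisotropic fluctuations, side-chain
rearrangements without backbone displacement, and docking scores whose
noise structure is not normal. The generator defaults are therefore
study conditions, not tuning knobs.

## Numerical choices and degenerate inputs

* Residues are indexed 1..N sequentially in file order; author PDB
  numbers are preserved for reporting. First alternate locations are
  kept; insertion codes fold into the sequential indexing.
* Kabsch superposition uses the SVD construction with the determinant
  correction, refuses fewer than three fit atoms or collinear fit
  geometry, and always returns a proper rotation. `bio3d::rot.lsq`
  serves as an independent cross-check in the tests, alongside a
  rotation-grid-search oracle.
* RMSF superposes twice (fit to first frame, re-fit to the resulting
  mean) so the reference is self-consistent; `calpha_rmsf()` fits on all
  atoms while reporting C-alphas, because fitting on the reported atoms
  alone absorbs six rigid-body degrees of freedom and biases small-set
  RMSF low.
* Running averages use a centred window, truncated at the edges;
  `n_points = 1` is the identity and windows longer than the series are
  an error.
* All-zero ΔC profiles and empty candidate sets short-circuit to empty
  selections or informative errors; selections are never silently empty.
* Hydrogens are ignored throughout the contact and SASA analysis (the
  ensembles consumed typically carry none consistently); unknown
  elements are an error naming the element, unknown residue types a
  warning naming the type.
* The demonstration pipeline uses 40-frame ensembles of a 60-residue
  scaffold and 480 SASA points — sizes chosen so a full run stays
  desk-scale while leaving every stage non-trivial; the statistical
  checks use 2000-frame ensembles where a law (σ√3) is being recovered.

## Known limitations

* The lens-area contact definition is a declared stand-in; absolute
  ΔC_i magnitudes are not comparable across contact definitions, only
  the residue ranking is intended to be stable.
* The hydrophobic-exposure thresholds (0.20 relative SASA, Eisenberg 0)
  are stand-ins for an interface predictor, not a reproduction of one.
* The verdict is a three-way classification against a same-length
  reference; no absolute yield regression is attempted.
* Binary trajectory formats are out of scope; ensembles arrive as
  multi-model PDB or ordered per-frame PDB files.
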