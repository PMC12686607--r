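# mfccpocket

Per-residue protein–ligand interaction energies by **molecular
fractionation with conjugated caps (MFCC)**, in R.

When a small molecule binds a protein, the binding energy is not spread
evenly over the pocket: a handful of residues usually dominate, and a few
may even oppose binding. `mfccpocket` is for structural bioinformaticians
and computational chemists who want that residue-level map from a prepared
protein–ligand structure — which residues attract, which repel, how the
total builds up with pocket radius, and which part of the ligand each
residue touches.

## The method

The protein is fragmented one residue at a time. Residue $R_i$ is kept in
its chemical context by two *conjugated caps* — the entire covalently
adjacent residues $C_{i-1}$ and $C_{i+1}$ — and every cut peptide bond is
saturated with a hydrogen along the former bond vector (N–H 1.01 Å,
C–H 1.09 Å). With the ligand $L$, four fragment systems are evaluated and
combined:

```
E(L−Ri) = E(L·C(i−1)RiC(i+1)) − E(L·C(i−1)C(i+1)) − E(C(i−1)RiC(i+1)) + E(C(i−1)C(i+1))
```

Cap contributions cancel, leaving the ligand–residue interaction energy
(negative = attractive, positive = repulsive, kcal/mol). Crystallographic
waters are attached to the residue with which they hydrogen-bond most
closely and travel with it through the four terms. Pocket residues are
collected in nested spheres of radius r = n/2 Å around the ligand; the
cumulative total is declared stable at the first radius where the next
shell changes it by less than 10 %, and the analysis is carried to
r = 10 Å by default.

Two interchangeable energy backends drive the combination:

* a **classical pairwise backend** (screened Coulomb
  `332.0637·q·q/(ε·d)` + Lennard-Jones, uniform dielectric ε, defaults
  ε = 10 and 40) for desk-scale work and exact algebraic validation, and
* a **QM deck writer / log parser** that emits Gaussian-style
  single-point inputs (B97D/6-311+G(d,p), CPCM with the chosen ε) for all
  four systems per residue and harvests the external engine's SCF
  energies back into the same reports.

## A worked example

Everything runs on seeded synthetic complexes, so no downloads are
needed:

```r
library(mfccpocket)

s   <- make_toy_complex(toy_spec(n_residues = 7, seed = 1))
dec <- decompose_pocket(s, r_max = 10, region_map = toy_ligand_regions())
glance(dec)
#> # A tibble: 2 × 5
#>   dielectric total_energy converged_radius n_residues n_failures
#>        <dbl>        <dbl>            <dbl>      <int>      <int>
#> 1         10        -2.34                3          6          0
#> 2         40        -2.33                3          6          0

rank_residues(dec)[, c("resid", "resname", "energy", "min_distance",
                       "contact_region", "classification")]
#> # A tibble: 6 × 6
#>   resid resname  energy min_distance contact_region classification
#>   <chr> <chr>     <dbl>        <dbl> <chr>          <chr>
#> 1 A:4:  ALA     -1.01           2.78 ii             attractive
#> 2 A:3:  ALA     -0.614          4.09 ii             attractive
#> 3 A:2:  ASP     -0.414          5.21 iii            attractive
#> 4 A:5:  ALA     -0.199          5.17 i              attractive
#> 5 A:6:  LYS     -0.0467         7.33 i              attractive
#> 6 A:1:  ALA     -0.0441         7.85 iii            attractive
```

Reading: at both dielectrics the pocket total is ≈ −2.3 kcal/mol and the
shell profile stabilises at r = 3 Å. The middle residue (closest to the
ligand, 2.78 Å) contributes the most attractive term; every residue also
carries the ligand region (i/ii/iii) of its nearest heavy-atom contact.
`tidy(dec)` returns the full per-residue/per-dielectric table,
`autoplot(dec)` and `autoplot(dec$profile)` plot the ranking and the
radial convergence.

For real structures: `read_pdb()` → `assign_protonation()` →
`decompose_pocket()`, or drive everything from a config with
`run_pipeline()` (classical reports, or a `qm_deck` tree plus
`harvest_qm()` once the external engine has run). The package validates
its fragment algebra against an independent supermolecule oracle
(`oracle_pairwise()`): for any pairwise-additive backend the four-term
combination must equal the direct ligand↔residue(+waters) sum, and the
test suite asserts this to 1e−8 kcal/mol across 100 seeded complexes.

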