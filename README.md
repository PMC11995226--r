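# chamscope

Conformational ensemble analysis of molecular chameleonicity for PROTACs
and other flexible bifunctional molecules.

Passive cell permeability of beyond-rule-of-5 compounds is governed less
by 2D descriptors than by conformational behaviour: permeable compounds
either fold in apolar media into compact conformations with low
solvent-accessible 3D polar surface area (SA 3D PSA), or they populate
*congruent* conformations — similar shape and polarity descriptors in
water and in the membrane. A compound whose alkyl linker collapses
hydrophobically in water but unfolds into extended, polar conformations
in apolar media (ΔR_gyr > 0 going water → membrane-like solvent) pays a
conformational penalty at the membrane and permeates poorly; a PEG-linker
analogue whose ensembles stay congruent does not.

`chamscope` provides the computational machinery for this analysis:

* **I/O** — multi-model PDB, multi-record SDF (V2000) and multi-frame XYZ
  conformer ensembles with per-conformer energies; NOE restraint tables
  as delimited text.
* **Descriptors** — radius of gyration
  (R_gyr = √(Σᵢwᵢ|rᵢ−r̄|²/Σᵢwᵢ)), Shrake–Rupley SASA on a deterministic
  Fibonacci lattice with a polar/nonpolar partition
  (SA 3D PSA + SA 3D NPSA = SASA exactly), intramolecular hydrogen-bond
  counts, fold classes, and the EPSA/TPSA ratio (ETR).
* **Ensemble analysis** — heavy-atom Kabsch-RMSD leader clustering,
  Boltzmann populations pᵢ ∝ e^(−ΔEᵢ/RT), the >1 % low-energy subset,
  minimum-energy-conformation (MEC) identification, property-space
  landscapes in the (R_gyr, SA 3D PSA) plane, and a cross-solvent
  congruence verdict (centroid shifts + landscape overlap).
* **NAMFIS-style deconvolution** — fits conformer populations w on the
  probability simplex so that r⁻⁶ ensemble-averaged distances
  d_calc,j(w) = (Σₖ wₖ d_jk⁻⁶)^(−1/6) reproduce NOE-derived distances,
  minimizing Σⱼ λⱼ(d_exp,j − d_calc,j)² with λⱼ = 1/tolⱼ²; returns a
  classed model object with `coef`/`residuals`/`summary`/`predict`
  methods, a restraint jackknife, and fold-class population summaries.
* **Synthetic data** — seed-deterministic PROTAC mimics (two rigid
  ligand bodies, an alkyl- or PEG-type linker) sampled under a
  pseudo-energy that reproduces hydrophobic collapse and congruence, plus
  NOE data simulated from known ground-truth populations.

## Worked example

```r
library(chamscope)

spec  <- protac_mimic_spec("alkyl")        # aliphatic-linker mimic
top   <- build_protac_mimic(spec)
print(top)
#> molecule_topology: 76 atoms, 75 bonds, 20 tagged protons
#>   composition: C46 H20 N4 O6

water  <- sample_conformers(top, n = 200, solvent_profile("water"), seed = 1)
chloro <- sample_conformers(top, n = 200, solvent_profile("chloroform"), seed = 2)
report <- run_chameleonicity_analysis(water, chloro)
print(report)
#> chameleonicity analysis
#>   polar  200 conformers, 66 clusters, MEC conf 154 (R_gyr 5.56 A, SA 3D PSA 184.4 A^2)
#>   apolar 200 conformers, 176 clusters, MEC conf 178 (R_gyr 7.67 A, SA 3D PSA 169.5 A^2)
#> solvent_comparison:
#>   delta R_gyr (apolar - polar): +1.191 A
#>   delta SA 3D PSA:              +4.14 A^2
#>   landscape overlap:            0.255
#>   verdict: non-congruent (|dRg| <= 1.50 A and overlap >= 0.50)
```

The alkyl mimic's MEC is compact in water (R_gyr 5.6 Å, hydrophobic
collapse around the linker) but extended in chloroform (7.7 Å); the
positive R_gyr shift and the low overlap of the two property-space
landscapes classify it non-congruent — the chameleon-breaking pattern.
Replacing `"alkyl"` with `"peg"` yields a congruent verdict.

Deconvoluting simulated NOE data back into populations:

```r
rg   <- vapply(water$coords, radius_of_gyration, 0, masses = top$masses)
pool <- conformer_ensemble(top, water$coords[order(rg)[seq(1, 200, 25)]])
sim  <- simulate_noes(pool, c(0.5, 0.3, 0.2, rep(0, 5)),
                      n_restraints = 14, noise_sd = 0, seed = 3)
fit  <- namfis_fit(build_distance_matrix(pool, sim$restraints), sim$restraints)
print(fit)
#> NAMFIS population fit: 8 conformers, 14 restraints
#>   ssd = 0 (weighting: tolerance, exponent: 6)
#>   populations above floor:
#>     1           50.0%
#>     2           30.0%
#>     3           20.0%
```

The generating mixture (50/30/20 % over the first three pool conformers)
is recovered exactly from noise-free data.

See `vignettes/chameleonicity-methods.Rmd` for the model assumptions,
parameter defaults and their rationale, and known limitations.

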