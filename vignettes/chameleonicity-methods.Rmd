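---
title: "Methods: conformational ensemble analysis of molecular chameleonicity"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: conformational ensemble analysis of molecular chameleonicity}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(chamscope)
```

## The scientific problem

Large bifunctional degraders (PROTACs) live well beyond the rule-of-5, and
their passive cell permeability is poorly predicted by 2D descriptors.
What matters instead is conformational behaviour: a permeable compound can
fold in a membrane-like (apolar) environment into compact conformations
that bury polar surface, or it can populate *congruent* conformations —
ensembles with similar shape and polarity descriptors in water and in the
membrane — so that no unfavourable conformational transition is needed on
crossing. A poorly permeable compound may do the opposite: collapse
hydrophobically in water but unfold into extended, polar conformations in
apolar media.

`chamscope` implements the computational side of this analysis as a
reusable package: per-conformer 3D descriptors, clustering plus Boltzmann
population analysis with minimum-energy-conformation (MEC) identification,
property-space landscapes and a cross-solvent congruence verdict, and a
NAMFIS-style deconvolution of NOE distance restraints into conformer
populations. A synthetic generator of linker-variant PROTAC mimics with
known ground truth makes every step testable without molecular-dynamics
trajectories or experimental spectra.

## Descriptors

**Radius of gyration.**
\(R_{gyr} = \sqrt{\sum_i w_i \lVert r_i-\bar r\rVert^2 / \sum_i w_i}\).
The default is mass-weighted over all atoms including hydrogens — the
convention of MD analysis tools — with geometric and heavy-atom-only
options, because published values do not always state their weighting.

**Solvent-accessible surface area.** The Shrake–Rupley rolling-probe
method on a deterministic Fibonacci sphere lattice (default 960 points per
atom, probe 1.4 Å, Bondi van der Waals radii). A deterministic lattice
makes the quadrature reproducible and lets tests compare against closed
forms: an isolated atom is exact to well under 0.5 % at 960 points, the
two-sphere case matches the spherical-cap solution to better than 1 % at
4096 points, and random clusters agree with a large Monte Carlo rejection
oracle to 1 %. Elements outside the Bondi table are a hard error rather
than a silent default radius.

**Polar/nonpolar partition.** SA 3D PSA sums the accessible area of polar
atoms, SA 3D NPSA the rest, and the two add to the total exactly. The
polar scheme defaults to N and O plus attached hydrogens, sulfur excluded.
Published SASA tools differ in their polar schemes and radii — two common
programs are known to disagree systematically while correlating strongly —
so absolute polar-surface values are tool-dependent; the scheme in force
is therefore echoed into every output, and the package's claims rest on
internally consistent comparisons, not on reproducing another tool's
absolute numbers.

**Intramolecular hydrogen bonds.** Geometric criterion: donors are H
bonded to N/O, acceptors N/O, H···A ≤ 2.5 Å, D–H···A ≥ 120°, at least
three bonds between the partners. These are the standard geometric cutoffs
in the absence of an electronic-structure definition.

**Fold classes.** Conformations are classed folded / semifolded /
extended by two thresholds on \(R_{gyr}\) (defaults 7.0 and 9.5 Å,
matching the bands reported for PROTAC-sized molecules: folded ≈ 5–7 Å,
semifolded ≈ 8 Å, extended ≈ 11 Å). The bands scale with molecular size,
so both thresholds are arguments everywhere they are used; a value exactly
on a threshold resolves to the more compact class, and tests pin that
convention. The synthetic mimics below are smaller than real PROTACs
(R_gyr ≈ 4.5–8 Å), so analyses of mimics should pass correspondingly
smaller thresholds.

**ETR.** The ratio of experimental (chromatographic) to topological polar
surface area, both supplied as scalars; values well below 1 flag
chameleonic shielding of polarity. The package computes neither TPSA nor
EPSA — they are inputs.

## Ensemble analysis

Conformers are clustered with a deterministic *leader* algorithm on
heavy-atom Kabsch RMSD (default cutoff 1.0 Å): visiting conformers in
ascending energy order, each joins the first cluster whose representative
is within the cutoff, else founds a new cluster. This guarantees
representatives are pairwise separated by more than the cutoff and are the
lowest-energy members of their clusters, and it is order-deterministic —
properties a stochastic clustering would not give the test suite. Boltzmann
weights use \(p_i \propto e^{-(E_i - E_{min})/RT}\) at 300 K by default
(R = 1.987204×10⁻³ kcal/(mol K)); the minimum-energy shift makes the
exponentials safe and the result exactly offset-invariant. A cluster's
population is the sum of its members' weights; the MEC is the
representative of the most populated cluster, with ties resolved by lower
representative energy and then lower index. The conventional reporting
subset keeps clusters with population strictly above 1 %.

**Landscapes and congruence.** Property-space landscapes are normalized
2D histograms of (R_gyr, SA 3D PSA), 40 bins per axis by default for
export and contouring. The cross-solvent comparison reports
population-weighted centroid shifts (apolar minus polar), a landscape
overlap coefficient \(\sum \min(d_A, d_B)\) on a common grid, and a
congruence verdict: congruent iff \(|\Delta R_{gyr}| \le 1.5\) Å and
overlap ≥ 0.5. The comparison grid is deliberately coarser (12 bins per
axis) than the export grid: with ensembles of a few hundred conformers,
the empirical overlap of two samples drawn from the *same* distribution on
a 40×40 grid is about 0.2 — pure multinomial noise — whereas on a 12×12
grid it stays near 0.8, so the verdict measures distributional difference
rather than sample size. Both grids and both thresholds are configurable;
the defaults were calibrated once against the synthetic generator so that
the PEG mimic reads congruent and the alkyl mimic does not.

For ensembles produced by Boltzmann sampling (MD frames or the Metropolis
generator below), landscape densities and centroids use uniform conformer
weights: the sampling itself already carries the thermodynamic weighting,
and re-applying Boltzmann factors would double-count it. The Boltzmann
weights of the stored energies are used where a per-conformer population
is the object of interest — cluster populations, the >1 % subset, and the
MEC.

## NAMFIS-style deconvolution

Given a pool of candidate conformers and NOE-derived distances, the fit
minimizes
\(\sum_j \lambda_j\,(d_{exp,j} - d_{calc,j}(w))^2\)
over the probability simplex, with
\(d_{calc,j}(w) = (\sum_k w_k d_{jk}^{-6})^{-1/6}\)
— the rigid-limit r⁻⁶ ensemble average (exponent 3 is available for the
flexible limit) — and \(\lambda_j = 1/\mathrm{tol}_j^2\) (uniform
weighting available). Tolerances default to 10 % of the distance, a
typical NOE calibration uncertainty. Equivalent-proton groups (methyls)
are r⁻⁶-averaged within each conformer.

The simplex constraint is enforced exactly by a softmax
reparameterization optimized with BFGS and an analytic gradient from
multiple starts: uniform, a nonnegative-least-squares start in the
transformed (r⁻⁶) space, the best single-conformer vertices, and seeded
random points; the best objective wins and the seed is an explicit
argument, so identical seeds give identical results. Populations under a
0.5 % reporting floor are zeroed and the fit repeated on the surviving
support. The fit is returned as a classed model object with `print`,
`summary`, `coef`, `residuals`, `fitted`, `predict` and `plot` methods; a
leave-one-restraint-out jackknife reports the range each population spans
across folds, and fold-class summaries aggregate populations into
folded/semifolded/extended percentages.

Identifiability deserves a caveat: with many more pool conformers than
restraints, several population vectors can reproduce the data exactly. The
package warns when the distance matrix is degenerate, and the validated
recovery regime (restraints at least twice the number of nonzero
populations and of order 0.6× the pool size) is the one exercised by the
tests: there, noise-free problems are recovered to ssd < 10⁻⁸ and
populations to < 0.01 in ≥ 95 % of random problems, and with 0.2 Å
Gaussian distance noise and 20 restraints the median maximum population
error over 50 problems stays ≤ 0.10.

## The synthetic generator

The generator emulates the statistical structure of the real study's MD
data — not its physics. A mimic is two rigid ligand-like bodies (22 heavy
atoms each, ~25 % N/O, eight tagged surface protons at spread depths)
joined by a flexible 12-atom linker, all-carbon ("alkyl") or with every
third atom oxygen ("peg"); interior linker atoms also carry tagged
protons, whose positions ride with the chain. An alkyl/PEG pair built
from the same seed differs only in those linker elements, mirroring a
CH₂→O swap. Total size is ~65 atoms: large enough for distinct fold
classes, small enough for seconds-scale tests.

Conformers are sampled by Metropolis moves on the linker dihedrals (plus
the second body's placement and spin angles) at 300 K under a
deliberately physics-light pseudo-energy:

* soft-sphere clash repulsion over nonbonded heavy-atom pairs;
* a hydrophobic term — the normalized count of nonpolar linker↔ligand
  contacts within 4.5 Å — weighted −100 kcal/mol per unit in the water
  profile and 0 in the apolar profiles. Contacts are linker↔body
  specifically, because the phenomenon being emulated is hydrophobic
  collapse *around the linker*; rewarding body–body contact would open a
  collapse channel common to both linker types and erase the contrast the
  generator exists to produce;
* a polar-exposure term penalizing buried polar *linker* atoms
  (+300 kcal/mol per normalized unit) in **every** profile: desolvating
  an ether-like oxygen into a nonpolar pocket costs energy in any medium.
  Because this term is solvent-independent, it cancels between the two
  ensembles of a PEG mimic — both are the same penalty-reweighted coil —
  while the water-only hydrophobic reward still collapses the alkyl
  mimic. This is what makes the PEG mimic congruent and the alkyl mimic
  chameleon-breaking, structurally rather than by a tuned average.

The weights were chosen once so that, at the default sizes, the effects
are large against kT (≈0.6 kcal/mol) without overwhelming the clash term;
they are not fitted to any experimental quantity. Sampling runs six
independent chains (burn-in 300 steps, thinning 5) whose draws are
concatenated; a single chain lingers in one basin long enough to make
ensemble statistics noisy. Everything is a deterministic function of
(spec, solvent, seed). Solvent profiles carry dielectric constants as
metadata (water 80, chloroform 4.8, membrane interior 3.0) — the
pseudo-energy never uses ε; it is bookkeeping for reports.

Simulated NOE data: all tagged-proton pairs are r⁻⁶ population-averaged
under a chosen ground-truth population vector; pairs averaging above the
5 Å observability ceiling are dropped (the NOE detection limit), Gaussian
noise of chosen width is added, and selection is stratified across
inter-ligand (long), linker-involving (medium) and intra-ligand (short)
classes so the restraint set spans the ranges an experimentalist would
assign. Intra-body pairs are rigid and thus uninformative about
populations; the medium- and long-range pairs carry the signal, which is
why the generator tags linker protons at all.

**What passing tests do and do not show.** The mimics reproduce the
*qualitative* phenomenon — solvent-dependent collapse for an alkyl
linker, congruence for a PEG linker, NOE sets that deconvolute to known
populations — under a pseudo-energy with no electrostatics, no real force
field, no solvent structure, and rigid ligand bodies. Passing tests
validate the analysis machinery, not any force field, and absolute
descriptor values of the mimics (R_gyr ≈ 4.5–8 Å, SASA of a ~65-atom
cage) are not comparable to real ~1 kDa PROTACs.

## Numerical choices and problem sizes

* SASA lattice 960 points (quadrature error well under the 1 % oracle
  band); 4096 where tests compare to closed forms.
* Kabsch rotation by SVD with proper-rotation sign correction; fewer than
  three non-collinear atoms is an error.
* Optimizer convergence: BFGS relative tolerance 1e-15, 500 iterations
  per start, 10 starts.
* Boundary conventions under test: fold-class ties resolve compact; the
  low-energy subset uses a strict inequality (population 0.01 at threshold
  0.01 is excluded); right-open histogram bins with a closed last bin.
* Degenerate inputs: empty ensembles, non-positive distances, unknown
  elements, mismatched model sizes and hydrogens without bond records all
  raise errors naming the offending object; coincident equal-radius atoms
  both keep full SASA.
* Validation problem sizes: ensembles of 600 conformers (six chains) for
  the cross-solvent contrast over 20 seeds; 100 noise-free and 50 noisy
  NAMFIS problems; 10⁶-sample Monte Carlo SASA oracles. These sizes give
  stable statistics for the seeds-based acceptance checks while keeping
  the full suite in the minutes range.

## Known limitations

* The conformer pool for NAMFIS must be supplied (or generated); the
  package does not perform conformational search.
* No NOE intensity-to-distance calibration, spin diffusion treatment, or
  J-coupling/chemical-shift restraints — restraint distances are inputs.
* The congruence verdict depends on two thresholds whose defaults were
  calibrated on the synthetic generator; for real compounds they should be
  reviewed against the molecule's size and descriptor ranges.
* PDB and XYZ files carry no bond information, so IMHB counting and
  attached-hydrogen polarity need an SDF input or an explicitly
  constructed topology.
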