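---
title: "Rigidity and stability analysis: models, parameters, and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Rigidity and stability analysis: models, parameters, and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(rigidiscope)
```

This vignette is the package's own account of the science it implements:
what each statistic measures, which assumptions it carries, what the
synthetic generators do and do not emulate, and where the design was
genuinely open and a choice had to be made.

## The question

A point mutation in a flexible loop can stabilize an entire oligomeric
enzyme. Three lines of ensemble evidence support such a claim: lower
per-residue fluctuations (RMSF) in the mutant, a more coordinated
distance-fluctuation (DF) matrix, and a shifted hydrogen-bonding pattern.
Two lines of assay evidence complement them: higher thermal midpoints
(T0.5 from thermal shift, T50 from residual activity) and unchanged
catalytic constants (the stabilization should not cost activity).
`rigidiscope` computes all of these from standard inputs — multi-model PDB
ensembles and two-column CSV curves — and ships generators that produce the
same inputs with known ground truth.

## Ensemble statistics

**Superposition and RMSD.** RMSD is reported after least-squares rigid
superposition (Kabsch, proper rotation enforced via the SVD sign
correction). Each frame is superposed independently onto the reference, so
the series measures internal deformation, not drift or tumbling. The
default atom subset is Cα everywhere — the DF statistic is defined on Cα,
and keeping one selection across analyses avoids silent inconsistencies.
No mass weighting is applied: on a Cα-only selection weights are uniform
anyway.

**RMSF.** Fluctuations are measured about the *iterated mean structure*:
frames are superposed onto a running average of the selection, the average
is recomputed, and the loop stops when the mean moves by less than 1e-6 Å
(typically 2–4 iterations). "Equilibrium position" is underdetermined in
ensemble analysis; the iterated mean is standard, deterministic, and
convergent, which is why it is the fixed choice here. Superposition is
whole-selection by default; per-monomer superposition was left as a
possible extension rather than an option, because the cross-monomer
averaging step (`average_over_chains`) already suppresses most of the
difference between the two conventions for near-symmetric oligomers.

**Difference-RMSF.** `delta_rmsf` subtracts chain-averaged profiles
(mutant − wild type) and summarizes the fraction of strictly negative
positions; ties count as non-rigidified, so the summary errs against the
rigidification claim.

**Distance fluctuations.** `df_matrix` computes, for every residue pair,
the variance over frames of the Cα–Cα distance. Two numerical choices are
deliberate:

* *Population variance* (divide by F, not F−1): the statistic is defined as
  a plain time average, and its estimator should converge to it without a
  small-sample correction.
* *No superposition*: internal distances are invariant under rigid motion
  by construction, so superposing first would only add a hidden free
  choice. The test suite checks invariance to 1e-9 Å² under random
  per-frame rotations and translations, and exact agreement (1e-12) with a
  naive double-loop implementation of the same definition.

Units are Å² and are recorded in the object; a variance has no natural
scale cut-off, so the package reports raw values and leaves thresholding
("low fluctuation") to the user.

## Hydrogen-bond persistence

Detection is geometric: donor–acceptor heavy-atom distance ≤ 3.5 Å and
D–H···A angle ≥ 135°, both configurable. These are common MD-analysis
conventions; nothing in the pipeline depends on them beyond the obvious
monotonicity (loosening either cutoff can only increase persistence, which
is tested). Donors are N/O/S heavy atoms that carry at least one hydrogen
*actually present in the input* — ensemble files without hydrogens yield an
empty donor set with a warning rather than imputed positions. Equivalent
hydrogens of one donor (an NH3+ group) are collapsed to a single record per
donor/acceptor pair, counting each frame once, because persistence tables
in the literature are residue-level. The default reporting threshold of
15% sits just below the smallest persistence typically worth tabulating;
it is a display filter, not part of the statistic.

## Thermal-stability descriptors

Both thermal curves are modelled as minimal two-state logistics — the data
are sigmoidal and a two-state model is the weakest assumption that yields
analytic descriptors:

* melting (rising): f(T) = 1/(1+exp((Tm−T)/k)); **T0.5 = Tm**;
  **maximum slope** of the percentage curve = 25/k %/°C (the analytic
  maximum of d(100 f)/dT);
  **onset** = Tm − k·ln(1/θ − 1) at threshold θ = 0.05 unfolded fraction.
* inactivation (falling): A(T) = 100/(1+exp((T−T50)/k)); **T50** is the
  midpoint. The logistic form for the inactivation curve is an assumption
  (plate-reader software fits an unnamed sigmoid); it is recorded in the
  fit object's `model` field.

The onset threshold of 5% is itself a definition, not a measurement — an
"initial unfolding temperature" has no standard meaning — so it is a
parameter of `fit_unfolding`, echoed in the output. The onset is computed
from the fitted (Tm, k) as the analytic 5% crossing rather than as the
first grid temperature exceeding 5%: the analytic form is
grid-resolution-independent and satisfies the exact identity
onset = Tm − k·ln(19) that the tests assert.

**Normalization.** Raw dye-fluorescence curves are mapped to unfolded
fraction with baseline = mean of the lowest-temperature 10% of points and
plateau = maximum of a 3-point moving average; the moving average makes the
plateau robust to the post-peak quenching characteristic of hydrophobic
dyes. Values are clipped to [0, 1.05]. A curve whose plateau and baseline
coincide (relative span below 1e-8) raises a "no transition" error rather
than producing an arbitrary fit.

Reported precision follows assay practice: midpoints to 2 decimals, slopes
to 1, efficiencies to 2.

## Kinetics

`fit_michaelis_menten` is a plain nonlinear least-squares fit of
v = Vmax·S/(Km+S) (Levenberg–Marquardt, with starts Vmax = 1.05·max(v) and
Km at the interpolated half-maximal substrate). Unit conventions are fixed
and explicit: substrate in mM, rates in µmol·min⁻¹ (the enzyme-Unit
scale), enzyme amount given in both mg and nmol so that
kcat = Vmax/(E0<sub>nmol</sub>·60/1000) s⁻¹ and specific activity =
Vmax/E0<sub>mg</sub> U/mg involve no hidden molar-mass lookup. Standard
errors for the derived quantities use the delta method with the full
parameter covariance. Designs that only probe S ≫ Km leave Km essentially
unidentified; the fit then reports a correspondingly wide standard error
(verified against a profile-likelihood check in the tests) instead of
failing.

## Intact-mass matching

Masses are *average* (isotope-abundance-weighted) masses — the quantity
produced by ESI-MS deconvolution of intact proteins — from the ExPASy
residue table plus one water; monoisotopic mode is out of scope. Only
N-terminal truncations are enumerated, matching the degradation chemistry
of the motivating loop; the default tolerance is 5 Da absolute, with a
relative mode (e.g. 0.02%) for instrument-specified accuracy. Matching a
His-tagged construct requires the user to supply the actual construct
sequence, tag and linker included; the package makes no assumption about
vector-derived residues.

## What the generators emulate — and what they do not

`simulate_block_trajectory` draws, per frame, one shared isotropic Gaussian
displacement per residue block (sd `sigma_block`) plus an independent
per-residue term (sd `sigma_local`), optionally wrapped in a random rigid
motion. This reproduces exactly the statistical structure the estimators
consume: block-coordinated motion gives low within-block DF and high
between-block DF, and the `scale` knob multiplies ground-truth RMSF by s
and DF by s². Displacements are frame-independent — there is no
autocorrelation, no anharmonicity, no solvent, no side chains. That is
sufficient because every estimator in the package is a pure ensemble
average, but it means passing tests demonstrate estimator correctness, not
fidelity to physical MD: correlation times, conformational transitions,
and force-field artefacts of real trajectories are outside what these
tests can show. Default study conditions used in the test suite: a
4-chain, 30-residue-per-chain tetramer, amplitudes sigma_block = 0.6 Å and
sigma_local = 0.25 Å, variant scale 0.8, and 2000 frames for the
sign-recovery checks — sizes at which the sampling error of RMSF (≈1.6%
relative) is far below the 20% ground-truth effect. Rigid motions are
drawn in a second pass over the RNG stream, so the same seed produces the
same internal displacements with tumbling on or off; the invariance tests
rely on this.

`simulate_hbond_series` is a two-residue toy whose single N–H···O=C bond
is present (2.9 Å, 170°) in each frame independently with probability p and
broken (5.5 Å) otherwise, making the persistence estimator's binomial
sampling behaviour exactly known. `simulate_melting_curve` and
`simulate_kinetics` add Gaussian noise — additive for fluorescence,
multiplicative (constant CV) for rates, the error structure typical of
activity assays.

All generators take explicit seeds and record them, with the full ground
truth, in the output metadata; identical seeds give bit-identical outputs.

## Numerical choices and degenerate inputs

* Duplicate temperatures/substrate concentrations in CSV input are averaged
  (replicate wells), then sorted.
* Multi-model PDB files must carry an identical atom list in every model;
  the reader names the first offending model otherwise. Coordinates
  round-trip at the PDB fixed-width precision of 0.001 Å.
* Superposition requires ≥ 3 non-collinear subset atoms (second singular
  value of the centred subset > 1e-8).
* Logistic fits fall back to monotone interpolation of the 0.5 crossing for
  the midpoint if the optimizer fails; a curve that never crosses 0.5 is an
  error.
* `block_spec` and the DF block summary insist on exact partitions —
  silent dropping of residues would bias the within/between contrast.

## Known limitations

Ensembles are held in memory as dense frame × coordinate matrices;
hundreds of thousands of frames would need chunked readers. H-bond
detection is O(donors × acceptors) per frame, fine for the intended
protein sizes but not optimized for solvated systems (water-mediated bonds
are out of scope anyway). The thermal models are strictly two-state: no
van 't Hoff enthalpy, no multi-transition deconvolution. The mmCIF format,
binary trajectory formats, and crystallographic symmetry expansion are not
handled.
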