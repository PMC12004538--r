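---
title: "Modeling heterocycle–nucleobase stacking with nucstack"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modeling heterocycle–nucleobase stacking with nucstack}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(nucstack)
```

## Scope and assumptions

`nucstack` models gas-phase π-stacking between a planar aromatic
heterocycle and a single nucleobase in an idealized parallel-stacked
arrangement. Three assumptions run through everything:

* **Rigid, planar monomers.** Both molecules are treated as rigid bodies
  whose heavy atoms define a molecular plane (total-least-squares fit).
  Constructed dimers keep the two planes exactly parallel; imported poses
  (e.g. from crystal structures) may be tilted, and `pose_metrics()`
  reports the tilt rather than hiding it.
* **Energies are intermolecular only.** The MM potential contains no
  bonded terms, no intramolecular contributions, no cutoffs and no
  periodicity: it is the interaction energy of two frozen monomers.
* **Quantum chemistry enters as data.** DFT/SAPT results are ingested as
  tables or volumetric grids; the package never runs an electronic-
  structure calculation. The native ESP backend is a point-charge
  approximation and is labelled as such in every descriptor row.

## Geometry: frames, poses, generators

A stacked pose is parameterized in the nucleobase's canonical frame:
lateral offsets `dx`, `dy`, vertical separation `dz` along the nucleobase
normal, rotation `theta` about the vertical axis, and the prochiral `face`
of the heterocycle. The canonical frame must be deterministic for pose
round-trips and rigid-motion invariance to be testable, so the in-plane
orientation is fixed by rules that depend only on atom order: nucleobases
are rotated so the glycosidic nitrogen sits on the lower-left diagonal
(the conventional orientation in which nucleobases are drawn), and other
molecules place their first off-centroid heavy atom on +x, with the facing
direction resolved by the first heavy atom off that axis. Any proper rigid
transform of the input therefore yields identical canonical coordinates.

Two pose generators emulate the ensembles used to study stacking away
from energy minima:

* **Fully random stacked dimers**: `dx`, `dy` uniform within ±2.5 Å per
  axis, `dz` uniform in 3.25 ± 0.25 Å, `theta` uniform in [0, 360)°, face
  drawn uniformly. The "±" phrasing of the source ranges is read as a
  uniform distribution; nothing in the stated bounds suggests anything
  else, and uniformity matches the "up to ±" language used for the
  perturbative generator. The lateral bound is applied per axis (a box),
  not radially (a disk); the axis-wise reading follows from bounds being
  stated "along the lateral axes". A radial reading would shrink the
  sampled area by π/4.
* **Nearby random stacked dimers**: perturbations of a reference pose by
  up to ±0.5 Å per lateral axis, ±0.25 Å vertically and ±15° about the
  vertical axis.

Poses whose minimum intermolecular heavy-atom distance falls below 2.0 Å
are *flagged*, not rejected — rejection would silently change ensemble
sizes and bias the sampled distribution; the threshold itself is a
package choice (roughly the shortest plausible non-bonded heavy-atom
contact). Every generator is a pure function of its inputs and seed, so
identical calls are byte-identical across platforms (R's default
Mersenne-Twister generator, isolated per call).

Ring centroids of stacked minima cluster over a discrete set of loci on
each nucleobase, located over atoms and bonds. `locus_assign()` projects
each heterocycle ring centroid into the nucleobase plane and assigns it to
the nearest feature among heavy atoms and heavy-atom bond midpoints, with
sub-nanometre ties resolved to the atom (the more specific feature).

## ESP plane descriptors

The descriptor plane sits at a signed height of 3.25 Å from the molecular
plane — the typical stacking separation, so the ESP there is what a
stacking partner actually feels. Descriptors (`esp_max`, `esp_min`,
`esp_mean`, `esp_range`) are statistics over the grid nodes inside the
projection of the molecule's van der Waals volume: the union of circles of
Bondi radius around each atom's in-plane position. Bondi radii (H 1.20,
C 1.70, N 1.55, O 1.52, S 1.80 Å) are bundled and overridable; no
particular radius set is canonical for this purpose, and Bondi is the
common default in the field.

Numerical choices:

* **Grid spacing 0.1 Å** by default. The spacing is not dictated by the
  model; 0.1 Å was chosen so that halving it changes `esp_max` and
  `esp_range` by well under 0.1 kcal/mol for the bundled fixtures (a
  property the test suite enforces). Descriptor targets quoted to one
  decimal carry a ±0.3 kcal/mol grid tolerance for the same reason.
* **Both faces** are computed under `face = "auto"`, and the face with
  the larger `esp_max` is reported. For planar molecules with
  mirror-symmetric charge distributions the faces are identical, so the
  choice matters only for genuinely face-asymmetric inputs.
* **Units**: ESP is stored in kcal/mol everywhere. Gaussian cube files
  conventionally store atomic units and are converted once at ingestion
  (× 627.509); cubes are sampled onto the plane by trilinear
  interpolation, and a plane outside the cube volume is an error rather
  than an extrapolation.
* The point-charge backend evaluates `332.0637 Σ qᵢ/rᵢ` directly; the
  constant fixes the e²/Å → kcal/mol conversion.

Reference descriptor constants for the five nucleobases (ESP_range: A
13.1, G 24.3, C 22.8, T 16.1, U 17.7 kcal/mol; heavy-atom counts 10, 11,
8, 9, 8) are bundled so the predictive model never requires quantum
chemistry at prediction time. The large guanine range — reinforcing local
dipoles of the ring nitrogen adjacent to the amide carbonyl — is what
makes G the strongest stacker; in adenine the imino-nitrogen dipoles
largely cancel.

## The maximum-stacking model

The model is linear in two fitted coefficients applied to a declared
feature map. The shipped `bilinear` map is

`E_max = c1 · (N_HA,het · N_HA,nuc) + c2 · (ESP_max,het · ESP_range,nuc)`

chosen as the simplest two-parameter form consistent with the model's
declared inputs: a size–size product (dispersion grows with the number of
heavy atoms on *both* sides) and an electrostatic coupling term (a
heterocycle's positive ESP extremum interacting with the spread of the
nucleobase's potential). The printed source form of the equation was not
machine-readable, so the feature map is exposed as a registry
(`register_feature_map()`): an alternative transcription — with a
constant, square roots, or size normalization — drops in without touching
the fitting or prediction code, and every test that does not pin the
bilinear algebra continues to apply. No intercept is included: two
parameters are what the model declares, and an intercept would let the
fit absorb a constant offset that the descriptors are supposed to carry.

Conventions: binding energies are negative and "maximum stacking" means
the most negative value; `r²` is always the squared Pearson correlation
between predicted and observed values; RMSE is the root mean squared
residual. Fitting uses ordinary linear least squares, which is the global
RMSE optimum for any form linear in the coefficients — the ±1%
perturbation test in the suite verifies the optimum rather than trusting
the algebra. Degenerate designs (collinear feature columns) error rather
than silently pseudo-inverting; degenerate correlations (zero variance)
report `r² = 0` with a warning so dataset sweeps complete.

A dipole-moment-based alternative model is deliberately not implemented:
plane-ESP descriptors exist precisely because dipole moments predict
stacking poorly.

## The scaled MM potential

`pair_sums()` accumulates the intermolecular Coulomb energy, the
heavy–heavy repulsive (`Σ A/r¹²`) and attractive (`Σ B/r⁶`) LJ sums, and
the unscaled LJ energy of every pair involving hydrogen. Decisions:

* **Lorentz–Berthelot combination** (`r_min` arithmetic, ε geometric):
  the convention of the AMBER-family force fields whose parameters are
  the intended import.
* **AMBER A/B convention** `A = ε r_min¹²`, `B = 2 ε r_min⁶`, documented
  so σ/ε tables are converted explicitly (`r_min = 2^{1/6} σ`) at import.
* **"Heavy-atom pair" means both atoms non-hydrogen**; pairs with at
  least one hydrogen always use `C_R = C_A = 1`. This keeps the scaling a
  perturbation of aromatic–aromatic dispersion/repulsion and leaves X–H
  contacts at the standard potential.
* **Closed-form fit.** Because the scaled energy is linear in
  `(C_R, C_A)`, the RMSE-optimal constants solve a 2×2 normal-equation
  system; the fit reports before/after RMSE and r², and `rmse_after`
  can never exceed the unscaled RMSE on the fitting set since
  `(1, 1)` is in the feasible set.
* **Charge-model specificity.** The fitted constants partly compensate
  for deficiencies of the electrostatic term, so a `scaling_fit` records
  its charge source and `evaluate_mm()` warns when constants are applied
  to data labelled with a different charge model.

## Synthetic data: what it emulates, what it does not

The generators exist so that every fitting and analysis path can be
checked against a known ground truth:

* `synth_maxstack_table()` draws features bracketing realistic descriptor
  ranges (5–16 heavy atoms; ESP_max −10 to +40 kcal/mol; nucleobase
  constants from the bundled table) and generates observations exactly
  from the bilinear model plus homoscedastic Gaussian noise.
* `synth_mm_dataset()` builds fully random poses of two charged toy rings
  and produces reference energies from the scaled MM potential at known
  `(C_R*, C_A*)` plus Gaussian noise.
* `synth_component_table()` draws SAPT-style components as loadings on a
  shared latent factor plus independent noise, with the total equal to
  the component sum by construction. Exactly prescribing all four
  population r² values under the sum constraint is over-determined, so
  the loadings parametrization is the contract: the requested structure
  is loadings/variances, and the r² pattern follows from them.

Gaussian homoscedastic noise is the weakest assumption that supports the
noise-consistency checks (fitted RMSE → σ). What passing these tests
shows is that the estimators are correct and calibrated; it does **not**
show that real quantum-chemistry energies follow the bilinear form or the
scaled LJ potential — those are empirical claims that require the
published reference tables, and the corresponding acceptance checks
report themselves as unmet until those tables are supplied under
`data/reference/`.

The bundled nucleobase geometries are idealized planar structures
generated from connectivity and flattened; they serve the geometric
machinery (frames, masks, poses, loci) and are not optimized
quantum-chemistry structures.

## Other analyses

* **Component correlations**: for each SAPT component X, `r²(X, total)`
  and the leave-one-out `r²(total − X, total)`. Near equilibrium, the
  balance of exchange and dispersion makes everything correlate with
  distance; the leave-one-out value is what identifies electrostatics and
  dispersion as determinative. Correlations are unweighted.
* **Tautomer shifts**: `ΔE(het···nuc) = ΔE(het) + (BE(t2) − BE(t1))` over
  global-minimum binding energies (binding, not interaction, energies:
  the quantities tabulated for global minima). The identity is
  antisymmetric under swapping the tautomers, and a sign change relative
  to the isolated preference flags a stacking-swapped tautomer.
* **Stacking efficiency**: `100 · E_pose / E_max`, rounded half away from
  zero to integer percent — the reporting granularity at which such
  numbers are quoted.

## Problem sizes and limitations

The test suite and `scripts/acceptance.R` use 2 700 fully random poses
(with a 10 000-pose draw for the separation-mean check), 1 000–2 000-row
noise-consistency fits, and a 1 854 × 5 screening table; these sizes make
the sampling-distribution checks tight while keeping the default run
fast on a single CPU.

Known limitations: the point-charge ESP backend ignores charge
penetration and polarization (QM grids can be substituted via cube
ingestion); gas-phase energies neglect desolvation, the dielectric of an
RNA pocket, entropy, and hydrogen-bonded base pairing; parallel-plane
poses cannot represent tilted or edge-to-face geometries (imported tilted
poses are measured, not generated); and SDF V2000 output carries four
decimal places of coordinate precision by format definition, so exact
round-trips belong to XYZ.
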