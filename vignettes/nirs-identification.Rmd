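---
title: "Unambiguous species identification from NIR spectra: methods and design"
author: "nirsova"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Unambiguous species identification from NIR spectra: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(nirsova)
```

## The problem

Cryptic species — genetically distinct but morphologically near-identical —
are common in insects, and identifying field material usually requires DNA
barcoding or expert morphometrics, both slow and expensive per specimen.
Near-infrared reflectance spectroscopy offers a cheap, non-destructive
alternative: species-specific cuticular chemistry (pigments in the visible
range, CH-overtone bands of surface hydrocarbons in the NIR) shifts the
reflectance curve slightly. The catch is that for genuinely cryptic taxa
the shifts are far smaller than within-species variation, so a naive
classifier misassigns a large fraction of specimens. The routine in this
package is built around a different goal: not the highest possible hit
rate, but a *residual misidentification risk of zero within the data* —
every specimen the routine identifies is identified unambiguously, at the
cost of leaving a (possibly large) remainder unidentified.

## The pipeline and its assumptions

The unit of sampling is the *nest*: several workers per nest, nests
grouped into populations (sites). Two assumptions carry the whole design:

1. **Nests are monospecific.** This justifies propagating an
   identification from one worker to its excluded nestmates.
2. **Populations, not specimens, are the independent units.** All nests of
   a population enter either the calibration or the validation set
   (population atomicity), so the validation set never shares a site with
   the material the model was trained on.

The stages, each an exported function:

1. *Preprocessing* (`trimWavelengths`, `subsampleGrid`, `fitCentering` /
   `applyCentering`). The grid is cut to the closed window [500, 2300] nm
   (sensor noise dominates outside it; on a 350–2,500 nm 1-nm grid this
   keeps 1,801 variables). Backends that cannot digest that many variables
   use a deterministic sparse grid: 150 wavelengths from 500 nm in 12-nm
   steps, ending at 2,288 nm. Spectra are mean-centred per wavelength with
   calibration-set means.
2. *Split* (`makeSplit`): per species, 30 calibration / 15 validation
   nests by default (configurable per species, e.g. 26/15 for a species
   with 41 nests), drawn population-atomically with a seeded randomised
   subset-sum over populations.
3. *One-vs-all tasks* (`runOneVsAll`): each species in turn is Class 1
   against the pooled rest. The backend is fitted on calibration spectra
   only; every validation specimen receives a continuous prediction value;
   value ≤ threshold assigns Class 1.
4. *Exclusion search* (`exclusionSearch`): widen a closed symmetric
   interval around the threshold by 0.05 per side per step until no false
   positives remain, or fail at the class-code cap.
5. *Nestmate propagation* (`nestmatePropagate`) and *reporting*
   (`runIdentification`): identified = retained true positives plus their
   excluded nestmates; the report tallies individuals and nests per
   species with validation-set denominators.

## Prediction backends

The PLS backend is the reference method and is implemented in the package
as NIPALS PLS1 on column-centred, unscaled data (`fitPls`): reflectance
spectra share one physical scale, so variable standardisation is neither
needed nor wanted. Each factor extracts the covariance direction between
predictor and response residuals; the per-factor weights, loadings and
response loadings collapse into a single regression vector, and training
scores of successive factors are mutually orthogonal (asserted to 1e-8
relative in the tests). At full rank the fit reproduces ordinary least
squares; the test suite also cross-checks predictions against an
independent PLS implementation (`mixOmics`) to 1e-6 on random 20×50
problems.

The number of factors is the model's main hyperparameter. Classical
chemometrics software leaves its choice to visual inspection of regression
coefficients and validation performance; that is not reproducible, so
`selectPlsFactors` replaces it with a quantitative surrogate: score every
candidate count (default 1–20, capped at the rank bound) by the
correct-classification rate of the validation set at the threshold, and
take the smallest candidate achieving the maximum. Ties to fewer factors
deliberately bias toward parsimony.

Random-forest (`randomForest`, ntree = 1000 by default, mtry at the
regression default unless overridden) and neural-network (`nnet`,
single-hidden-layer backpropagation, sigmoid output) backends fulfil the
same contract: continuous values on their code scale (0/1, threshold 0.5),
never clipped. Regression on the two numeric codes — rather than
classification — is deliberate throughout: the exclusion search needs the
continuous value, and values *outside* the code interval are meaningful
(see failure semantics). Both stochastic backends honour a seed.

## Numerical choices in the exclusion search

Several small decisions make the search well-defined on real-valued
predictions:

- **Ties at the threshold belong to Class 1** (the assignment rule is
  "≤"), and **interval endpoints are inclusive**. The two conventions must
  agree: an exclusion bound equal to a specimen's value excludes it.
- **Bounds live on the 0.05 lattice** around the threshold
  (1.45–1.55, 1.40–1.60, … for PLS codes). Bounds are snapped with one
  rounding step so floating-point drift cannot move a specimen across a
  bound.
- **Failure criterion.** Widening must terminate. The search caps the
  interval at the closed interval between the two class codes ([1, 2] for
  PLS, [0, 1] for rf/ann). A Class-2 specimen with a prediction value
  beyond the Class-1 code (e.g. 0.90 under PLS) can never be excluded by
  any symmetric interval inside the cap, so the task ends with
  `status = "failure"` — reported as such, never as an error, and the
  species simply yields zero identifications for that backend. Regression
  outputs beyond the codes are exactly how such rows arise in practice.
- **Success with an empty interval** (no false positives before any
  widening) is recorded with `NA` bounds and zero steps.
- **Widening is symmetric.** Observed exclusion ranges in this kind of
  routine are symmetric about the threshold; asymmetric widening would
  add a search dimension without a defined stopping preference, so it is
  not implemented.

Nestmate propagation is idempotent, never adds Class-2 specimens, and is
only defined on success. Conflicting identifications across tasks (one
specimen claimed by two species — impossible if nests are truly
monospecific and models are sane) are *reported* in the `conflicts` slot,
never silently resolved. "Nests correct" counts validation nests with at
least one retained true positive; under monospecific nests this is also
the number of nests whose every worker ends up identified after
propagation, which keeps individual and nest percentages consistent.

## The strategy cost calculus

Reducing c classes to two-class problems can follow three shapes: one
class against the pooled rest (one-vs-all); peeling one group off a
shrinking pool (binary decision type A); or halving the class set
recursively (type B). Costing an *exhaustive* search — every calibration
model any decision path could need — gives closed forms for the first two
(s = c − 1 for c = 2 else c; s = 2^(c−1)·c − c(c+1)/2). For type B the
printed closed form in the source literature is internally inconsistent
(its leading binomial terms alone exceed what its own worked totals
imply), so the package defines the count *normatively by enumeration*:
every subset whose size arises from repeatedly halving c (sizes
s → ⌈s/2⌉, ⌊s/2⌋ down to 2), partitioned every way into those two part
sizes, deduplicated as unordered comparisons. The enumeration reproduces
both anchor totals (9 models at c = 4, 266 at c = 7) and agrees with the
type-A closed form's own enumeration for c = 2…8 in the tests.

The per-model time defaults to exactly 4/3 h. The empirical figure is
usually quoted as 1.33 h, but the two large anchor totals (560.0 h for 420
models, 354.7 h for 266) are only consistent with 4/3 h, not with the
truncated 1.33; display rounding is half-up to one decimal, matching how
such totals are printed.

## The synthetic generator

`generateSpectra` emulates the structure of a real nest-based survey, with
defaults matching the survey scale the routine is designed for: 4 species
× 45 nests × 3 workers (540 specimens) on a 350–2,500 nm 1-nm grid,
averaged over 50 replica scans. Each species' expected curve is a shared
smooth baseline (sigmoidal VIS→NIR rise with two broad water-absorption
dips) minus δ times a set of Gaussian absorption bands; default band
centres sit in the visible (pigmentation) and CH-overtone/combination
regions, offset per species. On top of that: a nest-level additive offset
(sd 0.01), a specimen-level offset (sd 0.005), and per-wavelength replica
noise (single-scan sd 0.02). The offsets are scalar — they emulate the
between-colony baseline shifts seen in real mean spectra — and the noise
scales were chosen once so that at full separation (δ = 1) the routine
identifies essentially everything while δ → 0 degrades it smoothly;
δ multiplies only the species signal, so δ = 0 is an exact null.

Replica averaging is not materialised at generation time: the mean of n
independent Gaussian scans is itself Gaussian with sd divided by √n, so
the generator draws the averaged noise directly (the `simulateReplicas`
helper materialises actual scans where the averaging itself is under
test). What the generator does *not* emulate: wavelength-correlated
instrument drift, scattering baselines that would call for derivative or
SNV preprocessing, storage artefacts, and within-nest genetic structure.
Passing tests on this generator therefore demonstrate the *logic* of the
routine — zero-false-positive guarantee, split atomicity, monotone
response to separation — not field-data performance, which depends on the
taxa and instrument at hand. For the same reason the classification
percentages of any particular published survey are not reproduction
targets: they depend on an unrecorded random split and proprietary model
fits; the package reproduces the structure and the invariants instead.

## Problem sizes and determinism in the test suite

The tests run the full routine on a reduced design — 4 species × 12 nests
× 3 workers on a 500–2,300 nm grid at 12 nm (151 variables), 8/4 nests
calibration/validation — which keeps one end-to-end identification under a
second while preserving every structural feature (populations of two
nests, both code systems, factor selection). The separation–response
property uses δ ∈ {0, 0.25, 0.5, 1, 2} × 10 seeds and requires Spearman
ρ > 0.9 between δ and the mean identified fraction. All stochastic steps
take explicit seeds; reports re-serialise byte-identically under a fixed
seed.

## Known limitations

- The exclusion guarantee is "zero false positives *within the available
  validation data*": it bounds the observed risk, not the generalisation
  risk on new populations.
- Factor selection scores the same validation set that the report later
  summarises, mirroring the classical workflow; with abundant nests a
  three-way split (selection set distinct from the final validation set)
  would be cleaner, and `selectPlsFactors` accepts any held-out set.
- Binary-decision trees are costed but not executed; the identification
  engine is one-vs-all only.
- The ANN backend is a minimal single-hidden-layer network; it exists to
  exercise the backend contract, not to be competitive.
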