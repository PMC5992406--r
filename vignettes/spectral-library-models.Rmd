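---
title: "Building NIR content models from a spectral library"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Building NIR content models from a spectral library}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(nirlib)
```

## The problem

Diffuse-reflectance NIR spectroscopy can replace slow wet-chemistry assays
(HPLC for actives, Karl Fischer for water) in routine pharmaceutical
quality control, but only after a quantitative calibration model has been
built — and a sound calibration set needs tens of samples spanning the
concentration range of interest. For a "universal" model covering one
active ingredient across many manufacturers and dosage forms, collecting
those samples afresh for every model is the dominant cost. The workflow in
this package replaces collection with *selection*: a permanent spectral
library of assayed batches is indexed by spectral similarity, and each new
model draws its calibration set from the library.

## Similarity index

The index is the correlation coefficient between a sample spectrum and a
fixed reference spectrum (the pointwise mean of the library's plain-tablet
spectra), computed over 4,200–10,000 cm⁻¹:

$$ r_T = \frac{\mathrm{Cov}(y_1, y_2)}{\sigma_{y_1}\,\sigma_{y_2}} $$

$r_T$ runs from $-1$ (inverted spectra) to $+1$ (identical spectra) and is
reported as a percentage. Population ($1/n$) moments are used; the
convention cancels in the ratio, so this is a documentation choice, not a
numerical one. $r_T$ is likewise invariant to centring and scaling of
either spectrum, which means the index is unaffected by whether vector
normalization has been applied — we compute it on derivative spectra.

The reference defaults to *plain* tablets only (not dispersible or chewable
ones); the averaged form is an argument of `build_reference_spectrum()`, so
the stricter and looser readings of "tablets" are both available.

## Preprocessing chain

Fixed order: replicate averaging → Savitzky–Golay first derivative →
vector normalization.

* **Averaging** — three replicate scans per sample, pointwise mean.
* **SG first derivative** — 17-point window, polynomial order 2. The
  window length is part of the method definition; the polynomial order is
  not stated by the originating software's documentation, so order 2 (the
  common default for first-derivative pretreatment) was chosen and left
  configurable. Filter coefficients are divided by the grid spacing, making
  the output a true derivative with respect to wavenumber; the factor is
  immaterial once spectra are normalized, but keeps intermediate units
  interpretable. Edge handling drops the half-window (8 points) at each
  end rather than padding — padded edge values would be fabricated data
  and would perturb $r_T$.
* **Vector normalization** — centre to zero mean, scale to unit Euclidean
  norm. Whether the emulated software centres before scaling is not
  documented; the centred variant is used (and `vector_normalize()` is a
  public op, so the choice is replaceable). Normalization is computed over
  the *active* region only — the wavenumber intervals a model actually
  uses — because normalizing over spectral range that the model excludes
  would leak excluded-region intensity into the feature scaling.

All spectra are resampled on ingestion to a canonical uniform grid, 4,000
to 12,000 cm⁻¹ in 4 cm⁻¹ steps (2,001 points), within the span of the
8 cm⁻¹-resolution FT instruments the data model assumes. A uniform shared
grid makes every downstream vector operation well-defined.

## Calibration-set selection

**Library route.** The samples to be measured are indexed; their median and
range of $r_T$ anchor the selection. Library entries are sequenced by
$r_T$ and swept greedily: an entry is accepted when its $r_T$ differs from
the last accepted entry by at least the configured spacing. The default
spacing is 1.25 percentage points, the midpoint of the workable 1.0–1.5
band (2.0 demonstrably degrades representativeness; below 1.0 adds little).
The sweep is anchored at the entry nearest the target median and grows
outward alternately, so the selection stays centred on the samples it
serves. Two design points the method description leaves open:

* *Coverage at the extremes.* The library entries bracketing the target
  $r_T$ range are forced into the selection up front, and the greedy sweep
  fills inward around them. Selecting the bracketing entries first is what
  lets the result honour both contracts at once — range coverage *and*
  adjacent gaps ≥ spacing — where a naive outward sweep can strand itself
  within one spacing of the target maximum.
* *Shortfalls are flagged, not fixed.* If fewer than `n_min = 30` entries
  are reachable at the requested spacing, the library's endpoint entries
  are added and the result carries `n_min_shortfall` (and, where the
  forced entries sit closer than the spacing, `spacing_violated`). Callers
  decide whether a flagged selection is usable.

Ties in $r_T$ are broken by sample id, so selection is deterministic
without any seed. The selection is split 2/3 calibration : 1/3 test by
interleaving over the $r_T$-sorted list (every third entry to the test
set, endpoints kept in calibration). An interleaved split preserves the
$r_T$ and concentration span in both halves and is reproducible; a random
split would add a seed dependency for no benefit.

**Conventional route.** Ward-linkage hierarchical clustering (Euclidean
distance) of all preprocessed spectra into 19 groups; per group, three
members are drawn with a seeded generator — two to calibration, one to
validation. Groups smaller than three contribute to calibration only
(coverage of the calibration set takes priority over validation count).

## PLS1 and rank selection

The content model is single-response partial least squares fitted by
NIPALS with X-only deflation; for one response the weight direction per
component is exact in a single step. The regression vector is
$b = W (P^\top W)^{-1} q$, and at full rank the model coincides with
ordinary least squares — one of the oracle checks in the test suite.

The rank (number of latent variables) is chosen by leave-one-out cross
validation plus a one-sided F-test on PRESS, Haaland–Thomas style: take
the rank minimizing PRESS, then accept the *smallest* rank whose PRESS
ratio to that minimum is below the upper $1-\alpha$ quantile of
$F(n, n)$, with $\alpha = 0.25$. The emulated software does not publish
its exact rule; this is the dominant published convention for
PRESS-parsimonious rank choice, and both $\alpha$ and the rule's inputs
are exposed. The rank search is capped at 10 by default — validated
models of this class run 2–6 latent variables, and a cap prevents
overfitting runaway on small calibration sets.

Validation metrics follow the standard definitions: per-sample prediction
difference $\mathrm{Differ}_i = Y_{i,\mathrm{true}} - Y_{i,\mathrm{pred}}$,
$\mathrm{PRESS} = \sum \mathrm{Differ}_i^2$,
$R^2 = 100\,(1 - \mathrm{PRESS}/\mathrm{TSS})$, and
$\mathrm{RMSEP}$ or $\mathrm{RMSECV} = \sqrt{\mathrm{PRESS}/M}$ for
test-set and leave-one-out validation respectively. Accuracy is summarised
by the fractions of samples with absolute prediction difference above 5%
and below 1%, and by the mean absolute difference.

## Transfer-loop optimization

After validation, test spectra whose absolute prediction difference
exceeds the threshold (default 5%, the same limit the accuracy tables use)
are transferred into the calibration set and the model is refitted, for at
most five rounds. Two guards are design decisions: the rank is re-selected
after every transfer (the calibration set changed, so the parsimony
decision must be refreshed), and the loop stops if a transfer would shrink
the test set below 20% of the combined set — optimizing away the
validation surface would leave nothing to certify the model with.

## The synthetic library

The commercial spectra behind this workflow are not publicly deposited, so
the package carries a generator whose defaults state the world the method
assumes:

* assay ranges: amoxicillin 4.77–57.86%, clavulanate 1.03–20.17%, water
  0.24–9.30%; per dosage form the active occupies a sub-band of that range
  (tablets high, granules and suspensions low), which is what spreads the
  forms across distinct $r_T$ bands;
* 150 entries per library by default — tablet 30, dispersible tablet 31,
  chewable tablet 4, granule 38, oral suspension 47, the composition of a
  real post-marketing library scaled to desk size (full-size counts are a
  single argument);
* three replicates per sample; pointwise noise 0.5% of the mean signal;
  per-replicate baseline offset (SD 0.02 AU), baseline slope (SD 0.01 AU
  across the grid) and multiplicative scatter (SD 5%) — magnitudes typical
  of diffuse-reflectance work, applied *before* preprocessing so the
  derivative/normalization chain is genuinely exercised.

Pure components are sums of 5–15 Gaussian bands (widths 80–280 cm⁻¹,
matching broad NIR overtone/combination bands) placed in
component-characteristic windows: the active in the C–H overtone region
(8,300–9,500 cm⁻¹) and the 5,300–6,500 / 4,200–4,800 cm⁻¹ regions, water
near 5,200 and 7,000 cm⁻¹. Excipients come in four classes mapped to the
two dosage-form families; each class is a blend of a shared common-matrix
band set, a family band set and class-specific bands, so families are
cohesive but classes distinct. Each sample additionally blends up to 35%
of its family's partner class into the excipient — manufacturer-to-
manufacturer recipe variation — which is what fills the $r_T$ axis densely
enough for spacing-based selection to find 30 spectra.

A component draw is accepted only if it reproduces the $r_T$ architecture
the method relies on (checked on derivative spectra of typical mixtures):
tablets in a tight high band, dispersible tablets reaching mid-range,
the granule family low but positive, and water not confusable with the
active. Candidate draws are derived deterministically from the seed, so
the screened design is reproducible. This screening is part of the
generator's definition — it encodes the *kind* of library the method is
for, not a tuning loop.

What a green test establishes, and what it does not: the generator is
linear-in-concentration by construction (Beer–Lambert mixing), so passing
parameter-recovery tests demonstrates that the pipeline — selection,
preprocessing, rank choice, fitting, validation — recovers what is
recoverable; it does not demonstrate robustness to nonlinear instrument
effects, particle-size scattering beyond a multiplicative factor, band
shifts with moisture, or inter-instrument transfer, none of which are
modelled. One residual nonlinearity is real and intentional: unit-norm
scaling makes features ratios rather than absolute intensities, so the
model must infer content from band proportions — with a minority of seeds
the resulting test-set mean absolute prediction difference can exceed
1.5% when the split test set contains dosage forms at the edge of the
calibration coverage.

## Numerical choices and degenerate inputs

* Zero-variance spectra cannot be normalized or correlated; both raise a
  degenerate-input error naming the sample rather than returning NaN.
* `select_by_spacing(spacing = 0)` selects everything (every gap ≥ 0).
* Selection ties: lexicographic sample id, so equal-$r_T$ entries select
  deterministically.
* PCA axis signs are fixed (largest-magnitude loading positive) so score
  plots reproduce across platforms.
* All randomness (cluster sampling, generator draws) flows from integer
  seeds through one seeding helper that restores the caller's RNG state;
  per-sample substreams are derived by a stable string hash of the sample
  id, so adding entries does not reshuffle existing ones.

## Known limitations

Single-response models only (one model per analyte); no multiplicative
scatter correction or second-derivative options; JCAMP-DX support is
read-only and minimal; the F-test rank rule is one published convention
among several; the conventional route's cluster count (19) is inherited
from the sample-selection strategy it reproduces rather than optimized per
library.
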