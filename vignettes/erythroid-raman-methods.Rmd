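---
title: "Methods: Raman/SRS chemometrics for erythroid differentiation"
author: "RamanEry"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: Raman/SRS chemometrics for erythroid differentiation}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(RamanEry)
```

# The problem

Erythroid precursors induced to differentiate with low-dose doxorubicin
acquire an erythrocyte-like phenotype. Vibrational microscopy sees this as a
coordinated set of spectral shifts: hemoglobin's resonance-enhanced haem
bands grow; cytochrome c, which shares several haem bands (753, 1130, 1310,
1585 cm⁻¹) but not hemoglobin's oxidation markers, declines; nuclear
material becomes less prominent; glycogen rises; the lipid profile moves
toward saturated species; a mitochondrial-membrane-potential alkyne probe
(band at 2222 cm⁻¹, read in the 1800–2800 cm⁻¹ cell-silent window)
accumulates less; the silent-region fluorescence background grows; and the
cells enlarge. RamanEry implements the statistical machinery to extract and
validate these markers from three kinds of data: single-cell mean spectra,
hyperspectral image cubes, and single-wavenumber SRS frames.

This vignette records the models, the tunable parameters and their
defaults, the numerical choices, and what the synthetic validation does and
does not establish.

# The synthetic-data generator

All tests and the acceptance analysis run against data from the package's
own generator, because the analyses need ground truth (true endmembers,
true concentration maps, true class labels) that no real acquisition
provides.

**Endmembers.** Each of the nine built-in endmembers is a sum of
pseudo-Voigt bands (default pure Lorentzian; Raman lines are
near-Lorentzian, and a Gaussian or mixed shape is available per band) whose
positions follow the band assignments established for these species. The
silent-region fluorescence pedestal is a peak-normalized cubic bump confined
to 1800–2800 cm⁻¹; its analytic normalization makes the rendered spectrum
independent of how the axis samples the window. Two default axes mirror the
two acquisition modes: 600–3100 cm⁻¹ at 2 cm⁻¹ steps ("raman") and
2800–3050 cm⁻¹ at 6 cm⁻¹ steps ("hsSRS", the wavenumber step of
hyperspectral SRS stacks).

**Class profiles.** The two populations differ only through per-endmember
mean abundances, a probe multiplier, a background multiplier and a cell-size
multiplier. Absolute abundances are free parameters — the source studies
print directions and pixel-fraction statistics, not concentrations — chosen
once so that every contrast points in the reported direction with a
magnitude typical of strong staining-free contrast: hemoglobin 0.35 → 1.9,
cytochrome c 1.0 → 0.55, glycogen 0.45 → 0.95, nuclear 1.3 → 0.6,
saturated:unsaturated lipid 1:1 → 2.2:1, probe multiplier 1 → 0.35,
background multiplier 1 → 3, cell radius ×1.3 (differentiated cells are
larger). Per-cell abundances are gamma-distributed with CV 0.18 — a
mid-range single-cell biological variability; gamma keeps abundances
non-negative with the requested mean. The sample sizes used throughout
(50–60 cells per class for cohorts, 3–30 cells per phantom image) are the
package's own defaults for a well-powered two-group comparison; the source
studies do not state their counts.

**Phantoms and cubes.** Cells are non-overlapping ellipses with a nucleus,
a perinuclear mitochondrial ring, lipid droplets, and cytoplasm = cell −
nucleus. Endmembers map to compartments (nuclear → nucleus, cytochrome c →
mitochondrial ring, lipids → droplets, hemoglobin/glycogen/probe →
cytoplasm, protein and background → whole cell); the probe is rendered
across the cytoplasm rather than only the thin mitochondrial ring so that a
cytoplasmic median — the quantity the marker uses — carries the probe
signal, consistent with the probe's lipophilic partial distribution. The
noiseless cube is exactly `C·Sᵀ`; noise is Poisson shot noise at a
configurable gain plus Gaussian read noise plus rare single-channel spikes.
Simulated variance is validated against `gain·λ + σ²` by Monte Carlo.

**What passing tests show.** The generator produces linear mixtures with
Lorentzian bands, gamma abundance variation and stationary Gaussian-Poisson
noise. Real cells add non-linear baselines, focus drift, resonance
enhancement that varies with oxidation state, optical aberrations and
segmentation-confounding debris. Recovery on the phantom therefore
demonstrates correctness of the estimators, not expected field performance;
the printed performance numbers of the motivating studies live on real
hyperspectral data and are treated as directional references only.

# Preprocessing

Fixed stage order: despike → baseline → crop → normalize (the configuration
object offers no way to reorder; normalizing before baseline subtraction
would make the baseline scale-dependent). Despiking replaces channels whose
deviation from a rolling median (window 7) exceeds 8 robust SDs. The
default baseline is asymmetric least squares (λ = 1e5, p = 0.01, 20
iterations) — a standard generic choice when the original study's
preprocessing is not printed; a polynomial baseline is available.
Normalization is per-spectrum (vector norm by default; area by trapezoid);
per-spectrum scaling makes the downstream classifier insensitive to
absolute intensity. Label-free models crop out the 1800–2800 cm⁻¹ silent
window; probe analyses instead crop to 2150–2300 cm⁻¹ around the reporter
band.

# MCR-ALS

The cube is unfolded to pixels × channels and factorized as `D ≈ C·S` by
alternating non-negative least squares. Numerical choices:

- NNLS subproblems are solved by a fast combinatorial active-set method
  vectorized over right-hand sides (columns sharing a passive set are
  solved together), with a per-column Lawson–Hanson fallback on the rare
  cycling column and a ~1e-12-scaled ridge guarding singular passive
  blocks. The solver is validated against `pracma::lsqnonneg` per column.
- Scale convention: spectra are renormalized to unit Euclidean norm after
  every iteration with the magnitude absorbed into `C`. Factorizations are
  compared only through permutation- and scale-invariant metrics (cosine
  after optimal Hungarian matching, Pearson correlation of concentration
  maps) — elementwise equality is meaningless under the rotational
  ambiguity of bilinear models.
- Initialization is a SIMPLISMA-style purest-variable search (purity
  std/(mean + offset), offset 3% of the largest channel mean, later
  selections weighted by the determinant of the correlation-around-origin
  matrix so duplicate channels drop to purity 0), followed by one NNLS
  solve for the spectra.
- Stopping: relative lack-of-fit change below `tolLOF` (default 1e-6)
  against a starting reference of LOF = 100%, so an absurdly large
  tolerance stops after exactly one iteration; `converged = FALSE` plus
  diagnostics, never an exception, on hitting `maxIter`.
- The contribution-contrast step is a sum-preserving shrinkage of each
  pixel's concentration vector toward its dominant component,
  `C′ = (1−w)·C + w·proj`, ties to the lowest index. The literature does
  not pin down one canonical operator for contribution-contrast
  constraints, so this concrete, documented operator is the package's own
  choice and ships off by default (w = 0).
- `k = 10` is the default component count in full-fingerprint "raman" mode,
  matching the component count used for cell images in this problem
  domain; every analysis here that asserts recovery uses the k the ground
  truth dictates.
- High-intensity pixel fractions default to a pooled-percentile threshold
  (60th percentile of both classes pooled) because the original absolute
  thresholds are not printed; absolute and Otsu rules are available.

# OPLS-DA

One predictive latent variable plus `nOrtho` orthogonal ones (default 3:
"4 latent variables" with a single predictive direction is the natural
split for a binary response; the alternative readings are not
distinguishable from the available text). Classes are coded +1/−1 with
decision threshold 0 — the symmetric choice, since the published threshold
value is not printed. X is mean-centred only by default (spectra arrive
vector-normalized); unit-variance scaling is available.

Each orthogonal round follows the textbook recursion: weight `w ∝ Xᵀy`,
score `t = Xw`, loading `p`, orthogonal weight `wₒ = p − (wᵀp)w`. One
degenerate case is handled explicitly: on exactly planted data whose
structured part is strictly y-orthogonal, `p` equals `w` and the recursion
returns `wₒ = 0` even though orthogonal structure exists; the implementation
then takes the leading singular direction of the y-orthogonal residual
`X − t·pᵀ` (projected off `w`, score re-orthogonalized against y). This
recovers planted constructions exactly and leaves ordinary noisy fits
untouched. Orthogonal scores are uncorrelated with y to < 1e-8 by
construction, asserted in the tests after every fit.

With `nOrtho = 0` the model reduces exactly to one-component PLS1 (verified
against an independent NIPALS recursion to 1e-10). VIP for the single
predictive component is `√m·|w|/‖w‖`, so mean VIP² = 1 identically and
VIP > 1 flags channels contributing more than the average.

Validation statistics: group-stratified k-fold cross-validation (default
7-fold; folds never split a cell, and centring/scaling are re-estimated
inside every training fold — the tests include a null-data check that the
hygienic pipeline stays at MCC ≈ 0); label permutation at the group level
with the add-one-smoothed p-value `(1 + #{null ≥ obs})/(nPerm + 1)`
(default 999 permutations, statistic = cross-validated MCC; the acceptance
analysis verifies the test's empirical size at α = 0.05 over 200 null
repetitions, run at a small problem size of 16 cells × 12 channels × 99
permutations to keep the 200-fold replication cheap); ROC by threshold
sweep over unique values with trapezoid AUC (identical to the normalized
Mann–Whitney U, asserted exactly) and the operating threshold at maximal
Youden's J, ties resolved toward higher specificity. The Mann–Whitney test
is exact (null CDF) for tie-free samples with n₁n₂ ≤ 400, exact by
enumeration for small tied samples, and normal with tie and continuity
correction otherwise.

# Spectral phasor segmentation

Per pixel, `G` and `S` are the cosine and sine first-harmonic Fourier sums
of the spectrum normalized by total intensity (harmonic 1 by default; the
transform is scale-invariant and linear under mixing, and non-negative
spectra map inside the unit circle — all asserted to machine precision).
Pixels below 1% of the maximum total intensity are flagged invalid and
become background; the floor is the package's choice, as the original
thresholding is unstated. Valid-pixel phasors are clustered by seeded
k-means (10 restarts). For three clusters, regions are named by optimal
cosine assignment of the cluster-mean *spectra* to rendered reference
signatures (nuclear, cytoplasmic protein, saturated lipid) — an automatic
stand-in for the interactive phasor gating a microscopist would do, chosen
over raw 2850/2930 band shares because protein and nucleic-acid CH bands
overlap heavily. Nucleolar substructure is out of scope.

# The two-marker SRS classifier

From four registered frames: ratio `r = I₂₈₅₀/(I₂₈₅₀ + I₂₉₃₀)` (bounded in
[0,1], zero-denominator pixels invalid) and probe `p = max(I₂₂₂₂ − I₂₁₀₀, 0)`
— the off-resonance frame removes the silent-region background, and
negative differences are clipped because the probe signal is physically
non-negative. Cells are segmented on the 2930 cm⁻¹ protein frame (Gaussian
blur σ = 2 px, Otsu threshold, hole filling, connected components, minimum
area 12 µm²); the nucleus proxy is the largest connected low-ratio core
inside each cell and cytoplasm is its complement — recorded in the output,
since the original delineation is unstated. Markers are per-cell medians
(median, not mean, for robustness to bright droplets) divided by cell /
cytoplasm area in µm²; the per-area normalization divides the median by the
area, the reading consistent with the published units. Thresholds are
calibrated by ROC with precursor as the high-valued positive class;
quadrant calls are precursor (both markers above), erythrocyte-like (both
below), indeterminate otherwise — the published scheme defines only the two
concordant quadrants, and forcing mixed cells into them would fabricate
calls. The published fixed pair (1.021, 0.0005) is accepted via
`fixedThresholds()` for comparison runs but treated as
instrument-specific.

# IO, reproducibility and the CLI

Cubes travel in a versioned single-file container (cube array, strictly
increasing wavenumber axis, pixel size, modality, optional ground-truth
group) with layout violations reported by name; 2-D maps as unit-scaled
32-bit float TIFF with a JSON sidecar recording the scale (the TIFF float
path clamps to [0,1]); spectra as long-format CSV; thresholds and summaries
as JSON; configuration as YAML with unknown keys rejected. Every stage is a
pure function of declared inputs, config and seed; `runPipeline()` chained
twice with one seed reproduces every artifact byte for byte, which the
acceptance analysis checks.

# Known limitations

- No optical physics: resonance enhancement, laser-power effects and
  photodamage are not modeled, although the studies this package supports
  report power-dependent spectral distortion.
- MCR-ALS carries intrinsic rotational ambiguity; only matched,
  scale-invariant comparisons are meaningful, and no uncertainty bands are
  provided on endmembers.
- The cell phantom is geometric (ellipses, rings, discs); segmentation
  performance on it upper-bounds nothing about clumped or irregular real
  cells.
- Exact Mann–Whitney enumeration is limited to small tied samples;
  beyond that the tie-corrected normal approximation is used.
- The CLI is a thin wrapper for reproducible batch runs, not an
  instrument-vendor integration; no vendor file formats are read.
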