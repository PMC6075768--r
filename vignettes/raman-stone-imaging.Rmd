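---
title: "Resolving kidney stone composition maps from Raman hyperspectral cubes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Resolving kidney stone composition maps from Raman hyperspectral cubes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The problem

Kidney stone management depends on knowing what a stone is made of and,
increasingly, *where* each phase sits: the nucleus species, thin surface
coats, drug deposits, and the conversion history written into successive
layers. Raman chemical imaging acquires a full Raman spectrum at every
pixel of a sectioned stone surface, producing a hyperspectral cube
(H × W pixels × B wavenumber bands) from which per-component distribution
maps can be resolved. `ramanstones` implements that analysis as a tested
pipeline, together with a phantom simulator that provides ground truth
for validating every stage.

## The model

After unfolding the cube into a matrix `D` (`N` support pixels × `B`
bands), the data are modelled bilinearly,

    D ≈ C Sᵀ,   C ≥ 0 (N × k concentrations),   S ≥ 0 (B × k pure spectra),

and resolved by multivariate curve resolution – alternating least
squares (MCR-ALS) under non-negativity constraints on both factors. The
goodness of fit is the standard lack of fit,
`LOF(%) = 100 · sqrt(Σ(D − C Sᵀ)² / Σ D²)`, with
`explained variance = 100 · (1 − (LOF/100)²)`.

Each ALS half-step is an *exact* non-negative least-squares solve: for
the small component counts used here (k ≤ 12) the passive set of every
column is found by enumeration, vectorised over all pixels (or bands) at
once. Exactness matters because it guarantees the LOF is non-increasing
across iterations — an invariant the test suite asserts on every run —
whereas clip-after-solve schemes do not.

Initialization uses a deterministic purest-variable (SIMPLISMA-style)
selection: the k wavenumber columns maximizing the standard
deviation/mean purity ratio (noise offset α = 5% of the largest column
mean) with determinant-based down-weighting of columns correlated with
earlier picks. There is no randomness anywhere in the solver, so a run
is reproducible from its seed alone (the seed only shapes the simulated
noise).

Convergence is declared when the relative LOF change drops below `tol`
(default 1e-4) or the fit is effectively exact (LOF < 1e-7 %); the
iteration cap defaults to 200. Only non-negativity is enforced — no
closure, unimodality or selectivity constraints — deliberately matching
the minimal constraint set that the mapping task needs.

### Ambiguity, and a library design constraint

Non-negative bilinear factorizations are unique only up to permutation
and scale (the unit-maximum convention on the columns of `S` fixes the
scale), and, when component spectra overlap heavily, only up to
*rotation* within a feasible cone. ALS converges to the extreme rays of
that cone. This has a concrete consequence for the two calcium oxalate
monohydrate (COM) spectral variants, which share all their band
positions and differ in which of the 1487 / 1462 cm⁻¹ bands is the main
peak: if each variant carries a large secondary peak at the other
variant's main-peak position, the extreme rays are visibly
"over-separated" versions of the true spectra and their correlation to
the truth saturates well below 1 even on noiseless data. The shipped
band library therefore sets the secondary cross peak to amplitude 0.35
(main peak 1), which keeps the variants spectroscopically similar
(mutual correlation 0.75) while leaving the extreme rays within r ≈ 0.94
of the true variant spectra — comfortably above the 0.9 identification
threshold. This is a property of the synthetic library design, not a
tuning of any test tolerance.

## The spectral library

Pure spectra are sums of pseudo-Voigt bands (linear Gaussian/Lorentzian
blend; unit height at the centre, half maximum at ±fwhm/2). Twelve
species are shipped: the two COM variants, calcium oxalate dihydrate,
anhydrous and dihydrate uric acid, apatite, struvite, brushite,
whitlockite, ammonium urate, N-Acetyl-Sulfamethoxazole and atazanavir.
Only the COM main-peak positions (1487 and 1462 cm⁻¹) are anchored to
published values; all other band positions are fixed synthetic constants
placed near familiar mineral bands (e.g. phosphate ν₁ near 960 cm⁻¹)
and audited for identifiability: every pair of rendered spectra has
Pearson correlation < 0.95 on the default axis (`pairwise_correlations()`
checks this). The library serializes to a plain CSV (one band per row)
via `read_library()` / `write_library()`.

The default wavenumber axis spans 464–1853 cm⁻¹ at 1 cm⁻¹ spacing
(1390 bands). A 2 cm⁻¹ grid starting at 464 would put 1487 cm⁻¹ exactly
between two grid points, making the main-peak readout of variant A
ambiguous at the grid level; the 1 cm⁻¹ grid places both COM peaks
exactly on grid points.

## The phantom generator

`generate_phantom()` builds cubes whose noiseless part is *exactly*
bilinear: per-pixel species fractions (summing to 1 on material pixels)
times rendered pure spectra. Layout primitives — annuli with optional
angular sectors and radial mixture gradients, off-centre discs, and a
central material-free gap — compose into four canonical stones:

* `phantom_layered_oxalate()`: COM core, COD shell, apatite deposits;
* `phantom_core_gap_composite()`: porous nucleus (gap), a
  whitlockite+apatite body whose proportions vary radially, a thin COD
  ring, a brushite coat — four minerals plus a porosity at 50 µm step;
* `phantom_minor_inclusion()`: apatite/struvite/ammonium-urate majority
  with a COM inclusion on a chosen percentage of support pixels;
* `phantom_radial_com_drug()`: eight alternating COM-variant sectors
  under a 100 µm drug shell at 5 µm step (96 × 96 frame — at 5 µm a
  64-pixel frame could not hold both a measurable core and the shell).

Mixed regions use radial gradients rather than constant proportions
because a spatially constant mixture contributes only rank one to `D`;
the gradient is what lets curve resolution separate co-located phases,
which is also how real stones behave (proportions drift across a body).

Fluorescence is emulated as a broad positive Gaussian in wavenumber
(centre 300 cm⁻¹, width 900 cm⁻¹) scaled per pixel by a random amplitude
uniform in [0.5, 1.5] × 1 — a background comparable in height to the
unit-max Raman peaks. Noise is additive Gaussian (σ = 5 × 10⁻⁴, a small
detector floor) plus a dominant signal-proportional Gaussian term
(scale 0.03, a shot-noise proxy giving peak signal-to-noise ≈ 30);
intensities are clipped at zero. The gap emits 2% of the material
fluorescence — a hole returns almost no light, which is precisely what
makes porosities discoverable from intensity alone. Generation is
bit-reproducible under the spec's seed.

What the phantoms do *not* emulate: instrument line-shape drift,
cosmic-ray spikes, detector etaloning, focus/topography coupling, and
spectrally structured organic (protein/glycosaminoglycan) emission —
fluorescence here is a smooth baseline only, and is never resolved as a
component. Passing tests therefore demonstrate correctness of the
algorithmic chain under a faithful noise/background model, not
instrument-level robustness.

## Preprocessing

The chain is fixed: unfold → Savitzky–Golay smoothing → asymmetric least
squares (AsLS) baseline subtraction → low-signal masking.

* **Savitzky–Golay**: window 5, polynomial order 2 — a light smoothing
  that preserves narrow Raman bands; both are exposed in
  `preprocess_config()`. Interior points
  use the closed-form kernel ((−3, 12, 17, 12, −3)/35 for window 5,
  order 2); the first/last two points come from the same-degree
  polynomial fitted to the one-sided first/last five points.
* **AsLS**: minimizes `Σ wᵢ(yᵢ−zᵢ)² + λ Σ (Δ²zᵢ)²` with weights reset to
  `p` above the baseline and `1−p` below, starting from all ones;
  λ = 10⁵, p = 10⁻³, 10 reweighting iterations with early stop when the
  weights stabilise. Second-order differences are the standard penalty.
  The solver is a banded (pentadiagonal) Cholesky in C++ with one step
  of iterative refinement (the system's conditioning grows with λ, and
  plain substitution leaves ~10⁻⁷ relative error that the refinement
  removes). Corrected spectra are `y − z` clipped at zero, because the
  constrained bilinear model assumes non-negative data.
* **Porosity masking**: a pixel is excluded from unmixing when its total
  corrected intensity falls below 5% of the median total. The 5% factor
  is an artifact choice; with the shipped noise model it separates gap
  pixels from material by about a factor of two on each side of the
  threshold.

## Identification and structural readouts

Resolved spectra are matched to the library by greedy
maximum-correlation bipartite assignment (best pair first, both removed,
repeat), so no species is claimed twice; components whose best remaining
correlation falls below 0.9 are reported as unidentified. The 0.9
threshold is an artifact default, exposed as an argument. The main-peak
readout (`main_peak()`) is the axis value at the global maximum, ties
broken toward the lower wavenumber.

Layer thickness is measured by casting 36 equally spaced rays from the
centroid of the layer region and taking, per ray, the longest contiguous
run of layer pixels times the pixel step (rays sample at quarter-pixel
resolution; discretization error is about half a pixel). Regions whose
mean thickness exceeds half the support radius are flagged as not
shell-like. The radial organization score casts rays from the labelled
centroid and averages `1 − transitions/(run length − 1)` over rays:
sector-organised variant maps score near 1, salt-and-pepper fields near
0.5, and concentric lamellae near 0 (every ray crosses every ring
boundary). It is a descriptive geometry metric, not a clinical
classifier.

## Numerical choices and degenerate inputs

* Pixel geometry: a pixel belongs to the region containing its centre
  (centres at (i−0.5, j−0.5) × step); unfolding is row-major.
* NNLS ties/degeneracies: singular passive-set systems are skipped in
  the enumeration; a component whose spectrum collapses to zero raises
  an error advising a smaller k rather than silently refitting.
* `select_n_components()` counts singular values above 10× the median of
  the trailing half of the singular spectrum; it is advisory only and
  the pipeline never auto-runs without an explicit or confirmed k.
* An all-zero data matrix makes the LOF undefined and errors; an
  increase in LOF between iterations (impossible with exact solves)
  errors rather than continuing.
* Empty support, unknown species, zero-area regions, non-monotone axes,
  and ragged cube files all fail fast with location information.

## Problem sizes

The shipped analyses run at the sizes the phantoms define: 64 × 64
pixels × 1390 bands for the 50 µm stones and 96 × 96 × 1390 for the 5 µm
radial stone; a full pipeline run takes on the order of 10–20 s on one
core, and the complete validation suite a few minutes. These sizes were
chosen as the smallest frames that hold the structural features being
measured (a 20-pixel drug shell, a 5% inclusion, a thin ring and coat)
with comfortable margins.

## Known limitations

* Quantification is spatial (percent of pixels where a phase dominates),
  not mass- or FTIR-style semi-quantitative composition.
* Heavily overlapped spectra are resolved only up to the rotational
  ambiguity discussed above; constraints beyond non-negativity
  (selectivity, local rank) are out of scope.
* The porosity rule is intensity-based; porosities that still emit
  strongly (e.g. filled with organic matrix) would not be masked.
* Vendor instrument formats are not read; cubes enter via the documented
  text or binary dialects.
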