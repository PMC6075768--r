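# ramanstones

Raman chemical imaging of sectioned kidney stones resolves not just
*what* a stone contains but *where* each phase sits: porous nuclei, thin
surface coats, drug deposits, and the radial organisation of calcium
oxalate monohydrate (COM). `ramanstones` implements the full analysis
chain for such hyperspectral cubes, plus a phantom simulator with ground
truth for validating every stage:

1. **Simulation** — layered/sectored/inclusion stone phantoms with known
   per-pixel species fractions, fluorescence baseline and noise
   (`phantom_spec()`, `generate_phantom()`, canonical constructors
   `phantom_core_gap_composite()` and friends).
2. **Preprocessing** — unfolding, Savitzky–Golay smoothing (window 5,
   order 2), asymmetric least squares baseline removal (λ = 10⁵,
   p = 10⁻³), and porosity masking of low-signal pixels
   (`preprocess()`).
3. **Unmixing** — MCR-ALS: the unfolded cube `D` (pixels × bands) is
   factorized as `D ≈ C Sᵀ` with non-negativity on both the
   concentration maps `C` and the pure spectra `S`, by alternating
   *exact* non-negative least-squares solves with deterministic
   purest-variable initialization (`mcr_als()`). Fit quality is the
   lack of fit, `LOF(%) = 100·√(Σ(D−CSᵀ)²/ΣD²)`.
4. **Identification & structure** — greedy maximum-correlation matching
   of resolved spectra against a reference band library of stone
   constituents (`match_to_library()`), abundance-map refolding, pixel
   fractions, ray-cast layer thickness, COM 1487/1462 cm⁻¹ main-peak
   discrimination and a radial-organization score.

`run_pipeline()` ties the stages together and emits a structure report
(JSON + text + map rasters). A thin command-line front end lives at
`inst/cli/ramanstones.R` (subcommands `simulate`, `preprocess`, `unmix`,
`identify`, `run`).

## Worked example

A composite stone with a porous nucleus, a whitlockite+apatite body, a
thin calcium oxalate dihydrate (COD) ring and a brushite coat, scanned
at 50 µm:

```r
library(ramanstones)
rp <- run_pipeline(phantom_core_gap_composite(seed = 7), k = 4)
print(rp)
#> Raman chemical imaging structure report
#>   components detected: COD, brushite, apatite, whitlockite
#>   lack of fit: 15.91%  explained variance: 97.47%
#>   porosity/gap: 3.04% of support pixels
#>   layer COD: 147.2 um (sd 13.1)
#>   layer brushite: 186.1 um (sd 20.2)
#>   ...
rp$assignment
#> # A tibble: 4 × 4
#>   component species     correlation detected
#>       <int> <chr>             <dbl> <lgl>
#> 1         1 COD               0.990 TRUE
#> 2         2 brushite          0.988 TRUE
#> 3         3 apatite           0.933 TRUE
#> 4         4 whitlockite       0.987 TRUE
```

All four minerals are recovered (Pearson r ≥ 0.93 against the library),
the porous nucleus is flagged from its weak signal (3% of support
pixels), and the COD ring and brushite coat are measured at ~150 µm and
~190 µm — consistent with the drawn geometry (the ring spans 10% and the
coat 12% of the ~1520 µm stone radius). `tidy()`/`glance()` summarise
the MCR fit, and `autoplot(rp$maps)` draws the per-species abundance
maps (dark blue = absent, yellow = high).

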