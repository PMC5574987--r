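# relaxaniso

Orientation-anisotropy analysis of quantitative MRI relaxation parameters
in layered, collagen-ordered tissue such as articular cartilage.

In ordered tissue, transverse-like relaxation parameters (T2, T2\*,
adiabatic T2ρ, T_RAFF2, CW-T1ρ at low spin-lock amplitude) depend on the
angle θ between the collagen fibre axis and the main field B0 through the
residual dipolar factor `3 cos²θ − 1`, which vanishes at the magic angle
(54.74°); longitudinal-like parameters (T1, adiabatic T1ρ with HS1
pulses) are essentially orientation-free. Quantifying this per parameter
matters because clinically one cannot choose the scan geometry: a
parameter with high orientation sensitivity confounds tissue state with
tissue orientation.

The package provides, for researchers analysing multi-orientation
relaxometry of specimen slices:

* **Pixel-wise relaxation fitting** with Rician noise-floor subtraction
  (2-parameter monoexponential), exponential-with-baseline (CW spin-lock),
  3-parameter magnitude inversion recovery (T1), and joint steady-state
  fitting of inverted/non-inverted RAFF pulse trains — all bounded
  Levenberg–Marquardt with per-pixel convergence flags.
* **Depth-wise profiling** from the articular surface (0) to the bone
  interface (1): centre-band extraction (1.75 mm default), depth
  normalization, and zone statistics (superficial / transitional /
  radial).
* **MR anisotropy** per depth point as the Michelson contrast of
  relaxation rates across sample orientations,
  `A = (R_max − R_min) / (R_max + R_min)`, plus the deep-zone bulk value
  (mean over depth 40–80 %, reported ×100).
* **qPLM anisotropy** from polarized-light-microscopy orientation maps
  (5×5 entropy filter; anisotropy = 1/(entropy + 1)) with depth profiles
  of orientation (circular, 180°-periodic), retardation and anisotropy.
* **Correlation** of the MR and optical anisotropy profiles per sample,
  averaged across samples by Fisher's z transform.
* A fully seeded **synthetic magic-angle phantom** (tri-laminar fibre
  architecture, dispersion-damped `(3cos²θ−1)²` rate law, Rician noise,
  matched PLM maps) providing ground truth for every stage.

File formats: NIfTI image series with JSON schedule sidecars, 32-bit
float TIFF PLM maps, tidy CSV profiles and summaries.

## Worked example

```r
library(relaxaniso)

# one phantom specimen, one series, one fitted map
spec   <- phantom_spec(snr = 40, seed = 1)          # 64x64, SNR 40
series <- generate_series(spec, sample_orientation_deg = 60, kind = "T2")
map    <- fit_map(series)
map
#> <relax_map> T2 at 60 deg (monoexp_noisefloor): 3072 pixels fitted,
#>   3072 converged, median T = 54.1 ms
```

At 60° — the grid angle nearest the magic angle — deep-zone T2 is near
its maximum (the phantom's deep magic-angle T2 is 68 ms; at 0° it drops
to ≈7 ms). The full pipeline over orientations, samples and kinds:

```r
res <- run_all(list(kinds = c("T2", "T1"), n_samples = 2, seed = 1,
                    log_level = "quiet"))
res$summary[, c("kind", "anisotropy", "anisotropy_min",
                "anisotropy_max", "r_plm_anisotropy")]
#>   kind anisotropy anisotropy_min anisotropy_max r_plm_anisotropy
#> 1   T2      79.85          79.75         79.944            0.851
#> 2   T1       0.66           0.64          0.681           -0.165
```

Reading the table: deep-zone T2 anisotropy is ≈80 on the ×100 scale
(T2 rates nearly an order of magnitude higher with fibres along B0 than
at the magic angle) and tracks the optical anisotropy profile (r ≈ 0.85),
while T1 shows sub-1 % residual anisotropy — pure noise — and no
correlation with the collagen structure. That contrast is the scientific
point: T1-like parameters are safe to use regardless of scan geometry,
T2-like parameters are not.

`run_all()` also returns zone statistics, per-kind anisotropy depth
profiles and all per-orientation depth profiles, and writes them as CSVs
(plus a seeded manifest) when `outdir` is set. A thin command-line front
end is included at `inst/scripts/relaxaniso-run.R`.

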