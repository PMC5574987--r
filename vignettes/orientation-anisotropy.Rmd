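---
title: "Orientation anisotropy of quantitative MRI relaxation parameters: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Orientation anisotropy of quantitative MRI relaxation parameters: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

# The scientific problem

In ordered tissues — articular cartilage, tendon, white matter — several
quantitative MRI relaxation parameters depend on the angle between the
tissue's dominant fibre direction and the scanner's main field B0.  The
mechanism is residual dipolar interaction (RDI): incompletely
motion-averaged dipole–dipole coupling of water protons constrained by the
collagen network.  The dipolar Hamiltonian scales with

$$ 3\cos^2\theta - 1, $$

where $\theta$ is the fibre–field angle.  The factor vanishes at the magic
angle, $\theta_m = 54.7356^\circ$, where dipolar transverse relaxation is
nulled and transverse-like relaxation times reach their maximum.
Longitudinal relaxation (T1) lacks the secular dipolar contribution and is
essentially orientation-independent.

`relaxaniso` implements, as a reusable and tested pipeline, the analysis
needed to quantify this effect in depth-resolved tissue maps:

1. **Pixel-wise relaxation fitting** of multi-preparation-time magnitude
   image series (T1, T2, T2*, CW-T1ρ at several spin-lock amplitudes,
   adiabatic T1ρ/T2ρ, RAFF2), with Rician noise-floor handling.
2. **Depth-wise profiling** between the articular surface (depth 0) and
   the cartilage–bone interface (depth 1).
3. **MR orientation anisotropy** per depth point as the Michelson
   contrast of relaxation *rates* across sample orientations,
   $A = (R^{\max} - R^{\min}) / (R^{\max} + R^{\min})$, and a deep-zone
   bulk value (mean over depth 40–80%, reported ×100).
4. **qPLM anisotropy** from polarized-light-microscopy orientation maps:
   a 5×5 entropy filter, anisotropy $= 1/(\mathrm{entropy} + 1)$.
5. **Correlation** of the MR and optical anisotropy depth profiles per
   sample, averaged across samples with Fisher's z transform.

Because the analysis targets a layered specimen with a known answer, the
package ships a first-class synthetic phantom that emulates the angular
and statistical structure the analysis assumes.

# The phantom's forward model

## Geometry

The default phantom is a 64 × 64 pixel slice (62.5 µm depth resolution)
with a flat articular surface at row 9 and 48 cartilage rows below it.
Collagen fibre angle relative to the surface normal follows the
tri-laminar architecture of articular cartilage:

* **Superficial zone (SZ)**, depth 0–8%: fibres tangential (90°).
* **Transitional zone (TZ)**, depth 8–20%: smooth monotone arcade,
  modelled as a raised-cosine interpolation from 90° to 0°.
* **Radial zone (RZ)**, depth 20–100%: fibres radial (0°).

The zone bounds are configuration; the defaults bracket the anisotropy
minimum observed in real cartilage at roughly 12–14% depth.  The surface
angle is configurable below 90° (real sections often show ≈75° between
the superficial and deep orientations).

## Rates

Transverse-like parameter kinds relax at

$$ R(d, \phi_s) = R_{\mathrm{iso}} + \frac{c_{\mathrm{dip}}}{4}\,
   \mathbb{E}\!\left[(3\cos^2\theta - 1)^2\right],
   \qquad \theta \sim \mathcal{N}\!\big(\mu(d) - \phi_s,\ s(d)^2\big), $$

where $\mu(d)$ is the depth-wise fibre angle, $\phi_s$ the sample
orientation, and $s(d)$ the sub-voxel fibre-angle dispersion.  The
quadratic dependence on the dipolar factor is the standard second-order
RDI scaling; dividing by 4 makes $c_{\mathrm{dip}}$ the full excess rate
at $\theta = 0$.  The expectation has the closed form

$$ \tfrac{11}{8} + \tfrac{3}{2} e^{-2 s^2} \cos 2\mu
   + \tfrac{9}{8} e^{-8 s^2} \cos 4\mu , $$

which reduces to $(3\cos^2\mu - 1)^2$ at $s = 0$ and is verified against
Monte-Carlo integration in the test suite.  Averaging over the dispersion
is essential, not cosmetic: a point-fibre model has nearly full
orientation modulation at *every* depth (any 15°-spaced orientation grid
contains angles near both the magic angle and the fibre axis), so the
transitional-zone minimum of the anisotropy profile — the hallmark of the
disorganized TZ — only appears because dispersion damps the modulation
where the fibres are disordered.  Dispersion defaults are 12° (SZ), 28°
(TZ peak) and 4° (RZ), interpolated piecewise-linearly with the maximum
at mid-TZ.

T1 is modelled orientation-independent with $T_1 = 1400$ ms.  In-plane
rotation only is modelled ($\theta_{\mathrm{eff}} = \mu(d) - \phi_s$);
the azimuthal fan of superficial fibres enters only through the SZ
dispersion value, not as 3-D geometry.

## Calibration of the per-kind parameters

The functional link between RDI strength and each rotating-frame
parameter's rate is not established theory; the phantom therefore treats
each kind's $(R_{\mathrm{iso}}, c_{\mathrm{dip}})$ as configuration and
sets defaults from reported deep-cartilage bovine values at 9.4 T:
$R_{\mathrm{iso}}$ is the reciprocal of the deep-zone magic-angle
(maximum) relaxation time, and $c_{\mathrm{dip}}$ is solved in closed
form (`calibrate_c_dip()`) so that the noiseless deep-zone Michelson
anisotropy over the default 7-orientation grid equals the literature
value for that kind — from 0.800 for T2 down to 0.068 for adiabatic T1ρ
(HS1), with $c_{\mathrm{dip}} = 0$ for T1.  This makes the deep-zone
anisotropy *ranking* of the kinds part of the phantom's ground truth.

## Acquisition schedules and noise

Each kind carries its conventional preparation-time schedule (inversion
recovery TI 200–3000 ms for T1; spin-echo TE 10–128 ms for T2; multi-echo
GRE TE 2.5–37.5 ms for T2*; spin-lock durations 0–192 ms for CW-T1ρ;
pulse trains of 4.5 ms adiabatic pulses for adiabatic T1ρ/T2ρ; 0–8 pulses
of 9 ms for RAFF2, with and without inversion preparation).  Noise is
Rician: independent Gaussian noise of standard deviation σ on two
quadrature channels, with SNR defined as the mean noiseless foreground
signal at the first preparation time divided by σ.  The default SNR of 40
sits inside the 30–70 range typical of such protocols.  All randomness is
seeded from the phantom spec; the same spec yields bit-identical output.

## The matched qPLM maps

The PLM generator produces an orientation map following the same fibre
profile, and a retardation map that is lowest in the TZ and rises toward
the deep tissue.  Two realism choices matter for the entropy filter:

* The maps are generated on a grid 4× finer than the MRI grid.  Optical
  sections resolve orientation at micrometre scale, so the 5×5 entropy
  window must not straddle the steep TZ angle gradient of a coarse grid.
* The per-pixel orientation noise is a spatially correlated Gaussian
  field (correlation length 2 PLM pixels, unit marginal variance before
  scaling by the depth-wise dispersion).  Real collagen orientation
  varies smoothly at the window scale; with independent pixel noise the
  25-sample window entropy saturates near $\log_2 25$ bits at every
  depth and the anisotropy map loses its depth structure.

With these defaults the noiseless correlation between the T2 MR
anisotropy profile and the PLM anisotropy profile is ≈0.85–0.87, the
range reported for real specimens.  One acknowledged departure from the
printed literature: because the synthetic retardation *increases* toward
the deep tissue where the MR anisotropy is also maximal, the phantom's
MR-vs-retardation correlations are strongly **positive**, whereas
published tables report strongly negative coefficients alongside the same
stated retardation depth trend.  The package reports whatever sign the
data give; no acceptance property depends on it.

# Fitting models and numerical choices

All fits are bounded Levenberg–Marquardt least squares (`minpack.lm`),
time-constant bounds [1 ms, 10 s], relative tolerance 1e-8, at most 100
iterations per start.  Pixels that fail to converge, or whose time
constant lands on a bound, are flagged — never silently zeroed — and
excluded from profiles.

* **Monoexponential with noise floor** (T2, T2*, adiabatic kinds): the
  Rician floor is removed in quadrature,
  $s' = \sqrt{\max(s^2 - \sigma^2, 0)}$, with σ estimated from a
  background region via the Rayleigh mean (σ = mean/√(π/2)); then
  $S_0 e^{-t/T}$ is fitted, initialized log-linearly from points above
  the floor.  The correction is idempotent on noiseless data.
* **Exponential with baseline** (CW-T1ρ): $A e^{-t/T} + C$ with $C$
  unconstrained in sign.
* **Magnitude inversion recovery** (T1):
  $S_0 \lvert 1 - 2 f e^{-t/T_1}\rvert$ with inversion efficiency
  $f \in [0.5, 1]$.  The fit runs in the parametrization
  $\lvert S_0 - b\,e^{-t/T_1}\rvert$ with $b = 2 f S_0$: the f/T1 ridge
  of the magnitude model otherwise pins $f$ at a box bound from generic
  starting points.  $f$ is recovered afterwards and re-fitted in the
  constrained form only if it leaves [0.5, 1].  Initialization uses the
  signal-null TI ($T_1 \approx \mathrm{TI}_{\mathrm{null}}/\ln 2$), with
  a coarse log-grid fallback (flagged) when no null is bracketed.
* **RAFF steady state**: joint fit of the non-inverted and inverted
  pulse-train decays, $SS + (S_0^{\cdot} - SS) e^{-t/T}$ with shared
  $SS$ and $T$, $t = n_{\mathrm{pulses}} \times 9$ ms, the inverted
  prediction folded through the magnitude.  Because the signed inverted
  curve crosses zero at most once, the fold flips a prefix of the time
  axis; initialization enumerates the $m+1$ fold patterns, recovers $T$
  log-linearly from the pure-exponential difference (plain − signed
  inverted) and the three linear parameters by least squares, then
  polishes the two best candidates with LM.  This makes the fit exact on
  noiseless curves even when $T$ far exceeds the 72 ms sampled window.

The test suite checks every model against a dense log-grid brute-force
oracle (60 steps per decade, linear parameters profiled out at each grid
point) on noiseless and noisy curves.

## Attainable accuracy

A point often missed when setting accuracy targets: with the 5-point
spin-lock schedule (0–192 ms) and the 3-parameter baseline model, the
Cramér–Rao bound on the time-constant standard error at SNR 40 is
already 8–16% of $T$ for $T = 40$–110 ms, i.e. a median absolute
relative error of at least ≈5–11% for *any* unbiased estimator.  The
same holds marginally for adiabatic T1ρ (HS1), whose ≈220 ms time
constant is sampled only to 108 ms.  Map-median errors below 5% at
SNR 40 are therefore achievable for the T2-like, RAFF2 and T1 kinds but
not for the CW spin-lock family; the corresponding acceptance check is
expected to fail for those kinds and documents this bound.  Fit *bias*
is a different matter: the median relative bias of the noise-floor
monoexponential at SNR 30 is below 2% (Monte-Carlo, n = 1000).

# Profiling, anisotropy and correlation choices

* Profiles are means over a centre band of
  `round(1.75 mm / 0.0625 mm) = 28` columns, per depth row between the
  detected surface (first foreground pixel per column) and bone interface
  (last); columns with fewer than 5 foreground pixels are excluded.
  Depth rows where fewer than half the band's pixels converged are marked
  missing and bridged linearly.
* Depth normalization is linear interpolation onto a uniform 100-point
  [0, 1] axis (both counts configurable; the paper-style zones are
  half-open [0, 0.08), [0.08, 0.20), [0.20, 1]).
* The Michelson contrast is computed on rates (1/T).  With exactly two
  orientations the result is identical whether computed from rates or
  times; with more, rates are authoritative.  A depth point needs at
  least two non-missing orientations, else it propagates as missing.
  An optional 3-MAD trimmed variant guards against noise-driven extremes
  but is **off** by default, matching the plain published formula.
* The deep-zone bulk value is the mean over depth 40–80%, reported ×100.
* Entropy filtering quantizes orientations into 256 uniform bins over
  [0, 180) and uses base-2 logarithms with symmetric border padding,
  matching the conventional texture-entropy implementation.  The 0°/180°
  seam can inflate entropy where near-0° orientations wrap; a
  seam-aware mode (angle doubling before binning) is provided but off by
  default for faithfulness to the reference behaviour.  Bin count and
  window size are configuration.
* Correlations use the full common depth axis (no edge trimming by
  default; a depth window is available), Pearson's r per sample, and
  Fisher-z averaging across samples with |r| = 1 clipped at
  1 − 10⁻¹² and flagged.

# Pipeline, determinism and problem sizes

`run_all()` executes phantom → fits → profiles → anisotropy ∥ PLM →
correlation for `n_samples` phantom replicates (seeds `seed + 1000·i`)
and writes tidy CSVs (zone statistics, anisotropy summary ordered by
descending anisotropy with name tie-breaks, per-kind mean anisotropy
profiles, all depth profiles) plus a manifest with the config's MD5
hash.  Identical config and seed give byte-identical CSVs.  By default
only the 28-column centre band is fitted (`fit_scope = "band"`), which
leaves every profile-based result unchanged while cutting runtime
roughly in half; full-map fitting is one flag away.  The bundled
examples and checks use the 64 × 64 default phantom, 7 orientations and
4 replicates; a 6-kind run at that size completes in well under two
minutes per kind on a single core.

# Known limitations

* No Bloch or spin-dynamics simulation: the link from pulse physics to
  each kind's dipolar sensitivity is calibrated, not derived.
* Flat-surface geometry; depth is a row coordinate, not a streamline
  coordinate, and the specimen midline is the mask centroid.
* The Rician noise model ignores B0/B1 inhomogeneity, susceptibility
  effects on T2*, and structured (bone, debris) background texture.
* Passing the phantom-based checks shows the pipeline recovers the
  assumed angular law under realistic noise; it cannot validate the
  angular law itself against real tissue.
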